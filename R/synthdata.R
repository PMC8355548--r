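#' Simulate a bead movie with known beat frequencies
#'
#' Generates the synthetic counterpart of the bead assay: beads attached
#' to the ciliated surface oscillate sinusoidally while being filmed at
#' a fixed frame rate. Bead i's centre at frame t (0-based) is
#' `rest_i + drift * t + amplitude * sin(2*pi*f_i*t/fps + phi_i) * (cos(theta_i), sin(theta_i))`,
#' rendered as a Gaussian blob of sd `bead_radius` and signed peak
#' `bead_contrast` on a constant background, plus i.i.d. Gaussian noise.
#' A sinusoid is the minimal motion model exposing a single dominant
#' frequency per axis, which is all the estimator claims to recover.
#'
#' Defaults mirror the assay's acquisition regime: 120 fps for 20 s,
#' beads dark on a bright background (brightfield), oscillation
#' amplitude 3 px. The signal-to-noise ratio of the movie is
#' `abs(bead_contrast) / noise_sd` (10 with the defaults).
#'
#' @param n_beads Number of beads.
#' @param f_true True beat frequency in Hz; scalar (recycled) or one
#'   value per bead. Must satisfy `f_true < fps / 2`.
#' @param amplitude Oscillation amplitude in pixels (`>= 0`).
#' @param direction Oscillation direction per bead, radians; `NULL`
#'   draws them uniformly.
#' @param bead_radius Gaussian blob sd in pixels.
#' @param bead_contrast Signed peak intensity; negative = dark bead.
#' @param noise_sd Per-pixel Gaussian noise sd (intensity units).
#' @param drift Global drift in pixels/frame, length-2 `(dx, dy)`.
#' @param fps Frame rate, frames/second.
#' @param duration Movie length in seconds.
#' @param frame_shape `(height, width)` in pixels.
#' @param background Constant background level.
#' @param gradient Linear background gradient, intensity per pixel along
#'   `(y, x)`; default none, so a flat background can be switched to one
#'   that genuinely exercises background removal.
#' @param seed RNG seed; identical parameters and seed give a
#'   bit-identical movie.
#' @return A list: `movie` (a [cq_movie()]) and `ground_truth`, a tibble
#'   with one row per bead (`bead_id`, `f_true`, `x0`, `y0`,
#'   `direction`, `phase`).
#' @export
make_movie <- function(n_beads = 10, f_true = 15, amplitude = 3,
                       direction = NULL, bead_radius = 2,
                       bead_contrast = -30, noise_sd = 3,
                       drift = c(0, 0), fps = 120, duration = 20,
                       frame_shape = c(128, 128), background = 100,
                       gradient = c(0, 0), seed = 1) {
  f_true <- rep_len(f_true, n_beads)
  if (any(f_true >= fps / 2))
    stop("f_true must be below the Nyquist frequency fps/2", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  H <- frame_shape[1]; W <- frame_shape[2]
  n_t <- round(fps * duration)
  min_sep <- 4 * bead_radius
  margin <- amplitude + 4 * bead_radius + abs(drift) * n_t + 1

  withr::with_seed(seed, {
    rest <- place_points(n_beads, W, H, min_sep,
                         margin_x = margin[1], margin_y = margin[2],
                         what = "bead rest positions (bead overlap at rest)")
    theta <- if (is.null(direction)) stats::runif(n_beads, 0, 2 * pi)
             else rep_len(direction, n_beads)
    phi <- stats::runif(n_beads, 0, 2 * pi)

    bg <- matrix(background, H, W)
    if (any(gradient != 0))
      bg <- bg + outer(seq_len(H) - 1, seq_len(W) - 1,
                       function(y, x) gradient[1] * y + gradient[2] * x)
    frames <- array(0, dim = c(H, W, n_t))
    tt <- seq_len(n_t) - 1
    for (t in seq_len(n_t)) {
      fr <- bg
      if (noise_sd > 0) fr <- fr + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
      s <- amplitude * sin(2 * pi * f_true * tt[t] / fps + phi)
      cx <- rest$x + drift[1] * tt[t] + s * cos(theta)
      cy <- rest$y + drift[2] * tt[t] + s * sin(theta)
      for (i in seq_len(n_beads))
        fr <- add_blob(fr, cx[i], cy[i], bead_radius, bead_contrast)
      frames[, , t] <- fr
    }
  })

  list(
    movie = cq_movie(frames, fps = fps),
    ground_truth = tibble::tibble(
      bead_id = seq_len(n_beads), f_true = f_true,
      x0 = rest$x, y0 = rest$y, direction = theta, phase = phi
    )
  )
}

# add a Gaussian blob of sd `sigma` and peak `peak` at (cx, cy); local window
add_blob <- function(fr, cx, cy, sigma, peak) {
  H <- nrow(fr); W <- ncol(fr)
  r <- ceiling(4 * sigma)
  ys <- max(1, floor(cy) - r):min(H, ceiling(cy) + r)
  xs <- max(1, floor(cx) - r):min(W, ceiling(cx) + r)
  if (length(ys) == 0L || length(xs) == 0L) return(fr)
  g <- outer(exp(-((ys - cy)^2) / (2 * sigma^2)),
             exp(-((xs - cx)^2) / (2 * sigma^2)))
  fr[ys, xs] <- fr[ys, xs] + peak * g
  fr
}

# rejection-sample n points with pairwise separation >= min_sep
place_points <- function(n, W, H, min_sep, margin_x = 1, margin_y = 1,
                         what = "points", max_tries = 5000L) {
  if (W - 2 * margin_x <= 0 || H - 2 * margin_y <= 0)
    stop(sprintf("frame too small to place %s", what), call. = FALSE)
  x <- numeric(0); y <- numeric(0)
  tries <- 0L
  while (length(x) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf("could not place %s within the frame", what), call. = FALSE)
    px <- stats::runif(1, margin_x, W - margin_x)
    py <- stats::runif(1, margin_y, H - margin_y)
    if (length(x) == 0L || min((x - px)^2 + (y - py)^2) >= min_sep^2) {
      x <- c(x, px); y <- c(y, py)
    }
  }
  list(x = x, y = y)
}

#' Simulate a basal-body staining image with aligned and non-aligned cells
#'
#' Cells are laid out on a grid of non-overlapping disks (the mask).
#' In aligned cells, basal bodies form `rows_per_cell` parallel rows of
#' `bbs_per_row` Gaussian blobs spaced closely enough that a row merges
#' into one elongated connected component after thresholding;
#' `row_spread` is the perpendicular jitter sd, so smaller values give
#' straighter, thinner rows. Non-aligned cells receive the same number
#' of blobs grouped into compact random clusters, mimicking the short
#' basal-body arrays of immature or misorganised cells.
#'
#' @param n_cells Number of cells.
#' @param frac_aligned Fraction of cells in the aligned condition.
#' @param rows_per_cell Rows of basal bodies per aligned cell.
#' @param bbs_per_row Blobs per row.
#' @param row_spread Perpendicular jitter sd in pixels.
#' @param blob_sigma Blob Gaussian sd in pixels.
#' @param bb_intensity Blob peak intensity above background.
#' @param noise_sd Gaussian noise sd.
#' @param background Constant background level.
#' @param frame_shape `(height, width)` in pixels.
#' @param seed RNG seed.
#' @return A list: `image` ([cq_channel()]), `mask` ([cq_mask()]) and
#'   `ground_truth`, a tibble with `cell_id`, `aligned`, `cx`, `cy`.
#' @export
make_bb_image <- function(n_cells = 40, frac_aligned = 0.5,
                          rows_per_cell = 4, bbs_per_row = 8,
                          row_spread = 0.8, blob_sigma = 1.5,
                          bb_intensity = 60, noise_sd = 2, background = 10,
                          frame_shape = c(512, 512), seed = 1) {
  if (frac_aligned < 0 || frac_aligned > 1)
    stop("frac_aligned must be in [0, 1]", call. = FALSE)
  H <- frame_shape[1]; W <- frame_shape[2]
  g <- ceiling(sqrt(n_cells))
  cell_px <- floor(min(H, W) / g)
  cell_r <- cell_px / 2 - 2
  spacing <- 3 * blob_sigma                       # along-row spacing: blobs merge
  row_len <- (bbs_per_row - 1) * spacing
  if (row_len + 8 * blob_sigma > 2 * cell_r ||
      (rows_per_cell - 1) * 6 * blob_sigma + 8 * blob_sigma > 2 * cell_r)
    stop("cells cannot hold the requested basal-body layout; enlarge frame_shape",
         call. = FALSE)

  n_aligned <- round(frac_aligned * n_cells)
  withr::with_seed(seed, {
    aligned <- sample(rep(c(TRUE, FALSE), c(n_aligned, n_cells - n_aligned)))
    centers <- expand.grid(gy = seq_len(g), gx = seq_len(g))[seq_len(n_cells), ]
    cx <- (centers$gx - 0.5) * cell_px
    cy <- (centers$gy - 0.5) * cell_px

    img <- matrix(background, H, W)
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    labels <- matrix(0L, H, W)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)

    n_bb <- rows_per_cell * bbs_per_row
    for (i in seq_len(n_cells)) {
      labels[(xx - cx[i])^2 + (yy - cy[i])^2 <= cell_r^2] <- i
      if (aligned[i]) {
        ori <- stats::runif(1, 0, pi)
        ux <- cos(ori); uy <- sin(ori)          # along-row unit vector
        row_gap <- 6 * blob_sigma
        offs <- (seq_len(rows_per_cell) - (rows_per_cell + 1) / 2) * row_gap
        for (o in offs) {
          along <- (seq_len(bbs_per_row) - (bbs_per_row + 1) / 2) * spacing
          jit <- stats::rnorm(bbs_per_row, 0, row_spread)
          bx <- cx[i] + along * ux + (o + jit) * (-uy)
          by <- cy[i] + along * uy + (o + jit) * ux
          for (k in seq_len(bbs_per_row))
            img <- add_blob(img, bx[k], by[k], blob_sigma, bb_intensity)
        }
      } else {
        n_clust <- ceiling(n_bb / 3)
        cl <- place_points(n_clust, 2 * cell_r - 8 * blob_sigma,
                           2 * cell_r - 8 * blob_sigma,
                           min_sep = 8 * blob_sigma, margin_x = 0, margin_y = 0,
                           what = "basal-body clusters")
        clx <- cx[i] - cell_r + 4 * blob_sigma + cl$x
        cly <- cy[i] - cell_r + 4 * blob_sigma + cl$y
        per <- diff(round(seq(0, n_bb, length.out = n_clust + 1)))
        for (j in seq_len(n_clust)) {
          for (k in seq_len(per[j])) {
            img <- add_blob(img, clx[j] + stats::rnorm(1, 0, blob_sigma),
                            cly[j] + stats::rnorm(1, 0, blob_sigma),
                            blob_sigma, bb_intensity)
          }
        }
      }
    }
  })

  list(
    image = cq_channel(pmax(img, 0), "basal_bodies"),
    mask = cq_mask(labels),
    ground_truth = tibble::tibble(cell_id = seq_len(n_cells),
                                  aligned = aligned, cx = cx, cy = cy)
  )
}

#' Simulate a two-channel spot image pair with known co-occupancy
#'
#' Red spots are placed uniformly with a minimum separation; a fraction
#' `co_occupancy` of the green spots is centred exactly on randomly
#' chosen red spots and the remainder is placed at least
#' `4 * spot_sigma` away from every red spot, so ground-truth overlap is
#' controlled by construction.
#'
#' @param n_spots_red,n_spots_green Spot counts per channel.
#' @param co_occupancy Fraction of green spots placed on red spots, in
#'   `[0, 1]`.
#' @param spot_sigma Spot Gaussian sd in pixels.
#' @param spot_intensity Spot peak intensity above background.
#' @param noise_sd Gaussian noise sd.
#' @param background Constant background level.
#' @param frame_shape `(height, width)` in pixels.
#' @param seed RNG seed.
#' @return A list: `red`, `green` ([cq_channel()]) and `ground_truth`,
#'   a one-row tibble with the realised co-occupancy.
#' @export
make_coloc_pair <- function(n_spots_red = 200, n_spots_green = 200,
                            co_occupancy = 0.3, spot_sigma = 2,
                            spot_intensity = 100, noise_sd = 2,
                            background = 5, frame_shape = c(320, 320),
                            seed = 1) {
  if (co_occupancy < 0 || co_occupancy > 1)
    stop("co_occupancy must be in [0, 1]", call. = FALSE)
  H <- frame_shape[1]; W <- frame_shape[2]
  n_co <- round(co_occupancy * n_spots_green)

  withr::with_seed(seed, {
    red_pos <- place_points(n_spots_red, W, H, min_sep = 5 * spot_sigma,
                            margin_x = 4 * spot_sigma, margin_y = 4 * spot_sigma,
                            what = "red spots (frame overcrowded)")
    co_idx <- sample.int(n_spots_red, n_co, replace = n_co > n_spots_red)
    gx <- red_pos$x[co_idx]; gy <- red_pos$y[co_idx]
    tries <- 0L
    while (length(gx) < n_spots_green) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("could not place off-red green spots (frame overcrowded)", call. = FALSE)
      px <- stats::runif(1, 4 * spot_sigma, W - 4 * spot_sigma)
      py <- stats::runif(1, 4 * spot_sigma, H - 4 * spot_sigma)
      if (min((red_pos$x - px)^2 + (red_pos$y - py)^2) >= (4 * spot_sigma)^2) {
        gx <- c(gx, px); gy <- c(gy, py)
      }
    }
    red <- matrix(background, H, W)
    green <- matrix(background, H, W)
    if (noise_sd > 0) {
      red <- red + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
      green <- green + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    }
    for (i in seq_len(n_spots_red))
      red <- add_blob(red, red_pos$x[i], red_pos$y[i], spot_sigma, spot_intensity)
    for (i in seq_len(n_spots_green))
      green <- add_blob(green, gx[i], gy[i], spot_sigma, spot_intensity)
  })

  list(
    red = cq_channel(pmax(red, 0), "red"),
    green = cq_channel(pmax(green, 0), "green"),
    ground_truth = tibble::tibble(co_occupancy = n_co / n_spots_green,
                                  n_spots_red = n_spots_red,
                                  n_spots_green = n_spots_green)
  )
}

#' Simulate a sparse single-cell count matrix with a gate-gene split
#'
#' Cells fall into two latent groups: gate-gene-positive (carrying at
#' least one read of `split_gene`, probability `frac_jam3_pos`) and
#' gate-gene-negative (zero reads). Counts follow a negative-binomial
#' model (dispersion 0.3, a standard minimal scRNA-seq noise level)
#' with lognormal gene abundances and lognormal per-cell depth.
#' Deuterosomal marker genes have their mean multiplied by
#' `effect_deutero` in negative cells; mature markers and the reference
#' gene are identical across groups, so the generator encodes the
#' immature-cell expression pattern the comparison is meant to detect.
#'
#' @param n_genes Total genes (markers included).
#' @param n_cells Total cells.
#' @param frac_jam3_pos Probability a cell is gate-gene-positive.
#' @param marker_genes_deutero,marker_genes_mature Disjoint marker gene
#'   name vectors; neither may contain `split_gene`.
#' @param effect_deutero Fold-change of deuterosomal markers in
#'   negative cells (1 = null model).
#' @param depth_mean Expected reads per cell.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param split_gene,reference_gene Gate and reference gene names.
#' @param seed RNG seed.
#' @return A list: `counts` (sparse genes x cells `dgCMatrix` with
#'   dimnames) and `ground_truth`, a tibble with `cell_id`, `group`.
#' @export
make_counts <- function(n_genes = 2000, n_cells = 500, frac_jam3_pos = 0.5,
                        marker_genes_deutero = sprintf("DeutM%02d", 1:10),
                        marker_genes_mature = sprintf("MatM%02d", 1:10),
                        effect_deutero = 3, depth_mean = 5000,
                        dispersion = 0.3, split_gene = "Jam3",
                        reference_gene = "Foxj1", seed = 1) {
  if (length(intersect(marker_genes_deutero, marker_genes_mature)) > 0)
    stop("marker lists must be disjoint", call. = FALSE)
  if (split_gene %in% c(marker_genes_deutero, marker_genes_mature))
    stop("marker lists must not contain the split gene", call. = FALSE)
  special <- c(split_gene, reference_gene, marker_genes_deutero, marker_genes_mature)
  n_bg <- n_genes - length(special)
  if (n_bg < 0) stop("n_genes smaller than the named gene set", call. = FALSE)
  genes <- c(special, sprintf("Gene%05d", seq_len(n_bg)))

  withr::with_seed(seed, {
    w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    names(w) <- genes
    w <- w / sum(w)
    depth <- stats::rlnorm(n_cells, meanlog = log(depth_mean) - 0.3^2 / 2, sdlog = 0.3)
    pos <- stats::rbinom(n_cells, 1, frac_jam3_pos) == 1

    mu <- outer(w, depth)                         # genes x cells expected counts
    mu[marker_genes_deutero, !pos] <- mu[marker_genes_deutero, !pos] * effect_deutero
    counts <- matrix(stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu),
                     n_genes, n_cells, dimnames = list(genes, NULL))
    # gate gene: zero-truncated NB draw in positive cells, exact zero otherwise
    mu_j <- mu[split_gene, ]
    jam <- integer(n_cells)
    if (any(pos)) {
      p0 <- stats::dnbinom(0, size = 1 / dispersion, mu = mu_j[pos])
      q <- stats::runif(sum(pos), p0, 1)
      jam[pos] <- stats::qnbinom(pmin(q, 1 - 1e-12), size = 1 / dispersion,
                                 mu = mu_j[pos])
      jam[pos] <- pmax(jam[pos], 1L)
    }
    counts[split_gene, ] <- jam
  })

  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  colnames(counts) <- cell_ids
  list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    ground_truth = tibble::tibble(
      cell_id = cell_ids,
      group = ifelse(pos, "jam3_pos", "jam3_neg")
    )
  )
}
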