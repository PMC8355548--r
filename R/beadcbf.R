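#' Remove the static background of a movie
#'
#' Subtracts the per-pixel temporal median of the stack (computed on a
#' uniform subsample of at most `max_frames` frames) from every frame.
#' The median, unlike the mean, is robust to each bead's own transit
#' through a pixel, so static structures vanish while moving beads
#' leave signed residuals.
#'
#' @param m A [cq_movie()] with at least 10 frames.
#' @param max_frames Maximum frames used to estimate the median.
#' @return A [cq_movie()] of residuals (same fps; may be negative).
#' @export
remove_background <- function(m, max_frames = 200) {
  stopifnot(inherits(m, "cq_movie"))
  n_t <- n_frames(m)
  if (n_t < 10L) stop("background removal needs at least 10 frames", call. = FALSE)
  d <- dim(m$frames)
  sub <- unique(round(seq(1, n_t, length.out = min(max_frames, n_t))))
  flat <- matrix(m$frames[, , sub], nrow = d[1] * d[2])
  med <- matrix(apply(flat, 1, stats::median), d[1], d[2])
  res <- m$frames - as.vector(med)   # recycles med over the time dimension
  cq_movie(res, fps = m$fps, pixel_size = m$pixel_size)
}

#' Detect beads in a background-removed movie
#'
#' Per frame, pixels whose residual magnitude exceeds
#' `threshold_sd * sigma` (with `sigma = 1.4826 * MAD` of that frame, a
#' robust noise estimate) are grouped by 8-connectivity; components of
#' at least `min_area` pixels yield intensity-weighted centroids.
#'
#' @param residuals A residual [cq_movie()] from [remove_background()].
#' @param threshold_sd Detection threshold as a multiple of the robust
#'   per-frame noise sd.
#' @param min_area Minimum component area in pixels.
#' @param polarity `"dark"` (negative residuals), `"bright"` (positive)
#'   or `"both"`; beads imaged in brightfield are dark, fluorescent
#'   ones bright.
#' @param smooth_sigma Gaussian matched-filter sd in pixels applied to
#'   each residual frame before thresholding (`0` disables). A bead
#'   oscillating by about its own radius never fully leaves the
#'   temporal median, so raw per-pixel residuals sit near the noise
#'   floor; filtering at the blob scale restores the contrast without
#'   touching the detection rule itself.
#' @return A tibble with one row per detection: `frame`, `x`, `y`
#'   (pixel coordinates, x along columns), `area`, `peak_contrast`
#'   (signed residual of the strongest pixel).
#' @export
detect_beads <- function(residuals, threshold_sd = 5, min_area = 4,
                         polarity = c("both", "dark", "bright"),
                         smooth_sigma = 1.5) {
  stopifnot(inherits(residuals, "cq_movie"))
  polarity <- match.arg(polarity)
  d <- dim(residuals$frames)
  H <- d[1]; W <- d[2]
  kern <- if (smooth_sigma > 0) gauss_kernel(smooth_sigma) else NULL
  out <- vector("list", d[3])
  for (t in seq_len(d[3])) {
    fr <- residuals$frames[, , t]
    if (!is.null(kern)) fr <- EBImage::filter2(fr, kern)
    sigma <- stats::mad(fr)
    # noise-free frames have MAD 0: fall back to a floor that separates
    # true residual support from numerical fuzz of the convolution
    thr <- max(threshold_sd * sigma, 0.005 * max(abs(fr)))
    # dark and bright components are labelled separately: a dark bead's
    # vacated (bright) residual lobe must not merge with the bead itself
    lit_d <- if (polarity %in% c("dark", "both")) which(fr < -thr) else integer(0)
    lit_b <- if (polarity %in% c("bright", "both")) which(fr > thr) else integer(0)
    lit <- c(lit_d, lit_b)
    if (length(lit) == 0L) next
    lab_d <- label_components_8(lit_d, H, W)
    lab_b <- label_components_8(lit_b, H, W)
    lab <- c(lab_d, lab_b + max(lab_d, 0L))
    w <- abs(fr[lit])
    row <- (lit - 1L) %% H + 1L
    col <- (lit - 1L) %/% H + 1L
    area <- tabulate(lab)
    keep <- which(area >= min_area)
    if (length(keep) == 0L) next
    sw <- rowsum(w, lab)[, 1]
    cx <- rowsum(w * col, lab)[, 1] / sw
    cy <- rowsum(w * row, lab)[, 1] / sw
    peak <- vapply(seq_along(area),
                   function(k) { v <- fr[lit[lab == k]]; v[which.max(abs(v))] },
                   numeric(1))
    out[[t]] <- tibble::tibble(frame = t, x = cx[keep], y = cy[keep],
                               area = area[keep], peak_contrast = peak[keep])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L)
    res <- tibble::tibble(frame = integer(0), x = numeric(0), y = numeric(0),
                          area = integer(0), peak_contrast = numeric(0))
  res
}

#' Link per-frame detections into bead trajectories
#'
#' Greedy nearest-neighbour linking: candidate track-detection pairs
#' are accepted in order of ascending distance when the displacement is
#' below `max_disp` pixels per elapsed frame. Tracks tolerate up to
#' `max_gap` missing frames, filled by linear interpolation; tracks
#' observed in fewer than `min_coverage` of the movie's frames are
#' discarded. Beads in this assay are sparse and quasi-stationary, so
#' greedy linking suffices; dense, fast-crossing scenes would need a
#' global assignment solver.
#'
#' @param detections Detection tibble from [detect_beads()].
#' @param max_disp Maximum link displacement, pixels/frame.
#' @param min_coverage Minimum fraction of movie frames a track must be
#'   observed in.
#' @param n_total_frames Total frames in the movie (defaults to the
#'   largest detection frame).
#' @param max_gap Maximum missing frames bridged inside a track.
#' @return A tibble with `bead_id`, `frame`, `x`, `y`, `observed`
#'   (FALSE for interpolated rows), ordered by bead then frame.
#' @export
link_trajectories <- function(detections, max_disp = 8, min_coverage = 0.5,
                              n_total_frames = NULL, max_gap = 2) {
  if (nrow(detections) == 0L)
    return(tibble::tibble(bead_id = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0), observed = logical(0)))
  if (is.null(n_total_frames)) n_total_frames <- max(detections$frame)
  detections <- dplyr::arrange(detections, .data$frame)
  tr_x <- list(); tr_y <- list(); tr_f <- list()
  last_x <- numeric(0); last_y <- numeric(0); last_f <- integer(0)
  n_ambig <- 0L
  for (f in sort(unique(detections$frame))) {
    det <- detections[detections$frame == f, ]
    nd <- nrow(det)
    active <- which(last_f >= f - (max_gap + 1L))
    assigned_det <- rep(FALSE, nd)
    assigned_tr <- rep(FALSE, length(active))
    if (length(active) > 0L && nd > 0L) {
      dt <- f - last_f[active]
      dist <- sqrt(outer(last_x[active], det$x, "-")^2 +
                   outer(last_y[active], det$y, "-")^2)
      lim <- max_disp * dt
      cand <- which(dist <= lim, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        per_det <- tabulate(cand[, 2], nd)
        n_ambig <- n_ambig + sum(per_det > 1L)
        cand <- cand[order(dist[cand]), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (assigned_tr[i] || assigned_det[j]) next
          assigned_tr[i] <- TRUE; assigned_det[j] <- TRUE
          id <- active[i]
          tr_x[[id]] <- c(tr_x[[id]], det$x[j])
          tr_y[[id]] <- c(tr_y[[id]], det$y[j])
          tr_f[[id]] <- c(tr_f[[id]], f)
          last_x[id] <- det$x[j]; last_y[id] <- det$y[j]; last_f[id] <- f
        }
      }
    }
    for (j in which(!assigned_det)) {
      id <- length(tr_x) + 1L
      tr_x[[id]] <- det$x[j]; tr_y[[id]] <- det$y[j]; tr_f[[id]] <- f
      last_x[id] <- det$x[j]; last_y[id] <- det$y[j]; last_f[id] <- f
    }
  }
  if (n_ambig > 0L)
    message(sprintf("linking: %d ambiguous candidate links resolved by distance",
                    n_ambig))
  keep <- which(vapply(tr_f, length, integer(1)) / n_total_frames >= min_coverage)
  out <- purrr::imap(keep, function(id, rank) {
    ff <- tr_f[[id]]
    full <- seq(min(ff), max(ff))
    tibble::tibble(
      bead_id = rank,
      frame = full,
      x = stats::approx(ff, tr_x[[id]], xout = full)$y,
      y = stats::approx(ff, tr_y[[id]], xout = full)$y,
      observed = full %in% ff
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L)
    res <- tibble::tibble(bead_id = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0), observed = logical(0))
  res
}

# normalized Gaussian kernel with odd side length
gauss_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# periodogram of one axis series: detrend, Hann window, 4x zero-padding
axis_spectrum <- function(v, fps, pad_factor = 4, window = TRUE, detrend = TRUE) {
  n <- length(v)
  if (detrend) {
    tt <- seq_len(n)
    scale0 <- max(abs(v))
    v <- stats::lm.fit(cbind(1, tt), v)$residuals
    # constant / purely linear series leave only solver fuzz behind
    if (max(abs(v)) < 1e-9 * (scale0 + 1)) v <- numeric(n)
  }
  if (window) v <- v * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  m <- pad_factor * n
  p <- abs(stats::fft(c(v, numeric(m - n))))^2
  m_half <- floor(m / 2)
  tibble::tibble(freq = (seq_len(m_half) - 1) * fps / m,
                 power = p[seq_len(m_half)])
}

# dominant peak of a one-sided periodogram within [f_min, fps/2)
peak_of <- function(spec, f_min, fps, refine = TRUE) {
  band <- which(spec$freq >= f_min & spec$freq < fps / 2)
  if (length(band) == 0L || all(spec$power[band] == 0))
    return(list(freq = NA_real_, power = 0, med_power = NA_real_))
  k <- band[which.max(spec$power[band])]
  f <- spec$freq[k]
  if (refine && k > 1L && k < nrow(spec)) {
    p0 <- spec$power[k - 1]; p1 <- spec$power[k]; p2 <- spec$power[k + 1]
    den <- p0 - 2 * p1 + p2
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (p0 - p2) / den
      f <- f + delta * (spec$freq[2] - spec$freq[1])
    }
  }
  f <- min(max(f, f_min), spec$freq[nrow(spec)])
  list(freq = f, power = spec$power[k],
       med_power = stats::median(spec$power[band]))
}

#' Estimate beat frequency per bead by FFT of its trajectory
#'
#' Each axis series is linearly detrended, Hann-windowed, zero-padded
#' to four times its length and Fourier-transformed; the dominant
#' periodogram peak in `[f_min, fps/2)` gives the per-axis frequency,
#' optionally refined by 3-point parabolic interpolation around the
#' peak. The reported beat frequency is that of the axis with the
#' larger peak power; both per-axis values are kept so either
#' convention can be recovered. `quality` is the chosen axis's peak
#' power divided by the median spectral power in the band.
#'
#' @param trajectories Tibble from [link_trajectories()] (or any tibble
#'   with `bead_id`, `frame`, `x`, `y`; frames per bead must be
#'   contiguous).
#' @param fps Frame rate in frames/second.
#' @param f_min Lowest admissible frequency (Hz); excludes DC and drift
#'   leakage, and sits below the slowest beating of interest.
#' @param refine Apply parabolic peak interpolation.
#' @return A tibble with one row per bead: `bead_id`, `f_x`, `f_y`,
#'   `power_x`, `power_y`, `f_beat` (beats/second), `quality`,
#'   `n_samples`.
#' @export
estimate_cbf <- function(trajectories, fps, f_min = 0.5, refine = TRUE) {
  stopifnot(is.data.frame(trajectories), nrow(trajectories) > 0)
  min_len <- ceiling(2 * fps / f_min)
  trajectories |>
    dplyr::group_by(.data$bead_id) |>
    dplyr::group_modify(function(tr, key) {
      n <- nrow(tr)
      if (n < min_len)
        stop(sprintf("trajectory of bead %s too short (%d < %d samples)",
                     key$bead_id, n, min_len), call. = FALSE)
      px <- peak_of(axis_spectrum(tr$x, fps), f_min, fps, refine)
      py <- peak_of(axis_spectrum(tr$y, fps), f_min, fps, refine)
      if (px$power == 0 && py$power == 0) {
        return(tibble::tibble(f_x = NA_real_, f_y = NA_real_, power_x = 0,
                              power_y = 0, f_beat = NA_real_, quality = 0,
                              n_samples = n))
      }
      use_x <- px$power >= py$power
      best <- if (use_x) px else py
      tibble::tibble(
        f_x = px$freq, f_y = py$freq,
        power_x = px$power, power_y = py$power,
        f_beat = best$freq,
        quality = if (best$med_power > 0) best$power / best$med_power else Inf,
        n_samples = n
      )
    }) |>
    dplyr::ungroup()
}

#' Summarise per-bead frequencies at movie level
#'
#' Beads with `quality < quality_min` (or an undefined frequency) are
#' excluded; the median and interquartile range of the survivors'
#' `f_beat` are reported together with the number of beads used. When
#' every bead is excluded an empty summary (n = 0, NA statistics) is
#' returned rather than an error.
#'
#' @param results Per-bead tibble from [estimate_cbf()].
#' @param quality_min Minimum peak-to-median spectral power ratio.
#' @return A one-row tibble: `median_f_beat`, `iqr_f_beat`,
#'   `n_beads_used`, `n_beads_total`.
#' @export
summarize_movie <- function(results, quality_min = 5) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("need at least one CBF result", call. = FALSE)
  ok <- results[!is.na(results$f_beat) & results$quality >= quality_min, ]
  tibble::tibble(
    median_f_beat = if (nrow(ok)) stats::median(ok$f_beat) else NA_real_,
    iqr_f_beat = if (nrow(ok)) stats::IQR(ok$f_beat) else NA_real_,
    n_beads_used = nrow(ok),
    n_beads_total = nrow(results)
  )
}

#' Full cilia-beat-frequency pipeline on one movie
#'
#' Background removal, bead detection, trajectory linking, per-bead FFT
#' frequency estimation and movie-level summary in one call. The
#' pipeline defaults to `polarity = "dark"`: beads imaged in
#' brightfield are dark, and tracking the bright residual lobe a dark
#' bead leaves behind would report even harmonics of the true beat.
#'
#' @param m A [cq_movie()].
#' @param threshold_sd,min_area,polarity,smooth_sigma Passed to
#'   [detect_beads()].
#' @param max_disp,min_coverage Passed to [link_trajectories()].
#' @param f_min,refine Passed to [estimate_cbf()].
#' @param quality_min Passed to [summarize_movie()].
#' @return A list with `trajectories`, `per_bead` and `summary` tibbles.
#' @export
cbf_pipeline <- function(m, threshold_sd = 5, min_area = 4,
                         polarity = c("dark", "bright", "both"),
                         smooth_sigma = 1.5, max_disp = 8, min_coverage = 0.5,
                         f_min = 0.5, refine = TRUE, quality_min = 5) {
  polarity <- match.arg(polarity)
  res <- remove_background(m)
  det <- detect_beads(res, threshold_sd = threshold_sd, min_area = min_area,
                      polarity = polarity, smooth_sigma = smooth_sigma)
  trj <- link_trajectories(det, max_disp = max_disp,
                           min_coverage = min_coverage,
                           n_total_frames = n_frames(m))
  if (nrow(trj) == 0L)
    return(list(trajectories = trj,
                per_bead = tibble::tibble(),
                summary = tibble::tibble(median_f_beat = NA_real_,
                                         iqr_f_beat = NA_real_,
                                         n_beads_used = 0L,
                                         n_beads_total = 0L)))
  per_bead <- estimate_cbf(trj, fps = m$fps, f_min = f_min, refine = refine)
  list(trajectories = trj, per_bead = per_bead,
       summary = summarize_movie(per_bead, quality_min = quality_min))
}
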