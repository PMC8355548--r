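#' Minimum-area enclosing ellipse of a 2-D point set
#'
#' Computes the Loewner-John (minimum-volume, i.e. minimum-area in 2-D)
#' ellipse containing all points by Khachiyan's barycentric-coordinate
#' ascent. Iteration stops when the dual optimality gap falls below
#' `tol` (relative) or after `max_iter` sweeps.
#'
#' For a pixel ROI, call this on the four corner points of every member
#' pixel (see [roi_corner_points()]): corners give a one-pixel ROI a
#' finite circle and a single pixel row a valid thin ellipse instead of
#' a degenerate zero-area fit.
#'
#' @param points Two-column matrix (or data frame) of x, y coordinates.
#' @param tol Relative convergence tolerance of the dual gap.
#' @param max_iter Maximum iterations.
#' @return A list: `center` (x, y), `a`, `b` (semi-major and semi-minor
#'   axes, `a >= b`), `orientation` (radians of the major axis, in
#'   `(-pi/2, pi/2]`), `n_iter`.
#' @export
min_enclosing_ellipse <- function(points, tol = 1e-7, max_iter = 10000L) {
  P <- as.matrix(points)
  if (ncol(P) != 2L) stop("`points` must be n x 2", call. = FALSE)
  storage.mode(P) <- "double"
  P <- unique(P)
  n <- nrow(P)
  if (n < 1L) stop("need at least one point", call. = FALSE)
  if (n == 1L)
    return(list(center = as.numeric(P[1, ]), a = 0, b = 0, orientation = 0,
                n_iter = 0L))
  d <- 2
  # centre and scale for conditioning; undone below
  ctr <- colMeans(P)
  P0 <- sweep(P, 2, ctr)
  scl <- max(abs(P0), 1e-12)
  P <- P0 / scl
  Q <- t(cbind(P, 1))                       # (d+1) x n lifted points
  u <- rep(1 / n, n)
  it <- 0L
  scores <- function(u) {
    X <- Q %*% (u * t(Q))                   # (d+1) x (d+1)
    Xi <- tryCatch(solve(X), error = function(e) NULL)
    if (is.null(Xi))
      stop("degenerate point set (collinear); minimum ellipse undefined",
           call. = FALSE)
    list(kappa = colSums(Q * (Xi %*% Q)), Xi = Xi)
  }
  repeat {
    it <- it + 1L
    sc <- scores(u)
    kappa <- sc$kappa
    jp <- which.max(kappa)
    eps_plus <- kappa[jp] / (d + 1) - 1
    sup <- which(u > 0)
    jm <- sup[which.min(kappa[sup])]
    eps_minus <- 1 - kappa[jm] / (d + 1)
    if (max(eps_plus, eps_minus) <= tol) break
    if (it >= max_iter)
      stop(sprintf("minimum-ellipse fit did not converge in %d iterations",
                   max_iter), call. = FALSE)
    # Frank-Wolfe ascent with away steps (Todd-Yildirim): an away step
    # shrinks the weight of an interior point, keeping the iterate sparse
    if (eps_plus >= eps_minus) {
      j <- jp
      step <- (kappa[j] - d - 1) / ((d + 1) * (kappa[j] - 1))
    } else {
      j <- jm
      # the line-search formula is only valid for kappa > 1; deep
      # interior points (kappa <= 1) are dropped outright
      raw <- (kappa[j] - d - 1) / ((d + 1) * (kappa[j] - 1))
      if (!is.finite(raw) || raw > 0) raw <- -Inf
      step <- max(raw, -u[j] / (1 - u[j]))
    }
    u <- (1 - step) * u
    u[j] <- u[j] + step
    u[u < 0] <- 0
    # once the support has emerged, the step-size rule only re-balances
    # weights and zig-zags; a Newton solve of the support's optimality
    # system (kappa_j = d+1, sum u = 1) finishes quadratically
    if (it %% 100L == 0L) {
      un <- mvee_newton_polish(Q, u, d)
      if (!is.null(un)) {
        sc2 <- tryCatch(scores(un), error = function(e) NULL)
        if (!is.null(sc2)) {
          sup2 <- which(un > 0)
          gap2 <- max(max(sc2$kappa) / (d + 1) - 1,
                      1 - min(sc2$kappa[sup2]) / (d + 1))
          if (gap2 < max(eps_plus, eps_minus)) u <- un
        }
      }
    }
  }
  c_ <- as.numeric(t(P) %*% u)
  S <- t(P) %*% (u * P) - tcrossprod(c_)
  A <- solve(S) / d                          # ellipse: (x-c)' A (x-c) <= 1
  e <- eigen(A, symmetric = TRUE)
  # eigenvalues ascending in axis length: a = 1/sqrt(min lambda)
  a <- 1 / sqrt(e$values[2])
  b <- 1 / sqrt(e$values[1])
  if (a < b) { tmp <- a; a <- b; b <- tmp }
  v <- e$vectors[, which.min(e$values)]      # major-axis direction
  ang <- atan2(v[2], v[1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  list(center = c_ * scl + ctr, a = a * scl, b = b * scl,
       orientation = ang, n_iter = it)
}

# Equality-constrained Newton refinement of the support weights.
# kappa_j(u) has Jacobian d kappa_j / d u_k = -(q_j' X^{-1} q_k)^2, so
# the stationarity system {kappa_j = d+1 on the support, sum u = 1}
# solves in a handful of quadratically convergent steps. Returns the
# refined full-length weight vector, or NULL when the polish is not
# applicable (support too large) or fails to improve.
mvee_newton_polish <- function(Q, u, d, max_newton = 30L) {
  S <- which(u > 1e-9)
  m <- length(S)
  if (m < d + 1 || m > 40L) return(NULL)
  us <- u[S] / sum(u[S])
  for (k in seq_len(max_newton)) {
    m <- length(S)
    if (m < d + 1) return(NULL)
    Qs <- Q[, S, drop = FALSE]
    X <- Qs %*% (us * t(Qs))
    Xi <- tryCatch(solve(X), error = function(e) NULL)
    if (is.null(Xi)) return(NULL)
    K <- t(Qs) %*% Xi %*% Qs
    kap <- diag(K)
    if (max(abs(kap - d - 1)) < 1e-12 * (d + 1)) break
    kkt <- rbind(cbind(-K^2, 1), c(rep(1, m), 0))
    rhs <- c(d + 1 - kap, 0)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    du <- sol[seq_len(m)]
    if (any(us + du < 0)) {
      # a point leaving the support: drop the most negative and retry
      drop_i <- which.min(us + du)
      S <- S[-drop_i]
      us <- us[-drop_i] / sum(us[-drop_i])
      next
    }
    us <- us + du
    us <- us / sum(us)
  }
  out <- numeric(length(u))
  out[S] <- us
  out
}

#' Pixel-corner point set of an ROI
#'
#' Expands pixel centres (integer x = column, y = row) to the four
#' corners of each pixel, the point set the enclosing ellipse is fitted
#' to: pixels have extent, and corners avoid degenerate fits for
#' one-pixel or single-row ROIs.
#'
#' @param px,py Integer pixel coordinates (columns, rows).
#' @return A matrix of corner x, y coordinates (duplicates removed).
#' @export
roi_corner_points <- function(px, py) {
  corners <- rbind(
    cbind(px - 0.5, py - 0.5), cbind(px + 0.5, py - 0.5),
    cbind(px - 0.5, py + 0.5), cbind(px + 0.5, py + 0.5)
  )
  colnames(corners) <- c("x", "y")
  unique(corners)
}

#' Eccentricity and major/minor axis ratio of an ellipse
#'
#' Eccentricity is the distance between the focal points divided by the
#' major-axis length, `sqrt(a^2 - b^2) / a`; the Mm ratio is `a / b`.
#' Both grow with elongation: 0 and 1 for a circle, towards 1 and
#' infinity for a line, so either serves as an alignment score for
#' basal-body rows.
#'
#' @param a,b Semi-major and semi-minor axis lengths, `a >= b > 0`.
#' @return A list with `eccentricity` and `mm_ratio`.
#' @export
ellipse_metrics <- function(a, b) {
  if (any(b <= 0)) stop("semi-minor axis must be positive", call. = FALSE)
  if (any(a < b)) stop("need a >= b", call. = FALSE)
  list(eccentricity = sqrt(a^2 - b^2) / a, mm_ratio = a / b)
}

# TRUE when all points satisfy (p - c)' A (p - c) <= 1 + tol_rel
ellipse_contains <- function(fit, points, tol_rel = 1e-6) {
  R <- cbind(c(cos(fit$orientation), sin(fit$orientation)),
             c(-sin(fit$orientation), cos(fit$orientation)))
  A <- R %*% diag(1 / c(fit$a^2, fit$b^2)) %*% t(R)
  dif <- sweep(as.matrix(points), 2, fit$center)
  q <- rowSums((dif %*% A) * dif)
  all(q <= 1 + tol_rel)
}
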