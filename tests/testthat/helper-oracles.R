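# Independent reference computations used across tests.

# Minimal-ellipse area by an independent route: the D-optimal-design
# objective log det X(u) maximized over simplex weights with a generic
# quasi-Newton optimizer on a softmax parametrization, area from the
# dual reconstruction, rescaled outward so every point is enclosed.
mvee_oracle_area <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  ctr <- colMeans(P)
  P0 <- sweep(P, 2, ctr)
  scl <- max(abs(P0), 1e-12)
  P0 <- P0 / scl
  Q <- cbind(P0, 1)
  negf <- function(z) {
    u <- exp(z - max(z)); u <- u / sum(u)
    -determinant(crossprod(Q * sqrt(u)), logarithm = TRUE)$modulus
  }
  z <- rep(0, n)
  for (k in 1:6)
    z <- stats::optim(z, negf, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))$par
  u <- exp(z - max(z)); u <- u / sum(u)
  cc <- colSums(P0 * u)
  S <- crossprod(P0 * sqrt(u)) - tcrossprod(cc)
  q <- rowSums((sweep(P0, 2, cc) %*% solve(S)) * sweep(P0, 2, cc))
  2 * pi * sqrt(det(S * max(q) / 2)) * scl^2
}

# Plain-sum Mander's on matrices, written independently of the package.
manders_naive <- function(r, g, tr, tg) {
  m1 <- sum(r[r > tr & g > tg]) / sum(r[r > tr])
  m2 <- sum(g[g > tg & r > tr]) / sum(g[g > tg])
  c(M1 = m1, M2 = m2)
}

# Analytic bead-centre trajectory as a tibble, for oracle comparisons.
analytic_trajectory <- function(f, fps, duration, amplitude = 3,
                                direction = 0, phase = 0,
                                x0 = 50, y0 = 50, drift = c(0, 0),
                                bead_id = 1L) {
  tt <- seq_len(round(fps * duration)) - 1
  s <- amplitude * sin(2 * pi * f * tt / fps + phase)
  tibble::tibble(
    bead_id = bead_id,
    frame = tt + 1L,
    x = x0 + drift[1] * tt + s * cos(direction),
    y = y0 + drift[2] * tt + s * sin(direction)
  )
}
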