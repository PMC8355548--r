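# Sparse 8-connectivity component labelling.
#
# Works on the linear indices of foreground pixels only, so cost scales
# with the number of lit pixels, not the frame area -- bead and
# basal-body masks are sparse, and frames are processed per time point.

# idx: linear (column-major) indices of foreground pixels in an H x W frame.
# Returns an integer vector of component labels (1..k) parallel to idx.
label_components_8 <- function(idx, H, W) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  row <- (idx - 1L) %% H + 1L
  col <- (idx - 1L) %/% H + 1L
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # neighbour offsets covering half the 8-neighbourhood (the other half
  # is reached symmetrically)
  offs <- list(c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))
  for (o in offs) {
    nb_row <- row + o[1]; nb_col <- col + o[2]
    ok <- nb_row >= 1L & nb_row <= H & nb_col >= 1L & nb_col <= W
    nb_idx <- (nb_col - 1L) * H + nb_row
    j <- match(nb_idx, idx)          # position of the neighbour, if lit
    hit <- which(ok & !is.na(j))
    for (i in hit) {
      ri <- find(i); rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
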