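#' Movie container
#'
#' A grayscale time-lapse stack with an attached frame rate. Frames are
#' stored as a numeric `height x width x n_frames` array; `frames[, , t]`
#' is the t-th frame, rows are image rows (y), columns are x.
#'
#' @param frames Numeric 3-D array, `H x W x T` with `T >= 2`, all
#'   intensities finite.
#' @param fps Frames per second; finite, `> 0`. Always supplied by the
#'   user, never inferred from file metadata (see [read_movie()]).
#' @param pixel_size Micrometres per pixel; defaults to 1 (results are
#'   then in pixel units).
#' @return An object of class `cq_movie`.
#' @export
cq_movie <- function(frames, fps, pixel_size = 1) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (height x width x time)", call. = FALSE)
  if (dim(frames)[3] < 2L)
    stop("a movie needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(frames)))
    stop("frame intensities must all be finite", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single finite positive number", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  structure(
    list(frames = frames, fps = as.numeric(fps), pixel_size = as.numeric(pixel_size)),
    class = "cq_movie"
  )
}

#' @export
print.cq_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cq_movie> %d frames of %d x %d, %g fps (%.2f s)\n",
              d[3], d[1], d[2], x$fps, d[3] / x$fps))
  invisible(x)
}

#' @export
dim.cq_movie <- function(x) dim(x$frames)

#' Number of frames in a movie
#' @param m A [cq_movie()].
#' @return Integer frame count.
#' @export
n_frames <- function(m) {
  stopifnot(inherits(m, "cq_movie"))
  dim(m$frames)[3]
}

#' Single-channel image container
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param channel_name Label for the channel (e.g. `"red"`, `"green"`).
#' @return An object of class `cq_channel`.
#' @export
cq_channel <- function(pixels, channel_name = "channel") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  structure(
    list(pixels = pixels, channel_name = as.character(channel_name)[1]),
    class = "cq_channel"
  )
}

#' @export
print.cq_channel <- function(x, ...) {
  cat(sprintf("<cq_channel '%s'> %d x %d, range [%g, %g]\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.cq_channel <- function(x) dim(x$pixels)

#' Cell label-mask container
#'
#' Integer label image: 0 is background, `k > 0` marks cell `k`. A mask
#' file authored by any external segmentation tool stands in for the
#' interactive cell outlining of a point-and-click workflow.
#'
#' @param labels Integer matrix of non-negative labels.
#' @return An object of class `cq_mask`.
#' @export
cq_mask <- function(labels) {
  if (!is.matrix(labels) || length(labels) == 0L)
    stop("`labels` must be a non-empty matrix", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    stop("mask labels must be non-negative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "cq_mask")
}

#' @export
print.cq_mask <- function(x, ...) {
  k <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<cq_mask> %d x %d, %d cell(s)\n",
              nrow(x$labels), ncol(x$labels), length(k)))
  invisible(x)
}

#' @export
dim.cq_mask <- function(x) dim(x$labels)

# shared shape check
check_same_shape <- function(a, b, what_a, what_b) {
  da <- dim(a); db <- dim(b)
  if (!identical(da[1:2], db[1:2]))
    stop(sprintf("%s (%d x %d) and %s (%d x %d) must have the same shape",
                 what_a, da[1], da[2], what_b, db[1], db[2]), call. = FALSE)
  invisible(TRUE)
}
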