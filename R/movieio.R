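#' Read a time-lapse movie from TIFF
#'
#' Reads a multi-page grayscale TIFF (or a directory of single-page
#' TIFFs, taken in filename order) into a [cq_movie()]. The frame rate
#' is always the `fps` argument: consumer cameras embed unreliable rate
#' metadata, and the beat-frequency estimate scales linearly with fps,
#' so a silent misread would corrupt every downstream number. RGB pages
#' are converted to grayscale by the ITU-R BT.601 luma weights with a
#' message.
#'
#' @param path Path to a multi-page TIFF file, or to a directory of
#'   single-page TIFFs whose sorted filenames give acquisition order.
#' @param fps Acquisition frame rate (frames/second); required.
#' @param pixel_size Micrometres per pixel (optional, default 1).
#' @return A [cq_movie()].
#' @export
read_movie <- function(path, fps, pixel_size = 1) {
  if (missing(fps)) stop("`fps` is required and never inferred from metadata", call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) < 2L)
      stop("directory must contain at least 2 TIFF frames", call. = FALSE)
    pages <- lapply(files, function(f) read_tiff_pages(f)[[1]])
  } else {
    pages <- read_tiff_pages(path)
    if (length(pages) < 2L)
      stop("movie TIFF must have at least 2 pages", call. = FALSE)
  }
  pages <- lapply(pages, page_to_gray)
  shp <- dim(pages[[1]])
  ok <- vapply(pages, function(p) identical(dim(p), shp), logical(1))
  if (!all(ok)) stop("all frames must have the same shape", call. = FALSE)
  frames <- array(unlist(pages, use.names = FALSE), dim = c(shp, length(pages)))
  cq_movie(frames, fps = fps, pixel_size = pixel_size)
}

read_tiff_pages <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop(sprintf("cannot read TIFF '%s': %s",
                                                     path, conditionMessage(e)),
                                             call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  pages
}

# RGB (H x W x 3[ x4]) page -> BT.601 luma; grayscale page passes through
page_to_gray <- function(p) {
  if (is.matrix(p)) return(p)
  d <- dim(p)
  if (length(d) == 3L && d[3] >= 3L) {
    message("RGB frame converted to grayscale (BT.601 luma)")
    return(0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3])
  }
  if (length(d) == 3L && d[3] == 1L) return(p[, , 1])
  stop("unsupported TIFF sample layout", call. = FALSE)
}

#' Write a movie to a 16-bit multi-page TIFF
#'
#' Intensities must lie in `[0, 65535]`; they are stored as 16-bit
#' integers, so integer-valued stacks round-trip exactly through
#' [read_movie()].
#'
#' @param m A [cq_movie()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "cq_movie"))
  rng <- range(m$frames)
  if (rng[1] < 0 || rng[2] > 65535)
    stop("intensities must be within [0, 65535] for 16-bit storage", call. = FALSE)
  pages <- lapply(seq_len(n_frames(m)), function(t) m$frames[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a red/green channel pair
#'
#' Two single-channel 2-D TIFFs of identical shape; multi-channel files
#' are rejected so channel semantics stay explicit (one file per
#' channel). Integer TIFF intensities are preserved without rescaling.
#'
#' @param path_red,path_green Paths to the two single-channel TIFFs.
#' @return A list with elements `red` and `green`, each a [cq_channel()].
#' @export
read_channels <- function(path_red, path_green) {
  red <- read_channel(path_red, "red")
  green <- read_channel(path_green, "green")
  check_same_shape(red, green, "red image", "green image")
  list(red = red, green = green)
}

#' Read one single-channel TIFF image
#' @param path Path to a single-page grayscale TIFF.
#' @param channel_name Label attached to the result.
#' @return A [cq_channel()].
#' @export
read_channel <- function(path, channel_name = "channel") {
  pages <- read_tiff_pages(path)
  if (length(pages) != 1L)
    stop(sprintf("'%s' must be a single-page TIFF", path), call. = FALSE)
  px <- pages[[1]]
  if (!is.matrix(px))
    stop(sprintf("'%s' is not single-channel; supply one file per channel", path),
         call. = FALSE)
  cq_channel(px, channel_name)
}

#' Write one channel image to a 16-bit TIFF
#' @param img A [cq_channel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(img, path) {
  stopifnot(inherits(img, "cq_channel"))
  if (max(img$pixels) > 65535)
    stop("intensities must be within [0, 65535] for 16-bit storage", call. = FALSE)
  tiff::writeTIFF(img$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a cell label mask from TIFF
#' @param path Single-page TIFF whose integer pixel values are cell labels.
#' @return A [cq_mask()].
#' @export
read_mask <- function(path) {
  pages <- read_tiff_pages(path)
  if (length(pages) != 1L || !is.matrix(pages[[1]]))
    stop(sprintf("'%s' must be a single-page single-channel TIFF", path),
         call. = FALSE)
  cq_mask(round(pages[[1]]))
}

#' Write a cell label mask to TIFF
#' @param mask A [cq_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "cq_mask"))
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a flat table of records as CSV
#'
#' Deterministic output: columns are sorted alphabetically, UTF-8, '.'
#' decimal separator. Refuses empty input rather than emitting a
#' header-only file.
#'
#' @param records A data frame, or a list of named lists sharing one key
#'   set.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- tibble::as_tibble(records)
  } else if (is.list(records)) {
    if (length(records) == 0L)
      stop("empty record list: nothing to write", call. = FALSE)
    keys <- lapply(records, function(r) sort(names(r)))
    if (!all(vapply(keys, identical, logical(1), y = keys[[1]])))
      stop("records do not share a single key set", call. = FALSE)
    df <- dplyr::bind_rows(lapply(records, tibble::as_tibble))
  } else {
    stop("`records` must be a data frame or a list of named lists", call. = FALSE)
  }
  if (nrow(df) == 0L)
    stop("empty record list: nothing to write", call. = FALSE)
  df <- df[, sort(names(df)), drop = FALSE]
  readr::write_csv(df, path)
  invisible(path)
}
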