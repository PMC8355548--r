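#' Read a genes x cells count matrix
#'
#' Accepts a TSV (first column = gene id, remaining columns = cells) or
#' a MatrixMarket `.mtx` file with row- and column-label sidecar files
#' (one id per line). Counts must be non-negative integers.
#'
#' @param path Path to the `.tsv`/`.txt` or `.mtx` file.
#' @param genes_path,cells_path Label files for the MatrixMarket route;
#'   default `<path>.rownames` / `<path>.colnames` next to the matrix.
#' @return A sparse `dgCMatrix`, genes in rows, cells in columns.
#' @export
read_counts <- function(path, genes_path = NULL, cells_path = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    if (is.null(genes_path)) genes_path <- paste0(path, ".rownames")
    if (is.null(cells_path)) cells_path <- paste0(path, ".colnames")
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(cells_path)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    genes <- as.character(df[[1]])
    m <- Matrix::Matrix(as.matrix(df[, -1]), sparse = TRUE,
                        dimnames = list(genes, names(df)[-1]))
    m <- methods::as(m, "CsparseMatrix")
  }
  validate_counts(m)
  m
}

validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("count matrix needs unique gene and cell ids", call. = FALSE)
  v <- m@x
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("counts must be finite non-negative integers", call. = FALSE)
  invisible(m)
}

#' Read a marker gene list (one gene per line)
#'
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path Plain-text file path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Split cells by expression of a gate gene
#'
#' A cell is positive when it carries at least one read of
#' `split_gene`; the partition is exhaustive and disjoint.
#'
#' @param counts Genes x cells count matrix (sparse or dense) with
#'   dimnames.
#' @param split_gene Gate gene id (default `"Jam3"`).
#' @return A tibble with `cell_id` and `group`
#'   (`"positive"`/`"negative"`).
#' @export
split_by_gene <- function(counts, split_gene = "Jam3") {
  if (!split_gene %in% rownames(counts))
    stop(sprintf("gene '%s' not present in the matrix", split_gene), call. = FALSE)
  v <- as.numeric(counts[split_gene, ])
  if (all(v == 0))
    warning(sprintf("'%s' has zero reads in every cell; all cells negative",
                    split_gene), call. = FALSE)
  tibble::tibble(cell_id = colnames(counts),
                 group = ifelse(v >= 1, "positive", "negative"))
}

#' Per-cell marker-set score
#'
#' Library-size normalizes each cell (counts-per-million by default, or
#' plain fractions of library size) and averages the normalized
#' expression of the listed genes with equal weights. Listed genes
#' missing from the matrix are dropped with a warning; a cell with zero
#' total counts gets an `NA` score.
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param genes Marker gene ids (at least one present).
#' @param normalize `"cpm"` (counts per million) or `"fraction"`.
#' @return A tibble with `cell_id` and `score`.
#' @export
marker_score <- function(counts, genes, normalize = c("cpm", "fraction")) {
  normalize <- match.arg(normalize)
  genes <- unique(genes)
  present <- intersect(genes, rownames(counts))
  if (length(present) == 0L)
    stop("none of the listed genes is present in the matrix", call. = FALSE)
  if (length(present) < length(genes))
    warning(sprintf("%d listed gene(s) absent from the matrix and dropped",
                    length(genes) - length(present)), call. = FALSE)
  depth <- Matrix::colSums(counts)
  scale <- if (normalize == "cpm") 1e6 else 1
  sub <- counts[present, , drop = FALSE]
  mean_counts <- Matrix::colMeans(sub)
  score <- ifelse(depth > 0, mean_counts * scale / depth, NA_real_)
  tibble::tibble(cell_id = colnames(counts), score = unname(score))
}

#' Compare marker-set expression between gate-positive and -negative cells
#'
#' Splits cells on the gate gene, scores each marker panel per cell and
#' tests positive vs negative cells per panel (deuterosomal, mature,
#' and the reference gene alone) with a two-sided Mann-Whitney test by
#' default — counts are sparse and skewed, so a rank test is the safer
#' default — or Welch's t-test via `test = "t"`.
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param deutero,mature Character vectors of marker gene ids (must be
#'   non-empty, disjoint, and exclude the split gene).
#' @param split_gene Gate gene (default `"Jam3"`).
#' @param reference_gene Reference gene scored alone (default
#'   `"Foxj1"`).
#' @param test `"wilcox"` or `"t"`.
#' @param normalize Passed to [marker_score()].
#' @return An object of class `cq_marker_comparison`: a list with
#'   `tests` (one row per panel: `panel`, `mean_positive`,
#'   `mean_negative`, `statistic`, `p_value`, `n_positive`,
#'   `n_negative`), `scores` (per cell and panel) and `groups`.
#' @export
compare_marker_sets <- function(counts, deutero, mature, split_gene = "Jam3",
                                reference_gene = "Foxj1",
                                test = c("wilcox", "t"),
                                normalize = "cpm") {
  test <- match.arg(test)
  if (length(deutero) == 0L || length(mature) == 0L)
    stop("marker lists must be non-empty", call. = FALSE)
  if (length(intersect(deutero, mature)) > 0L)
    stop("marker lists must be disjoint", call. = FALSE)
  if (split_gene %in% c(deutero, mature))
    stop("marker lists must not contain the split gene", call. = FALSE)
  groups <- split_by_gene(counts, split_gene)
  pos <- groups$group == "positive"
  if (!any(pos) || all(pos))
    stop("both gate-positive and gate-negative cells are required", call. = FALSE)
  panels <- list(deuterosomal = deutero, mature = mature,
                 reference = reference_gene)
  scores <- purrr::imap(panels, function(genes, panel) {
    marker_score(counts, genes, normalize = normalize) |>
      dplyr::mutate(panel = panel)
  }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(groups, by = "cell_id")
  tests <- scores |>
    dplyr::group_by(.data$panel) |>
    dplyr::group_modify(function(d, key) {
      sp <- d$score[d$group == "positive"]
      sn <- d$score[d$group == "negative"]
      ht <- if (test == "wilcox") stats::wilcox.test(sp, sn, exact = FALSE)
            else stats::t.test(sp, sn, var.equal = FALSE)
      tibble::tibble(mean_positive = mean(sp, na.rm = TRUE),
                     mean_negative = mean(sn, na.rm = TRUE),
                     statistic = unname(ht$statistic),
                     p_value = ht$p.value,
                     n_positive = length(sp), n_negative = length(sn))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$panel, names(panels)))
  structure(list(tests = tests, scores = scores, groups = groups,
                 test = test, split_gene = split_gene,
                 reference_gene = reference_gene),
            class = "cq_marker_comparison")
}

#' @export
print.cq_marker_comparison <- function(x, ...) {
  cat(sprintf("<cq_marker_comparison> split on %s (%s test)\n",
              x$split_gene, x$test))
  print(x$tests)
  invisible(x)
}
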