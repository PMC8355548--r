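toy_counts <- function() {
  m <- Matrix::Matrix(rbind(
    Jam3  = c(0, 1, 7, 0),
    Foxj1 = c(5, 5, 5, 5),
    A     = c(10, 0, 2, 4),
    B     = c(0, 10, 2, 4),
    C     = c(85, 84, 84, 87)
  ), sparse = TRUE)
  colnames(m) <- paste0("c", 1:4)
  methods::as(m, "CsparseMatrix")
}

test_that("the gate splits cells at one read, exhaustively and disjointly", {
  g <- split_by_gene(toy_counts(), "Jam3")
  expect_equal(g$group, c("negative", "positive", "positive", "negative"))
  expect_equal(nrow(g), 4)
  expect_error(split_by_gene(toy_counts(), "Nope"), "not present")
  zero <- toy_counts(); zero["Jam3", ] <- 0
  expect_warning(split_by_gene(zero, "Jam3"), "zero reads")
})

test_that("marker scores are CPM means with the documented edge cases", {
  m <- toy_counts()
  # cell 1: gene A has 10 of 100 reads -> cpm 1e5
  s <- marker_score(m, "A")
  expect_equal(s$score[1], 1e5)
  # averaging two genes with equal cpm returns that cpm
  s2 <- marker_score(m, c("A", "A"))
  expect_equal(s2$score, marker_score(m, "A")$score)
  expect_warning(sAB <- marker_score(m, c("A", "Missing")), "absent")
  expect_equal(sAB$score, marker_score(m, "A")$score)
  expect_error(marker_score(m, c("X", "Y")), "none of the listed")
  zero_cell <- cbind(m, c0 = rep(0, 5))
  expect_true(is.na(marker_score(zero_cell, "A")$score[5]))
  # fraction mode is cpm / 1e6
  expect_equal(marker_score(m, "A", normalize = "fraction")$score[1], 0.1)
})

test_that("scores are invariant to depth scaling and cell permutation", {
  sim <- make_counts(n_genes = 200, n_cells = 60, seed = 2)
  m <- sim$counts
  m2 <- m
  m2[, 3] <- m2[, 3] * 5L
  expect_equal(marker_score(m, sprintf("DeutM%02d", 1:10))$score[3],
               marker_score(m2, sprintf("DeutM%02d", 1:10))$score[3])
  perm <- sample(ncol(m))
  cmp1 <- compare_marker_sets(m, sprintf("DeutM%02d", 1:10),
                              sprintf("MatM%02d", 1:10))
  cmp2 <- compare_marker_sets(m[, perm], sprintf("DeutM%02d", 1:10),
                              sprintf("MatM%02d", 1:10))
  expect_equal(tidy(cmp1)$p_value, tidy(cmp2)$p_value)
})

test_that("the deuterosomal effect is recovered and mature markers stay null", {
  sim <- make_counts(n_cells = 500, effect_deutero = 3, seed = 11)
  cmp <- compare_marker_sets(sim$counts, sprintf("DeutM%02d", 1:10),
                             sprintf("MatM%02d", 1:10))
  tt <- tidy(cmp)
  deut <- tt[tt$panel == "deuterosomal", ]
  expect_lt(deut$p_value, 0.01)
  expect_gt(deut$mean_negative, deut$mean_positive)
  # roughly the programmed 3-fold effect in the negative cells
  expect_lt(abs(deut$mean_negative / deut$mean_positive - 3), 0.9)
  expect_gt(tt$p_value[tt$panel == "mature"], 0.05)
  expect_gt(tt$p_value[tt$panel == "reference"], 0.05)
})

test_that("a null effect keeps the false-positive rate near nominal", {
  set.seed(17)
  p <- vapply(1:30, function(i) {
    sim <- make_counts(n_genes = 150, n_cells = 150, effect_deutero = 1,
                       seed = 1000 + i)
    tt <- tidy(compare_marker_sets(sim$counts, sprintf("DeutM%02d", 1:10),
                                   sprintf("MatM%02d", 1:10)))
    tt$p_value[tt$panel == "deuterosomal"]
  }, numeric(1))
  expect_lt(mean(p < 0.05), 0.2)
  expect_gt(min(p), 1e-4)
})

test_that("marker-set comparison validates its inputs", {
  sim <- make_counts(n_genes = 100, n_cells = 40, seed = 4)
  expect_error(compare_marker_sets(sim$counts, c("A", "B"), c("B", "C")),
               "disjoint")
  expect_error(compare_marker_sets(sim$counts, "Jam3", "MatM01"), "split gene")
  expect_error(compare_marker_sets(sim$counts, character(0), "MatM01"),
               "non-empty")
})

test_that("count matrices round-trip through TSV and MatrixMarket", {
  sim <- make_counts(n_genes = 80, n_cells = 25, seed = 6)
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(sim$counts, mtx)
  writeLines(rownames(sim$counts), paste0(mtx, ".rownames"))
  writeLines(colnames(sim$counts), paste0(mtx, ".colnames"))
  back <- read_counts(mtx)
  expect_equal(as.matrix(back), as.matrix(sim$counts))
  tsv <- file.path(dir, "counts.tsv")
  df <- data.frame(gene = rownames(sim$counts), as.matrix(sim$counts),
                   check.names = FALSE)
  readr::write_tsv(df, tsv)
  back2 <- read_counts(tsv)
  expect_equal(as.matrix(back2), as.matrix(sim$counts))
})

test_that("tidy, glance and autoplot expose the comparison", {
  sim <- make_counts(n_genes = 100, n_cells = 60, seed = 5)
  cmp <- compare_marker_sets(sim$counts, sprintf("DeutM%02d", 1:10),
                             sprintf("MatM%02d", 1:10))
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(nrow(tidy(cmp)), 3)
  gl <- glance(cmp)
  expect_equal(gl$n_cells, 60)
  expect_equal(gl$n_positive + gl$n_negative, 60)
  expect_s3_class(autoplot(cmp), "ggplot")
})
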