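test_that("summarize_qc matches hand values and the quantile oracle", {
  m <- matrix(0L, 5, 2, dimnames = list(paste0("c", 1:5), c("G1", "G2")))
  m[, 1] <- 1:5
  ds <- CellDataset(m)
  qc <- summarize_qc(ds, "total_counts")
  s <- qc$metrics$total_counts
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  expect_equal(unname(s$quantiles["q25"]), 2.0)
  expect_equal(qc$n_cells, 5L)

  expect_error(summarize_qc(ds, "nope"), "unknown metric")

  # constant column: sd 0, all quantiles equal
  meta <- data.frame(constant = rep(7, 5))
  ds2 <- CellDataset(m, cell_meta = meta)
  s2 <- summarize_qc(ds2, "constant")$metrics$constant
  expect_equal(s2$sd, 0)
  expect_true(all(s2$quantiles == 7))

  # oracle property on random vectors
  set.seed(1)
  probs <- c(1, 5, 10, 25, 50, 75, 90, 95, 99) / 100
  for (i in 1:100) {
    v <- stats::rnorm(sample(5:50, 1))
    mds <- CellDataset(
      matrix(0L, length(v), 1, dimnames = list(NULL, "G1")),
      cell_meta = data.frame(x = v))
    got <- summarize_qc(mds, "x")$metrics$x$quantiles
    want <- vapply(probs, function(p) oracle_quantile(v, p), 1.0)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("library_size_stats uses sample sd and counts zeros", {
  m <- matrix(c(10, 0, 0, 0,
                0, 20, 0, 0,
                0, 0, 30, 0), 3, 4, byrow = TRUE,
              dimnames = list(NULL, paste0("G", 1:4)))
  ds <- CellDataset(m)
  s <- library_size_stats(ds)
  expect_equal(s$libsize_cv, 0.5)           # sd(10,20,30)/mean = 10/20
  expect_equal(s$zero_fraction, 9 / 12)
  expect_equal(s$libsize_median, 20)

  constant <- CellDataset(matrix(c(5L, 5L, 5L), 3, 1,
                                 dimnames = list(NULL, "G1")))
  expect_equal(library_size_stats(constant)$libsize_cv, 0)

  zero <- CellDataset(matrix(0L, 2, 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(library_size_stats(zero), "nothing to normalize")
})

test_that("variance_explained normalizes and accumulates", {
  ds <- tiny_dataset()
  ds$layers$pc_variance <- c(4, 3, 2, 1)
  v <- variance_explained(ds)
  expect_equal(v$fractions, c(0.4, 0.3, 0.2, 0.1))
  expect_equal(v$cumulative, c(0.4, 0.7, 0.9, 1.0))

  ds$layers$pc_variance <- 3.7
  expect_equal(variance_explained(ds)$fractions, 1.0)

  set.seed(2)
  for (i in 1:20) {
    ds$layers$pc_variance <- stats::runif(sample(2:30, 1), 0.01, 10)
    v <- variance_explained(ds)
    expect_equal(sum(v$fractions), 1, tolerance = 1e-9)
    expect_true(all(diff(v$cumulative) >= 0))
    expect_lte(max(v$cumulative), 1 + 1e-9)
  }
})

test_that("top_pc_genes splits signs and breaks ties lexicographically", {
  ds <- tiny_dataset()
  L <- matrix(c(0.9, -0.8, 0.1, 0.05), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), "PC1"))
  ds$layers$pc_loadings <- L
  t1 <- top_pc_genes(ds, 1, 1)
  expect_equal(t1$PC1$positive$gene, "A")
  expect_equal(t1$PC1$negative$gene, "B")

  # tie |0.5|,|0.5| broken by gene name
  L2 <- matrix(c(0.5, 0.5, -0.2, 0.1), 4, 1,
               dimnames = list(c("Zed", "Abc", "B", "C"), "PC1"))
  ds$layers$pc_loadings <- L2
  expect_equal(top_pc_genes(ds, 1, 2)$PC1$positive$gene[1:2],
               c("Abc", "Zed"))

  expect_error(top_pc_genes(ds, 2, 1), "n_pcs")
  expect_error(top_pc_genes(ds, 1, 9), "n_genes")
})

test_that("expression_variability follows the stated dispersion definition", {
  ds <- tiny_dataset()
  # gene A values [0,2]: var 2, mean 1 -> 2; gene B [1,1] -> 0; mean = 1
  ln <- Matrix::Matrix(matrix(c(0, 2, 1, 1), 2, 2,
                              dimnames = list(NULL, c("A", "B"))),
                       sparse = TRUE)
  ds2 <- CellDataset(matrix(0L, 2, 2, dimnames = list(NULL, c("A", "B"))))
  ds2$layers$lognorm <- ln
  ds2$layers$hvg_flags <- c(TRUE, TRUE)
  expect_equal(expression_variability(ds2), 1.0)

  ds2$layers$lognorm <- Matrix::Matrix(matrix(3, 2, 2), sparse = TRUE)
  expect_equal(expression_variability(ds2), 0.0)

  ds2$layers$hvg_flags <- c(FALSE, FALSE)
  expect_error(expression_variability(ds2), "no HVGs")

  # brute-force per-gene loop oracle on NB data, and order invariance
  ds <- small_synth(seed = 3, n_cells = 80, n_genes = 60)
  got <- expression_variability(ds)
  ln <- as.matrix(ds$layers$lognorm)
  idx <- which(ds$layers$hvg_flags)
  oracle <- mean(vapply(idx, function(j) {
    v <- stats::var(ln[, j]); mu <- mean(ln[, j])
    if (mu > 0) v / mu else 0
  }, 1.0))
  expect_equal(got, oracle, tolerance = 1e-12)

  perm_g <- sample(ncol(ds$counts)); perm_c <- sample(nrow(ds$counts))
  ds_p <- ds
  ds_p$layers$lognorm <- ds$layers$lognorm[perm_c, perm_g]
  ds_p$layers$hvg_flags <- ds$layers$hvg_flags[perm_g]
  expect_equal(expression_variability(ds_p), got, tolerance = 1e-12)
})

test_that("median_neighbor_distance matches hand and brute-force oracles", {
  ds <- tiny_dataset()
  ds$layers$pc_embedding <- matrix(c(0, 1, 3), 3, 1)
  expect_equal(median_neighbor_distance(ds, k = 1, n_pcs = 1), 1)
  # k=2: distances {1,3, 1,2, 2,3} -> median 2
  expect_equal(median_neighbor_distance(ds, k = 2, n_pcs = 1), 2)
  expect_error(median_neighbor_distance(ds, k = 3, n_pcs = 1), "k \\(3\\)")

  set.seed(4)
  emb <- matrix(stats::rnorm(50 * 5), 50, 5)
  ds$layers$pc_embedding <- emb
  for (k in c(1, 5, 20)) {
    d <- as.matrix(stats::dist(emb)); diag(d) <- Inf
    oracle <- stats::median(as.numeric(
      apply(d, 1, function(r) sort(r)[seq_len(k)])))
    expect_equal(median_neighbor_distance(ds, k = k, n_pcs = 5), oracle,
                 info = paste("k =", k))
  }
})

test_that("top_markers filters, ranks, and tie-breaks", {
  mt <- data.frame(
    cluster = c(0, 0, 0, 1, 1),
    gene = c("A", "B", "C", "X", "Y"),
    avg_log2FC = c(2.0, 1.0, 0.5, 1.5, 1.5),
    p_val_adj = c(0.001, 0.002, 0.2, 0.01, 0.01))
  tm <- top_markers(mt, n = 2)
  expect_equal(tm[["0"]]$gene, c("A", "B"))   # C fails the p cutoff
  expect_equal(tm[["1"]]$gene, c("X", "Y"))   # lfc tie -> name order

  mt$p_val_adj <- 0.9
  expect_warning(tm2 <- top_markers(mt, n = 2), "no significant markers")
  expect_equal(nrow(tm2[["0"]]), 0)

  expect_error(top_markers(mt[, -4], n = 1), "p_val_adj")
})

test_that("metric operations are pure: identical output on repeat calls", {
  ds <- small_synth(seed = 5, n_cells = 60, n_genes = 80)
  expect_identical(summarize_qc(ds), summarize_qc(ds))
  expect_identical(expression_variability(ds), expression_variability(ds))
  expect_identical(median_neighbor_distance(ds, 5, 5),
                   median_neighbor_distance(ds, 5, 5))
})
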