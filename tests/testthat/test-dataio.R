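test_that("MTX triplet round-trips through load_counts", {
  dir <- write_tiny_mtx()
  ds <- load_counts(dir, "mtx_dir")
  expect_s3_class(ds, "CellDataset")
  expect_equal(dim(ds$counts), c(3L, 4L))
  expect_equal(as.matrix(ds$counts), tiny_counts(),
               ignore_attr = TRUE)
  expect_equal(ds$gene_names, paste0("G", 1:4))
  # QC columns recomputed on load
  expect_equal(ds$cell_meta$total_counts, c(3, 4, 0))
  expect_equal(ds$cell_meta$n_genes_detected, c(2L, 2L, 0L))
  expect_true(validate_dataset(ds))
})

test_that("missing MTX triplet members and malformed CSVs error usefully", {
  dir <- write_tiny_mtx()
  file.remove(file.path(dir, "barcodes.tsv"))
  expect_error(load_counts(dir, "mtx_dir"), "barcodes.tsv")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,G1,G2", "c1,1,1.5", "c2,2,0"), csv)
  err <- expect_error(load_counts(csv, "csv"), "non-integer")
  expect_match(conditionMessage(err), "c1")
  expect_match(conditionMessage(err), "G2")
})

test_that("duplicated gene names are rejected with the duplicates listed", {
  m <- tiny_counts()
  colnames(m) <- c("G1", "G2", "G2", "G3")
  expect_error(CellDataset(m), "G2")
})

test_that("CSV counts load with cells as rows", {
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tiny_counts(), csv)
  ds <- load_counts(csv, "csv")
  expect_equal(as.matrix(ds$counts), tiny_counts(), ignore_attr = TRUE)
  expect_equal(rownames(ds$counts), paste0("c", 1:3))
})

test_that("h5ad counts load natively (dense and sparse X)", {
  skip_if_not_installed("rhdf5")
  h5 <- withr::local_tempfile(fileext = ".h5ad")
  ok <- system2("python", c("-c", shQuote(paste0(
    "import anndata, numpy as np, scipy.sparse as sp\n",
    "m = np.array([[0,2,1,0],[3,0,0,1],[0,0,0,0]], dtype=np.float32)\n",
    "a = anndata.AnnData(X=sp.csr_matrix(m))\n",
    "a.obs_names = ['c1','c2','c3']; a.var_names = ['G1','G2','G3','G4']\n",
    "a.write_h5ad('", h5, "')"))), stdout = FALSE, stderr = FALSE)
  skip_if(ok != 0, "python/anndata unavailable to build the fixture")
  ds <- load_counts(h5, "h5ad")
  expect_equal(as.matrix(ds$counts), tiny_counts(), ignore_attr = TRUE)
  expect_equal(ds$gene_names, paste0("G", 1:4))
  expect_equal(rownames(ds$counts), paste0("c", 1:3))
})

test_that("GMT parsing dedups members and rejects malformed input", {
  p <- write_tiny_gmt(c("S1\tdesc\tA\tB\tA", "S2\td2\tC"))
  sets <- read_gene_sets(p)
  expect_setequal(sets$S1, c("A", "B"))
  expect_equal(sets$S2, "C")

  expect_error(read_gene_sets(write_tiny_gmt(c("S1\td\tA", "S1\td\tB"))),
               "duplicate set name")
  expect_error(read_gene_sets(write_tiny_gmt("S1\tonlydesc")),
               "fewer than 3 fields")
  empty <- withr::local_tempfile(fileext = ".gmt")
  file.create(empty)
  expect_warning(sets <- read_gene_sets(empty), "empty")
  expect_length(sets, 0)
})

test_that("records round-trip losslessly, including hostile content", {
  rec <- recommendation_record("recommend_res", "prompt {x}", "resp",
                               parsed_payload = list(start = 0.2),
                               model_id = "m", backend_name = "replay")
  p <- withr::local_tempfile(fileext = ".json")
  write_record(rec, p)
  back <- read_record(p)
  for (f in c("task_id", "rendered_prompt", "raw_response", "model_id",
              "backend_name", "timestamp")) {
    expect_identical(back[[f]], rec[[f]], info = f)
  }

  # fuzz: multi-line responses with delimiter/quote/brace characters
  set.seed(42)
  chars <- c(letters, '"', "\\", "{", "}", "|", "\t", "\n", ":", ",", "[")
  for (i in 1:20) {
    raw <- paste(sample(chars, 200, replace = TRUE), collapse = "")
    r <- recommendation_record("analyze_pcs", "p", raw)
    write_record(r, p)
    expect_identical(read_record(p)$raw_response, raw)
  }

  writeLines('{"task_id": "x"', p)
  expect_error(read_record(p), "corrupt")
})

test_that("attach_labels maps clusters, is idempotent, and is strict", {
  ds <- tiny_dataset()
  ds$layers$cluster_labels <- c("0", "1", "0")
  ds2 <- attach_labels(ds, "cell_type", c("0" = "NK", "1" = "T"))
  expect_equal(ds2$cell_meta$cell_type, c("NK", "T", "NK"))

  # idempotent under the same mapping (with overwrite)
  ds3 <- attach_labels(ds2, "cell_type", c("0" = "NK", "1" = "T"),
                       overwrite = TRUE)
  expect_identical(ds3$cell_meta, ds2$cell_meta)

  expect_error(attach_labels(ds, "ct", c("0" = "NK")), "missing: 1")
  expect_error(attach_labels(ds2, "cell_type", c("0" = "B", "1" = "T")),
               "overwrite")
})

test_that("percent columns outside [0,100] are rejected", {
  meta <- data.frame(percent_mito = c(5, 101, 2))
  expect_error(CellDataset(tiny_counts(), cell_meta = meta), "percent")
  expect_error(CellDataset(tiny_counts() - 1), "non-negative")
  expect_error(CellDataset(tiny_counts() + 0.5), "integral")
})
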