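test_that("parse_seq_range handles both dialects and rejects prose", {
  expect_equal(
    unclass(parse_seq_range("**Recommended Resolution:** seq(0.2, 1.2, 0.1)"))[1:3],
    list(start = 0.2, stop = 1.2, step = 0.1))
  expect_equal(
    unclass(parse_seq_range("resolution 0.4 to 0.8 in increments of 0.2"))[1:3],
    list(start = 0.4, stop = 0.8, step = 0.2))
  expect_error(parse_seq_range("use a moderate resolution"),
               "no recognizable")
  expect_error(resolution_range(1.0, 0.2, 0.1), "start > stop")
  expect_error(resolution_range(0.2, 1.2, 0), "positive")
  expect_error(resolution_range(0.2, 0.4, 0.5), "exceeds")
})

test_that("parse_seq_range inverts formatting on random triples", {
  set.seed(9)
  for (i in 1:200) {
    start <- round(stats::runif(1, 0.05, 2), 2)
    stop <- start + round(stats::runif(1, 0.1, 2), 2)
    step <- round(stats::runif(1, 0.01, stop - start), 2)
    if (step <= 0) next
    txt1 <- sprintf("Recommended: seq(%g, %g, %g)", start, stop, step)
    txt2 <- sprintf("try %g to %g in steps of %g", start, stop, step)
    for (txt in c(txt1, txt2)) {
      r <- parse_seq_range(txt)
      expect_equal(c(r$start, r$stop, r$step), c(start, stop, step),
                   info = txt)
    }
  }
})

test_that("parse_cutoffs binds numbers to metrics and directions", {
  r <- parse_cutoffs("filter cells with nFeature_RNA > 200 and < 5000",
                     "n_genes_detected")
  expect_equal(r$cutoffs$n_genes_detected$lower, 200)
  expect_equal(r$cutoffs$n_genes_detected$upper, 5000)

  r2 <- parse_cutoffs("percent_mito below 10", "percent_mito")
  expect_null(r2$cutoffs$percent_mito$lower)
  expect_equal(r2$cutoffs$percent_mito$upper, 10)

  expect_error(
    parse_cutoffs("n_genes_detected min 5000 max 200", "n_genes_detected"),
    "lower \\(5000\\) must be below upper \\(200\\)")
  expect_error(parse_cutoffs("percent_mito looks fine", "percent_mito"),
               "no numbers")
  expect_error(parse_cutoffs("nothing relevant 42", "percent_mito"),
               "no metric mention")
})

test_that("parse_annotations covers clusters and flags gaps", {
  txt <- "Cluster 0: NK cells\nCluster 1: CD8 T cells - granzyme markers"
  tab <- parse_annotations(txt, c("0", "1"))
  expect_equal(tab$label, c("NK cells", "CD8 T cells"))
  expect_equal(tab$reasoning[2], "granzyme markers")

  expect_warning(tab2 <- parse_annotations(paste0(txt, "\nCluster 9: junk"),
                                           c("0", "1")),
                 "unknown cluster")
  expect_equal(nrow(tab2), 2)

  expect_error(parse_annotations("Cluster 0: NK cells", c("0", "1")),
               "missing: 1")
})

test_that("run_ora matches the enumeration oracle and worked example", {
  # worked example: N=20, K=5, n=5, k=3 -> 1126/15504
  uni <- sprintf("g%02d", 1:20)
  sets <- list(S = uni[1:5])
  query <- c(uni[1:3], uni[10:11])        # overlap 3
  tab <- run_ora(query, uni, sets, max_q = Inf)
  expect_equal(tab$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(tab[, c("k", "K", "n", "N")],
               data.frame(k = 3L, K = 5L, n = 5L, N = 20L),
               ignore_attr = TRUE)

  # k = 0 -> p = 1; full overlap -> p = 1 when query = set = universe
  expect_equal(run_ora(uni[10:14], uni, list(S = uni[1:5]),
                       max_q = Inf)$p, 1.0)
  expect_equal(run_ora(uni, uni, list(S = uni), max_q = Inf)$p, 1.0)

  # random oracle sweep, all N <= 60
  set.seed(10)
  for (i in 1:60) {
    N <- sample(5:60, 1)
    uni <- sprintf("u%03d", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    set <- sample(uni, K); query <- sample(uni, n)
    k <- length(intersect(set, query))
    tab <- run_ora(query, uni, list(S = set), max_q = Inf)
    expect_equal(tab$p, oracle_hyper_tail(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("run_ora BH adjustment matches the direct sorted-formula oracle", {
  set.seed(11)
  uni <- sprintf("u%03d", 1:100)
  sets <- lapply(1:15, function(i) sample(uni, sample(5:30, 1)))
  names(sets) <- paste0("S", 1:15)
  query <- sample(uni, 20)
  tab <- run_ora(query, uni, sets, max_q = Inf)
  expect_equal(tab$q, oracle_bh(tab$p), tolerance = 1e-12)
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_true(!is.unsorted(tab$q))
  expect_true(all(tab$p > 0 & tab$p <= 1))
})

test_that("run_ora drops non-universe query genes and matches case-insensitively", {
  uni <- c("TNF", "IL6", "ACTB", "GAPDH")
  expect_warning(
    tab <- run_ora(c("tnf", "il6", "NOTAGENE"), uni,
                   list(S = c("Tnf", "Il6")), max_q = Inf),
    "not in universe")
  expect_equal(tab$k, 2L)
  expect_equal(tab$n, 2L)
  expect_error(suppressWarnings(run_ora("NOTAGENE", uni, list(S = "TNF"))),
               "empty query")
})

test_that("planted-signal markers rank their set first", {
  ds <- small_synth(seed = 12, n_cells = 150, n_genes = 200)
  mt <- generate_marker_table(ds)
  planted <- attr(ds, "planted_markers")[[1]]
  set.seed(13)
  sets <- list(PLANTED = planted,
               RANDOM1 = sample(ds$gene_names, 25),
               RANDOM2 = sample(ds$gene_names, 25))
  res <- analyze_enrichment(ds, sets, replay_cfg(),
                            opts = list(marker_table = mt), max_q = Inf)
  expect_equal(res$table$set[1], "PLANTED")
  expect_s3_class(res$record, "RecommendationRecord")
})

test_that("run_task returns full provenance and parses recommend_res", {
  ds <- small_synth(seed = 14, n_cells = 80, n_genes = 100)
  rec <- run_task("recommend_res", ds, replay_cfg())
  expect_true(rec$parsed_ok)
  expect_equal(c(rec$parsed_payload$start, rec$parsed_payload$stop,
                 rec$parsed_payload$step), c(0.2, 1.2, 0.1))
  expect_match(rec$rendered_prompt, "Mean expression variability")
  expect_match(rec$raw_response, "0.868717336264306")

  # unparseable fixture: record flagged unparsed, raw preserved
  cfg <- replay_cfg(list(recommend_res = "use a moderate resolution"))
  rec2 <- run_task("recommend_res", ds, cfg)
  expect_false(rec2$parsed_ok)
  expect_null(rec2$parsed_payload)
  expect_equal(rec2$raw_response, "use a moderate resolution")
  expect_match(rec2$provenance$parse_error, "no recognizable")

  # metric preconditions propagate with task context
  bare <- tiny_dataset()
  err <- expect_error(run_task("recommend_res", bare, replay_cfg()))
  expect_match(conditionMessage(err), "recommend_res")
})

test_that("annotation write-back is atomic and optional", {
  ds <- small_synth(seed = 15, n_cells = 90, n_genes = 120)
  mt <- generate_marker_table(ds)
  cfg <- replay_cfg()

  res <- analyze_and_annotate(ds, mt, cfg, apply = FALSE)
  expect_identical(res$ds, ds)            # untouched without apply

  res2 <- analyze_and_annotate(ds, mt, cfg, apply = TRUE)
  expect_false(anyNA(res2$ds$cell_meta$cell_type_labels))
  expect_length(unique(res2$ds$cell_meta$cell_type_labels), 3)

  # corrupted fixture missing cluster 2: no write occurs
  bad <- replay_cfg(list(analyze_and_annotate =
                           "Cluster 0: NK cells\nCluster 1: T cells"))
  expect_warning(res3 <- analyze_and_annotate(ds, mt, bad, apply = TRUE),
                 "unchanged")
  expect_identical(res3$ds, ds)
  expect_false(res3$record$parsed_ok)
})

test_that("summary_network parses edges, dedups, and writes HTML", {
  enr <- recommendation_record("analyze_enrichment", "p",
                               "TNF and NFKB1 drive IL6")
  cfg <- replay_cfg(list(summary_network =
    "TNF|activates|NFKB1\nNFKB1|regulates|IL6"))
  html <- withr::local_tempfile(fileext = ".html")
  net <- summary_network(enr, cfg, html_path = html)
  expect_equal(igraph::vcount(net$graph), 3)
  expect_equal(igraph::ecount(net$graph), 2)
  expect_true(file.exists(html))
  expect_match(paste(readLines(html), collapse = ""), "NFKB1")

  # malformed lines skipped with warning; duplicates deduped
  expect_warning(
    e <- parse_network_edges("A|r|B\nA activates\nA|r|B\nB|r2|C"),
    "malformed")
  expect_equal(nrow(e), 2)

  cfg_bad <- replay_cfg(list(summary_network = "free prose, no pipes"))
  expect_error(summary_network(enr, cfg_bad), "network extraction failed")
})

test_that("empty significant enrichment yields an explicit no-signal prompt", {
  ds <- small_synth(seed = 16, n_cells = 60, n_genes = 80)
  tab <- run_ora(ds$gene_names[1:5], ds$gene_names,
                 list(S = ds$gene_names[50:60]), max_q = Inf)
  empty <- tab[tab$q < 0, , drop = FALSE]  # force zero rows
  rec <- run_task("analyze_enrichment", ds, replay_cfg(),
                  opts = list(enrichment_table = empty))
  expect_match(rec$rendered_prompt, "No significant enrichment")
})

test_that("the registry holds exactly the ten tasks", {
  reg <- task_registry()
  expect_length(reg, 10)
  expect_setequal(names(reg), task_ids())
})
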