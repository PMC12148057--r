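# shared tiny fixtures, all built in code at test time

tiny_counts <- function() {
  m <- matrix(c(0, 2, 1, 0,
                3, 0, 0, 1,
                0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), paste0("G", 1:4)))
  m
}

tiny_dataset <- function() CellDataset(tiny_counts())

small_synth <- function(seed = 11, n_cells = 120, n_genes = 200, pops = 3) {
  prepare_layers(generate_counts(synth_config(
    n_cells = n_cells, n_genes = n_genes, n_populations = pops,
    seed = seed)))
}

replay_cfg <- function(responses = list()) {
  make_replay_backend(build_fixture_store(responses))
}

write_tiny_mtx <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_counts(tiny_dataset(), dir)
  dir
}

write_tiny_gmt <- function(lines, path = withr::local_tempfile(
                             fileext = ".gmt", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# independent quantile oracle: sort and linearly interpolate (type 7)
oracle_quantile <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# independent hypergeometric upper-tail oracle by direct enumeration
oracle_hyper_tail <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# independent BH oracle: direct formula on the sorted vector with cummin
oracle_bh <- function(p) {
  m <- length(p); o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m); q[o] <- pmin(q_sorted, 1)
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
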