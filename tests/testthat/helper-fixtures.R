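# Shared fixture builders: tiny hand-specified networks, random networks for
# property tests, and a cached small generator dataset.

toy_network <- function(S, w, kind = "cellline", genes = NULL) {
  n <- length(w)
  if (is.null(genes)) genes <- LETTERS[seq_len(n)]
  dimnames(S) <- list(genes, genes)
  names(w) <- genes
  build_network(S, w, kind)
}

# random symmetric affinity in [-1, 1] on a random edge set, random weights
random_network <- function(n, density = 0.4, seed = 1, kind = "cellline") {
  set.seed(seed)
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (runif(1) < density) S[i, j] <- S[j, i] <- runif(1, -1, 1)
    }
  }
  w <- rnorm(n)
  toy_network(S, w, kind, genes = sprintf("g%02d", seq_len(n)))
}

adjusted_rand <- function(x, y) {
  t <- table(x, y)
  a <- sum(choose(t, 2))
  b <- sum(choose(rowSums(t), 2))
  c <- sum(choose(colSums(t), 2))
  n <- choose(sum(t), 2)
  (a - b * c / n) / ((b + c) / 2 - b * c / n)
}

# small generated dataset shared across tests (built once per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(generator_spec(
        n_genes = 20, n_clusters = 2, genes_per_cluster = 10,
        planted_sl_pairs = rbind(c("G003", "G007")), seed = 11))
    }
    cache
  }
})

small_ctx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      cache <<- dscn_context(sim$tumor, sim$normal, sim$cellline, sim$ess,
                             sim$ppi, seed = 1)
    }
    cache
  }
})

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
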