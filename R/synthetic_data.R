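# Synthetic dataset generator with planted structure: block-correlated
# expression (shared-factor model), a PPI scaffold respecting the blocks,
# planted essential genes, and planted synthetic-lethal pairs realized as a
# conditional essentiality shift — exactly the signal the knockdown
# subsampling is designed to detect. Every stage of the pipeline is testable
# against the planted ground truth with no downloads.

#' Specification for the synthetic dataset generator
#'
#' Defaults describe a small but realistic world: log2 microarray-like
#' expression (baseline mean 7, unit variance), within-block correlation 0.7
#' and zero between blocks, every gene mildly up-regulated in tumors
#' (log2 fold change ~ U(0.5, 1.5)), essentiality ~ N(-0.2, 0.5), PPI edge
#' densities 0.3 within and 0.02 between blocks (with a guaranteed
#' within-block spanning path), and planted SL pairs shifting each partner's
#' essentiality by `sl_effect` in the lines where the other partner is
#' below-mean essential.
#'
#' @param n_genes total genes (= `n_clusters * genes_per_cluster`).
#' @param n_clusters,genes_per_cluster planted block structure.
#' @param n_tumor,n_normal,n_cellline expression sample counts.
#' @param n_lines essentiality cell-line count.
#' @param within_block_corr,between_block_corr expression correlations.
#' @param fold_change_effects named vector: per-gene tumor log2 fold-change
#'   overrides.
#' @param essentiality_effects named vector: per-gene essentiality mean
#'   overrides (e.g. -2 for a planted highly essential gene).
#' @param planted_sl_pairs 2-column character matrix of planted SL pairs.
#' @param sl_effect conditional essentiality shift of a planted SL partner.
#' @param edge_density_within,edge_density_between PPI edge probabilities.
#' @param baseline_mean,noise_sd expression baseline and scale.
#' @param ess_mean,ess_sd essentiality baseline distribution.
#' @param seed integer seed; generation is fully reproducible.
#' @return `dscn_generator_spec` list.
#' @export
generator_spec <- function(n_genes = 30, n_clusters = 3, genes_per_cluster = 10,
                           n_tumor = 100, n_normal = 50, n_cellline = 100,
                           n_lines = 30, within_block_corr = 0.7,
                           between_block_corr = 0,
                           fold_change_effects = NULL,
                           essentiality_effects = NULL,
                           planted_sl_pairs = NULL, sl_effect = -2,
                           edge_density_within = 0.3,
                           edge_density_between = 0.02,
                           baseline_mean = 7, noise_sd = 1,
                           ess_mean = -0.2, ess_sd = 0.5, seed = 1) {
  spec <- list(n_genes = n_genes, n_clusters = n_clusters,
               genes_per_cluster = genes_per_cluster, n_tumor = n_tumor,
               n_normal = n_normal, n_cellline = n_cellline, n_lines = n_lines,
               within_block_corr = within_block_corr,
               between_block_corr = between_block_corr,
               fold_change_effects = fold_change_effects,
               essentiality_effects = essentiality_effects,
               planted_sl_pairs = planted_sl_pairs, sl_effect = sl_effect,
               edge_density_within = edge_density_within,
               edge_density_between = edge_density_between,
               baseline_mean = baseline_mean, noise_sd = noise_sd,
               ess_mean = ess_mean, ess_sd = ess_sd, seed = seed)
  if (n_clusters * genes_per_cluster != n_genes) {
    dscn_input_error("n_clusters * genes_per_cluster must equal n_genes")
  }
  for (r in c("within_block_corr", "between_block_corr")) {
    if (spec[[r]] < -1 || spec[[r]] > 1) dscn_input_error(sprintf("%s outside [-1, 1]", r))
  }
  if (between_block_corr > within_block_corr) {
    dscn_input_error("between_block_corr must not exceed within_block_corr")
  }
  for (r in c("edge_density_within", "edge_density_between")) {
    if (spec[[r]] < 0 || spec[[r]] > 1) dscn_input_error(sprintf("%s outside [0, 1]", r))
  }
  class(spec) <- "dscn_generator_spec"
  spec
}

# block-factor expression draw: within-block corr rho, between-block corr rho0
.sim_expression <- function(genes, block, n, rho, rho0, mu, sd, shift = NULL) {
  p <- length(genes)
  g <- matrix(stats::rnorm(n), 1L, n)                       # global factor
  f <- matrix(stats::rnorm(max(block) * n), max(block), n)  # block factors
  e <- matrix(stats::rnorm(p * n), p, n)
  a0 <- sqrt(max(rho0, 0))
  a1 <- sqrt(max(rho - rho0, 0))
  a2 <- sqrt(max(1 - rho, 0))
  X <- a0 * g[rep(1L, p), , drop = FALSE] + a1 * f[block, , drop = FALSE] + a2 * e
  X <- mu + sd * X
  if (!is.null(shift)) X <- X + shift
  rownames(X) <- genes
  colnames(X) <- paste0("s", seq_len(n))
  X
}

#' Generate a full synthetic dataset
#'
#' @param spec a [generator_spec()].
#' @return list (class `dscn_sim`) with elements `tumor`, `normal`,
#'   `cellline` (`dscn_expr`), `ess` (`dscn_essentiality`), `ppi`
#'   (`dscn_ppi`), `targets` (drug-target list covering all genes),
#'   `sl_truth` (2-column matrix of planted pairs), `blocks` (named integer
#'   vector of planted cluster labels), `fold_changes` (named vector of true
#'   tumor log2 fold changes), and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dscn_generator_spec"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  block <- rep(seq_len(spec$n_clusters), each = spec$genes_per_cluster)
  names(block) <- genes

  # true tumor log2 fold changes: positive baseline, per-gene overrides
  fc <- stats::runif(spec$n_genes, 0.5, 1.5)
  names(fc) <- genes
  if (!is.null(spec$fold_change_effects)) {
    ov <- spec$fold_change_effects
    bad <- setdiff(toupper(names(ov)), genes)
    if (length(bad)) dscn_input_error(sprintf("planted gene(s) outside gene set: %s", paste(bad, collapse = ", ")))
    fc[toupper(names(ov))] <- as.numeric(ov)
  }

  normal <- .sim_expression(genes, block, spec$n_normal, spec$within_block_corr,
                            spec$between_block_corr, spec$baseline_mean, spec$noise_sd)
  tumor <- .sim_expression(genes, block, spec$n_tumor, spec$within_block_corr,
                           spec$between_block_corr, spec$baseline_mean, spec$noise_sd,
                           shift = fc)
  cellline <- .sim_expression(genes, block, spec$n_cellline, spec$within_block_corr,
                              spec$between_block_corr, spec$baseline_mean, spec$noise_sd)
  colnames(cellline) <- paste0("CL", seq_len(spec$n_cellline))

  # essentiality: per-gene mean (overridable), line-level noise
  ess_mu <- rep(spec$ess_mean, spec$n_genes)
  names(ess_mu) <- genes
  if (!is.null(spec$essentiality_effects)) {
    ov <- spec$essentiality_effects
    bad <- setdiff(toupper(names(ov)), genes)
    if (length(bad)) dscn_input_error(sprintf("planted gene(s) outside gene set: %s", paste(bad, collapse = ", ")))
    ess_mu[toupper(names(ov))] <- as.numeric(ov)
  }
  E <- ess_mu + matrix(stats::rnorm(spec$n_genes * spec$n_lines, 0, spec$ess_sd),
                       spec$n_genes, spec$n_lines)
  rownames(E) <- genes
  colnames(E) <- paste0("LINE", seq_len(spec$n_lines))

  # planted SL pairs (x = anchor, y = partner): y's essentiality is shifted by
  # sl_effect in the anchor-low lines and recentred so y's marginal stays at
  # baseline — synthetic lethality is a conditional signal, invisible in the
  # marginal screen and revealed only by the knockdown subsampling
  sl <- spec$planted_sl_pairs
  if (!is.null(sl)) {
    sl <- matrix(toupper(as.matrix(sl)), ncol = 2L)
    bad <- setdiff(as.vector(sl), genes)
    if (length(bad)) dscn_input_error(sprintf("planted SL gene(s) outside gene set: %s", paste(bad, collapse = ", ")))
    E0 <- E
    for (r in seq_len(nrow(sl))) {
      x <- sl[r, 1L]; y <- sl[r, 2L]
      low_x <- E0[x, ] < mean(E0[x, ])
      E[y, ] <- E[y, ] + spec$sl_effect * (as.numeric(low_x) - mean(low_x))
    }
  } else {
    sl <- matrix(character(0), 0L, 2L)
  }
  colnames(sl) <- c("geneA", "geneB")

  # PPI scaffold: spanning path within each block plus random edges
  ea <- character(0); eb <- character(0)
  for (k in seq_len(spec$n_clusters)) {
    memb <- genes[block == k]
    ea <- c(ea, memb[-length(memb)])
    eb <- c(eb, memb[-1L])
  }
  for (i in seq_len(spec$n_genes - 1L)) {
    for (j in seq((i + 1L), spec$n_genes)) {
      dens <- if (block[i] == block[j]) spec$edge_density_within else spec$edge_density_between
      if (stats::runif(1) < dens) { ea <- c(ea, genes[i]); eb <- c(eb, genes[j]) }
    }
  }
  score <- round(stats::runif(length(ea), 400, 999))
  ppi <- ppi_edge_list(ea, eb, score)

  targets <- stats::setNames(as.list(genes), paste0("DRUG_", genes))

  structure(list(
    tumor = expression_matrix(tumor, "tumor"),
    normal = expression_matrix(normal, "normal"),
    cellline = expression_matrix(cellline, "cellline"),
    ess = essentiality_table(E),
    ppi = ppi, targets = targets, sl_truth = sl,
    blocks = block, fold_changes = fc, spec = spec
  ), class = "dscn_sim")
}

#' Write a generated dataset to standard-format files
#'
#' Emits the plain-text files the readers consume: tumor/normal/cell-line
#' expression TSVs, an essentiality TSV, a STRING-style PPI edge list, a
#' drug-target map and the planted SL pair list.
#'
#' @param sim a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "dscn_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    tumor = file.path(dir, "tumor_expr.tsv"),
    normal = file.path(dir, "normal_expr.tsv"),
    cellline = file.path(dir, "cellline_expr.tsv"),
    ess = file.path(dir, "essentiality.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    targets = file.path(dir, "targets.tsv"),
    sl = file.path(dir, "sl_pairs.tsv"))
  write_expression(sim$tumor, paths["tumor"])
  write_expression(sim$normal, paths["normal"])
  write_expression(sim$cellline, paths["cellline"])
  df <- data.frame(gene = sim$ess$genes, sim$ess$values, check.names = FALSE)
  utils::write.table(df, paths["ess"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(protein1 = sim$ppi$geneA, protein2 = sim$ppi$geneB,
               combined_score = sim$ppi$score),
    paths["ppi"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(drug_id = rep(names(sim$targets), lengths(sim$targets)),
               gene = unlist(sim$targets, use.names = FALSE)),
    paths["targets"], sep = "\t", quote = FALSE, row.names = FALSE)
  sl <- if (nrow(sim$sl_truth)) {
    data.frame(geneA = sim$sl_truth[, 1L], geneB = sim$sl_truth[, 2L], sl_score = 1)
  } else data.frame(geneA = character(0), geneB = character(0), sl_score = numeric(0))
  utils::write.table(sl, paths["sl"], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
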