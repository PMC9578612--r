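# First-target knockdown by subsampling (drop samples/lines where the target
# is at or above its mean), conditional second-target scoring on the rebuilt
# cell-line network, the additive pair score IS(T1,T2) = IS(T1) + IS(T2|T1),
# the synergy rule IS(T1,T2) < IS(T1) + IS(T2), and ranking over a druggable
# target universe.

#' Knockdown subsample of a first target
#'
#' Models knockdown of `target`: keeps expression samples with the target's
#' expression strictly below its sample mean, and (independently)
#' essentiality lines with the target's essentiality strictly below its line
#' mean.
#'
#' @param expr_c cell-line `dscn_expr`.
#' @param ess `dscn_essentiality` table, or NULL to subsample expression only
#'   (the per-sample DSCNi mode).
#' @param target gene symbol present in both sources.
#' @param min_samples minimum retained count per source (default 3).
#' @return list with `target`, `kept_expression_samples`,
#'   `kept_essentiality_lines` (NULL when `ess` is NULL), `thresholds`.
#' @export
subsample_knockdown <- function(expr_c, ess, target, min_samples = 3) {
  target <- toupper(target)
  if (!target %in% expr_c$genes) {
    dscn_input_error(sprintf("target %s not in cell-line expression", target))
  }
  v <- expr_c$values[target, ]
  mu_e <- mean(v, na.rm = TRUE)
  keep_s <- expr_c$samples[!is.na(v) & v < mu_e]
  if (length(keep_s) < min_samples) {
    dscn_degenerate_error(sprintf(
      "knockdown subsample of %s keeps %d expression sample(s) (< %d)",
      target, length(keep_s), min_samples))
  }
  keep_l <- NULL
  mu_s <- NA_real_
  if (!is.null(ess)) {
    if (!target %in% ess$genes) {
      dscn_input_error(sprintf("target %s not in essentiality table", target))
    }
    u <- ess$values[target, ]
    mu_s <- mean(u, na.rm = TRUE)
    keep_l <- ess$cell_lines[!is.na(u) & u < mu_s]
    if (length(keep_l) < min_samples) {
      dscn_degenerate_error(sprintf(
        "knockdown subsample of %s keeps %d essentiality line(s) (< %d)",
        target, length(keep_l), min_samples))
    }
  }
  list(target = target, kept_expression_samples = keep_s,
       kept_essentiality_lines = keep_l,
       thresholds = c(expression = mu_e, essentiality = mu_s))
}

#' Conditional cell-line network after first-target knockdown
#'
#' Rebuilds the cell-line network with edge correlations over the kept
#' expression samples and node weights averaged over the kept essentiality
#' lines.
#'
#' @param expr_c cell-line `dscn_expr`.
#' @param ess `dscn_essentiality`.
#' @param skeleton `dscn_ppi`.
#' @param sub a [subsample_knockdown()] result.
#' @param genes gene universe.
#' @return `dscn_network`.
#' @export
conditional_network <- function(expr_c, ess, skeleton, sub, genes) {
  S <- correlation_affinity(.subset_expr(expr_c, sub$kept_expression_samples),
                            skeleton, genes)
  w <- cellline_node_weights(ess, sub$kept_essentiality_lines, genes)
  build_network(S, w, "cellline")
}

#' Conditional impact score IS(T2 | T1)
#'
#' Scores the second target on the conditional network, mapped through the
#' same tissue clustering (the tissue side is never re-clustered).
#'
#' @param net_sub conditional `dscn_network`.
#' @param t2 second target gene.
#' @param scheme,scope,assign,cfg as in [impact_score()].
#' @return numeric score.
#' @export
conditional_score <- function(net_sub, t2, scheme = "diffusion", scope = "local",
                              assign = NULL, cfg = list()) {
  impact_score(net_sub, t2, scheme, scope, assign, cfg)$value
}

#' Score an ordered-target pair both ways
#'
#' Evaluates IS(t1) + IS(t2|t1) and IS(t2) + IS(t1|t2) and reports the smaller
#' (more impactful) order as the pair score; `t1`/`t2` in the result name the
#' winning order, so `is_pair = is_t1 + is_t2_given_t1` always holds. The pair
#' is synergistic when IS(T1,T2) < IS(T1) + IS(T2), equivalently
#' IS(T2|T1) < IS(T2).
#'
#' @param ctx `dscn_context`.
#' @param t1,t2 distinct target genes in the context's network.
#' @return one-row data.frame (class `dscn_pair`) with columns `gene1, gene2`
#'   (unordered, sorted), `t1, t2` (winning order), `is_t1, is_t2_given_t1,
#'   is_pair, is_t1_marginal, is_t2_marginal, synergy`, plus both ordered
#'   scores `order12, order21`.
#' @export
score_pair <- function(ctx, t1, t2) {
  stopifnot(inherits(ctx, "dscn_context"))
  t1 <- toupper(t1); t2 <- toupper(t2)
  if (t1 == t2) dscn_input_error("pair targets must be distinct")
  for (t in c(t1, t2)) {
    if (!t %in% ctx$genes) dscn_input_error(sprintf("target %s not in network", t))
  }
  a <- min(t1, t2); b <- max(t1, t2)
  m_a <- .ctx_marginal_is(ctx, a)$value
  m_b <- .ctx_marginal_is(ctx, b)$value
  c_b_a <- conditional_score(.ctx_conditional_net(ctx, a), b, ctx$scheme,
                             ctx$scope, ctx$assign, .ctx_cfg(ctx, b))
  c_a_b <- conditional_score(.ctx_conditional_net(ctx, b), a, ctx$scheme,
                             ctx$scope, ctx$assign, .ctx_cfg(ctx, a))
  o_ab <- m_a + c_b_a   # a first, then b
  o_ba <- m_b + c_a_b
  if (o_ab <= o_ba) {
    first <- a; second <- b; is1 <- m_a; is2g1 <- c_b_a; is2m <- m_b
  } else {
    first <- b; second <- a; is1 <- m_b; is2g1 <- c_a_b; is2m <- m_a
  }
  out <- data.frame(
    gene1 = a, gene2 = b, t1 = first, t2 = second,
    is_t1 = is1, is_t2_given_t1 = is2g1, is_pair = is1 + is2g1,
    is_t1_marginal = if (first == a) m_a else m_b,
    is_t2_marginal = is2m,
    synergy = (is1 + is2g1) < (is1 + is2m),
    order12 = o_ab, order21 = o_ba,
    stringsAsFactors = FALSE)
  class(out) <- c("dscn_pair", "data.frame")
  out
}

#' Rank all target pairs by combined impact score
#'
#' Scores every unordered pair over the druggable target universe and sorts
#' ascending by `is_pair` (the impact score usually takes negative values; the
#' smaller, the more impactful), with a lexicographic tiebreak. Pairs whose
#' knockdown subsample is degenerate (a flat target) are skipped with a
#' warning.
#'
#' @param ctx `dscn_context`.
#' @param targets character vector of target genes, or a drug-target list as
#'   from [read_targets()] (the union of its gene sets is used).
#' @return data.frame of scored pairs (columns of [score_pair()] plus
#'   `IS_T1, IS_T2_given_T1, IS_pair` aliases), ordered ascending.
#' @export
rank_all_pairs <- function(ctx, targets) {
  stopifnot(inherits(ctx, "dscn_context"))
  if (is.list(targets)) targets <- unique(unlist(targets, use.names = FALSE))
  targets <- sort(intersect(toupper(targets), ctx$genes))
  if (length(targets) < 2L) dscn_input_error("fewer than 2 usable targets in the network")
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(length(targets) - 1L)) {
    for (j in seq((i + 1L), length(targets))) {
      r <- tryCatch(score_pair(ctx, targets[i], targets[j]),
                    dscn_degenerate_error = function(e) NULL)
      if (is.null(r)) {
        skipped <- c(skipped, paste(targets[i], targets[j], sep = "-"))
      } else rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(skipped)) {
    dscn_warn(sprintf("%d pair(s) skipped for degenerate knockdown subsamples", length(skipped)))
  }
  if (length(rows) == 0L) dscn_input_error("no scorable target pair")
  out <- do.call(rbind, rows)
  out <- out[order(out$is_pair, out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out$IS_T1 <- out$is_t1
  out$IS_T2_given_T1 <- out$is_t2_given_t1
  out$IS_pair <- out$is_pair
  class(out) <- c("dscn_pair_ranking", "data.frame")
  out
}

#' Predicted knockdown fold changes of neighbor genes
#'
#' The subsampling-validation computation: samples are split at the target's
#' mean expression, and each neighbor gene's predicted log2 fold change under
#' target knockdown is its mean in the low-target group minus its mean in the
#' high-target group.
#'
#' @param expr `dscn_expr`.
#' @param target gene symbol.
#' @param neighbors gene symbols (subset of `expr$genes`).
#' @return named numeric vector of predicted log2 fold changes.
#' @export
predicted_knockdown_foldchange <- function(expr, target, neighbors) {
  target <- toupper(target); neighbors <- toupper(neighbors)
  if (!target %in% expr$genes) dscn_input_error(sprintf("target %s not in expression", target))
  miss <- setdiff(neighbors, expr$genes)
  if (length(miss)) dscn_input_error(sprintf("neighbor gene(s) missing: %s", paste(miss, collapse = ", ")))
  v <- expr$values[target, ]
  low <- !is.na(v) & v < mean(v, na.rm = TRUE)
  high <- !low & !is.na(v)
  if (!any(low) || !any(high)) dscn_degenerate_error("empty low/high group at the target mean")
  lfc <- rowMeans(expr$values[neighbors, low, drop = FALSE], na.rm = TRUE) -
    rowMeans(expr$values[neighbors, high, drop = FALSE], na.rm = TRUE)
  stats::setNames(lfc, neighbors)
}

#' Double-knockout combination count
#'
#' Number of gRNA-pair combinations when screening `n_genes` genes with
#' `grnas_per_gene` guides each: (grnas_per_gene * n_genes)^2 / 2.
#'
#' @param n_genes,grnas_per_gene positive integers.
#' @return combination count (floored with a warning if fractional).
#' @export
combination_count <- function(n_genes, grnas_per_gene) {
  if (length(n_genes) != 1L || length(grnas_per_gene) != 1L ||
      !is.finite(n_genes) || !is.finite(grnas_per_gene) ||
      n_genes <= 0 || grnas_per_gene <= 0 ||
      n_genes %% 1 != 0 || grnas_per_gene %% 1 != 0) {
    dscn_input_error("n_genes and grnas_per_gene must be positive integers")
  }
  x <- (grnas_per_gene * n_genes)^2 / 2
  if (x %% 1 != 0) {
    dscn_warn(sprintf("fractional combination count %.1f floored", x))
    x <- floor(x)
  }
  x
}
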