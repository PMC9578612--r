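# The analysis context bundles the shared gene universe, the tissue and
# cell-line networks, the tissue spectral clustering, and the scoring
# configuration, plus a cache of per-target conditional networks so ranking
# all pairs stays O(#targets) network rebuilds.

#' Build a DSCN analysis context
#'
#' Intersects the gene universes of all inputs with the PPI skeleton, builds
#' the tissue network (tumor-sample correlations on PPI edges, tumor-vs-normal
#' log2 fold-change node weights) and the cell-line network (cell-line
#' correlations, mean log2 essentiality node weights), normalizes the tissue
#' Laplacian and spectrally clusters it.
#'
#' @param tumor,normal,cellline `dscn_expr` objects.
#' @param ess `dscn_essentiality` table.
#' @param skeleton `dscn_ppi` edge list.
#' @param lines cell lines used for node weights (default all).
#' @param scheme,scope default scoring configuration (`"diffusion"`,
#'   `"local"` — the configuration that best separates known synthetic-lethal
#'   pairs).
#' @param k_max,hartigan_threshold,kmeans_restarts spectral clustering knobs.
#' @param seed integer seed driving K-means and random walks.
#' @param min_samples minimum retained samples/lines in a knockdown subsample.
#' @param walk_steps random-walk length override (default 2n).
#' @param diffusion_ratio use the ratio reading of the diffusion tier term.
#' @return `dscn_context` object.
#' @export
dscn_context <- function(tumor, normal, cellline, ess, skeleton,
                         lines = NULL, scheme = "diffusion", scope = "local",
                         k_max = 10, hartigan_threshold = 10,
                         kmeans_restarts = 10, seed = 1, min_samples = 3,
                         walk_steps = NULL, diffusion_ratio = FALSE) {
  stopifnot(inherits(tumor, "dscn_expr"), inherits(normal, "dscn_expr"),
            inherits(cellline, "dscn_expr"), inherits(ess, "dscn_essentiality"),
            inherits(skeleton, "dscn_ppi"))
  ppi_genes <- union(skeleton$geneA, skeleton$geneB)
  genes <- Reduce(intersect, list(tumor$genes, normal$genes, cellline$genes,
                                  ess$genes, ppi_genes))
  genes <- sort(genes)
  if (length(genes) < 2L) dscn_input_error("fewer than 2 genes shared across all inputs")

  S_t <- correlation_affinity(tumor, skeleton, genes)
  w_t <- tissue_node_weights(tumor, normal, genes)
  net_t <- build_network(S_t, w_t, "tissue")

  S_c <- correlation_affinity(cellline, skeleton, genes)
  w_c <- cellline_node_weights(ess, lines, genes)
  net_c <- build_network(S_c, w_c, "cellline")

  lapN_t <- normalize_laplacian(laplacian(net_t))
  assign <- spectral_cluster(lapN_t, k_max = k_max, threshold = hartigan_threshold,
                             restarts = kmeans_restarts, seed = seed)

  structure(list(
    genes = genes, tumor = tumor, normal = normal, cellline = cellline,
    ess = ess, skeleton = skeleton, lines = lines,
    net_t = net_t, net_c = net_c, lapN_t = lapN_t, assign = assign,
    scheme = scheme, scope = scope, seed = seed, min_samples = min_samples,
    walk_steps = walk_steps, diffusion_ratio = diffusion_ratio,
    mode = "dscn", line = NULL,
    cache = new.env(parent = emptyenv())
  ), class = "dscn_context")
}

#' Per-sample (DSCNi) analysis context
#'
#' Same construction as [dscn_context()] but the cell-line node weights are a
#' single line's essentiality vector, which stays fixed during conditional
#' scoring (only the expression panel is subsampled to model knockdown).
#'
#' @param line cell-line id whose essentiality vector supplies node weights.
#' @inheritParams dscn_context
#' @return `dscn_context` with `mode = "dscni"`.
#' @export
dscni_context <- function(tumor, normal, cellline, ess, skeleton, line, ...) {
  if (!line %in% ess$cell_lines) {
    dscn_input_error(sprintf("cell line %s not in essentiality table", line))
  }
  ctx <- dscn_context(tumor, normal, cellline, ess, skeleton, lines = line, ...)
  ctx$mode <- "dscni"
  ctx$line <- line
  ctx
}

# scoring configuration for a given target (deterministic walk seed per gene)
.ctx_cfg <- function(ctx, target) {
  list(walk_steps = ctx$walk_steps,
       walk_seed = ctx$seed + match(target, ctx$genes),
       diffusion_ratio = ctx$diffusion_ratio)
}

.ctx_marginal_is <- function(ctx, target) {
  key <- paste0("m.", target)
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  is <- impact_score(ctx$net_c, target, ctx$scheme, ctx$scope, ctx$assign,
                     .ctx_cfg(ctx, target))
  ctx$cache[[key]] <- is
  is
}

.ctx_conditional_net <- function(ctx, t1) {
  key <- paste0("c.", t1)
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  net <- if (ctx$mode == "dscni") {
    sub <- subsample_knockdown(ctx$cellline, NULL, t1, ctx$min_samples)
    S <- correlation_affinity(
      .subset_expr(ctx$cellline, sub$kept_expression_samples),
      ctx$skeleton, ctx$genes)
    build_network(S, ctx$net_c$w, "cellline")
  } else {
    sub <- subsample_knockdown(ctx$cellline, ctx$ess, t1, ctx$min_samples)
    conditional_network(ctx$cellline, ctx$ess, ctx$skeleton, sub, ctx$genes)
  }
  ctx$cache[[key]] <- net
  net
}

.subset_expr <- function(expr, samples) {
  expression_matrix(expr$values[, samples, drop = FALSE], expr$condition)
}
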