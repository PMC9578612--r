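# DSCNi: the per-sample variant. Node weights are a single cell line's (or
# patient's) essentiality vector, which stays fixed during conditional
# scoring; first-target knockdown only subsamples the background expression
# panel used for edge correlations.

#' Rank target pairs for a single cell line (DSCNi)
#'
#' Builds a per-sample context with [dscni_context()] and ranks all target
#' pairs with the same formulas and scale as the cohort-level method, so
#' scores are directly comparable (on a one-line essentiality table DSCNi
#' equals the cohort method restricted to that line, up to the essentiality
#' half of the knockdown subsample, which a single line cannot support).
#'
#' @inheritParams dscni_context
#' @param targets target gene vector or drug-target list.
#' @param ... passed to [dscni_context()] (scheme, scope, seed, ...).
#' @return list with `ranking` (data.frame as [rank_all_pairs()]) and `ctx`.
#' @export
dscni_rank_pairs <- function(tumor, normal, cellline, ess, skeleton, line,
                             targets, ...) {
  ctx <- dscni_context(tumor, normal, cellline, ess, skeleton, line, ...)
  list(ranking = rank_all_pairs(ctx, targets), ctx = ctx)
}
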