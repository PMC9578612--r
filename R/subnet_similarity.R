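# Tissue vs cell-line subnetwork similarity: node-weight trace matching,
# edge renormalization by node weight, and a squared off-diagonal distance
# between the two normalized Laplacians. Reported as a diagnostic table; it
# does not gate pair scoring.

#' Scale cell-line node weights to match the tissue trace
#'
#' Each cell-line node weight is multiplied by
#' sum(tissue weights) / sum(cell-line weights) so both diagonals have equal
#' trace.
#'
#' @param d_tissue,d_cellline numeric vectors of equal length.
#' @return scaled cell-line vector.
#' @export
match_node_weights <- function(d_tissue, d_cellline) {
  if (length(d_tissue) != length(d_cellline)) dscn_input_error("node weight length mismatch")
  s_c <- sum(d_cellline)
  if (abs(s_c) < 1e-12) dscn_input_error("cell-line node weights sum to zero; cannot scale")
  d_cellline * (sum(d_tissue) / s_c)
}

#' Renormalize Laplacian edge weights by node weight
#'
#' Off-diagonal (j, l) becomes w_jl * |w_j| / sum_x |w_jx|, preserving the
#' sign of the original edge weight; the diagonal is kept. Rows without edges
#' keep zero off-diagonals.
#'
#' @param lap unnormalized `dscn_laplacian` (off-diagonals hold -w_jl).
#' @return matrix L'' with signed renormalized edge weights off the diagonal
#'   and node weights on the diagonal.
#' @export
renormalize_edges <- function(lap) {
  stopifnot(inherits(lap, "dscn_laplacian"))
  S <- -lap$L
  diag(S) <- 0
  n <- nrow(S)
  out <- matrix(0, n, n, dimnames = dimnames(lap$L))
  zero_row <- FALSE
  for (j in seq_len(n)) {
    rs <- sum(abs(S[j, ]))
    if (rs == 0) { zero_row <- TRUE; next }
    out[j, ] <- S[j, ] * abs(lap$w[j]) / rs
  }
  if (zero_row) dscn_warn("row(s) with no edges kept zero off-diagonals")
  diag(out) <- lap$w
  out
}

#' Distance between two renormalized subnetwork Laplacians
#'
#' Sum over all off-diagonal cells (j, l), l != j, of the squared difference;
#' the diagonal is excluded, and no square root is taken.
#'
#' @param l_tissue,l_cellline matrices from [renormalize_edges()] over the
#'   same gene order.
#' @return non-negative distance.
#' @export
subnetwork_distance <- function(l_tissue, l_cellline) {
  if (!all(dim(l_tissue) == dim(l_cellline))) dscn_input_error("matrix shape mismatch")
  D <- (l_tissue - l_cellline)^2
  diag(D) <- 0
  sum(D)
}

#' Tissue/cell-line similarity table over all spectral clusters
#'
#' For each cluster: scales the cell-line node weights to the tissue trace,
#' renormalizes both Laplacians' edges, and reports the off-diagonal distance.
#' Clusters whose cell-line weights sum to ~0 are reported with NA distance.
#'
#' @param ctx `dscn_context`.
#' @return data.frame with columns `cluster`, `n_genes`, `distance`.
#' @export
subnet_similarity_table <- function(ctx) {
  stopifnot(inherits(ctx, "dscn_context"))
  out <- data.frame(cluster = seq_len(ctx$assign$K_prime), n_genes = NA_integer_,
                    distance = NA_real_)
  for (i in seq_len(ctx$assign$K_prime)) {
    genes <- ctx$assign$genes[ctx$assign$labels == i]
    out$n_genes[i] <- length(genes)
    sub_t <- induce_subnetwork(ctx$net_t, genes)
    sub_c <- induce_subnetwork(ctx$net_c, genes)
    w_c <- tryCatch(match_node_weights(sub_t$w, sub_c$w),
                    dscn_input_error = function(e) NULL)
    if (is.null(w_c)) next
    lt <- laplacian(sub_t)
    lc <- laplacian(build_network(sub_c$S, w_c, "cellline"))
    out$distance[i] <- subnetwork_distance(
      suppressWarnings(renormalize_edges(lt)),
      suppressWarnings(renormalize_edges(lc)))
  }
  out
}
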