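# Construction of the tissue network G_t and cell-line network G_c on the
# shared PPI skeleton: G = S + D with S the affinity matrix of PPI-edge
# Pearson correlations and D the diagonal of node weights (tumor/normal log2
# fold change for tissue; mean log2 essentiality for cell lines), plus the
# Laplacian L = D - S and its row normalization used for spectral clustering.

.adjacency_from_ppi <- function(skeleton, genes) {
  n <- length(genes)
  A <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  keep <- skeleton$geneA %in% genes & skeleton$geneB %in% genes
  if (any(keep)) {
    ia <- match(skeleton$geneA[keep], genes)
    ib <- match(skeleton$geneB[keep], genes)
    A[cbind(ia, ib)] <- TRUE
    A[cbind(ib, ia)] <- TRUE
  }
  A
}

#' Correlation affinity matrix on a PPI skeleton
#'
#' Pearson correlations between gene pairs over samples, restricted to PPI
#' edges; all non-edge entries are zero. Zero-variance genes yield edge weight
#' 0 (with a warning) rather than NaN.
#'
#' @param expr a `dscn_expr` object (>= 3 samples).
#' @param skeleton a `dscn_ppi` edge list.
#' @param genes ordered gene symbols (subset of `expr$genes`).
#' @return n x n symmetric numeric matrix with zero diagonal.
#' @export
correlation_affinity <- function(expr, skeleton, genes) {
  stopifnot(inherits(expr, "dscn_expr"))
  genes <- toupper(genes)
  if (length(expr$samples) < 3L) dscn_input_error("need >= 3 samples for correlations")
  missing <- setdiff(genes, expr$genes)
  if (length(missing)) {
    dscn_input_error(sprintf("genes absent from expression data: %s",
                             paste(utils::head(missing, 5L), collapse = ", ")))
  }
  X <- expr$values[genes, , drop = FALSE]
  C <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
  if (anyNA(C)) {
    dscn_warn("zero-variance gene(s): affected edge weights set to 0")
    C[is.na(C)] <- 0
  }
  A <- .adjacency_from_ppi(skeleton, genes)
  S <- C * A
  diag(S) <- 0
  S
}

#' Tissue node weights: tumor vs normal log2 fold change
#'
#' w_i = mean log2 expression in tumors minus mean in normals; positive means
#' up-regulated in the tumor.
#'
#' @param tumor,normal `dscn_expr` objects covering `genes`.
#' @param genes gene symbols.
#' @return named numeric vector.
#' @export
tissue_node_weights <- function(tumor, normal, genes) {
  genes <- toupper(genes)
  miss <- union(setdiff(genes, tumor$genes), setdiff(genes, normal$genes))
  if (length(miss)) {
    dscn_input_error(sprintf("genes missing from tumor/normal expression: %s",
                             paste(utils::head(miss, 10L), collapse = ", ")))
  }
  w <- rowMeans(tumor$values[genes, , drop = FALSE], na.rm = TRUE) -
    rowMeans(normal$values[genes, , drop = FALSE], na.rm = TRUE)
  names(w) <- genes
  w
}

#' Cell-line node weights: mean log2 essentiality
#'
#' More negative = more essential (cell count drops after knockout).
#'
#' @param ess an `dscn_essentiality` table.
#' @param lines cell-line ids to average over (default all).
#' @param genes gene symbols.
#' @return named numeric vector.
#' @export
cellline_node_weights <- function(ess, lines = NULL, genes = ess$genes) {
  stopifnot(inherits(ess, "dscn_essentiality"))
  genes <- toupper(genes)
  if (is.null(lines)) lines <- ess$cell_lines
  if (length(lines) == 0L) dscn_degenerate_error("empty cell-line set for node weights")
  bad <- setdiff(lines, ess$cell_lines)
  if (length(bad)) dscn_input_error(sprintf("unknown cell line(s): %s", paste(bad, collapse = ", ")))
  miss <- setdiff(genes, ess$genes)
  if (length(miss)) {
    dscn_input_error(sprintf("genes missing from essentiality table: %s",
                             paste(utils::head(miss, 10L), collapse = ", ")))
  }
  w <- rowMeans(ess$values[genes, lines, drop = FALSE], na.rm = TRUE)
  names(w) <- genes
  w
}

#' Assemble a weighted network G = S + D
#'
#' @param affinity symmetric affinity matrix with zero diagonal (gene dimnames).
#' @param node_weights named numeric vector aligned with `affinity`.
#' @param kind `"tissue"` or `"cellline"`.
#' @return `dscn_network` object with fields `genes`, `S`, `w`, `kind`.
#' @export
build_network <- function(affinity, node_weights, kind = c("tissue", "cellline")) {
  kind <- match.arg(kind)
  if (!is.matrix(affinity) || nrow(affinity) != ncol(affinity)) {
    dscn_input_error("affinity must be a square matrix")
  }
  if (length(node_weights) != nrow(affinity)) dscn_input_error("node weight length mismatch")
  if (max(abs(affinity - t(affinity))) > 1e-9) dscn_internal_error("affinity matrix not symmetric")
  if (any(diag(affinity) != 0)) dscn_internal_error("affinity diagonal must be zero")
  if (max(abs(affinity)) > 1 + 1e-9) dscn_internal_error("affinity entries must be in [-1, 1]")
  if (any(!is.finite(node_weights))) dscn_input_error("non-finite node weight")
  genes <- rownames(affinity)
  if (is.null(genes)) dscn_input_error("affinity needs gene dimnames")
  if (!is.null(names(node_weights)) && !identical(names(node_weights), genes)) {
    node_weights <- node_weights[genes]
    if (anyNA(node_weights)) dscn_input_error("node weights do not cover all genes")
  }
  names(node_weights) <- genes
  structure(list(genes = genes, S = affinity, w = node_weights, kind = kind),
            class = "dscn_network")
}

#' Induced subnetwork on a gene subset
#'
#' @param net `dscn_network`.
#' @param genes subset of `net$genes`.
#' @return `dscn_network` on `genes` keeping only internal edges.
#' @export
induce_subnetwork <- function(net, genes) {
  stopifnot(inherits(net, "dscn_network"))
  miss <- setdiff(genes, net$genes)
  if (length(miss)) dscn_input_error(sprintf("genes not in network: %s", paste(miss, collapse = ", ")))
  build_network(net$S[genes, genes, drop = FALSE], net$w[genes], net$kind)
}

#' Laplacian matrix L = D - S
#'
#' @param net `dscn_network`.
#' @return `dscn_laplacian` object with fields `genes`, `L`, `w`, `normalized`.
#' @export
laplacian <- function(net) {
  stopifnot(inherits(net, "dscn_network"))
  L <- diag(net$w, nrow = length(net$w)) - net$S
  dimnames(L) <- list(net$genes, net$genes)
  structure(list(genes = net$genes, L = L, w = net$w, normalized = FALSE),
            class = "dscn_laplacian")
}

#' Row-normalized Laplacian
#'
#' Keeps the signed node weight w_i on the diagonal and sets off-diagonal
#' (i, j) to -|w_ij * w_i| / sum_k |w_ik|, so that for every connected row the
#' absolute off-diagonal sum equals the absolute diagonal. Rows without edges
#' keep zero off-diagonals.
#'
#' @param lap an unnormalized `dscn_laplacian`.
#' @param node_weights optional replacement node weights (defaults to the
#'   weights stored in `lap`).
#' @return normalized `dscn_laplacian`.
#' @export
normalize_laplacian <- function(lap, node_weights = lap$w) {
  stopifnot(inherits(lap, "dscn_laplacian"))
  if (isTRUE(lap$normalized)) dscn_input_error("Laplacian already normalized")
  n <- length(lap$genes)
  S <- -lap$L
  diag(S) <- 0
  Ln <- matrix(0, n, n, dimnames = list(lap$genes, lap$genes))
  isolated <- FALSE
  for (i in seq_len(n)) {
    rs <- sum(abs(S[i, ]))
    if (rs == 0) { isolated <- TRUE; next }
    Ln[i, ] <- -abs(S[i, ] * node_weights[i]) / rs
  }
  if (isolated) dscn_warn("row(s) with no edges: off-diagonals left at zero")
  diag(Ln) <- node_weights
  structure(list(genes = lap$genes, L = Ln, w = node_weights, normalized = TRUE),
            class = "dscn_laplacian")
}
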