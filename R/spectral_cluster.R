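# Spectral clustering of the normalized tissue Laplacian into K' <= 10
# subnetworks, with Hartigan's statistic guiding the choice of K, and mapping
# of the tissue clusters onto the cell-line network by shared node names.

#' Eigendecomposition of a normalized Laplacian
#'
#' The row-normalized Laplacian is asymmetric; by default its symmetric part
#' (L' + t(L'))/2 is decomposed so the spectrum is real. The embedding H holds
#' the eigenvectors of the k smallest eigenvalues. The model assumes a
#' non-negative spectrum (0 = lambda_1 <= ... <= lambda_n); with signed node
#' weights the symmetrized operator can push the near-null cluster-indicator
#' directions slightly negative, so by default small negative eigenvalues stay
#' eligible (dropping them discards exactly the informative directions).
#' `drop_negative = TRUE` restores the strict rule: negatives are excluded
#' from selection and an error is raised if fewer than k non-negative
#' eigenvalues remain.
#'
#' @param lapN normalized `dscn_laplacian`.
#' @param k number of eigenvectors to keep (1 <= k <= n).
#' @param symmetrize decompose the symmetric part (default TRUE); if FALSE the
#'   raw matrix is decomposed and real parts are taken. For positive node
#'   weights the raw operator is similar to a symmetric PSD matrix, so its
#'   spectrum is real and non-negative, but its first eigenvector is the
#'   constant vector.
#' @param drop_negative exclude negative eigenvalues from selection.
#' @return list with `genes`, `eigenvalues` (full ascending spectrum),
#'   `selected` (the k kept eigenvalues, tiny negatives clamped to 0), and
#'   `H` (n x k matrix).
#' @export
eigendecompose <- function(lapN, k, symmetrize = TRUE, drop_negative = FALSE) {
  stopifnot(inherits(lapN, "dscn_laplacian"))
  if (!isTRUE(lapN$normalized)) dscn_input_error("eigendecompose expects a normalized Laplacian")
  n <- length(lapN$genes)
  if (k < 1L || k > n) dscn_input_error(sprintf("k = %d outside 1..%d", k, n))
  if (symmetrize) {
    M <- (lapN$L + t(lapN$L)) / 2
    ee <- eigen(M, symmetric = TRUE)
    vals <- rev(ee$values)
    vecs <- ee$vectors[, rev(seq_len(n)), drop = FALSE]
  } else {
    ee <- eigen(lapN$L)
    ord <- order(Re(ee$values))
    vals <- Re(ee$values)[ord]
    vecs <- Re(ee$vectors)[, ord, drop = FALSE]
  }
  tol <- 1e-8 * max(1, max(abs(vals)))
  if (drop_negative) {
    eligible <- which(vals >= -tol)
    if (length(eligible) < k) {
      dscn_input_error(sprintf("only %d non-negative eigenvalues available, need %d",
                               length(eligible), k))
    }
  } else {
    eligible <- seq_along(vals)
  }
  sel <- eligible[seq_len(k)]
  H <- vecs[, sel, drop = FALSE]
  rownames(H) <- lapN$genes
  selected <- vals[sel]
  selected[selected < 0 & selected >= -tol] <- 0
  list(genes = lapN$genes, eigenvalues = vals, selected = selected, H = H)
}

# Total within-cluster sum of squares (and labels) for K-means with K
# centers, plus the embedding's total sum of squares T (around the column
# means). W/T is the fraction of unexplained variance: per-K embeddings have
# incomparable raw scales (each extra eigenvector adds ~1 unit of variance),
# so Hartigan ratios are formed on W/T. Degenerate inputs (fewer distinct
# rows than K) get a perfect zero-W fit.
.kmeans_fit <- function(X, K, restarts, seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  total <- sum(sweep(X, 2L, colMeans(X))^2)
  if (K == 1L) {
    return(list(W = total, total = total, labels = rep(1L, n)))
  }
  ux <- unique(X)
  if (nrow(ux) <= K) {
    lab <- match(apply(X, 1L, paste, collapse = "\r"),
                 apply(ux, 1L, paste, collapse = "\r"))
    return(list(W = 0, total = total, labels = as.integer(lab)))
  }
  set.seed(seed)
  km <- stats::kmeans(X, centers = K, nstart = restarts, iter.max = 100L)
  list(W = km$tot.withinss, total = total, labels = km$cluster)
}

# relabel clusters by order of first appearance so output is canonical
.canonical_labels <- function(labels, genes) {
  lev <- unique(labels)
  out <- match(labels, lev)
  names(out) <- genes
  out
}

#' Choose the cluster count with Hartigan's statistic
#'
#' For K = 1, 2, ... the rows of the width-K spectral embedding are K-means
#' clustered and Hartigan's number H(K) = (W_K / W_(K+1) - 1) (n - K - 1) is
#' computed from the total within-cluster sums of squares. Because W_K and
#' W_(K+1) come from embeddings of different widths, each is first divided by
#' its embedding's total sum of squares (the unexplained-variance fraction) so
#' the ratio is dimension-free. K' is the smallest K with H(K) <= threshold,
#' capped at `k_max` (<= 10).
#'
#' @param H_builder function(k) returning the n x k embedding for width k.
#' @param n number of genes (rows).
#' @param k_max maximum K considered (capped at 10).
#' @param threshold Hartigan acceptance threshold (classical value 10).
#' @param restarts K-means restarts (>= 10 recommended).
#' @param seed integer seed; repeated calls are identical.
#' @return `dscn_clusters` object: `genes`, `labels` (1..K'), `K_prime`,
#'   `quality` (named H(K) values).
#' @export
hartigan_select_k <- function(H_builder, n, k_max = 10, threshold = 10,
                              restarts = 10, seed = 1) {
  if (n < 2L) dscn_input_error("need at least 2 genes to cluster")
  k_max <- min(k_max, 10L, n - 1L)
  fits <- list()
  fit_at <- function(K) {
    key <- as.character(K)
    if (is.null(fits[[key]])) {
      fits[[key]] <<- .kmeans_fit(H_builder(K), K, restarts, seed + K)
    }
    fits[[key]]
  }
  wfrac <- function(f) if (f$total <= 1e-12) 0 else f$W / f$total
  quality <- stats::setNames(numeric(0), character(0))
  K_sel <- k_max
  for (K in seq_len(k_max)) {
    fk <- fit_at(K)
    if (wfrac(fk) <= 1e-12) { K_sel <- K; quality[as.character(K)] <- 0; break }
    if (K == k_max) { K_sel <- K; break }
    fk1 <- tryCatch(fit_at(K + 1L), dscn_error = function(e) NULL)
    if (is.null(fk1)) { K_sel <- K; break }
    H <- if (wfrac(fk1) <= 1e-12) Inf else (wfrac(fk) / wfrac(fk1) - 1) * (n - K - 1)
    quality[as.character(K)] <- H
    if (H <= threshold) { K_sel <- K; break }
  }
  labels <- .canonical_labels(fit_at(K_sel)$labels, rownames(H_builder(K_sel)))
  structure(list(genes = names(labels), labels = labels,
                 K_prime = as.integer(K_sel), quality = quality),
            class = "dscn_clusters")
}

#' Spectral clustering of a tissue Laplacian
#'
#' Convenience wrapper: builds width-k embeddings with [eigendecompose()] and
#' selects K' with [hartigan_select_k()].
#'
#' @param lapN normalized `dscn_laplacian` of the tissue network.
#' @inheritParams hartigan_select_k
#' @param symmetrize passed to [eigendecompose()].
#' @return `dscn_clusters` object.
#' @export
spectral_cluster <- function(lapN, k_max = 10, threshold = 10, restarts = 10,
                             seed = 1, symmetrize = TRUE) {
  hartigan_select_k(function(k) eigendecompose(lapN, k, symmetrize)$H,
                    n = length(lapN$genes), k_max = k_max,
                    threshold = threshold, restarts = restarts, seed = seed)
}

#' Map tissue clusters onto the cell-line network
#'
#' Each tissue cluster induces the cell-line subnetwork on the same gene names
#' (edges internal to the cluster only).
#'
#' @param assign `dscn_clusters` from the tissue network.
#' @param net_c cell-line `dscn_network` over the identical gene universe.
#' @return list of `dscn_network` subnetworks, one per cluster id.
#' @export
map_to_cellline <- function(assign, net_c) {
  stopifnot(inherits(assign, "dscn_clusters"), inherits(net_c, "dscn_network"))
  if (!setequal(assign$genes, net_c$genes)) {
    dscn_input_error("cluster assignment and cell-line network cover different genes")
  }
  lapply(seq_len(assign$K_prime), function(i) {
    induce_subnetwork(net_c, assign$genes[assign$labels == i])
  })
}
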