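# Network construction: correlation affinities, fold-change/essentiality node
# weights, G = S + D, L = D - S and the row-normalized Laplacian.

make_expr <- function(values, condition = "tumor") {
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, condition)
}

test_that("correlation affinity restricts Pearson r to PPI edges", {
  vals <- rbind(A = c(1, 2, 3, 4), B = c(1, 3, 2, 4), C = c(4, 3, 2, 1))
  colnames(vals) <- paste0("s", 1:4)
  expr <- make_expr(vals)
  ppi <- ppi_edge_list(c("A", "A"), c("B", "C"), c(900, 900))
  S <- correlation_affinity(expr, ppi, c("A", "B", "C"))
  expect_equal(S["A", "B"], 0.8)          # hand Pearson computation
  expect_equal(S["A", "C"], -1)           # exact anti-correlation
  expect_equal(S["B", "C"], 0)            # no PPI edge
  expect_equal(S, t(S))

  # identical vectors on an edge give r = 1
  v2 <- rbind(A = c(1, 2, 3), B = c(1, 2, 3))
  colnames(v2) <- paste0("s", 1:3)
  S2 <- correlation_affinity(make_expr(v2), ppi_edge_list("A", "B", 1), c("A", "B"))
  expect_equal(S2["A", "B"], 1)
})

test_that("degenerate correlation inputs are handled", {
  vals <- rbind(A = c(1, 1, 1), B = c(1, 2, 3))
  colnames(vals) <- paste0("s", 1:3)
  ppi <- ppi_edge_list("A", "B", 1)
  expect_warning(S <- correlation_affinity(make_expr(vals), ppi, c("A", "B")),
                 class = "dscn_warning")
  expect_equal(S["A", "B"], 0)  # zero-variance gene: edge weight 0

  two <- vals[, 1:2]
  expect_error(correlation_affinity(make_expr(two), ppi, c("A", "B")),
               class = "dscn_input_error")
})

test_that("tissue node weights are log2 fold changes of means", {
  tum <- make_expr(rbind(A = c(5, 5), B = c(3, 3), C = c(1, 1)), "tumor")
  nor <- make_expr(rbind(A = c(3, 3), B = c(3, 3), C = c(4, 4)), "normal")
  w <- tissue_node_weights(tum, nor, c("A", "B", "C"))
  expect_equal(unname(w), c(2, 0, -3))
  err <- expect_error(tissue_node_weights(tum, nor, c("A", "ZZZ")),
                      class = "dscn_input_error")
  expect_match(conditionMessage(err), "ZZZ")
})

test_that("cell-line node weights average essentiality over lines", {
  em <- rbind(A = c(-2, -4), B = c(0, 1))
  colnames(em) <- c("L1", "L2")
  ess <- essentiality_table(em)
  expect_equal(unname(cellline_node_weights(ess, genes = "A")), -3)
  expect_equal(unname(cellline_node_weights(ess, lines = colnames(ess$values)[1],
                                            genes = "B")), 0)
  expect_error(cellline_node_weights(ess, lines = character(0), genes = "A"),
               class = "dscn_degenerate_error")
  expect_error(cellline_node_weights(ess, genes = "MISSING"),
               class = "dscn_input_error")
})

test_that("build_network validates its invariants", {
  S <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  net <- build_network(S, c(A = 1, B = 2), "tissue")
  expect_s3_class(net, "dscn_network")
  expect_error(build_network(S, c(A = 1), "tissue"), class = "dscn_input_error")
  bad <- S; bad[1, 2] <- 0.7
  expect_error(build_network(bad, c(A = 1, B = 2), "tissue"),
               class = "dscn_internal_error")
  diag_bad <- S; diag(diag_bad) <- 1
  expect_error(build_network(diag_bad, c(A = 1, B = 2), "tissue"),
               class = "dscn_internal_error")
})

test_that("laplacian is D - S", {
  net <- toy_network(matrix(c(0, 0.5, 0.5, 0), 2), c(2, 3))
  L <- laplacian(net)$L
  expect_equal(unname(L), rbind(c(2, -0.5), c(-0.5, 3)))

  netS0 <- toy_network(matrix(0, 2, 2), c(2, 3))
  expect_equal(unname(laplacian(netS0)$L), diag(c(2, 3)))

  netW0 <- toy_network(matrix(c(0, 0.4, 0.4, 0), 2), c(0, 0))
  expect_equal(unname(laplacian(netW0)$L), -netW0$S, ignore_attr = TRUE)
})

test_that("normalized Laplacian matches hand-worked examples", {
  # 2 genes, weights (2, 3), edge 0.5: each row's off-diagonal carries the
  # full |w_i| since there is a single edge
  net <- toy_network(matrix(c(0, 0.5, 0.5, 0), 2), c(2, 3))
  Ln <- normalize_laplacian(laplacian(net))$L
  expect_equal(unname(Ln), rbind(c(2, -2), c(-3, 3)))

  # 3-gene star, center weight 4, two equal edges: |w| split equally
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- 0.5; S[1, 3] <- S[3, 1] <- 0.5
  star <- toy_network(S, c(4, 1, 1))
  Ls <- normalize_laplacian(laplacian(star))$L
  expect_equal(unname(Ls[1, ]), c(4, -2, -2))

  # isolated gene keeps its weight and zero off-diagonals
  S2 <- matrix(0, 3, 3); S2[1, 2] <- S2[2, 1] <- 0.3
  iso <- toy_network(S2, c(1, 1, 7))
  expect_warning(Li <- normalize_laplacian(laplacian(iso))$L, class = "dscn_warning")
  expect_equal(unname(Li[3, ]), c(0, 0, 7))

  expect_error(normalize_laplacian(normalize_laplacian(laplacian(net))),
               class = "dscn_input_error")
})

test_that("row invariant holds and normalization has the stated symmetries", {
  for (s in 1:20) {
    net <- random_network(sample(3:12, 1), density = 0.5, seed = s)
    Ln <- suppressWarnings(normalize_laplacian(laplacian(net)))$L
    for (i in seq_along(net$w)) {
      if (any(net$S[i, ] != 0)) {
        expect_lt(abs(sum(abs(Ln[i, -i])) - abs(Ln[i, i])), 1e-9)
      } else {
        expect_equal(sum(abs(Ln[i, -i])), 0)
      }
    }
  }

  # uniform positive rescaling of the edge weights leaves L' unchanged
  net <- random_network(6, density = 0.6, seed = 3)
  scaled <- build_network(net$S * 0.25, net$w, net$kind)
  expect_equal(normalize_laplacian(laplacian(net))$L,
               normalize_laplacian(laplacian(scaled))$L, tolerance = 1e-12)

  # symmetric S generally yields an asymmetric L' (must not be symmetrized)
  asym <- normalize_laplacian(laplacian(toy_network(
    matrix(c(0, 0.5, 0.5, 0), 2), c(2, 3))))$L
  expect_false(isTRUE(all.equal(asym, t(asym))))
})
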