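# The three impact-scoring schemes and their dispatcher.

test_that("most-probable-path score takes the minimum child product", {
  iso <- toy_network(matrix(0, 2, 2), c(-1.5, 1))
  expect_equal(most_probable_path_score(iso, "A")$value, -1.5)

  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- 0.5; S[1, 3] <- S[3, 1] <- 0.2
  net <- toy_network(S, c(-2, 1, -3))
  # products {1 * 0.5, -3 * 0.2} = {0.5, -0.6}; min is -0.6
  res <- most_probable_path_score(net, "A")
  expect_equal(res$value, -2.6)
  expect_equal(res$s_t1, -2)
  expect_equal(res$propagation, -0.6)

  one <- toy_network(matrix(c(0, -0.5, -0.5, 0), 2), c(3, 2))
  expect_equal(most_probable_path_score(one, "A")$value, 3 + 2 * -0.5)
  expect_error(most_probable_path_score(net, "ZZ"), class = "dscn_input_error")
})

test_that("transition matrix normalizes absolute edge weights", {
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- 0.3; S[1, 3] <- S[3, 1] <- -0.7
  net <- toy_network(S, c(1, 1, 1))
  P <- transition_matrix(net)
  expect_equal(P[1, 2], 0.3)
  expect_equal(P[1, 3], 0.7)   # sign dropped for the kernel
  expect_equal(P[2, 1], 1)     # single neighbor

  iso <- toy_network(matrix(0, 2, 2), c(1, 1))
  expect_equal(diag(transition_matrix(iso)), c(A = 1, B = 1))

  for (s in 1:10) {
    net <- random_network(sample(3:10, 1), 0.5, seed = 100 + s)
    expect_equal(rowSums(transition_matrix(net)), rep(1, length(net$w)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("random-walk score records forced first-visit parents", {
  two <- toy_network(matrix(c(0, 0.4, 0.4, 0), 2), c(-1, 2))
  res <- random_walk_score(two, "A", seed = 3)
  # the only possible first step visits B with parent A
  expect_equal(res$value, -1 + 2 * 0.4)
  expect_equal(unname(res$first_parent["B"]), "A")

  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- 0.5; S[2, 3] <- S[3, 2] <- -0.3
  chain <- toy_network(S, c(1, -2, 4))
  for (seed in 1:5) {
    r <- random_walk_score(chain, "A", seed = seed)
    if ("C" %in% names(r$first_parent)) {
      expect_equal(unname(r$first_parent["C"]), "B")  # path forces the parent
    }
  }

  iso <- toy_network(matrix(0, 2, 2), c(-3, 1))
  expect_warning(r <- random_walk_score(iso, "A"), class = "dscn_warning")
  expect_equal(r$value, -3)
})

test_that("random-walk score is deterministic and matches trajectory replay", {
  net <- random_network(4, density = 0.8, seed = 12)
  r1 <- random_walk_score(net, "g01", seed = 99)
  r2 <- random_walk_score(net, "g01", seed = 99)
  expect_identical(r1$value, r2$value)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_length(r1$trajectory, 2 * 4 + 1)

  t_idx <- match("g01", net$genes)
  expect_equal(r1$value,
               oracle_walk_replay(net$S, unname(net$w), t_idx, r1$trajectory))
})

test_that("diffusion tiers follow BFS distance", {
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- 1; S[1, 3] <- S[3, 1] <- 0.5; S[1, 4] <- S[4, 1] <- -0.2
  star <- toy_network(S, rep(1, 4))
  expect_equal(unname(diffusion_tiers(star, "A")), c(0, 1, 1, 1))

  Sc <- matrix(0, 3, 3); Sc[1, 2] <- Sc[2, 1] <- 0.5; Sc[2, 3] <- Sc[3, 2] <- 0.4
  chain <- toy_network(Sc, rep(1, 3))
  expect_equal(unname(diffusion_tiers(chain, "A")), c(0, 1, 2))

  iso <- toy_network(matrix(0, 2, 2), c(1, 1))
  expect_equal(unname(diffusion_tiers(iso, "A")), c(0, NA))
})

test_that("diffusion score accumulates upper- and same-tier terms", {
  # chain T1 - N1 (w 2, edge 0.5) - N2 (w -1, edge -0.4):
  # N1 term 2 * 0.5, N2 term (-1) * (-0.4); total w_T1 + 1.4
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- 0.5; S[2, 3] <- S[3, 2] <- -0.4
  chain <- toy_network(S, c(-2, 2, -1))
  expect_equal(diffusion_score(chain, "A")$value, -2 + 1.4)

  # triangle: both neighbors are tier 1, each adds its upper-tier edge to T1
  # plus the same-tier edge to the other neighbor
  St <- matrix(0, 3, 3)
  St[1, 2] <- St[2, 1] <- 0.6; St[1, 3] <- St[3, 1] <- -0.2; St[2, 3] <- St[3, 2] <- 0.9
  tri <- toy_network(St, c(1, -2, 3))
  expected <- 1 + (-2) * (0.6 + 0.9) + 3 * (-0.2 + 0.9)
  expect_equal(diffusion_score(tri, "A")$value, expected)

  lonely <- toy_network(matrix(0, 2, 2), c(-7, 1))
  expect_equal(diffusion_score(lonely, "A")$value, -7)

  # ratio reading divides the tier edge sum by the node weight
  expect_equal(diffusion_score(chain, "A", ratio = TRUE)$value,
               -2 + 0.5 / 2 + (-0.4) / (-1))
})

test_that("diffusion score is permutation invariant and edge-monotone", {
  net <- random_network(7, density = 0.5, seed = 21)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  pnet <- build_network(net$S[perm, perm], net$w[perm], net$kind)
  expect_equal(diffusion_score(net, "g05")$value,
               diffusion_score(pnet, "g05")$value, tolerance = 1e-12)

  # all node weights <= 0, edges >= 0: each added edge term is <= 0. Edges
  # are added target-star first so BFS tiers stay fixed while edges accrue
  # (tier reshuffling can reassign a term between endpoints).
  set.seed(8)
  for (rep in 1:5) {
    n <- 6
    S <- matrix(0, n, n)
    edges <- which(upper.tri(S), arr.ind = TRUE)
    edges <- edges[order(edges[, 1] != 1, sample(nrow(edges))), ]
    w <- -runif(n)
    vals <- c()
    for (e in seq_len(nrow(edges))) {
      S[edges[e, 1], edges[e, 2]] <- S[edges[e, 2], edges[e, 1]] <- runif(1, 0.1, 1)
      vals <- c(vals, diffusion_score(toy_network(S, w), "A")$value)
    }
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("impact_score dispatches schemes and scopes", {
  ctx <- small_ctx()
  tgt <- ctx$genes[1]

  # singleton cluster: every scheme returns the bare node weight
  fake <- ctx$assign
  fake$labels[] <- 2L
  fake$labels[tgt] <- 1L
  for (scheme in c("most_probable", "random_walk", "diffusion")) {
    got <- suppressWarnings(
      impact_score(ctx$net_c, tgt, scheme, "local", fake))
    expect_equal(got$value, unname(ctx$net_c$w[tgt]))
  }

  # local scope ignores cross-cluster edges: equals scoring the induced block
  lab <- ctx$assign$labels[tgt]
  members <- ctx$assign$genes[ctx$assign$labels == lab]
  local <- impact_score(ctx$net_c, tgt, "diffusion", "local", ctx$assign)
  oracle <- diffusion_score(induce_subnetwork(ctx$net_c, members), tgt)
  expect_equal(local$value, oracle$value)

  expect_error(impact_score(ctx$net_c, tgt, "heat_kernel", "local", ctx$assign),
               class = "dscn_config_error")
  expect_error(impact_score(ctx$net_c, tgt, "diffusion", "sideways", ctx$assign),
               class = "dscn_config_error")
  expect_error(impact_score(ctx$net_c, tgt, "diffusion", "local", NULL),
               class = "dscn_config_error")
})

test_that("additive decomposition matches brute force on small graphs", {
  for (s in 1:10) {
    net <- random_network(sample(3:6, 1), density = 0.6, seed = 400 + s)
    t_idx <- sample(length(net$w), 1)
    tgt <- net$genes[t_idx]
    mp <- most_probable_path_score(net, tgt)
    expect_equal(mp$value, oracle_most_probable(net$S, unname(net$w), t_idx))
    expect_equal(mp$value - mp$s_t1, mp$propagation)
    df <- diffusion_score(net, tgt)
    expect_equal(df$value, oracle_diffusion(net$S, unname(net$w), t_idx))
    expect_equal(df$value - df$s_t1, df$propagation)
  }
})
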