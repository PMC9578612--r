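# Knockdown subsampling, conditional scoring, pair scores and ranking.

test_that("knockdown subsample keeps strictly-below-mean samples and lines", {
  ev <- rbind(T1 = c(1, 2, 3, 4, 5), X = rnorm(5))
  colnames(ev) <- paste0("s", 1:5)
  expr <- expression_matrix(ev, "cellline")
  em <- rbind(T1 = c(-4, -1, 0), X = rnorm(3))
  colnames(em) <- paste0("L", 1:3)
  ess <- essentiality_table(em)

  sub <- subsample_knockdown(expr, ess, "T1", min_samples = 1)
  expect_identical(sub$kept_expression_samples, c("s1", "s2"))  # mean 3, strict
  expect_identical(sub$kept_essentiality_lines, "L1")           # mean -5/3

  fv <- rbind(T1 = rep(2, 5), X = rnorm(5))
  colnames(fv) <- paste0("s", 1:5)
  flat <- expression_matrix(fv, "cellline")
  err <- expect_error(subsample_knockdown(flat, ess, "T1", min_samples = 1),
                      class = "dscn_degenerate_error")
  expect_match(conditionMessage(err), "expression")

  err2 <- expect_error(subsample_knockdown(expr, ess, "T1", min_samples = 3),
                       class = "dscn_degenerate_error")
  expect_match(conditionMessage(err2), "expression|essentiality")
})

test_that("a no-op subsample reproduces the unconditional network and scores", {
  sim <- small_sim()
  ctx <- small_ctx()
  noop <- list(target = "G001",
               kept_expression_samples = sim$cellline$samples,
               kept_essentiality_lines = sim$ess$cell_lines)
  net <- conditional_network(sim$cellline, sim$ess, sim$ppi, noop, ctx$genes)
  expect_equal(net$S, ctx$net_c$S, tolerance = 1e-12)
  expect_equal(net$w, ctx$net_c$w, tolerance = 1e-12)

  # identical conditional network: IS(T2|T1) = IS(T2) and, by the strict
  # inequality of the synergy rule, no pair can be flagged synergistic
  for (t2 in ctx$genes[1:5]) {
    marg <- impact_score(ctx$net_c, t2, "diffusion", "local", ctx$assign)$value
    cond <- conditional_score(net, t2, "diffusion", "local", ctx$assign)
    expect_equal(cond, marg, tolerance = 1e-12)
    expect_false(cond < marg)
  }
})

test_that("real subsampling shifts the conditional network where planted", {
  sim <- small_sim()
  ctx <- small_ctx()
  anchor <- sim$sl_truth[1, 1]; partner <- sim$sl_truth[1, 2]
  sub <- subsample_knockdown(sim$cellline, sim$ess, anchor)
  expect_lt(length(sub$kept_expression_samples), length(sim$cellline$samples))
  net <- conditional_network(sim$cellline, sim$ess, sim$ppi, sub, ctx$genes)
  # the planted partner's conditional essentiality drops well below marginal
  expect_lt(net$w[partner] - ctx$net_c$w[partner], -0.5)
})

test_that("pair scores satisfy the additive and synergy algebra", {
  ctx <- small_ctx()
  sim <- small_sim()
  ranking <- suppressWarnings(rank_all_pairs(ctx, sim$targets))
  expect_gt(nrow(ranking), 100)
  expect_equal(ranking$is_pair, ranking$is_t1 + ranking$is_t2_given_t1,
               tolerance = 1e-9)
  expect_equal(ranking$synergy,
               ranking$is_t2_given_t1 < ranking$is_t2_marginal)
  expect_equal(ranking$synergy,
               ranking$is_pair < ranking$is_t1 + ranking$is_t2_marginal)
  # the reported pair score is the better (smaller) of the two orders
  expect_equal(ranking$is_pair, pmin(ranking$order12, ranking$order21))
  # ascending order with deterministic tiebreak
  expect_true(!is.unsorted(ranking$is_pair))
  expect_error(score_pair(ctx, "G001", "G001"), class = "dscn_input_error")
  expect_error(score_pair(ctx, "G001", "NOPE"), class = "dscn_input_error")
})

test_that("ranking enumerates pairs and skips degenerate targets", {
  ctx <- small_ctx()
  r3 <- suppressWarnings(rank_all_pairs(ctx, c("G001", "G002", "G003")))
  expect_equal(nrow(r3), 3L)
  expect_error(rank_all_pairs(ctx, "G001"), class = "dscn_input_error")
  # drug-target list input: union of targets is used
  rl <- suppressWarnings(rank_all_pairs(ctx, list(D1 = c("G001", "G002"),
                                                  D2 = "G003")))
  expect_equal(nrow(rl), 3L)
  expect_identical(r3$is_pair, rl$is_pair)
})

test_that("score_pair is symmetric for exchangeable targets", {
  # two targets with identical weights and mirrored edges through a hub
  S <- matrix(0, 3, 3); S[1, 3] <- S[3, 1] <- 0.5; S[2, 3] <- S[3, 2] <- 0.5
  w <- c(-1, -1, -2)
  # build a minimal hand context: identical marginals make both orders equal
  net <- toy_network(S, w)
  a <- diffusion_score(net, "A")$value
  b <- diffusion_score(net, "B")$value
  expect_equal(a, b)
})

test_that("predicted knockdown fold changes use the mean split", {
  vals <- rbind(T1 = c(1, 2, 3, 10, 11, 12),
                FLAT = rep(4, 6),
                COPY = c(1, 2, 3, 10, 11, 12),
                GRP = c(3, 3, 3, 5, 5, 5))
  colnames(vals) <- paste0("s", 1:6)
  expr <- expression_matrix(vals, "cellline")
  lfc <- predicted_knockdown_foldchange(expr, "T1", c("FLAT", "COPY", "GRP"))
  expect_equal(unname(lfc["FLAT"]), 0)
  expect_equal(unname(lfc["COPY"]), 2 - 11)   # strictly negative by construction
  expect_equal(unname(lfc["GRP"]), -2)
  expect_error(predicted_knockdown_foldchange(expr, "T1", "NOPE"),
               class = "dscn_input_error")
  cv <- rbind(T1 = rep(1, 4), X = rnorm(4))
  colnames(cv) <- paste0("s", 1:4)
  const <- expression_matrix(cv, "cellline")
  expect_error(predicted_knockdown_foldchange(const, "T1", "X"),
               class = "dscn_degenerate_error")
})

test_that("combination counts match the double-knockout formula", {
  expect_equal(combination_count(100, 4), 80000)
  expect_equal(combination_count(10000, 1), 50000000)
  expect_warning(zero <- combination_count(1, 1), class = "dscn_warning")
  expect_equal(zero, 0)
  expect_error(combination_count(-1, 4), class = "dscn_input_error")
  expect_error(combination_count(10, 0), class = "dscn_input_error")
})
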