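# Target impact scores IS(T1) = S(T1) + sum_i S[N_i | Pa(N_i)]: the target's
# own node weight plus its propagated effect on network neighbors, under three
# propagation schemes (most-probable path, random walk, diffusion path), on
# either the global network or the target's local spectral cluster.

.neighbors <- function(net, i) which(net$S[i, ] != 0)

.new_impact <- function(target, scheme, scope, s_t1, propagation, extra = list()) {
  structure(c(list(target = target, scheme = scheme, scope = scope,
                   value = s_t1 + propagation, s_t1 = s_t1,
                   propagation = propagation), extra),
            class = "dscn_impact")
}

#' Most-probable-path impact score
#'
#' IS = w_T1 + min over immediate children N of (w_N * w_T1,N). With no
#' children the propagation term is 0.
#'
#' @param net `dscn_network`.
#' @param target gene symbol in the network.
#' @param scope label recorded on the result (`"global"` or `"local"`).
#' @return `dscn_impact` object (field `value` is the score).
#' @export
most_probable_path_score <- function(net, target, scope = "global") {
  i <- match(target, net$genes)
  if (is.na(i)) dscn_input_error(sprintf("target %s not in network", target))
  ch <- .neighbors(net, i)
  prop <- if (length(ch) == 0L) 0 else min(net$w[ch] * net$S[i, ch])
  .new_impact(target, "most_probable", scope, unname(net$w[i]), prop)
}

#' Random-walk transition matrix
#'
#' P[j, i] = |w_ji| / sum_x |w_jx| over j's neighbors (absolute edge weights:
#' a Markov kernel must be non-negative; signs still enter the score through
#' the parent edge weight). Isolated nodes are absorbing.
#'
#' @param net `dscn_network`.
#' @return row-stochastic matrix.
#' @export
transition_matrix <- function(net) {
  P <- abs(net$S)
  rs <- rowSums(P)
  for (i in seq_along(rs)) {
    if (rs[i] == 0) P[i, i] <- 1 else P[i, ] <- P[i, ] / rs[i]
  }
  P
}

#' Random-walk impact score
#'
#' A single seeded walk of `steps` steps (default 2n) from the target under
#' [transition_matrix()]. For each node first reached, its first-visit parent
#' Pa(N) is recorded, and IS = w_T1 + sum over first-visited nodes of
#' w_N * w_{N, Pa(N)}.
#'
#' @param net `dscn_network`.
#' @param target gene symbol.
#' @param steps walk length; default 2 * n.
#' @param seed integer seed (the global RNG state is restored afterwards).
#' @param scope label recorded on the result.
#' @return `dscn_impact` with extra fields `trajectory` (visited gene indices,
#'   starting at the target) and `first_parent` (named vector of parent genes).
#' @export
random_walk_score <- function(net, target, steps = NULL, seed = 1, scope = "global") {
  i0 <- match(target, net$genes)
  if (is.na(i0)) dscn_input_error(sprintf("target %s not in network", target))
  n <- length(net$genes)
  if (is.null(steps)) steps <- 2L * n
  if (steps < 1L) dscn_config_error("walk needs >= 1 step")
  if (length(.neighbors(net, i0)) == 0L) {
    dscn_warn(sprintf("target %s is isolated: IS = node weight", target))
    return(.new_impact(target, "random_walk", scope, unname(net$w[i0]), 0,
                       list(trajectory = i0, first_parent = stats::setNames(character(0), character(0)))))
  }
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  P <- transition_matrix(net)
  parent <- rep(NA_integer_, n)
  traj <- integer(steps + 1L)
  traj[1L] <- cur <- i0
  for (s in seq_len(steps)) {
    nb <- which(P[cur, ] > 0)
    nxt <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L, prob = P[cur, nb])]
    if (nxt != i0 && is.na(parent[nxt])) parent[nxt] <- cur
    traj[s + 1L] <- cur <- nxt
  }
  visited <- which(!is.na(parent))
  prop <- if (length(visited)) sum(net$w[visited] * net$S[cbind(visited, parent[visited])]) else 0
  fp <- stats::setNames(net$genes[parent[visited]], net$genes[visited])
  .new_impact(target, "random_walk", scope, unname(net$w[i0]), prop,
              list(trajectory = traj, first_parent = fp))
}

#' Breadth-first tiers from a target
#'
#' Tier 0 is the target; tier t holds nodes at BFS distance t over the nonzero
#' edges. Unreachable nodes get NA.
#'
#' @param net `dscn_network`.
#' @param target gene symbol.
#' @return named integer vector of tiers (NA = unreachable).
#' @export
diffusion_tiers <- function(net, target) {
  i0 <- match(target, net$genes)
  if (is.na(i0)) dscn_input_error(sprintf("target %s not in network", target))
  n <- length(net$genes)
  tier <- rep(NA_integer_, n)
  tier[i0] <- 0L
  frontier <- i0
  t <- 0L
  while (length(frontier)) {
    t <- t + 1L
    nxt <- unique(unlist(lapply(frontier, function(i) .neighbors(net, i))))
    nxt <- nxt[is.na(tier[nxt])]
    tier[nxt] <- t
    frontier <- nxt
  }
  stats::setNames(tier, net$genes)
}

#' Diffusion-path impact score
#'
#' Deterministic tiered propagation: IS = w_T1 + sum over reachable nodes i of
#' w_i * (sum of edges to the tier above + sum of edges within the same tier).
#' With `ratio = TRUE` the alternative reading (edge sum divided by w_i) is
#' used instead of the product.
#'
#' @param net `dscn_network`.
#' @param target gene symbol.
#' @param ratio use the ratio reading of the tier term (default FALSE).
#' @param scope label recorded on the result.
#' @return `dscn_impact` with extra field `tiers`.
#' @export
diffusion_score <- function(net, target, ratio = FALSE, scope = "global") {
  tier <- diffusion_tiers(net, target)
  i0 <- match(target, net$genes)
  idx <- which(!is.na(tier) & seq_along(tier) != i0)
  prop <- 0
  for (i in idx) {
    nb <- .neighbors(net, i)
    up <- nb[!is.na(tier[nb]) & tier[nb] == tier[i] - 1L]
    same <- nb[!is.na(tier[nb]) & tier[nb] == tier[i]]
    esum <- sum(net$S[i, up]) + sum(net$S[i, same])
    prop <- prop + unname(if (ratio) {
      if (net$w[i] == 0) 0 else esum / net$w[i]
    } else net$w[i] * esum)
  }
  .new_impact(target, "diffusion", scope, unname(net$w[i0]), prop,
              list(tiers = tier))
}

#' Impact score dispatcher
#'
#' Runs the chosen scheme on either the full network (`scope = "global"`) or
#' the induced subnetwork of the target's spectral cluster
#' (`scope = "local"`, requires `assign`). The default pipeline configuration
#' is `scheme = "diffusion"`, `scope = "local"`.
#'
#' @param net `dscn_network` (cell-line network, possibly conditional).
#' @param target gene symbol.
#' @param scheme `"most_probable"`, `"random_walk"` or `"diffusion"`.
#' @param scope `"global"` or `"local"`.
#' @param assign `dscn_clusters` (tissue clustering), required for local scope.
#' @param cfg list of scheme options: `walk_steps`, `walk_seed`,
#'   `diffusion_ratio`.
#' @return `dscn_impact`.
#' @export
impact_score <- function(net, target, scheme = "diffusion", scope = "local",
                         assign = NULL, cfg = list()) {
  if (!scheme %in% c("most_probable", "random_walk", "diffusion")) {
    dscn_config_error(sprintf("unknown scheme '%s'", scheme))
  }
  if (!scope %in% c("global", "local")) dscn_config_error(sprintf("unknown scope '%s'", scope))
  if (scope == "local") {
    if (is.null(assign)) dscn_config_error("local scope needs a cluster assignment")
    lab <- assign$labels[target]
    if (is.na(lab)) dscn_input_error(sprintf("target %s has no cluster label", target))
    members <- assign$genes[assign$labels == lab]
    net <- induce_subnetwork(net, intersect(net$genes, members))
  }
  switch(scheme,
    most_probable = most_probable_path_score(net, target, scope),
    random_walk = random_walk_score(net, target,
                                    steps = cfg$walk_steps,
                                    seed = if (is.null(cfg$walk_seed)) 1L else cfg$walk_seed,
                                    scope = scope),
    diffusion = diffusion_score(net, target,
                                ratio = isTRUE(cfg$diffusion_ratio), scope = scope))
}
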