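# Independent brute-force oracles. These deliberately avoid the package's
# internals: tiers come from adjacency-matrix powers, scores from plain
# double loops, and the random-walk oracle replays the emitted trajectory.

oracle_most_probable <- function(S, w, t) {
  prods <- c()
  for (j in seq_along(w)) {
    if (j != t && S[t, j] != 0) prods <- c(prods, w[j] * S[t, j])
  }
  if (length(prods) == 0) w[t] else w[t] + min(prods)
}

# BFS distance via boolean matrix powers: d[i] = smallest t with (A^t)[t1,i]>0
oracle_tiers <- function(S, t) {
  n <- nrow(S)
  A <- (S != 0) * 1
  d <- rep(NA_integer_, n)
  d[t] <- 0L
  reach <- replace(rep(0, n), t, 1)
  for (step in seq_len(n)) {
    reach <- as.numeric(reach %*% A > 0)
    d[reach > 0 & is.na(d)] <- step
  }
  d
}

oracle_diffusion <- function(S, w, t) {
  d <- oracle_tiers(S, t)
  total <- w[t]
  for (i in seq_along(w)) {
    if (i == t || is.na(d[i])) next
    esum <- 0
    for (j in seq_along(w)) {
      if (S[i, j] != 0 && !is.na(d[j]) && (d[j] == d[i] - 1 || d[j] == d[i])) {
        esum <- esum + S[i, j]
      }
    }
    total <- total + w[i] * esum
  }
  total
}

# score implied by a recorded trajectory: first-visit parents by linear scan
oracle_walk_replay <- function(S, w, t, trajectory) {
  n <- length(w)
  parent <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  seen[t] <- TRUE
  for (s in seq_along(trajectory)[-1]) {
    node <- trajectory[s]
    if (!seen[node]) {
      parent[node] <- trajectory[s - 1]
      seen[node] <- TRUE
    }
  }
  total <- w[t]
  for (i in which(!is.na(parent))) total <- total + w[i] * S[i, parent[i]]
  total
}

# all connected labeled graphs on n nodes as edge lists (bitmask enumeration)
connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    on <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (length(on) < n - 1) next
    A <- matrix(FALSE, n, n)
    for (e in on) {
      A[pairs[e, 1], pairs[e, 2]] <- TRUE
      A[pairs[e, 2], pairs[e, 1]] <- TRUE
    }
    reach <- rep(FALSE, n); reach[1] <- TRUE
    for (k in seq_len(n)) reach <- reach | (A %*% reach > 0)
    if (all(reach)) out[[length(out) + 1L]] <- A
  }
  out
}
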