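# Independent oracles used across the suite.  None of these share code with
# the implementation paths they check.

# Upper-tail pooled hypergeometric probability by direct summation of
# C(K,k) C(N-K, n-k) / C(N,n) over k = r..min(K,n).  Exact in doubles for
# N <= 30 (all binomial terms are integers below 2^53).
oracle_hypergeom_upper <- function(N, K, n, r) {
  if (r <= 0) return(1)
  ks <- seq.int(r, min(K, n))
  if (!length(ks) || r > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# The complement form as displayed (1 - sum_{k < r}), for cross-checking the
# two algebraic readings agree.
oracle_hypergeom_complement <- function(N, K, n, r) {
  if (r <= 0) return(1)
  ks <- seq.int(0, r - 1)
  1 - sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# All maximal node subsets with pairwise shortest-path distance <= k, by
# exhaustive bitmask enumeration (n <= 14).  D is the distance matrix of the
# full graph; returns a list of sorted node-name vectors.
oracle_max_distk_sets <- function(D, k) {
  n <- nrow(D)
  nodes <- rownames(D)
  B <- is.finite(D) & D <= k
  diag(B) <- TRUE
  compat <- vapply(seq_len(n), function(v) {
    sum(2^(which(B[v, ]) - 1))
  }, numeric(1))
  nmask <- 2^n - 1
  valid <- logical(nmask)
  for (s in 1:nmask) {
    v <- floor(log2(s)) + 1          # highest set bit
    rest <- s - 2^(v - 1)
    valid[s] <- (rest == 0 || valid[rest]) &&
      bitwAnd(rest, compat[v]) == rest
  }
  out <- list()
  for (s in which(valid)) {
    outside <- which(bitwAnd(s, 2^(seq_len(n) - 1)) == 0)
    if (all(!valid[s + 2^(outside - 1)]) || !length(outside)) {
      out[[length(out) + 1L]] <- sort(nodes[bitwAnd(s, 2^(seq_len(n) - 1)) != 0])
    }
  }
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

# Single-covariate Cox partial likelihood maximised with optimize(); valid
# when event times are untied (Breslow/Efron coincide).  Returns beta-hat.
oracle_cox_partial_likelihood <- function(x, time, event) {
  stopifnot(!anyDuplicated(time[event == 1]))
  negll <- function(beta) {
    -sum(vapply(which(event == 1), function(i) {
      risk <- time >= time[i]
      x[i] * beta - log(sum(exp(x[risk] * beta)))
    }, numeric(1)))
  }
  stats::optimize(negll, c(-30, 30), tol = 1e-10)$minimum
}

# Hand-rolled two-group log-rank statistic (observed - expected with
# hypergeometric variance at each event time).
oracle_logrank_chi2 <- function(time, event, group) {
  lev <- sort(unique(group))
  stopifnot(length(lev) == 2)
  ts <- sort(unique(time[event == 1]))
  oe <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lev[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lev[1])
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

# Small random connected-ish graph for oracle comparisons.
random_pathway <- function(n_nodes, edge_prob, pathway_id = "t") {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  edges <- if (n_nodes >= 2) {
    pairs <- t(combn(nodes, 2))
    pairs[runif(nrow(pairs)) < edge_prob, , drop = FALSE]
  } else {
    matrix(character(), ncol = 2)
  }
  pathway_graph(pathway_id, nodes = nodes, edges = edges)
}

# Distance matrix of a pathway_graph via breadth-first search (no igraph).
bfs_distances <- function(g) {
  n <- length(g$nodes)
  adj <- lapply(g$nodes, function(v) {
    unique(c(g$edges[g$edges[, 1] == v, 2], g$edges[g$edges[, 2] == v, 1]))
  })
  names(adj) <- g$nodes
  D <- matrix(Inf, n, n, dimnames = list(g$nodes, g$nodes))
  for (s in g$nodes) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!is.finite(D[s, w])) {
          D[s, w] <- D[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  D
}

# Tiny clinical table with untied times.
make_clinical <- function(times, events, ids = sprintf("S%02d", seq_along(times))) {
  data.frame(sample_id = ids, time_months = times, event = events,
             stringsAsFactors = FALSE)
}
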