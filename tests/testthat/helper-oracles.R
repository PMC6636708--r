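# Independent brute-force oracles.  These deliberately avoid the package's
# own step-function machinery: ages come straight from edge arithmetic and
# counts from interval stabbing, so they can adjudicate compute_ltt/ltt_at.

# number of branches of `tree` in force at time t (years BP), by checking
# every edge's [age_child, age_parent) interval; valid at non-event times
oracle_ltt_count <- function(tree, t) {
  ages <- oracle_node_ages(tree)
  age_p <- ages[tree$edge[, 1L]]
  age_c <- ages[tree$edge[, 2L]]
  vapply(t, function(ti) sum(age_c <= ti & ti < age_p), numeric(1))
}

# node ages recomputed by walking each node's path up to the root and
# summing edge lengths (no ape depth helpers involved)
oracle_node_ages <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  root <- n + 1L
  parent_of <- integer(n + m)
  len_of <- numeric(n + m)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  len_of[tree$edge[, 2L]] <- tree$edge.length
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + len_of[node]
      node <- parent_of[node]
    }
    d
  }
  depths <- vapply(seq_len(n + m), depth, numeric(1))
  max(depths[seq_len(n)]) - depths
}

# closed-form normal-equations polynomial fit (intercept + degree terms)
oracle_normal_equations <- function(x, y, degree) {
  X <- vapply(0:degree, function(k) x^k, numeric(length(x)))
  solve(t(X) %*% X, t(X) %*% y)[, 1L]
}

# quick seeded Yule/birth-death tree for property tests
sim_tree <- function(seed, lambda0 = 0.002, mu0 = 0, max_time = NULL,
                     max_tips = NULL, ...) {
  if (is.null(max_time) && is.null(max_tips)) max_time <- 3000
  simulate_tree(bd_params(lambda0 = lambda0, mu0 = mu0, max_time = max_time,
                          max_tips = max_tips, seed = seed, ...))
}

# random non-event query times for a series, away from step discontinuities
query_times <- function(series, k) {
  span <- series$times[1L]
  repeat {
    t <- runif(k, 0, span)
    if (!any(t %in% series$times)) return(t)
  }
}
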