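#' Birth-death simulation parameters
#'
#' Generative parameters for the forward-in-time branching simulator.
#' Three speciation regimes are supported: `constant` (per-lineage rate
#' lambda0 throughout), `exponential_time` (lambda(t) = lambda0 *
#' exp(beta * t) with t the elapsed time in years, sampled exactly by
#' thinning), and `density_dependent` (logistic niche-filling,
#' lambda(N) = lambda0 * max(0, 1 - N/K)).  Extinction runs at constant
#' per-lineage rate mu0.  Exactly one stopping rule applies: `max_time`
#' (years of simulation) or `max_tips` (stop the instant the Nth lineage is
#' born).
#'
#' Defaults mirror the empirical world the simulator is meant to emulate:
#' lambda0 = 0.001 yr^-1 (the headline net diversification rate of Holocene
#' language families) and mu0 = 0 (the estimators only ever see net rates,
#' so the pure-birth baseline is the analysable null).
#'
#' @param lambda0 baseline speciation rate, yr^-1 (> 0).
#' @param mu0 extinction rate, yr^-1 (>= 0).
#' @param mode speciation regime (see above).
#' @param beta exponential time coefficient, yr^-1 (required in
#'   `exponential_time` mode).
#' @param K carrying capacity (>= 2; required in `density_dependent` mode).
#' @param max_time,max_tips stopping rule: exactly one must be given.
#' @param seed integer seed; every simulation runs on its own stream.
#' @return An object of class `"bd_params"`.
#' @export
bd_params <- function(lambda0 = 0.001, mu0 = 0,
                      mode = c("constant", "exponential_time",
                               "density_dependent"),
                      beta = NULL, K = NULL,
                      max_time = NULL, max_tips = NULL, seed) {
  mode <- match.arg(mode)
  if (lambda0 <= 0) stop("`lambda0` must be > 0", call. = FALSE)
  if (mu0 < 0) stop("`mu0` must be >= 0", call. = FALSE)
  if (mode == "exponential_time" && is.null(beta))
    stop("`beta` is required in exponential_time mode", call. = FALSE)
  if (mode == "density_dependent") {
    if (is.null(K) || K < 2) stop("`K` must be >= 2 in density mode",
                                  call. = FALSE)
  }
  if (is.null(max_time) == is.null(max_tips))
    stop("exactly one of `max_time` or `max_tips` must be set", call. = FALSE)
  if (!is.null(max_time) && max_time <= 0)
    stop("`max_time` must be > 0", call. = FALSE)
  if (!is.null(max_tips) && max_tips < 2)
    stop("`max_tips` must be >= 2", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  structure(list(lambda0 = lambda0, mu0 = mu0, mode = mode,
                 beta = if (is.null(beta)) NA_real_ else beta,
                 K = if (is.null(K)) NA_real_ else K,
                 max_time = max_time, max_tips = max_tips,
                 seed = as.integer(seed)),
            class = "bd_params")
}

speciation_rate <- function(params, t, n) {
  switch(params$mode,
         constant = params$lambda0,
         exponential_time = params$lambda0 * exp(params$beta * t),
         density_dependent = params$lambda0 * max(0, 1 - n / params$K))
}

#' Simulate a dated tree under a birth-death process
#'
#' Exact event-driven (Gillespie) simulation from a single ancestral
#' lineage.  Waiting times are exponential with total rate
#' N * (lambda + mu), rates are refreshed after every event, and the
#' time-varying regime is sampled exactly by thinning against a local
#' dominating rate.  By default the simulation is conditioned on at least
#' two extant lineages at the stopping time, by rejection with a retry cap;
#' set `condition = FALSE` for the unconditioned process (used for
#' expectation checks — extinct outcomes then return a `NULL` tree).
#'
#' The returned tree is the crown tree of the survivors: extinct lineages
#' are pruned and `root_age` is the crown age (the age of the survivors'
#' most recent common ancestor).  The stem age — the full elapsed time back
#' to the single founding lineage — is reported separately, since the
#' ln(N)/T estimator's N0 = 1 convention refers to the stem.
#'
#' @param params a [bd_params].
#' @param condition condition on >= 2 survivors (default TRUE).
#' @param max_retries rejection cap when conditioning.
#' @return An object of class `"sim_result"`: list with `tree` (a
#'   [dated_tree] of extant survivors, or `NULL` if none), `event_log`
#'   (data frame `time`, `event`, `lineage`, in event order; times are years
#'   since the origin), `n_extant`, `stem_age`, `present` (years simulated),
#'   `params`, and `attempts`.
#' @export
simulate_tree <- function(params, condition = TRUE, max_retries = 10000) {
  stopifnot(inherits(params, "bd_params"))
  with_local_seed(params$seed, {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      sim <- bd_run_once(params)
      if (!condition || sim$n_extant >= 2L) break
      if (attempts >= max_retries)
        stop(sprintf(paste0("conditioning failed: no run with >= 2 ",
                            "survivors in %d attempts (estimated survival ",
                            "probability < %.2g)"),
                     max_retries, 1 / max_retries), call. = FALSE)
    }
    sim$attempts <- attempts
    sim$params <- params
    class(sim) <- "sim_result"
    sim
  })
}

# one unconditioned forward run; assumes the RNG stream is already set
bd_run_once <- function(params) {
  mu <- params$mu0
  # lineage bookkeeping: each split closes a lineage and opens two children.
  # vectors are preallocated and doubled on demand (trees can reach
  # thousands of lineages)
  cap <- 64L
  parent <- rep(NA_integer_, cap)
  t_start <- rep(NA_real_, cap)
  t_end <- rep(NA_real_, cap)
  status <- rep(NA_character_, cap)
  parent[1L] <- NA_integer_; t_start[1L] <- 0; status[1L] <- "active"
  n_lineages <- 1L
  alive <- 1L
  t <- 0
  lcap <- 64L
  log_t <- numeric(lcap); log_ev <- character(lcap); log_id <- integer(lcap)
  n_log <- 0L
  horizon <- if (!is.null(params$max_time)) params$max_time else Inf
  # thinning window for increasing time-varying rates: dominating rate is
  # at most e * lambda(t) over each window
  win <- if (params$mode == "exponential_time" && params$beta > 0)
    1 / params$beta else Inf

  repeat {
    n <- length(alive)
    if (n == 0L) break
    if (!is.null(params$max_tips) && n >= params$max_tips) break
    lam_now <- speciation_rate(params, t, n)
    lam_dom <- if (params$mode == "exponential_time" && params$beta > 0)
      speciation_rate(params, min(t + win, horizon), n) else lam_now
    total <- n * (lam_dom + mu)
    if (total <= 0) {                     # stalled (e.g. N = K, mu = 0)
      if (is.finite(horizon)) t <- horizon
      else stop("simulation stalled: total event rate is 0 under a max_tips ",
                "stopping rule", call. = FALSE)
      break
    }
    wait <- stats::rexp(1L, rate = total)
    chunk <- min(win, horizon - t)
    if (wait > chunk) {                   # no event inside the window
      t <- t + chunk
      if (t >= horizon) { t <- horizon; break }
      next
    }
    t_prop <- t + wait
    u <- stats::runif(1L)
    p_death <- mu / (lam_dom + mu)
    if (u < p_death) {                    # extinction event
      t <- t_prop
      victim <- pick_one(alive)
      t_end[victim] <- t
      status[victim] <- "dead"
      alive <- alive[alive != victim]
      n_log <- n_log + 1L
      if (n_log > lcap) {
        lcap <- lcap * 2L
        length(log_t) <- lcap; length(log_ev) <- lcap; length(log_id) <- lcap
      }
      log_t[n_log] <- t; log_ev[n_log] <- "death"; log_id[n_log] <- victim
    } else {
      # accept a birth with probability lambda(t_prop) / lambda_dom
      lam_prop <- speciation_rate(params, t_prop, length(alive))
      accept <- lam_dom <= 0 ||
        u < p_death + (1 - p_death) * (lam_prop / lam_dom)
      t <- t_prop
      if (accept) {
        splitter <- pick_one(alive)
        t_end[splitter] <- t
        status[splitter] <- "split"
        if (n_lineages + 2L > cap) {
          cap <- cap * 2L
          length(parent) <- cap; length(t_start) <- cap
          length(t_end) <- cap; length(status) <- cap
        }
        new_ids <- n_lineages + 1:2
        parent[new_ids] <- splitter
        t_start[new_ids] <- t
        t_end[new_ids] <- NA_real_
        status[new_ids] <- "active"
        n_lineages <- n_lineages + 2L
        alive <- c(alive[alive != splitter], new_ids)
        n_log <- n_log + 1L
        if (n_log > lcap) {
          lcap <- lcap * 2L
          length(log_t) <- lcap; length(log_ev) <- lcap; length(log_id) <- lcap
        }
        log_t[n_log] <- t; log_ev[n_log] <- "birth"; log_id[n_log] <- new_ids[2L]
      }
    }
  }

  present <- t
  t_end[alive] <- present
  keep <- seq_len(n_lineages)
  lineages <- data.frame(id = keep, parent = parent[keep],
                         t_start = t_start[keep], t_end = t_end[keep],
                         status = status[keep], stringsAsFactors = FALSE)
  n_extant <- length(alive)
  tree <- if (n_extant >= 1L)
    lineages_to_crown_tree(lineages, alive, present) else NULL
  seq_log <- seq_len(n_log)
  list(tree = tree,
       event_log = data.frame(time = log_t[seq_log], event = log_ev[seq_log],
                              lineage = log_id[seq_log],
                              stringsAsFactors = FALSE),
       n_extant = n_extant, stem_age = present, present = present,
       lineages = lineages)
}

pick_one <- function(x) x[sample.int(length(x), 1L)]

# build the full phylo from the lineage table, then prune to the survivors'
# crown tree
lineages_to_crown_tree <- function(lineages, alive, present) {
  is_tip <- lineages$status != "split"
  tip_ids <- lineages$id[is_tip]
  int_ids <- lineages$id[!is_tip]
  if (!length(int_ids)) {                 # root never split: single tip
    phy <- single_tip_tree(paste0("t", tip_ids[1L]), present)
    return(dated_tree(phy))
  }
  node_of <- integer(nrow(lineages))
  node_of[tip_ids] <- seq_along(tip_ids)
  node_of[int_ids] <- length(tip_ids) + seq_along(int_ids)  # root id 1 first
  child <- lineages$id[-1L]               # every lineage but the root lineage
  edge <- cbind(node_of[lineages$parent[child]], node_of[child])
  phy <- list(edge = edge,
              edge.length = lineages$t_end[child] - lineages$t_start[child],
              tip.label = paste0("t", tip_ids),
              Nnode = length(int_ids),
              root.edge = lineages$t_end[1L] - lineages$t_start[1L])
  class(phy) <- "phylo"
  extant_labels <- paste0("t", alive)
  if (length(alive) == 1L) {
    depth <- present   # sole survivor sits at the present, stem age deep
    return(dated_tree(single_tip_tree(extant_labels, depth)))
  }
  pruned <- ape::keep.tip(phy, extant_labels)
  pruned$root.edge <- NULL
  dated_tree(pruned)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("Birth-death simulation: %d extant tip(s), %d event(s), ",
                     "stem age %.6g yr (mode %s)\n"),
              x$n_extant, nrow(x$event_log), x$stem_age, x$params$mode))
  invisible(x)
}

#' Expected lineage count under constant rates
#'
#' Closed form E[N(t)] = e^{(lambda - mu) t} for the unconditioned
#' constant-rate birth-death process started from one lineage.
#'
#' @param params a [bd_params] in `constant` mode.
#' @param t elapsed time in years.
#' @return Expected number of lineages.
#' @export
expected_n <- function(params, t) {
  stopifnot(inherits(params, "bd_params"))
  if (params$mode != "constant")
    stop("closed-form expectation is only available in constant mode",
         call. = FALSE)
  exp((params$lambda0 - params$mu0) * t)
}

#' Simulate a synthetic family table
#'
#' Draws `n_families` root ages uniformly from `root_age_range` (default
#' 1,000-8,700 years, the span of documented family root ages), runs one
#' conditioned birth-death simulation per family with the drawn age as the
#' simulated time span, and assembles a family table in the same layout as
#' [family_table()]: both catalog counts are set to the number of extant
#' simulated lineages, and `root_age_yr` is the crown age of the returned
#' tree (the quantity observable from a real consensus tree).
#'
#' @param n_families number of families (>= 1).
#' @param root_age_range length-2 numeric range of simulated time spans, yr.
#' @param template a [bd_params] whose rates/mode are reused; its stopping
#'   rule and seed are replaced per family (the drawn root age becomes each
#'   family's `max_time`).
#' @param seed integer seed for the whole table.
#' @return A list with `records` (data frame: `family`, `n_sample`,
#'   `n_ethnologue`, `n_glottolog`, `root_age_yr`, `sim_time_yr`, `source`)
#'   and `trees` (list of [dated_tree]).
#' @export
simulate_family_table <- function(n_families, root_age_range = c(1000, 8700),
                                  template = bd_params(max_time = 1, seed = 1),
                                  seed) {
  if (n_families < 1) stop("`n_families` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  draws <- with_local_seed(seed, list(
    ages = stats::runif(n_families, root_age_range[1L], root_age_range[2L]),
    seeds = sample.int(.Machine$integer.max, n_families)))
  trees <- vector("list", n_families)
  rows <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    p <- template
    p$max_time <- draws$ages[i]
    p$max_tips <- NULL
    p$seed <- draws$seeds[i]
    sim <- simulate_tree(p)
    fam <- sprintf("sim%03d", i)
    tree <- dated_tree(strip_dated(sim$tree), family = fam)
    trees[[i]] <- tree
    # root_age_yr is the drawn time span (the stem age of the simulation);
    # the crown age of the pruned tree is reported alongside it
    rows[[i]] <- data.frame(family = fam, n_sample = sim$n_extant,
                            n_ethnologue = sim$n_extant,
                            n_glottolog = sim$n_extant,
                            root_age_yr = draws$ages[i],
                            crown_age_yr = root_age(tree),
                            source = "synthetic birth-death simulation",
                            stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rows), trees = trees)
}
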