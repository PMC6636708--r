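test_that("bd_params validates its inputs", {
  expect_error(bd_params(lambda0 = 0, max_time = 1, seed = 1), "> 0")
  expect_error(bd_params(mu0 = -1, max_time = 1, seed = 1), ">= 0")
  expect_error(bd_params(max_time = 1, max_tips = 5, seed = 1), "exactly one")
  expect_error(bd_params(seed = 1), "exactly one")
  expect_error(bd_params(mode = "density_dependent", K = 1, max_time = 1,
                         seed = 1), ">= 2")
  expect_error(bd_params(mode = "exponential_time", max_time = 1, seed = 1),
               "beta")
  expect_error(bd_params(max_time = 1), "required")
})

test_that("identical seeds give bit-identical simulations", {
  p <- bd_params(lambda0 = 0.002, mu0 = 0.0005, max_time = 2500, seed = 7)
  a <- simulate_tree(p)
  b <- simulate_tree(p)
  expect_identical(a$event_log, b$event_log)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  # a different seed changes the outcome
  p2 <- p; p2$seed <- 8L
  expect_false(identical(simulate_tree(p2)$event_log, a$event_log))
  # and the caller's RNG state is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); simulate_tree(p); after <- runif(1)
  expect_identical(before, after)
})

test_that("event logs keep the branching-process books", {
  for (seed in c(5, 28, 91)) {
    sim <- sim_tree(seed, lambda0 = 0.003, mu0 = 0.0012, max_time = 2500)
    log <- sim$event_log
    # lineage count after every prefix equals births - deaths + 1
    delta <- ifelse(log$event == "birth", 1L, -1L)
    counts <- 1L + cumsum(delta)
    expect_true(all(counts >= 0))
    expect_equal(counts[length(counts)], sim$n_extant)
    expect_true(!is.unsorted(log$time))
    # crown age never exceeds the simulated time span
    expect_lte(root_age(sim$tree), sim$stem_age + 1e-9)
  }

  # pure birth: no death events, n_extant = births + 1
  sim <- sim_tree(13, lambda0 = 0.002, mu0 = 0, max_time = 3000)
  expect_false(any(sim$event_log$event == "death"))
  expect_equal(sim$n_extant, sum(sim$event_log$event == "birth") + 1L)
})

test_that("density-dependent mode respects the carrying capacity", {
  p <- bd_params(lambda0 = 0.004, mode = "density_dependent", K = 25,
                 max_time = 10000, seed = 31)
  sim <- simulate_tree(p)
  log <- sim$event_log
  counts <- 1L + cumsum(ifelse(log$event == "birth", 1L, -1L))
  expect_true(all(counts <= 25 + 1))
  expect_equal(sim$n_extant, 25L)  # mu = 0: the process fills K and stalls
})

test_that("max_tips stops at the target size", {
  p <- bd_params(lambda0 = 0.002, max_tips = 40, seed = 17)
  sim <- simulate_tree(p)
  expect_equal(sim$n_extant, 40L)
  expect_equal(ape::Ntip(sim$tree), 40L)
})

test_that("Yule expectation: mean N matches e^(lambda T)", {
  # unconditioned process, lambda*T = 1 => E[N] = e
  ns <- vapply(1:400, function(seed) {
    simulate_tree(bd_params(lambda0 = 0.001, max_time = 1000,
                            seed = 10000 + seed),
                  condition = FALSE)$n_extant
  }, numeric(1))
  se <- sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - exp(1)), 3 * se)
})

test_that("expected_n gives the constant-rate closed form", {
  p <- bd_params(lambda0 = 0.001, max_time = 1, seed = 1)
  expect_equal(expected_n(p, log(2) / 0.001), 2)
  pz <- bd_params(lambda0 = 0.002, mu0 = 0.002, max_time = 1, seed = 1)
  expect_equal(expected_n(pz, 5000), 1)
  pd <- bd_params(mode = "density_dependent", K = 10, max_time = 1, seed = 1)
  expect_error(expected_n(pd, 100), "constant mode")
})

test_that("simulate_family_table emulates the documented ranges", {
  fam <- simulate_family_table(18, seed = 55)
  expect_equal(nrow(fam$records), 18L)
  expect_true(all(fam$records$root_age_yr >= 1000 &
                    fam$records$root_age_yr <= 8700))
  # the crown age of the surviving tree never exceeds the simulated span
  expect_true(all(fam$records$crown_age_yr <= fam$records$root_age_yr + 1e-9))
  expect_true(all(fam$records$n_ethnologue >= 2))
  expect_equal(fam$records$n_ethnologue, fam$records$n_glottolog)
  expect_equal(fam$records$n_sample,
               vapply(fam$trees, ape::Ntip, integer(1)))
  # deterministic under the same seed
  fam2 <- simulate_family_table(18, seed = 55)
  expect_identical(fam$records, fam2$records)
})

test_that("pipeline closure: simulate -> write -> read -> ltt -> bins", {
  set.seed(707)
  draws <- data.frame(
    seed = sample.int(1e6, 40),
    lambda0 = exp(runif(40, log(5e-4), log(2e-3))),
    mu0 = runif(40, 0, 4e-4),
    max_time = runif(40, 800, 2000),
    mode = sample(c("constant", "exponential_time", "density_dependent"),
                  40, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".nwk")
  for (i in seq_len(nrow(draws))) {
    p <- bd_params(lambda0 = draws$lambda0[i], mu0 = draws$mu0[i],
                   mode = draws$mode[i],
                   beta = if (draws$mode[i] == "exponential_time")
                     2e-4 else NULL,
                   K = if (draws$mode[i] == "density_dependent") 60 else NULL,
                   max_time = draws$max_time[i], seed = draws$seed[i])
    sim <- simulate_tree(p)
    write_newick(sim$tree, path)
    back <- prune_to_extant(read_newick(path)[[1]])
    s <- compute_ltt(back)
    norm <- normalize_ltt(s, ape::Ntip(back), root_age(back))
    br <- binned_rates(norm)
    expect_equal(nrow(br), 10L)
    expect_true(all(is.finite(br$rate)))
  }
})
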