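test_that("overall_rate and doubling_time implement ln(N)/T and ln2/r", {
  expect_equal(round(overall_rate(5, 5500), 5), 0.00029)
  expect_equal(round(overall_rate(1268, 5230), 5), 0.00137)
  expect_equal(overall_rate(1, 1000), 0)
  expect_equal(doubling_time(log(2)), 1)
  expect_equal(round(doubling_time(0.00029)), 2390)
  expect_equal(round(doubling_time(0.00082)), 845)

  expect_error(overall_rate(0, 1000), ">= 1")
  expect_error(overall_rate(5, 0), "> 0")
  expect_error(doubling_time(0), "> 0")

  # inverse link: r * t2(r) = ln 2, exactly, for any positive rate
  r <- exp(runif(20, log(1e-5), log(1e-2)))
  expect_equal(r * doubling_time(r), rep(log(2), 20))
})

test_that("rate_table reproduces the printed family table", {
  ft <- family_table()
  expect_equal(nrow(ft), 18L)
  rt <- rate_table(ft)
  expect_equal(nrow(rt), 36L)  # 18 families x 2 catalogs

  matches_printed <- function(r, printed) {
    round(r, 5) == printed | trunc(r * 1e5) / 1e5 == printed
  }
  eth <- merge(rt[rt$catalog == "ethnologue", ],
               ft[, c("family", "r_ethno_printed", "t2_ethno_printed")])
  glo <- merge(rt[rt$catalog == "glottolog", ],
               ft[, c("family", "r_glotto_printed", "t2_glotto_printed")])
  # every family except the internally inconsistent Dravidian row reproduces
  ok_e <- matches_printed(eth$r_e, eth$r_ethno_printed)
  ok_g <- matches_printed(glo$r_e, glo$r_glotto_printed)
  expect_identical(eth$family[!ok_e], "Dravidian")
  expect_identical(glo$family[!ok_g], "Dravidian")

  # printed Ethnologue doubling times follow round(ln2/round(r, 5)) for all
  # rows but Dravidian and Pama-Nyungan...
  d4 <- eth$family[eth$doubling_time_yr == eth$t2_ethno_printed]
  expect_setequal(setdiff(eth$family, d4), c("Dravidian", "Pama-Nyungan"))
  # ...and Pama-Nyungan matches the unrounded-rate ("raw") convention
  raw <- rate_table(ft, convention = "raw")
  pn <- raw[raw$family == "Pama-Nyungan" & raw$catalog == "ethnologue", ]
  expect_equal(pn$doubling_time_yr,
               ft$t2_ethno_printed[ft$family == "Pama-Nyungan"])
})

test_that("rate_table ordering, permutation invariance, and column oracle", {
  ft <- family_table()
  rt <- rate_table(ft)
  eth <- rt[rt$catalog == "ethnologue", ]
  expect_true(!is.unsorted(eth$r_e))

  shuffled <- rate_table(ft[sample(nrow(ft)), ])
  expect_equal(shuffled, rt)

  # direct-formula recomputation, column-wise
  expect_equal(rt$r_e, log(rt$n_used) / rt$root_age_yr)

  # records missing both counts are skipped with a warning
  broken <- ft
  broken$n_ethnologue[1] <- NA
  broken$n_glottolog[1] <- NA
  expect_warning(out <- rate_table(broken), "skipped")
  expect_false(ft$family[1] %in% out$family)
  expect_error(suppressWarnings(rate_table(ft[0, ])), "no usable")
})

test_that("normalize_ltt rescales and round-trips", {
  s <- compute_ltt(read_newick("(A:2,B:2);")[[1]])
  norm <- normalize_ltt(s, n_max = 2, root_age = 2)
  expect_equal(norm$t_prime, 1)
  expect_equal(norm$n_prime, 1)

  tr <- sim_tree(61, lambda0 = 0.002, max_time = 3000)$tree
  s <- compute_ltt(tr)
  n_max <- ape::Ntip(tr)
  norm <- normalize_ltt(s, n_max = n_max, root_age = root_age(tr))
  expect_equal(norm$n_prime[length(norm$n_prime)], 1)
  # de-normalizing recovers the original series
  expect_equal(norm$t_prime * root_age(tr), s$times, tolerance = 1e-12)
  expect_equal(norm$n_prime * n_max, s$counts, tolerance = 1e-12)

  expect_error(normalize_ltt(s, n_max = n_max - 1, root_age = root_age(tr)),
               "configuration mistake")
})

test_that("binned_rates: constant-rate identity, zeros, and telescoping", {
  # N doubling every 10% of the time depth: all bins share one rate
  root_age <- 4000
  s <- ltt_series(seq(1, 0, by = -0.1) * root_age, 2^(1:11))
  norm <- normalize_ltt(s, n_max = 2048, root_age = root_age)
  br <- binned_rates(norm)
  expect_equal(br$rate, rep(log(2) / (0.1 * root_age), 10))
  expect_equal(br$ln_n_start[1], log(2))

  # constant series: every bin rate is 0
  const <- normalize_ltt(ltt_series(root_age, 4), 4, root_age)
  expect_equal(binned_rates(const)$rate, rep(0, 10))

  # telescoping invariant on simulated trees, at 10 and 7 bins
  for (seed in c(8, 19, 42, 77, 90)) {
    tr <- sim_tree(seed, lambda0 = 0.0025, max_time = 2500)$tree
    s <- compute_ltt(tr)
    norm <- normalize_ltt(s, ape::Ntip(tr), root_age(tr))
    for (nb in c(10, 7)) {
      br <- binned_rates(norm, n_bins = nb)
      lhs <- sum(br$rate * (br$t_hi - br$t_lo) * root_age(tr))
      expect_equal(lhs, log(s$counts[length(s$counts)] / s$counts[1]),
                   tolerance = 1e-12)
    }
  }
  expect_error(binned_rates(norm, n_bins = 1), ">= 2")
})

test_that("mean_rate is deterministic, degenerate-safe, and calibrated", {
  r <- c(0.001, 0.002, 0.0005, 0.0015, 0.0008)
  a <- mean_rate(r, reps = 2000, seed = 11)
  b <- mean_rate(r, reps = 2000, seed = 11)
  expect_identical(a, b)
  expect_equal(a$mean, mean(r))
  expect_lte(a$ci[1], a$mean)
  expect_gte(a$ci[2], a$mean)

  same <- mean_rate(rep(0.001, 5), reps = 1000, seed = 3)
  expect_equal(unname(same$ci), c(0.001, 0.001))

  # percentile CI roughly agrees with the normal-theory CI on Gaussian rates
  set.seed(99)
  g <- rnorm(60, mean = 0.001, sd = 0.0002)
  ci <- mean_rate(g, reps = 5000, seed = 21)$ci
  se <- sd(g) / sqrt(length(g))
  ref <- mean(g) + c(-1.96, 1.96) * se
  expect_equal(unname(ci), ref, tolerance = 0.1)

  expect_error(mean_rate(0.001, seed = 1), ">= 2")
  expect_error(mean_rate(r, reps = 10, seed = 1), ">= 1000")
  expect_error(mean_rate(r, reps = 1000), "required")
})
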