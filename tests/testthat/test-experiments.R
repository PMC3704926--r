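small_pop <- function(strategy = "UNI", alpha = 0.1, cost = 0.1, n = 80,
                      L = 200, h = 0.2) {
  init_population(n, 20, genetic_params(L = L, s = 0.1, h = h),
                  dispersal_params(alpha_U = alpha, alpha_F = alpha,
                                   cost = cost), strategy = strategy)
}

test_that("steady-state runs start at fitness one and converge deterministically", {
  set.seed(31)
  eq <- run_steady_state(small_pop(), min_gens = 100, max_gens = 400,
                         window = 80, check_every = 40)
  expect_equal(eq$records$mean_fitness[1], 1)
  expect_lt(eq$steady$mean_fitness, 1)
  expect_equal(eq$generations + 1, nrow(eq$records))
  # declining-trend initial phase: early fitness above late fitness
  expect_gt(mean(head(eq$records$mean_fitness, 20)),
            mean(tail(eq$records$mean_fitness, 20)))
  # rerun under the same seed reproduces the plateau statistics exactly
  set.seed(31)
  eq2 <- run_steady_state(small_pop(), min_gens = 100, max_gens = 400,
                          window = 80, check_every = 40)
  expect_identical(eq$steady, eq2$steady)
  expect_identical(eq$records, eq2$records)
  # a heterogeneous population is rejected
  mixed <- introduce_invader(small_pop(), "FAD", f = 0.1)
  expect_error(run_steady_state(mixed), "homogeneous")
})

test_that("invader introduction hits the requested allele frequency exactly", {
  set.seed(32)
  pop <- small_pop(n = 100)
  inv <- introduce_invader(pop, "FAD", f = 0.05)
  expect_equal(sum(inv$mod_a == 2 & inv$mod_b == 2), 5)
  expect_equal(population_summary(inv)$invader_freq, 0.05)
  expect_equal(inv$alleles$strategy, c("UNI", "FAD"))
  expect_error(introduce_invader(pop, "FAD", f = 0), "strictly between")
  expect_error(introduce_invader(inv, "FAD", f = 0.05), "homogeneous")
  # an explicit invader dispersal rate overrides the strategy default
  inv2 <- introduce_invader(pop, "UNI", invader_alpha = 0.4, f = 0.05)
  expect_equal(inv2$alleles$alpha[2], 0.4)
})

test_that("invasions end in one of the three declared outcomes", {
  set.seed(33)
  pop <- small_pop(n = 60)
  burn <- run_generations(pop, 150, record = FALSE)$pop
  for (i in 1:5) {
    res <- run_invasion(burn, "FAD", f = 0.05, g_max = 400,
                        seed = 1000 + i)
    expect_true(res$outcome %in% c("fixed", "extinct", "timeout"))
    expect_equal(res$trajectory$invader_freq[1], 0.05)
    final <- switch(res$outcome, fixed = 1, extinct = 0, res$final_freq)
    expect_equal(res$final_freq, final)
    if (res$outcome == "timeout") expect_equal(res$generations, 400)
  }
})

test_that("takeover time follows the threshold-crossing definition", {
  expect_equal(takeover_time(c(0.01, 0.3, 0.85)), 2)
  expect_true(is.na(takeover_time(c(0.01, 0.5, 0.79))))
  # already above the lower threshold: measured from generation 0
  expect_equal(takeover_time(c(0.05, 0.2, 0.9)), 2)
  expect_equal(takeover_time(c(0.005, 0.02, 0.5, 0.81)), 2)
  traj <- data.frame(generation = c(0, 5, 10), invader_freq = c(0.01, 0.4, 0.9))
  expect_equal(takeover_time(traj), 10)
})

test_that("the exact binomial test equals direct tail summation", {
  expect_equal(exact_binomial_test(0, 10, 0.05), 1)
  expect_equal(exact_binomial_test(100, 100, 0.05), 0.05^100)
  expect_equal(exact_binomial_test(20, 50, 0.05),
               brute_binom_upper_tail(20, 50, 0.05))
  for (k in c(1, 3, 7, 12)) {
    expect_equal(exact_binomial_test(k, 25, 0.2),
                 brute_binom_upper_tail(k, 25, 0.2))
  }
  expect_error(exact_binomial_test(5, 4, 0.1), "k <= n")
  expect_error(exact_binomial_test(-1, 4, 0.1), "k <= n")
  expect_error(exact_binomial_test(2, 4, 0), "p0")
  expect_error(exact_binomial_test(2.5, 4, 0.1), "integer")
})

test_that("invasion outcome cells classify as in the four-way scheme", {
  fake <- function(n, fixed, timeout_freq = numeric(0)) {
    n_to <- length(timeout_freq)
    data.frame(outcome = c(rep("fixed", fixed), rep("timeout", n_to),
                           rep("extinct", n - fixed - n_to)),
               final_freq = c(rep(1, fixed), timeout_freq,
                              rep(0, n - fixed - n_to)))
  }
  expect_equal(as.character(classify_invasion_outcomes(
    fake(100, 80), fake(100, 30), f = 0.01)), "both_succeed")
  expect_equal(as.character(classify_invasion_outcomes(
    fake(100, 80), fake(100, 1), f = 0.01)), "only_FAD")
  expect_equal(as.character(classify_invasion_outcomes(
    fake(100, 0), fake(100, 0), f = 0.01)), "none")
  expect_equal(as.character(classify_invasion_outcomes(
    fake(100, 0, rep(0.5, 60)), fake(100, 0), f = 0.01)),
    "FAD_polymorphism")
  expect_error(classify_invasion_outcomes(fake(10, 1), fake(9, 1), 0.01),
               "same number")
})

test_that("neutral invasions fix at about the initial frequency", {
  set.seed(34)
  pop <- small_pop(n = 60, L = 100)
  burn <- run_generations(pop, 200, record = FALSE)$pop
  tb <- run_invasion_replicates(burn, 60, "UNI", f = 0.1, g_max = 5000,
                                base_seed = 99)
  k <- sum(tb$outcome == "fixed")
  # two-sided exact test against p = 0.1 must not reject at the 1% level
  expect_gt(stats::binom.test(k, 60, 0.1)$p.value, 0.01)
  expect_true(all(tb$outcome %in% c("fixed", "extinct", "timeout")))
})

test_that("replicate seeds are deterministic, distinct, and below 2^31", {
  s1 <- vapply(1:500, function(i) replicate_seed(7, i), integer(1))
  expect_equal(anyDuplicated(s1), 0)
  expect_true(all(s1 > 0 & s1 < 2^31))
  expect_identical(replicate_seed(7, 3), replicate_seed(7, 3))
  expect_false(replicate_seed(8, 3) == replicate_seed(7, 3))
})

test_that("parameter sweeps produce one row per replicate and rerun identically", {
  grid <- expand.grid(alpha = c(0.1), cost = c(0, 0.3))
  args <- list(grid = grid, experiment = "invasion", n_reps = 3,
               n_total = 60, L = 100, f = 0.05, g_max = 300, base_seed = 5,
               steady = list(min_gens = 80, max_gens = 150, window = 50,
                             check_every = 50))
  sw1 <- do.call(run_parameter_sweep, args)
  sw2 <- do.call(run_parameter_sweep, args)
  expect_identical(sw1$replicates, sw2$replicates)
  expect_equal(nrow(sw1$replicates), nrow(grid) * 3)
  expect_equal(nrow(sw1$cells), nrow(grid))
  expect_true(all(c("run_id", "seed", "alpha_res", "alpha_inv", "c", "h",
                    "s", "strategy_res", "strategy_inv", "f0", "outcome",
                    "takeover_gens", "final_freq", "mean_fitness_end",
                    "het_fraction_end") %in% names(sw1$replicates)))
  # per-cell failures are recorded without aborting the sweep
  bad <- expand.grid(alpha = c(1), cost = c(1))
  swb <- run_parameter_sweep(bad, "invasion", n_reps = 2, n_total = 30,
                             L = 50, f = 0.05, g_max = 50, base_seed = 5,
                             steady = list(min_gens = 20, max_gens = 40,
                                           window = 20, check_every = 20))
  expect_true(all(swb$cells$status == "error"))
  expect_match(swb$cells$message[1], "extinct|reproduce")
})

test_that("steady-state sweeps report per-cell plateau statistics", {
  grid <- data.frame(alpha = 0.1, cost = 0.1, strategy = c("UNI", "FAD"))
  sw <- run_parameter_sweep(grid, "steady_state", n_reps = 2, n_total = 60,
                            L = 100, base_seed = 3,
                            steady = list(min_gens = 60, max_gens = 120,
                                          window = 40, check_every = 30))
  expect_equal(nrow(sw$cells), 2)
  expect_true(all(c("mean_fitness", "mean_fitness_se", "het_fraction",
                    "het_fraction_se") %in% names(sw$cells)))
  expect_true(all(sw$cells$mean_fitness > 0 & sw$cells$mean_fitness <= 1))
})
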