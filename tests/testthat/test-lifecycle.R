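test_that("zero dispersal rates leave the population untouched", {
  g <- genetic_params(L = 50)
  pop <- make_test_pop(runif(30, 0.5, 1), rep(1:3, each = 10), genetics = g,
                       dispersal = dispersal_params(alpha_U = 0, alpha_F = 0,
                                                    cost = 0.5))
  set.seed(4)
  out <- dispersal_stage(pop)
  expect_identical(out$deme, pop$deme)
  expect_identical(out$fitness, pop$fitness)
  expect_equal(length(out$fitness), length(pop$fitness))
})

test_that("certain dispersal with certain death extinguishes an all-FAD population", {
  g <- genetic_params(L = 50)
  pop <- make_test_pop(rep(1, 10), rep(1:2, each = 5), genetics = g,
                       strategy = "FAD",
                       dispersal = dispersal_params(alpha_U = 1, alpha_F = 1,
                                                    cost = 1))
  set.seed(5)
  expect_error(dispersal_stage(pop), "extinct")
})

test_that("FAD dispersers are exactly the lowest-fitness individuals", {
  g <- genetic_params(L = 50)
  set.seed(6)
  for (rep in 1:30) {
    fit <- sample(seq(0.1, 1, length.out = 10))
    pop <- make_test_pop(fit, rep(1:2, 5), genetics = g, strategy = "FAD",
                         dispersal = dispersal_params(alpha_U = 0.3,
                                                      alpha_F = 0.3,
                                                      cost = 1))
    # cost = 1 kills every disperser, so the survivors reveal who was marked
    out <- tryCatch(dispersal_stage(pop), error = function(e) NULL)
    if (is.null(out)) next # all ten dispersed and perished
    k <- 10 - length(out$fitness)
    # the k killed dispersers must be the k lowest-fitness individuals
    expect_equal(sort(out$fitness), sort(fit)[seq(k + 1, 10)])
  }
})

test_that("UNI disperser counts are marginally Binomial(N, alpha)", {
  g <- genetic_params(L = 10)
  set.seed(7)
  pop <- make_test_pop(rep(1, 5000), rep(1:250, each = 20), genetics = g,
                       dispersal = dispersal_params(alpha_U = 0.3, cost = 1))
  n_rep <- 1000
  killed <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    killed[i] <- 5000 - length(dispersal_stage(pop)$fitness)
  }
  se <- sqrt(5000 * 0.3 * 0.7 / n_rep)
  expect_lt(abs(mean(killed) - 1500), 3 * se)
})

test_that("FAD disperser counts match the binomial expectation and cost is genotype-blind", {
  g <- genetic_params(L = 10)
  set.seed(8)
  # equal-fitness all-FAD population: the count distribution is Binomial
  pop <- make_test_pop(rep(1, 1000), rep(1:50, each = 20), genetics = g,
                       strategy = "FAD",
                       dispersal = dispersal_params(alpha_F = 0.3, cost = 0.5))
  n_rep <- 500
  killed <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    killed[i] <- 1000 - length(dispersal_stage(pop)$fitness)
  }
  # deaths ~ Binomial(n_F, alpha_F * cost): mean 150
  se <- sqrt(1000 * 0.15 * 0.85 / n_rep)
  expect_lt(abs(mean(killed) - 150), 3 * se)
})

test_that("dispersal relocates survivors uniformly across demes (island model)", {
  g <- genetic_params(L = 10)
  set.seed(9)
  pop <- make_test_pop(rep(1, 400), rep(1:20, each = 20), genetics = g,
                       dispersal = dispersal_params(alpha_U = 1, cost = 0))
  counts <- numeric(20)
  n_rep <- 50
  for (i in seq_len(n_rep)) {
    out <- dispersal_stage(pop)
    counts <- counts + tabulate(out$deme, 20)
  }
  # every deme expects 400/20 = 20 landings per stage
  expect_lt(max(abs(counts / n_rep - 20)), 3 * sqrt(20 / n_rep) + 1)
  expect_equal(sum(counts), 400 * n_rep)
})

test_that("parent demes are chosen by size among demes with at least two adults", {
  g <- genetic_params(L = 10)
  pop <- make_test_pop(rep(1, 11), c(rep(1, 2), rep(2, 8), 3), genetics = g)
  set.seed(10)
  draws <- replicate(10000, choose_parent_deme(pop))
  expect_false(any(draws == 3)) # singleton deme is never eligible
  p2 <- mean(draws == 2)
  expect_lt(abs(p2 - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  # single eligible deme is always chosen
  pop1 <- make_test_pop(rep(1, 3), c(1, 1, 2), genetics = g)
  expect_true(all(replicate(50, choose_parent_deme(pop1)) == 1))
  # no eligible deme is an error
  pop0 <- make_test_pop(rep(1, 2), c(1, 2), genetics = g)
  expect_error(choose_parent_deme(pop0), "cannot reproduce")
})

test_that("offspring production follows Mendelian rules and viability selection", {
  g <- genetic_params(L = 50, U = 0)
  pop <- make_test_pop(rep(1, 2), c(1, 1), genetics = g,
                       strategy = "UNI", invader_strategy = "FAD",
                       mod_a = c(1L, 2L), mod_b = c(1L, 2L),
                       phenotype = c(1L, 2L))
  set.seed(11)
  # mutation-free parents, U = 0: every conception survives with fitness 1
  for (i in 1:20) {
    child <- produce_offspring(pop, 1)
    expect_s3_class(child, "fad_individual")
    expect_identical(child$fitness, 1)
    # UNI/UNI x FAD/FAD -> always heterozygous
    expect_setequal(child$modifier, c(1L, 2L))
  }
  expect_error(produce_offspring(pop, 2), "fewer than two")
})

test_that("reproduction restores the census and only breeds eligible demes", {
  g <- genetic_params(L = 100, U = 0.5)
  set.seed(12)
  pop <- make_test_pop(rep(1, 40), c(rep(1, 39), 2), capacity = 50,
                       genetics = g)
  out <- reproduction_stage(pop)
  expect_equal(length(out$fitness), 40)
  expect_true(all(out$deme == 1)) # the singleton deme cannot breed
  # fitness caches on the offspring are coherent with their genomes
  mn <- fadsim:::engine_mn_matrix(fadsim:::pop_to_engine(out))
  expect_equal(out$fitness, fitness_of(mn[, "m"], mn[, "n"], g))
})

test_that("a full generation conserves the census and respects capacity", {
  set.seed(13)
  pop <- init_population(200, 20, genetic_params(L = 200),
                         dispersal_params(alpha_U = 0.2, cost = 0.3))
  for (i in 1:5) {
    pop <- step_generation(pop)
    expect_population_invariants(pop)
    rec <- attr(pop, "generation_record")
    expect_s3_class(rec, "data.frame")
    expect_equal(rec$n_demes, pop$n_demes)
  }
})

test_that("a closed deme without mutation or dispersal keeps its census forever", {
  g <- genetic_params(L = 50, U = 0)
  pop <- make_test_pop(rep(1, 10), rep(1, 10), capacity = 20, genetics = g,
                       dispersal = dispersal_params(alpha_U = 0,
                                                    alpha_F = 0, cost = 0))
  set.seed(14)
  res <- run_generations(pop, 20)
  expect_true(all(res$records$mean_fitness == 1))
  expect_true(all(res$records$n_demes == 1))
})

test_that("runs are bit-identical under a fixed seed", {
  run_once <- function() {
    set.seed(20240101)
    pop <- init_population(100, 20, genetic_params(L = 200),
                           dispersal_params(alpha_U = 0.1, alpha_F = 0.1,
                                            cost = 0.1))
    run_generations(pop, 30)$records
  }
  expect_identical(run_once(), run_once())
})

test_that("equal-rate FAD and UNI dispersal are indistinguishable at equal fitness", {
  g <- genetic_params(L = 10)
  set.seed(15)
  deaths <- function(strategy) {
    pop <- make_test_pop(rep(1, 800), rep(1:40, each = 20), genetics = g,
                         strategy = strategy,
                         dispersal = dispersal_params(alpha_U = 0.25,
                                                      alpha_F = 0.25,
                                                      cost = 1))
    replicate(400, 800 - length(dispersal_stage(pop)$fitness))
  }
  d_uni <- deaths("UNI")
  d_fad <- deaths("FAD")
  # both marginally Binomial(800, 0.25): compare means within 3 SE
  se <- sqrt(2 * 800 * 0.25 * 0.75 / 400)
  expect_lt(abs(mean(d_uni) - mean(d_fad)), 3 * se)
})
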