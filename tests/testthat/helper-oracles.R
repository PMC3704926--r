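# Independent brute-force oracles (plain R, per-locus scans) and small
# population builders used across the test files.

# per-locus scan of both chromosome copies
brute_count_classes <- function(hap_a, hap_b, L) {
  m <- 0L
  n <- 0L
  for (j in 0:(L - 1)) {
    a <- j %in% hap_a
    b <- j %in% hap_b
    if (a && b) m <- m + 1L
    if (xor(a, b)) n <- n + 1L
  }
  c(m = m, n = n)
}

# per-locus crossover oracle: locus j comes from the starting copy when an
# even number of breakpoints lies at or below it
brute_splice <- function(hap_a, hap_b, breakpoints, start_a, L) {
  out <- integer(0)
  for (j in 0:(L - 1)) {
    seg <- sum(breakpoints <= j)
    from_a <- (seg %% 2 == 0) == start_a
    carried <- if (from_a) j %in% hap_a else j %in% hap_b
    if (carried) out <- c(out, j)
  }
  out
}

# direct tail summation for the one-sided exact binomial test
brute_binom_upper_tail <- function(k, n, p0) {
  i <- k:n
  sum(choose(n, i) * p0^i * (1 - p0)^(n - i))
}

# random sparse haplotype over L loci
random_hap <- function(L, max_size = 10) {
  k <- sample(0:max_size, 1)
  sort(sample(0:(L - 1), k))
}

# small population with explicit fields, for controlled lifecycle tests;
# all individuals share the genetics/dispersal configuration given
make_test_pop <- function(fitness, deme, phenotype = NULL,
                          mod_a = NULL, mod_b = NULL,
                          capacity = 20,
                          genetics = genetic_params(L = 100),
                          dispersal = dispersal_params(),
                          strategy = "UNI", invader_strategy = NULL,
                          invader_alpha = NULL) {
  n <- length(fitness)
  pop <- init_population(n, capacity, genetics, dispersal,
                         strategy = strategy,
                         invader_strategy = invader_strategy,
                         invader_alpha = invader_alpha)
  pop$fitness <- as.numeric(fitness)
  pop$deme <- as.integer(deme)
  pop$n_demes <- max(pop$deme)
  if (!is.null(mod_a)) pop$mod_a <- as.integer(mod_a)
  if (!is.null(mod_b)) pop$mod_b <- as.integer(mod_b)
  if (!is.null(phenotype)) pop$phenotype <- as.integer(phenotype)
  else pop$phenotype <- pop$mod_a
  pop
}

# deme sizes never exceed capacity and sum to n_total
expect_population_invariants <- function(pop) {
  expect_length(pop$fitness, pop$n_total)
  expect_true(all(deme_sizes(pop) >= 1))
  expect_true(all(deme_sizes(pop) <= pop$capacity))
  expect_equal(sum(deme_sizes(pop)), pop$n_total)
}
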