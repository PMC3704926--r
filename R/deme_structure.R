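#' Dispersal parameters
#'
#' @param alpha_U Dispersal probability of a UNI individual, in \[0, 1\].
#' @param alpha_F Mean dispersal rate of the FAD sub-population, in \[0, 1\]:
#'   the number of FAD dispersers is Binomial(`n_F`, `alpha_F`) and the
#'   least fit FAD individuals disperse first.
#' @param cost Cost of dispersal `c` in \[0, 1\]: the probability that a
#'   disperser perishes before reaching its target deme.
#' @param fad_ranking `"global"` ranks FAD individuals population-wide
#'   (default); `"per_deme"` draws the binomial count and ranks within each
#'   deme, provided for sensitivity analysis.
#' @return An object of class `fad_dispersal_params`.
#' @examples
#' dispersal_params(alpha_U = 0.1, cost = 0.3)
#' @export
dispersal_params <- function(alpha_U = 0.1, alpha_F = alpha_U, cost = 0,
                             fad_ranking = c("global", "per_deme")) {
  for (nm in c("alpha_U", "alpha_F", "cost")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(nm, " must be a probability in [0, 1]")
  }
  structure(list(alpha_U = alpha_U, alpha_F = alpha_F, cost = cost,
                 fad_ranking = match.arg(fad_ranking)),
            class = "fad_dispersal_params")
}

#' @export
print.fad_dispersal_params <- function(x, ...) {
  cat(sprintf(
    "Dispersal parameters: alpha_U = %g, alpha_F = %g, cost = %g (%s FAD ranking)\n",
    x$alpha_U, x$alpha_F, x$cost, x$fad_ranking))
  invisible(x)
}

strategy_alpha <- function(strategy, dispersal) {
  ifelse(strategy == "FAD", dispersal$alpha_F, dispersal$alpha_U)
}

# allele-slot table: slot 1 is the resident allele, slot 2 the invader
# (identical to slot 1 in homogeneous populations)
allele_table <- function(resident_strategy, dispersal,
                         invader_strategy = NULL, invader_alpha = NULL) {
  resident_strategy <- match.arg(resident_strategy, c("UNI", "FAD"))
  inv <- invader_strategy %||% resident_strategy
  inv <- match.arg(inv, c("UNI", "FAD"))
  data.frame(
    strategy = c(resident_strategy, inv),
    alpha = c(strategy_alpha(resident_strategy, dispersal),
              invader_alpha %||% strategy_alpha(inv, dispersal)),
    stringsAsFactors = FALSE)
}

#' Initialize a population
#'
#' Allocates `n_total` mutation-free individuals (fitness 1) to
#' `ceiling(n_total / capacity)` demes of size at most `capacity`.  The
#' modifier locus holds two allele slots: slot 1 carries the resident
#' strategy, slot 2 the invader strategy (equal to the resident when no
#' invader is configured).  `round(invader_freq * n_total)` individuals,
#' chosen uniformly at random, are made invader-homozygous, so the initial
#' invader allele frequency is exactly `invader_freq` up to rounding.
#'
#' @param n_total Total population size, constant across generations
#'   (default 5000).
#' @param capacity Maximum deme size `K` (default 20).
#' @param genetics [genetic_params()].
#' @param dispersal [dispersal_params()].
#' @param strategy Resident dispersal strategy, `"UNI"` or `"FAD"`.
#' @param invader_strategy,invader_alpha Strategy and dispersal rate of the
#'   invader allele slot; default to the resident's.
#' @param invader_freq Initial invader allele frequency in \[0, 1\].
#' @param attempt_factor Conception attempts allowed per generation, as a
#'   multiple of `n_total`, before the reproduction stage aborts with a
#'   diagnostic error.
#' @return An object of class `fad_population`.
#' @examples
#' pop <- init_population(n_total = 100, capacity = 20,
#'                        genetics = genetic_params(L = 100))
#' deme_sizes(pop)
#' @export
init_population <- function(n_total = 5000, capacity = 20,
                            genetics = genetic_params(),
                            dispersal = dispersal_params(),
                            strategy = "UNI", invader_strategy = NULL,
                            invader_alpha = NULL, invader_freq = 0,
                            attempt_factor = 1000) {
  n_total <- as.integer(n_total)
  capacity <- as.integer(capacity)
  if (is.na(n_total) || n_total < 2)
    stop("n_total must be at least 2")
  if (is.na(capacity) || capacity < 1)
    stop("capacity must be a positive integer")
  if (!is.numeric(invader_freq) || invader_freq < 0 || invader_freq > 1)
    stop("invader_freq must lie in [0, 1]")
  alleles <- allele_table(strategy, dispersal, invader_strategy,
                          invader_alpha)
  n_demes <- as.integer(ceiling(n_total / capacity))
  deme <- rep(seq_len(n_demes), each = capacity)[seq_len(n_total)]
  mod <- rep(1L, n_total)
  k <- round(invader_freq * n_total)
  if (k > 0) mod[sample.int(n_total, k)] <- 2L
  empty <- replicate(n_total, integer(0), simplify = FALSE)
  pop <- structure(list(
    hap_a = empty, hap_b = empty,
    mod_a = mod, mod_b = mod,
    phenotype = mod, # homozygotes express their own allele
    fitness = rep(1, n_total),
    deme = deme,
    n_demes = n_demes, n_total = n_total, capacity = capacity,
    genetics = genetics, dispersal = dispersal, alleles = alleles,
    attempt_factor = attempt_factor), class = "fad_population")
  pop
}

# engine boundary helpers -----------------------------------------------------

pop_to_engine <- function(pop) {
  pop[c("hap_a", "hap_b", "mod_a", "mod_b", "phenotype", "fitness", "deme",
        "n_demes", "n_total", "capacity")]
}

pop_from_engine <- function(raw, template) {
  out <- template
  for (f in names(raw)) out[[f]] <- raw[[f]]
  out
}

engine_params_of <- function(pop) {
  g <- pop$genetics
  list(L = g$L, s = g$s, h = g$h, U = g$U, R = g$R,
       strategy = as.integer(pop$alleles$strategy == "FAD"),
       alpha = as.numeric(pop$alleles$alpha),
       cost = pop$dispersal$cost,
       fad_per_deme = identical(pop$dispersal$fad_ranking, "per_deme"),
       attempt_factor = pop$attempt_factor)
}

#' Deme census
#'
#' @param pop A `fad_population`.
#' @return Integer vector of deme sizes (length `pop$n_demes`; empty demes
#'   count 0).
#' @export
deme_sizes <- function(pop) {
  tabulate(pop$deme, nbins = pop$n_demes)
}

#' Split demes above capacity
#'
#' Every deme whose size strictly exceeds the capacity `K` is replaced by two
#' demes partitioning its members uniformly at random into halves of size
#' `floor(n/2)` and `ceiling(n/2)`; halves still above `K` are re-split.
#' Total membership is conserved.
#'
#' @param pop A `fad_population`.
#' @return The population with renumbered demes, each of size at most `K`.
#' @export
split_oversized_demes <- function(pop) {
  pop_from_engine(engine_split_demes(pop_to_engine(pop)), pop)
}

#' Remove empty demes
#'
#' Demes with no members are dropped and the remaining demes renumbered;
#' individuals are untouched.
#'
#' @param pop A `fad_population`.
#' @return The compacted population.
#' @export
drop_empty_demes <- function(pop) {
  pop_from_engine(engine_drop_empty_demes(pop_to_engine(pop)), pop)
}

#' Population summary statistics (one generation record)
#'
#' Computes the arithmetic mean viability; the heterozygosity fraction
#' (by default pooled population-wide: the summed heterozygous mutation count
#' over the summed mutant allele copies, with 0/0 defined as 0); the mean
#' number of heterozygous deleterious loci per individual; the invader
#' (allele slot 2) frequency and the FAD-strategy allele frequency at the
#' modifier locus; the mean viability of the carriers of FAD-strategy and of
#' UNI-strategy modifier allele copies (allele-copy-weighted, the quantity
#' tracked along invasion trajectories); the expected
#' dispersal-mortality-inclusive mean fitness (each adult's viability
#' discounted by `cost` times its probability of dispersing this
#' generation, the statistic on which the cost of dispersal acts directly);
#' and the deme count.
#'
#' @param pop A non-empty `fad_population`.
#' @param het_method `"pooled"` (default) or `"per_individual"` (mean over
#'   individuals of `n / (n + 2m)`, individuals without mutations counting 0).
#' @return One-row data frame with columns `mean_fitness`, `het_fraction`,
#'   `invader_freq`, `fad_allele_freq`, `n_demes`, `mean_fitness_fad`,
#'   `mean_fitness_uni`, `mean_het_loci`, `mean_fitness_costed`.
#' @examples
#' pop <- init_population(50, 10, genetic_params(L = 100))
#' population_summary(pop)
#' @export
population_summary <- function(pop, het_method = c("pooled",
                                                   "per_individual")) {
  het_method <- match.arg(het_method)
  if (length(pop$fitness) == 0) stop("cannot summarize an empty population")
  s <- engine_summary(pop_to_engine(pop), engine_params_of(pop))
  het <- s[["het_fraction"]]
  if (het_method == "per_individual") {
    mn <- engine_mn_matrix(pop_to_engine(pop))
    tot <- mn[, "n"] + 2 * mn[, "m"]
    frac <- ifelse(tot > 0, mn[, "n"] / tot, 0)
    het <- mean(frac)
  }
  data.frame(mean_fitness = s[["mean_fitness"]],
             het_fraction = het,
             invader_freq = s[["freq_slot2"]],
             fad_allele_freq = fad_allele_freq(s[["freq_slot2"]],
                                               pop$alleles),
             n_demes = as.integer(s[["n_demes"]]),
             mean_fitness_fad = s[["mean_fitness_fad"]],
             mean_fitness_uni = s[["mean_fitness_uni"]],
             mean_het_loci = s[["mean_het_loci"]],
             mean_fitness_costed = s[["mean_fitness_costed"]])
}

# frequency of FAD-strategy alleles given the slot-2 frequency
fad_allele_freq <- function(freq2, alleles) {
  is_fad <- alleles$strategy == "FAD"
  if (is_fad[1] && is_fad[2]) rep(1, length(freq2))
  else if (is_fad[2]) freq2
  else if (is_fad[1]) 1 - freq2
  else rep(0, length(freq2))
}

#' @export
print.fad_population <- function(x, ...) {
  s <- population_summary(x)
  cat(sprintf("Island-model population: %d individuals in %d demes (K = %d)\n",
              length(x$fitness), x$n_demes, x$capacity))
  cat(sprintf("  alleles: 1 = %s (alpha = %g), 2 = %s (alpha = %g), cost = %g\n",
              x$alleles$strategy[1], x$alleles$alpha[1],
              x$alleles$strategy[2], x$alleles$alpha[2], x$dispersal$cost))
  cat(sprintf("  mean fitness %.4f, het fraction %.4f, invader freq %.4f\n",
              s$mean_fitness, s$het_fraction, s$invader_freq))
  invisible(x)
}
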