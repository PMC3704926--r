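#' Genetic parameters
#'
#' Bundles the parameters of the genome model: `L` bi-allelic fitness loci on
#' one linear map, selection coefficient `s` and dominance coefficient `h` of
#' the deleterious mutant alleles, genome-wide mutation rate `U` (expected new
#' mutations per diploid genome per generation, Poisson), and map length `R`
#' (expected crossover events among the fitness loci per transmitted gamete,
#' Poisson).
#'
#' @param L Number of diploid fitness loci (default 10000).
#' @param s Selection coefficient against a homozygous deleterious mutation,
#'   in (0, 1).  A homozygote at `m` loci and heterozygote at `n` loci
#'   survives to adulthood with probability `(1 - s)^m * (1 - h*s)^n`.
#' @param h Dominance coefficient in \[0, 1\]; `h = 0.5` means no masking of
#'   the mutant allele in heterozygotes.
#' @param U Expected number of new deleterious mutations per diploid genome
#'   per generation.
#' @param R Expected number of crossover events among the fitness loci per
#'   gamete.
#' @return An object of class `fad_genetic_params`.
#' @examples
#' genetic_params(L = 1000, s = 0.1, h = 0.2)
#' @export
genetic_params <- function(L = 10000, s = 0.1, h = 0.2, U = 0.5, R = 20) {
  L <- as.integer(L)
  if (is.na(L) || L < 1) stop("L must be a positive integer")
  if (!is.numeric(s) || s <= 0 || s >= 1)
    stop("s must lie strictly between 0 and 1 (s >= 1 would give ",
         "non-positive fitness)")
  if (!is.numeric(h) || h < 0 || h > 1) stop("h must lie in [0, 1]")
  if (!is.numeric(U) || U < 0) stop("U must be non-negative")
  if (!is.numeric(R) || R < 0) stop("R must be non-negative")
  structure(list(L = L, s = s, h = h, U = U, R = R),
            class = "fad_genetic_params")
}

#' @export
print.fad_genetic_params <- function(x, ...) {
  cat(sprintf(
    "Genetic parameters: L = %d loci, s = %g, h = %g, U = %g, R = %g\n",
    x$L, x$s, x$h, x$U, x$R))
  invisible(x)
}

#' Construct a haplotype
#'
#' A haplotype is the sparse set of 0-based fitness-locus indices carrying
#' the deleterious mutant allele on one chromosome copy, stored as a sorted
#' integer vector.
#'
#' @param loci Integer vector of mutant locus indices in `[0, L - 1]`.
#' @param L Number of fitness loci.
#' @return Sorted integer vector of unique, in-range locus indices.
#' @examples
#' haplotype(c(7, 2, 2), L = 10)
#' @export
haplotype <- function(loci = integer(0), L = 10000) {
  loci <- as.integer(loci)
  if (anyNA(loci)) stop("haplotype loci must not be NA")
  if (length(loci) && (min(loci) < 0 || max(loci) >= L))
    stop("haplotype loci must lie in [0, L - 1]")
  sort(unique(loci))
}

#' Construct an individual
#'
#' An individual is two haplotypes, a diploid modifier genotype (two allele
#' slots), a dispersal phenotype fixed at birth (the allele slot the
#' individual expresses), a cached viability, and a deme membership.  The
#' fitness cache is computed here, at birth, and genomes are immutable
#' afterwards, so the cache is exact.
#'
#' @param hap_a,hap_b Haplotypes (see [haplotype()]).
#' @param modifier Integer vector of two allele slots (1 or 2), one per
#'   chromosome copy.
#' @param params [genetic_params()].
#' @param deme_id Deme membership (1-based).
#' @param phenotype Expressed allele slot; if `NULL`, drawn by the birth rule
#'   (homozygotes deterministic, heterozygotes a fair coin, see
#'   [assign_phenotype()]).
#' @return An object of class `fad_individual`.
#' @examples
#' ind <- new_individual(haplotype(c(0, 3), 100), haplotype(3, 100),
#'                       params = genetic_params(L = 100))
#' ind$fitness
#' @export
new_individual <- function(hap_a = integer(0), hap_b = integer(0),
                           modifier = c(1L, 1L), params = genetic_params(),
                           deme_id = 1L, phenotype = NULL) {
  hap_a <- haplotype(hap_a, params$L)
  hap_b <- haplotype(hap_b, params$L)
  modifier <- as.integer(modifier)
  if (length(modifier) != 2 || !all(modifier %in% 1:2))
    stop("modifier must be two allele slots, each 1 or 2")
  if (is.null(phenotype)) phenotype <- assign_phenotype(modifier)
  phenotype <- as.integer(phenotype)
  if (!(phenotype %in% modifier))
    stop("phenotype must be one of the carried modifier alleles")
  mn <- engine_count_classes(hap_a, hap_b)
  structure(list(hap_a = hap_a, hap_b = hap_b, modifier = modifier,
                 phenotype = phenotype,
                 fitness = fitness_of(mn[["m"]], mn[["n"]], params),
                 deme_id = as.integer(deme_id)),
            class = "fad_individual")
}

#' Count homozygous and heterozygous deleterious mutations
#'
#' `m` is the number of fitness loci mutant on both chromosome copies,
#' `n` the number mutant on exactly one copy.
#'
#' @param ind A `fad_individual`, or a list with `hap_a`/`hap_b` haplotypes.
#' @return Named integer vector `c(m = , n = )`.
#' @examples
#' ind <- new_individual(c(5, 7), 7, params = genetic_params(L = 10))
#' count_mutation_classes(ind)  # m = 1, n = 1
#' @export
count_mutation_classes <- function(ind) {
  engine_count_classes(ind$hap_a, ind$hap_b)
}

#' Viability from mutation counts
#'
#' Survival probability to adulthood of a juvenile carrying `m` homozygous
#' and `n` heterozygous deleterious mutations: `(1 - s)^m * (1 - h*s)^n`.
#' Multiplicative across loci; equals 1 only for a mutation-free genome.
#'
#' @param m,n Non-negative counts of homozygous / heterozygous deleterious
#'   mutations (vectorized).
#' @param params [genetic_params()] supplying `s` and `h`.
#' @return Fitness value(s) in (0, 1].
#' @examples
#' fitness_of(2, 1, genetic_params(s = 0.1, h = 0.2))  # 0.9^2 * 0.98
#' @export
fitness_of <- function(m, n, params = genetic_params()) {
  if (any(m < 0) || any(n < 0)) stop("m and n must be non-negative")
  (1 - params$s)^m * (1 - params$h * params$s)^n
}

#' Apply new deleterious mutations to a newborn genome
#'
#' Draws `k ~ Poisson(U)` target allele copies uniformly at random among the
#' `2L` fitness-allele copies of the diploid genome.  A targeted wild-type
#' copy becomes mutant; a targeted copy that is already mutant stays mutant
#' (no back mutation).  The modifier locus never mutates.  The fitness cache
#' is recomputed, since this is the birth step that fixes it.
#'
#' @param ind A `fad_individual`.
#' @param params [genetic_params()].
#' @return The mutated individual.
#' @export
draw_and_apply_mutations <- function(ind, params = genetic_params()) {
  res <- engine_apply_mutations(ind$hap_a, ind$hap_b, params$U, params$L)
  ind$hap_a <- res$hap_a
  ind$hap_b <- res$hap_b
  mn <- engine_count_classes(ind$hap_a, ind$hap_b)
  ind$fitness <- fitness_of(mn[["m"]], mn[["n"]], params)
  ind
}

#' Form a gamete by meiosis
#'
#' The crossover count is drawn from Poisson(`R`) (capped at `L - 1`), the
#' breakpoints are placed uniformly at random without replacement among the
#' `L - 1` inter-locus intervals, and the gamete haplotype alternates between
#' the two parental haplotypes at the breakpoints, starting from a uniformly
#' chosen copy.  The transmitted modifier allele is either parental allele
#' with probability 1/2, independent of the fitness-locus outcome (free
#' recombination between the modifier and the fitness map).
#'
#' @param ind A `fad_individual`.
#' @param params [genetic_params()].
#' @return List with elements `hap` (the gamete haplotype) and `allele` (the
#'   transmitted modifier allele slot).
#' @export
make_gamete <- function(ind, params = genetic_params()) {
  engine_make_gamete(ind$hap_a, ind$hap_b, ind$modifier[1], ind$modifier[2],
                     params$R, params$L)
}

#' Resolve the dispersal phenotype at birth
#'
#' Modifier homozygotes express their allele deterministically; heterozygotes
#' express either allele with probability 1/2, decided once at birth and
#' immutable thereafter.
#'
#' @param modifier Length-2 vector of modifier alleles (allele slots, or any
#'   two labels such as `c("UNI", "FAD")`).
#' @return One element of `modifier`: the expressed allele.
#' @examples
#' assign_phenotype(c("UNI", "UNI"))  # always "UNI"
#' @export
assign_phenotype <- function(modifier) {
  if (length(modifier) != 2) stop("modifier must hold exactly two alleles")
  if (identical(modifier[[1]], modifier[[2]])) return(modifier[[1]])
  modifier[[engine_assign_phenotype(1L, 2L)]]
}

#' @export
print.fad_individual <- function(x, ...) {
  mn <- engine_count_classes(x$hap_a, x$hap_b)
  cat(sprintf(
    "Individual: m = %d, n = %d, fitness = %.5f, modifier = %d/%d, %s\n",
    mn[["m"]], mn[["n"]], x$fitness, x$modifier[1], x$modifier[2],
    sprintf("phenotype slot %d, deme %d", x$phenotype, x$deme_id)))
  invisible(x)
}
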