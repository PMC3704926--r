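#' Dispersal stage
#'
#' First stage of every generation.  Each UNI-expressing individual disperses
#' independently with its allele's rate; for the FAD-expressing individuals a
#' disperser count is drawn from Binomial(`n_F`, `alpha_F`) and filled by
#' ascending fitness rank (ties broken uniformly at random), so the least fit
#' disperse first.  Every disperser dies with probability `cost`; survivors
#' are reassigned to a uniformly random deme (island model, natal deme
#' included).  Dead dispersers are removed from the population.
#'
#' @param pop A `fad_population` of adults at the start of a generation.
#' @return The population after movement and cost mortality.  Errors if every
#'   individual perishes.
#' @export
dispersal_stage <- function(pop) {
  pop_from_engine(engine_dispersal_stage(pop_to_engine(pop),
                                         engine_params_of(pop)), pop)
}

#' Choose a parent deme
#'
#' Samples a deme with probability proportional to its current adult count,
#' restricted to demes holding at least two adults (mating without selfing
#' needs two distinct parents; singleton demes are never chosen).
#'
#' @param pop A `fad_population` after dispersal.
#' @return A deme id (1-based integer).
#' @export
choose_parent_deme <- function(pop) {
  sizes <- deme_sizes(pop)
  w <- ifelse(sizes >= 2, as.numeric(sizes), 0)
  if (sum(w) == 0)
    stop("population cannot reproduce: no deme has two or more adults")
  sample.int(pop$n_demes, 1L, prob = w)
}

#' Produce one offspring from a deme (conception attempt)
#'
#' Two distinct parents are drawn uniformly without replacement from the
#' deme; each transmits one gamete ([make_gamete()]); the newborn genome
#' receives new mutations ([draw_and_apply_mutations()]); the dispersal
#' phenotype is fixed at birth; and the juvenile survives viability selection
#' with probability equal to its fitness.  Rejection (death of the juvenile)
#' is a normal outcome, returned as `NULL`.
#'
#' @param pop A `fad_population`.
#' @param deme_id Deme to breed from (must hold at least two adults).
#' @return A `fad_individual` assigned to `deme_id`, or `NULL` if the
#'   juvenile did not survive.
#' @export
produce_offspring <- function(pop, deme_id) {
  members <- which(pop$deme == deme_id)
  if (length(members) < 2)
    stop("deme ", deme_id, " has fewer than two adults")
  pick <- sample(members, 2L)
  g <- pop$genetics
  gam1 <- engine_make_gamete(pop$hap_a[[pick[1]]], pop$hap_b[[pick[1]]],
                             pop$mod_a[pick[1]], pop$mod_b[pick[1]],
                             g$R, g$L)
  gam2 <- engine_make_gamete(pop$hap_a[[pick[2]]], pop$hap_b[[pick[2]]],
                             pop$mod_a[pick[2]], pop$mod_b[pick[2]],
                             g$R, g$L)
  haps <- engine_apply_mutations(gam1$hap, gam2$hap, g$U, g$L)
  mn <- engine_count_classes(haps$hap_a, haps$hap_b)
  fit <- fitness_of(mn[["m"]], mn[["n"]], g)
  pheno <- engine_assign_phenotype(gam1$allele, gam2$allele)
  if (runif(1) >= fit) return(NULL)
  structure(list(hap_a = haps$hap_a, hap_b = haps$hap_b,
                 modifier = c(gam1$allele, gam2$allele),
                 phenotype = pheno, fitness = fit,
                 deme_id = as.integer(deme_id)),
            class = "fad_individual")
}

#' Reproduction stage
#'
#' Repeats deme choice and offspring production until exactly `n_total`
#' juveniles have survived viability selection; the parental generation is
#' then replaced.  Offspring join the next generation of their parents' deme.
#' Deme weights are computed once per stage (parents are not consumed).  A
#' configurable conception-attempt ceiling (`attempt_factor * n_total`)
#' guards against unbounded rejection loops.
#'
#' @param pop A `fad_population` after dispersal.
#' @return The offspring population of size `n_total`.
#' @export
reproduction_stage <- function(pop) {
  pop_from_engine(engine_reproduction_stage(pop_to_engine(pop),
                                            engine_params_of(pop)), pop)
}

#' Advance one full generation
#'
#' Applies, in order: dispersal, reproduction with viability selection,
#' splitting of demes above capacity, and removal of empty demes.  The
#' resulting population carries its generation record (see
#' [population_summary()]) in the attribute `"generation_record"`.
#'
#' @param pop A `fad_population`.
#' @return The next-generation population.
#' @export
step_generation <- function(pop) {
  out <- pop_from_engine(engine_step_generation(pop_to_engine(pop),
                                                engine_params_of(pop)), pop)
  attr(out, "generation_record") <- population_summary(out)
  out
}

#' Run many generations in the compiled engine
#'
#' Steps the population for up to `n_gens` generations entirely on the C++
#' side, recording one summary row per generation (row 0 is the initial
#' state).  With `stop_on_absorption = TRUE` the run halts as soon as the
#' invader allele (slot 2) is lost or fixed.
#'
#' @param pop A `fad_population`.
#' @param n_gens Maximum number of generations to step.
#' @param stop_on_absorption Halt at invader-allele frequency 0 or 1.
#' @param record Keep the per-generation summary table.
#' @return List with elements `pop`, `records` (data frame, or `NULL`),
#'   `generations` (number actually stepped), `absorbed`, `final_freq`.
#' @examples
#' pop <- init_population(60, 10, genetic_params(L = 200), dispersal_params())
#' res <- run_generations(pop, 5)
#' res$records$mean_fitness
#' @export
run_generations <- function(pop, n_gens, stop_on_absorption = FALSE,
                            record = TRUE) {
  res <- engine_run(pop_to_engine(pop), engine_params_of(pop),
                    as.integer(n_gens), stop_on_absorption, record)
  list(pop = pop_from_engine(res$pop, pop),
       records = if (record) records_as_df(res$records, pop$alleles),
       generations = res$generations,
       absorbed = res$absorbed,
       final_freq = res$final_freq)
}

# engine record matrix -> data frame in the trajectory column layout
records_as_df <- function(mat, alleles) {
  df <- as.data.frame(mat)
  names(df)[names(df) == "freq_slot2"] <- "invader_freq"
  df$fad_allele_freq <- fad_allele_freq(df$invader_freq, alleles)
  df[c("generation", "mean_fitness", "het_fraction", "invader_freq",
       "fad_allele_freq", "n_demes", "mean_fitness_fad",
       "mean_fitness_uni", "mean_het_loci", "mean_fitness_costed")]
}

#' Write / read a trajectory time series
#'
#' Tab-separated time series of generation records with columns
#' `generation`, `mean_fitness`, `het_fraction`, `fad_allele_freq`,
#' `n_demes`, `mean_fitness_fad`, `mean_fitness_uni` (plus `invader_freq`
#' when present).  Values are written at full precision.
#'
#' @param records Data frame of generation records (e.g. from
#'   [run_generations()]).
#' @param path Output file.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the data frame.
#' @export
write_trajectory <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.table(path, header = TRUE, sep = "\t", colClasses = "numeric")
}
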