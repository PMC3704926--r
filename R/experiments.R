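#' Run a homogeneous population to mutation-selection balance
#'
#' Steps a population homogeneous at the modifier locus until mean fitness
#' and heterozygosity reach a steady state, defined by a sliding-window rule:
#' after a hard minimum burn-in, the run stops once the regression slopes of
#' both statistics over the last `window` generations are statistically
#' indistinguishable from zero at the nominal `level` (checked every
#' `check_every` generations), or once `max_gens` is reached, in which case
#' `converged` is `FALSE`.
#'
#' @param pop A homogeneous `fad_population` (see [init_population()]).
#' @param min_gens Hard minimum burn-in before convergence is tested.
#' @param max_gens Generation cap.
#' @param window Sliding-window length for the stationarity test and for the
#'   reported steady-state statistics.
#' @param check_every Generations between convergence checks.
#' @param level Nominal significance level of the slope test.
#' @return An object of class `fad_steady_state`: list with the equilibrated
#'   `population`, the full `records` time series, `generations`,
#'   `converged`, and `steady` (mean and standard error of mean fitness and
#'   heterozygosity fraction over the final window).
#' @examples
#' pop <- init_population(60, 10, genetic_params(L = 200),
#'                        dispersal_params(alpha_U = 0.1))
#' eq <- run_steady_state(pop, min_gens = 30, max_gens = 60, window = 20,
#'                        check_every = 10)
#' eq$steady$mean_fitness
#' @export
run_steady_state <- function(pop, min_gens = 2000, max_gens = 20000,
                             window = 500, check_every = 100, level = 0.05) {
  if (any(pop$mod_a != pop$mod_a[1]) || any(pop$mod_b != pop$mod_a[1]))
    stop("run_steady_state expects a population homogeneous at the ",
         "modifier locus")
  records <- vector("list", ceiling(max_gens / check_every) + 1L)
  first <- run_generations(pop, 0)
  records[[1]] <- first$records
  gens <- 0L
  converged <- FALSE
  i <- 1L
  while (gens < max_gens) {
    chunk <- min(check_every, max_gens - gens)
    res <- run_generations(pop, chunk)
    pop <- res$pop
    rows <- res$records[-1, , drop = FALSE] # drop duplicated initial row
    rows$generation <- rows$generation + gens
    i <- i + 1L
    records[[i]] <- rows
    gens <- gens + chunk
    if (gens >= max(min_gens, window)) {
      all_rec <- do.call(rbind, records[seq_len(i)])
      tail_rec <- all_rec[seq(nrow(all_rec) - window + 1, nrow(all_rec)), ]
      if (slope_p_value(tail_rec$mean_fitness) > level &&
          slope_p_value(tail_rec$het_fraction) > level) {
        converged <- TRUE
        break
      }
    }
  }
  all_rec <- do.call(rbind, records[seq_len(i)])
  rownames(all_rec) <- NULL
  tail_rec <- all_rec[seq(max(1, nrow(all_rec) - window + 1), nrow(all_rec)), ]
  w <- sqrt(nrow(tail_rec))
  steady <- list(
    mean_fitness = mean(tail_rec$mean_fitness),
    mean_fitness_se = sd(tail_rec$mean_fitness) / w,
    het_fraction = mean(tail_rec$het_fraction),
    het_fraction_se = sd(tail_rec$het_fraction) / w,
    mean_het_loci = mean(tail_rec$mean_het_loci),
    mean_het_loci_se = sd(tail_rec$mean_het_loci) / w,
    mean_fitness_costed = mean(tail_rec$mean_fitness_costed),
    mean_fitness_costed_se = sd(tail_rec$mean_fitness_costed) / w)
  structure(list(population = pop, records = all_rec, generations = gens,
                 converged = converged, window = window, steady = steady),
            class = "fad_steady_state")
}

# p-value of the regression slope of y against its index; a constant series
# is stationary by definition
slope_p_value <- function(y) {
  if (sd(y) == 0) return(1)
  fit <- stats::lm(y ~ seq_along(y))
  p <- stats::coef(summary(fit))[2, 4]
  if (is.na(p)) 1 else p
}

#' @export
print.fad_steady_state <- function(x, ...) {
  cat(sprintf(
    "Steady state after %d generations (%s): mean fitness %.4f +/- %.4f, het fraction %.4f +/- %.4f\n",
    x$generations, if (x$converged) "converged" else "generation cap reached",
    x$steady$mean_fitness, x$steady$mean_fitness_se,
    x$steady$het_fraction, x$steady$het_fraction_se))
  invisible(x)
}

#' Introduce an invading modifier allele
#'
#' Converts an exact-count (`round(f * n_total)`) uniformly random subset of
#' a homogeneous resident population to invader-homozygous modifier
#' genotypes, re-assigning their phenotypes, so the initial invader allele
#' frequency is exactly `f` up to rounding.
#'
#' @param pop A homogeneous resident `fad_population`.
#' @param invader_strategy `"UNI"` or `"FAD"`.
#' @param invader_alpha Dispersal rate of the invader allele; defaults to the
#'   resident rate for that strategy from the population's
#'   [dispersal_params()].
#' @param f Initial invader allele frequency in (0, 1).
#' @return The population with allele slot 2 configured and seeded.
#' @export
introduce_invader <- function(pop, invader_strategy = "FAD",
                              invader_alpha = NULL, f = 0.01) {
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("f must lie strictly between 0 and 1")
  if (any(pop$mod_a != 1L) || any(pop$mod_b != 1L))
    stop("resident population must be homogeneous for allele slot 1")
  pop$alleles <- allele_table(pop$alleles$strategy[1], pop$dispersal,
                              invader_strategy, invader_alpha)
  k <- round(f * pop$n_total)
  if (k < 1) stop("f is too small: no individual would be converted")
  idx <- sample.int(pop$n_total, k)
  pop$mod_a[idx] <- 2L
  pop$mod_b[idx] <- 2L
  pop$phenotype[idx] <- 2L
  pop
}

#' Run one modifier-allele invasion
#'
#' Introduces the invader allele into an equilibrated resident population and
#' steps generations until the invader allele frequency hits 0 (`extinct`) or
#' 1 (`fixed`), or `g_max` generations have passed (`timeout`).
#'
#' @param resident A homogeneous `fad_population` at mutation-selection
#'   balance, or a `fad_steady_state` object.
#' @param invader_strategy,invader_alpha Invader allele (see
#'   [introduce_invader()]).
#' @param f Initial invader allele frequency in (0, 1).
#' @param g_max Generation cap (default 30000).
#' @param seed Optional integer seed set before the invasion (introduction
#'   included), making the replicate reproducible.
#' @param record Keep the full per-generation trajectory.
#' @return An object of class `fad_invasion_result`: `outcome` (one of
#'   `"fixed"`, `"extinct"`, `"timeout"`), `takeover_time` (generations from
#'   invader frequency 0.01 to 0.8, `NA` when 0.8 was never reached),
#'   `trajectory`, `final_freq`, `generations`, `seed`, and the invasion
#'   parameters.
#' @export
run_invasion <- function(resident, invader_strategy = "FAD",
                         invader_alpha = NULL, f = 0.01, g_max = 30000,
                         seed = NULL, record = TRUE) {
  if (inherits(resident, "fad_steady_state")) resident <- resident$population
  if (!is.null(seed)) set.seed(seed)
  pop <- introduce_invader(resident, invader_strategy, invader_alpha, f)
  res <- run_generations(pop, g_max, stop_on_absorption = TRUE,
                         record = record)
  outcome <- if (res$final_freq >= 1) "fixed"
             else if (res$final_freq <= 0) "extinct"
             else "timeout"
  structure(list(
    outcome = outcome,
    takeover_time = if (record) takeover_time(res$records) else NA_real_,
    trajectory = res$records,
    final_freq = res$final_freq,
    generations = res$generations,
    seed = seed, f = f,
    invader_strategy = pop$alleles$strategy[2],
    invader_alpha = pop$alleles$alpha[2],
    population = res$pop), class = "fad_invasion_result")
}

#' @export
print.fad_invasion_result <- function(x, ...) {
  cat(sprintf(
    "Invasion of %s (alpha = %g) at f0 = %g: %s after %d generations%s\n",
    x$invader_strategy, x$invader_alpha, x$f, x$outcome, x$generations,
    if (!is.na(x$takeover_time))
      sprintf(" (takeover time %d)", as.integer(x$takeover_time)) else ""))
  invisible(x)
}

#' Takeover time of an invading allele
#'
#' The number of generations for the invading allele frequency to rise from
#' `low` to `high`: the first generation at which the frequency is at least
#' `high` minus the first generation at which it is at least `low`.  If the
#' trajectory starts at or above `low`, measurement starts at generation 0.
#' Undefined (`NA`) when `high` is never reached.
#'
#' @param traj Numeric vector of per-generation allele frequencies (the
#'   element for generation 0 first), or a trajectory data frame holding
#'   columns `generation` and `invader_freq`.
#' @param low,high Frequency thresholds (defaults 0.01 and 0.8).
#' @return Number of generations, or `NA`.
#' @examples
#' takeover_time(c(0.01, 0.3, 0.85))  # 2
#' @export
takeover_time <- function(traj, low = 0.01, high = 0.8) {
  if (is.data.frame(traj)) {
    gen <- traj$generation
    freq <- traj$invader_freq
  } else {
    freq <- as.numeric(traj)
    gen <- seq_along(freq) - 1
  }
  i_high <- which(freq >= high)[1]
  if (is.na(i_high)) return(NA_real_)
  i_low <- which(freq >= low)[1]
  gen[i_high] - gen[i_low]
}

#' Exact binomial test
#'
#' Exact binomial p-value for `k` successes in `n` trials against the null
#' success probability `p0`; by default the one-sided upper tail
#' `P(X >= k | n, p0)` used to call an invasion significantly more successful
#' than a neutral allele.
#'
#' @param k Number of successes (e.g. fixations).
#' @param n Number of trials (replicates).
#' @param p0 Null success probability in (0, 1) (e.g. the initial frequency
#'   of a neutral allele).
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`.
#' @return The p-value.
#' @examples
#' exact_binomial_test(20, 50, 0.05)
#' @export
exact_binomial_test <- function(k, n, p0,
                                alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(k) || !is.numeric(n) || k != round(k) || n != round(n) ||
      k < 0 || n < 1 || k > n)
    stop("need integer counts with 0 <= k <= n and n >= 1")
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly between 0 and 1")
  stats::binom.test(k, n, p = p0, alternative = alternative)$p.value
}

#' Deterministic per-replicate seed derivation
#'
#' Maps a base seed and a counter to a replicate seed below 2^31 without
#' reusing seeds across counters, so whole experiment batteries are
#' reproducible from a single base seed.
#'
#' @param base_seed Integer base seed.
#' @param counter Replicate counter (positive integer).
#' @return An integer seed.
#' @export
replicate_seed <- function(base_seed, counter) {
  as.integer((as.double(base_seed) %% 2147483629 * 1000003 + counter) %%
               2147483629) + 1L
}

#' Run a battery of replicate invasions
#'
#' Repeats [run_invasion()] against the same equilibrated resident
#' population, one derived seed per replicate (see [replicate_seed()]).
#'
#' @param resident Homogeneous resident population at mutation-selection
#'   balance (or `fad_steady_state`).
#' @param n_reps Number of replicates.
#' @param invader_strategy,invader_alpha,f,g_max See [run_invasion()].
#' @param base_seed Base seed for the replicate seeds.
#' @param counter_offset Offset added to the replicate counter, letting
#'   several batteries share one base seed without seed reuse.
#' @param keep_trajectories Keep each replicate's full trajectory (memory
#'   permitting) in the `"trajectories"` attribute of the result.
#' @return Data frame with one row per replicate: `rep`, `seed`, `outcome`,
#'   `takeover_gens`, `final_freq`, `generations`, `mean_fitness_end`,
#'   `het_fraction_end`.
#' @export
run_invasion_replicates <- function(resident, n_reps, invader_strategy = "FAD",
                                    invader_alpha = NULL, f = 0.01,
                                    g_max = 30000, base_seed = 1,
                                    counter_offset = 0,
                                    keep_trajectories = FALSE) {
  if (inherits(resident, "fad_steady_state")) resident <- resident$population
  rows <- vector("list", n_reps)
  trajs <- if (keep_trajectories) vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sd_r <- replicate_seed(base_seed, counter_offset + r)
    inv <- run_invasion(resident, invader_strategy, invader_alpha, f, g_max,
                        seed = sd_r, record = TRUE)
    last <- inv$trajectory[nrow(inv$trajectory), ]
    rows[[r]] <- data.frame(
      rep = r, seed = sd_r, outcome = inv$outcome,
      takeover_gens = inv$takeover_time, final_freq = inv$final_freq,
      generations = inv$generations,
      mean_fitness_end = last$mean_fitness,
      het_fraction_end = last$het_fraction,
      stringsAsFactors = FALSE)
    if (keep_trajectories) trajs[[r]] <- inv$trajectory
  }
  out <- do.call(rbind, rows)
  if (keep_trajectories) attr(out, "trajectories") <- trajs
  out
}

#' Classify a parameter cell from paired FAD and UNI invasion batteries
#'
#' A strategy "succeeds" in a cell when its fixation count over replicates is
#' significantly above the neutral expectation `f` (one-sided
#' [exact_binomial_test()] below `p_threshold`).  FAD is called polymorphic
#' when at least `poly_fraction` of its replicates end in timeout with the
#' invader frequency inside `poly_band`.
#'
#' @param fad,uni Replicate tables from [run_invasion_replicates()] for the
#'   FAD and UNI invasions of the same cell (equal replicate counts).
#' @param f Initial invader allele frequency (neutral success probability).
#' @param p_threshold Significance threshold (default 0.05).
#' @param poly_band Frequency interval defining an unresolved polymorphic
#'   replicate.
#' @param poly_fraction Minimum fraction of polymorphic replicates for a
#'   polymorphism call.
#' @return One of `"both_succeed"`, `"only_FAD"`, `"FAD_polymorphism"`,
#'   `"none"`, with the two p-values attached as attributes.
#' @export
classify_invasion_outcomes <- function(fad, uni, f, p_threshold = 0.05,
                                       poly_band = c(0.05, 0.95),
                                       poly_fraction = 0.5) {
  if (nrow(fad) != nrow(uni))
    stop("FAD and UNI batteries must have the same number of replicates")
  p_fad <- exact_binomial_test(sum(fad$outcome == "fixed"), nrow(fad), f)
  p_uni <- exact_binomial_test(sum(uni$outcome == "fixed"), nrow(uni), f)
  fad_poly <- mean(fad$outcome == "timeout" &
                     fad$final_freq > poly_band[1] &
                     fad$final_freq < poly_band[2])
  cls <- if (p_fad < p_threshold && p_uni < p_threshold) "both_succeed"
         else if (p_fad < p_threshold) "only_FAD"
         else if (fad_poly >= poly_fraction) "FAD_polymorphism"
         else "none"
  structure(cls, p_fad = p_fad, p_uni = p_uni,
            fad_polymorphic_fraction = fad_poly)
}

#' Factorial parameter sweep
#'
#' Runs one experiment per cell of a parameter grid, with per-cell burn-in of
#' the resident population and derived seeds throughout, so a rerun with the
#' same base seed reproduces the tables exactly.  Three experiment kinds are
#' supported: `"invasion"` (a battery of invasions by `invader_strategy`),
#' `"paired_invasion"` (FAD and UNI batteries sharing the cell's resident,
#' classified with [classify_invasion_outcomes()]), and `"steady_state"`
#' (replicate steady-state runs of a homogeneous population).  A failure in
#' one cell is recorded and the sweep continues.
#'
#' @param grid Data frame of cells; recognized columns: `alpha` (resident
#'   dispersal rate), `cost`, `h`, `s`, `strategy` (resident or homogeneous
#'   strategy), `invader_alpha`.  Missing columns fall back to the defaults
#'   below.
#' @param experiment `"invasion"`, `"paired_invasion"`, or `"steady_state"`.
#' @param n_reps Replicates per cell (per strategy, for paired invasions).
#' @param n_total,capacity,L Population dimensions for every cell.
#' @param s,h Default selection and dominance coefficients.
#' @param strategy Default resident / homogeneous strategy.
#' @param invader_strategy Invading strategy for `"invasion"`.
#' @param f Initial invader allele frequency.
#' @param g_max Invasion generation cap.
#' @param base_seed Base seed from which every burn-in and replicate seed is
#'   derived.
#' @param steady Named list of [run_steady_state()] control arguments
#'   (`min_gens`, `max_gens`, `window`, `check_every`, `level`).
#' @return List with `replicates` (one row per replicate, including all cell
#'   parameters and seeds) and `cells` (one row per cell with summary
#'   statistics, classification or error message).
#' @export
run_parameter_sweep <- function(grid,
                                experiment = c("invasion", "paired_invasion",
                                               "steady_state"),
                                n_reps = 10, n_total = 300, capacity = 20,
                                L = 1000, s = 0.1, h = 0.2,
                                strategy = "UNI", invader_strategy = "FAD",
                                f = 0.01, g_max = 30000, base_seed = 1,
                                steady = list()) {
  experiment <- match.arg(experiment)
  std <- modifyList(list(min_gens = 2000, max_gens = 20000, window = 500,
                         check_every = 100, level = 0.05), steady)
  grid <- as.data.frame(grid)
  cells <- vector("list", nrow(grid))
  reps <- vector("list", nrow(grid))
  # each cell consumes a fixed block of the seed counter space
  block <- 2L * n_reps + 2L
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, , drop = FALSE]
    p <- list(
      alpha = cell[["alpha"]] %||% 0.1,
      cost = cell[["cost"]] %||% 0,
      h = cell[["h"]] %||% h,
      s = cell[["s"]] %||% s,
      strategy = as.character(cell[["strategy"]] %||% strategy),
      invader_alpha = cell[["invader_alpha"]] %||% NULL)
    if (!is.null(p$invader_alpha) && is.na(p$invader_alpha))
      p$invader_alpha <- NULL
    base_counter <- (i - 1L) * block
    res <- tryCatch(
      sweep_cell(p, experiment, n_reps, n_total, capacity, L,
                 invader_strategy, f, g_max, base_seed, base_counter, std),
      error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$error)) {
      cells[[i]] <- data.frame(cell_id = i, p[c("alpha", "cost", "h", "s")],
                               status = "error", message = res$error,
                               stringsAsFactors = FALSE)
    } else {
      cells[[i]] <- data.frame(cell_id = i, res$cell, stringsAsFactors = FALSE)
      rr <- res$replicates
      rr <- data.frame(cell_id = i, run_id = paste0(i, "_", seq_len(nrow(rr))),
                       alpha_res = p$alpha,
                       alpha_inv = rr$alpha_inv, c = p$cost, h = p$h, s = p$s,
                       strategy_res = p$strategy,
                       strategy_inv = rr$strategy_inv, f0 = rr$f0,
                       seed = rr$seed, outcome = rr$outcome,
                       takeover_gens = rr$takeover_gens,
                       final_freq = rr$final_freq,
                       mean_fitness_end = rr$mean_fitness_end,
                       het_fraction_end = rr$het_fraction_end,
                       stringsAsFactors = FALSE)
      reps[[i]] <- rr
    }
  }
  list(replicates = do.call(rbind, reps[!vapply(reps, is.null, TRUE)]),
       cells = do.call(rbind, lapply(cells, pad_columns,
                                     union_names(cells))))
}

union_names <- function(dfs) unique(unlist(lapply(dfs, names)))

pad_columns <- function(df, nms) {
  for (nm in setdiff(nms, names(df))) df[[nm]] <- NA
  df[nms]
}

sweep_cell <- function(p, experiment, n_reps, n_total, capacity, L,
                       invader_strategy, f, g_max, base_seed, base_counter,
                       std) {
  genetics <- genetic_params(L = L, s = p$s, h = p$h)
  make_pop <- function(strat) {
    init_population(n_total, capacity, genetics,
                    dispersal_params(alpha_U = p$alpha, alpha_F = p$alpha,
                                     cost = p$cost),
                    strategy = strat)
  }
  burn <- function(strat, counter) {
    set.seed(replicate_seed(base_seed, base_counter + counter))
    do.call(run_steady_state, c(list(make_pop(strat)), std))
  }
  if (experiment == "steady_state") {
    rows <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      sd_r <- replicate_seed(base_seed, base_counter + r)
      set.seed(sd_r)
      eq <- do.call(run_steady_state, c(list(make_pop(p$strategy)), std))
      rows[[r]] <- data.frame(
        seed = sd_r, strategy_inv = NA_character_, alpha_inv = NA_real_,
        f0 = NA_real_,
        outcome = if (eq$converged) "converged" else "max_gens",
        takeover_gens = NA_real_, final_freq = NA_real_,
        mean_fitness_end = eq$steady$mean_fitness,
        het_fraction_end = eq$steady$het_fraction,
        mean_het_loci_end = eq$steady$mean_het_loci,
        mean_fitness_costed_end = eq$steady$mean_fitness_costed,
        stringsAsFactors = FALSE)
    }
    rr <- do.call(rbind, rows)
    cell <- data.frame(
      alpha = p$alpha, cost = p$cost, h = p$h, s = p$s, status = "ok",
      strategy = p$strategy,
      mean_fitness = mean(rr$mean_fitness_end),
      mean_fitness_se = sd(rr$mean_fitness_end) / sqrt(n_reps),
      het_fraction = mean(rr$het_fraction_end),
      het_fraction_se = sd(rr$het_fraction_end) / sqrt(n_reps),
      mean_het_loci = mean(rr$mean_het_loci_end),
      mean_het_loci_se = sd(rr$mean_het_loci_end) / sqrt(n_reps),
      mean_fitness_costed = mean(rr$mean_fitness_costed_end),
      mean_fitness_costed_se = sd(rr$mean_fitness_costed_end) / sqrt(n_reps),
      stringsAsFactors = FALSE)
    return(list(replicates = rr, cell = cell))
  }
  eq <- burn(p$strategy, 0L)
  battery <- function(strat, offset) {
    tb <- run_invasion_replicates(eq, n_reps, strat, p$invader_alpha, f,
                                  g_max, base_seed,
                                  counter_offset = base_counter + offset)
    tb$strategy_inv <- strat
    tb$alpha_inv <- p$invader_alpha %||% p$alpha
    tb$f0 <- f
    tb
  }
  if (experiment == "invasion") {
    rr <- battery(invader_strategy, 1L)
    n_fix <- sum(rr$outcome == "fixed")
    cell <- data.frame(
      alpha = p$alpha, cost = p$cost, h = p$h, s = p$s, status = "ok",
      strategy = p$strategy, n_fixed = n_fix, n_reps = n_reps,
      p_value = exact_binomial_test(n_fix, n_reps, f),
      mean_takeover = mean(rr$takeover_gens[rr$outcome == "fixed"],
                           na.rm = TRUE),
      resident_converged = eq$converged, stringsAsFactors = FALSE)
    return(list(replicates = rr, cell = cell))
  }
  fad <- battery("FAD", 1L)
  uni <- battery("UNI", 1L + n_reps)
  cls <- classify_invasion_outcomes(fad, uni, f)
  rr <- rbind(fad, uni)
  cell <- data.frame(
    alpha = p$alpha, cost = p$cost, h = p$h, s = p$s, status = "ok",
    strategy = p$strategy, classification = as.character(cls),
    p_fad = attr(cls, "p_fad"), p_uni = attr(cls, "p_uni"),
    fad_polymorphic_fraction = attr(cls, "fad_polymorphic_fraction"),
    resident_converged = eq$converged, stringsAsFactors = FALSE)
  list(replicates = rr, cell = cell)
}
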