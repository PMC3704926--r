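# Configuration schema: name -> list(default, check, description).  Defaults
# are the full-scale study conditions; desk-scale runs override them.
config_schema <- function() {
  prob <- function(v) is.numeric(v) && length(v) == 1 && !is.na(v) &&
    v >= 0 && v <= 1
  posint <- function(v) is.numeric(v) && length(v) == 1 && !is.na(v) &&
    v == round(v) && v >= 1
  nonneg <- function(v) is.numeric(v) && length(v) == 1 && !is.na(v) && v >= 0
  choice <- function(opts) function(v) is.character(v) && length(v) == 1 &&
    v %in% opts
  probvec <- function(v) is.numeric(v) && length(v) >= 1 && all(!is.na(v)) &&
    all(v >= 0 & v <= 1)
  list(
    experiment = list("steady_state", choice(c("steady_state", "invade",
                                               "sweep"))),
    n_total = list(5000L, posint),
    capacity = list(20L, posint),
    L = list(10000L, posint),
    s = list(0.1, function(v) is.numeric(v) && length(v) == 1 && v > 0 &&
               v < 1),
    h = list(0.2, prob),
    U = list(0.5, nonneg),
    R = list(20, nonneg),
    alpha_U = list(0.1, prob),
    alpha_F = list(NULL, prob),       # defaults to alpha_U
    cost = list(0.1, prob),
    fad_ranking = list("global", choice(c("global", "per_deme"))),
    resident_strategy = list("UNI", choice(c("UNI", "FAD"))),
    invader_strategy = list("FAD", choice(c("UNI", "FAD"))),
    invader_alpha = list(NULL, prob), # defaults to the strategy's rate
    f0 = list(0.01, function(v) is.numeric(v) && length(v) == 1 && v > 0 &&
                v < 1),
    g_max = list(30000L, posint),
    n_reps = list(50L, posint),
    base_seed = list(1L, posint),
    output_dir = list("fadsim-out", function(v) is.character(v) &&
                        length(v) == 1),
    min_gens = list(2000L, posint),
    max_gens = list(20000L, posint),
    window = list(500L, posint),
    check_every = list(100L, posint),
    level = list(0.05, prob),
    attempt_factor = list(1000, nonneg),
    alpha_values = list(c(0.01, 0.1, 0.3), probvec),
    cost_values = list(c(0, 0.1, 0.3, 0.5), probvec),
    h_values = list(c(0.2, 0.3, 0.4, 0.5), probvec))
}

#' Default run configuration
#'
#' All keys with their defaults: the full-scale study conditions
#' (`n_total = 5000`, `L = 10000`, `U = 0.5`, `R = 20`, `s = 0.1`,
#' `capacity = 20`, `g_max = 30000`) plus operational settings.
#'
#' @return A named list of class `fad_config`.
#' @export
default_config <- function() {
  sc <- config_schema()
  structure(lapply(sc, `[[`, 1), class = "fad_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, a YAML subset) document of configuration keys,
#' fills omitted keys with the defaults of [default_config()], and validates
#' every value against its declared range.  Unknown keys and range violations
#' are errors naming the offending key.
#'
#' @param path Path to the configuration file.  An empty document yields the
#'   defaults.
#' @return A validated `fad_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping of keys to values")
  as_config(raw)
}

#' Validate a configuration list
#'
#' @param x Named list of configuration values (possibly partial).
#' @return A complete, validated `fad_config`.
#' @export
as_config <- function(x) {
  sc <- config_schema()
  unknown <- setdiff(names(x), names(sc))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- default_config()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) next
    if (nm %in% c("n_total", "capacity", "L", "g_max", "n_reps", "base_seed",
                  "min_gens", "max_gens", "window", "check_every") &&
        is.numeric(v))
      v <- as.integer(v)
    if (!sc[[nm]][[2]](v))
      stop("configuration value out of range for key \"", nm, "\"")
    cfg[[nm]] <- v
  }
  if (cfg$capacity > cfg$n_total)
    stop("configuration value out of range for key \"capacity\" ",
         "(exceeds n_total)")
  cfg
}

#' Write a configuration to YAML
#'
#' Round-trips with [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg` for every valid configuration.
#'
#' @param cfg A `fad_config` (or partial named list).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], path)
  invisible(path)
}

config_population <- function(cfg, strategy = cfg$resident_strategy) {
  init_population(
    n_total = cfg$n_total, capacity = cfg$capacity,
    genetics = genetic_params(L = cfg$L, s = cfg$s, h = cfg$h, U = cfg$U,
                              R = cfg$R),
    dispersal = dispersal_params(alpha_U = cfg$alpha_U,
                                 alpha_F = cfg$alpha_F %||% cfg$alpha_U,
                                 cost = cfg$cost,
                                 fad_ranking = cfg$fad_ranking),
    strategy = strategy, attempt_factor = cfg$attempt_factor)
}

# ---------------------------------------------------------------------------
# fixture populations (tiny hand-checkable inputs for tests)

#' Generate a small deterministic fixture population
#'
#' Builds a population whose per-individual homozygous / heterozygous
#' mutation counts match `counts` exactly, with a fixed locus layout:
#' individual `i`'s homozygous mutations occupy loci `0..m-1` on both copies
#' and its heterozygous mutations alternate between the copies at loci
#' `m..m+n-1`.  Useful as a hand-checkable input for tests.
#'
#' @param counts Data frame with integer columns `m` and `n` (one row per
#'   individual) and optional columns `mod_a`, `mod_b` (allele slots,
#'   default 1).
#' @param genetics [genetic_params()]; `counts` must satisfy
#'   `m + n <= L`.
#' @param dispersal [dispersal_params()].
#' @param capacity Deme capacity for the block allocation.
#' @param seed Seed fixing the heterozygote phenotype draws.
#' @param path Optional path; when given, the population is also serialized
#'   to JSON (see [write_population_json()]).
#' @return A `fad_population`.
#' @examples
#' pop <- generate_fixture_population(data.frame(m = c(0, 2), n = c(0, 1)),
#'                                    genetic_params(L = 50))
#' pop$fitness
#' @export
generate_fixture_population <- function(counts,
                                        genetics = genetic_params(L = 50),
                                        dispersal = dispersal_params(),
                                        capacity = 20, seed = 1,
                                        path = NULL) {
  counts <- as.data.frame(counts)
  if (!all(c("m", "n") %in% names(counts)))
    stop("counts must have columns m and n")
  if (any(counts$m + counts$n > genetics$L))
    stop("infeasible fixture: m + n exceeds L for some individual")
  if (any(counts$m < 0 | counts$n < 0)) stop("m and n must be non-negative")
  n_ind <- nrow(counts)
  set.seed(seed)
  pop <- init_population(max(n_ind, 2), capacity, genetics, dispersal)
  pop <- truncate_population(pop, n_ind)
  mod_a <- as.integer(counts$mod_a %||% rep(1L, n_ind))
  mod_b <- as.integer(counts$mod_b %||% rep(1L, n_ind))
  for (i in seq_len(n_ind)) {
    m <- counts$m[i]
    n <- counts$n[i]
    hom <- seq_len(m) - 1L
    het <- m + seq_len(n) - 1L
    pop$hap_a[[i]] <- as.integer(c(hom, het[seq_along(het) %% 2 == 1]))
    pop$hap_b[[i]] <- as.integer(c(hom, het[seq_along(het) %% 2 == 0]))
    pop$mod_a[i] <- mod_a[i]
    pop$mod_b[i] <- mod_b[i]
    pop$phenotype[i] <- as.integer(assign_phenotype(c(mod_a[i], mod_b[i])))
    pop$fitness[i] <- fitness_of(m, n, genetics)
  }
  if (!is.null(path)) write_population_json(pop, path)
  pop
}

truncate_population <- function(pop, n) {
  keep <- seq_len(n)
  pop$hap_a <- pop$hap_a[keep]
  pop$hap_b <- pop$hap_b[keep]
  pop$mod_a <- pop$mod_a[keep]
  pop$mod_b <- pop$mod_b[keep]
  pop$phenotype <- pop$phenotype[keep]
  pop$fitness <- pop$fitness[keep]
  pop$deme <- pop$deme[keep]
  pop$n_total <- n
  pop$n_demes <- max(pop$deme)
  pop
}

#' Serialize / load a population as JSON
#'
#' Writes every individual (haplotypes, modifier slots, phenotype, fitness,
#' deme) together with the population and model parameters, at full
#' precision; `read_population_json()` reconstructs the `fad_population`.
#'
#' @param pop A `fad_population`.
#' @param path File path.
#' @return `write_population_json` returns `path` invisibly;
#'   `read_population_json` returns the population.
#' @export
write_population_json <- function(pop, path) {
  obj <- list(
    n_total = pop$n_total, capacity = pop$capacity, n_demes = pop$n_demes,
    genetics = unclass(pop$genetics), dispersal = unclass(pop$dispersal),
    alleles = pop$alleles, attempt_factor = pop$attempt_factor,
    hap_a = pop$hap_a, hap_b = pop$hap_b, mod_a = pop$mod_a,
    mod_b = pop$mod_b, phenotype = pop$phenotype, fitness = pop$fitness,
    deme = pop$deme)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_population_json
#' @export
read_population_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- obj$genetics
  d <- obj$dispersal
  as_int_haps <- function(h) lapply(h, function(v) as.integer(unlist(v)))
  structure(list(
    hap_a = as_int_haps(obj$hap_a), hap_b = as_int_haps(obj$hap_b),
    mod_a = as.integer(obj$mod_a), mod_b = as.integer(obj$mod_b),
    phenotype = as.integer(obj$phenotype),
    fitness = as.numeric(obj$fitness), deme = as.integer(obj$deme),
    n_demes = as.integer(obj$n_demes), n_total = as.integer(obj$n_total),
    capacity = as.integer(obj$capacity),
    genetics = genetic_params(g$L, g$s, g$h, g$U, g$R),
    dispersal = dispersal_params(d$alpha_U, d$alpha_F, d$cost,
                                 d$fad_ranking),
    alleles = as.data.frame(obj$alleles),
    attempt_factor = obj$attempt_factor), class = "fad_population")
}
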