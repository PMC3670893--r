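#' Per-context clone survival distributions
#'
#' The number of adult wasps developing from a single egg (the clone size)
#' is drawn from a normal distribution, truncated below at zero and rounded
#' to the nearest integer. Which distribution applies depends on the egg's
#' sex and on the composition of the brood it develops in: single-sex
#' broods, mixed-sex broods whose clones all share a maternal lineage
#' ("related"), and mixed-sex broods containing unrelated clones, where
#' female soldier larvae kill male competitors and depress male emergence.
#'
#' Defaults for the single-sex contexts are the field estimates for
#' *Copidosoma koehleri*: 45.7 +/- 10.9 adults per female clone and
#' 32.4 +/- 10.4 per male clone. Related mixed broods reuse the single-sex
#' distributions (soldiers spare kin). The unrelated mixed-brood defaults
#' are calibrated stand-ins chosen so that males make up about one third of
#' the adults emerging from mixed-sex broods, the proportion observed in
#' this species; they can be overridden for other systems.
#'
#' @param female_single_sex,male_single_sex,female_in_related_mixed,
#'   male_in_related_mixed,female_in_unrelated_mixed,male_in_unrelated_mixed
#'   Numeric vectors `c(mean, sd)` of the clone-size distribution in each
#'   brood context, in adults per clone.
#' @return An object of class `"survival_distributions"`: a named list of
#'   `c(mean, sd)` pairs, one per brood context.
#' @examples
#' surv <- survival_distributions()
#' surv$female_single_sex
#' @export
survival_distributions <- function(female_single_sex = c(45.7, 10.9),
                                   male_single_sex = c(32.4, 10.4),
                                   female_in_related_mixed = female_single_sex,
                                   male_in_related_mixed = male_single_sex,
                                   female_in_unrelated_mixed = c(40, 10),
                                   male_in_unrelated_mixed = c(20, 8)) {
  s <- list(
    female_single_sex = as.numeric(female_single_sex),
    male_single_sex = as.numeric(male_single_sex),
    female_in_related_mixed = as.numeric(female_in_related_mixed),
    male_in_related_mixed = as.numeric(male_in_related_mixed),
    female_in_unrelated_mixed = as.numeric(female_in_unrelated_mixed),
    male_in_unrelated_mixed = as.numeric(male_in_unrelated_mixed)
  )
  for (nm in names(s)) {
    v <- s[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || any(v < 0)) {
      stop("survival context '", nm, "' must be c(mean, sd) with mean, sd >= 0",
           call. = FALSE)
    }
    names(s[[nm]]) <- c("mean", "sd")
  }
  structure(s, class = "survival_distributions")
}

#' Simulation configuration
#'
#' Environment-level constants of the host-parasitoid simulation. These are
#' fixed for a run; heritable wasp traits live in [strategy()] objects, of
#' which only the sex-choice probabilities evolve.
#'
#' @param host_count Number of fresh hosts presented each generation.
#' @param host_limit Carrying capacity of a host, in eggs; a host receiving
#'   more eggs than this dies prematurely together with all eggs it holds.
#' @param generations Number of non-overlapping generations to simulate.
#' @param initial_wasp_count Founding wasps per strategy.
#' @param initial_sex_distribution Proportion of males among founders.
#' @param initial_virgin_ratio Proportion of founding females that start
#'   unmated (virgins can only lay male eggs).
#' @param host_acceptance_threshold Attractiveness a host must strictly
#'   exceed to receive an egg, in `[0, 1]`. Low thresholds admit
#'   already-parasitized hosts, i.e. permit superparasitism.
#' @param info_level What a female senses about a host's contents before
#'   choosing egg sex: `"none"` (empty vs parasitized), `"relatedness"`
#'   (adds kinship of prior eggs), or `"sex_and_relatedness"` (full cross
#'   of kinship and sex of prior eggs).
#' @param lifespan Eggs a female can lay, which equals the number of host
#'   presentations she receives (one host per time step).
#' @param rng_seed Integer seed giving bit-for-bit reproducible runs.
#' @return An object of class `"simulation_config"` (a validated list).
#' @examples
#' cfg <- simulation_config(host_count = 50, generations = 10)
#' cfg$host_limit
#' @seealso [strategy()], [run_simulation()], [load_config()]
#' @export
simulation_config <- function(host_count = 200L,
                              host_limit = 3L,
                              generations = 100L,
                              initial_wasp_count = 100L,
                              initial_sex_distribution = 0.5,
                              initial_virgin_ratio = 0,
                              host_acceptance_threshold = 0.5,
                              info_level = c("sex_and_relatedness",
                                             "relatedness", "none"),
                              lifespan = 20L,
                              rng_seed = 1L) {
  info_level <- match.arg(info_level)
  cfg <- structure(list(
    host_count = as.integer(host_count),
    host_limit = as.integer(host_limit),
    generations = as.integer(generations),
    initial_wasp_count = as.integer(initial_wasp_count),
    initial_sex_distribution = as.numeric(initial_sex_distribution),
    initial_virgin_ratio = as.numeric(initial_virgin_ratio),
    host_acceptance_threshold = as.numeric(host_acceptance_threshold),
    info_level = info_level,
    lifespan = as.integer(lifespan),
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk_pos_int <- function(key) {
    v <- cfg[[key]]
    if (length(v) != 1 || is.na(v) || v < 1) {
      stop("config key '", key, "' must be a positive integer", call. = FALSE)
    }
  }
  chk_prop <- function(key) {
    v <- cfg[[key]]
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("config key '", key, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  chk_pos_int("host_count")
  chk_pos_int("host_limit")
  chk_pos_int("initial_wasp_count")
  chk_pos_int("lifespan")
  if (length(cfg$generations) != 1 || is.na(cfg$generations) ||
      cfg$generations < 0) {
    stop("config key 'generations' must be a non-negative integer",
         call. = FALSE)
  }
  chk_prop("initial_sex_distribution")
  chk_prop("initial_virgin_ratio")
  chk_prop("host_acceptance_threshold")
  if (!cfg$info_level %in% c("none", "relatedness", "sex_and_relatedness")) {
    stop("config key 'info_level' must be one of 'none', 'relatedness', ",
         "'sex_and_relatedness'", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a simulation configuration file
#'
#' Configurations are stored as YAML with two optional top-level blocks:
#' `config` (keys of [simulation_config()]) and `strategy` (overrides for
#' the non-evolving fields of [strategy()], including a `survival` block of
#' `context: [mean, sd]` entries). Missing keys take package defaults, so
#' an empty file is a valid configuration; unknown keys are rejected.
#'
#' @param path Path of a YAML file.
#' @return `load_config()` returns `list(config = <simulation_config>,
#'   strategy = <strategy>)`; `save_config()` returns `path`, invisibly.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' save_config(simulation_config(host_count = 50), path = p)
#' identical(load_config(p)$config$host_count, 50L)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("config", "strategy"))
  if (length(bad)) {
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  craw <- if (is.null(raw$config)) list() else raw$config
  bad <- setdiff(names(craw), names(formals(simulation_config)))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- do.call(simulation_config, craw)

  sraw <- if (is.null(raw$strategy)) list() else raw$strategy
  allowed <- c("sex_choice", "egg_count_influence", "in_host_mating_ratio",
               "dispersal_mating", "strategy_inheritance", "virility",
               "virgin_son_virility", "survival")
  bad <- setdiff(names(sraw), allowed)
  if (length(bad)) {
    stop("unknown strategy key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(sraw$survival)) {
    sraw$survival <- do.call(survival_distributions, sraw$survival)
  }
  if (!is.null(sraw$sex_choice)) {
    sraw$sex_choice <- unlist(sraw$sex_choice)
  }
  strat <- do.call(strategy, c(sraw, list(info_level = cfg$info_level)))
  list(config = cfg, strategy = strat)
}

#' @param config A [simulation_config()].
#' @param strat A [strategy()] template, or `NULL` to write the defaults.
#' @rdname load_config
#' @export
save_config <- function(config = simulation_config(), strat = NULL,
                        path) {
  validate_config(config)
  if (is.null(strat)) strat <- strategy(info_level = config$info_level)
  out <- list(
    config = unclass(config),
    strategy = list(
      sex_choice = as.list(strat$sex_choice),
      egg_count_influence = strat$egg_count_influence,
      in_host_mating_ratio = strat$in_host_mating_ratio,
      dispersal_mating = strat$dispersal_mating,
      strategy_inheritance = strat$strategy_inheritance,
      virility = strat$virility,
      virgin_son_virility = strat$virgin_son_virility,
      survival = lapply(unclass(strat$survival), as.list)
    )
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
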