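# Largest egg load a host can reach under threshold acceptance:
# eggs are accepted while max(0, 1 - influence * count) > threshold, so
# the count saturates at the smallest c failing that test. Exact up to
# floating-point representation of the threshold grid.
max_egg_load <- function(threshold, egg_count_influence) {
  if (egg_count_influence <= 0) {
    return(if (1 > threshold) Inf else 0)
  }
  cand <- (1 - threshold) / egg_count_influence
  c0 <- floor(cand + 1e-9)
  if (max(0, 1 - egg_count_influence * c0) > threshold) c0 <- c0 + 1
  max(0, c0)
}

#' Dispersal mating
#'
#' Pairs the population's unmated females with males at random. Each male
#' can fertilize at most his remaining capacity (his virility, or his
#' virgin-son virility if his mother was unmated, minus any brood-mates he
#' fertilized before dispersal); a female's partner is drawn uniformly
#' over the remaining fertilization slots. Females left over when male
#' capacity is exhausted stay virgin and will lay only male eggs.
#'
#' @param pop A `"wasp_population"` (see [initial_population()]).
#' @return The population with updated mating records.
#' @examples
#' set.seed(1)
#' cfg <- simulation_config(initial_sex_distribution = 0.5,
#'                          initial_virgin_ratio = 1)
#' pop <- disperse_and_mate(initial_population(cfg, strategy()))
#' sum(pop$females$mated)
#' @export
disperse_and_mate <- function(pop) {
  unm <- which(!pop$females$mated)
  slots <- rep(seq_len(pop$males$n), pop$males$capacity)
  k <- min(length(unm), length(slots))
  if (k > 0) {
    chosen_f <- if (length(unm) == k) unm else
      unm[sample.int(length(unm), k)]
    chosen_s <- slots[sample.int(length(slots), k)]
    pop$females$mated[chosen_f] <- TRUE
    pop$females$mate_strat[chosen_f, ] <-
      pop$males$strat[chosen_s, , drop = FALSE]
    pop$females$mate_anc[chosen_f, ] <-
      pop$males$anc[chosen_s, , drop = FALSE]
    used <- tabulate(chosen_s, nbins = pop$males$n)
    pop$males$capacity <- pop$males$capacity - used
  }
  pop
}

#' Advance the simulation by one generation
#'
#' Executes one full non-overlapping generation: a fresh set of
#' `config$host_count` hosts is created; for each of `lifespan` time steps
#' every living female is presented one uniformly random host, accepts it
#' if its attractiveness strictly exceeds her threshold, senses its state
#' at her information level and lays one egg whose sex follows her
#' strategy (virgins lay males); hosts are then resolved (overcrowded
#' hosts die; each egg proliferates into a clone via the context-matched
#' survival distribution; a fraction of emerging females mates within the
#' brood), dispersal mating pairs the remaining virgins with males, and
#' the offspring replace their parents.
#'
#' @param pop The current adults, a `"wasp_population"`.
#' @param config A [simulation_config()].
#' @param template A [strategy()] supplying the shared life-history
#'   constants (egg-count influence, mating ratio, inheritance weight,
#'   virilities, survival distributions).
#' @param presentation Optional `n_females x lifespan` integer matrix of
#'   host indices fixing which host each female is shown at each time
#'   step (females are then processed in row order). Used for exact
#'   reproducibility in tests; by default presentation is uniform random.
#' @return A list with `population` (the offspring generation) and
#'   `stats`, a list of per-generation observables: eggs and adults by
#'   sex, premature host deaths, extinction flag, and the adult
#'   population's ancestry mass per founder strategy (`ancestry`; sums to
#'   the adult count).
#' @seealso [run_simulation()] for the multi-generation driver.
#' @export
step_generation <- function(pop, config, template, presentation = NULL) {
  validate_config(config)
  keys <- pop$keys
  n_f <- pop$females$n
  c_stop <- max_egg_load(config$host_acceptance_threshold,
                         template$egg_count_influence)

  stats <- list(eggs_male = 0L, eggs_female = 0L, adults_male = 0L,
                adults_female = 0L, premature_host_deaths = 0L,
                extinct = FALSE, ancestry = numeric(pop$n_tags))
  finish <- function(newpop) {
    stats$adults_male <- newpop$males$n
    stats$adults_female <- newpop$females$n
    stats$extinct <- newpop$males$n + newpop$females$n == 0L
    stats$ancestry <- ancestry_mass(newpop)
    list(population = newpop, stats = stats)
  }
  if (n_f == 0L || c_stop == 0) {
    return(finish(empty_population(keys, pop$n_tags)))
  }
  if (!is.null(presentation)) {
    presentation <- as.matrix(presentation)
    storage.mode(presentation) <- "integer"
    stopifnot(nrow(presentation) == n_f,
              ncol(presentation) == config$lifespan,
              all(presentation >= 1L), all(presentation <= config$host_count))
  }
  surv <- template$survival
  ctx_names <- c("male_single_sex", "female_single_sex",
                 "male_in_related_mixed", "female_in_related_mixed",
                 "male_in_unrelated_mixed", "female_in_unrelated_mixed")
  K <- length(keys)
  # ancestry weights are blended by the same convex rule as the strategy
  # values, so they ride along as extra columns of the strategy matrices
  res <- .cpp_generation(
    cbind(pop$females$strat, pop$females$anc), pop$females$mated,
    cbind(pop$females$mate_strat, pop$females$mate_anc),
    as.integer(pop$females$lineage),
    config$host_count, config$lifespan, config$host_limit,
    config$host_acceptance_threshold, template$egg_count_influence,
    c_stop, template$strategy_inheritance, template$in_host_mating_ratio,
    template$virility, template$virgin_son_virility,
    match(config$info_level, c("none", "relatedness",
                               "sex_and_relatedness")) - 1L,
    vapply(ctx_names, function(nm) surv[[nm]][[1L]], numeric(1)),
    vapply(ctx_names, function(nm) surv[[nm]][[2L]], numeric(1)),
    presentation
  )
  stats$eggs_male <- res$eggs_male
  stats$eggs_female <- res$eggs_female
  stats$premature_host_deaths <- res$premature_hosts
  sc <- seq_len(K)
  split_cols <- function(m) {
    s <- m[, sc, drop = FALSE]
    colnames(s) <- keys
    list(s, m[, -sc, drop = FALSE])
  }
  f <- split_cols(res$f_strat)
  fm <- split_cols(res$f_mate)
  m <- split_cols(res$m_strat)
  newpop <- new_population(
    keys,
    f[[1]], res$f_mated, fm[[1]], fm[[2]], res$f_lin, f[[2]],
    m[[1]], res$m_lin, m[[2]], res$m_vson, res$m_cap
  )
  if (template$dispersal_mating) newpop <- disperse_and_mate(newpop)
  finish(newpop)
}

#' Run a multi-generation simulation
#'
#' Drives [step_generation()] for `config$generations` generations (or
#' until extinction), recording per-generation observables and founder
#' strategy frequencies. All randomness flows from `seed`, so two runs
#' with the same inputs are identical.
#'
#' @param config A [simulation_config()].
#' @param strategies A [strategy()] or list of strategies competing in one
#'   shared environment.
#' @param counts Founders per strategy (default
#'   `config$initial_wasp_count` each).
#' @param seed Integer seed; defaults to `config$rng_seed`.
#' @return A `"wasp_sim"` object: `stats` (data frame with one row per
#'   generation: `generation`, `eggs_male`, `eggs_female`, `adults_male`,
#'   `adults_female`, `premature_host_deaths`, `extinct`), `freq` (matrix
#'   of founder-ancestry mass over adults, generations x strategies),
#'   `final` (last
#'   population), `extinct` flag, and the inputs.
#' @examples
#' cfg <- simulation_config(host_count = 30, generations = 3, lifespan = 5)
#' sim <- run_simulation(cfg, strategy(0.4), seed = 1)
#' sim$stats[, c("generation", "adults_male", "adults_female")]
#' @export
run_simulation <- function(config, strategies, counts = NULL,
                           seed = config$rng_seed) {
  validate_config(config)
  if (inherits(strategies, "wasp_strategy")) strategies <- list(strategies)
  template <- strategies[[1]]
  set.seed(seed)
  pop <- initial_population(config, strategies, counts)
  res <- simulate_from(pop, config, template, config$generations)
  structure(c(res, list(config = config, strategies = strategies,
                        seed = seed)),
            class = "wasp_sim")
}

# Generation loop shared by run_simulation() and the tournament rounds.
# fixation_run > 0 adds an early stop once recombination has homogenized
# the population (every founder-ancestry weight constant across adults)
# for that many consecutive generations — the blending analogue of
# fixation of a discrete strategy.
simulate_from <- function(pop, config, template, generations,
                          fixation_run = 0L) {
  n_tags <- pop$n_tags
  cols <- c("eggs_male", "eggs_female", "adults_male", "adults_female",
            "premature_host_deaths")
  rec <- matrix(0L, generations, length(cols), dimnames = list(NULL, cols))
  ext_flag <- logical(generations)
  freq <- matrix(0, generations, n_tags)
  mono <- 0L
  g_done <- 0L
  extinct <- FALSE
  for (g in seq_len(generations)) {
    out <- step_generation(pop, config, template)
    pop <- out$population
    st <- out$stats
    g_done <- g
    rec[g, ] <- c(st$eggs_male, st$eggs_female, st$adults_male,
                  st$adults_female, st$premature_host_deaths)
    ext_flag[g] <- st$extinct
    freq[g, ] <- st$ancestry
    if (st$extinct) {
      extinct <- TRUE
      break
    }
    if (fixation_run > 0L) {
      mono <- if (ancestry_converged(pop)) mono + 1L else 0L
      if (mono >= fixation_run) break
    }
  }
  gs <- seq_len(g_done)
  stats <- data.frame(generation = gs, rec[gs, , drop = FALSE],
                      extinct = ext_flag[gs])
  list(stats = stats, freq = freq[gs, , drop = FALSE],
       final = pop, extinct = extinct)
}

#' @export
print.wasp_sim <- function(x, ...) {
  g <- nrow(x$stats)
  cat("<wasp_sim>", g, "generation(s);",
      if (x$extinct) "population extinct" else "population extant", "\n")
  if (g > 0) {
    last <- x$stats[g, ]
    cat(sprintf("  final adults: %d female / %d male\n",
                last$adults_female, last$adults_male))
  }
  invisible(x)
}

#' Primary and secondary sex ratios of a simulation
#'
#' The primary sex ratio is the proportion of male eggs laid; the
#' secondary sex ratio the proportion of males among emerging adults.
#' Both are averaged over the final `window` recorded generations with
#' eggs/adults present.
#'
#' @param sim A `"wasp_sim"` (or any object with a compatible `$stats`).
#' @param window Number of trailing generations to average over.
#' @return Named numeric vector `c(primary, secondary)`.
#' @export
sim_sex_ratios <- function(sim, window = 50L) {
  st <- sim$stats
  st <- st[seq(max(1L, nrow(st) - window + 1L), nrow(st)), , drop = FALSE]
  eggs <- st$eggs_male + st$eggs_female
  adults <- st$adults_male + st$adults_female
  c(primary = mean((st$eggs_male / eggs)[eggs > 0]),
    secondary = mean((st$adults_male / adults)[adults > 0]))
}
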