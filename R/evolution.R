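#' Derive a child seed from a base seed
#'
#' Deterministic seed derivation used wherever the package fans one
#' user-supplied seed out to replicates, rounds or sweep cells, so that a
#' whole experiment is reproducible from a single integer. The result is
#' always a positive integer below 2^31.
#'
#' @param base Base seed (integer).
#' @param index Non-negative index of the child stream.
#' @return An integer seed.
#' @examples
#' derive_seed(1, 1:3)
#' @export
derive_seed <- function(base, index) {
  as.integer(((as.numeric(base) + 48271 * as.numeric(index)) %%
                2147483646) + 1)
}

cond_error <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Viability screen for a sex-allocation strategy
#'
#' A strategy is viable when a population using it exclusively does not go
#' extinct. The screen seeds `config$initial_wasp_count` mated females
#' with the candidate strategy and simulates `horizon` generations;
#' non-viable allocations (e.g. laying only male eggs) collapse within a
#' few generations because males leave no eggs.
#'
#' @param strat The candidate [strategy()].
#' @param config A [simulation_config()].
#' @param horizon Generations to simulate before declaring viability.
#' @param seed Optional seed; when `NULL` (the default) the screen draws
#'   from the current RNG stream, so callers control reproducibility.
#' @return `TRUE` iff the population survives the screening horizon.
#' @examples
#' cfg <- simulation_config(host_count = 50, lifespan = 5)
#' set.seed(1)
#' viability_screen(strategy(1, info_level = cfg$info_level), cfg)
#' @export
viability_screen <- function(strat, config, horizon = 25L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  cfg$initial_sex_distribution <- 0
  cfg$initial_virgin_ratio <- 0
  pop <- initial_population(cfg, strat)
  res <- simulate_from(pop, cfg, strat, as.integer(horizon))
  !res$extinct
}

#' Simulate one competition round between strategies
#'
#' The competing strategies are seeded into one shared environment,
#' `config$initial_wasp_count` mated females each, and the population is
#' simulated until one founder strategy has held all adults for
#' `fixation_run` consecutive generations or `max_generations` is
#' reached. Fitness follows the long-term population-share criterion: a
#' founder strategy's share in a generation is its mean ancestry weight
#' over adults (daughters carry `w` of their father's and `1 - w` of
#' their mother's ancestry, exactly as they blend strategy values; sons
#' carry their mother's), and the winner is the founder with the highest
#' mean share across the round's generations (ties broken by
#' final-generation share, then by lowest strategy index). The returned
#' winning strategy carries the population's mean sex-choice vector at
#' the end of the round — the allocation that actually took over, which
#' through recombination is a convex blend of the founders' values
#' dominated by the winner's.
#'
#' @param strategies Non-empty list of [strategy()] candidates.
#' @param config A [simulation_config()].
#' @param max_generations Generation cap for the round.
#' @param fixation_run Consecutive single-strategy generations that end
#'   the round early.
#' @return A list: `winner` (evolved strategy), `winner_index`,
#'   `mean_share`, `stats`, `freq`, `generations_run`, `fixed`.
#' @examples
#' cfg <- simulation_config(host_count = 40, generations = 10, lifespan = 5)
#' set.seed(1)
#' r <- run_round(list(strategy(0.3, info_level = cfg$info_level)), cfg,
#'                max_generations = 5)
#' r$winner_index
#' @export
run_round <- function(strategies, config, max_generations = 500L,
                      fixation_run = 10L) {
  if (!length(strategies)) stop("empty strategy subset", call. = FALSE)
  template <- strategies[[1]]
  cfg <- config
  cfg$initial_sex_distribution <- 0   # rounds are seeded with females
  cfg$initial_virgin_ratio <- 0
  pop <- initial_population(cfg, strategies)
  res <- simulate_from(pop, cfg, template, as.integer(max_generations),
                       fixation_run = as.integer(fixation_run))
  total <- rowSums(res$freq)
  live <- total > 0
  if (res$extinct || !any(live)) {
    cond_error("polywasp_extinction",
               paste0("all ", length(strategies),
                      " strategies in the subset went extinct"))
  }
  share <- res$freq[live, , drop = FALSE] / total[live]
  mean_share <- colMeans(share)
  best <- which(mean_share == max(mean_share))
  if (length(best) > 1) {
    fin <- res$freq[max(which(live)), best]
    best <- best[fin == max(fin)]
  }
  winner_index <- min(best)
  evolved <- template
  evolved$sex_choice[] <- population_mean_strategy(res$final)
  list(winner = evolved, winner_index = winner_index,
       mean_share = mean_share, stats = res$stats, freq = res$freq,
       generations_run = nrow(res$stats),
       fixed = ancestry_converged(res$final))
}

#' Tournament selection of an evolutionarily stable sex allocation
#'
#' Draws `n_strategies` random viable strategies (uniform sex-choice
#' values, redrawing non-viable candidates), splits them at random into
#' subsets of `subset_size`, and lets each subset compete in a shared
#' environment ([run_round()]). Round winners are randomly re-split and
#' compete again until a single winning strategy remains; with the
#' default 125 candidates in subsets of 5 this yields 25, then 5, then 1
#' winners over three rounds.
#'
#' @param config A [simulation_config()].
#' @param template [strategy()] providing the non-evolving components.
#' @param n_strategies Number of random viable starting strategies.
#' @param subset_size Strategies per competition subset.
#' @param seed Seed governing every draw, screen and round.
#' @param screen_horizon Generations for [viability_screen()].
#' @param max_generations,fixation_run Passed to [run_round()].
#' @param max_draw_attempts Cap on candidate draws before giving up on
#'   finding viable strategies.
#' @return A `"tournament_result"`: `winner` (evolved strategy),
#'   `alloc_empty` (its empty-host male-egg probability),
#'   `realized_primary`/`realized_secondary` (sex ratios realized over
#'   the last generations of the final round), `rounds` (per-round subset
#'   assignments and winner counts), `n_strategies`, `seed`.
#' @examples
#' cfg <- simulation_config(host_count = 40, lifespan = 5)
#' \donttest{
#' tr <- tournament(cfg, n_strategies = 5, seed = 1,
#'                  screen_horizon = 5, max_generations = 15)
#' tr$alloc_empty
#' }
#' @export
tournament <- function(config,
                       template = strategy(info_level = config$info_level),
                       n_strategies = 125L, subset_size = 5L,
                       seed = config$rng_seed, screen_horizon = 25L,
                       max_generations = 500L, fixation_run = 10L,
                       max_draw_attempts = 50L * n_strategies) {
  validate_config(config)
  set.seed(seed)
  candidates <- vector("list", n_strategies)
  attempts <- 0L
  for (i in seq_len(n_strategies)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_draw_attempts) {
        cond_error("polywasp_no_viable",
                   paste0("failed to draw ", n_strategies,
                          " viable strategies within ", max_draw_attempts,
                          " attempts (threshold may not sustain a ",
                          "population)"))
      }
      cand <- make_random_strategy(template)
      if (viability_screen(cand, config, horizon = screen_horizon)) {
        candidates[[i]] <- cand
        break
      }
    }
  }

  current <- candidates
  rounds <- list()
  last_round_result <- NULL
  round_no <- 0L
  while (length(current) > 1L) {
    round_no <- round_no + 1L
    perm <- sample.int(length(current))
    groups <- split(perm, ceiling(seq_along(perm) / subset_size))
    winners <- vector("list", length(groups))
    winner_src <- integer(length(groups))
    for (gi in seq_along(groups)) {
      rr <- run_round(current[groups[[gi]]], config,
                      max_generations = max_generations,
                      fixation_run = fixation_run)
      winners[[gi]] <- rr$winner
      winner_src[gi] <- groups[[gi]][rr$winner_index]
      last_round_result <- rr
    }
    rounds[[round_no]] <- list(subsets = groups, n_winners = length(winners),
                               winner_source = winner_src)
    current <- winners
  }
  if (length(current) == 1L && round_no == 0L) {
    # degenerate single-candidate tournament: one self-competition round
    last_round_result <- run_round(current, config,
                                   max_generations = max_generations,
                                   fixation_run = fixation_run)
    current <- list(last_round_result$winner)
    rounds[[1]] <- list(subsets = list(1L), n_winners = 1L,
                        winner_source = 1L)
  }
  winner <- current[[1]]
  ratios <- sim_sex_ratios(last_round_result, window = 50L)
  structure(list(
    winner = winner,
    alloc_empty = unname(winner$sex_choice[["empty"]]),
    realized_primary = unname(ratios[["primary"]]),
    realized_secondary = unname(ratios[["secondary"]]),
    rounds = rounds, n_strategies = n_strategies,
    subset_size = subset_size, seed = seed
  ), class = "tournament_result")
}

#' @export
print.tournament_result <- function(x, ...) {
  cat("<tournament_result>", x$n_strategies, "starting strategies;",
      "winners per round:",
      paste(vapply(x$rounds, function(r) r$n_winners, 1L), collapse = " -> "),
      "\n")
  cat(sprintf("  evolved empty-host allocation: %.3f\n", x$alloc_empty))
  cat(sprintf("  realized primary %.3f / secondary %.3f sex ratio\n",
              x$realized_primary, x$realized_secondary))
  invisible(x)
}

#' Replicate tournaments and summarize the winning allocation
#'
#' Runs `n_replicates` independent [tournament()]s with seeds derived
#' from `base_seed` and reports the mean and standard deviation of the
#' winning sex allocation. Because the model never states a single
#' scalar "allocation" of a multi-key strategy, two summaries are
#' emitted side by side: the winner's empty-host male-egg probability and
#' the primary sex ratio actually realized at the end of the final round
#' (plus the realized secondary ratio).
#'
#' @param config A [simulation_config()].
#' @param n_replicates Number of independent tournaments.
#' @param base_seed Seed from which replicate seeds are derived via
#'   [derive_seed()].
#' @param ... Passed on to [tournament()] (`template`, `n_strategies`,
#'   `max_generations`, ...).
#' @return A `"tournament_replicates"` object: `replicates` (one row per
#'   tournament) and `summary` (mean and SD columns; SD is 0 for a single
#'   replicate).
#' @export
replicate_tournaments <- function(config, n_replicates = 5L,
                                  base_seed = config$rng_seed, ...) {
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    tr <- tournament(config, seed = derive_seed(base_seed, i), ...)
    rows[[i]] <- data.frame(
      replicate = i, seed = tr$seed, alloc_empty = tr$alloc_empty,
      realized_primary = tr$realized_primary,
      realized_secondary = tr$realized_secondary
    )
  }
  reps <- do.call(rbind, rows)
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  summary <- data.frame(
    n_replicates = n_replicates,
    alloc_empty_mean = mean(reps$alloc_empty),
    alloc_empty_sd = sd0(reps$alloc_empty),
    primary_mean = mean(reps$realized_primary),
    primary_sd = sd0(reps$realized_primary),
    secondary_mean = mean(reps$realized_secondary),
    secondary_sd = sd0(reps$realized_secondary)
  )
  structure(list(replicates = reps, summary = summary),
            class = "tournament_replicates")
}

#' @export
print.tournament_replicates <- function(x, ...) {
  s <- x$summary
  cat("<tournament_replicates>", s$n_replicates, "replicate(s)\n")
  cat(sprintf("  empty-host allocation: %.3f +/- %.3f\n",
              s$alloc_empty_mean, s$alloc_empty_sd))
  cat(sprintf("  realized primary:      %.3f +/- %.3f\n",
              s$primary_mean, s$primary_sd))
  cat(sprintf("  realized secondary:    %.3f +/- %.3f\n",
              s$secondary_mean, s$secondary_sd))
  invisible(x)
}
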