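# Small configurations keep these runs to seconds; the full-scale
# tournament structure is exercised in test-acceptance.R.
small_cfg <- function(host_acceptance_threshold = 0.35, ...) {
  simulation_config(host_count = 40, lifespan = 5,
                    host_acceptance_threshold = host_acceptance_threshold,
                    initial_wasp_count = 30L, ...)
}

test_that("viability screening separates collapsing from persisting allocations", {
  cfg <- small_cfg()
  all_male <- strategy(1, info_level = cfg$info_level)
  balanced <- strategy(0.5, info_level = cfg$info_level)
  expect_false(viability_screen(all_male, cfg, horizon = 10, seed = 1))
  expect_true(viability_screen(balanced, cfg, horizon = 10, seed = 1))
  # all-female allocations self-destruct through virgin granddaughters:
  # daughters find no males, so the following generation is all male
  all_female <- strategy(0, info_level = cfg$info_level)
  expect_false(viability_screen(all_female, cfg, horizon = 10, seed = 1))
  # deterministic given a seed
  expect_identical(viability_screen(balanced, cfg, horizon = 10, seed = 5),
                   viability_screen(balanced, cfg, horizon = 10, seed = 5))
})

test_that("a round ranks strategies by long-term ancestry share", {
  cfg <- small_cfg()
  viable <- strategy(0.5, info_level = cfg$info_level)
  set.seed(2)
  rr <- run_round(list(viable), cfg, max_generations = 10)
  expect_identical(rr$winner_index, 1L)

  # a non-viable all-male lineage self-extinguishes against a viable one
  all_male <- strategy(1, info_level = cfg$info_level)
  set.seed(3)
  rr <- run_round(list(viable, all_male), cfg, max_generations = 30)
  expect_identical(rr$winner_index, 1L)
  expect_lt(rr$mean_share[2], rr$mean_share[1])

  set.seed(4)
  a <- run_round(list(viable, strategy(0.4, info_level = cfg$info_level)),
                 cfg, max_generations = 15)
  set.seed(4)
  b <- run_round(list(viable, strategy(0.4, info_level = cfg$info_level)),
                 cfg, max_generations = 15)
  expect_identical(a$winner_index, b$winner_index)
  expect_identical(a$stats, b$stats)

  expect_error(run_round(list(), cfg), "empty")
  set.seed(5)
  expect_error(
    run_round(list(all_male, all_male), cfg, max_generations = 20),
    class = "polywasp_extinction")
})

test_that("degenerate tournaments collapse to a single round", {
  cfg <- small_cfg()
  tr <- tournament(cfg, template = strategy(info_level = cfg$info_level),
                   n_strategies = 5, seed = 1, screen_horizon = 5,
                   max_generations = 15)
  expect_length(tr$rounds, 1L)
  expect_identical(tr$rounds[[1]]$n_winners, 1L)
  expect_s3_class(tr$winner, "wasp_strategy")
  expect_true(tr$alloc_empty >= 0 && tr$alloc_empty <= 1)
})

test_that("tournament winners stay inside the founders' convex hull", {
  # recombination is convex and there is no mutation, so no evolved
  # sex-choice value can escape the range spanned by the candidates
  cfg <- small_cfg(info_level = "none")
  set.seed(6)
  tr <- tournament(cfg, template = strategy(info_level = "none"),
                   n_strategies = 5, seed = 6, screen_horizon = 5,
                   max_generations = 20)
  expect_true(all(tr$winner$sex_choice >= 0 & tr$winner$sex_choice <= 1))
  expect_true(tr$alloc_empty > 0 && tr$alloc_empty < 1)
})

test_that("an impossible threshold fails the viability stage, not the session", {
  cfg <- small_cfg(host_acceptance_threshold = 1)  # nothing accepted
  expect_error(
    tournament(cfg, template = strategy(info_level = cfg$info_level),
               n_strategies = 2, seed = 1, screen_horizon = 3,
               max_draw_attempts = 6),
    class = "polywasp_no_viable")
})

test_that("replicate summaries report mean and SD of the winning allocation", {
  cfg <- small_cfg()
  reps <- replicate_tournaments(cfg, n_replicates = 1, base_seed = 9,
                                template = strategy(info_level = cfg$info_level),
                                n_strategies = 5, screen_horizon = 5,
                                max_generations = 15)
  expect_identical(nrow(reps$replicates), 1L)
  expect_identical(reps$summary$alloc_empty_sd, 0)  # single replicate
  expect_identical(reps$summary$primary_sd, 0)

  # derived seeds differ across replicates, and are below 2^31
  expect_false(derive_seed(9, 1) == derive_seed(9, 2))
  expect_true(all(derive_seed(9, 1:100) > 0))
  expect_true(all(derive_seed(9, 1:100) < 2^31))
})
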