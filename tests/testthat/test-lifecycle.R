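test_that("attractiveness declines linearly with egg load, floored at 0", {
  expect_equal(attractiveness(0, 0.5), 1)
  expect_equal(attractiveness(1, 0.5), 0.5)
  expect_equal(attractiveness(3, 0.5), 0)
  h <- host(data.frame(mother_id = 1, lineage = 1, sex = "male"))
  expect_equal(attractiveness(h, 0.3), 0.7)
})

test_that("host acceptance is strict and admits superparasitism at low thresholds", {
  expect_true(accept_host(1, threshold = 0.4, egg_count_influence = 0.5))
  expect_false(accept_host(1, threshold = 0.5, egg_count_influence = 0.5))
  expect_true(accept_host(host(), threshold = 0.99,
                          egg_count_influence = 0.3))
  expect_false(accept_host(host(alive = FALSE), threshold = 0,
                           egg_count_influence = 0.3))
  # low threshold accepts a parasitized host (superparasitism), high refuses
  h1 <- host(data.frame(mother_id = 1, lineage = 1, sex = "female"))
  expect_true(accept_host(h1, threshold = 0.2, egg_count_influence = 0.3))
  expect_false(accept_host(h1, threshold = 0.8, egg_count_influence = 0.3))
})

test_that("maximum egg load matches the strict acceptance rule exactly", {
  chk <- function(thr, inf) {
    c_stop <- polywasp:::max_egg_load(thr, inf)
    if (is.finite(c_stop)) {
      if (c_stop > 0) expect_true(max(0, 1 - inf * (c_stop - 1)) > thr)
      expect_false(max(0, 1 - inf * c_stop) > thr)
    }
  }
  for (thr in c(0, 0.05, 0.1, 0.25, 0.4, 0.7, 0.85, 1)) chk(thr, 0.3)
  for (inf in c(0.1, 0.2, 0.25, 1 / 3)) chk(0.4, inf)
  expect_identical(polywasp:::max_egg_load(0.5, 0), Inf)
  expect_identical(polywasp:::max_egg_load(1, 0), 0)
})

test_that("virgins lay only male eggs; mated females follow their strategy", {
  expect_identical(choose_egg_sex(strategy(0, info_level = "none"),
                                  "empty", virgin = TRUE, n = 10),
                   rep("male", 10))
  expect_identical(choose_egg_sex(strategy(0, info_level = "none"),
                                  "empty", n = 10), rep("female", 10))
  set.seed(2)
  sexes <- choose_egg_sex(strategy(0.6, info_level = "none"), "empty",
                          n = 10000)
  expect_lt(abs(mean(sexes == "male") - 0.6), 0.02)
})

test_that("brood resolution kills overcrowded hosts and sizes clones by context", {
  surv0 <- survival_distributions(
    female_single_sex = c(45.7, 0), male_single_sex = c(32.4, 0),
    female_in_unrelated_mixed = c(40, 0), male_in_unrelated_mixed = c(20, 0))

  over <- host(data.frame(mother_id = 1:4, lineage = 1:4,
                          sex = rep("female", 4)))
  out <- resolve_host(over, surv0, host_limit = 3)
  expect_true(out$premature_death)
  expect_identical(out$emerging_males + out$emerging_females, 0L)

  one <- host(data.frame(mother_id = 1, lineage = 1, sex = "female"))
  out <- resolve_host(one, surv0, host_limit = 3)
  expect_identical(out$emerging_females, 46L)  # round(45.7)
  expect_identical(out$emerging_males, 0L)

  mix <- host(data.frame(mother_id = c(1, 2), lineage = c(1, 2),
                         sex = c("male", "female")))
  out <- resolve_host(mix, surv0, host_limit = 3, in_host_mating_ratio = 1,
                      virility = 1)
  expect_identical(out$emerging_males, 20L)    # soldier-suppressed males
  expect_identical(out$emerging_females, 40L)
  expect_identical(sum(out$emergers$mated), 20L)  # capped by virility

  # related mixed broods are spared by soldiers: single-sex clone sizes
  kin <- host(data.frame(mother_id = c(1, 1), lineage = c(1, 1),
                         sex = c("male", "female")))
  out <- resolve_host(kin, surv0, host_limit = 3)
  expect_identical(out$emerging_males, 32L)
  expect_identical(out$emerging_females, 46L)
})

test_that("dispersal mating respects virility caps and leaves leftovers virgin", {
  mkpop <- function(n_f, n_m, capacity) {
    keys <- sex_choice_keys("none")
    fs <- matrix(0.5, n_f, 2, dimnames = list(NULL, keys))
    ms <- matrix(0.5, n_m, 2, dimnames = list(NULL, keys))
    polywasp:::new_population(
      keys, fs, rep(FALSE, n_f), fs * NA, matrix(NA_real_, n_f, 1),
      seq_len(n_f), matrix(1, n_f, 1),
      ms, seq_len(n_m), matrix(1, n_m, 1), rep(FALSE, n_m),
      rep(as.integer(capacity), n_m))
  }
  set.seed(1)
  p <- disperse_and_mate(mkpop(3, 1, 5))   # capacity >= demand
  expect_identical(sum(p$females$mated), 3L)

  p <- disperse_and_mate(mkpop(3, 1, 1))   # virgin's-son-like cap of 1
  expect_identical(sum(p$females$mated), 1L)
  expect_identical(sum(!p$females$mated), 2L)

  p <- disperse_and_mate(mkpop(4, 0, 1))   # no males at all
  expect_identical(sum(p$females$mated), 0L)
})

test_that("a lone mother on empty hosts yields two all-daughter broods", {
  # degenerate configuration enumerated by hand: sd = 0, all-female
  # allocation, threshold so high only empty hosts are accepted,
  # lifespan 2 -> two hosts parasitized, 2 x round(45.7) = 92 daughters
  cases <- oracle_cases()
  cs <- cases$single_mother_daughters_only
  pop <- oracle_population(cs$females, cs$config, cs$template)
  out <- step_generation(pop, cs$config, cs$template,
                         presentation = cs$presentation)
  expect_identical(out$stats$eggs_female, 2L)
  expect_identical(out$stats$eggs_male, 0L)
  expect_identical(out$stats$adults_female, 92L)
  expect_identical(out$stats$adults_male, 0L)
  # daughters of an unmated brood stay virgin
  expect_identical(sum(out$population$females$mated), 0L)
})

test_that("step_generation conserves eggs and flags extinction", {
  cfg <- simulation_config(host_count = 20, lifespan = 5,
                           host_acceptance_threshold = 0.35)
  tpl <- strategy(0.5, info_level = cfg$info_level)
  set.seed(4)
  pop <- initial_population(cfg, tpl, counts = 30L)
  out <- step_generation(pop, cfg, tpl)
  total_eggs <- out$stats$eggs_male + out$stats$eggs_female
  # egg capacity: acceptance saturates each host at the maximum egg load
  c_stop <- polywasp:::max_egg_load(cfg$host_acceptance_threshold,
                                    tpl$egg_count_influence)
  expect_lte(total_eggs, c_stop * cfg$host_count)
  # adults descend only from eggs: every clone id refers to a laid egg
  expect_true(all(out$population$females$lineage <= total_eggs))
  expect_true(all(out$population$males$lineage <= total_eggs))
  # ancestry mass equals the adult head count
  expect_equal(sum(out$stats$ancestry),
               out$stats$adults_male + out$stats$adults_female)

  empty <- polywasp:::empty_population(sex_choice_keys(cfg$info_level), 1L)
  out0 <- step_generation(empty, cfg, tpl)
  expect_true(out0$stats$extinct)
  expect_identical(out0$stats$adults_female + out0$stats$adults_male, 0L)
})

test_that("run_simulation is seed-deterministic and handles edge cases", {
  cfg <- simulation_config(host_count = 30, generations = 4, lifespan = 5,
                           host_acceptance_threshold = 0.35)
  tpl <- strategy(0.5, info_level = cfg$info_level)
  a <- run_simulation(cfg, tpl, seed = 7)
  b <- run_simulation(cfg, tpl, seed = 7)
  expect_identical(a$stats, b$stats)
  expect_identical(a$freq, b$freq)

  cfg0 <- simulation_config(host_count = 30, generations = 0, lifespan = 5)
  s0 <- run_simulation(cfg0, strategy(0.5), seed = 1)
  expect_identical(nrow(s0$stats), 0L)

  # an all-male allocation leaves no daughters: extinction within lifespan
  all_male <- strategy(1, info_level = cfg$info_level)
  sm <- run_simulation(cfg, all_male, seed = 2)
  expect_true(sm$extinct)
  expect_lte(nrow(sm$stats), cfg$lifespan)
})

test_that("virgin mothers never contribute female eggs", {
  cfg <- simulation_config(host_count = 15, generations = 1, lifespan = 4,
                           host_acceptance_threshold = 0.35,
                           initial_virgin_ratio = 1)
  tpl <- strategy(0, info_level = cfg$info_level)  # would lay females if mated
  set.seed(9)
  pop <- initial_population(cfg, tpl, counts = 10L)
  out <- step_generation(pop, cfg, tpl)
  expect_identical(out$stats$eggs_female, 0L)
  expect_gt(out$stats$eggs_male, 0L)
  expect_true(all(out$population$males$virgins_son))
})
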