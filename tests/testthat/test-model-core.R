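test_that("simulation_config validates its fields", {
  cfg <- simulation_config(host_count = 50, generations = 10)
  expect_s3_class(cfg, "simulation_config")
  expect_identical(cfg$host_count, 50L)
  expect_error(simulation_config(host_limit = 0), "host_limit")
  expect_error(simulation_config(host_count = 0), "host_count")
  expect_error(simulation_config(initial_sex_distribution = 1.2),
               "initial_sex_distribution")
  expect_error(simulation_config(host_acceptance_threshold = -0.1),
               "host_acceptance_threshold")
  expect_error(simulation_config(info_level = "telepathy"))
})

test_that("survival distributions carry the field clone-size estimates", {
  s <- survival_distributions()
  expect_equal(unname(s$female_single_sex), c(45.7, 10.9))
  expect_equal(unname(s$male_single_sex), c(32.4, 10.4))
  # soldiers spare kin: related mixed broods develop like single-sex ones
  expect_equal(s$female_in_related_mixed, s$female_single_sex)
  expect_equal(s$male_in_related_mixed, s$male_single_sex)
  expect_error(survival_distributions(male_single_sex = c(-1, 2)), "male")
})

test_that("sex-choice key sets follow the information level", {
  expect_identical(sex_choice_keys("none"), c("empty", "parasitized"))
  expect_identical(sex_choice_keys("relatedness"),
                   c("empty", "related", "unrelated", "mixed"))
  full <- sex_choice_keys("sex_and_relatedness")
  expect_length(full, 10L)
  expect_identical(full[1], "empty")
  expect_identical(full[2:4],
                   c("related_male", "related_female", "related_mixed"))
  expect_error(sex_choice_keys("psychic"))
})

test_that("strategy objects enforce their invariants", {
  s <- strategy(0.4, info_level = "none")
  expect_equal(unname(s$sex_choice), c(0.4, 0.4))
  expect_error(strategy(1.2), "sex_choice")
  expect_error(strategy(0.5, in_host_mating_ratio = 2), "in_host_mating")
  expect_error(strategy(0.5, virility = 1, virgin_son_virility = 3),
               "virgin_son_virility")
  expect_error(strategy(c(a = 0.5), info_level = "none"), "names")
})

test_that("random strategies are uniform and keep the template's constants", {
  tpl <- strategy(info_level = "none", virility = 5L,
                  virgin_son_virility = 2L, egg_count_influence = 0.7)
  set.seed(11)
  a <- make_random_strategy(tpl)
  set.seed(11)
  b <- make_random_strategy(tpl)
  expect_identical(a, b)           # deterministic under seeding
  expect_identical(a$virility, 5L) # non-evolving fields copied
  expect_identical(a$virgin_son_virility, 2L)
  expect_identical(a$egg_count_influence, 0.7)

  set.seed(3)
  draws <- replicate(10000, make_random_strategy(tpl)$sex_choice[["empty"]])
  expect_gte(min(draws), 0)
  expect_lte(max(draws), 1)
  expect_lt(abs(mean(draws) - 0.5), 0.02)  # uniform mean 1/2
  expect_lt(abs(var(draws) - 1 / 12), 0.005)
})

test_that("clone-size sampling truncates at zero and rounds", {
  expect_identical(sample_clone_size(3, 45.7, 0), rep(46L, 3))
  set.seed(5)
  z <- sample_clone_size(5000, 0, 1)
  expect_true(all(z >= 0L))
  set.seed(6)
  m <- mean(sample_clone_size(10000, 45.7, 10.9))
  expect_lt(abs(m - 45.7), 0.5)
  expect_error(sample_clone_size(1, -1, 0), "mean")
  # c(mean, sd) pairs from survival_distributions() are accepted directly
  expect_identical(
    sample_clone_size(1, survival_distributions(
      female_single_sex = c(45.7, 0))$female_single_sex), 46L)
})

test_that("host state sensing classifies kinship and sexes, then coarsens", {
  empty <- host()
  expect_identical(host_state_key(empty, 1, "none"), "empty")
  expect_identical(host_state_key(empty, 1, "sex_and_relatedness"), "empty")

  h <- host(data.frame(mother_id = 9, lineage = 9, sex = "male"))
  expect_identical(host_state_key(h, 1, "sex_and_relatedness"),
                   "unrelated_male")
  expect_identical(host_state_key(h, 9, "sex_and_relatedness"),
                   "related_male")
  expect_identical(host_state_key(h, 1, "relatedness"), "unrelated")
  expect_identical(host_state_key(h, 1, "none"), "parasitized")

  h2 <- host(data.frame(mother_id = c(9, 1), lineage = c(9, 1),
                        sex = c("male", "female")))
  expect_identical(host_state_key(h2, 1, "sex_and_relatedness"),
                   "mixed_mixed")
  expect_identical(host_state_key(h2, 2, "sex_and_relatedness"),
                   "unrelated_mixed")

  dead <- host(alive = FALSE)
  expect_error(host_state_key(dead, 1, "none"), "dead")

  # pure function: repeated calls agree
  expect_identical(host_state_key(h2, 1, "relatedness"),
                   host_state_key(h2, 1, "relatedness"))
})

test_that("strategy blending is convex and sons copy their mother", {
  m <- strategy(0.2, info_level = "none")
  f <- strategy(0.8, info_level = "none")
  expect_equal(inherit_strategy(m, f, w = 0)$sex_choice, m$sex_choice)
  expect_equal(inherit_strategy(m, f, w = 1)$sex_choice, f$sex_choice)
  expect_equal(unname(inherit_strategy(m, f, w = 0.5)$sex_choice[1]), 0.5)
  expect_identical(inherit_strategy(m, f, sex = "male"), m)
  expect_error(inherit_strategy(m, f, w = 2), "w")

  set.seed(8)
  for (i in 1:25) {
    a <- make_random_strategy(strategy())
    b <- make_random_strategy(strategy())
    w <- runif(1)
    d <- inherit_strategy(a, b, w)$sex_choice
    expect_true(all(d >= pmin(a$sex_choice, b$sex_choice) - 1e-12))
    expect_true(all(d <= pmax(a$sex_choice, b$sex_choice) + 1e-12))
  }
})
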