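test_that("census objects validate their counts", {
  cen <- brood_census(13, 13, 14, 420, 590, 630)
  expect_s3_class(cen, "brood_census")
  expect_error(brood_census(-1, 0, 0), "non-negative")
  expect_error(brood_census(5, 0, 0, wasps_in_male_broods = 3), "at least")
})

test_that("mixed-brood proportion estimates the superparasitism frequency", {
  expect_equal(mixed_brood_proportion(brood_census(13, 13, 14)), 0.35)
  expect_equal(mixed_brood_proportion(brood_census(1, 1, 0)), 0)
  expect_equal(mixed_brood_proportion(brood_census(0, 0, 5)), 1)
  expect_error(mixed_brood_proportion(brood_census(0, 0, 0)), "no broods")
})

test_that("primary sex-ratio estimator reproduces hand-computed values", {
  # symmetric counts cancel the correction entirely
  expect_equal(estimate_primary_sex_ratio(brood_census(10, 10, 0), 0.2), 0.5)
  # hand arithmetic: (1.35*50 + 20) / (1.35*80 + 40) = 87.5 / 148
  expect_equal(estimate_primary_sex_ratio(brood_census(50, 30, 20), 0.35),
               87.5 / 148)
  expect_equal(estimate_primary_sex_ratio(brood_census(0, 10, 0), 0.35), 0)
  # integer-allocation variant: ceil(0.35*50)=18 and ceil(0.35*30)=11
  # extra eggs -> (50+18+20) / (50+18+30+11+40)
  expect_equal(estimate_primary_sex_ratio(brood_census(50, 30, 20), 0.35,
                                          method = "integer"), 88 / 149)
  expect_error(estimate_primary_sex_ratio(brood_census(0, 0, 0)), "no broods")
  expect_error(estimate_primary_sex_ratio(brood_census(1, 1, 1), 2),
               "p_super")
})

test_that("secondary sex-ratio estimator applies the mixed-brood male third", {
  expect_equal(
    estimate_secondary_sex_ratio(brood_census(3, 3, 3, 300, 300, 300)),
    (300 + 100) / 900)
  expect_equal(
    estimate_secondary_sex_ratio(brood_census(2, 2, 0, 100, 100, 0)), 0.5)
  expect_equal(
    estimate_secondary_sex_ratio(brood_census(0, 5, 0, 0, 700, 0)), 0)
  expect_error(estimate_secondary_sex_ratio(brood_census(1, 1, 0)),
               "no wasps")
})

test_that("estimators are scale-invariant and monotone in brood counts", {
  base <- brood_census(40, 25, 15, 1200, 1100, 900)
  scaled <- brood_census(120, 75, 45, 3600, 3300, 2700)
  expect_equal(estimate_primary_sex_ratio(base, 0.35),
               estimate_primary_sex_ratio(scaled, 0.35))
  expect_equal(estimate_secondary_sex_ratio(base),
               estimate_secondary_sex_ratio(scaled))
  expect_equal(mixed_brood_proportion(base), mixed_brood_proportion(scaled))

  for (k in c(5, 10, 20)) {
    up <- estimate_primary_sex_ratio(brood_census(40 + k, 25, 15), 0.35)
    down <- estimate_primary_sex_ratio(brood_census(40, 25 + k, 15), 0.35)
    ref <- estimate_primary_sex_ratio(brood_census(40, 25, 15), 0.35)
    expect_gt(up, ref)
    expect_lt(down, ref)
  }
  # every estimate stays a proportion
  set.seed(10)
  for (i in 1:30) {
    cnt <- rpois(3, 20) + c(1, 1, 0)
    cen <- brood_census(cnt[1], cnt[2], cnt[3],
                        cnt[1] * 30, cnt[2] * 45, cnt[3] * 60)
    p <- estimate_primary_sex_ratio(cen, runif(1))
    s <- estimate_secondary_sex_ratio(cen)
    expect_true(p >= 0 && p <= 1)
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("the synthetic census generator mirrors its design", {
  set.seed(12)
  solo <- generate_brood_census(0.5, 0, 500)
  expect_identical(solo$n_mixed_broods, 0L)  # single eggs cannot mix

  set.seed(13)
  cen <- generate_brood_census(0.5, 0.35, 10000)
  # P(mixed) = p_double * 2 r (1-r) = 0.35 * 0.5 = 0.175
  expect_lt(abs(mixed_brood_proportion(cen) - 0.175), 0.015)
  b <- cen$broods
  expect_identical(nrow(b), 10000L)
  expect_true(all(b$n_eggs %in% 1:2))
})

test_that("generator-to-estimator round trip recovers the true ratio", {
  set.seed(14)
  cen <- generate_brood_census(0.6, 0.35, 10000)
  p_hat <- single_sex_double_fraction(cen)
  est <- estimate_primary_sex_ratio(cen, p_super = p_hat)
  expect_lt(abs(est - 0.6), 0.03)
  # and the same within tolerance across independent censuses
  set.seed(15)
  ests <- replicate(5, {
    cc <- generate_brood_census(0.6, 0.35, 8000)
    estimate_primary_sex_ratio(cc, p_super = single_sex_double_fraction(cc))
  })
  expect_true(all(abs(ests - 0.6) < 0.03))
})

test_that("arcsine-square-root transform maps proportions to [0, pi/2]", {
  expect_equal(asin_sqrt(c(0, 0.5, 1)), c(0, asin(sqrt(0.5)), pi / 2))
  expect_error(asin_sqrt(1.5), "proportions")
})
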