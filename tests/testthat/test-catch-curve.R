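test_that("age assignment inverts the growth curve, floors, and caps", {
  lh <- grouper_lh()
  # inversion identity: length at exact age 1 maps back to age 1
  expect_equal(as.integer(assign_age(lh$l_inf * (1 - exp(-lh$k_growth)), lh)), 1L)
  expect_equal(as.integer(assign_age(46.8, lh)), 5L)  # 5.16 yr floored
  # at or beyond Linf: capped at tmax and counted
  a <- assign_age(c(110, 150), lh)
  expect_equal(as.integer(a), c(21L, 21L))
  expect_equal(attr(a, "n_capped"), 2L)
  # non-decreasing in length
  tl <- seq(1, 130, by = 0.5)
  expect_true(all(diff(as.integer(assign_age(tl, lh))) >= 0))
})

test_that("age frequency finds the peak and recodes the descending limb", {
  af <- build_age_frequency(ages = rep(c(2, 3, 4, 5), c(1, 5, 3, 2)))
  expect_equal(af$peak_age, 3L)
  expect_equal(af$descending_limb, 3:5)
  expect_equal(af$limb_counts, c(5L, 3L, 2L))
  expect_equal(af$recoded, 0:2)
  # peak-plus-one variant drops the peak class
  af2 <- build_age_frequency(ages = rep(c(2, 3, 4, 5), c(1, 5, 3, 2)),
                             limb = "peak_plus_one")
  expect_equal(af2$descending_limb, 4:5)
  expect_equal(af2$recoded, 0:1)
  expect_error(build_age_frequency(ages = rep(3L, 10)), "one age class")
  lh <- grouper_lh()
  ds <- length_dataset(rep(2012, 3), "s", c(10, 10.1, 10.2))  # all age 0
  expect_error(build_age_frequency(ds, lh), "age class")
})

test_that("Chapman-Robson matches the closed-form hand oracle", {
  est <- chapman_robson(list(limb_counts = c(4, 2, 1), recoded = 0:2))
  # n = 7, T = 4: S = 4 / (7 + 4 - 1)
  expect_equal(est$s_annual, 0.4)
  expect_equal(est$n_used, 7)
  expect_equal(est$t_sum, 4)
  expect_equal(est$z_total, -log(0.4) - (6 * 5) / (7 * 5 * 10))
  expect_equal(est$se_s, sqrt(0.4 * (0.4 - 3 / 9)))  # (T-1)/(n+T-2) = 3/9
  # degenerate: every limb fish at the peak age
  deg <- chapman_robson(list(limb_counts = c(5, 0), recoded = 0:1))
  expect_true(deg$degenerate)
  expect_equal(deg$s_annual, 0)
  expect_error(chapman_robson(list(limb_counts = c(2), recoded = 0)),
               "2 age classes")
  expect_error(chapman_robson(list(limb_counts = c(1, 1), recoded = 0:1)),
               "3 fish")
})

test_that("survival estimate is consistent on a geometric catch curve", {
  # perfectly geometric limb with ratio r at large n recovers S = r
  r <- 0.55
  counts <- round(1e4 * r^(0:9))
  est <- chapman_robson(list(limb_counts = counts, recoded = 0:9))
  expect_equal(est$s_annual, r, tolerance = 0.01)
  # bias-corrected Z never exceeds the naive -log(S)
  set.seed(21)
  for (i in 1:20) {
    cts <- rmultinom(1, 500, 0.6^(0:6))[, 1]
    if (sum(cts) < 3 || sum(cts * 0:6) == 0) next
    e <- chapman_robson(list(limb_counts = cts, recoded = 0:6))
    expect_lte(e$z_total, -log(e$s_annual))
  }
})

test_that("catch curve on simulated data tracks the true total mortality", {
  lh <- grouper_lh()
  sel <- gear()
  z_true <- lh$m_nat * 3  # fully selected: Z = M (1 + F/M) = 0.87
  # exact ages: the limb is near-geometric with ratio exp(-Z); selectivity
  # still rising at the peak age and the tmax cap leave a modest downward
  # deviation from the fully-selected Z
  pop <- equilibrium_population(lh, 2, sel)
  set.seed(13)
  w <- pop$rel_numbers * selectivity_at_length(pop$mean_len_at_age, sel)
  ages <- sample(pop$ages, 20000, replace = TRUE, prob = w)
  est_exact <- chapman_robson(build_age_frequency(ages = ages))
  expect_equal(est_exact$z_total, z_true, tolerance = 0.1)
  # ages assigned from lengths: the growth curve flattens near Linf, so
  # length-at-age variability smears old ages and attenuates Z ("age
  # slicing"); the estimate still tracks mortality to first order
  ds <- sample_catch_lengths(pop, sel, 20000, seed = 13)
  est <- chapman_robson(build_age_frequency(ds, lh))
  expect_equal(est$z_total, z_true, tolerance = 0.35)
  expect_lt(est$z_total, -log(est$s_annual) + 1e-12)
  expect_gt(est$s_annual, 0.3)
  expect_lt(est$s_annual, 0.65)
})

test_that("generational turnover is the midpoint of maturity and maximum age", {
  expect_equal(generational_turnover(6.5, 21)$gt_years, 13.75)
  expect_equal(generational_turnover(8, 8)$gt_years, 8)
  expect_equal(generational_turnover(0, 10)$gt_years, 5)
  gt <- generational_turnover(6.5, 21)
  expect_true(gt$gt_years >= gt$am && gt$gt_years <= gt$tmax)
  expect_error(generational_turnover(10, 8), "exceed")
})
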