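test_that("logistic ogives hit their 50% and 95% anchors exactly", {
  sel <- gear(39, 46.7)
  expect_equal(selectivity_at_length(39, sel), 0.5, tolerance = 1e-12)
  expect_equal(selectivity_at_length(46.7, sel), 0.95, tolerance = 1e-12)
  # direct evaluation of the logistic at an interior point
  expect_equal(selectivity_at_length(43, sel),
               1 / (1 + exp(-log(19) * (43 - 39) / (46.7 - 39))))
  expect_equal(round(selectivity_at_length(43, sel), 3), 0.822)
  lh <- grouper_lh()
  expect_equal(maturity_at_length(65.3, lh), 0.5, tolerance = 1e-12)
  expect_equal(maturity_at_length(lh$lm95, lh), 0.95, tolerance = 1e-12)
  expect_equal(maturity_at_length(lh$lm95 + 60, lh), 1, tolerance = 1e-3)
  expect_equal(maturity_at_length(70, lh),
               1 / (1 + exp(-log(19) * (70 - 65.3) / (lh$lm95 - 65.3))))
  expect_error(selectivity_params(46.7, 39), "sl50 < sl95")
})

test_that("expected composition matches the brute-force oracle", {
  lh <- grouper_lh()
  edges <- make_length_bins(lh)
  cases <- list(c(2.0, 39, 46.7),        # typical exploited gear
                c(0.0, 39, 46.7),        # unfished
                c(1.0, 40, 40.001),      # near knife-edge
                c(3.5, 25, 60))          # wide ogive, heavy fishing
  for (cs in cases) {
    got <- expected_length_composition(lh, cs[1],
                                       list(sl50 = cs[2], sl95 = cs[3]),
                                       bin_edges = edges, n_gtg = 1)
    want <- oracle_composition(lh, cs[1], cs[2], cs[3], edges)
    expect_equal(got$prop, want, tolerance = 1e-8)
  }
})

test_that("expected composition is a proper distribution and widens with CV", {
  sel <- gear()
  vars <- vapply(c(0.05, 0.10, 0.15), function(cv) {
    lh <- grouper_lh(cv_linf = cv)
    comp <- expected_length_composition(lh, 1.5, sel)
    expect_equal(sum(comp$prop), 1, tolerance = 1e-9)
    expect_true(all(comp$prop >= 0))
    sum(comp$prop * comp$mids^2) - sum(comp$prop * comp$mids)^2
  }, 0)
  expect_true(all(diff(vars) > 0))
})

test_that("composition proportions are invariant to count rescaling", {
  lh <- grouper_lh()
  comp <- expected_length_composition(lh, 2, gear())
  c1 <- length_composition(bin_edges = comp$bin_edges,
                           counts = round(comp$prop * 1000))
  c2 <- length_composition(bin_edges = comp$bin_edges,
                           counts = round(comp$prop * 1000) * 7)
  expect_equal(c1$prop, c2$prop)
})

test_that("SPR is 1 with no fishing, decreasing in F/M, and vanishes at high F", {
  lh <- grouper_lh()
  sel <- gear()
  expect_identical(spawning_potential_ratio(lh, 0, sel), 1)
  spr <- vapply(seq(0, 6, by = 0.5),
                function(f) spawning_potential_ratio(lh, f, sel), 0)
  expect_true(all(diff(spr) < 0))
  expect_true(all(spr >= 0 & spr <= 1))
  # heavy fishing with gear recruiting far below maturity exhausts spawning
  small_gear <- gear(20, 25)   # sl50 far below lm50 = 65.3
  expect_lt(spawning_potential_ratio(lh, 60, small_gear), 1e-3)
})

test_that("maximum-likelihood fit recovers parameters from exact proportions", {
  lh <- grouper_lh()
  truth <- expected_length_composition(lh, 2.0, list(sl50 = 39, sl95 = 47))
  obs <- length_composition(bin_edges = truth$bin_edges,
                            counts = round(truth$prop * 1e5))
  fit <- fit_lbspr(obs, lh, n_boot = 0)
  expect_true(fit$converged)
  expect_equal(fit$f_over_m, 2.0, tolerance = 0.01)
  expect_equal(fit$sel$sl50, 39, tolerance = 0.01)
  expect_equal(fit$sel$sl95, 47, tolerance = 0.01)
})

test_that("fit flags the zero-fishing boundary on unfished data", {
  lh <- grouper_lh()
  truth <- expected_length_composition(lh, 0, list(sl50 = 39, sl95 = 47))
  obs <- length_composition(bin_edges = truth$bin_edges,
                            counts = round(truth$prop * 5e4))
  fit <- fit_lbspr(obs, lh, n_boot = 0)
  expect_true(fit$at_boundary)
})

test_that("bootstrap SDs are produced and fit errors are informative", {
  lh <- grouper_lh()
  truth <- expected_length_composition(lh, 2, gear())
  obs <- length_composition(bin_edges = truth$bin_edges,
                            counts = round(truth$prop * 2000))
  fit <- fit_lbspr(obs, lh, n_boot = 20, seed = 3)
  expect_true(all(is.finite(c(fit$sd_f_over_m, fit$sd_sl50, fit$sd_sl95,
                              fit$sd_spr))))
  expect_gt(fit$sd_f_over_m, 0)
  # too few occupied bins is an error; small n only a warning
  few <- length_composition(bin_edges = c(0, 10, 20, 30),
                            counts = c(0, 30, 0))
  expect_error(fit_lbspr(few, lh), "3 non-empty")
  small <- length_composition(bin_edges = truth$bin_edges,
                              counts = round(truth$prop * 30))
  expect_warning(try(fit_lbspr(small, lh, n_boot = 0), silent = TRUE),
                 "fewer than 50")
})
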