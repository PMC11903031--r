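# longitudinal pairs scored against a toy model fitted at sigma2 = 1
zdiff_fixture <- function(n_controls, seed, sigma_eta2 = 0.7, sigma_xi2 = 0.3,
                          general_rho = NULL, delta = 0, n_patients = 0) {
  m <- toy_model(n_train = 2000, seed = 1)
  spec <- cohort_spec(sigma_eta2 = sigma_eta2, sigma_xi2 = sigma_xi2,
                      general_rho = general_rho, delta = delta, seed = seed)
  lg <- gen_longitudinal(spec, n_controls, n_patients)
  list(model = m, visits = lg$visits, truth = lg$truth)
}

test_that("visit pairing validates structure", {
  fx <- zdiff_fixture(5, seed = 2)
  pairs <- make_visit_pairs(fx$visits, "thickness")
  expect_equal(nrow(pairs), 5)
  expect_true(all(pairs$interval > 0))

  three <- dplyr::bind_rows(fx$visits,
                            dplyr::mutate(fx$visits[1, ], visit = 3L))
  expect_error(make_visit_pairs(three, "thickness"), "> 2 visits")

  cross <- fx$visits
  cross$site[cross$subject_id == cross$subject_id[1] & cross$visit == 2] <- "siteB2"
  expect_error(make_visit_pairs(cross, "thickness"), "Cross-site")
})

test_that("noise estimator recovers 2*sigma_xi^2 and degenerates correctly", {
  fx <- zdiff_fixture(200, seed = 3, sigma_eta2 = 0.7, sigma_xi2 = 0.3)
  pairs <- make_visit_pairs(fx$visits, "thickness")
  ns <- estimate_noise(pairs, fx$model)
  expect_lt(abs(ns$two_sigma_xi2 - 0.6) / 0.6, 0.15)
  expect_equal(ns$n_calibration, 200)
  expect_false(ns$tracking_violation)
  expect_gt(ns$implied_rho, 0)

  # identical visits: model term vanishes with matching covariates, raw = 0
  same <- pairs
  same$age2 <- same$age1
  same$y2 <- same$y1
  ns0 <- suppressWarnings(estimate_noise(same, fx$model))
  expect_equal(ns0$raw_value, 0)
  expect_gt(ns0$two_sigma_xi2, 0) # clamped to the floor

  expect_error(estimate_noise(pairs[1, ], fx$model), "at least 2")
})

test_that("negative-autocorrelation data trip the centile-tracking diagnostic", {
  fx <- zdiff_fixture(200, seed = 4, general_rho = -0.5)
  pairs <- make_visit_pairs(fx$visits, "thickness")
  ns <- estimate_noise(pairs, fx$model)
  # raw estimate near 2 * sigma2 * (1 - rho) = 3, exceeding 2 * sigma2
  expect_lt(abs(ns$raw_value - 3) / 3, 0.25)
  expect_true(ns$tracking_violation)
  expect_lt(1 - ns$raw_value / (2 * fx$model$sigma2), 0)
})

test_that("noise estimator is consistent as |C| grows", {
  errs <- vapply(c(50, 200, 1000), function(n) {
    fx <- zdiff_fixture(n, seed = 5)
    ns <- estimate_noise(make_visit_pairs(fx$visits, "thickness"), fx$model)
    abs(ns$two_sigma_xi2 - 0.6)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.1)
})

test_that("z-diff hand cases, symmetry and site-offset invariance", {
  fx <- zdiff_fixture(10, seed = 6)
  pairs <- make_visit_pairs(fx$visits, "thickness")

  # identical visits score exactly 0
  same <- pairs
  same$age2 <- same$age1; same$y2 <- same$y1
  expect_equal(zdiff_score(same, fx$model, 0.25)$zdiff, rep(0, 10))

  # warped difference 1, expected difference ~ itself, noise 0.25 -> ~2:
  # build an exact case through a prior-only model with no uncertainty left
  m0 <- fit_posterior(matrix(numeric(), 0, 3), numeric(), sigma2 = 1,
                      omega2 = 1e-12,
                      basis = basis_spec(boundary_knots = c(0, 1), degree = 1,
                                         linear_covariates = character(),
                                         site_labels = "s",
                                         intercept = FALSE))
  p1 <- tibble::tibble(subject_id = "a", sex = 0, site = "s",
                       age1 = 0.5, age2 = 0.5, interval = 1e-9,
                       y1 = 0, y2 = 1, idp = "idp")
  expect_equal(zdiff_score(p1, m0, 0.25)$zdiff, 2, tolerance = 1e-4)

  # swapping visit labels negates the score exactly
  z <- zdiff_score(pairs, fx$model, 0.6)$zdiff
  swapped <- pairs
  swapped[c("age1", "age2", "y1", "y2")] <- pairs[c("age2", "age1", "y2", "y1")]
  expect_equal(zdiff_score(swapped, fx$model, 0.6)$zdiff, -z)

  # a constant site offset added to both visits cancels
  shifted <- pairs
  shifted$y1 <- shifted$y1 + 0.4
  shifted$y2 <- shifted$y2 + 0.4
  expect_equal(zdiff_score(shifted, fx$model, 0.6)$zdiff, z, tolerance = 1e-12)
})

test_that("z-diff is standard normal under the healthy null", {
  fx <- zdiff_fixture(2000, seed = 7)
  pairs <- make_visit_pairs(fx$visits, "thickness")
  # score with the true noise scale 2 * sigma_xi^2 = 0.6
  z <- zdiff_score(pairs, fx$model, 0.6)$zdiff
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(var(z) - 1), 0.1)
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("null flag rate equals theta at any eta/xi split", {
  for (sx in c(0.1, 0.5, 0.9)) {
    fx <- zdiff_fixture(2000, seed = 8 + round(100 * sx),
                        sigma_eta2 = 1 - sx, sigma_xi2 = sx)
    pairs <- make_visit_pairs(fx$visits, "thickness")
    z <- zdiff_score(pairs, fx$model, 2 * sx)$zdiff
    rate <- mean(flag_score(z, 0.05))
    # 99% binomial CI around 0.05 at n = 2000
    expect_lt(abs(rate - 0.05), 2.576 * sqrt(0.05 * 0.95 / 2000))
  }
})

test_that("naive subtraction variance is 2(1 - rho), matching z-diff only at rho = 0.5", {
  for (rho in c(0, 0.5)) {
    fx <- zdiff_fixture(2000, seed = 20 + 10 * rho,
                        sigma_eta2 = rho, sigma_xi2 = 1 - rho)
    pairs <- make_visit_pairs(fx$visits, "thickness")
    nv <- naive_zdiff(pairs, fx$model)$naive
    expect_lt(abs(var(nv) - 2 * (1 - rho)), 0.15)
  }
  # identical visits give exactly 0
  fx <- zdiff_fixture(5, seed = 30)
  pairs <- make_visit_pairs(fx$visits, "thickness")
  pairs$age2 <- pairs$age1; pairs$y2 <- pairs$y1
  expect_equal(naive_zdiff(pairs, fx$model)$naive, rep(0, 5))
})

test_that("flagging thresholds implement the two-sided quantile rule", {
  expect_false(flag_score(1.0, 0.05))
  expect_true(flag_score(2.5, 0.05))
  expect_true(all(flag_score(c(-3, 0, 3), 1)))
  expect_error(flag_score(1, 0), "theta")
})

test_that("group Wilcoxon + BH behaves on null, shifted and hand cases", {
  # all-zero scores: no signal, nothing significant
  null_scores <- tibble::tibble(idp = rep(c("a", "b"), each = 10), zdiff = 0)
  gw <- group_wilcoxon(null_scores)
  expect_equal(gw$p, c(1, 1))
  expect_false(any(gw$significant))

  # N(1, 1) scores at n = 100 are detected
  set.seed(41)
  shifted <- tibble::tibble(idp = "a", zdiff = rnorm(100, 1))
  expect_true(group_wilcoxon(shifted)$significant)

  # BH step-up on (0.01, 0.02, 0.04, 0.9) at level 0.05: thresholds are
  # k * 0.05 / 4 = (0.0125, 0.025, 0.0375, 0.05); the largest k with
  # p(k) <= threshold is k = 2 (0.04 > 0.0375), so exactly 2 rejections
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.9), "BH") <= 0.05,
               c(TRUE, TRUE, FALSE, FALSE))
})
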