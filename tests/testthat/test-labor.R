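test_that("dropout curve interpolates the published anchors", {
  expect_equal(dropout_reduction(0, FALSE), 0)
  expect_equal(dropout_reduction(10, FALSE), 0.11)
  expect_equal(dropout_reduction(20, FALSE), 0.22)
  expect_equal(dropout_reduction(40, FALSE), 0.55)
  expect_equal(dropout_reduction(15, FALSE), 0.165)
  # beyond the last anchor the curve continues at its mean slope (1.375/h)
  expect_equal(dropout_reduction(42, FALSE), 0.5775)
  # clamped at 100 percentage points
  expect_equal(dropout_reduction(1000, FALSE), 1)
  # no association for FDW households, at any load
  expect_equal(dropout_reduction(40, TRUE), 0)
  expect_equal(dropout_reduction(c(10, 40), c(FALSE, TRUE)), c(0.11, 0))
  expect_error(dropout_reduction(-1, FALSE), "non-negative")
})

test_that("dropout curve is non-decreasing in hours", {
  h <- seq(0, 120, by = 0.5)
  r <- dropout_reduction(h, FALSE)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("curve constructor validates anchors", {
  expect_error(dropout_curve(data.frame(hours = c(0, 0), reduction = c(0, 1))),
               "strictly increasing")
  expect_error(dropout_curve(data.frame(hours = c(0, 10),
                                        reduction = c(20, 10))),
               "non-decreasing")
})

test_that("dropout counts sum employable caregivers over no-FDW home cells", {
  mix <- single_cell_mix("high", "home_unpaid", 1000)
  # 42 h/week -> 57.75 pp reduction; 65% employable
  expect_equal(count_dropouts(mix), 1000 * 0.65 * 0.5775)
  # nursing homes and FDW cells contribute nothing
  expect_equal(count_dropouts(single_cell_mix("high", "nursing_home", 1000)),
               0)
  expect_equal(count_dropouts(single_cell_mix("high", "home_fdw", 1000)), 0)
  expect_equal(count_dropouts(mix, employable_fraction = 0), 0)
  # services cell uses the with-services hours table
  svc <- single_cell_mix("low", "home_services", 100)
  expect_equal(count_dropouts(svc),
               100 * 0.65 * dropout_reduction(25, FALSE))
})

test_that("paid labor follows the patient-to-staff ratios", {
  empty <- single_cell_mix("low", "home_unpaid", 0)
  expect_equal(paid_labor_required(empty), 0)
  m <- empty
  m["high", "nursing_home"] <- 10000
  m["low", "home_services"] <- 14000
  m["medium", "home_fdw"] <- 5000
  expect_equal(paid_labor_required(m), 10000 / 5 + 14000 / 7 + 5000)
  nh_only <- single_cell_mix("high", "nursing_home", 22400)
  expect_equal(paid_labor_required(nh_only), 4480)
  # households with both services count once (FDW) unless double counting
  both <- single_cell_mix("medium", "home_services_fdw", 700)
  expect_equal(paid_labor_required(both), 700)
  expect_equal(paid_labor_required(both, double_count_fdw_hcbs = TRUE),
               700 + 100)
  # degree-1 homogeneity and additivity in the mix
  set.seed(3)
  mix <- single_cell_mix("low", "home_unpaid", 0)
  mix[] <- runif(15, 0, 1e4)
  expect_equal(paid_labor_required(mix * 3), 3 * paid_labor_required(mix))
})

test_that("labor-requirement ratio reproduces the published rounding", {
  expect_equal(round(labor_requirement_ratio(35500, 20900), 1), 1.7)
  expect_equal(round(labor_requirement_ratio(27200, 21500), 1), 1.3)
  expect_equal(labor_requirement_ratio(0, 100), 0)
  expect_error(labor_requirement_ratio(100, 0), "positive")
})

test_that("survey preparation recodes hours and applies exclusions", {
  raw <- data.frame(cgh = c(150, 40, 30, 20),
                    never_employed = c(0, 0, 1, 0),
                    multi_recipient = c(0, 0, 0, 1),
                    has_fdw = c(0, 1, 0, 0))
  d <- prepare_survey(raw)
  expect_equal(nrow(d), 2)
  expect_equal(d$cgh, c(112, 40))   # 150 capped at 112 (16 h/day)
  d2 <- prepare_survey(raw, drop_fdw = TRUE)
  expect_equal(d2$cgh, 112)
})

test_that("two-stage probit recovers the generating hours effect", {
  sp <- synthetic_survey_spec(seed = 2024)
  d <- prepare_survey(make_caregiver_survey(sp), drop_fdw = TRUE)
  fit <- fit_iv_probit_tsls(d)
  # tolerance: 3 x the Monte-Carlo sd of gamma1-hat at n = 20,000 (0.0031,
  # measured over independent replicates of this generator)
  expect_lt(abs(fit$gamma[["gamma1"]] - (-0.035)), 3 * 0.0031)
  # stage 1 recovers the severity gradient in hours
  expect_equal(unname(fit$beta[c("beta1", "beta2")]), c(5, 11),
               tolerance = 0.15)
  # predicted hours carried on the fit
  expect_length(fit$predicted_cgh, nrow(d))
})

test_that("a null hours effect is rarely declared significant", {
  set.seed(99)
  seeds <- sample.int(1e6, 200)
  nonsig <- vapply(seeds, function(s) {
    sp <- synthetic_survey_spec(
      n = 2000, true_gamma = c(0.9, 0, 0.2, 0.1, -0.1, 0.3, 0.1), seed = s)
    d <- prepare_survey(make_caregiver_survey(sp), drop_fdw = TRUE)
    f <- fit_iv_probit_tsls(d)
    abs(coef(summary(f$stage2))["cgh_hat", "z value"]) < 1.96
  }, logical(1))
  expect_gte(mean(nonsig), 0.90)
})

test_that("degenerate designs raise estimation errors", {
  sp <- synthetic_survey_spec(n = 500, seed = 5)
  d <- prepare_survey(make_caregiver_survey(sp))
  d1 <- d; d1$lfp <- 1
  expect_error(fit_iv_probit_tsls(d1), "separation")
  d2 <- d; d2$adl1 <- 0; d2$adl2 <- 0
  expect_error(fit_iv_probit_tsls(d2), "instrument")
  expect_error(fit_iv_probit_tsls(d[1:10, ]), "at least")
})

test_that("bootstrap standard errors are finite and bracket the estimate", {
  sp <- synthetic_survey_spec(n = 1500, seed = 7)
  d <- prepare_survey(make_caregiver_survey(sp), drop_fdw = TRUE)
  se <- iv_probit_boot(d, n_boot = 30, seed = 11)
  expect_equal(nrow(se), 7)
  expect_true(all(is.finite(se$se)))
  expect_true(all(se$lower < se$estimate & se$estimate < se$upper))
})

test_that("a fitted model exports a monotone dropout curve", {
  sp <- synthetic_survey_spec(seed = 31)
  d <- prepare_survey(make_caregiver_survey(sp), drop_fdw = TRUE)
  fit <- fit_iv_probit_tsls(d)
  curve <- as_dropout_curve(fit)
  expect_s3_class(curve, "dropout_curve")
  expect_equal(curve$anchors$hours, c(0, 10, 20, 40))
  expect_true(all(diff(curve$anchors$reduction) >= 0))
  # generating probit was chosen near the published anchors
  expect_equal(curve$anchors$reduction[2:4], c(11, 22, 55), tolerance = 0.2)
})
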