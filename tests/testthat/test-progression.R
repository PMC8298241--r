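test_that("log transform is the natural log of CAC plus one", {
  expect_equal(log_cac(0), 0)
  expect_equal(log_cac(exp(1) - 1), 1, tolerance = 1e-15)
  expect_equal(log_cac(99), log(100), tolerance = 1e-15)
  expect_error(log_cac(-1), ">= 0")
})

test_that("a cohort on exact log-linear percentile lines recovers the slope", {
  ph <- make_on_model_cohort(slope = 0.1)
  m <- fit_percentile_model(ph, percentile_grid = (1:9 - 0.5) / 9,
                            min_stratum = 10, age_window = 10, age_step = 10)
  for (s in c("F", "M")) {
    expect_equal(unname(m$sex_fits[[s]]$coefs[, "slope"]), rep(0.1, 9),
                 tolerance = 1e-9)
  }
})

test_that("age-constant CAC yields flat percentile lines", {
  ph <- make_on_model_cohort(slope = 0)
  m <- fit_percentile_model(ph, percentile_grid = (1:9 - 0.5) / 9,
                            min_stratum = 10, age_window = 10, age_step = 10)
  expect_equal(unname(m$sex_fits[["F"]]$coefs[, "slope"]), rep(0, 9),
               tolerance = 1e-9)
  # zero-slope model: everyone predicted at their own baseline value
  pred <- predict_cac5y(m, ph)
  expect_equal(pred, ph$cac_b, tolerance = 1e-9)
})

test_that("evaluated percentile values are monotone at any age", {
  set.seed(61)
  n <- 600
  ph <- data.frame(id = as.character(1:n), age = runif(n, 45, 75),
                   sex = sample(c("F", "M"), n, TRUE),
                   cac_b = round(ifelse(runif(n) < 0.3, 0,
                                        exp(rnorm(n, 3, 2))), 1),
                   dt_years = 5, stringsAsFactors = FALSE)
  m <- fit_percentile_model(ph)
  for (s in c("F", "M")) {
    for (a in c(47, 59, 73)) {
      v <- vapply(m$grid, function(p) {
        cacgrs:::eval_percentile_model(m, s, a, p)
      }, numeric(1))
      expect_true(all(diff(v) >= -1e-12))
    }
  }
})

test_that("the stratum-size guard names the deficient sex", {
  ph <- make_on_model_cohort()
  ph <- ph[ph$sex == "F" | seq_len(nrow(ph)) <= 40, ]
  expect_error(fit_percentile_model(ph, min_stratum = 100), "stratum 'F'|stratum 'M'")
})

test_that("classification applies the 20%-of-observed band rule", {
  expect_identical(as.character(classify_progression(150, 100)$class), "rapid")
  expect_identical(as.character(classify_progression(90, 100)$class),
                   "expected")
  expect_identical(as.character(classify_progression(42, 42)$class),
                   "expected")
  # below the band
  expect_identical(as.character(classify_progression(50, 100)$class), "slow")
  # band endpoints ordered and centered at the prediction
  cl <- classify_progression(c(150, 90), c(100, 100))
  expect_true(all(cl$band_low <= cl$band_high))
  expect_error(classify_progression(10, 10, band_frac = 1.2), "band_frac")
})

test_that("increasing observed CAC traverses slow, expected, rapid once", {
  pred <- 80
  f <- 0.2
  obs <- seq(0, 300, by = 0.25)
  cls <- as.character(classify_progression(obs, rep(pred, length(obs)), f)$class)
  runs <- rle(cls)$values
  expect_identical(runs, c("slow", "expected", "rapid"))
  # thresholds at predicted/(1+f) and predicted/(1-f)
  lo <- pred / (1 + f); hi <- pred / (1 - f)
  expect_identical(as.character(classify_progression(lo - 0.01, pred)$class),
                   "slow")
  expect_identical(as.character(classify_progression(lo + 0.01, pred)$class),
                   "expected")
  expect_identical(as.character(classify_progression(hi - 0.01, pred)$class),
                   "expected")
  expect_identical(as.character(classify_progression(hi + 0.01, pred)$class),
                   "rapid")
})

test_that("the predicted-anchor alternative shifts the band as documented", {
  # observed 90 vs predicted 100: inside +/-20% of predicted,
  # outside 20%-of-observed only when observed shrinks the band
  expect_identical(as.character(
    classify_progression(83, 100, anchor = "predicted")$class), "expected")
  expect_identical(as.character(
    classify_progression(83, 100, anchor = "observed")$class), "slow")
})

test_that("extreme-change flags follow the re-reading triggers", {
  f <- flag_extreme_change(5, 60, 5)
  expect_true(f$low_to_high); expect_false(any(f$high_to_low, f$annual_rise))
  f <- flag_extreme_change(25, 8, 5)
  expect_true(f$high_to_low)
  f <- flag_extreme_change(100, 110, 5)
  expect_false(any(unlist(f)))        # ~1.9%/year rise
  r <- (301 / 101)^(1 / 3) - 1        # > 30%/year
  f <- flag_extreme_change(100, 300, 3)
  expect_true(r > 0.30 && f$annual_rise)
  f <- flag_extreme_change(100, 60, 5) # about -9.7%/year
  expect_true(f$annual_fall)
  expect_error(flag_extreme_change(1, 1, 0), "dt_years")
})

test_that("cohort classification partitions participants and ignores order", {
  ph <- make_on_model_cohort(slope = 0.08, dt = 3)
  set.seed(62)
  ph$cac_5y <- ph$cac_5y * exp(rnorm(nrow(ph), 0, 0.4))
  pr <- cac_progression(ph, min_stratum = 10, age_window = 10, age_step = 10)
  expect_identical(sum(table(pr$class)), nrow(ph))
  shuf <- sample(nrow(ph))
  pr2 <- cac_progression(ph[shuf, ], min_stratum = 10, age_window = 10,
                         age_step = 10)
  expect_identical(pr2$class[match(pr$id, pr2$id)], pr$class)
})

test_that("follow-up ages beyond the fitted range warn but still predict", {
  ph <- make_on_model_cohort(dt = 2.5)
  m <- fit_percentile_model(ph, percentile_grid = (1:9 - 0.5) / 9,
                            min_stratum = 10, age_window = 10, age_step = 10)
  far <- ph[1, ]; far$dt_years <- 40
  expect_warning(predict_cac5y(m, far), "extrapolat")
})
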