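#' Log-transform a CAC score
#'
#' The natural log of the Agatston score plus one, the standard variance
#' stabilizer for the right-skewed, zero-inflated CAC distribution.
#'
#' @param cac Agatston score(s), non-negative.
#' @return `ln(cac + 1)`.
#' @export
log_cac <- function(cac) {
  if (any(cac < 0, na.rm = TRUE)) stop_invalid("CAC scores must be >= 0")
  log1p(cac)
}

#' Fit the age- and sex-specific CAC percentile model
#'
#' Per sex, each participant receives a baseline percentile as the midrank of
#' `log(CAC_b+1)` within the sliding age window (`age_window` years wide)
#' centered on their own age; zeros share the bottom mass through midranks.
#' For every percentile of `percentile_grid` the empirical quantile (type 5,
#' the midrank-consistent definition) of overlapping fixed windows (centers
#' stepped by `age_step`) is regressed linearly on the window-center age,
#' giving one log-scale percentile line per grid point.
#' Evaluation interpolates between grid lines and enforces monotonicity in
#' the percentile by a cumulative-maximum adjustment.
#'
#' @param table phenotype data.frame with `id`, `age`, `sex`, `cac_b`.
#' @param percentile_grid strictly increasing percentiles in (0,1).
#' @param min_stratum minimum participants per sex stratum.
#' @param age_window window width in years (default 10).
#' @param age_step spacing of window centers in years (default 5).
#' @return object of class `percentile_model`.
#' @export
fit_percentile_model <- function(table,
                                 percentile_grid = seq(0.05, 0.95, by = 0.05),
                                 min_stratum = 30,
                                 age_window = 10, age_step = 5) {
  stopifnot(all(c("id", "age", "sex", "cac_b") %in% names(table)))
  g <- percentile_grid
  if (any(g <= 0 | g >= 1) || is.unsorted(g, strictly = TRUE)) {
    stop_invalid("percentile_grid must be strictly increasing within (0,1)")
  }
  sexes <- sort(unique(table$sex))
  fits <- list()
  percentiles <- stats::setNames(rep(NA_real_, nrow(table)), table$id)
  for (s in sexes) {
    idx <- which(table$sex == s)
    if (length(idx) < min_stratum) {
      stop_invalid("sex stratum '%s' has %d participants (< min_stratum = %d)",
                   s, length(idx), min_stratum)
    }
    age <- table$age[idx]
    y <- log_cac(table$cac_b[idx])
    centers <- seq(min(age), max(age), by = age_step)
    half <- age_window / 2
    qmat <- matrix(NA_real_, length(g), length(centers))
    zero_frac <- numeric(length(centers))
    wage <- numeric(length(centers))  # mean member age: the regression
                                      # abscissa (edge windows are one-sided)
    for (w in seq_along(centers)) {
      inwin <- abs(age - centers[w]) <= half
      yy <- y[inwin]
      if (!length(yy)) { zero_frac[w] <- NA; next }
      qmat[, w] <- stats::quantile(yy, g, type = 5, names = FALSE)
      zero_frac[w] <- mean(yy == 0)
      wage[w] <- mean(age[inwin])
    }
    ok <- !is.na(zero_frac)
    coefs <- t(apply(qmat[, ok, drop = FALSE], 1, function(v) {
      if (sum(ok) == 1) c(v, 0)
      else stats::coef(stats::lm(v ~ wage[ok]))
    }))
    colnames(coefs) <- c("intercept", "slope")
    # midrank percentile within a sliding window centered on the participant
    # (zeros share the bottom mass through the midrank of the ties)
    ord <- order(age)
    age_s <- age[ord]; y_s <- y[ord]
    lo <- findInterval(age_s - half, age_s, left.open = TRUE) + 1
    hi <- findInterval(age_s + half, age_s)
    pr <- vapply(seq_along(ord), function(i) {
      yy <- y_s[lo[i]:hi[i]]
      (sum(yy < y_s[i]) + (sum(yy == y_s[i]) + 1) / 2 - 0.5) / length(yy)
    }, numeric(1))
    percentiles[idx[ord]] <- pr
    # zero-mass boundary: linear trend of the CAC = 0 fraction in age
    zf_coef <- if (sum(ok) == 1) c(zero_frac[ok], 0)
               else stats::coef(stats::lm(zero_frac[ok] ~ wage[ok]))
    fits[[s]] <- list(centers = centers, coefs = coefs, zero_frac = zero_frac,
                      zf_coef = unname(zf_coef),
                      age_range = c(min(centers) - half, max(centers) + half))
  }
  structure(list(sex_fits = fits, grid = g, percentiles = percentiles,
                 age_window = age_window, age_step = age_step),
            class = "percentile_model")
}

# evaluate the fitted log(CAC+1) surface at (sex, age, percentile)
eval_percentile_model <- function(model, sex, age, percentile) {
  fit <- model$sex_fits[[sex]]
  if (is.null(fit)) stop_invalid("no percentile model fitted for sex '%s'", sex)
  v <- cummax(fit$coefs[, "intercept"] + fit$coefs[, "slope"] * age)
  if (length(model$grid) == 1) return(v)
  stats::approx(model$grid, v, xout = percentile, rule = 2)$y
}

# inverse lookup: percentile of a baseline value at (sex, age)
assign_percentile <- function(model, sex, age, cac_b) {
  fit <- model$sex_fits[[sex]]
  v <- cummax(fit$coefs[, "intercept"] + fit$coefs[, "slope"] * age)
  y <- log_cac(cac_b)
  if (y <= v[1]) return(model$grid[1])
  if (y >= v[length(v)]) return(model$grid[length(v)])
  stats::approx(v, model$grid, xout = y, rule = 2, ties = "ordered")$y
}

#' Predict follow-up CAC along the baseline percentile
#'
#' Carries each participant forward along their own CAC percentile line: the
#' line through the participant's baseline value with the slope of their
#' percentile, evaluated at `age + dt_years` and back-transformed,
#' `predicted = exp(L) - 1` with
#' `L = log(CAC_b + 1) + slope(percentile) * dt_years`, floored at zero. A
#' participant on a fitted percentile line `L(age) = a + b*age` is therefore
#' predicted at `exp(a + b*(age + dt)) - 1`, and one whose percentile stays
#' within the zero mass stays at zero. Participants seen at fit time reuse
#' their stored midrank percentile; unseen participants get one by inverse
#' interpolation of the fitted surface at their baseline age.
#'
#' @param model a fitted [percentile_model][fit_percentile_model].
#' @param participant one-or-more phenotype rows (`id`, `age`, `sex`,
#'   `cac_b`, `dt_years`).
#' @return numeric vector of predicted follow-up CAC (Agatston units).
#' @export
predict_cac5y <- function(model, participant) {
  stopifnot(inherits(model, "percentile_model"))
  n <- nrow(participant)
  out <- numeric(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    row <- participant[i, ]
    pct <- unname(model$percentiles[as.character(row$id)])
    if (is.na(pct) || is.null(pct)) {
      pct <- assign_percentile(model, row$sex, row$age, row$cac_b)
    }
    fit <- model$sex_fits[[row$sex]]
    if (is.null(fit)) stop_invalid("no percentile model fitted for sex '%s'",
                                   row$sex)
    target_age <- row$age + row$dt_years
    rng <- fit$age_range
    if (!warned && (target_age < rng[1] || target_age > rng[2])) {
      warning(sprintf("follow-up age %.1f outside fitted range [%.1f, %.1f]; extrapolating",
                      target_age, rng[1], rng[2]))
      warned <- TRUE
    }
    # inside the zero mass at the follow-up age: predicted stays zero
    zf_target <- min(max(fit$zf_coef[1] + fit$zf_coef[2] * target_age, 0), 1)
    if (row$cac_b == 0 && pct <= zf_target) {
      out[i] <- 0
      next
    }
    slope <- if (length(model$grid) == 1) fit$coefs[, "slope"]
             else stats::approx(model$grid, fit$coefs[, "slope"],
                                xout = pct, rule = 2)$y
    out[i] <- max(expm1(log_cac(row$cac_b) + slope * row$dt_years), 0)
  }
  out
}

#' Classify CAC progression against the individual prediction
#'
#' The acceptance band has half-width `band_frac` times the anchor value
#' (the observed follow-up CAC by default, following the published wording;
#' `anchor = "predicted"` gives the +/-20%-of-predicted alternative),
#' centered at the predicted value. Observations above the band are
#' `rapid`, below it `slow`, inside it `expected`. Differences below 1e-9
#' Agatston units are treated as zero so exp/log round-trips cannot flip a
#' class.
#'
#' @param observed,predicted follow-up CAC values (Agatston units, >= 0).
#' @param band_frac half-width fraction in (0,1), default 0.2.
#' @param anchor `"observed"` (default) or `"predicted"`.
#' @return list with `class` (factor slow/expected/rapid), `band_low`,
#'   `band_high`.
#' @export
classify_progression <- function(observed, predicted, band_frac = 0.2,
                                 anchor = c("observed", "predicted")) {
  anchor <- match.arg(anchor)
  check_fraction(band_frac, "band_frac", open_left = TRUE, open_right = TRUE)
  if (any(observed < 0) || any(predicted < 0)) {
    stop_invalid("CAC values must be >= 0")
  }
  a <- if (anchor == "observed") observed else predicted
  tol <- 1e-9
  half <- band_frac * a
  cls <- ifelse(observed - predicted > half + tol, "rapid",
                ifelse(predicted - observed > half + tol, "slow", "expected"))
  list(class = factor(cls, levels = c("slow", "expected", "rapid")),
       band_low = pmax(predicted - half, 0), band_high = predicted + half)
}

#' Flag extreme CAC changes for re-reading
#'
#' Review flags mirroring the scan re-evaluation triggers: a jump from
#' `CAC_b <= 10` to `CAC_5y > 50` (`low_to_high`), a fall from `CAC_b > 20`
#' to `CAC_5y <= 10` (`high_to_low`), or otherwise an annualized geometric
#' change of `(CAC_5y+1)^(1/dt) / (CAC_b+1)^(1/dt) - 1` above 30%
#' (`annual_rise`) or below -7% (`annual_fall`). Flags mark records for
#' review; they never alter values or classes.
#'
#' @param cac_b,cac_5y baseline and follow-up Agatston scores.
#' @param dt_years follow-up interval (> 0).
#' @return data.frame of four logical flag columns.
#' @export
flag_extreme_change <- function(cac_b, cac_5y, dt_years) {
  if (any(dt_years <= 0)) stop_invalid("dt_years must be > 0")
  low_to_high <- cac_b <= 10 & cac_5y > 50
  high_to_low <- cac_b > 20 & cac_5y <= 10
  r <- ((cac_5y + 1) / (cac_b + 1))^(1 / dt_years) - 1
  quiet <- !low_to_high & !high_to_low
  data.frame(low_to_high = low_to_high, high_to_low = high_to_low,
             annual_rise = quiet & r > 0.30,
             annual_fall = quiet & r < -0.07)
}

#' Full CAC progression classification for a cohort
#'
#' Fits the percentile model on the cohort, predicts each participant's
#' follow-up CAC along their baseline percentile, classifies progression and
#' attaches the extreme-change review flags.
#'
#' @param pheno phenotype table (`id`, `age`, `sex`, `cac_b`, `cac_5y`,
#'   `dt_years`).
#' @param band_frac,band_anchor see [classify_progression()].
#' @param ... passed to [fit_percentile_model()].
#' @return data.frame `id, percentile, predicted_cac5y, band_low, band_high,
#'   class` plus the four flag columns; the fitted model is attached as
#'   attribute `"model"`.
#' @export
cac_progression <- function(pheno, band_frac = 0.2,
                            band_anchor = c("observed", "predicted"), ...) {
  band_anchor <- match.arg(band_anchor)
  model <- fit_percentile_model(pheno, ...)
  pred <- predict_cac5y(model, pheno)
  cl <- classify_progression(pheno$cac_5y, pred, band_frac, band_anchor)
  flags <- flag_extreme_change(pheno$cac_b, pheno$cac_5y, pheno$dt_years)
  out <- data.frame(id = pheno$id,
                    percentile = unname(model$percentiles[as.character(pheno$id)]),
                    predicted_cac5y = pred,
                    band_low = cl$band_low, band_high = cl$band_high,
                    class = cl$class, stringsAsFactors = FALSE)
  out <- cbind(out, flags)
  attr(out, "model") <- model
  out
}
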