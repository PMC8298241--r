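#' Fit a log-linear relative-risk model (modified Poisson)
#'
#' Maximizes the Poisson working log-likelihood with log link on a binary
#' outcome by iteratively reweighted least squares, and reports the robust
#' sandwich covariance \eqn{A^{-1} B A^{-1}} (A the expected information
#' \eqn{X'WX} with \eqn{W = \mu}, B the outer-product sum of scores
#' \eqn{X' diag((y-\mu)^2) X}). Exponentiated coefficients are relative
#' risks; Wald confidence intervals and p-values use the normal reference.
#' `family = "log-binomial"` fits the true binomial likelihood with the log
#' link instead, with step-halving to keep fitted risks below one.
#'
#' @param design either a list with elements `y` (binary outcome) and `X`
#'   (numeric model matrix including the intercept column), e.g. from
#'   [build_design()], or the `X` matrix itself with `y` supplied separately.
#' @param y binary outcome vector when `design` is a matrix.
#' @param family `"poisson"` (default, the modified-Poisson estimator) or
#'   `"log-binomial"`.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the relative deviance change;
#'   the maximum absolute score must also fall below `1e-8`.
#' @return object of class `rr_glm`.
#' @seealso [rr_glm()] for the formula interface.
#' @export
fit_rr_model <- function(design, y = NULL,
                         family = c("poisson", "log-binomial"),
                         max_iter = 100, tol = 1e-10) {
  family <- match.arg(family)
  if (is.list(design) && !is.data.frame(design) && !is.matrix(design)) {
    X <- design$X; y <- design$y
  } else {
    X <- as.matrix(design)
  }
  stopifnot(is.numeric(y), length(y) == nrow(X))
  if (!all(y %in% c(0, 1))) stop_invalid("outcome must be binary 0/1")
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop_invalid("need at least one event and one non-event")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_invalid("design is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", "))
  }

  n <- nrow(X); p <- ncol(X)
  beta <- rep(0, p)
  has_int <- which(apply(X, 2, function(c) all(c == 1)))[1]
  if (!is.na(has_int)) beta[has_int] <- log(mean(y))
  eta <- as.vector(X %*% beta)
  if (family == "log-binomial") eta <- pmin(eta, -1e-8)
  mu <- exp(eta)

  deviance_of <- function(mu) {
    if (family == "poisson") {
      2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    } else {
      -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
    }
  }
  dev <- deviance_of(mu)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    if (family == "poisson") {
      w <- mu
      z <- eta + (y - mu) / mu
    } else {
      w <- mu / (1 - mu)
      z <- eta + (y - mu) / mu
    }
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    step <- beta_new - beta
    # step-halving on divergence (and on risks >= 1 for log-binomial)
    for (h in 0:25) {
      cand <- beta + step / 2^h
      eta_c <- as.vector(X %*% cand)
      if (family == "log-binomial" && any(eta_c >= 0)) next
      mu_c <- exp(eta_c)
      dev_c <- deviance_of(mu_c)
      if (is.finite(dev_c) && (dev_c <= dev + 1e-12 || h == 25)) break
    }
    beta <- cand; eta <- eta_c; mu <- mu_c
    dev_old <- dev; dev <- dev_c
    score <- as.vector(crossprod(X, if (family == "poisson") y - mu
                                    else (y - mu) / (1 - mu)))
    if (abs(dev - dev_old) / (0.1 + abs(dev)) < tol &&
        max(abs(score)) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop_invalid("IRLS did not converge in %d iterations (deviance %.6g, max score %.3g)",
                 max_iter, dev, max(abs(score)))
  }

  w_info <- if (family == "poisson") mu else mu / (1 - mu)
  s_i <- if (family == "poisson") y - mu else (y - mu) / (1 - mu)
  A <- crossprod(X * sqrt(w_info))
  B <- crossprod(X * s_i)
  Ainv <- chol2inv(chol(A))
  V <- Ainv %*% B %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  zq <- stats::qnorm(0.975)
  names(beta) <- colnames(X)

  structure(list(coefficients = beta, vcov = V, se = se,
                 rr = exp(beta),
                 ci_low = exp(beta - zq * se), ci_high = exp(beta + zq * se),
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 family = family, converged = converged, iter = iter,
                 n = n, events = sum(y), deviance = dev,
                 fitted.values = mu, linear.predictors = eta,
                 y = y, X = X),
            class = "rr_glm")
}

#' Relative-risk regression with a formula interface
#'
#' Formula front-end to [fit_rr_model()]: log-linear (modified Poisson)
#' regression of a binary outcome returning relative risks with robust
#' sandwich standard errors — the standard estimator when odds ratios from
#' logistic regression would overstate risk ratios for common outcomes.
#'
#' @param formula model formula; the response must be binary 0/1.
#' @param data data.frame holding the variables.
#' @param ... passed to [fit_rr_model()] (`family`, `max_iter`, `tol`).
#' @return object of class `rr_glm`.
#' @examples
#' d <- data.frame(y = rbinom(500, 1, 0.2), x = rnorm(500))
#' fit <- rr_glm(y ~ x, d)
#' summary(fit)
#' @export
rr_glm <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- fit_rr_model(list(y = as.numeric(y), X = X), ...)
  fit$terms <- attr(mf, "terms")
  fit$call <- match.call()
  fit
}

#' @export
print.rr_glm <- function(x, digits = 3, ...) {
  cat(sprintf("Log-linear relative-risk model (%s working likelihood)\n",
              x$family))
  cat(sprintf("n = %d, events = %d, IRLS iterations = %d\n",
              x$n, x$events, x$iter))
  print(round(cbind(RR = x$rr, `2.5%` = x$ci_low, `97.5%` = x$ci_high,
                    p = x$p_value), digits))
  invisible(x)
}

#' @export
summary.rr_glm <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients,
                    robust_se = object$se,
                    rr = object$rr, ci_low = object$ci_low,
                    ci_high = object$ci_high, p = object$p_value)
  out <- list(table = tab, n = object$n, events = object$events,
              family = object$family, iter = object$iter)
  class(out) <- "summary.rr_glm"
  out
}

#' @export
print.summary.rr_glm <- function(x, digits = 4, ...) {
  cat(sprintf("Relative-risk regression (%s), n = %d, events = %d\n\n",
              x$family, x$n, x$events))
  print(round(x$table, digits))
  invisible(x)
}

#' @export
coef.rr_glm <- function(object, ...) object$coefficients

#' @export
vcov.rr_glm <- function(object, ...) object$vcov

#' @export
nobs.rr_glm <- function(object, ...) object$n

#' @export
confint.rr_glm <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * object$se,
              object$coefficients + zq * object$se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.rr_glm <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    if (is.null(object$terms)) {
      stop_invalid("predict() on new data needs a fit from rr_glm(formula, ...)")
    }
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    eta <- as.vector(X %*% object$coefficients)
  }
  if (type == "link") eta else exp(eta)
}

#' @export
residuals.rr_glm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted.values
  if (type == "pearson") r <- r / sqrt(object$fitted.values)
  r
}

#' @export
simulate.rr_glm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- pmin(object$fitted.values, 1)
  out <- as.data.frame(replicate(nsim, stats::rbinom(object$n, 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
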