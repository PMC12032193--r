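P_FLOOR <- 1e-300

#' Fit a Poisson log-link regression by IRLS
#'
#' The structured equations of the piecewise SEM are plain Poisson GLMs.
#' This fitter runs iteratively reweighted least squares with a
#' deviance-based convergence criterion, and returns Wald inference from the
#' inverse Fisher information together with the fitted and intercept-only
#' log-likelihoods and Nagelkerke pseudo R-squared.
#'
#' @param y Non-negative integer response vector.
#' @param X Predictor matrix (no intercept column; an intercept is always
#'   included). `NULL` or a zero-column matrix fits the intercept-only model.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Relative deviance-change convergence tolerance (default 1e-8).
#' @param response,predictors Optional names recorded in the result.
#' @return An object of class `equation_fit`: coefficients and intercept on
#'   the link scale, `std_errors`, two-sided Wald `wald_p`, `log_lik`,
#'   `null_log_lik`, `pseudo_r2`, `fitted_eta`, `n`, `residual_df`.
#' @export
fit_poisson <- function(y, X = NULL, max_iter = 100, tol = 1e-8,
                        response = "y", predictors = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(is.na(y)) || any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stop("response must be non-negative integer counts", call. = FALSE)
  }
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y lengths differ", call. = FALSE)
  if (is.null(predictors)) {
    predictors <- colnames(X)
    if (is.null(predictors) && ncol(X) > 0) {
      predictors <- paste0("x", seq_len(ncol(X)))
    }
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  if (n <= p - 1) stop("need more observations than predictors",
                       call. = FALSE)
  qrX <- qr(Xd)
  if (qrX$rank < p) {
    stop("design matrix is rank deficient (perfect collinearity)",
         call. = FALSE)
  }

  beta <- c(log(mean(y) + 1e-8), rep(0, p - 1))
  dev <- poisson_deviance(y, exp(drop(Xd %*% beta)))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    w <- mu
    fit <- stats::lm.wfit(Xd, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) {
      stop("design matrix is rank deficient (perfect collinearity)",
           call. = FALSE)
    }
    dev_new <- poisson_deviance(y, exp(pmin(drop(Xd %*% beta_new), 30)))
    beta <- beta_new
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  eta <- drop(Xd %*% beta)
  mu <- exp(eta)
  if (!converged) {
    cond <- structure(
      class = c("camtrapSEM_convergence_error", "error", "condition"),
      list(message = paste0("IRLS did not converge in ", max_iter,
                            " iterations"),
           call = sys.call(-1), last_beta = beta))
    stop(cond)
  }

  info <- crossprod(Xd, Xd * mu)
  cov_beta <- tryCatch(solve(info), error = function(e) {
    stop("Fisher information is singular", call. = FALSE)
  })
  se <- sqrt(diag(cov_beta))
  zval <- beta / se
  pval <- pmax(2 * stats::pnorm(-abs(zval)), P_FLOOR)

  log_lik <- sum(stats::dpois(y, mu, log = TRUE))
  null_log_lik <- sum(stats::dpois(y, mean(y), log = TRUE))

  out <- list(
    response = response,
    predictors = if (p > 1) predictors else character(0),
    intercept = unname(beta[1]),
    coefficients = stats::setNames(beta[-1], predictors),
    std_errors = stats::setNames(se[-1], predictors),
    intercept_se = unname(se[1]),
    wald_p = stats::setNames(pval[-1], predictors),
    intercept_p = unname(pval[1]),
    std_estimates = stats::setNames(rep(NA_real_, p - 1), predictors),
    std_method = NA_character_,
    log_lik = log_lik,
    null_log_lik = null_log_lik,
    n = n,
    residual_df = as.integer(n - p),
    fitted_eta = eta,
    deviance = dev,
    iterations = iter,
    pseudo_r2 = nagelkerke_r2(log_lik, null_log_lik, n)
  )
  class(out) <- "equation_fit"
  out
}

poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Nagelkerke pseudo R-squared
#'
#' `R2 = (1 - exp(2 (ll0 - ll1) / n)) / (1 - exp(2 ll0 / n))`, the
#' Cox-and-Snell likelihood ratio R-squared rescaled to a maximum of one;
#' reported per structured equation as the proportion of explained variation
#' relative to the intercept-only model. The value is clamped to [0, 1].
#'
#' @param log_lik Fitted-model log-likelihood.
#' @param null_log_lik Intercept-only log-likelihood.
#' @param n Number of observations.
#' @return A value in [0, 1].
#' @export
nagelkerke_r2 <- function(log_lik, null_log_lik, n) {
  stopifnot(n >= 1)
  if (log_lik < null_log_lik - 1e-8) {
    stop("fitted log-likelihood below the null log-likelihood", call. = FALSE)
  }
  denom <- 1 - exp(2 * null_log_lik / n)
  if (!is.finite(denom) || denom <= 0) {
    stop("degenerate null likelihood (denominator <= 0)", call. = FALSE)
  }
  r2 <- (1 - exp(2 * (null_log_lik - log_lik) / n)) / denom
  min(max(r2, 0), 1)
}

#' Standardized coefficients for a Poisson equation
#'
#' Path coefficients are rescaled to effect sizes comparable across paths:
#' `std_b = b * sd(x) / sd_latent(y)`. The default `latent_linear` method
#' takes `sd_latent(y)` as the standard deviation of the fitted linear
#' predictor (no canonical latent error variance exists for the log link);
#' `observation_empirical` instead uses the spread of the observed counts
#' mapped through the link (zeros floored at 0.5 before the log). The method
#' used is recorded in the fit.
#'
#' @param fit An [fit_poisson()] result.
#' @param sd_predictors Named (or positionally matched) vector of predictor
#'   standard deviations on the scale entering the linear predictor.
#' @param method `"latent_linear"` (default) or `"observation_empirical"`.
#' @param y Observed counts; required for `observation_empirical`.
#' @return The fit with `std_estimates` and `std_method` filled in.
#' @export
standardize_coefficients <- function(fit, sd_predictors,
                                     method = c("latent_linear",
                                                "observation_empirical"),
                                     y = NULL) {
  method <- match.arg(method)
  if (length(fit$predictors) == 0) {
    fit$std_method <- method
    return(fit)
  }
  if (!is.null(names(sd_predictors))) {
    sd_predictors <- sd_predictors[fit$predictors]
  }
  if (length(sd_predictors) != length(fit$predictors) ||
      any(!is.finite(sd_predictors)) || any(sd_predictors <= 0)) {
    stop("sd_predictors must be positive, one per predictor", call. = FALSE)
  }
  sd_latent <- switch(method,
    latent_linear = stats::sd(fit$fitted_eta),
    observation_empirical = {
      if (is.null(y)) stop("observed counts y required for method ",
                           "'observation_empirical'", call. = FALSE)
      stats::sd(log(pmax(y, 0.5)))
    }
  )
  if (!is.finite(sd_latent) || sd_latent <= 0) sd_latent <- 1
  fit$std_estimates <- stats::setNames(
    unname(fit$coefficients) * unname(sd_predictors) / sd_latent,
    fit$predictors)
  fit$std_method <- method
  fit
}

#' Tidy coefficient table for one or more equation fits
#'
#' @param fits An `equation_fit` or list of them.
#' @return Data frame with columns `response`, `predictor`, `estimate`,
#'   `se`, `df`, `p`, `std_estimate` (one row per predictor).
#' @export
coef_table <- function(fits) {
  if (inherits(fits, "equation_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    if (length(f$predictors) == 0) return(NULL)
    data.frame(response = f$response, predictor = f$predictors,
               estimate = unname(f$coefficients),
               se = unname(f$std_errors),
               df = f$residual_df,
               p = unname(f$wald_p),
               std_estimate = unname(f$std_estimates),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    response = character(0), predictor = character(0), estimate = numeric(0),
    se = numeric(0), df = integer(0), p = numeric(0),
    std_estimate = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.equation_fit <- function(x, ...) {
  cat("Poisson equation:", x$response, "~",
      if (length(x$predictors) > 0) paste(x$predictors, collapse = " + ")
      else "1", "\n")
  cat(sprintf("  n = %d, residual df = %d, logLik = %.3f, pseudo-R2 = %.3f\n",
              x$n, x$residual_df, x$log_lik, x$pseudo_r2))
  if (length(x$predictors) > 0) {
    print(coef_table(x)[-1], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Build and fit one structured equation from a model specification
#'
#' Builds the design for `response ~ parents(response)` (plus any
#' `extra_predictors`): covariate parents enter as their scaled columns,
#' species parents as raw counts (scaling is applied to landscape variables
#' only). Standardized estimates use the predictors' sample sds and the
#' default latent-linear response sd.
#'
#' @param spec A [sem_spec()].
#' @param table A scaled [station_table()].
#' @param response Endogenous vertex to fit.
#' @param extra_predictors Additional predictor vertices (used by the tests
#'   of directed separation).
#' @param std_method Standardization method, see
#'   [standardize_coefficients()].
#' @return An `equation_fit`.
#' @export
fit_equation <- function(spec, table, response, extra_predictors = NULL,
                         std_method = "latent_linear") {
  if (!response %in% spec$endogenous) {
    stop("response '", response, "' is not endogenous", call. = FALSE)
  }
  preds <- unique(c(spec_parents(spec, response), extra_predictors))
  preds <- setdiff(preds, response)
  X <- if (length(preds) > 0) {
    as.matrix(as.data.frame(table)[preds])
  } else NULL
  fit <- fit_poisson(table[[response]], X, response = response,
                     predictors = preds)
  if (length(preds) > 0) {
    sds <- vapply(preds, function(v) stats::sd(table[[v]]), numeric(1))
    fit <- standardize_coefficients(fit, sds, method = std_method,
                                    y = table[[response]])
  }
  fit
}
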