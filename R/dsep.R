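#' Fisher's C from independence-claim p-values
#'
#' `C = -2 * sum(log p_i)` over the basis-set claim p-values, compared to a
#' chi-square distribution with `2 k` degrees of freedom. P-values are
#' floored at 1e-300 before the logarithm so the statistic stays finite.
#'
#' @param p_values Claim p-values in (0, 1].
#' @return List with elements `C` and `df`. An empty input yields `C = 0`,
#'   `df = 0` (saturated model) with a message.
#' @export
fishers_c <- function(p_values) {
  if (length(p_values) == 0) {
    message("empty basis set: model is saturated (C = 0, df = 0)")
    return(list(C = 0, df = 0L))
  }
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  list(C = -2 * sum(log(pmax(p_values, P_FLOOR))),
       df = 2L * length(p_values))
}

#' Upper-tail chi-square probability for a goodness-of-fit statistic
#'
#' Both Fisher's C and the likelihood-ratio chi-square are referred to a
#' chi-square distribution; a non-significant p (> 0.05) indicates the
#' causal structure is consistent with the data.
#'
#' @param statistic Non-negative test statistic.
#' @param df Degrees of freedom (>= 1; `df = 0` with `statistic = 0` returns
#'   1 for the saturated case).
#' @return Upper-tail probability.
#' @export
gof_p <- function(statistic, df) {
  stopifnot(statistic >= 0)
  if (df == 0) return(1)
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Test one independence claim
#'
#' Regresses the claim's response (Poisson log link) on its conditioning set
#' plus the other member of the pair; the claim p-value is the Wald p of the
#' other member's coefficient. When `response = "both"` (two endogenous,
#' neither an ancestor of the other) both directions are fitted and the
#' smaller p-value kept.
#'
#' @param claim One row of a [basis_set()] data frame (or a list with
#'   elements `a`, `b`, `response`, `conditioning`).
#' @param table A scaled [station_table()].
#' @param spec A [sem_spec()].
#' @return The claim as a list with `p_value` (and `fitted_response`, the
#'   direction that produced it) appended.
#' @export
test_claim <- function(claim, table, spec) {
  if (is.data.frame(claim)) {
    claim <- list(a = claim$a[1], b = claim$b[1],
                  response = claim$response[1],
                  conditioning = claim$conditioning[[1]])
  }
  cond <- claim$conditioning
  directions <- if (identical(claim$response, "both")) {
    c(claim$a, claim$b)
  } else claim$response
  p_best <- Inf
  resp_best <- NA_character_
  for (resp in directions) {
    other <- setdiff(c(claim$a, claim$b), resp)
    fit <- tryCatch(
      fit_equation(spec, table, resp,
                   extra_predictors = unique(c(cond, other))),
      error = function(e) {
        stop("claim (", claim$a, ", ", claim$b, " | ",
             paste(cond, collapse = ", "), "): ", conditionMessage(e),
             call. = FALSE)
      })
    p <- unname(fit$wald_p[other])
    if (p < p_best) {
      p_best <- p
      resp_best <- resp
    }
  }
  claim$p_value <- p_best
  claim$fitted_response <- resp_best
  claim
}

test_basis_set <- function(basis, table, spec) {
  if (nrow(basis) == 0) {
    basis$p_value <- numeric(0)
    basis$fitted_response <- character(0)
    return(basis)
  }
  res <- lapply(seq_len(nrow(basis)), function(i) {
    test_claim(basis[i, , drop = FALSE], table, spec)
  })
  basis$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  basis$fitted_response <- vapply(res, `[[`, character(1), "fitted_response")
  basis
}

#' Likelihood-ratio chi-square against topologically saturated equations
#'
#' Each structured equation is compared against its saturated counterpart,
#' which regresses the same response on every topologically permissible
#' predecessor: all exogenous vertices plus every endogenous vertex earlier
#' in the deterministic causal order (see [topological_order()]).
#' `chi2 = -2 * (sum logLik(model) - sum logLik(saturated))`; `df` is the
#' difference in total parameter count.
#'
#' @param spec A [sem_spec()].
#' @param table A scaled [station_table()].
#' @param fits Optional pre-computed list of model equation fits (one per
#'   endogenous vertex, named).
#' @return List with `chi2`, `df`, `p`.
#' @export
chi2_gof <- function(spec, table, fits = NULL) {
  ord <- topological_order(spec)
  endo_ord <- ord[ord %in% spec$endogenous]
  if (is.null(fits)) {
    fits <- lapply(stats::setNames(endo_ord, endo_ord), function(v) {
      fit_equation(spec, table, v)
    })
  }
  ll_model <- 0
  ll_sat <- 0
  par_model <- 0L
  par_sat <- 0L
  for (i in seq_along(endo_ord)) {
    v <- endo_ord[i]
    fit <- fits[[v]]
    ll_model <- ll_model + fit$log_lik
    par_model <- par_model + length(fit$predictors) + 1L
    sat_preds <- c(spec$exogenous, endo_ord[seq_len(i - 1)])
    sat_preds <- sort(setdiff(unique(sat_preds), v))
    if (setequal(sat_preds, fit$predictors)) {
      sat_fit <- fit
    } else {
      sat_fit <- tryCatch(
        fit_equation(spec, table, v, extra_predictors = sat_preds),
        error = function(e) {
          stop("saturated fit failed for equation '", v, "': ",
               conditionMessage(e), call. = FALSE)
        })
    }
    ll_sat <- ll_sat + sat_fit$log_lik
    par_sat <- par_sat + length(sat_fit$predictors) + 1L
  }
  chi2 <- max(0, -2 * (ll_model - ll_sat))
  df <- par_sat - par_model
  list(chi2 = chi2, df = as.integer(df), p = gof_p(chi2, df))
}

#' Fit a piecewise SEM and assess global goodness of fit
#'
#' Fits every structured equation (one Poisson regression per endogenous
#' vertex on its parents), tests all independence claims in the basis set,
#' and computes Fisher's C with its chi-square p-value together with the
#' likelihood-ratio chi-square against the topologically saturated model.
#'
#' @param spec A [sem_spec()].
#' @param table A [station_table()]; scaled automatically (with a message)
#'   if it is not already.
#' @param std_method Standardization method for coefficients.
#' @return An object of class `sem_gof` with fields `fisher_c`, `c_df`,
#'   `c_p`, `chi2`, `chi2_df`, `chi2_p`, `claims` (tested basis set),
#'   `fits` (named list of `equation_fit`), `spec`, `n`.
#' @export
sem_fit <- function(spec, table, std_method = "latent_linear") {
  assert_valid_spec(spec)
  if (nrow(table) == 0) stop("empty station table", call. = FALSE)
  if (!is_scaled(table)) {
    message("scaling covariates before fitting")
    table <- scale_covariates(table)
  }
  ord <- topological_order(spec, check = FALSE)
  endo_ord <- ord[ord %in% spec$endogenous]
  fits <- lapply(stats::setNames(endo_ord, endo_ord), function(v) {
    fit_equation(spec, table, v, std_method = std_method)
  })
  claims <- test_basis_set(basis_set(spec, check = FALSE), table, spec)
  fc <- if (nrow(claims) == 0) {
    list(C = 0, df = 0L)
  } else {
    fishers_c(claims$p_value)
  }
  chi2 <- chi2_gof(spec, table, fits = fits)
  out <- list(
    fisher_c = fc$C, c_df = fc$df, c_p = gof_p(fc$C, fc$df),
    chi2 = chi2$chi2, chi2_df = chi2$df, chi2_p = chi2$p,
    claims = claims, fits = fits, spec = spec, n = nrow(table),
    std_method = std_method
  )
  class(out) <- "sem_gof"
  out
}

#' @export
print.sem_gof <- function(x, ...) {
  cat("Piecewise SEM fit (n =", x$n, ")\n")
  cat(sprintf("  Fisher's C = %.3f, df = %d, p = %.3f\n",
              x$fisher_c, x$c_df, x$c_p))
  cat(sprintf("  chi-square = %.3f, df = %d, p = %.3f\n",
              x$chi2, x$chi2_df, x$chi2_p))
  cat("  claims tested:", nrow(x$claims), "\n")
  invisible(x)
}

#' Compare fitted models by goodness of fit
#'
#' @param reports Named list of [sem_fit()] results (at least two).
#' @param alpha Poor-fit threshold on the Fisher's C p-value (default 0.05).
#' @return Data frame (one row per model) with `C`, `C_p`, `C_df`, `chi2`,
#'   `chi2_p`, `chi2_df`, `poor_fit`, sorted by `C_p` descending with stable
#'   ties; best-fitting model first.
#' @export
compare_models <- function(reports, alpha = 0.05) {
  if (length(reports) < 2) stop("need at least two models to compare",
                                call. = FALSE)
  if (is.null(names(reports)) || any(names(reports) == "")) {
    names(reports) <- paste0("model", seq_along(reports))
  }
  out <- data.frame(
    model = names(reports),
    C = vapply(reports, `[[`, numeric(1), "fisher_c"),
    C_p = vapply(reports, `[[`, numeric(1), "c_p"),
    C_df = vapply(reports, function(r) as.integer(r$c_df), integer(1)),
    chi2 = vapply(reports, `[[`, numeric(1), "chi2"),
    chi2_p = vapply(reports, `[[`, numeric(1), "chi2_p"),
    chi2_df = vapply(reports, function(r) as.integer(r$chi2_df), integer(1)),
    stringsAsFactors = FALSE
  )
  out$poor_fit <- out$C_p < alpha
  out <- out[order(-out$C_p, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a goodness-of-fit report
#'
#' `write_gof_csv` writes the model-comparison shape (one row per model);
#' `write_gof_json` writes the full per-claim and per-equation detail.
#'
#' @param reports Named list of `sem_gof` objects (CSV) or one object
#'   (JSON).
#' @param path Output path.
#' @export
write_gof_csv <- function(reports, path) {
  utils::write.csv(compare_models(reports), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gof_csv
#' @param report A single `sem_gof`.
#' @export
write_gof_json <- function(report, path) {
  claims <- report$claims
  obj <- list(
    fisher_c = report$fisher_c, c_df = report$c_df, c_p = report$c_p,
    chi2 = report$chi2, chi2_df = report$chi2_df, chi2_p = report$chi2_p,
    n = report$n,
    claims = lapply(seq_len(nrow(claims)), function(i) {
      list(a = claims$a[i], b = claims$b[i],
           conditioning = claims$conditioning[[i]],
           response = claims$response[i],
           fitted_response = claims$fitted_response[i],
           p_value = claims$p_value[i])
    }),
    equations = lapply(report$fits, function(f) {
      list(response = f$response, predictors = f$predictors,
           intercept = f$intercept,
           coefficients = as.list(f$coefficients),
           std_errors = as.list(f$std_errors),
           wald_p = as.list(f$wald_p),
           std_estimates = as.list(f$std_estimates),
           log_lik = f$log_lik, pseudo_r2 = f$pseudo_r2,
           n = f$n, residual_df = f$residual_df)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
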