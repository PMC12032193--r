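test_that("Fisher's C follows its closed form and guards against underflow", {
  expect_equal(fishers_c(c(1, 1)), list(C = 0, df = 4L))
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$C, -4 * log(0.5), tolerance = 1e-12)
  expect_equal(fc$df, 4L)
  # extreme p-values are floored, keeping C finite
  fc_small <- fishers_c(1e-310)
  expect_true(is.finite(fc_small$C))
  expect_equal(fc_small$C, -2 * log(1e-300))
  expect_message(fc0 <- fishers_c(numeric(0)), "saturated")
  expect_equal(fc0, list(C = 0, df = 0L))
  expect_error(fishers_c(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fishers_c(1.2), "\\(0, 1\\]")

  # C is monotone decreasing in every claim p-value
  base <- fishers_c(c(0.3, 0.6, 0.9))$C
  expect_gt(fishers_c(c(0.2, 0.6, 0.9))$C, base)
  expect_gt(fishers_c(c(0.3, 0.5, 0.9))$C, base)
})

test_that("upper-tail chi-square probabilities match the published table", {
  expect_equal(gof_p(0, 5), 1)
  expect_equal(round(gof_p(27.973, 26), 2), 0.36)
  expect_equal(round(gof_p(64.787, 28), 2), 0.00)
  expect_lt(gof_p(64.787, 28), 0.001)
})

test_that("claim tests regress the response on conditioning set plus other vertex", {
  tr <- calib_truth()
  tab <- scale_covariates(simulate_stations(500, tr, seed = 5,
                                            covariates = calib_covs()))
  b <- basis_set(tr$spec)
  # claim (a, c): a is an ancestor of c, so c is the response
  row <- pick_claim(b, "a", "c")
  expect_equal(row$response, "c")
  claim <- test_claim(row, tab, tr$spec)
  expect_true(claim$p_value >= 0 && claim$p_value <= 1)
  expect_equal(claim$fitted_response, "c")

  # a claim whose "other" vertex copies a conditioning vertex is rank deficient
  tab_dup <- tab
  tab_dup$x1 <- tab_dup$x3  # x3 conditions the (x1, c) claim
  row2 <- pick_claim(b, "x1", "c")
  expect_error(test_claim(row2, tab_dup, tr$spec), "rank deficient")
})

test_that("claim p-values reject at the nominal rate without the path and detect a real one", {
  # type I at the claim level: data generated without x1 -> c
  tr <- calib_truth()
  b <- basis_set(tr$spec)
  row <- pick_claim(b, "x1", "c")
  set.seed(501)
  seeds <- sample.int(1e6, 400)
  p_null <- vapply(seeds, function(s) {
    tab <- scale_covariates(simulate_stations(300, tr, seed = s,
                                              covariates = calib_covs()))
    test_claim(row, tab, tr$spec)$p_value
  }, numeric(1))
  rate <- mean(p_null < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)

  # power: the same claim when the path truly exists (effect 0.5)
  tr_extra <- calib_truth_extra(0.5)
  set.seed(502)
  seeds <- sample.int(1e6, 100)
  p_alt <- vapply(seeds, function(s) {
    tab <- scale_covariates(simulate_stations(300, tr_extra, seed = s,
                                              covariates = calib_covs()))
    test_claim(row, tab, tr$spec)$p_value
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.9)
})

test_that("the chi-square compares against topologically saturated equations", {
  sat <- sem_spec(endogenous = c("a", "b"), exogenous = "x",
                  paths = path_df(list("x", "a", "none"),
                                  list("a", "b", "none"),
                                  list("x", "b", "none")))
  tr <- list(spec = sat,
             coefficients = data.frame(cause = c("x", "a", "x"),
                                       effect = c("a", "b", "b"),
                                       coef = c(0.3, 0.1, 0.2),
                                       stringsAsFactors = FALSE),
             intercepts = c(a = log(3), b = log(2)))
  tab <- scale_covariates(simulate_stations(200, tr, seed = 9,
                                            covariates = unit_covariates("x")))
  res <- chi2_gof(sat, tab)
  expect_equal(res$chi2, 0)
  expect_equal(res$df, 0L)
  expect_equal(res$p, 1)

  # removing one path frees exactly one parameter
  res1 <- chi2_gof(remove_path(sat, "x", "b"), tab)
  expect_equal(res1$df, 1L)
  expect_gte(res1$chi2, 0)
})

test_that("sem_fit assembles equations, claims and goodness of fit coherently", {
  tr <- calib_truth()
  tab <- scale_covariates(simulate_stations(400, tr, seed = 13,
                                            covariates = calib_covs()))
  g <- sem_fit(tr$spec, tab)
  expect_s3_class(g, "sem_gof")
  expect_equal(g$c_df, 2L * nrow(g$claims))
  expect_equal(g$fisher_c, -2 * sum(log(g$claims$p_value)), tolerance = 1e-12)
  expect_equal(g$c_p, gof_p(g$fisher_c, g$c_df))
  expect_equal(sort(names(g$fits)), sort(tr$spec$endogenous))
  for (f in g$fits) {
    expect_true(all(f$wald_p >= 0 & f$wald_p <= 1))
    expect_true(f$pseudo_r2 >= 0 && f$pseudo_r2 <= 1)
    expect_equal(f$residual_df, f$n - length(f$predictors) - 1L)
  }
  # JSON serialization carries the full per-claim detail
  path <- withr::local_tempfile(fileext = ".json")
  write_gof_json(g, path)
  back <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  expect_equal(back$fisher_c, g$fisher_c, tolerance = 1e-12)
  expect_equal(length(back$claims), nrow(g$claims))
})

test_that("model comparison ranks by Fisher's C p with stable ties", {
  mk <- function(c_p, chi2_p) {
    structure(list(fisher_c = 1, c_df = 2L, c_p = c_p, chi2 = 1,
                   chi2_df = 1L, chi2_p = chi2_p, claims = NULL, fits = NULL),
              class = "sem_gof")
  }
  cmp <- compare_models(list(topdown = mk(0.00, 0.00),
                             combined = mk(0.36, 1)))
  expect_equal(cmp$model, c("combined", "topdown"))
  expect_equal(cmp$poor_fit, c(FALSE, TRUE))

  # identical reports keep their original order
  cmp2 <- compare_models(list(first = mk(0.5, 0.5), second = mk(0.5, 0.5)))
  expect_equal(cmp2$model, c("first", "second"))

  expect_error(compare_models(list(only = mk(0.5, 0.5))), "at least two")
})
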