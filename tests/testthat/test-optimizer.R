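test_that("a non-significant sign-mismatched hypothesized path is pruned", {
  # truth has no x2 -> a effect, but the model hypothesizes it as positive;
  # under this seed the fitted sign is negative and non-significant
  spec <- sem_spec(
    endogenous = c("a", "c"),
    exogenous = c("x1", "x2"),
    paths = path_df(list("x1", "a", "positive"),
                    list("x2", "a", "positive"),
                    list("x2", "c", "positive"),
                    list("a", "c", "positive")))
  truth <- list(spec = spec,
                coefficients = data.frame(
                  cause = c("x1", "x2", "x2", "a"),
                  effect = c("a", "a", "c", "c"),
                  coef = c(0.4, 0, 0.4, 0.1), stringsAsFactors = FALSE),
                intercepts = c(a = log(3), c = log(2)))
  tab <- scale_covariates(simulate_stations(400, truth, seed = 20,
                                            covariates = optim_covs()))
  fitted <- fit_equation(spec, tab, "a")
  expect_lt(fitted$coefficients[["x2"]], 0)        # sign mismatch ...
  expect_gt(fitted$wald_p[["x2"]], 0.05)           # ... and non-significant
  res <- suppressMessages(optimize_sem(spec, tab))
  expect_false(any(res$spec$paths$cause == "x2" &
                   res$spec$paths$effect == "a"))
  expect_true("remove_path" %in% res$trace$steps$action)
  # the other (truthful) hypothesized paths survive
  expect_true(any(res$spec$paths$cause == "x1" & res$spec$paths$effect == "a"))
})

test_that("optimization is deterministic and its trace replays to the final spec", {
  truth <- optim_truth(extra_coef = 0.5)
  start <- optim_truth()$spec  # whitelist holds the missing x1 -> c path
  tab <- scale_covariates(simulate_stations(600, truth, seed = 3,
                                            covariates = optim_covs()))
  res1 <- suppressMessages(optimize_sem(start, tab))
  res2 <- suppressMessages(optimize_sem(start, tab))
  expect_identical(res1$trace$steps, res2$trace$steps)
  expect_equal(res1$spec$paths, res2$spec$paths)

  replayed <- replay_trace(res1$trace)
  expect_equal(replayed$paths, res1$spec$paths)
  expect_equal(replayed$correlated_errors, res1$spec$correlated_errors)

  # every accepted addition lowered Fisher's C and came from the whitelist
  adds <- res1$trace$steps[res1$trace$steps$action == "add_path", ]
  if (nrow(adds) > 0) {
    expect_true(all(adds$fisher_c_after < adds$fisher_c_before))
    wl <- optim_truth()$spec$whitelist
    expect_true(all(paste(adds$cause, adds$effect) %in%
                    paste(wl$cause, wl$effect)))
  }
})

test_that("combining specs unions paths, drops superseded correlated errors, and validates", {
  exo <- "x"
  a <- sem_spec(endogenous = c("A", "B"), exogenous = exo,
                paths = path_df(list("x", "B", "none")))
  b <- sem_spec(endogenous = c("A", "B"), exogenous = exo,
                paths = path_df(list("A", "B", "none")))
  comb <- combine_specs(a, b)
  expect_equal(nrow(comb$paths), 2)

  # idempotence
  same <- combine_specs(a, a)
  expect_equal(same$paths, a$paths)

  # differing vertex sets
  c_spec <- sem_spec(endogenous = c("A", "Z"), exogenous = exo)
  expect_error(combine_specs(a, c_spec), "different vertex sets")

  # expected-sign conflict on a shared path
  pos <- sem_spec(endogenous = c("A", "B"), exogenous = exo,
                  paths = path_df(list("A", "B", "positive")))
  neg <- sem_spec(endogenous = c("A", "B"), exogenous = exo,
                  paths = path_df(list("A", "B", "negative")))
  expect_error(combine_specs(pos, neg), "sign conflict")

  # a correlated error superseded by a path from the other model is dropped
  with_ce <- sem_spec(endogenous = c("A", "B"), exogenous = exo,
                      correlated_errors = data.frame(a = "A", b = "B"))
  comb2 <- combine_specs(with_ce, b)
  expect_equal(nrow(comb2$correlated_errors), 0)

  # a cyclic union without data is an error; with data it resolves
  fwd <- sem_spec(endogenous = c("A", "B"), exogenous = exo,
                  paths = path_df(list("x", "A", "none"),
                                  list("A", "B", "none")))
  rev <- sem_spec(endogenous = c("A", "B"), exogenous = exo,
                  paths = path_df(list("x", "A", "none"),
                                  list("B", "A", "none")))
  expect_error(combine_specs(fwd, rev), "cyclic")
  tr <- list(spec = fwd,
             coefficients = data.frame(cause = c("x", "A"),
                                       effect = c("A", "B"),
                                       coef = c(0.4, 0.2),
                                       stringsAsFactors = FALSE),
             intercepts = c(A = log(3), B = log(2)))
  tab <- scale_covariates(simulate_stations(400, tr, seed = 31,
                                            covariates = unit_covariates("x")))
  comb3 <- combine_specs(fwd, rev, table = tab)
  # the data were generated with A -> B, so that direction wins
  expect_true(any(comb3$paths$cause == "A" & comb3$paths$effect == "B"))
  expect_false(any(comb3$paths$cause == "B" & comb3$paths$effect == "A"))
})

test_that("the optimized fixtures merge into the combined fixture's path set", {
  comb <- combine_specs(spec_topdown_optimized(), spec_bottomup_optimized())
  want <- spec_combined()$paths
  expect_setequal(paste(comb$paths$cause, comb$paths$effect),
                  paste(want$cause, want$effect))
})

test_that("the study pipeline returns three coherent reports on synthetic data", {
  tr <- default_truth()
  tab <- simulate_stations(140, tr, seed = 42)
  res <- suppressMessages(run_study(tab))
  expect_s3_class(res, "sem_study")
  expect_setequal(names(res$reports), c("top_down", "bottom_up", "combined"))
  expect_equal(nrow(res$comparison), 3)
  expect_true(all(c("response", "predictor", "estimate", "std_estimate") %in%
                  names(res$coefficients)))
  # deterministic given table and specs
  res2 <- suppressMessages(run_study(tab))
  expect_equal(res$comparison, res2$comparison)
  expect_equal(res$coefficients, res2$coefficients)
  expect_error(suppressMessages(run_study(tab[0, ])), "empty")
})
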