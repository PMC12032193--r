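test_that("spec validation reports each invariant violation as data", {
  # effect must be endogenous
  s1 <- sem_spec(endogenous = c("wolf", "fox"),
                 exogenous = "road_density",
                 paths = path_df(list("wolf", "road_density", "none")),
                 validate = FALSE)
  expect_match(paste(validate_spec(s1), collapse = "; "),
               "effect is exogenous")

  # cycles are flagged
  s2 <- sem_spec(endogenous = c("wolf", "fox"), exogenous = "elevation",
                 paths = path_df(list("wolf", "fox", "none"),
                                 list("fox", "wolf", "none")),
                 validate = FALSE)
  expect_match(paste(validate_spec(s2), collapse = "; "), "cycle")

  # adjacent correlated-error pair
  s3 <- sem_spec(endogenous = c("wolf", "fox"), exogenous = "elevation",
                 paths = path_df(list("wolf", "fox", "none")),
                 correlated_errors = data.frame(a = "wolf", b = "fox"),
                 validate = FALSE)
  expect_match(paste(validate_spec(s3), collapse = "; "), "adjacent")

  # whitelist duplicating an existing path
  s4 <- sem_spec(endogenous = c("wolf", "fox"), exogenous = "elevation",
                 paths = path_df(list("wolf", "fox", "none")),
                 whitelist = path_df(list("wolf", "fox", "none", FALSE)),
                 validate = FALSE)
  expect_match(paste(validate_spec(s4), collapse = "; "), "duplicates")

  # the packaged fixtures are all valid
  for (spec in list(spec_topdown(), spec_bottomup(), spec_combined(),
                    spec_topdown_optimized(), spec_bottomup_optimized())) {
    expect_identical(validate_spec(spec), character(0))
  }
})

test_that("topological order puts exogenous first and causes before effects", {
  chain <- sem_spec(endogenous = c("B", "C"), exogenous = "A",
                    paths = path_df(list("A", "B", "none"),
                                    list("B", "C", "none")))
  expect_identical(topological_order(chain), c("A", "B", "C"))

  collider <- sem_spec(endogenous = "Z", exogenous = c("X", "Y"),
                       paths = path_df(list("X", "Z", "none"),
                                       list("Y", "Z", "none")))
  expect_identical(topological_order(collider), c("X", "Y", "Z"))

  ord <- topological_order(spec_combined())
  expect_identical(ord[1:4], sort(station_covariates()))
  pos <- stats::setNames(seq_along(ord), ord)
  p <- spec_combined()$paths
  for (i in seq_len(nrow(p))) {
    expect_lt(pos[[p$cause[i]]], pos[[p$effect[i]]])
  }
})

test_that("basis set matches hand-worked cases", {
  chain <- sem_spec(endogenous = c("B", "C"), exogenous = "A",
                    paths = path_df(list("A", "B", "none"),
                                    list("B", "C", "none")))
  b <- basis_set(chain)
  expect_equal(nrow(b), 1)
  expect_equal(b$a, "A")
  expect_equal(b$b, "C")
  expect_equal(b$response, "C")
  expect_equal(b$conditioning[[1]], "B")
  expect_equal(2L * nrow(b), 2L)

  saturated <- sem_spec(endogenous = c("B", "C"), exogenous = "A",
                        paths = path_df(list("A", "B", "none"),
                                        list("B", "C", "none"),
                                        list("A", "C", "none")))
  expect_equal(nrow(basis_set(saturated)), 0)

  # descendant is the response when both members are endogenous and ordered
  anc <- sem_spec(endogenous = c("B", "C", "D"), exogenous = "A",
                  paths = path_df(list("A", "B", "none"),
                                  list("B", "C", "none"),
                                  list("C", "D", "none")))
  bd <- basis_set(anc)
  row <- bd[bd$a == "B" & bd$b == "D", ]
  expect_equal(row$response, "D")

  # unordered endogenous pairs are tested in both directions
  fork <- sem_spec(endogenous = c("B", "C"), exogenous = "A",
                   paths = path_df(list("A", "B", "none"),
                                   list("A", "C", "none")))
  expect_equal(basis_set(fork)$response, "both")
})

test_that("basis set agrees with the brute-force enumerator on random DAGs", {
  for (seed in 1:40) {
    spec <- random_dag_spec(seed)
    got <- basis_set(spec)
    want <- oracle_basis_pairs(spec)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$a[k], want[[k]]$a)
      expect_equal(got$b[k], want[[k]]$b)
      expect_equal(sort(got$conditioning[[k]]), want[[k]]$conditioning)
    }
  }
})

test_that("the combined fixture's basis set reproduces the reported df", {
  b <- basis_set(spec_combined())
  expect_equal(nrow(b), 13)
  expect_equal(2L * nrow(b), 26L)
  want <- oracle_basis_pairs(spec_combined())
  expect_equal(nrow(b), length(want))
})

test_that("spec edits are pure and adjust the basis set by exactly one claim", {
  spec <- spec_topdown()
  n0 <- nrow(basis_set(spec))
  spec2 <- add_path(spec, "red_deer", "fox", sign = "positive")
  expect_equal(nrow(basis_set(spec2)), n0 - 1)
  expect_equal(nrow(basis_set(spec)), n0)  # input untouched

  # add then remove restores the original basis set
  spec3 <- remove_path(spec2, "red_deer", "fox")
  b0 <- basis_set(spec)
  b3 <- basis_set(spec3)
  expect_equal(b3[c("a", "b", "response")], b0[c("a", "b", "response")])

  expect_error(add_path(spec, "wolf", "wild_boar"), "already present")
  expect_error(add_correlated_error(spec, "wolf", "wild_boar"), "adjacent")

  spec4 <- add_correlated_error(spec, "red_deer", "roe_deer")
  expect_equal(nrow(basis_set(spec4)), n0 - 1)
  expect_error(add_correlated_error(spec4, "roe_deer", "red_deer"),
               "already present")
})

test_that("specs round-trip through YAML and JSON and export to DOT", {
  spec <- spec_topdown()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_sem_spec(spec, path)
    back <- read_sem_spec(path)
    expect_equal(back$endogenous, spec$endogenous)
    expect_equal(back$exogenous, spec$exogenous)
    expect_equal(back$paths, spec$paths)
    expect_equal(back$correlated_errors, spec$correlated_errors)
    expect_equal(back$whitelist, spec$whitelist)
  }
  dot <- sem_spec_dot(spec)
  expect_match(dot, "digraph")
  expect_match(dot, "\"wolf\" -> \"wild_boar\" \\[style=dashed\\]")
  expect_match(dot, "\"wolf\" -> \"fox\" \\[style=solid\\]")
})
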