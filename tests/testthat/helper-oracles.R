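# Brute-force basis-set enumerator, written longhand and kept independent of
# the package's implementation: every unordered vertex pair, adjacency by
# direct scan of the path list, exclusion rules applied one by one.
oracle_basis_pairs <- function(spec) {
  verts <- sort(c(spec$exogenous, spec$endogenous))
  out <- list()
  for (a in verts) {
    for (b in verts) {
      if (a >= b) next
      if (a %in% spec$exogenous && b %in% spec$exogenous) next
      adjacent <- FALSE
      for (i in seq_len(nrow(spec$paths))) {
        u <- spec$paths$cause[i]
        v <- spec$paths$effect[i]
        if ((u == a && v == b) || (u == b && v == a)) adjacent <- TRUE
      }
      if (adjacent) next
      excluded <- FALSE
      for (i in seq_len(nrow(spec$correlated_errors))) {
        pr <- sort(c(spec$correlated_errors$a[i], spec$correlated_errors$b[i]))
        if (pr[1] == a && pr[2] == b) excluded <- TRUE
      }
      if (excluded) next
      parents_a <- character(0)
      parents_b <- character(0)
      for (i in seq_len(nrow(spec$paths))) {
        if (spec$paths$effect[i] == a) {
          parents_a <- c(parents_a, spec$paths$cause[i])
        }
        if (spec$paths$effect[i] == b) {
          parents_b <- c(parents_b, spec$paths$cause[i])
        }
      }
      cond <- sort(setdiff(unique(c(parents_a, parents_b)), c(a, b)))
      out[[length(out) + 1]] <- list(a = a, b = b, conditioning = cond)
    }
  }
  out
}

# Random DAG over <= 12 vertices: edges respect vertex index order (hence
# acyclic), exogenous vertices never receive edges, and a couple of
# correlated errors are sprinkled on non-adjacent endogenous pairs chosen by
# a longhand adjacency scan.
random_dag_spec <- function(seed, p_edge = 0.3) {
  set.seed(seed)
  n <- sample(4:12, 1)
  verts <- sprintf("v%02d", seq_len(n))
  n_exo <- sample(seq_len(min(3, n - 2)), 1)
  exo <- verts[seq_len(n_exo)]
  endo <- setdiff(verts, exo)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (verts[j] %in% exo) next
      if (stats::runif(1) < p_edge) {
        rows[[length(rows) + 1]] <- data.frame(
          cause = verts[i], effect = verts[j], sign = "none",
          hypothesized = TRUE, note = "", stringsAsFactors = FALSE)
      }
    }
  }
  paths <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  ce <- NULL
  if (length(endo) >= 2) {
    nonadj <- list()
    for (i in seq_len(length(endo) - 1)) {
      for (j in seq(i + 1, length(endo))) {
        a <- endo[i]; b <- endo[j]
        hit <- FALSE
        for (k in seq_along(rows)) {
          u <- rows[[k]]$cause; v <- rows[[k]]$effect
          if ((u == a && v == b) || (u == b && v == a)) hit <- TRUE
        }
        if (!hit) nonadj[[length(nonadj) + 1]] <- c(a, b)
      }
    }
    if (length(nonadj) > 0) {
      k <- sample(0:min(2, length(nonadj)), 1)
      if (k > 0) {
        picks <- sample(length(nonadj), k)
        ce <- do.call(rbind, lapply(nonadj[picks], function(p) {
          data.frame(a = p[1], b = p[2], stringsAsFactors = FALSE)
        }))
      }
    }
  }
  sem_spec(endogenous = endo, exogenous = exo, paths = paths,
           correlated_errors = ce)
}

# select a basis-set claim by unordered pair
pick_claim <- function(basis, u, v) {
  pair <- sort(c(u, v))
  basis[basis$a == pair[1] & basis$b == pair[2], , drop = FALSE]
}

# uniform(-1, 1) covariate configs for small simulation specs
unit_covariates <- function(nms) {
  stats::setNames(lapply(nms, function(n) {
    list(dist = "uniform", min = -1, max = 1)
  }), nms)
}

path_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(cause = r[[1]], effect = r[[2]], sign = r[[3]],
               hypothesized = if (length(r) > 3) r[[4]] else TRUE,
               note = "", stringsAsFactors = FALSE)
  }))
}

# Three-covariate / three-species chain used for the d-separation
# calibration experiments; every basis-set claim has a unique response.
calib_truth <- function() {
  spec <- sem_spec(
    endogenous = c("a", "b", "c"),
    exogenous = c("x1", "x2", "x3"),
    paths = path_df(
      list("x1", "a", "positive"),
      list("x2", "b", "positive"),
      list("a", "b", "positive"),
      list("x3", "c", "positive"),
      list("b", "c", "positive")))
  list(spec = spec,
       coefficients = data.frame(
         cause = c("x1", "x2", "a", "x3", "b"),
         effect = c("a", "b", "b", "c", "c"),
         coef = c(0.3, 0.3, 0.1, 0.3, 0.1),
         stringsAsFactors = FALSE),
       intercepts = c(a = log(3), b = log(2), c = log(2)))
}

calib_covs <- function() unit_covariates(c("x1", "x2", "x3"))

# calibration truth plus one extra direct path x1 -> c (omitted from the
# fitted model in the power experiments)
calib_truth_extra <- function(effect_size = 0.5) {
  tr <- calib_truth()
  tr$spec <- add_path(tr$spec, "x1", "c", sign = "positive")
  tr$coefficients <- rbind(tr$coefficients, data.frame(
    cause = "x1", effect = "c", coef = effect_size, stringsAsFactors = FALSE))
  tr
}

# Two-covariate / two-species truth for the optimizer experiments; the
# whitelist carries the candidate path x1 -> c.
optim_truth <- function(extra_coef = NULL) {
  spec <- sem_spec(
    endogenous = c("a", "c"),
    exogenous = c("x1", "x2"),
    paths = path_df(
      list("x1", "a", "positive"),
      list("x2", "c", "positive"),
      list("a", "c", "positive")),
    whitelist = path_df(list("x1", "c", "positive", FALSE)))
  co <- data.frame(cause = c("x1", "x2", "a"), effect = c("a", "c", "c"),
                   coef = c(0.4, 0.4, 0.1), stringsAsFactors = FALSE)
  truth <- list(spec = spec, coefficients = co,
                intercepts = c(a = log(3), c = log(2)))
  if (!is.null(extra_coef)) {
    truth$spec <- add_path(truth$spec, "x1", "c", sign = "positive")
    truth$coefficients <- rbind(truth$coefficients, data.frame(
      cause = "x1", effect = "c", coef = extra_coef,
      stringsAsFactors = FALSE))
  }
  truth
}

optim_covs <- function() unit_covariates(c("x1", "x2"))

# Two-path truth with non-zero coefficients for parameter recovery.
recovery_truth <- function() {
  spec <- sem_spec(
    endogenous = c("a", "b"),
    exogenous = c("x1", "x2"),
    paths = path_df(
      list("x1", "a", "positive"),
      list("x2", "b", "negative"),
      list("a", "b", "positive")))
  list(spec = spec,
       coefficients = data.frame(
         cause = c("x1", "x2", "a"), effect = c("a", "b", "b"),
         coef = c(0.5, -0.3, 0.1), stringsAsFactors = FALSE),
       intercepts = c(a = log(3), b = log(2)))
}

# tiny deterministic station table for I/O tests
toy_station_df <- function() {
  set.seed(99)
  n <- 6
  df <- data.frame(
    station_id = sprintf("S%02d", seq_len(n)),
    season = rep(c("winter", "autumn"), each = 3),
    elevation = c(700, 900, 1100, 1300, 1500, 1600),
    tri = c(90, 150, 210, 280, 350, 480),
    forest = c(0.2, 0.4, 0.6, 0.7, 0.9, 1.0),
    road_density = c(0.21, 0.24, 0.27, 0.3, 0.32, 0.34),
    stringsAsFactors = FALSE
  )
  for (sp in station_species()) df[[sp]] <- rpois(n, 3)
  df
}
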