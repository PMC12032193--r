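trace_step <- function(action, cause, effect, p_value, c_before, c_after,
                       reason, sign = NA_character_, note = NA_character_) {
  data.frame(action = action, cause = cause, effect = effect,
             sign = sign, note = note, p_value = p_value,
             fisher_c_before = c_before, fisher_c_after = c_after,
             reason = reason, stringsAsFactors = FALSE)
}

empty_trace_steps <- function() {
  trace_step(character(0), character(0), character(0), numeric(0),
             numeric(0), numeric(0), character(0), character(0),
             character(0))
}

#' Stepwise optimization of a piecewise SEM
#'
#' Implements the study's optimization protocol. Each pass: (1) fit all
#' equations and run the tests of directed separation; (2) walk the
#' significant claims (p < `alpha`) in ascending-p order (ties broken
#' lexicographically): a claim matching a whitelist entry is tentatively
#' added as a path and kept only if it lowers Fisher's C (otherwise the
#' candidate is recorded as rejected); a significant species-species claim
#' with no whitelist match becomes a correlated error (an association
#' attributed to unmodelled ecological processes, which removes the claim
#' from the basis set); anything else is rejected as not fitting the model
#' hypothesis; (3) remove hypothesized paths that are both non-significant
#' and fitted with a sign contradicting their expected sign (non-significant
#' hypothesized paths with the expected sign are retained). Passes repeat
#' until nothing changes. Paths removed in step (3) never re-enter, and
#' paths added during optimization are never pruned, so the loop terminates.
#'
#' @param spec A valid [sem_spec()]; its `whitelist` defines the candidate
#'   paths optimization may add.
#' @param table A scaled [station_table()].
#' @param alpha Significance level (default 0.05).
#' @param max_passes Safety cap on optimization passes (default 50).
#' @return List with `spec` (the optimized specification) and `trace` (an
#'   object of class `sem_trace`: per-step records plus the initial and
#'   final specs).
#' @export
optimize_sem <- function(spec, table, alpha = 0.05, max_passes = 50) {
  assert_valid_spec(spec)
  if (!is_scaled(table)) {
    message("scaling covariates before optimization")
    table <- scale_covariates(table)
  }
  initial_spec <- spec
  steps <- list()
  removed_keys <- character(0)

  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    gof <- sem_fit(spec, table)
    cur_c <- gof$fisher_c
    claims <- gof$claims
    sig <- claims[claims$p_value < alpha, , drop = FALSE]
    sig <- sig[order(sig$p_value, sig$a, sig$b), , drop = FALSE]

    for (k in seq_len(nrow(sig))) {
      a <- sig$a[k]; b <- sig$b[k]; p_k <- sig$p_value[k]
      # the claim may have left the basis set after an earlier edit this pass
      cur_basis <- basis_set(spec, check = FALSE)
      if (!any(cur_basis$a == a & cur_basis$b == b)) next
      wl <- spec$whitelist
      hit <- which((wl$cause == a & wl$effect == b) |
                   (wl$cause == b & wl$effect == a))
      hit <- hit[!paste(wl$cause[hit], wl$effect[hit]) %in% removed_keys]
      if (length(hit) > 0) {
        w <- wl[hit[1], ]
        cand <- add_path(spec, w$cause, w$effect, sign = w$sign,
                         hypothesized = FALSE, note = w$note)
        c_after <- sem_fit(cand, table)$fisher_c
        if (c_after < cur_c) {
          steps[[length(steps) + 1]] <- trace_step(
            "add_path", w$cause, w$effect, p_k, cur_c, c_after,
            "significant whitelisted claim; Fisher's C decreased",
            sign = w$sign, note = w$note)
          spec <- cand
          cur_c <- c_after
          changed <- TRUE
        } else {
          steps[[length(steps) + 1]] <- trace_step(
            "reject_candidate", w$cause, w$effect, p_k, cur_c, c_after,
            "whitelisted path did not lower Fisher's C")
        }
      } else if (a %in% spec$endogenous && b %in% spec$endogenous) {
        spec <- add_correlated_error(spec, a, b)
        c_after <- sem_fit(spec, table)$fisher_c
        steps[[length(steps) + 1]] <- trace_step(
          "add_correlated_error", a, b, p_k, cur_c, c_after,
          "significant species-species claim outside the whitelist")
        cur_c <- c_after
        changed <- TRUE
      } else {
        steps[[length(steps) + 1]] <- trace_step(
          "reject_candidate", a, b, p_k, cur_c, NA_real_,
          "significant claim does not fit the model hypothesis")
      }
    }

    # pruning: hypothesized, non-significant, sign-mismatched paths
    gof <- sem_fit(spec, table)
    cur_c <- gof$fisher_c
    coefs <- coef_table(gof$fits)
    prune <- spec$paths[spec$paths$hypothesized &
                        spec$paths$sign != "none", , drop = FALSE]
    for (k in seq_len(nrow(prune))) {
      cause <- prune$cause[k]; effect <- prune$effect[k]
      row <- coefs[coefs$response == effect & coefs$predictor == cause, ]
      if (nrow(row) != 1) next
      fitted_sign <- if (row$estimate >= 0) "positive" else "negative"
      if (row$p >= alpha && fitted_sign != prune$sign[k]) {
        spec <- remove_path(spec, cause, effect)
        removed_keys <- c(removed_keys, paste(cause, effect))
        c_after <- sem_fit(spec, table)$fisher_c
        steps[[length(steps) + 1]] <- trace_step(
          "remove_path", cause, effect, row$p, cur_c, c_after,
          "non-significant and fitted sign contradicts expectation")
        cur_c <- c_after
        changed <- TRUE
        coefs <- coef_table(sem_fit(spec, table)$fits)
      }
    }

    if (!changed) break
  }

  trace <- structure(list(
    steps = if (length(steps) > 0) do.call(rbind, steps) else
      empty_trace_steps(),
    initial_spec = initial_spec,
    final_spec = spec,
    alpha = alpha
  ), class = "sem_trace")
  list(spec = spec, trace = trace)
}

#' Replay an optimization trace
#'
#' Applies the trace's accepted actions to its initial spec; the result must
#' equal the trace's final spec (used as a consistency check).
#'
#' @param trace A `sem_trace` from [optimize_sem()].
#' @return The reconstructed final [sem_spec()].
#' @export
replay_trace <- function(trace) {
  spec <- trace$initial_spec
  st <- trace$steps
  for (i in seq_len(nrow(st))) {
    spec <- switch(st$action[i],
      add_path = add_path(spec, st$cause[i], st$effect[i],
                          sign = st$sign[i], hypothesized = FALSE,
                          note = st$note[i]),
      add_correlated_error = add_correlated_error(spec, st$cause[i],
                                                  st$effect[i]),
      remove_path = remove_path(spec, st$cause[i], st$effect[i]),
      reject_candidate = spec
    )
  }
  spec
}

#' @export
print.sem_trace <- function(x, ...) {
  cat("Optimization trace:", nrow(x$steps), "step(s), alpha =", x$alpha, "\n")
  if (nrow(x$steps) > 0) {
    print(x$steps[c("action", "cause", "effect", "p_value",
                    "fisher_c_before", "fisher_c_after")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Merge two optimized model specifications
#'
#' Builds the combined model from the retained paths of two optimized
#' models: the union of their paths and correlated errors over a common
#' vertex set. Duplicate paths collapse; a shared path with conflicting
#' expected signs is an error. A correlated error whose pair becomes
#' adjacent through the union is dropped (the path supersedes it).
#'
#' @param opt_a,opt_b Valid [sem_spec()] objects over the same vertex set.
#' @param table Optional scaled [station_table()]. Two separately optimized
#'   models can retain species-species paths whose union is cyclic (the
#'   simplest case: the same pair retained in opposite directions). With a
#'   table, such conflicts are resolved by support: while the union has a
#'   cycle, the on-cycle species-species path with the weakest support
#'   (largest Wald p-value, refit within its own source model) is dropped.
#'   Without a table a cyclic union is an error.
#' @return The combined [sem_spec()].
#' @export
combine_specs <- function(opt_a, opt_b, table = NULL) {
  assert_valid_spec(opt_a)
  assert_valid_spec(opt_b)
  if (!setequal(opt_a$endogenous, opt_b$endogenous) ||
      !setequal(opt_a$exogenous, opt_b$exogenous)) {
    stop("specifications are over different vertex sets", call. = FALSE)
  }
  if (!is.null(table) && !is_scaled(table)) table <- scale_covariates(table)
  resolved <- resolve_union_cycles(opt_a, opt_b, table)
  opt_a <- resolved$opt_a
  opt_b <- resolved$opt_b
  paths <- rbind(opt_a$paths, opt_b$paths)
  key <- paste(paths$cause, paths$effect)
  for (k in unique(key[duplicated(key)])) {
    signs <- unique(paths$sign[key == k])
    signs <- setdiff(signs, "none")
    if (length(signs) > 1) {
      stop("sign conflict on shared path ", sub(" ", " -> ", k),
           call. = FALSE)
    }
  }
  paths <- paths[!duplicated(key), , drop = FALSE]
  ce <- as_pairs_df(rbind(opt_a$correlated_errors, opt_b$correlated_errors))
  ce <- ce[!duplicated(paste(ce$a, ce$b)), , drop = FALSE]
  adjacent <- vapply(seq_len(nrow(ce)), function(i) {
    any((paths$cause == ce$a[i] & paths$effect == ce$b[i]) |
        (paths$cause == ce$b[i] & paths$effect == ce$a[i]))
  }, logical(1))
  if (length(adjacent) > 0) ce <- ce[!adjacent, , drop = FALSE]
  wl <- rbind(opt_a$whitelist, opt_b$whitelist)
  wl <- wl[!duplicated(paste(wl$cause, wl$effect)), , drop = FALSE]
  wl <- wl[!paste(wl$cause, wl$effect) %in% paste(paths$cause, paths$effect),
           , drop = FALSE]
  sem_spec(endogenous = sort(unique(opt_a$endogenous)),
           exogenous = sort(unique(opt_a$exogenous)),
           paths = paths, correlated_errors = ce, whitelist = wl)
}

# Iteratively drop the weakest-supported species-species path that lies on
# a cycle of the union graph, until the union of the two path sets is
# acyclic. Support is the path's Wald p-value refit within its source model.
resolve_union_cycles <- function(opt_a, opt_b, table) {
  repeat {
    pa <- opt_a$paths
    pa$model <- rep("a", nrow(pa))
    pb <- opt_b$paths
    pb$model <- rep("b", nrow(pb))
    paths <- rbind(pa, pb)
    on_cycle <- edges_on_cycles(paths)
    if (!any(on_cycle)) return(list(opt_a = opt_a, opt_b = opt_b))
    if (is.null(table)) {
      bad <- paths[on_cycle, ]
      stop("union of retained paths is cyclic (",
           paste(unique(paste(bad$cause, bad$effect, sep = "->")),
                 collapse = ", "),
           "); supply `table` to resolve by support", call. = FALSE)
    }
    cand <- paths[on_cycle, , drop = FALSE]
    cand$p <- vapply(seq_len(nrow(cand)), function(i) {
      src <- if (cand$model[i] == "a") opt_a else opt_b
      unname(fit_equation(src, table, cand$effect[i])$wald_p[cand$cause[i]])
    }, numeric(1))
    cand <- cand[order(-cand$p, cand$cause, cand$effect), , drop = FALSE]
    drop <- cand[1, ]
    if (drop$model == "a") {
      opt_a <- remove_path(opt_a, drop$cause, drop$effect)
    } else {
      opt_b <- remove_path(opt_b, drop$cause, drop$effect)
    }
  }
}

# For each edge u -> v, TRUE when v reaches u through the union graph
# (i.e. the edge closes a directed cycle).
edges_on_cycles <- function(paths) {
  reach <- function(from) {
    seen <- character(0)
    frontier <- from
    while (length(frontier) > 0) {
      nxt <- unique(paths$effect[paths$cause %in% frontier])
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  vapply(seq_len(nrow(paths)), function(i) {
    paths$cause[i] %in% reach(paths$effect[i])
  }, logical(1))
}

#' Run the full three-model study workflow
#'
#' End-to-end pipeline: optimize the top-down and bottom-up hypothesized
#' models separately, merge their retained paths into a combined model, and
#' evaluate all three with Fisher's C and the likelihood-ratio chi-square.
#' Deterministic given the table and the specs.
#'
#' @param table A [station_table()] (scaled automatically if needed).
#' @param topdown_spec,bottomup_spec Hypothesized [sem_spec()] objects
#'   (defaults: the packaged reconstructions [spec_topdown()] and
#'   [spec_bottomup()]).
#' @param alpha Significance level (default 0.05).
#' @return List of class `sem_study` with `reports` (named `sem_gof` list:
#'   top_down, bottom_up, combined), `traces`, `comparison` (the
#'   model-comparison table), and `coefficients` (tidy coefficient table of
#'   the combined model).
#' @export
run_study <- function(table, topdown_spec = spec_topdown(),
                      bottomup_spec = spec_bottomup(), alpha = 0.05) {
  if (nrow(table) == 0) stop("empty station table", call. = FALSE)
  if (!is_scaled(table)) table <- scale_covariates(table)
  opt_td <- optimize_sem(topdown_spec, table, alpha = alpha)
  opt_bu <- optimize_sem(bottomup_spec, table, alpha = alpha)
  combined <- combine_specs(opt_td$spec, opt_bu$spec, table = table)
  reports <- list(
    top_down = sem_fit(opt_td$spec, table),
    bottom_up = sem_fit(opt_bu$spec, table),
    combined = sem_fit(combined, table)
  )
  out <- list(
    reports = reports,
    traces = list(top_down = opt_td$trace, bottom_up = opt_bu$trace),
    comparison = compare_models(reports, alpha = alpha),
    coefficients = coef_table(reports$combined$fits)
  )
  class(out) <- "sem_study"
  out
}

#' @export
print.sem_study <- function(x, ...) {
  cat("Three-model piecewise SEM study\n")
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}
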