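path_signs <- c("positive", "negative", "none")

empty_paths <- function() {
  data.frame(cause = character(0), effect = character(0),
             sign = character(0), hypothesized = logical(0),
             note = character(0), stringsAsFactors = FALSE)
}

as_paths_df <- function(paths) {
  if (is.null(paths) || (is.data.frame(paths) && nrow(paths) == 0) ||
      (!is.data.frame(paths) && length(paths) == 0)) {
    return(empty_paths())
  }
  if (!is.data.frame(paths)) {
    paths <- do.call(rbind, lapply(paths, function(p) {
      data.frame(cause = p$cause, effect = p$effect,
                 sign = if (is.null(p$sign)) "none" else p$sign,
                 hypothesized = if (is.null(p$hypothesized)) TRUE
                                else isTRUE(p$hypothesized),
                 note = if (is.null(p$note)) "" else p$note,
                 stringsAsFactors = FALSE)
    }))
  }
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  if (is.null(paths$sign)) paths$sign <- "none"
  if (is.null(paths$hypothesized)) paths$hypothesized <- TRUE
  if (is.null(paths$note)) paths$note <- ""
  rownames(paths) <- NULL
  paths[c("cause", "effect", "sign", "hypothesized", "note")]
}

as_pairs_df <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      p <- unlist(p, use.names = FALSE)
      data.frame(a = p[1], b = p[2], stringsAsFactors = FALSE)
    }))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("a", "b")
  swap <- pairs$a > pairs$b
  tmp <- pairs$a[swap]
  pairs$a[swap] <- pairs$b[swap]
  pairs$b[swap] <- tmp
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Construct a piecewise SEM model specification
#'
#' A model specification is the causal DAG of the analysis: endogenous
#' vertices (species, each modelled by a Poisson log-link equation),
#' exogenous vertices (landscape covariates), directed paths with expected
#' signs, correlated-error pairs (acknowledged associations without a causal
#' path; their independence claims leave the basis set), and a whitelist of
#' paths that may be added during stepwise optimization.
#'
#' @param endogenous,exogenous Character vectors of vertex names.
#' @param paths Data frame (or list of lists) with columns `cause`, `effect`,
#'   `sign` (`"positive"`, `"negative"` or `"none"`), `hypothesized`
#'   (logical; `FALSE` marks a path added during optimization), `note`.
#' @param correlated_errors Data frame or list of unordered vertex pairs.
#' @param whitelist Same shape as `paths`: candidate paths that optimization
#'   is allowed to add.
#' @param validate Stop on invariant violations (default `TRUE`).
#' @return An object of class `sem_spec`.
#' @export
sem_spec <- function(endogenous, exogenous, paths = NULL,
                     correlated_errors = NULL, whitelist = NULL,
                     validate = TRUE) {
  spec <- structure(list(
    endogenous = as.character(endogenous),
    exogenous = as.character(exogenous),
    paths = as_paths_df(paths),
    correlated_errors = as_pairs_df(correlated_errors),
    whitelist = as_paths_df(whitelist)
  ), class = "sem_spec")
  if (validate) assert_valid_spec(spec)
  spec
}

spec_vertices <- function(spec) c(spec$exogenous, spec$endogenous)

#' Parents of a vertex under a model specification
#' @noRd
spec_parents <- function(spec, v) {
  sort(unique(spec$paths$cause[spec$paths$effect == v]))
}

adjacent_in_spec <- function(spec, a, b) {
  any((spec$paths$cause == a & spec$paths$effect == b) |
      (spec$paths$cause == b & spec$paths$effect == a))
}

#' Validate a model specification
#'
#' Collects every invariant violation (unknown vertices, exogenous effects,
#' cycles, adjacent correlated-error pairs, whitelist duplicates, ...) as
#' messages; an empty return value means the spec is valid.
#'
#' @param spec A [sem_spec()].
#' @return Character vector of violation messages (`character(0)` if valid).
#' @export
validate_spec <- function(spec) {
  out <- character(0)
  verts <- spec_vertices(spec)
  if (any(duplicated(verts))) {
    out <- c(out, paste0("duplicate vertex name(s): ",
                         paste(unique(verts[duplicated(verts)]),
                               collapse = ", ")))
  }
  p <- spec$paths
  for (i in seq_len(nrow(p))) {
    if (!p$cause[i] %in% verts) {
      out <- c(out, paste0("path ", p$cause[i], " -> ", p$effect[i],
                           ": unknown cause vertex"))
    }
    if (!p$effect[i] %in% verts) {
      out <- c(out, paste0("path ", p$cause[i], " -> ", p$effect[i],
                           ": unknown effect vertex"))
    } else if (p$effect[i] %in% spec$exogenous) {
      out <- c(out, paste0("path ", p$cause[i], " -> ", p$effect[i],
                           ": effect is exogenous"))
    }
    if (identical(p$cause[i], p$effect[i])) {
      out <- c(out, paste0("path ", p$cause[i], " -> ", p$effect[i],
                           ": self-loop"))
    }
    if (!p$sign[i] %in% path_signs) {
      out <- c(out, paste0("path ", p$cause[i], " -> ", p$effect[i],
                           ": invalid sign '", p$sign[i], "'"))
    }
  }
  key <- paste(p$cause, p$effect)
  if (anyDuplicated(key)) {
    out <- c(out, paste0("duplicate path(s): ",
                         paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  ord <- try(topological_order(spec, check = FALSE), silent = TRUE)
  if (inherits(ord, "try-error")) {
    out <- c(out, "cycle in path graph")
  }
  ce <- spec$correlated_errors
  for (i in seq_len(nrow(ce))) {
    lab <- paste0(ce$a[i], " ~~ ", ce$b[i])
    if (!all(c(ce$a[i], ce$b[i]) %in% verts)) {
      out <- c(out, paste0("correlated error ", lab, ": unknown vertex"))
    } else if (identical(ce$a[i], ce$b[i])) {
      out <- c(out, paste0("correlated error ", lab, ": self-pair"))
    } else if (adjacent_in_spec(spec, ce$a[i], ce$b[i])) {
      out <- c(out, paste0("correlated error ", lab,
                           ": pair is adjacent in the path graph"))
    }
  }
  if (anyDuplicated(paste(ce$a, ce$b))) {
    out <- c(out, "duplicate correlated-error pair(s)")
  }
  w <- spec$whitelist
  for (i in seq_len(nrow(w))) {
    lab <- paste0(w$cause[i], " -> ", w$effect[i])
    if (!all(c(w$cause[i], w$effect[i]) %in% verts)) {
      out <- c(out, paste0("whitelist ", lab, ": unknown vertex"))
    } else if (w$effect[i] %in% spec$exogenous) {
      out <- c(out, paste0("whitelist ", lab, ": effect is exogenous"))
    }
    if (any(p$cause == w$cause[i] & p$effect == w$effect[i])) {
      out <- c(out, paste0("whitelist ", lab, ": duplicates an existing path"))
    }
  }
  out
}

assert_valid_spec <- function(spec) {
  bad <- validate_spec(spec)
  if (length(bad) > 0) {
    stop("invalid model specification:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  invisible(spec)
}

#' Deterministic topological order of the model DAG
#'
#' Kahn's algorithm with exogenous vertices emitted first and lexicographic
#' tie-breaking, so that the order (and everything derived from it, such as
#' saturated-model construction) is reproducible.
#'
#' @param spec A [sem_spec()].
#' @param check Validate the spec first (default `TRUE`).
#' @return Character vector of vertex names, causes before effects.
#' @export
topological_order <- function(spec, check = TRUE) {
  if (check) assert_valid_spec(spec)
  verts <- spec_vertices(spec)
  edges <- spec$paths[c("cause", "effect")]
  indeg <- stats::setNames(integer(length(verts)), verts)
  for (e in seq_len(nrow(edges))) {
    indeg[[edges$effect[e]]] <- indeg[[edges$effect[e]]] + 1L
  }
  is_exo <- stats::setNames(verts %in% spec$exogenous, verts)
  out <- character(0)
  remaining <- verts
  while (length(remaining) > 0) {
    ready <- remaining[indeg[remaining] == 0L]
    if (length(ready) == 0) stop("cycle in path graph", call. = FALSE)
    ready_exo <- sort(ready[is_exo[ready]])
    pick <- if (length(ready_exo) > 0) ready_exo[1] else sort(ready)[1]
    out <- c(out, pick)
    remaining <- setdiff(remaining, pick)
    kids <- edges$effect[edges$cause == pick]
    for (k in kids) indeg[[k]] <- indeg[[k]] - 1L
  }
  out
}

spec_ancestors <- function(spec, v) {
  out <- character(0)
  frontier <- v
  while (length(frontier) > 0) {
    ps <- unique(spec$paths$cause[spec$paths$effect %in% frontier])
    ps <- setdiff(ps, out)
    out <- c(out, ps)
    frontier <- ps
  }
  out
}

#' Enumerate the d-separation basis set
#'
#' One independence claim per unordered non-adjacent vertex pair with at
#' least one endogenous member, excluding exogenous-exogenous pairs (their
#' covariances are unconstrained by the model) and correlated-error pairs
#' (an acknowledged association removes the claim). The conditioning set of
#' a claim is the union of both vertices' parents, minus the pair itself.
#'
#' The regression response of a claim is the endogenous member when only one
#' is endogenous; the descendant when both are endogenous and one is an
#' ancestor of the other; otherwise both directions are tested and the
#' smaller p-value kept (`response = "both"`), a conservative choice since
#' the test is not direction-symmetric for non-Gaussian responses.
#'
#' @param spec A [sem_spec()].
#' @param check Validate the spec first (default `TRUE`).
#' @return Data frame with columns `a`, `b` (lexicographic pair), `response`
#'   (a vertex name or `"both"`), and list-column `conditioning`; rows sorted
#'   by pair. Fisher's C has `2 * nrow` degrees of freedom.
#' @export
basis_set <- function(spec, check = TRUE) {
  if (check) assert_valid_spec(spec)
  verts <- sort(spec_vertices(spec))
  ce_key <- paste(spec$correlated_errors$a, spec$correlated_errors$b,
                  sep = "\r")
  rows <- list()
  n <- length(verts)
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq((i + 1), n)) {
      a <- verts[i]; b <- verts[j]
      a_endo <- a %in% spec$endogenous
      b_endo <- b %in% spec$endogenous
      if (!a_endo && !b_endo) next
      if (adjacent_in_spec(spec, a, b)) next
      if (paste(a, b, sep = "\r") %in% ce_key) next
      cond <- setdiff(union(spec_parents(spec, a), spec_parents(spec, b)),
                      c(a, b))
      response <- if (a_endo && b_endo) {
        if (a %in% spec_ancestors(spec, b)) b
        else if (b %in% spec_ancestors(spec, a)) a
        else "both"
      } else if (a_endo) a else b
      rows[[length(rows) + 1]] <- list(a = a, b = b, response = response,
                                       conditioning = sort(cond))
    }
  }
  out <- data.frame(
    a = vapply(rows, `[[`, character(1), "a"),
    b = vapply(rows, `[[`, character(1), "b"),
    response = vapply(rows, `[[`, character(1), "response"),
    stringsAsFactors = FALSE
  )
  out$conditioning <- I(lapply(rows, `[[`, "conditioning"))
  out
}

#' Edit a model specification
#'
#' Pure edits: the input spec is unchanged and the result re-validated.
#' Adding a path over a previously non-adjacent pair removes exactly one
#' claim from the basis set; adding a correlated error likewise.
#'
#' @param spec A [sem_spec()].
#' @param cause,effect Path endpoints.
#' @param sign Expected sign (`"positive"`, `"negative"`, `"none"`).
#' @param hypothesized Was the path part of the a-priori model (default
#'   `FALSE`, i.e. added during optimization)?
#' @param note Free-text rationale.
#' @return A new `sem_spec`.
#' @export
add_path <- function(spec, cause, effect, sign = "none",
                     hypothesized = FALSE, note = "") {
  if (any(spec$paths$cause == cause & spec$paths$effect == effect)) {
    stop("path ", cause, " -> ", effect, " already present", call. = FALSE)
  }
  ce <- spec$correlated_errors
  if (any((ce$a == cause & ce$b == effect) |
          (ce$a == effect & ce$b == cause))) {
    stop("pair ", cause, " / ", effect,
         " has a correlated error; remove it before adding a path",
         call. = FALSE)
  }
  spec$paths <- rbind(spec$paths, data.frame(
    cause = cause, effect = effect, sign = sign,
    hypothesized = hypothesized, note = note, stringsAsFactors = FALSE))
  w <- spec$whitelist
  spec$whitelist <- w[!(w$cause == cause & w$effect == effect), , drop = FALSE]
  assert_valid_spec(spec)
  spec
}

#' @rdname add_path
#' @export
remove_path <- function(spec, cause, effect) {
  hit <- spec$paths$cause == cause & spec$paths$effect == effect
  if (!any(hit)) {
    stop("path ", cause, " -> ", effect, " not present", call. = FALSE)
  }
  spec$paths <- spec$paths[!hit, , drop = FALSE]
  rownames(spec$paths) <- NULL
  assert_valid_spec(spec)
  spec
}

#' @rdname add_path
#' @param a,b Unordered pair for a correlated error.
#' @export
add_correlated_error <- function(spec, a, b) {
  spec$correlated_errors <- as_pairs_df(rbind(
    spec$correlated_errors,
    data.frame(a = a, b = b, stringsAsFactors = FALSE)))
  if (anyDuplicated(paste(spec$correlated_errors$a,
                          spec$correlated_errors$b))) {
    stop("correlated error ", a, " ~~ ", b, " already present", call. = FALSE)
  }
  assert_valid_spec(spec)
  spec
}

#' Read / write model specifications (YAML or JSON)
#'
#' The file encodes `endogenous`, `exogenous`, `paths` (list of
#' `{cause, effect, sign, hypothesized, note}`), `correlated_errors` (list of
#' pairs) and `whitelist` (same shape as `paths`). Format is chosen by file
#' extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path File path.
#' @return For `read_sem_spec`, a validated [sem_spec()].
#' @export
read_sem_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  sem_spec(endogenous = unlist(raw$endogenous),
           exogenous = unlist(raw$exogenous),
           paths = raw$paths,
           correlated_errors = raw$correlated_errors,
           whitelist = raw$whitelist)
}

#' @rdname read_sem_spec
#' @param spec A [sem_spec()].
#' @export
write_sem_spec <- function(spec, path) {
  obj <- list(
    endogenous = spec$endogenous,
    exogenous = spec$exogenous,
    paths = lapply(seq_len(nrow(spec$paths)), function(i) {
      as.list(spec$paths[i, , drop = FALSE])
    }),
    correlated_errors = lapply(seq_len(nrow(spec$correlated_errors)),
                               function(i) {
      c(spec$correlated_errors$a[i], spec$correlated_errors$b[i])
    }),
    whitelist = lapply(seq_len(nrow(spec$whitelist)), function(i) {
      as.list(spec$whitelist[i, , drop = FALSE])
    })
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Export a model specification as a DOT graph
#'
#' Positive paths are drawn solid, negative paths dashed; correlated errors
#' as undirected dotted edges. The text can be rendered with Graphviz.
#'
#' @param spec A [sem_spec()].
#' @return A character scalar of DOT source.
#' @export
sem_spec_dot <- function(spec) {
  lines <- c("digraph sem {", "  rankdir=LR;")
  for (v in sort(spec$exogenous)) {
    lines <- c(lines, sprintf("  \"%s\" [shape=box];", v))
  }
  for (v in sort(spec$endogenous)) {
    lines <- c(lines, sprintf("  \"%s\" [shape=ellipse];", v))
  }
  p <- spec$paths
  for (i in seq_len(nrow(p))) {
    style <- if (p$sign[i] == "negative") "dashed" else "solid"
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [style=%s];",
                              p$cause[i], p$effect[i], style))
  }
  ce <- spec$correlated_errors
  for (i in seq_len(nrow(ce))) {
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [dir=both, style=dotted];", ce$a[i], ce$b[i]))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("Piecewise SEM specification\n")
  cat("  exogenous: ", paste(sort(x$exogenous), collapse = ", "), "\n")
  cat("  endogenous:", paste(sort(x$endogenous), collapse = ", "), "\n")
  cat("  paths:", nrow(x$paths),
      "| correlated errors:", nrow(x$correlated_errors),
      "| whitelist:", nrow(x$whitelist), "\n")
  invisible(x)
}
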