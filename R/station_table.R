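#' @keywords internal
"_PACKAGE"

#' Canonical landscape covariates and target species
#'
#' The survey design records four landscape covariates per camera station
#' (elevation in m, terrain ruggedness index, proportion forest, local road
#' density in km/km2) and per-station occurrence counts for eight mammal
#' species (two apex carnivores, two mesocarnivores, four prey species).
#'
#' @return Character vector of column names.
#' @export
station_covariates <- function() {
  c("elevation", "tri", "forest", "road_density")
}

#' @rdname station_covariates
#' @export
station_species <- function() {
  c("lynx", "wolf", "fox", "wildcat", "hare", "red_deer", "roe_deer",
    "wild_boar")
}

station_seasons <- c("winter", "autumn")

#' Construct a station table
#'
#' A station table holds one row per camera station x season, with landscape
#' covariates (raw or scaled) and non-negative integer occurrence counts per
#' species. Scaling state and parameters are carried as attributes so raw
#' values remain recoverable.
#'
#' @param df Data frame with columns `station_id`, `season`, the covariates
#'   and the species counts.
#' @param covariates Covariate column names (default the canonical four).
#' @param species Species count column names (default the canonical eight;
#'   may be `character(0)` for a covariates-only table).
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `station_table` (a data frame).
#' @export
station_table <- function(df, covariates = station_covariates(),
                          species = station_species(), validate = TRUE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  attr(df, "covariates") <- covariates
  attr(df, "species") <- species
  if (is.null(attr(df, "scaling"))) attr(df, "scaling") <- NULL
  class(df) <- unique(c("station_table", class(df)))
  if (validate) validate_station_table(df)
  df
}

is_scaled <- function(table) isTRUE(attr(table, "scaled"))

#' @noRd
validate_station_table <- function(table) {
  covariates <- attr(table, "covariates")
  species <- attr(table, "species")
  required <- c("station_id", "season", covariates, species)
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    stop("station table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_season <- !table$season %in% station_seasons
  if (any(bad_season)) {
    stop("invalid season value(s) in row(s) ",
         paste(which(bad_season), collapse = ", "),
         " (expected 'winter' or 'autumn')", call. = FALSE)
  }
  key <- paste(table$station_id, table$season, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (station_id, season) in row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  for (sp in species) {
    x <- table[[sp]]
    if (!is.numeric(x)) {
      stop("count column '", sp, "' is not numeric", call. = FALSE)
    }
    bad <- is.na(x) | x < 0 | abs(x - round(x)) > 1e-8
    if (any(bad)) {
      stop("count column '", sp, "' has negative or non-integer value in row ",
           which(bad)[1], call. = FALSE)
    }
  }
  for (cv in covariates) {
    if (!is.numeric(table[[cv]])) {
      stop("covariate column '", cv, "' is not numeric", call. = FALSE)
    }
    if (anyNA(table[[cv]])) {
      stop("covariate column '", cv, "' has missing values", call. = FALSE)
    }
  }
  if (!is_scaled(table)) {
    # range invariants only make sense on the raw measurement scale
    if ("forest" %in% covariates) {
      bad <- table$forest < 0 | table$forest > 1
      if (any(bad)) {
        stop("forest proportion outside [0, 1] in row ", which(bad)[1],
             call. = FALSE)
      }
    }
    for (cv in intersect(c("elevation", "tri", "road_density"), covariates)) {
      bad <- table[[cv]] < 0
      if (any(bad)) {
        stop("covariate '", cv, "' negative in row ", which(bad)[1],
             call. = FALSE)
      }
    }
  }
  invisible(table)
}

#' Read a camera-station count table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row. Default column
#' names are `station_id`, `season`, the four covariates and the eight
#' species; `column_map` renames non-standard headers.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional named character vector mapping canonical names
#'   (names) to the file's column names (values).
#' @param covariates,species Expected covariate / species columns.
#' @return A validated, unscaled [station_table()]; row order as in the file.
#' @export
read_station_table <- function(path, column_map = NULL,
                               covariates = station_covariates(),
                               species = station_species()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(df)) {
        stop("column_map points '", canonical, "' at missing column '", src,
             "'", call. = FALSE)
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  required <- c("station_id", "season", covariates, species)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  table <- station_table(df[required], covariates = covariates,
                         species = species)
  tab <- table(factor(table$season, levels = station_seasons))
  message("read ", nrow(table), " station rows (",
          paste(paste0(names(tab), ": ", as.integer(tab)), collapse = ", "),
          ")")
  table
}

#' Write a station table to CSV
#'
#' @param table A [station_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_station_table <- function(table, path) {
  cols <- c("station_id", "season", attr(table, "covariates"),
            attr(table, "species"))
  utils::write.csv(as.data.frame(table)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Centre and scale the landscape covariates
#'
#' Each covariate column is replaced by `(x - mean) / sd` with the sample
#' standard deviation (n - 1 denominator); counts are untouched. The raw
#' means and sds are stored in the `scaling` attribute so the raw values can
#' be recovered with [unscale_covariates()]. Applying the function to an
#' already-scaled table is a no-op up to numerical precision.
#'
#' @param table A [station_table()].
#' @return The scaled table.
#' @export
scale_covariates <- function(table) {
  covariates <- attr(table, "covariates")
  prior <- attr(table, "scaling")
  scaling <- data.frame(covariate = covariates, mean = NA_real_, sd = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in seq_along(covariates)) {
    cv <- covariates[i]
    x <- table[[cv]]
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      stop("covariate '", cv, "' is constant; cannot scale", call. = FALSE)
    }
    m <- mean(x)
    table[[cv]] <- (x - m) / s
    if (!is.null(prior)) {
      # compose with the previous transform so raw values stay recoverable
      j <- match(cv, prior$covariate)
      scaling$mean[i] <- prior$mean[j] + prior$sd[j] * m
      scaling$sd[i] <- prior$sd[j] * s
    } else {
      scaling$mean[i] <- m
      scaling$sd[i] <- s
    }
  }
  attr(table, "scaling") <- scaling
  attr(table, "scaled") <- TRUE
  table
}

#' Recover raw covariate values from a scaled table
#'
#' @param table A scaled [station_table()].
#' @return The table on the raw covariate scale.
#' @export
unscale_covariates <- function(table) {
  scaling <- attr(table, "scaling")
  if (is.null(scaling)) stop("table carries no scaling parameters",
                             call. = FALSE)
  for (i in seq_len(nrow(scaling))) {
    cv <- scaling$covariate[i]
    table[[cv]] <- table[[cv]] * scaling$sd[i] + scaling$mean[i]
  }
  attr(table, "scaling") <- NULL
  attr(table, "scaled") <- FALSE
  table
}

#' Pairwise Pearson correlations among covariates
#'
#' Used as a collinearity screen before modelling; a warning is issued for
#' any pair with |r| at or above `threshold` (the conventional screen keeps
#' all covariates when correlations stay low).
#'
#' @param table A [station_table()].
#' @param threshold Warning threshold on |r| (default 0.25).
#' @return Symmetric correlation matrix over the covariates.
#' @export
pearson_correlations <- function(table, threshold = 0.25) {
  covariates <- attr(table, "covariates")
  if (nrow(table) < 3) stop("need at least 3 rows", call. = FALSE)
  r <- stats::cor(as.data.frame(table)[covariates])
  high <- which(abs(r) >= threshold & upper.tri(r), arr.ind = TRUE)
  if (nrow(high) > 0) {
    pairs <- apply(high, 1, function(ij) {
      sprintf("%s~%s (r = %.3f)", covariates[ij[1]], covariates[ij[2]],
              r[ij[1], ij[2]])
    })
    warning("covariate correlation(s) at or above ", threshold, ": ",
            paste(pairs, collapse = "; "), call. = FALSE)
  }
  r
}

#' Summarise detections per species
#'
#' @param table A [station_table()].
#' @return A list of class `detection_summary` with elements `species` (data
#'   frame of totals and percentage shares), `grand_total`, and
#'   `season_share` (named proportion of detections per season). Percentages
#'   are `NA` when the table contains no detections.
#' @export
detection_summary <- function(table) {
  if (nrow(table) == 0) stop("empty station table", call. = FALSE)
  species <- attr(table, "species")
  totals <- vapply(species, function(sp) sum(table[[sp]]), numeric(1))
  grand <- sum(totals)
  pct <- if (grand > 0) 100 * totals / grand else rep(NA_real_, length(totals))
  by_season <- vapply(station_seasons, function(se) {
    rows <- table$season == se
    sum(vapply(species, function(sp) sum(table[[sp]][rows]), numeric(1)))
  }, numeric(1))
  season_share <- if (grand > 0) by_season / grand else
    stats::setNames(rep(NA_real_, 2), station_seasons)
  out <- list(
    species = data.frame(species = species, total = unname(totals),
                         percent = unname(pct), stringsAsFactors = FALSE),
    grand_total = grand,
    season_share = season_share
  )
  class(out) <- "detection_summary"
  out
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("Detections:", x$grand_total, "total\n")
  df <- x$species[order(-x$species$total), ]
  df$percent <- round(df$percent, 1)
  print(df, row.names = FALSE)
  cat("Season share:",
      paste(sprintf("%s %.0f%%", names(x$season_share),
                    100 * x$season_share), collapse = ", "), "\n")
  invisible(x)
}
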