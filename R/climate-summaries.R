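#' Thin occurrences to one record per climate pixel
#'
#' Keeps at most one record per (species, pixel), retaining the first in
#' input order, and drops records falling outside the raster extent or
#' on masked pixels (a count of dropped records is reported).
#'
#' @param occurrences data frame with `species`, `longitude`,
#'   `latitude`.
#' @param raster a [climate_raster()].
#' @return The pruned occurrence data frame.
#' @export
prune_to_pixels <- function(occurrences, raster) {
  if (nrow(occurrences) == 0L) return(occurrences)
  idx <- pixel_index(raster, occurrences$longitude, occurrences$latitude)
  n_bad <- sum(!idx$inside)
  if (n_bad > 0L)
    message(n_bad, " occurrence record(s) outside the raster or on ",
            "masked pixels dropped")
  keep <- idx$inside
  key <- paste(occurrences$species, idx$row, idx$col)
  keep[keep] <- !duplicated(key[keep])
  occurrences[keep, , drop = FALSE]
}

#' Extract climate values at occurrence points
#'
#' Each point gets the values of its containing pixel (half-open pixel
#' membership; no interpolation). Points outside the extent or on
#' masked pixels get `NA` values and are flagged.
#'
#' @param points data frame with `longitude`, `latitude` (a `species`
#'   column, if present, is carried through).
#' @param raster a [climate_raster()].
#' @return `points` with twelve appended climate columns and a logical
#'   `valid` column.
#' @export
extract_climate <- function(points, raster) {
  idx <- pixel_index(raster, points$longitude, points$latitude)
  out <- points
  for (code in names(raster$values)) {
    v <- rep(NA_real_, nrow(points))
    ok <- idx$inside
    v[ok] <- raster$values[[code]][cbind(idx$row[ok], idx$col[ok])]
    out[[code]] <- v
  }
  out$valid <- idx$inside
  if (any(!idx$inside))
    message(sum(!idx$inside), " point(s) could not be extracted ",
            "(outside extent or masked)")
  out
}

summary_stat_names <- function() c("p5", "p25", "mean", "p75", "p95")

#' Per-species climate envelope summaries
#'
#' For every species with at least `min_pixels` valid pixel-level
#' records, computes five statistics (5th percentile, 25th percentile,
#' mean, 75th percentile, 95th percentile) for each of the twelve
#' climate variables, in native units. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#' Species below the floor are skipped with a diagnostic.
#'
#' @param climate data frame from [extract_climate()] (post-pruning),
#'   with a `species` column.
#' @param min_pixels minimum number of occupied pixels (default 3).
#' @return Data frame: `species`, `n_pixels`, then 60 columns named
#'   `<code>_<stat>`.
#' @export
summarize_species <- function(climate, min_pixels = 3) {
  codes <- climate_codes()
  if ("valid" %in% names(climate)) climate <- climate[climate$valid, ]
  pieces <- split(climate, climate$species)
  stats_nm <- summary_stat_names()
  cols <- as.vector(t(outer(codes, stats_nm, paste, sep = "_")))
  skipped <- character()
  rows <- list()
  for (sp in names(pieces)) {
    d <- pieces[[sp]]
    if (nrow(d) < min_pixels) {
      skipped <- c(skipped, sp)
      next
    }
    vals <- unlist(lapply(codes, function(code) {
      x <- d[[code]]
      q <- stats::quantile(x, c(0.05, 0.25, 0.75, 0.95), type = 7,
                           names = FALSE)
      c(q[1L], q[2L], mean(x), q[3L], q[4L])
    }))
    row <- data.frame(species = sp, n_pixels = nrow(d))
    row[cols] <- as.list(vals)
    rows[[sp]] <- row
  }
  if (length(skipped))
    message("species below the ", min_pixels, "-pixel floor skipped: ",
            paste(skipped, collapse = ", "))
  if (!length(rows)) {
    out <- data.frame(species = character(), n_pixels = integer())
    for (cc in cols) out[[cc]] <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species x statistics matrix from envelope summaries
#'
#' @param summaries output of [summarize_species()].
#' @return Numeric matrix (species x 60) with species rownames.
#' @export
summary_matrix <- function(summaries) {
  cols <- setdiff(names(summaries), c("species", "n_pixels"))
  m <- as.matrix(summaries[, cols, drop = FALSE])
  rownames(m) <- summaries$species
  m
}

#' Column-standardize a summary matrix
#'
#' Converts each column to standard normal deviates (mean 0, SD 1 with
#' the n-1 denominator). Errors on constant columns, naming them.
#'
#' @param m numeric matrix with >= 2 rows.
#' @return Standardized matrix of the same shape.
#' @export
standardize_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows to standardize")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Principal component analysis of a standardized summary matrix
#'
#' PCA via the covariance of the (already standardized) columns,
#' equivalent to correlation PCA on the raw summaries. Axes are ordered
#' by decreasing variance fraction, and each loading vector is signed so
#' that its largest-magnitude entry is positive.
#'
#' @param m standardized species x statistics matrix.
#' @param n_axes number of axes to retain (default 5); truncated with a
#'   warning if it exceeds the matrix rank.
#' @return List of class `climate_pca`: `loadings` (columns =
#'   retained axes), `scores` (species coordinates), and
#'   `variance_fraction` over *all* axes (sums to 1).
#' @export
climate_pca <- function(m, n_axes = 5) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need more than one species")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  frac <- var_all / sum(var_all)
  rank <- sum(var_all > max(var_all) * 1e-12)
  if (n_axes > rank) {
    warning("n_axes = ", n_axes, " exceeds rank ", rank, "; truncated")
    n_axes <- rank
  }
  load <- pc$rotation[, seq_len(n_axes), drop = FALSE]
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  for (k in seq_len(n_axes)) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(loadings = load, scores = scores,
                 variance_fraction = frac),
            class = "climate_pca")
}

#' @export
print.climate_pca <- function(x, ...) {
  k <- ncol(x$loadings)
  cat("climate_pca:", k, "retained axes\n")
  cat("  variance fractions:",
      paste(sprintf("%.2f%%", 100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
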