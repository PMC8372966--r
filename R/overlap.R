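check_surface_pair <- function(p, q) {
  p <- as.vector(as.matrix(p))
  q <- as.vector(as.matrix(q))
  if (length(p) != length(q))
    stop("surfaces are defined on different pixel sets")
  nap <- is.na(p)
  if (!identical(nap, is.na(q)))
    stop("surfaces have mismatched valid-pixel masks")
  p <- p[!nap]
  q <- q[!nap]
  for (nm in c("p", "q")) {
    x <- get(nm)
    s <- sum(x)
    if (abs(s - 1) > 1e-6) {
      warning("surface '", nm, "' does not sum to 1; normalizing")
      x <- x / s
      assign(nm, x)
    }
  }
  list(p = p, q = q)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|p - q|)` over the shared pixel set: 1 for
#' identical normalized suitability surfaces, 0 for surfaces with
#' disjoint support.
#'
#' @param p,q suitability surfaces (vectors or matrices) on the same
#'   pixel set, each summing to 1 (surfaces off by more are normalized
#'   with a warning).
#' @return Overlap in `[0, 1]`.
#' @export
schoener_d <- function(p, q) {
  s <- check_surface_pair(p, q)
  min(max(1 - 0.5 * sum(abs(s$p - s$q)), 0), 1)
}

#' Warren's I niche overlap
#'
#' `I = 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)`, i.e. one minus half the
#' squared Hellinger distance between the two normalized surfaces.
#'
#' @inheritParams schoener_d
#' @return Overlap in `[0, 1]`.
#' @export
warren_i <- function(p, q) {
  s <- check_surface_pair(p, q)
  min(max(1 - 0.5 * sum((sqrt(s$p) - sqrt(s$q))^2), 0), 1)
}

#' Mean occurrence point of a species
#'
#' Arithmetic mean of the (post-pruning) occurrence coordinates.
#'
#' @param occurrences data frame with `longitude`, `latitude` (>= 1
#'   row).
#' @return Named numeric vector `c(longitude, latitude)`.
#' @export
species_mean_point <- function(occurrences) {
  if (nrow(occurrences) == 0L) stop("no occurrence records")
  c(longitude = mean(occurrences$longitude),
    latitude = mean(occurrences$latitude))
}

#' Great-circle distance in kilometers
#'
#' Geodesic distance on the WGS84 ellipsoid (default) or, as a flagged
#' fallback, on a sphere of radius 6371.0088 km.
#'
#' @param a,b points as `c(longitude, latitude)` in decimal degrees.
#' @param method `"wgs84"` (ellipsoidal geodesic) or `"sphere"`.
#' @return Distance in km (symmetric; zero iff the points coincide).
#' @export
great_circle_km <- function(a, b, method = c("wgs84", "sphere")) {
  method <- match.arg(method)
  lat <- c(a[2L], b[2L])
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  m <- if (method == "wgs84") geosphere::distGeo(a[1:2], b[1:2])
  else geosphere::distHaversine(a[1:2], b[1:2], r = 6371008.8)
  unname(m) / 1000
}

#' Assemble the pairwise niche-overlap table
#'
#' One row per unordered pair of modeled species classified arboreal
#' (`A`) or terrestrial (`T`) under the active scheme, carrying both
#' overlap metrics and the two distance covariates. Species lacking a
#' surface, an A/T classification, occurrences, or a place in the
#' covariance matrix are excluded with a diagnostic.
#'
#' @param surfaces named list of normalized suitability surfaces (from
#'   [project_suitability()], one per species).
#' @param labels named character vector of scheme categories per
#'   species; only `"A"` and `"T"` species enter the table.
#' @param occurrences post-pruning occurrence data frame (`species`,
#'   `longitude`, `latitude`) used for mean points.
#' @param C phylogenetic covariance over (at least) the included
#'   species.
#' @param geo_method distance method passed to [great_circle_km()].
#' @return Data frame of class `pair_overlap_table`: `species_a`,
#'   `species_b`, `pair_type` (`AA`/`AT`/`TT`), `D`, `I`, `geo_km`,
#'   `phylo_dist`.
#' @export
build_pair_table <- function(surfaces, labels, occurrences, C,
                             geo_method = "wgs84") {
  sp <- names(surfaces)
  at <- names(labels)[labels %in% c("A", "T")]
  keep <- intersect(sp, at)
  keep <- keep[keep %in% unique(occurrences$species)]
  miss_tree <- setdiff(keep, rownames(C))
  if (length(miss_tree))
    message("species missing from the covariance matrix excluded: ",
            paste(miss_tree, collapse = ", "))
  keep <- sort(setdiff(keep, miss_tree))
  if (length(keep) < 2L) stop("fewer than two usable species")
  pts <- t(vapply(keep, function(s)
    species_mean_point(occurrences[occurrences$species == s, , drop = FALSE]),
    numeric(2L)))
  Dmat <- phylo_pair_distance(C[keep, keep])
  prs <- utils::combn(keep, 2L)
  n <- ncol(prs)
  out <- data.frame(species_a = prs[1L, ], species_b = prs[2L, ],
                    pair_type = character(n), D = numeric(n),
                    I = numeric(n), geo_km = numeric(n),
                    phylo_dist = numeric(n))
  for (j in seq_len(n)) {
    a <- prs[1L, j]
    b <- prs[2L, j]
    out$pair_type[j] <- paste(sort(c(labels[[a]], labels[[b]])),
                              collapse = "")
    out$D[j] <- schoener_d(surfaces[[a]], surfaces[[b]])
    out$I[j] <- warren_i(surfaces[[a]], surfaces[[b]])
    out$geo_km[j] <- great_circle_km(pts[a, ], pts[b, ],
                                     method = geo_method)
    out$phylo_dist[j] <- Dmat[a, b]
  }
  attr(out, "geo_method") <- geo_method
  class(out) <- c("pair_overlap_table", class(out))
  out
}
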