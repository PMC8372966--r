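# Per-layer location/scale used to put simulated layers on realistic
# native scales (degrees C, mm, PET units, meters, index units).
LAYER_MEANS <- c(BIO1 = 15, BIO5 = 28, BIO6 = 2, BIO12 = 1200, BIO16 = 500,
                 BIO17 = 120, PET.A = 1000, PET.W = 350, PET.D = 150,
                 Elev = 800, CM = 0.5, CC = 50)
LAYER_SDS <- c(BIO1 = 5, BIO5 = 5, BIO6 = 6, BIO12 = 400, BIO16 = 180,
               BIO17 = 80, PET.A = 250, PET.W = 120, PET.D = 60,
               Elev = 600, CM = 0.4, CC = 15)

#' Default cross-layer correlation matrix
#'
#' A two-factor structure: a thermal factor loading on the temperature
#' and PET layers (negatively on elevation), and a moisture factor
#' loading on the precipitation, climatic-moisture and cloud layers.
#' Positive semi-definite by construction.
#'
#' @return A 12 x 12 correlation matrix over [climate_codes()].
#' @export
default_layer_correlation <- function() {
  codes <- climate_codes()
  thermal <- c(BIO1 = 0.9, BIO5 = 0.8, BIO6 = 0.8, BIO12 = 0.1, BIO16 = 0.1,
               BIO17 = 0, PET.A = 0.7, PET.W = 0.6, PET.D = 0.6,
               Elev = -0.6, CM = -0.1, CC = 0)
  moisture <- c(BIO1 = 0, BIO5 = -0.2, BIO6 = 0.2, BIO12 = 0.8, BIO16 = 0.75,
                BIO17 = 0.6, PET.A = -0.2, PET.W = 0, PET.D = -0.3,
                Elev = 0, CM = 0.8, CC = 0.7)
  L <- cbind(thermal[codes], moisture[codes])
  S <- tcrossprod(L)
  diag(S) <- 1
  stats::cov2cor(S)
}

#' Configuration for a synthetic world
#'
#' Bundles every knob of the synthetic-data generator: the raster
#' (dimensions, geographic frame, spatial smoothing, cross-layer
#' correlation, latitudinal temperature gradient), the pure-birth
#' chronogram, the asymmetric Markov microhabitat process, the Brownian
#' niche-center model with its additive arboreal shift, and the
#' Gaussian-suitability occurrence sampler.
#'
#' @param n_species number of species (>= 2).
#' @param grid_rows,grid_cols raster dimensions.
#' @param lon_origin,lat_origin NW pixel corner, decimal degrees.
#' @param pixel_size pixel edge, arc-minutes.
#' @param smoothing_radius Gaussian smoothing radius in pixels (>= 0);
#'   induces spatial autocorrelation.
#' @param layer_correlation 12 x 12 correlation imposed across layers at
#'   co-located pixels (symmetric, unit diagonal, PSD).
#' @param temp_lat_gradient decline of BIO1 in degrees C per degree of
#'   absolute latitude.
#' @param birth_rate speciation rate of the pure-birth tree (> 0).
#' @param gain_rate,loss_rate terrestrial-to-arboreal and
#'   arboreal-to-terrestrial transition rates (>= 0).
#' @param bm_sigma per-variable Brownian rate (SD per unit sqrt-time);
#'   scalar or named length-12 vector.
#' @param arboreal_shift per-variable additive offset applied to
#'   arboreal species' niche centers; scalar or named length-12 vector.
#' @param niche_breadth per-variable positive Gaussian niche SD.
#' @param points_per_species length-2 range of occurrence counts.
#' @param tree_depth if non-`NULL`, rescale the simulated chronogram to
#'   this root-to-tip depth (useful to fix Brownian tip variance).
#' @param seed integer RNG seed; the whole world is a deterministic
#'   function of the configuration.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_species = 40,
                         grid_rows = 60, grid_cols = 60,
                         lon_origin = -100, lat_origin = 20,
                         pixel_size = 2.5,
                         smoothing_radius = 2,
                         layer_correlation = default_layer_correlation(),
                         temp_lat_gradient = 0.7,
                         birth_rate = 1,
                         gain_rate = 0.6, loss_rate = 1.8,
                         bm_sigma = LAYER_SDS / 2,
                         arboreal_shift = c(BIO1 = 2, BIO5 = 2, BIO6 = 2.7,
                                            PET.A = 64, Elev = -445),
                         niche_breadth = LAYER_SDS,
                         points_per_species = c(15, 60),
                         tree_depth = NULL,
                         seed = 1) {
  codes <- climate_codes()
  expand <- function(x, default = 0) {
    out <- rep(default, 12)
    names(out) <- codes
    if (length(x) == 1L && is.null(names(x))) out[] <- x
    else if (is.null(names(x)) && length(x) == 12L) out[] <- x
    else out[names(x)] <- x
    out
  }
  cfg <- list(n_species = n_species, grid_rows = grid_rows,
              grid_cols = grid_cols, lon_origin = lon_origin,
              lat_origin = lat_origin, pixel_size = pixel_size,
              smoothing_radius = smoothing_radius,
              layer_correlation = layer_correlation,
              temp_lat_gradient = temp_lat_gradient,
              birth_rate = birth_rate, gain_rate = gain_rate,
              loss_rate = loss_rate,
              bm_sigma = expand(bm_sigma),
              arboreal_shift = expand(arboreal_shift),
              niche_breadth = expand(niche_breadth, default = 1),
              points_per_species = points_per_species,
              tree_depth = tree_depth, seed = seed)
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  if (cfg$n_species < 2) stop("n_species must be >= 2")
  if (cfg$grid_rows < 1 || cfg$grid_cols < 1) stop("grid must be nonempty")
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  if (cfg$smoothing_radius < 0) stop("smoothing_radius must be >= 0")
  R <- cfg$layer_correlation
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-10))
    stop("layer_correlation must be symmetric with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("layer_correlation must be positive semi-definite")
  if (cfg$birth_rate <= 0) stop("birth_rate must be > 0")
  if (cfg$gain_rate < 0 || cfg$loss_rate < 0)
    stop("transition rates must be >= 0")
  if (any(cfg$bm_sigma < 0)) stop("bm_sigma must be >= 0")
  if (any(cfg$niche_breadth <= 0)) stop("niche_breadth must be > 0")
  if (any(cfg$points_per_species < 1)) stop("points_per_species must be >= 1")
  invisible(cfg)
}

# Row-normalized Gaussian smoothing operator along one axis; edge
# weights renormalize over the available neighborhood.
smoothing_matrix <- function(n, radius) {
  if (radius <= 0) return(diag(n))
  sd <- max(radius / 2, 0.5)
  d <- outer(seq_len(n), seq_len(n), "-")
  W <- exp(-0.5 * (d / sd)^2) * (abs(d) <= radius)
  W / rowSums(W)
}

#' Generate a synthetic multi-layer climate raster
#'
#' Draws correlated Gaussian fields (cross-layer correlation imposed by
#' an eigen square root of `layer_correlation` before smoothing), smooths
#' them with a Gaussian kernel to induce spatial autocorrelation,
#' rescales each layer to its native location/scale, superimposes a
#' latitudinal gradient on BIO1, and truncates elevation at zero.
#'
#' @param config a [world_config()].
#' @return A [climate_raster()]. Deterministic given `config$seed`.
#' @export
generate_climate_raster <- function(config) {
  validate_world_config(config)
  set.seed(config$seed)
  codes <- climate_codes()
  nr <- config$grid_rows
  nc <- config$grid_cols
  npix <- nr * nc
  eg <- eigen(config$layer_correlation, symmetric = TRUE)
  A <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  Z <- matrix(stats::rnorm(npix * 12L), npix, 12L) %*% A
  Sr <- smoothing_matrix(nr, config$smoothing_radius)
  Sc <- smoothing_matrix(nc, config$smoothing_radius)
  lat <- config$lat_origin - (seq_len(nr) - 0.5) * config$pixel_size / 60
  abslat <- abs(lat)
  values <- vector("list", 12L)
  names(values) <- codes
  for (j in seq_along(codes)) {
    g <- matrix(Z[, j], nr, nc)
    if (config$smoothing_radius > 0) {
      g <- Sr %*% g %*% t(Sc)
      s <- stats::sd(as.vector(g))
      if (s > 0) g <- (g - mean(g)) / s  # restore unit scale post-smoothing
    }
    v <- LAYER_MEANS[codes[j]] + LAYER_SDS[codes[j]] * g
    if (codes[j] == "BIO1" && config$temp_lat_gradient != 0)
      v <- v - config$temp_lat_gradient * (abslat - mean(abslat))
    if (codes[j] == "Elev") v <- pmax(v, 0)
    values[[j]] <- v
  }
  climate_raster(values, config$lon_origin, config$lat_origin,
                 config$pixel_size)
}

#' Simulate a pure-birth (Yule) chronogram
#'
#' Starts from the root split (two lineages), waits exponential times
#' with total rate `k * birth_rate` while `k` lineages are alive, splits
#' a uniformly chosen lineage at each event until `n_species` tips
#' exist, then cuts the tree at the next (unrealized) speciation time.
#' The expected root-to-tip depth is therefore
#' `sum(1 / (k * birth_rate))` for `k = 2, ..., n_species`.
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate (> 0).
#' @param seed optional integer seed.
#' @return An ultrametric `ape::phylo` tree with tips `s1..sn`.
#' @export
simulate_chronogram <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  parent <- c(0L, 0L)
  t_start <- c(0, 0)
  t_end <- c(NA_real_, NA_real_)
  kids <- list(NULL, NULL)
  live <- c(1L, 2L)
  t <- 0
  while (length(live) < n_species) {
    k <- length(live)
    t <- t + stats::rexp(1L, k * birth_rate)
    sp <- live[sample.int(k, 1L)]
    t_end[sp] <- t
    i1 <- length(parent) + 1L
    i2 <- i1 + 1L
    parent[c(i1, i2)] <- sp
    t_start[c(i1, i2)] <- t
    t_end[c(i1, i2)] <- NA_real_
    kids[[sp]] <- c(i1, i2)
    kids[c(i1, i2)] <- list(NULL, NULL)
    live <- c(live[live != sp], i1, i2)
  }
  t <- t + stats::rexp(1L, n_species * birth_rate)
  t_end[live] <- t

  is_tip <- vapply(kids, is.null, logical(1L))
  tip_lin <- sort(which(is_tip))
  int_lin <- sort(which(!is_tip))
  n <- length(tip_lin)
  node_of <- integer(length(parent))   # phylo node at each lineage's end
  node_of[tip_lin] <- seq_len(n)
  node_of[int_lin] <- n + 1L + seq_along(int_lin)
  root <- n + 1L
  edge <- matrix(0L, length(parent), 2L)
  elen <- numeric(length(parent))
  for (i in seq_along(parent)) {
    from <- if (parent[i] == 0L) root else node_of[parent[i]]
    edge[i, ] <- c(from, node_of[i])
    elen[i] <- t_end[i] - t_start[i]
  }
  tree <- structure(
    list(edge = edge, edge.length = elen,
         tip.label = paste0("s", seq_len(n)), Nnode = n - 1L),
    class = "phylo", order = "cladewise")
  ape::reorder.phylo(tree, "cladewise")
}

# parent lookup and preorder edge traversal helpers
tree_edges_preorder <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(edge = tree$edge, length = tree$edge.length,
       n_tip = ape::Ntip(tree), tree = tree)
}

#' Evolve binary microhabitat states along a chronogram
#'
#' Two-state Markov process (terrestrial <-> arboreal) simulated by
#' drawing each node's state from the exact transition probability of
#' the chain over the connecting branch.
#'
#' @param tree an `ape::phylo` chronogram.
#' @param gain_rate terrestrial-to-arboreal rate (>= 0).
#' @param loss_rate arboreal-to-terrestrial rate (>= 0).
#' @param root_state `"terrestrial"` or `"arboreal"`.
#' @param seed optional integer seed.
#' @return Named character vector over tips, values `"arboreal"` /
#'   `"terrestrial"`.
#' @export
assign_microhabitats <- function(tree, gain_rate, loss_rate,
                                 root_state = "terrestrial", seed = NULL) {
  if (gain_rate < 0 || loss_rate < 0) stop("transition rates must be >= 0")
  root_state <- match.arg(root_state, c("terrestrial", "arboreal"))
  if (!is.null(seed)) set.seed(seed)
  te <- tree_edges_preorder(tree)
  n <- te$n_tip
  state <- integer(n + te$tree$Nnode)  # 0 terrestrial, 1 arboreal
  state[n + 1L] <- as.integer(root_state == "arboreal")
  q <- gain_rate + loss_rate
  u <- stats::runif(nrow(te$edge))
  for (i in seq_len(nrow(te$edge))) {
    p <- state[te$edge[i, 1L]]
    len <- te$length[i]
    p_switch <- if (q == 0) 0 else {
      if (p == 0L) gain_rate / q * (1 - exp(-q * len))
      else loss_rate / q * (1 - exp(-q * len))
    }
    state[te$edge[i, 2L]] <- if (u[i] < p_switch) 1L - p else p
  }
  out <- ifelse(state[seq_len(n)] == 1L, "arboreal", "terrestrial")
  names(out) <- te$tree$tip.label
  out
}

#' Evolve multivariate niche centers by Brownian motion
#'
#' Tip values diffuse from `root_value` with per-variable rate
#' `bm_sigma` (increment SD `bm_sigma * sqrt(branch length)`); arboreal
#' tips then receive the additive `arboreal_shift`. The shift is a fixed
#' tip-level offset, which is all the downstream mean-difference tests
#' require.
#'
#' @param tree an `ape::phylo` chronogram.
#' @param labels named vector over tips, `"arboreal"`/`"terrestrial"`.
#' @param bm_sigma per-variable Brownian rate, length 12 (or scalar).
#' @param arboreal_shift per-variable additive offset, length 12 (or
#'   scalar).
#' @param root_value per-variable root state, length 12 (or scalar).
#' @param seed optional integer seed.
#' @return Matrix species x 12, rownames = tip labels.
#' @export
evolve_niche_centers <- function(tree, labels, bm_sigma, arboreal_shift = 0,
                                 root_value = 0, seed = NULL) {
  if (any(bm_sigma < 0)) stop("bm_sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  codes <- climate_codes()
  bm_sigma <- rep_len(bm_sigma, 12L)
  arboreal_shift <- rep_len(arboreal_shift, 12L)
  root_value <- rep_len(root_value, 12L)
  te <- tree_edges_preorder(tree)
  n <- te$n_tip
  vals <- matrix(0, n + te$tree$Nnode, 12L)
  vals[n + 1L, ] <- root_value
  for (i in seq_len(nrow(te$edge))) {
    inc <- stats::rnorm(12L, 0, bm_sigma * sqrt(te$length[i]))
    vals[te$edge[i, 2L], ] <- vals[te$edge[i, 1L], ] + inc
  }
  out <- vals[seq_len(n), , drop = FALSE]
  rownames(out) <- te$tree$tip.label
  colnames(out) <- codes
  arb <- names(labels)[labels == "arboreal"]
  arb <- intersect(arb, rownames(out))
  if (length(arb))
    out[arb, ] <- sweep(out[arb, , drop = FALSE], 2L, arboreal_shift, "+")
  out
}

#' Sample occurrence points from Gaussian niche suitability
#'
#' Pixel suitability is the product-Gaussian
#' `exp(-0.5 * sum(((x - center) / breadth)^2))` of the pixel climate
#' around the species' niche center (computed in log space, so a far
#' center degrades gracefully to the nearest-climate pixel). Pixels are
#' drawn with replacement proportionally to suitability and points are
#' placed at pixel centers.
#'
#' @param center length-12 niche center (named by [climate_codes()]).
#' @param niche_breadth length-12 positive niche SDs.
#' @param raster a [climate_raster()].
#' @param n_points number of points to draw (>= 1).
#' @param seed optional integer seed.
#' @return Data frame with `longitude`, `latitude`.
#' @export
sample_occurrences <- function(center, niche_breadth, raster, n_points,
                               seed = NULL) {
  if (n_points < 1) stop("n_points must be >= 1")
  if (any(niche_breadth <= 0)) stop("niche_breadth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  X <- raster_values(raster)
  center <- rep_len(center, 12L)
  niche_breadth <- rep_len(niche_breadth, 12L)
  z <- sweep(X, 2L, center)
  z <- sweep(z, 2L, niche_breadth, "/")
  logsuit <- -0.5 * rowSums(z^2)
  m <- max(logsuit)
  if (!is.finite(m))
    stop("all pixels have zero suitability: niche center lies too far ",
         "outside the raster climate")
  prob <- exp(logsuit - m)
  pick <- sample.int(length(prob), n_points, replace = TRUE, prob = prob)
  pixel_center(raster, attr(X, "row")[pick], attr(X, "col")[pick])
}

#' Generate a complete synthetic world
#'
#' Runs the whole generator: raster, chronogram (optionally rescaled to
#' `tree_depth`), microhabitat labels, Brownian niche centers rooted at
#' the raster layer means, and per-species occurrences. All sub-seeds
#' derive deterministically from `config$seed`.
#'
#' @param config a [world_config()].
#' @return List with elements `config`, `raster`, `tree`, `labels`,
#'   `centers` and `occurrences` (data frame `species`, `longitude`,
#'   `latitude`).
#' @export
simulate_world <- function(config) {
  validate_world_config(config)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 4L + config$n_species)
  raster <- generate_climate_raster(config)
  tree <- simulate_chronogram(config$n_species, config$birth_rate,
                              seed = seeds[1L])
  if (!is.null(config$tree_depth)) {
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * config$tree_depth / depth
  }
  labels <- assign_microhabitats(tree, config$gain_rate, config$loss_rate,
                                 seed = seeds[2L])
  centers <- evolve_niche_centers(tree, labels, config$bm_sigma,
                                  config$arboreal_shift,
                                  root_value = LAYER_MEANS,
                                  seed = seeds[3L])
  set.seed(seeds[4L])
  rng <- config$points_per_species
  n_pts <- sample(seq(rng[1L], rng[2L]), config$n_species, replace = TRUE)
  occ <- vector("list", config$n_species)
  for (i in seq_len(config$n_species)) {
    pts <- sample_occurrences(centers[i, ], config$niche_breadth, raster,
                              n_pts[i], seed = seeds[4L + i])
    occ[[i]] <- data.frame(species = rownames(centers)[i], pts)
  }
  list(config = config, raster = raster, tree = tree, labels = labels,
       centers = centers, occurrences = do.call(rbind, occ))
}
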