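# small FNV-1a hash of a deparsed object, for reproducibility stamps
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483648
  sprintf("%08x", as.integer(h))
}

run_meta <- function(config, seed) {
  list(seed = seed,
       version = as.character(utils::packageVersion("arboclim")),
       config_hash = config_hash(config))
}

#' Comparative climate-envelope analysis
#'
#' The full comparative pipeline: thin occurrences to one record per
#' pixel, extract climate, summarize species envelopes (five statistics
#' by twelve variables), then test microhabitat differences three ways
#' with phylogenetic RRPP ANOVAs: (i) all 60 standardized statistics
#' jointly, (ii) each of the first `n_axes` principal components, and
#' (iii) each climate variable as a five-dimensional block in native
#' units. Pairwise arboreal-terrestrial comparisons are corrected by
#' Holm sequential Bonferroni within the PC family and within the
#' 12-variable family. Optionally restricts to tropical arboreal and
#' terrestrial species and/or summarizes robustness over posterior
#' trees.
#'
#' @param occurrences data frame `species`, `longitude`, `latitude`.
#' @param raster a [climate_raster()].
#' @param tree an `ape::phylo` chronogram covering the species.
#' @param labels named character vector of microhabitat categories per
#'   species (from [classify_table()]), with arboreal `A` and
#'   terrestrial `T` the focal groups.
#' @param min_pixels comparative inclusion floor (default 3 pixels).
#' @param n_axes number of PC axes tested (default 5).
#' @param n_perm permutations per test (default 999).
#' @param family_alpha family-wise alpha for the Holm ladders.
#' @param tropical if `TRUE`, keep only A/T species whose mean
#'   occurrence latitude satisfies `|lat| <= tropical_bound`.
#' @param tropical_bound tropical latitude bound in degrees (default
#'   23.43655).
#' @param posterior_trees optional list of trees for a robustness
#'   interval on the all-statistics pairwise Z.
#' @param seed integer seed driving every permutation schedule.
#' @return List of class `comparative_report`: `summaries`, `groups`,
#'   `pca`, `fits` (all/per-axis/per-variable), `variable_table`
#'   (Variable, Z, P, Alpha), `pc_table`, `robustness`, `meta`.
#' @export
run_comparative <- function(occurrences, raster, tree, labels,
                            min_pixels = 3, n_axes = 5, n_perm = 999,
                            family_alpha = 0.05, tropical = FALSE,
                            tropical_bound = 23.43655,
                            posterior_trees = NULL, seed = 1) {
  stopifnot(n_perm >= 99, min_pixels >= 1)
  pruned <- prune_to_pixels(occurrences, raster)
  clim <- extract_climate(pruned, raster)
  summ <- summarize_species(clim, min_pixels = min_pixels)
  species <- intersect(summ$species, intersect(names(labels),
                                               tree$tip.label))
  if (tropical) {
    mean_lat <- vapply(species, function(s)
      mean(pruned$latitude[pruned$species == s]), numeric(1L))
    species <- species[abs(mean_lat) <= tropical_bound &
                         labels[species] %in% c("A", "T")]
  }
  summ <- summ[summ$species %in% species, , drop = FALSE]
  grp <- labels[summ$species]
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    message("categories with < 2 species dropped: ",
            paste(small, collapse = ", "))
    keep <- !(grp %in% small)
    summ <- summ[keep, , drop = FALSE]
    grp <- grp[keep]
  }
  if (length(unique(grp)) < 2L)
    stop("fewer than two microhabitat groups remain after filtering")
  if (!all(c("A", "T") %in% grp))
    stop("both arboreal (A) and terrestrial (T) groups are required")

  M <- summary_matrix(summ)
  groups <- factor(grp)
  names(groups) <- summ$species
  Csub <- phylo_covariance(ape::keep.tip(tree, summ$species))

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2L + n_axes + 12L)
  S <- standardize_matrix(M)
  fit_all <- rrpp_anova(S, groups, Csub, n_perm = n_perm, seed = seeds[1L])
  pw_all <- pairwise_comparisons(S, groups, Csub, n_perm = n_perm,
                                 seed = seeds[1L])
  pca <- climate_pca(S, n_axes = n_axes)
  n_axes <- ncol(pca$scores)

  at_row <- function(pw) {
    hit <- (pw$group_a == "A" & pw$group_b == "T") |
      (pw$group_a == "T" & pw$group_b == "A")
    pw[hit, , drop = FALSE]
  }

  axis_fits <- vector("list", n_axes)
  axis_pw <- vector("list", n_axes)
  for (k in seq_len(n_axes)) {
    y <- pca$scores[, k, drop = FALSE]
    axis_fits[[k]] <- rrpp_anova(y, groups, Csub, n_perm = n_perm,
                                 seed = seeds[2L + k])
    axis_pw[[k]] <- at_row(pairwise_comparisons(y, groups, Csub,
                                                n_perm = n_perm,
                                                seed = seeds[2L + k]))
  }
  codes <- climate_codes()
  var_fits <- vector("list", 12L)
  var_pw <- vector("list", 12L)
  names(var_fits) <- names(var_pw) <- codes
  for (j in seq_along(codes)) {
    ycols <- paste(codes[j], summary_stat_names(), sep = "_")
    y <- M[, ycols, drop = FALSE]
    var_fits[[j]] <- rrpp_anova(y, groups, Csub, n_perm = n_perm,
                                seed = seeds[2L + n_axes + j])
    var_pw[[j]] <- at_row(pairwise_comparisons(y, groups, Csub,
                                               n_perm = n_perm,
                                               seed = seeds[2L + n_axes + j]))
  }

  pc_p <- vapply(axis_pw, function(d) d$p, numeric(1L))
  pc_holm <- sequential_bonferroni(pc_p, family_alpha,
                                   labels = paste0("PC", seq_len(n_axes)))
  var_p <- vapply(var_pw, function(d) d$p, numeric(1L))
  var_holm <- sequential_bonferroni(var_p, family_alpha, labels = codes)

  variable_table <- rbind(
    data.frame(Variable = "All",
               Z = at_row(pw_all)$Z, P = at_row(pw_all)$p,
               Alpha = family_alpha),
    data.frame(Variable = pc_holm$label,
               Z = vapply(axis_pw, function(d) d$Z, numeric(1L)),
               P = pc_p, Alpha = round(pc_holm$alpha, 4)),
    data.frame(Variable = codes,
               Z = vapply(var_pw, function(d) d$Z, numeric(1L)),
               P = var_p, Alpha = round(var_holm$alpha, 4)))

  pc_table <- data.frame(
    axis = paste0("PC", seq_len(n_axes)),
    variance_pct = 100 * pca$variance_fraction[seq_len(n_axes)],
    overall_Z = vapply(axis_fits, function(f) f$Z, numeric(1L)),
    overall_P = vapply(axis_fits, function(f) f$p, numeric(1L)),
    pairwise_Z = vapply(axis_pw, function(d) d$Z, numeric(1L)),
    pairwise_P = pc_p,
    alpha = round(pc_holm$alpha, 4))

  robustness <- NULL
  if (!is.null(posterior_trees))
    robustness <- posterior_robustness(S, groups, posterior_trees,
                                       n_perm = n_perm, seed = seeds[2L],
                                       statistic = "pairwise",
                                       pair = c("A", "T"))

  structure(list(summaries = summ, groups = groups, pca = pca,
                 fits = list(all = fit_all, all_pairwise = pw_all,
                             axes = axis_fits, axes_pairwise = axis_pw,
                             variables = var_fits,
                             variables_pairwise = var_pw),
                 variable_table = variable_table, pc_table = pc_table,
                 holm = list(pc = pc_holm, variables = var_holm),
                 robustness = robustness,
                 meta = run_meta(list(min_pixels = min_pixels,
                                      n_axes = n_axes, n_perm = n_perm,
                                      family_alpha = family_alpha,
                                      tropical = tropical,
                                      tropical_bound = tropical_bound),
                                 seed)),
            class = "comparative_report")
}

#' @export
print.comparative_report <- function(x, ...) {
  cat("Comparative climate-envelope report\n")
  cat(sprintf("  %d species (%s)\n", length(x$groups),
              paste(sprintf("%s: %d", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  print(transform(x$variable_table, Z = round(Z, 3), P = round(P, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Ecological niche modeling analysis
#'
#' Fits a maximum-entropy suitability model for every arboreal or
#' terrestrial species with at least `enm_floor` occupied pixels
#' (background = all valid raster pixels), projects the models onto the
#' raster, assembles the pairwise overlap table with geographic and
#' phylogenetic distances, and runs the residualized pair-type test
#' separately for Schoener's D and Warren's I.
#'
#' @inheritParams run_comparative
#' @param enm_floor minimum occupied pixels per modeled species
#'   (default 15).
#' @param l2_penalty ridge penalty for [fit_maxent()].
#' @return List of class `enm_report`: `models`, `auc` (named vector),
#'   `pair_table`, `tests` (per-metric [pair_type_test()] plus
#'   regression coefficients), `group_means` (raw and residual means
#'   per pair type and metric), `meta`.
#' @export
run_enm <- function(occurrences, raster, tree, labels, enm_floor = 15,
                    n_perm = 999, l2_penalty = 0.01, seed = 1) {
  stopifnot(n_perm >= 99, enm_floor >= 1)
  pruned <- prune_to_pixels(occurrences, raster)
  clim <- extract_climate(pruned, raster)
  clim <- clim[clim$valid, , drop = FALSE]
  counts <- table(clim$species)
  eligible <- names(counts)[counts >= enm_floor]
  eligible <- eligible[eligible %in% names(labels)[labels %in% c("A", "T")]]
  eligible <- eligible[eligible %in% tree$tip.label]
  if (length(eligible) < 4L)
    stop("fewer than four species eligible for niche modeling")
  background <- raster_values(raster)
  codes <- climate_codes()
  models <- list()
  surfaces <- list()
  for (s in eligible) {
    pres <- as.matrix(clim[clim$species == s, codes, drop = FALSE])
    m <- fit_maxent(pres, background, l2_penalty = l2_penalty)
    if (!m$converged)
      warning("maxent model for ", s, " did not converge; overlap ",
              "values involving it are approximate")
    models[[s]] <- m
    surfaces[[s]] <- project_suitability(m, raster)
  }
  C <- phylo_covariance(ape::keep.tip(tree, eligible))
  pair_table <- build_pair_table(surfaces, labels[eligible], pruned, C)
  if (length(unique(pair_table$pair_type)) < 3L)
    stop("need species of both types (>= 2 each) for the pair-type test")

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2L)
  tests <- list()
  group_means <- list()
  for (metric in c("D", "I")) {
    res <- residualize_overlap(pair_table[[metric]], pair_table$geo_km,
                               pair_table$phylo_dist)
    tst <- pair_type_test(res$residuals, pair_table$pair_type,
                          n_perm = n_perm,
                          seed = seeds[match(metric, c("D", "I"))])
    tests[[metric]] <- list(regression = res$coefficients, test = tst)
    group_means[[metric]] <- data.frame(
      pair_type = names(tst$group_means),
      mean_overlap = as.vector(tapply(pair_table[[metric]],
                                      pair_table$pair_type, mean)),
      mean_residual = as.vector(tst$group_means))
  }
  structure(list(models = models,
                 auc = vapply(models, function(m) m$auc, numeric(1L)),
                 pair_table = pair_table, tests = tests,
                 group_means = group_means,
                 meta = run_meta(list(enm_floor = enm_floor,
                                      n_perm = n_perm,
                                      l2_penalty = l2_penalty), seed)),
            class = "enm_report")
}

#' @export
print.enm_report <- function(x, ...) {
  cat("Niche-overlap report\n")
  cat(sprintf("  %d models, AUC %.3f-%.3f; %d pairs\n",
              length(x$models), min(x$auc), max(x$auc),
              nrow(x$pair_table)))
  for (metric in names(x$tests)) {
    t <- x$tests[[metric]]$test
    cat(sprintf("  %s: overall Z = %.3f, p = %.4g\n", metric, t$Z, t$p))
  }
  invisible(x)
}
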