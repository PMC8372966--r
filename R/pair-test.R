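#' Regress niche overlap on geographic and phylogenetic distance
#'
#' Ordinary least squares of overlap on an intercept plus the two
#' distance covariates of each species pair; the residuals carry the
#' part of overlap not explained by proximity and are the input to
#' [pair_type_test()].
#'
#' @param overlap numeric vector of per-pair overlap values (D or I).
#' @param geo_km great-circle distances per pair.
#' @param phylo_dist phylogenetic distances per pair.
#' @return List: `coefficients` (intercept, geo_km, phylo_dist),
#'   `residuals`, `fitted`.
#' @export
residualize_overlap <- function(overlap, geo_km, phylo_dist) {
  n <- length(overlap)
  if (n < 4L) stop("need at least 4 pairs")
  X <- cbind(intercept = 1, geo_km = geo_km, phylo_dist = phylo_dist)
  kn <- kappa(X, exact = TRUE)
  if (!is.finite(kn) || kn > 1e10)
    stop("distance covariates are collinear (condition number ",
         format(kn, digits = 3), ")")
  fit <- stats::lm.fit(X, overlap)
  list(coefficients = stats::coef(fit), residuals = fit$residuals,
       fitted = fit$fitted.values)
}

#' Permutation test of residual overlap across pair types
#'
#' One-way ANOVA of the residualized overlap across the three pair
#' types (AA, AT, TT), with significance from residual randomization:
#' residual values are shuffled across pair rows (the observed
#' arrangement counts as one permutation). Also reports the three
#' pairwise mean-difference contrasts, each with its own permutation
#' distribution (statistic: absolute mean difference), and the group
#' residual means. An optional species-level mode permutes microhabitat
#' labels across species and rebuilds the pair types, respecting the
#' dependence of pairs sharing a species.
#'
#' @param residuals numeric vector of residualized overlap values.
#' @param pair_types character/factor of `AA`/`AT`/`TT` per pair; all
#'   three types must be present with >= 2 pairs each.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param mode `"row"` (default; free row shuffle) or `"species"`
#'   (label permutation; requires `species_a`, `species_b`, `labels`).
#' @param species_a,species_b,labels pair species ids and per-species
#'   A/T labels, used only in `"species"` mode.
#' @param z_cutoff significance cutoff on Z (default 1.645).
#' @return Object of class `pair_type_test`: overall `F_obs`, `Z`,
#'   `p`; `contrasts` data frame (mean difference, Z, p, significant
#'   per type pair); `group_means`; `n_perm`; `seed`; `mode`.
#' @export
pair_type_test <- function(residuals, pair_types, n_perm = 999,
                           seed = NULL, mode = c("row", "species"),
                           species_a = NULL, species_b = NULL,
                           labels = NULL, z_cutoff = 1.645) {
  mode <- match.arg(mode)
  types <- as.character(pair_types)
  need <- c("AA", "AT", "TT")
  missing <- setdiff(need, unique(types))
  if (length(missing))
    stop("pair type(s) missing: ", paste(missing, collapse = ", "))
  if (min(table(types)) < 2L) stop("every pair type needs >= 2 pairs")
  n <- length(residuals)
  types <- factor(types, levels = need)

  group_stats <- function(x, tp) {
    mns <- tapply(x, tp, mean)
    ns <- tabulate(tp)
    grand <- mean(x)
    ssb <- sum(ns * (mns - grand)^2)
    ssw <- sum((x - mns[as.integer(tp)])^2)
    list(means = mns, F = if (ssw == 0) 0 else
      (ssb / (nlevels(tp) - 1)) / (ssw / (length(x) - nlevels(tp))))
  }
  obs <- group_stats(residuals, types)
  prs <- utils::combn(need, 2L)
  d_of <- function(mns) apply(prs, 2L, function(pr)
    mns[[pr[1L]]] - mns[[pr[2L]]])
  d_obs <- d_of(obs$means)

  degenerate <- stats::var(residuals) == 0
  if (!is.null(seed)) set.seed(seed)
  F_perm <- numeric(n_perm)
  d_perm <- matrix(0, n_perm, ncol(prs))
  if (!degenerate) {
    if (mode == "species") {
      if (is.null(species_a) || is.null(species_b) || is.null(labels))
        stop("species mode needs species_a, species_b and labels")
      sp <- names(labels)
      for (i in seq_len(n_perm)) {
        lab_i <- labels[sample.int(length(labels))]
        names(lab_i) <- sp
        tp_i <- factor(paste0(pmin(lab_i[species_a], lab_i[species_b]),
                              pmax(lab_i[species_a], lab_i[species_b])),
                       levels = need)
        gs <- group_stats(residuals, tp_i)
        F_perm[i] <- gs$F
        d_perm[i, ] <- d_of(gs$means)
      }
    } else {
      for (i in seq_len(n_perm)) {
        gs <- group_stats(residuals[sample.int(n)], types)
        F_perm[i] <- gs$F
        d_perm[i, ] <- d_of(gs$means)
      }
    }
  }

  if (degenerate) {
    p <- 1
    Z <- NA_real_
    contr <- data.frame(type_a = prs[1L, ], type_b = prs[2L, ],
                        mean_diff = d_obs, Z = NA_real_, p = 1,
                        significant = FALSE)
  } else {
    stats_all <- c(obs$F, F_perm)
    p <- perm_pval(stats_all)
    Z <- effect_size_z(stats_all)
    contr <- data.frame(type_a = prs[1L, ], type_b = prs[2L, ],
                        mean_diff = d_obs, Z = NA_real_, p = NA_real_)
    for (j in seq_len(ncol(prs))) {
      da <- c(abs(d_obs[j]), abs(d_perm[, j]))
      contr$p[j] <- perm_pval(da)
      contr$Z[j] <- effect_size_z(da)
    }
    contr$significant <- !is.na(contr$Z) & contr$Z > z_cutoff
  }
  structure(list(F_obs = obs$F, Z = Z, p = p, contrasts = contr,
                 group_means = obs$means, n_perm = n_perm, seed = seed,
                 mode = mode),
            class = "pair_type_test")
}

#' @export
print.pair_type_test <- function(x, ...) {
  cat(sprintf("pair-type residual test (%s permutation): F = %.4f, Z = %.3f, p = %.4g\n",
              x$mode, x$F_obs, x$Z, x$p))
  cat("group residual means:\n")
  print(round(x$group_means, 4))
  cat("contrasts:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
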