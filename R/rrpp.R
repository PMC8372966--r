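#' GLS whitening transform
#'
#' Computes `P = C^{-1/2}` by symmetric eigen-factorization (eigenvalue
#' floor `1e-12` relative to the largest) and returns the transformed
#' pair `(PY, PX)`. Ordinary least squares on the transformed data is
#' generalized least squares on the originals under covariance `C`.
#'
#' @param Y response matrix (n x p).
#' @param X design matrix (n x k).
#' @param C n x n positive-definite covariance.
#' @return List with `Y`, `X` (transformed) and the factor `P`.
#' @export
gls_transform <- function(Y, X, C) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values))
    stop("covariance matrix is singular or nearly so; ",
         "check for near-duplicate tips (zero-length terminal branches)")
  P <- eg$vectors %*% ((1 / sqrt(eg$values)) * t(eg$vectors))
  list(Y = P %*% Y, X = P %*% X, P = P)
}

# Align Y/groups/C in a canonical (sorted) species order so permutation
# schedules are invariant to input order; falls back to given order
# when Y has no rownames.
align_species <- function(Y, groups, C) {
  Y <- as.matrix(Y)
  if (!is.null(rownames(Y))) {
    ord <- order(rownames(Y))
    Y <- Y[ord, , drop = FALSE]
    groups <- groups[ord]
    if (!is.null(C)) {
      if (!is.null(dimnames(C)[[1L]])) {
        missing <- setdiff(rownames(Y), rownames(C))
        if (length(missing))
          stop("species missing from covariance matrix: ",
               paste(missing, collapse = ", "))
        C <- C[rownames(Y), rownames(Y)]
      } else {
        C <- C[ord, ord]
      }
    }
  }
  list(Y = Y, groups = groups, C = C)
}

make_perm_index <- function(n, n_perm, seed) {
  if (!is.null(seed)) set.seed(seed)
  matrix(replicate(n_perm, sample.int(n)), nrow = n_perm, byrow = TRUE)
}

# permutation p-value with the observed statistic first; exceedance is
# counted with a small relative tolerance so that permutations
# reproducing the observed arrangement tie exactly despite
# floating-point noise
perm_pval <- function(stats_all) {
  obs <- stats_all[1L]
  mean(stats_all >= obs - 1e-8 * (abs(obs) + 1e-12))
}

# effect size of the observed statistic against its permutation
# distribution (observed included); log scale unless non-positive
# values make the log undefined
effect_size_z <- function(stats_all, z_scale = "log") {
  s <- if (z_scale == "log" && all(stats_all > 0)) log(stats_all)
  else stats_all
  sdev <- stats::sd(s)
  if (!is.finite(sdev) || sdev == 0) return(NA_real_)
  (s[1L] - mean(s)) / sdev
}

#' Phylogenetic ANOVA with randomized residual permutation
#'
#' Fits the one-factor multivariate linear model `Y ~ groups` by
#' generalized least squares under phylogenetic covariance `C`, using a
#' trace-based multivariate F statistic (sum of model sums of squares
#' over sum of residual sums of squares across responses, scaled by
#' degrees of freedom). Significance comes from randomized residual
#' permutation: rows of the reduced-model (intercept-only) residuals
#' are shuffled, added back to the reduced-model fit, and the model is
#' refit; the observed arrangement counts as one permutation. The
#' effect size `Z` standardizes the (log) observed statistic against
#' the permutation distribution.
#'
#' @param Y response matrix (species x variables), rownames = species.
#' @param groups factor (or coercible) of group labels, >= 2 groups
#'   with >= 2 members each.
#' @param C phylogenetic covariance from [phylo_covariance()], or
#'   `NULL` for ordinary (identity-covariance) ANOVA.
#' @param n_perm number of random permutations (>= 99; default 999).
#' @param seed integer seed for the permutation schedule.
#' @param z_scale `"log"` (default) or `"raw"` scale for the effect
#'   size.
#' @param perm_index optional explicit permutation schedule (matrix,
#'   one permutation of `1:n` per row) overriding `n_perm`/`seed`.
#' @return Object of class `rrpp_fit`: `F_obs`, `perm_stats` (observed
#'   first), `Z`, `p`, `coefficients` (GLS group means and pairwise
#'   contrasts), `df`, `n_perm`, `seed`.
#' @export
rrpp_anova <- function(Y, groups, C = NULL, n_perm = 999, seed = NULL,
                       z_scale = c("log", "raw"), perm_index = NULL) {
  z_scale <- match.arg(z_scale)
  groups <- droplevels(as.factor(groups))
  al <- align_species(Y, groups, C)
  Y <- al$Y
  groups <- al$groups
  C <- al$C
  n <- nrow(Y)
  g <- nlevels(groups)
  if (g < 2L) stop("need at least two groups")
  if (min(table(groups)) < 2L) stop("every group needs >= 2 members")
  if (is.null(perm_index) && n_perm < 99) stop("n_perm must be >= 99")

  Xf <- stats::model.matrix(~groups)
  Xr <- matrix(1, n, 1L)
  if (!is.null(C)) {
    tr <- gls_transform(Y, Xf, C)
    Yt <- tr$Y
    Xft <- tr$X
    Xrt <- tr$P %*% Xr
  } else {
    Yt <- Y
    Xft <- Xf
    Xrt <- Xr
  }
  Qf <- qr.Q(qr(Xft))
  Qr <- qr.Q(qr(Xrt))
  fit_F <- function(Ystar) {
    tot <- sum(Ystar^2)
    rss_r <- tot - sum(crossprod(Qr, Ystar)^2)
    rss_f <- tot - sum(crossprod(Qf, Ystar)^2)
    c(rss_r = rss_r, rss_f = rss_f)
  }
  df1 <- g - 1L
  df2 <- n - g
  obs <- fit_F(Yt)
  if (obs[["rss_r"]] <= 1e-12 * max(1, sum(Yt^2)))
    stop("response has no variation after reduced-model fit")
  if (obs[["rss_f"]] <= 1e-12 * max(1, sum(Yt^2)))
    stop("zero residual variance in the full model")
  F_of <- function(v) ((v[["rss_r"]] - v[["rss_f"]]) / df1) /
    (v[["rss_f"]] / df2)
  F_obs <- F_of(obs)

  E <- Yt - Qr %*% crossprod(Qr, Yt)     # reduced-model residuals
  Fr <- Yt - E                           # reduced-model fitted values
  if (is.null(perm_index)) perm_index <- make_perm_index(n, n_perm, seed)
  n_perm <- nrow(perm_index)
  F_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    Ystar <- Fr + E[perm_index[i, ], , drop = FALSE]
    F_perm[i] <- F_of(fit_F(Ystar))
  }
  perm_stats <- c(F_obs, F_perm)
  p <- perm_pval(perm_stats)
  Z <- effect_size_z(perm_stats, z_scale)

  # GLS group means and their pairwise contrasts
  Xm <- stats::model.matrix(~ groups - 1)
  Xmt <- if (is.null(C)) Xm else tr$P %*% Xm
  means <- qr.coef(qr(Xmt), Yt)
  rownames(means) <- levels(groups)
  pairs <- utils::combn(levels(groups), 2L)
  contrasts <- matrix(NA_real_, ncol(pairs), ncol(Yt))
  for (j in seq_len(ncol(pairs)))
    contrasts[j, ] <- means[pairs[1L, j], ] - means[pairs[2L, j], ]
  rownames(contrasts) <- apply(pairs, 2L, paste, collapse = " - ")
  colnames(contrasts) <- colnames(Y)

  structure(list(F_obs = F_obs, perm_stats = perm_stats, Z = Z, p = p,
                 coefficients = list(means = means, contrasts = contrasts),
                 df = c(df1, df2), n_perm = n_perm, seed = seed),
            class = "rrpp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rrpp_fit <- function(x, ...) {
  cat(sprintf("RRPP ANOVA: F = %.4f (df %d, %d), Z = %.3f, p = %.4g (%d permutations)\n",
              x$F_obs, x$df[1L], x$df[2L], x$Z, x$p, x$n_perm))
  invisible(x)
}

#' Pairwise group comparisons under RRPP
#'
#' The statistic for each group pair is the Euclidean distance between
#' GLS-estimated group mean vectors; the permutation schedule is the
#' same reduced-model residual shuffle as [rrpp_anova()] (so with two
#' groups and identity covariance the single pairwise test reproduces
#' the overall test's p-value). Significance flags use the one-sided
#' standard-normal convention `Z > 1.645`.
#'
#' @inheritParams rrpp_anova
#' @param z_cutoff effect-size significance cutoff (default 1.645, the
#'   one-sided standard-normal 5% critical value).
#' @return Data frame, one row per group pair: `group_a`, `group_b`,
#'   `d` (mean distance), `Z`, `p`, `significant`.
#' @export
pairwise_comparisons <- function(Y, groups, C = NULL, n_perm = 999,
                                 seed = NULL, z_scale = c("log", "raw"),
                                 perm_index = NULL, z_cutoff = 1.645) {
  z_scale <- match.arg(z_scale)
  groups <- droplevels(as.factor(groups))
  al <- align_species(Y, groups, C)
  Y <- al$Y
  groups <- al$groups
  C <- al$C
  n <- nrow(Y)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (min(table(groups)) < 2L) stop("every group needs >= 2 members")
  if (is.null(perm_index) && n_perm < 99) stop("n_perm must be >= 99")

  Xm <- stats::model.matrix(~ groups - 1)
  Xr <- matrix(1, n, 1L)
  if (!is.null(C)) {
    tr <- gls_transform(Y, Xm, C)
    Yt <- tr$Y
    Xmt <- tr$X
    Xrt <- tr$P %*% Xr
  } else {
    Yt <- Y
    Xmt <- Xm
    Xrt <- Xr
  }
  qrm <- qr(Xmt)
  Qr <- qr.Q(qr(Xrt))
  lv <- levels(groups)
  pairs <- utils::combn(seq_along(lv), 2L)
  pair_d <- function(Ystar) {
    mns <- qr.coef(qrm, Ystar)
    apply(pairs, 2L, function(pr)
      sqrt(sum((mns[pr[1L], ] - mns[pr[2L], ])^2)))
  }
  d_obs <- pair_d(Yt)
  E <- Yt - Qr %*% crossprod(Qr, Yt)
  Fr <- Yt - E
  if (is.null(perm_index)) perm_index <- make_perm_index(n, n_perm, seed)
  n_perm <- nrow(perm_index)
  d_perm <- matrix(0, n_perm, ncol(pairs))
  for (i in seq_len(n_perm))
    d_perm[i, ] <- pair_d(Fr + E[perm_index[i, ], , drop = FALSE])
  out <- data.frame(group_a = lv[pairs[1L, ]], group_b = lv[pairs[2L, ]],
                    d = d_obs, Z = NA_real_, p = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    stats_all <- c(d_obs[j], d_perm[, j])
    out$p[j] <- perm_pval(stats_all)
    out$Z[j] <- effect_size_z(stats_all, z_scale)
  }
  out$significant <- !is.na(out$Z) & out$Z > z_cutoff
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Holm sequential Bonferroni correction
#'
#' Ranks tests by ascending p-value (stable on ties), assigns the
#' rank-k adjusted alpha `family_alpha / (m - k + 1)`, and applies the
#' step-down stopping rule: the first non-significant rank blocks all
#' later ranks.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param family_alpha family-wise error rate (default 0.05).
#' @param labels optional test labels.
#' @return Data frame in input order: `label`, `p`, `rank`, `alpha`,
#'   `significant`.
#' @export
sequential_bonferroni <- function(p, family_alpha = 0.05, labels = NULL) {
  if (length(p) == 0L)
    return(data.frame(label = character(), p = numeric(),
                      rank = integer(), alpha = numeric(),
                      significant = logical()))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(labels)) labels <- paste0("test", seq_len(m))
  ord <- order(p)                      # stable: ties keep input order
  rank <- integer(m)
  rank[ord] <- seq_len(m)
  alpha <- family_alpha / (m - rank + 1)
  sig_sorted <- p[ord] <= alpha[ord]
  blocked <- cumsum(!sig_sorted) > 0   # Holm stopping
  sig_sorted <- sig_sorted & !blocked
  significant <- logical(m)
  significant[ord] <- sig_sorted
  data.frame(label = labels, p = p, rank = rank, alpha = alpha,
             significant = significant)
}

#' Robustness of the effect size to phylogenetic uncertainty
#'
#' Re-runs the RRPP test over a sample of candidate chronograms
#' (e.g. posterior trees) and summarizes the effect sizes by empirical
#' quantile interval.
#'
#' @inheritParams rrpp_anova
#' @param trees list of `ape::phylo` trees (or an `ape::multiPhylo`),
#'   each covering the analyzed species; trees missing species are
#'   skipped with a diagnostic.
#' @param statistic `"overall"` (model Z from [rrpp_anova()]) or
#'   `"pairwise"` (Z of the group pair named in `pair`).
#' @param pair length-2 character vector naming the group pair used
#'   when `statistic = "pairwise"`.
#' @param probs interval probabilities (default 2.5% and 97.5%).
#' @return List: `Z` (one per usable tree), `interval`, `n_skipped`.
#' @export
posterior_robustness <- function(Y, groups, trees, n_perm = 999,
                                 seed = NULL,
                                 statistic = c("overall", "pairwise"),
                                 pair = NULL, probs = c(0.025, 0.975)) {
  statistic <- match.arg(statistic)
  Y <- as.matrix(Y)
  species <- rownames(Y)
  if (is.null(species)) stop("Y must have species rownames")
  Z <- rep(NA_real_, length(trees))
  n_skipped <- 0L
  for (i in seq_along(trees)) {
    tree <- trees[[i]]
    if (!all(species %in% tree$tip.label)) {
      message("tree ", i, " does not cover all species; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    tree <- ape::keep.tip(tree, species)
    C <- phylo_covariance(tree)
    if (statistic == "overall") {
      Z[i] <- rrpp_anova(Y, groups, C, n_perm = n_perm, seed = seed)$Z
    } else {
      pw <- pairwise_comparisons(Y, groups, C, n_perm = n_perm,
                                 seed = seed)
      hit <- (pw$group_a == pair[1L] & pw$group_b == pair[2L]) |
        (pw$group_a == pair[2L] & pw$group_b == pair[1L])
      Z[i] <- pw$Z[hit]
    }
  }
  Zok <- Z[!is.na(Z)]
  list(Z = Z,
       interval = stats::quantile(Zok, probs, names = TRUE, type = 7),
       n_skipped = n_skipped)
}
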