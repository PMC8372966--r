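# logsumexp over a vector
lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

maxent_features <- function(X, mu, sdv) {
  Z <- sweep(sweep(as.matrix(X), 2L, mu), 2L, sdv, "/")
  out <- cbind(Z, Z^2)
  colnames(out) <- c(paste0(colnames(Z), ".l"), paste0(colnames(Z), ".q"))
  out
}

#' Fit a presence-background maximum-entropy niche model
#'
#' Models the probability that a pixel is occupied as a Gibbs
#' distribution `exp(w . f(x)) / sum_background exp(w . f(x'))` over the
#' background pixel set, with per-variable linear and quadratic
#' features standardized by the background mean and SD. Weights
#' maximize the L2-penalized average log-probability of the presence
#' pixels; the problem is convex and solved deterministically by BFGS
#' from a zero start.
#'
#' @param presence matrix of presence-pixel climates (>= 15 distinct
#'   rows), columns named by [climate_codes()] (or any consistent set).
#' @param background matrix of background-pixel climates, strictly more
#'   rows than `presence` (typically [raster_values()] of the study
#'   extent).
#' @param l2_penalty ridge penalty on the weights (default 0.01).
#' @param max_iter optimizer iteration cap.
#' @param tol convergence tolerance on the gradient norm.
#' @param init optional starting weights (defaults to zero; the optimum
#'   is start-independent up to `tol`).
#' @return Object of class `maxent_model` holding the feature
#'   standardization, weights, background log-normalizer and training
#'   metadata (`n_presence`, `converged`, `auc`, ...).
#' @export
fit_maxent <- function(presence, background, l2_penalty = 0.01,
                       max_iter = 500, tol = 1e-6, init = NULL) {
  presence <- as.matrix(presence)
  background <- as.matrix(background)
  if (nrow(presence) < 15L)
    stop("fewer than 15 presence pixels; species should be skipped ",
         "from niche modeling")
  if (nrow(background) <= nrow(presence))
    stop("background must be strictly larger than the presence set")
  if (!all(is.finite(presence)) || !all(is.finite(background)))
    stop("non-finite feature values")
  if (is.null(colnames(background)))
    colnames(background) <- paste0("V", seq_len(ncol(background)))
  if (is.null(colnames(presence)))
    colnames(presence) <- colnames(background)
  codes <- colnames(background)
  presence <- presence[, codes, drop = FALSE]
  mu <- colMeans(background)
  sdv <- apply(background, 2L, stats::sd)
  if (any(sdv == 0))
    stop("constant background variable(s): ",
         paste(codes[sdv == 0], collapse = ", "))
  Fp <- maxent_features(presence, mu, sdv)
  Fb <- maxent_features(background, mu, sdv)
  fbar <- colMeans(Fp)
  nfeat <- ncol(Fb)
  fn <- function(w) {
    eta <- drop(Fb %*% w)
    -sum(fbar * w) + lse(eta) + l2_penalty * sum(w^2)
  }
  gr <- function(w) {
    eta <- drop(Fb %*% w)
    pr <- exp(eta - lse(eta))
    -fbar + drop(crossprod(Fb, pr)) + 2 * l2_penalty * w
  }
  w0 <- if (is.null(init)) numeric(nfeat) else rep_len(init, nfeat)
  opt <- stats::optim(w0, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-15))
  # polish until the gradient norm meets tol or the budget runs out
  it <- opt$counts[["function"]]
  while (sqrt(sum(gr(opt$par)^2)) > tol && it < max_iter * 10) {
    opt2 <- stats::optim(opt$par, fn, gr, method = "BFGS",
                         control = list(maxit = max_iter, reltol = 1e-15))
    it <- it + opt2$counts[["function"]]
    if (opt2$value >= opt$value - 1e-15) {
      opt <- opt2
      break
    }
    opt <- opt2
  }
  w <- opt$par
  names(w) <- colnames(Fb)
  converged <- sqrt(sum(gr(w)^2)) <= tol
  eta_b <- drop(Fb %*% w)
  model <- structure(
    list(codes = codes, mean = mu, sd = sdv, weights = w,
         log_normalizer = lse(eta_b), n_presence = nrow(presence),
         l2_penalty = l2_penalty, iterations = it,
         converged = converged, auc = NA_real_),
    class = "maxent_model")
  model$auc <- auc_presence_background(model, presence, background)
  model
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d presences, %d features, AUC = %.3f, %sconverged\n",
    x$n_presence, length(x$weights), x$auc,
    if (x$converged) "" else "NOT "))
  invisible(x)
}

maxent_scores <- function(model, X) {
  X <- as.matrix(X)
  missing <- setdiff(model$codes, colnames(X))
  if (length(missing))
    stop("variables missing from input: ", paste(missing, collapse = ", "))
  Fx <- maxent_features(X[, model$codes, drop = FALSE], model$mean, model$sd)
  drop(Fx %*% model$weights)
}

#' Project model suitability over a raster
#'
#' Evaluates the fitted Gibbs distribution on every valid pixel and
#' normalizes so the surface sums to 1 (strictly positive on valid
#' pixels, `NA` on masked ones).
#'
#' @param model a [fit_maxent()] model.
#' @param raster a [climate_raster()] containing all training
#'   variables.
#' @return Matrix of per-pixel suitabilities (same shape as the raster
#'   grids).
#' @export
project_suitability <- function(model, raster) {
  X <- raster_values(raster)
  eta <- maxent_scores(model, X)
  s <- exp(eta - lse(eta))
  out <- matrix(NA_real_, raster$n_rows, raster$n_cols)
  out[cbind(attr(X, "row"), attr(X, "col"))] <- s
  out
}

#' Presence-background AUC
#'
#' Probability that a randomly drawn presence pixel outscores a
#' randomly drawn background pixel under the model, with ties counted
#' one half (rank / Mann-Whitney formulation).
#'
#' @param model a [fit_maxent()] model.
#' @param presence,background climate matrices (both nonempty).
#' @return AUC in `[0, 1]`.
#' @export
auc_presence_background <- function(model, presence, background) {
  if (nrow(as.matrix(presence)) == 0L || nrow(as.matrix(background)) == 0L)
    stop("presence and background sets must be nonempty")
  sp <- maxent_scores(model, presence)
  sb <- maxent_scores(model, background)
  np <- length(sp)
  nb <- length(sb)
  r <- rank(c(sp, sb))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Serialize / restore a maxent model as plain text
#'
#' Key-value text with 17-digit numeric formatting, so the round trip
#' is bit-exact.
#'
#' @param model a [fit_maxent()] model.
#' @param path file path.
#' @return `write_maxent_model` returns `path` invisibly;
#'   `read_maxent_model` returns the model.
#' @export
write_maxent_model <- function(model, path) {
  num <- function(x) paste(fmt_full(x), collapse = ",")
  lines <- c(
    paste0("codes: ", paste(model$codes, collapse = ",")),
    paste0("mean: ", num(model$mean)),
    paste0("sd: ", num(model$sd)),
    paste0("weights: ", num(model$weights)),
    paste0("log_normalizer: ", num(model$log_normalizer)),
    paste0("n_presence: ", model$n_presence),
    paste0("l2_penalty: ", num(model$l2_penalty)),
    paste0("iterations: ", model$iterations),
    paste0("converged: ", model$converged),
    paste0("auc: ", num(model$auc)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  lines <- readLines(path)
  get <- function(key) sub(paste0("^", key, ": "), "",
                           grep(paste0("^", key, ": "), lines, value = TRUE))
  nums <- function(key) as.numeric(strsplit(get(key), ",")[[1L]])
  codes <- strsplit(get("codes"), ",")[[1L]]
  named <- function(x) {
    names(x) <- codes
    x
  }
  w <- nums("weights")
  names(w) <- c(paste0(codes, ".l"), paste0(codes, ".q"))
  structure(
    list(codes = codes, mean = named(nums("mean")), sd = named(nums("sd")),
         weights = w, log_normalizer = nums("log_normalizer"),
         n_presence = as.integer(get("n_presence")),
         l2_penalty = nums("l2_penalty"),
         iterations = as.integer(get("iterations")),
         converged = as.logical(get("converged")), auc = nums("auc")),
    class = "maxent_model")
}
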