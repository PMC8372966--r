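# Independent oracles and tiny fixture builders shared across tests.

# all permutations of 1:n (n small), one per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

# classical one-way (multivariate trace) F statistic, computed from
# sums of squares directly
trace_f_oracle <- function(Y, groups) {
  Y <- as.matrix(Y)
  groups <- as.factor(groups)
  grand <- colMeans(Y)
  ssw <- 0
  ssb <- 0
  for (g in levels(groups)) {
    Yg <- Y[groups == g, , drop = FALSE]
    mg <- colMeans(Yg)
    ssw <- ssw + sum(sweep(Yg, 2L, mg)^2)
    ssb <- ssb + nrow(Yg) * sum((mg - grand)^2)
  }
  df1 <- nlevels(groups) - 1L
  df2 <- nrow(Y) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

# tiny all-valid raster with analytically simple layers
toy_raster <- function(nr = 10, nc = 10, lon0 = 0, lat0 = 10,
                       pixel_size = 30) {
  codes <- climate_codes()
  values <- lapply(seq_along(codes), function(j) {
    matrix(seq_len(nr * nc) + 100 * j, nr, nc)
  })
  names(values) <- codes
  values$Elev <- abs(values$Elev)
  climate_raster(values, lon0, lat0, pixel_size)
}

# a normalized strictly positive suitability surface
random_surface <- function(n = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n) + 0.01
  x / sum(x)
}

at_labels <- function(world) {
  stats::setNames(ifelse(world$labels == "arboreal", "A", "T"),
                  names(world$labels))
}
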