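# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# O(L^4) signed distance: per pixel, scan every opposite-class pixel.
brute_sdf <- function(px) {
  L <- nrow(px)
  fg <- which(px == 1, arr.ind = TRUE)
  bg <- which(px == 0, arr.ind = TRUE)
  out <- matrix(0, L, L)
  for (r in seq_len(L)) for (c in seq_len(L)) {
    other <- if (px[r, c] == 1) bg else fg
    d <- sqrt(min((other[, 1] - r)^2 + (other[, 2] - c)^2))
    out[r, c] <- if (px[r, c] == 1) -d else d
  }
  out
}

# Random binary image guaranteed to contain both classes.
random_shape <- function(L, p = 0.4) {
  repeat {
    px <- matrix(as.numeric(rbinom(L * L, 1, p)), L, L)
    if (sum(px) > 0 && sum(px) < L * L) return(px)
  }
}

# Explicit double-loop pairwise energy (normalised form).
brute_energy <- function(images) {
  n <- length(images)
  E <- 0
  if (n < 2) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (r in seq_len(nrow(images[[i]]))) for (c in seq_len(ncol(images[[i]]))) {
      num <- num + (images[[i]][r, c] - images[[j]][r, c])^2
      den <- den + (images[[i]][r, c] + images[[j]][r, c])^2
    }
    if (den > 0) E <- E + num / den
  }
  E
}

# Direct Bayes-rule posterior via products of univariate normal densities
# (valid only for small m, where nothing underflows).
brute_posterior <- function(Y, om, mu1, mu2, sigma2) {
  t(vapply(seq_len(nrow(Y)), function(i) {
    f1 <- prod(dnorm(Y[i, ], mu1, sqrt(sigma2)))
    f2 <- prod(dnorm(Y[i, ], mu2, sqrt(sigma2)))
    tot <- om[i, 1] * f1 + om[i, 2] * f2
    c(om[i, 1] * f1, om[i, 2] * f2) / tot
  }, numeric(2)))
}

# A modestly asymmetric leaf used wherever a realistic test shape is needed.
test_leaf <- function(L = 32) {
  generate_leaf(leaf_params(n_lobes = 5, lobe_depth = 0.35, base_radius = 0.24,
                            elongation = 1.3, serration = 0.04), L)
}
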