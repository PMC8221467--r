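# Shared fixtures, built in code.

# small 8-landmark scheme: 2 midline + 3 bilateral pairs
small_scheme <- function() {
  symmetry_scheme(pairs = cbind(c(3L, 5L, 7L), c(4L, 6L, 8L)), midline = 1:2)
}

rand_config <- function(k = 10L, id = "s1", sd = 10) {
  landmark_config(id, matrix(stats::rnorm(k * 3L, 0, sd), k, 3L))
}

# independent random rotation (used as an oracle ingredient; deliberately
# not the package's own helper)
rand_rotation <- function() {
  repeat {
    m <- matrix(stats::rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) > 0) return(q)
  }
}

# dataset of n perturbed copies of one base shape
noisy_dataset <- function(base, n, sd, transform = TRUE) {
  k <- nrow(base)
  configs <- lapply(seq_len(n), function(i) {
    x <- base + matrix(stats::rnorm(k * 3L, 0, sd), k, 3L)
    if (transform) {
      x <- exp(stats::rnorm(1, 0, 0.2)) * x %*% rand_rotation()
      x <- sweep(x, 2, stats::runif(3, -5, 5), `+`)
    }
    landmark_config(sprintf("n%02d", i), x)
  })
  shape_dataset(configs)
}

center_config_t <- function(m) sweep(m, 2, colMeans(m))

# two gaussian classes in feature space at a given Mahalanobis distance
two_class_features <- function(n_per = 50L, m = 4L, mahal = 3) {
  X <- rbind(matrix(stats::rnorm(n_per * m), n_per, m),
             matrix(stats::rnorm(n_per * m), n_per, m))
  X[seq_len(n_per), 1] <- X[seq_len(n_per), 1] + mahal
  labels <- rep(c("DANISH", "PREMED_BRITISH"), each = n_per)
  rownames(X) <- sprintf("%s_%02d", labels, sequence(c(n_per, n_per)))
  list(X = X, labels = labels)
}

# small fast simulation settings (one specimen per cell unless overridden)
small_params <- function(seed = 1L, sizes = 8L, ...) {
  gs <- matrix(as.integer(sizes), 4L, 2L,
               dimnames = list(c("EARLY_AS", "MIDDLE_AS",
                                 "PREMED_BRITISH", "DANISH"), c("F", "M")))
  simulation_params(group_sizes = gs, seed = seed, ...)
}
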