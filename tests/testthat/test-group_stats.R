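test_that("the stepwise stopping rule reads the curve literally", {
  # first strict drop below the running maximum ends the search
  expect_equal(cranmorph:::bf_select(c(60, 70, 65))$n_retained, 2L)
  # monotone non-decreasing curve retains everything
  expect_equal(cranmorph:::bf_select(c(50, 60, 60, 70))$n_retained, 4L)
  # ties extend the search but do not move the retained prefix
  expect_equal(cranmorph:::bf_select(c(60, 70, 70, 65))$n_retained, 2L)
  # a later new maximum updates the prefix
  expect_equal(cranmorph:::bf_select(c(60, 70, 70, 75, 40))$n_retained, 4L)
  expect_equal(cranmorph:::bf_select(c(80))$n_retained, 1L)
})

test_that("PC reduction retains informative leading PCs, deterministically", {
  set.seed(61)
  n_per <- 20L
  f <- gl(3, n_per)
  scores <- matrix(rnorm(3 * n_per * 10, 0, 0.5), 3 * n_per, 10)
  scores[f == 2, 1] <- scores[f == 2, 1] + 3
  scores[f == 3, 2] <- scores[f == 3, 2] + 3
  red <- baylac_friess_reduce(scores, f)
  expect_true(length(red$retained_indices) >= 2L)
  expect_true(length(red$retained_indices) <= 10L)
  expect_identical(red$retained_indices, seq_along(red$retained_indices))
  expect_true(all(red$cv_curve$cv_pct >= 0 & red$cv_curve$cv_pct <= 100))
  # deterministic: identical rerun
  red2 <- baylac_friess_reduce(scores, f)
  expect_identical(red$cv_curve, red2$cv_curve)
  expect_error(baylac_friess_reduce(scores[, 1, drop = FALSE], f), "fewer than 2")
})

test_that("Wilks MANOVA: degenerate and closed-form univariate cases", {
  # identical group means -> lambda 1, F 0 (second group is the first
  # point-reflected through its mean: same mean, full-rank scatter)
  set.seed(60)
  G1 <- matrix(rnorm(15), 5, 3)
  G2 <- sweep(-G1, 2, 2 * colMeans(G1), `+`)
  X <- rbind(G1, G2)
  f <- rep(c("a", "b"), each = 5)
  w <- suppressWarnings(wilks_manova(X, f))
  expect_equal(w$lambda, 1, tolerance = 1e-12)
  expect_equal(w$F, 0, tolerance = 1e-12)

  # one feature: lambda = SSW/SST and F equals one-way ANOVA exactly
  set.seed(62)
  y <- rnorm(30) + rep(c(0, 1, 2), each = 10)
  g <- gl(3, 10)
  w1 <- wilks_manova(matrix(y), g)
  a <- anova(stats::aov(y ~ g))
  expect_equal(w1$F, a[["F value"]][1], tolerance = 1e-10)
  expect_equal(w1$p, a[["Pr(>F)"]][1], tolerance = 1e-10)
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  sst <- sum((y - mean(y))^2)
  expect_equal(w1$lambda, ssw / sst, tolerance = 1e-12)
})

test_that("Wilks lambda and its F approximation match independent oracles", {
  set.seed(63)
  X <- matrix(rnorm(45 * 4), 45, 4)
  f <- gl(3, 15)
  X[f == 2, 1] <- X[f == 2, 1] + 1
  w <- wilks_manova(X, f)

  # determinant-ratio oracle with explicitly looped SSCP matrices
  m <- ncol(X)
  W <- matrix(0, m, m)
  for (lev in levels(f)) {
    sub <- X[f == lev, , drop = FALSE]
    dev <- sweep(sub, 2, colMeans(sub))
    for (i in seq_len(nrow(dev))) W <- W + tcrossprod(dev[i, ])
  }
  Tm <- matrix(0, m, m)
  dev <- sweep(X, 2, colMeans(X))
  for (i in seq_len(nrow(dev))) Tm <- Tm + tcrossprod(dev[i, ])
  expect_equal(w$lambda, det(W) / det(Tm), tolerance = 1e-10)

  # full F approximation against the reference implementation in stats
  sm <- summary(stats::manova(X ~ f), test = "Wilks")$stats
  expect_equal(w$lambda, sm[1, 2], tolerance = 1e-10)
  expect_equal(w$F, sm[1, 3], tolerance = 1e-10)
  expect_equal(w$df1, unname(sm[1, 4]))
  expect_equal(w$df2, unname(sm[1, 5]), tolerance = 1e-10)
  expect_equal(w$p, sm[1, 6], tolerance = 1e-10)

  # partial eta squared from Rao's exponent
  s <- sqrt((16 * 4 - 4) / (16 + 4 - 5))
  expect_equal(w$partial_eta_sq, 1 - w$lambda^(1 / s), tolerance = 1e-12)
})

test_that("pairwise MANOVAs cover requested pairs on a shared feature space", {
  set.seed(64)
  X <- matrix(rnorm(48 * 3), 48, 3)
  f <- gl(4, 12, labels = c("EARLY_AS", "MIDDLE_AS", "PREMED_BRITISH", "DANISH"))
  pw <- pairwise_manova(X, f)
  expect_equal(nrow(pw$table), 6L)

  pairs <- list(c("DANISH", "PREMED_BRITISH"), c("EARLY_AS", "DANISH"))
  pw2 <- pairwise_manova(X, f, pairs = pairs)
  expect_equal(pw2$table$group1, c("DANISH", "EARLY_AS"))
  expect_equal(pw2$table$group2, c("PREMED_BRITISH", "DANISH"))
  # a pair computed directly agrees
  idx <- f %in% pairs[[1]]
  expect_equal(pw2$results[[1]]$lambda, wilks_manova(X[idx, ], f[idx])$lambda)

  expect_error(pairwise_manova(X, f, pairs = list(c("DANISH", "SAXONS"))),
               "unknown group")

  pw3 <- pairwise_manova(X, f, p_adjust = "holm")
  expect_true(all(pw3$table$p_adj >= pw3$table$p))
})

test_that("relabelling one sample half-and-half gives a calibrated null", {
  # identical groups by construction: p approximately uniform, lambda near 1
  set.seed(65)
  n <- 40L
  reps <- 500L
  pvals <- numeric(reps)
  lambdas <- numeric(reps)
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(n * 3), n, 3)
    f <- sample(rep(c("g1", "g2"), each = n / 2))
    w <- wilks_manova(X, f)
    pvals[r] <- w$p
    lambdas[r] <- w$lambda
  }
  expect_gt(mean(lambdas), 0.8)
  rej <- sum(pvals < 0.05)
  bounds <- stats::qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(rej, bounds[1])
  expect_lte(rej, bounds[2])
})
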