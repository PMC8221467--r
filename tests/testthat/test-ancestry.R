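test_that("two-source LDA separates what is separable and not what is not", {
  set.seed(71)
  well <- two_class_features(n_per = 50, m = 4, mahal = 6)
  fit <- fit_lda(well$X, well$labels)
  expect_gte(fit$loocv_accuracy, 0.95)
  expect_identical(fit$classes, c("DANISH", "PREMED_BRITISH"))
  expect_true(isSymmetric(fit$pooled_covariance))
  expect_true(all(eigen(fit$pooled_covariance, only.values = TRUE)$values > 0))

  none <- two_class_features(n_per = 50, m = 4, mahal = 0)
  fit0 <- fit_lda(none$X, none$labels)
  expect_lt(abs(fit0$loocv_accuracy - 0.5), 0.2)

  expect_error(fit_lda(well$X, rep(c("a", "b", "c"), length.out = 100)),
               "exactly 2")
  suppressWarnings(
    expect_error(fit_lda(matrix(rnorm(4 * 10), 4, 10), rep(c("a", "b"), 2)),
                 "singular"))
})

test_that("posteriors follow the linear discriminant closed form", {
  set.seed(72)
  d <- two_class_features(n_per = 40, m = 3, mahal = 8)
  fit <- fit_lda(d$X, d$labels)

  # the midpoint of the class means scores (0.5, 0.5) under equal priors
  mid <- (fit$class_means[1, ] + fit$class_means[2, ]) / 2
  p_mid <- predict_posteriors(fit, matrix(mid, 1))
  expect_equal(as.numeric(p_mid), c(0.5, 0.5), tolerance = 1e-9)

  # a point at a class mean of two distant classes is all but certain
  p_at <- predict_posteriors(fit, fit$class_means)
  expect_gt(p_at[1, 1], 0.99)
  expect_gt(p_at[2, 2], 0.99)
  expect_equal(rowSums(p_at), c(1, 1), tolerance = 1e-9, ignore_attr = TRUE)

  # one feature: the decision boundary is the midpoint of the class means
  X1 <- matrix(c(rnorm(20, 0), rnorm(20, 4)))
  f1 <- rep(c("DANISH", "PREMED_BRITISH"), each = 20)
  fit1 <- fit_lda(X1, f1)
  m1 <- mean(fit1$class_means)
  eps <- 1e-6
  below <- predict_posteriors(fit1, matrix(m1 - eps))
  above <- predict_posteriors(fit1, matrix(m1 + eps))
  expect_true(which.max(below) != which.max(above))

  expect_error(predict_posteriors(fit, matrix(0, 1, 5)), "dimension")
})

test_that("posteriors are invariant under invertible linear transforms", {
  set.seed(73)
  d <- two_class_features(n_per = 30, m = 4, mahal = 3)
  fit <- fit_lda(d$X, d$labels)
  test_pts <- matrix(rnorm(10 * 4), 10, 4)
  ref <- predict_posteriors(fit, test_pts)
  for (rep in 1:20) {
    M <- matrix(rnorm(16), 4, 4)
    while (abs(det(M)) < 0.1) M <- matrix(rnorm(16), 4, 4)
    fit2 <- fit_lda(d$X %*% M, d$labels)
    p2 <- predict_posteriors(fit2, test_pts %*% M)
    expect_equal(p2, ref, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("posteriors agree with the reference LDA implementation", {
  set.seed(74)
  d <- two_class_features(n_per = 35, m = 3, mahal = 2.5)
  fit <- fit_lda(d$X, d$labels)
  test_pts <- matrix(rnorm(15 * 3), 15, 3)
  ours <- predict_posteriors(fit, test_pts)
  ref <- MASS::lda(d$X, grouping = d$labels, prior = c(0.5, 0.5))
  theirs <- predict(ref, test_pts)$posterior
  expect_equal(ours[, colnames(theirs)], theirs,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the posterior threshold rule attributes or abstains", {
  post <- rbind(c(0.63, 0.37), c(0.55, 0.45), c(0.54, 0.46), c(0.20, 0.80))
  colnames(post) <- c("DANISH", "PREMED_BRITISH")
  lab <- attribute_posterior(post)
  expect_identical(lab, c("DANISH", "DANISH", "UNATTRIBUTABLE", "PREMED_BRITISH"))
  expect_identical(attribute_posterior(post, threshold = 0.75),
                   c("UNATTRIBUTABLE", "UNATTRIBUTABLE", "UNATTRIBUTABLE",
                     "PREMED_BRITISH"))
  expect_error(attribute_posterior(c(0.7, 0.4)), "sum to 1")
  expect_error(attribute_posterior(post, threshold = 0.4), "threshold")
})

test_that("group summaries compute percentages and mean posteriors", {
  # 27 individuals split 17 / 7 / 3
  lab <- c(rep("DANISH", 17), rep("PREMED_BRITISH", 7), rep("UNATTRIBUTABLE", 3))
  post_d <- c(rep(0.8, 17), rep(0.2, 7), rep(0.52, 3))
  att <- data.frame(specimen_id = sprintf("e%02d", 1:27),
                    DANISH = post_d, PREMED_BRITISH = 1 - post_d,
                    label = lab, check.names = FALSE)
  rep_ <- summarize_attribution(att, target_group = "EARLY_AS")
  expect_equal(unname(rep_$pct["DANISH"]), 100 * 17 / 27)
  expect_equal(unname(rep_$pct["PREMED_BRITISH"]), 100 * 7 / 27)
  expect_equal(unname(rep_$pct["UNATTRIBUTABLE"]), 100 * 3 / 27)
  expect_equal(round(unname(rep_$pct[c("DANISH", "PREMED_BRITISH",
                                       "UNATTRIBUTABLE")])),
               c(63, 26, 11))
  expect_equal(sum(rep_$pct), 100, tolerance = 1e-9)
  expect_equal(unname(rep_$mean_posterior["DANISH"]), mean(post_d))

  # all unattributable
  att2 <- att
  att2$label <- "UNATTRIBUTABLE"
  rep2 <- summarize_attribution(att2)
  expect_equal(unname(rep2$pct[c("DANISH", "PREMED_BRITISH", "UNATTRIBUTABLE")]),
               c(0, 0, 100))

  # mean posteriors are plain arithmetic means
  att3 <- data.frame(specimen_id = c("a", "b"),
                     DANISH = c(0.9, 0.5), PREMED_BRITISH = c(0.1, 0.5),
                     label = c("DANISH", "UNATTRIBUTABLE"), check.names = FALSE)
  rep3 <- summarize_attribution(att3)
  expect_equal(unname(rep3$mean_posterior), c(0.7, 0.3))
})

test_that("mean-posterior mixture estimates are nearly unbiased when sources separate", {
  # two gaussian sources at LOOCV ~ 0.9 separation; targets drawn as a
  # 0.65 : 0.35 mixture; the mean posterior estimates the mixing fraction
  set.seed(75)
  biases <- numeric(20)
  agree_strong <- numeric(10)
  agree_weak <- numeric(10)
  for (s in 1:20) {
    src <- two_class_features(n_per = 50, m = 4, mahal = 2.6)
    fit <- fit_lda(src$X, src$labels)
    n_t <- 40L
    origin <- stats::rbinom(n_t, 1, 0.65)   # 1 = danish-derived
    Xt <- matrix(rnorm(n_t * 4), n_t, 4)
    Xt[, 1] <- Xt[, 1] + ifelse(origin == 1, 2.6, 0)
    post <- predict_posteriors(fit, Xt)
    est <- mean(post[, "DANISH"])
    biases[s] <- est - mean(origin)
    if (s <= 10) {
      hard <- mean(attribute_posterior(post) == "DANISH")
      agree_strong[s] <- abs(100 * est - 100 * hard)
    }
  }
  expect_lte(abs(mean(biases)), 0.10)
  expect_lte(max(abs(biases)), 0.15)

  # weak separation: hard attribution and mean posterior diverge more
  for (s in 1:10) {
    src <- two_class_features(n_per = 50, m = 4, mahal = 0.8)
    fit <- fit_lda(src$X, src$labels)
    n_t <- 40L
    origin <- stats::rbinom(n_t, 1, 0.65)
    Xt <- matrix(rnorm(n_t * 4), n_t, 4)
    Xt[, 1] <- Xt[, 1] + ifelse(origin == 1, 0.8, 0)
    post <- predict_posteriors(fit, Xt)
    hard <- mean(attribute_posterior(post) == "DANISH")
    agree_weak[s] <- abs(100 * mean(post[, "DANISH"]) - 100 * hard)
  }
  expect_lte(mean(agree_strong), 15)
  expect_gt(mean(agree_weak), mean(agree_strong))
})
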