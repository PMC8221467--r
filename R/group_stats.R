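# Group comparison: stepwise cross-validated PC reduction and MANOVA on
# the retained PCs.

# --- pooled-covariance linear discriminant internals --------------------
# Multi-class Gaussian discriminant with shared covariance, used both by
# the PC-reduction cross-validation and by the ancestry module.

lda_core_fit <- function(X, f, priors = NULL) {
  X <- as.matrix(X)
  f <- droplevels(factor(f))
  g <- nlevels(f); n <- nrow(X); m <- ncol(X)
  counts <- as.vector(table(f))
  if (any(counts < 2L)) stop_cm("every class needs at least 2 observations")
  if (n - g < m) {
    stop_cm("pooled covariance is singular (n - g < m); ",
            "reduce the feature dimension first")
  }
  means <- rowsum(X, f) / counts
  S <- crossprod(X - means[f, , drop = FALSE]) / (n - g)
  priors <- priors %||% rep(1 / g, g)
  if (length(priors) != g || any(priors < 0)) stop_cm("invalid priors")
  priors <- priors / sum(priors)
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) {
    stop_cm("pooled covariance is singular; reduce the feature dimension first")
  })
  list(means = means, cov = S, cov_inv = Sinv, priors = priors,
       classes = levels(f), counts = counts)
}

# Linear discriminant scores delta_c(x); posteriors by softmax.
lda_core_posterior <- function(fit, newX) {
  newX <- as.matrix(newX)
  if (ncol(newX) != ncol(fit$means)) {
    stop_cm("feature dimension (", ncol(newX), ") does not match model (",
            ncol(fit$means), ")")
  }
  Sinv <- fit$cov_inv
  lin <- newX %*% Sinv %*% t(fit$means)
  const <- -0.5 * rowSums((fit$means %*% Sinv) * fit$means) + log(fit$priors)
  delta <- sweep(lin, 2, const, `+`)
  delta <- delta - apply(delta, 1, max)
  p <- exp(delta)
  p <- p / rowSums(p)
  colnames(p) <- fit$classes
  rownames(p) <- rownames(newX)
  p
}

lda_core_classify <- function(fit, newX) {
  p <- lda_core_posterior(fit, newX)
  factor(fit$classes[max.col(p, ties.method = "first")], levels = fit$classes)
}

# Leave-one-out cross-validated correct-classification percentage.
# Deterministic for a fixed row order (and independent of it in fact).
lda_loocv <- function(X, f, priors = NULL) {
  X <- as.matrix(X)
  f <- droplevels(factor(f))
  n <- nrow(X)
  pred <- character(n)
  post <- matrix(NA_real_, n, nlevels(f), dimnames = list(rownames(X), levels(f)))
  for (i in seq_len(n)) {
    fit <- lda_core_fit(X[-i, , drop = FALSE], f[-i], priors = priors)
    p <- lda_core_posterior(fit, X[i, , drop = FALSE])
    post[i, colnames(p)] <- p
    pred[i] <- colnames(p)[which.max(p)]
  }
  list(accuracy = mean(pred == as.character(f)),
       predicted = factor(pred, levels = levels(f)),
       posteriors = post)
}

# --- stepwise PC reduction ---------------------------------------------

# Stopping rule on a vector of cross-validation percentages: scan in
# order, track the running maximum, stop at the first strict drop below
# it (ties extend the search); retain the prefix achieving the maximum
# (earliest index if attained more than once).
bf_select <- function(pcts) {
  stopifnot(length(pcts) >= 1L)
  best <- pcts[1]; best_at <- 1L
  for (j in seq_along(pcts)[-1]) {
    if (pcts[j] < best) return(list(n_retained = best_at, stopped_at = j))
    if (pcts[j] > best) { best <- pcts[j]; best_at <- j }
  }
  list(n_retained = best_at, stopped_at = length(pcts))
}

#' Stepwise cross-validated PC reduction (Baylac-Friess)
#'
#' Progressively adds variance-ordered principal components to a
#' leave-one-out cross-validated linear discriminant classification over
#' the supplied group labels, and stops as soon as the cross-validation
#' percentage drops below its running maximum; the retained set is the
#' prefix of PCs that achieved the maximum.  The procedure discards
#' low-variance noise dimensions while keeping group-relevant shape
#' information when coordinates far outnumber specimens.
#'
#' @param pca a [shape_pca()] result (or a score matrix with columns in
#'   decreasing variance order).
#' @param labels group labels used for the cross-validation (all groups
#'   present enter the classifier, with equal priors).
#' @param max_pcs optional cap on the number of PCs scanned; defaults to
#'   all PCs compatible with a non-singular pooled covariance.
#' @return object of class `pc_reduction`: `retained_indices`, `cv_curve`
#'   (data.frame `n_pcs`, `cv_pct`), `retained_variance_fraction`.
#' @export
baylac_friess_reduce <- function(pca, labels, max_pcs = NULL) {
  scores <- if (inherits(pca, "shape_pca")) pca$scores else as.matrix(pca)
  f <- droplevels(factor(labels))
  if (nlevels(f) < 2L) stop_cm("PC reduction needs at least 2 groups")
  n <- nrow(scores); g <- nlevels(f)
  limit <- min(ncol(scores), n - g - 1L, max_pcs %||% Inf)
  if (limit < 2L) stop_cm("fewer than 2 usable PCs")
  pcts <- numeric(0)
  best <- -Inf
  for (j in seq_len(limit)) {
    pcts[j] <- 100 * lda_loocv(scores[, seq_len(j), drop = FALSE], f)$accuracy
    if (pcts[j] < best) break
    if (pcts[j] > best) best <- pcts[j]
  }
  sel <- bf_select(pcts)
  retained <- seq_len(sel$n_retained)
  vf <- if (inherits(pca, "shape_pca")) {
    sum(pca$variance_fractions[retained])
  } else {
    NA_real_
  }
  structure(list(retained_indices = retained,
                 cv_curve = data.frame(n_pcs = seq_along(pcts), cv_pct = pcts),
                 retained_variance_fraction = vf),
            class = "pc_reduction")
}

#' @export
print.pc_reduction <- function(x, ...) {
  cat("Stepwise PC reduction: retained ", length(x$retained_indices),
      " PCs (cross-validation ",
      sprintf("%.1f%%", x$cv_curve$cv_pct[length(x$retained_indices)]), ")\n",
      sep = "")
  if (!is.na(x$retained_variance_fraction)) {
    cat("  variance retained: ",
        sprintf("%.1f%%", 100 * x$retained_variance_fraction), "\n", sep = "")
  }
  invisible(x)
}

# --- Wilks MANOVA -------------------------------------------------------

#' MANOVA via Wilks' lambda with Rao's F approximation
#'
#' Computes lambda = det(W) / det(W + B) from the within- and between-group
#' sums-of-squares-and-cross-products matrices, Rao's F approximation with
#' its degrees of freedom, and the multivariate partial eta squared
#' `1 - lambda^(1/s)` where `s` is Rao's exponent.
#'
#' @param features n x m numeric matrix (rows = specimens).
#' @param labels group labels, at least 2 groups.
#' @return object of class `wilks_manova` with `lambda`, `F`, `df1`, `df2`,
#'   `p`, `partial_eta_sq`, `n`, `m`, `g`.
#' @export
wilks_manova <- function(features, labels) {
  X <- as.matrix(features)
  f <- droplevels(factor(labels))
  n <- nrow(X); m <- ncol(X); g <- nlevels(f)
  if (g < 2L) stop_cm("MANOVA needs at least 2 groups")
  if (length(f) != n) stop_cm("labels length must match rows of features")
  if (n - g <= m) {
    warning("error degrees of freedom (n - g = ", n - g,
            ") do not exceed the number of variables (", m,
            "); the test is unreliable", call. = FALSE)
  }
  counts <- as.vector(table(f))
  means <- rowsum(X, f) / counts
  W <- crossprod(X - means[f, , drop = FALSE])
  gm <- colMeans(X)
  Bd <- sweep(means, 2, gm)
  B <- crossprod(Bd * sqrt(counts))
  T <- W + B
  det_T <- det(T)
  if (!is.finite(det_T) || det_T <= 0) stop_cm("singular total scatter matrix")
  lambda <- det(W) / det_T
  lambda <- min(max(lambda, 0), 1)

  p_ <- m; q_ <- g - 1L
  s <- if (p_^2 + q_^2 - 5 > 0) sqrt((p_^2 * q_^2 - 4) / (p_^2 + q_^2 - 5)) else 1
  t_ <- (n - 1) - (p_ + q_ + 1) / 2
  df1 <- p_ * q_
  df2 <- t_ * s - p_ * q_ / 2 + 1
  lam_s <- lambda^(1 / s)
  Fstat <- if (lam_s > 0) (1 - lam_s) / lam_s * df2 / df1 else Inf
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2,
                 p = pval, partial_eta_sq = 1 - lam_s,
                 n = n, m = m, g = g),
            class = "wilks_manova")
}

#' @export
print.wilks_manova <- function(x, ...) {
  cat(sprintf(
    "Wilks MANOVA: lambda = %.3f, F(%d, %.1f) = %.3f, p = %.4g, partial eta^2 = %.2f\n",
    x$lambda, x$df1, x$df2, x$F, x$p, x$partial_eta_sq))
  invisible(x)
}

#' Pairwise MANOVAs on a shared feature space
#'
#' Runs [wilks_manova()] for each requested pair of groups on the same
#' (retained-PC) feature matrix used for the overall test.  No
#' multiple-testing correction is applied by default; Holm or Bonferroni
#' adjustment of the p values is available.
#'
#' @param features n x m numeric matrix.
#' @param labels group labels.
#' @param pairs list of length-2 character vectors; defaults to all
#'   unordered pairs of the observed groups.
#' @param p_adjust `"none"` (default), `"holm"`, or `"bonferroni"`.
#' @return object of class `pairwise_manova`: a data.frame `table` with one
#'   row per pair and a list `results` of `wilks_manova` objects.
#' @export
pairwise_manova <- function(features, labels, pairs = NULL,
                            p_adjust = c("none", "holm", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  f <- droplevels(factor(labels))
  X <- as.matrix(features)
  if (is.null(pairs)) {
    cmb <- utils::combn(levels(f), 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  results <- lapply(pairs, function(pr) {
    if (length(pr) != 2L) stop_cm("each pair must name exactly 2 groups")
    missing <- setdiff(pr, levels(f))
    if (length(missing)) stop_cm("unknown group in pair: ", paste(missing, collapse = ", "))
    idx <- f %in% pr
    wilks_manova(X[idx, , drop = FALSE], f[idx])
  })
  tab <- data.frame(
    group1 = vapply(pairs, `[[`, character(1), 1L),
    group2 = vapply(pairs, `[[`, character(1), 2L),
    lambda = vapply(results, `[[`, numeric(1), "lambda"),
    F = vapply(results, `[[`, numeric(1), "F"),
    df1 = vapply(results, `[[`, numeric(1), "df1"),
    df2 = vapply(results, `[[`, numeric(1), "df2"),
    p = vapply(results, `[[`, numeric(1), "p"),
    partial_eta_sq = vapply(results, `[[`, numeric(1), "partial_eta_sq"),
    stringsAsFactors = FALSE
  )
  if (p_adjust != "none") tab$p_adj <- stats::p.adjust(tab$p, method = p_adjust)
  structure(list(table = tab, results = results), class = "pairwise_manova")
}

#' @export
print.pairwise_manova <- function(x, ...) {
  cat("Pairwise MANOVAs (Wilks):\n")
  tab <- x$table
  tab$lambda <- sprintf("%.3f", tab$lambda)
  tab$F <- sprintf("%.3f", tab$F)
  tab$df2 <- sprintf("%.1f", tab$df2)
  tab$p <- format.pval(x$table$p, digits = 3)
  tab$partial_eta_sq <- sprintf("%.2f", x$table$partial_eta_sq)
  print(tab, row.names = FALSE)
  invisible(x)
}
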