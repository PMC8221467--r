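# Ordination: PCA of symmetrized Procrustes coordinates and canonical
# variates analysis among groups.

features_of <- function(x) {
  if (inherits(x, "shape_dataset")) flatten_coords(x)
  else if (inherits(x, "gpa")) flatten_coords(x$aligned)
  else if (inherits(x, "shape_pca")) x$scores
  else as.matrix(x)
}

#' Principal components analysis of shape coordinates
#'
#' Eigendecomposition of the covariance of the flattened (n x 3k)
#' coordinate matrix.  Components with eigenvalues below `1e-12` of the
#' largest are treated as the null space left by superimposition and
#' symmetrization and are dropped, so the retained variance fractions sum
#' to one.
#'
#' @param x a symmetrized/aligned [shape_dataset()], a [gpa()] result, or a
#'   numeric matrix (rows = specimens).
#' @param tangent if `TRUE`, orthogonally project the centred data out of
#'   the mean-shape direction before the decomposition (tangent-space
#'   projection).  Off by default: shape variation in these applications is
#'   small enough that the Procrustes coordinates are used directly, the
#'   only effect of the projection being the removal of one near-null
#'   curvature dimension.
#' @return an object of class `shape_pca` with `scores` (n x m),
#'   `components` (m x p, orthonormal rows), `variance_fractions`,
#'   `eigenvalues`, and `mean_vector`.
#' @export
shape_pca <- function(x, tangent = FALSE) {
  X <- features_of(x)
  n <- nrow(X)
  if (n < 3L) stop_cm("PCA needs at least 3 specimens")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (tangent) {
    mhat <- mu / sqrt(sum(mu^2))
    Xc <- Xc - (Xc %*% mhat) %*% t(mhat)
  }
  s <- svd(Xc)
  ev <- s$d^2 / (n - 1)
  keep <- ev > max(ev) * 1e-12
  m <- sum(keep)
  scores <- s$u[, keep, drop = FALSE] %*% diag(s$d[keep], m, m)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(m))
  components <- t(s$v[, keep, drop = FALSE])
  rownames(components) <- colnames(scores)
  colnames(components) <- colnames(X)
  structure(list(scores = scores,
                 components = components,
                 eigenvalues = ev[keep],
                 variance_fractions = ev[keep] / sum(ev[keep]),
                 mean_vector = mu),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- length(x$variance_fractions)
  cat("Shape PCA: ", nrow(x$scores), " specimens, ", m, " components\n", sep = "")
  shown <- utils::head(x$variance_fractions, 5)
  cat("  variance fractions: ",
      paste(sprintf("%.3f", shown), collapse = " "),
      if (m > 5) " ...", "\n", sep = "")
  invisible(x)
}

#' Canonical variates analysis
#'
#' Finds the axes maximizing between-group relative to pooled within-group
#' variance.  Because shape data typically have many more coordinates than
#' specimens, the features are first projected onto the principal
#' components spanning their non-null variance (relative eigenvalue
#' > 1e-12) and the within/between eigenproblem is solved there.  The
#' within-group scatter is pooled with divisor n - g.  Canonical vectors
#' are scaled to unit within-group variance, and each axis is oriented so
#' that its largest-magnitude loading is positive.
#'
#' @param features an n x m matrix (or a `shape_dataset` / `shape_pca`).
#' @param labels group labels, length n; at least 2 groups with >= 2
#'   members each.
#' @return an object of class `cva`: `cv_scores` (n x (g-1)),
#'   `cv_variance_fractions`, `group_means_cv`, `eigenvalues`,
#'   `coefficients` (feature-space loadings), `groups`.
#' @export
cva <- function(features, labels) {
  X <- features_of(features)
  f <- factor(labels)
  f <- droplevels(f)
  if (nlevels(f) < 2L) stop_cm("CVA needs at least 2 groups")
  if (any(table(f) < 2L)) stop_cm("every group needs at least 2 members")
  n <- nrow(X); g <- nlevels(f)
  if (length(f) != n) stop_cm("labels length must match rows of features")

  # rank guard: project onto the non-null PC subspace
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc)
  ev <- s$d^2
  keep <- which(ev > max(ev) * 1e-12)
  # the pooled within-group scatter has n - g degrees of freedom, so at
  # most n - g dimensions are usable
  if (length(keep) > n - g) keep <- keep[seq_len(n - g)]
  V <- s$v[, keep, drop = FALSE]
  Z <- Xc %*% V
  m <- ncol(Z)

  means <- rowsum(Z, f) / as.vector(table(f))
  W <- crossprod(Z - means[f, , drop = FALSE]) / (n - g)
  counts <- as.vector(table(f))
  gm <- colMeans(Z)
  Bd <- sweep(means, 2, gm)
  B <- crossprod(Bd * sqrt(counts))

  U <- tryCatch(chol(W), error = function(e) {
    stop_cm("within-group scatter is singular; reduce the feature ",
            "dimension (e.g. retain fewer PCs) before CVA")
  })
  M <- backsolve(U, t(backsolve(U, t(B), transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  ncv <- min(g - 1L, m)
  lambda <- pmax(eig$values[seq_len(ncv)], 0)
  A <- backsolve(U, eig$vectors[, seq_len(ncv), drop = FALSE])

  # loadings back in the original feature space; sign convention
  coef <- V %*% A
  for (j in seq_len(ncv)) {
    i_max <- which.max(abs(coef[, j]))
    if (coef[i_max, j] < 0) {
      coef[, j] <- -coef[, j]
      A[, j] <- -A[, j]
    }
  }
  scores <- Z %*% A
  colnames(scores) <- paste0("CV", seq_len(ncv))
  rownames(scores) <- rownames(X)
  gmeans <- rowsum(scores, f) / counts
  structure(list(cv_scores = scores,
                 cv_variance_fractions = if (sum(lambda) > 0) lambda / sum(lambda)
                                         else rep(NA_real_, ncv),
                 group_means_cv = gmeans,
                 eigenvalues = lambda,
                 coefficients = coef,
                 groups = f),
            class = "cva")
}

#' @export
print.cva <- function(x, ...) {
  ncv <- ncol(x$cv_scores)
  cat("Canonical variates analysis: ", nlevels(x$groups), " groups, ",
      ncv, " canonical variates\n", sep = "")
  cat("  variance fractions: ",
      paste(sprintf("%.1f%%", 100 * x$cv_variance_fractions), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Scatter plot of canonical variate scores
#'
#' @param x a [cva()] result.
#' @param axes length-2 integer vector of canonical variates to plot.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot.cva <- function(x, axes = c(1, 2), ...) {
  ncv <- ncol(x$cv_scores)
  if (any(axes > ncv)) stop_cm("only ", ncv, " canonical variates available")
  s <- x$cv_scores[, axes, drop = FALSE]
  cols <- seq_len(nlevels(x$groups))[x$groups]
  pct <- sprintf("%.0f%%", 100 * x$cv_variance_fractions[axes])
  graphics::plot(s, col = cols, pch = 16,
                 xlab = paste0(colnames(s)[1], " (", pct[1], ")"),
                 ylab = paste0(colnames(s)[2], " (", pct[2], ")"), ...)
  graphics::legend("topright", legend = levels(x$groups),
                   col = seq_len(nlevels(x$groups)), pch = 16, cex = 0.8)
  invisible(x)
}

#' Export ordination scores as CSV
#'
#' @param x a `shape_pca` or `cva` object.
#' @param path output file.
#' @export
write_scores <- function(x, path) {
  scores <- if (inherits(x, "cva")) x$cv_scores else x$scores
  df <- data.frame(specimen_id = rownames(scores), scores,
                   check.names = FALSE)
  if (inherits(x, "cva")) df$group <- x$groups
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
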