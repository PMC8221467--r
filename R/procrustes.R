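# Generalized Procrustes analysis.
#
# Convention: every configuration is centred and fixed at unit centroid
# size (no inverse-consensus rescaling step), and the consensus is the
# arithmetic mean of the aligned configurations.  Reflections are never
# allowed in superimposition; mirror-image handling lives in the symmetry
# module.

coords_of <- function(x) {
  if (inherits(x, "landmark_config")) x$coords
  else check_matrix3(as.matrix(x))
}

#' Centroid size of a configuration
#'
#' Square root of the summed squared deviations of the landmarks from
#' their centroid; the standard size measure removed by Procrustes scaling.
#'
#' @param config a [landmark_config()] or k x 3 matrix.
#' @return non-negative scalar.
#' @export
centroid_size <- function(config) {
  m <- coords_of(config)
  ctr <- colMeans(m)
  sqrt(sum(sweep(m, 2, ctr)^2))
}

center_config <- function(m) sweep(m, 2, colMeans(m))

# Centre and scale to unit centroid size; errors on degenerate input.
preshape <- function(m) {
  m <- center_config(m)
  cs <- sqrt(sum(m^2))
  if (cs <= .Machine$double.eps^0.5 * nrow(m)) {
    stop_cm("degenerate configuration: all landmarks (nearly) coincident")
  }
  m / cs
}

#' Optimal rotation between two centred configurations
#'
#' Returns the proper rotation R (det +1) minimizing ||A R - B||_F, via the
#' singular value decomposition of A'B with the smallest singular value
#' sign-corrected so that reflections are excluded.
#'
#' @param A,B centred k x 3 matrices.
#' @return 3 x 3 rotation matrix.
#' @export
optimal_rotation <- function(A, B) {
  A <- coords_of(A); B <- coords_of(B)
  if (!identical(dim(A), dim(B))) stop_cm("configurations differ in size")
  s <- svd(crossprod(A, B))
  if (s$d[2] <= 1e-12 * max(s$d[1], .Machine$double.eps)) {
    stop_cm("degenerate configuration: rank < 2, rotation not identifiable")
  }
  dsign <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, dsign)) %*% t(s$v)
}

# Iterative GPA on a k x 3 x n array of preshapes.
# symmetric_scheme: if non-NULL, the consensus is projected onto its
# symmetric component each iteration so the frame's reflection plane is
# exactly the first coordinate plane (used by symmetrize()).
gpa_core <- function(arr, tol = 1e-10, max_iter = 100L, symmetric_scheme = NULL) {
  n <- dim(arr)[3]
  for (i in seq_len(n)) arr[, , i] <- preshape(arr[, , i])
  # initial orientation: align everything to the first configuration
  ref <- arr[, , 1]
  for (i in seq_len(n)) arr[, , i] <- arr[, , i] %*% optimal_rotation(arr[, , i], ref)
  consensus <- apply(arr, c(1, 2), mean)
  if (!is.null(symmetric_scheme)) {
    consensus <- symmetric_component(consensus, symmetric_scheme)
  }
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      arr[, , i] <- arr[, , i] %*% optimal_rotation(arr[, , i], consensus)
    }
    new_consensus <- apply(arr, c(1, 2), mean)
    if (!is.null(symmetric_scheme)) {
      new_consensus <- symmetric_component(new_consensus, symmetric_scheme)
    }
    objective <- c(objective, sum(sweep(arr, c(1, 2), new_consensus)^2))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  # final pass so every configuration is optimally rotated to the
  # final consensus
  for (i in seq_len(n)) {
    arr[, , i] <- arr[, , i] %*% optimal_rotation(arr[, , i], consensus)
  }
  list(aligned = arr, consensus = consensus, iterations = iter,
       converged = converged, objective = objective)
}

# Deterministic canonical frame: rotate so the consensus sits on its
# principal axes, with signs fixed by the largest-magnitude coordinate of
# each of the first two axes (third axis completes a right-handed frame).
# Makes GPA output invariant to arbitrary similarity transforms of the
# inputs.
canonical_orientation <- function(consensus) {
  V <- svd(consensus)$v
  if (det(V) < 0) V[, 3] <- -V[, 3]
  C <- consensus %*% V
  for (j in 1:2) {
    if (C[which.max(abs(C[, j])), j] < 0) V[, j] <- -V[, j]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V
}

#' Generalized Procrustes analysis
#'
#' Removes translation, scale, and rotation from a set of configurations by
#' iterative alignment to the consensus until the consensus change falls
#' below `tol`.  The sum of squared distances to the consensus is
#' non-increasing across iterations.  The converged solution is rotated to
#' the principal axes of the consensus, giving a reproducible frame that
#' does not depend on the input orientations.
#'
#' @param dataset a [shape_dataset()] with at least 2 configurations.
#' @param tol convergence tolerance on the Frobenius change of the consensus.
#' @param max_iter iteration cap; exceeding it flags `converged = FALSE`.
#' @return an object of class `gpa` with elements `aligned` (a
#'   `shape_dataset` of unit-centroid-size aligned configurations),
#'   `consensus`, `centroid_sizes`, `iterations`, `converged`, `objective`.
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  if (n_specimens(dataset) < 2L) stop_cm("GPA needs at least 2 configurations")
  sizes <- apply(dataset$coords, 3, centroid_size)
  names(sizes) <- specimen_ids(dataset)
  core <- gpa_core(dataset$coords, tol = tol, max_iter = max_iter)
  R_can <- canonical_orientation(core$consensus)
  core$consensus <- core$consensus %*% R_can
  for (i in seq_len(dim(core$aligned)[3])) {
    core$aligned[, , i] <- core$aligned[, , i] %*% R_can
  }
  aligned <- dataset
  aligned$coords <- core$aligned
  dimnames(aligned$coords) <- dimnames(dataset$coords)
  structure(list(aligned = aligned,
                 consensus = core$consensus,
                 centroid_sizes = sizes,
                 iterations = core$iterations,
                 converged = core$converged,
                 objective = core$objective),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat("Generalized Procrustes analysis\n")
  cat("  specimens:   ", n_specimens(x$aligned), "\n", sep = "")
  cat("  landmarks:   ", n_landmarks(x$aligned), "\n", sep = "")
  cat("  iterations:  ", x$iterations,
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  cat("  Procrustes SS around consensus: ",
      format(utils::tail(x$objective, 1), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Both configurations are centred and scaled to unit centroid size, the
#' second is optimally rotated onto the first, and the square root of the
#' summed squared coordinate differences is returned (partial Procrustes
#' distance).  This pairwise superimposition is self-contained; it does not
#' reuse positions from any joint GPA.
#'
#' @param A,B [landmark_config()] objects or k x 3 matrices with equal k.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(A, B) {
  a <- preshape(coords_of(A))
  b <- preshape(coords_of(B))
  if (!identical(dim(a), dim(b))) stop_cm("configurations differ in landmark count")
  R <- optimal_rotation(b, a)
  sqrt(sum((a - b %*% R)^2))
}

#' All pairwise Procrustes distances within a dataset
#'
#' @param dataset a `shape_dataset`.
#' @return a `dist` object of pairwise two-configuration Procrustes distances.
#' @export
pairwise_procrustes_distances <- function(dataset) {
  n <- n_specimens(dataset)
  pre <- lapply(seq_len(n), function(i) preshape(dataset$coords[, , i]))
  d <- matrix(0, n, n, dimnames = list(specimen_ids(dataset), specimen_ids(dataset)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      R <- optimal_rotation(pre[[j]], pre[[i]])
      d[i, j] <- d[j, i] <- sqrt(sum((pre[[i]] - pre[[j]] %*% R)^2))
    }
  }
  stats::as.dist(d)
}
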