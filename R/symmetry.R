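# Object symmetry: reflected relabelling and removal of bilateral
# asymmetry by averaging each configuration with its mirror image.

#' Define a bilateral symmetry scheme
#'
#' Partitions the landmark indices `1..k` into left/right pairs and midline
#' (unpaired) landmarks.  The anatomical pairing is study-specific input,
#' not something the package can infer.
#'
#' @param pairs two-column matrix (or list of length-2 vectors) of
#'   (left, right) landmark indices.
#' @param midline integer vector of midline landmark indices.
#' @param k total landmark count; defaults to the number of indices given.
#' @return an object of class `symmetry_scheme`.
#' @export
symmetry_scheme <- function(pairs, midline, k = NULL) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  midline <- as.integer(midline)
  if (any(pairs[, 1] == pairs[, 2])) stop_cm("a landmark cannot be paired with itself")
  all_idx <- c(as.vector(pairs), midline)
  k <- k %||% length(all_idx)
  if (anyDuplicated(all_idx)) stop_cm("symmetry scheme repeats a landmark index")
  if (!setequal(all_idx, seq_len(k)) || length(all_idx) != k) {
    stop_cm("pairs and midline must partition 1..k")
  }
  structure(list(pairs = pairs, midline = midline, k = k),
            class = "symmetry_scheme")
}

#' @export
print.symmetry_scheme <- function(x, ...) {
  cat("Symmetry scheme: ", x$k, " landmarks = ", nrow(x$pairs),
      " bilateral pairs + ", length(x$midline), " midline\n", sep = "")
  invisible(x)
}

#' Read/write a symmetry scheme as a small YAML config
#'
#' Format: `midline: [..]` and `pairs: [[l, r], ..]`.
#'
#' @param path file path.
#' @return for the reader, a [symmetry_scheme()].
#' @export
read_symmetry_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pairs) || is.null(cfg$midline)) {
    stop_cm("scheme file needs 'pairs' and 'midline' entries")
  }
  symmetry_scheme(cfg$pairs, cfg$midline)
}

#' @rdname read_symmetry_scheme
#' @param scheme a [symmetry_scheme()].
#' @export
write_symmetry_scheme <- function(scheme, path) {
  yaml::write_yaml(list(midline = as.integer(scheme$midline),
                        pairs = lapply(seq_len(nrow(scheme$pairs)),
                                       function(i) as.integer(scheme$pairs[i, ]))),
                   path)
  invisible(path)
}

# Permutation sending each landmark position to the index it takes its
# mirrored coordinates from (left <- right, right <- left, midline fixed).
scheme_permutation <- function(scheme) {
  p <- seq_len(scheme$k)
  p[scheme$pairs[, 1]] <- scheme$pairs[, 2]
  p[scheme$pairs[, 2]] <- scheme$pairs[, 1]
  p
}

reflect_relabel_matrix <- function(m, scheme) {
  if (nrow(m) != scheme$k) {
    stop_cm("scheme is for ", scheme$k, " landmarks; configuration has ", nrow(m))
  }
  m2 <- m
  m2[, 1] <- -m2[, 1]
  m2[scheme_permutation(scheme), , drop = FALSE]
}

#' Reflect and relabel a configuration
#'
#' Mirrors the coordinates across the first coordinate plane (x negated)
#' and swaps the left/right landmark labels; midline landmarks keep their
#' labels.  Applying the operation twice returns the original
#' configuration exactly.
#'
#' @param config a [landmark_config()] or k x 3 matrix.
#' @param scheme a [symmetry_scheme()] partitioning the k landmarks.
#' @return object of the same type as `config`.
#' @export
reflect_relabel <- function(config, scheme) {
  if (inherits(config, "landmark_config")) {
    m <- reflect_relabel_matrix(config$coords, scheme)
    rownames(m) <- config$labels
    landmark_config(config$specimen_id, m, config$labels)
  } else {
    reflect_relabel_matrix(coords_of(config), scheme)
  }
}

# Symmetric / antisymmetric components of a single configuration in a
# frame whose reflection plane is the first coordinate plane.
symmetric_component <- function(m, scheme) {
  (m + reflect_relabel_matrix(m, scheme)) / 2
}

antisymmetric_component <- function(m, scheme) {
  (m - reflect_relabel_matrix(m, scheme)) / 2
}

#' Remove bilateral asymmetry from a dataset
#'
#' Runs a joint generalized Procrustes analysis on the n original
#' configurations together with their n reflected-relabelled copies, then
#' returns, per specimen, the landmark-wise average of its two aligned
#' copies — the symmetric component of shape.  The consensus of the joint
#' GPA is projected onto its own symmetric component at each iteration, so
#' the output frame's reflection plane is the first coordinate plane and
#' midline landmarks of the output lie on it.
#'
#' @param dataset a [shape_dataset()].
#' @param scheme a [symmetry_scheme()] for the dataset's landmarks.
#' @param tol,max_iter forwarded to the internal GPA.
#' @return a `shape_dataset` of symmetrized configurations (same specimens
#'   and metadata), with the scheme attached and the symmetric consensus in
#'   attribute `"consensus"`.
#' @export
symmetrize <- function(dataset, scheme, tol = 1e-10, max_iter = 200L) {
  k <- n_landmarks(dataset); n <- n_specimens(dataset)
  if (k != scheme$k) stop_cm("scheme is for ", scheme$k, " landmarks; dataset has ", k)
  doubled <- array(NA_real_, dim = c(k, 3L, 2L * n))
  doubled[, , seq_len(n)] <- dataset$coords
  for (i in seq_len(n)) {
    doubled[, , n + i] <- reflect_relabel_matrix(dataset$coords[, , i], scheme)
  }
  core <- gpa_core(doubled, tol = tol, max_iter = max_iter,
                   symmetric_scheme = scheme)
  sym <- dataset$coords
  for (i in seq_len(n)) {
    sym[, , i] <- (core$aligned[, , i] + core$aligned[, , n + i]) / 2
  }
  out <- dataset
  out$coords <- sym
  out$scheme <- scheme
  attr(out, "consensus") <- core$consensus
  attr(out, "gpa_converged") <- core$converged
  out
}
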