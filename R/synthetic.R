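# Synthetic landmark-study generator with known ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# four groups at the study's sample sizes, two source groups with distinct
# symmetric mean shapes, target groups drawn as two-component mixtures of
# the sources, sexual dimorphism, fluctuating bilateral asymmetry,
# landmark digitization noise, and arbitrary specimen orientation.

#' Default bilateral symmetry scheme for synthetic crania
#'
#' 6 midline landmarks followed by 14 bilateral (left, right) pairs, k = 34
#' by default.  Real studies must supply the anatomical pairing for their
#' landmark set; this scheme structures the synthetic data.
#'
#' @param k landmark count (even remainder after `n_midline`).
#' @param n_midline number of midline landmarks.
#' @return a [symmetry_scheme()].
#' @export
default_symmetry_scheme <- function(k = 34L, n_midline = 6L) {
  if ((k - n_midline) %% 2L != 0L) stop_cm("k - n_midline must be even")
  left <- seq(n_midline + 1L, k, by = 2L)
  symmetry_scheme(pairs = cbind(left, left + 1L), midline = seq_len(n_midline),
                  k = k)
}

#' Parameters for the synthetic study generator
#'
#' Defaults reproduce the study conditions: 34 landmarks, the four-group
#' design at the published per-sex sample sizes (Early Anglo-Saxon 27/20,
#' Middle Anglo-Saxon 13/29, Pre-Medieval British 45/56, Danish 14/32 for
#' F/M), target groups mixed from the two sources with a Danish fraction
#' of 0.65 (Early) and 0.35 (Middle), and noise scales chosen to give
#' source-group separability comparable to the study's (leave-one-out
#' accuracy around 0.9).
#'
#' @param k landmark count.
#' @param scheme a [symmetry_scheme()]; default [default_symmetry_scheme()].
#' @param group_sizes matrix of per-group (rows) by sex (`F`, `M` columns)
#'   sample sizes.
#' @param source_separation mean-shape separation between the two sources,
#'   on the scale of the within-group standard deviation (approximately
#'   the Mahalanobis distance between sources).
#' @param mixture_fractions named vector of Danish-origin probabilities
#'   for the target groups.
#' @param dimorphism_scale magnitude (mm) of the male-female mean shape
#'   offset; males additionally get a 5\% centroid-size increase.
#' @param within_sd per-coordinate within-group standard deviation (mm).
#' @param asymmetry_sd per-coordinate scale (mm) of fluctuating bilateral
#'   asymmetry (antisymmetric, zero-mean).
#' @param digitization_sd per-coordinate landmark digitization noise (mm).
#' @param base_size centroid size (mm) of the base shape.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(k = 34L,
                              scheme = default_symmetry_scheme(k),
                              group_sizes = default_group_sizes(),
                              source_separation = 3.4,
                              mixture_fractions = c(EARLY_AS = 0.65,
                                                    MIDDLE_AS = 0.35),
                              dimorphism_scale = 1.5,
                              within_sd = 1.0,
                              asymmetry_sd = 0.5,
                              digitization_sd = 0.25,
                              base_size = 100,
                              seed = 1L) {
  group_sizes <- as.matrix(group_sizes)
  if (ncol(group_sizes) != 2L) stop_cm("group_sizes needs two sex columns")
  if (is.null(colnames(group_sizes))) colnames(group_sizes) <- c("F", "M")
  stopifnot(k >= 4L, scheme$k == k,
            all(group_sizes >= 0L),
            all(mixture_fractions >= 0 & mixture_fractions <= 1),
            source_separation >= 0, within_sd >= 0, asymmetry_sd >= 0,
            digitization_sd >= 0, dimorphism_scale >= 0, base_size > 0)
  if (!all(rownames(group_sizes) %in% GROUP_LEVELS)) {
    stop_cm("group_sizes rownames must be study groups")
  }
  targets <- intersect(rownames(group_sizes), TARGET_GROUPS)
  if (!all(targets %in% names(mixture_fractions))) {
    stop_cm("mixture_fractions must name every target group")
  }
  structure(list(k = k, scheme = scheme, group_sizes = group_sizes,
                 source_separation = source_separation,
                 mixture_fractions = mixture_fractions,
                 dimorphism_scale = dimorphism_scale,
                 within_sd = within_sd, asymmetry_sd = asymmetry_sd,
                 digitization_sd = digitization_sd,
                 base_size = base_size, seed = as.integer(seed)),
            class = "simulation_params")
}

#' @rdname simulation_params
#' @export
default_group_sizes <- function() {
  m <- rbind(EARLY_AS = c(27L, 20L),
             MIDDLE_AS = c(13L, 29L),
             PREMED_BRITISH = c(45L, 56L),
             DANISH = c(14L, 32L))
  colnames(m) <- c("F", "M")
  m
}

# Deterministic symmetric pseudo-anatomical point cloud plus symmetric
# perturbation directions, all derived from the seed.
synthetic_base <- function(params) {
  with_seed(params$seed * 7919L %% .Machine$integer.max, {
    k <- params$k; sch <- params$scheme
    base <- matrix(0, k, 3L)
    base[sch$midline, 2] <- stats::rnorm(length(sch$midline), 0, 30)
    base[sch$midline, 3] <- stats::rnorm(length(sch$midline), 0, 30)
    left <- sch$pairs[, 1]
    base[left, 1] <- -abs(stats::rnorm(length(left), 20, 8))
    base[left, 2] <- stats::rnorm(length(left), 0, 30)
    base[left, 3] <- stats::rnorm(length(left), 0, 30)
    base[sch$pairs[, 2], ] <- base[left, ]
    base[sch$pairs[, 2], 1] <- -base[left, 1]
    base <- center_config(base)
    base <- base * params$base_size / centroid_size(base)

    unit_sym_direction <- function() {
      d <- symmetric_component(matrix(stats::rnorm(k * 3L), k, 3L), sch)
      d <- center_config(d)
      d / sqrt(sum(d^2))
    }
    list(base = base,
         source_dir = unit_sym_direction(),
         sex_dir = unit_sym_direction())
  })
}

#' Mean shapes of the two source groups
#'
#' A symmetric base shape plus a symmetric offset of controlled magnitude
#' separating the Pre-Medieval British and Danish means; the realized
#' Procrustes separation scales monotonically with `source_separation`.
#'
#' @param params a [simulation_params()].
#' @return list with `british_mean` and `danish_mean` (k x 3 matrices).
#' @export
make_mean_shapes <- function(params) {
  b <- synthetic_base(params)
  half <- 0.5 * params$source_separation * params$within_sd * b$source_dir
  list(british_mean = b$base - half, danish_mean = b$base + half)
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulate a complete landmark study with known ground truth
#'
#' Each specimen is its origin's source mean, plus a sex offset, a
#' within-individual symmetric deviation, zero-mean antisymmetric
#' asymmetry, and landmark-wise digitization noise, then arbitrarily
#' rotated, translated, and scaled.  Source-group specimens carry their
#' own group's origin; target-group origins are Bernoulli draws with the
#' group's Danish mixture fraction.
#'
#' @param params a [simulation_params()].
#' @return list with `dataset` (a [shape_dataset()]) and `truth`
#'   (`per_specimen` origin table and realized per-target-group
#'   `group_fractions` of Danish-derived specimens).
#' @export
simulate_study <- function(params = simulation_params()) {
  b <- synthetic_base(params)
  means <- make_mean_shapes(params)
  sch <- params$scheme
  k <- params$k
  with_seed(params$seed, {
    configs <- list()
    meta <- list()
    origin <- character(0)
    for (grp in rownames(params$group_sizes)) {
      for (sx in colnames(params$group_sizes)) {
        n <- params$group_sizes[grp, sx]
        if (n == 0L) next
        if (grp %in% SOURCE_GROUPS) {
          org <- rep(if (grp == "DANISH") "DANISH_DERIVED" else "BRITISH_DERIVED", n)
        } else {
          pi_d <- params$mixture_fractions[[grp]]
          org <- ifelse(stats::rbinom(n, 1L, pi_d) == 1L,
                        "DANISH_DERIVED", "BRITISH_DERIVED")
        }
        for (i in seq_len(n)) {
          mu <- if (org[i] == "DANISH_DERIVED") means$danish_mean else means$british_mean
          x <- mu
          if (sx == "M") x <- x + params$dimorphism_scale * b$sex_dir
          x <- x + symmetric_component(
            matrix(stats::rnorm(k * 3L, 0, params$within_sd), k, 3L), sch)
          x <- x + antisymmetric_component(
            matrix(stats::rnorm(k * 3L, 0, params$asymmetry_sd), k, 3L), sch)
          x <- x + matrix(stats::rnorm(k * 3L, 0, params$digitization_sd), k, 3L)
          size_factor <- exp(stats::rnorm(1, 0, 0.05)) * if (sx == "M") 1.05 else 1
          x <- size_factor * x %*% random_rotation_matrix()
          x <- sweep(x, 2, stats::runif(3, -50, 50), `+`)
          id <- sprintf("%s_%s_%02d", grp, sx, i)
          configs[[length(configs) + 1L]] <- landmark_config(id, x)
          meta[[length(meta) + 1L]] <- data.frame(
            specimen_id = id, group = grp, sex = sx,
            site = "synthetic", stringsAsFactors = FALSE)
          origin <- c(origin, org[i])
        }
      }
    }
    dataset <- shape_dataset(configs, meta = do.call(rbind, meta),
                             scheme = sch)
    per_specimen <- data.frame(specimen_id = specimen_ids(dataset),
                               origin = origin, stringsAsFactors = FALSE)
    targets <- intersect(rownames(params$group_sizes), TARGET_GROUPS)
    group_fractions <- vapply(targets, function(grp) {
      idx <- dataset$meta$group == grp
      mean(per_specimen$origin[idx] == "DANISH_DERIVED")
    }, numeric(1))
    list(dataset = dataset,
         truth = list(per_specimen = per_specimen,
                      group_fractions = group_fractions,
                      params = params))
  })
}

#' Simulate repeated digitizations of one specimen
#'
#' @param base_config a [landmark_config()] to re-digitize.
#' @param n_repeats number of repeated digitizations (>= 2).
#' @param digitization_sd per-coordinate noise (same units as the config).
#' @param seed integer seed.
#' @return a [shape_dataset()] of `n_repeats` noisy copies.
#' @export
simulate_repeats <- function(base_config, n_repeats = 10L,
                             digitization_sd = 0.25, seed = 1L) {
  if (n_repeats < 2L) stop_cm("need at least 2 repeats")
  m <- coords_of(base_config)
  k <- nrow(m)
  with_seed(seed, {
    configs <- lapply(seq_len(n_repeats), function(i) {
      landmark_config(sprintf("repeat_%02d", i),
                      m + matrix(stats::rnorm(k * 3L, 0, digitization_sd), k, 3L))
    })
    shape_dataset(configs)
  })
}

#' Write a ground-truth table as CSV
#'
#' @param truth the `truth` element of [simulate_study()].
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth$per_specimen, path, row.names = FALSE)
  invisible(path)
}
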