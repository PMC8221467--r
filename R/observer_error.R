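# Intra-observer error assessment: repeated digitizations of a single
# cranium compared against between-specimen shape variation.

#' Assess intra-observer digitization error
#'
#' Compares the greatest pairwise Procrustes distance among repeated
#' digitizations of a single specimen with the smallest pairwise
#' Procrustes distance among distinct specimens.  Digitization error is
#' deemed acceptable when the smallest between-specimen distance exceeds
#' the largest within-repeat distance (ratio > 1), i.e. measurement noise
#' is smaller than the finest real shape difference in the sample.
#'
#' @param repeats a [shape_dataset()] of >= 2 repeated digitizations of
#'   one specimen.
#' @param specimens a [shape_dataset()] of >= 2 distinct individuals.
#' @return object of class `observer_error`: `max_repeat_distance`,
#'   `min_between_distance`, `ratio`, `acceptable`.
#' @export
assess_observer_error <- function(repeats, specimens) {
  if (n_specimens(repeats) < 2L) stop_cm("need at least 2 repeated digitizations")
  if (n_specimens(specimens) < 2L) stop_cm("need at least 2 distinct specimens")
  d_rep <- pairwise_procrustes_distances(repeats)
  d_btw <- pairwise_procrustes_distances(specimens)
  max_rep <- max(d_rep)
  min_btw <- min(d_btw)
  ratio <- min_btw / max_rep
  structure(list(max_repeat_distance = max_rep,
                 min_between_distance = min_btw,
                 ratio = ratio,
                 acceptable = is.finite(ratio) && ratio > 1 || max_rep == 0),
            class = "observer_error")
}

#' @export
print.observer_error <- function(x, ...) {
  cat("Intra-observer error assessment\n")
  cat(sprintf("  greatest distance among repeats:     %.6g\n", x$max_repeat_distance))
  cat(sprintf("  smallest distance between specimens: %.6g\n", x$min_between_distance))
  cat(sprintf("  ratio (between / repeat):            %.3g\n", x$ratio))
  cat("  verdict: digitization error is ",
      if (x$acceptable) "acceptable" else "NOT acceptable",
      " for shape analysis\n", sep = "")
  invisible(x)
}
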