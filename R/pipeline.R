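# Orchestration of the full study: per-sex GPA, symmetrization, PCA, CVA,
# stepwise PC reduction, overall and pairwise MANOVAs, and two-source LDA
# attribution, with mixed-sex and mean-posterior supplements.

#' Run one analysis chain on a (sub)dataset
#'
#' Symmetrization (which embeds its own joint GPA), PCA, CVA over all
#' groups, stepwise PC reduction, overall and pairwise MANOVAs on the
#' retained PCs, LDA fit on the two source groups in the same retained-PC
#' space, and threshold attribution of each target group.  Target
#' specimens are projected into the PCA fitted on all groups jointly, so
#' sources and targets share one shape space.
#'
#' @param dataset a [shape_dataset()] with group metadata.
#' @param scheme a [symmetry_scheme()].
#' @param source_groups exactly two group names used as known samples.
#' @param target_groups groups to attribute.
#' @param threshold posterior attribution threshold.
#' @param label a name for the chain (e.g. `"F"`, `"M"`, `"mixed"`).
#' @return list with `symmetrized`, `pca`, `cva`, `reduction`,
#'   `manova_overall`, `manova_pairwise`, `lda`, `attribution` (one
#'   [summarize_attribution()] report per target group).
#' @export
run_chain <- function(dataset, scheme,
                      source_groups = SOURCE_GROUPS,
                      target_groups = TARGET_GROUPS,
                      threshold = 0.55,
                      label = "all") {
  if (length(source_groups) != 2L) stop_cm("exactly two source groups required")
  groups <- dataset$meta$group
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_cm("[", label, "/", what, "] ", conditionMessage(e))
    })
  }
  sym <- stage("symmetrize", symmetrize(dataset, scheme))
  pca <- stage("pca", shape_pca(sym))
  cva_res <- stage("cva", cva(flatten_coords(sym), groups))
  red <- stage("pc_reduction", baylac_friess_reduce(pca, groups))
  feats <- pca$scores[, red$retained_indices, drop = FALSE]
  overall <- stage("manova", wilks_manova(feats, groups))
  pw <- stage("pairwise_manova", pairwise_manova(feats, groups))
  src_idx <- groups %in% source_groups
  lda <- stage("lda", fit_lda(feats[src_idx, , drop = FALSE], groups[src_idx]))
  attribution <- lapply(target_groups, function(tg) {
    idx <- groups == tg
    if (!any(idx)) return(NULL)
    per_ind <- stage(paste0("attribution/", tg),
                     attribute_targets(lda, feats[idx, , drop = FALSE],
                                       ids = specimen_ids(dataset)[idx],
                                       threshold = threshold))
    summarize_attribution(per_ind, target_group = tg)
  })
  names(attribution) <- target_groups
  list(label = label, n = n_specimens(dataset), symmetrized = sym,
       pca = pca, cva = cva_res, reduction = red,
       manova_overall = overall, manova_pairwise = pw,
       lda = lda, attribution = attribution)
}

#' Run the full study
#'
#' Processes each sex fully independently (separate superimposition, PCA,
#' PC reduction, tests, and LDA), then optionally a mixed-sex supplement
#' that pools the raw configurations and repeats the whole chain.  The
#' mean-posterior admixture estimates are part of every attribution
#' summary.  The run is deterministic given the dataset and configuration.
#'
#' @param dataset a [shape_dataset()] with `group` and (for per-sex runs)
#'   `sex` metadata.
#' @param scheme a [symmetry_scheme()]; defaults to the dataset's.
#' @param source_groups,target_groups,threshold see [run_chain()].
#' @param per_sex run the two sex-specific chains.
#' @param mixed_sex run the pooled-sex supplementary chain.
#' @param verbose print one progress line per stage group.
#' @return object of class `study_report` with elements `chains` (named
#'   list of [run_chain()] outputs) and `config`.
#' @export
run_study <- function(dataset, scheme = NULL,
                      source_groups = SOURCE_GROUPS,
                      target_groups = TARGET_GROUPS,
                      threshold = 0.55,
                      per_sex = TRUE, mixed_sex = TRUE,
                      verbose = FALSE) {
  scheme <- scheme %||% dataset$scheme
  if (is.null(scheme)) stop_cm("a symmetry scheme is required")
  chains <- list()
  say <- function(...) if (verbose) message(...)
  if (per_sex) {
    for (sx in c("F", "M")) {
      sub <- subset_specimens(dataset, sex = sx)
      say("chain ", sx, ": n = ", n_specimens(sub))
      chains[[sx]] <- run_chain(sub, scheme, source_groups, target_groups,
                                threshold, label = sx)
      say("  retained PCs: ", length(chains[[sx]]$reduction$retained_indices),
          "; overall lambda = ",
          sprintf("%.3f", chains[[sx]]$manova_overall$lambda))
    }
  }
  if (mixed_sex) {
    say("chain mixed: n = ", n_specimens(dataset))
    chains[["mixed"]] <- run_chain(dataset, scheme, source_groups,
                                   target_groups, threshold, label = "mixed")
  }
  structure(list(chains = chains,
                 config = list(source_groups = source_groups,
                               target_groups = target_groups,
                               threshold = threshold,
                               per_sex = per_sex, mixed_sex = mixed_sex)),
            class = "study_report")
}

#' Attribution summary table of a study report
#'
#' One row per chain x target group with hard-attribution percentages and
#' mean posteriors.
#'
#' @param report a `study_report`.
#' @return data.frame.
#' @export
attribution_table <- function(report) {
  rows <- list()
  for (ch in report$chains) {
    for (tg in names(ch$attribution)) {
      rep_ <- ch$attribution[[tg]]
      if (is.null(rep_)) next
      cls <- names(rep_$mean_posterior)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch$label, target_group = tg, n = rep_$n,
        pct_danish = unname(rep_$pct[grep("DANISH", cls, value = TRUE)[1]]),
        pct_british = unname(rep_$pct[grep("BRITISH", cls, value = TRUE)[1]]),
        pct_unknown = unname(rep_$pct[UNATTRIBUTABLE]),
        mean_post_danish = unname(rep_$mean_posterior[grep("DANISH", cls, value = TRUE)[1]]),
        mean_post_british = unname(rep_$mean_posterior[grep("BRITISH", cls, value = TRUE)[1]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Cranial shape ancestry study\n")
  for (ch in x$chains) {
    cat("\n== Chain ", ch$label, " (n = ", ch$n, ") ==\n", sep = "")
    cat("  CV variance fractions: ",
        paste(sprintf("%.0f%%", 100 * ch$cva$cv_variance_fractions),
              collapse = " "), "\n", sep = "")
    cat("  retained PCs: ", length(ch$reduction$retained_indices),
        " (", sprintf("%.0f%%", 100 * ch$reduction$retained_variance_fraction),
        " of shape variance)\n", sep = "")
    print(ch$manova_overall)
    cat("  source LDA leave-one-out accuracy: ",
        sprintf("%.1f%%", 100 * ch$lda$loocv_accuracy), "\n", sep = "")
    for (tg in names(ch$attribution)) {
      if (!is.null(ch$attribution[[tg]])) print(ch$attribution[[tg]])
    }
  }
  invisible(x)
}

#' Write all study report tables as CSV files
#'
#' Emits `cva_summary.csv`, `manova_table.csv`, `attribution_summary.csv`,
#' and `attribution_individuals.csv` into a directory.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cva_rows <- do.call(rbind, lapply(report$chains, function(ch) {
    data.frame(chain = ch$label,
               cv = seq_along(ch$cva$cv_variance_fractions),
               variance_fraction = ch$cva$cv_variance_fractions,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(cva_rows, file.path(dir, "cva_summary.csv"), row.names = FALSE)

  manova_rows <- do.call(rbind, lapply(report$chains, function(ch) {
    ov <- ch$manova_overall
    rbind(data.frame(chain = ch$label, group1 = "overall", group2 = "",
                     lambda = ov$lambda, F = ov$F, df1 = ov$df1, df2 = ov$df2,
                     p = ov$p, partial_eta_sq = ov$partial_eta_sq,
                     stringsAsFactors = FALSE),
          cbind(chain = ch$label, ch$manova_pairwise$table))
  }))
  utils::write.csv(manova_rows, file.path(dir, "manova_table.csv"), row.names = FALSE)

  utils::write.csv(attribution_table(report),
                   file.path(dir, "attribution_summary.csv"), row.names = FALSE)

  ind_rows <- do.call(rbind, lapply(report$chains, function(ch) {
    do.call(rbind, lapply(names(ch$attribution), function(tg) {
      rep_ <- ch$attribution[[tg]]
      if (is.null(rep_)) return(NULL)
      cbind(chain = ch$label, target_group = tg, rep_$per_individual)
    }))
  }))
  utils::write.csv(ind_rows, file.path(dir, "attribution_individuals.csv"),
                   row.names = FALSE)
  invisible(dir)
}
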