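#' Full assay-performance evaluation report
#'
#' Runs the complete benchmarking analysis for a fitted panel: for every
#' assay, classification mode (IC50 and/or MOS), and threshold on the
#' practical grid, compounds are called positive/negative (censored = never
#' positive), tallied against known DILI labels, and summarized
#' column-for-column in the published performance-table schema: N+, N-, TP,
#' TN, FP, FN, threshold, sensitivity %, specificity %, PLR, NLR, kappa,
#' p-value. When Cmax values are present an exposure-only ROC block is
#' appended: AUC, the distance-optimized Cmax threshold, and (when a CV
#' seed is supplied) tenfold cross-validated sensitivity/specificity.
#'
#' The report is a pure function of its inputs: rerunning with the same
#' fits, compounds, and seed reproduces it exactly.
#'
#' @param fits Fit tibble covering one or more assays ([fit_panel()]).
#' @param compounds Compound tibble with DILI labels (and `cmax_uM` for MOS
#'   mode and the Cmax ROC block).
#' @param modes Subset of `c("ic50", "mos")`.
#' @param thresholds Positive increasing vector; default the practical grid
#'   10/25/50/100 (uM in IC50 mode, fold in MOS mode).
#' @param cv_seed Integer seed for the cross-validated Cmax block; `NULL`
#'   skips CV.
#' @param cv_folds Folds for cross-validation (default 10).
#' @param boundary Tie rule at the threshold, see [classify()].
#' @return List of class `"hepatoscreen_report"`: `performance` (one row
#'   per assay x mode x threshold, full precision), `performance_formatted`
#'   (report-rounded), and `cmax_roc` (or `NULL`).
#' @export
run_full_evaluation <- function(fits, compounds,
                                modes = c("ic50", "mos"),
                                thresholds = c(10, 25, 50, 100),
                                cv_seed = NULL, cv_folds = 10,
                                boundary = c("lte", "lt")) {
  boundary <- match.arg(boundary)
  modes <- match.arg(modes, several.ok = TRUE)
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  if ("mos" %in% modes && all(is.na(compounds$cmax_uM))) {
    stop("MOS mode requires Cmax values; none present in the compound table",
         call. = FALSE)
  }

  rows <- list()
  for (a in unique(fits$assay_id)) {
    fa <- fits[fits$assay_id == a, ]
    for (mode in modes) {
      for (t in thresholds) {
        calls <- classify_panel(fa, compounds, mode = mode, threshold = t,
                                boundary = boundary)
        m <- metrics(confusion(calls, compounds))
        m <- tibble::add_column(m, assay_id = a, mode = mode, threshold = t,
                                .before = 1)
        rows[[length(rows) + 1]] <- m
      }
    }
  }
  performance <- dplyr::bind_rows(rows)

  cmax_roc <- NULL
  if (any(!is.na(compounds$cmax_uM))) {
    has_cmax <- !is.na(compounds$cmax_uM)
    r <- roc(compounds$cmax_uM[has_cmax], compounds$dili_label[has_cmax],
             direction = "higher-is-positive")
    opt <- optimize_threshold(r)
    cv <- if (!is.null(cv_seed)) {
      cross_validated_performance(
        compounds$cmax_uM[has_cmax], compounds$dili_label[has_cmax],
        direction = "higher-is-positive", k = cv_folds, seed = cv_seed
      )
    } else NULL
    lr <- likelihood_ratios(opt$tpr, 1 - opt$fpr)
    cmax_roc <- list(roc = r, auc = r$auc,
                     optimal_threshold_uM = opt$threshold,
                     sensitivity = opt$tpr, specificity = 1 - opt$fpr,
                     plr = lr$plr, nlr = lr$nlr, cv = cv)
  }

  fmt <- format_metrics(performance)
  fmt <- tibble::add_column(fmt, assay_id = performance$assay_id,
                            mode = performance$mode,
                            threshold = performance$threshold, .before = 1)
  structure(list(performance = performance, performance_formatted = fmt,
                 cmax_roc = cmax_roc),
            class = "hepatoscreen_report")
}

#' @export
print.hepatoscreen_report <- function(x, ...) {
  cat("Assay performance (censoring-aware fixed-threshold calls)\n")
  print(as.data.frame(x$performance_formatted), row.names = FALSE)
  if (!is.null(x$cmax_roc)) {
    cat(sprintf(
      "\nCmax-only ROC: AUC %.1f, optimized threshold %.3g uM, sens %.1f%%, spec %.1f%%, PLR %.2f, NLR %.2f\n",
      100 * x$cmax_roc$auc, x$cmax_roc$optimal_threshold_uM,
      100 * x$cmax_roc$sensitivity, 100 * x$cmax_roc$specificity,
      x$cmax_roc$plr, x$cmax_roc$nlr))
    if (!is.null(x$cmax_roc$cv)) {
      cat(sprintf("  cross-validated (k = %d): sens %.1f%%, spec %.1f%%\n",
                  x$cmax_roc$cv$k, 100 * x$cmax_roc$cv$cv_sensitivity,
                  100 * x$cmax_roc$cv$cv_specificity))
    }
  }
  invisible(x)
}
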