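#' Confusion matrix of assay calls against known DILI labels
#'
#' @param calls Call tibble from [classify_panel()] (columns `compound`,
#'   `call`).
#' @param compounds Compound tibble with `name` and `dili_label`.
#' @return One-row tibble of counts `tp`, `tn`, `fp`, `fn`, `n`.
#' @export
confusion <- function(calls, compounds) {
  idx <- match(normalize_name(calls$compound), normalize_name(compounds$name))
  if (anyNA(idx)) {
    stop("no DILI label for compound(s): ",
         paste(unique(calls$compound[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  label <- compounds$dili_label[idx]
  confusion_from_pairs(calls$call, label)
}

#' @rdname confusion
#' @param call,label Character vectors of `"+"`/`"-"` calls and labels.
#' @export
confusion_from_pairs <- function(call, label) {
  stopifnot(length(call) == length(label),
            all(call %in% c("+", "-")), all(label %in% c("+", "-")))
  tibble::tibble(
    tp = sum(call == "+" & label == "+"),
    tn = sum(call == "-" & label == "-"),
    fp = sum(call == "+" & label == "-"),
    fn = sum(call == "-" & label == "+"),
    n = length(call)
  )
}

#' Positive and negative likelihood ratios
#'
#' PLR = sensitivity / (1 - specificity): how many times more likely a
#' positive assay result is for a DILI-positive than a DILI-negative
#' compound. NLR = (1 - sensitivity) / specificity, interpreted inversely.
#' Both are prevalence-robust, which matters for low-incidence events such
#' as DILI. A perfectly specific assay has infinite PLR (flagged, not an
#' error).
#'
#' @param sensitivity,specificity Proportions in \[0, 1\].
#' @return Tibble with `plr`, `nlr`, and flags `plr_infinite`,
#'   `nlr_infinite`.
#' @export
#' @examples
#' likelihood_ratios(50 / 69, 30 / 41)  # PLR 2.70, NLR 0.38
likelihood_ratios <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  plr <- ifelse(specificity == 1, Inf, sensitivity / (1 - specificity))
  nlr <- ifelse(specificity == 0, Inf, (1 - sensitivity) / specificity)
  tibble::tibble(plr = plr, nlr = nlr,
                 plr_infinite = is.infinite(plr),
                 nlr_infinite = is.infinite(nlr))
}

#' Cohen's kappa for a 2x2 call/label table
#'
#' Chance-corrected agreement between assay calls and known DILI labels:
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement
#' p_o = (TP + TN)/n and expected chance agreement p_e computed from the
#' marginal proportions. kappa = 1 is full agreement; kappa <= 0 no
#' agreement beyond chance.
#'
#' @param cm One-row confusion tibble (`tp`, `tn`, `fp`, `fn`).
#' @return Tibble with `kappa`, `p_o`, `p_e`, and `degenerate` (TRUE when
#'   p_e = 1 and kappa is undefined).
#' @export
cohens_kappa <- function(cm) {
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  stopifnot(n > 0)
  p_o <- (cm$tp + cm$tn) / n
  # marginals: label +/- vs call +/-
  r_pos <- (cm$tp + cm$fn) / n
  c_pos <- (cm$tp + cm$fp) / n
  p_e <- r_pos * c_pos + (1 - r_pos) * (1 - c_pos)
  degenerate <- p_e >= 1 - .Machine$double.eps^0.5
  kappa <- ifelse(degenerate, NA_real_, (p_o - p_e) / (1 - p_e))
  tibble::tibble(kappa = kappa, p_o = p_o, p_e = p_e, degenerate = degenerate)
}

#' Test of the null hypothesis kappa = 0
#'
#' Large-sample test using the standard error of kappa under the null of
#' chance agreement (Fleiss-style), computed from the marginal proportions:
#' \deqn{se_0 = \frac{\sqrt{p_e + p_e^2 - \sum_i r_i c_i (r_i + c_i)}}
#'   {(1 - p_e)\sqrt{n}}}
#' with \eqn{r_i}, \eqn{c_i} the row/column marginal proportions. The
#' statistic z = kappa / se0 is referred to the standard normal; the p-value
#' is two-sided.
#'
#' @param cm One-row confusion tibble.
#' @return Tibble with `kappa`, `se0`, `z`, `p_value`, and `flagged` (TRUE
#'   when se0 = 0 and the p-value is undefined).
#' @export
kappa_null_test <- function(cm) {
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  stopifnot(n > 0)
  k <- cohens_kappa(cm)
  r <- c((cm$tp + cm$fn) / n, (cm$fp + cm$tn) / n)
  cc <- c((cm$tp + cm$fp) / n, (cm$fn + cm$tn) / n)
  p_e <- k$p_e
  se0 <- sqrt(p_e + p_e^2 - sum(r * cc * (r + cc))) / ((1 - p_e) * sqrt(n))
  flagged <- !is.finite(se0) || se0 == 0 || k$degenerate
  z <- if (flagged) NA_real_ else k$kappa / se0
  # two-sided normal tail
  p <- if (flagged) NA_real_ else 2 * stats::pnorm(-abs(z))
  tibble::tibble(kappa = k$kappa, se0 = se0, z = z, p_value = p,
                 flagged = flagged)
}

#' Full concordance metrics from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), likelihood ratios,
#' Cohen's kappa and its null test, at full precision. Use
#' [format_metrics()] for report-style rounding (percentages to 1 decimal,
#' ratios to 2, kappa to 3).
#'
#' @param cm One-row confusion tibble (`tp`, `tn`, `fp`, `fn`).
#' @return One-row tibble with counts, `sensitivity`, `specificity` (as
#'   proportions), `plr`, `nlr`, `kappa`, `p_o`, `p_e`, `se0`, `z`,
#'   `p_value`.
#' @export
#' @examples
#' metrics(tibble::tibble(tp = 42, tn = 35, fp = 6, fn = 27))
metrics <- function(cm) {
  if (cm$tp + cm$fn == 0 || cm$fp + cm$tn == 0) {
    stop("metrics need at least one compound in each DILI class ",
         "(tp+fn > 0 and fp+tn > 0)", call. = FALSE)
  }
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  lr <- likelihood_ratios(sens, spec)
  kt <- kappa_null_test(cm)
  kp <- cohens_kappa(cm)
  tibble::tibble(
    tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
    n_pos = cm$tp + cm$fn, n_neg = cm$fp + cm$tn,
    sensitivity = sens, specificity = spec,
    plr = lr$plr, nlr = lr$nlr,
    kappa = kp$kappa, p_o = kp$p_o, p_e = kp$p_e,
    se0 = kt$se0, z = kt$z, p_value = kt$p_value
  )
}

#' Round metrics for report parity
#'
#' Percentages to 1 decimal, PLR/NLR to 2 decimals, kappa to 3 decimals,
#' p-values to 3 significant figures with a `"<0.0001"` floor -- the
#' rounding profile of the published performance tables.
#'
#' @param m Metrics tibble from [metrics()].
#' @return Tibble with character-formatted `sensitivity_pct`,
#'   `specificity_pct`, `plr`, `nlr`, `kappa`, `p_value` alongside counts.
#' @export
format_metrics <- function(m) {
  fmt_p <- function(p) {
    ifelse(is.na(p), NA_character_,
           ifelse(p < 1e-4, "<0.0001", formatC(signif(p, 3), format = "fg")))
  }
  tibble::tibble(
    tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
    sensitivity_pct = sprintf("%.1f", 100 * m$sensitivity),
    specificity_pct = sprintf("%.1f", 100 * m$specificity),
    plr = ifelse(is.infinite(m$plr), "Inf", sprintf("%.2f", m$plr)),
    nlr = ifelse(is.infinite(m$nlr), "Inf", sprintf("%.2f", m$nlr)),
    kappa = sprintf("%.3f", m$kappa),
    p_value = fmt_p(m$p_value)
  )
}

#' ROC analysis over a continuous per-compound score
#'
#' Sweeps every distinct score value as a candidate threshold and records
#' the (FPR, TPR) operating points, anchored at (0,0) and (1,1); ties share
#' one threshold. AUC is the trapezoidal area. `direction` states which end
#' of the score scale indicates DILI: IC50 and MOS scores are
#' `"lower-is-positive"`, a Cmax score is `"higher-is-positive"`.
#'
#' Compounds with undefined scores (censored fits) are dropped by default
#' (`censored = "remove"`), mirroring the first-pass analysis in which only
#' compounds with IC50 values can enter a ROC; `censored = "never-positive"`
#' instead keeps them with a score beyond every threshold, consistent with
#' ND-as-negative fixed-threshold analyses.
#'
#' @param score Numeric vector; `NA` = undefined (censored).
#' @param label Character vector of `"+"`/`"-"` DILI labels.
#' @param direction `"lower-is-positive"` or `"higher-is-positive"`.
#' @param censored `"remove"` or `"never-positive"`.
#' @return List of class `"hepatoscreen_roc"`: `points` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `direction`, `n_pos`, `n_neg`,
#'   `n_removed`.
#' @export
roc <- function(score, label,
                direction = c("lower-is-positive", "higher-is-positive"),
                censored = c("remove", "never-positive")) {
  direction <- match.arg(direction)
  censored <- match.arg(censored)
  stopifnot(length(score) == length(label), all(label %in% c("+", "-")))
  undef <- is.na(score)
  n_removed <- 0L
  if (any(undef)) {
    if (censored == "remove") {
      n_removed <- sum(undef)
      score <- score[!undef]
      label <- label[!undef]
    } else {
      score[undef] <- if (direction == "lower-is-positive") Inf else -Inf
    }
  }
  n_pos <- sum(label == "+")
  n_neg <- sum(label == "-")
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one compound of each class with a defined score",
         call. = FALSE)
  }
  # orient so that larger oriented score = more DILI-like
  s <- if (direction == "lower-is-positive") -score else score
  v <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(v, function(t) sum(s >= t & label == "+") / n_pos, 0)
  fpr <- vapply(v, function(t) sum(s >= t & label == "-") / n_neg, 0)
  # reported threshold for the point {s >= v_k} is the midpoint of the gap
  # (v_{k+1}, v_k]; any value there yields the same calls, and a midpoint
  # generalizes better to unseen scores (e.g. in cross-validation)
  thr <- v
  if (length(v) > 1) {
    mids <- (v[-length(v)] + v[-1]) / 2
    mids[is.nan(mids)] <- v[-length(v)][is.nan(mids)]
    thr <- c(mids, v[length(v)])
  }
  thr_orig <- if (direction == "lower-is-positive") -thr else thr
  points <- tibble::tibble(
    threshold = c(NA_real_, thr_orig),
    fpr = c(0, fpr), tpr = c(0, tpr)
  )
  if (points$fpr[nrow(points)] != 1 || points$tpr[nrow(points)] != 1) {
    points <- rbind(points,
                    tibble::tibble(threshold = NA_real_, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(
    list(points = points, auc = auc, direction = direction,
         n_pos = n_pos, n_neg = n_neg, n_removed = n_removed),
    class = "hepatoscreen_roc"
  )
}

#' @export
print.hepatoscreen_roc <- function(x, ...) {
  cat(sprintf("ROC: %d+/%d- compounds (%d removed), AUC = %.3f\n",
              x$n_pos, x$n_neg, x$n_removed, x$auc))
  invisible(x)
}

#' Distance-optimized classification threshold on a ROC curve
#'
#' Picks the threshold whose operating point minimizes the Euclidean
#' distance to the perfect assay (sensitivity 100%, specificity 100%),
#' d = sqrt(FPR^2 + (1 - TPR)^2); ties are broken toward higher specificity
#' (lower FPR).
#'
#' @param r A `"hepatoscreen_roc"` object from [roc()].
#' @return One-row tibble: `threshold`, `fpr`, `tpr`, `distance`.
#' @export
optimize_threshold <- function(r) {
  stopifnot(inherits(r, "hepatoscreen_roc"))
  pts <- r$points[!is.na(r$points$threshold), ]
  if (nrow(pts) == 0) stop("degenerate ROC: no candidate thresholds",
                           call. = FALSE)
  d <- sqrt(pts$fpr^2 + (1 - pts$tpr)^2)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.min(pts$fpr[best])]
  tibble::tibble(threshold = pts$threshold[best], fpr = pts$fpr[best],
                 tpr = pts$tpr[best], distance = d[best])
}

# call vector for a score at a ROC-style threshold, honoring direction
call_at_threshold <- function(score, threshold, direction) {
  if (direction == "lower-is-positive") {
    ifelse(!is.na(score) & score <= threshold, "+", "-")
  } else {
    ifelse(!is.na(score) & score >= threshold, "+", "-")
  }
}

#' Cross-validated sensitivity and specificity of the optimized threshold
#'
#' Tenfold cross-validation of the threshold-optimized classifier: in each
#' fold the threshold is optimized (distance to the perfect assay) on the
#' training compounds only and applied to the held-out compounds; held-out
#' calls are pooled into a single confusion matrix. Folds are stratified by
#' DILI label so that the smaller class is spread across folds; a seed is
#' required for the fold assignment.
#'
#' @inheritParams roc
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment (required).
#' @return One-row tibble: `cv_sensitivity`, `cv_specificity`, `k`, plus
#'   the pooled confusion counts.
#' @export
cross_validated_performance <- function(score, label,
                                        direction = c("lower-is-positive",
                                                      "higher-is-positive"),
                                        k = 10, seed,
                                        censored = c("remove",
                                                     "never-positive")) {
  direction <- match.arg(direction)
  censored <- match.arg(censored)
  if (missing(seed)) stop("seed is required for fold assignment",
                          call. = FALSE)
  undef <- is.na(score)
  if (any(undef)) {
    if (censored == "remove") {
      score <- score[!undef]
      label <- label[!undef]
    } else {
      score[undef] <- if (direction == "lower-is-positive") Inf else -Inf
    }
  }
  n <- length(score)
  if (n < k) stop("need at least k compounds", call. = FALSE)
  # stratified fold assignment
  fold <- integer(n)
  set.seed(seed)
  for (cls in c("+", "-")) {
    idx <- which(label == cls)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  call <- rep(NA_character_, n)
  for (f in seq_len(k)) {
    train <- fold != f
    if (length(unique(label[train])) < 2) {
      stop("training fold with a single class; use stratified folds / more data",
           call. = FALSE)
    }
    r <- roc(score[train], label[train], direction = direction,
             censored = "never-positive")
    thr <- optimize_threshold(r)$threshold
    test <- which(fold == f)
    call[test] <- call_at_threshold(score[test], thr, direction)
  }
  cm <- confusion_from_pairs(call, label)
  tibble::tibble(
    cv_sensitivity = cm$tp / (cm$tp + cm$fn),
    cv_specificity = cm$tn / (cm$tn + cm$fp),
    k = k, tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn
  )
}
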