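#' Margin of safety: IC50 over clinical exposure
#'
#' The margin of safety (MOS) expresses cytotoxic potency relative to
#' clinical exposure as the dimensionless fold IC50 / total plasma Cmax.
#' It is undefined when the fit is censored (no IC50) or Cmax is missing;
#' an undefined MOS never compares below any threshold.
#'
#' @param ic50_uM IC50 in micromolar; `NA` for censored fits.
#' @param censored Logical, fit censored (ND)?
#' @param cmax_uM Total plasma Cmax in micromolar, `NA` if unknown.
#' @return Tibble with `mos`, `defined`, and `reason` (`NA` when defined,
#'   else `"censored"` or `"missing_cmax"`).
#' @export
#' @examples
#' margin_of_safety(25, FALSE, 2)   # mos = 12.5
margin_of_safety <- function(ic50_uM, censored, cmax_uM) {
  n <- max(length(ic50_uM), length(censored), length(cmax_uM))
  ic50_uM <- rep_len(ic50_uM, n)
  censored <- rep_len(censored, n)
  cmax_uM <- rep_len(cmax_uM, n)
  reason <- rep(NA_character_, n)
  reason[is.na(cmax_uM)] <- "missing_cmax"
  reason[censored | is.na(ic50_uM)] <- "censored"
  defined <- is.na(reason)
  mos <- ifelse(defined, ic50_uM / cmax_uM, NA_real_)
  tibble::tibble(mos = mos, defined = defined, reason = reason)
}

#' Censoring-aware binary DILI call at a threshold
#'
#' A compound is called positive when its score (IC50 in `"ic50"` mode, MOS
#' fold in `"mos"` mode) is defined and at or below the threshold. Censored
#' or undefined scores are negative at every finite threshold: the absence
#' of a cytotoxicity signal is a negative signal. Values exactly at the
#' threshold are positive by default (`boundary = "lte"`); set
#' `boundary = "lt"` for strict inequality.
#'
#' @param value IC50 (uM) or MOS (fold); `NA` when undefined.
#' @param threshold Positive scalar, same units as `value`.
#' @param boundary `"lte"` (default, ties positive) or `"lt"`.
#' @return Character vector of calls, `"+"` or `"-"`.
#' @export
classify <- function(value, threshold, boundary = c("lte", "lt")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a positive scalar", call. = FALSE)
  }
  hit <- if (boundary == "lte") value <= threshold else value < threshold
  ifelse(!is.na(value) & hit, "+", "-")
}

#' Call every compound of a fitted panel at one threshold
#'
#' In `"ic50"` mode compounds are scored by their fitted IC50; in `"mos"`
#' mode by IC50/Cmax. Compounds whose score is undefined (censored fit, or
#' missing Cmax in MOS mode) are called negative, with the reason recorded.
#' The practical threshold grid used in reporting is 10/25/50/100 (uM for
#' IC50 mode, fold for MOS mode); any positive threshold is accepted.
#'
#' @param fits Fit tibble from [fit_panel()] (or [read_fit_table()]).
#' @param compounds Compound tibble; needed for `cmax_uM` in MOS mode.
#' @param mode `"ic50"` or `"mos"`.
#' @param threshold Positive scalar.
#' @param boundary Passed to [classify()].
#' @return Tibble: `compound`, `assay_id`, `mode`, `threshold`, `value`,
#'   `call`, `reason`.
#' @export
classify_panel <- function(fits, compounds, mode = c("ic50", "mos"),
                           threshold, boundary = c("lte", "lt")) {
  mode <- match.arg(mode)
  boundary <- match.arg(boundary)
  if (mode == "mos") {
    idx <- match(normalize_name(fits$compound), normalize_name(compounds$name))
    if (anyNA(idx)) {
      stop("compound(s) missing from compound table: ",
           paste(unique(fits$compound[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    ms <- margin_of_safety(fits$ic50_uM, fits$censored, compounds$cmax_uM[idx])
    value <- ms$mos
    reason <- ms$reason
  } else {
    value <- ifelse(fits$censored, NA_real_, fits$ic50_uM)
    reason <- ifelse(fits$censored, "censored", NA_character_)
  }
  call <- classify(value, threshold, boundary)
  tibble::tibble(
    compound = fits$compound,
    assay_id = fits$assay_id,
    mode = mode,
    threshold = threshold,
    value = value,
    call = call,
    reason = reason
  )
}
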