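#' Quadrant breakdown of MOS calls across DILI severity categories
#'
#' For each severity category, counts compounds below the MOS threshold
#' (called positive), above it, and with no IC50 determined (ND). For
#' categories 1-3 a below-threshold compound is a true positive and
#' above/ND are false negatives; for categories 4-5 below-threshold is a
#' false positive and above/ND are true negatives -- the quadrant view of
#' an exposure-corrected cytotoxicity scatter with the threshold drawn as a
#' horizontal line (50-fold by default).
#'
#' @param mos Numeric MOS per compound (`NA` = ND/undefined).
#' @param compounds Compound tibble aligned by name with `names`.
#' @param names Character vector naming each element of `mos`.
#' @param threshold MOS threshold (fold), default 50.
#' @param boundary Passed to [classify()].
#' @return Tibble with one row per category: `severity_category`,
#'   `n`, `below`, `above`, `nd`, `quadrant_below`, `quadrant_above_or_nd`.
#' @export
stratify_by_category <- function(mos, compounds, names, threshold = 50,
                                 boundary = c("lte", "lt")) {
  boundary <- match.arg(boundary)
  idx <- match(normalize_name(names), normalize_name(compounds$name))
  if (anyNA(idx)) {
    stop("compound(s) without a severity category: ",
         paste(unique(names[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  cat <- compounds$severity_category[idx]
  call <- classify(mos, threshold, boundary)
  below <- call == "+"
  nd <- is.na(mos)
  above <- !below & !nd
  out <- lapply(sort(unique(cat)), function(k) {
    in_k <- cat == k
    tibble::tibble(
      severity_category = k,
      n = sum(in_k),
      below = sum(below & in_k),
      above = sum(above & in_k),
      nd = sum(nd & in_k),
      quadrant_below = if (k <= 3) "TP" else "FP",
      quadrant_above_or_nd = if (k <= 3) "FN" else "TN"
    )
  })
  dplyr::bind_rows(out)
}

#' Default matched pairs of structural analogues
#'
#' Structurally related hepatotoxic / non-hepatotoxic drug groups used for
#' side-by-side margin-of-safety comparison: COMT inhibitors (tolcapone vs
#' entacapone), endothelin-receptor antagonists (sitax(s)entan and bosentan
#' vs ambrisentan), insulin sensitizers (troglitazone vs rosiglitazone),
#' and sedatives/antidepressants (nefazodone vs buspirone).
#'
#' @return Tibble: `pair_group`, `compound`.
#' @export
matched_pairs_default <- function() {
  tibble::tibble(
    pair_group = c("COMT inhibitors", "COMT inhibitors",
                   "Endothelin-receptor antagonists",
                   "Endothelin-receptor antagonists",
                   "Endothelin-receptor antagonists",
                   "Insulin sensitizers", "Insulin sensitizers",
                   "Sedatives/antidepressants", "Sedatives/antidepressants"),
    compound = c("Tolcapone", "Entacapone",
                 "Sitax(s)entan", "Bosentan", "Ambrisentan",
                 "Troglitazone", "Rosiglitazone",
                 "Nefazodone", "Buspirone")
  )
}

#' Side-by-side MOS comparison for matched drug pairs
#'
#' Reports the margin of safety (or ND) and the binary call at a stated
#' threshold for named groups of structural analogues. Pair members missing
#' from the panel are reported as absent rather than raising an error.
#'
#' @param pairs Tibble with `pair_group` and `compound`
#'   (default [matched_pairs_default()]).
#' @param mos Numeric MOS per compound (`NA` = ND).
#' @param names Compound names aligned with `mos`.
#' @param threshold MOS threshold for the call, default 50.
#' @return Tibble: `pair_group`, `compound`, `present`, `mos`, `call`.
#' @export
matched_pair_report <- function(mos, names, pairs = matched_pairs_default(),
                                threshold = 50) {
  idx <- match(normalize_name(pairs$compound), normalize_name(names))
  value <- ifelse(is.na(idx), NA_real_, mos[idx])
  tibble::tibble(
    pair_group = pairs$pair_group,
    compound = pairs$compound,
    present = !is.na(idx),
    mos = value,
    call = ifelse(is.na(idx), NA_character_, classify(value, threshold))
  )
}

#' Compare IC50 values between short and long exposure durations
#'
#' Pairs fits of the same compounds under a short (e.g. 5-6 day) and long
#' (e.g. 14 day) treatment and classifies each pair: `decreased` when the
#' long-exposure IC50 falls below the short one beyond the fold criterion
#' (`ic50_long * fold < ic50_short`), `increased` symmetrically,
#' `unchanged` otherwise. Pairs in which censoring resolves under the long
#' exposure (short ND, long determined) are tallied separately as
#' `nd_resolved` -- potency detected only with prolonged treatment --
#' and the reverse as `nd_emergent`; both-censored pairs are
#' `not_comparable`. The default fold of 1 counts any nominal change.
#'
#' @param fits_short,fits_long Fit tibbles sharing compounds.
#' @param fold Fold criterion >= 1 (default 1 = any nominal change).
#' @return List: `per_compound` tibble (`compound`, `ic50_short`,
#'   `ic50_long`, `status`) and `tally` tibble of status counts.
#' @export
compare_durations <- function(fits_short, fits_long, fold = 1) {
  stopifnot(fold >= 1)
  idx <- match(normalize_name(fits_short$compound),
               normalize_name(fits_long$compound))
  keep <- !is.na(idx)
  s <- fits_short[keep, ]
  l <- fits_long[idx[keep], ]
  ic50_s <- ifelse(s$censored, NA_real_, s$ic50_uM)
  ic50_l <- ifelse(l$censored, NA_real_, l$ic50_uM)
  status <- dplyr::case_when(
    is.na(ic50_s) & is.na(ic50_l) ~ "not_comparable",
    is.na(ic50_s) & !is.na(ic50_l) ~ "nd_resolved",
    !is.na(ic50_s) & is.na(ic50_l) ~ "nd_emergent",
    ic50_l * fold < ic50_s ~ "decreased",
    ic50_s * fold < ic50_l ~ "increased",
    TRUE ~ "unchanged"
  )
  per_compound <- tibble::tibble(
    compound = s$compound, ic50_short = ic50_s, ic50_long = ic50_l,
    status = status
  )
  lev <- c("decreased", "increased", "unchanged", "nd_resolved",
           "nd_emergent", "not_comparable")
  counts <- vapply(lev, function(x) sum(status == x), 0L)
  tally <- tibble::tibble(status = lev, count = unname(counts))
  list(per_compound = per_compound, tally = tally)
}
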