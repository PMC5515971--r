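test_that("category breakdown re-sums to the panel category sizes", {
  panel <- generate_panel(synthetic_config(), seed = 21)
  fits <- fit_panel(panel$wells, "hLiMT-14d", quiet = TRUE)
  ms <- margin_of_safety(fits$ic50_uM, fits$censored,
                         panel$compounds$cmax_uM[
                           match(fits$compound, panel$compounds$name)])
  bd <- stratify_by_category(ms$mos, panel$compounds, fits$compound,
                             threshold = 50)
  expect_equal(bd$n, c(23, 23, 23, 16, 25))
  expect_equal(bd$below + bd$above + bd$nd, bd$n)
  expect_equal(bd$quadrant_below, c("TP", "TP", "TP", "FP", "FP"))
})

test_that("quadrant tallies agree with a brute-force per-category recount", {
  panel <- generate_panel(synthetic_config(n_compounds = 40), seed = 8)
  fits <- fit_panel(panel$wells, "PHH-48h", quiet = TRUE)
  idx <- match(fits$compound, panel$compounds$name)
  ms <- margin_of_safety(fits$ic50_uM, fits$censored,
                         panel$compounds$cmax_uM[idx])
  bd <- stratify_by_category(ms$mos, panel$compounds, fits$compound,
                             threshold = 50)
  cat <- panel$compounds$severity_category[idx]
  for (k in unique(cat)) {
    in_k <- cat == k
    expect_equal(bd$below[bd$severity_category == k],
                 sum(!is.na(ms$mos[in_k]) & ms$mos[in_k] <= 50))
    expect_equal(bd$nd[bd$severity_category == k],
                 sum(is.na(ms$mos[in_k])))
  }
})

test_that("quadrant totals equal the classification confusion matrix", {
  panel <- generate_panel(synthetic_config(), seed = 13)
  fits <- fit_panel(panel$wells, "hLiMT-14d", quiet = TRUE)
  calls <- classify_panel(fits, panel$compounds, mode = "mos",
                          threshold = 50)
  cm <- confusion(calls, panel$compounds)
  idx <- match(fits$compound, panel$compounds$name)
  ms <- margin_of_safety(fits$ic50_uM, fits$censored,
                         panel$compounds$cmax_uM[idx])
  bd <- stratify_by_category(ms$mos, panel$compounds, fits$compound,
                             threshold = 50)
  pos_cat <- bd$severity_category <= 3
  expect_equal(sum(bd$below[pos_cat]), cm$tp)
  expect_equal(sum(bd$above[pos_cat]) + sum(bd$nd[pos_cat]), cm$fn)
  expect_equal(sum(bd$below[!pos_cat]), cm$fp)
  expect_equal(sum(bd$above[!pos_cat]) + sum(bd$nd[!pos_cat]), cm$tn)
})

test_that("matched-pair report shows analogue MOS side by side", {
  mos <- c(12.5, 8.7, NA, 2.1)
  names <- c("Bosentan", "Sitax(s)entan", "Ambrisentan", "Tolcapone")
  rep <- matched_pair_report(mos, names, threshold = 50)
  expect_equal(rep$call[rep$compound == "Bosentan"], "+")
  expect_equal(rep$call[rep$compound == "Sitax(s)entan"], "+")
  expect_equal(rep$call[rep$compound == "Ambrisentan"], "-")  # ND
  # members absent from the panel are reported, not errors
  expect_false(rep$present[rep$compound == "Buspirone"])
  expect_true(is.na(rep$call[rep$compound == "Buspirone"]))
})

test_that("duration comparison classifies pairs and is antisymmetric", {
  mk <- function(compound, ic50, censored) {
    tibble::tibble(compound = compound, assay_id = "hLiMT",
                   ic50_uM = ifelse(censored, NA_real_, ic50),
                   censored = censored, top_tested_uM = 100)
  }
  short <- mk(c("A", "B", "C", "D", "E"),
              c(10, 10, 40, NA, NA), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  long <- mk(c("A", "B", "C", "D", "E"),
             c(10, 40, 10, 5, NA), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  cmp <- compare_durations(short, long, fold = 1)
  st <- setNames(cmp$per_compound$status, cmp$per_compound$compound)
  expect_equal(unname(st[c("A", "B", "C", "D", "E")]),
               c("unchanged", "increased", "decreased", "nd_resolved",
                 "not_comparable"))
  expect_equal(sum(cmp$tally$count), 5)

  # swapping short and long swaps decreased/increased and the ND strata
  rev <- compare_durations(long, short, fold = 1)
  str <- setNames(rev$per_compound$status, rev$per_compound$compound)
  swap <- c(decreased = "increased", increased = "decreased",
            unchanged = "unchanged", nd_resolved = "nd_emergent",
            nd_emergent = "nd_resolved", not_comparable = "not_comparable")
  expect_equal(unname(str), unname(swap[st]))
})

test_that("identical fits give no change; fold criterion widens 'unchanged'", {
  panel <- generate_panel(synthetic_config(n_compounds = 20), seed = 2)
  fits <- fit_panel(panel$wells, "hLiMT-14d", quiet = TRUE)
  same <- compare_durations(fits, fits, fold = 1)
  expect_equal(sum(same$tally$count[same$tally$status %in%
                                      c("decreased", "increased")]), 0)
  # 2-fold criterion cannot call more changes than any-change
  short <- fits
  long <- fits
  long$ic50_uM <- long$ic50_uM / 1.5  # modest potency shift
  any_change <- compare_durations(short, long, fold = 1)
  two_fold <- compare_durations(short, long, fold = 2)
  n_changed <- function(x) sum(x$tally$count[x$tally$status %in%
                                               c("decreased", "increased")])
  expect_lte(n_changed(two_fold), n_changed(any_change))
})

test_that("a long-exposure potency shift yields a 'decreased' majority", {
  panel <- generate_panel(
    synthetic_config(n_compounds = 40, noise_cv = 0.05,
                     assay_shifts = c("hLiMT-5d" = 0.5, "hLiMT-14d" = 0)),
    seed = 44
  )
  f_short <- fit_panel(panel$wells, "hLiMT-5d", quiet = TRUE)
  f_long <- fit_panel(panel$wells, "hLiMT-14d", quiet = TRUE)
  cmp <- compare_durations(f_short, f_long, fold = 1)
  tl <- setNames(cmp$tally$count, cmp$tally$status)
  # truth-based recount: pairs with both IC50s determined must mostly drop
  both <- !f_short$censored & !f_long$censored[
    match(f_short$compound, f_long$compound)]
  expect_gt(tl[["decreased"]], tl[["increased"]])
  expect_gte(sum(both), tl[["decreased"]])
})
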