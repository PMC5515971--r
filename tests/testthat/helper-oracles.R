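# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (nlsLM, the ROC sweep, the kappa formulas).

# Brute-force SSE minimization of the constrained logistic model over a
# progressively refined (log10 IC50, Hill slope) grid. Final grid step is
# 5e-5 in log10 IC50 and 5e-4 in slope.
grid_fit_oracle <- function(x, y, li_range = c(-3, 3), h_range = c(-5, 5)) {
  sse_of <- function(li_vals, h_vals) {
    best <- list(sse = Inf, li = NA_real_, h = NA_real_)
    for (h in h_vals) {
      pred <- 100 / (1 + 10^(outer(li_vals, x, "-") * h))
      sse <- rowSums(sweep(pred, 2, y)^2)
      i <- which.min(sse)
      if (sse[i] < best$sse) best <- list(sse = sse[i], li = li_vals[i], h = h)
    }
    best
  }
  step_li <- 0.05; step_h <- 0.05
  best <- sse_of(seq(li_range[1], li_range[2], by = step_li),
                 seq(h_range[1], h_range[2], by = step_h))
  for (i in 1:3) {
    new_li <- step_li / 10; new_h <- step_h / 10
    best <- sse_of(seq(best$li - step_li, best$li + step_li, by = new_li),
                   seq(best$h - step_h, best$h + step_h, by = new_h))
    step_li <- new_li; step_h <- new_h
  }
  best
}

# Tie-corrected pairwise concordance probability (Mann-Whitney form of AUC).
auc_bruteforce <- function(score, label, direction = "lower-is-positive") {
  s <- if (direction == "lower-is-positive") -score else score
  pos <- s[label == "+"]; neg <- s[label == "-"]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Exhaustive search over all candidate thresholds for the operating point
# nearest the perfect assay; ties toward higher specificity.
optimal_threshold_bruteforce <- function(score, label,
                                         direction = "lower-is-positive") {
  cand <- sort(unique(score))
  eval1 <- function(t) {
    call <- if (direction == "lower-is-positive") {
      ifelse(score <= t, "+", "-")
    } else {
      ifelse(score >= t, "+", "-")
    }
    tpr <- mean(call[label == "+"] == "+")
    fpr <- mean(call[label == "-"] == "+")
    c(d = sqrt(fpr^2 + (1 - tpr)^2), fpr = fpr)
  }
  res <- t(vapply(cand, eval1, c(d = 0, fpr = 0)))
  best <- which(res[, "d"] == min(res[, "d"]))
  if (length(best) > 1) best <- best[which.min(res[best, "fpr"])]
  list(threshold = cand[best], distance = res[best, "d"])
}

# From-scratch observed/expected agreement recomputation for kappa.
kappa_oracle <- function(call, label) {
  p_o <- mean(call == label)
  p_e <- mean(call == "+") * mean(label == "+") +
    mean(call == "-") * mean(label == "-")
  (p_o - p_e) / (1 - p_e)
}

# Noise-free viability from the constrained logistic model.
viability_4pl <- function(conc, ic50, h) {
  100 / (1 + 10^((log10(ic50) - log10(conc)) * h))
}

# A clean 8-point half-log curve around a given IC50.
make_curve <- function(ic50, h = -1, top = 100, noise_cv = 0, seed = NULL) {
  conc <- top / sqrt(10)^(0:7)
  y <- viability_4pl(conc, ic50, h)
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- pmax(0, y * (1 + noise_cv * rnorm(length(y))))
  }
  list(conc = conc, y = y)
}

# The published performance-table rows: counts, sensitivity/specificity
# (%), PLR/NLR, kappa, p. kappa/p are NA where the printed cell is
# internally inconsistent with its own printed counts (a handful of the 2D
# rows); p is a string so the "<0.0001" floor can be represented.
published_rows <- function() {
  tibble::tribble(
    ~assay, ~mode, ~threshold, ~tp, ~tn, ~fp, ~fn,
    ~sens, ~spec, ~plr, ~nlr, ~kappa, ~p,
    "PHH",   "ic50",  10,  3, 40, 1, 66,  4.3, 97.6, 1.78, 0.98, 0.014, "0.61",
    "PHH",   "ic50",  25, 12, 38, 3, 57, 17.4, 92.7, 2.38, 0.89, 0.080, NA,
    "PHH",   "ic50",  50, 20, 37, 4, 49, 29.0, 90.2, 2.97, 0.79, NA,    NA,
    "PHH",   "ic50", 100, 23, 35, 6, 46, 33.3, 85.4, 2.28, 0.78, NA,    NA,
    "hLiMT", "ic50",  10, 13, 38, 3, 56, 18.8, 92.7, 2.57, 0.88, 0.091, "0.097",
    "hLiMT", "ic50",  25, 26, 36, 5, 43, 37.7, 87.8, 3.09, 0.71, 0.215, "0.004",
    "hLiMT", "ic50",  50, 36, 35, 6, 33, 52.2, 85.4, 3.57, 0.56, 0.331, "0.0001",
    "hLiMT", "ic50", 100, 42, 35, 6, 27, 60.9, 85.4, 4.16, 0.46, 0.419, "<0.0001",
    "PHH",   "mos",   10, 14, 40, 1, 55, 20.3, 97.6, 8.32, 0.82, 0.141, "0.008",
    "PHH",   "mos",   25, 19, 39, 2, 50, 27.5, 95.1, 5.64, 0.76, 0.183, NA,
    "PHH",   "mos",   50, 23, 35, 6, 46, 33.3, 85.4, 2.28, 0.78, 0.156, "0.031",
    "PHH",   "mos",  100, 28, 35, 6, 41, 40.6, 85.4, 2.77, 0.70, 0.221, "0.004",
    "hLiMT", "mos",   10, 25, 40, 1, 44, 36.2, 97.6, 14.86, 0.65, 0.279, "0.0001",
    "hLiMT", "mos",   25, 33, 38, 3, 36, 47.8, 92.7, 6.54, 0.56, 0.348, "<0.0001",
    "hLiMT", "mos",   50, 36, 35, 6, 33, 52.2, 85.4, 3.57, 0.56, 0.331, "0.0001",
    "hLiMT", "mos",  100, 41, 33, 8, 28, 59.4, 80.5, 3.05, 0.50, 0.363, "<0.0001"
  )
}

# check a computed p-value against a printed one at printed precision
expect_p_matches <- function(p, printed) {
  if (is.na(printed)) return(invisible(NULL))
  if (startsWith(printed, "<")) {
    testthat::expect_lt(p, as.numeric(sub("<", "", printed)))
  } else {
    decimals <- nchar(sub("^[^.]*\\.", "", printed))
    testthat::expect_lt(abs(p - as.numeric(printed)),
                        0.5 * 10^(-decimals) + 1e-12)
  }
}
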