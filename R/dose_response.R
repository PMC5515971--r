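#' Highest concentration to test for a compound
#'
#' The screening design tests up to 100-fold the total clinical plasma Cmax,
#' unless the solubility limit in 1% DMSO vehicle binds first.
#'
#' @param cmax Total plasma Cmax in micromolar; must be positive.
#' @param solubility_cap Solubility limit in micromolar, or `NA` when the
#'   100x margin is achievable.
#' @return Top test concentration in micromolar.
#' @export
#' @examples
#' top_test_concentration(1)          # 100
#' top_test_concentration(10, 500)    # capped at 500
top_test_concentration <- function(cmax, solubility_cap = NA_real_) {
  if (any(is.na(cmax)) || any(cmax <= 0)) {
    stop("cmax must be positive", call. = FALSE)
  }
  ifelse(is.na(solubility_cap), 100 * cmax, pmin(100 * cmax, solubility_cap))
}

# Constrained 4PL response: top = 100, bottom = 0, x = log10 concentration.
# h < 0 gives viability decreasing with dose (cytotoxic direction).
hill4pl <- function(x, log10_ic50, h) {
  100 / (1 + 10^((log10_ic50 - x) * h))
}

#' Fit a constrained four-parameter logistic dose-response curve
#'
#' Least-squares fit of percent viability against log10 concentration with
#' the top asymptote fixed at 100% and the bottom at 0%, leaving the
#' midpoint (log10 IC50) and a variable Hill slope free:
#' \deqn{y = 100 / (1 + 10^{(\log_{10} IC_{50} - x)\,h})}
#' Vehicle (0 uM) wells are excluded (their role is normalization; log of
#' zero is undefined); replicate wells enter as individual observations.
#' Minimization uses Levenberg-Marquardt ([minpack.lm::nlsLM]); log10 IC50
#' starts at the tested concentration whose mean response is nearest 50%
#' and the slope at -1, with the median tested log-concentration as a
#' fallback start.
#'
#' A fit is marked censored (no IC50 determined) when the optimizer fails,
#' when all responses are identical, or when the fitted slope is positive --
#' viability increasing with dose carries no cytotoxic signal. Censoring
#' against the highest tested concentration is applied separately by
#' [apply_censoring()].
#'
#' @param concentration_uM Numeric vector of well concentrations (uM),
#'   vehicle wells as 0.
#' @param viability_pct Numeric vector, % of vehicle control, same length.
#' @return One-row tibble: `log10_ic50`, `hill_slope`, `ic50_uM`, `top`,
#'   `bottom`, `converged`, `censored`, `sse`, `n_obs`.
#' @export
fit_curve <- function(concentration_uM, viability_pct) {
  stopifnot(length(concentration_uM) == length(viability_pct))
  keep <- concentration_uM > 0 & !is.na(viability_pct)
  x <- log10(concentration_uM[keep])
  y <- viability_pct[keep]
  if (length(unique(x)) < 4) {
    stop("need at least 4 distinct non-vehicle concentrations, got ",
         length(unique(x)), call. = FALSE)
  }

  result <- function(li, h, converged, censored, sse) {
    tibble::tibble(
      log10_ic50 = li, hill_slope = h,
      ic50_uM = if (censored) NA_real_ else 10^li,
      top = 100, bottom = 0,
      converged = converged, censored = censored,
      sse = sse, n_obs = length(y)
    )
  }

  if (stats::sd(y) == 0) {
    return(result(NA_real_, NA_real_, FALSE, TRUE, 0))
  }

  mean_by_conc <- tapply(y, x, mean)
  xs <- as.numeric(names(mean_by_conc))
  li0 <- xs[which.min(abs(mean_by_conc - 50))]
  starts <- list(c(li = li0, h = -1), c(li = stats::median(x), h = -1))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ 100 / (1 + 10^((li - x) * h)),
        start = list(li = s[["li"]], h = s[["h"]]),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) {
        cf <- stats::coef(fit)
        best <- list(li = unname(cf["li"]), h = unname(cf["h"]), sse = sse)
      }
    }
  }

  if (is.null(best)) {
    return(result(NA_real_, NA_real_, FALSE, TRUE, NA_real_))
  }
  if (best$h >= 0) {
    # viability not decreasing with dose: no cytotoxic signal
    return(result(best$li, best$h, TRUE, TRUE, best$sse))
  }
  result(best$li, best$h, TRUE, FALSE, best$sse)
}

#' Censor a fit against the highest tested concentration
#'
#' An IC50 is reported as not determined (ND) when the fit did not converge
#' or the estimate lies above the highest concentration tested -- even if the
#' optimizer converged on an extrapolated value. Censored fits carry no
#' usable IC50 downstream and are treated as negative calls at every
#' threshold.
#'
#' @param fit One-row fit tibble from [fit_curve()].
#' @param top_tested Highest tested concentration in micromolar.
#' @return The fit with `censored` and `top_tested_uM` updated;
#'   `ic50_uM` is `NA` when censored.
#' @export
apply_censoring <- function(fit, top_tested) {
  fit$top_tested_uM <- top_tested
  extrapolated <- fit$converged & !is.na(fit$log10_ic50) &
    10^fit$log10_ic50 > top_tested
  fit$censored <- fit$censored | !fit$converged | extrapolated
  fit$ic50_uM <- ifelse(fit$censored, NA_real_, 10^fit$log10_ic50)
  fit
}

#' Fit every curve of one assay in a panel
#'
#' Groups a well-level viability table by compound for the requested assay,
#' fits each group with [fit_curve()], and censors each fit at that curve's
#' highest tested concentration. Per-curve failures are not errors: they
#' become censored fits.
#'
#' @param wells Well-level viability tibble (see [read_viability_table()]).
#' @param assay_id Assay to fit, e.g. `"hLiMT-14d"`.
#' @param quiet Suppress the censoring summary message.
#' @return Tibble with one row per compound: fit columns plus `compound`,
#'   `assay_id`, `top_tested_uM`.
#' @export
fit_panel <- function(wells, assay_id, quiet = FALSE) {
  sub <- wells[wells$assay_id == assay_id, ]
  if (nrow(sub) == 0) {
    return(tibble::tibble(
      compound = character(), assay_id = character(),
      log10_ic50 = numeric(), hill_slope = numeric(), ic50_uM = numeric(),
      top = numeric(), bottom = numeric(), converged = logical(),
      censored = logical(), sse = numeric(), n_obs = integer(),
      top_tested_uM = numeric()
    ))
  }
  fits <- lapply(split(sub, sub$compound), function(d) {
    top_tested <- max(d$concentration_uM)
    fit <- tryCatch(
      fit_curve(d$concentration_uM, d$viability_pct),
      error = function(e) tibble::tibble(
        log10_ic50 = NA_real_, hill_slope = NA_real_, ic50_uM = NA_real_,
        top = 100, bottom = 0, converged = FALSE, censored = TRUE,
        sse = NA_real_, n_obs = nrow(d)
      )
    )
    fit <- apply_censoring(fit, top_tested)
    fit$compound <- d$compound[1]
    fit
  })
  out <- dplyr::bind_rows(fits)
  out$assay_id <- assay_id
  out <- out[, c("compound", "assay_id", "log10_ic50", "hill_slope",
                 "ic50_uM", "top", "bottom", "converged", "censored",
                 "sse", "n_obs", "top_tested_uM")]
  out <- out[order(out$compound), ]
  rownames(out) <- NULL
  if (!quiet) {
    message(sprintf("%s: %d/%d fits censored (ND)", assay_id,
                    sum(out$censored), nrow(out)))
  }
  out
}
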