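#' Configuration for the synthetic compound-panel generator
#'
#' Defines the statistical structure of a virtual screening campaign:
#' a compound panel with the reference severity mix (23/23/23/16/25 across
#' categories 1-5, 69/110 DILI-positive), log-normal total plasma Cmax with
#' DILI-positives sitting at higher clinical exposure, cytotoxic potency
#' parameterized on the margin-of-safety scale (log10 MOS normal for
#' DILI-positives; DILI-negatives cytotoxic only with probability
#' `p_tox_neg`), a per-assay additive log10-IC50 shift (the 2D assay is
#' less sensitive than the 3D one), Hill-shaped viability decay with
#' multiplicative well noise, and 8-point serial dilutions from
#' min(100 x Cmax, solubility cap) down.
#'
#' IC50 is derived as MOS x Cmax, so the prevalence of low-MOS compounds --
#' the quantity the classifier sees -- is controlled directly.
#'
#' @param n_compounds Panel size (default 110).
#' @param severity_counts Integer counts for categories 1-5; scaled to
#'   `n_compounds` by largest remainder when they do not sum to it.
#' @param cmax_log10_mean_pos,cmax_log10_mean_neg,cmax_log10_sd log10 Cmax
#'   (uM) distribution per DILI class.
#' @param mos_log10_mean_pos,mos_log10_sd_pos True log10 MOS distribution
#'   for DILI-positive compounds.
#' @param p_tox_neg Probability a DILI-negative compound has any finite
#'   cytotoxic potency.
#' @param mos_log10_mean_neg,mos_log10_sd_neg log10 MOS for the cytotoxic
#'   fraction of DILI-negatives.
#' @param assay_shifts Named numeric: additive log10-IC50 offset per assay;
#'   positive = less sensitive.
#' @param hill_mean,hill_sd Hill slope distribution (negative = viability
#'   decreasing with dose).
#' @param noise_cv Multiplicative Gaussian well noise (coefficient of
#'   variation), truncated at 0.
#' @param cap_log10_mean,cap_log10_sd log10 solubility cap (uM)
#'   distribution.
#' @param dilution_factor Serial dilution factor (> 1; default half-log).
#' @param n_dilutions Non-vehicle concentrations per curve (default 8).
#' @param n_replicates Wells per concentration (default 2).
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_compounds = 110,
                             severity_counts = c(23L, 23L, 23L, 16L, 25L),
                             cmax_log10_mean_pos = 0.6,
                             cmax_log10_mean_neg = -0.4,
                             cmax_log10_sd = 0.8,
                             mos_log10_mean_pos = 1.4,
                             mos_log10_sd_pos = 1.6,
                             p_tox_neg = 0.25,
                             mos_log10_mean_neg = 1.5,
                             mos_log10_sd_neg = 0.6,
                             assay_shifts = c("hLiMT-14d" = 0,
                                              "PHH-48h" = 0.5),
                             hill_mean = -1, hill_sd = 0.25,
                             noise_cv = 0.1,
                             cap_log10_mean = 2.3, cap_log10_sd = 0.5,
                             dilution_factor = sqrt(10),
                             n_dilutions = 8,
                             n_replicates = 2) {
  cfg <- list(
    n_compounds = as.integer(n_compounds),
    severity_counts = as.integer(severity_counts),
    cmax_log10_mean_pos = cmax_log10_mean_pos,
    cmax_log10_mean_neg = cmax_log10_mean_neg,
    cmax_log10_sd = cmax_log10_sd,
    mos_log10_mean_pos = mos_log10_mean_pos,
    mos_log10_sd_pos = mos_log10_sd_pos,
    p_tox_neg = p_tox_neg,
    mos_log10_mean_neg = mos_log10_mean_neg,
    mos_log10_sd_neg = mos_log10_sd_neg,
    assay_shifts = assay_shifts,
    hill_mean = hill_mean, hill_sd = hill_sd,
    noise_cv = noise_cv,
    cap_log10_mean = cap_log10_mean, cap_log10_sd = cap_log10_sd,
    dilution_factor = dilution_factor,
    n_dilutions = as.integer(n_dilutions),
    n_replicates = as.integer(n_replicates)
  )
  stopifnot(cfg$n_compounds >= 2,
            length(cfg$severity_counts) == 5,
            all(cfg$severity_counts >= 0),
            cfg$cmax_log10_sd > 0,
            cfg$mos_log10_sd_pos > 0, cfg$mos_log10_sd_neg > 0,
            cfg$p_tox_neg >= 0, cfg$p_tox_neg <= 1,
            length(cfg$assay_shifts) >= 1,
            !is.null(names(cfg$assay_shifts)),
            cfg$noise_cv >= 0,
            cfg$dilution_factor > 1,
            cfg$n_dilutions >= 4,
            cfg$n_replicates >= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

# scale category counts to n by largest remainder
scale_counts <- function(counts, n) {
  if (sum(counts) == n) return(counts)
  raw <- counts / sum(counts) * n
  base <- floor(raw)
  short <- n - sum(base)
  extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
  base[extra] <- base[extra] + 1
  as.integer(base)
}

#' Generate a synthetic compound panel with raw viability curves
#'
#' Draws a full virtual campaign from a [synthetic_config()]: compound
#' annotations (severity category, DILI label, Cmax, solubility cap),
#' per-assay true IC50s (infinite for non-cytotoxic compounds), and
#' well-level viability from the constrained logistic model plus
#' multiplicative noise. The ground truth is retained so recovery can be
#' measured at every pipeline stage. The same seed reproduces the panel
#' exactly.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (required).
#' @return List: `compounds` (compound tibble), `wells` (well-level
#'   viability tibble), `truth` (per compound x assay: `true_log10_ic50`
#'   -- `Inf` when non-cytotoxic -- `true_mos`, `true_hill`,
#'   `top_tested_uM`, `true_censored`), and `config`.
#' @export
generate_panel <- function(config = synthetic_config(), seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  cfg <- config

  counts <- scale_counts(cfg$severity_counts, cfg$n_compounds)
  category <- rep(1:5, times = counts)
  n <- length(category)
  name <- sprintf("SYN-%03d", seq_len(n))
  label <- dili_label_from_category(category)
  pos <- label == "+"

  lcmax <- stats::rnorm(n,
                        mean = ifelse(pos, cfg$cmax_log10_mean_pos,
                                      cfg$cmax_log10_mean_neg),
                        sd = cfg$cmax_log10_sd)
  cmax <- 10^lcmax
  cap <- 10^stats::rnorm(n, cfg$cap_log10_mean, max(cfg$cap_log10_sd, 1e-12))

  # true potency on the MOS scale; Inf = non-cytotoxic
  toxic <- pos | (stats::runif(n) < cfg$p_tox_neg)
  lmos <- ifelse(
    pos,
    stats::rnorm(n, cfg$mos_log10_mean_pos, cfg$mos_log10_sd_pos),
    stats::rnorm(n, cfg$mos_log10_mean_neg, cfg$mos_log10_sd_neg)
  )
  lmos[!toxic] <- Inf
  hill <- stats::rnorm(n, cfg$hill_mean, max(cfg$hill_sd, 1e-12))
  hill <- pmin(hill, -0.2)  # keep curves in the cytotoxic direction

  compounds <- tibble::tibble(
    name = name,
    severity_category = as.integer(category),
    dili_label = label,
    cmax_uM = cmax,
    solubility_cap_uM = cap
  )

  top <- top_test_concentration(cmax, cap)
  assays <- names(cfg$assay_shifts)

  truth_list <- list()
  well_list <- list()
  conc_steps <- cfg$dilution_factor^(0:(cfg$n_dilutions - 1))
  for (a in assays) {
    shift <- cfg$assay_shifts[[a]]
    li <- lmos + lcmax + shift        # log10 true IC50, Inf stays Inf
    truth_list[[a]] <- tibble::tibble(
      compound = name, assay_id = a,
      true_log10_ic50 = li,
      true_mos = 10^(lmos + shift),
      true_hill = hill,
      top_tested_uM = top,
      true_censored = li > log10(top)
    )
    conc <- rep(top, each = cfg$n_dilutions) / rep(conc_steps, times = n)
    x <- log10(conc)
    li_w <- rep(li, each = cfg$n_dilutions)
    h_w <- rep(hill, each = cfg$n_dilutions)
    clean <- ifelse(is.infinite(li_w), 100, hill4pl(x, li_w, h_w))
    nw <- length(conc) # one assay, one replicate block
    for (r in seq_len(cfg$n_replicates)) {
      noisy <- if (cfg$noise_cv > 0) {
        pmax(0, clean * (1 + cfg$noise_cv * stats::rnorm(nw)))
      } else clean
      veh <- if (cfg$noise_cv > 0) {
        pmax(0, 100 * (1 + cfg$noise_cv * stats::rnorm(n)))
      } else rep(100, n)
      well_list[[paste(a, r)]] <- tibble::tibble(
        compound = c(rep(name, each = cfg$n_dilutions), name),
        assay_id = a,
        concentration_uM = c(conc, rep(0, n)),
        viability_pct = c(noisy, veh),
        replicate = r
      )
    }
  }
  wells <- dplyr::bind_rows(well_list)
  wells <- wells[order(wells$assay_id, wells$compound,
                       wells$concentration_uM, wells$replicate), ]
  rownames(wells) <- NULL
  list(compounds = compounds, wells = wells,
       truth = dplyr::bind_rows(truth_list), config = cfg)
}

# Gauss-style grid expectation over the (log10 cmax, log10 cap) joint for
# one DILI class; f(lim, mu_m) must be vectorized over lim.
class_expectation <- function(cfg, positive, shift, f, nodes = 201) {
  mu_c <- if (positive) cfg$cmax_log10_mean_pos else cfg$cmax_log10_mean_neg
  grid1 <- function(mu, sd) {
    if (sd < 1e-10) return(list(x = mu, w = 1))
    x <- seq(mu - 6 * sd, mu + 6 * sd, length.out = nodes)
    w <- stats::dnorm(x, mu, sd)
    list(x = x, w = w / sum(w))
  }
  gc <- grid1(mu_c, cfg$cmax_log10_sd)
  gk <- grid1(cfg$cap_log10_mean, cfg$cap_log10_sd)
  # lim = log10(top/cmax) = min(2, lcap - lcmax)
  lim <- outer(gc$x, gk$x, function(lc, lk) pmin(2, lk - lc))
  w <- outer(gc$w, gk$w)
  sum(w * f(lim))
}

#' Analytic censoring probability under a synthetic configuration
#'
#' Probability that a compound's true IC50 exceeds its highest tested
#' concentration min(100 x Cmax, solubility cap), computed from the
#' configuration by numerical integration over the Cmax and solubility
#' distributions (non-cytotoxic compounds are censored with probability 1).
#' Used to validate the generator's empirical ND fractions.
#'
#' @param config A [synthetic_config()].
#' @param assay_id One of `names(config$assay_shifts)`.
#' @param label `"+"` or `"-"`.
#' @return Scalar probability.
#' @export
censoring_probability <- function(config, assay_id, label) {
  stopifnot(inherits(config, "synthetic_config"),
            assay_id %in% names(config$assay_shifts),
            label %in% c("+", "-"))
  shift <- config$assay_shifts[[assay_id]]
  positive <- label == "+"
  mu <- if (positive) config$mos_log10_mean_pos else config$mos_log10_mean_neg
  sd <- if (positive) config$mos_log10_sd_pos else config$mos_log10_sd_neg
  # censored iff log10 observed MOS (= true lmos + shift) > lim
  p_cens_toxic <- class_expectation(
    config, positive, shift,
    function(lim) 1 - stats::pnorm(lim, mean = mu + shift, sd = sd)
  )
  if (positive) p_cens_toxic
  else (1 - config$p_tox_neg) + config$p_tox_neg * p_cens_toxic
}

#' Theoretical sensitivity and specificity at a MOS threshold
#'
#' The generator's own operating characteristics: the probability that a
#' compound of each class is called positive at a MOS threshold, accounting
#' for censoring at the top tested concentration (a censored compound is
#' never positive). Computed by numerical integration as in
#' [censoring_probability()].
#'
#' @inheritParams censoring_probability
#' @param threshold MOS threshold (fold).
#' @return One-row tibble: `sensitivity`, `specificity`.
#' @export
theoretical_performance <- function(config, assay_id, threshold) {
  stopifnot(inherits(config, "synthetic_config"),
            assay_id %in% names(config$assay_shifts), threshold > 0)
  shift <- config$assay_shifts[[assay_id]]
  lt <- log10(threshold)
  p_call <- function(positive) {
    mu <- if (positive) config$mos_log10_mean_pos else config$mos_log10_mean_neg
    sd <- if (positive) config$mos_log10_sd_pos else config$mos_log10_sd_neg
    class_expectation(
      config, positive, shift,
      function(lim) stats::pnorm(pmin(lt, lim), mean = mu + shift, sd = sd)
    )
  }
  sens <- p_call(TRUE)
  spec <- 1 - config$p_tox_neg * p_call(FALSE)
  tibble::tibble(sensitivity = sens, specificity = spec)
}

#' Construct a call/label set with an exact confusion matrix
#'
#' Fixture factory: builds a synthetic panel of labeled compounds and binary
#' calls whose confusion matrix is exactly the requested (TP, FP, TN, FN) --
#' useful for reproducing published performance-table rows from their
#' printed counts.
#'
#' @param tp,fp,tn,fn Non-negative counts; `tp + fp + tn + fn > 0`.
#' @return List: `calls` (tibble `compound`, `call`) and `compounds`
#'   (compound tibble with labels).
#' @export
#' @examples
#' sc <- generate_confusion_scenario(42, 6, 35, 27)
#' confusion(sc$calls, sc$compounds)
generate_confusion_scenario <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  label <- c(rep("+", tp + fn), rep("-", fp + tn))
  call <- c(rep("+", tp), rep("-", fn), rep("+", fp), rep("-", tn))
  n <- length(label)
  name <- sprintf("CMP-%04d", seq_len(n))
  compounds <- tibble::tibble(
    name = name,
    severity_category = ifelse(label == "+", 1L, 5L),
    dili_label = label,
    cmax_uM = NA_real_,
    solubility_cap_uM = NA_real_
  )
  calls <- tibble::tibble(compound = name, call = call)
  list(calls = calls, compounds = compounds)
}
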