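---
title: "Benchmarking hepatotoxicity assays against clinical DILI labels: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking hepatotoxicity assays against clinical DILI labels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepatoscreen)
```

# The problem

Retrospective benchmarking of an in vitro cytotoxicity assay asks: given a
panel of marketed drugs whose clinical drug-induced liver injury (DILI)
status is known, how well does the assay's potency readout separate the
hepatotoxicants from the safe drugs? The reference design tests 110 drugs
spanning five clinical severity categories — 1 (severe DILI: withdrawn or
boxed warning), 2 (acute liver failure reported), 3 (symptomatic injury),
4 (enzyme elevations only), 5 (no DILI) — with categories 1–3 treated as
DILI-positive (69 compounds) and 4–5 as negative (41). Two assay formats
are compared: 2D plated primary human hepatocytes (PHH, short exposure)
and 3D liver microtissue spheroids (hLiMT, repeat-dose long exposure),
both reading total cellular ATP as the viability endpoint.

This vignette documents the package's modeling choices. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

# Dose–response model and censoring

Viability, normalized to vehicle control (%), is fit against
$x = \log_{10}$ concentration (µM) with a constrained four-parameter
logistic:

$$y = \frac{100}{1 + 10^{(\log_{10}\mathrm{IC}_{50} - x)\,h}}$$

The top and bottom asymptotes are fixed at 100 % and 0 %: the model assumes
complete kill at saturating dose and no effect at vanishing dose, which is
appropriate for an ATP endpoint normalized to vehicle and avoids two extra
parameters that 8-point designs cannot support. Only the midpoint and the
Hill slope $h$ are free; $h < 0$ is the cytotoxic direction.

Numerical choices (the underlying convention gives no guidance, so these
are the package's own):

* **Observations.** Replicate wells enter the regression individually, not
  as means — with only 8 concentrations, discarding within-dose variance
  information is wasteful. Vehicle (0 µM) wells serve normalization only
  and are excluded ($\log 0$ undefined).
* **Minimizer.** Levenberg–Marquardt (`minpack.lm::nlsLM`), 500 iterations,
  relative SSE tolerance $10^{-10}$.
* **Initialization.** $\log_{10}\mathrm{IC}_{50}$ starts at the tested
  concentration whose mean response is nearest 50 %, $h$ at $-1$; the
  median tested log-concentration is a fallback start. Both starts are
  tried and the lower-SSE solution kept.
* **Degenerate inputs.** Fewer than 4 distinct non-vehicle concentrations
  is an error; all-identical responses yield a non-converged, censored fit;
  a fitted $h \ge 0$ (viability not decreasing with dose) carries no
  cytotoxic signal and is censored.

**Censoring (ND).** Each compound is tested up to
$\min(100 \times C_{\max}, \text{solubility limit})$. A fit is reported as
"not determined" when the optimizer fails *or* the converged IC50
extrapolates above the highest tested concentration. The second clause
matters: without it, a curve showing 20 % kill at top dose yields a
formally converged IC50 far outside the tested range, and the ND
accounting that drives the whole censoring-aware analysis becomes
irreproducible from raw curves. Censored compounds are negative calls at
every finite threshold — the absence of a cytotoxicity signal is a
negative signal.

The test suite checks the fitter against an independent progressive
grid-search SSE oracle (final grid step $5\times10^{-5}$ log10 units) and
requires noiseless model data to be recovered to $10^{-6}$ log10 units.

# Exposure correction and binary calls

The margin of safety $\mathrm{MOS} = \mathrm{IC}_{50} / C_{\max}$ (total
plasma $C_{\max}$, µM — total, not free fraction) is the dimensionless fold
separating cytotoxic potency from clinical exposure. Calls at a threshold
$t$: positive iff the value is defined and $\le t$.

* **Tie rule.** A value exactly at threshold is positive. The underlying
  convention ("falling below the threshold") does not address ties; `<=`
  is chosen so a compound whose MOS prints exactly at the line is flagged —
  conservative for safety screening. `boundary = "lt"` gives the strict
  rule.
* **Threshold grid.** 10/25/50/100 (µM or fold) is the practical reporting
  grid; any positive threshold is accepted. Calls are provably nested
  along the grid, and sensitivity (specificity) is non-decreasing
  (non-increasing) in the threshold — both are property-tested.
* **Missing $C_{\max}$** leaves MOS undefined (negative call with a
  recorded reason) rather than erroring at load time, because IC50-mode
  analyses never need exposure data.

# Concordance statistics

With calls tallied against labels into TP/FP/TN/FN: sensitivity
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$, specificity
$\mathrm{TN}/(\mathrm{TN}+\mathrm{FP})$, likelihood ratios
$\mathrm{PLR} = \mathrm{sens}/(1-\mathrm{spec})$,
$\mathrm{NLR} = (1-\mathrm{sens})/\mathrm{spec}$ (infinities flagged, not
errors — a perfectly specific assay is a legitimate outcome at strict
thresholds), and Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_o$ the observed agreement and
$p_e$ the chance agreement from the margins.

**Null test for kappa.** The test of $\kappa = 0$ uses the large-sample
(Fleiss-style) null standard error computed from the marginal proportions
$r_i$ (labels) and $c_i$ (calls):

$$\mathrm{se}_0 = \frac{\sqrt{p_e + p_e^2 - \sum_i r_i c_i (r_i + c_i)}}
{(1 - p_e)\sqrt{n}}, \qquad z = \kappa/\mathrm{se}_0,$$

two-sided against the standard normal. Several null-SE conventions exist;
this one reproduces the published reference p-values exactly (0.097 and
≈ 0.61 from their confusion matrices, asserted in the acceptance tests),
which is why it is fixed here.

**ROC.** The curve sweeps every distinct score value, anchors at (0,0) and
(1,1), groups ties at one threshold, and integrates by trapezoid (equal to
tie-corrected pairwise concordance; oracle-tested). Reported thresholds
are midpoints of inter-score gaps: the operating points are identical, but
a midpoint generalizes to unseen scores, which matters in cross-validation
(a perfectly separable panel then cross-validates to 100 %/100 % as it
should). The optimized threshold minimizes the Euclidean distance
$\sqrt{\mathrm{FPR}^2 + (1-\mathrm{TPR})^2}$ to the perfect-assay corner,
ties broken toward higher specificity.

**Censored scores in ROC.** Two supported behaviors: `remove` (default)
drops ND compounds, mirroring the first-pass analysis in which only
compounds with IC50 values can enter — and illustrating its bias;
`never-positive` keeps them with a score beyond every threshold,
consistent with the fixed-threshold analyses. Fixed-threshold calls always
treat ND as negative.

**Cross-validation.** Tenfold, threshold re-optimized on each training
split, held-out calls pooled into one confusion matrix. Folds are
stratified by DILI label — with 41 negatives across 10 folds, unstratified
sampling risks one-class training splits — and require an explicit seed.
Whether the reference analysis stratified is unknown; stratification is
this package's choice, and CV targets are therefore property-based only.

**Rounding profile** (report output only; full precision internally):
percentages 1 decimal, PLR/NLR 2 decimals, kappa 3 decimals, p-values 3
significant figures with a `<0.0001` floor.

# Stratification and duration comparison

The quadrant view counts, per severity category, compounds below threshold
(positive), above, and ND at the default 50× MOS line; categories 1–3 map
below/other to TP/FN and categories 4–5 to FP/TN. Matched-pair reports
place structural analogues side by side (COMT inhibitors, endothelin
antagonists, glitazones, nefazodone/buspirone by default).

Short- vs long-exposure comparison classifies each compound pair as
decreased / increased / unchanged by a configurable fold criterion. The
reference analysis gives no explicit criterion for "decreased"; the
default fold of 1 (any nominal change) is surfaced prominently because
tallies depend on it. Pairs where censoring resolves (short ND, long
determined) are tallied separately as `nd_resolved` rather than forced
into "decreased" — an ND-to-value transition is qualitatively different
evidence — and the classification is exactly antisymmetric under swapping
the two exposure arms (property-tested).

# The synthetic generator

`generate_panel()` emulates the statistical structure the analysis
assumes, with ground truth retained:

* **Panel.** 110 compounds, severity mix 23/23/23/16/25, hence 69/41
  positive/negative.
* **Exposure.** $\log_{10} C_{\max} \sim N(0.6, 0.8)$ for DILI-positives
  and $N(-0.4, 0.8)$ for negatives (µM scale). The class separation is
  deliberate: clinical exposure alone is a known DILI risk factor (drugs
  with total $C_{\max}$ above ~1 µM are enriched for DILI), and the
  per-label means place the exposure-only ROC operating point near
  sensitivity ≈ specificity ≈ 73 % at a threshold just above 1 µM, the
  neighborhood the field reports. A single-mean configuration is one
  parameter change away.
* **Potency.** Parameterized on the MOS scale — the quantity the
  classifier sees — with IC50 derived as MOS × $C_{\max}$.
  DILI-positives: $\log_{10}\mathrm{MOS} \sim N(1.4, 1.6)$. DILI-negatives
  are cytotoxic at all with probability 0.25, then
  $\log_{10}\mathrm{MOS} \sim N(1.5, 0.6)$. These defaults were set once
  from the published marginal ND fractions and false-positive counts
  (roughly one-third of positives and three-quarters of negatives ND in
  the more sensitive assay) and are not tuned to any test outcome; no
  acceptance value depends on them.
* **Assay shift.** An additive log10-IC50 offset per assay
  (`hLiMT-14d` 0, `PHH-48h` +0.5): the 2D assay is about 3-fold less
  sensitive, reproducing the ordering of ND counts between formats.
* **Design.** Top dose $\min(100 \times C_{\max}, \text{cap})$ with
  $\log_{10}\text{cap} \sim N(2.3, 0.5)$ µM (a solubility-in-vehicle
  scale on which the cap binds mainly for high-exposure drugs); 8
  half-log dilutions; 2 replicate wells; Hill slopes $N(-1, 0.25)$
  truncated at $-0.2$; multiplicative Gaussian well noise, CV 10 %,
  truncated at 0.

The analytic companions `censoring_probability()` and
`theoretical_performance()` integrate the same model numerically
(probability grids over the $C_{\max}$ and solubility distributions,
normal tails for MOS), so the generator can be validated against closed
computation rather than against itself: empirical ND fractions at
$n = 10{,}000$ and pooled classification at the generator's own decision
boundary must match within 3-σ binomial error.

**What the generator does not emulate** — and hence what green tests do
not certify about real campaigns: pharmacokinetic realism beyond a
log-normal $C_{\max}$, correlation between potency and exposure,
donor-to-donor and run-to-run variability, plate-position effects,
biphasic or hormetic dose–response shapes, and any mechanistic structure
(transporter inhibition, mitochondrial toxicity). Conclusions about a real
assay still require real data; the synthetic path certifies the
*machinery*.

# Problem sizes in the checked analyses

The shipped tests run the full pipeline at the reference panel size
(n = 110, two assays), validate the generator's censoring fractions on a
10,000-compound panel (truth only, no fitting), pool ten 110-compound
panels for the boundary-recovery check, and exercise oracle comparisons on
8-point curves and ≤ 30-compound ROC instances. These sizes make every
statistical tolerance meaningful while keeping the default suite fast.

# Known limitations

* No confidence intervals on IC50 or AUC, no DeLong tests, no ordinal
  (5-category) concordance — point estimates only, matching the reference
  analysis scope.
* The constrained 4PL cannot represent partial-kill plateaus; compounds
  with genuine non-zero bottoms will fit with shallow slopes and inflated
  IC50s (usually censored).
* PLR is infinite when FP = 0; reported with a flag rather than smoothed.
* Compound identity is matched case-insensitively after trimming;
  spelling variants in the reference compound list (e.g. "Celocoxib",
  "Sitax(s)entan") are preserved verbatim, so user tables must follow the
  fixture's spellings when joining against `reference_panel()`.
* The published per-compound $C_{\max}$ and IC50 tables live in
  supplementary material not shipped here; analyses needing them accept
  user-supplied tables, and the package's own demonstrations use the
  synthetic generator instead.
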