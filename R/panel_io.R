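#' Derive the binary DILI label from a severity category
#'
#' Clinical DILI severity is graded 1-5: 1 severe clinical DILI (withdrawn or
#' boxed warning), 2 high concern (acute liver failure reported), 3 low
#' concern (symptomatic injury without failure), 4 enzyme elevations only,
#' 5 no DILI. Categories 1-3 are DILI-positive, 4-5 DILI-negative.
#'
#' @param severity_category Integer vector with values in 1:5.
#' @return Character vector, `"+"` or `"-"`.
#' @export
#' @examples
#' dili_label_from_category(c(1, 3, 4, 5))
dili_label_from_category <- function(severity_category) {
  if (!all(severity_category %in% 1:5)) {
    bad <- which(!severity_category %in% 1:5)
    stop("severity_category must be in 1..5; offending entries: ",
         paste0("[", bad, "] = ", severity_category[bad], collapse = ", "),
         call. = FALSE)
  }
  ifelse(severity_category <= 3, "+", "-")
}

normalize_name <- function(x) tolower(trimws(x))

#' Read a compound annotation table
#'
#' Expects a CSV with columns `name` and `severity_category`, and optionally
#' `cmax_uM` (total plasma Cmax, micromolar) and `solubility_cap_uM` (highest
#' concentration achievable in 1% DMSO vehicle). The binary DILI label is
#' derived from the severity category; a missing Cmax is kept as `NA`, never
#' coerced to zero, so that IC50-threshold analyses (which do not need
#' exposure data) still run.
#'
#' @param path Path to a CSV file.
#' @return A tibble of compounds: `name`, `severity_category`, `dili_label`,
#'   `cmax_uM`, `solubility_cap_uM`.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("name", "severity_category")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("compound table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$severity_category %in% 1:5)
  if (length(bad) > 0) {
    stop("unknown severity category in row(s) ",
         paste0(bad, " (", df$name[bad], ": ", df$severity_category[bad], ")",
                collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(normalize_name(df$name))
  if (any(dup)) {
    stop("duplicate compound name(s): ",
         paste(unique(df$name[dup]), collapse = ", "), call. = FALSE)
  }
  if (!"cmax_uM" %in% names(df)) df$cmax_uM <- NA_real_
  if (!"solubility_cap_uM" %in% names(df)) df$solubility_cap_uM <- NA_real_
  if (any(!is.na(df$cmax_uM) & df$cmax_uM <= 0)) {
    stop("cmax_uM must be positive where present", call. = FALSE)
  }
  tibble::tibble(
    name = as.character(df$name),
    severity_category = as.integer(df$severity_category),
    dili_label = dili_label_from_category(df$severity_category),
    cmax_uM = as.numeric(df$cmax_uM),
    solubility_cap_uM = as.numeric(df$solubility_cap_uM)
  )
}

#' Write a compound table to CSV
#'
#' @param compounds Tibble as returned by [read_compound_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(compounds, path) {
  out <- compounds[, c("name", "severity_category", "cmax_uM", "solubility_cap_uM")]
  out$cmax_uM <- signif(out$cmax_uM, 6)
  out$solubility_cap_uM <- signif(out$solubility_cap_uM, 6)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' The 110-drug DILI reference panel
#'
#' The marketed-drug test set used throughout this package's worked analyses:
#' 110 compounds spanning five clinical DILI severity categories
#' (23/23/23/16/25 compounds in categories 1-5), of which 69 are
#' DILI-positive (categories 1-3) and 41 DILI-negative (4-5). Names are kept
#' verbatim from the published compound list, including non-standard
#' spellings such as "Celocoxib" and "Sitax(s)entan". Clinical Cmax values
#' are not part of the fixture (supply your own, or use
#' [generate_panel()] for a fully synthetic panel with exposure data).
#'
#' @return A compound tibble (see [read_compound_table()]) with `cmax_uM` and
#'   `solubility_cap_uM` set to `NA`.
#' @export
#' @examples
#' table(reference_panel()$severity_category)
reference_panel <- function() {
  cat1 <- c("Amiodarone", "Benaxoprofen", "Benzbromarone", "Bosentan",
            "Danazol", "Dantrolene", "Felbamate", "Flutamide", "Ketoconazole",
            "Lapatinib", "Methotrexate", "Nefazodone", "Perhexiline",
            "Sitax(s)entan", "Stavudine", "Sudoxicam", "Sunitinib",
            "Tienilic Acid", "Tolcapone", "Troglitazone", "Trovafloxacin",
            "Valproic Acid", "Ximelagatran")
  cat2 <- c("Amodiaquine", "Atorvastatin", "Azathioprine", "Carbamazepine",
            "Celocoxib", "Clozapine", "Diclofenac", "Flucloxacillin",
            "Imipramine", "Indomethacin", "Itraconazole", "Levofloxacin",
            "Meloxicam", "Naproxen", "Nimesulide", "Nitrofurantoin",
            "Paroxetine", "Rosiglitazone", "Simvastatin", "Tacrine",
            "Tamoxifen", "Ticlopidine", "Zileuton")
  cat3 <- c("Acetaminophen", "Acetylsalicylic Acid", "Amitriptyline",
            "Beta-Estradiol", "Chlorpheniramine", "Chlorpromazine",
            "Clomipramine", "Cyclophosphamide", "Desipramine", "Fluoxetine",
            "Furazolidone", "Metformin", "Mitomycin C", "Nifedipine",
            "Penicillin V", "Phenformin", "Pimozide", "Pioglitazone",
            "Quinacrine", "Rosuvastatin", "Spectinomycin", "Tretinoin",
            "Verapamil")
  cat4 <- c("Bumentanide", "Buspirone", "Cycloserine", "Dabigatran",
            "Dexamethasone", "Entacapone", "Ethotion", "Felodipine",
            "Fludarabine", "Meclofenamate", "Minoxidil", "Nadolol",
            "Nicardipine", "Pargyline", "Penbutolol", "Theophylline")
  cat5 <- c("Albuterol", "Alendronate", "Ambrisentan", "Benserazide",
            "Benztropine", "Digoxin", "Flavoxate", "Flumazenil",
            "Guanethidine", "Hyoscyamine (Daturine)", "Indoramine",
            "Levocarnitine", "Liothyronine", "Mecamylamine", "Metergoline",
            "Neostigmine", "Orphenadrine", "Oxybutynin", "Phenoxybenzamine",
            "Phentolomine", "Procyclidine", "Propantheline", "Pyridostigmine",
            "Streptomycin", "Zomepirac")
  name <- c(cat1, cat2, cat3, cat4, cat5)
  severity_category <- rep(1:5, times = c(length(cat1), length(cat2),
                                          length(cat3), length(cat4),
                                          length(cat5)))
  tibble::tibble(
    name = name,
    severity_category = as.integer(severity_category),
    dili_label = dili_label_from_category(severity_category),
    cmax_uM = NA_real_,
    solubility_cap_uM = NA_real_
  )
}

#' Read a long-format plate viability table
#'
#' One row per well: `compound`, `assay_id`, `concentration_uM`,
#' `viability_pct` (% of vehicle control), `replicate`. Vehicle wells carry
#' concentration 0. The design uses 8-point serial dilutions plus vehicle;
#' the reader accepts any number of points but downstream fitting requires
#' at least four distinct non-vehicle concentrations.
#'
#' @param path Path to a CSV file.
#' @return A tibble of wells, grouped conceptually by (compound, assay_id);
#'   use [fit_panel()] to fit one curve per group.
#' @export
read_viability_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("compound", "assay_id", "concentration_uM", "viability_pct")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("viability table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (any(df$concentration_uM < 0)) {
    bad <- which(df$concentration_uM < 0)
    stop("negative concentration in row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out_of_range <- df$viability_pct < -20 | df$viability_pct > 200
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " viability value(s) outside [-20, 200]% kept as-is",
            call. = FALSE)
  }
  tibble::tibble(
    compound = as.character(df$compound),
    assay_id = as.character(df$assay_id),
    concentration_uM = as.numeric(df$concentration_uM),
    viability_pct = as.numeric(df$viability_pct),
    replicate = as.integer(df$replicate)
  )
}

#' Write a viability table to CSV
#'
#' @param wells Tibble as returned by [read_viability_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_viability_table <- function(wells, path) {
  out <- wells[, c("compound", "assay_id", "concentration_uM",
                   "viability_pct", "replicate")]
  out$concentration_uM <- signif(out$concentration_uM, 6)
  out$viability_pct <- signif(out$viability_pct, 6)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write dose-response fit tables
#'
#' Fit tables persist the output of [fit_panel()]: `compound`, `assay_id`,
#' `ic50_uM` (empty for censored fits), `hill_slope`, `censored`,
#' `top_tested_uM`.
#'
#' @param path Path to a CSV file.
#' @return A tibble of fits.
#' @export
read_fit_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("compound", "assay_id", "ic50_uM", "censored", "top_tested_uM")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("fit table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"hill_slope" %in% names(df)) df$hill_slope <- NA_real_
  tibble::tibble(
    compound = as.character(df$compound),
    assay_id = as.character(df$assay_id),
    ic50_uM = as.numeric(df$ic50_uM),
    hill_slope = as.numeric(df$hill_slope),
    censored = as.logical(df$censored),
    top_tested_uM = as.numeric(df$top_tested_uM)
  )
}

#' @rdname read_fit_table
#' @param fits Tibble of fits as returned by [fit_panel()].
#' @export
write_fit_table <- function(fits, path) {
  out <- tibble::tibble(
    compound = fits$compound,
    assay_id = fits$assay_id,
    ic50_uM = signif(ifelse(fits$censored, NA_real_, fits$ic50_uM), 6),
    hill_slope = signif(fits$hill_slope, 6),
    censored = fits$censored,
    top_tested_uM = signif(fits$top_tested_uM, 6)
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
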