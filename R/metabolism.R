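# Data reductions for caffeine regiospecificity assays of CPR-variant /
# CYP1A2 membrane fractions: metabolite fractions, WT-normalized relative
# profiles, mass balance, CPR:CYP stoichiometry, stability flags, ROS
# background correction, absorbance-to-rate conversion and
# caffeine-gradient normalization.

#' Default assay constants
#'
#' DCPIP extinction coefficient, caffeine assay concentration
#' (approximately twice the Km of the three CYP1A2-mediated reactions),
#' CYP concentration and the caffeine gradient range used in cytochrome c
#' competition assays.
#'
#' @return named list: `dcpip_epsilon` (1/M/cm), `caffeine_concentration`
#'   (uM), `cyp_concentration` (nM), `caffeine_gradient` (uM range).
#' @export
assay_constants <- function() {
  list(
    dcpip_epsilon = 21000,       # M^-1 cm^-1
    caffeine_concentration = 600, # uM, ~2x Km
    cyp_concentration = 60,       # nM
    caffeine_gradient = c(0, 1000) # uM
  )
}

#' Read a membrane-fraction characterization table
#'
#' Delimited text with one row per membrane fraction. Required columns:
#' `variant_id`, `cpr_region`, `wt_reference_id`, `cyp_content`,
#' `cpr_content` (pmol/mg), `stability_ratio` (cyt c reduction 6 h / 0 h),
#' `caffeine_consumed`, `theophylline`, `theobromine`, `paraxanthine`
#' (uM). Extra columns (e.g. printed ratios, SDs) are carried through.
#' `NA` entries mark not-detected values (CPR-null controls).
#'
#' @param path TSV/CSV file; the delimiter is sniffed from the header.
#' @return data.frame.
#' @export
read_membrane_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tbl <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", "ND"))
  req <- c("variant_id", "cpr_region", "wt_reference_id", "cyp_content",
           "cpr_content", "stability_ratio", "caffeine_consumed",
           "theophylline", "theobromine", "paraxanthine")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tbl
}

#' The packaged membrane-fraction characterization table
#'
#' Seventeen CPR-variant and wild-type membrane fractions co-expressing
#' CYP1A2, plus the CPR-null control: protein contents, stability ratios,
#' caffeine consumption and the three metabolite amounts, with the
#' wild-type reference mapping used for relative profiles. Values are
#' published means; `*_sd` columns carry the printed standard deviations
#' (N = 3 technical replicates).
#'
#' @return data.frame (see [read_membrane_table()] for the column
#'   contract; `printed_ratio` is the CPR:CYP ratio as printed).
#' @export
caffeine_membrane_fractions <- function() {
  path <- system.file("extdata", "membrane_fractions_caffeine.tsv",
                      package = "cprfit", mustWork = TRUE)
  read_membrane_table(path)
}

# internal: pull named columns from a one-row record (data.frame row or list)
.rec <- function(r, field) {
  v <- r[[field]]
  if (is.null(v)) stop("record lacks field '", field, "'")
  v
}

#' Metabolite regiospecificity fractions
#'
#' Fraction of each primary caffeine metabolite (theophylline, theobromine,
#' paraxanthine) relative to the metabolite sum. Vectorized over table
#' rows; any row whose metabolite sum is not positive (e.g. a CPR-null
#' control) is an error.
#'
#' @param r membrane-fraction table (or single record).
#' @return data.frame (variant_id, fraction_theophylline,
#'   fraction_theobromine, fraction_paraxanthine); fractions sum to 1.
#' @export
metabolite_fractions <- function(r) {
  tp <- .rec(r, "theophylline")
  tb <- .rec(r, "theobromine")
  px <- .rec(r, "paraxanthine")
  id <- if (!is.null(r$variant_id)) r$variant_id else
    paste0("record", seq_along(tp))
  total <- tp + tb + px
  bad <- is.na(total) | total <= 0
  if (any(bad)) {
    stop("metabolite sum not positive for: ", paste(id[bad], collapse = ", "))
  }
  data.frame(
    variant_id = id,
    fraction_theophylline = tp / total,
    fraction_theobromine = tb / total,
    fraction_paraxanthine = px / total,
    stringsAsFactors = FALSE
  )
}

#' Caffeine mass balance check
#'
#' Compares consumed caffeine with the sum of the three measured
#' metabolites; under complete N-demethylation accounting the two agree to
#' reporting precision.
#'
#' @param r membrane-fraction table (or single record).
#' @param tol residual tolerance in uM (default 0.02, i.e. printed
#'   two-decimal precision).
#' @return data.frame (variant_id, caffeine_consumed, metabolite_sum,
#'   residual, pass).
#' @export
mass_balance <- function(r, tol = 0.02) {
  tp <- .rec(r, "theophylline")
  tb <- .rec(r, "theobromine")
  px <- .rec(r, "paraxanthine")
  cons <- .rec(r, "caffeine_consumed")
  id <- if (!is.null(r$variant_id)) r$variant_id else
    paste0("record", seq_along(tp))
  if (any(is.na(c(tp, tb, px, cons)))) {
    stop("missing amounts for: ",
         paste(id[is.na(tp + tb + px + cons)], collapse = ", "))
  }
  msum <- tp + tb + px
  residual <- abs(cons - msum)
  data.frame(
    variant_id = id, caffeine_consumed = cons, metabolite_sum = msum,
    residual = residual, pass = residual <= tol, stringsAsFactors = FALSE
  )
}

#' Relative metabolite profile and consumption versus matched wild type
#'
#' Per-metabolite ratio of the variant's regiospecificity fraction over
#' its matched wild-type reference's fraction, plus the relative caffeine
#' consumption (consumed-uM ratio as a proxy for the observed-rate ratio:
#' all couples share incubation time and CYP concentration).
#'
#' @param v variant record (single row).
#' @param wt matched wild-type reference record (single row).
#' @param check_reference verify that `wt$variant_id` equals
#'   `v$wt_reference_id` (default TRUE; disable to compare against an
#'   arbitrary reference).
#' @return data.frame (variant_id, wt_id, ratio_theophylline,
#'   ratio_theobromine, ratio_paraxanthine, relative_consumption).
#' @export
relative_profile <- function(v, wt, check_reference = TRUE) {
  if (length(.rec(v, "theophylline")) != 1L ||
      length(.rec(wt, "theophylline")) != 1L) {
    stop("relative_profile compares one variant row with one reference row")
  }
  if (check_reference &&
      !identical(as.character(v$wt_reference_id),
                 as.character(wt$variant_id))) {
    stop("reference mismatch: variant '", v$variant_id, "' expects '",
         v$wt_reference_id, "' but got '", wt$variant_id,
         "' (set check_reference = FALSE to override)")
  }
  fv <- metabolite_fractions(v)
  fw <- metabolite_fractions(wt)
  data.frame(
    variant_id = v$variant_id, wt_id = wt$variant_id,
    ratio_theophylline = fv$fraction_theophylline / fw$fraction_theophylline,
    ratio_theobromine = fv$fraction_theobromine / fw$fraction_theobromine,
    ratio_paraxanthine = fv$fraction_paraxanthine / fw$fraction_paraxanthine,
    relative_consumption = v$caffeine_consumed / wt$caffeine_consumed,
    stringsAsFactors = FALSE
  )
}

# round half away from zero (base round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' CPR:CYP stoichiometry as the integer n of "1:n"
#'
#' `n = round(cyp_content / cpr_content)`, half away from zero. Microsomal
#' membranes characteristically carry sub-molar CPR relative to CYP.
#'
#' @param r membrane-fraction table (or single record).
#' @return data.frame (variant_id, cyp_content, cpr_content, ratio_n,
#'   ratio_label).
#' @export
cpr_cyp_ratio <- function(r) {
  cyp <- .rec(r, "cyp_content")
  cpr <- .rec(r, "cpr_content")
  id <- if (!is.null(r$variant_id)) r$variant_id else
    paste0("record", seq_along(cyp))
  bad <- is.na(cpr) | cpr <= 0 | is.na(cyp)
  if (any(bad)) {
    stop("missing or non-positive CPR content for: ",
         paste(id[bad], collapse = ", "))
  }
  n <- as.integer(.round_half_away(cyp / cpr))
  data.frame(
    variant_id = id, cyp_content = cyp, cpr_content = cpr,
    ratio_n = n, ratio_label = paste0("1:", n), stringsAsFactors = FALSE
  )
}

#' Flag unstable membrane fractions
#'
#' A fraction is flagged when its cytochrome c reduction activity after
#' the 6 h incubation drops below `threshold` of the 0 h activity.
#'
#' @param r membrane-fraction table (or single record).
#' @param threshold stability ratio below which a fraction is flagged
#'   (default 0.8).
#' @return data.frame (variant_id, stability_ratio, unstable).
#' @export
stability_flag <- function(r, threshold = 0.8) {
  ratio <- .rec(r, "stability_ratio")
  id <- if (!is.null(r$variant_id)) r$variant_id else
    paste0("record", seq_along(ratio))
  data.frame(
    variant_id = id, stability_ratio = ratio,
    unstable = !is.na(ratio) & ratio < threshold,
    stringsAsFactors = FALSE
  )
}

#' Background-correct a fluorescence rate signal
#'
#' Subtracts the paired no-NADPH control from the raw ROS formation rate.
#' Negative corrected rates are retained and flagged rather than clipped.
#'
#' @param raw raw signal (FU/min).
#' @param control paired control without the NADPH regenerating system
#'   (FU/min); same length as `raw`.
#' @return data.frame (raw, control, corrected, negative).
#' @export
background_correct <- function(raw, control) {
  if (length(control) != length(raw)) {
    stop("raw and control must be paired (equal length)")
  }
  if (any(is.na(control))) stop("missing control values")
  corrected <- raw - control
  data.frame(raw = raw, control = control, corrected = corrected,
             negative = corrected < 0)
}

#' Convert an absorbance slope to a molar rate
#'
#' Beer-Lambert conversion `rate = dAbs / (epsilon * path)`, in
#' mol L^-1 min^-1. The default extinction coefficient is the DCPIP delta
#' epsilon at 600 nm.
#'
#' @param dabs_per_min absorbance change per minute.
#' @param epsilon molar extinction coefficient (1/M/cm; default 21000).
#' @param path_cm optical path length in cm (default 1).
#' @return rate in mol L^-1 min^-1.
#' @export
absorbance_to_rate <- function(dabs_per_min,
                               epsilon = assay_constants()$dcpip_epsilon,
                               path_cm = 1) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (path_cm <= 0) stop("path length must be positive")
  dabs_per_min / (epsilon * path_cm)
}

#' Normalize a caffeine-gradient rate curve to the wild-type zero-caffeine
#' rate
#'
#' Divides each observed rate by the wild-type rate without caffeine and
#' summarizes inhibition as the maximum fractional drop relative to the
#' curve's own lowest-concentration value.
#'
#' @param caffeine caffeine concentrations (uM).
#' @param rate observed rates at those concentrations.
#' @param wt_zero_rate wild-type rate at 0 uM caffeine (> 0).
#' @return data.frame (caffeine, rate, normalized) with attribute
#'   `max_drop` (0 for a flat or rising curve).
#' @export
gradient_normalize <- function(caffeine, rate, wt_zero_rate) {
  if (length(caffeine) != length(rate)) {
    stop("caffeine and rate must have equal length")
  }
  if (is.na(wt_zero_rate) || wt_zero_rate <= 0) {
    stop("wild-type zero-caffeine rate must be positive")
  }
  ord <- order(caffeine)
  out <- data.frame(caffeine = caffeine[ord], rate = rate[ord],
                    normalized = rate[ord] / wt_zero_rate)
  base <- out$normalized[1L]
  attr(out, "max_drop") <- max(0, (base - min(out$normalized)) / base)
  out
}
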