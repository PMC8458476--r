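# Config-driven logistic risk scoring with bilateral (maternal/paternal)
# evaluation and computational affected-side assignment.

#' Construct the per-side predictor record for the risk model
#'
#' One record per parental side, normally produced by [aggregate_side()].
#' Counts are non-negative; a minimum age may be present only when the
#' corresponding count (or indicator) is positive. Absent ages are handled
#' by the coefficient file's declared absent-age policy at scoring time.
#'
#' @param proband_sex_male Logical.
#' @param proband_age Proband's current age in years.
#' @param proband_crc_count,proband_crc_min_age Proband colorectal cancers:
#'   count and youngest known age at diagnosis (`NA` when unknown).
#' @param proband_ec,proband_other_ls Proband endometrial / other
#'   Lynch-associated cancer indicators.
#' @param fdr_crc_count,fdr_crc_min_age,sdr_crc_count,sdr_crc_min_age
#'   First-/second-degree relative colorectal cells.
#' @param fdr_ec,sdr_ec Relative endometrial indicators by degree.
#' @param fdr_sdr_other_ls Any other Lynch-associated cancer in a first- or
#'   second-degree relative.
#' @param ec_min_age Youngest known endometrial diagnosis age across proband
#'   and relatives.
#' @return A `premm5_inputs` object.
#' @export
premm5_inputs <- function(proband_sex_male = FALSE, proband_age = 45,
                          proband_crc_count = 0L, proband_crc_min_age = NA,
                          proband_ec = FALSE, proband_other_ls = FALSE,
                          fdr_crc_count = 0L, fdr_crc_min_age = NA,
                          sdr_crc_count = 0L, sdr_crc_min_age = NA,
                          fdr_ec = FALSE, sdr_ec = FALSE,
                          fdr_sdr_other_ls = FALSE, ec_min_age = NA) {
  counts <- c(proband_crc_count = proband_crc_count,
              fdr_crc_count = fdr_crc_count, sdr_crc_count = sdr_crc_count)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  chk <- function(count_ok, age, nm) {
    if (!is.na(age) && !count_ok) {
      stop(nm, " present but its count/indicator is zero")
    }
    .check_age(age, nm)
  }
  structure(list(
    proband_sex_male = isTRUE(proband_sex_male),
    proband_age = as.integer(proband_age),
    proband_crc_count = as.integer(proband_crc_count),
    proband_crc_min_age = chk(proband_crc_count >= 1, proband_crc_min_age, "proband_crc_min_age"),
    proband_ec = isTRUE(proband_ec),
    proband_other_ls = isTRUE(proband_other_ls),
    fdr_crc_count = as.integer(fdr_crc_count),
    fdr_crc_min_age = chk(fdr_crc_count >= 1, fdr_crc_min_age, "fdr_crc_min_age"),
    sdr_crc_count = as.integer(sdr_crc_count),
    sdr_crc_min_age = chk(sdr_crc_count >= 1, sdr_crc_min_age, "sdr_crc_min_age"),
    fdr_ec = isTRUE(fdr_ec),
    sdr_ec = isTRUE(sdr_ec),
    fdr_sdr_other_ls = isTRUE(fdr_sdr_other_ls),
    ec_min_age = chk(isTRUE(proband_ec) || isTRUE(fdr_ec) || isTRUE(sdr_ec),
                     ec_min_age, "ec_min_age")
  ), class = "premm5_inputs")
}

# features whose value is an age (subject to the absent-age policy)
.age_features <- c("proband_crc_min_age", "fdr_crc_min_age",
                   "sdr_crc_min_age", "ec_min_age")

#' Load and validate a risk-model coefficient file
#'
#' Coefficient files are versioned, provenance-stamped JSON:
#' `{version, provenance, intercept, terms: [{feature, transform,
#' coefficient}], absent_age_policy}`. Each `feature` must name a
#' [premm5_inputs()] field; `transform` is one of
#' * `{"type": "identity"}` — the raw value (indicators become 0/1),
#' * `{"type": "count_capped", "cap": k}` — `min(value, k)`,
#' * `{"type": "youth", "center": c, "scale": s}` — `max(0, (c - age)/s)`,
#'   so younger diagnoses increase the predictor and ages at or beyond the
#'   center contribute zero,
#' * `{"type": "centered_decade", "center": c}` — `(value - c)/10`.
#'
#' `absent_age_policy` is mandatory: either
#' `{"mode": "reference_age", "value": a}` (absent ages scored as age `a`)
#' or `{"mode": "zero_contribution"}` (absent-age terms contribute 0).
#' Files without a policy are refused.
#'
#' @param path Path to the JSON coefficient file.
#' @return A `premm5_coefficients` object.
#' @export
load_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("version", "provenance", "intercept", "terms", "absent_age_policy")) {
    if (is.null(x[[f]])) stop("coefficient file missing required field '", f, "'")
  }
  pol <- x$absent_age_policy
  if (is.null(pol$mode) || !pol$mode %in% c("reference_age", "zero_contribution")) {
    stop("absent_age_policy mode must be 'reference_age' or 'zero_contribution'")
  }
  if (pol$mode == "reference_age" && !is.numeric(pol$value)) {
    stop("absent_age_policy 'reference_age' requires a numeric 'value'")
  }
  fields <- names(formals(premm5_inputs))
  terms <- lapply(x$terms, function(tm) {
    if (is.null(tm$feature) || is.null(tm$transform) || is.null(tm$coefficient)) {
      stop("each term needs feature, transform and coefficient")
    }
    if (!tm$feature %in% fields) {
      stop("term feature '", tm$feature, "' does not resolve to a model input")
    }
    tt <- tm$transform
    if (is.null(tt$type) ||
        !tt$type %in% c("identity", "count_capped", "youth", "centered_decade")) {
      stop("unknown transform type for feature '", tm$feature, "'")
    }
    if (tt$type == "count_capped" && !is.numeric(tt$cap)) stop("count_capped needs 'cap'")
    if (tt$type == "youth" && (!is.numeric(tt$center) || !is.numeric(tt$scale))) {
      stop("youth transform needs 'center' and 'scale'")
    }
    if (tt$type == "centered_decade" && !is.numeric(tt$center)) {
      stop("centered_decade needs 'center'")
    }
    list(feature = tm$feature, transform = tt,
         coefficient = as.numeric(tm$coefficient))
  })
  structure(list(version = x$version, provenance = x$provenance,
                 intercept = as.numeric(x$intercept), terms = terms,
                 absent_age_policy = pol),
            class = "premm5_coefficients")
}

#' Default shipped coefficient file (synthetic stand-in)
#'
#' The published model coefficients are not redistributed here; the shipped
#' default is a documented synthetic set with the published model's
#' structure (positive cancer-history effects, younger diagnosis ages more
#' informative) whose provenance field marks it as synthetic. Substitute a
#' transcription of the published coefficients for clinical use.
#'
#' @return A `premm5_coefficients` object.
#' @export
default_coefficients <- function() {
  load_coefficients(system.file("extdata", "premm5-coefficients-synthetic.json",
                                package = "lynchtriage", mustWork = TRUE))
}

.transform_value <- function(value, transform) {
  switch(transform$type,
    identity = value,
    count_capped = min(value, transform$cap),
    youth = max(0, (transform$center - value) / transform$scale),
    centered_decade = (value - transform$center) / 10,
    stop("unknown transform type: ", transform$type)
  )
}

#' Evaluate the logistic risk model on one predictor record
#'
#' Computes `p = 1 / (1 + exp(-eta))` with
#' `eta = intercept + sum(coefficient * transform(feature))`. Absent ages
#' are resolved through the coefficient file's absent-age policy before the
#' transform is applied.
#'
#' @param inputs A [premm5_inputs()] record.
#' @param coeffs A [load_coefficients()] object.
#' @return Mutation-carrier probability in (0, 1).
#' @export
score_inputs <- function(inputs, coeffs) {
  stopifnot(inherits(inputs, "premm5_inputs"),
            inherits(coeffs, "premm5_coefficients"))
  pol <- coeffs$absent_age_policy
  eta <- coeffs$intercept
  for (tm in coeffs$terms) {
    v <- inputs[[tm$feature]]
    if (is.null(v)) stop("coefficient term references unknown feature: ", tm$feature)
    if (is.logical(v)) v <- as.numeric(v)
    if (tm$feature %in% .age_features && is.na(v)) {
      if (pol$mode == "zero_contribution") next
      v <- pol$value
    }
    if (is.na(v)) stop("missing value for feature ", tm$feature)
    eta <- eta + tm$coefficient * .transform_value(v, tm$transform)
  }
  stats::plogis(eta)
}

#' Bilateral scoring with computational affected-side assignment
#'
#' Scores the maternal and the paternal aggregation of the family history
#' separately and assigns the affected side as the side with the higher
#' score (ties broken maternal). The reported score is the winning side's
#' score, so the patient never has to choose an affected side.
#'
#' @param fh A [family_history()] object.
#' @param coeffs A [load_coefficients()] object.
#' @param threshold Clinical-significance threshold on the probability
#'   scale; default 0.025 (2.5 percent).
#' @return A `premm5_result` with fields `maternal_score`, `paternal_score`,
#'   `affected_side`, `reported_score`, `clinically_significant`.
#' @export
score_bilateral <- function(fh, coeffs, threshold = 0.025) {
  stopifnot(inherits(fh, "lynch_family_history"))
  m <- score_inputs(aggregate_side(fh, "maternal"), coeffs)
  p <- score_inputs(aggregate_side(fh, "paternal"), coeffs)
  side <- if (m >= p) "maternal" else "paternal"
  reported <- max(m, p)
  structure(list(
    maternal_score = m, paternal_score = p, affected_side = side,
    reported_score = reported,
    clinically_significant = classify_significant(reported, threshold),
    threshold = threshold
  ), class = "premm5_result")
}

#' @export
print.premm5_result <- function(x, ...) {
  cat(sprintf("<risk score> maternal %.1f%% / paternal %.1f%% -> %s side, reported %.1f%% (%s)\n",
              100 * x$maternal_score, 100 * x$paternal_score, x$affected_side,
              100 * x$reported_score,
              if (x$clinically_significant) "clinically significant" else "below threshold"))
  invisible(x)
}

#' Clinical-significance classification
#'
#' Inclusive comparison against the clinically significant risk threshold
#' (a score of exactly 2.5 percent qualifies).
#'
#' @param p Probability in `[0, 1]`.
#' @param threshold Threshold probability, default 0.025.
#' @return Logical.
#' @export
classify_significant <- function(p, threshold = 0.025) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  p >= threshold
}

#' Limited family knowledge / structure evaluation
#'
#' A pedigree is uninformative when the proband was adopted or does not know
#' one side's cancer history (limited knowledge), or when fewer than 2
#' female relatives lived beyond age 45 on either side (limited structure).
#' Prior genetic testing for Lynch syndrome or hereditary breast/ovarian
#' cancer is screened and reported alongside.
#'
#' @param fh A [family_history()] object.
#' @return A `limited_history_result` with logical fields
#'   `limited_knowledge`, `limited_structure`, `prior_testing`.
#' @export
evaluate_limited_history <- function(fh) {
  stopifnot(inherits(fh, "lynch_family_history"))
  structure(list(
    limited_knowledge = fh$adopted || !fh$knows_maternal_history ||
      !fh$knows_paternal_history,
    limited_structure = fh$females_over_45_maternal < 2 ||
      fh$females_over_45_paternal < 2,
    prior_testing = fh$prior_ls_testing || fh$prior_hboc_testing
  ), class = "limited_history_result")
}

#' Hereditary breast/ovarian cancer screen (non-validated stub)
#'
#' Plug-in boundary for the companion breast-cancer genetics referral
#' screen. The shipped stub is NOT the validated instrument: it returns
#' `"moderate"` whenever any breast or ovarian diagnosis is present in the
#' proband or a relative, or the Ashkenazi ancestry flag is set, and
#' `"negative"` otherwise. Inject a real implementation through the
#' `brst_impl` argument of [route()] to replace it.
#'
#' @param fh A [family_history()] object.
#' @return A `brst_result` with field `level` in
#'   `{"negative", "moderate", "high"}`.
#' @export
brst_screen <- function(fh) {
  stopifnot(inherits(fh, "lynch_family_history"))
  types <- c("breast", "ovarian")
  hit <- .has_type(fh$proband$diagnoses, types) ||
    any(vapply(fh$relatives, function(r) .has_type(r$diagnoses, types), logical(1))) ||
    fh$ashkenazi
  structure(list(level = if (hit) "moderate" else "negative"),
            class = "brst_result")
}
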