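# Analytic-validity statistics: agreement between patient-derived and
# genetic counselor-derived risk scores.

#' Paired participant/counselor risk scores
#'
#' @param id Identifier strings.
#' @param participant_score,counselor_score Probabilities in `[0, 1]`; `NA`
#'   when the respective rater produced no score (e.g. the patient reported
#'   no Lynch-associated cancer history and was routed past the scoring
#'   questions).
#' @return A data.frame of class `paired_scores`.
#' @export
paired_scores <- function(id, participant_score, counselor_score) {
  stopifnot(length(id) == length(participant_score),
            length(id) == length(counselor_score))
  chk <- function(x, nm) {
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      stop(nm, " must be probabilities in [0, 1] (or NA)")
    }
    as.numeric(x)
  }
  structure(data.frame(id = as.character(id),
                       participant_score = chk(participant_score, "participant_score"),
                       counselor_score = chk(counselor_score, "counselor_score"),
                       stringsAsFactors = FALSE),
            class = c("paired_scores", "data.frame"))
}

#' Read / write paired scores as CSV
#'
#' Header `id,participant_score,counselor_score`; blank cells denote absent
#' scores.
#'
#' @param path CSV file path.
#' @param pairs A [paired_scores()] data.frame.
#' @return `read_paired_scores` returns a [paired_scores()] data.frame.
#' @export
read_paired_scores <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("character", "numeric", "numeric"))
  paired_scores(x$id, x$participant_score, x$counselor_score)
}

#' @rdname read_paired_scores
#' @export
write_paired_scores <- function(pairs, path) {
  utils::write.csv(as.data.frame(unclass(pairs))[
    c("id", "participant_score", "counselor_score")], path,
    row.names = FALSE, na = "")
  invisible(path)
}

#' Zero-impute absent scores
#'
#' A rater who recorded no Lynch-associated cancer history produced no
#' score; such scores are synthetically set to 0 so that false-negative
#' candidates (no patient score, positive counselor score) and
#' counselor-confirmed negative histories both enter the agreement
#' analysis.
#'
#' @param pairs A [paired_scores()] data.frame.
#' @return The pairs with every absent score replaced by 0; present scores
#'   unchanged.
#' @export
impute_zero <- function(pairs) {
  pairs$participant_score[is.na(pairs$participant_score)] <- 0
  pairs$counselor_score[is.na(pairs$counselor_score)] <- 0
  pairs
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moments, per the original estimator. Measures agreement
#' with the identity line, penalizing both imprecision and location/scale
#' shift.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`; at least one must
#'   be non-constant.
#' @return The concordance correlation coefficient in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA (impute first)")
  n <- length(x)
  if (n < 2) stop("insufficient data: need n >= 2 pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) stop("undefined statistic: both vectors are constant")
  denom <- sx2 + sy2 + (mx - my)^2
  2 * sxy / denom
}

#' Asymptotic confidence interval for Lin's CCC
#'
#' Fisher z-transforms the estimate and applies Lin's corrected asymptotic
#' variance, which involves the Pearson correlation `r` and the
#' standardized location shift `u = (mean(x) - mean(y)) / sqrt(s_x s_y)`:
#' `Var(z) = [ (1 - r^2) ccc^2 / ((1 - ccc^2) r^2)`
#' ` + 2 ccc^3 (1 - ccc) u^2 / (r (1 - ccc^2)^2)`
#' ` - ccc^4 u^4 / (2 r^2 (1 - ccc^2)^2) ] / (n - 2)`.
#' With no location shift and `r = ccc` this reduces to `1 / (n - 2)`. A
#' nonparametric bootstrap interval is available as an option.
#'
#' @param x,y Numeric vectors, `n >= 3`.
#' @param alpha Two-sided error rate (default 0.05 for a 95 percent CI).
#' @param method `"asymptotic"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `method = "bootstrap"`.
#' @return List with `estimate`, `lower`, `upper`.
#' @export
ccc_ci <- function(x, y, alpha = 0.05, method = c("asymptotic", "bootstrap"),
                   boot_reps = 2000L) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3) stop("insufficient data: need n >= 3 pairs")
  ccc <- lin_ccc(x, y)
  if (abs(ccc) >= 1) stop("degenerate CI: |ccc| = 1")
  if (method == "bootstrap") {
    est <- vapply(seq_len(boot_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      lin_ccc(x[idx], y[idx])
    }, numeric(1))
    q <- stats::quantile(est, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    return(list(estimate = ccc, lower = q[1], upper = q[2]))
  }
  r <- stats::cor(x, y)
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  u <- (mean(x) - mean(y)) / sqrt(sx * sy)
  v <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
          2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
          ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  z <- atanh(ccc)
  zq <- stats::qnorm(1 - alpha / 2)
  list(estimate = ccc, lower = tanh(z - zq * sqrt(v)),
       upper = tanh(z + zq * sqrt(v)))
}

#' Power of a one-sided test on Lin's CCC
#'
#' Power to reject `H0: ccc = ccc0` in favor of a larger true concordance
#' `ccc1` with `n` pairs at one-sided level `alpha`, via the Fisher-z
#' asymptotic method under no location/scale shift between raters (`u = 0`,
#' `r = ccc1`), where the z-scale variance is `1 / (n - 2)`:
#' `power = Phi( (atanh(ccc1) - atanh(ccc0)) * sqrt(n - 2) - z_{1-alpha} )`.
#'
#' @param ccc0 Null (minimum acceptable) concordance, in (0, 1).
#' @param ccc1 True concordance under the alternative, `ccc1 > ccc0`.
#' @param n Number of paired observations, `n >= 3`.
#' @param alpha One-sided significance level in (0, 0.5).
#' @return Power in `[0, 1]`.
#' @export
ccc_power <- function(ccc0, ccc1, n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha < 0.5, ccc0 > 0, ccc0 < 1, ccc1 < 1)
  if (ccc1 <= ccc0) stop("invalid alternative: ccc1 must exceed ccc0")
  stats::pnorm((atanh(ccc1) - atanh(ccc0)) * sqrt(n - 2) -
                 stats::qnorm(1 - alpha))
}

#' Threshold misclassification counts
#'
#' At threshold `tau` (clinically significant risk), a pair is a true
#' positive when both scores are `>= tau`, a true negative when both are
#' `< tau`, a false positive when only the participant score reaches `tau`,
#' and a false negative when only the counselor score does. Sensitivity is
#' `tp / (tp + fn)`, specificity `tn / (tn + fp)` (NA on empty
#' denominators).
#'
#' @param pairs Imputed [paired_scores()] (no absent scores).
#' @param threshold Probability threshold, default 0.025.
#' @return List `tp`, `tn`, `fp`, `fn`, `sensitivity`, `specificity`.
#' @export
confusion_counts <- function(pairs, threshold = 0.025) {
  p <- pairs$participant_score; g <- pairs$counselor_score
  if (anyNA(p) || anyNA(g)) stop("absent scores present: impute first")
  tp <- sum(p >= threshold & g >= threshold)
  tn <- sum(p < threshold & g < threshold)
  fp <- sum(p >= threshold & g < threshold)
  fn <- sum(p < threshold & g >= threshold)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Flag highly discrepant and outlying pairs
#'
#' A pair is highly discrepant when the absolute score difference is at
#' least `cut` (a priori 0.05, i.e. 5 percentage points); extreme outliers
#' use the larger cut 0.15. Both comparisons are inclusive.
#'
#' @param pairs Imputed [paired_scores()].
#' @param cut Absolute difference cut on the probability scale.
#' @return Character vector of flagged ids.
#' @export
flag_discrepant <- function(pairs, cut = 0.05) {
  p <- pairs$participant_score; g <- pairs$counselor_score
  if (anyNA(p) || anyNA(g)) stop("absent scores present: impute first")
  pairs$id[abs(p - g) >= cut]
}

#' @rdname flag_discrepant
#' @export
flag_outliers <- function(pairs, cut = 0.15) {
  flag_discrepant(pairs, cut = cut)
}

#' Analysis configuration for the validity report
#'
#' @param threshold Clinically significant risk threshold (probability).
#' @param discrepancy_cut,outlier_cut Absolute-difference cuts
#'   (probability scale).
#' @param alpha CI error rate.
#' @param ci_two_sided Two-sided CI (the default).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(threshold = 0.025, discrepancy_cut = 0.05,
                            outlier_cut = 0.15, alpha = 0.05,
                            ci_two_sided = TRUE) {
  stopifnot(threshold > 0, threshold < 1,
            discrepancy_cut > 0, discrepancy_cut < 1,
            outlier_cut > 0, outlier_cut < 1,
            alpha > 0, alpha <= 0.5)
  structure(list(threshold = threshold, discrepancy_cut = discrepancy_cut,
                 outlier_cut = outlier_cut, alpha = alpha,
                 ci_two_sided = isTRUE(ci_two_sided)),
            class = "analysis_config")
}

#' Full concordance report
#'
#' Zero-imputes absent scores, computes Lin's CCC with its CI on all pairs
#' and again excluding extreme outliers (inclusive absolute difference at
#' or above the outlier cut), and attaches the threshold confusion counts,
#' sensitivity/specificity and the discrepancy/outlier flags.
#'
#' @param pairs A [paired_scores()] data.frame (absent scores allowed; they
#'   are imputed to 0 first).
#' @param config An [analysis_config()].
#' @return A `concordance_report` list.
#' @export
summarize_concordance <- function(pairs, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  pairs <- impute_zero(pairs)
  n <- nrow(pairs)
  if (n < 3) stop("insufficient data: need n >= 3 pairs after imputation")
  x <- pairs$participant_score; y <- pairs$counselor_score
  ccc <- lin_ccc(x, y)
  ci <- if (abs(ccc) < 1) ccc_ci(x, y, alpha = config$alpha) else
    list(estimate = ccc, lower = NA_real_, upper = NA_real_)
  outlier_ids <- flag_outliers(pairs, cut = config$outlier_cut)
  keep <- !pairs$id %in% outlier_ids
  if (sum(keep) >= 3 && length(outlier_ids) > 0) {
    ccc_ex <- lin_ccc(x[keep], y[keep])
    ci_ex <- if (abs(ccc_ex) < 1) ccc_ci(x[keep], y[keep], alpha = config$alpha) else
      list(estimate = ccc_ex, lower = NA_real_, upper = NA_real_)
  } else {
    ccc_ex <- ccc
    ci_ex <- ci
  }
  conf <- confusion_counts(pairs, threshold = config$threshold)
  structure(list(
    n = n, ccc = ccc, ci = c(lower = ci$lower, upper = ci$upper),
    ccc_excluding_outliers = ccc_ex,
    ci_excluding_outliers = c(lower = ci_ex$lower, upper = ci_ex$upper),
    tp = conf$tp, tn = conf$tn, fp = conf$fp, fn = conf$fn,
    sensitivity = conf$sensitivity, specificity = conf$specificity,
    discrepant_ids = flag_discrepant(pairs, cut = config$discrepancy_cut),
    outlier_ids = outlier_ids,
    config = config
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(render_concordance_report(x), "\n")
  invisible(x)
}

#' Markdown rendering of a concordance report
#'
#' @param report A `concordance_report`.
#' @return Character scalar (markdown table plus flags).
#' @export
render_concordance_report <- function(report) {
  stopifnot(inherits(report, "concordance_report"))
  fmt_ci <- function(ci) sprintf("[%.2f, %.2f]", ci["lower"], ci["upper"])
  lines <- c(
    "# Analytic validity summary", "",
    sprintf("| metric | value |"),
    sprintf("|---|---|"),
    sprintf("| n pairs | %d |", report$n),
    sprintf("| CCC (all pairs) | %.2f %s |", report$ccc, fmt_ci(report$ci)),
    sprintf("| CCC (excluding outliers) | %.2f %s |",
            report$ccc_excluding_outliers, fmt_ci(report$ci_excluding_outliers)),
    sprintf("| TP / TN / FP / FN | %d / %d / %d / %d |",
            report$tp, report$tn, report$fp, report$fn),
    sprintf("| sensitivity | %s |", .fmt_or_na(report$sensitivity)),
    sprintf("| specificity | %s |", .fmt_or_na(report$specificity)),
    sprintf("| highly discrepant (>= %.0f%%) | %s |",
            100 * report$config$discrepancy_cut, .fmt_ids(report$discrepant_ids)),
    sprintf("| extreme outliers (>= %.0f%%) | %s |",
            100 * report$config$outlier_cut, .fmt_ids(report$outlier_ids))
  )
  paste(lines, collapse = "\n")
}

.fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
.fmt_ids <- function(ids) if (length(ids) == 0) "none" else paste(ids, collapse = ", ")

#' Write a concordance report as JSON
#'
#' @param report A `concordance_report`.
#' @param path Output JSON path.
#' @export
write_concordance_report <- function(report, path) {
  x <- unclass(report)
  x$config <- unclass(x$config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
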