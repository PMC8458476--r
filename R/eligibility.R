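# Eligibility routing: gate questions -> randomized risk-screen exposure ->
# limited-family-history module -> eligibility outcome.

#' Gate answers
#'
#' The two initial questions that determine which risk-assessment modules a
#' patient is exposed to: personal history of cancer, and family history of
#' cancer.
#'
#' @param personal_cancer,family_cancer Logical.
#' @return A `gate_answers` object.
#' @export
gate_answers <- function(personal_cancer, family_cancer) {
  stopifnot(is.logical(personal_cancer), is.logical(family_cancer),
            !is.na(personal_cancer), !is.na(family_cancer))
  structure(list(personal_cancer = personal_cancer,
                 family_cancer = family_cancer),
            class = "gate_answers")
}

# run code with a private RNG stream, leaving the global stream untouched
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Randomize the order of the two risk screens
#'
#' Patients with a personal or family history of cancer are exposed to the
#' Lynch-syndrome score and the hereditary breast/ovarian screen in a
#' randomized order. Deterministic given the seed; over seeds each order
#' occurs with frequency 1/2.
#'
#' @param rng_seed Integer seed.
#' @return Character vector: a permutation of `c("premm5", "brst")`.
#' @export
randomize_order <- function(rng_seed) {
  stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L)
  first <- .with_seed(as.integer(rng_seed), stats::runif(1) < 0.5)
  if (first) c("premm5", "brst") else c("brst", "premm5")
}

#' Route a patient through the eligibility assessment
#'
#' Implements the eligibility state machine. With no personal or family
#' history at the gate, only the limited-family-history module is exposed
#' and decides eligibility. Otherwise both risk screens run (in randomized
#' order); a positive screen (risk score at or above the threshold, or a
#' moderate/high breast-ovarian screen) qualifies the patient and the
#' limited module is not exposed; if both screens are negative the limited
#' module is exposed and its rules decide. Prior genetic testing is
#' recorded as a flag whenever the limited module reports it, but does not
#' itself change eligibility.
#'
#' @param gate A [gate_answers()] object.
#' @param fh A [family_history()] object.
#' @param coeffs A [load_coefficients()] object.
#' @param brst_impl Breast/ovarian screen implementation; a function of the
#'   family history returning a `brst_result`. Defaults to the
#'   non-validated stub [brst_screen()].
#' @param rng_seed Seed for the module-order randomization (recorded in the
#'   outcome for auditability).
#' @param threshold Clinical-significance threshold (probability scale).
#' @return A `routing_outcome`: exposed modules in order, per-module
#'   results, the eligibility verdict and its qualifying criteria.
#' @export
route <- function(gate, fh, coeffs, brst_impl = brst_screen, rng_seed = 1L,
                  threshold = 0.025) {
  stopifnot(inherits(gate, "gate_answers"),
            inherits(fh, "lynch_family_history"))
  history <- gate$personal_cancer || gate$family_cancer
  premm5 <- NULL; brst <- NULL; limited <- NULL
  eligible_via <- character(0)

  if (!history) {
    exposed <- c("gate", "limited")
  } else {
    exposed <- c("gate", randomize_order(rng_seed))
    premm5 <- score_bilateral(fh, coeffs, threshold = threshold)
    brst <- brst_impl(fh)
    if (!inherits(brst, "brst_result") &&
        is.list(brst) && !is.null(brst$level)) {
      brst <- structure(list(level = brst$level), class = "brst_result")
    }
    if (premm5$clinically_significant) eligible_via <- c(eligible_via, "premm5")
    if (brst$level %in% c("moderate", "high")) eligible_via <- c(eligible_via, "brst")
    if (length(eligible_via) == 0) exposed <- c(exposed, "limited")
  }

  prior_testing_flag <- FALSE
  if ("limited" %in% exposed) {
    limited <- evaluate_limited_history(fh)
    if (limited$limited_knowledge) eligible_via <- c(eligible_via, "limited_knowledge")
    if (limited$limited_structure) eligible_via <- c(eligible_via, "limited_structure")
    prior_testing_flag <- limited$prior_testing
  }

  structure(list(
    exposed_modules = exposed,
    module_order_seed = as.integer(rng_seed),
    premm5 = premm5, brst = brst, limited = limited,
    eligible = length(eligible_via) > 0,
    eligible_via = eligible_via,
    prior_testing_flag = prior_testing_flag
  ), class = "routing_outcome")
}

#' Serialize a routing outcome as JSON
#'
#' @param outcome A `routing_outcome`.
#' @param path Output JSON file.
#' @export
write_routing_outcome <- function(outcome, path) {
  stopifnot(inherits(outcome, "routing_outcome"))
  x <- lapply(unclass(outcome), function(v) if (is.null(v)) NULL else {
    if (inherits(v, c("premm5_result", "brst_result", "limited_history_result"))) {
      unclass(v)
    } else v
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Human-readable eligibility report
#'
#' Renders a markdown block naming the qualifying criteria; when the risk
#' score was computed and is clinically significant, the Lynch-syndrome
#' explanation block (from the localization tables) is included.
#'
#' @param outcome A `routing_outcome`.
#' @param language Report language (localization key lookup).
#' @return Character scalar (markdown).
#' @export
render_eligibility_report <- function(outcome, language = "en") {
  stopifnot(inherits(outcome, "routing_outcome"))
  strings <- load_localization(language)
  txt <- function(key, fallback) if (key %in% names(strings)) strings[[key]] else fallback
  lines <- c(paste0("# ", txt("report.title", "Risk assessment result")), "")
  crit_name <- c(premm5 = "risk score >= 2.5%",
                 brst = "moderate/high breast-ovarian screen",
                 limited_knowledge = "limited family knowledge",
                 limited_structure = "limited family structure")
  if (!is.null(outcome$premm5)) {
    lines <- c(lines, sprintf("- Lynch syndrome risk score: %.1f%% (%s side)",
                              100 * outcome$premm5$reported_score,
                              outcome$premm5$affected_side))
  }
  if (!is.null(outcome$brst)) {
    lines <- c(lines, paste0("- Breast/ovarian screen: ", outcome$brst$level))
  }
  if (outcome$eligible) {
    lines <- c(lines, "",
               paste0(txt("report.eligible", "Eligible for genetic testing via: "),
                      paste(crit_name[outcome$eligible_via], collapse = "; ")))
  } else {
    lines <- c(lines, "", txt("report.not_eligible", "Not eligible for genetic testing."))
  }
  if (outcome$prior_testing_flag) {
    lines <- c(lines, txt("report.prior_testing",
                          "Note: prior genetic testing was reported."))
  }
  if (!is.null(outcome$premm5) && outcome$premm5$clinically_significant) {
    lines <- c(lines, "", txt("aid.lynch_explanation",
                              "Lynch syndrome is an inherited condition that raises the risk of colorectal and other cancers."))
  }
  paste(lines, collapse = "\n")
}
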