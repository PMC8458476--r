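# Seeded generator of gold-standard family histories and misreported
# patient-facing versions, with known ground truth for validity testing.
#
# Misreport operates on diagnoses (add / drop / age jitter) rather than on
# questionnaire answers, since risk scores are what the downstream validity
# analysis consumes; the misreport process is biased toward overreport,
# matching the direction of patient error the field observes.

#' Default per-relative-class cancer rates
#'
#' Probabilities that a relative of a given class carries a diagnosis of a
#' given cancer, used by [generate_truth()]. Classes: `parent`,
#' `sibling_child`, `grandparent`, `aunt_uncle`, `proband`. Illustrative
#' desk-scale rates (lifetime Lynch-spectrum cancer frequencies in an
#' unselected family), not calibrated incidence.
#'
#' @return Nested named list `class -> cancer_type -> probability`.
#' @export
default_cancer_rates <- function() {
  list(
    proband       = list(colorectal = 0.01, endometrial = 0.005, other_ls = 0.005, breast = 0.01),
    parent        = list(colorectal = 0.05, endometrial = 0.02, other_ls = 0.03, breast = 0.04),
    sibling_child = list(colorectal = 0.01, endometrial = 0.005, other_ls = 0.01, breast = 0.01),
    grandparent   = list(colorectal = 0.08, endometrial = 0.02, other_ls = 0.05, breast = 0.04),
    aunt_uncle    = list(colorectal = 0.04, endometrial = 0.015, other_ls = 0.03, breast = 0.03)
  )
}

#' Parameters of a synthetic cohort
#'
#' @param n_families Number of families (>= 1).
#' @param cancer_rates Per-class diagnosis probabilities; see
#'   [default_cancer_rates()].
#' @param age_at_dx Named vector `c(mean, sd, floor, ceiling)` of the
#'   (truncated normal) age-at-diagnosis distribution.
#' @param proband_age_range Proband ages are drawn uniformly in this band;
#'   default 18-49, the tool's target population.
#' @param overreport_prob Per-family probability that the patient adds one
#'   spurious Lynch-associated diagnosis to a random relative. Default 0.15
#'   (illustrative; patient misreport is predominantly overreport).
#' @param underreport_prob Per-family probability that one true diagnosis
#'   is dropped. Default 0.02.
#' @param age_error_sd SD (years) of rounded Gaussian jitter on known
#'   diagnosis ages in the patient-reported version. Default 3.
#' @param seed Integer master seed; named substreams (structure, diagnoses,
#'   misreport) are derived from it so changing one rate does not reshuffle
#'   unrelated draws.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_families = 200L,
                          cancer_rates = default_cancer_rates(),
                          age_at_dx = c(mean = 62, sd = 12, floor = 25, ceiling = 90),
                          proband_age_range = c(18L, 49L),
                          overreport_prob = 0.15,
                          underreport_prob = 0.02,
                          age_error_sd = 3,
                          seed = 1L) {
  stopifnot(n_families >= 1,
            overreport_prob >= 0, overreport_prob <= 1,
            underreport_prob >= 0, underreport_prob <= 1,
            age_error_sd >= 0)
  structure(list(n_families = as.integer(n_families),
                 cancer_rates = cancer_rates,
                 age_at_dx = age_at_dx,
                 proband_age_range = proband_age_range,
                 overreport_prob = overreport_prob,
                 underreport_prob = underreport_prob,
                 age_error_sd = age_error_sd,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# deterministic substream seed from (master seed, stream name, index);
# kept below 2^31
.substream <- function(seed, name, i = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 69621 + i * 16807) %% 2147483647)
}

.rtrunc_age <- function(n, spec) {
  a <- round(stats::rnorm(n, spec[["mean"]], spec[["sd"]]))
  pmin(pmax(a, spec[["floor"]]), spec[["ceiling"]])
}

.other_ls_types <- function() {
  setdiff(lynch_cancer_types(), c("colorectal", "endometrial"))
}

# draw diagnoses for one person of a given class and sex
.draw_diagnoses <- function(rates, sex, age_spec) {
  dx <- list()
  add <- function(type) {
    dx[[length(dx) + 1L]] <<- cancer_diagnosis(type, .rtrunc_age(1, age_spec))
  }
  if (stats::runif(1) < (rates$colorectal %||% 0)) add("colorectal")
  if (sex == "female" && stats::runif(1) < (rates$endometrial %||% 0)) add("endometrial")
  if (stats::runif(1) < (rates$other_ls %||% 0)) add(sample(.other_ls_types(), 1))
  if (sex == "female" && stats::runif(1) < (rates$breast %||% 0)) add("breast")
  dx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixed nuclear roster plus Poisson-sized sibling and aunt/uncle sets
.draw_roster <- function() {
  roster <- list(
    list(relation = "mother", class = "parent", sex = "female"),
    list(relation = "father", class = "parent", sex = "male"),
    list(relation = "maternal_grandmother", class = "grandparent", sex = "female"),
    list(relation = "maternal_grandfather", class = "grandparent", sex = "male"),
    list(relation = "paternal_grandmother", class = "grandparent", sex = "female"),
    list(relation = "paternal_grandfather", class = "grandparent", sex = "male")
  )
  n_sib <- stats::rpois(1, 2)
  for (i in seq_len(n_sib)) {
    rel <- sample(c("sister", "brother"), 1)
    roster[[length(roster) + 1L]] <- list(relation = rel, class = "sibling_child",
                                          sex = if (rel == "sister") "female" else "male")
  }
  for (side in c("maternal", "paternal")) {
    n_au <- stats::rpois(1, 1.5)
    for (i in seq_len(n_au)) {
      kind <- sample(c("aunt", "uncle"), 1)
      roster[[length(roster) + 1L]] <- list(
        relation = paste(side, kind, sep = "_"), class = "aunt_uncle",
        sex = if (kind == "aunt") "female" else "male")
    }
  }
  roster
}

#' Generate a gold-standard synthetic cohort
#'
#' Deterministic given the seed. Each family has a fixed nuclear roster
#' (parents, four grandparents) plus Poisson-sized sibling and aunt/uncle
#' sets; diagnoses are sampled per `cancer_rates`, with ages from the
#' truncated normal `age_at_dx` distribution.
#'
#' @param params A [cohort_params()] object.
#' @return List of [family_history()] objects, length `n_families`.
#' @export
generate_truth <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  lapply(seq_len(params$n_families), function(i) {
    .with_seed(.substream(params$seed, "structure", i), {
      roster <- .draw_roster()
      pb_sex <- sample(c("female", "male"), 1, prob = c(0.8, 0.2))
      pb_age <- sample(params$proband_age_range[1]:params$proband_age_range[2], 1)
    })
    .with_seed(.substream(params$seed, "diagnoses", i), {
      pb_dx <- .draw_diagnoses(params$cancer_rates$proband %||% list(),
                               pb_sex, params$age_at_dx)
      rels <- lapply(roster, function(r) {
        relative(r$relation,
                 diagnoses = .draw_diagnoses(params$cancer_rates[[r$class]] %||% list(),
                                             r$sex, params$age_at_dx))
      })
    })
    suppressWarnings(
      family_history(proband(pb_sex, pb_age, diagnoses = pb_dx), rels)
    )
  })
}

#' Misreport a gold-standard family history
#'
#' Produces the patient-reported version of a true history: with
#' probability `overreport_prob` one spurious Lynch-associated diagnosis is
#' added to a random relative; with probability `underreport_prob` one true
#' diagnosis is dropped; known diagnosis ages receive rounded Gaussian
#' jitter (`age_error_sd` years) clamped to `[0, 120]`. With all error
#' parameters zero the report equals the truth.
#'
#' @param fh_truth A [family_history()] object.
#' @param params A [cohort_params()] object.
#' @param seed Seed for this family's misreport substream.
#' @return The misreported `lynch_family_history`.
#' @export
perturb_report <- function(fh_truth, params, seed = params$seed) {
  stopifnot(inherits(fh_truth, "lynch_family_history"),
            inherits(params, "cohort_params"))
  fh <- fh_truth
  .with_seed(.substream(seed, "misreport"), {
    if (length(fh$relatives) > 0 && stats::runif(1) < params$overreport_prob) {
      i <- sample.int(length(fh$relatives), 1)
      r <- fh$relatives[[i]]
      type <- if (identical(r$sex, "female")) {
        sample(c("colorectal", "endometrial", .other_ls_types()), 1)
      } else {
        sample(c("colorectal", .other_ls_types()), 1)
      }
      r$diagnoses[[length(r$diagnoses) + 1L]] <-
        cancer_diagnosis(type, .rtrunc_age(1, params$age_at_dx))
      fh$relatives[[i]] <- r
    }
    if (stats::runif(1) < params$underreport_prob) {
      carriers <- which(vapply(fh$relatives, function(r) length(r$diagnoses) > 0,
                               logical(1)))
      if (length(carriers) > 0) {
        i <- carriers[sample.int(length(carriers), 1)]
        r <- fh$relatives[[i]]
        j <- sample.int(length(r$diagnoses), 1)
        r$diagnoses[[j]] <- NULL
        fh$relatives[[i]] <- r
      }
    }
    if (params$age_error_sd > 0) {
      fh$relatives <- lapply(fh$relatives, function(r) {
        r$diagnoses <- lapply(r$diagnoses, function(d) {
          if (!is.na(d$age_at_diagnosis)) {
            jit <- round(stats::rnorm(1, 0, params$age_error_sd))
            d$age_at_diagnosis <- as.integer(
              min(120L, max(0L, d$age_at_diagnosis + jit)))
          }
          d
        })
        r
      })
    }
  })
  fh
}

#' Generate a paired truth/reported cohort
#'
#' @param params A [cohort_params()] object.
#' @return List with `truth` and `reported`, each a list of
#'   [family_history()] objects.
#' @export
generate_cohort <- function(params) {
  truth <- generate_truth(params)
  reported <- lapply(seq_along(truth), function(i) {
    perturb_report(truth[[i]], params, seed = .substream(params$seed, "family", i))
  })
  list(truth = truth, reported = reported)
}

.has_ls_history <- function(fh) {
  ls <- lynch_cancer_types()
  .has_type(fh$proband$diagnoses, ls) ||
    any(vapply(fh$relatives, function(r) .has_type(r$diagnoses, ls), logical(1)))
}

#' Score a paired cohort
#'
#' `participant_score` is the bilateral reported score of the misreported
#' history; `counselor_score` that of the truth. A score is absent (`NA`)
#' when the respective history contains no Lynch-associated cancer at all
#' and the gate would route that rater past the scoring questions --
#' exercising the zero-imputation step of the validity analysis.
#'
#' @param cohort Output of [generate_cohort()].
#' @param coeffs A [load_coefficients()] object.
#' @param threshold Clinical-significance threshold.
#' @return A [paired_scores()] data.frame, one row per family.
#' @export
build_paired_scores <- function(cohort, coeffs, threshold = 0.025) {
  score_or_na <- function(fh) {
    if (!.has_ls_history(fh)) return(NA_real_)
    score_bilateral(fh, coeffs, threshold = threshold)$reported_score
  }
  n <- length(cohort$truth)
  paired_scores(
    id = sprintf("fam%04d", seq_len(n)),
    participant_score = vapply(cohort$reported, score_or_na, numeric(1)),
    counselor_score = vapply(cohort$truth, score_or_na, numeric(1))
  )
}
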