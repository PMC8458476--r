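# Shared fixtures: synthetic coefficient sets and small family histories,
# built in code.

coeff_term <- function(feature, coefficient, type = "identity", ...) {
  list(feature = feature, transform = c(list(type = type), list(...)),
       coefficient = coefficient)
}

# write a synthetic coefficient file and load it
make_coeffs <- function(intercept = -4.3, terms = list(),
                        absent_age_policy = list(mode = "reference_age", value = 45)) {
  path <- tempfile(fileext = ".json")
  x <- list(version = "test-1", provenance = "synthetic test coefficients",
            intercept = intercept, terms = terms)
  if (!is.null(absent_age_policy)) x$absent_age_policy <- absent_age_policy
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  load_coefficients(path)
}

# a full synthetic coefficient set mirroring the shipped structure
full_test_coeffs <- function(intercept = -4.3) {
  make_coeffs(intercept = intercept, terms = list(
    coeff_term("proband_sex_male", 0.3),
    coeff_term("proband_crc_count", 0.9, type = "count_capped", cap = 2),
    coeff_term("proband_crc_min_age", 0.45, type = "youth", center = 45, scale = 10),
    coeff_term("proband_ec", 1.0),
    coeff_term("proband_other_ls", 0.4),
    coeff_term("fdr_crc_count", 0.6, type = "count_capped", cap = 2),
    coeff_term("fdr_crc_min_age", 0.35, type = "youth", center = 45, scale = 10),
    coeff_term("sdr_crc_count", 0.35, type = "count_capped", cap = 2),
    coeff_term("sdr_crc_min_age", 0.2, type = "youth", center = 45, scale = 10),
    coeff_term("fdr_ec", 0.55),
    coeff_term("sdr_ec", 0.3),
    coeff_term("fdr_sdr_other_ls", 0.25),
    coeff_term("ec_min_age", 0.15, type = "youth", center = 45, scale = 10),
    coeff_term("proband_age", -0.1, type = "centered_decade", center = 45)
  ))
}

# independent oracle: evaluate the logistic model by direct arithmetic on
# the same inputs/coefficients, without the package's transform machinery
brute_force_score <- function(inputs, coeffs) {
  eta <- coeffs$intercept
  for (tm in coeffs$terms) {
    v <- inputs[[tm$feature]]
    if (is.logical(v)) v <- as.numeric(v)
    tt <- tm$transform
    if (is.na(v)) {
      if (coeffs$absent_age_policy$mode == "zero_contribution") next
      v <- coeffs$absent_age_policy$value
    }
    x <- if (tt$type == "identity") v
      else if (tt$type == "count_capped") min(v, tt$cap)
      else if (tt$type == "youth") max(0, (tt$center - v) / tt$scale)
      else (v - tt$center) / 10
    eta <- eta + tm$coefficient * x
  }
  1 / (1 + exp(-eta))
}

# small random family history for property tests
random_family <- function(seed) {
  set.seed(seed)
  rels <- list()
  pool <- c("mother", "father", "sister", "brother", "maternal_aunt",
            "paternal_uncle", "maternal_grandmother", "paternal_grandfather")
  for (rel in sample(pool, sample(0:5, 1))) {
    dx <- list()
    if (runif(1) < 0.6) {
      type <- sample(c("colorectal", "endometrial", "stomach", "ovarian", "breast"), 1)
      sex <- if (rel %in% c("mother", "sister", "maternal_aunt",
                            "maternal_grandmother")) "female" else "male"
      if (type == "endometrial" && sex == "male") type <- "colorectal"
      age <- if (runif(1) < 0.8) sample(30:80, 1) else NA
      dx <- list(cancer_diagnosis(type, age))
    }
    rels[[length(rels) + 1L]] <- relative(rel, diagnoses = dx)
  }
  pb_dx <- if (runif(1) < 0.2) list(cancer_diagnosis("colorectal", sample(25:49, 1))) else list()
  family_history(proband(sample(c("female", "male"), 1), sample(18:49, 1),
                         diagnoses = pb_dx),
                 rels)
}

# drive a session through the questionnaire with a deterministic answer
# policy; `policy(question)` returns the answer value
walk_session <- function(config, policy, started_at = 0) {
  s <- new_session(config, started_at = started_at)
  t <- started_at
  repeat {
    q <- next_question(config, s)
    if (identical(q, TERMINAL)) break
    t <- t + 1
    s <- record_answer(s, config, q$id, policy(q), at = t)
  }
  s
}

# random answer policy over the abstract answer kinds
random_policy <- function() {
  function(q) {
    switch(q$kind,
      yes_no = sample(c("yes", "no"), 1),
      single_choice = sample(q$choices, 1),
      multi_select = {
        k <- sample(0:min(3, length(q$choices)), 1)
        if (k == 0) character(0) else sample(q$choices, k)
      },
      count = sample(0:3, 1),
      age = sample(c(30:70, NA), 1)
    )
  }
}
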