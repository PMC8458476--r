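test_that("logistic evaluation matches closed-form arithmetic", {
  co <- make_coeffs(intercept = -3.66, terms = list())
  p <- score_inputs(premm5_inputs(), co)
  expect_equal(p, 1 / (1 + exp(3.66)), tolerance = 1e-12)
  co0 <- make_coeffs(intercept = 0, terms = list())
  expect_equal(score_inputs(premm5_inputs(), co0), 0.5, tolerance = 1e-15)
})

test_that("scoring agrees with an independent brute-force evaluation", {
  co <- full_test_coeffs()
  set.seed(404)
  for (i in 1:50) {
    inp <- premm5_inputs(
      proband_sex_male = runif(1) < 0.5,
      proband_age = sample(18:49, 1),
      proband_crc_count = k1 <- sample(0:3, 1),
      proband_crc_min_age = if (k1 > 0 && runif(1) < 0.8) sample(25:80, 1) else NA,
      proband_ec = e1 <- runif(1) < 0.3,
      proband_other_ls = runif(1) < 0.3,
      fdr_crc_count = k2 <- sample(0:3, 1),
      fdr_crc_min_age = if (k2 > 0 && runif(1) < 0.8) sample(25:80, 1) else NA,
      sdr_crc_count = k3 <- sample(0:3, 1),
      sdr_crc_min_age = if (k3 > 0 && runif(1) < 0.8) sample(25:80, 1) else NA,
      fdr_ec = e2 <- runif(1) < 0.3,
      sdr_ec = e3 <- runif(1) < 0.3,
      fdr_sdr_other_ls = runif(1) < 0.3,
      ec_min_age = if ((e1 || e2 || e3) && runif(1) < 0.8) sample(25:80, 1) else NA
    )
    expect_equal(score_inputs(inp, co), brute_force_score(inp, co),
                 tolerance = 1e-12)
  }
})

test_that("adding affected history never lowers a positive-coefficient score", {
  co <- full_test_coeffs()
  expect_gt(score_inputs(premm5_inputs(fdr_crc_count = 1), co),
            score_inputs(premm5_inputs(), co))
  for (seed in 1:15) {
    fh <- random_family(seed)
    base_m <- score_bilateral(fh, co)$maternal_score
    base_p <- score_bilateral(fh, co)$paternal_score
    add <- sample(list(
      relative("sister", diagnoses = list(cancer_diagnosis("colorectal", sample(c(30:80, NA), 1)))),
      relative("maternal_aunt", diagnoses = list(cancer_diagnosis("endometrial", sample(c(30:80, NA), 1)))),
      relative("paternal_grandfather", diagnoses = list(cancer_diagnosis("stomach", NA)))
    ), 1)[[1]]
    fh$relatives <- c(fh$relatives, list(add))
    res <- score_bilateral(fh, co)
    expect_gte(res$maternal_score, base_m - 1e-12)
    expect_gte(res$paternal_score, base_p - 1e-12)
  }
})

test_that("lowering a diagnosis age never lowers the score", {
  co <- full_test_coeffs()
  ages <- c(70, 55, 44, 38, 25)
  scores <- vapply(ages, function(a) {
    fh <- family_history(proband("female", 35), list(
      relative("mother", diagnoses = list(cancer_diagnosis("colorectal", a)))))
    score_bilateral(fh, co)$maternal_score
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("scoring is side-local", {
  co <- full_test_coeffs()
  fh <- family_history(proband("female", 35), list(
    relative("maternal_aunt", diagnoses = list(cancer_diagnosis("colorectal", 50)))))
  before <- score_bilateral(fh, co)
  fh$relatives <- c(fh$relatives, list(
    relative("paternal_uncle", diagnoses = list(cancer_diagnosis("colorectal", 40)))))
  after <- score_bilateral(fh, co)
  expect_identical(after$maternal_score, before$maternal_score)
  expect_gt(after$paternal_score, before$paternal_score)
})

test_that("affected side is the argmax with maternal tie-break", {
  co <- full_test_coeffs()
  # mirror-symmetric history: equal scores, maternal wins the tie
  fh <- family_history(proband("female", 35), list(
    relative("maternal_aunt", diagnoses = list(cancer_diagnosis("colorectal", 50))),
    relative("paternal_aunt", diagnoses = list(cancer_diagnosis("colorectal", 50)))))
  res <- score_bilateral(fh, co)
  expect_equal(res$maternal_score, res$paternal_score)
  expect_identical(res$affected_side, "maternal")
  expect_identical(res$reported_score, max(res$maternal_score, res$paternal_score))

  fh2 <- family_history(proband("female", 35), list(
    relative("maternal_aunt", diagnoses = list(cancer_diagnosis("colorectal", 40)))))
  res2 <- score_bilateral(fh2, co)
  expect_gt(res2$maternal_score, res2$paternal_score)
  expect_identical(res2$affected_side, "maternal")

  # empty family: both sides at baseline
  fh3 <- family_history(proband("female", 45))
  res3 <- score_bilateral(fh3, co)
  expect_equal(res3$maternal_score, res3$paternal_score)
  expect_equal(res3$reported_score, plogis(-4.3), tolerance = 1e-12)
})

test_that("clinical significance threshold is inclusive", {
  expect_true(classify_significant(0.025))
  expect_false(classify_significant(0.0249))
  expect_true(classify_significant(1.0))
  expect_false(classify_significant(0))
})

test_that("coefficient files validate before use", {
  expect_error(make_coeffs(absent_age_policy = NULL), "absent_age_policy")
  expect_error(make_coeffs(absent_age_policy = list(mode = "whatever")),
               "reference_age|zero_contribution")
  expect_error(make_coeffs(terms = list(coeff_term("not_a_feature", 1))),
               "does not resolve")
  expect_error(make_coeffs(terms = list(list(feature = "fdr_ec", coefficient = 1))),
               "transform")
  # shipped default loads and is marked synthetic
  co <- default_coefficients()
  expect_s3_class(co, "premm5_coefficients")
  expect_match(co$provenance, "SYNTHETIC")
})

test_that("absent-age policy drives scoring of unknown ages", {
  terms <- list(coeff_term("fdr_crc_count", 0.5),
                coeff_term("fdr_crc_min_age", 0.4, type = "youth", center = 45, scale = 10))
  ref <- make_coeffs(intercept = -3, terms = terms,
                     absent_age_policy = list(mode = "reference_age", value = 35))
  zero <- make_coeffs(intercept = -3, terms = terms,
                      absent_age_policy = list(mode = "zero_contribution"))
  inp <- premm5_inputs(fdr_crc_count = 1, fdr_crc_min_age = NA)
  expect_equal(score_inputs(inp, ref), plogis(-3 + 0.5 + 0.4 * 1), tolerance = 1e-12)
  expect_equal(score_inputs(inp, zero), plogis(-3 + 0.5), tolerance = 1e-12)
})

test_that("limited-history rules: knowledge, structure, prior testing", {
  base <- proband("female", 30)
  r <- evaluate_limited_history(family_history(base,
    females_over_45_maternal = 1, females_over_45_paternal = 3))
  expect_true(r$limited_structure)   # < 2 on either side suffices
  expect_false(r$limited_knowledge)

  r2 <- evaluate_limited_history(family_history(base,
    females_over_45_maternal = 2, females_over_45_paternal = 2))
  expect_false(r2$limited_structure) # boundary: exactly 2 is not limited
  expect_false(r2$limited_knowledge)
  expect_false(r2$prior_testing)

  expect_true(evaluate_limited_history(
    family_history(base, adopted = TRUE))$limited_knowledge)
  expect_true(evaluate_limited_history(
    family_history(base, knows_paternal_history = FALSE))$limited_knowledge)
  expect_true(evaluate_limited_history(
    family_history(base, prior_hboc_testing = TRUE))$prior_testing)
})

test_that("breast/ovarian screen stub and plug-in contract", {
  fh <- family_history(proband("female", 30))
  expect_identical(brst_screen(fh)$level, "negative")
  fh2 <- family_history(proband("female", 30), list(
    relative("mother", diagnoses = list(cancer_diagnosis("breast", 48)))))
  expect_identical(brst_screen(fh2)$level, "moderate")
  fh3 <- family_history(proband("female", 30), ashkenazi = TRUE)
  expect_identical(brst_screen(fh3)$level, "moderate")
  # injected implementation overrides the stub verbatim
  co <- make_coeffs(intercept = -10)
  custom <- function(fh) structure(list(level = "high"), class = "brst_result")
  out <- route(gate_answers(FALSE, TRUE), fh, co, brst_impl = custom)
  expect_identical(out$brst$level, "high")
  expect_true("brst" %in% out$eligible_via)
})
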