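# Domain model: probands, relatives, cancer diagnoses, and the per-side
# aggregations the risk model consumes.

#' Recognized cancer type codes
#'
#' Twelve cancer codes are recognized. The Lynch-qualifying subset (the
#' cancers a mismatch-repair mutation predisposes to) is exactly the set
#' returned by [lynch_cancer_types()]: colorectal, endometrial, ovarian,
#' stomach, small intestine, urinary tract (bladder/kidney), bile duct,
#' brain, pancreatic, and sebaceous gland skin tumors. `breast` and `other`
#' are carried for the hereditary breast/ovarian screen and for
#' non-qualifying histories.
#'
#' @return Character vector of valid cancer type codes.
#' @export
cancer_types <- function() {
  c("colorectal", "endometrial", "ovarian", "stomach", "small_intestine",
    "urinary_tract", "bile_duct", "brain", "pancreatic",
    "sebaceous_gland_tumor", "breast", "other")
}

#' @rdname cancer_types
#' @export
lynch_cancer_types <- function() {
  c("colorectal", "endometrial", "ovarian", "stomach", "small_intestine",
    "urinary_tract", "bile_duct", "brain", "pancreatic",
    "sebaceous_gland_tumor")
}

#' Test whether a cancer code is Lynch-qualifying
#'
#' Total membership test over the closed Lynch-qualifying cancer set.
#'
#' @param code Character vector of cancer type codes.
#' @return Logical vector.
#' @export
is_lynch_cancer <- function(code) {
  stopifnot(is.character(code))
  bad <- setdiff(code, cancer_types())
  if (length(bad) > 0) {
    stop("unknown cancer type code(s): ", paste(bad, collapse = ", "))
  }
  code %in% lynch_cancer_types()
}

#' Recognized relative relation codes
#'
#' @return Character vector of relation codes.
#' @export
relations <- function() {
  c("mother", "father", "sister", "brother", "daughter", "son",
    "maternal_grandmother", "maternal_grandfather",
    "paternal_grandmother", "paternal_grandfather",
    "maternal_aunt", "maternal_uncle", "paternal_aunt", "paternal_uncle",
    "half_sibling")
}

# relation -> implied side; NA means the relation does not fix a side
.relation_side <- c(
  mother = "maternal", father = "paternal",
  sister = "unsided", brother = "unsided",
  daughter = "unsided", son = "unsided",
  maternal_grandmother = "maternal", maternal_grandfather = "maternal",
  paternal_grandmother = "paternal", paternal_grandfather = "paternal",
  maternal_aunt = "maternal", maternal_uncle = "maternal",
  paternal_aunt = "paternal", paternal_uncle = "paternal",
  half_sibling = NA_character_
)

.relation_sex <- c(
  mother = "female", father = "male", sister = "female", brother = "male",
  daughter = "female", son = "male",
  maternal_grandmother = "female", maternal_grandfather = "male",
  paternal_grandmother = "female", paternal_grandfather = "male",
  maternal_aunt = "female", maternal_uncle = "male",
  paternal_aunt = "female", paternal_uncle = "male",
  half_sibling = NA_character_
)

#' Kinship degree of a relation
#'
#' Parents, siblings and children are first-degree relatives; grandparents,
#' aunts, uncles and half-siblings (kinship coefficient 1/4 of the full-sib
#' value) are second-degree.
#'
#' @param relation Relation code, one of [relations()].
#' @return `"first"` or `"second"` (vectorized).
#' @export
degree_of <- function(relation) {
  bad <- setdiff(relation, relations())
  if (length(bad) > 0) {
    stop("unknown relation code(s): ", paste(bad, collapse = ", "))
  }
  first <- c("mother", "father", "sister", "brother", "daughter", "son")
  ifelse(relation %in% first, "first", "second")
}

#' Construct a cancer diagnosis
#'
#' @param cancer_type One of [cancer_types()].
#' @param age_at_diagnosis Age in years at diagnosis, in `[0, 120]`, or `NA`
#'   when unknown.
#' @return A `lynch_diagnosis` object.
#' @export
cancer_diagnosis <- function(cancer_type, age_at_diagnosis = NA) {
  stopifnot(length(cancer_type) == 1L)
  if (!cancer_type %in% cancer_types()) {
    stop("unknown cancer type code: ", cancer_type)
  }
  age <- .check_age(age_at_diagnosis, "age_at_diagnosis")
  structure(list(cancer_type = cancer_type, age_at_diagnosis = age),
            class = "lynch_diagnosis")
}

.check_age <- function(age, what) {
  if (length(age) != 1L) stop(what, " must be a single value")
  if (is.na(age)) return(NA_integer_)
  if (!is.numeric(age) || age < 0 || age > 120) {
    stop(what, " must be in [0, 120] or NA, got ", age)
  }
  as.integer(round(age))
}

.as_diagnoses <- function(diagnoses) {
  stopifnot(is.list(diagnoses))
  lapply(diagnoses, function(d) {
    if (inherits(d, "lynch_diagnosis")) return(d)
    cancer_diagnosis(d$cancer_type,
                     if (is.null(d$age_at_diagnosis)) NA else d$age_at_diagnosis)
  })
}

#' Construct a relative
#'
#' The parental side is implied by the relation where the relation encodes it
#' (mother is maternal, paternal uncles are paternal, ...). Siblings and
#' children are `"unsided"`: they share both parental lineages with the
#' proband and contribute to both side aggregations. Half-siblings must be
#' given an explicit side (or `"unsided"` when unknown).
#'
#' @param relation One of [relations()].
#' @param side `"maternal"`, `"paternal"` or `"unsided"`; only consulted for
#'   `half_sibling`, otherwise it must agree with the relation if supplied.
#' @param sex `"female"` or `"male"`; implied by most relations.
#' @param alive Logical or `NA`.
#' @param age_now_or_at_death Years or `NA`.
#' @param diagnoses List of [cancer_diagnosis()] objects.
#' @return A `lynch_relative` object.
#' @export
relative <- function(relation, side = NULL, sex = NULL, alive = NA,
                     age_now_or_at_death = NA, diagnoses = list()) {
  if (!relation %in% relations()) stop("unknown relation code: ", relation)
  implied <- .relation_side[[relation]]
  if (is.na(implied)) {
    side <- if (is.null(side)) "unsided" else match.arg(side, c("maternal", "paternal", "unsided"))
  } else {
    if (!is.null(side) && side != implied) {
      stop("relation '", relation, "' implies side '", implied,
           "', got '", side, "'")
    }
    side <- implied
  }
  implied_sex <- .relation_sex[[relation]]
  if (is.na(implied_sex)) {
    sex <- if (is.null(sex)) NA_character_ else match.arg(sex, c("female", "male"))
  } else {
    if (!is.null(sex) && sex != implied_sex) {
      stop("relation '", relation, "' implies sex '", implied_sex, "'")
    }
    sex <- implied_sex
  }
  structure(list(
    relation = relation, side = side, sex = sex,
    alive = alive,
    age_now_or_at_death = .check_age(age_now_or_at_death, "age_now_or_at_death"),
    diagnoses = .as_diagnoses(diagnoses)
  ), class = "lynch_relative")
}

#' Construct a proband
#'
#' @param sex `"female"` or `"male"`.
#' @param age Current age in years, in `[18, 120]`.
#' @param diagnoses List of [cancer_diagnosis()] objects.
#' @param study_band Age band of the intended screening population; a proband
#'   outside it triggers a warning (not an error). Default `c(18, 49)`,
#'   the predominantly healthy adult band the triage tool targets.
#' @return A `lynch_proband` object.
#' @export
proband <- function(sex, age, diagnoses = list(), study_band = c(18L, 49L)) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.numeric(age) || length(age) != 1L || age < 18 || age > 120) {
    stop("proband age must be in [18, 120], got ", age)
  }
  if (age < study_band[1] || age > study_band[2]) {
    warning("proband age ", age, " is outside the study band [",
            study_band[1], ", ", study_band[2], "]")
  }
  structure(list(sex = sex, age = as.integer(round(age)),
                 diagnoses = .as_diagnoses(diagnoses)),
            class = "lynch_proband")
}

#' Construct a family history
#'
#' The object the questionnaire produces and the bilateral scorer consumes:
#' a proband, a list of typed relatives, and the limited-family-history
#' answers (adoption, per-side knowledge of cancer history, per-side counts
#' of female relatives living beyond age 45, prior genetic testing). The
#' female-over-45 counts are direct questionnaire answers, not derived from
#' the relative roster.
#'
#' @param proband A [proband()] object.
#' @param relatives List of [relative()] objects (may be empty).
#' @param adopted Was the proband adopted?
#' @param knows_maternal_history,knows_paternal_history Does the proband know
#'   the cancer history of that parental side?
#' @param females_over_45_maternal,females_over_45_paternal Reported counts of
#'   female relatives living beyond age 45 on each side (non-negative).
#'   Defaults (2) describe an adequately informative family structure.
#' @param prior_ls_testing,prior_hboc_testing Prior genetic testing for Lynch
#'   syndrome / hereditary breast-ovarian cancer.
#' @param ashkenazi Ashkenazi Jewish ancestry flag, consulted only by the
#'   non-validated hereditary breast/ovarian screen stub.
#' @return A `lynch_family_history` object.
#' @export
family_history <- function(proband, relatives = list(), adopted = FALSE,
                           knows_maternal_history = TRUE,
                           knows_paternal_history = TRUE,
                           females_over_45_maternal = 2L,
                           females_over_45_paternal = 2L,
                           prior_ls_testing = FALSE,
                           prior_hboc_testing = FALSE,
                           ashkenazi = FALSE) {
  stopifnot(inherits(proband, "lynch_proband"), is.list(relatives))
  relatives <- lapply(relatives, function(r) {
    if (!inherits(r, "lynch_relative")) stop("relatives must be relative() objects")
    r
  })
  for (nm in c("females_over_45_maternal", "females_over_45_paternal")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(nm, " must be a non-negative count")
    }
  }
  structure(list(
    proband = proband, relatives = relatives, adopted = isTRUE(adopted),
    knows_maternal_history = isTRUE(knows_maternal_history),
    knows_paternal_history = isTRUE(knows_paternal_history),
    females_over_45_maternal = as.integer(females_over_45_maternal),
    females_over_45_paternal = as.integer(females_over_45_paternal),
    prior_ls_testing = isTRUE(prior_ls_testing),
    prior_hboc_testing = isTRUE(prior_hboc_testing),
    ashkenazi = isTRUE(ashkenazi)
  ), class = "lynch_family_history")
}

#' Reported count of female relatives over 45 on one side
#'
#' Returns the stored questionnaire answer (a direct report, not a
#' derivation from the relative roster).
#'
#' @param fh A [family_history()] object.
#' @param side `"maternal"` or `"paternal"`.
#' @return Non-negative integer.
#' @export
female_over_45_count <- function(fh, side) {
  stopifnot(inherits(fh, "lynch_family_history"))
  side <- match.arg(side, c("maternal", "paternal"))
  if (side == "maternal") fh$females_over_45_maternal else fh$females_over_45_paternal
}

# min over known ages; NA when no known age
.min_known_age <- function(ages) {
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) NA_integer_ else as.integer(min(ages))
}

.diag_ages <- function(diagnoses, types) {
  vapply(Filter(function(d) d$cancer_type %in% types, diagnoses),
         function(d) as.integer(d$age_at_diagnosis), integer(1))
}

.has_type <- function(diagnoses, types) {
  any(vapply(diagnoses, function(d) d$cancer_type %in% types, logical(1)))
}

#' Aggregate one parental side into risk-model predictors
#'
#' Builds the per-side predictor record for the logistic model. Relatives
#' counted toward a side are those explicitly on that side plus all unsided
#' relatives (siblings/children belong to both lineages); the proband's own
#' diagnoses contribute identically to both sides. Each degree-by-cancer cell
#' carries a count of affected relatives and the minimum known age at
#' diagnosis among them (absent when no age is known). Unknown diagnosis
#' ages are excluded from minimum-age aggregation.
#'
#' @param fh A [family_history()] object.
#' @param side `"maternal"` or `"paternal"`.
#' @return A `premm5_inputs` object (see [premm5_inputs()]).
#' @export
aggregate_side <- function(fh, side) {
  stopifnot(inherits(fh, "lynch_family_history"))
  side <- match.arg(side, c("maternal", "paternal"))
  rel <- Filter(function(r) r$side == side || r$side == "unsided", fh$relatives)
  deg <- vapply(rel, function(r) degree_of(r$relation), character(1))
  fdr <- rel[deg == "first"]
  sdr <- rel[deg == "second"]

  other_ls <- setdiff(lynch_cancer_types(), c("colorectal", "endometrial"))
  pb <- fh$proband

  crc_cell <- function(relatives) {
    affected <- Filter(function(r) .has_type(r$diagnoses, "colorectal"), relatives)
    ages <- unlist(lapply(affected, function(r) .diag_ages(r$diagnoses, "colorectal")))
    list(count = length(affected), min_age = .min_known_age(ages))
  }
  fdr_crc <- crc_cell(fdr)
  sdr_crc <- crc_cell(sdr)

  ec_ages <- c(
    .diag_ages(pb$diagnoses, "endometrial"),
    unlist(lapply(c(fdr, sdr), function(r) .diag_ages(r$diagnoses, "endometrial")))
  )

  premm5_inputs(
    proband_sex_male = pb$sex == "male",
    proband_age = pb$age,
    proband_crc_count = sum(vapply(pb$diagnoses, function(d) d$cancer_type == "colorectal", logical(1))),
    proband_crc_min_age = .min_known_age(.diag_ages(pb$diagnoses, "colorectal")),
    proband_ec = .has_type(pb$diagnoses, "endometrial"),
    proband_other_ls = .has_type(pb$diagnoses, other_ls),
    fdr_crc_count = fdr_crc$count,
    fdr_crc_min_age = fdr_crc$min_age,
    sdr_crc_count = sdr_crc$count,
    sdr_crc_min_age = sdr_crc$min_age,
    fdr_ec = any(vapply(fdr, function(r) .has_type(r$diagnoses, "endometrial"), logical(1))),
    sdr_ec = any(vapply(sdr, function(r) .has_type(r$diagnoses, "endometrial"), logical(1))),
    fdr_sdr_other_ls = any(vapply(c(fdr, sdr), function(r) .has_type(r$diagnoses, other_ls), logical(1))),
    ec_min_age = .min_known_age(ec_ages)
  )
}

#' Tabular export of a relative roster
#'
#' One row per diagnosis (relatives without diagnoses contribute one row with
#' empty cancer fields), for genetic-counselor review.
#'
#' @param fh A [family_history()] object.
#' @return A data.frame with columns relation, side, sex, cancer_type,
#'   age_at_diagnosis.
#' @export
relatives_table <- function(fh) {
  stopifnot(inherits(fh, "lynch_family_history"))
  rows <- lapply(fh$relatives, function(r) {
    if (length(r$diagnoses) == 0) {
      data.frame(relation = r$relation, side = r$side, sex = r$sex,
                 cancer_type = NA_character_, age_at_diagnosis = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(r$diagnoses, function(d) {
        data.frame(relation = r$relation, side = r$side, sex = r$sex,
                   cancer_type = d$cancer_type,
                   age_at_diagnosis = d$age_at_diagnosis,
                   stringsAsFactors = FALSE)
      }))
    }
  })
  if (length(rows) == 0) {
    return(data.frame(relation = character(0), side = character(0),
                      sex = character(0), cancer_type = character(0),
                      age_at_diagnosis = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Serialize / deserialize a family history as JSON
#'
#' Field names follow the published schema: enumerations are lower-snake-case
#' strings, unknown ages are `null`.
#'
#' @param fh A [family_history()] object.
#' @param path File path; for `write_family_history` the output JSON file.
#' @return `read_family_history` returns a [family_history()] object.
#' @export
write_family_history <- function(fh, path) {
  stopifnot(inherits(fh, "lynch_family_history"))
  x <- list(
    proband = list(sex = fh$proband$sex, age = fh$proband$age,
                   diagnoses = lapply(fh$proband$diagnoses, unclass)),
    relatives = lapply(fh$relatives, function(r) {
      list(relation = r$relation, side = r$side, sex = r$sex, alive = r$alive,
           age_now_or_at_death = r$age_now_or_at_death,
           diagnoses = lapply(r$diagnoses, unclass))
    }),
    adopted = fh$adopted,
    knows_maternal_history = fh$knows_maternal_history,
    knows_paternal_history = fh$knows_paternal_history,
    females_over_45_maternal = fh$females_over_45_maternal,
    females_over_45_paternal = fh$females_over_45_paternal,
    prior_ls_testing = fh$prior_ls_testing,
    prior_hboc_testing = fh$prior_hboc_testing,
    ashkenazi = fh$ashkenazi
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_family_history
#' @export
read_family_history <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  null_na <- function(v) if (is.null(v)) NA else v
  pb <- proband(x$proband$sex, x$proband$age,
                diagnoses = lapply(x$proband$diagnoses, function(d) {
                  cancer_diagnosis(d$cancer_type, null_na(d$age_at_diagnosis))
                }))
  rels <- lapply(x$relatives, function(r) {
    relative(r$relation,
             side = if (identical(r$relation, "half_sibling")) null_na(r$side) else NULL,
             alive = null_na(r$alive),
             age_now_or_at_death = null_na(r$age_now_or_at_death),
             diagnoses = lapply(r$diagnoses, function(d) {
               cancer_diagnosis(d$cancer_type, null_na(d$age_at_diagnosis))
             }))
  })
  family_history(pb, rels, adopted = isTRUE(x$adopted),
                 knows_maternal_history = isTRUE(x$knows_maternal_history),
                 knows_paternal_history = isTRUE(x$knows_paternal_history),
                 females_over_45_maternal = x$females_over_45_maternal,
                 females_over_45_paternal = x$females_over_45_paternal,
                 prior_ls_testing = isTRUE(x$prior_ls_testing),
                 prior_hboc_testing = isTRUE(x$prior_hboc_testing),
                 ashkenazi = isTRUE(x$ashkenazi))
}

#' @export
print.lynch_family_history <- function(x, ...) {
  cat("<family history>\n")
  cat("  proband:", x$proband$sex, x$proband$age, "y,",
      length(x$proband$diagnoses), "diagnosis(es)\n")
  cat("  relatives:", length(x$relatives),
      sprintf("(adopted=%s, knows maternal=%s, paternal=%s)\n",
              x$adopted, x$knows_maternal_history, x$knows_paternal_history))
  cat("  females >45: maternal", x$females_over_45_maternal,
      "/ paternal", x$females_over_45_paternal, "\n")
  invisible(x)
}
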