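# Compilation of completed questionnaire sessions into the family-history
# domain model. The mapping is keyed to the shipped question inventory
# (see inst/extdata/questionnaire-premm5.json): relatives are asked about
# in familially meaningful groups, so group-level reports (e.g. "2 of your
# brothers, sisters or children had colorectal cancer, the youngest at 40")
# are materialized as canonical group members -- the count and the youngest
# known diagnosis age, which are what the per-side aggregation consumes,
# are preserved exactly.

# group prefix -> canonical relations used when materializing group-level
# reports: [colorectal carrier, endometrial carrier (female), other-cancer carrier]
.group_relations <- list(
  sc = c("sister", "sister", "brother"),
  mg = c("maternal_grandfather", "maternal_grandmother", "maternal_grandfather"),
  pg = c("paternal_grandfather", "paternal_grandmother", "paternal_grandfather"),
  ma = c("maternal_uncle", "maternal_aunt", "maternal_uncle"),
  pa = c("paternal_uncle", "paternal_aunt", "paternal_uncle")
)

.compile_typed_relative <- function(relation, types, crc_age, ec_age) {
  dx <- list()
  for (tp in types) {
    age <- if (tp == "colorectal") crc_age else if (tp == "endometrial") ec_age else NA
    if (is.null(age)) age <- NA
    dx[[length(dx) + 1L]] <- cancer_diagnosis(tp, age)
  }
  relative(relation, diagnoses = dx)
}

.compile_group <- function(ans, prefix) {
  rels <- list()
  if (!identical(ans[[paste0(prefix, "_any")]], "yes")) return(rels)
  canon <- .group_relations[[prefix]]
  k <- ans[[paste0(prefix, "_crc_count")]]
  if (!is.null(k) && k >= 1) {
    age <- ans[[paste0(prefix, "_crc_age")]]
    for (i in seq_len(k)) {
      rels[[length(rels) + 1L]] <- relative(
        canon[1],
        diagnoses = list(cancer_diagnosis("colorectal",
                                          if (i == 1L && !is.null(age)) age else NA)))
    }
  }
  if (identical(ans[[paste0(prefix, "_ec_any")]], "yes")) {
    rels[[length(rels) + 1L]] <- relative(
      canon[2],
      diagnoses = list(cancer_diagnosis("endometrial",
                                        if (is.null(ans[[paste0(prefix, "_ec_age")]])) NA
                                        else ans[[paste0(prefix, "_ec_age")]])))
  }
  other <- ans[[paste0(prefix, "_other_types")]]
  for (tp in other) {
    rels[[length(rels) + 1L]] <- relative(
      canon[3], diagnoses = list(cancer_diagnosis(tp, NA)))
  }
  rels
}

#' Compile a completed session into a family history
#'
#' Total mapping from the shipped question inventory to the
#' [family_history()] model: gate answers populate nothing beyond proband
#' flags, unanswered optional blocks map to absent relatives, and
#' group-level relative reports are materialized as canonical group members
#' preserving counts and youngest diagnosis ages. Proband sex and age are
#' session metadata (supplied at intake, not asked by the questionnaire).
#'
#' @param session A completed `lynch_session` on the default questionnaire.
#' @param config The questionnaire config the session was recorded against.
#' @param proband_sex,proband_age Proband demographics.
#' @param limited_session Optional completed session on
#'   [limited_questionnaire()]; supplies adoption, per-side knowledge,
#'   females-over-45 counts and prior-testing flags. When absent, neutral
#'   defaults (full knowledge, adequate structure, no prior testing) apply.
#' @return A [family_history()] object.
#' @export
compile_family_history <- function(session, config, proband_sex = "female",
                                   proband_age = 35,
                                   limited_session = NULL) {
  stopifnot(inherits(session, "lynch_session"))
  if (!isTRUE(session$completed)) {
    stop("incomplete session: cannot compile a family history")
  }
  ans <- .answer_map(session)

  # proband diagnoses
  pb_dx <- list()
  for (tp in ans$pb_types) {
    if (tp == "colorectal") {
      k <- if (is.null(ans$pb_crc_count)) 1L else max(1L, ans$pb_crc_count)
      for (i in seq_len(k)) {
        pb_dx[[length(pb_dx) + 1L]] <- cancer_diagnosis(
          "colorectal", if (i == 1L && !is.null(ans$pb_crc_age)) ans$pb_crc_age else NA)
      }
    } else if (tp == "endometrial") {
      pb_dx[[length(pb_dx) + 1L]] <- cancer_diagnosis(
        "endometrial", if (is.null(ans$pb_ec_age)) NA else ans$pb_ec_age)
    } else {
      pb_dx[[length(pb_dx) + 1L]] <- cancer_diagnosis(tp, NA)
    }
  }
  pb <- proband(proband_sex, proband_age, diagnoses = pb_dx)

  rels <- list()
  if (identical(ans$mo_any, "yes") && length(ans$mo_types) > 0) {
    rels[[length(rels) + 1L]] <- .compile_typed_relative(
      "mother", ans$mo_types, ans$mo_crc_age, ans$mo_ec_age)
  }
  if (identical(ans$fa_any, "yes") && length(ans$fa_types) > 0) {
    rels[[length(rels) + 1L]] <- .compile_typed_relative(
      "father", ans$fa_types, ans$fa_crc_age, NULL)
  }
  for (prefix in names(.group_relations)) {
    rels <- c(rels, .compile_group(ans, prefix))
  }
  if (identical(ans$hs_any, "yes")) {
    rels[[length(rels) + 1L]] <- relative(
      "half_sibling", side = if (is.null(ans$hs_side)) "unsided" else ans$hs_side,
      diagnoses = list(cancer_diagnosis("colorectal",
                                        if (is.null(ans$hs_crc_age)) NA else ans$hs_crc_age)))
  }

  lim <- list(adopted = FALSE, know_mat = TRUE, know_pat = TRUE,
              fem_mat = 2L, fem_pat = 2L, prior_ls = FALSE, prior_hboc = FALSE)
  if (!is.null(limited_session)) {
    if (!isTRUE(limited_session$completed)) {
      stop("incomplete session: limited-history session is not complete")
    }
    la <- .answer_map(limited_session)
    lim$adopted <- identical(la$lh_adopted, "yes")
    if (!is.null(la$lh_know_mat)) lim$know_mat <- identical(la$lh_know_mat, "yes")
    if (!is.null(la$lh_know_pat)) lim$know_pat <- identical(la$lh_know_pat, "yes")
    if (!is.null(la$lh_fem45_mat)) lim$fem_mat <- la$lh_fem45_mat
    if (!is.null(la$lh_fem45_pat)) lim$fem_pat <- la$lh_fem45_pat
    lim$prior_ls <- identical(la$lh_prior_ls, "yes")
    lim$prior_hboc <- identical(la$lh_prior_hboc, "yes")
  }

  family_history(pb, rels, adopted = lim$adopted,
                 knows_maternal_history = lim$know_mat,
                 knows_paternal_history = lim$know_pat,
                 females_over_45_maternal = lim$fem_mat,
                 females_over_45_paternal = lim$fem_pat,
                 prior_ls_testing = lim$prior_ls,
                 prior_hboc_testing = lim$prior_hboc)
}

#' Gate answers recorded in a session
#'
#' @param session A `lynch_session` on the default questionnaire (the two
#'   gate questions must be answered).
#' @return A [gate_answers()] object.
#' @export
session_gate_answers <- function(session) {
  ans <- .answer_map(session)
  if (is.null(ans$g_personal) || is.null(ans$g_family)) {
    stop("session has no recorded gate answers")
  }
  gate_answers(identical(ans$g_personal, "yes"), identical(ans$g_family, "yes"))
}
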