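# Generates the shipped questionnaire configs and localization tables.
# Run from the repo root: Rscript tools/make_configs.R

lynch12 <- c("colorectal", "endometrial", "ovarian", "stomach", "small_intestine",
             "urinary_tract", "bile_duct", "brain", "pancreatic",
             "sebaceous_gland_tumor", "breast", "other")
other9 <- c("ovarian", "stomach", "small_intestine", "urinary_tract", "bile_duct",
            "brain", "pancreatic", "sebaceous_gland_tumor", "breast")

q <- function(id, module, kind, rules, choices = NULL, aid_keys = NULL) {
  x <- list(id = id, module = module, kind = kind,
            text_key = paste0("q.", id))
  if (!is.null(choices)) x$choices <- as.list(choices)
  if (!is.null(aid_keys)) x$aid_keys <- as.list(aid_keys)
  x$rules <- rules
  x
}
r <- function(goto, q = NULL, op = NULL, value = NULL) {
  if (is.null(q)) list(goto = goto)
  else list(when = list(q = q, op = op, value = value), goto = goto)
}

# A second-degree-group block: any -> crc count -> crc age -> ec any ->
# ec age -> other types; exits to `nxt`.
sdr_block <- function(p, nxt) {
  list(
    q(paste0(p, "_any"), "premm5", "yes_no", aid_keys = "aid.blood_relatives",
      rules = list(r(paste0(p, "_crc_count"), paste0(p, "_any"), "eq", "yes"), r(nxt))),
    q(paste0(p, "_crc_count"), "premm5", "count", aid_keys = "aid.colorectal",
      rules = list(r(paste0(p, "_crc_age"), paste0(p, "_crc_count"), "ge", 1),
                   r(paste0(p, "_ec_any")))),
    q(paste0(p, "_crc_age"), "premm5", "age",
      rules = list(r(paste0(p, "_ec_any")))),
    q(paste0(p, "_ec_any"), "premm5", "yes_no", aid_keys = "aid.endometrial",
      rules = list(r(paste0(p, "_ec_age"), paste0(p, "_ec_any"), "eq", "yes"),
                   r(paste0(p, "_other_types")))),
    q(paste0(p, "_ec_age"), "premm5", "age",
      rules = list(r(paste0(p, "_other_types")))),
    q(paste0(p, "_other_types"), "premm5", "multi_select", choices = other9,
      aid_keys = "aid.sebaceous",
      rules = list(r(nxt)))
  )
}

questions <- c(
  list(
    q("g_personal", "gate", "yes_no", rules = list(r("g_family"))),
    q("g_family", "gate", "yes_no", aid_keys = "aid.blood_relatives",
      rules = list(r("pb_types", "g_personal", "eq", "yes"),
                   r("mo_any", "g_family", "eq", "yes"),
                   r("TERMINAL"))),
    q("pb_types", "premm5", "multi_select", choices = lynch12,
      aid_keys = c("aid.colorectal", "aid.sebaceous"),
      rules = list(r("pb_crc_count", "pb_types", "contains", "colorectal"),
                   r("pb_ec_age", "pb_types", "contains", "endometrial"),
                   r("mo_any", "g_family", "eq", "yes"),
                   r("TERMINAL"))),
    q("pb_crc_count", "premm5", "count", rules = list(r("pb_crc_age"))),
    q("pb_crc_age", "premm5", "age",
      rules = list(r("pb_ec_age", "pb_types", "contains", "endometrial"),
                   r("mo_any", "g_family", "eq", "yes"),
                   r("TERMINAL"))),
    q("pb_ec_age", "premm5", "age",
      rules = list(r("mo_any", "g_family", "eq", "yes"), r("TERMINAL"))),
    q("mo_any", "premm5", "yes_no",
      rules = list(r("mo_types", "mo_any", "eq", "yes"), r("fa_any"))),
    q("mo_types", "premm5", "multi_select", choices = lynch12,
      aid_keys = "aid.sebaceous",
      rules = list(r("mo_crc_age", "mo_types", "contains", "colorectal"),
                   r("mo_ec_age", "mo_types", "contains", "endometrial"),
                   r("fa_any"))),
    q("mo_crc_age", "premm5", "age",
      rules = list(r("mo_ec_age", "mo_types", "contains", "endometrial"),
                   r("fa_any"))),
    q("mo_ec_age", "premm5", "age", rules = list(r("fa_any"))),
    q("fa_any", "premm5", "yes_no",
      rules = list(r("fa_types", "fa_any", "eq", "yes"), r("sc_any"))),
    q("fa_types", "premm5", "multi_select", choices = setdiff(lynch12, "endometrial"),
      aid_keys = "aid.sebaceous",
      rules = list(r("fa_crc_age", "fa_types", "contains", "colorectal"),
                   r("sc_any"))),
    q("fa_crc_age", "premm5", "age", rules = list(r("sc_any")))
  ),
  sdr_block("sc", "mg_any"),
  sdr_block("mg", "pg_any"),
  sdr_block("pg", "ma_any"),
  sdr_block("ma", "pa_any"),
  sdr_block("pa", "hs_any"),
  list(
    q("hs_any", "premm5", "yes_no", aid_keys = "aid.blood_relatives",
      rules = list(r("hs_side", "hs_any", "eq", "yes"), r("TERMINAL"))),
    q("hs_side", "premm5", "single_choice", choices = c("maternal", "paternal"),
      rules = list(r("hs_crc_age"))),
    q("hs_crc_age", "premm5", "age", rules = list(r("TERMINAL")))
  )
)

cfg <- list(version = "1.0", start_id = "g_personal",
            languages = list("en", "es"), questions = questions)
jsonlite::write_json(cfg, "inst/extdata/questionnaire-premm5.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

# limited-family-history module
lim_q <- list(
  q("lh_adopted", "limited", "yes_no", rules = list(r("lh_know_mat"))),
  q("lh_know_mat", "limited", "yes_no", rules = list(r("lh_know_pat"))),
  q("lh_know_pat", "limited", "yes_no", rules = list(r("lh_fem45_mat"))),
  q("lh_fem45_mat", "limited", "count", rules = list(r("lh_fem45_pat"))),
  q("lh_fem45_pat", "limited", "count", rules = list(r("lh_prior_ls"))),
  q("lh_prior_ls", "limited", "yes_no", rules = list(r("lh_prior_hboc"))),
  q("lh_prior_hboc", "limited", "yes_no", rules = list(r("TERMINAL")))
)
lim <- list(version = "1.0", start_id = "lh_adopted",
            languages = list("en", "es"), questions = lim_q)
jsonlite::write_json(lim, "inst/extdata/questionnaire-limited.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

# localization tables: every q.<id> key plus aid/report keys
ids <- vapply(c(questions, lim_q), function(x) x$id, character(1))
en <- character(0); es <- character(0)

text_en <- c(
  g_personal = "Have you ever had cancer?",
  g_family = "Has anyone in your family tree (blood relatives) had cancer?",
  pb_types = "Which kinds of cancer have you had? Select all that apply.",
  pb_crc_count = "How many colorectal (colon or rectal) cancers have you had?",
  pb_crc_age = "How old were you when your first colorectal cancer was found?",
  pb_ec_age = "How old were you when your endometrial (uterine) cancer was found?",
  mo_any = "Did your mother have cancer?",
  mo_types = "Which kinds of cancer did your mother have?",
  mo_crc_age = "How old was your mother when her colorectal cancer was found?",
  mo_ec_age = "How old was your mother when her endometrial (uterine) cancer was found?",
  fa_any = "Did your father have cancer?",
  fa_types = "Which kinds of cancer did your father have?",
  fa_crc_age = "How old was your father when his colorectal cancer was found?",
  hs_any = "Do you have half-brothers or half-sisters who had colorectal cancer?",
  hs_side = "Are they related to you through your mother's side or your father's side?",
  hs_crc_age = "How old was the youngest of them when the cancer was found?",
  lh_adopted = "Were you adopted?",
  lh_know_mat = "Do you know about cancer in your mother's side of the family?",
  lh_know_pat = "Do you know about cancer in your father's side of the family?",
  lh_fem45_mat = "How many women on your mother's side lived past age 45?",
  lh_fem45_pat = "How many women on your father's side lived past age 45?",
  lh_prior_ls = "Have you ever had genetic testing for Lynch syndrome?",
  lh_prior_hboc = "Have you ever had genetic testing for hereditary breast or ovarian cancer?"
)
text_es <- c(
  g_personal = "¿Alguna vez ha tenido cáncer?",
  g_family = "¿Alguien de su árbol familiar (parientes directos) ha tenido cáncer?",
  lh_adopted = "¿Fue usted adoptado/a?",
  hs_side = "¿Son parientes por el lado de su madre o de su padre?"
)

group_en <- c(sc = "your brothers, sisters or children",
              mg = "your mother's parents",
              pg = "your father's parents",
              ma = "your mother's brothers and sisters",
              pa = "your father's brothers and sisters")
for (id in ids) {
  key <- paste0("q.", id)
  if (id %in% names(text_en)) {
    en[key] <- text_en[[id]]
  } else {
    p <- sub("_.*", "", id)
    suffix <- sub("^[a-z]+_", "", id)
    g <- group_en[[p]]
    en[key] <- switch(suffix,
      any = paste0("Did any of ", g, " have cancer?"),
      crc_count = paste0("How many of ", g, " had colorectal (colon or rectal) cancer?"),
      crc_age = paste0("How old was the youngest of ", g, " when colorectal cancer was found?"),
      ec_any = paste0("Did any of ", g, " have endometrial (uterine) cancer?"),
      ec_age = paste0("How old was the youngest of ", g, " when endometrial cancer was found?"),
      other_types = paste0("Did any of ", g, " have one of these other cancers? Select all that apply."),
      stop("no text for ", id))
  }
  es[key] <- if (id %in% names(text_es)) text_es[[id]] else paste0("[es] ", en[key])
}
aids_en <- c(
  "aid.blood_relatives" = "Blood relatives are people in your family tree related to you by birth, like parents, brothers, sisters, children, grandparents, aunts and uncles. First cousins and in-laws do not count here.",
  "aid.colorectal" = "Colorectal cancer is cancer of the colon (large bowel) or rectum.",
  "aid.endometrial" = "Endometrial cancer is cancer of the lining of the uterus (womb).",
  "aid.sebaceous" = "A sebaceous gland skin tumor is a rare growth of the skin's oil glands. It is not the same as common skin cancer.",
  "report.title" = "Your cancer risk assessment result",
  "report.eligible" = "You qualify for genetic testing based on: ",
  "report.not_eligible" = "Based on your answers, you do not qualify for genetic testing at this time.",
  "report.prior_testing" = "You reported having had genetic testing before.",
  "aid.lynch_explanation" = "Lynch syndrome is a condition that can run in families. People with Lynch syndrome have a higher chance of getting colorectal, uterine and some other cancers, often at younger ages. A genetic test can tell whether you have it."
)
for (k in names(aids_en)) {
  en[k] <- aids_en[[k]]
  es[k] <- paste0("[es] ", aids_en[[k]])
}
es["aid.blood_relatives"] <- "Los parientes directos son las personas de su árbol familiar emparentadas con usted por nacimiento. Los primos y los parientes políticos no cuentan aquí."

jsonlite::write_json(as.list(en), "inst/extdata/localization-en.json",
                     auto_unbox = TRUE, pretty = TRUE)
jsonlite::write_json(as.list(es), "inst/extdata/localization-es.json",
                     auto_unbox = TRUE, pretty = TRUE)
cat("wrote configs:", length(questions), "premm5 questions,",
    length(lim_q), "limited questions,", length(en), "en keys\n")
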