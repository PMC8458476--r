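{
  "q.g_personal": "Have you ever had cancer?",
  "q.g_family": "Has anyone in your family tree (blood relatives) had cancer?",
  "q.pb_types": "Which kinds of cancer have you had? Select all that apply.",
  "q.pb_crc_count": "How many colorectal (colon or rectal) cancers have you had?",
  "q.pb_crc_age": "How old were you when your first colorectal cancer was found?",
  "q.pb_ec_age": "How old were you when your endometrial (uterine) cancer was found?",
  "q.mo_any": "Did your mother have cancer?",
  "q.mo_types": "Which kinds of cancer did your mother have?",
  "q.mo_crc_age": "How old was your mother when her colorectal cancer was found?",
  "q.mo_ec_age": "How old was your mother when her endometrial (uterine) cancer was found?",
  "q.fa_any": "Did your father have cancer?",
  "q.fa_types": "Which kinds of cancer did your father have?",
  "q.fa_crc_age": "How old was your father when his colorectal cancer was found?",
  "q.sc_any": "Did any of your brothers, sisters or children have cancer?",
  "q.sc_crc_count": "How many of your brothers, sisters or children had colorectal (colon or rectal) cancer?",
  "q.sc_crc_age": "How old was the youngest of your brothers, sisters or children when colorectal cancer was found?",
  "q.sc_ec_any": "Did any of your brothers, sisters or children have endometrial (uterine) cancer?",
  "q.sc_ec_age": "How old was the youngest of your brothers, sisters or children when endometrial cancer was found?",
  "q.sc_other_types": "Did any of your brothers, sisters or children have one of these other cancers? Select all that apply.",
  "q.mg_any": "Did any of your mother's parents have cancer?",
  "q.mg_crc_count": "How many of your mother's parents had colorectal (colon or rectal) cancer?",
  "q.mg_crc_age": "How old was the youngest of your mother's parents when colorectal cancer was found?",
  "q.mg_ec_any": "Did any of your mother's parents have endometrial (uterine) cancer?",
  "q.mg_ec_age": "How old was the youngest of your mother's parents when endometrial cancer was found?",
  "q.mg_other_types": "Did any of your mother's parents have one of these other cancers? Select all that apply.",
  "q.pg_any": "Did any of your father's parents have cancer?",
  "q.pg_crc_count": "How many of your father's parents had colorectal (colon or rectal) cancer?",
  "q.pg_crc_age": "How old was the youngest of your father's parents when colorectal cancer was found?",
  "q.pg_ec_any": "Did any of your father's parents have endometrial (uterine) cancer?",
  "q.pg_ec_age": "How old was the youngest of your father's parents when endometrial cancer was found?",
  "q.pg_other_types": "Did any of your father's parents have one of these other cancers? Select all that apply.",
  "q.ma_any": "Did any of your mother's brothers and sisters have cancer?",
  "q.ma_crc_count": "How many of your mother's brothers and sisters had colorectal (colon or rectal) cancer?",
  "q.ma_crc_age": "How old was the youngest of your mother's brothers and sisters when colorectal cancer was found?",
  "q.ma_ec_any": "Did any of your mother's brothers and sisters have endometrial (uterine) cancer?",
  "q.ma_ec_age": "How old was the youngest of your mother's brothers and sisters when endometrial cancer was found?",
  "q.ma_other_types": "Did any of your mother's brothers and sisters have one of these other cancers? Select all that apply.",
  "q.pa_any": "Did any of your father's brothers and sisters have cancer?",
  "q.pa_crc_count": "How many of your father's brothers and sisters had colorectal (colon or rectal) cancer?",
  "q.pa_crc_age": "How old was the youngest of your father's brothers and sisters when colorectal cancer was found?",
  "q.pa_ec_any": "Did any of your father's brothers and sisters have endometrial (uterine) cancer?",
  "q.pa_ec_age": "How old was the youngest of your father's brothers and sisters when endometrial cancer was found?",
  "q.pa_other_types": "Did any of your father's brothers and sisters have one of these other cancers? Select all that apply.",
  "q.hs_any": "Do you have half-brothers or half-sisters who had colorectal cancer?",
  "q.hs_side": "Are they related to you through your mother's side or your father's side?",
  "q.hs_crc_age": "How old was the youngest of them when the cancer was found?",
  "q.lh_adopted": "Were you adopted?",
  "q.lh_know_mat": "Do you know about cancer in your mother's side of the family?",
  "q.lh_know_pat": "Do you know about cancer in your father's side of the family?",
  "q.lh_fem45_mat": "How many women on your mother's side lived past age 45?",
  "q.lh_fem45_pat": "How many women on your father's side lived past age 45?",
  "q.lh_prior_ls": "Have you ever had genetic testing for Lynch syndrome?",
  "q.lh_prior_hboc": "Have you ever had genetic testing for hereditary breast or ovarian cancer?",
  "aid.blood_relatives": "Blood relatives are people in your family tree related to you by birth, like parents, brothers, sisters, children, grandparents, aunts and uncles. First cousins and in-laws do not count here.",
  "aid.colorectal": "Colorectal cancer is cancer of the colon (large bowel) or rectum.",
  "aid.endometrial": "Endometrial cancer is cancer of the lining of the uterus (womb).",
  "aid.sebaceous": "A sebaceous gland skin tumor is a rare growth of the skin's oil glands. It is not the same as common skin cancer.",
  "report.title": "Your cancer risk assessment result",
  "report.eligible": "You qualify for genetic testing based on: ",
  "report.not_eligible": "Based on your answers, you do not qualify for genetic testing at this time.",
  "report.prior_testing": "You reported having had genetic testing before.",
  "aid.lynch_explanation": "Lynch syndrome is a condition that can run in families. People with Lynch syndrome have a higher chance of getting colorectal, uterine and some other cancers, often at younger ages. A genetic test can tell whether you have it."
}
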