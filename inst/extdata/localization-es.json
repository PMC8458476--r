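{
  "q.g_personal": "¿Alguna vez ha tenido cáncer?",
  "q.g_family": "¿Alguien de su árbol familiar (parientes directos) ha tenido cáncer?",
  "q.pb_types": "[es] Which kinds of cancer have you had? Select all that apply.",
  "q.pb_crc_count": "[es] How many colorectal (colon or rectal) cancers have you had?",
  "q.pb_crc_age": "[es] How old were you when your first colorectal cancer was found?",
  "q.pb_ec_age": "[es] How old were you when your endometrial (uterine) cancer was found?",
  "q.mo_any": "[es] Did your mother have cancer?",
  "q.mo_types": "[es] Which kinds of cancer did your mother have?",
  "q.mo_crc_age": "[es] How old was your mother when her colorectal cancer was found?",
  "q.mo_ec_age": "[es] How old was your mother when her endometrial (uterine) cancer was found?",
  "q.fa_any": "[es] Did your father have cancer?",
  "q.fa_types": "[es] Which kinds of cancer did your father have?",
  "q.fa_crc_age": "[es] How old was your father when his colorectal cancer was found?",
  "q.sc_any": "[es] Did any of your brothers, sisters or children have cancer?",
  "q.sc_crc_count": "[es] How many of your brothers, sisters or children had colorectal (colon or rectal) cancer?",
  "q.sc_crc_age": "[es] How old was the youngest of your brothers, sisters or children when colorectal cancer was found?",
  "q.sc_ec_any": "[es] Did any of your brothers, sisters or children have endometrial (uterine) cancer?",
  "q.sc_ec_age": "[es] How old was the youngest of your brothers, sisters or children when endometrial cancer was found?",
  "q.sc_other_types": "[es] Did any of your brothers, sisters or children have one of these other cancers? Select all that apply.",
  "q.mg_any": "[es] Did any of your mother's parents have cancer?",
  "q.mg_crc_count": "[es] How many of your mother's parents had colorectal (colon or rectal) cancer?",
  "q.mg_crc_age": "[es] How old was the youngest of your mother's parents when colorectal cancer was found?",
  "q.mg_ec_any": "[es] Did any of your mother's parents have endometrial (uterine) cancer?",
  "q.mg_ec_age": "[es] How old was the youngest of your mother's parents when endometrial cancer was found?",
  "q.mg_other_types": "[es] Did any of your mother's parents have one of these other cancers? Select all that apply.",
  "q.pg_any": "[es] Did any of your father's parents have cancer?",
  "q.pg_crc_count": "[es] How many of your father's parents had colorectal (colon or rectal) cancer?",
  "q.pg_crc_age": "[es] How old was the youngest of your father's parents when colorectal cancer was found?",
  "q.pg_ec_any": "[es] Did any of your father's parents have endometrial (uterine) cancer?",
  "q.pg_ec_age": "[es] How old was the youngest of your father's parents when endometrial cancer was found?",
  "q.pg_other_types": "[es] Did any of your father's parents have one of these other cancers? Select all that apply.",
  "q.ma_any": "[es] Did any of your mother's brothers and sisters have cancer?",
  "q.ma_crc_count": "[es] How many of your mother's brothers and sisters had colorectal (colon or rectal) cancer?",
  "q.ma_crc_age": "[es] How old was the youngest of your mother's brothers and sisters when colorectal cancer was found?",
  "q.ma_ec_any": "[es] Did any of your mother's brothers and sisters have endometrial (uterine) cancer?",
  "q.ma_ec_age": "[es] How old was the youngest of your mother's brothers and sisters when endometrial cancer was found?",
  "q.ma_other_types": "[es] Did any of your mother's brothers and sisters have one of these other cancers? Select all that apply.",
  "q.pa_any": "[es] Did any of your father's brothers and sisters have cancer?",
  "q.pa_crc_count": "[es] How many of your father's brothers and sisters had colorectal (colon or rectal) cancer?",
  "q.pa_crc_age": "[es] How old was the youngest of your father's brothers and sisters when colorectal cancer was found?",
  "q.pa_ec_any": "[es] Did any of your father's brothers and sisters have endometrial (uterine) cancer?",
  "q.pa_ec_age": "[es] How old was the youngest of your father's brothers and sisters when endometrial cancer was found?",
  "q.pa_other_types": "[es] Did any of your father's brothers and sisters have one of these other cancers? Select all that apply.",
  "q.hs_any": "[es] Do you have half-brothers or half-sisters who had colorectal cancer?",
  "q.hs_side": "¿Son parientes por el lado de su madre o de su padre?",
  "q.hs_crc_age": "[es] How old was the youngest of them when the cancer was found?",
  "q.lh_adopted": "¿Fue usted adoptado/a?",
  "q.lh_know_mat": "[es] Do you know about cancer in your mother's side of the family?",
  "q.lh_know_pat": "[es] Do you know about cancer in your father's side of the family?",
  "q.lh_fem45_mat": "[es] How many women on your mother's side lived past age 45?",
  "q.lh_fem45_pat": "[es] How many women on your father's side lived past age 45?",
  "q.lh_prior_ls": "[es] Have you ever had genetic testing for Lynch syndrome?",
  "q.lh_prior_hboc": "[es] Have you ever had genetic testing for hereditary breast or ovarian cancer?",
  "aid.blood_relatives": "Los parientes directos son las personas de su árbol familiar emparentadas con usted por nacimiento. Los primos y los parientes políticos no cuentan aquí.",
  "aid.colorectal": "[es] Colorectal cancer is cancer of the colon (large bowel) or rectum.",
  "aid.endometrial": "[es] Endometrial cancer is cancer of the lining of the uterus (womb).",
  "aid.sebaceous": "[es] A sebaceous gland skin tumor is a rare growth of the skin's oil glands. It is not the same as common skin cancer.",
  "report.title": "[es] Your cancer risk assessment result",
  "report.eligible": "[es] You qualify for genetic testing based on: ",
  "report.not_eligible": "[es] Based on your answers, you do not qualify for genetic testing at this time.",
  "report.prior_testing": "[es] You reported having had genetic testing before.",
  "aid.lynch_explanation": "[es] Lynch syndrome is a condition that can run in families. People with Lynch syndrome have a higher chance of getting colorectal, uterine and some other cancers, often at younger ages. A genetic test can tell whether you have it."
}
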