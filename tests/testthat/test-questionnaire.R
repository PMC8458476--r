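# small in-code config used across several blocks: one yes/no branch and a
# dependent count question
tiny_config <- function() {
  questionnaire_config(list(
    list(id = "q1", module = "gate", kind = "yes_no", text_key = "k1",
         rules = list(list(when = list(q = "q1", op = "eq", value = "yes"),
                           goto = "q2"),
                      list(goto = TERMINAL))),
    list(id = "q2", module = "premm5", kind = "count", text_key = "k2",
         rules = list(list(when = list(q = "q2", op = "ge", value = 1),
                           goto = "q3"),
                      list(goto = TERMINAL))),
    list(id = "q3", module = "premm5", kind = "age", text_key = "k3",
         rules = list(list(goto = TERMINAL)))
  ), start_id = "q1", languages = "en")
}

test_that("config validation rejects structural defects", {
  # cyclic graph
  expect_error(questionnaire_config(list(
    list(id = "a", module = "gate", kind = "yes_no", rules = list(list(goto = "b"))),
    list(id = "b", module = "gate", kind = "yes_no", rules = list(list(goto = "a")))
  ), start_id = "a"), "cyclic")
  # missing default rule
  expect_error(questionnaire_config(list(
    list(id = "a", module = "gate", kind = "yes_no",
         rules = list(list(when = list(q = "a", op = "eq", value = "yes"),
                           goto = TERMINAL)))
  ), start_id = "a"), "default")
  # dangling goto
  expect_error(questionnaire_config(list(
    list(id = "a", module = "gate", kind = "yes_no", rules = list(list(goto = "zzz")))
  ), start_id = "a"), "unknown id")
  # choice kind without choices
  expect_error(questionnaire_config(list(
    list(id = "a", module = "gate", kind = "multi_select", rules = list(list(goto = TERMINAL)))
  ), start_id = "a"), "no choices")
})

test_that("shipped configs load, declare en/es, and localization keys resolve", {
  cfg <- default_questionnaire()   # errors if any key unresolved in en or es
  expect_setequal(cfg$languages, c("en", "es"))
  expect_length(cfg$questions, 46L)
  lim <- limited_questionnaire()
  expect_length(lim$questions, 7L)
  expect_true(all(c("en", "es") %in% cfg$languages))
  # a missing key errors
  cfg_bad <- cfg
  expect_error(
    questionnaire_config(list(
      list(id = "a", module = "gate", kind = "yes_no", text_key = "nope",
           rules = list(list(goto = TERMINAL)))
    ), start_id = "a", languages = "en", strings = list(en = c(other = "x"))),
    "localization keys missing")
})

test_that("next_question follows skip rules deterministically", {
  cfg <- tiny_config()
  s <- new_session(cfg, started_at = 0)
  expect_identical(next_question(cfg, s)$id, "q1")
  s <- record_answer(s, cfg, "q1", "no", at = 1)
  expect_identical(next_question(cfg, s), TERMINAL)
  expect_true(s$completed)

  s2 <- new_session(cfg, started_at = 0)
  s2 <- record_answer(s2, cfg, "q1", "yes", at = 1)
  expect_identical(next_question(cfg, s2)$id, "q2")
  s2 <- record_answer(s2, cfg, "q2", 0, at = 2)
  expect_identical(next_question(cfg, s2), TERMINAL)
})

test_that("gate answers route into or past the risk questions in the default config", {
  cfg <- default_questionnaire()
  s <- new_session(cfg, started_at = 0)
  expect_identical(next_question(cfg, s)$id, "g_personal")
  s <- record_answer(s, cfg, "g_personal", "no", at = 1)
  s <- record_answer(s, cfg, "g_family", "no", at = 2)
  # no history: the risk module is skipped entirely (the router then
  # exposes the limited-family-history module)
  expect_identical(next_question(cfg, s), TERMINAL)

  s2 <- new_session(cfg, started_at = 0)
  s2 <- record_answer(s2, cfg, "g_personal", "no", at = 1)
  s2 <- record_answer(s2, cfg, "g_family", "yes", at = 2)
  s2 <- record_answer(s2, cfg, "mo_any", "yes", at = 3)
  # selecting that the mother had cancer exposes the mother cancer-type screen
  expect_identical(next_question(cfg, s2)$id, "mo_types")
})

test_that("record_answer validates values and timestamps", {
  cfg <- tiny_config()
  s <- new_session(cfg, started_at = 0)
  expect_error(record_answer(s, cfg, "q2", 1, at = 1), "not the current question")
  s <- record_answer(s, cfg, "q1", "yes", at = 1)
  expect_error(record_answer(s, cfg, "q2", -1, at = 2), "non-negative")
  s <- record_answer(s, cfg, "q2", 2, at = 2)
  expect_error(record_answer(s, cfg, "q3", 130, at = 3), "\\[0, 120\\]")
  expect_error(record_answer(s, cfg, "q3", 50, at = 1), "non-decreasing")
  s <- record_answer(s, cfg, "q3", "unknown", at = 3)
  expect_true(s$completed)
})

test_that("re-answering truncates downstream answers and re-evaluates the path", {
  cfg <- tiny_config()
  s <- new_session(cfg, started_at = 0)
  s <- record_answer(s, cfg, "q1", "yes", at = 1)
  s <- record_answer(s, cfg, "q2", 1, at = 2)
  s <- record_answer(s, cfg, "q3", 44, at = 3)
  expect_true(s$completed)
  s <- record_answer(s, cfg, "q1", "no", at = 4)
  expect_length(s$answers, 1L)
  expect_true(s$completed)  # "no" routes straight to terminal
})

test_that("sessions replay deterministically and stay inside the path envelope", {
  cfg <- default_questionnaire()
  env <- enumerate_paths(cfg)
  set.seed(99)
  for (i in 1:12) {
    s <- walk_session(cfg, random_policy())
    expect_true(s$completed)
    n <- length(s$answers)
    expect_gte(n, env$min_questions)
    expect_lte(n, env$max_questions)
    # replaying the recorded answers reproduces the identical sequence
    s2 <- new_session(cfg, started_at = 0)
    for (a in s$answers) {
      expect_identical(next_question(cfg, s2)$id, a$question_id)
      s2 <- record_answer(s2, cfg, a$question_id, a$value,
                          at = a$answered_at + 1e6)
    }
    expect_identical(next_question(cfg, s2), TERMINAL)
  }
})

test_that("corrupted sessions are detected", {
  cfg <- tiny_config()
  s <- new_session(cfg, started_at = 0)
  s$answers <- list(list(question_id = "q2", value = 1, answered_at = 1))
  expect_error(next_question(cfg, s), "session corrupt")
})

test_that("path enumeration: trivial and branching configs", {
  single <- questionnaire_config(list(
    list(id = "only", module = "gate", kind = "yes_no",
         rules = list(list(goto = TERMINAL)))
  ), start_id = "only")
  expect_identical(enumerate_paths(single),
                   list(min_questions = 1L, max_questions = 1L,
                        n_terminal_paths = 2))
  tiny <- enumerate_paths(tiny_config())
  # paths: no | yes-0 | yes-(>=1)-age
  expect_identical(tiny$min_questions, 1L)
  expect_identical(tiny$max_questions, 3L)
  expect_identical(tiny$n_terminal_paths, 3)
})

test_that("completed sessions compile into family histories", {
  cfg <- default_questionnaire()
  # no personal or family history: empty relatives, no proband diagnoses
  s0 <- walk_session(cfg, function(q) "no")
  fh0 <- compile_family_history(s0, cfg)
  expect_length(fh0$relatives, 0L)
  expect_length(fh0$proband$diagnoses, 0L)

  # mother with colorectal cancer at 52
  pol <- function(q) {
    switch(q$id,
      g_personal = "no", g_family = "yes",
      mo_any = "yes", mo_types = "colorectal", mo_crc_age = 52,
      "no")
  }
  s1 <- walk_session(cfg, pol)
  fh1 <- compile_family_history(s1, cfg)
  expect_length(fh1$relatives, 1L)
  expect_identical(fh1$relatives[[1]]$relation, "mother")
  expect_identical(fh1$relatives[[1]]$side, "maternal")
  expect_identical(fh1$relatives[[1]]$diagnoses[[1]]$cancer_type, "colorectal")
  expect_identical(fh1$relatives[[1]]$diagnoses[[1]]$age_at_diagnosis, 52L)

  # group-level report: 2 siblings with colorectal cancer, youngest at 40
  pol2 <- function(q) {
    switch(q$id,
      g_personal = "no", g_family = "yes",
      sc_any = "yes", sc_crc_count = 2, sc_crc_age = 40, sc_ec_any = "no",
      if (q$kind == "multi_select") character(0) else "no")
  }
  s2 <- walk_session(cfg, pol2)
  fh2 <- compile_family_history(s2, cfg)
  agg <- aggregate_side(fh2, "maternal")
  expect_identical(agg$fdr_crc_count, 2L)
  expect_identical(agg$fdr_crc_min_age, 40L)

  # incomplete sessions refuse to compile
  s3 <- new_session(cfg, started_at = 0)
  s3 <- record_answer(s3, cfg, "g_personal", "yes", at = 1)
  expect_error(compile_family_history(s3, cfg), "incomplete session")
})

test_that("limited-module answers populate the pedigree flags", {
  cfg <- default_questionnaire()
  lim <- limited_questionnaire()
  s <- walk_session(cfg, function(q) "no")
  slim <- new_session(lim, started_at = 0)
  vals <- list(lh_adopted = "yes", lh_know_mat = "yes", lh_know_pat = "no",
               lh_fem45_mat = 1, lh_fem45_pat = 3,
               lh_prior_ls = "no", lh_prior_hboc = "yes")
  t <- 0
  for (id in names(vals)) {
    t <- t + 1
    slim <- record_answer(slim, lim, id, vals[[id]], at = t)
  }
  fh <- compile_family_history(s, cfg, limited_session = slim)
  expect_true(fh$adopted)
  expect_false(fh$knows_paternal_history)
  expect_identical(fh$females_over_45_maternal, 1L)
  expect_identical(fh$females_over_45_paternal, 3L)
  expect_true(fh$prior_hboc_testing)
  expect_false(fh$prior_ls_testing)
})

test_that("module duration sums inter-answer gaps for the tagged questions", {
  cfg <- tiny_config()
  # single premm5 question answered 30 s after start
  s <- new_session(cfg, started_at = 0)
  s <- record_answer(s, cfg, "q1", "yes", at = 10)   # gate
  s <- record_answer(s, cfg, "q2", 0, at = 30)       # premm5
  expect_identical(module_duration(s, cfg, "premm5"), 20)
  expect_identical(module_duration(s, cfg, "gate"), 10)
  expect_identical(module_duration(s, cfg, "limited"), 0)

  # gate at t=5, three premm5 answers at t=10, 25, 40: 5 + 15 + 15 = 35
  chain <- questionnaire_config(list(
    list(id = "g", module = "gate", kind = "yes_no", rules = list(list(goto = "p1"))),
    list(id = "p1", module = "premm5", kind = "count", rules = list(list(goto = "p2"))),
    list(id = "p2", module = "premm5", kind = "count", rules = list(list(goto = "p3"))),
    list(id = "p3", module = "premm5", kind = "count", rules = list(list(goto = TERMINAL)))
  ), start_id = "g")
  s2 <- new_session(chain, started_at = 0)
  s2 <- record_answer(s2, chain, "g", "yes", at = 5)
  s2 <- record_answer(s2, chain, "p1", 1, at = 10)
  s2 <- record_answer(s2, chain, "p2", 1, at = 25)
  s2 <- record_answer(s2, chain, "p3", 1, at = 40)
  expect_identical(module_duration(s2, chain, "premm5"), 35)
  cfg46 <- default_questionnaire()
  s3 <- new_session(cfg46, started_at = 0)
  s3 <- record_answer(s3, cfg46, "g_personal", "yes", at = 5)
  s3 <- record_answer(s3, cfg46, "g_family", "no", at = 10)
  s3 <- record_answer(s3, cfg46, "pb_types", "stomach", at = 25)
  expect_identical(module_duration(s3, cfg46, "premm5"), 15)
  expect_identical(module_duration(s3, cfg46, "gate"), 10)
})

test_that("sessions round-trip through JSON", {
  cfg <- tiny_config()
  s <- new_session(cfg, session_id = "abc", language = "en",
                   setting = "remote", started_at = 0)
  s <- record_answer(s, cfg, "q1", "yes", at = 2.5)
  s <- record_answer(s, cfg, "q2", 0, at = 4)
  path <- tempfile(fileext = ".json")
  write_session(s, path)
  s2 <- read_session(path)
  expect_identical(s2$session_id, "abc")
  expect_identical(s2$setting, "remote")
  expect_true(s2$completed)
  expect_identical(next_question(cfg, s2), TERMINAL)
  expect_identical(module_duration(s2, cfg, "premm5"), 1.5)
})

test_that("the numeracy sum respects its bounds", {
  expect_identical(sns3_sum(1, 1, 1), 3L)
  expect_identical(sns3_sum(6, 6, 6), 18L)
  expect_identical(sns3_sum(4, 5, 3), 12L)
  expect_error(sns3_sum(0, 5, 3), "\\[1, 6\\]")
  expect_error(sns3_sum(2, 7, 3), "\\[1, 6\\]")
})
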