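# Declarative skip-logic questionnaire engine: question graph validation,
# session capture, compilation into a family history, exhaustive path
# enumeration, and time/numeracy quality metrics.

#' Terminal sentinel for the question graph
#' @export
TERMINAL <- "TERMINAL"

.answer_kinds <- c("yes_no", "single_choice", "multi_select", "count", "age")
.module_tags <- c("gate", "premm5", "brst", "limited")

#' Build a questionnaire configuration from R lists
#'
#' Each question is a list with fields `id`, `module` (gate/premm5/brst/
#' limited), `kind` (yes_no/single_choice/multi_select/count/age), optional
#' `choices` (required for choice kinds), `text_key`, optional `aid_keys`,
#' and `rules`: an ordered list of skip rules `list(when = list(q, op,
#' value), goto = id)` whose last element must be an unconditional default
#' (`when = NULL`). Rule predicates support `op` in `eq`, `ge`, `contains`
#' and may only reference questions answered earlier on the path; a
#' predicate over an unanswered question evaluates false. `goto` is a
#' question id or [TERMINAL].
#'
#' The graph must be acyclic, every referenced id must exist, and (given
#' those) every question reaches the terminal. When `strings` (a list of
#' per-language key-to-text tables) is supplied, every `text_key`/`aid_key`
#' must resolve in every declared language.
#'
#' @param questions List of question lists (see Details).
#' @param start_id Id of the first question.
#' @param version Config version string.
#' @param languages Declared languages (must include "en" and "es" for the
#'   shipped configs).
#' @param strings Optional named list `language -> named character vector`
#'   used to validate localization keys.
#' @return A `questionnaire_config` object.
#' @export
questionnaire_config <- function(questions, start_id, version = "0",
                                 languages = c("en", "es"), strings = NULL) {
  stopifnot(is.list(questions), length(questions) >= 1L)
  qs <- list()
  for (q in questions) {
    if (is.null(q$id) || is.null(q$kind) || is.null(q$module)) {
      stop("each question needs id, module and kind")
    }
    if (!q$kind %in% .answer_kinds) stop("unknown answer kind: ", q$kind)
    if (!q$module %in% .module_tags) stop("unknown module tag: ", q$module)
    if (q$id %in% names(qs)) stop("duplicate question id: ", q$id)
    choice_kind <- q$kind %in% c("single_choice", "multi_select")
    q$choices <- as.character(unlist(q$choices))
    if (choice_kind && length(q$choices) == 0) {
      stop("question '", q$id, "' is a choice kind but has no choices")
    }
    if (!choice_kind && length(q$choices) > 0) {
      stop("question '", q$id, "' has choices but is not a choice kind")
    }
    if (is.null(q$rules) || length(q$rules) == 0) {
      stop("question '", q$id, "' has no skip rules")
    }
    last <- q$rules[[length(q$rules)]]
    if (!is.null(last$when)) {
      stop("question '", q$id, "' lacks a default (unconditional) final rule")
    }
    for (r in q$rules) {
      if (is.null(r$goto)) stop("rule without goto in question '", q$id, "'")
      if (!is.null(r$when)) {
        if (is.null(r$when$q) || is.null(r$when$op) || is.null(r$when$value)) {
          stop("malformed predicate in question '", q$id, "'")
        }
        if (!r$when$op %in% c("eq", "ge", "contains")) {
          stop("unknown predicate op '", r$when$op, "' in question '", q$id, "'")
        }
      }
    }
    q$aid_keys <- as.character(unlist(q$aid_keys))
    qs[[q$id]] <- q
  }
  if (!start_id %in% names(qs)) stop("start_id '", start_id, "' not found")
  cfg <- structure(list(questions = qs, start_id = start_id,
                        version = as.character(version),
                        languages = as.character(languages)),
                   class = "questionnaire_config")
  .validate_graph(cfg)
  if (!is.null(strings)) .validate_strings(cfg, strings)
  cfg
}

.validate_graph <- function(cfg) {
  qs <- cfg$questions
  ids <- names(qs)
  for (q in qs) {
    for (r in q$rules) {
      if (!identical(r$goto, TERMINAL) && !r$goto %in% ids) {
        stop("question '", q$id, "' routes to unknown id '", r$goto, "'")
      }
      if (!is.null(r$when) && !r$when$q %in% ids) {
        stop("question '", q$id, "' predicate references unknown id '",
             r$when$q, "'")
      }
    }
  }
  # cycle check over goto edges (DFS, three colors)
  color <- stats::setNames(rep(0L, length(ids)), ids)
  visit <- function(id) {
    if (identical(id, TERMINAL)) return(invisible())
    if (color[[id]] == 1L) stop("questionnaire graph is cyclic at '", id, "'")
    if (color[[id]] == 2L) return(invisible())
    color[[id]] <<- 1L
    for (r in qs[[id]]$rules) visit(r$goto)
    color[[id]] <<- 2L
  }
  for (id in ids) visit(id)
  unreachable <- ids[color == 0L]
  # acyclicity + valid gotos guarantee every question reaches TERMINAL;
  # unreachable-from-start questions are a config smell, not an error
  visit2 <- new.env(parent = emptyenv())
  reach <- function(id) {
    if (identical(id, TERMINAL) || !is.null(visit2[[id]])) return(invisible())
    visit2[[id]] <- TRUE
    for (r in qs[[id]]$rules) reach(r$goto)
  }
  reach(cfg$start_id)
  orphan <- setdiff(ids, ls(visit2))
  if (length(orphan) > 0) {
    warning("questions unreachable from start: ", paste(orphan, collapse = ", "))
  }
  invisible(cfg)
}

.validate_strings <- function(cfg, strings) {
  for (lang in cfg$languages) {
    tab <- strings[[lang]]
    if (is.null(tab)) stop("no localization table for declared language '", lang, "'")
    for (q in cfg$questions) {
      keys <- c(q$text_key, q$aid_keys)
      missing <- setdiff(keys, names(tab))
      if (length(missing) > 0) {
        stop("localization keys missing in '", lang, "': ",
             paste(missing, collapse = ", "))
      }
    }
  }
  invisible(cfg)
}

#' Load a questionnaire configuration from JSON or YAML
#'
#' @param path Config file (`.json`, `.yaml` or `.yml`).
#' @param strings Optional localization tables, as in
#'   [questionnaire_config()]; keys are then validated for every declared
#'   language.
#' @return A `questionnaire_config` object.
#' @export
load_questionnaire <- function(path, strings = NULL) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  questionnaire_config(x$questions, start_id = x$start_id,
                       version = x$version,
                       languages = unlist(x$languages), strings = strings)
}

#' Load a shipped localization table
#'
#' @param language Language code ("en" or "es" are shipped).
#' @return Named character vector mapping localization keys to display text.
#' @export
load_localization <- function(language) {
  path <- system.file("extdata", paste0("localization-", language, ".json"),
                      package = "lynchtriage")
  if (!nzchar(path)) stop("no shipped localization for language '", language, "'")
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Shipped default questionnaire configurations
#'
#' `default_questionnaire()` is the patient-facing risk-assessment
#' inventory: two gate questions (personal / family history of cancer)
#' followed by skip-logic blocks for the proband and for relatives grouped
#' familially (mother, father, brothers/sisters/children, grandparents and
#' aunts/uncles per side, half-siblings). Its complete answer paths span 2
#' to 46 questions. `limited_questionnaire()` is the limited-family-history
#' module (adoption, per-side knowledge, females over 45 per side, prior
#' genetic testing) that the eligibility router exposes separately.
#'
#' @return A `questionnaire_config` object.
#' @export
default_questionnaire <- function() {
  strings <- list(en = load_localization("en"), es = load_localization("es"))
  load_questionnaire(system.file("extdata", "questionnaire-premm5.json",
                                 package = "lynchtriage", mustWork = TRUE),
                     strings = strings)
}

#' @rdname default_questionnaire
#' @export
limited_questionnaire <- function() {
  strings <- list(en = load_localization("en"), es = load_localization("es"))
  load_questionnaire(system.file("extdata", "questionnaire-limited.json",
                                 package = "lynchtriage", mustWork = TRUE),
                     strings = strings)
}

#' Start a questionnaire session
#'
#' @param config A `questionnaire_config`.
#' @param session_id Identifier string.
#' @param language Session language; must be declared by the config.
#' @param setting `"in_clinic"` or `"remote"`.
#' @param assisted Was the participant assisted?
#' @param started_at Numeric timestamp (seconds); defaults to the wall
#'   clock. Supply explicitly for reproducible timing metrics.
#' @return A `lynch_session` object.
#' @export
new_session <- function(config, session_id = "s1", language = "en",
                        setting = c("in_clinic", "remote"), assisted = FALSE,
                        started_at = as.numeric(Sys.time())) {
  stopifnot(inherits(config, "questionnaire_config"))
  if (!language %in% config$languages) {
    stop("language '", language, "' is not declared by the config")
  }
  structure(list(session_id = session_id, language = language,
                 setting = match.arg(setting), assisted = isTRUE(assisted),
                 started_at = as.numeric(started_at),
                 answers = list(), completed = FALSE),
            class = "lynch_session")
}

.answer_map <- function(session) {
  vals <- lapply(session$answers, function(a) a$value)
  names(vals) <- vapply(session$answers, function(a) a$question_id, character(1))
  vals
}

.eval_pred <- function(pred, answers) {
  v <- answers[[pred$q]]
  if (is.null(v)) return(FALSE)
  switch(pred$op,
    eq = identical(as.character(v)[1], as.character(pred$value)),
    ge = is.numeric(v) && !is.na(v) && v >= pred$value,
    contains = as.character(pred$value) %in% as.character(v),
    FALSE
  )
}

.next_id <- function(config, qid, answers) {
  for (r in config$questions[[qid]]$rules) {
    if (is.null(r$when) || .eval_pred(r$when, answers)) return(r$goto)
  }
  stop("no rule matched for question '", qid, "'") # unreachable: default exists
}

# Replay the session from the start; returns the id the session sits at
# (TERMINAL when complete). Errors if recorded answers diverge from the
# skip-logic path.
.replay <- function(config, session) {
  qid <- config$start_id
  answers <- list()
  for (a in session$answers) {
    if (identical(qid, TERMINAL)) {
      stop("session corrupt: answer recorded after terminal")
    }
    if (!identical(a$question_id, qid)) {
      stop("session corrupt: answer for unreachable question '",
           a$question_id, "' (expected '", qid, "')")
    }
    answers[[a$question_id]] <- a$value
    qid <- .next_id(config, qid, answers)
  }
  qid
}

#' Next question of a session
#'
#' Deterministic replay of the skip logic: the first rule of the last
#' answered question whose predicate holds yields the next id; an empty
#' session starts at `start_id`; the terminal is absorbing.
#'
#' @param config A `questionnaire_config`.
#' @param session A `lynch_session` consistent with the config.
#' @return The next question (a list), or the string [TERMINAL].
#' @export
next_question <- function(config, session) {
  stopifnot(inherits(config, "questionnaire_config"),
            inherits(session, "lynch_session"))
  qid <- .replay(config, session)
  if (identical(qid, TERMINAL)) TERMINAL else config$questions[[qid]]
}

.validate_answer <- function(q, value) {
  switch(q$kind,
    yes_no = {
      if (is.logical(value)) value <- if (isTRUE(value)) "yes" else "no"
      if (!value %in% c("yes", "no")) {
        stop("field '", q$id, "': yes_no answer must be yes/no")
      }
      value
    },
    count = {
      if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0) {
        stop("field '", q$id, "': count must be a non-negative integer")
      }
      as.integer(round(value))
    },
    age = {
      if (identical(value, "unknown")) return(NA_integer_)
      if (length(value) == 1L && is.na(value)) return(NA_integer_)
      if (!is.numeric(value) || length(value) != 1L || value < 0 || value > 120) {
        stop("field '", q$id, "': age must be in [0, 120] or unknown")
      }
      as.integer(round(value))
    },
    single_choice = {
      if (!is.character(value) || length(value) != 1L || !value %in% q$choices) {
        stop("field '", q$id, "': answer must be one of the declared choices")
      }
      value
    },
    multi_select = {
      value <- as.character(value)
      bad <- setdiff(value, q$choices)
      if (length(bad) > 0) {
        stop("field '", q$id, "': selections not among choices: ",
             paste(bad, collapse = ", "))
      }
      value
    }
  )
}

#' Record an answer in a session
#'
#' The question must be the session's current next question. Re-answering
#' an earlier question discards it and every downstream answer first (the
#' skip-logic path is then re-evaluated), keeping the session consistent by
#' construction. Timestamps must be non-decreasing.
#'
#' @param session A `lynch_session`.
#' @param config The session's `questionnaire_config`.
#' @param question_id Id of the question being answered.
#' @param value The answer (type must match the question's answer kind).
#' @param at Numeric timestamp; defaults to the wall clock.
#' @return The updated session; `completed` becomes `TRUE` when the skip
#'   logic reaches the terminal.
#' @export
record_answer <- function(session, config, question_id, value,
                          at = as.numeric(Sys.time())) {
  stopifnot(inherits(session, "lynch_session"),
            inherits(config, "questionnaire_config"))
  answered <- vapply(session$answers, function(a) a$question_id, character(1))
  if (question_id %in% answered) {
    keep <- seq_len(match(question_id, answered) - 1L)
    session$answers <- session$answers[keep]
    session$completed <- FALSE
  }
  nxt <- .replay(config, session)
  if (!identical(nxt, question_id)) {
    stop("question '", question_id, "' is not the current question (expected '",
         nxt, "')")
  }
  q <- config$questions[[question_id]]
  value <- .validate_answer(q, value)
  last_t <- if (length(session$answers) > 0) {
    session$answers[[length(session$answers)]]$answered_at
  } else {
    session$started_at
  }
  at <- as.numeric(at)
  if (at < last_t) stop("answer timestamps must be non-decreasing")
  session$answers[[length(session$answers) + 1L]] <-
    list(question_id = question_id, value = value, answered_at = at)
  session$completed <- identical(.replay(config, session), TERMINAL)
  session
}

#' Time spent on one module's questions
#'
#' The duration attributed to a question is the gap between its answer
#' timestamp and the previous answer's (the first question is measured from
#' session start); the result is the sum over questions carrying the given
#' module tag.
#'
#' @param session A `lynch_session` with at least one answer.
#' @param config The session's config.
#' @param module_tag One of gate, premm5, brst, limited.
#' @return Seconds (0 when no question carries the tag).
#' @export
module_duration <- function(session, config, module_tag) {
  stopifnot(inherits(session, "lynch_session"), length(session$answers) >= 1L)
  module_tag <- match.arg(module_tag, .module_tags)
  t_prev <- session$started_at
  total <- 0
  for (a in session$answers) {
    gap <- a$answered_at - t_prev
    if (identical(config$questions[[a$question_id]]$module, module_tag)) {
      total <- total + gap
    }
    t_prev <- a$answered_at
  }
  total
}

#' Three-item subjective numeracy score
#'
#' Sum of three items each scored 1-6; the summed range is 3-18, higher
#' scores indicating higher numeracy.
#'
#' @param item1,item2,item3 Integers in `[1, 6]`.
#' @return Integer in `[3, 18]`.
#' @export
sns3_sum <- function(item1, item2, item3) {
  items <- c(item1, item2, item3)
  if (any(!is.numeric(items)) || any(is.na(items)) ||
      any(items < 1) || any(items > 6) || any(items != round(items))) {
    stop("SNS-3 items must be integers in [1, 6]")
  }
  as.integer(sum(items))
}

#' Serialize / deserialize a session as JSON
#'
#' @param session A `lynch_session`.
#' @param path JSON file path.
#' @return `read_session` returns a `lynch_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "lynch_session"))
  jsonlite::write_json(unclass(session), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$answers <- lapply(x$answers, function(a) {
    v <- a$value
    if (is.list(v)) v <- as.character(unlist(v))
    if (is.null(v)) v <- NA_integer_
    list(question_id = a$question_id, value = v,
         answered_at = as.numeric(a$answered_at))
  })
  x$started_at <- as.numeric(x$started_at)
  x$completed <- isTRUE(x$completed)
  structure(x, class = "lynch_session")
}
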