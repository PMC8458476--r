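# Exhaustive path enumeration over the skip-logic graph.
#
# Answer domains are abstracted to branch-relevant classes: yes/no and
# referenced choice values are expanded, while count and age answers
# collapse to the equivalence classes induced by the predicates that read
# them (an unreferenced numeric answer contributes a single class). The
# traversal is memoized dynamic programming over the DAG: the memo key is
# the current question plus the restriction of the abstract answer
# environment to the variables that predicates reachable from that question
# can still read, so structurally independent blocks do not multiply.

.collect_predicates <- function(config) {
  preds <- list()
  for (q in config$questions) {
    for (r in q$rules) {
      if (!is.null(r$when)) preds[[length(preds) + 1L]] <- r$when
    }
  }
  preds
}

.abstract_domains <- function(config) {
  preds <- .collect_predicates(config)
  refs_on <- function(id) Filter(function(p) identical(p$q, id), preds)
  domains <- list()
  for (q in config$questions) {
    p <- refs_on(q$id)
    domains[[q$id]] <- switch(q$kind,
      yes_no = list("yes", "no"),
      single_choice = as.list(q$choices),
      multi_select = {
        vals <- sort(unique(vapply(Filter(function(x) x$op == "contains", p),
                                   function(x) as.character(x$value), character(1))))
        if (length(vals) == 0) {
          list(character(0))
        } else {
          # all subsets of the referenced values
          idx <- expand.grid(rep(list(c(FALSE, TRUE)), length(vals)))
          lapply(seq_len(nrow(idx)), function(i) vals[unlist(idx[i, ])])
        }
      },
      { # count / age: one representative per branch-relevant equivalence
        # class (the partition induced by the predicates that read it)
        vals <- unlist(lapply(p, function(x) as.numeric(x$value)))
        lo <- 0
        hi <- if (q$kind == "age") 120 else .Machine$integer.max
        reps <- sort(unique(pmin(hi, pmax(lo, c(vals, vals - 1, vals + 1)))))
        if (length(reps) == 0) reps <- if (q$kind == "age") 50 else 0
        sig <- vapply(reps, function(v) {
          env <- stats::setNames(list(v), q$id)
          paste(vapply(p, function(pr) .eval_pred(pr, env), logical(1)),
                collapse = "")
        }, character(1))
        as.list(reps[!duplicated(sig)])
      }
    )
  }
  domains
}

.needed_vars <- function(config) {
  qs <- config$questions
  ids <- names(qs)
  refs <- lapply(qs, function(q) {
    unique(vapply(Filter(function(r) !is.null(r$when), q$rules),
                  function(r) r$when$q, character(1)))
  })
  succ <- lapply(qs, function(q) {
    setdiff(unique(vapply(q$rules, function(r) r$goto, character(1))), TERMINAL)
  })
  # need(q) = refs of every question reachable from q (including q itself);
  # fixpoint over the finite acyclic graph
  need <- refs
  repeat {
    changed <- FALSE
    for (id in ids) {
      merged <- unique(c(need[[id]], unlist(need[succ[[id]]])))
      if (length(merged) != length(need[[id]])) {
        need[[id]] <- merged
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  need
}

.abstract_next <- function(config, qid, env) {
  for (r in config$questions[[qid]]$rules) {
    if (is.null(r$when) || .eval_pred(r$when, env)) return(r$goto)
  }
  stop("no rule matched") # unreachable
}

#' Enumerate all complete answer paths of a questionnaire
#'
#' Exhaustively traverses the skip-logic graph over abstracted answer
#' domains (yes/no and referenced choice values expanded; count and age
#' answers collapsed to the classes that skip rules distinguish) and
#' returns the shortest and longest complete paths in number of questions
#' presented, together with the number of distinct abstract terminal paths.
#'
#' @param config A `questionnaire_config` (cyclic configs are rejected at
#'   load).
#' @return List with `min_questions`, `max_questions`, `n_terminal_paths`.
#' @export
enumerate_paths <- function(config) {
  stopifnot(inherits(config, "questionnaire_config"))
  domains <- .abstract_domains(config)
  need <- .needed_vars(config)
  memo <- new.env(parent = emptyenv())
  enc <- function(v) paste(as.character(v), collapse = ",")

  rec <- function(qid, env) {
    if (identical(qid, TERMINAL)) {
      return(list(min = 0L, max = 0L, count = 1))
    }
    keep <- sort(intersect(names(env), need[[qid]]))
    key <- paste0(qid, "|", paste(keep, vapply(env[keep], enc, character(1)),
                                  sep = "=", collapse = ";"))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    mn <- Inf; mx <- -Inf; cnt <- 0
    for (cls in domains[[qid]]) {
      env2 <- env
      env2[[qid]] <- cls
      sub <- rec(.abstract_next(config, qid, env2), env2)
      mn <- min(mn, 1L + sub$min)
      mx <- max(mx, 1L + sub$max)
      cnt <- cnt + sub$count
    }
    res <- list(min = mn, max = mx, count = cnt)
    memo[[key]] <- res
    res
  }

  res <- rec(config$start_id, list())
  list(min_questions = as.integer(res$min), max_questions = as.integer(res$max),
       n_terminal_paths = res$count)
}
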