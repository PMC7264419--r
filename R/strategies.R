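# The catalogue of correct and erroneous Bayesian answer strategies, written
# as executable expressions over the schematic letters of symbol_map():
# lowercase letters are probabilities, uppercase letters absolute counts.
# Conditional questions ask for P(A|B) (the Bayesian posterior); joint
# questions ask for P(A&notB).

.strategy <- function(id, name, type, prob_expr, freq_pair, note = "") {
  structure(list(id = id, name = name, question_type = type,
                 prob_expr = prob_expr, freq_pair = freq_pair, note = note),
            class = "strategy_definition")
}

#' @export
print.strategy_definition <- function(x, ...) {
  fp <- if (is.null(x$freq_pair)) "not applicable" else {
    paste(x$freq_pair[1], "out of", x$freq_pair[2])
  }
  pe <- if (is.null(x$prob_expr)) "not applicable" else x$prob_expr
  cat(sprintf("%s (%s question): probability %s; frequency %s\n",
              x$id, x$question_type, pe, fp))
  invisible(x)
}

#' The built-in strategy catalogue
#'
#' Answer-generating rules for the two question types of a two-event
#' Bayesian reasoning task, covering the correct Bayesian answer and the
#' documented erroneous strategies. Each strategy gives a probability-form
#' prediction (an expression over the [symbol_map()] letters) and, where one
#' exists, a natural-frequency-form prediction ("X out of Y" as a pair of
#' count letters).
#'
#' Conditional-question catalogue (target `P(A|B)`): `correct`
#' (`b*j/(b*j + m*c)`, "F out of D"), `joint_occurrence` (`b*j`, "F out of
#' A"), `fisherian` (the transposed conditional `j`, "F out of B"),
#' `base_rate_only` (`b`), `evidence_only` (`d`), `likelihood_subtraction`
#' (`j - m`, probability only), `pre_bayes` ("B out of D", frequency only),
#' and `pos_rate_over_false_rate` (`j/m`, probability only; note this ratio
#' can exceed 1).
#'
#' Joint-question catalogue (target `P(A&notB)`): `correct` (`b*q`, "H out
#' of A"), the `q_error` and `p_error` (answering with one of the two
#' corresponding conditionals `q` or `p`), the `m_error` and `n_error`
#' (conditionals with misread negations), `independence_error` (`b*e`, the
#' product of the marginals), `double_joint` (`2*h`, computing the joint
#' both ways and adding), and the two double-tree branch confusions
#' (`double_tree_confusion_I` = `l`, `double_tree_confusion_II` = `e*l`),
#' whose formulas are reconstructed from the reported confusion of the
#' crossing branches carrying `p` and `l`.
#'
#' @param question_type `"conditional"`, `"joint"`, or `"all"`.
#' @return a named list of `"strategy_definition"` objects, in catalogue
#'   order (used for tie-breaking in [classify_response()]).
#' @export
builtin_strategies <- function(question_type = c("all", "conditional",
                                                 "joint")) {
  question_type <- match.arg(question_type)
  conditional <- list(
    .strategy("correct", "Correct solution (Bayesian)", "conditional",
              "b*j/(b*j + m*c)", c("F", "D")),
    .strategy("joint_occurrence", "Joint occurrence", "conditional",
              "b*j", c("F", "A")),
    .strategy("fisherian", "Fisherian (transposed conditional)",
              "conditional", "j", c("F", "B")),
    .strategy("base_rate_only", "Base rate only / conservatism",
              "conditional", "b", c("B", "A")),
    .strategy("evidence_only", "Evidence only", "conditional",
              "d", c("D", "A")),
    .strategy("likelihood_subtraction", "Likelihood subtraction",
              "conditional", "j - m", NULL,
              "difference of proportions; no natural-frequency pair"),
    .strategy("pre_bayes", "Pre-Bayes", "conditional", NULL, c("B", "D")),
    .strategy("pos_rate_over_false_rate",
              "Correct positive rate / false positive rate", "conditional",
              "j/m", NULL, "ratio; may exceed 1")
  )
  joint <- list(
    .strategy("correct", "Correct solution (multiplication rule)", "joint",
              "b*q", c("H", "A")),
    .strategy("q_error", "q-error: conditional P(notB|A) instead of joint",
              "joint", "q", c("H", "B")),
    .strategy("p_error", "p-error: conditional P(A|notB) instead of joint",
              "joint", "p", c("H", "E")),
    .strategy("m_error", "m-error: P(B|notA), misread negations", "joint",
              "m", c("G", "C")),
    .strategy("n_error", "n-error: P(notB|notA), misread negations", "joint",
              "n", c("I", "C")),
    .strategy("independence_error",
              "Independence error: product of the marginals", "joint",
              "b*e", NULL),
    .strategy("double_joint",
              "Double joint: both computation routes added", "joint",
              "2*h", NULL),
    .strategy("double_tree_confusion_I",
              "Double-tree confusion I: p-error on the swapped branch",
              "joint", "l", c("G", "D"),
              "reconstructed: the branches carrying p and l were confused"),
    .strategy("double_tree_confusion_II",
              "Double-tree confusion II: multiplication rule with the swapped branch",
              "joint", "e*l", NULL,
              "reconstructed: multiplication rule applied to the wrong branch")
  )
  sets <- list(conditional = conditional, joint = joint)
  pick <- switch(question_type, all = c(conditional, joint),
                 conditional = conditional, joint = joint)
  names(pick) <- vapply(pick, function(s) s$id, character(1))
  pick
}

# letter environments --------------------------------------------------------

# lowercase letters -> rational probabilities of the situation
.prob_letters <- function(situation) {
  map <- symbol_map()$prob
  env <- list()
  for (letter in names(map)) {
    v <- situation$derived[[map[[letter]]]]
    if (!is.null(v)) env[[letter]] <- v
  }
  env
}

# uppercase letters -> counts; rounded-table counts reproduce study stimuli
.freq_letters <- function(situation, N, rounded = TRUE) {
  ft <- to_frequencies(situation, N,
                       policy = if (rounded) "round" else "exact")
  list(A = ft$total, B = ft$n_a, C = ft$n_na, D = ft$n_b, E = ft$n_nb,
       F = ft$n_ab, G = ft$n_na_b, H = ft$n_a_nb, I = ft$n_na_nb)
}

.task_situation <- function(task) {
  if (inherits(task, "task_spec")) return(task$situation)
  if (inherits(task, "completed_situation")) return(task)
  stop("task must be a task_spec or a completed_situation")
}

.task_N <- function(task, N = NULL) {
  if (!is.null(N)) return(N)
  n <- if (inherits(task, "task_spec")) task$N else task$N
  if (is.null(n)) stop("a population size N is required")
  n
}

#' Predict a strategy's answer for a task
#'
#' Evaluates the strategy's expression exactly on the task's completed
#' situation through the letter map: probability format yields an exact
#' rational; frequency format yields the pair of counts "numerator out of
#' denominator" from the task's frequency table (rounded counts, matching
#' the frequency stimuli).
#'
#' @param strategy a `"strategy_definition"` (or its id, looked up in
#'   [builtin_strategies()] for the given question type).
#' @param task a `"task_spec"` or a `"completed_situation"` with `N`.
#' @param format `"probability"` or `"frequency"`.
#' @param question_type needed only when `strategy` is given by id.
#' @return a rational (probability format) or a numeric pair
#'   `c(numerator, denominator)` (frequency format).
#' @examples
#' task <- builtin_tasks()$mammography
#' predicted_answer("fisherian", task, "probability")        # 4/5
#' predicted_answer("joint_occurrence", task, "frequency")   # 160, 10000
#' @export
predicted_answer <- function(strategy, task,
                             format = c("probability", "frequency"),
                             question_type = NULL) {
  format <- match.arg(format)
  if (is.character(strategy)) {
    if (is.null(question_type)) {
      stop("question_type is required when strategy is given by id")
    }
    cat_ <- builtin_strategies(question_type)
    if (!strategy %in% names(cat_)) stop("unknown strategy: ", strategy)
    strategy <- cat_[[strategy]]
  }
  sit <- .task_situation(task)
  if (format == "probability") {
    if (is.null(strategy$prob_expr)) {
      stop("strategy '", strategy$id,
           "' has no probability-form prediction")
    }
    env <- .prob_letters(sit)
    expr <- parse(text = strategy$prob_expr)[[1]]
    vars <- intersect(all.vars(expr), names(symbol_map()$prob))
    missing <- setdiff(vars, names(env))
    if (length(missing)) {
      stop("strategy '", strategy$id, "' needs undefined quantities: ",
           paste(missing, collapse = ", "))
    }
    eval(expr, envir = env)
  } else {
    if (is.null(strategy$freq_pair)) {
      stop("strategy '", strategy$id, "' has no frequency-form prediction")
    }
    env <- .freq_letters(sit, .task_N(task))
    num <- env[[strategy$freq_pair[1]]]
    den <- env[[strategy$freq_pair[2]]]
    c(numerator = as.numeric(num), denominator = as.numeric(den))
  }
}

# coding interval ------------------------------------------------------------

# The study's rounding rule: a probability answer counts as the predicted
# value if it lies within the interval [floor(exact%), ceil(exact%)] on the
# percent scale — "rounded up or down to the next full percentage point" —
# except that the interval is cut, exclusively, at any *other* catalogued
# prediction (rounded to display precision) falling inside it. That
# reproduces the one documented case: the correct mammography joint answer
# 0.4% is accepted up to, but excluding, 0.5% — the displayed p-error.
.coding_interval <- function(pred_pct, other_pcts, display_decimals = 1) {
  lo <- floor(pred_pct)
  hi <- ceiling(pred_pct)
  lo_excl <- -Inf
  hi_excl <- Inf
  for (o in round(other_pcts, display_decimals)) {
    if (o > pred_pct && o <= hi) hi_excl <- min(hi_excl, o)
    if (o < pred_pct && o >= lo) lo_excl <- max(lo_excl, o)
  }
  list(lo = lo, hi = hi, lo_excl = lo_excl, hi_excl = hi_excl)
}

.in_coding_interval <- function(resp_pct, iv, eps = 1e-9) {
  if (resp_pct < iv$lo - eps || resp_pct > iv$hi + eps) return(FALSE)
  if (is.finite(iv$hi_excl) && resp_pct >= iv$hi_excl - eps) return(FALSE)
  if (is.finite(iv$lo_excl) && resp_pct <= iv$lo_excl + eps) return(FALSE)
  TRUE
}

#' Classify a numeric response against the strategy catalogue
#'
#' Matches a participant-style response — a probability, or a pair of
#' absolute frequencies "numerator out of denominator" — against every
#' applicable strategy of the catalogue. A probability response matches a
#' strategy when it is within `tolerance` percentage points of the
#' strategy's prediction, or when it falls in the study-style rounding
#' interval of that prediction (next full percentage point, with exclusive
#' bounds where another catalogued prediction intrudes). A frequency-pair
#' response matches only on exact equality of both counts. All matches are
#' returned, exact matches first, then by distance, with ties broken by
#' catalogue order.
#'
#' @param task a `"task_spec"` or `"completed_situation"` with `N`.
#' @param question_type `"conditional"` or `"joint"`.
#' @param response a single probability (on the 0-1 scale), or a numeric
#'   pair of counts `c(numerator, denominator)`.
#' @param tolerance matching tolerance in percentage points (default 0.5).
#' @return an object of class `"classification"`: a list with `matches` (a
#'   data frame with columns `strategy`, `distance` in percentage points, and
#'   `exact`), `coded_correct` (see [code_correct()]), `unclassified`, and
#'   `malformed` (a frequency pair with numerator > denominator).
#' @examples
#' task <- builtin_tasks()$mammography
#' classify_response(task, "conditional", 0.14)        # correct
#' classify_response(task, "conditional", c(160, 10000))  # joint_occurrence
#' classify_response(task, "joint", 0.005)             # p_error, not correct
#' @export
classify_response <- function(task, question_type = c("conditional", "joint"),
                              response, tolerance = 0.5) {
  question_type <- match.arg(question_type)
  if (tolerance < 0) stop("tolerance must be non-negative")
  strategies <- builtin_strategies(question_type)
  is_pair <- length(response) == 2L
  if (!is.numeric(response) || !length(response) %in% c(1L, 2L)) {
    stop("response must be a single probability or a pair of counts")
  }
  malformed <- FALSE
  rows <- list()
  if (is_pair) {
    if (any(response < 0) || any(response != trunc(response))) {
      stop("frequency responses must be non-negative integers")
    }
    if (response[1] > response[2]) {
      malformed <- TRUE
    } else {
      for (s in strategies) {
        if (is.null(s$freq_pair)) next
        pred <- predicted_answer(s, task, "frequency")
        if (pred[1] == response[1] && pred[2] == response[2]) {
          rows[[length(rows) + 1L]] <- data.frame(
            strategy = s$id, distance = 0, exact = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
  } else {
    if (response < 0) stop("probability response must be non-negative")
    resp_pct <- response * 100
    preds <- vapply(strategies, function(s) {
      if (is.null(s$prob_expr)) NA_real_
      else as.numeric(predicted_answer(s, task, "probability")) * 100
    }, numeric(1))
    for (i in seq_along(strategies)) {
      if (is.na(preds[i])) next
      dist <- abs(resp_pct - preds[i])
      iv <- .coding_interval(preds[i], preds[-i][!is.na(preds[-i])])
      if (dist <= tolerance + 1e-12 || .in_coding_interval(resp_pct, iv)) {
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strategies[[i]]$id, distance = dist,
          exact = dist < 1e-9, stringsAsFactors = FALSE)
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(strategy = character(0), distance = numeric(0),
               exact = logical(0), stringsAsFactors = FALSE)
  }
  if (nrow(matches) > 0L) {
    matches <- matches[order(!matches$exact, matches$distance), ,
                       drop = FALSE]
    rownames(matches) <- NULL
  }
  coded <- !malformed && code_correct(task, question_type, response)
  structure(list(matches = matches, coded_correct = coded,
                 unclassified = nrow(matches) == 0L, malformed = malformed,
                 question_type = question_type, response = response,
                 tolerance = tolerance),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  resp <- if (length(x$response) == 2L) {
    paste(x$response[1], "out of", x$response[2])
  } else .fmt_pct(x$response, 2)
  cat("response", resp, "to the", x$question_type, "question\n")
  if (x$malformed) cat("malformed: numerator exceeds denominator\n")
  if (x$unclassified) {
    cat("unclassified (no strategy within",
        x$tolerance, "percentage points)\n")
  } else {
    print(x$matches)
  }
  cat("coded correct:", x$coded_correct, "\n")
  invisible(x)
}

#' Study-style correctness coding
#'
#' Frequency format: correct iff both counts equal the natural-frequency
#' answer exactly. Probability format: correct iff the response equals the
#' exact value, or lies in the rounding interval to the next full percentage
#' point — with an exclusive bound where another catalogued prediction falls
#' inside the interval (for the mammography joint question: answers in
#' \[0.4%, 0.5%) are correct, 0.5% itself is not, being an expected wrong
#' solution).
#'
#' @inheritParams classify_response
#' @return `TRUE` or `FALSE`.
#' @examples
#' task <- builtin_tasks()$mammography
#' code_correct(task, "conditional", c(160, 1140))  # TRUE
#' code_correct(task, "joint", 0.0045)              # TRUE
#' code_correct(task, "joint", 0.005)               # FALSE
#' @export
code_correct <- function(task, question_type = c("conditional", "joint"),
                         response) {
  question_type <- match.arg(question_type)
  strategies <- builtin_strategies(question_type)
  if (length(response) == 2L) {
    pred <- predicted_answer(strategies[["correct"]], task, "frequency")
    return(pred[1] == response[1] && pred[2] == response[2])
  }
  resp_pct <- response * 100
  exact_pct <- as.numeric(
    predicted_answer(strategies[["correct"]], task, "probability")) * 100
  if (abs(resp_pct - exact_pct) < 1e-9) return(TRUE)
  others <- vapply(strategies[names(strategies) != "correct"], function(s) {
    if (is.null(s$prob_expr)) NA_real_
    else as.numeric(predicted_answer(s, task, "probability")) * 100
  }, numeric(1))
  iv <- .coding_interval(exact_pct, others[!is.na(others)])
  .in_coding_interval(resp_pct, iv)
}

#' Audit near-collisions between strategy predictions
#'
#' Computes the pairwise distances (in percentage points) between all
#' probability-form strategy predictions for a task, and reports every pair
#' closer than `tolerance` — pairs a probability response cannot reliably
#' separate. For the mammography joint question this includes the boundary
#' collision between the correct answer (0.4%) and the p-error (~0.45%).
#'
#' @inheritParams classify_response
#' @return data frame with columns `strategy_1`, `strategy_2`,
#'   `prediction_1`, `prediction_2` (percent), and `distance`.
#' @export
strategy_collisions <- function(task,
                                question_type = c("conditional", "joint"),
                                tolerance = 0.5) {
  question_type <- match.arg(question_type)
  strategies <- builtin_strategies(question_type)
  preds <- vapply(strategies, function(s) {
    if (is.null(s$prob_expr)) NA_real_
    else as.numeric(predicted_answer(s, task, "probability")) * 100
  }, numeric(1))
  ids <- names(preds)[!is.na(preds)]
  preds <- preds[!is.na(preds)]
  out <- list()
  if (length(preds) >= 2L) {
    for (i in 1:(length(preds) - 1L)) {
      for (j in (i + 1L):length(preds)) {
        d <- abs(preds[i] - preds[j])
        if (d < tolerance) {
          out[[length(out) + 1L]] <- data.frame(
            strategy_1 = ids[i], strategy_2 = ids[j],
            prediction_1 = preds[[i]], prediction_2 = preds[[j]],
            distance = d, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(strategy_1 = character(0), strategy_2 = character(0),
               prediction_1 = numeric(0), prediction_2 = numeric(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  }
}

#' Classify a table of responses
#'
#' Batch interface over [classify_response()] for response tables with
#' columns `task_id`, `question_type`, `format` (`"probability"` or
#' `"frequency"`), `response_numerator` and `response_denominator` (blank /
#' `NA` for probability responses, where `response_numerator` holds the
#' probability on the 0-1 scale). Appends `matched_strategy` (the first
#' match, `NA` when unclassified), `distance` and `coded_correct`.
#'
#' @param responses a data frame (or path to a CSV file) with the columns
#'   above.
#' @param tasks named list of tasks; defaults to [builtin_tasks()].
#' @param tolerance percentage-point tolerance for probability matching.
#' @param out optional path; when given, the classified table is also
#'   written there as CSV.
#' @return the classified data frame, invisibly when `out` is given.
#' @export
classify_responses <- function(responses, tasks = builtin_tasks(),
                               tolerance = 0.5, out = NULL) {
  if (is.character(responses)) {
    responses <- utils::read.csv(responses, stringsAsFactors = FALSE)
  }
  need <- c("task_id", "question_type", "format", "response_numerator")
  if (!all(need %in% names(responses))) {
    stop("response table needs columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(responses)
  matched <- character(n)
  distance <- numeric(n)
  coded <- logical(n)
  for (i in seq_len(n)) {
    task <- tasks[[responses$task_id[i]]]
    if (is.null(task)) stop("unknown task id: ", responses$task_id[i])
    den <- if ("response_denominator" %in% names(responses)) {
      responses$response_denominator[i]
    } else NA
    resp <- if (!is.na(den) && nzchar(as.character(den))) {
      c(responses$response_numerator[i], as.numeric(den))
    } else {
      responses$response_numerator[i]
    }
    cl <- classify_response(task, responses$question_type[i], resp,
                            tolerance = tolerance)
    matched[i] <- if (cl$unclassified) NA_character_ else
      cl$matches$strategy[1]
    distance[i] <- if (cl$unclassified) NA_real_ else cl$matches$distance[1]
    coded[i] <- cl$coded_correct
  }
  responses$matched_strategy <- matched
  responses$distance <- distance
  responses$coded_correct <- coded
  if (!is.null(out)) {
    utils::write.csv(responses, out, row.names = FALSE)
    return(invisible(responses))
  }
  responses
}
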