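# The task bank: parameterized problem contexts with cover story, statistics
# templates and the two questions (conditional first, then joint), plus the
# generator for the balanced 4 (visualization) x 2 (format) x 2 (context)
# design.

#' Question specification
#'
#' @param target the asked-for quantity: a conditional (e.g. `"P(A|B)"`) or a
#'   joint (e.g. `"P(A&notB)"`).
#' @param event_order which event category is named first in the question
#'   wording — metadata for studying order effects on the p-/q-error; it does
#'   not change predictions.
#' @return an object of class `"question_spec"`.
#' @export
question_spec <- function(target, event_order = c("A", "B")) {
  target <- parse_quantity(target)
  kind <- quantity_kind(target)
  if (!kind %in% c("conditional", "joint")) {
    stop("question target must be a conditional or joint quantity")
  }
  structure(list(target = target, type = kind, event_order = event_order),
            class = "question_spec")
}

#' Task specification
#'
#' A problem context: event labels, the three Bayesian parameters (base
#' rate, P(B|A), P(B|not A)), a population size, text templates, and the two
#' questions. The parameters must form a determining set — construction
#' solves them and fails otherwise. The frequency-stimulus counts come from
#' the rounded frequency table (so the economics stimulus reproduces its
#' rounded 205 out of 320 even though the exact count is 204.8; the
#' `rounding_note` flag records the mismatch).
#'
#' @param id short identifier.
#' @param events an [event_pair()].
#' @param params named list of the given probabilities.
#' @param N population size for the frequency version.
#' @param cover_story introduction text.
#' @param templates named list of text templates (see [builtin_tasks()] for
#'   the slots used).
#' @param questions list with elements `conditional` and `joint`, each a
#'   [question_spec()].
#' @return an object of class `"task_spec"` carrying the solved
#'   `"completed_situation"` and the rounded frequency table.
#' @export
task_spec <- function(id, events, params, N, cover_story, templates,
                      questions) {
  res <- solve_situation(params, events = events, N = N)
  if (res$status != "complete") {
    stop("task parameters do not determine the situation (status: ",
         res$status, ")")
  }
  sit <- res$situation
  ft <- to_frequencies(sit, N, policy = "round")
  structure(list(id = id, events = events, params = params, N = N,
                 cover_story = cover_story, templates = templates,
                 questions = questions, situation = sit,
                 freq_table = ft, rounding_note = !ft$exact_counts),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat("task:", x$id, "\n")
  print(x$events)
  cat("parameters:",
      paste(names(x$params), "=", unlist(lapply(x$params, .fmt_pct)),
            collapse = ", "), "; N =", .fmt_count(x$N), "\n")
  if (x$rounding_note) {
    cat("note: frequency stimulus uses rounded counts\n")
  }
  invisible(x)
}

#' The built-in task bank
#'
#' Two classic Bayesian reasoning contexts:
#' \describe{
#'   \item{mammography}{breast-cancer screening; base rate 2%, sensitivity
#'     80%, false-positive rate 10%, N = 10,000. All expected counts are
#'     integral.}
#'   \item{economics}{course choice and career orientation; base rate 32%,
#'     P(career-oriented | attends) = 64%, P(career-oriented | does not
#'     attend) = 60%, N = 1,000. The frequency stimulus uses the rounded
#'     count 205 (exact 204.8), so its conditional answer 205 out of 613
#'     differs slightly from the probability-version 64%.}
#' }
#' Each task asks the conditional question first (target `P(A|B)`) and the
#' joint question second (target `P(A&notB)`), as in the study design.
#'
#' @return named list of two `"task_spec"` objects.
#' @examples
#' tasks <- builtin_tasks()
#' situation_value(tasks$mammography$situation, "P(A|B)")  # 8/57
#' @export
builtin_tasks <- function() {
  mammography <- task_spec(
    id = "mammography",
    events = event_pair("breast cancer", "positive test result",
                        "no breast cancer", "negative test result"),
    params = c("P(A)" = 0.02, "P(B|A)" = 0.8, "P(B|notA)" = 0.1),
    N = 10000,
    cover_story = paste(
      "You are preparing a magazine article on breast-cancer screening and",
      "want to explain what a positive mammography result really means.",
      "A physician provides the following information about women of a",
      "particular age group who participate in routine screening:"),
    templates = list(
      prob = c(
        "The probability of breast cancer is {p_a} for a woman who participates in routine screening.",
        "If a woman who participates in routine screening has breast cancer, the probability is {p_b_a} that she will have a positive test result.",
        "If a woman who participates in routine screening does not have breast cancer, the probability is {p_b_na} that she will have a positive test result."),
      freq = c(
        "{n_a} out of {n} women who participate in routine screening have breast cancer.",
        "Out of {n_a} women who participate in routine screening and have breast cancer, {n_ab} will have a positive result.",
        "Out of {n_na} women who participate in routine screening and have no breast cancer, {n_na_b} will also have a positive result."),
      q_conditional_prob = "What is the probability that a woman who participates in routine screening and receives a positive test result has breast cancer?",
      q_conditional_freq = "How many of the women who participate in routine screening and receive a positive test result have breast cancer?",
      q_joint_prob = "What is the probability that a woman who participates in routine screening receives a negative test result and has breast cancer?",
      q_joint_freq = "How many of the women who participate in routine screening receive a negative test result and have breast cancer?"),
    questions = list(
      conditional = question_spec("P(A|B)", event_order = c("B", "A")),
      joint = question_spec("P(A&notB)", event_order = c("notB", "A")))
  )
  economics <- task_spec(
    id = "economics",
    events = event_pair("attends the economics course", "career-oriented",
                        "does not attend the economics course",
                        "not career-oriented"),
    params = c("P(A)" = 0.32, "P(B|A)" = 0.64, "P(B|notA)" = 0.6),
    N = 1000,
    cover_story = paste(
      "You wonder whether career-oriented students are more likely to take",
      "an economics course. The school psychological service has evaluated",
      "the relation between personality characteristics and course choice",
      "and reports the following information:"),
    templates = list(
      prob = c(
        "The probability that a student attends the economics course is {p_a}.",
        "If a student attends the economics course, the probability that he is career-oriented is {p_b_a}.",
        "If a student does not attend the economics course, the probability that he is still career-oriented is {p_b_na}."),
      freq = c(
        "{n_a} out of {n} students attend the economics course.",
        "Out of {n_a} students who attend the economics course, {n_ab} are career-oriented.",
        "Out of {n_na} students who do not attend the economics course, {n_na_b} are still career-oriented."),
      q_conditional_prob = "What is the probability that a student attends the economics course if he is career-oriented?",
      q_conditional_freq = "How many of the students who are career-oriented attend the economics course?",
      q_joint_prob = "What is the probability that a student attends the economics course and is not career-oriented?",
      q_joint_freq = "How many of the students are not career-oriented and attend the economics course?"),
    questions = list(
      conditional = question_spec("P(A|B)", event_order = c("A", "B")),
      joint = question_spec("P(A&notB)", event_order = c("A", "notB")))
  )
  list(mammography = mammography, economics = economics)
}

# fill {slot} placeholders from the task's parameters and rounded counts
.fill_template <- function(tpl, task) {
  sit <- task$situation
  ft <- task$freq_table
  cnt <- function(r) .fmt_count(r)
  subs <- c(
    p_a = .fmt_pct(situation_value(sit, "P(A)")),
    p_b_a = .fmt_pct(situation_value(sit, "P(B|A)")),
    p_b_na = .fmt_pct(situation_value(sit, "P(B|notA)")),
    n = cnt(ft$total), n_a = cnt(ft$n_a), n_na = cnt(ft$n_na),
    n_b = cnt(ft$n_b), n_nb = cnt(ft$n_nb),
    n_ab = cnt(ft$n_ab), n_a_nb = cnt(ft$n_a_nb),
    n_na_b = cnt(ft$n_na_b), n_na_nb = cnt(ft$n_na_nb))
  for (k in names(subs)) {
    tpl <- gsub(paste0("{", k, "}"), subs[[k]], tpl, fixed = TRUE)
  }
  tpl
}

.VISUALIZATIONS <- c("text_only", "two_by_two", "double_tree", "net")
.FORMATS <- c("probabilities", "frequencies")

#' Render a problem document
#'
#' Assembles one of the 16 problem versions of the design: a cover story,
#' either the three-sentence Bayesian statistics text (text_only) or an
#' embedded diagram in the matching mode — visualization versions do not
#' repeat the statistics sentences — and the two questions with the
#' format's answer blanks (`"_______"` for probabilities, `"____ out of
#' ____"` for frequency pairs).
#'
#' The frequency versions of the diagrams are built from the rounded
#' frequency table, so the displayed counts are the stimulus counts.
#'
#' @param task a `"task_spec"`.
#' @param format `"probabilities"` or `"frequencies"`.
#' @param visualization `"text_only"`, `"two_by_two"`, `"double_tree"`, or
#'   `"net"`.
#' @param question_order `"conditional_first"` (the study's fixed order) or
#'   `"joint_first"`.
#' @return an object of class `"problem_document"`: a list with
#'   `cover_story`, `statistics` (character sentences, text_only) or `graph`
#'   (a `"diagram_graph"`), and `questions` (each with `text` and `blank`).
#' @examples
#' doc <- render_problem(builtin_tasks()$mammography, "frequencies",
#'                       "text_only")
#' @export
render_problem <- function(task,
                           format = c("probabilities", "frequencies"),
                           visualization = c("text_only", "two_by_two",
                                             "double_tree", "net"),
                           question_order = c("conditional_first",
                                              "joint_first")) {
  format <- match.arg(format)
  visualization <- match.arg(visualization)
  question_order <- match.arg(question_order)
  stats <- NULL
  graph <- NULL
  if (visualization == "text_only") {
    tpl <- if (format == "probabilities") task$templates$prob else
      task$templates$freq
    stats <- .fill_template(tpl, task)
  } else {
    mode <- if (format == "probabilities") "prob" else "freq"
    # frequency diagrams display the (rounded) stimulus counts
    sit <- if (mode == "freq") from_frequencies(task$freq_table) else
      task$situation
    graph <- switch(visualization,
      two_by_two = build_two_by_two(sit, task$N, mode),
      double_tree = build_double_tree(sit, task$N, mode),
      net = build_net(sit, task$N, mode))
  }
  q_text <- function(type) {
    key <- paste0("q_", type, "_",
                  if (format == "probabilities") "prob" else "freq")
    task$templates[[key]]
  }
  blank <- if (format == "probabilities") "_______" else "____ out of ____"
  order <- if (question_order == "conditional_first") {
    c("conditional", "joint")
  } else c("joint", "conditional")
  questions <- lapply(order, function(type) {
    list(type = type, text = q_text(type), blank = blank,
         spec = task$questions[[type]])
  })
  structure(list(task_id = task$id, format = format,
                 visualization = visualization, cover_story = task$cover_story,
                 statistics = stats, graph = graph, questions = questions),
            class = "problem_document")
}

#' @export
print.problem_document <- function(x, ...) {
  cat(x$cover_story, "\n\n")
  if (!is.null(x$statistics)) {
    cat(x$statistics, sep = "\n")
  } else {
    cat(render_text(x$graph), sep = "\n")
  }
  for (q in x$questions) {
    cat("\n", q$text, "\n Answer: ", q$blank, "\n", sep = "")
  }
  invisible(x)
}

#' @rdname render_problem
#' @param document a `"problem_document"`.
#' @return `problem_text()` returns the document as a character vector of
#'   lines.
#' @export
problem_text <- function(document) {
  utils::capture.output(print(document))
}

#' Enumerate versions and assign balanced booklets
#'
#' Enumerates the 16 problem versions (2 contexts x 2 information formats x
#' 4 visualizations) and builds the set of two-problem booklets satisfying
#' the design constraints: each booklet contains both contexts, one with
#' probabilities and the other with frequencies, and two different
#' visualizations. The booklet order is shuffled deterministically by
#' `seed`.
#'
#' @param tasks named list of (at least two) `"task_spec"` objects.
#' @param seed integer seed for the deterministic shuffle.
#' @return a list with `versions` (16-row data frame: context, format,
#'   visualization) and `booklets` (data frame with one row per booklet:
#'   `booklet`, and context/format/visualization for each of the two
#'   problems).
#' @export
design_matrix <- function(tasks = builtin_tasks(), seed = 1) {
  if (length(tasks) < 2L) stop("at least two tasks are required")
  ids <- vapply(tasks, function(t) t$id, character(1))[1:2]
  versions <- expand.grid(context = ids, format = .FORMATS,
                          visualization = .VISUALIZATIONS,
                          stringsAsFactors = FALSE)
  versions <- versions[order(versions$context, versions$format,
                             versions$visualization), ]
  rownames(versions) <- NULL
  rows <- list()
  for (first_ctx in 1:2) {
    ctx1 <- ids[first_ctx]
    ctx2 <- ids[3 - first_ctx]
    for (fmt1 in .FORMATS) {
      fmt2 <- setdiff(.FORMATS, fmt1)
      for (v1 in .VISUALIZATIONS) {
        for (v2 in setdiff(.VISUALIZATIONS, v1)) {
          rows[[length(rows) + 1L]] <- data.frame(
            context_1 = ctx1, format_1 = fmt1, visualization_1 = v1,
            context_2 = ctx2, format_2 = fmt2, visualization_2 = v2,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  booklets <- do.call(rbind, rows)
  perm <- .seeded_permutation(nrow(booklets), seed)
  booklets <- booklets[perm, , drop = FALSE]
  booklets <- cbind(booklet = seq_len(nrow(booklets)), booklets)
  rownames(booklets) <- NULL
  list(versions = versions, booklets = booklets)
}

# deterministic permutation without touching the caller's RNG stream
.seeded_permutation <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(n)
}
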