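#' Frequency table of a situation
#'
#' Converts a completed situation into the nine absolute frequencies of its
#' frequency displays: the population total, the four margins and the four
#' cells. Counts are expected counts `N * probability`.
#'
#' Policies:
#' \describe{
#'   \item{`exact`}{counts stay exact rationals (possibly non-integral).}
#'   \item{`round`}{each cell is rounded half-up to an integer, then margins
#'     and the total are recomputed by additivity from the rounded cells, so
#'     the table's additivity invariants always hold (as in the economics
#'     frequency stimulus, where 204.8 becomes 205).}
#'   \item{`require_integer`}{errors, naming the offending quantity, unless
#'     every count is integral.}
#' }
#'
#' @param situation a `"completed_situation"`.
#' @param N positive integer population size (default: the situation's).
#' @param policy one of `"exact"`, `"round"`, `"require_integer"`.
#' @return an object of class `"frequency_table"`: a list of nine rational
#'   counts (`total`, `n_a`, `n_na`, `n_b`, `n_nb`, `n_ab`, `n_a_nb`,
#'   `n_na_b`, `n_na_nb`), the event pair, and the flag `exact_counts`
#'   (`TRUE` when every `N * probability` was integral before any rounding).
#' @examples
#' sit <- complete_situation(cell_distribution(0.016, 0.004, 0.098, 0.882))
#' to_frequencies(sit, N = 10000)        # cells 160, 40, 980, 8820
#' @export
to_frequencies <- function(situation, N = situation$N,
                           policy = c("exact", "round", "require_integer")) {
  policy <- match.arg(policy)
  if (is.null(N)) stop("a population size N is required")
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != trunc(N)) {
    stop("N must be a positive integer")
  }
  Nr <- rational(N)
  cellq <- .CELLS
  cells <- lapply(cellq, function(q) Nr * situation$derived[[q]])
  names(cells) <- cellq
  integral <- vapply(cells, function(x) rat_is_integer(x), logical(1))
  exact_counts <- all(integral)

  if (policy == "require_integer" && !exact_counts) {
    stop("count for ", cellq[which(!integral)[1L]],
         " is not integral at N = ", N)
  }
  if (policy == "round") {
    cells <- lapply(cells, rat_round_half_up)
  }
  n_ab <- cells[["P(A&B)"]]; n_a_nb <- cells[["P(A&notB)"]]
  n_na_b <- cells[["P(notA&B)"]]; n_na_nb <- cells[["P(notA&notB)"]]
  total <- if (policy == "round") {
    n_ab + n_a_nb + n_na_b + n_na_nb
  } else Nr
  structure(list(
    total = total,
    n_a = n_ab + n_a_nb, n_na = n_na_b + n_na_nb,
    n_b = n_ab + n_na_b, n_nb = n_a_nb + n_na_nb,
    n_ab = n_ab, n_a_nb = n_a_nb, n_na_b = n_na_b, n_na_nb = n_na_nb,
    events = situation$events, exact_counts = exact_counts
  ), class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  fmt <- function(r) {
    if (rat_is_integer(r)) .fmt_count(as.numeric(r)) else format(r)
  }
  cat("frequency table (total ", fmt(x$total), ")\n", sep = "")
  cat(sprintf("  %-12s %s / %s\n", "A margin:", fmt(x$n_a), fmt(x$n_na)))
  cat(sprintf("  %-12s %s / %s\n", "B margin:", fmt(x$n_b), fmt(x$n_nb)))
  cat(sprintf("  cells: %s, %s, %s, %s\n", fmt(x$n_ab), fmt(x$n_a_nb),
              fmt(x$n_na_b), fmt(x$n_na_nb)))
  if (!x$exact_counts) cat("  (counts involve rounding)\n")
  invisible(x)
}

#' Situation from a frequency table
#'
#' The inverse of [to_frequencies()] with the `exact` policy: cells become
#' `count / total` and the total becomes the situation's population size.
#' Additivity of the table is validated first; a violated margin is named.
#'
#' @param table a `"frequency_table"`, or a named list/vector with the nine
#'   counts (`total`, `n_a`, `n_na`, `n_b`, `n_nb`, `n_ab`, `n_a_nb`,
#'   `n_na_b`, `n_na_nb`).
#' @param events an [event_pair()]; defaults to the table's, if present.
#' @return a `"completed_situation"` with `N` set to the table total.
#' @export
from_frequencies <- function(table, events = NULL) {
  need <- c("total", "n_a", "n_na", "n_b", "n_nb",
            "n_ab", "n_a_nb", "n_na_b", "n_na_nb")
  if (!all(need %in% names(table))) {
    stop("frequency table needs entries: ", paste(need, collapse = ", "))
  }
  v <- lapply(need, function(k) as_rational(table[[k]]))
  names(v) <- need
  if (any(vapply(v, function(r) r$num < 0, logical(1)))) {
    stop("counts must be non-negative")
  }
  checks <- list(
    c("n_a", "n_ab", "n_a_nb"), c("n_na", "n_na_b", "n_na_nb"),
    c("n_b", "n_ab", "n_na_b"), c("n_nb", "n_a_nb", "n_na_nb")
  )
  for (ch in checks) {
    if (!(v[[ch[1]]] == v[[ch[2]]] + v[[ch[3]]])) {
      stop("additivity violated for margin ", ch[1], ": ",
           format(v[[ch[1]]]), " != ", format(v[[ch[2]]]), " + ",
           format(v[[ch[3]]]))
    }
  }
  if (!(v$total == v$n_a + v$n_na)) {
    stop("additivity violated: margins of the first event do not sum to the total")
  }
  if (!(v$total == v$n_b + v$n_nb)) {
    stop("additivity violated: margins of the second event do not sum to the total")
  }
  if (v$total$num == 0) stop("total count must be positive")
  if (is.null(events)) {
    events <- if (!is.null(table$events)) table$events else event_pair()
  }
  N <- if (rat_is_integer(v$total)) as.numeric(v$total) else NULL
  complete_situation(
    cell_distribution(v$n_ab / v$total, v$n_a_nb / v$total,
                      v$n_na_b / v$total, v$n_na_nb / v$total),
    events = events, N = N)
}

#' Natural-frequency form of a quantity
#'
#' Expresses a probability as a natural frequency, a pair of counts
#' "numerator out of denominator" over nested reference sets of one
#' population: for a conditional P(X|Y) the pair is
#' (N * P(X & Y), N * P(Y)); for a joint or marginal it is (N * value, N).
#'
#' @param situation a `"completed_situation"`.
#' @param N positive integer population size (default: the situation's).
#' @param q quantity string; must not be `TOTAL`, and for a conditional the
#'   conditioning event must have positive probability.
#' @return a list of class `"natural_frequency"` with `numerator`,
#'   `denominator` (rational counts) and `reference_set` (a description of
#'   the denominator's reference set in words).
#' @examples
#' sit <- complete_situation(cell_distribution(0.016, 0.004, 0.098, 0.882),
#'                           event_pair("breast cancer", "positive test"))
#' natural_frequency(sit, 10000, "P(A|B)")   # 160 out of 1,140
#' @export
natural_frequency <- function(situation, N = situation$N, q) {
  if (is.null(N)) stop("a population size N is required")
  q <- parse_quantity(q)
  if (q == "TOTAL") stop("TOTAL has no natural-frequency form")
  Nr <- rational(N)
  ev <- situation$events
  kind <- quantity_kind(q)
  if (kind == "conditional") {
    parts <- .quantity_parts(q)
    marg <- situation$derived[[paste0("P(", parts$given, ")")]]
    if (marg == rational(0)) {
      stop(q, " is undefined: the conditioning event '",
           event_label(ev, parts$given), "' has probability 0")
    }
    joint <- situation$derived[[.joint_of(parts$target, parts$given)]]
    ref <- sprintf("those with %s", event_label(ev, parts$given))
    structure(list(numerator = Nr * joint, denominator = Nr * marg,
                   reference_set = ref, quantity = q),
              class = "natural_frequency")
  } else {
    val <- situation$derived[[q]]
    ref <- sprintf("the whole population of %s", .fmt_count(N))
    structure(list(numerator = Nr * val, denominator = Nr,
                   reference_set = ref, quantity = q),
              class = "natural_frequency")
  }
}

#' @export
print.natural_frequency <- function(x, ...) {
  fmt <- function(r) {
    if (rat_is_integer(r)) .fmt_count(as.numeric(r)) else format(r)
  }
  cat(fmt(x$numerator), "out of", fmt(x$denominator),
      paste0("(", x$quantity, "; reference set: ", x$reference_set, ")\n"))
  invisible(x)
}
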