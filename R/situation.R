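#' Event pair
#'
#' The two dichotomous events of a situation, with display labels for both
#' categories of each. The first event plays the role of A (for a diagnostic
#' test: the condition, e.g. "breast cancer"), the second the role of B (the
#' evidence, e.g. "positive test result").
#'
#' @param first,second labels of the two events.
#' @param first_negation,second_negation labels of the complementary
#'   categories; default `"no <label>"`.
#' @return an object of class `"event_pair"`.
#' @examples
#' event_pair("breast cancer", "positive test result")
#' @export
event_pair <- function(first = "A", second = "B",
                       first_negation = paste("no", first),
                       second_negation = paste("no", second)) {
  labels <- c(first, second, first_negation, second_negation)
  if (!is.character(labels) || any(!nzchar(labels))) {
    stop("event labels must be non-empty strings")
  }
  if (anyDuplicated(labels)) stop("event labels must be pairwise distinct")
  structure(list(first = first, second = second,
                 first_negation = first_negation,
                 second_negation = second_negation),
            class = "event_pair")
}

#' @export
print.event_pair <- function(x, ...) {
  cat("event pair: A =", x$first, "/", x$first_negation,
      "; B =", x$second, "/", x$second_negation, "\n")
  invisible(x)
}

# label of one event category ("A", "notA", "B", "notB")
event_label <- function(events, category) {
  switch(category,
    "A" = events$first, "notA" = events$first_negation,
    "B" = events$second, "notB" = events$second_negation,
    stop("unknown category: ", category))
}

#' Cell distribution
#'
#' The four joint-cell probabilities P(A&B), P(A&notB), P(notA&B),
#' P(notA&notB) — the canonical internal state of a situation. Cells must be
#' exact rationals (or exact decimals) in [0, 1] summing to exactly 1, which
#' is the X-rule of the net.
#'
#' @param p_ab,p_a_nb,p_na_b,p_na_nb the four cell probabilities, each a
#'   number, fraction string, or rational.
#' @return a `"cell_distribution"`: a named rational vector of length 4 in
#'   the order (A&B, A&notB, notA&B, notA&notB).
#' @examples
#' cell_distribution(0.016, 0.004, 0.098, 0.882)  # the mammography cells
#' @export
cell_distribution <- function(p_ab, p_a_nb, p_na_b, p_na_nb) {
  cells <- c(as_rational(p_ab), as_rational(p_a_nb),
             as_rational(p_na_b), as_rational(p_na_nb))
  if (!rat_in_unit(cells)) stop("cell probabilities must lie in [0, 1]")
  if (!(sum(cells) == rational(1))) {
    stop("cell probabilities must sum to exactly 1 (X-rule)")
  }
  structure(cells, class = c("cell_distribution", "rational"),
            cell_names = .CELLS)
}

#' @export
print.cell_distribution <- function(x, ...) {
  cat("cell distribution:",
      paste(.CELLS, "=", format.rational(x), collapse = ", "), "\n")
  invisible(x)
}

#' Complete a situation from its four cells
#'
#' Derives all sixteen probabilities of the two-event situation from the four
#' joint cells, exactly. Conditionals whose conditioning event has probability
#' zero are undefined and stored as `NULL`; they propagate as unlabeled
#' branches in diagrams and as errors in [natural_frequency()]. By
#' construction the result satisfies the four net rules (line, triangle, V, X)
#' at tolerance zero.
#'
#' @param cells a [cell_distribution()] (or anything coercible: a numeric
#'   vector of length 4).
#' @param events an [event_pair()].
#' @param N optional population size the situation refers to.
#' @return an object of class `"completed_situation"` with components
#'   `events`, `cells`, `N` and `derived` (named list mapping each of the 16
#'   probability quantities to a rational, or `NULL` when undefined).
#' @examples
#' sit <- complete_situation(cell_distribution(0.016, 0.004, 0.098, 0.882),
#'                           event_pair("breast cancer", "positive test"),
#'                           N = 10000)
#' situation_value(sit, "P(A|B)")   # the positive predictive value, 8/57
#' @export
complete_situation <- function(cells, events = event_pair(), N = NULL) {
  if (!inherits(cells, "cell_distribution")) {
    if (is.numeric(cells) && length(cells) == 4L) {
      cells <- cell_distribution(cells[1], cells[2], cells[3], cells[4])
    } else if (is_rational(cells) && length(cells) == 4L) {
      cells <- cell_distribution(cells[1], cells[2], cells[3], cells[4])
    } else stop("cells must be a cell_distribution or a length-4 vector")
  }
  if (!is.null(N)) {
    if (!is.numeric(N) || length(N) != 1L || N < 1 || N != trunc(N)) {
      stop("N must be a positive integer")
    }
    N <- as.numeric(N)
  }
  derived <- .derive_quantities(cells)
  structure(list(events = events, cells = cells, N = N, derived = derived),
            class = "completed_situation")
}

.derive_quantities <- function(cells) {
  f <- cells[1]; h <- cells[2]; g <- cells[3]; i <- cells[4]
  d <- list(
    "P(A&B)" = f, "P(A&notB)" = h, "P(notA&B)" = g, "P(notA&notB)" = i,
    "P(A)" = f + h, "P(notA)" = g + i, "P(B)" = f + g, "P(notB)" = h + i
  )
  cond <- function(joint, marg) {
    if (marg == rational(0)) NULL else joint / marg
  }
  d[["P(A|B)"]]        <- cond(f, d[["P(B)"]])
  d[["P(notA|B)"]]     <- cond(g, d[["P(B)"]])
  d[["P(A|notB)"]]     <- cond(h, d[["P(notB)"]])
  d[["P(notA|notB)"]]  <- cond(i, d[["P(notB)"]])
  d[["P(B|A)"]]        <- cond(f, d[["P(A)"]])
  d[["P(notB|A)"]]     <- cond(h, d[["P(A)"]])
  d[["P(B|notA)"]]     <- cond(g, d[["P(notA)"]])
  d[["P(notB|notA)"]]  <- cond(i, d[["P(notA)"]])
  d[setdiff(quantity_ids(), "TOTAL")]
}

#' Look up a derived quantity
#'
#' @param situation a `"completed_situation"`.
#' @param q a quantity string (any spelling accepted by [parse_quantity()]).
#' @param as how to return the value: exact rational, numeric, or `NA` for
#'   undefined conditionals.
#' @return the exact rational value (default), a numeric, or `NULL`/`NA` when
#'   the conditional is undefined.
#' @export
situation_value <- function(situation, q, as = c("rational", "numeric")) {
  as <- match.arg(as)
  q <- parse_quantity(q)
  if (q == "TOTAL") {
    if (is.null(situation$N)) stop("situation has no population size")
    return(if (as == "numeric") situation$N else rational(situation$N))
  }
  v <- situation$derived[[q]]
  if (is.null(v)) return(if (as == "numeric") NA_real_ else NULL)
  if (as == "numeric") as.numeric(v) else v
}

#' @export
print.completed_situation <- function(x, ...) {
  cat("completed two-event situation\n")
  print(x$events)
  if (!is.null(x$N)) cat("population size N =", .fmt_count(x$N), "\n")
  df <- as.data.frame(x)
  cat(paste0("  ", format(df$quantity, width = 14), " ",
             format(df$exact, width = 10), " ",
             df$percent, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.data.frame.completed_situation <- function(x, ...) {
  qs <- setdiff(quantity_ids(), "TOTAL")
  exact <- vapply(qs, function(q) {
    v <- x$derived[[q]]
    if (is.null(v)) "undefined" else format(v)
  }, character(1))
  num <- vapply(qs, function(q) {
    v <- x$derived[[q]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  data.frame(quantity = qs, exact = exact, value = num,
             percent = ifelse(is.na(num), "undefined",
                              paste0(.fmt_pct_num(num * 100, 2), "%")),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# net rules

# every instantiable rule instance of the net:
#   line:     two complement sums over marginals
#   triangle: marginal * conditional = joint (8 instances)
#   V:        two adjoining joints sum to the enclosed marginal (4 instances)
#   X:        the four joints sum to 1
.rule_instances <- function() {
  tri <- list(
    c("P(A)", "P(B|A)", "P(A&B)"),       c("P(A)", "P(notB|A)", "P(A&notB)"),
    c("P(notA)", "P(B|notA)", "P(notA&B)"),
    c("P(notA)", "P(notB|notA)", "P(notA&notB)"),
    c("P(B)", "P(A|B)", "P(A&B)"),       c("P(B)", "P(notA|B)", "P(notA&B)"),
    c("P(notB)", "P(A|notB)", "P(A&notB)"),
    c("P(notB)", "P(notA|notB)", "P(notA&notB)")
  )
  v <- list(
    c("P(A&B)", "P(A&notB)", "P(A)"),    c("P(notA&B)", "P(notA&notB)", "P(notA)"),
    c("P(A&B)", "P(notA&B)", "P(B)"),    c("P(A&notB)", "P(notA&notB)", "P(notB)")
  )
  line <- list(c("P(A)", "P(notA)"), c("P(B)", "P(notB)"))
  list(line = line, triangle = tri, v = v, x = list(.CELLS))
}

#' Check an assignment against the four net rules
#'
#' Evaluates every rule instance of the frequency net that is instantiable
#' from the supplied (possibly partial) assignment of probabilities:
#' the line rule (complements sum to 1), the triangle rule (marginal times
#' conditional equals joint — the multiplication rule), the V-rule (adjoining
#' joints sum to the enclosed marginal — the addition rule), and the X-rule
#' (the four joints sum to 1). Residuals are computed exactly; a violation is
#' reported when the residual exceeds `tolerance`.
#'
#' @param assignment a named list or vector mapping quantity strings to
#'   values in [0, 1] (numbers, fraction strings, or rationals).
#' @param tolerance non-negative absolute tolerance; `0` demands exactness.
#' @return a data frame with columns `rule`, `quantities` (the participating
#'   quantities, "+"-collapsed), and `residual`; zero rows means the
#'   assignment is consistent at the given tolerance.
#' @examples
#' check_net_rules(c("P(A)" = 0.3, "P(notA)" = 0.7))            # consistent
#' check_net_rules(c("P(A)" = 0.3, "P(notA)" = 0.6))            # line-rule hit
#' @export
check_net_rules <- function(assignment, tolerance = 0) {
  vals <- .parse_assignment(assignment)
  tol <- as_rational(tolerance)
  if (tol < rational(0)) stop("tolerance must be non-negative")
  rules <- .rule_instances()
  out <- list()
  add <- function(rule, qs, resid) {
    out[[length(out) + 1L]] <<- data.frame(
      rule = rule, quantities = paste(qs, collapse = " + "),
      residual = as.numeric(resid), stringsAsFactors = FALSE)
  }
  has <- function(qs) all(qs %in% names(vals))
  for (qs in rules$line) if (has(qs)) {
    r <- abs(vals[[qs[1]]] + vals[[qs[2]]] - rational(1))
    if (r > tol) add("line", qs, r)
  }
  for (qs in rules$triangle) if (has(qs)) {
    r <- abs(vals[[qs[1]]] * vals[[qs[2]]] - vals[[qs[3]]])
    if (r > tol) add("triangle", qs, r)
  }
  for (qs in rules$v) if (has(qs)) {
    r <- abs(vals[[qs[1]]] + vals[[qs[2]]] - vals[[qs[3]]])
    if (r > tol) add("v", qs, r)
  }
  qs <- rules$x[[1]]
  if (has(qs)) {
    r <- abs(sum(rat_c_list(vals[qs])) - rational(1))
    if (r > tol) add("x", qs, r)
  }
  if (length(out) == 0L) {
    return(data.frame(rule = character(0), quantities = character(0),
                      residual = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# named values -> named list of rationals with canonical quantity names
.parse_assignment <- function(assignment) {
  if (length(assignment) == 0L) return(list())
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("assignment must be fully named by quantity strings")
  }
  vals <- list()
  for (i in seq_along(assignment)) {
    q <- parse_quantity(names(assignment)[i])
    v <- as_rational(assignment[[i]])
    if (!rat_in_unit(v)) stop("value for ", q, " outside [0, 1]")
    if (q %in% names(vals)) stop("duplicate entry for ", q)
    vals[[q]] <- v
  }
  vals
}

#' Extract the derived assignment of a completed situation
#'
#' All defined quantities of the situation as a named list of exact
#' rationals, suitable for [check_net_rules()].
#'
#' @param situation a `"completed_situation"`.
#' @return named list of rationals.
#' @export
situation_assignment <- function(situation) {
  d <- situation$derived
  d[!vapply(d, is.null, logical(1))]
}
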