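#' The seventeen quantity identifiers
#'
#' A situation with two dichotomous events A and B carries sixteen
#' probabilities — four marginals, four joints and eight conditionals — plus
#' the population total. Quantities are named by a canonical string syntax:
#' `"P(A)"`, `"P(notA)"`, `"P(A&B)"`, `"P(A|notB)"`, and `"TOTAL"` for the
#' population size. The letters A and B are positional aliases that are bound
#' to concrete event labels by an [event_pair()].
#'
#' @return character vector of the 17 canonical quantity identifiers.
#' @examples
#' quantity_ids()
#' quantity_kind("P(A|B)")
#' @export
quantity_ids <- function() {
  c("TOTAL",
    "P(A)", "P(notA)", "P(B)", "P(notB)",
    "P(A&B)", "P(A&notB)", "P(notA&B)", "P(notA&notB)",
    "P(A|B)", "P(notA|B)", "P(A|notB)", "P(notA|notB)",
    "P(B|A)", "P(notB|A)", "P(B|notA)", "P(notB|notA)")
}

# internal cell order used by every linear-algebra routine:
# (A&B, A&notB, notA&B, notA&notB)
.CELLS <- c("P(A&B)", "P(A&notB)", "P(notA&B)", "P(notA&notB)")
.MARGINALS <- c("P(A)", "P(notA)", "P(B)", "P(notB)")
.CONDITIONALS <- c("P(A|B)", "P(notA|B)", "P(A|notB)", "P(notA|notB)",
                   "P(B|A)", "P(notB|A)", "P(B|notA)", "P(notB|notA)")

#' Parse a quantity string to canonical form
#'
#' Accepts the canonical syntax with optional whitespace and a few common
#' spellings of negation and conjunction (`!A`, `~A`, `not A`, `A ∩ B`,
#' `A and B`, `¬A`).
#'
#' @param s a single quantity string.
#' @return the canonical identifier (an element of [quantity_ids()]).
#' @export
parse_quantity <- function(s) {
  if (!is.character(s) || length(s) != 1L) stop("quantity must be one string")
  raw <- s
  s <- gsub("[[:space:]]", "", s)
  if (toupper(s) %in% c("TOTAL", "N")) return("TOTAL")
  s <- gsub("∩|&&|and", "&", s)          # intersections
  s <- gsub("¬|~", "!", s)               # negations to a case-stable marker
  s <- gsub("not", "!", s, ignore.case = TRUE)
  s <- toupper(s)
  s <- gsub("!", "not", s, fixed = TRUE)
  if (!s %in% quantity_ids()) {
    stop("unrecognized quantity: '", raw, "'")
  }
  s
}

#' @rdname parse_quantity
#' @param q a canonical quantity identifier.
#' @return `quantity_kind()` returns one of `"total"`, `"marginal"`,
#'   `"joint"`, `"conditional"`.
#' @export
quantity_kind <- function(q) {
  if (q == "TOTAL") return("total")
  if (q %in% .MARGINALS) return("marginal")
  if (q %in% .CELLS) return("joint")
  if (q %in% .CONDITIONALS) return("conditional")
  stop("unrecognized quantity: ", q)
}

# split "P(X|Y)" -> list(target = "X", given = "Y"); "P(X&Y)" -> components
.quantity_parts <- function(q) {
  inner <- sub("^P\\((.*)\\)$", "\\1", q)
  if (grepl("|", inner, fixed = TRUE)) {
    p <- strsplit(inner, "|", fixed = TRUE)[[1L]]
    list(kind = "conditional", target = p[1L], given = p[2L])
  } else if (grepl("&", inner, fixed = TRUE)) {
    p <- strsplit(inner, "&", fixed = TRUE)[[1L]]
    list(kind = "joint", a_side = p[1L], b_side = p[2L])
  } else {
    list(kind = "marginal", target = inner)
  }
}

# events ("A", "notA", "B", "notB") -> indicator over the four cells
.event_cells <- function(ev) {
  switch(ev,
    "A"    = c(1, 1, 0, 0),
    "notA" = c(0, 0, 1, 1),
    "B"    = c(1, 0, 1, 0),
    "notB" = c(0, 1, 0, 1),
    stop("unknown event category: ", ev)
  )
}

# quantity -> 0/1 coefficient vector over the four cells (for marginals and
# joints); conditionals need the value and are handled in the solver
.quantity_cells <- function(q) {
  kind <- quantity_kind(q)
  if (kind == "marginal") return(.event_cells(.quantity_parts(q)$target))
  if (kind == "joint") return(as.numeric(.CELLS == q))
  stop("no fixed cell coefficients for ", q)
}

#' The schematic letter map
#'
#' The didactics literature labels the quantities of the two-event situation
#' with schematic letters: lowercase letters for probabilities and uppercase
#' letters for the corresponding absolute frequencies. This mapping is what
#' the strategy catalogue's formulas (for example the correct Bayesian answer
#' `b*j / (b*j + m*c)`, or the frequency answer "F out of D") are written in.
#'
#' Letters e, h, i and uppercase E, H, I are not all printed in the source
#' figure; they are inferred from the usage of "F out of D" vs "I out of E"
#' style frequency expressions and from the placement of the remaining
#' letters, completing the scheme symmetrically.
#'
#' @return a list with components `prob` (lowercase letter to probability
#'   quantity) and `freq` (uppercase letter to the quantity whose absolute
#'   frequency the letter denotes; `"A"` is the population total).
#' @examples
#' symbol_map()$prob[["k"]]   # the Bayesian posterior P(A|B)
#' symbol_map()$freq[["D"]]   # count of the second event
#' @export
symbol_map <- function() {
  list(
    prob = c(
      b = "P(A)",    c = "P(notA)", d = "P(B)",    e = "P(notB)",
      f = "P(A&B)",  g = "P(notA&B)", h = "P(A&notB)", i = "P(notA&notB)",
      j = "P(B|A)",  k = "P(A|B)",  l = "P(notA|B)", m = "P(B|notA)",
      n = "P(notB|notA)", p = "P(A|notB)", q = "P(notB|A)"
    ),
    freq = c(
      A = "TOTAL",
      B = "P(A)",   C = "P(notA)", D = "P(B)",   E = "P(notB)",
      F = "P(A&B)", G = "P(notA&B)", H = "P(A&notB)", I = "P(notA&notB)"
    )
  )
}
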