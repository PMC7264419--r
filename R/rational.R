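#' @title Exact rational numbers
#'
#' @description
#' A small exact rational type used throughout the package. All probabilities
#' that enter or leave the completion machinery are held as reduced fractions
#' of integer-valued doubles, so that the net rules (line, triangle, V, X) can
#' be checked at tolerance zero and quantities such as 8/57 or 2/443 survive
#' unchanged. Decimals supplied at the API boundary are converted by exact
#' decimal-to-fraction parsing, never by floating approximation.
#'
#' Numerators and denominators are stored as doubles but kept integral and
#' guarded against leaving the exactly-representable integer range (2^53);
#' probabilities and desk-scale counts never come close to that bound.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), non-zero. Recycled against `num`.
#' @return `rational()` returns an object of class `"rational"`, a vector of
#'   exact fractions supporting arithmetic (`+`, `-`, `*`, `/`), comparison,
#'   `sum()`, `abs()`, `as.numeric()` and `format()`.
#' @examples
#' rational(8, 57) + rational(49, 57)
#' as_rational(0.02) * as_rational("4/5")
#' as.numeric(as_rational("14.03%"))
#' @export
rational <- function(num, den = 1) {
  if (length(num) == 0L) {
    return(structure(list(num = numeric(0), den = numeric(0)),
                     class = "rational"))
  }
  n <- max(length(num), length(den))
  num <- rep_len(as.numeric(num), n)
  den <- rep_len(as.numeric(den), n)
  if (any(den == 0)) stop("rational: zero denominator")
  if (any(num != trunc(num)) || any(den != trunc(den))) {
    stop("rational: numerator and denominator must be integer-valued")
  }
  .rat_guard(num)
  .rat_guard(den)
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  g <- .rat_gcd(num, den)
  structure(list(num = num / g, den = den / g), class = "rational")
}

.RAT_MAX <- 2^53

.rat_guard <- function(x) {
  if (any(abs(x) >= .RAT_MAX)) {
    stop("rational: integer overflow beyond exactly representable range")
  }
  invisible(x)
}

# vectorized Euclid; gcd(0, 0) mapped to 1 so 0/1 stays reduced
.rat_gcd <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(abs(a), n)
  b <- rep_len(abs(b), n)
  while (any(b != 0)) {
    r <- ifelse(b != 0, a %% b, 0)
    a <- ifelse(b != 0, b, a)
    b <- r
  }
  ifelse(a == 0, 1, a)
}

#' Coerce to an exact rational
#'
#' Numeric input is accepted only when it is exactly a finite decimal (at most
#' 15 decimal digits), and is parsed exactly: `0.02` becomes 1/50. Character
#' input may be a fraction `"8/57"`, a decimal `"0.25"`, or a percentage
#' `"14.03%"`. Anything that is not an exact decimal (such as `1/3` computed
#' in floating point) is rejected rather than silently approximated.
#'
#' @param x a rational, numeric vector, or character vector.
#' @return a `"rational"` vector.
#' @export
as_rational <- function(x) {
  if (is_rational(x)) return(x)
  if (is.character(x)) {
    parsed <- lapply(x, .rat_parse_chr)
    return(rat_c_list(parsed))
  }
  if (is.numeric(x)) {
    parsed <- lapply(x, .rat_from_decimal)
    return(rat_c_list(parsed))
  }
  stop("cannot coerce object of class '", class(x)[1L], "' to rational")
}

.rat_from_decimal <- function(x) {
  if (!is.finite(x)) stop("rational: non-finite value")
  if (x == trunc(x)) return(rational(x, 1))
  for (k in 1:15) {
    scaled <- x * 10^k
    n <- round(scaled)
    if (abs(n) < .RAT_MAX && n / 10^k == x) {
      return(rational(n, 10^k))
    }
  }
  stop("value ", format(x, digits = 17),
       " is not an exact decimal; supply it as a fraction string like \"1/3\"")
}

.rat_parse_chr <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  pct <- grepl("%$", s)
  if (pct) s <- sub("%$", "", s)
  r <- if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed fraction string: ", s)
    rational(.chr_int(parts[1L]), .chr_int(parts[2L]))
  } else {
    .rat_from_decimal(.chr_num(s))
  }
  if (pct) r <- r / rational(100) else r
}

.chr_int <- function(s) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) || v != trunc(v)) stop("not an integer: ", s)
  v
}

.chr_num <- function(s) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("not a number: ", s)
  v
}

#' @rdname as_rational
#' @export
is_rational <- function(x) inherits(x, "rational")

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) rational(x$num[i], x$den[i])

#' @export
`[<-.rational` <- function(x, i, value) {
  value <- as_rational(value)
  num <- x$num
  den <- x$den
  num[i] <- value$num
  den[i] <- value$den
  rational(num, den)
}

#' @export
c.rational <- function(...) rat_c_list(lapply(list(...), as_rational))

rat_c_list <- function(xs) {
  rational(unlist(lapply(xs, function(r) r$num)),
           unlist(lapply(xs, function(r) r$den)))
}

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(rational(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rationals")
  }
  e1 <- as_rational(e1)
  e2 <- as_rational(e2)
  switch(.Generic,
    "+" = {
      .rat_guard(e1$num * e2$den)
      .rat_guard(e2$num * e1$den)
      rational(e1$num * e2$den + e2$num * e1$den, e1$den * e2$den)
    },
    "-" = {
      .rat_guard(e1$num * e2$den)
      .rat_guard(e2$num * e1$den)
      rational(e1$num * e2$den - e2$num * e1$den, e1$den * e2$den)
    },
    "*" = {
      # cross-reduce before multiplying to keep magnitudes small
      g1 <- .rat_gcd(e1$num, e2$den)
      g2 <- .rat_gcd(e2$num, e1$den)
      rational((e1$num / g1) * (e2$num / g2), (e1$den / g2) * (e2$den / g1))
    },
    "/" = {
      if (any(e2$num == 0)) stop("rational: division by zero")
      g1 <- .rat_gcd(e1$num, e2$num)
      g2 <- .rat_gcd(e2$den, e1$den)
      rational((e1$num / g1) * (e2$den / g2), (e1$den / g2) * (e2$num / g1))
    },
    "==" = e1$num * e2$den == e2$num * e1$den,
    "!=" = e1$num * e2$den != e2$num * e1$den,
    "<"  = e1$num * e2$den <  e2$num * e1$den,
    "<=" = e1$num * e2$den <= e2$num * e1$den,
    ">"  = e1$num * e2$den >  e2$num * e1$den,
    ">=" = e1$num * e2$den >= e2$num * e1$den,
    stop("operation ", .Generic, " not defined for rationals")
  )
}

#' @export
sum.rational <- function(..., na.rm = FALSE) {
  x <- rat_c_list(lapply(list(...), as_rational))
  acc <- rational(0)
  for (i in seq_len(length(x))) acc <- acc + x[i]
  acc
}

#' @export
abs.rational <- function(x) rational(abs(x$num), x$den)

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
format.rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
print.rational <- function(x, ...) {
  cat(format(x), sep = " ")
  cat("\n")
  invisible(x)
}

#' @export
as.character.rational <- function(x, ...) format(x)

# floor(num/den), exact (R's %/% on doubles has floor semantics)
rat_floor <- function(x) rational(x$num %/% x$den, 1)

# round half up: floor(x + 1/2), the schoolbook rounding used for counts
rat_round_half_up <- function(x) rat_floor(x + rational(1, 2))

rat_is_integer <- function(x) x$den == 1

# does every element lie in [0, 1]?
rat_in_unit <- function(x) all(x$num >= 0 & x$num <= x$den)
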