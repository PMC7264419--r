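# Exact completion of a partially specified situation.
#
# Every given quantity is a linear equation over the four cell unknowns
# x = (P(A&B), P(A&notB), P(notA&B), P(notA&notB)):
#   marginal = sum of its two cells, joint = one cell, and a conditional
#   P(X|Y) = v contributes  x[X&Y] - v * sum(Y cells) = 0.
# Together with the normalization sum(x) = 1 and non-negativity this is a
# small exact linear-feasibility problem, solved by rational Gauss-Jordan
# elimination plus basic-solution enumeration for the underdetermined case.

# rows: list of rational vectors of length 5 (4 coefficients + rhs).
# Returns reduced rows, pivot columns (within 1..4), and a flag for a pivot
# in the rhs column (an inconsistent system).
.rref <- function(rows) {
  nvar <- 4L
  pivots <- integer(0)
  r <- 1L
  for (col in seq_len(nvar + 1L)) {
    if (r > length(rows)) break
    piv <- NULL
    for (k in r:length(rows)) {
      if (rows[[k]]$num[col] != 0) { piv <- k; break }
    }
    if (is.null(piv)) next
    tmp <- rows[[r]]; rows[[r]] <- rows[[piv]]; rows[[piv]] <- tmp
    rows[[r]] <- rows[[r]] / rows[[r]][col]
    for (k in seq_along(rows)) {
      if (k != r && rows[[k]]$num[col] != 0) {
        rows[[k]] <- rows[[k]] - rows[[r]] * rows[[k]][col]
      }
    }
    if (col <= nvar) pivots <- c(pivots, col) else {
      return(list(rows = rows, pivots = pivots, contradiction = TRUE))
    }
    r <- r + 1L
  }
  list(rows = rows[seq_len(length(pivots))], pivots = pivots,
       contradiction = FALSE)
}

# value of the linear functional coef . x if it is determined by the reduced
# system; NULL when it varies over the solution space
.determined_value <- function(rref, coef, rhs = rational(0)) {
  coef <- as_rational(coef)
  val <- rhs
  for (i in seq_along(rref$pivots)) {
    p <- rref$pivots[i]
    if (coef$num[p] != 0) {
      w <- coef[p]
      row <- rref$rows[[i]]
      val <- val + w * row[5]
      coef <- rat_c_list(lapply(1:4, function(j) coef[j] - w * row[j]))
    }
  }
  if (any(coef$num != 0)) NULL else val
}

#' Solve a partially specified situation
#'
#' Completes a two-event situation exactly from any subset of the sixteen
#' probabilities and/or absolute frequencies. Each given value becomes a
#' linear constraint on the four joint cells; the system (together with
#' normalization and non-negativity) is solved in exact rational arithmetic.
#'
#' The result's `status` is `"complete"` when the constraints determine a
#' unique distribution on the probability simplex, `"underdetermined"` when a
#' feasible solution space of dimension >= 1 remains (the number of free
#' degrees of freedom is reported), and `"inconsistent"` when no distribution
#' satisfies the constraints (the conflicting net rules / cell bounds are
#' reported). A conditional given on an event whose probability the system
#' forces to zero is reported inconsistent.
#'
#' @param given named list or vector mapping quantity strings to probability
#'   values in \[0, 1\] (numbers, fraction strings like `"8/57"`, or
#'   rationals).
#' @param events an [event_pair()].
#' @param frequencies optional named list of absolute counts (interpreted as
#'   count / `N`); requires `N`.
#' @param N optional positive integer population size.
#' @return an object of class `"solve_result"`: a list with `status` and
#'   either `situation` (a `"completed_situation"`, when complete) or
#'   `diagnostics` (free degrees of freedom, or conflict messages plus a
#'   rule-violation data frame).
#' @examples
#' solve_situation(c("P(A)" = 0.02, "P(B|A)" = 0.8, "P(B|notA)" = 0.1),
#'                 events = event_pair("breast cancer", "positive test"))
#' solve_situation(c("P(A)" = 0.3))              # underdetermined, 2 dof
#' solve_situation(c("P(A)" = 0.4, "P(A&B)" = 0.5))  # inconsistent
#' @export
solve_situation <- function(given = list(), events = event_pair(),
                            frequencies = NULL, N = NULL) {
  vals <- .parse_assignment(given)
  if ("TOTAL" %in% names(vals)) stop("TOTAL cannot be given as a probability")
  if (!is.null(frequencies)) {
    if (is.null(N)) stop("frequencies require a population size N")
    for (i in seq_along(frequencies)) {
      q <- parse_quantity(names(frequencies)[i])
      cnt <- frequencies[[i]]
      if (!is.numeric(cnt) || cnt != trunc(cnt) || cnt < 0 || cnt > N) {
        stop("count for ", q, " must be an integer in [0, N]")
      }
      if (q %in% names(vals)) stop("duplicate entry for ", q)
      vals[[q]] <- rational(cnt, N)
    }
  }

  rows <- list(rat_c_list(list(rational(1), rational(1), rational(1),
                               rational(1), rational(1))))  # normalization
  conditionals <- list()
  for (q in names(vals)) {
    v <- vals[[q]]
    kind <- quantity_kind(q)
    if (kind %in% c("marginal", "joint")) {
      coef <- as_rational(.quantity_cells(q))
      rows[[length(rows) + 1L]] <- c(coef, v)
    } else {
      parts <- .quantity_parts(q)
      tcoef <- as_rational(as.numeric(.CELLS == .joint_of(parts$target,
                                                          parts$given)))
      gcoef <- as_rational(.event_cells(parts$given))
      coef <- rat_c_list(lapply(1:4, function(j) tcoef[j] - v * gcoef[j]))
      rows[[length(rows) + 1L]] <- c(coef, rational(0))
      conditionals[[length(conditionals) + 1L]] <-
        list(q = q, given = parts$given)
    }
  }

  red <- .rref(rows)
  if (red$contradiction) {
    return(.solve_inconsistent(vals,
      "the given quantities are mutually contradictory (no exact solution)"))
  }
  dof <- 4L - length(red$pivots)

  if (dof == 0L) {
    x <- rat_c_list(lapply(1:4, function(j) {
      i <- match(j, red$pivots)
      red$rows[[i]][5]
    }))
    bad <- which(!(x$num >= 0 & x$num <= x$den))
    if (length(bad) > 0L) {
      msgs <- sprintf("derived cell %s = %s violates the [0, 1] bound",
                      .CELLS[bad], format(x[bad]))
      return(.solve_inconsistent(vals, msgs))
    }
    # a conditional conditioning on a zero-probability event is inconsistent
    for (cd in conditionals) {
      marg <- sum(rat_c_list(lapply(which(.event_cells(cd$given) == 1),
                                    function(j) x[j])))
      if (marg == rational(0)) {
        return(.solve_inconsistent(vals, sprintf(
          "%s was given but the system implies P(%s) = 0",
          cd$q, cd$given)))
      }
    }
    sit <- complete_situation(
      cell_distribution(x[1], x[2], x[3], x[4]), events, N)
    return(structure(list(status = "complete", situation = sit,
                          diagnostics = NULL), class = "solve_result"))
  }

  # underdetermined rank: is the remaining solution space feasible at all?
  if (!.feasible(red, rows)) {
    return(.solve_inconsistent(vals, paste(
      "the constraints admit no probability distribution",
      "(solution space misses the simplex)")))
  }
  for (cd in conditionals) {
    marg <- .determined_value(red, .event_cells(cd$given))
    if (!is.null(marg) && marg == rational(0)) {
      return(.solve_inconsistent(vals, sprintf(
        "%s was given but the system implies P(%s) = 0", cd$q, cd$given)))
    }
  }
  structure(list(status = "underdetermined", situation = NULL,
                 diagnostics = list(free_dof = dof)),
            class = "solve_result")
}

.joint_of <- function(x, y) {
  # canonical joint id for categories x (target) and y (given)
  a_side <- intersect(c(x, y), c("A", "notA"))
  b_side <- intersect(c(x, y), c("B", "notB"))
  if (length(a_side) != 1L || length(b_side) != 1L) {
    stop("conditional must involve one category of each event")
  }
  paste0("P(", a_side, "&", b_side, ")")
}

.solve_inconsistent <- function(vals, msgs) {
  viol <- check_net_rules(vals, tolerance = 0)
  structure(list(status = "inconsistent", situation = NULL,
                 diagnostics = list(messages = msgs, violations = viol)),
            class = "solve_result")
}

# Exact feasibility of the (bounded) solution polytope {Ax = b, 0 <= x <= 1}:
# if it is non-empty it has a vertex, and every vertex fixes at least
# (4 - rank) coordinates at a bound. Enumerate all such fixings.
.feasible <- function(red, rows) {
  dof <- 4L - length(red$pivots)
  for (k in dof:3L) {
    subsets <- utils::combn(4L, k, simplify = FALSE)
    for (S in subsets) {
      for (mask in 0:(2^k - 1L)) {
        bounds <- as.numeric(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
        x <- .solve_fixed(red, S, bounds)
        if (!is.null(x) && .satisfies_all(rows, x)) return(TRUE)
      }
    }
  }
  FALSE
}

# solve the reduced system with variables S fixed at the given 0/1 bounds;
# NULL unless the remaining system has a unique in-bounds solution
.solve_fixed <- function(red, S, bounds) {
  free <- setdiff(1:4, S)
  sub <- list()
  for (row in red$rows) {
    rhs <- row[5]
    for (i in seq_along(S)) rhs <- rhs - row[S[i]] * rational(bounds[i])
    sub[[length(sub) + 1L]] <- c(rat_c_list(lapply(free, function(j) row[j])),
                                 rhs)
  }
  # eliminate over the free variables only
  piv <- integer(0)
  r <- 1L
  nfree <- length(free)
  for (col in seq_len(nfree)) {
    if (r > length(sub)) break
    hit <- NULL
    for (kk in r:length(sub)) if (sub[[kk]]$num[col] != 0) { hit <- kk; break }
    if (is.null(hit)) next
    tmp <- sub[[r]]; sub[[r]] <- sub[[hit]]; sub[[hit]] <- tmp
    sub[[r]] <- sub[[r]] / sub[[r]][col]
    for (kk in seq_along(sub)) {
      if (kk != r && sub[[kk]]$num[col] != 0) {
        sub[[kk]] <- sub[[kk]] - sub[[r]] * sub[[kk]][col]
      }
    }
    piv <- c(piv, col)
    r <- r + 1L
  }
  for (kk in seq_along(sub)) {  # contradiction rows
    lead <- sub[[kk]]$num[seq_len(nfree)]
    if (all(lead == 0) && sub[[kk]]$num[nfree + 1L] != 0) return(NULL)
  }
  if (length(piv) < nfree) return(NULL)  # still underdetermined: not a vertex
  x <- rep(list(rational(0)), 4L)
  for (i in seq_along(S)) x[[S[i]]] <- rational(bounds[i])
  for (i in seq_along(piv)) x[[free[piv[i]]]] <- sub[[i]][nfree + 1L]
  rat_c_list(x)
}

.satisfies_all <- function(rows, x) {
  if (!rat_in_unit(x)) return(FALSE)
  for (row in rows) {
    lhs <- sum(rat_c_list(lapply(1:4, function(j) row[j] * x[j])))
    if (!(lhs == row[5])) return(FALSE)
  }
  TRUE
}

#' @export
print.solve_result <- function(x, ...) {
  cat("solve status:", x$status, "\n")
  if (x$status == "complete") {
    print(x$situation)
  } else if (x$status == "underdetermined") {
    cat("free degrees of freedom:", x$diagnostics$free_dof, "\n")
  } else {
    for (m in x$diagnostics$messages) cat("conflict:", m, "\n")
    if (nrow(x$diagnostics$violations) > 0L) {
      cat("net-rule violations among the given quantities:\n")
      print(x$diagnostics$violations)
    }
  }
  invisible(x)
}
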