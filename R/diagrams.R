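# Builders for the four visualizations. Each returns a "diagram_graph": an
# explicit node/edge structure with roles, grid positions and dual
# (probability / frequency) labels, which render_text() and render_svg()
# turn into artifacts. Label values are carried exactly (numerator /
# denominator columns) alongside their formatted strings, so structural
# tests can compare labels against derived quantities without rounding.

.diagram_modes <- c("prob", "freq", "both")

.check_mode_N <- function(mode, N, situation) {
  mode <- match.arg(mode, .diagram_modes)
  if (mode %in% c("freq", "both")) {
    N <- if (!is.null(N)) N else situation$N
    if (is.null(N)) {
      stop("mode '", mode, "' requires a population size N")
    }
  }
  list(mode = mode, N = N)
}

# node row: probability value attached where the node represents a quantity
.node <- function(id, role, x, y, name, value = NULL, N = NULL,
                  mode = "prob", show_prob = FALSE, decimals = 1) {
  has_val <- !is.null(value)
  count <- if (has_val && !is.null(N)) rational(N) * value else NULL
  data.frame(
    id = id, role = role, x = x, y = y, name = name,
    value_num = if (has_val) value$num else NA_real_,
    value_den = if (has_val) value$den else NA_real_,
    label_freq = if (!is.null(count) && mode %in% c("freq", "both")) {
      .fmt_count(count)
    } else NA_character_,
    label_prob = if (has_val && show_prob && mode %in% c("prob", "both")) {
      .fmt_pct(value, decimals)
    } else NA_character_,
    stringsAsFactors = FALSE)
}

.edge <- function(id, from, to, role, style, quantity, value,
                  mode = "prob", decimals = 1,
                  quantity2 = NA_character_, value2 = NULL,
                  crossing = FALSE) {
  labelled <- mode %in% c("prob", "both")
  lab <- if (labelled && !is.null(value)) {
    paste0(quantity, " = ", .fmt_pct(value, decimals))
  } else NA_character_
  lab2 <- if (labelled && !is.null(value2)) {
    paste0(quantity2, " = ", .fmt_pct(value2, decimals))
  } else NA_character_
  data.frame(
    id = id, from = from, to = to, role = role, style = style,
    quantity = quantity,
    value_num = if (!is.null(value)) value$num else NA_real_,
    value_den = if (!is.null(value)) value$den else NA_real_,
    label = lab,
    quantity2 = quantity2,
    value2_num = if (!is.null(value2)) value2$num else NA_real_,
    value2_den = if (!is.null(value2)) value2$den else NA_real_,
    label2 = lab2,
    crossing = crossing, stringsAsFactors = FALSE)
}

.graph <- function(kind, mode, situation, N, nodes, edges, decimals,
                   layout_options = list()) {
  structure(list(kind = kind, mode = mode, events = situation$events,
                 N = N, decimals = decimals,
                 nodes = do.call(rbind, nodes),
                 edges = if (length(edges)) do.call(rbind, edges) else NULL,
                 layout_options = layout_options),
            class = "diagram_graph")
}

#' @export
print.diagram_graph <- function(x, ...) {
  cat(render_text(x), sep = "\n")
  invisible(x)
}

.sval <- function(situation, q) situation$derived[[q]]

#' Build a frequency-net diagram
#'
#' The net has nine nodes — a central total node, four margin nodes on the
#' axes and four cell nodes on the diagonals — and sixteen branches: the four
#' marginals run horizontally/vertically from the center, the four joints
#' run diagonally (dashed) from the center to the corner cells, and the
#' eight conditionals sit on the border between margin and cell nodes. No
#' branches cross and no node is doubled. In `freq` and `both` modes the
#' nodes carry absolute counts; in `prob` and `both` modes the branches carry
#' probabilities. Undefined conditionals give unlabeled branches.
#'
#' @param situation a `"completed_situation"`.
#' @param N population size; required for modes `"freq"` and `"both"`
#'   (defaults to the situation's).
#' @param mode `"prob"`, `"freq"`, or `"both"`.
#' @param decimals decimal places for percentage labels (trailing zeros are
#'   trimmed).
#' @return a `"diagram_graph"` with `kind = "net"`.
#' @examples
#' sit <- complete_situation(cell_distribution(0.016, 0.004, 0.098, 0.882),
#'                           N = 10000)
#' net <- build_net(sit, mode = "both")
#' @export
build_net <- function(situation, N = NULL, mode = "prob", decimals = 1) {
  mn <- .check_mode_N(mode, N, situation)
  mode <- mn$mode; N <- mn$N
  s <- situation
  ev <- s$events
  one <- rational(1)
  nodes <- list(
    .node("center", "center", 0, 0, "total", one, N, mode, FALSE, decimals),
    .node("margin_A", "margin", -2, 0, event_label(ev, "A"),
          .sval(s, "P(A)"), N, mode, FALSE, decimals),
    .node("margin_notA", "margin", 2, 0, event_label(ev, "notA"),
          .sval(s, "P(notA)"), N, mode, FALSE, decimals),
    .node("margin_B", "margin", 0, 2, event_label(ev, "B"),
          .sval(s, "P(B)"), N, mode, FALSE, decimals),
    .node("margin_notB", "margin", 0, -2, event_label(ev, "notB"),
          .sval(s, "P(notB)"), N, mode, FALSE, decimals),
    .node("cell_AB", "cell", -2, 2, "A&B", .sval(s, "P(A&B)"),
          N, mode, FALSE, decimals),
    .node("cell_notAB", "cell", 2, 2, "notA&B", .sval(s, "P(notA&B)"),
          N, mode, FALSE, decimals),
    .node("cell_AnotB", "cell", -2, -2, "A&notB", .sval(s, "P(A&notB)"),
          N, mode, FALSE, decimals),
    .node("cell_notAnotB", "cell", 2, -2, "notA&notB",
          .sval(s, "P(notA&notB)"), N, mode, FALSE, decimals)
  )
  marg <- function(id, to, q) {
    .edge(id, "center", to, "marginal", "solid", q, .sval(s, q),
          mode, decimals)
  }
  joint <- function(id, to, q) {
    .edge(id, "center", to, "joint", "dashed", q, .sval(s, q),
          mode, decimals)
  }
  cond <- function(id, from, to, q) {
    .edge(id, from, to, "conditional", "solid", q, .sval(s, q),
          mode, decimals)
  }
  edges <- list(
    marg("m_A", "margin_A", "P(A)"),
    marg("m_notA", "margin_notA", "P(notA)"),
    marg("m_B", "margin_B", "P(B)"),
    marg("m_notB", "margin_notB", "P(notB)"),
    joint("j_AB", "cell_AB", "P(A&B)"),
    joint("j_notAB", "cell_notAB", "P(notA&B)"),
    joint("j_AnotB", "cell_AnotB", "P(A&notB)"),
    joint("j_notAnotB", "cell_notAnotB", "P(notA&notB)"),
    cond("c_A.B", "margin_B", "cell_AB", "P(A|B)"),
    cond("c_notA.B", "margin_B", "cell_notAB", "P(notA|B)"),
    cond("c_A.notB", "margin_notB", "cell_AnotB", "P(A|notB)"),
    cond("c_notA.notB", "margin_notB", "cell_notAnotB", "P(notA|notB)"),
    cond("c_B.A", "margin_A", "cell_AB", "P(B|A)"),
    cond("c_notB.A", "margin_A", "cell_AnotB", "P(notB|A)"),
    cond("c_B.notA", "margin_notA", "cell_notAB", "P(B|notA)"),
    cond("c_notB.notA", "margin_notA", "cell_notAnotB", "P(notB|notA)")
  )
  .graph("net", mode, s, N, nodes, edges, decimals)
}

#' Build a double-tree diagram
#'
#' Six nodes: a total node at the top, the two categories of the first event
#' in the upper band, the two categories of the second event in the lower
#' band, and the total node repeated at the bottom (the doubled node of the
#' double-tree). The four middle branches carry conditionals in both reading
#' directions: the downward label conditions on the first event, the upward
#' label on the second. Two middle branches cross; their `crossing` flag is
#' set, since labels near the crossing are easy to attach to the wrong
#' branch. With `disambiguated = TRUE` the renderer pulls the two reading
#' directions' labels apart so each is unambiguously anchored to its branch.
#'
#' @inheritParams build_net
#' @param disambiguated logical; request the crossing-safe label layout.
#' @return a `"diagram_graph"` with `kind = "double_tree"`.
#' @export
build_double_tree <- function(situation, N = NULL, mode = "prob",
                              decimals = 1, disambiguated = FALSE) {
  mn <- .check_mode_N(mode, N, situation)
  mode <- mn$mode; N <- mn$N
  s <- situation
  ev <- s$events
  one <- rational(1)
  nodes <- list(
    .node("total_top", "center", 0, 4, "total", one, N, mode, FALSE, decimals),
    .node("margin_A", "margin", -1.5, 2, event_label(ev, "A"),
          .sval(s, "P(A)"), N, mode, FALSE, decimals),
    .node("margin_notA", "margin", 1.5, 2, event_label(ev, "notA"),
          .sval(s, "P(notA)"), N, mode, FALSE, decimals),
    .node("margin_B", "margin", -1.5, -2, event_label(ev, "B"),
          .sval(s, "P(B)"), N, mode, FALSE, decimals),
    .node("margin_notB", "margin", 1.5, -2, event_label(ev, "notB"),
          .sval(s, "P(notB)"), N, mode, FALSE, decimals),
    .node("total_bottom", "center", 0, -4, "total", one, N, mode,
          FALSE, decimals)
  )
  mid <- function(id, from, to, qdn, qup, crossing) {
    .edge(id, from, to, "conditional", "solid", qdn, .sval(s, qdn),
          mode, decimals, quantity2 = qup, value2 = .sval(s, qup),
          crossing = crossing)
  }
  edges <- list(
    .edge("m_A", "total_top", "margin_A", "marginal", "solid",
          "P(A)", .sval(s, "P(A)"), mode, decimals),
    .edge("m_notA", "total_top", "margin_notA", "marginal", "solid",
          "P(notA)", .sval(s, "P(notA)"), mode, decimals),
    mid("c_AB", "margin_A", "margin_B", "P(B|A)", "P(A|B)", FALSE),
    mid("c_AnotB", "margin_A", "margin_notB", "P(notB|A)", "P(A|notB)", TRUE),
    mid("c_notAB", "margin_notA", "margin_B", "P(B|notA)", "P(notA|B)", TRUE),
    mid("c_notAnotB", "margin_notA", "margin_notB",
        "P(notB|notA)", "P(notA|notB)", FALSE),
    .edge("m_B", "margin_B", "total_bottom", "marginal", "solid",
          "P(B)", .sval(s, "P(B)"), mode, decimals),
    .edge("m_notB", "margin_notB", "total_bottom", "marginal", "solid",
          "P(notB)", .sval(s, "P(notB)"), mode, decimals)
  )
  .graph("double_tree", mode, s, N, nodes, edges, decimals,
         layout_options = list(disambiguated = isTRUE(disambiguated)))
}

#' Build a tree diagram
#'
#' Seven nodes and six branches: a root total, the chosen first-level event's
#' two categories, and the four joint cells as leaves. Marginals label the
#' first level; conditionals given the first-level event label the second
#' level — so only four of the eight conditionals appear, which is the
#' tree's structural limitation. Both orientations are sub-diagrams of the
#' net.
#'
#' @inheritParams build_net
#' @param orientation `"A_first"` or `"B_first"`: which event branches first.
#' @return a `"diagram_graph"` with `kind = "tree_A_first"` or
#'   `"tree_B_first"`.
#' @export
build_tree <- function(situation, N = NULL, mode = "prob", decimals = 1,
                       orientation = c("A_first", "B_first")) {
  orientation <- match.arg(orientation)
  mn <- .check_mode_N(mode, N, situation)
  mode <- mn$mode; N <- mn$N
  s <- situation
  ev <- s$events
  one <- rational(1)
  if (orientation == "A_first") {
    lvl <- c("A", "notA")
    leaves <- list(
      list(id = "cell_AB", parent = "margin_A", q = "P(A&B)",
           cond = "P(B|A)", name = "A&B"),
      list(id = "cell_AnotB", parent = "margin_A", q = "P(A&notB)",
           cond = "P(notB|A)", name = "A&notB"),
      list(id = "cell_notAB", parent = "margin_notA", q = "P(notA&B)",
           cond = "P(B|notA)", name = "notA&B"),
      list(id = "cell_notAnotB", parent = "margin_notA", q = "P(notA&notB)",
           cond = "P(notB|notA)", name = "notA&notB")
    )
  } else {
    lvl <- c("B", "notB")
    leaves <- list(
      list(id = "cell_AB", parent = "margin_B", q = "P(A&B)",
           cond = "P(A|B)", name = "A&B"),
      list(id = "cell_notAB", parent = "margin_B", q = "P(notA&B)",
           cond = "P(notA|B)", name = "notA&B"),
      list(id = "cell_AnotB", parent = "margin_notB", q = "P(A&notB)",
           cond = "P(A|notB)", name = "A&notB"),
      list(id = "cell_notAnotB", parent = "margin_notB", q = "P(notA&notB)",
           cond = "P(notA|notB)", name = "notA&notB")
    )
  }
  nodes <- list(
    .node("root", "center", 0, 2, "total", one, N, mode, FALSE, decimals),
    .node(paste0("margin_", lvl[1]), "margin", -1.5, 0,
          event_label(ev, lvl[1]), .sval(s, paste0("P(", lvl[1], ")")),
          N, mode, FALSE, decimals),
    .node(paste0("margin_", lvl[2]), "margin", 1.5, 0,
          event_label(ev, lvl[2]), .sval(s, paste0("P(", lvl[2], ")")),
          N, mode, FALSE, decimals)
  )
  xs <- c(-2.25, -0.75, 0.75, 2.25)
  edges <- list(
    .edge("m_1", "root", paste0("margin_", lvl[1]), "marginal", "solid",
          paste0("P(", lvl[1], ")"), .sval(s, paste0("P(", lvl[1], ")")),
          mode, decimals),
    .edge("m_2", "root", paste0("margin_", lvl[2]), "marginal", "solid",
          paste0("P(", lvl[2], ")"), .sval(s, paste0("P(", lvl[2], ")")),
          mode, decimals)
  )
  for (i in seq_along(leaves)) {
    lf <- leaves[[i]]
    nodes[[length(nodes) + 1L]] <- .node(lf$id, "cell", xs[i], -2, lf$name,
                                         .sval(s, lf$q), N, mode, FALSE,
                                         decimals)
    edges[[length(edges) + 1L]] <- .edge(paste0("c_", i), lf$parent, lf$id,
                                         "conditional", "solid", lf$cond,
                                         .sval(s, lf$cond), mode, decimals)
  }
  .graph(paste0("tree_", orientation), mode, s, N, nodes, edges, decimals)
}

#' Build a 2x2 contingency-table diagram
#'
#' A 4x4 node grid: header row and column, the four joint cells, the margin
#' row and column, and the total. The probability version shows joint and
#' marginal probabilities only — the 2x2 table has no place for
#' conditionals — and the frequency version shows the nine absolute counts.
#' The 2x2 table cannot display both formats simultaneously, so
#' `mode = "both"` is an error.
#'
#' @inheritParams build_net
#' @return a `"diagram_graph"` with `kind = "two_by_two"` and no edges.
#' @export
build_two_by_two <- function(situation, N = NULL, mode = "prob",
                             decimals = 1) {
  mode <- match.arg(mode, .diagram_modes)
  if (mode == "both") {
    stop("the 2x2 table cannot display probabilities and frequencies ",
         "simultaneously; use mode 'prob' or 'freq'")
  }
  mn <- .check_mode_N(mode, N, situation)
  N <- mn$N
  s <- situation
  ev <- s$events
  one <- rational(1)
  hdr <- function(id, x, y, name) .node(id, "header", x, y, name)
  val <- function(id, role, x, y, name, q) {
    .node(id, role, x, y, name, .sval(s, q), N, mode, show_prob = TRUE,
          decimals = decimals)
  }
  nodes <- list(
    hdr("corner", 0, 0, ""),
    hdr("head_A", 1, 0, event_label(ev, "A")),
    hdr("head_notA", 2, 0, event_label(ev, "notA")),
    hdr("head_total_col", 3, 0, "total"),
    hdr("head_B", 0, 1, event_label(ev, "B")),
    hdr("head_notB", 0, 2, event_label(ev, "notB")),
    hdr("head_total_row", 0, 3, "total"),
    val("cell_AB", "cell", 1, 1, "A&B", "P(A&B)"),
    val("cell_notAB", "cell", 2, 1, "notA&B", "P(notA&B)"),
    val("cell_AnotB", "cell", 1, 2, "A&notB", "P(A&notB)"),
    val("cell_notAnotB", "cell", 2, 2, "notA&notB", "P(notA&notB)"),
    val("margin_B", "margin", 3, 1, "B", "P(B)"),
    val("margin_notB", "margin", 3, 2, "notB", "P(notB)"),
    val("margin_A", "margin", 1, 3, "A", "P(A)"),
    val("margin_notA", "margin", 2, 3, "notA", "P(notA)")
  )
  nodes[[length(nodes) + 1L]] <- .node("total", "center", 3, 3, "total",
                                       one, N, mode, show_prob = TRUE,
                                       decimals = decimals)
  .graph("two_by_two", mode, s, N, nodes, list(), decimals)
}
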