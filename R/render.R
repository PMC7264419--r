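#' Render a diagram as monospaced text
#'
#' Deterministic plain-text layouts: the 2x2 table is drawn as an aligned
#' grid; the node-branch diagrams (net, trees, double-tree) are drawn as a
#' skeleton of node boxes with every branch label printed exactly once. In
#' the double-tree the two crossing middle branches are marked with the
#' glyph `x` (straight branches use `|`).
#'
#' @param graph a `"diagram_graph"`.
#' @return a character vector of lines (UTF-8).
#' @export
render_text <- function(graph) {
  switch(graph$kind,
    two_by_two = .text_two_by_two(graph),
    net = .text_net(graph),
    double_tree = .text_double_tree(graph),
    tree_A_first = ,
    tree_B_first = .text_tree(graph),
    stop("unknown diagram kind: ", graph$kind)
  )
}

# label shown inside a node box: count in freq/both modes, else the caption
.node_text <- function(graph, id) {
  n <- graph$nodes[graph$nodes$id == id, ]
  if (!is.na(n$label_freq)) n$label_freq
  else if (!is.na(n$label_prob)) n$label_prob
  else n$name
}

.node_box <- function(graph, id) paste0("[", .node_text(graph, id), "]")

# branch label; empty string when unlabeled (freq mode, undefined value)
.edge_text <- function(graph, id, secondary = FALSE) {
  e <- graph$edges[graph$edges$id == id, ]
  lab <- if (secondary) e$label2 else e$label
  if (is.na(lab)) "" else lab
}

.text_two_by_two <- function(graph) {
  g <- function(id) .node_text(graph, id)
  rows <- list(
    c(g("corner"), g("head_A"), g("head_notA"), g("head_total_col")),
    c(g("head_B"), g("cell_AB"), g("cell_notAB"), g("margin_B")),
    c(g("head_notB"), g("cell_AnotB"), g("cell_notAnotB"), g("margin_notB")),
    c(g("head_total_row"), g("margin_A"), g("margin_notA"), g("total"))
  )
  widths <- vapply(1:4, function(j) {
    max(nchar(vapply(rows, function(r) r[j], character(1))))
  }, numeric(1))
  vapply(rows, function(r) {
    paste0(formatC(r[1], width = widths[1], flag = "-"), "  ",
           paste(vapply(2:4, function(j) formatC(r[j], width = widths[j]),
                        character(1)), collapse = "  "))
  }, character(1))
}

.text_net <- function(graph) {
  nb <- function(id) .node_box(graph, id)
  el <- function(id) .edge_text(graph, id)
  dash <- function(lab) if (nzchar(lab)) paste0("--", lab, "--") else "----"
  c(
    paste(nb("cell_AB"), dash(el("c_A.B")), nb("margin_B"),
          dash(el("c_notA.B")), nb("cell_notAB")),
    paste0("   \\ ", el("j_AB"), "   |   ", el("j_notAB"), " /"),
    paste0(el("c_B.A"), "      ", el("m_B"), "      ", el("c_B.notA")),
    paste(nb("margin_A"), dash(el("m_A")), nb("center"),
          dash(el("m_notA")), nb("margin_notA")),
    paste0(el("c_notB.A"), "      ", el("m_notB"), "      ",
           el("c_notB.notA")),
    paste0("   / ", el("j_AnotB"), "   |   ", el("j_notAnotB"), " \\"),
    paste(nb("cell_AnotB"), dash(el("c_A.notB")), nb("margin_notB"),
          dash(el("c_notA.notB")), nb("cell_notAnotB"))
  )
}

.text_double_tree <- function(graph) {
  nb <- function(id) .node_box(graph, id)
  el <- function(id, s = FALSE) .edge_text(graph, id, secondary = s)
  mid_line <- function(id) {
    e <- graph$edges[graph$edges$id == id, ]
    glyph <- if (e$crossing) "x" else "|"
    dn <- el(id)
    up <- el(id, s = TRUE)
    lab <- if (nzchar(dn) || nzchar(up)) {
      paste0("  down ", dn, "   up ", up)
    } else ""
    paste0("  ", glyph, " ", e$from, " -> ", e$to, lab)
  }
  c(
    paste0("        ", nb("total_top")),
    paste0("   ", el("m_A"), " / \\ ", el("m_notA")),
    paste(nb("margin_A"), "          ", nb("margin_notA")),
    mid_line("c_AB"),
    mid_line("c_AnotB"),
    mid_line("c_notAB"),
    mid_line("c_notAnotB"),
    paste(nb("margin_B"), "          ", nb("margin_notB")),
    paste0("   ", el("m_B"), " \\ / ", el("m_notB")),
    paste0("        ", nb("total_bottom"))
  )
}

.text_tree <- function(graph) {
  nb <- function(id) .node_box(graph, id)
  el <- function(id) .edge_text(graph, id)
  margins <- graph$nodes$id[graph$nodes$role == "margin"]
  leaves <- graph$nodes$id[graph$nodes$role == "cell"]
  c(
    paste0("            ", nb("root")),
    paste0("     ", el("m_1"), " / \\ ", el("m_2")),
    paste(nb(margins[1]), "            ", nb(margins[2])),
    paste0("  ", el("c_1"), " / \\ ", el("c_2"), "    ",
           el("c_3"), " / \\ ", el("c_4")),
    paste(nb(leaves[1]), nb(leaves[2]), " ", nb(leaves[3]), nb(leaves[4]))
  )
}

# ---------------------------------------------------------------------------
# SVG

#' SVG layout configuration
#'
#' @param unit pixels per grid unit of the diagram's node positions.
#' @param margin outer margin in pixels.
#' @param node_radius node circle radius in pixels.
#' @param font_size label font size in pixels.
#' @param min_label_sep minimum distance, in pixels, between the anchors of
#'   the two reading-direction labels near the double-tree crossing when the
#'   disambiguated layout is requested.
#' @return a layout configuration list for [render_svg()].
#' @export
svg_layout <- function(unit = 90, margin = 70, node_radius = 24,
                       font_size = 12, min_label_sep = 40) {
  list(unit = unit, margin = margin, node_radius = node_radius,
       font_size = font_size, min_label_sep = min_label_sep)
}

#' Render a diagram as SVG
#'
#' Produces a deterministic standalone SVG 1.1 document. Joint branches are
#' drawn dashed (`stroke-dasharray`), marginal and conditional branches
#' solid. Node coordinates come from a fixed per-kind layout table scaled by
#' the layout configuration. For double-trees built with
#' `disambiguated = TRUE`, the downward-reading labels are anchored near the
#' upper end and the upward-reading labels near the lower end of each middle
#' branch, at least `min_label_sep` pixels apart, so the two probabilities on
#' a crossing branch cannot be attributed to the wrong branch.
#'
#' @param graph a `"diagram_graph"`.
#' @param layout a configuration from [svg_layout()].
#' @return a single string containing the SVG document.
#' @export
render_svg <- function(graph, layout = svg_layout()) {
  if (!inherits(graph, "diagram_graph")) stop("not a diagram_graph")
  if (!graph$kind %in% c("net", "double_tree", "tree_A_first",
                         "tree_B_first", "two_by_two")) {
    stop("unknown diagram kind: ", graph$kind)
  }
  nodes <- graph$nodes
  px <- function(x) layout$margin + (x - min(nodes$x)) * layout$unit
  py <- function(y) layout$margin + (max(nodes$y) - y) * layout$unit
  width <- layout$margin * 2 + (max(nodes$x) - min(nodes$x)) * layout$unit
  height <- layout$margin * 2 + (max(nodes$y) - min(nodes$y)) * layout$unit
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  out <- c(sprintf(
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
           "width=\"%.0f\" height=\"%.0f\" viewBox=\"0 0 %.0f %.0f\">"),
    width, height, width, height),
    sprintf(paste0("<style>text { font-family: monospace; font-size: %dpx; ",
                   "text-anchor: middle; }</style>"), layout$font_size))

  disamb <- isTRUE(graph$layout_options$disambiguated)
  if (!is.null(graph$edges)) {
    for (i in seq_len(nrow(graph$edges))) {
      e <- graph$edges[i, ]
      n1 <- nodes[nodes$id == e$from, ]
      n2 <- nodes[nodes$id == e$to, ]
      x1 <- px(n1$x); y1 <- py(n1$y); x2 <- px(n2$x); y2 <- py(n2$y)
      dash <- if (e$style == "dashed") " stroke-dasharray=\"7,5\"" else ""
      out <- c(out, sprintf(
        paste0("<line id=\"edge-%s\" class=\"edge %s\" x1=\"%.1f\" ",
               "y1=\"%.1f\" x2=\"%.1f\" y2=\"%.1f\" stroke=\"#333333\"",
               "%s/>"),
        e$id, e$role, x1, y1, x2, y2, dash))
      anchor <- function(t) c(x1 + t * (x2 - x1), y1 + t * (y2 - y1))
      has2 <- !is.na(e$label2)
      # dual-direction labels: default near the middle (reproducing the
      # crossing hazard); disambiguated pulls them towards the branch ends
      t_dn <- if (!has2) 0.5 else if (disamb) 0.2 else 0.42
      t_up <- if (disamb) 0.8 else 0.58
      if (disamb && has2) {
        len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
        if (len > 0 && (t_up - t_dn) * len < layout$min_label_sep) {
          half <- layout$min_label_sep / (2 * len)
          t_dn <- 0.5 - half
          t_up <- 0.5 + half
        }
      }
      if (!is.na(e$label)) {
        a <- anchor(t_dn)
        out <- c(out, sprintf(
          "<text id=\"lbl-%s-dn\" x=\"%.1f\" y=\"%.1f\">%s</text>",
          e$id, a[1], a[2] - 4, esc(e$label)))
      }
      if (has2) {
        a <- anchor(t_up)
        out <- c(out, sprintf(
          "<text id=\"lbl-%s-up\" x=\"%.1f\" y=\"%.1f\">%s</text>",
          e$id, a[1], a[2] + layout$font_size, esc(e$label2)))
      }
    }
  }
  for (i in seq_len(nrow(nodes))) {
    n <- nodes[i, ]
    x <- px(n$x); y <- py(n$y)
    shape <- if (graph$kind == "two_by_two") {
      sprintf(paste0("<rect id=\"node-%s\" class=\"node %s\" x=\"%.1f\" ",
                     "y=\"%.1f\" width=\"%.1f\" height=\"%.1f\" ",
                     "fill=\"white\" stroke=\"#333333\"/>"),
              n$id, n$role, x - layout$unit * 0.45, y - layout$unit * 0.25,
              layout$unit * 0.9, layout$unit * 0.5)
    } else {
      sprintf(paste0("<circle id=\"node-%s\" class=\"node %s\" cx=\"%.1f\" ",
                     "cy=\"%.1f\" r=\"%.1f\" fill=\"white\" ",
                     "stroke=\"#333333\"/>"),
              n$id, n$role, x, y, layout$node_radius)
    }
    out <- c(out, shape)
    inner <- if (!is.na(n$label_freq)) n$label_freq
             else if (!is.na(n$label_prob)) n$label_prob
             else n$name
    if (nzchar(inner)) {
      out <- c(out, sprintf(
        "<text id=\"txt-%s\" x=\"%.1f\" y=\"%.1f\">%s</text>",
        n$id, x, y + 4, esc(inner)))
    }
    if (!is.na(n$label_freq) && !identical(inner, n$name) &&
        graph$kind != "two_by_two") {
      out <- c(out, sprintf(
        "<text id=\"cap-%s\" x=\"%.1f\" y=\"%.1f\">%s</text>",
        n$id, x, y - layout$node_radius - 6, esc(n$name)))
    }
  }
  paste(c(out, "</svg>"), collapse = "\n")
}
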