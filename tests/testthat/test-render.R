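test_that("net text shows nine node boxes and each label exactly once", {
  net <- build_net(mammography_situation(), mode = "both", N = 10000)
  txt <- render_text(net)
  all_text <- paste(txt, collapse = "\n")
  boxes <- gregexpr("\\[[^]]*\\]", all_text)[[1]]
  expect_length(boxes, 9L)
  for (lab in net$edges$label) {
    hits <- gregexpr(lab, all_text, fixed = TRUE)[[1]]
    expect_length(hits[hits > 0], 1L)
  }
  for (cnt in net$nodes$label_freq) {
    expect_true(grepl(paste0("[", cnt, "]"), all_text, fixed = TRUE))
  }
})

test_that("text rendering is deterministic", {
  sit <- economics_situation()
  for (graph in list(build_net(sit, mode = "both", N = 1000),
                     build_double_tree(sit, mode = "prob"),
                     build_tree(sit, mode = "freq", N = 1000),
                     build_two_by_two(sit, 1000, "freq"))) {
    expect_identical(render_text(graph), render_text(graph))
    expect_identical(render_svg(graph), render_svg(graph))
  }
})

test_that("the frequency 2x2 grid prints all nine counts", {
  txt <- paste(render_text(build_two_by_two(mammography_situation(),
                                            10000, "freq")),
               collapse = "\n")
  for (cnt in c("160", "980", "40", "8,820", "200", "9,800", "1,140",
                "8,860", "10,000")) {
    expect_true(grepl(cnt, txt, fixed = TRUE), label = cnt)
  }
})

test_that("double-tree text marks crossing branches with a distinct glyph", {
  txt <- render_text(build_double_tree(mammography_situation(),
                                       mode = "prob"))
  crossing_lines <- grep("^  x ", txt)
  straight_lines <- grep("^  \\| ", txt)
  expect_length(crossing_lines, 2L)
  expect_length(straight_lines, 2L)
})

test_that("SVG output is well-formed with dashed joints and edge ids", {
  skip_if_not_installed("xml2")
  net <- build_net(mammography_situation(), mode = "both", N = 10000)
  svg <- render_svg(net)
  doc <- xml2::read_xml(svg)
  lines <- xml2::xml_find_all(doc, "//*[local-name() = 'line']")
  expect_length(lines, 16L)
  ids <- xml2::xml_attr(lines, "id")
  expect_true(all(grepl("^edge-", ids)))
  dashed <- !is.na(xml2::xml_attr(lines, "stroke-dasharray"))
  classes <- xml2::xml_attr(lines, "class")
  expect_identical(dashed, grepl("joint", classes))
})

test_that("the disambiguated double-tree separates the dual label anchors", {
  skip_if_not_installed("xml2")
  layout <- svg_layout(min_label_sep = 40)
  anchor_dist <- function(disamb) {
    dt <- build_double_tree(mammography_situation(), mode = "prob",
                            disambiguated = disamb)
    doc <- xml2::read_xml(render_svg(dt, layout))
    dists <- vapply(c("c_AnotB", "c_notAB"), function(id) {
      dn <- xml2::xml_find_first(doc, sprintf(
        "//*[@id = 'lbl-%s-dn']", id))
      up <- xml2::xml_find_first(doc, sprintf(
        "//*[@id = 'lbl-%s-up']", id))
      sqrt((as.numeric(xml2::xml_attr(dn, "x")) -
              as.numeric(xml2::xml_attr(up, "x")))^2 +
             (as.numeric(xml2::xml_attr(dn, "y")) -
                as.numeric(xml2::xml_attr(up, "y")))^2)
    }, numeric(1))
    dists
  }
  expect_true(all(anchor_dist(TRUE) >= 40))
  expect_true(all(anchor_dist(TRUE) > anchor_dist(FALSE)))
})

test_that("unknown kinds are rejected", {
  net <- build_net(mammography_situation(), mode = "prob")
  net$kind <- "mosaic"
  expect_error(render_svg(net), "unknown diagram kind")
  expect_error(render_text(net), "unknown diagram kind")
})
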