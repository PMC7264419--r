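test_that("the net has 9 nodes and 16 branches with the right roles", {
  net <- build_net(mammography_situation(), mode = "prob")
  expect_equal(nrow(net$nodes), 9L)
  expect_equal(sum(net$nodes$role == "center"), 1L)
  expect_equal(sum(net$nodes$role == "margin"), 4L)
  expect_equal(sum(net$nodes$role == "cell"), 4L)
  expect_equal(nrow(net$edges), 16L)
  expect_equal(sum(net$edges$role == "marginal"), 4L)
  expect_equal(sum(net$edges$role == "joint"), 4L)
  expect_equal(sum(net$edges$role == "conditional"), 8L)
  expect_true(all(net$edges$style[net$edges$role == "joint"] == "dashed"))
  expect_true(all(net$edges$style[net$edges$role != "joint"] == "solid"))
  expect_false(any(net$edges$crossing))
})

test_that("every branch label equals the derived quantity exactly", {
  sit <- mammography_situation()
  for (graph in list(build_net(sit, mode = "both", N = 10000),
                     build_double_tree(sit, mode = "both", N = 10000),
                     build_tree(sit, mode = "both", N = 10000))) {
    for (i in seq_len(nrow(graph$edges))) {
      e <- graph$edges[i, ]
      expect_true(rat_equal(row_value(e), situation_value(sit, e$quantity)),
                  label = paste(graph$kind, e$quantity))
      if (!is.na(e$quantity2)) {
        expect_true(rat_equal(row_value(e, secondary = TRUE),
                              situation_value(sit, e$quantity2)),
                    label = paste(graph$kind, e$quantity2))
      }
    }
  }
})

test_that("uniform independence shows 25% diagonals and 50% borders", {
  sit <- complete_situation(cell_distribution(0.25, 0.25, 0.25, 0.25))
  net <- build_net(sit, mode = "prob")
  joints <- net$edges[net$edges$role == "joint", ]
  expect_true(all(grepl("25%", joints$label)))
  conds <- net$edges[net$edges$role == "conditional", ]
  expect_true(all(grepl("50%", conds$label)))
})

test_that("modes gate which labels appear", {
  sit <- mammography_situation()
  freq <- build_net(sit, mode = "freq", N = 10000)
  expect_true(all(is.na(freq$edges$label)))
  expect_true(all(!is.na(freq$nodes$label_freq)))
  prob <- build_net(sit, mode = "prob")
  expect_true(all(is.na(prob$nodes$label_freq)))
  expect_true(all(!is.na(prob$edges$label)))
  both <- build_net(sit, mode = "both", N = 10000)
  expect_true(all(!is.na(both$nodes$label_freq)))
  expect_true(all(!is.na(both$edges$label)))
  expect_identical(both$nodes$label_freq[both$nodes$id == "center"], "10,000")
  s2 <- mammography_situation(); s2$N <- NULL
  expect_error(build_net(s2, mode = "freq"), "requires a population size")
})

test_that("undefined conditionals leave their border branches unlabeled", {
  sit <- complete_situation(c(1, 0, 0, 0))
  net <- build_net(sit, mode = "prob")
  undefined <- c("P(A|notB)", "P(notA|notB)", "P(B|notA)", "P(notB|notA)")
  e <- net$edges
  expect_true(all(is.na(e$label[e$quantity %in% undefined])))
  expect_true(all(!is.na(e$label[e$role == "conditional" &
                                   !e$quantity %in% undefined])))
})

test_that("the double-tree doubles its total and crosses exactly one pair", {
  sit <- mammography_situation()
  dt <- build_double_tree(sit, mode = "freq", N = 10000)
  expect_equal(nrow(dt$nodes), 6L)
  expect_equal(nrow(dt$edges), 8L)
  totals <- dt$nodes[dt$nodes$role == "center", ]
  expect_equal(nrow(totals), 2L)                    # the doubled node
  expect_identical(unique(totals$label_freq), "10,000")
  # frequency node band: 10,000 / 200, 9,800 / 1,140, 8,860 / 10,000
  expect_identical(dt$nodes$label_freq,
                   c("10,000", "200", "9,800", "1,140", "8,860", "10,000"))
  crossing <- dt$edges[dt$edges$crossing, ]
  expect_setequal(crossing$id, c("c_AnotB", "c_notAB"))
  # all four middle edges carry both reading directions
  mid <- dt$edges[dt$edges$role == "conditional", ]
  expect_equal(nrow(mid), 4L)
  expect_true(all(!is.na(mid$quantity2)))
})

test_that("the crossing branches carry the confusable upward labels", {
  dt <- build_double_tree(mammography_situation(), mode = "prob")
  up <- function(id) {
    row_value(dt$edges[dt$edges$id == id, ], secondary = TRUE)
  }
  expect_true(rat_equal(up("c_notAB"), "49/57"))   # about 86.0%
  expect_true(rat_equal(up("c_AnotB"), "2/443"))   # about 0.45%
  lab <- dt$edges$label2[dt$edges$id == "c_notAB"]
  expect_match(lab, "86%")
})

test_that("trees expose exactly four conditionals on the second level", {
  sit <- mammography_situation()
  for (orient in c("A_first", "B_first")) {
    tr <- build_tree(sit, mode = "prob", orientation = orient)
    expect_equal(nrow(tr$nodes), 7L)
    expect_equal(nrow(tr$edges), 6L)
    expect_equal(sum(tr$edges$role == "marginal"), 2L)
    conds <- tr$edges[tr$edges$role == "conditional", ]
    expect_equal(nrow(conds), 4L)
    # conditional edges only on the second level: they start at margins
    margins <- tr$nodes$id[tr$nodes$role == "margin"]
    expect_true(all(conds$from %in% margins))
  }
  trb <- build_tree(sit, mode = "prob", orientation = "B_first")
  pab <- trb$edges[trb$edges$quantity == "P(A|B)", ]
  expect_true(rat_equal(row_value(pab), "8/57"))
  pnab <- trb$edges[trb$edges$quantity == "P(notA|B)", ]
  expect_true(rat_equal(row_value(pnab), "49/57"))
})

test_that("the 2x2 table is a 4x4 grid without conditionals", {
  sit <- mammography_situation()
  freq <- build_two_by_two(sit, 10000, "freq")
  expect_equal(nrow(freq$nodes), 16L)
  expect_null(freq$edges)
  cells <- freq$nodes[freq$nodes$role == "cell", ]
  expect_setequal(cells$label_freq, c("160", "980", "40", "8,820"))
  margins <- freq$nodes[freq$nodes$role == "margin", ]
  expect_setequal(margins$label_freq, c("200", "9,800", "1,140", "8,860"))
  expect_identical(freq$nodes$label_freq[freq$nodes$id == "total"], "10,000")
  prob <- build_two_by_two(sit, mode = "prob")
  pcells <- prob$nodes[prob$nodes$role == "cell", ]
  expect_setequal(pcells$label_prob, c("1.6%", "9.8%", "0.4%", "88.2%"))
  expect_false(any(grepl("\\|", c(prob$nodes$label_prob,
                                  prob$nodes$name), fixed = FALSE)))
  expect_error(build_two_by_two(sit, 10000, "both"), "simultaneously")
})

test_that("both trees and both 2x2 tables embed in the net", {
  sit <- mammography_situation()
  net_b <- build_net(sit, mode = "both", N = 10000)
  net_labels <- paste(net_b$edges$quantity, net_b$edges$label)
  for (orient in c("A_first", "B_first")) {
    tr <- build_tree(sit, mode = "both", N = 10000, orientation = orient)
    tree_labels <- paste(tr$edges$quantity, tr$edges$label)
    expect_true(all(tree_labels %in% net_labels), label = orient)
  }
  # probability 2x2 table: its cells and margins sit on the net's branches
  p22 <- build_two_by_two(sit, mode = "prob")
  for (role in c("cell", "margin")) {
    vals <- p22$nodes[p22$nodes$role == role, ]
    for (i in seq_len(nrow(vals))) {
      hit <- net_b$edges$value_num == vals$value_num[i] &
        net_b$edges$value_den == vals$value_den[i]
      expect_true(any(hit), label = vals$id[i])
    }
  }
  # frequency 2x2 table: its nine counts are the net's node counts
  f22 <- build_two_by_two(sit, 10000, "freq")
  f22_counts <- f22$nodes$label_freq[!is.na(f22$nodes$label_freq)]
  expect_setequal(f22_counts, net_b$nodes$label_freq)
})
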