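test_that("built-in tasks solve and reproduce the stimulus numbers", {
  tasks <- builtin_tasks()
  m <- tasks$mammography
  e <- tasks$economics
  expect_true(rat_equal(situation_value(m$situation, "P(A|B)"), "8/57"))
  res <- solve_situation(m$params, events = m$events)
  expect_identical(res$status, "complete")
  expect_false(m$rounding_note)
  expect_true(e$rounding_note)   # 204.8 rounded to 205 in the stimulus
  expect_true(rat_equal(e$freq_table$n_ab, 205))
  expect_true(rat_equal(e$freq_table$n_na_b, 408))
})

test_that("frequency text carries the five stimulus counts", {
  doc <- render_problem(builtin_tasks()$mammography, "frequencies",
                        "text_only")
  expect_length(doc$statistics, 3L)
  txt <- paste(doc$statistics, collapse = " ")
  expect_match(txt, "200 out of 10,000 women who participate in routine screening have breast cancer",
               fixed = TRUE)
  counts <- c("200", "10,000", "160", "9,800", "980")
  for (cnt in counts) expect_true(grepl(cnt, txt, fixed = TRUE), label = cnt)
  edoc <- render_problem(builtin_tasks()$economics, "frequencies",
                         "text_only")
  etxt <- paste(edoc$statistics, collapse = " ")
  for (cnt in c("320", "1,000", "205", "680", "408")) {
    expect_true(grepl(cnt, etxt, fixed = TRUE), label = cnt)
  }
})

test_that("probability text states the three Bayesian parameters", {
  doc <- render_problem(builtin_tasks()$economics, "probabilities",
                        "text_only")
  txt <- paste(doc$statistics, collapse = " ")
  expect_match(txt, "32%", fixed = TRUE)
  expect_match(txt, "64%", fixed = TRUE)
  expect_match(txt, "60%", fixed = TRUE)
  mdoc <- render_problem(builtin_tasks()$mammography, "probabilities",
                         "text_only")
  mtxt <- paste(mdoc$statistics, collapse = " ")
  for (p in c("2%", "80%", "10%")) {
    expect_true(grepl(p, mtxt, fixed = TRUE), label = p)
  }
})

test_that("visualization versions embed a diagram and drop the text", {
  doc <- render_problem(builtin_tasks()$economics, "probabilities", "net")
  expect_null(doc$statistics)
  expect_s3_class(doc$graph, "diagram_graph")
  expect_identical(doc$graph$kind, "net")
  expect_identical(doc$graph$mode, "prob")
  expect_equal(sum(!is.na(doc$graph$edges$label)), 16L)  # all 16 at a glance
  fdoc <- render_problem(builtin_tasks()$economics, "frequencies",
                         "double_tree")
  expect_identical(fdoc$graph$mode, "freq")
  # frequency diagrams show the rounded stimulus counts
  expect_true("613" %in% fdoc$graph$nodes$label_freq)
})

test_that("answer blanks and question order follow the design", {
  m <- builtin_tasks()$mammography
  fdoc <- render_problem(m, "frequencies", "text_only")
  expect_identical(fdoc$questions[[1]]$type, "conditional")
  expect_identical(fdoc$questions[[2]]$type, "joint")
  expect_identical(fdoc$questions[[1]]$blank, "____ out of ____")
  pdoc <- render_problem(m, "probabilities", "text_only")
  expect_identical(pdoc$questions[[1]]$blank, "_______")
  swapped <- render_problem(m, "probabilities", "text_only",
                            question_order = "joint_first")
  expect_identical(swapped$questions[[1]]$type, "joint")
  expect_identical(pdoc$questions[[1]]$spec$target, "P(A|B)")
  expect_identical(pdoc$questions[[2]]$spec$target, "P(A&notB)")
  lines <- problem_text(pdoc)
  expect_true(any(grepl("Answer: _______", lines, fixed = TRUE)))
})

test_that("the design matrix enumerates 16 versions and legal booklets", {
  dm <- design_matrix(builtin_tasks(), seed = 11)
  expect_equal(nrow(dm$versions), 16L)
  expect_equal(nrow(unique(dm$versions)), 16L)
  expect_equal(nrow(dm$booklets), 48L)
  b <- dm$booklets
  expect_true(all(b$context_1 != b$context_2))
  expect_true(all(b$format_1 != b$format_2))
  expect_true(all(b$visualization_1 != b$visualization_2))
  dm2 <- design_matrix(builtin_tasks(), seed = 11)
  expect_identical(dm, dm2)
  dm3 <- design_matrix(builtin_tasks(), seed = 12)
  expect_false(identical(dm$booklets, dm3$booklets))
  expect_error(design_matrix(builtin_tasks()[1]), "at least two")
})

test_that("the design shuffle does not disturb the session RNG", {
  set.seed(42)
  before <- .Random.seed
  design_matrix(builtin_tasks(), seed = 3)
  expect_identical(.Random.seed, before)
})
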