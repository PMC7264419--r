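test_that("the catalogue has the documented strategies and forms", {
  cond <- builtin_strategies("conditional")
  expect_length(cond, 8L)
  expect_true("correct" %in% names(cond))
  joint <- builtin_strategies("joint")
  expect_length(joint, 9L)
  expect_null(cond$pre_bayes$prob_expr)
  expect_null(cond$likelihood_subtraction$freq_pair)
  expect_null(cond$pos_rate_over_false_rate$freq_pair)
  expect_null(joint$independence_error$freq_pair)
  expect_length(builtin_strategies("all"), 17L)
})

test_that("strategy predictions evaluate exactly through the letter map", {
  task <- builtin_tasks()$mammography
  expect_true(rat_equal(
    predicted_answer("correct", task, "probability", "conditional"), "8/57"))
  expect_true(rat_equal(
    predicted_answer("fisherian", task, "probability", "conditional"),
    "4/5"))
  expect_equal(
    unname(predicted_answer("joint_occurrence", task, "frequency",
                            question_type = "conditional")),
    c(160, 10000))
  expect_true(rat_equal(
    predicted_answer("p_error", task, "probability", "joint"), "2/443"))
  expect_true(rat_equal(
    predicted_answer("independence_error", task, "probability", "joint"),
    as_rational(0.01772)))
  expect_true(rat_equal(
    predicted_answer("double_tree_confusion_II", task, "probability",
                     "joint"),
    as_rational(0.886) * rational(49, 57)))
  expect_true(rat_equal(
    predicted_answer("double_joint", task, "probability", "joint"),
    as_rational(0.008)))
  # the ratio strategy exceeds 1 for these parameters
  expect_true(rat_equal(
    predicted_answer("pos_rate_over_false_rate", task, "probability",
                     "conditional"), 8))
  expect_error(predicted_answer("pre_bayes", task, "probability",
                                "conditional"), "no probability-form")
  expect_error(predicted_answer("likelihood_subtraction", task, "frequency",
                                question_type = "conditional"),
               "no frequency-form")
})

test_that("responses classify to the documented strategies", {
  task <- builtin_tasks()$mammography
  cl <- classify_response(task, "conditional", 0.14)
  expect_identical(cl$matches$strategy[1], "correct")
  expect_true(cl$coded_correct)
  cl <- classify_response(task, "conditional", c(160, 10000))
  expect_identical(cl$matches$strategy, "joint_occurrence")
  cl <- classify_response(task, "joint", 0.005)
  expect_identical(cl$matches$strategy[1], "p_error")
  expect_false(cl$coded_correct)
  cl <- classify_response(task, "joint", 0.01772)
  expect_identical(cl$matches$strategy[1], "independence_error")
  expect_true(cl$matches$exact[1])
  cl <- classify_response(task, "conditional", 0.55)
  expect_true(cl$unclassified)
  expect_equal(nrow(cl$matches), 0L)
})

test_that("exact matches come first, ties break by catalogue order", {
  task <- builtin_tasks()$mammography
  # 0.45% is nearest to the p-error but also within tolerance of correct
  cl <- classify_response(task, "joint", 0.0045)
  expect_true(all(c("p_error", "correct") %in% cl$matches$strategy))
  expect_identical(cl$matches$strategy[1], "p_error")
  expect_true(cl$coded_correct)  # inside the coded interval [0.4%, 0.5%)
})

test_that("malformed frequency pairs are flagged and unclassified", {
  task <- builtin_tasks()$mammography
  cl <- classify_response(task, "conditional", c(1140, 160))
  expect_true(cl$malformed)
  expect_true(cl$unclassified)
  expect_false(cl$coded_correct)
  expect_error(classify_response(task, "conditional", c(-1, 10)),
               "non-negative")
  expect_error(classify_response(task, "conditional", 0.5, tolerance = -1),
               "non-negative")
})

test_that("correctness coding applies the exclusive interval bounds", {
  tasks <- builtin_tasks()
  m <- tasks$mammography
  e <- tasks$economics
  expect_true(code_correct(m, "conditional", c(160, 1140)))
  expect_false(code_correct(m, "conditional", c(160, 10000)))
  expect_true(code_correct(m, "conditional", 0.14))
  expect_true(code_correct(m, "conditional", 0.1403))
  expect_true(code_correct(m, "joint", 0.004))
  expect_true(code_correct(m, "joint", 0.0045))
  expect_false(code_correct(m, "joint", 0.005))   # the expected wrong answer
  expect_true(code_correct(e, "joint", 0.113))    # within 11% and 12%
  expect_true(code_correct(e, "joint", 0.115))
  expect_false(code_correct(e, "joint", 0.125))
  expect_true(code_correct(e, "conditional", c(205, 613)))
  expect_false(code_correct(e, "conditional", c(204, 613)))
  expect_true(code_correct(e, "conditional", 0.334))
  expect_true(code_correct(e, "conditional", 0.335))
})

test_that("the collision audit reports the posterior/p-error boundary", {
  task <- builtin_tasks()$mammography
  col <- strategy_collisions(task, "joint")
  pair <- col[(col$strategy_1 == "correct" & col$strategy_2 == "p_error") |
                (col$strategy_1 == "p_error" & col$strategy_2 == "correct"), ]
  expect_equal(nrow(pair), 1L)
  expect_lt(pair$distance, 0.5)
})

test_that("response tables classify in batch with appended columns", {
  tbl <- data.frame(
    task_id = c("mammography", "mammography", "economics", "mammography"),
    question_type = c("conditional", "conditional", "joint", "joint"),
    format = c("probability", "frequency", "probability", "probability"),
    response_numerator = c(0.8, 160, 0.115, 0.37),
    response_denominator = c(NA, 1140, NA, NA),
    stringsAsFactors = FALSE)
  out <- classify_responses(tbl)
  expect_identical(out$matched_strategy[1:3],
                   c("fisherian", "correct", "correct"))
  expect_true(is.na(out$matched_strategy[4]))
  expect_identical(out$coded_correct, c(FALSE, TRUE, TRUE, FALSE))
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tbl, tmp, row.names = FALSE)
  out2 <- classify_responses(tmp, out = tmp)
  reread <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_identical(reread$matched_strategy[1], "fisherian")
})
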