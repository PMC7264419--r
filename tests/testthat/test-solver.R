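test_that("the Bayesian parameter set solves to the exact posterior", {
  res <- solve_situation(c("P(A)" = 0.02, "P(B|A)" = 0.8, "P(B|notA)" = 0.1),
                         events = mammography_events())
  expect_identical(res$status, "complete")
  expect_true(rat_equal(situation_value(res$situation, "P(A|B)"), "8/57"))
  expect_true(rat_equal(res$situation$cells[1], rational(2, 125)))
})

test_that("a single marginal leaves two free degrees of freedom", {
  res <- solve_situation(c("P(A)" = 0.3))
  expect_identical(res$status, "underdetermined")
  expect_equal(res$diagnostics$free_dof, 2L)
  res4 <- solve_situation(list())
  expect_identical(res4$status, "underdetermined")
  expect_equal(res4$diagnostics$free_dof, 3L)
})

test_that("a joint exceeding its containing marginal is inconsistent", {
  res <- solve_situation(c("P(A)" = 0.4, "P(A&B)" = 0.5))
  expect_identical(res$status, "inconsistent")
  expect_true(length(res$diagnostics$messages) > 0)
})

test_that("joints violating normalization report the X-rule", {
  res <- solve_situation(c("P(A&B)" = 0.3, "P(A&notB)" = 0.3,
                           "P(notA&B)" = 0.2, "P(notA&notB)" = 0.1))
  expect_identical(res$status, "inconsistent")
  expect_true("x" %in% res$diagnostics$violations$rule)
})

test_that("three joints force the fourth cell by normalization", {
  res <- solve_situation(c("P(A&B)" = 0.2048, "P(A&notB)" = 0.1152,
                           "P(notA&B)" = 0.408))
  expect_identical(res$status, "complete")
  expect_true(rat_equal(res$situation$cells[4], as_rational(0.272)))
  expect_equal(situation_value(res$situation, "P(A|B)", as = "numeric"),
               0.2048 / 0.6128)
})

test_that("a conditional on an event forced to probability zero conflicts", {
  res <- solve_situation(c("P(A)" = 0, "P(B|A)" = 0.5, "P(B)" = 0.3))
  expect_identical(res$status, "inconsistent")
  expect_true(any(grepl("P\\(A\\) = 0", res$diagnostics$messages)))
})

test_that("absolute frequencies solve like their exact proportions", {
  res <- solve_situation(frequencies = c("P(A)" = 200, "P(A&B)" = 160,
                                         "P(B)" = 1140),
                         N = 10000, events = mammography_events())
  expect_identical(res$status, "complete")
  expect_true(rat_equal(situation_value(res$situation, "P(A|B)"), "8/57"))
  expect_error(solve_situation(frequencies = c("P(A)" = 200)),
               "require a population size")
  expect_error(solve_situation(frequencies = c("P(A)" = 20000), N = 10000),
               "\\[0, N\\]")
})

test_that("malformed specifications are rejected before solving", {
  expect_error(solve_situation(c("P(A)" = 1.2)), "outside")
  expect_error(solve_situation(c("P(A)" = 0.3, "P(A)" = 0.4)), "duplicate")
  expect_error(solve_situation(c("TOTAL" = 0.5)), "TOTAL")
})

test_that("redundant but consistent constraints still solve", {
  res <- solve_situation(c("P(A&B)" = 0.25, "P(A&notB)" = 0.25,
                           "P(notA&B)" = 0.25, "P(notA&notB)" = 0.25,
                           "P(A)" = 0.5, "P(A|B)" = 0.5))
  expect_identical(res$status, "complete")
  expect_true(rat_equal(situation_value(res$situation, "P(B|A)"),
                        rational(1, 2)))
})

test_that("an underdetermined system off the simplex is inconsistent", {
  # two joints already exceed 1; rank leaves a free direction, yet no
  # probability distribution is compatible
  res <- solve_situation(c("P(A&B)" = 0.6, "P(A&notB)" = 0.6))
  expect_identical(res$status, "inconsistent")
})
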