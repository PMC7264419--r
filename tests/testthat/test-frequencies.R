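test_that("exact expected counts reproduce the screening frequency table", {
  ft <- to_frequencies(mammography_situation(), 10000)
  expect_true(rat_equal(ft$n_ab, 160))
  expect_true(rat_equal(ft$n_a_nb, 40))
  expect_true(rat_equal(ft$n_na_b, 980))
  expect_true(rat_equal(ft$n_na_nb, 8820))
  expect_true(rat_equal(ft$n_a, 200))
  expect_true(rat_equal(ft$n_na, 9800))
  expect_true(rat_equal(ft$n_b, 1140))
  expect_true(rat_equal(ft$n_nb, 8860))
  expect_true(ft$exact_counts)
  # linear scaling: at N = 1,000 the false-negative cell is 4
  ft2 <- to_frequencies(mammography_situation(), 1000)
  expect_true(rat_equal(ft2$n_a_nb, 4))
})

test_that("half-up rounding keeps additivity (204.8 becomes 205)", {
  ft <- to_frequencies(economics_situation(), 1000, policy = "round")
  expect_true(rat_equal(ft$n_ab, 205))
  expect_true(rat_equal(ft$n_a_nb, 115))
  expect_true(rat_equal(ft$n_na_b, 408))
  expect_true(rat_equal(ft$n_na_nb, 272))
  expect_true(rat_equal(ft$n_a, 320))
  expect_true(rat_equal(ft$n_b, 613))
  expect_true(rat_equal(ft$total, 1000))
  expect_false(ft$exact_counts)
  # margins recomputed from rounded cells, so additivity holds exactly
  expect_true(rat_equal(ft$n_a, ft$n_ab + ft$n_a_nb))
  expect_true(rat_equal(ft$total, ft$n_b + ft$n_nb))
})

test_that("require_integer names the offending quantity", {
  expect_error(to_frequencies(economics_situation(), 1000,
                              policy = "require_integer"),
               "P\\(A&B\\)")
  expect_silent(to_frequencies(mammography_situation(), 10000,
                               policy = "require_integer"))
  expect_error(to_frequencies(mammography_situation(), 0), "positive integer")
  s <- economics_situation(); s$N <- NULL
  expect_error(to_frequencies(s), "required")
})

test_that("frequency tables invert exactly to situations", {
  sit <- mammography_situation()
  ft <- to_frequencies(sit, 10000)
  back <- from_frequencies(ft)
  expect_true(rat_equal(back$cells, sit$cells))
  expect_equal(back$N, 10000)
  # the rounded economics table gives the rounded conditional 205/320
  fe <- to_frequencies(economics_situation(), 1000, policy = "round")
  site <- from_frequencies(fe)
  expect_true(rat_equal(situation_value(site, "P(B|A)"),
                        rational(205, 320)))
  expect_equal(situation_value(site, "P(B|A)", as = "numeric"), 0.640625)
})

test_that("degenerate and malformed tables are handled", {
  tb <- list(total = 50, n_a = 50, n_na = 0, n_b = 50, n_nb = 0,
             n_ab = 50, n_a_nb = 0, n_na_b = 0, n_na_nb = 0)
  sit <- from_frequencies(tb)
  expect_true(rat_equal(situation_value(sit, "P(A&B)"), 1))
  expect_null(situation_value(sit, "P(A|notB)"))
  tb$n_ab <- 40
  expect_error(from_frequencies(tb), "additivity violated for margin n_a")
  expect_error(from_frequencies(list(total = 10)), "needs entries")
})

test_that("natural frequencies pair nested reference-set counts", {
  sit <- mammography_situation()
  nf <- natural_frequency(sit, 10000, "P(A|B)")
  expect_true(rat_equal(nf$numerator, 160))
  expect_true(rat_equal(nf$denominator, 1140))
  expect_match(nf$reference_set, "positive test result")
  nf2 <- natural_frequency(sit, 10000, "P(A&notB)")
  expect_true(rat_equal(nf2$numerator, 40))
  expect_true(rat_equal(nf2$denominator, 10000))
  nf3 <- natural_frequency(sit, 10000, "P(B|A)")
  expect_true(rat_equal(nf3$numerator, 160))
  expect_true(rat_equal(nf3$denominator, 200))
  point <- complete_situation(c(1, 0, 0, 0))
  expect_error(natural_frequency(point, 100, "P(A|notB)"), "undefined")
  expect_error(natural_frequency(sit, 10000, "TOTAL"), "TOTAL")
})
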