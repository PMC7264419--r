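# Shared fixtures, all built in code.

mammography_events <- function() {
  event_pair("breast cancer", "positive test result",
             "no breast cancer", "negative test result")
}

# cells implied by base rate 2%, sensitivity 80%, false-positive rate 10%
mammography_situation <- function(N = 10000) {
  complete_situation(cell_distribution(0.016, 0.004, 0.098, 0.882),
                     mammography_events(), N = N)
}

economics_situation <- function(N = 1000) {
  complete_situation(cell_distribution(0.2048, 0.1152, 0.408, 0.272),
                     event_pair("attends the economics course",
                                "career-oriented",
                                "does not attend the economics course",
                                "not career-oriented"),
                     N = N)
}

# random exact cell distribution: a composition of D into four parts
random_cells <- function(max_den = 60, positive = FALSE) {
  if (positive) {
    D <- sample(8:max_den, 1)
    cuts <- sort(sample(seq_len(D - 1), 3))
  } else {
    D <- sample(4:max_den, 1)
    cuts <- sort(sample(0:D, 3, replace = TRUE))
  }
  parts <- diff(c(0, cuts, D))
  cell_distribution(rational(parts[1], D), rational(parts[2], D),
                    rational(parts[3], D), rational(parts[4], D))
}

rat_equal <- function(a, b) isTRUE(all(as_rational(a) == as_rational(b)))

# rational value stored in a diagram node/edge row
row_value <- function(row, secondary = FALSE) {
  if (secondary) rational(row$value2_num, row$value2_den)
  else rational(row$value_num, row$value_den)
}
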