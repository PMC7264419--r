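# Number formatting shared by the renderers: probabilities as percentages
# with trailing-zero trimming, counts with thousands separators ("1,140").

.fmt_pct_num <- function(pct, decimals = 1) {
  s <- formatC(round(pct, decimals), format = "f", digits = decimals)
  if (decimals > 0) {
    s <- sub("0+$", "", s)
    s <- sub("\\.$", "", s)
  }
  s
}

# rational or numeric probability -> "14%" / "0.45%"
.fmt_pct <- function(p, decimals = 1) {
  p <- if (is_rational(p)) as.numeric(p) else p
  paste0(.fmt_pct_num(p * 100, decimals), "%")
}

.fmt_count <- function(n, decimals = 0) {
  if (is_rational(n)) {
    if (!rat_is_integer(n)) return(format(n))
    n <- as.numeric(n)
  }
  formatC(n, format = "f", digits = decimals, big.mark = ",")
}

# rational -> JSON/YAML-friendly scalar: a plain number when the fraction is
# an exact decimal (denominator 2^a * 5^b), otherwise a fraction string
.rat_serialize <- function(r) {
  den <- r$den
  while (den %% 2 == 0) den <- den / 2
  while (den %% 5 == 0) den <- den / 5
  if (den == 1) as.numeric(r) else format(r)
}
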