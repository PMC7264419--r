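# freqnet

Exact analysis and visualization of probability situations with two
dichotomous events — the setting of Bayesian reasoning tasks and of
diagnostic-test statistics (base rate, sensitivity, false-positive rate,
positive predictive value).

A two-event situation carries sixteen probabilities: four marginals
P(A), P(¬A), P(B), P(¬B); four joints P(A∩B), …; and eight conditionals
P(A|B), P(B|A), …. Given any determining subset — for a screening test,
the base rate P(A), the sensitivity P(B|A) and the false-alarm rate
P(B|¬A) — the rest follow from Bayes' rule:

    P(A|B) = P(A)·P(B|A) / (P(A)·P(B|A) + P(¬A)·P(B|¬A))

`freqnet` completes such situations **exactly** (all internal arithmetic is
rational; 0.02 is 1/50, never a floating approximation), validates
assignments against the four algebraic rules of the *frequency net*
visualization (line, triangle, V, and X rules), converts probabilities to
natural frequencies ("160 out of 1,140"), builds 2×2 tables, tree diagrams,
double-trees and frequency nets as explicit node/edge structures rendered
to monospaced text or SVG, and encodes the catalogue of correct and
erroneous Bayesian answer strategies used to code participant responses
(joint-occurrence and Fisherian errors, p-/q-errors, the independence
error, double-tree branch confusions, …), including study-style correctness
coding with its exclusive interval bounds.

The package is aimed at researchers in statistics education and risk
communication who need to generate stimulus materials, check them for
internal consistency, and code numeric responses reproducibly — and at
anyone who wants exact two-event probability bookkeeping.

## Worked example

The classic screening situation: prevalence 2%, sensitivity 80%,
false-positive rate 10%, reference population 10,000.

```r
library(freqnet)

res <- solve_situation(
  c("P(A)" = 0.02, "P(B|A)" = 0.8, "P(B|notA)" = 0.1),
  events = event_pair("breast cancer", "positive test result",
                      "no breast cancer", "negative test result"),
  N = 10000)

situation_value(res$situation, "P(A|B)")
#> 8/57
natural_frequency(res$situation, 10000, "P(A|B)")
#> 160 out of 1,140 (P(A|B); reference set: those with positive test result)
```

The positive predictive value is exactly 8/57 ≈ 14.03%: of the 1,140 women
with a positive result (160 true positives + 980 false positives), only 160
actually have the condition. The frequency net shows all sixteen
probabilities and all nine counts at once:

```r
cat(render_text(build_net(res$situation, mode = "both")), sep = "\n")
#> [160] --P(A|B) = 14%-- [1,140] --P(notA|B) = 86%-- [980]
#>    \ P(A&B) = 1.6%   |   P(notA&B) = 9.8% /
#> P(B|A) = 80%      P(B) = 11.4%      P(B|notA) = 10%
#> [200] --P(A) = 2%-- [10,000] --P(notA) = 98%-- [9,800]
#> P(notB|A) = 20%      P(notB) = 88.6%      P(notB|notA) = 90%
#>    / P(A&notB) = 0.4%   |   P(notA&notB) = 88.2% \
#> [40] --P(A|notB) = 0.5%-- [8,860] --P(notA|notB) = 99.5%-- [8,820]
```

A response of "160 out of 10,000" to the conditional question is the
classic joint-occurrence error — the right numerator over the whole
population instead of the positive-test reference set:

```r
classify_response(builtin_tasks()$mammography, "conditional", c(160, 10000))
#> response 160 out of 10000 to the conditional question
#>           strategy distance exact
#> 1 joint_occurrence        0  TRUE
#> coded correct: FALSE
```

`render_svg()` draws any of the diagrams as SVG (joint branches dashed);
`render_problem()` assembles complete stimulus documents in the 2 contexts
× 2 formats × 4 visualizations design; `design_matrix()` enumerates the 16
versions and the 48 legal two-problem booklets. A command-line interface is
installed under `exec/`:

```sh
freqnet solve --in inst/extdata/mammography.json
freqnet render --task mammography --kind net --mode both --out net.svg
freqnet classify --task mammography --question conditional --answer "80%"
```

## Documentation

The methods vignette (`vignettes/frequency-net-methods.Rmd`) describes the
net's rule system, the exact solver and its feasibility enumeration, the
rounding and coding conventions, the strategy catalogue (including which
formulas are interpretive reconstructions), and the package's limitations.
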