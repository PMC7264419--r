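---
title: "The frequency net: exact completion, visualization, and error coding of two-event probability situations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The frequency net: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqnet)
```

## The problem

A situation with two dichotomous events A and B — in the canonical example,
*having breast cancer* and *receiving a positive mammogram* — carries sixteen
probabilities: four marginals, four joints, and eight conditionals. Bayesian
reasoning tasks give a determining subset of these (typically the base rate
P(A), the sensitivity P(B|A), and the false-positive rate P(B|¬A)) and ask
for an inverse conditional such as the positive predictive value P(A|B), or
for a joint such as P(A ∩ ¬B). People reason about such situations far more
successfully when the quantities are expressed as *natural frequencies* —
nested counts such as "160 out of 1,140" in one reference population — and
when the situation is visualized.

The classical visualizations are partial: the 2×2 table shows joints and
marginals but no conditionals; tree diagrams and double-trees show
conditionals and marginals but no joints. The *frequency net* is a nine-node,
sixteen-branch node-branch structure that shows all sixteen probabilities and
all nine absolute frequencies at once: a central total node, four margin
nodes on the axes, four cell nodes on the diagonals; marginal branches run
from the center horizontally and vertically, joint branches run diagonally
(drawn dashed), and the eight conditionals sit on the border between margin
and cell nodes. Unlike the double-tree it has no crossing branches and no
doubled node.

This package implements that structure computationally: exact completion of
a situation from partial information, validation, frequency conversion,
construction and rendering of the four visualizations, and executable
definitions of the correct and erroneous answer strategies used to code
responses in studies of Bayesian reasoning.

## The four net rules

The net's branches obey four families of algebraic constraints, which double
as the validation rules of `check_net_rules()`:

* **Line rule** — opposing branches from the center carry complements:
  P(A) + P(¬A) = 1 and P(B) + P(¬B) = 1.
* **Triangle rule** (the multiplication rule of the tree diagram) — in each
  of the eight right triangles, marginal × conditional = joint, e.g.
  P(B) · P(A|B) = P(A ∩ B).
* **V-rule** (the addition rule) — two adjoining diagonal branches sum to
  the enclosed marginal, e.g. P(A ∩ B) + P(A ∩ ¬B) = P(A).
* **X-rule** — the four joints sum to 1.

The four joint cells are therefore the canonical state: everything else
derives from them, and the rules hold *exactly, by construction* for every
completed situation. The package checks this at tolerance zero — there is no
floating-point slack anywhere in the validation path.

## Exact rational arithmetic

All internal arithmetic is exact rational (`rational()`, a small fraction
type over integer-valued doubles, overflow-guarded at 2^53). Decimals at the
API boundary are parsed exactly (`0.02` becomes 1/50; a value that is not an
exact decimal is rejected rather than approximated), and fraction strings
such as `"8/57"` are accepted everywhere. This matters because the
quantities of interest are exact fractions — the screening posterior is
8/57, the confusable conditional P(A|¬B) is 2/443 — and because rule
checking at tolerance zero would be meaningless under floating error. No
rational-arithmetic package ships with base R, and the exactness guarantees
are load-bearing for the whole design, so the type is implemented here;
probabilities and desk-scale counts stay far below the representable bound.

Conditionals conditioning on a zero-probability event are **undefined**, not
zero: they are omitted from derived assignments, render as unlabeled
branches, and raise an error in `natural_frequency()`. Degenerate situations
(point masses) are otherwise fully supported.

## The solver

`solve_situation()` turns each given quantity into a linear equation over
the four cells — a marginal is the sum of two cells, a joint is one cell,
and a conditional P(X|Y) = v contributes cell(X∩Y) − v · ΣY = 0 — adds the
normalization Σ = 1, and reduces the system by rational Gauss–Jordan
elimination:

* unique in-bounds solution → **complete** (all sixteen quantities derived);
* solution space of dimension ≥ 1 meeting the probability simplex →
  **underdetermined**, with the number of free degrees of freedom;
* otherwise → **inconsistent**, with the conflicting constraints and any
  net-rule violations instantiable from the given values.

Feasibility in the underdetermined case is decided exactly by basic-solution
enumeration: the polytope {Ax = b, 0 ≤ x ≤ 1} is bounded, so if it is
non-empty it has a vertex fixing at least (4 − rank) coordinates at a bound;
all such fixings are enumerated (at most a few dozen small rational solves).
A conditional given on an event whose probability the system *determines* to
be zero is reported inconsistent; in directions the system leaves free, the
marginal is not determined and no such conflict can be implied.

```{r solver}
res <- solve_situation(
  c("P(A)" = 0.02, "P(B|A)" = 0.8, "P(B|notA)" = 0.1),
  events = event_pair("breast cancer", "positive test result",
                      "no breast cancer", "negative test result"),
  N = 10000)
situation_value(res$situation, "P(A|B)")
natural_frequency(res$situation, 10000, "P(A|B)")
```

## Frequencies and rounding

`to_frequencies()` produces the nine expected counts N · p under three
policies. `exact` keeps rationals (possibly non-integral); `round` applies
schoolbook half-up rounding *per cell* and then recomputes margins and total
by additivity, so a frequency table can never violate its own additivity
invariants through rounding; `require_integer` refuses non-integral counts,
naming the offender. No continuity corrections or pseudo-counts are applied
anywhere — counts are expected counts.

The rounding policy is what reproduces the published course-choice stimulus:
with P(A) = 32%, P(B|A) = 64% and N = 1,000 the exact cell count is 204.8,
displayed as 205; the frequency-version answer 205 out of 613 therefore
differs slightly from the probability-version 64%. The built-in task stores
both parameterizations and flags the mutual inconsistency
(`rounding_note`).

## Diagrams

Four builders return the same explicit structure (`diagram_graph`): nodes
with roles (center/total, margin, cell, header) and grid positions, edges
with roles (marginal, joint, conditional), solid/dashed style, exact values,
and formatted labels. Three display modes: `prob` (labels on branches),
`freq` (counts in nodes), `both` (simultaneously — the net and the trees
support this; the 2×2 table cannot and rejects `both`). Structural facts
usable as tests: both tree orientations and both 2×2 tables embed in the
net; the double-tree has exactly one crossing pair of middle branches and
one doubled total node.

The geometry is a fixed layout table — center at the origin, margins on the
axes, cells on the diagonals at equal radius for the net — since only the
topology, not the metric layout, is prescribed by the visualization's
definition. Percent labels default to one decimal with trailing-zero
trimming; counts use thousands separators ("1,140").

The double-tree's middle branches carry conditionals in both reading
directions (downward conditioning on the first event, upward on the
second). The default SVG layout anchors both labels near the middle of each
branch, which on the two crossing branches reproduces a documented hazard:
the upward labels of the crossing pair (for the screening situation, 86.0%
and 0.45%) sit where they cannot be unambiguously assigned to a branch.
`disambiguated = TRUE` pulls the two labels of each branch apart to at least
`min_label_sep` pixels, anchored unambiguously near the branch ends. The
upward reading direction of the lower half is an interpretive choice: it is
inferred from which two values are confusable at the crossing, and recorded
here as such.

## The strategy catalogue and response coding

`builtin_strategies()` encodes the answer-generating rules as expressions
over the schematic letter map (lowercase = probabilities, uppercase =
counts): for conditional questions the correct Bayesian rule
`b·j/(b·j + m·c)` ("F out of D") plus seven documented errors
(joint occurrence, Fisherian, base rate only, evidence only, likelihood
subtraction, pre-Bayes, positive-rate/false-positive-rate ratio); for joint
questions the multiplication rule `b·q` ("H out of A") plus the p-, q-, m-
and n-errors, the independence error `b·e`, the double-joint error `2·h`,
and two double-tree branch confusions. The letters e, h, i (and uppercase
E, H, I) are inferred to complete the scheme symmetrically; the double-tree
confusion formulas (I = `l`, II = `e·l`) are reconstructed from the reported
confusion of the crossing branches carrying `p` and `l` — both inferences
are interpretive and flagged in the documentation. The ratio strategy `j/m`
can exceed 1 (it is 8 for the screening parameters); it is kept as defined
rather than clamped.

`classify_response()` matches a probability response within a tolerance
(default 0.5 percentage points) *or* within the study-style rounding
interval of a prediction; frequency pairs match only exactly. All matches
are returned ordered (exact first, then by distance, ties by catalogue
order) — where predictions collide, `strategy_collisions()` documents the
ambiguity instead of hiding it. `code_correct()` implements the coding rule:
a probability answer is correct inside [floor(exact%), ceil(exact%)], with
an exclusive bound wherever another catalogued prediction — rounded to the
one-decimal display precision — falls inside the interval. That
generalization reproduces the one documented case exactly: the correct
joint answer 0.4% for the screening task is accepted up to but excluding
0.5%, the displayed value of the p-error 2/443 ≈ 0.4515%. Free-text answers
("algorithm right, no final number") are out of scope; only numeric
responses are coded. The event order in the question wording is stored as
metadata but deliberately does not change predictions — it exists to
support studying order-provoked p- versus q-errors.

```{r coding}
task <- builtin_tasks()$mammography
classify_response(task, "joint", 0.005)   # the expected wrong solution
code_correct(task, "joint", 0.0045)       # inside [0.4%, 0.5%)
```

## Stimuli and design

`builtin_tasks()` carries the two contexts (screening, N = 10,000, all
counts integral; course choice, N = 1,000, rounded counts) with templated
cover stories, statistics sentences, and the two questions in the study's
fixed order (conditional first; a flag allows swapping for order-effect
research). `render_problem()` assembles any of the 16 versions — 2 contexts
× 2 information formats × 4 visualizations (text only, 2×2 table,
double-tree, net) — embedding the diagram *instead of* the statistics
sentences in visualization versions, with the format's answer blank shapes
(`"_______"` for probabilities, `"____ out of ____"` for frequency pairs).
Every number in a generated problem is computed from the task parameters
through the completion machinery; nothing numeric is hand-typed. The
frequency diagrams are built from the rounded table so they display the
stimulus counts. `design_matrix()` enumerates the 16 versions and the 48
legal two-problem booklets (both contexts, formats differing, visualizations
differing), shuffled deterministically by seed without touching the session
RNG.

## What the generated test data do and do not show

Property tests draw random exact cell distributions (compositions k/D with
denominators up to 60, strictly positive where conditionals must exist) and
check: rule closure at tolerance zero (1,000 draws in the acceptance suite),
exact solver round-trips through four catalogued determining subsets (40
situations × 4 subsets), frequency/serialization round-trips, and agreement
of the solver's status with an independent symbolic oracle (an exact
rational rank-and-vertex-enumeration solver written against a computer
algebra system in Python) on 36 small specs drawn from a denominator ≤ 20
grid. These are algebraic identities of the method, so passing them is
strong evidence of implementation correctness; they say nothing about
empirical phenomena — the generator produces exact textbook situations, not
noisy human data, and the participant-performance results reported for
these materials require the original response dataset, which this package
deliberately does not model.

## Numerical and design choices, in brief

* Exact rational state; decimal inputs parsed exactly; tolerance 0 is the
  default for rule checking (a caller-supplied absolute tolerance is
  available for externally rounded assignments).
* Undefined conditionals propagate as absent labels, never as 0.
* Rounding of counts: half-up per cell, margins recomputed by additivity.
* Coding intervals: floor/ceil on the percent scale with exclusive bounds
  at display-rounded colliding predictions.
* Tie-breaking in classification: exactness, then distance, then catalogue
  order; all matches are reported.
* The `both` display mode is refused for the 2×2 table.
* Problem sizes in the test suite (1,000 rule-closure draws, 160 solver
  round-trips, 36 oracle specs) keep the full run in well under a minute on
  one CPU while exercising every code path; the properties are
  scale-invariant, so larger samples add runtime, not information.

## Limitations

The frequency net, and hence this package, is limited to exactly two binary
events — the structure does not extend to 2-test or 3-test chains the way
tree diagrams do. All quantities are treated as givens, not estimates: there
is no sampling model, no confidence intervals, no tests. Rendering is
static (monospaced text and SVG); interactive or animated output is out of
scope.
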