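---
title: "Exact post-hoc comparison of Friedman rank sums: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact post-hoc comparison of Friedman rank sums: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frsd)
```

## The problem

A Friedman layout has `n` independent blocks (datasets, subjects, judges),
each ranking the same `k` groups (classifiers, treatments, methods) with the
integers `1..k`.  After a significant omnibus test — and often regardless of
it — the question of practical interest is pairwise: *which* groups differ?
The natural pairwise statistic is the difference in rank sums,
`D = R_i - R_j`, with support `[-n(k-1), n(k-1)]`.

The textbook critical differences for `D` are large-sample approximations.
They were derived for `n` large, yet the common benchmarking situation —
many methods, few datasets (`k` large, `n` small) — is exactly where they are
least trustworthy.  This package computes the *exact* discrete null
distribution of `D` and exact p-values, critical differences, and
multiple-comparison tables built on it, alongside the standard
approximations so the two can be compared on equal terms.

## The exact null distribution

Under the null hypothesis every within-block permutation of `1..k` is
equally likely.  A single block then contributes a difference
`t = r_i - r_j` with `k - |t|` of the `k(k-1)` ordered rank pairs realising
each `t` in `{-(k-1), ..., -1, 1, ..., k-1}` (a within-block difference of
zero is impossible without ties).  Because blocks are independent, the
distribution of `D` over `n` blocks is the n-fold convolution of this
per-block multiplicity vector, normalised by `{k(k-1)}^n`.

The package evaluates this distribution by two independent routes:

* `build_distribution()` performs the integer convolution directly — the
  transparent construction that serves as the oracle in the test suite;
* `count_compositions()`, `pvalue_ge()` and friends evaluate a closed-form
  composition-count expression derived from the probability generating
  function, reduced from a double to a single alternating binomial sum.
  This is the fast route: a p-value at `k = n = 100` takes well under a
  second, and a full exact critical-difference search at that size a couple
  of seconds.

The alternating sums cancel catastrophically in floating point — the terms
reach hundreds of digits — so all combinatorial work is done in exact
arbitrary-precision integer arithmetic implemented in C++ (`src/bignum.cpp`).
Probabilities are exact rationals (decimal numerator/denominator strings in
the API, e.g. in `exact_pvalue()`); doubles appear only at the reporting
boundary, where the quotient is formed from the leading 96 bits of each
operand and is accurate to far below display precision.

One convention matters and is not obvious: the binomial coefficients in the
composition-count formula must use the empty-product rule `C(a, 0) = 1` for
*every* integer `a`, including `C(-1, 0) = 1` (with `C(a, b) = 0` whenever
`b < 0` or `0 <= a < b`).  Under the stricter rule `C(a, b) = 0` for all
`a < b`, the point-count formula loses its `h = 0` term and is wrong at
`d = 0` for every design, which the convolution oracle exposes immediately.
The test suite pins this down by asserting exact equality of the three
evaluation routes (single sum, unreduced double sum, convolution) over all
`k <= 6`, `n <= 6` and every `d` in the support.

### p-values, folding and the mid p-value

Since the distribution is symmetric, two-sided p-values fold the signed
distribution: `P(D >= |d|)` is twice the one-sided tail for `d >= 1` and
exactly 1 at `d = 0` (doubling would exceed unity there).  The endpoints are
exact anchors: `pvalue_ge(0, k, n)` is identically 1 and
`pvalue_ge(n*(k-1), k, n)` is `2 {k(k-1)}^{-n}`.

Discreteness makes the exact test conservative, so `mid_pvalue()` implements
the usual remedy, half the point probability plus the strict tail:
`P_mid = P(D = d)/2 + P(D > d)`.  With midrank ties the observed `d` can be
an integer plus one half; the mid p-value of such a `d` is the average of
the exact p-values of the two adjacent integers, which coincides
algebraically with the mid-p definition.  Tied results are flagged, because
a mid p-value is not an exact frequency probability.

A subtlety worth recording: the reference table of "exact and mid p-values
at the unadjusted exact critical difference" pairs the exact p-value *at*
the critical difference CD with the mid p-value at the boundary `CD - 1/2`
(equivalently at `CD - 1`), i.e. the tied mid p-value of the last
non-rejected difference.  Reproductions in this package follow that layout.
Four of the fifty printed values in that reference grid differ from the
exact rationals in the final printed digit (all upward:
`.0440/.0494/.0487/.0499` printed against `.04395/.04935/.04865/.04985`
computed); the package reproduces the remaining forty-six to four decimals
and documents these four as printed-value artifacts, verified by three
mutually independent evaluation routes.

### Critical differences and exact search

`critical_difference(..., method = "exact")` finds the smallest `d` whose
Bonferroni-adjusted exact p-value is *strictly* below the familywise level.
The exact tail is non-increasing in `d`, so bisection over the support is
valid; every comparison `m * p(d) < alpha` is decided in integer arithmetic
(alpha is read as a rational at 12 decimal places), so no floating-point
boundary case can flip a decision.  When even the maximal difference
`n(k-1)` is not significant the function warns and returns `NA` — the
analogue of the out-of-support entries in published critical-difference
tables.

## The approximations

For comparison and for large designs the package provides the recommended
large-sample critical differences, all on the scale of rank-sum differences
with null variance `Var(D) = nk(k+1)/6`:

| method | quantile | familywise control |
|---|---|---|
| `normal` | `z_{alpha/(2m)}` | Bonferroni over `m` comparisons |
| `mvn` | two-sided equicoordinate point of `k-1` equicorrelated (rho = 1/2) standard normals | built-in (many-one) |
| `range` | Studentized range `q_{alpha, k, Inf} / sqrt(2)` | built-in (all-pairs) |
| `chisq` | `sqrt(chi^2_{alpha, k-1})` | built-in |

Two design choices here follow the published numbers rather than published
notation.  First, the normal critical differences are reproducible only
with the *two-sided* quantile `z_{alpha/(2m)}`, although the one-to-many
formula is sometimes typeset as `z_{alpha/c1}`; we follow the numbers.
Second, the equicorrelated-maximum point is the two-sided (Dunnett-type,
infinite-df) critical value: the one-sided point (about 2.16 at `k = 5`)
cannot reproduce the reference values, the two-sided one (about 2.44) can.

The `mvn` quantile is computed deterministically: with common correlation
one half, the coordinates are conditionally independent given a shared
latent factor, so the coverage probability is a one-dimensional integral
evaluated by adaptive quadrature (relative tolerance 1e-12) inside a root
search (tolerance 1e-9).  Reference implementations of this quantile often
use Monte-Carlo integration; five cells of the published
critical-difference table (at `(k, n)` = (10,100), (100,5), (100,10),
(100,50), (100,100)) sit on or near a ceiling boundary and come out one
unit higher under deterministic quadrature (116, 303, 428, 956, 1352; the
(10,100) case is extreme, with a true value of 115.017).  The package
reports the deterministic values.  One further printed cell, the all-pairs
normal critical difference at `(k, n) = (5, 25)`, prints 33 in the
reference table although the formula above gives `2.807 * sqrt(125) =
31.38 -> 32` under the stated rounding rule; we reproduce 32 and record the
disagreement.  Likewise a single printed Studentized-range p-value in the
qPCR application table (0.334 at `d = 23`) disagrees with both R's
`ptukey()` and an independent implementation (0.33347 -> 0.333).

All approximate critical differences are rounded *up* to the smallest
integer not below the calculated value; a value landing exactly on an
integer stays there (pure ceiling, no epsilon slack).  An approximate
critical difference may exceed the largest attainable difference
`n(k-1)`, in which case no pair can be significant by that method —
`cd_table()` keeps the value so the comparison with `max_d` stays visible.

The relative-error diagnostic `relative_error()` reports
`100 (P_normal(d - c) - P_exact(d)) / P_exact(d)` with optional continuity
correction `c = 0.5`.  Its sign structure is the practical story: the
normal tail *underestimates* large exact p-values and *overestimates* small
ones, increasingly so deep in the tail — which is precisely where
significance decisions live, and why the exact engine is worth having.

## Incomplete designs

Because blocks are independent, a design whose blocks split into complete
parts — say nine blocks ranking all twelve methods and one block ranking
only ten, the others being missing *by design* — has a total difference
`D = sum_t D_t` whose distribution is the convolution of the per-part
signed distributions.  `pvalue_parts()` convolves the exact per-part count
vectors (in integers, smallest support first purely for speed; the result
is order-invariant) and folds once at the end, exactly as in the complete
case.  A single part reduces to `pvalue_ge()` identically, and splitting a
common-`k` design into sub-blocks reproduces the complete answer rationally,
digit for digit — both are asserted in the tests.

The pair being compared must be present in every part: a part that contains
only one of the two groups contributes rank information about that group
alone and has no within-part difference to convolve.  The package therefore
restricts to pairs present throughout and rejects anything else; the
packaged cell-differentiation example satisfies this, since both compared
methods are ranked in all ten datasets.  Bonferroni multipliers for such
designs use the full group count (here `c1 = 11`, `c2 = 66`), matching the
published analysis.

## Synthetic data and what the tests show

`generate_null()` draws each block as an independent uniform permutation —
the null model itself, which is the study condition for every distributional
property asserted in the tests.  Optional tie injection replaces one
uniformly chosen adjacent rank pair per block (with a given per-block
probability) by midranks, preserving block sums while exercising the
half-integer mid-p path.  Seeding is explicit and scoped (`withr`), so a
seed fully determines the output without disturbing the caller's RNG.

`null_pvalue_uniformity()` computes all pairwise exact p-values on one
simulated null matrix.  With all null hypotheses true, p-values of a
continuous statistic would be uniform with mean 1/2 and variance 1/12; the
discrete exact p-values approach this as the support densifies.  The
acceptance checks run `k = 50, n = 5` and average over seeds 1–20: the mean
and variance land comfortably within 0.5 ± 0.03 and 0.0833 ± 0.01.  The
summary also reports a Kolmogorov distance of the `1 - p` sample against
the diagonal, but note it is a blunt instrument here: the 1225 pairwise
p-values are driven by only 50 underlying rank sums, and that strong
dependence makes single-realisation distances fluctuate around 0.05.  The
generator emulates the *null* only — no treatment effects, no between-block
dependence, no non-exchangeable noise — so passing tests certify the null
calibration of the machinery, not its power under alternatives, and say
nothing about whether a given real dataset satisfies the Friedman
assumptions.

A small empirical note on shape: at small designs the signed distribution's
modality alternates with the parity of `n` (per-block differences cannot be
zero, so an odd number of blocks favours odd totals): modes at ±1 for small
odd `n`, a single mode at 0 for even `n`, with the alternation fading as
`n` grows.  Statements that the small-`n` distribution is "bimodal at ±1"
hold for the odd-`n` cases only, so the package documents the observed
modality rather than asserting bimodality as an invariant.

## Packaged data

Two small fixtures ship with the package, both transcribed from published
comparisons: the rank sums of eleven qPCR curve-analysis methods over four
performance indicators (`qpcr_rank_sums()`), and the 12-method × 10-dataset
midrank table of a cell-differentiation benchmarking study
(`zagar_ranks()`), whose tenth dataset ranks only ten methods.  Their
transcription is validated structurally in the tests (every complete block
is a midrank permutation; the incomplete block sums to `10·11/2`).  A third
file, `qpcr_ranks_synthetic.csv`, is a *synthetic* 4 × 11 rank layout
constructed so its column sums equal the published qPCR rank sums; the
published study did not print its per-indicator ranks, and this stand-in
exists so file-reading examples and the command-line `compare` subcommand
have a complete layout to work on.

## Problem sizes, budgets and limitations

The test and acceptance workloads are desk-scale by construction: oracle
equivalence and moment identities on `k, n <= 6`; the full published
critical-difference and p-value grids up to `k = n = 100` (the complete
exact p/mid grid recomputes in roughly ten seconds; a single exact
critical-difference search at `k = n = 100` takes a couple of seconds);
applications at `(k = 11, n = 4)` and `(k = 12, n = 9) + (10, 1)`; and the
uniformity experiment at `k = 50, n = 5` over twenty seeds.

Out of scope by design: the exact joint distribution of all `k` rank sums
(the exact omnibus Friedman test), tie-corrected omnibus statistics,
rank-score t-tests (Rosenthal–Ferguson, Conover), step-down/step-up
multiplicity procedures (Bonferroni only, as in the reference tables),
finite-df Studentized range, saddlepoint or Laplace tail approximations,
and imputation of missing ranks (incomplete designs are handled only when
missingness is by design and blocks split into complete parts).
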