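---
title: "Kano-model demand analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kano-model demand analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanosurvey)
```

This vignette is the package's account of the statistical procedure it
implements, the choices that were genuinely open, and what its synthetic
data can and cannot show.

## The classification model

Each service attribute is probed with a functional question ("if provided,
how would you feel?") and a dysfunctional question ("if not provided?"),
both on the five-level scale *like / must be / neutral / live with /
dislike* (integer codes 1–5). The pair is looked up in the standard 25-cell
Kano evaluation table (`kano_evaluation_table()`), whose cell histogram is
A: 3, O: 1, M: 3, I: 9, R: 7, Q: 2. The two questionable (Q) cells are the
contradictory extremes — "like" to both provision and absence, or "dislike"
to both. Classification is a pure lookup: no parameters, no randomness.

## Per-attribute statistics

For an attribute with tallies $M, O, A, I, R, Q$ over $n$ respondents:

* **Final category** — the argmax over $\{M, O, A, I, R\}$. Q is tallied
  and reported but can never be a final category: a questionable answer
  indicates a response error, not a demand judgement. Published tables
  never encounter ties, but arbitrary data can; we fix the deterministic
  priority $M > O > A > I > R$ (most to least demanding of provision) so
  repeated runs on identical data always agree. This priority is our
  choice, documented here, not something the field standardises.
* **Category strength** $= 100\,(\text{largest} - \text{second largest})/n$,
  with $n$ including Q and R responses. Recomputing published tables
  confirms this denominator (e.g. tallies 105/88/73/73/7/2 give
  $100 \cdot (105-88)/348 = 4.89$, the printed value).
* **Total strength** $= 100\,(M+O+A)/n$ — the proportion of respondents
  wanting the service. Together with $100\,(I+R+Q)/n$ it closes to 100%.
* **Better** $= 100\,(A+O)/(A+O+M+I)$ and
  **Worse** $= 100\,(O+M)/(A+O+M+I)$: the expected satisfaction gain from
  providing, and dissatisfaction from withholding, the attribute. The
  formulas exclude Q and R from numerator and denominator, which published
  values confirm row by row.

Reported values are rounded to two decimals **half away from zero**:
published tables print e.g. $289/348 \cdot 100 = 83.0459...$ as 83.05,
which base R's round-half-even would sometimes miss. Raw values are kept
internally; pass `digits = NULL` to any metric function to get them.

## The Better–Worse plot

Attributes are placed at $(\text{Worse}, \text{Better})$ and labelled by
quadrant at a threshold of 50%: high Better/low Worse is Attractive,
high/high One-dimensional, low/high Must-be, low/low Indifferent, with a
coordinate exactly at the threshold counting as high. The fixed 50%
threshold is the field's convention and is concordant with the modal final
category for all 15 bundled attributes; `better_worse_points()` accepts
any threshold in (0, 100) should a data-driven cut (e.g. the mean of the
coefficients) be preferred.

## Group comparison

Demand differences between two respondent groups are tested per attribute
with a two-sided Mann–Whitney/Wilcoxon rank-sum test on the classified
categories. Three choices deserve explanation:

* **Ordinal encoding.** A rank test needs the six categories on an ordinal
  scale, and reports that print rank-sum Z values for Kano outcomes rarely
  state their coding. The default here is descending demand intensity
  M = 5, O = 4, A = 3, I = 2, R = 1, Q = 0. On the bundled two-group
  tables this default reproduces the published qualitative conclusion
  (every attribute p > 0.05) and tracks the published |Z| values closely,
  but since the original coding is unstated we assert only the qualitative
  conclusion, and the encoding is a user-settable argument.
* **Engine.** Mid-ranks with tie-corrected variance and the normal
  approximation, no continuity correction by default (a toggle exists) —
  categories produce heavy ties, for which this is the standard treatment,
  and printed Z statistics imply the normal approximation. For pooled
  samples of at most 12 observations the p-value instead comes from
  complete enumeration of all rank assignments. Z is reported as a
  magnitude alongside the signed statistic.
* **Multiplicity.** Fifteen attributes mean fifteen tests; no adjustment
  is applied by default, matching how such tables are published, and
  `adjust` accepts any `p.adjust` method for stricter error control.

Questionable respondents are included in the test by default (published
per-group tables report their tallies); `include_q = FALSE` drops them.
Because every statistic depends only on category tallies,
`kano_compare_counts()` can run the identical test directly from per-group
count rows, and tests verify it agrees exactly with the respondent-level
route.

## Survey validation

A survey CSV row is excluded as *incomplete* when any of its 2K answers is
missing or unparseable (problems are collected with the respondent id and
column). A respondent is excluded as *questionable* when more than a
configurable fraction (default 50%) of their pairs classify as Q — reports
of such surveys exclude a handful of respondents for "questionable
answers" without stating the rule, so this default is ours; attribute-level
Q answers below the fraction are retained, which is why count tables carry
nonzero Q tallies. The effective rate is 100·valid/received.

The sample-size helper implements the cross-sectional rule of thumb of
10–20 respondents per independent variable, inflated by the anticipated
dropout rate: with 15 variables and 20% dropout, 180–360 respondents.

## Synthetic respondents

`simulate_kano_survey()` draws, independently per attribute, a category
from that attribute's mixture and then an answer pair uniformly among the
evaluation-table cells of that category, so classification round-trips to
the generating category by construction. Defaults are the bundled study's
conditions: n = 348, the empirical per-attribute category mixtures, and
covariates drawn from the study's sociodemographic margins (a joint
city-by-residence cell plus independent gender, age band, education and
living condition). The base-R Mersenne–Twister generator is used; the seed
argument is recorded in the dataset's attributes and a fixed seed gives
identical output.

What the generator does **not** emulate: correlations between attributes
within a respondent (each attribute is drawn independently), any dependence
of answers on covariates, and instrument-level properties such as
test–retest reliability. Passing tests on simulated data therefore
demonstrate correctness of the computational pipeline under known category
mixtures — not robustness to the response structure of real populations.

`reconstruct_kano_survey()` goes the other way: given per-attribute
category counts it builds a dataset of exactly n respondents that tabulates
back to those counts. Cell assignment is deterministic — each category's
quota is filled with its first evaluation-table cell in row-major order,
categories in the order M, O, A, I, Q, R — making fixtures byte-stable.
Any assignment consistent with the counts yields identical downstream
statistics, since all of them depend only on the tallies.

## Numerical and degenerate-input choices

* Empty surveys, all-zero count vectors, and attributes whose
  $A+O+M+I = 0$ (Better/Worse undefined) raise errors rather than NaN.
* Two groups with identical pooled values have zero rank-sum variance; the
  test returns Z = 0, p = 1 with a warning instead of dividing by zero.
* Mixture probability vectors must be non-negative and sum to 1 within
  1e-9.
* Count-table inputs are validated (non-negative integers, tallies summing
  to n) before any statistic is computed, and the bundled study tables
  re-check their published marginal totals on every access.

## Verification problem sizes

The test suite checks the statistical guarantees at sizes chosen to give
tight Monte-Carlo error at interactive runtimes: the generator round-trip
over 10,000 seeded draws; reconstruction identity over 200 random count
vectors up to n = 500; mixture recovery at n = 10,000 within 0.02; modal
final-category recovery over 500 replicates at n = 348; and type-I error
of the rank-sum test over 2,000 replicates of two groups of 100 drawn from
one category mixture, required to land in 0.05 ± 0.02.

## Known limitations

* The final-category tie-break and the ordinal encoding for the rank test
  are documented conventions, not field standards; conclusions that hinge
  on them deserve a sensitivity check (both are arguments).
* The rank-sum normal approximation is asymptotic; for very small groups
  the exact path covers only pooled sizes ≤ 12 by default (raise
  `exact_max` at combinatorial cost).
* Frequency summaries of covariates are purely descriptive; no weighting
  or design effects are implemented.
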