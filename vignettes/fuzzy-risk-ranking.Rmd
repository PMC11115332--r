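---
title: "Fuzzy FMEA and hybrid multi-criteria risk ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy FMEA and hybrid multi-criteria risk ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzrisk)
```

## The problem

Failure Modes and Effects Analysis (FMEA) prioritises risks by scoring each
failure mode on three factors — Occurrence (O), Severity (S) and Detection
(D) — and multiplying them into a Risk Priority Number. In clinical
settings such as post-transplant patient care, those scores come from
expert panels speaking in words ("very high", "dangerous without warning"),
not in calibrated numbers. `fuzzrisk` models that linguistic uncertainty
with triangular fuzzy numbers (TFNs), scores failure modes with fuzzy risk
priority numbers, ranks them with three fuzzy multi-criteria methods (ARAS,
VIKOR, WASPAS), and — because different MCDM methods routinely disagree on
mid-field ranks — merges the three rankings into a single, more robust one
through an ideal-distance hybrid.

## Triangular fuzzy numbers

Every fuzzy quantity is a TFN $(\alpha, \beta, \gamma)$ with
$\alpha \le \beta \le \gamma$: membership rises linearly from $\alpha$ to 1
at the modal value $\beta$ and falls back to 0 at $\gamma$. Arithmetic is
componentwise — addition $(a{+}d, b{+}e, c{+}f)$, multiplication
$(ad, be, cf)$, non-negative scaling — and is restricted to non-negative
supports, which every rating scale here satisfies. Constructors reject
unordered triples by default; the explicit `repair = "sort"` mode exists
because componentwise *subtraction* (used inside fuzzy VIKOR) can disorder
a triple legitimately. Silent re-ordering elsewhere would hide data-entry
errors, so it is opt-in.

Two defuzzifiers are provided:

* `centroid_mean`, $(\alpha + \beta + \gamma)/3$ — the centre of area of
  the triangle; used throughout the rankers.
* `graded_mean` / `likert_mean`, $(\alpha + 4\beta + \gamma)/6$ — the
  graded-mean integration value; used for expert Likert triples. The two
  names share one formula and exist only for call-site clarity.

They coincide exactly when the triangle is symmetric about $\beta$.

Fuzzy "max"/"min" (needed for ideal rows and best/worst values) are taken
under a total order: defuzzified value first, ties broken by $\beta$, then
$\alpha$, then $\gamma$. The ordering rule is a package design decision;
the underlying methods leave it unstated.

## Rating scales

Occurrence and Severity use nine-level ladders of unit-spaced TFNs from
$(1,2,3)$ up to $(9,10,10)$; Detection uses a coarser ladder from $(1,1,3)$
("very high chance of discovery") to $(8,10,10)$ ("no realistic chance"),
so *larger values always mean more risk*. The output scale for the fuzzy
RPN places five categories VL–VH on $[0,1]$.

Two scale quirks deserve a note. The worked example's published occurrence table
duplicates the severity wording verbatim (a typesetting slip), so the
default occurrence scale keeps the nine severity TFNs but carries
conventional occurrence labels (Remote … Very High) chosen so that every
occurrence grade appearing in the worked example resolves. The worked
example also grades two failure modes' detectability "Very Low", a label
missing from the printed detection scale; the default scale carries it at
$(8,10,10)$, the same grade as "Remote", reading it as "no realistic chance
of detection". Both scales are plain data and fully user-overridable via
`read_scales()`.

## Expert aggregation and the fuzzy RPN

Each expert rates each failure mode on each factor; the panel consensus is
the expert-weight-weighted componentwise mean (`aggregate_experts()`).
Expert weights default to uniform — the worked example assigned distinct
weights but did not publish them. The multiplicative fuzzy RPN is the
componentwise triple product $O \times S \times D$, defuzzified by centroid
and labelled with the nearest output category (nearest centroid, ties to
the higher category — the assignment rule behind labels like "VH 0.93" is
another unstated detail we had to fix).

## Mamdani inference

`mamdani_infer()` implements the classic max–min pipeline: fuzzification
of crisp inputs, rule firing strengths (min for AND, max for OR), clipping
(min) implication, pointwise-max aggregation over a sampled output grid,
and discrete centroid defuzzification $\sum x\mu(x) / \sum \mu(x)$.
Universes are $[1,10]$ for the three inputs and $[0,1]$ for the output;
the default grid has 1001 points (doubling it moves outputs by less than
half a coarse grid step; see the convergence test). TFN inputs are
fuzzified at their defuzzified value, matching the practice of aggregating
the panel before inference.

The worked example's own rule base was never published, so its printed
crisp outputs (0.930, 0.911, …) are *not* reproduction targets and are
carried only as reference metadata. `default_rule_base()` supplies a
deterministic, complete, monotone stand-in: the consequent of each input
combination is the output category at the rounded mean of the three
antecedent ordinal positions (each rescaled to $[0,1]$ within its ladder).
Users can supply their own rule base as JSON.

## The three fuzzy rankers

All three operate on a `fuzzy_decision_matrix()`: one TFN per (failure
mode, factor), benefit direction (more is riskier) and equal crisp weights
$1/3$ by default.

**F-ARAS** appends a hypothetical ideal row (per-criterion fuzzy max),
normalises each column, weights, sums, and defuzzifies into the optimality
score $S_i$; the utility degree $K_i = S_i / S_0$ compares each failure
mode with the ideal, so $0 < K_i \le 1$. Fuzzy division by a fuzzy column
sum has no standard definition; we divide components by the
*crisp* (defuzzified) column sum, which preserves the TFN ordering, cannot
invert spans, and is exact for crisp inputs. This normalisation dialect is
the main reason third-decimal reproduction of the published per-method
indices is not claimed.

**F-VIKOR** computes, per criterion, weighted normalised distances to the
fuzzy best value; their sum is the group utility $S_i$, their maximum the
individual regret $R_i$, merged into $Q_i$ with trade-off $v = 0.5$.
Computation stays fuzzy through the merge: componentwise differences are
re-sorted when disordered, and only the final values are defuzzified.
Because the centroid mean is permutation-invariant in the three
components, the re-sort never changes the defuzzified result — which also
guarantees $Q_i \in [0,1]$ exactly. Constant criteria (best = worst)
contribute zero with a warning; an all-constant matrix is an error. The
standard acceptability conditions are evaluated, and the compromise set is
enlarged in the usual way when one fails.

**F-WASPAS** normalises each column componentwise against its fuzzy
extreme, then blends the weighted-sum utility $Q_i$ and weighted-product
utility $P_i$ into $K'_i = \lambda Q_i + (1-\lambda) P_i$ with
$\lambda = 0.5$ (or the data-driven
$\lambda = \sum P / (\sum Q + \sum P)$ via `lambda = "auto"`). With
normalised entries and weights summing to one, $P_i \le Q_i$ by the
weighted AM–GM inequality, and the row matching every column maximum
scores exactly 1.

## The hybrid ultimate utility index

The hybrid stage works on plain numbers: a matrix of per-method benefit
indices in $[0,1]$ — ARAS $K_i$, VIKOR transformed to the efficiency form
$1 - Q_i$, WASPAS $K'_i$ (any number of method columns is accepted; three
is the default). Per column, the maximum $\eta^+$ and minimum $\eta^-$ over
the failure modes form the positive and negative ideal vectors — the
max/min scope is per-column over the matrix itself, the reading verified to
reproduce the worked example exactly. Each row's Euclidean distances
$\psi^+_c$, $\psi^-_c$ to the ideals are normalised by their column sums
and differenced:

$$ UUI_c \;=\; \frac{\psi^-_c}{\sum_c \psi^-_c} \;-\;
               \frac{\psi^+_c}{\sum_c \psi^+_c} \in [-1, 1], $$

so the indices sum to zero and a higher value means higher risk priority.

```{r hybrid}
t7 <- load_fixture("table7")
h <- hybrid_rank(t7)
head(h$table[order(h$table$rank), ], 5)
```

Fed the packaged 20-row index matrix, the hybrid reproduces the published
distance and utility columns to within a few units in the sixth decimal —
the residual is exactly the quantisation of the published inputs, which
are printed rounded to $10^{-6}$. Four failure modes (FM2, FM3, FM12,
FM13) carry *identical* index rows, so their utilities tie exactly;
the published table breaks that tie arbitrarily across ranks 5–7 (and
prints one of the four with a last-digit discrepancy), whereas this
package applies competition ranking throughout: tied entries share the
minimum rank of their block, stable in input order.

## Synthetic registers and what the tests show

`generate_register()` emulates the study design — twenty failure modes
rated by a five-expert panel with uniform weights by default — with two
testing handles: a *dominance chain* (a fraction of failure modes whose
grades decrease componentwise, strictly on O and S, so their true order is
known by construction; capped at the nine-level ladder length) and
category-jitter *noise* applied per expert (default 0.1, a mild
disagreement level typical of elicitation panels; the chain default 0.3
keeps most of the register unconstrained). Seeded runs are reproducible.

The property suites run the rankers on 100 seeded noiseless chains of
length six (small enough for strict dominance, large enough to exercise
every ranking path) and require exact recovery by the fuzzy RPN, all three
MCDM rankers and the hybrid; conservation of the hybrid's distance shares
is checked on 1000 random index matrices to $10^{-9}$; the centroid
defuzzifier is checked against adaptive quadrature; and the Mamdani engine
is checked for grid convergence, monotonicity, and agreement with an
independent straightforward reimplementation. What passing these tests
shows is internal consistency and faithfulness to the stated formulas on
idealised inputs; it does not validate the linguistic scales against real
clinical frequencies, cover correlated expert error, or certify the
default rule base as a model of any particular panel's reasoning.

## Known limitations

* The three MCDM rankers reproduce the worked example at the ordinal
  level (the riskiest failure mode first); their third decimals depend on
  unpublished details (exact expert-level inputs, weightings, and fuzzy
  normalisation dialects), so the bit-exact surface is the hybrid stage.
* The expert-agreement percentages quoted alongside the worked example
  have no published formula; the package ships generic rank-agreement
  statistics (Spearman, Kendall, top-k overlap) instead.
* Only triangular fuzzy numbers are supported — no trapezoidal or type-2
  shapes, and no alpha-cut interval arithmetic.
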