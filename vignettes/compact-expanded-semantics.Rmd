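---
title: "Weighted UniFrac significance under compact and expanded tree semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted UniFrac significance under compact and expanded tree semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wunifrac)
```

## The model

Weighted UniFrac compares two communities placed on a shared rooted
phylogeny. Each leaf is an OTU; an *environment table* assigns each leaf a
count of individuals per sample. Branch lengths may be any non-negative
distance (typically sequence edit distances, but the method only assumes a
metric). For a pair of samples with totals $A_T$, $B_T$ and, on each branch
$i$ of length $b_i$, the number of individuals $A_i$, $B_i$ descending
through it:

$$u \;=\; \sum_i b_i \left| \frac{A_i}{A_T} - \frac{B_i}{B_T} \right|,
\qquad
U \;=\; \frac{u}{\sum_j d_j \left( \frac{A_j}{A_T} + \frac{B_j}{B_T} \right)},$$

with $d_j$ the root-to-leaf depth of leaf $j$. $U \in [0,1]$: it is 0 iff
the samples have identical relative abundance at every leaf and 1 when all
shared branch length is zero. Inside the package the denominator is
accumulated **per branch** as $\sum_i b_i (A_i/A_T + B_i/B_T)$, which equals
the per-leaf form by exchanging the order of summation along each
root-to-leaf path. We use the branch form for a numerical reason discussed
below.

The significance test randomly reassigns the leaf annotations and reports

$$p \;=\; \frac{\#\{\text{labelings with } U_{\text{null}} \ge U_{\text{obs}}\}}
             {\#\{\text{labelings}\}} .$$

## Compact and expanded forms, and why they disagree

The same data can be written with abundance counts on leaves (*compact*) or
with one unit-count leaf per individual joined by zero-length branches
(*expanded*). `expand_tree()` and `collapse_tree()` convert between the two;
the transform is invertible, conserves per-sample totals, and leaves every
weighted UniFrac distance unchanged — a branch of length exactly zero means
"identical", by the coincidence axiom of metrics.

The permutation test, however, depends on what a "labeling" is:

* **compact semantics** shuffle each leaf's whole annotation bundle (its
  sample:count pairs) as an indivisible unit across leaves;
* **expanded semantics** shuffle unit labels across the expanded leaves.

On the two-leaf tree with counts (4, 4) the compact null space has
$2! = 2$ labelings, both symmetric images of the observed one, so $p = 1$
always — even with counts of 10,000 on branches of length 0.9, i.e. two
large, disjoint, distant communities. The expanded null space has
$\binom{8}{4} = 70$ distinct labelings of which only the original and its
mirror attain the observed distance, so $p = 2/70 \approx 0.029$. Both
numbers are reproduced by `unifrac_signif()` and checked in the test suite.
We take no position on which semantics is "right"; the package's job is to
make the choice explicit. The expanded form is arguably more robust: if the
zero-length branches are replaced by small positive lengths (as happens
when sequences are clustered at less than 100% identity), the expanded
p-value moves continuously (the suite checks that $\varepsilon = 0.01$
changes it by less than 0.01), while the compact p-value jumps to 1.

## Null distributions

`method = "exact"` enumerates every **distinct** arrangement of the
annotation multiset exactly once. A uniform random shuffle of $n$ items
induces the uniform distribution over distinct arrangements (each
corresponds to exactly $\prod_k m_k!$ of the $n!$ orderings, for
multiplicities $m_k$), so equal weighting is multiplicity-correct; the
tests verify this against a brute-force enumeration of all $n!$ orderings.
Enumeration is capped at $10^6$ arrangements (about the most that is
comfortably evaluated in memory at once); beyond the cap the function
directs you to Monte-Carlo.

`method = "mc"` draws `n_perm` independent shuffles. The default
`n_perm = 100` mirrors the historical web-service default and is
deliberately kept — it is the setting under which the discrepancy was
observed — but it is statistically coarse: the standard error of a p-value
near 0.03 at $n = 100$ is about 0.017. The `seed` is recorded in every
result. The estimator is the plain fraction $n_{\ge}/n_{\mathrm{null}}$,
which matches the original definition and can legitimately return 0;
`plus_one = TRUE` gives the $(n_{\ge}+1)/(n_{\mathrm{null}}+1)$ correction
recommended in the modern permutation-test literature.

For multi-sample trees, each pair's test uses only that pair's counts
(other samples' individuals are excluded), and bundles are shuffled across
**all** leaves by default, leaves empty for the pair acting as empty slots
(`scope = "occupied"` restricts shuffling to annotated leaves; the
historical tool's multi-sample behavior is not documented, so both are
provided).

## Numerical choices

* **Tie detection.** The test counts $U_{\text{null}} \ge U_{\text{obs}}$
  with a relative tolerance of $10^{-9}$ on the equality side. Symmetric
  images of the observed labeling must tie; accumulation order is fixed, so
  ties are exact in practice and the tolerance only guards platform drift.
* **Bitwise transform invariance.** Distances on a tree and on its
  expansion are *bitwise* identical, not merely close. This falls out of
  two choices: the per-branch denominator (expansion then only inserts
  terms that are exactly 0, and $x + 0 = x$ exactly), and a fixed
  post-order edge sequence for every sum (expansion interleaves new edges
  without permuting the surviving ones). The per-leaf denominator would
  break this: a leaf of count 3 contributes $3 \cdot \tfrac{1}{3} \ne
  \tfrac13+\tfrac13+\tfrac13$ bitwise.
* **Exact zero test.** `collapse_tree()` collapses only branches of length
  exactly 0 by default; an explicit `tol` is available. An implicit epsilon
  would silently change which trees count as equivalent.
* **Missing branch lengths** are a hard parse error unless the caller
  supplies a substitute, for the same reason: a silent default of 0 would
  manufacture collapsible branches.
* **Degenerate input.** If every individual of both samples sits at depth
  0 the normalized distance is 0/0; the user-facing function raises an
  explicit error. Inside the null loop such labelings are scored as
  distance 0 (they can only arise when the observed distance is also
  degenerate-free, so they never inflate $n_{\ge}$ incorrectly).
* **Serialization.** Branch lengths are written with the fewest digits
  that reparse to the identical double, so round-trips are exact and files
  stay readable.

## The fixture generator

`gen_labeled_tree(fixture_spec(...))` emulates small OTU phylogenies:
random recursive bifurcation with occasional multifurcation, branch lengths
uniform on `[0.05, 1]` (a typical within-gene substitution-distance scale),
counts uniform on `1:max_count` (default 4, the scale of the worked
examples), an optional fraction of branches at exactly 0, about 20% of
leaves carrying a second sample label, and guaranteed coverage of every
sample. Everything is deterministic given the spec's seed.

What it does **not** emulate: realistic tree shapes (coalescent or
birth–death imbalance), realistic abundance distributions (log-series
skew, thousands of singletons), sequencing noise, or sample sizes in the
tens of thousands. Passing property tests on these fixtures demonstrates
the algebraic contracts (round-trips, invariances, enumeration
correctness) — it does not calibrate statistical power on real surveys.

## Problem sizes in the test suite

Exact-enumeration cross-checks against the all-orderings brute force use
trees of 4–5 leaves (null spaces up to a few thousand orderings);
Monte-Carlo/exact agreement is checked at $10^5$ permutations on 5-leaf
fixtures against the 99.9% binomial interval; transform and distance
invariances run on 50–200 random fixtures of up to 12 leaves; agreement
with an independent ecosystem implementation (phyloseq, after resolving
multifurcations to binary with zero-length branches, which its fast path
requires) is checked to $10^{-10}$ on 50 fixtures.

## Known limitations

* Only the weighted variant is implemented; unweighted, generalized and
  variance-adjusted UniFrac are out of scope.
* Trees must be rooted; no re-rooting heuristics are attempted.
* Exact enumeration is practical only for small null spaces (the cap is
  $10^6$ distinct arrangements); real surveys will use Monte-Carlo.
* Sample-level metadata, rarefaction and ordination are left to the
  ecosystem packages this one interoperates with.
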