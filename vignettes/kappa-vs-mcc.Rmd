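---
title: "When Cohen's Kappa disagrees with the Matthews Correlation Coefficient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{When Cohen's Kappa disagrees with the Matthews Correlation Coefficient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappamcc)
```

## The two statistics

Both Cohen's Kappa and the Matthews Correlation Coefficient (MCC) evaluate
a classifier from its confusion matrix $C$, the $N \times N$ table whose
entry $C_{ij}$ counts testing cases of actual class $i$ assigned to class
$j$.  Writing $S$ for the grand total, $r_i$ and $c_i$ for the row and
column sums,

$$\mathrm{Acc} = \frac{\sum_i C_{ii}}{S}, \qquad
  P_e = \frac{\sum_i r_i c_i}{S^2}, \qquad
  K = \frac{\mathrm{Acc} - P_e}{1 - P_e},$$

and MCC is the Pearson correlation between the one-hot indicator encodings
of the actual and predicted classes, averaged over classes, which reduces
to the closed form

$$\mathrm{MCC} = \frac{S \sum_k C_{kk} - \sum_k r_k c_k}
  {\sqrt{S^2 - \sum_k r_k^2}\,\sqrt{S^2 - \sum_k c_k^2}}.$$

`mcc_multiclass()` implements the closed form with the $O(N^2)$
marginal-sum numerator; `mcc_indicator_oracle()` implements the
definition directly by expanding the matrix into its $S \times N$
indicator matrices and averaging per-column covariances.  The two code
paths share nothing, and their agreement (to $10^{-10}$ over thousands of
random matrices) is one of the package's standing tests.  For $N = 2$ the
closed form collapses to $(ad - bc)/\sqrt{(a+b)(b+d)(a+c)(c+d)}$ for the
cell layout $\bigl(\begin{smallmatrix} a & b \\ c & d
\end{smallmatrix}\bigr)$.

Both statistics are invariant under multiplication of the matrix by a
positive constant, so all of the parametric families below may use
real-valued representatives of their integer equivalence classes.  All
metric functions require every row and column sum to be positive;
degenerate marginals raise errors rather than propagating `NaN`, because
the statistics are genuinely undefined there (a matrix with all mass in
one diagonal cell has $\mathrm{Acc} = P_e = 1$).

Three structural facts anchor everything else:

* **Symmetric matrices:** if $C = C^T$ then $K = \mathrm{MCC}$ exactly.
* **Binary decomposition:** with $\alpha = (ad-bc)/((a+b)(b+d))$ and
  $\beta = (ad-bc)/((a+c)(c+d))$, Kappa is the harmonic and $|\mathrm{MCC}|$
  the geometric mean of $(\alpha, \beta)$; hence
  $0 < K \le \mathrm{MCC}$ when $ad > bc$ and
  $\mathrm{MCC} \le K < 0$ when $ad < bc$.
* **No false positives ($c = 0$):** $K = 2m^2/(1+m^2)$ with
  $m = \mathrm{MCC}$, a monotone link, so the two statistics cannot
  disagree in direction; their largest gap, found by maximizing
  $m - 2m^2/(1+m^2)$, is about $0.13$ near $m = 0.3$ (`c0_max_gap()`).

## The incoherence being diagnosed

Along several one-parameter families the classification gets strictly
worse as the parameter grows, MCC decreases monotonically — and Kappa
does not.  The package provides each family as a `family_spec()` with a
generator, a domain and a default grid:

* the one-false-positive binary families `[[a, b], [1, d]]` (sub-cases
  `C1_equal_diag`, `C1_zero_d`, `C1_unit_d`), swept in the
  false-negative cell $b$;
* the `ZA` family (all ones, top-right cell $A$) in any dimension;
* five 3x3 families `M1`–`M5` whose layouts decouple the diagnostics
  below.

For each of these, Kappa's interior minimum has a closed form
(`kappa_min_closed_form()`): $b_0 = a^2 + (a+1)\sqrt{a^2+1}$ for
`C1_equal_diag`, $\sqrt{a+1}$ for `C1_zero_d`, $a + \sqrt{2}(a+1)$ for
`C1_unit_d`, and $A^* = 1 + N\sqrt{N(N-1)}$ for `ZA`.  These expressions
were re-derived from the stationarity conditions of the explicit Kappa
formulas (for example, for `ZA`, $K(A) = N(1-A)/[(1-A)^2 - 2N(N-1)(1-A)
+ N^3(N-1)]$, whose stationarity reduces to $(1-A)^2 = N^3(N-1)$), and
each is pinned by a test against `find_kappa_minimum()`, a deterministic
coarse-grid scan (200 points, geometric when the bracket is positive)
followed by golden-section refinement to $10^{-8}$.  A wrong closed form
cannot pass silently.

## The diagnostics and the regime rule

Two structural measures of the matrix separate the benign from the
pathological sweeps:

* **Asymmetry** `asymmetry()`: the Frobenius norm $\lVert M - M^T
  \rVert$.  Zero iff the matrix is symmetric; scales linearly with the
  counts.
* **Off-diagonal entropy** `offdiag_entropy()`: base-2 Shannon entropy of
  the normalized $N^2 - N$ off-diagonal cells, with $0 \log 0 = 0$.
  Ranges over $[0, \log_2(N^2 - N)]$; measures how evenly the
  misclassification mass is spread.  Base 2 and the zero convention are
  both forced by the reference values the tests reproduce (e.g.
  $\mathrm{Ent}(M_2(10)) = 0.7135$; base $e$ would give $0.4946$).

The empirical rule — and the content of `classify_regime()` — is that
Kappa moves against MCC exactly when the off-diagonal entropy decreases
to zero along the sweep, which forces the asymmetry to grow without bound
(if the entropy vanishes, one off-diagonal cell dominates and its
transpose partner cannot keep up).  Neither growing asymmetry alone
(`M1`, `C0`) nor decreasing-but-positive entropy (`M3`, `M5`) produces
the phenomenon.

## Numerical choices in the classifier

`classify_regime()` works on the sweep grid alone, so its thresholds
deserve a record:

* **Trend tolerance**: consecutive differences within $10^{-9}$ count as
  flat; this absorbs floating-point noise on genuinely constant stretches
  (e.g. `M1`'s entropy, identical in every bit across the grid).
* **"Decreases to zero"** means: monotone non-increasing over the last
  20% of the grid *and* final value below 10% of the attainable maximum
  $\log_2(N^2 - N)$.  The threshold is taken relative to the attainable
  maximum rather than the grid maximum because a family may enter its
  sweep already far from uniform: `M4` on its domain $[50, 100]$ ends at
  $\mathrm{Ent} = 0.083$ bits, which is 7% of its own grid maximum but
  3% of $\log_2 6$, and it is unambiguously a vanishing-entropy family
  (its entropy continues to zero if the family's offset parameter is
  enlarged).  With this rule the eight families separate with wide
  margins: the vanishing-entropy sweeps end below 0.09 bits, the
  positive-limit sweeps above 1.6 bits.
* **Concordance cross-check**: the label is also compared against the
  signs of the per-step changes of Kappa and MCC on the grid tail.  A
  step enters this count only when both metrics move by more than
  $10^{-5}$ of their full-grid variation: at the far end of a long grid
  both statistics converge to their limits, and sub-noise creep in
  opposite directions carries no information (on a grid reaching $10^6$,
  `M5`'s Kappa drifts by $\sim 10^{-6}$ per step against MCC while both
  approach their limits; the genuinely divergent families move 50-1000x
  more per tail step).  A contradiction raises a warning, never a silent
  relabel.
* **Inconclusive tails error out.**  `M5`'s entropy rises to an interior
  maximum near $A = 400$ before settling towards its positive limit
  $\log_2 7 - 2/7 \approx 2.52$; a grid whose tail straddles that peak is
  refused with "extend grid" rather than guessed at.  This is why `M5`'s
  default grid runs to $10^6$ while the other unbounded families stop at
  $10^4$.

`M5` is also the one family where the printed closed form for its entropy
is inconsistent with its own off-diagonal multiset $\{2A, A, A, A{+}100,
A, A\}$ (a $2A\log 2$ term is dropped); the package computes the exact
entropy, and the qualitative behaviour — decrease to a positive limit —
is unchanged.  Similarly, the `M3` layout is fixed here as the cyclic
arrangement of three $B$/$B{+}100$ transpose pairs; any arrangement with
those pairs yields identical metrics and diagnostics, and the
reconstruction is pinned by its constant asymmetry $100\sqrt{6}$ and its
entropy closed form.

## The synthetic families and what the tests do not show

The parametric families are deterministic mathematical objects, not
samples from any classifier: they are chosen to isolate single structural
features (constant diagonal, one dominant error cell, paired error
cells).  `random_confusion()` adds seeded multinomial integer matrices —
every cell at least 1, so marginals are always valid — used for the
property tests (symmetry, scaling, transpose, oracle agreement, binary
mean identities).  Sweeps use 200-point grids; random-matrix properties
are asserted over batches of 1000 matrices with totals of 20-160 cases
and up to 8 classes.

Consequently the tests demonstrate exact algebraic structure, not
behaviour on real data: real confusion matrices come with sampling noise,
and a single matrix does not reveal a trend.  What carries over is the
audit heuristic: `audit_confusion()` flags a matrix whose off-diagonal
entropy is below a configurable fraction (default 25%) of
$\log_2(N^2-N)$ while the matrix is asymmetric — the fingerprint of the
regime in which Kappa can reward a worse classifier.  The 25% default is
an operationalization of a qualitative criterion (the underlying rule is
about a limit along a family, which no single matrix exhibits); it is
deliberately conservative and configurable, and the flag is advisory
only — it never alters the computed values.

## Known limitations

* Kappa's attainable range is not bounded by the package; only MCC is
  certified to lie in $[-1, 1]$.  (On every family treated here Kappa
  happens to stay in $[-1, 1]$ as well.)
* `find_kappa_minimum()` assumes unimodality on the bracket — true for
  the families above, not checked in general.
* The exact ordering-chain boundaries for the `C1_zero_d` sub-case are
  implemented only for the unambiguous sign structure (both statistics
  negative, $K > \mathrm{MCC}$) plus the reconstructed minimizer
  $\sqrt{a+1}$; the remaining bound chains of that sub-case are not
  asserted.
* One-sided sweeps only: all families vary a single parameter, as in the
  study they implement; there is no two-parameter sweep machinery.
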