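---
title: "Methods: regularized NMF with missing entries, imputation, rank selection and guided deconvolution"
author: "nmfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized NMF in nmfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmfkit)
```

## The model

`nmfkit` factorizes a non-negative features-by-samples matrix
$A \in \mathbb{R}^{n \times m}$ as $A \approx WH$ with
$W \in \mathbb{R}^{n \times k}_{\ge 0}$ (basis profiles, "metagenes") and
$H \in \mathbb{R}^{k \times m}_{\ge 0}$ (sample loadings), minimizing

$$\sum_{(i,j)\ \text{observed}} L(a_{ij}, (WH)_{ij}) \;+\; J_W(W) + J_H(H),$$

with $L$ either the square error $\tfrac12 (a - \hat a)^2$ or the
Kullback–Leibler divergence $a \log(a/\hat a) - a + \hat a$, the deviance
of a Poisson model. Square loss suits data whose entries share a common
scale; KL suits skewed or count-like data where large entries would
otherwise dominate a quadratic fit.

Each penalty is a weighted sum of three functionals, with weights
$\alpha = (\alpha_1, \alpha_2, \alpha_3)$ on $W$ and
$\beta = (\beta_1, \beta_2, \beta_3)$ on $H^\top$:
$J_1(X) = \tfrac12\lVert X\rVert_F^2$ (ridge),
$J_2(X) = \sum_{i<j} X_{\cdot i}^\top X_{\cdot j}$ (angle: penalizing it
pushes columns toward orthogonality) and $J_3(X) = \sum_{ij} |x_{ij}|$
(L1 sparsity). Because the weights on $H$ act on $H^\top$, the angle term
decorrelates *rows* of $H$. The identity $J_1 + J_2 = \tfrac12
\operatorname{tr}(XEX^\top)$ (half the sum of squared row sums, $E$ the
all-ones matrix) connects this family to column-wise sparse NMF; it is
verified as a property test.

Units: penalty weights live on the scale of squared data entries; they
are absolute, not normalized by $n$ or $m$. All defaults are 0 —
regularization is opt-in.

## Solvers

**Coordinate descent (default, `method = "scd"`).** With $W$ fixed, the
square-loss subproblem for each column $h$ of $H$ is the penalized
non-negative quadratic program $\tfrac12 h^\top V h + u^\top h$, $h \ge
0$, with $V = W^\top W + \beta_1 I + \beta_2 (E - I)$ and
$u = -W^\top a + \beta_3$. Coordinates are swept in fixed ascending
order; each is minimized exactly and clamped,
$h_{\bar k} \leftarrow \max(0,\, h_{\bar k} - g_{\bar k} / v_{\bar k \bar
k})$, where the gradient $g = Vh + u$ is maintained incrementally: it is
updated by $(h^{new}_{\bar k} - h^{old}_{\bar k}) V_{\cdot \bar k}$ only
when the coordinate actually changed (tested by exact inequality on the
clamped values, not a tolerance — cheap, and exact zero steps genuinely
need no update). Every step is non-increasing in the quadratic
objective, so sweeps converge to a KKT point. The $W$ update is the same
code path on the transposed problem ($A^\top$, $H^\top$, $W^\top$,
$\alpha$). Columns are independent and *could* be updated in parallel;
the implementation is deliberately single-threaded for reproducibility.

Since $E - I$ is indefinite, the diagonal of $V$ is guaranteed positive
by requiring $\beta_1 > \beta_2$ (or $\beta_2 = 0$); the constructor
rejects weight triples violating this. During alternation a basis column
can still collapse to all zeros, making a diagonal entry zero with zero
penalties; the kernel floors the divisor at `eps` $= 10^{-16}$ so the
coordinate is simply left unchanged instead of producing NaN.

**KL coordinate descent (`method = "scd", loss = "mkl"`).** The KL loss
is not quadratic in one coordinate, so each coordinate takes a clamped
Newton step on its second-order Taylor model: with
$b = \sum_l (w_{l\bar k} - a_{lj} w_{l\bar k}/(WH)_{lj})$ and
$a = \sum_l a_{lj} (w_{l\bar k}/(WH)_{lj})^2$,

$$h^{new} = \max\!\left(0,\; \frac{a\,h - b - \beta_2 \sum_{l \ne \bar k}
h_{lj} - \beta_3}{a + \beta_1}\right).$$

$(WH)_{lj}$ is refreshed incrementally after every accepted coordinate
change (a once-per-sweep variant would be cheaper but less accurate; the
incremental form is used for correctness). Denominators $(WH)_{lj}$
carry a $+$`eps` guard; $a + \beta_1$ is replaced by `eps` only when it
is non-positive, so the stationary-point identity ($b = 0$, no penalties
$\Rightarrow$ $h^{new} = h$) holds exactly. The Taylor model makes each
step only locally justified; a property test checks that full sweeps do
not increase the true KL objective (slack $10^{-10}$) on random
instances, but no global monotonicity guarantee is claimed, and no line
search is applied — the clamped analytic step is used as-is.

**Multiplicative updates (`method = "lee"`).** The classic rules
generalized to the penalties, e.g. under square loss
$h \leftarrow h \cdot (W^\top A) / ([W^\top W + \beta_1 I + \beta_2(E -
I)]H + \beta_3 E)$, with all-`beta`-zero reducing exactly to the original
algorithms (verified against an independent textbook implementation to
$10^{-12}$ over five alternations). Multiplicative updates preserve
zeros forever, so the driver warns when an initialization contains
zeros; true sparsity cannot emerge without thresholding, which this
package does not do. Denominators carry the same `eps` guard.

## Missing entries

The loss is a sum over entries, so unobserved entries simply contribute
no terms. Per column $j$ with observed rows $I_j$, the subproblem uses
$V_j = W_{I_j\cdot}^\top W_{I_j\cdot} + \beta_1 I + \beta_2 (E-I)$ and
$u_j = -W_{I_j\cdot}^\top a_{I_j} + \beta_3$; $V_j$ now depends on $j$
and is built lazily column-by-column (never materializing $k^2 m$
memory). The same restriction applies to the KL sums and to the
multiplicative numerators/denominators. A metamorphic test asserts the
contract bit-exactly: scrambling unobserved values changes no output of
`nmfFactorize`, `nmfImpute` or `selectRank`.

Rows or columns with *no* observed entry are rejected by the
`targetMatrix()` constructor — their reconstruction would be arbitrary.
(The low-level per-column operations accept blocks with fully missing
rows, which legitimately arise when a single column is examined in
isolation.)

## Driver, epochs and convergence

Each outer alternation solves $H$ then $W$ (order fixed for
reproducibility), warm-starting each factor at its previous value, with
`nInner` solver sweeps per factor. One *epoch* is a complete scan over
all entries of $W$ and $H$, so an outer alternation advances the epoch
count by `nInner`. Square-loss solvers amortize the expensive
cross-products over inner sweeps, hence `nInner = 50` by default; KL
solvers must refresh $WH$ every sweep and gain nothing from inner
iterations, hence `nInner = 1`.

Convergence is declared when the relative change of the mean
observed-entry loss between consecutive alternations,
$|\ell_{prev} - \ell| / \max(\ell_{prev}, \varepsilon)$, falls below
`relTol` (default $10^{-4}$), or when `maxEpochs` (default 2000) is
exhausted. This is a stated definition, not a canonical one — stopping
rules for NMF are conventions. Note that on *exactly* low-rank targets
the loss decays geometrically toward zero, so the relative change never
vanishes and the run uses its full budget; this is expected behaviour,
and the loss trace (`lossTrace`, `objectiveTrace`, `epochTrace`) is the
object to inspect. For the square-loss solvers the penalized objective
trace is monotone non-increasing (tested with relative slack
$10^{-12}$); alternation on an ill-conditioned factor pair has a slow
linear tail, so tolerances near machine precision require generous
epoch budgets.

Initialization draws both factors iid uniform(0, 1) from a seed owned by
the call; the caller's RNG state is saved and restored, and the same seed
reproduces the fit bit-for-bit. User matrices override the draw.

## Masking

`maskW`/`maskH` mark entries as *fixed* for the whole run — hard
regularization. Fixed entries take their value from the user
initialization (or 0 when none is given) and are *skipped* by all
solvers rather than overwritten after each update: the result is
identical (fixed entries are bit-exact in the output), but skipping keeps
every sweep a legitimate coordinate-descent step on the free coordinates,
preserving monotonicity. `markerMask()` builds gene-set-guided basis
masks (pathway mode confines a column to its set; marker mode forbids a
column from other sets' markers); `sharedProfileMask()` builds the
block-structured coefficient mask that lets shared basis columns load on
all datasets of a column-concatenated matrix while dataset-specific
columns load only on their own samples.

**Deconvolution.** `deconvolve()` realizes $A \approx WH + W_0H_1$ as one
masked factorization over the stacked basis $[\,W \mid W_0\,]$ with the
$W_0$ block fixed — no special-case solver. Purity is the ratio of
reconstructed mass $\hat r_j = \sum_i (WH)_{ij} / \sum_i (WH +
W_0H_1)_{ij}$, which is invariant to the joint scale of the factors (no
normalization is imposed between the blocks). Both coefficient blocks
receive the same $\beta$ weights. By default a small angle penalty
(with twice that weight as ridge, to satisfy the positivity constraint)
is placed on the stacked basis: independence between the unknown and the
known profiles is exactly what deconvolution needs, and with dense
correlated profiles the decomposition is otherwise weakly identified —
a free column can partially absorb a known profile without changing the
fit. The weight is scaled to $10^{-6}$ of the mean observed entry so it
never competes with the data term. Samples whose reconstruction is
identically zero get `NA` purity.

## Imputation and rank selection

`nmfImpute()` fills missing entries with the reconstruction; observed
entries pass through untouched and imputed values are non-negative by
construction. The procedure assumes entries are missing completely at
random (MCAR): if missingness correlates with the underlying value, the
reconstruction is biased. Heavily missing rows/columns make their
reconstruction unstable; the constructor's coverage requirement is a
minimal, not sufficient, safeguard.

`selectRank()` deletes `holdoutFrac` (default 30%) of the observed
entries uniformly without replacement — redrawing (up to 50 times) any
pattern that would empty a row or column — imputes them at each rank of
`kGrid`, and repeats for `nRuns` independent patterns. The selected rank
minimizes the *mean* held-out MSE across runs, ties broken toward the
smaller rank for parsimony; per-run argmins and the full error surfaces
(held-out MSE, held-out mean KL, training MSE) are all retained, since
aggregation by mean versus per-run argmin is a convention. Disjoint-fold
cross-validation is a straightforward variant of the same machinery
(delete each fold in turn); the uniform-deletion form is what is
implemented. The justifying behaviour — training error monotone
non-increasing in $k$, held-out error U-shaped with its minimum at the
generative rank — is asserted in the test suite.

## Synthetic designs

The package ships seeded generators used throughout the tests.
`simulateRankData()` is the reference rank-selection design: $W$ (400
× 3) iid uniform(0, 1), $H$ (3 × 50) iid uniform(0, 10), $A =
\max(WH + \mathcal N(0,1), 0)$. The per-entry signal mean ($\approx
7.5$) dominates the unit noise, so clipping is rare (< 5%, asserted
empirically). `simulateLowRank()` generalizes the shape/rank/noise and
adds MCAR deletion with coverage-preserving redraws.
`simulateMixture()` builds $A = W_cH_c + W_0H_1$ with per-sample purity
drawn uniformly and loading columns rescaled so the recorded purity
equals the generative mixing fraction exactly.

These designs emulate low-rank structure plus homoscedastic Gaussian
noise and uniform missingness. They do **not** emulate heavy-tailed or
count distributions, correlated or value-dependent missingness, batch
effects, or the correlation structure of real expression panels. Tests
passing on them validate the optimization and the protocol logic — not
robustness to those real-data features.

Problem sizes in the test suite are chosen to exercise every code path
while keeping the suite fast: solver oracles run at $k \le 4$ against
exhaustive active-set enumeration; driver-level checks use matrices
between 40 × 25 and 400 × 50; the convergence-speed comparison uses 200
× 100 at $k = 15$ over ten seeds.

## Known limitations

* NMF is non-convex: different seeds reach different local minima, and
  the factors are identified only up to joint permutation and scaling
  (`matchColumns()` handles permutation in comparisons;
  `normalizeBasis()` fixes a scale convention post hoc).
* The alternating scheme has a slow linear convergence tail on
  ill-conditioned problems; near-exact recovery needs large epoch
  budgets.
* KL sweeps are locally-modeled Newton steps without a descent
  guarantee; monotonicity is observed empirically, not proven here.
* Guided deconvolution with dense, mutually correlated profiles is only
  weakly identified; the default angle penalty mitigates but cannot
  remove this.
* Inner sweeps run a fixed count (`nInner`), with early exit only when a
  sweep changes nothing; no other inner stopping rule is applied.
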