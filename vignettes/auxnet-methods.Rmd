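---
title: "Methods: from two-way Y2H screens to covariate-aware block models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from two-way Y2H screens to covariate-aware block models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxnet)
```

# The problem

The auxin signalling pathway of *Arabidopsis thaliana* is governed by a
family of transcriptional regulators — ARF activators (ARF+), ARF
repressors (ARF-) and Aux/IAA proteins — that dimerise through two
conserved C-terminal sub-domains (DIII and DIV).  A two-way yeast-2-hybrid
(Y2H) screen tests every protein pair in both orientations (each protein
fused once to the Gal4 binding domain, once to the activation domain) with
two reporter genes: a colorimetric X-Gal test scored on a 7-level ordinal
scale (`'-' < '-?' < '?' < '+?' < '+' < '++' < '+++'`) and a growth-based
HIS3 test scored as an optical-density ratio (histidine-free over
histidine-rich medium, roughly in [0, 1.7]).  For 49 cloned regulators
this yields `49^2 = 2401` ordered tests over `49 * 50 / 2 = 1225`
unordered pairs, with two biological replicates per orientation (4900 test
results).  `auxnet` turns such a screen into binary and valued
protein-interaction networks, clusters them with mixture models for random
graphs, and quantifies how dimerisation-sequence dissimilarities modulate
interaction likelihoods.

Three proteins are excluded before modelling: ARF3 and ARF17 lack DIII/IV
altogether, and ARF11 shows no connections in the published binary
network; `filter_regulators()` therefore reduces the 49-protein roster to
the 46 proteins all networks are built on.

# Binarization

Each reporter is thresholded: X-Gal marks at or above `'+'` are positive
(the cut between `'+?'` and `'+'`), and HIS3 ratios at or above 0.45.
The HIS3 cut is supported by a Gaussian mixture on the pooled OD-ratio
sample (`fit_od_mixture()`, delegated to **mclust** with unequal-variance
univariate models and BIC selection): the boundary where the posterior
probabilities of the second and third components are equal falls close to
0.45, and the upper component aligns with marks at or above `'+'`.
Presets 0.3 and 0.65 are supported for sensitivity analysis; raising the
threshold can only remove edges, never create them.

The four boolean outcomes of an unordered pair (two orientations, two
reporters) fall into configurations: all four positive (1), exactly three
(2), two positives in one orientation (3), one reporter positive in each
orientation (4), or the same reporter positive in both orientations (5).
Configurations 1–4 define an edge; configuration 5 is discarded as
unreliable, and at most one positive means no interaction.  Two points
the source material leaves open are fixed here as package conventions: a
pair with a missing orientation is treated as two negative tests (with a
warning), and homodimer pairs — tested in a single orientation — are
classified with that orientation duplicated and stored on the matrix
diagonal, outside the model.

# Standardization (the valued network)

Binarization throws information away.  The valued network instead
replaces each test output by its mid-rank in a single pooled marginal per
test (all ordered pairs, diagonal included; ties share the mean of the
ranks they span) and mixes the two reporters:

$$x_{ij} = w_{\mathrm{XGal}} \frac{\mathrm{Rank}(y_{ij}) +
\mathrm{Rank}(y_{ji})}{1 + M_{\mathrm{XGal}}} + w_{\mathrm{HIS3}}
\frac{\mathrm{Rank}(z_{ij}) + \mathrm{Rank}(z_{ji})}{1 + M_{\mathrm{HIS3}}},$$

with $w_{\mathrm{XGal}} + w_{\mathrm{HIS3}} = 1$ and $M$ the number of
observed values per test ($N^2$ when complete, giving the usual
$(1 + N^2)/2$ mean rank).  HIS3 is deliberately treated as ordinal: its
response is monotone but strongly nonlinear (Michaelis–Menten-like), so
only its order is trusted.  Consequently $x$ is invariant under any
strictly increasing transform of the ratios, and with complete data the
mean of $x$ over all ordered pairs is exactly 1 — an identity the tests
assert to 1e-10.  The preset weightings are `XGal-only` (1, 0), `A`
(0.75, 0.25), `B` (0.5, 0.5), `C` (0.25, 0.75) and `HIS3-only` (0, 1).

Missing values: each directed rank term is normalized by $(1 + M)/2$ and
the present terms are averaged per test, which reduces exactly to the
two-term formula when both orientations are present and to
$\mathrm{Rank}(z_{ij}) / \{(1 + M_{\mathrm{HIS3}})/2\}$ when one is
missing.  A test missing in both orientations drops out and the weights
renormalize over the available tests; a pair with both tests fully
missing is `NA`.  Whether homodimer (diagonal) observations belong in the
pooled marginals is genuinely open; they are included here, which keeps
the $1 + N^2$ normalization and the mean-1 identity mutually consistent,
and the diagonal is then ignored by the models.

# Block models, variational EM, ICL

Vertices belong to one of $Q$ latent clusters with weights $\alpha_q$;
conditional on memberships, edges are independent:

* **Bernoulli** (binary graph): $Z_{ij} \sim \mathcal B(\pi_{q\ell})$;
* **Gaussian** (valued graph): $X_{ij} \sim \mathcal N(\mu_{q\ell}, \sigma^2)$;
* **Regression** (valued graph, $d$ edge covariates):
  $X_{ij} \sim \mathcal N(\mu_{q\ell} + \mathbf Y_{ij}^\top \mathbf b_{q\ell}, \sigma^2)$,

with a single shared variance $\sigma^2$ (the model equations carry an
unsubscripted $\sigma^2$), undirected edges, no self-loops, and all sums
over $i < j$; the model has $(Q-1) + Q^2(d+1)$ independent parameters.
The covariates are sequence distances between dimerisation domains
(DIII/IV combined, or DIII and DIV separately), read from PROTDIST-style
PHYLIP square matrices; the upstream alignment pipeline (CLUSTAL-W,
Gblocks, PROTDIST/PAM) is consumed through its output format, not
reimplemented.

The membership posterior is intractable, so the E-step uses the
mean-field fixed point
$\tau_{iq} \propto \alpha_q \prod_{j \neq i} \prod_\ell
(\phi_{ij}^{q\ell})^{\tau_{j\ell}}$, iterated in the log domain with
per-row renormalization until the largest change falls below 1e-6 (at
most 100 sweeps).  Raw fixed-point iteration can oscillate; a damping
factor of 1/2 is applied when the update residual grows.  The M-step is
the $\tau_{iq}\tau_{j\ell}$-weighted least-squares regression per
unordered cluster pair (a weighted mean for the Bernoulli family), with a
tiny ridge (1e-8) stabilizing near-empty cluster pairs.  EM alternates
until the relative change of the lower bound $J$ is below 1e-8 or 500
iterations.  Initialization is one Ward hierarchical clustering of the
adjacency rows plus random soft starts (default 5 starts in total); the
best final $J$ wins, and everything is deterministic given a seed.

Cluster counts are compared with the ICL criterion,

$$\mathrm{ICL} = J - \frac{Q-1}{2}\log n -
\frac{Q^2(d+1)}{2}\log\frac{n(n-1)}{2},$$

whose double penalty charges membership parameters against the $n$
vertices and edge parameters against the $n(n-1)/2$ edges.  A gap of at
least $\log(100) = 4.6$ is treated as substantial (Jeffreys' rule of
thumb).  `model_scan()` also reports posterior model probabilities as the
exp-normalized (softmax) ICL across the scanned models — the source
material prints such probabilities without a formula, and softmax
reproduces the pattern that near-tied ICL values share the mass.
Because no significance procedure is specified for the regression
coefficients either, `coefficient_significance()` implements this
package's own convention: a nonparametric bootstrap over vertices
(default 200 resamples) holding the MAP labels fixed, flagging
coefficients whose 95% percentile interval excludes zero.

# Cluster-quality diagnostics

Model parameters do not measure dispersion, so cluster quality is judged
from connectivity profiles: $D(i,j) = \sum_k |x_{ik} - x_{jk}|/N$, which
for a binary matrix is the Sokal–Michener mismatch proportion.  From
these come soft protein-to-cluster distances $D(i,q)$ (reducing for hard
assignments to means over $n_q - 1$ or $n_q$ members), cluster-to-cluster
distances with denominators $n_q(n_q-1)$ and $n_q n_\ell$, and
within/between summaries.  A cluster is "strongly defined" when its
within distance is below all its between distances.  The profile sum runs
over all $N$ columns with the matrix diagonal set to zero first — the
printed formulas exclude no column, and a fixed convention keeps
distances comparable; this choice is declared, not inferred.  Partitions
from different models are compared by the maximal agreement count over
injective cluster-label matchings (exact enumeration on the confusion
matrix, feasible since $Q \le 7$ here), reported as a percentage of the
roster.

# The synthetic-data generator

Every stage is testable offline through seeded simulators whose defaults
emulate the study conditions rather than a convenient regime:

* `simulate_y2h_dataset()`: 46 proteins in three groups with weights
  roughly (6, 12, 28)/46 — mirroring the ARF+, ARF- and Aux/IAA family
  sizes — and an interaction-probability matrix with strong
  ARF+–Aux/IAA connectivity (0.8), moderate within-ARF+ (0.6) and
  within-Aux/IAA (0.3) rates, and sparse ARF- rows (0.1), the
  qualitative structure reported for the real network.  X-Gal marks are
  drawn from interaction-conditional ordinal distributions supported on
  the correct side of the `'+'` threshold, and HIS3 ratios from a
  3-component Gaussian mixture (non-interacting mass at means 0.12 and
  0.30, interacting mass at 1.0) truncated at the 0.45 boundary, so the
  zero-noise round trip through `build_binary_network()` is exact by
  construction.  Orientation-level status flips and HIS3 missingness are
  configurable rates.
* `simulate_blockmodel_graph()`: planted partitions with
  cluster-pair-dependent edge laws for all three families.
* `simulate_covariates()`: symmetric, zero-diagonal distance matrices
  with within/between-cluster means (defaults 0.3 / 0.7, jitter 0.1).

What the generator does *not* emulate: replicate-level variability (the
input schema carries one mark and one ratio per ordered pair, as the
published example table does), correlated noise between the two
reporters, and real sequence evolution (covariates are Gaussian
dissimilarity surrogates, not substitution-model distances).  Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the model's own assumptions, not robustness to the
biological noise structure of a real screen.

# Numerical choices and problem sizes

Tolerances: EM stops at relative $\Delta J <$ 1e-8; the E-step fixed
point at max $|\Delta\tau| <$ 1e-6; $\sigma^2$ is floored at 1e-12;
Bernoulli probabilities are clipped to [1e-10, 1 − 1e-10] before logs.
Ties in ranks are mid-ranked, matching the ordinal rank formula.  The
test suite exercises label and coefficient recovery at n = 80 (Q = 3,
two covariates, $\sigma$ = 0.05, twenty seeds), ICL selection at n = 60
over Q = 1..6 (ten seeds), and oracle equivalence against exhaustive
enumeration of all $2^8$ labelings at n = 8 — sizes chosen so the
enumeration oracle stays exact and a desk-scale run finishes in minutes
while matching the study's 46-protein scale where it matters.

# Known limitations

* The Bernoulli family takes no covariates (no logistic link), and there
  is no directed, degree-corrected or Poisson variant.
* ICL is asymptotic; at n = 46 it is indicative, and it is known to
  overparameterize here — the diagnostics exist precisely to temper it.
* The valued network is a likelihood-of-interaction surrogate, not a
  binding affinity.
* Off-diagonal missing entries are not handled by the block models
  themselves; standardization's missing-value rules must produce a
  complete matrix first.
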