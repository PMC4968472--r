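---
title: "Models and methods in corvnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in corvnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corvnet)
```

corvnet analyses how a novel skill spreads through an animal social group:
which social ties predict who watches whom, and which ties predict the
order in which individuals first perform the behaviour. This vignette is
the package's own account of the models it implements, the defaults it
chooses, and what its synthetic-data tests do and do not establish.

## Data model

Field data arrive as two sampling streams collected on non-trial days:
all-occurrence records of affiliative (physical contact, sharing) and
agonistic interactions, and instantaneous scan samples (every 15 min) of
proximity (sitting close; sitting on the same branch, which excludes pairs
already sitting close — three birds A,B,C seated in a row are encoded by
the data producer as `sit_close(A,B)`, `sit_close(B,C)`,
`same_branch(A,C)`; the ingest layer never re-derives geometry). The two
streams must never be pooled into a single count matrix: their units
differ, and `count_matrix()` refuses to mix them. The composite
affiliative network is the cell-wise **sum** of the physical-contact and
share counts; summation preserves event counts, and whether the two
components should instead be weighted is exposed simply by analysing the
component networks alongside the composite. Raw counts over the study
window are used as tie weights — no observation-time correction — because
the sampling design fixes a common window for all dyads.

## Observation networks

Observation is recorded only for naive individuals before their own first
solution, so observation ties are non-reciprocal by construction. Because
informed individuals differ in how often they solve, raw watch counts are
normalized by opportunity: if *j* solved X times before *i*'s first
solution and *i* watched Y of them, the directed tie *i* → *j* is Y/X.
Cells with no opportunity are set to 0 and counted in a log message rather
than treated as missing; this is a pragmatic choice that keeps the MRQAP
design matrix complete.

## Centralities

Three measures are computed per network, with group-relative ranks
(1 = most central, ties averaged): out/in-strength (weighted out/in
degree); eigenvector centrality; and Stephenson–Zelen information
centrality, `1 / (C_ii + (T - 2 R_i)/n)` with `C = (D - S + J)^-1`.
Published analyses often report these for directed networks without
stating the symmetrization; corvnet symmetrizes by `S = W + t(W)`, which
preserves total weight, and records the choice in the function
documentation so it can be audited. Eigenvector scores come from power
iteration (uniform start, relative tolerance 1e-10, a small diagonal shift
to guarantee convergence on bipartite-like spectra) and are normalized to
unit maximum. Information centrality requires a connected graph; the
strict function errors on disconnected input, while `centrality_table()`
scores the largest component and returns `NA` elsewhere, since a node cut
off from the main component has no defined information flow to it.
Correlation stages drop `NA` pairs and report the effective n.

## Dominance

Social rank comes from retreats after threats: `D[i, j]` counts j's
retreats from i. The I&SI criterion seeks the order minimizing
lexicographically the number I of dyads inconsistent with the order (a
dyad is inconsistent only under a strict majority of retreats in the
"wrong" direction; ties, including 0–0, are neutral) and then the summed
rank distance SI of those dyads. The search is heuristic — one
descending-wins start plus seeded random restarts, refined by pairwise
swaps *and* single-element insertions until no move improves — because
the exact problem is factorial; the test suite verifies exact agreement
with exhaustive enumeration for n ≤ 7 across 100 random matrices.
Insertion moves matter: swap-only search demonstrably sticks in local
optima one insertion away from the optimum.

## MRQAP with double-Dekker semipartialling

Point estimates are ordinary least squares on the n(n−1) off-diagonal
cells (intercept included; standardized coefficients are reported
alongside raw ones, as network software conventionally does). Inference
for predictor k permutes the rows and columns of its residual matrix
(residualized on the other predictors) by one node permutation per draw
and refits; the p-value counts permuted coefficients at least as extreme
as the observed one, with the observed statistic included in the null set,
so p ≥ 1/(permutations + 1). Two-tailed comparison is the default
(empirical network regressions routinely turn up significant negative
coefficients, so tail handling matters); a one-tailed positive option
exists. Node permutation
preserves the row/column dependence of network data; the acceptance suite
verifies the 5% nominal type-I error to ±1 percentage point under
independent random matrices and the exact equality of point estimates
with plain OLS.

## OADA

At acquisition event k the probability that naive individual i is the next
solver is `R_i / sum(R)` over all naive individuals, with
`R_i = (1 + s T_i) exp(beta' x_i)` and `T_i = sum_j a_ij w_j z_j`. Design
choices a user should know:

- **ILVs act multiplicatively on the whole rate** (social and asocial
  terms alike). The alternative — additive ILVs on the asocial term only —
  would break the clean nesting of the asocial null; multiplicative is the
  standard OADA default.
- **Transmission weights are cumulative**: `w_j(k)` is the number of j's
  solutions *before* event k, because information cannot flow from future
  solutions. The end-of-study-total reading is available as
  `weight_mode = "total"`; which of the two an empirical report used is
  often not decidable from its text.
- **Direction**: the rate of naive i uses row i of the weight matrix (the
  tie i initiates toward informed j), which is the natural reading for
  observation-driven transmission; for undirected networks the choice is
  immaterial.
- **Separated individuals** (moved out of observation range near the end
  of a study) stay in the risk set — they are still naive and still
  acquire — but their social term is zeroed from the stated event onward.
- **Never-solvers** contribute no event but stay in every denominator;
  right-censoring in time requires time-of-acquisition data, which is out
  of scope for order-based analysis.
- The null (asocial, no-ILV) model has k = 0 parameters, for which the
  AICc formula reduces exactly to −2 logLik; no special-casing is applied.

Fitting maximizes the log-likelihood over `s ≥ 0` on a log scale
(multi-start from s ∈ {0.1, 1, 10, 100}, BFGS jointly with the ILV
coefficients, a 1-D profile refinement, and an explicit boundary check at
s = 0). Exposure and risk-set matrices are precomputed once per model, so
a 28-model set fits in seconds. Confidence intervals for s are profile
likelihood based; order data are often nearly uninformative about very
large s (once s·T ≫ 1 for everyone, the order depends only on relative
exposures), so flat right tails are reported as right-open intervals
rather than pretending to a finite bound. %ST is the mean over acquisition
events of `s T / (1 + s T)`, the social share of the acquirer's hazard;
its CI re-evaluates at the profile bounds with ILV coefficients
re-optimized.

Model sets enumerate networks singly (never jointly) × weight flag × ILV
subset, plus asocial models for every ILV subset including the empty null.
Support ratios divide the summed Akaike weight of models containing a
network by the summed weight of the asocial models; as a calibration, a
one-parameter likelihood-ratio test at p = 0.05 corresponds to a support
ratio of 2.5, which the acceptance suite verifies from the AICc machinery
itself.

## The synthetic world

The generator emulates the study design the package targets: two aviary
groups (12 subadults with 7 females; 10 juveniles in three sibling
groups), 98 observation days, scan samples during daily sessions
(default 4/day, i.e. 15-min scans over about an hour of observation), one
trained demonstrator seeded with 10 prior solutions, and repeated solving
by informed birds.

Its parameters were fixed in advance at values realistic for selective
captive corvid groups, not tuned to test outcomes:

- **Sparse latent bonds**: a non-kin dyad carries a bond with probability
  0.25 (kin always, boosted 3×), bond strengths Gamma(2, 1). Only bonded
  dyads interact affiliatively, reproducing the social selectivity such
  groups show — synthetic affiliative densities land near 0.2–0.3,
  agonistic near 0.5, proximity near 0.45.
- **Proximity** mixes the bond (weight 0.6) with its own sparse noise
  component, so proximity correlates with affiliation without duplicating
  it — as in real groups, where tolerated proximity is broader than active
  affiliation.
- **Dominance** events follow a latent linear order with upset probability
  0.1; the loser retreats.
- **Diffusion** is a continuous-time competing-hazards simulation of the
  OADA model itself (baseline rate 1/day, which cancels in the order
  likelihood; informed birds keep solving at 2/day so weights grow).
  Recovery and end-to-end tests simulate on the affiliative network
  rescaled to unit mean connection (`scale_network()`), because s is
  defined per unit connection: on raw count scales s·T ≫ 1 for every
  naive bird and the order likelihood is flat in s, making any particular
  s value meaningless.
- **Observation** of each solving event is Bernoulli with probability
  `plogis(-4 + 4 * min(a/mean(a>0), 2))` in the affiliative tie — a link
  strong enough that who watches whom is dominated by affiliation
  (affiliative–observation in-strength correlations near 0.9), the tight
  coupling described for corvids watching their affiliates. The resulting
  observation networks are sparser (density ≈ 0.07) than real observation
  networks tend to be (≈ 0.3); the mismatch is known and deliberate (a
  higher baseline would dilute the affiliative signal the tests rely on).
- A field experiment has **one diffusion per group**; a single n = 12
  order identifies s only weakly, so recovery and end-to-end tests pool
  10–50 seeded diffusions into one joint likelihood — the standard NBDA
  power device. A green end-to-end test therefore establishes that the
  pipeline recovers the generative structure *at that information level*,
  not that a single observed diffusion would.

What the generator does **not** emulate: fission–fusion dynamics, spatial
enclosure geometry, observer-effort variation, inter-observer reliability,
or any time-of-acquisition structure beyond the hazard model.

## Numerical and procedural choices

- Spearman correlations use average ranks; p-values are exact (full
  permutation enumeration) for n ≤ 9 and t-approximate above. Solving
  order is coded 1 = first solver, so positive correlations mean central
  individuals solved sooner; never-solvers are placed after all solvers,
  tied at the maximum rank, and the demonstrator is excluded from every
  rank-correlation input.
- Multiple testing: unadjusted p-values are primary, as is conventional
  in this literature; Benjamini–Hochberg-adjusted values are reported
  side by side for transparency.
- All stochastic stages (MRQAP permutations, I&SI restarts, every
  generator) take explicit integer seeds, restore the caller's RNG state,
  and record their seeds in the report bundle; rerunning a pipeline with
  identical seeds reproduces the JSON report byte for byte.
- Degenerate inputs: all-zero dominance matrices return an arbitrary
  order flagged `unresolved`; empty acquisition orders have log-likelihood
  0; constant rank vectors yield an undefined Spearman rho with an
  explicit flag rather than NaN arithmetic.

## Limitations

Order-of-acquisition analysis discards acquisition times, so s is
estimated on relative information only and upper confidence bounds are
frequently unbounded. The MRQAP and OADA stages treat networks as fixed
and error-free; uncertainty in the networks themselves (sampling effort
per dyad) is not propagated. The I&SI search is heuristic above the
exhaustively verified sizes, though restarts make failures unlikely at
group sizes of 10–12. Kinship enters as a binary sibling network; graded
relatedness is not modelled.
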