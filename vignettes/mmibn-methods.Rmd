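---
title: "Methods: mixed mutual information selection and Bayesian network modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed mutual information selection and Bayesian network modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Overview

`mmibn` analyzes a cohort in which each gene carries three molecular
components — a binary somatic-mutation indicator S, continuous expression
E, continuous promoter methylation M — against a binary clinical outcome Y
(tumor status, or survival dichotomized at 730 days). The analysis has two
stages with a deliberately adjustable hand-off: a cheap mixed-type mutual
information (MMI) filter reduces thousands of genes to a handful, and a
discrete Bayesian network (BN) over the expanded S/E/M nodes of the
selected genes models their joint dependence structure with the outcome.

# Stage 1: the mixed MI estimator

For gene g the statistic is I((S_g, E_g, M_g); Y), estimated from
k-nearest-neighbour distances in the joint space. Distances are max-norm
across coordinates, with |x_i − x_j| on continuous coordinates and the
indicator metric (0 if equal, 1 otherwise) on discrete ones. For each point
i, ρ_i is the k-th smallest joint distance to another point; the marginal
neighbour counts n_{x,i} and n_{y,i} count points whose marginal distance
is strictly below ρ_i (the point itself included); the estimate is

    mean_i [ ψ(k̃_i) − log n_{x,i} − log n_{y,i} ] + log n ,

where k̃_i = k normally and, for points whose k-th neighbour is at joint
distance zero (possible because discrete coordinates create ties), k̃_i and
the marginal counts fall back to the multiplicity of the tied point.

**Why strict inequality.** With a binary outcome the joint radius ρ_i is
frequently *exactly* 1 — the indicator distance to the nearest
opposite-class point. A closed ball (≤ ρ_i) then absorbs the entire
opposite class into n_{y,i}, producing a large negative bias (measured at
≈ −0.25 nats at n = 300 for the 3-column configuration). The open-ball
convention used here matches the estimator's reference implementation and
is near-unbiased under independence at moderate n (|bias| < 0.01 at
n = 2000).

**Known small-sample offset.** At n ≈ 300 the estimator retains a positive
offset of ≈ +0.13 nats in the (S, E, M) vs binary-Y configuration,
decaying to ≈ +0.02 by n = 1000. The offset is common to all genes of a
dataset, so rankings, CDF-quantile selection and Jaccard diagnostics are
unaffected; absolute MMI values at small n should not be read as
calibrated information estimates, and the test suite asserts relative
(rank) behaviour at small n and absolute accuracy at large n.

**Parameters.** `k = 15` (default): small k inflates variance, k > 20 adds
computation and smoothing without improving the selected set; the
`jaccard_curve` diagnostic reproduces the stabilization of the selected set
for k in the 8–20 band. Continuous columns are standardized to unit
variance before distances (`standardize_continuous = TRUE`); the max-norm
otherwise weights E against M by their arbitrary units. Standardization
makes the estimate exactly invariant to affine rescaling of any continuous
column; ranks are used everywhere downstream, so heavier-tailed or skewed
marginals are handled without special treatment. Estimates are in nats.
Determinism: no jitter is injected; ties are handled by the k̃ rule.

**Selection.** `select_top_cdf(tab, q)` keeps genes with empirical CDF
position above q — exactly N − floor(qN) genes when scores are distinct
(24/63/81 genes at q = 0.995 for N = 4782/12516/16164); genes tied with the
boundary score are all kept, making the rule deterministic and
conservative. `select_by_threshold(tab, t)` implements the alternative
"natural cutoff" rule (strictly greater than t, e.g. t = 0.08).

# Stage 2: discretization and network learning

Each selected gene becomes three nodes (`<gene>_S/E/M`); E and M are
discretized into three equal-frequency bins — the maximum-entropy
realization of a fixed-arity discretization. Boundaries sit at the
ceil(n·i/3)-th order statistics; values equal to a boundary fall into the
lower bin, so the bin label is a function of the value alone and tied
values always share a bin (ties can unbalance occupancies, which the code
reports). Constant vectors are an error rather than a silent single bin.

Structure learning is score-based: the BDeu log marginal likelihood with
equivalent sample size 1.0 (the score is only specified up to "a" marginal
likelihood ratio upstream; BDeu satisfies that exactly and is the standard
default), a sparse-candidate restriction of each node to its m = 10
highest plug-in-MI partners (symmetrically closed), parent sets capped at
4, and greedy hill climbing over add/delete/reverse moves with acyclicity
enforced at every step.

**Steepest ascent rather than first improvement.** The search accepts the
*best* improving move per iteration (random tie-breaking, seeded) rather
than the first one found. First-improvement is cheaper per sweep but
measurably more often terminates inside a score-equivalence plateau (e.g.
escaping a fork for the globally better collider requires passing through a
Δ = 0 reversal); steepest ascent with 5 seeded restarts (empty start plus
random candidate-pair DAG seeds) reaches the brute-force optimum on all
3-node benchmark problems in the test suite and is deterministic given the
seed. Edge strengths are reported as log10 Bayes factors — the family-score
difference with and without the edge — matching the magnitude range
(≈ 0.02–20) familiar from cohort-scale runs of this analysis.

The Markov neighborhood (radius 1, optionally 2) of the outcome node is the
practical surrogate for its Markov blanket: with edge directions ignored,
all nodes within one (two) step(s).

# Post-hoc testing

Each molecular member of the neighborhood is tested for a marginal
group difference on the *original* (undiscretized) values: two-sample
Kolmogorov–Smirnov for E/M (D by ECDF sweep; p from the asymptotic
Kolmogorov distribution at effective size n0·n1/(n0+n1) — group sizes here
are in the tens-to-hundreds where the asymptotic p is adequate; no exact
small-sample p is attempted), and the two-sided Fisher exact test for S
(sum of hypergeometric probabilities ≤ that of the observed table, with a
1e-7 relative guard against floating-point ties). Significance is flagged
at α = 0.05 without multiplicity correction, matching the presentation
style this report mirrors; a Benjamini–Hochberg column is included for
transparency. S rows with fewer than `min_count = 5` mutated samples in
*both* outcome groups are flagged excluded — a mutation this rare supports
no stable inference regardless of p. P-values of at least 0.995 are
*displayed* as "~1.0" (cosmetic only; the numeric column is exact).

# The synthetic world

`generate_multiomics` emulates the statistical shape of a preprocessed
cohort: hundreds of patients, thousands of genes, a binary outcome with
configurable balance, sparse S (default prevalence 0.05), standard-normal
E/M, and a small planted fraction of genes whose components carry the
outcome signal (mean shifts delta_E/delta_M in SD units, mutation odds
ratio gamma_S). The `lgg_like_spec()` preset fixes 273 samples × 4782
genes, the shape of a real lower-grade-glioma tumor-status analysis.
Continuous components are Gaussian rather than beta-like methylation
fractions deliberately: every downstream step (kNN ranks, quantile bins,
KS) is rank-based, so the marginal shape is immaterial — a green test
therefore establishes correct mechanics, not robustness to real-data
artifacts such as batch effects, missingness patterns, or copy-number
confounding, which the generator does not model. Inter-gene couplings are
induced by shared latent Gaussian factors.

`generate_bn_fixture` samples ancestrally from an explicit DAG + CPTs. The
collider benchmark (Z = noisy XOR of X, Y) uses *biased* parent marginals
P(X=1) = 0.3, P(Y=1) = 0.4: with fair coins the XOR joint is pairwise
independent, so no single-edge addition can ever improve a decomposable
score and the three collider orientations are likelihood-equivalent — no
score-based learner could recover "the" collider. Bias keeps X–Z and Y–Z
marginally dependent and makes the v-structure the unique optimal class.

# Numerical choices and degenerate inputs

- Zero-variance continuous columns in the MMI contribute zero distance
  (warning), rather than erroring a whole cohort for one flat gene.
- `assemble_dataset` is complete-case per gene and errors on empty
  intersections or a single-class outcome; every drop is logged.
- BDeu cells and parent configurations absent from the data contribute
  exactly zero to the score (Γ-ratio of equals), so scoring is sparse-safe.
- Score comparisons use a 1e-9 improvement epsilon; equal-score moves are
  never accepted, keeping traces strictly monotone and the search finite.
- Survival dichotomy: deaths before day 730 are high-risk; anyone with
  follow-up ≥ 730 days is low-risk; living patients censored before 730
  days are excluded as uninformative for the dichotomy.
- Somatic binarization is per patient (S[g, s] per sample), since patients
  are the observations for both MMI and the BN.

# Limitations

- The MMI estimator's absolute values at small n carry the documented
  positive offset; only ranks should be interpreted below n ≈ 1000.
- Greedy BDeu search offers no global-optimality guarantee beyond the
  small-problem brute-force checks; restarts mitigate but cannot eliminate
  local optima at cohort scale.
- The asymptotic KS p is anticonservative for group sizes below ~25.
- The pipeline treats discretization as fixed preprocessing; no adaptive
  re-binning during search, and no mixed local probability models.
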