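---
title: "Methods: diagnosing adaptive radiation on a chronogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnosing adaptive radiation on a chronogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`karstrad` bundles the comparative analyses used to ask whether a clade
diversified by adaptive radiation: an early burst of speciation, a pulse
of ecological (discrete habitat) change, a late expansion of
morphological disparity, and convergence onto a limited set of adaptive
peaks. This vignette explains the models behind each stage, the
parameters that matter, the synthetic data the package tests itself on,
and the numerical and design choices a maintainer should know about.

All analyses assume a rooted, binary, ultrametric chronogram with branch
lengths in millions of years. Ages are measured backward from the
present (tips at 0), so every "time of shift" parameter is an age in My.
Ultrametricity is checked with a relative tolerance (maximum tip-age
deviation of 1e-6 times tree height) to absorb Newick rounding;
polytomies are resolved deterministically into zero-length binary splits
(children rotated into lexicographic order first), since consensus trees
contain them.

## Lineage diversification

The γ statistic measures whether internal nodes concentrate early
(γ < 0) relative to a constant-rate expectation; it is computed from the
inter-node intervals and is invariant to rescaling all branch lengths.
The Monte-Carlo test simulates pure-birth trees conditioned on the same
tip count. Because γ depends only on branching times, the nulls are
drawn directly as inter-node durations, exponential with rate k·λ while
k lineages exist — including the final interval with n lineages, which
is what makes the null γ mean zero. The default p-value is one-sided
(lower tail): the hypothesis of interest, an early burst, is
directional. The (r+1)/(N+1) correction means an exact zero is never
reported.

Model fitting covers the shifted diversity-dependent family: per-lineage
speciation λ(N) = max(0, λ₀ − (λ₀ − μ)·N/K) with a single shift in any
subset of (λ, μ, K) at an age that is itself estimated. All likelihoods
are conditioned on the crown age and on survival of both crown lineages,
the standard convention for this family, and share one density
convention so AICs are directly comparable. Three computational routes
agree exactly where they overlap:

* constant or time-shifted rates without diversity dependence use the
  closed-form one-lineage density p1 and extinction probability E,
  composed across rate segments;
* any μ = 0 member collapses analytically (no extinct hidden lineages
  can exist), which is what makes the fitting loops fast;
* the general case integrates the master equation for the number of
  hidden (doomed) lineages between branching events. The hidden-birth
  inflow coefficient is (n−1+2k): a hidden birth from one of the k
  observed lineages admits two spine embeddings. With that bookkeeping
  the propagated vector reduces exactly to products of p1 in the
  constant-rate limit, which the tests assert, alongside a dense
  matrix-exponential oracle on small trees.

The master equation truncates the hidden count at n+100 (or 2K when the
carrying capacity binds below that), warning if boundary mass exceeds
1e-8. Survival conditioning under diversity dependence is computed
exactly from the two-family master equation over descendant counts of
the two crown lineages, with a sticky truncation boundary (states that
large survive almost surely). A free shift time is profiled on a 0.5-My
grid across the central 90% of the crown age and refined locally;
likelihoods can be multimodal in K, so each fit starts from 8
deterministic points spanning speciation and carrying-capacity scales.

One caveat established during validation: the ML extinction rate carries
the well-known small-sample upward bias (about +36% at n = 60 for
μ = 0.1), even though the conditioned density itself matches forward
simulation exactly. The speciation rate is recovered essentially
unbiased. Tests assert tight recovery for λ and a sanity window for μ.

## Ecological disparification

Habitat evolution is modelled as a continuous-time Markov process over
the six field categories (unsaturated fissure systems, interstitial,
cave lakes, cave streams, shallow subterranean, specific chemistry).
The default structure is symmetric (SYM): with six states, an
all-rates-different matrix has 30 free rates, which is overparameterised
at a few hundred tips; equal-rates and ARD remain available. Species
with unknown habitat stay in the analysis and contribute equal
likelihood for every state; the root prior is flat.

Stochastic maps are sampled exactly: a pruning pass gives conditional
node distributions, nodes are sampled root-to-tip, and within-branch
histories conditioned on both endpoints are drawn by uniformization with
the virtual-jump chain sampled from the truncated Poisson series.
Changes-through-time (CTT) curves divide the mean change count per age
bin (50 equal-width bins by default; the binning is a free choice) by
the branch length present in the bin, so the conservation identity
Σ bins (value × edge length) = mean changes per map holds exactly.

The CTT null follows the literal convention of simulated character
histories: free forward simulations from the fitted Q, one per
replicate, root state from the flat prior, unconditioned on tips. That
convention makes the observed statistic (a mean over conditioned maps)
smoother than any single null history, so the package also offers an
exchangeable parametric-bootstrap mode ("conditional"): each null
replicate simulates tip data under Q and rebuilds the mean curve from
maps conditioned on those simulated tips. The calibration tests use the
exchangeable mode; the default remains the literal one and the choice is
a switch.

## Morphological disparification

Disparity is the mean squared Euclidean distance over unordered species
pairs (computed via the centred-sum identity, so it is exact and O(n)).
The DTT curve visits divergence events from the root: the value at an
event is the mean relative disparity (subclade over whole clade) of the
lineages entering that event. Lineages just after event i are the
lineages entering event i+1, so this indexing starts the curve at 1 at
the root and is the same curve as the "just after" phrasing shifted by
one event; the curve ends with an explicit point at the present, where
all lineages are singletons (value 0), giving the MDI integral its full
0–1 relative-time support. The MDI is the trapezoidal integral of
(observed − null mean); its Monte-Carlo p compares the observed MDI with
each null curve's MDI against the remaining nulls, and both the
two-sided and the upper-tail version are reported since the directional
convention is a free choice. Null curves are Brownian simulations under
the full trait covariance estimated from phylogenetically independent
contrasts — traits are correlated, and an independent-traits null would
miscalibrate. Traits are used as supplied (body length raw, the rest as
size-corrected residuals); species missing any trait are dropped
listwise and the tree pruned accordingly.

The rank envelope test computes each curve's extreme rank: the minimum
over grid points of its pointwise rank from below or above among all
N+1 curves, ties sharing ranks; the p-interval counts nulls strictly
more extreme (lower bound) or at least as extreme (upper bound). Curves
built from discrete change counts tie heavily — most bins are exactly
zero for most curves — which saturates the interval. The package
therefore also reports the standard extreme-rank-length refinement: the
sorted vectors of pointwise depths, computed with conservative
(shared-maximum) tie ranks, compared lexicographically. That point
p-value is used for verdicts; it is exact under exchangeability and
slightly conservative under ties (measured rejection ~2.5–5% at nominal
5%). Grid points where every curve is identical carry no ordering
information and are dropped.

Size correction regresses each trait on body length by GLS under
Brownian covariance (log-transform available but off by default, since
no transform is canonical); phylogenetic PCA eigen-decomposes the
GLS-estimated evolutionary covariance and centres scores on the
phylogenetic mean, reducing to ordinary PCA on a star tree. The node
height test regresses absolute standardised contrasts on node height by
OLS (no robust variant is standard here). Ward clustering uses
`hclust(method = "ward.D2")` on Euclidean distances with species order
as the deterministic tie-break; nine clusters is the default `k`.

## Trait-evolution models with a mode shift

The multivariate model family covers BM, EB/ACDC (instantaneous rate
multiplied by exp(r·t) with t measured from the root; ACDC is the same
transform with r allowed positive) and OU (scalar attraction α shared
across axes, keeping parameter counts modest), in single-mode form and
in all ordered mode pairs switching at a fixed age — by convention the
diversification-shift estimate, not re-optimised. "Independent drift"
gives the post-shift phase its own rate matrix Σ₂ (one extra symmetric
2×2 block, 3 parameters, consistent with the 9-versus-6 parameter
spacing of the family). Tip covariance is assembled additively over the
two time slices; a slice element at time u from the root contributes
du (BM), exp(r·u)du (EB), or exp(−2α(T−u))du (OU, decaying toward the
present). The OU decay-to-present convention is what makes a shift with
matched phase parameters exactly equal to the no-shift model, an
identity the tests assert at 1e-8. Means are profiled by GLS; mode
parameters are optimised from a small deterministic start grid; the
profiled mean counts toward k in the AIC. Parameter counts are derived
from these definitions rather than copied from any published table,
whose counts are internally inconsistent in places.

## Convergence (adaptive peaks)

The Hansen model gives each trait an OU process whose optimum follows a
regime painting of the branches; per trait its own α and σ², optima per
regime, traits independent given the painting, and the root at the root
regime's optimum (stationarity). Tip expectations are the classical
α-weighted mixtures of optima along root-to-tip paths. The forward
phase starts from one regime and adds, at each step, the shift (whole
branch, painting its descendants until overridden) that most improves
AICc — small-sample corrected, with sample size n·m and parameters
2m + (regimes)·m; shift locations are not counted, following the
stepwise convention. The backward phase greedily merges regime pairs
while AICc improves; surviving regimes reached by more than one origin
(counting the root) are convergent. For speed, α is profiled per trait
over a fixed 10-point log grid (0.5/T to 3 per My) with the OU
covariance Cholesky cached per grid value, so each candidate costs one
small GLS solve; the exact-likelihood function `hansen_loglik` is
retained and tested against the single-optimum OU model.

A property worth stating plainly: a stepwise search that accepts the
best of ~2n candidate shifts whenever AICc improves will accept spurious
shifts on pure noise quite often — the best candidate's likelihood gain
is the maximum of many correlated χ²(m) draws, which regularly exceeds
the AICc penalty for one extra peak. This overfitting propensity is
inherent to the acceptance rule, matches published experience with
stepwise OU-shift searches, and is why the backward phase and the peak
counts, not the raw forward shift count, are the interpretable outputs.

## Ancestral geography

Longitude/latitude are embedded on the unit sphere,
(cos lat·cos lon, cos lat·sin lon, sin lat), which removes the
distortions of treating degrees as Euclidean. Each Cartesian axis
evolves by BM with a single rate estimated by REML from contrasts and
shared across axes (isotropy of the embedding). Ancestral positions —
at nodes or at every lineage crossing a fixed age — are sampled from the
exact conditional Gaussian given the tips, including the
prediction-variance term for the flat prior on the ancestral mean, then
projected back to the sphere. Because the BM posterior is Gaussian,
exact sampling replaces MCMC with no change in distribution. The 95%
credible region keeps the ⌈0.95·N⌉ samples closest (great-circle) to
the normalised mean vector. For small extents this agrees with a naive
lon/lat reconstruction to first order.

## The synthetic reference dataset

`make_reference_dataset()` is first-class, tested code, and its defaults
are the study conditions every downstream test runs under: 377 tips,
crown age exactly 47 My, a speciation-rate increase at exactly 15.7 My,
six monophyletic clades of sizes 28, 41, 29, 41, 38, 25; habitat states
for 331 tips under a symmetric six-state process (root in the
interstitial/shallow pool); 11 correlated traits (body length in mm plus
ten dimensionless residuals) for 256 tips with a several-fold rate
increase after the shift; and spherical-BM coordinates from a
west-European origin. The tree is built as a slow diversity-dependent
backbone (λ₁ = 0.09/My, the pre-shift value of the fitted model family;
carrying capacity 505) carrying six fast post-shift radiations
(λ₀ = 0.5/My, per-clade K at 1.1× the clade size so each radiation shows
its own slowdown), grafted monophyletically onto stems older than their
crowns; the backbone itself saturates after the shift. Exact tip counts
come from resimulation (capped at 10,000 tries); with a tip-count target
and no fixed crown age the present is placed an exponential waiting time
after the count is first reached (the memoryless stopping rule, which is
what gives the pure-birth γ null its zero mean). Missing data are
injected at random tips — never whole clades, so clade definitions stay
valid — except that trait missingness is concentrated in one clade to
emulate a radiation whose disparity analysis is undeterminable. All
stochastic operations take explicit seeds; there is no global random
state.

What the generator does not emulate: phylogenetic uncertainty (a single
true tree, no posterior sample), measurement error in traits,
non-uniform sampling of missing data in the field, habitat-dependent
diversification (habitats evolve neutrally on the tree), and range
evolution with barriers. Passing tests therefore demonstrate that the
machinery recovers known structure under its own model assumptions, not
that those assumptions hold for any empirical system.

## Problem sizes used by the test suite

The statistical checks run at desk scale, chosen once: γ calibration on
1000 pure-birth trees of 100 tips (199 nulls each); carrying-capacity
recovery on 100 diversity-dependent trees of 36 tips; shift detection on
25 replicates of 150 tips under the study-shaped shift; stochastic-map
marginals from 10,000 maps on a 6-tip tree; CTT calibration on 100
replicates (30 tips, 5 maps, 59 exchangeable nulls); MDI centring and
envelope calibration on 200 replicates of 48 tips; node-height
calibration on 500 replicates (64 tips) and power on 200 replicates
(100 tips, r = 0.5); trait-model shift recovery on 25 replicates of 64
tips; convergence false-positive and recovery runs on 20 and 12
replicates at 40–48 tips. `scripts/acceptance.R` runs the full pipeline
once on the 377-tip reference dataset.

## Known limitations

* The shifted birth–death fits with free μ and finite K go through the
  ODE route and are markedly slower than the μ = 0 members; the default
  model set therefore exposes a `mu` argument so extinction can be fixed
  when the data cannot inform it.
* The α profile grid in the adaptive-peak search trades a little
  precision in α̂ for a large speed gain; optima and the peak structure
  are insensitive to this at the grid density used.
* The rank envelope p-interval saturates under heavy ties; use the
  extreme-rank-length point p-value for decisions.
* Multi-tree (posterior-sample) analyses are supported by mapping the
  single-tree functions over a list of trees; the package does not
  weight trees by posterior probability.
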