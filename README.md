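# karstrad

Diagnosing adaptive radiation on time-calibrated phylogenies.

Adaptive radiations leave three coupled signatures on a clade: a burst of
lineage accumulation that later slows, rapid diversification of ecological
(habitat) states, and a late expansion of morphological disparity, often
with convergence onto a limited set of adaptive peaks. `karstrad`
implements the full inference pipeline used to diagnose this pattern on an
ultrametric chronogram (branch lengths in My), with a synthetic-data
generator that reproduces the dimensions and statistical structure of a
large subterranean radiation (377 tips, crown age 47 My, a
diversification-rate shift at 15.7 My, six focal subclades), so every
stage is testable without external data.

## What it computes

**Lineage diversification.** The γ statistic of node-time concentration,

γ = [ (1/(n−2)) Σᵢ₌₂ⁿ⁻¹ Σₖ₌₂ⁱ k·gₖ − T/2 ] / ( T·√(1/(12(n−2))) ),

with Monte-Carlo pure-birth nulls conditioned on tip count; and
maximum-likelihood fits of birth–death models with diversity dependence
λ(N) = max(0, λ₀ − (λ₀−μ)N/K) and a single rate shift at an estimated time
t, compared by Akaike weights. The μ > 0 likelihood integrates the
master equation of hidden (doomed) lineage counts between branching
events, conditioned on crown age and survival of both crown lineages; the
μ = 0 members collapse to an exact analytic form.

**Ecological disparification.** Mk (ER/SYM/ARD) model fitting by the
pruning algorithm with missing states integrated out, stochastic character
mapping (conditional node sampling plus uniformization of within-branch
histories), changes-through-time (CTT) curves — mean changes per unit
branch length per time bin — against simulated nulls under the fitted Q,
and ancestral habitat frequencies across maps.

**Morphological disparification.** Disparity (mean squared pairwise
Euclidean distance), disparity-through-time (DTT) curves with Brownian
nulls using the estimated trait covariance, the morphological disparity
index (MDI, the integrated observed-minus-null curve), global rank
envelope tests with an extreme-rank-length tie refinement, PGLS size
correction, phylogenetic PCA, the node height test, Ward clustering of
morphotypes, and multivariate trait-evolution models (BM / EB / ACDC / OU)
with a fixed-time mode shift and optional independent post-shift drift.

**Convergence.** A stepwise-AICc search for multi-optimum
Ornstein–Uhlenbeck (Hansen) adaptive peaks: forward addition of regime
shifts on branches, backward merging of similar peaks, and a count of
convergent versus unique peaks.

**Geography.** Ancestral range reconstruction by Brownian motion on
sphere-embedded Cartesian coordinates, sampled from the exact conditional
Gaussian given the tips, with 95% centroid-trimmed credible regions at
nodes or fixed time slices.

## Worked example

```r
library(karstrad)

b <- make_reference_dataset(seed = 1)   # 377-tip synthetic radiation
gamma_test(b$tree, n_null = 1000, seed = 7)
#> Gamma test: gamma = -6.8799, p = 0.000999 (less, 377 tips, 1000 nulls)

f1 <- fit_diversification(b$tree, diversification_model("lambda", mu = 0))
f0 <- fit_diversification(b$tree,
                          diversification_model("none", dd = TRUE, mu = 0))
f1
#> shift in speciation rate: logLik = -1137.201, k = 4, AIC = 2282.40
#>   la1 = 0.1203, mu1 = 0, K1 = 454 | la2 = 0.2705, mu2 = 0, K2 = 454, t-shift = 14.42
compare_models(list(shift = f1, none = f0))
#>   model    logLik k      AIC     dAIC         AICw
#> 1 shift -1137.201 4 2282.402  0.00000 9.999484e-01
#> 2  none -1149.073 2 2302.146 19.74389 5.159953e-05
```

The strongly negative γ (early burst) and the decisive support for a
speciation-rate increase dated within ~1.3 My of the generator's true
shift (15.7 My) are exactly the diagnostics the pipeline is built to
recover. Habitat, disparity, convergence and geography stages run the
same way; `run_pipeline()` chains them from one configuration (list or
YAML) into a directory of tab-separated reports, genus-wide and per
clade.

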