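---
title: "Models and methods behind muldekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind muldekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

muldekit packages the quantitative machinery for a recurring situation in
palaeobiology: a stratigraphic series of fossil assemblages shows an
apparent body-size decrease across an environmental crisis (a Lilliput
effect), and the question is whether the pattern survives honest
treatment of sampling noise and record incompleteness. This vignette
explains the models, the tunable parameters, what the synthetic
generators do and do not emulate, and the numerical conventions — it is
the design record for the package.

## 1. The size series and the change statistic

The unit of analysis is the *assemblage*: one dated locality with its
lateral-arm-plate areas (mm²). Plate area is a proxy for arm size, not
disc diameter; nothing in the package tries to convert between the two.
When only plate length and width are available, area is a fixed
convention: `rectangle` (length × width, the default) or `ellipse`
(π/4 × length × width). The choice is a global multiplicative rescaling,
and because the permutation test below is scale-equivariant it provably
cannot change any p-value; the default is therefore the simplest option
rather than a substantive claim about plate geometry.

For a crisis event the user names the oldest and youngest bounding
assemblages (an explicit events table — the pairing is scientific input,
not something the code infers), and the statistic is the difference of
means, Δ = mean(oldest) − mean(youngest), positive for a decrease.
Exactly two assemblages enter Δ; intermediate localities affect the null
distribution (they contribute to the permutation pool) but not the
observed statistic.

Localities with fewer than `min_n = 2` plates are excluded (a singleton
carries no variance information and cannot enter the simulation); the
exclusion is logged by name.

## 2. The Monte Carlo permutation null

Each of `n_sims` (default 10,000) iterations:

1. **simulates** a hypothetical fossil record — for every locality, `n`
   draws from Normal(mean, SD) with the empirical per-site moments and
   sample size (sample SD, n−1 denominator, matching the simulator);
2. **permutes** it — all simulated values are pooled and reassigned at
   random to localities, each keeping its `n` and age ("pool" mode, the
   default and the worst case for temporal signal; an "age-shuffle" mode
   that permutes only the age labels is available for sensitivity);
3. records Δ of the permuted record for every event.

The p-value is one-tailed for a decrease by default (the scientific
claims are directional), with `(1+k)/(1+n_sims)` add-one correction:
zero exceedances at 10,000 simulations gives 1/10001, which is why such
results are quoted as bounds (p < 1e-4) rather than zero. Two-sided and
increase tails are configuration, not code edits.

Two deliberate modelling choices: the normal distributions are **not
truncated at zero** — the stated model is a plain normal, and truncating
would quietly shift small-mean sites — so negative simulated areas are
possible; their count is logged as a diagnostic. And all events share one
simulation stream per iteration (each simulated record is examined across
all events), which is both faster and closer to "simulate a record, look
at all three crises" than independent streams per event.

Seeding uses a master seed plus a per-iteration substream seed
(`(master·69069 + k·1000003) mod (2³¹−1)`), so draw *k* is reproducible
in isolation and the whole analysis is bit-reproducible.

Calibration is a tested property, not an assumption: under a global null
(all localities one normal) the rejection rate at α = 0.05 must sit in
the exact binomial 99 % band over 1000 replicate analyses, and an
injected 2-SD decrease with n = 20 per site must be detected with power
> 0.9 (the test suite runs these with 399 simulations per replicate, at
which the add-one rejection rule has exact level 20/400 = 0.05).

## 3. Completeness and ancestor–descendant sampling

With extinction rate μ and fossil sampling rate ψ (per lineage per Myr),
an extinct taxon's chance of being sampled at least once is the chance
the first sampling event beats extinction, accumulated over its lifetime:
Φ = ψ/(μ+ψ). Sampling both members of an ancestor–descendant pair
requires two independent successes, Pr[AD] = Φ². `per_stage_completeness()`
applies these per posterior draw and summarizes with quantiles
(R type 7, midpoint interpolation — the median of two draws is their
mean; stated here because two-draw stages appear in tests).

The forward simulator `gen_fbd_record()` is the independent check on
this algebra: exact event-time simulation (competing exponentials per
lineage, rates switching at stage boundaries — no time discretization,
so no discretization bias in the oracle), budding speciation in which
the mother taxon persists, and Poisson(ψ) occurrences along each
taxon's duration. The empirical sampled-fraction of extinct taxa matches
Φ within binomial error in the acceptance suite.

## 4. Sampled ancestors on posterior trees

Two serialization conventions for sampled ancestors circulate, and the
producer of a tree file rarely documents which one it used; both are
first-class here. A tip is flagged as a sampled ancestor if its pendant
branch is ≤ `sa_branch_tolerance` (default 1e-8 Myr — effectively "zero
within round-off" and far below any real stratigraphic duration), or if
it carries an explicit `[&SA]` comment, which overrides the length rule.

"*a* is an ancestor of *b*" requires the flag **and** that *b* descends
from *a*'s attachment node; descent is transitive, because
sampled-ancestor placement is about lineage identity, not tree
adjacency. Posterior support is plain counting over the sample. Because
the underlying phrase "placed as an ancestor" is genuinely ambiguous
between "ancestor of a specific taxon" and "ancestor of anything",
`ad_posterior()` implements both (`b = taxon` or `b = "ANY"`) and the
pipeline reports both rather than guessing.

Per-branch rate multipliers (relaxed-clock output, retained from
`[&rate=…]` comments) are summarized on a reference tree by rooted
clade identity: each reference branch gets the mean multiplier over
sample trees containing the same subtended tip set, plus a support
count. Sampled-ancestor pendant branches have zero duration and are
excluded from the mapping. The maximum-rate branch is reported with a
deterministic tie rule (smallest clade, then lexicographic tip labels,
tie logged).

## 5. Three-timer sampling probabilities and the Beta prior

For interior interval *i*, 3T counts taxa present in *i−1*, *i*, *i+1*
and PT those present in *i−1* and *i+1* but not *i*; the sampling
probability estimate is 3T/(3T+PT). This is the basic, enumerable form —
no cross-interval correction factor is applied (the corrected variant is
deliberately left unimplemented; the uncorrected ratio is the version an
exhaustive enumeration oracle can confirm cell by cell). Edge intervals
and interiors with 3T+PT = 0 are NA, not errors.

Probabilities convert to rates assuming Poisson sampling within each
interval's own duration from the user-supplied stage table
(ψ = −log(1−p)/Δt; p = 1 is rejected as an infinite rate). The Beta
prior is moment-matched on the unweighted mean and variance of the
per-interval rates — no duration weighting, since the target is the
distribution of rates across intervals — with the feasibility bound
variance < mean(1−mean) enforced. Note the moment-matched Beta only
exists when the mean rate is below 1/Myr; with faster sampling a Beta
prior on the rate is the wrong family, and the function says so rather
than clamping.

## 6. What the generators emulate — and what they do not

`gen_assemblages()` draws per-locality normal samples with an optional
step decrease at a named event age: that is exactly the world the
permutation test assumes, so a green calibration test establishes that
the test is correct *under its own model*. Real plate data add
taphonomic sorting, non-normal size distributions, age-model error and
autocorrelated trends, none of which are emulated; a green test here
does not certify robustness to those.

`gen_tree_sample()` builds random topologies and plants the designated
ancestor–descendant pair in exactly `round(ad_fraction × n_trees)` trees
(a zero-length tip attached on the descendant's pendant edge), so
`ad_posterior()` must return `ad_fraction` exactly — a construction
oracle, not a statistical one. The trees are not FBD-distributed; they
exercise counting and parsing, not tree-model fit.

`gen_occurrences()` gives each taxon a contiguous true range (both
endpoints uniform over intervals) and Bernoulli presence within range;
with constant p the three-timer estimator is conditionally unbiased for
p, which the consistency test checks at 3 binomial SEs. Range-through
biases from non-contiguous true ranges are out of scope.

Defaults that are the stated world rather than tuning: 10,000
simulations per test, min_n = 2 (the singleton-exclusion rule), one
normal per locality, budding speciation in the FBD simulator. The
shipped locality table is a *synthetic stand-in* (the original
supplementary measurements are archived externally): locality names,
ordering, total count > 1300, the Hoburgen singleton and a ~4× drop at
the Mulde event follow the published description, and its numbers were
fixed once, before any test was run.

## 7. Numerical conventions and degenerate inputs

- Ages are Ma before present, larger = older; intervals are half-open
  [start, end). One convention, enforced everywhere.
- Sample SD uses n−1 everywhere (summaries and simulator alike).
- An SD of 0 is legal: simulation then returns the site mean exactly.
- p-values never equal 0 (add-one) and never exceed 1.
- All file formats are plain text (CSV with `#` comments, Newick/NEXUS,
  JSON config); every generator writes its seed into the output header
  and its truth into a `.truth.json` sidecar.
- JSON is the only configuration format (no YAML dependency).

## 8. Known limitations

- The Bayesian tip-dating inference itself (Mk likelihood, clock and
  SA-FBD priors, MCMC) is out of scope; the package consumes its
  outputs. Headline inferential numbers of that kind (e.g. a specific
  branch's 24.76 rate multiplier) appear in tests only as fixture
  constants for the summarization code.
- The permutation test treats localities as exchangeable under the
  null; it does not model autocorrelated evolutionary trends (random
  walks, OU) — rejecting the null rejects "no signal at all", nothing
  finer.
- Branch identity across trees uses rooted clades; trees with
  conflicting root placements will map rates onto fewer shared
  branches (reported via support counts and NA means).
- `read_nexus_matrix()` targets standard discrete morphology blocks
  (symbols 0–9, `?`, `-`); interleaved matrices surface as a
  dimension error rather than being silently concatenated.
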