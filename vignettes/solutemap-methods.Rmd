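---
title: "Methods: Bayesian stochastic mapping of habitat preference and pathway characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian stochastic mapping of habitat preference and pathway characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solutemap)
```

## The problem

Habitat preference in cyanobacteria — the propensity to grow in high- (`H`)
or low-salinity (`L`) water — is a complex trait underpinned by the
biosynthesis of compatible solutes (sucrose, trehalose, glucosylglycerol,
glucosylglycerate, glycine betaine). Each pathway is encoded by one to three
genes whose presence or absence in a genome is easy to score, and salt
tolerance physiology says the solute repertoire should covary with habitat.
`solutemap` implements a Bayesian stochastic-mapping workflow that infers the
joint evolution of such a focal trait and the pathway characters it depends
on, on a *sample* of dated trees, so that uncertainty in node ages, model
choice, model parameters, and character histories all propagate into the
final estimates.

## Models

Every Markov character evolves by a continuous-time Markov chain on its state
space. Time is measured in Myr (node ages in Ma before present, tips at 0),
so all rates are per Myr. Four parameterizations of the generator are
supported for a binary character: `UNI` (one direction only), `ER` (one rate
both ways), `SYM`, and `ARD` (each ordered pair its own rate); on an
`s`-state space these carry 1, `(s^2-s)/2`, and `s^2-s` free rates for
ER/SYM/ARD. Multi-gene pathways are modeled either as independent characters
(the generator of the joint process is the Kronecker sum of the per-gene
generators, so simultaneous changes have rate zero) or as a single dependent
"supercharacter" on the product space — for two genes the states are ordered
`(AA, AP, PA, PP)` with the first gene varying slowest, which is also how the
gain (`AA` to anything), loss (`PP` to anything), and exchange
(`PA` <-> `AP`) rate classes index into the generator.

The model space enumerated for a pathway applies one parameterization tag
uniformly across the blocks of each dependency partition, and offers SYM only
where a block spans more than two states. This convention reproduces the
published counts — 5 candidate models for a 2-gene pathway and 14 for a
3-gene pathway — and is, to our knowledge, the only uniform-tag rule that
does; per-block tag mixing would inflate the space combinatorially (this was
a genuinely open design point and is isolated in
`enumerate_pathway_models()`).

The focal character can instead be *conditioned* on the others: it has no
rates of its own, and its state is drawn from a conditional probability table
`pi(focal | joint state of the conditioning characters)`. This needs about
`s^n` parameters instead of `s^(2n)` and avoids exponentiating large
generators. In the likelihood, each tip contributes
`pi(observed focal | conditioning tip state)`; when a conditioning tip is
ambiguous the sum over its allowed states is carried inside one pruning pass
on the joint (Kronecker-sum) space, and the test suite asserts the exact
factorization identity in the unambiguous case.

## Inference

`mle_fit()` maximizes the pruning likelihood by multi-start Nelder-Mead on
log rates (Brent for one parameter), with rates bounded to `[1e-9, 1e3]`
per Myr; conditional tables have a closed-form row-wise multinomial MLE when
tips are unambiguous, which separates exactly from the rate optimization.

Priors follow an empirical-Bayes recipe: LogNormal(log MLE, 1) per rate —
median at the MLE and ~98% of mass (exactly 0.9787) within a factor 10 of it
— switching to Exponential(100 per Myr^-1) when the MLE is at or below 0.01,
because a log-normal centered on a vanishing estimate would be degenerate.
The same Exponential(100) on every rate is the "low-rates" prior expressing
that marine–freshwater switches are rare. Conditional-table rows get flat
Dirichlet priors. The root prior over states is uniform by default
(configurable to stationary or a fixed vector); the choice matters for deep
nodes, which is why it is exposed rather than hidden.

`mcmc_sample()` is a Metropolis–Hastings sampler with log-multiplier
proposals on rates, Dirichlet proposals on table rows, and a uniformly
resampled tree index each iteration — the tree sample is an equally weighted
set of draws from a clock posterior, and resampling its index integrates
over it as a nuisance parameter. Convergence diagnostics are per-parameter
ESS (initial-positive-sequence estimator) and rank-normalized split R-hat
across chains; a low ESS is recorded as metadata, not an error.

`stepping_stone_logml()` estimates the log marginal likelihood with a
power-posterior ladder `beta_k = (k/K)^(1/0.3)` (Beta(0.3, 1) quantiles,
concentrating rungs near the prior, where the integrand varies fastest). The
prior rung is sampled i.i.d.; each subsequent rung continues the chain at its
power; the estimate sums per-rung log mean importance ratios, with a standard
error from each rung's weight ESS. For independent multi-block models the
marginal likelihood factorizes and is computed block-wise and summed — exact
and much cheaper. Model posterior probabilities use a uniform model prior:
the empirical-Bayes priors are equally spread on the log scale across models
(same sigma), so spread-based model priors would add complexity without
changing the comparison.

## Stochastic mapping

Histories are drawn by (i) sampling all node states jointly from the exact
conditional distribution (root from prior x partial, then a pre-order
descent), and (ii) filling each branch with an endpoint-conditioned CTMC path
by uniformization with constant `Omega = 1.05 x max |q_ii|` — a small
virtual-jump overhead while keeping `R = I + Q/Omega` comfortably
substochastic-safe. A plain rejection sampler exists solely as an independent
oracle; the suite checks both samplers agree in distribution. Branches whose
expected uniformized jump count exceeds 5e4 abort with an error: on a
3000-Myr tree that regime only arises from degenerate rate estimates and
histories there would be meaningless.

For a conditioned focal character, the path-level behaviour between
conditioning change-points is not determined by the tip likelihood alone.
The semantics implemented: the joint conditioning state is piecewise constant
along the tree; on each maximal constant segment the focal state is drawn
once from the table row, independently across segments, except that the
segment abutting each tip is clamped to the observed focal state (drawn from
the table row restricted to the allowed set if the observation is
ambiguous). This reproduces the factorized tip likelihood and yields
branch-wise focal posteriors; it is isolated in `overlay_conditioned()` so
alternative semantics can be swapped in.

Model averaging happens at the history level: each draw picks a model with
probability equal to its mPP, then a retained posterior draw of that model
(whose stored tree index selects the tree).

## The D-test

For two mapped characters, each draw yields joint dwell-time fractions
`A_ij` and marginals `a_i`, `b_j` over the whole tree; the deviation
`Delta_ij = A_ij - a_i b_j` is averaged over draws into the effect `d_ij`
(reported in percent), with `D = sum |d_ij|`. The deviation is taken against
the product of *same-draw* marginals: that choice makes the row/column sums
of `d` exactly zero, so for binary pairs `d_11 = d_22 = -d_12 = -d_21`,
`D = 4|d_11|`, and all per-cell P values coincide — the symmetry structure
the test suite asserts. Significance is posterior-predictive: each null
replicate simulates both characters forward — tip data and all — under an
independent-evolution null with one posterior parameter/tree draw, and
recomputes the same statistic; `P` is the fraction of replicates whose null
statistic reaches the observed one. A replicate may carry a whole batch of
history draws whose mean is its statistic: that mirrors the posterior-mean
construction of the observed `d` and makes the two exchangeable under the
null, which is what calibrates the rejection rate near the nominal level
(single-draw null replicates are also supported and are conservative — their
statistics are noisier than the observed mean). Raw P values are reported
with a 5% threshold flag and no multiple-testing correction across candidate
characters.

## Post-processing

From a history collection the package computes: node posteriors and
branch-time posteriors on a regular age grid (default 10 Myr; branches
matched across trees by tip-set bipartition, so draws on trees lacking a
bipartition contribute only to branches they have); first-occurrence ages of
a state condition (per draw, the oldest age at which any lineage satisfies
it, with the probability the event predates a reference age such as the
Great Oxygenation Event at 2460 Ma); transition rates through time (counts
per bin divided by lineage-time in lineage-Gyr; default 100-Myr bins — the
underlying quantity is continuous, binning is a presentation choice);
gain/loss/exchange rate-class sums and their ratios per posterior draw; and
HPD intervals (shortest contiguous window, defaults 0.89 and 0.95, with a
multimodality warning when the shortest window is >10% shorter than the
central interval — relevant because first-occurrence ages can be genuinely
bimodal).

## Synthetic data

`benchmark_dataset()` generates the study conditions the tests run under:
one birth–death topology (conditioned on the taxon count) scaled to a
3200-Ma root, replicated into a tree sample by log-normal jitter (sd 0.05
log-units) of internal node ages — emulating dated trees saved from a
relaxed-clock chain with a fixed topology — and characters simulated forward
under known rates in the 1e-3 to 1e-2 per-Myr range, the magnitudes a
3200-Myr-deep tree implies. Presets: `tiny` (8 tips, 10 trees), `small`
(50 tips, 100 trees, ARD habitat + 2-gene ER pathway), `study_scale`
(189 tips, 1000 trees, five pathway characters and a habitat character drawn
from a table favouring high salinity when the GG-like pathway is complete or
the GGA-like character present). What the generator does *not* emulate:
topology variation across the tree sample (the clock run used a fixed
topology, but all downstream code matches branches by bipartition and
tolerates varying topologies), correlated gene gain via lateral transfer
bursts, time-varying rates, and sampling biases in taxon selection — so
passing tests demonstrate algorithmic correctness under the stated model,
not robustness to violations of it.

## Numerical choices and problem sizes

Binary generators use closed-form transition probabilities (vectorized over
all edges inside the pruning pass); equal-rates generators on any state count
use the complete-graph closed form `P(t) = e^{-srt} I + (1 - e^{-srt})/s J`;
other generators are eigendecomposed once per pruning pass (complex
arithmetic, validated by reconstruction) with per-edge exponentials, falling
back to scaling-and-squaring for defective matrices. Pruning partials are renormalized per node with the
log-norm accumulated, so likelihoods of 189-taxon product spaces do not
underflow. Ultrametricity is enforced within `1e-6 x` root age
(configurable; non-ultrametric inputs can be repaired by clamping tips to
age 0). Ties at HPD boundaries resolve to the first shortest window.

The test and example sizes are desk-scale choices: MCMC chains of 1e4–6e4
proposals, stepping stone with 8–16 rungs and a few hundred to 2500 samples
per rung, 60–100 history draws per D-test side, 20-seed recovery studies on
the 50-tip preset. Production analyses should scale these up (the original
habitat analyses used chains of ~1e6 proposals, 32 rungs with 1e4 samples,
and 5000 exported histories); all sizes are plain arguments
(`fit_control()`, `mcmc_config()`).

## Known limitations

Rate magnitudes of a binary character on a deep (multi-Gyr) tree are weakly
identified once the state correlation length `1/(r_LH + r_HL)` falls below
the deep branch lengths: tips then behave like nearly independent draws from
the stationary distribution, the likelihood develops a broad ridge/plateau in
the rate plane (the same broad-peak geometry the habitat landscape shows),
and under the Exponential(100) fallback prior the posterior median of an ARD
rate can sit several-fold above a simulated truth even when computed exactly
by quadrature. The 20-seed recovery study in the test suite documents this
honestly at the 50-tip scale: the equal-rates pathway rate recovers within a
factor 2, the ARD habitat rate magnitudes do not, and neither longer chains
nor the joint rate-scale proposal change that (it is a property of the
posterior, not the sampler). Rates and conditional probabilities are
constant through time and across lineages; the conditioned overlay's between-change-point semantics is a
modeling choice (see above); the approximate combination weights for large
conditioned models assume the per-character marginal-likelihood differences
transfer to the composite models (they do when the additional characters'
contribution is insensitive to the alternatives, which the component
analyses can verify); and ML-based fits reuse the MLE in every mapping draw,
understating parameter uncertainty relative to the Bayesian path.
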