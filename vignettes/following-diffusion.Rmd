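---
title: "Following networks and time-of-acquisition diffusion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Following networks and time-of-acquisition diffusion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggdiff)
```

`aggdiff` analyses how a behavioural trait — here, discovery of a novel food
patch in the corner zone of a compartmentalized arena — spreads through small
collectives of non-grouping animals. This vignette documents the models, the
conventions and the numerical choices, in the order the pipeline applies
them.

## From event logs to occupancy

The raw input is a BORIS-style event log: point events for zone transitions
(trial, individual, time in seconds, origin and destination zone, flag) and
state events for feeding bouts. Two exclusion rules apply before any
analysis: transitions flagged as pre-trial escapes are removed entirely,
while transitions flagged as startle/pushed transits are kept for occupancy
(the animal did move) but are ineligible on either side of a following
interaction. Flags rather than deleted rows keep the raw export auditable.

The arena is a `zone_graph`: a set of zones, a set of gates, a start zone and
a target zone. The default is a 3×3 lattice with rook adjacency (12 gates),
start in corner zone 1 and target in the opposite corner zone 9. Because the
physical gate layout of any particular arena may differ, every function
depends only on the graph object, which can be built explicitly or read from
YAML.

Occupancy intervals are **half-open** `[enter, exit)`: at the instant of a
transition the individual is in the destination zone. This convention makes
the "leader still in the zone when the follower arrived" predicate decidable
when a follower arrives exactly as a leader departs (the leader is gone), and
it assigns a conspecific count unambiguously at transition instants. The
trial's final instant belongs to the last interval. Equal event timestamps
are ordered stably by file order — the export's own ordering at its time
resolution is taken as authoritative, since the data carry no finer
information.

## Following interactions and individual networks

A transition makes its individual a *leader* through that gate; a *follower*
is another individual that later transits the same gate (same origin, same
destination) while the leader still occupies the destination zone. Two caps
keep the mapping one-to-one:

* each leader transition credits at most one following — its first follower;
* each follower transition is attributed to at most one leader — the most
  recent eligible leader transition through that gate that has not yet
  credited a follower, falling back to the next most recent open one when
  the most recent is already credited. Equal leader times resolve to the
  later-listed event.

The fallback rule is a genuine design choice: with several recent leaders
through the same gate the observable data cannot say which one was followed.
Crediting the most recent open leader keeps both caps while discarding the
fewest candidate interactions; the brute-force re-derivation used in the
tests applies the same rule independently, so the choice is at least applied
consistently.

Tie strength from focal `i` toward partner `j` sums reciprocal following
latencies, standardizes by `i`'s discovery time and scales to a 10-minute
rate: `w_ij = sum(1/Δt) / t_i × 600`. Only followings that occur before the
focal's own discovery contribute — the network is meant to explain that
discovery, so later interactions are outside its window. Focals that never
discover are standardized by the full trial duration (2400 s), their actual
exposure. A focal's leader-side events after its own discovery can still
seed followings in *other* (still naive) focals' networks; only the
follower's window is truncated.

The exploration rate — the focal's pre-discovery transitions that were not
the follower side of any interaction, per 10 minutes — enters the diffusion
models as the asocial individual-level covariate. The follower side of a
following still counts as a zone transition for occupancy and transition
totals; it is excluded only from this numerator.

## The diffusion models

Acquisition (first entry into the target zone) is modelled with the
continuous time-of-acquisition variant of network-based diffusion analysis.
Naive individual `i` acquires at hazard

```
lambda_i(t) = lambda_0(t) * (1 - z_i(t)) * R_i(t)
R_i(t) = s * sum_j a_ij z_j(t) + (1 - s) * exp(sum_k beta_k x_ki)   (additive)
R_i(t) = (s * sum_j a_ij z_j(t) + (1 - s)) * exp(sum_k beta_k x_ki) (multiplicative)
```

where `z_j(t)` is 1 once `j` has acquired (uncensored individuals only),
`a_ij` is the focal's own network row — for individual following networks the
weight of `i`'s ties toward `j` — and `x` are the ILVs. The model grid varies
the baseline (constant, or the hazard of a gamma distribution parameterized
by shape and rate, shape 1 recovering the constant case exactly), the
interaction form, the structure of `s` across collective types (absent,
C-only, S-only, shared, by type), the network (following or homogeneous
all-ones) and the ILV set. `default_model_grid()` enumerates the 52 distinct
cells this produces for one ILV; equivalent cells (interaction form without
both `s` and an ILV; network without `s`) are normalized so the grid holds no
duplicates. The first discoverer of each collective necessarily acquires
through the asocial term — there is no seeding parameter.

**The `(1 - s)` asocial weight.** Under the conventional additive
parameterization the asocial term carries weight `(1 - s)`, which becomes
negative when `s > 1` even though estimates well above 1 are entirely
plausible. The package implements the printed form exactly and floors every
relative-rate evaluation at `1e-12`; it also provides an `asocial_weight =
"unit"` switch giving `s·network + asocial`, which is well behaved for all
`s ≥ 0`. Simulation studies of recovery at `s > 1` use the unit form for both
generation and fitting, because under the complement form the first
acquisition in a fully naive collective would have (floored) rate near zero
and no diffusion could start. Results tables record which form was used via
the spec.

**Likelihood.** Within a collective the informed set is piecewise constant
between acquisition events, so the log-likelihood is a sum of event terms
`log lambda_i(t_i)` and survival integrals computed segment-by-segment as
`R_i × ΔH`, with `H` the baseline cumulative hazard (`λ0 t` constant;
`-log S_gamma(t)` computed on the log scale for the gamma baseline).
Collectives are independent. Simultaneous acquisition times are processed in
stable order, the earlier-listed event informing the later; the zero-length
segment between them contributes nothing to the integral.

**Fitting.** Parameters are optimized on unconstrained transforms: log for
`lambda0` and the gamma shape, softplus for the nonnegative `s` parameters,
identity for betas. For every constant-baseline model `lambda0` is profiled
out analytically (the log-likelihood is `n log λ0 + const − λ0 I`), which
reduces the asocial constant-baseline fit to the closed-form censored
exponential MLE `events / exposure` and leaves at most a few free parameters
elsewhere; those are optimized by golden-section search (one parameter) or
multi-start Nelder–Mead with BFGS polishing (several), five jittered starts
by default, and an honest `converged` flag. AICc uses `n` = the number of
uncensored acquisition events — each event is one likelihood term; this is
the package's convention (the literature is not uniform) and is configurable
via `options$aicc_n`.

**Profile confidence intervals.** Bounds solve
`2 (logL_max − profile logL(θ)) = χ²₁(0.95)` by bracketed root search,
re-optimizing all other parameters at each candidate θ. Lower bounds of `s`
parameters are clipped at 0 when the profile never drops enough there
(including whenever the estimate itself sits on the boundary); a bound the
profile never crosses within the search range is reported open with an
attribute. Because profiles of `s` are typically strongly asymmetric,
unconditional (Wald) standard errors are deliberately not offered; the
model-averaged estimates carry *conditional* CIs taken from the
highest-ranked model of the best set that contains the parameter.

**Model averaging.** The best-model set is everything within 5 ΔAICc of the
top model. Averages are weighted means over the models that contain the
parameter, with weights renormalized within that subset (natural averaging);
`renormalize = FALSE` gives the zero-shrinkage alternative. `p_social`
evaluates `sΣ/(1+sΣ)` per uncensored discoverer at its acquisition instant
and averages over discoverers; by default it is restricted to C collectives
with the model-averaged `s_C`, the context in which a social transmission
estimate is interpretable, but the collective filter and the `s` source are
arguments.

## What the simulators emulate — and what they do not

Two levels are deliberately separated. The **arena simulator** generates
event logs with the structure the ingest chain assumes: collectives of 8 on
the 9-zone arena for 2400 s, exponential per-individual movement at 0.66
transitions/min for controls (about 26 transitions per individual per trial,
the observed order of magnitude) and 0.55× that for tutors (tutors are less
active), a gate-choice bias of 3 toward gates a conspecific used within the
last 10 s and still stands behind, and feeding onset delayed by exponential
neophobia (mean 12000 s for naive individuals — most never feed within a
trial — versus 1500 s for tutors). These defaults are the simulated study
conditions; they were chosen once for realism, not fitted to anything. The
**hazard simulator** draws acquisition times exactly from the model's own
hazard by total-cumulative-hazard inversion, so parameter-recovery targets
attach to it alone: arena trials do not make the NBDA model literally true
(gate bias is local and memoryless, visual range is not modelled), so
end-to-end arena runs support only qualitative claims — e.g. that following
bias raises the support of following-network models. Passing tests therefore
show internal correctness and qualitative behaviour, not that real tadpole
data satisfy the model.

Test and acceptance problem sizes are the package's own choices: likelihood
checks run 50 randomized instances of up to 8 individuals on 200 s horizons
against 0.01 s-grid quadrature; recovery runs about 200 replicates of 16
collectives × 8 individuals at `s ∈ {2, 5, 10}`; selection sanity runs 100
replicates per regime; the network detector is cross-checked against an
all-pairs oracle on 100 simulated trials.

## Known limitations

* The default rook-adjacency gate layout is a stand-in for whatever physical
  layout a given arena has; analyses of real data should supply the true
  graph.
* Networks are static within a trial; time-varying weights and
  order-of-acquisition (OADA) variants are out of scope.
* Individual networks enter through the focal's own row only; reverse ties
  play no role in that focal's hazard.
* The gamma-baseline likelihood requires shape > 0 but is numerically
  delicate for shapes far below 1 (hazard singular at 0); fits there rely on
  the floor and the multi-start machinery.
* `p_social` interprets the fitted `s` causally within the model; it is a
  model-based decomposition, not an observed fraction.
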