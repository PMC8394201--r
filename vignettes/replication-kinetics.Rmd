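---
title: "Modelling stochastic origin firing and DNA combing observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stochastic origin firing and DNA combing observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replifire)
```

## The model

replifire simulates S-phase DNA replication on a one-dimensional lattice
of `L` blocks, one block per kilobase -- the spatial resolution of DNA
combing. A block is 0 (unreplicated) or 1 (replicated). Replication
initiates at *potential origins*, either one per block ("continuous"
layout) or scattered at random with a mean spacing of 2.3 kb
("discrete" layout, the default, matching the measured density of
licensed origins in *Xenopus* egg extracts).

Firing is limited by a trans-acting factor pool that grows linearly in
time, `N(t) = N0 + J t`. In each Monte Carlo round every unreplicated,
origin-eligible block draws a uniform number and becomes a firing
candidate when the draw falls below its firing probability. If more
candidates exist than free factors, a uniform random subset of size
`Nf(t) = floor(N(t)) - Nb(t)` fires; `Nb` is the number of sequestered
factors. Each firing sequesters one factor and creates two diverging
forks; forks advance one block per round (0.5 kb/min with 2-minute
rounds) and an eye therefore grows symmetrically by 2 blocks per round.
When converging forks meet they coalesce and release their factor; a
fork reaching a chromosome end counts as half a release, which makes
factor conservation exact: at completion `fired_total =
released_total`, and at all times `Nb` equals half the number of active
forks.

The nested variants toggle three refinements:

* **MM1** -- mean field: a single probability `Pout` everywhere.
* **MM2** -- variable fork speed: each active fork independently draws
  its speed from {0, 1, 2, 3} kb/min every round.
* **MM3** -- fork-proximal stimulation: within `d` kb downstream of an
  active fork the firing probability is `Plocal` (replacing the
  background value). "Downstream" means ahead of the fork, over
  unreplicated DNA, truncated at the next replicated block.
* **MM4** -- genome heterogeneity: a fraction `theta` of the genome
  fires with probability `Pin`, the rest with `Pout`.
* **MM5** -- MM3 + MM4 combined; all seven parameters are active.

In the unlimited-factor, continuous-origin MM1 limit the model is a
lattice nucleation-and-growth (KJMA-type) process with the exact
closed-form kinetics `f(t) = 1 - (1 - p)^(t^2)` for unit fork steps;
the test suite holds the simulator to that law within 0.02 absolute.

### Units and the round clock

One round represents `round_minutes` of real time, 2 min by default:
symmetric 2-block growth at 0.5 kb/min per fork. The import rate `J` is
expressed in factors per round internally. Published parameter tables
for this class of models sometimes print `J` in s^-1, which cannot be
reconciled exactly with a 2-minute round without an explicit convention;
users consuming such values should rescale `J` themselves (multiply by
seconds per round if the printed value is truly per second). All results
in this package are stated in the per-round convention.

### Two segmentation modes

`generate_region_mask()` supports block-level segmentation (exactly
`round(theta * L)` IN blocks chosen uniformly -- the default for
fitting combing data) and region-level segmentation (contiguous IN
intervals with lengths drawn uniformly in `(0, region_length_max]`,
rescaled or trimmed so coverage is exactly `theta * L`, placed
uniformly without overlap by a stick-breaking draw of the inter-region
gaps -- used for replication-timing profiles). The placement algorithm
is a package choice; only the coverage constraint is inherent to the
model.

## Combing emulation

Real observations are single stretched DNA fibres, so simulated genomes
must be degraded to the same resolution before any comparison:

1. **Shredding.** Molecule lengths are drawn i.i.d. from a length model
   (default: lognormal with 100-kb median and log-sd 0.5, a reasonable
   stand-in for combed-fibre length distributions; any empirical length
   vector can be supplied instead). Fragments are laid end to end from
   a uniformly random offset around the circularised genome until its
   length is used up; the final partial fragment is discarded. The
   circular frame avoids systematically discarding genome at the ends
   while keeping each molecule linear; the single eye that may straddle
   the rotation point is split in two.
2. **Reshaping.** Interior gaps of at most 1 kb are merged into their
   flanking eyes, then eyes not larger than 1 kb are dropped, iterated
   to a fixed point. Merging runs before filtering; because merging
   never changes gap sizes and dropping can only enlarge gaps, the
   fixed point is order-independent (the test suite checks this against
   an exhaustive enumeration of merge orders).
3. **Scoring.** Eyes with length in `(1, 3]` kb are new firing events:
   at 0.5 kb/min per fork they arose within the last 3 minutes, which
   is the detection window `dt` used for the firing rate
   `I = n_new / ((1 - f) * length * dt)`. The 1-kb bound is strict, for
   consistency with the "larger than 1 kb" eye-scoring rule.
4. **Fraction matching.** A simulated time point is compared with a
   sample by shredding the lattice snapshots that bracket the sample's
   global replicated fraction (sum of eye lengths over sum of molecule
   lengths) and keeping the nearer one.

## The six observables and the fitness

`observable_curves()` computes, per dataset: `I(f)` and fork density
`Nfork(f)` in 20 equal-width bins of the per-molecule replicated
fraction; the distribution of per-molecule fractions; and eye-length,
gap-length and eye-to-eye-distance histograms (2-kb bins, gaps taken
between eyes on the same molecule, eye-to-eye distances
centre-to-centre). Within an f-bin, `I` and fork density are
ratio-of-sums estimates (total events over total exposure); the
unweighted mean of per-molecule ratios, available in
`per_molecule_curves()`, lets single short molecules dominate sparse
bins and makes the fitting objective heavy-tailed.

The fitness between simulated and experimental curves is, per
observable, the sum of squared differences divided by the squared mean
of the experimental curve, summed over the six observables; simulated
curves are always computed on the experimental grids (`template`
argument).

## Parameter inference

`fit_condition()` couples the simulator to a multi-population genetic
algorithm: 3 subpopulations of 20 individuals, 3 elites each, 60%
scattered-crossover and 40% uniform-mutation children (per-gene
mutation probability 0.2, redraw uniform within bounds), roulette
selection on `max(fitness) - fitness`, ring migration of the best 10%
every 5 generations, 50 generations by default. Bounds: `N0` in
[1, 2000], `J` in [0, 4000], probabilities and `theta` in [0, 1], `d`
in [0, 1000] kb.

Because every objective evaluation is a fresh stochastic simulation,
two safeguards against noise-induced selection bias are applied: elite
fitness is re-evaluated every generation (a single lucky draw cannot
lock an individual in), and each run reports the best individual of the
final population by its current fitness rather than the lowest value
ever observed. Each evaluation shreds the matched lattice twice and
pools the molecules, halving the shredding contribution to the
objective variance. The optimisation is repeated independently
(`repeats`, 100 by default) and the ensemble mean and SD over the runs'
best elites are the fit result; `compare_parameters()` applies Welch
t-tests with Bonferroni correction across parameters to two such
ensembles. The Welch/Bonferroni choice is the package's own (the test
behind published condition comparisons of this kind is typically not
specified in main texts).

### Identifiability

In the factor-limited regime (candidates far exceeding free factors,
which the default truth parameters produce early in S phase) the
block-level mask makes `theta`, `Pin` and `Pout` act mainly through the
candidate density, so they are constrained by the late-S unsaturated
phase and only weakly separable early on; `Pin` and `Plocal` trade off
almost freely at small `d`. A second structural limit: all six
observables are indexed by the replicated fraction or are length
distributions at a matched fraction, so absolute time never enters and
`N0`/`J` are constrained only through the amplitude and shape of
`I(f)`. The package's recovery checks on ground-truth synthetic data
quantify the consequence: at ~500-molecule samples and a reduced
optimisation budget, `theta` is recovered while `N0`, `J` and `Pout`
ensembles remain spread over several-fold ranges whose replicate-mean
fitness is indistinguishable from the truth's. Fit ensembles expose
this as large SDs and strong correlations across runs -- inspect
`tidy(fit)` rather than trusting the mean alone.

## Synthetic ground-truth data

`synthetic_spec()` + `generate_dataset()` produce pseudo-experimental
combing datasets with a known truth: simulate with true parameters,
fraction-match at the target global fractions (defaults 8%, 19%, 22%,
46%, 53% -- the sample series studied experimentally), shred, subsample
to ~500 molecules, reshape, and record the truth sidecar (parameters,
matched rounds, initiation events inside retained molecules). The
default truth is the published MM5 example set (N0 = 1231, J = 287 per
round, theta = 0.46, Pin = Plocal = 0.34, Pout = 0.01, d = 138 kb on a
1e6-kb genome); when the genome is scaled down, `N0` and `J` scale
proportionally so per-kb dynamics are unchanged. An optional noise
model (Gaussian eye-edge jitter, spurious gaps) exists for robustness
testing only and is off by default -- it is an artifact addition, not
part of the replication model.

What the generator does *not* emulate: fluorescence imaging and
thresholding of raw combing images, stretching-factor variability,
inter-experiment batch effects, or correlated measurement error along a
fibre. Passing recovery tests on these data therefore demonstrates the
correctness and identifiability of the inference machinery under the
model's own assumptions, not robustness to every bias of real combing
data.

## Replication-timing profiles

`simulate_timing()` builds a fictitious chromosome with contiguous
high-probability regions (region-level mask; the published example uses
a 2e5-kb chromosome with 398 regions of at most 3 Mb), replicates it
repeatedly with the same region layout, and pools replicates into a
per-position mean replication time plus a firing-abundance track (the
fraction of replicates with an initiation at that position -- one
reasonable reading of a per-position "abundance", stated here as the
package's definition). The profile is smoothed by locally weighted
regression (`lowess`, default span 0.02 of the chromosome) and
segmented by `segment_ctr_ttr()`: runs where the absolute smoothed
slope stays below `slope_threshold` and that are at least `min_len` kb
long (default 10) are constant timing regions, early or late relative
to the chromosome median; everything between is a timing transition
region. The default threshold is the root-mean-square slope of the
smoothed profile itself: plateau-versus-transition contrast varies by
an order of magnitude between chromosome sizes and replicate depths, so
no fixed number serves all runs, while the RMS slope always separates
the flat majority from the steep tail. Fixed thresholds remain
available, and the segmentation is validated against a run-length
oracle on step fixtures in the tests.

One caveat found while characterising the segmentation: with the
example parameter set, fork-proximal stimulation (`d` = 138 kb,
comparable to the inter-region spacing) places induced, often early,
firing events inside transition zones. TTRs are therefore depleted of
early firings relative to the early CTRs where those concentrate, but
not relative to the pooled CTR average, and the fired-origin density
contrast between TTRs and CTRs is weak (a few percent). The package
reports per-class firing statistics (`segment_firing_stats()`) so these
contrasts can be examined rather than assumed.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen so the full suite
completes in minutes while every law being tested is still
well-powered: conservation and reduction equivalences on 1e4-kb
lattices (200 seeds for distributional comparisons), the closed-form
kinetics on 1e5 kb, parameter recovery on a 1e5-kb genome with three
~500-molecule samples and a reduced optimisation budget (10 repeats,
15 generations), and timing profiles at one-tenth of the published
chromosome setup (2e4 kb, 40 regions, 10 replicates, with `N0` and `J`
scaled alike). Full-scale runs are supported through the same
interfaces.

## Known limitations

* Probabilities are per-round, so comparisons across different
  `round_minutes` require rescaling both `J` and all firing
  probabilities.
* The GA at reduced budgets inherits the identifiability limits above;
  `Pin`/`Plocal`/`d` should be interpreted only through their ensemble
  spread.
* Replication is single-S-phase: no re-replication, no explicit
  checkpoint signalling (conditions such as checkpoint inhibition are
  represented as different fitted parameter values), and no
  sequence-dependent origin placement.
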