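---
title: "Glocal exploration of viable parameter regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glocal exploration of viable parameter regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viaspace)
```

## The problem

A synthetic gene circuit is robust when it keeps doing its job — oscillating,
switching, counting — under perturbations of its biochemical parameters:
transcription and translation rates, degradation rates, binding affinities.
Formally, each candidate parameter vector $\theta$ lives in the feasible
hyper-box $\Theta^p = \Theta_1 \times \dots \times \Theta_p$ spanned by
physiological rate ranges, a cost $E(\theta)$ scores how far the simulated
behaviour is from the target behaviour, and the *viable space* is
$\{\theta : E(\theta) < E_0\}$. The volume of the viable space — in
particular the *relative* volume, viable volume over
$\mathrm{Vol}(\Theta^p)$ — is a robustness measure that lets circuits and
functional variants of one circuit be compared on equal footing.

The difficulty is that viable regions occupy tiny fractions of a
high-dimensional box (down to $10^{-6}$ relative volume in our flip-flop
variants) and, for circuits with several modes of behaviour, may fall apart
into poorly connected pieces. The package attacks this "glocally", in three
stages:

1. **Global harvest** (`run_ga()`): a generational genetic algorithm over
   $\Theta^p$ that — unlike an optimiser — records *every* viable
   individual it ever evaluates. Uniform initial population (default 5000),
   tournament selection (tournament = population/10), two-point crossover,
   per-coordinate multiplicative mutation by $U(0.8, 1.2)$ with probability
   0.75, 10 generations. Few generations on purpose: the GA only sketches
   where viable territory is; more generations would only bias the sketch
   toward the GA's evolvability preferences.
2. **Local refinement** (`explore_regions()`): iterative Gaussian sampling
   along the principal components of the current viable set,
   $S^{(i)} = \{ \mathbb{E}[\nu^{(i-1)}] + \lambda^{(i-1)} \xi_j \}$, with
   the variance inflation $\lambda$ decreasing linearly from 4 to 2 over
   the (default 10) iterations; newly viable candidates are unioned into
   the set. When a clustering trigger fires, the gap statistic (K-means,
   uniform reference over the PCA-aligned bounding box) decides whether
   the region should split; children are explored independently.
3. **Robustness** (`mc_volume()`): Monte-Carlo integration over the
   PCA-aligned bounding box of each region, with the worst-case Bernoulli
   error bound turned into an explicit sample budget
   (`required_samples()`).

Stochastic validation (`project_qssa()`, `ssa_run()`) re-simulates selected
viable points with the Gillespie direct method to confirm that behaviour
classified on deterministic trajectories survives molecular noise.

## Models

Three benchmark circuits are built in (`grn_model()`), all in nM and hours:

* the **repressilator** — three mRNA/protein pairs in a repression ring
  (7 free parameters);
* the **AC-DC circuit** — a repressilator sharing two edges with a toggle
  switch, able to oscillate or latch bistably with the same wiring
  (9 free parameters; the external signalling molecule is outside scope);
* the **edge-triggered master-slave D flip-flop** — two clocked bistable
  latches; in counter mode ($d = q_c$) a working flip-flop divides the
  clock frequency by two. Structure flags choose competitive vs
  independent TF binding at the master promoters ($\Omega_1$) and
  Michaelian vs linear protein degradation ($\Omega_2$; the Michaelian
  variant shares a protease pool across all four proteins and adds the
  fixed 0.6/h dilution, bringing $K_M$ and the protease level $E$ into the
  search and making $p = 10$ instead of 8).

Parameter bounds are field-typical prokaryote/eukaryote ranges
(transcription/translation $10^{-2}$–50/h, protein degradation
$10^{-3}$–50/h, mRNA degradation 0.1–100/h, dissociation/Michaelis
constants $10^{-2}$–250 nM, protease 10–1000 nM, Hill coefficient 1–5).
Integration uses lsoda (compiled right-hand sides, rtol $10^{-6}$, atol
$10^{-9}$ nM): Hill exponents up to 5 make corners of the box stiff.

## Costs, windows and measurement conventions

All spectral quantities are one-sided DFT magnitudes normalised so a pure
sine of amplitude $A$ reports $A$ (nM); the mean is excluded. `viaspace`
measures oscillation amplitude as the leading spectral magnitude and the
period as its inverse frequency (`measure_oscillation()`), the same
convention the costs use. For the spiky waveforms of relaxation-type gene
oscillators this reports the dominant rhythmic component; half the
peak-to-trough excursion would systematically overshoot it.

Three cost families (`cost_spec()`):

* **Harmonic error** ($E = \sum_i (\hat h_i - h_i)^2$ over the first
  $n$ harmonics of the target period): used with a per-harmonic budget —
  viable when the *mean absolute* harmonic deviation is at most `tol` nM.
  We read the budget as mean absolute (not root-mean-square) deviation:
  it is the only reading under which the repressilator case-study point
  printed with the model definition is itself viable (it lands at 9.8 nM
  of its 10 nM budget, while its RMS deviation is 20.6 nM), and the RMS
  reading empirically leaves the strict oscillation scenario with an
  (essentially) empty viable set, which would contradict the documented
  region comparisons. Viability additionally requires the target
  fundamental to be genuinely present — the observed first harmonic must
  dominate the comb and carry at least half the ideal amplitude. For
  large ideals (200-300 nM) the deviation budget already implies this;
  for the 50 nM flip-flop ideal the 10-harmonic average would otherwise
  dilute the missing fundamental so much that a dead (flat) flip-flop,
  or one slavishly following the clock at the wrong period, would pass.
  The cost is phase-invariant because magnitudes discard phase.
* **Peak prominence** (loose oscillation score): detect frequency-ordered
  strict local maxima $\gamma_1..\gamma_P$ of the magnitude spectrum
  (prominence at least 1% of the spectrum maximum, within the first 50
  harmonic bins), score
  $E = -\tfrac1P\sum_i \sigma_i - \sum_{i\ge2}(\gamma_{i-1}-\gamma_i)$
  with $\sigma_i$ the 3-bin standard deviation around peak $i$. The
  second term telescopes to $\gamma_1 - \gamma_P$: one sharp dominant
  peak scores strongly negative. (Written with the opposite index order
  the sum would *reward* spectra whose peaks grow with frequency and no
  clean oscillator could reach a negative threshold; we use the order
  that matches the score's stated intent.) Viability combines $E < E_0$
  with a leading-harmonic amplitude window.
* **Time-domain switching error**: RMS distance of the toggle readouts
  from their target levels (0/400 nM) under two mirrored initial
  conditions, scored over the final half of the window. The window choice
  matters: the approach transient alone (e.g. 280 to 400 nM at a ~1 h
  time constant) exceeds a 4 nM budget if scored from $t = 0$, so the
  score uses the settled half.

**Evaluation windows.** Deterministic evaluation runs 48 h for the
repressilator and AC-DC circuit and 4 clock periods (96 h) for the
flip-flop, sampled at 0.05 h (0.1 h during search, still 25-fold above the
10th harmonic's Nyquist requirement). 48 h is an integer number (4) of
ideal 12 h periods, so the harmonic comb lies exactly on DFT bins; a
100 h window would place the 1/12 h$^{-1}$ comb between bins and leak
energy out of every harmonic of any near-12 h oscillator. The coarse 1/48
h$^{-1}$ resolution is also what makes the strict cost satisfiable at
all: genuine limit cycles have periods near, not exactly at, 12 h.
`measure_oscillation()` discards the first 25% of the window as transient
by default; the costs score the full window (a discard knob exists).

## Sampler and clustering choices

PCA is fitted on raw (linear-scale) coordinates, because the Gaussian
proposals are drawn in those units; K-means and the gap statistic instead
run on coordinates standardised by the bounds span, so that nM-scale
dissociation constants cannot dominate /h-scale rates in distances. The
gap statistic compares $\log W_k$ to its expectation over 20 uniform
reference draws from the PCA-aligned bounding box (the rotation-invariant
reference choice) and we cap the cluster count at 2, because the
statistic is known to overestimate on non-uniform data; only the root
region may split at all, and it may split only once. Clustering triggers:
budget exhausted; a 10-fold collapse of the per-iteration viable yield;
or a principal-component jump $C$ above $C_0 = 0.2\sqrt{p}$ (the Frobenius
norm of a $p \times p$ difference grows like $\sqrt p$; the threshold is
configurable and, as specified, the trigger fires on *large* jumps, i.e.
unstable components). The component distance is computed after greedy
sign/permutation alignment, since principal directions are defined only up
to sign and, at equal variance, up to relabeling. Iteration stops early
once $C$ falls below 0.01. Viable sets accumulate across iterations: the
proposal distribution only needs the previous iteration's mean and
components, and keeping earlier points both stabilises the PCA and
matches the harvest-everything spirit of the GA stage.

Out-of-bounds proposals are discarded before evaluation; children of a
mutation or crossover are clipped to the bounds instead, which preserves
population size at negligible bias for ±20% mutation steps. A region
whose viable set falls below $p + 2$ points is retired with a warning
rather than fitted.

## Volumes

Each region's volume is estimated inside its PCA-aligned bounding box:
$\mathrm{Vol}(V) \approx (|\nu|/|S|) \cdot \mathrm{Vol}(B)$ with uniform
samples mapped back through the basis; samples outside $\Theta^p$ count as
non-viable. With the worst-case Bernoulli variance 1/4, the CLT bound
gives $|S| \ge |\Phi^{-1}((1-\beta)/2) \mathrm{Vol}(B)/(2\delta)|^2$ —
at $\beta = 0.95$ and $\delta = 1\%$ of $\mathrm{Vol}(B)$ that is 9604,
hence the default budget of $10^4$ oracle calls per region
(`required_samples(0.01, 0.95, 1)`). Per-region volumes are reported
separately; overlapping regions are not deduplicated (both boxes hug the
same viable cloud only after a split, where clouds are disjoint by
construction).

No margin is added beyond the min/max extents of the projections: the box
is a scaffold for importance-free sampling, not a region estimate, and an
inflation knob would trade variance for bias in the ratio estimator.

## Stochastic validation

`project_qssa()` maps each ODE onto one production and one degradation
channel per species, with Hill/Michaelis–Menten factors evaluated at
integer copy numbers; the fixed reaction volume $V_R N_A = 1\,$nM$^{-1}$
makes one molecule one nM. The flip-flop clock stays a deterministic
square wave: between its edges the propensities are constant, so the
direct method remains exact if waiting times are truncated at each edge
(the built-in kernels do this). An optional scale factor $\Omega$
multiplies copy numbers ($a(x) = \Omega\, a_{det}(x/\Omega)$) to probe
the mean-field limit: the test suite verifies that the ensemble mean
approaches the ODE solution as $\Omega$ grows to 100. Ensemble summaries
use a hysteresis cycle detector (band of 20% of the signal range) rather
than raw local maxima, because shot noise creates spurious extrema;
amplitude is half the mean peak-to-trough excursion, matching the
deterministic leading-harmonic convention on clean signals.

## What the synthetic fixtures do and do not show

The clustering, exploration and volume machinery is tested against
synthetic ground truth (`make_fixture()`): Gaussian blobs with known
labels, uniform clouds, axis-aligned box oracles with known volume, and
the inscribed sphere with its $\pi/6$ cube fraction. These fixtures have
sharp boundaries, isotropic interiors and exactly known answers — real
viable regions are curved, anisotropic shells whose boundary is defined
by an ODE-based cost. Passing the fixture suite therefore certifies the
*machinery* (the samplers, estimators and split logic), not the
biological conclusions; those are exercised by the scaled case-study runs
in the acceptance suite.

## Seeding protocols for region comparison

The GA stage is the package's global discovery tool, but volume
*comparisons* between two costs on the same circuit do not require global
discovery — they require that both regions be measured by the same
protocol. `seed_from_point()` therefore offers a literature-seeded
alternative (in the spirit of the original glocal methodology, which
started from published parameter values): multiplicative log-normal
perturbations of a known viable point are filtered by the cost and handed
to the explorer. The shipped volume-ordering comparisons seed the two
repressilator scenarios and the two AC-DC modes symmetrically from their
printed case-study points, because at desk scale the strictest costs sit
at the edge of what a few-hundred-strong GA population reliably seeds: a
10 nM average harmonic budget confines the oscillation period to within a
spectral bin of 12 h, and the bistable switch needs dissociation
constants near 1 nM out of a 250 nM linear range — needles a small
uniform initialisation rarely covers. The flip-flop comparisons, whose
GA seeds reliably at a 300-strong population, run the full GA pipeline.

## Problem sizes in the test suite

The shipped tests run the full pipeline at reduced scale, chosen as the
package's reference desk-scale protocol: GA population 300–500 with 10
generations, the standard 10 sampler iterations per region at
1200–5000 proposals each, and 1500-sample volume estimates. At these
scales region counts, tags and the repressilator volume ordering are
stable; absolute volumes carry at least order-of-magnitude uncertainty,
and comparisons across model variants with different dimensionality
(the 10-parameter Michaelian flip-flop vs the 8-parameter linear one)
are systematically biased against the higher-dimensional variant, whose
extra dimensions the scaled run cannot fill out. The full-budget
protocol ($5000$-strong GA, $10^5$ proposals per iteration,
$10^4$-sample volumes) is what sharp cross-variant comparisons
require.

## Known limitations

* The GA stage is stochastic; at desk scale the strictest costs (the
  10 nM sinusoidal repressilator budget, the 4 nM bistable budget) sit at
  the edge of what a 500-strong population reliably seeds. The package
  reports an explicit "no viable seed" outcome rather than an empty
  region list.
* The gap statistic assumes a uniform null; on curved viable shells it
  can overestimate the cluster count, which is why splits are capped and
  one-shot.
* Bounding boxes of isotropic regions (e.g. a cube) are orientation-
  arbitrary, and the box volume can exceed the region volume by the
  dimension-dependent diagonal factor; the Monte-Carlo ratio corrects
  this in the volume estimate, at the price of more non-viable samples.
* Volumes of overlapping regions, if exploration is started from
  user-supplied overlapping seeds, are reported per region and may
  double-count.
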