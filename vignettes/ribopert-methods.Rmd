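---
title: "Modelling translation perturbations with ribopert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling translation perturbations with ribopert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopert)
```

## The model

ribopert treats translation elongation as a totally asymmetric simple
exclusion process (TASEP) with extended particles: ribosomes of footprint
$s$ codons (default 9) move 5′→3′ along the $n$ sense codons of an ORF,
never overlapping or overtaking. A ribosome's position is the codon it is
decoding; it covers codons $[i, i+s-1]$. Initiation places a ribosome at
codon 1 at rate $\lambda_0$ whenever the first $s$ codons are clear — so
a ribosome delayed anywhere in codons $1..s$ also throttles initiation,
which is the physical origin of most of what this package measures. A
ribosome at codon $i < n$ advances at the codon-specific decoding rate
$\lambda_i$ (codons/s) when the codon it would newly cover is free, and
the ribosome at codon $n$ leaves the lattice at rate $\lambda_n$; no
separate termination rate is introduced. All waiting times are
exponential, making the dynamics a continuous-time Markov chain that
`simulate_tasep()` simulates exactly (event-driven, one exponential draw
per event over the currently enabled events). The stop codon is not part
of the lattice.

The translation rate TR is the number of terminations per second of
simulated time after the process has reached steady state. Two
assumptions are deliberate simplifications: rates are constant within a
run (slow cellular fluctuations are approximated by comparing steady
states), and initiation does not feed back on the free-ribosome pool.
Both cause the reported sensitivities to be, if anything,
underestimates.

### Steady-state procedure

How long to discard as burn-in is not derivable from the model, so the
package defines it operationally: events are discarded until 200
terminations have occurred, or until simulated time exceeds
$20\,n/\bar\lambda$ for initiation-starved genes that rarely terminate
(both configurable via `sim_config()`). Measurement then runs until a
termination quota (default 2000) or a time cap, in which case the result
is flagged `low_confidence` rather than silently returned; cohort
drivers skip and log such genes. Small, dense lattices approach steady
state slowly relative to their termination count because the run starts
from an empty lattice — the verification suite uses a longer burn-in
(1000 terminations) there.

### Random numbers and pairing

Each replicate draws from its own counter-based stream (xoshiro256**
seeded from the root seed and the replicate index), so results are
bit-reproducible, independent of how many replicates are requested, and
platform-independent. Perturbation statistics pair replicate $k$ of the
perturbed gene with replicate $k$ of the baseline on the same stream
(common random numbers). This matters: the stochastic variability of
TASEP can exceed the effect of a single-codon perturbation, and pairing
cancels most of it without biasing the estimate.

## Sensitivity

A perturbation multiplies targeted decoding rates by $1+p$ and the
initiation rate by $\alpha$; `sensitivity()` reports

$$\mathrm{sensitivity} \;=\;
\frac{\langle TR(\text{perturbed})\rangle - \langle TR(\text{baseline})\rangle}
     {\langle TR(\text{baseline})\rangle},$$

a signed fraction (tables print percent). When $\alpha \ne 1$ the
baseline also carries $\alpha\lambda_0$, so the statistic isolates the
rate perturbation at that initiation level rather than conflating it
with the initiation change. Profiles (`sensitivity_profile()`) evaluate
the statistic one position at a time, reusing one set of baseline
replicates for every position. Moving-average smoothing
(`smooth_profile()`, window 5) exists for display only; summaries always
use raw stored values.

The key dimensionless control parameter is
$\xi = \lambda_0/\langle\lambda_i\rangle$. On the default synthetic gene
(500 codons, all rates 1 — for which $\xi = \lambda_0$) the start-region
sensitivity (mean over codons 1–9) for $p=-50\%$ rises in magnitude with
$\xi$ up to $\xi \approx 0.1$, decays over $0.1 < \xi < 0.5$, and is
flat and negligible beyond (`classify_regime()`'s three regimes;
boundaries are arguments, not constants, because rate composition moves
them). Saturation in regime 3 is asserted as practical equivalence: the
magnitude plus two standard errors must stay below 0.3 percentage
points, under a thirteenth of the regime-1 peak (~4%). A pure
significance test would be a statement about simulation precision, not
about the gene: with enough replicates a residual of ~0.2pp at
$\xi = 0.5$ is reliably distinguishable from zero.

### Block detection

Two detectors summarize profile geometry, chosen to match what they
measure rather than a single significance rule:

* `leading_sensitive_block()` finds the leading elevated block of a
  single-codon profile as a change point — the largest drop in magnitude
  between consecutive positions — validated against a downstream
  reference stretch (default positions 19–30). A significance frontier
  would be wrong here: the second footprint block (codons 10–18) is
  genuinely, measurably elevated (~0.6% against ~0.1% downstream at
  $\xi=0.05$), yet an order of magnitude below the first block (~3%);
  the scientific claim is the sharp transition at $s+1$, which the
  change point operationalizes directly.
* `sensitive_plateau_length()` serves prolonged (multi-codon)
  perturbations, where the profile declines gradually once the perturbed
  block starts sticking out of the initiation-coupled region: it scans
  for the first position significantly below the running plateau mean
  (one-sided, default $z = \Phi^{-1}(0.9995)$). For block length $L_p$
  on a uniform gene at low $\xi$ the plateau spans the first
  $s + 1 - L_p$ start positions.

## Initiation-rate calibration

`calibrate_initiation_rate()` recovers a gene's effective $\lambda_0$
from a target mean bound-ribosome count (the package's stand-in for a
polysome-profiling measurement). The objective — expected ribosome count
as a function of $\lambda_0$ — is monotone but observed with noise, so
the search brackets the target by doubling/halving from the initial
guess $\bar\lambda/10$ (a typical $\xi$) and then bisects geometrically,
with every evaluation averaged over at least 8 replicates on common
random streams so evaluations are directly comparable. Convergence
demands a relative density error of at most 2% (the target's
`rel_tolerance`); the iteration cap is 60; infeasible targets (above the
packing bound $n/s$ or above the jam-density ceiling established by one
saturating pilot run) fail loudly with the saturation value. The
tolerance is applied to the ribosome *count*, not density per codon —
the calibration target is "average number of ribosomes". A calibrated
$\lambda_0$ is a baseline; the condition factor $\alpha$ multiplies it
afterwards and is never recalibrated, preserving the relative ordering
of initiation rates across genes.

## Codon-order null model

`permute_codons()` builds variants that keep everything about a gene
except the order of its codons: positions $2..n$ are uniformly permuted
(start codon fixed), and rates are re-derived from the decoding-rate
table so sequence and rates cannot drift apart. Length, codon usage,
mean rate and $\xi$ are preserved exactly. The full permutation reads
"preserve protein composition" as preserving the amino-acid multiset —
the only reading under which codon order itself is randomized
genome-wide; a `mode = "synonymous"` variant preserves the exact protein
sequence and shuffles only synonymous choices.

For a region $a..b$, the per-gene difference between the original
region-mean sensitivity $O_g$ and the variant-averaged one $M_g$ is
tested for zero mean (one-sample two-sided t-test, at least 3 genes per
cell), and $\Pi_{a,b} = -\log_{10} p$ is reported with the effect
direction for all $a \le b \le 200$ (20100 cells), thresholded by
Bonferroni at a 1% family-wise cutoff: $\Pi \ge -\log_{10}(0.01/20100)
\approx 6.30$. Region means divide by the inclusive count $b-a+1$, so
$a=b$ cells are single-position values rather than divisions by zero.
Both the cell count and the cutoff are arguments, since other test
families are conceivable. The cells are computed vectorially from
cumulative sums; the test suite pins one cell against `stats::t.test()`.

## Synthetic data

The generator produces everything the pipeline consumes, with ground
truth retained where a test needs it:

* decoding-rate tables: log-normal across the 61 sense codons
  (`meanlog = log 6`, `sdlog = 0.35`), placing rates mostly in ~2–15
  codons/s, the physiological decoding-speed range;
* cohorts: ORF lengths log-normal (`meanlog = log 400`, `sdlog = 0.6`,
  truncated to 50–4000 codons, matching typical ORF-length spreads),
  ATG first, body codons sampled by usage weights (uniform by default),
  rates looked up from the table;
* initiation rates: log-normal (`meanlog = log 0.3`, `sdlog = 0.7`),
  putting the median gene near $\xi \approx 0.05$ — the low-$\xi$ regime
  where baseline genes live;
* density targets: forward simulation at the known $\lambda_0$, with
  the truth returned separately so calibration tests can score recovery
  without the targets file leaking it;
* protein abundance: log-normal marginal through a Gaussian copula with
  weights +0.5 on the initiation-rate ranks and −0.3 on the length
  ranks, giving realized Spearman correlations near those targets at
  cohort sizes of a few hundred.

What the generator does *not* emulate: real codon-usage bias, the 5′
ramp of slow codons, correlated rate structure along real ORFs, or
measurement error in densities and abundances. Green tests therefore
show that the machinery is correct and that the model's qualitative
claims hold under controlled conditions — not that any particular
genome-wide coefficient would be reproduced on real data.

## Problem sizes and numerical choices

The analyses in the test suite and the acceptance script use the
package's default problem sizes: 2000-termination measurement windows,
10–20 paired replicates per profile position, the 8-point $\xi$ grid for
the regime map, 30-position profiles for block detection, 3-gene
calibration round trips, and an 8-gene, 20-position codon-order cohort.
These give standard errors of roughly 0.05–0.15 percentage points on
sensitivities — an order of magnitude below the effects under test.
Exact small-lattice verification caps the enumerated state space at
20000 configurations and solves the stationary system with a sparse LU
factorization. Ties in rank correlations are mid-ranked; regime ties at
the boundaries go to the lower regime at 0.1 and to regime 3 at 0.5.

## Known limitations

Single-CPU stochastic simulation bounds cohort sizes; the cohort
analyses here run on tens of genes, not thousands. No ribosome drop-off,
no collision-induced abortion, no finite ribosome pool, no
time-dependent rates. The bottleneck factor's "effective elongation rate
of $s$ codons" uses the harmonic traversal-time form
$s/\sum_{j \in w} \lambda_j^{-1}$ (exposed option: slowest single rate),
a modelling choice documented rather than derived. Fitted genome-wide
coefficients from real yeast data are out of scope; the fitting
machinery (`loglinear_fit()`, binned correlations, $\Gamma$ strata) is
in scope and tested on synthetic cohorts.
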