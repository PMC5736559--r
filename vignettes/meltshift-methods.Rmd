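---
title: "Thermal-shift target deconvolution with meltshift: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-shift target deconvolution with meltshift: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(meltshift)
```

## The measurement and the model

In a proteome-wide cellular thermal shift assay (MS-CETSA), a cell lysate
is split into ten aliquots, each heated briefly at one temperature of a
gradient (37-64 °C by default here), and the protein remaining soluble is
quantified by multiplexed mass spectrometry. For each protein, abundance
at each temperature is referenced to the lowest temperature, giving a
fold-change melting curve that starts at 1.0 and decays sigmoidally as
the protein denatures. A ligand that binds a protein stabilizes it: its
curve shifts toward higher temperatures in the compound-treated condition
relative to the vehicle (DMSO) control. The analysis problem is to find
the few truly shifted proteins among thousands, given two fully
independent replicates per condition.

Each melting curve is modelled with the four-parameter log-logistic
(LL4) function

$$f(T) = c + \frac{d - c}{1 + \exp\{b(\ln T - \ln e)\}}$$

with lower plateau $c$, upper plateau $d$, slope $b$ (positive for
decreasing curves under this sign convention) and inflection temperature
$e$. The melting point $T_m$ is defined as the temperature at which the
fitted curve crosses the absolute 0.5 fold-change level — not the
half-way point between the fitted plateaus — and has the closed form

$$T_m = e\left(\frac{d - 0.5}{0.5 - c}\right)^{1/b},$$

defined whenever $c < 0.5 < d$. `melting_point()` implements this solve;
it agrees with a numeric root-finder to below 1e-9 °C (verified in the
test suite over 1,000 random parameter sets).

## Normalization

Run-level effects (labelling efficiency, loading, instrument response)
multiply whole channels. Per run (one condition × replicate), the
per-temperature median fold-change over all complete proteins is taken
as the proteome melting trend and fitted with the same LL4 model. Three
vectors follow:

* the **fitting factor**, fitted median / observed median at each
  temperature, which maps the observed medians exactly onto the smooth
  trend;
* the **scaling factor**, $1/\text{fitted}(T_{min})$, a single scalar
  anchoring the fitted trend at 1.0 at the lowest temperature so that
  baselines agree across runs;
* their product, the **normalization factor** applied to every protein's
  value at that temperature in that run.

Because the factors are per-run-per-temperature scalars, normalization
never reorders proteins within a channel. After normalization the run's
median profile *is* the anchored fitted curve, so a second normalization
pass returns factors equal to 1 up to fit tolerance — an idempotence
property the tests check. The sigmoid fitted to the medians is
unconstrained (no plateau is pinned); a flat median profile raises an
error rather than silently passing, with an explicit identity-fallback
option for pre-normalized or degenerate input.

This procedure removes a constant per-run bias *exactly* (a scaled LL4
curve is again an LL4 curve, so the anchored fit is identical across
runs), but a strongly temperature-dependent bias is only partially
absorbed by the fit. That removability analysis shaped the synthetic
generator's distortion model (below).

## Plateau filtering

Two filters on the control-condition curves (averaged over control
replicates) remove proteins whose shift estimates would be meaningless:

* **bottom plateau**: mean fold-change over the 3 highest temperatures
  must be < 0.3 — otherwise the protein never melted and the curve
  carries no $T_m$;
* **top plateau**: mean over the 3 lowest temperatures must be > 0.85 —
  proteins already melting at ~37 °C are prone to false-positive shifts.

Proteins failing either filter keep their plateau statistics in the
score table with an exclusion reason, but receive no shift scores.

## Shift scoring

For each retained protein complete in all four samples, with normalized
10-point curves $v_1, v_2$ (vehicle replicates) and $t_1, t_2$
(compound replicates):

$$\mathrm{ED\ score} =
  \frac{\sum \mathrm{ED}_{\text{inter-treatment}}}
       {10^{\sum \mathrm{ED}_{\text{inter-replicate}}}}$$

where the numerator sums the Euclidean distances between treated and
control curves (all four treated × control pairs by default) and the
exponent sums the within-condition replicate distances
$\mathrm{ED}(v_1, v_2) + \mathrm{ED}(t_1, t_2)$. A large apparent shift
is thus penalized exponentially by replicate disagreement: a protein
scores highly only when it shifts *reproducibly*. $\Delta T_m$ is the
mean over matched replicate indices of
$T_m(\text{compound}, k) - T_m(\text{vehicle}, k)$, defined only when
all four melting points are defined (curves that never cross 0.5 yield
an undefined $T_m$ with a recorded reason).

Two genuinely open choices are exposed in `analysis_config()` and
recorded in the run report rather than hidden:

* `ed_pairing`: the inter-treatment sum is unindexed in the method's
  definition; `all_pairs` (4 terms) is the default because it uses both
  fully independent replicates symmetrically, `matched_pairs` (2 terms)
  is available.
* `curve_basis`: distances are computed on the normalized fold-change
  vectors by default; computing them on fitted curves evaluated on the
  grid is available (`fitted_curves`) and agrees with the default on
  clean data, but on noisy data the default preserves the replicate
  noise that the ED-score denominator is designed to measure — smoothing
  before scoring would systematically understate
  $\sum \mathrm{ED}_{\text{inter-replicate}}$.

## Hit selection

Both score distributions are summarized robustly: cutoff = median +
2.75 × MAD, where MAD is the *raw* median absolute deviation
(no 1.4826 consistency constant — `mad_cutoff()` exposes the scaled
variant only for sensitivity analysis). The ED cutoff is computed over
all scored proteins; the ΔTm cutoff over all scored proteins with a
defined ΔTm (the two selections are treated as parallel, not nested).
Hits must *strictly* exceed both cutoffs — so in the degenerate
all-equal null case (MAD = 0, cutoff = median) nothing is called — and
are ranked by descending ED score, ties broken by descending ΔTm then
protein ID, making the ranking deterministic. With fewer than 50 scored
proteins the cutoffs are flagged as unstable (warning, not error).

Hits whose control fits have amplitude $d - c < 0.5$ or bottom plateau
$c > 0.25$ receive a non-fatal "inspect manually" flag: flat,
high-plateau curves are less likely to reflect direct binding, but such
proteins are flagged for visual inspection (`plot_melt_curves()` draws
the multiplot grid), never removed automatically — automated curation
would hide exactly the borderline cases a reviewer should see.

Two compound analyses are intersected with `intersect_hit_lists()`
(proteins hit in both, ordered by rank sum) — the "commonly targeted"
list that distinguishes shared targets from compound-specific binders.

## The synthetic generator

Real proteome-wide CETSA tables are rarely public, so benchmarking rests
on `generate_dataset()`, which emulates the experimental design with
known ground truth. Design choices, each fixed up front:

* **Anchored curves.** Each protein's generating curve has its upper
  plateau solved so the curve passes through exactly 1.0 at the lowest
  temperature — the series equals its generating LL4 curve on the grid
  *and* respects the fold-change reference. A consequence: for targets,
  the compound curve (inflection shifted by the spiked
  $\delta$, plateau re-anchored) has a 0.5-crossing shift close to but
  not identical to $\delta$; the truth table therefore records both the
  inflection shift and the exact 0.5-crossings per condition, and
  recovery is judged against the crossing difference — the quantity the
  method measures.
* **Deterministic class quotas.** `floor(frac × n)` proteins are
  non-melters (bottom plateau ≥ 0.35) and early melters (already below
  0.85 average at the start), placed by a seeded shuffle. Quotas, not
  Bernoulli draws, so filter-count expectations are exact. Within each
  class, parameters are drawn by rejection sampling with margins around
  the filter cutoffs (melters: first-3 average ≥ 0.88 and last-3
  average ≤ 0.27; early melters: first-3 ≤ 0.82) so that zero-noise
  class membership maps one-to-one onto filter outcomes even after the
  small perturbation normalization introduces.
* **Targets** are drawn from the melter class (a shift in a non-melting
  curve is unobservable by this method) with positive inflection shifts
  from a truncated normal, default mean +4 °C, sd 1 °C — a plausible
  stabilization magnitude for a direct binder, chosen as a benchmarking
  default, not an estimate from any particular compound.
* **Distortion.** Each run is multiplied by a constant baseline bias of
  up to the configured amplitude (the removable signal the scaling
  factor corrects) times a smooth linear-in-temperature-index drift at
  one fifth of the amplitude. The split follows the removability
  analysis above: the generator's contract is that its injected
  distortion is the kind the normalization stage removes, and a
  full-amplitude tilt is not of that kind.
* **Noise** is additive Gaussian on the fold-change scale, truncated at
  0 (the reporter-ratio scale is bounded below); default sd 0.02,
  a replicate-level precision typical of well-behaved TMT quantification.
* Same seed and configuration give byte-identical output; the generator
  restores the caller's RNG state.

What the generator does *not* emulate: peptide/PSM-level quantification
and protein inference, isobaric co-isolation interference,
temperature-dependent heteroscedasticity, missingness correlated with
abundance, and promiscuous binders with genuine small shifts. Passing
spike-in benchmarks on this generator therefore demonstrates that the
scoring and selection machinery is correct and well-calibrated under the
design's assumptions — not that real data meet those assumptions.

## Numerical choices

* Fits use Levenberg-Marquardt least squares with a fixed, documented
  initialization (lower = min, upper = max, slope = +10, inflection =
  temperature of the point nearest mid-range) and two fallback restarts
  perturbing the starting slope ±50%; no randomness, so identical
  inputs give identical parameters. Tolerances 1e-10 (ftol/ptol), at
  most 2,000 function evaluations per attempt; the only hard bound is
  inflection > 0.
* A series with range below 1e-8 is a flat sentinel
  (`converged = FALSE`), not an error; downstream stages treat it as an
  undefined fit.
* Fits require at least 5 finite points; incomplete series are excluded
  upstream with a recorded reason.
* Table floats are serialized with 6 significant digits so re-runs are
  byte-identical and write/read round-trips are exact at that documented
  precision.

## Verification scale

The packaged verification runs (test suite and `scripts/acceptance.R`)
use 200-1,000 proteins, 2 + 2 replicates and 10 simulation seeds: large
enough that the MAD cutoffs operate in their intended regime (hundreds
of null proteins) and that spike-in recall/precision estimates are
stable to a few percent, while a full run stays in the minutes range.
At these settings the pipeline recovers essentially all +4 °C spike-ins
with mean precision a little above 0.8 — the residual false positives
are genuine upper-tail null proteins under joint ED/ΔTm cutoffs, which
is the intended operating point of a median + 2.75 × MAD rule, not a
bug.

## Known limitations

* One curve is fitted per replicate (ΔTm is averaged over matched
  replicate pairs); pooled per-condition fits are not offered.
* No p-value model for ED scores: selection is rank- plus MAD-based by
  design.
* Alternative melt models (splines, thermodynamic two-state) are out of
  scope.
* The flat-curve flag encodes a simple amplitude/plateau heuristic; it
  is a pointer for visual inspection, not a classifier of binding
  mechanism.
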