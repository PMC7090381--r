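---
title: "Quantifying in vivo axonal transport of signaling endosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in vivo axonal transport of signaling endosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`endotrack` turns manually or automatically generated endosome track tables
into animal-level transport statistics and group comparisons. This vignette
explains the quantification model, the tunable parameters and their
defaults, the generative model behind the synthetic cohorts, and the
numerical and design choices that were genuinely open.

## The measurement model

The raw observation is a track: one endosome localised in consecutive
movie frames, with in-plane coordinates in micrometres. Coordinates live in
a per-axon frame whose +x axis points in the retrograde direction (toward
the cell body); the imaging interval Δt is a per-movie scalar in the
2.4–3.2 s range. Frames within a track must be consecutive — a gap means
the identity of the punctum was lost, and such tables are rejected rather
than silently bridged.

From an *n*-frame track the pipeline computes *n* − 1 frame-to-frame
steps. Step speed is the Euclidean in-plane displacement divided by Δt —
not the axial component alone, because point tracking measures total
punctum motion and transverse wobble is genuine motion of the cargo. A
step is a **pause** when its displacement magnitude is below the tolerance
ε; a run of L consecutive paused steps means the endosome sat at one
position for L + 1 consecutive images.

Three inclusion rules are applied per track, in order, recording the first
that fires:

1. **too_short** — fewer than 5 consecutive frames;
2. **long_pause** — a pause spanning more than 10 consecutive images
   (endosomes that park for long periods are suspect for phototoxicity);
3. **anterograde** — the track moves solely anterogradely: it has at least
   one moving step, every moving step has negative axial displacement, and
   the net axial displacement is negative. The "at least one moving step"
   clause is ours: a fully stationary track is not *moving* anterogradely,
   and without the clause the rule's direction test would be decided by
   localisation noise.

Aggregation is strictly per animal, the unit of inference:

- **mean speed** — the mean over included tracks of the per-track mean
  step speed, *paused steps included*: the reported speed is the speed
  across the entire tracked run, not the speed while motile;
- **maximum speed** — the fastest per-track mean speed of the animal.
  "Fastest endosome speed" is ambiguous between the fastest per-track mean
  and the fastest single step; we use the per-track mean because the
  endosome is the unit everywhere else, and keep the fastest single step
  as an auxiliary column (`max_step_speed_um_s`);
- **% time paused** — pooled: 100 × (paused steps over all included
  tracks) / (all steps). A per-track-averaged variant is kept as an
  auxiliary column (`pct_time_paused_track_avg`); the two differ when
  track lengths vary, and pooling weights every imaged interval equally;
- **% pausing endosomes** — the percentage of included tracks with at
  least one pause;
- **speed-frequency histogram** — all step speeds of the animal binned as
  [k·w, (k+1)·w) from zero, expressed as percentages (each animal sums to
  100); group curves are the across-animal mean ± SEM per bin.

Animals with fewer than 6 included tracks or fewer than 2 distinct axons —
the study's reporting minima — trigger a warning, not an error.

**Axon caliber** is proxied by the punctum extent orthogonal to the
transport axis. Because a dwelling endosome yields many near-identical
width readings, widths are subsampled to one measurement (the
earliest-frame reading) per 1-µm axial bin before averaging per axon — the
measurement is along the axon, not per frame. Whether the original
protocol measured one or several endosomes per position is not knowable;
axial-bin subsampling is our choice and `bin_um` is exposed. Ten
measurements per axon and three axons per animal are the design minima;
deviations warn.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `epsilon` (pause tolerance) | 0.1 | µm | "same position" needs a tolerance; 0.1 µm approximates single-pixel localisation granularity of manual tracking at the stated zoom. All pause metrics are functions of ε and are reported alongside it. |
| `min_frames` | 5 | frames | inclusion rule 1 |
| `max_pause_images` | 10 | images | inclusion rule 2 |
| `bin_width` (histogram) | 0.2 | µm/s | the original binning is unpublished; 0.2 µm/s resolves the distribution at ~10 steps per bin for typical animals |
| `bin_um` (caliber subsampling) | 1 | µm | of the order of the punctum size, so one bin ≈ one independent position |
| `alpha` | 0.05 | — | two-tailed throughout |

## The statistical decision tree

Metrics are assumed normally distributed unless the D'Agostino–Pearson
omnibus K² test provides evidence to the contrary at α = 0.05. K² combines
D'Agostino's transformed skewness and the Anscombe–Glynn transformed
kurtosis, referred to χ²(2); it is implemented in-package (no installed
package provides it) and its Z transformations are checked against frozen
reference values in the tests. The transformation is undefined below n = 8,
so groups with fewer than 8 animals default to the normality assumption —
at cohort sizes of 5–11 animals the omnibus test could not have been run
for the smaller groups, which makes the default the only faithful reading.
A group is flagged non-normal only if the test rejects *and* n ≥ 8; the
overall verdict is non-normal if any group is.

Routing is then fully deterministic:

| design | normal | non-normal |
|---|---|---|
| two groups, same animals | paired t | paired t (within-animal contrasts are always paired t in this workflow) |
| two independent groups | pooled-variance unpaired t | Mann–Whitney U |
| ≥ 3 groups vs control | one-way ANOVA + two-sided Dunnett | Kruskal–Wallis + Dunn vs control |

Numerical choices:

- **Pooled-variance t** rather than Welch, matching the convention of the
  era's graphing software; `var_equal = FALSE` switches to Welch.
- **Mann–Whitney U**: for both groups n ≤ 8 the exact two-tailed p is
  computed by full enumeration of all `choose(n1+n2, n1)` assignments of
  the pooled values (ties handled naturally via half-counts), as the tail
  mass of |U − n₁n₂/2|; larger samples use the normal approximation with
  tie-corrected variance and 0.5 continuity correction.
- **Dunnett comparisons** use the exact multivariate-t distribution of the
  maximum absolute statistic (correlations
  `sqrt(n_i n_j / ((n_i+n0)(n_j+n0)))`, error df N − k) evaluated with
  `mvtnorm::pmvt` under a fixed local seed. An earlier design sketch called
  for Monte-Carlo max-|t| quantiles; the quasi-Monte-Carlo multivariate-t
  integral is strictly more accurate and the brute-force max-|t| simulation
  is retained as the independent oracle in the test suite. Because the
  integral carries ~1e-5 absolute error, adjusted p-values are clamped into
  their exact envelope p ≤ p_Dunnett ≤ (k−1)·p so that dominance over the
  raw p holds even for extreme statistics.
- **Dunn comparisons** use mean-rank z statistics with tie-corrected
  variance. Which multiplicity adjustment the original software applied is
  not stated anywhere; we fix Bonferroni over the k − 1 control contrasts
  (configurable via any `p.adjust` method). Bonferroni over correlated
  contrasts is mildly conservative, which is visible in the calibration
  results below.

## The synthetic cohort generator

No tracking data are deposited with the study, so the simulator is the
test bed. Motility is a discrete-time two-state Markov chain at frame
resolution — run or pause per step — because the 2.4–3.2 s sampling cannot
resolve sub-frame motor switching; a generative model below frame
resolution would add parameters the data could never constrain. Per step:

- **run**: axial displacement v·Δt with v lognormal (median `v_med_um_s`,
  shape `sigma_v`); lognormal because speeds are strictly positive and
  right-skewed, consistent with the single-mode, bell-shaped step-speed
  distributions of the real assay. The sign is retrograde except with
  probability `q_antero` per step;
- **pause**: zero true displacement;
- transitions move→pause with `p_mp`, pause→move with `p_pm`. The chain is
  started from its stationary distribution (long-run pause fraction
  π_P = p_MP/(p_MP+p_PM)): a tracked endosome enters the field of view
  mid-journey, in steady state. Starting in the moving state would bias
  short-track pause occupancy low by ~π_P/(L·(p_MP+p_PM));
- isotropic Gaussian localisation noise `sigma_loc_um` (default 0.02 µm)
  on every coordinate of every frame, and a per-frame punctum width around
  the axon's true caliber.

Cohort structure follows the study design: 5–11 animals per group, 50
tracks per animal spread over 3 axons, per-animal Δt drawn once from
[2.4, 3.2] s, track lengths 4 + Geometric steps with mean 9 (so ~10 frames
and ~460 steps per animal, matching the reported per-animal tracking
effort), and a small between-animal lognormal speed multiplier
(`animal_cv = 0.05`) supplying the animal-level variance that makes the
animal the correct unit of inference. In paired designs the same animals
contribute axons to both classes and share their speed multiplier — which
is exactly why the within-animal paired t is powerful there.

The presets encode the study designs, **not** measured values — no
quantitative speed or pausing parameter is published for any genotype, so
preset effect sizes are synthetic implementer choices calibrated to be
detectable at the study's group sizes: `tdp43_9mo` gives mutants a 25%
lower `v_med` and doubled `p_mp`; `motor_vs_sensory` gives motor axons
faster transport (2.2 vs 1.8 µm/s median) and larger caliber (3.5 vs
1.8 µm); `fus_18mo` matches moving speeds and raises only `p_mp`; `null`
makes all three groups identical.

What the simulator deliberately does *not* emulate: photobleaching and
phototoxicity (the long-pause exclusion exists for that reason, but the
optics are not modelled), track-linking errors, drift, axon curvature
(axons are straight lines in the per-axon frame), and any sub-frame
motility structure. Passing tests therefore validate the computational
pipeline and its statistical calibration — they cannot certify behaviour
on real microscope artefacts.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle:

- pause-run detection and the inclusion rules against brute-force scans on
  exhaustively enumerated step sequences (all pause placements up to 12
  frames; all pause/retro/antero step-type sequences up to 8 frames);
- per-animal aggregation against naive recomputation from the step table;
- the omnibus K² against frozen reference values; t, ANOVA F and exact
  Mann–Whitney p against textbook closed forms; Dunnett against both
  `multcomp` and a 40,000-draw max-|t| null simulation;
- generative-model recovery: pooled % time paused on a 5-animal × 200-track
  × 100-step cohort (σ_loc = 0.01 µm, ε = 0.1 µm, no anterograde steps)
  against π_P within 3 SE, where the SE carries the chain's autocorrelation
  inflation factor (1+r)/(1−r), r = 1 − p_MP − p_PM. The comparison is made
  on all tracked steps *before* inclusion filtering, because the closed
  form describes the raw chain while the long-pause rule deliberately
  censors pause-heavy tracks (the filtered value is also checked, with a
  wider band);
- type-I-error calibration: 2000 end-to-end replicates of the null preset
  (3 groups × 8 animals) per statistical path; the familywise rejection
  rate of the mean-speed contrast must lie in [3.5%, 6.5%]. The
  ANOVA+Dunnett path sits near 4.5%; the Kruskal–Wallis+Dunn path runs
  slightly lower (Bonferroni conservatism plus rank discreteness at
  n = 8), around 4%;
- pattern reproduction: 50 seeded replicates of `tdp43_9mo` must show, in
  at least 80% of replicates, both mutant groups significantly slower with
  significantly more pausing while the wildtype-transgene group shows no
  significant difference on any of the three metrics, and 50 replicates of
  `motor_vs_sensory` must show motor speed and caliber above sensory by
  paired t. The main leak in the TDP-43 pattern is, as expected, an
  occasional false positive on the wildtype-transgene group across the
  three metrics tested.

These sizes (2000 and 50 replicates, 100k-step recovery cohorts) were
chosen to keep Monte-Carlo error comfortably inside the acceptance bands.

## Known limitations

- Speed is 2-D in-plane; out-of-plane motion shortens apparent
  displacements. The real assay has the same limitation.
- ε is a hard threshold: a slow creep below ε/Δt µm/s is a pause, and with
  large localisation noise genuine pauses exceed ε. The defaults
  (σ_loc ≈ 0.02 µm vs ε = 0.1 µm) keep both misclassification rates
  negligible, but noisy tracking data may need a recalibrated ε.
- The pooled % time paused conditions on inclusion; heavily pausing tracks
  removed by the long-pause rule bias it slightly downward relative to the
  underlying motility process. This mirrors the original protocol.
- The Dunn path's familywise error is conservative by construction
  (Bonferroni); with many groups, power against the control is lost
  relative to the exact Dunnett path.
- In paired designs an animal appears once per axon class; the
  track-table invariant "one group per axon" (rather than per animal)
  exists for this reason.
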