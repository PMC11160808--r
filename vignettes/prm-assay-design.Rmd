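---
title: "Designing and evaluating scheduled PRM assays with prmforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating scheduled PRM assays with prmforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmforge)
```

## The problem

Highly multiplexed targeted proteomics on a linear-ion-trap PRM instrument
trades three coupled resources: how many precursors are monitored at once
(concurrency), how often each one is sampled across its LC peak (points per
peak), and how long ions are accumulated per spectrum (injection time, the
PRM analog of SRM dwell time). `prmforge` implements the computational side
of building such assays from transition-level evidence and of judging the
resulting data: transition filtering, window scheduling and cycle-time
feasibility, an instrument timing model with dynamic AGC allocation,
real-time retention-time (RT) alignment, and dilution-curve figures of
merit. A synthetic LC-MS simulator generates ground-truth data so every
component is testable without instrument files.

## Peak-width arithmetic

Chromatographic peaks are treated as Gaussian. A peak's full width at half
maximum (FWHM, minutes) is converted to an estimated base width by the
conventional factor 2.547 (`base_width_factor()`); the 6-sigma Gaussian
derivation gives 6/(2 sqrt(2 ln 2)) = 2.548, and the package standardizes on
the conventional printed 2.547 (the 0.04% difference is far below any
tolerance that matters here). The base width drives three quantities:

* points per peak: `ppp = fwhm * 2.547 / cycle_time`, with 6 points the
  accepted minimum approximating Nyquist sampling for a Gaussian;
* the required cycle time for a target sampling rate
  (`required_cycle_time()`);
* the base-peak-width transition filter and the RT-alignment buffer.

## Instrument timing model

`instrument_timing_model()` collects the constants the scheduling arithmetic
needs. The analyzer offers scan rates of 33, 67, 125 and 200 kDa/s
(numerically Th/ms for singly charged ions), and a scan over a range of
`W` Th takes `W / rate + overhead` milliseconds. The per-scan overhead
(default 4.7 ms) is not published directly; it is calibrated so the model
reproduces two reference operating points simultaneously: ~70 Hz for a
200-1400 Th scan at 125 kDa/s and ~175 Hz for a 200 Th scan at 200 kDa/s.

```{r}
scan_period(1200, 125)
scan_period(200, 200)
```

Ion accumulation is pipelined with mass analysis: ions for scan *k+1* are
collected while scan *k* is analyzed, so only a portion of the per-scan
overhead blocks accumulation. That non-pipelined portion
(`transfer_overhead_ms`, default 2.3 ms) is likewise calibrated, against an
accumulation duty cycle of ~85% at a 65 Hz acquisition rate. A strictly
serial model cannot exceed `1 - 4.7/15.4 = 69%` there, which is why the
pipelined contract is part of the model rather than an option.

SRM dwell arithmetic is the serial counterpart: `n` concurrent transitions
in a cycle each receive `cycle/n` minus a ~1 ms hardware switching overhead
(`srm_dwell()`); at 624 concurrent transitions and a 1.5 s cycle this leaves
1.404 ms, the regime where a triple quadrupole runs out of signal. The
parallel-accumulation advantage of PRM - all `N` products accumulated for
the full event - is then at least `N`-fold and grows as dwells approach the
switching overhead (`simulate_srm_vs_prm()`).

Automatic gain control sets the injection time as `target_ions / flux`,
clipped to the gate linearity range (3e-6 to 0.3 s) with a default target of
1e4 charges per spectrum. The dynamic maximum injection time
(`dynamic_max_injection_times()`) distributes the cycle surplus - cycle time
minus the summed mass-analysis time of the active targets -
inverse-proportionally to target abundance, so faint targets gain the most
accumulation. Unknown or zero abundances are treated as the smallest
observed abundance in the active set: an unknown target should not starve.
Counting statistics close the loop: a relative standard deviation `r`
requires at least `ceil(1/r^2)` ions (25 ions for 20%), so the available
injection time bounds attainable precision (`min_ions_for_rsd()`,
`ions_per_spectrum()`).

## Transition filtering and precursor qualification

Six independent rules judge each transition (`filter_transitions()`):
absolute area, relative area within its precursor, signal-to-background,
Pearson correlation to the precursor's point-wise median trace, LC base
width, and RT range. Rules are evaluated independently so a verdict lists
everything that failed; a missing value fails its rule. A zero background is
treated as infinite signal-to-background because background-free (e.g.
simulated) data must not be penalized. Correlation is computed on raw, not
background-subtracted, traces. Precursors qualify with at least
`min_qualifying_transitions` (typically 3) passing transitions.

Defaults (`filter_thresholds()`): min area 0, relative area 0.05, S/B 3,
correlation 0.8, base width 0.02-1.0 min, full RT range. These are
deliberately permissive values that still exercise every rule; any serious
use overrides them per assay. Heavy/light partners are filtered
independently.

## Scheduling and feasibility

`assign_windows()` centers a window of the nominal width (e.g. 0.6 min for a
standard-flow gradient, 0.35 min for a short one) on each target's RT and
clips to the gradient. Targets eluting in the first or last 10% of the
gradient get 50% wider windows, since RT variability concentrates at the
gradient edges; neither the zone nor the factor is published, so both are
arguments. Window membership is half-open, `[start, end)`, so a window
boundary is never double-counted in the concurrency profile
(`concurrency_profile()`, default grid step 1 s).

Feasibility (`feasibility_report()`) compares, at every grid point, the
summed scan periods of the concurrent targets to the required cycle time.
`optimize_scan_ranges()` first shrinks each target's scan range to its
transitions plus a 5 Th pad (clipped to the 200-1500 Th instrument range);
ranges of 600 Th or less are assigned the fast 125 kDa/s rate, wider ranges
keep the slower default (67 kDa/s) with its better peak shape. An
oversubscribed target set is either reduced with `balanced_load()` (the best
N peptides per protein by summed qualifying area, ties broken by transition
count then peptide string, so selection is order-invariant) or partitioned
with `split_assays()`, which takes the smallest number of assays such that a
round-robin assignment in RT order makes every assay feasible. The
round-robin rule is this package's own choice - any partition rule would do,
but round-robin in RT order keeps the per-assay concurrency profiles nearly
identical.

## Real-time RT alignment

A reference run (MS1 or narrow-window DIA) is compressed into a
`reference_map`: spectra binned to 1 Th, top-50 bins kept per spectrum,
serialized as a JSON header plus sparse triplets. During a run,
`estimate_shift()` compares the incoming spectra to the reference within a
±2 min search window and updates the shift estimate; `update_active_windows()`
then re-centers the scheduled windows, at a natural cadence of 3.5 updates
per LC base peak width.

The matching details are this package's own design (the commercial
implementation is proprietary, and no equivalence is claimed): cosine
similarity on a rolling block of the last 5 binned spectra, an argmax over
the search window with near-ties resolved toward the current shift estimate,
a median-of-5 smoother for the reported shift, and the median absolute
deviation of those raw shifts as the uncertainty. Matching a short block
rather than a single spectrum matters: cosine similarity of one spectrum is
scale-invariant, hence flat wherever a single analyte dominates, and the
block's temporal elution pattern breaks that degeneracy. If every similarity
falls below 0.1 the state is left unchanged and flagged low-confidence.
The active-window buffer is `max(uncertainty, one base width)` per side, so
alignment never shrinks a window below its static width. Nonlinear drift
needs no special handling because the shift is re-estimated locally in time.

## Dilution-curve figures of merit

The limit of detection is the turning point of a bilinear (hinge) fit on the
linear response scale: `response(x) = b + s * max(0, x - k)`, least squares
over a knot grid at the measured levels with a 10x refinement between
adjacent levels, slope constrained non-negative (`fit_bilinear_lod()`). The
fit is returned as a `bilinear_fit` object with the usual `coef`/`predict`/
`plot` methods. Note a structural fact the synthetic tests make visible: if
the mean response is strictly linear above a constant background, the best
knot is 0 - a positive LOD appears only when the mean response genuinely
flattens at low amounts.

The limit of quantification scans levels from high to low on the
summed-transition response: the candidate is the lowest level such that
every level at or above it has replicate CV <= 0.2 and mean above the fitted
baseline; the reported LOQ is the smallest measured level that also exceeds
2 x LOD (`estimate_loq()`). The exact precision rule of prior scripts is not
published, so this rule is declared here and threshold-configurable; the
2 x LOD constraint and the "lowest quantifiable level" semantics are the
fixed points. `optimize_transition_subset()` picks the transition subset
(size >= 3) minimizing the LOQ - exhaustively up to 12 transitions, greedy
backward elimination beyond - with ties broken by lower LOD, then fewer
transitions, then lexicographic order, so results are deterministic. Summed
(not per-transition) responses are used throughout, matching the notion of a
subset that jointly yields the best curve.

Because low-concentration replicates lose their peak boundaries under
automated picking, `align_integration_boundaries()` cross-correlates each
low-level run's summed trace against a high-concentration reference within
±2 min and transfers the reference boundaries at the best lag (copy-through
with a flag if the correlation peak is below 0.25), emitting a
Skyline-dialect boundary list.

## The simulator, and what passing tests do and do not show

`simulate_*` functions generate Gaussian LC peaks (default FWHM 0.15 min on
a 30 min gradient) with per-transition apex fluxes log-uniform over
1e3-1e7 charges/s (four orders of magnitude, as in a real assay), AGC-
limited injection times, Poisson ion counting, lognormal multiplicative
noise for LC/ESI variability (CV 5% in dilution series), a constant
background flux per transition, and continuous RT drift (linear, piecewise,
or seeded smooth spline). Dilution series default to the 3x serial, 7-level,
3-replicate design with a blank.

The simulator deliberately omits: isotope structure and profile-mode peaks,
chimeric interference beyond constant background, detector saturation and
space-charge distortion, and RT-dependent peak-width changes. Tests passing
on simulated data therefore demonstrate the *arithmetic and algorithms* -
concurrency counting, allocation conservation, drift recovery, knot
recovery, subset optimality - not instrument-level accuracy on real data.

Problem sizes used by the test suite and the acceptance script are chosen to
exercise the asymptotics while staying desk-scale: 100 random 200-target
assays for the concurrency oracle, an 80-peptide run with 1.5 min smooth
drift for alignment (capture >= 95% aligned vs < 50% static with 0.6 min
windows), 100 seeded noisy series for LOD knot recovery (>= 90% within one
level spacing), and 50 series for the LOQ >= 2 x LOD bound.

## Known limitations

* The exported target list is a generic CSV; no vendor method file or
  binary reference-map format is produced.
* Qualification pools transitions per precursor across files; per-file
  qualification would need the report split by `file_name` first.
* The greedy subset path (> 12 transitions) is a heuristic; it is only
  guaranteed not to do worse than the full transition set.
* The LOQ rule is a documented stand-in for unpublished prior art; treat
  absolute LOQ values as rule-relative.
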