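# prmforge

Tools for building and evaluating highly multiplexed **parallel reaction
monitoring (PRM)** assays on linear-ion-trap instruments — for targeted
proteomics practitioners who need to turn transition-level evidence (a
Skyline-style report) into a feasible scheduled instrument method, and to
quantify what the resulting assay can measure.

A scheduled PRM assay couples three resources. At retention time *t*, the
concurrent targets must share one cycle: the cycle time needed to sample a
Gaussian LC peak of width `fwhm` at `ppp` points per peak is

```
cycle = fwhm × 2.547 × 60 / ppp        (seconds; 2.547 converts FWHM to base width)
```

Each target's scan takes `W/rate + overhead` ms for a scan range of `W` Th,
and the cycle surplus is redistributed to the targets' maximum injection
times inverse-proportionally to their abundance (dynamic AGC), with the
injection time otherwise set by automatic gain control as
`IT = target_ions / flux` within the gate's linearity range. Poisson counting
statistics bound the attainable precision: an RSD of `r` needs at least
`⌈1/r²⌉` ions (25 ions for 20 %). Dilution-curve figures of merit use a
bilinear calibration fit `response(x) = b + s·max(0, x − k)` whose turning
point `k` is the LOD, and an LOQ defined as the lowest level with replicate
CV ≤ 20 % and mean above baseline, constrained to exceed 2 × LOD, minimized
over transition subsets of size ≥ 3.

The package covers:

- **I/O** — transition reports, scheduled target lists, Skyline-dialect peak
  boundary lists, serialized reference maps (all plain text).
- **Filtering** — six transition-quality rules and precursor qualification.
- **Assay design** — window assignment with edge widening, concurrency
  profiles, cycle-time feasibility, scan-range optimization, balanced-load
  selection, multi-assay splitting.
- **Timing model** — scan periods, SRM dwell arithmetic, AGC injection
  times, dynamic maximum injection time, duty cycle, ion-count bounds.
- **Adaptive RT** — compressed reference maps, streaming shift estimation,
  scheduled-window updating.
- **Figures of merit** — replicate CVs, points per peak, bilinear LOD, LOQ
  with transition-subset optimization, integration-boundary alignment.
- **Simulator** — Gaussian LC peaks, Poisson ion counting, AGC-limited
  injection times, RT drift, dilution series; the ground truth every test is
  checked against.

## Worked example

Build an assay from a (simulated) transition report and check feasibility:

```r
library(prmforge)

pk      <- simulate_ground_truth(n_peptides = 40, gradient = c(2, 32),
                                 fwhm = 0.15, seed = 1)
report  <- simulate_transition_report(pk, seed = 2)

thr      <- filter_thresholds(min_area = 50, min_signal_to_background = 3)
verdicts <- filter_transitions(report, thresholds = thr)
summary(verdicts)
#> 233 / 238 transitions passed
#>   min_area                   3
#>   min_relative_area          2
#>   min_signal_to_background   2

qual <- qualify_precursors(verdicts, 3)
qual
#> 40 qualified precursors, 233 qualifying transitions

targets <- scheduled_targets(
  qual$precursors$peptide, qual$precursors$precursor_charge,
  qual$precursors$precursor_mz, qual$precursors$rt,
  transitions = split(qual$transitions$product_mz,
                      factor(qual$transitions$peptide,
                             levels = qual$precursors$peptide)),
  abundance  = qual$precursors$total_area,
  protein_id = qual$precursors$protein_id
)
targets <- assign_windows(targets, nominal_width = 0.6, gradient = c(2, 32))
targets <- optimize_scan_ranges(targets)

concurrency_profile(targets)
#> Concurrency profile: 1801 grid points, max 5 precursors (13.30 min),
#>   max 27 transitions (13.30 min)

cycle <- required_cycle_time(0.15, points_per_peak = 6)  # 3.821 s
feasibility_report(targets, cycle_requirement_s = cycle)
#> Assay FEASIBLE at a 3.821 s cycle (minimum required cycle: 0.075 s)
#>   min available max injection time: 17.70 ms
```

At most 5 precursors are ever concurrent, their summed scan periods need
only 75 ms of the 3.82 s cycle, and the dynamic AGC allocation guarantees
every target at least 17.7 ms of injection time — comfortably feasible;
`write_target_list(targets, "assay.csv")` exports the method. The timing
model itself reproduces the instrument's reference operating points:

```r
scan_period(1200, 125)   # 200–1400 Th full range: 14.3 ms → 70 Hz
min_ions_for_rsd(0.20)   # 25 ions for 20 % RSD
```

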