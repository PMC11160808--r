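#' Ground-truth peak table for the LC-MS simulator
#'
#' Describes the true analytes behind a simulated run: Gaussian elution
#' profiles with per-transition apex ion fluxes. Fluxes spanning several
#' orders of magnitude emulate a realistic targeted assay.
#'
#' @param peptide Character labels.
#' @param rt_true True apex retention times, minutes.
#' @param fwhm LC peak FWHM, minutes, `> 0`.
#' @param transition_mz List of product m/z vectors.
#' @param flux List of per-transition apex fluxes, charges/second.
#' @param precursor_mz Precursor m/z (default: mean of transitions).
#' @param charge Precursor charge (default 2).
#' @param protein_id Protein accession (default one per peptide).
#' @return Data frame with one row per peptide, list columns
#'   `transition_mz` and `flux`.
#' @export
ground_truth_peaks <- function(peptide, rt_true, fwhm, transition_mz, flux,
                               precursor_mz = NULL, charge = 2L,
                               protein_id = NULL) {
  n <- length(peptide)
  stopifnot(length(rt_true) == n, length(transition_mz) == n,
            length(flux) == n, all(fwhm > 0),
            all(vapply(flux, function(f) all(f >= 0), TRUE)))
  df <- data.frame(
    peptide = as.character(peptide),
    rt_true = as.numeric(rt_true),
    fwhm = rep_len(as.numeric(fwhm), n),
    charge = rep_len(as.integer(charge), n),
    protein_id = if (is.null(protein_id)) paste0("PROT", seq_len(n))
                 else rep_len(as.character(protein_id), n)
  )
  df$transition_mz <- lapply(transition_mz, as.numeric)
  df$flux <- lapply(flux, as.numeric)
  df$precursor_mz <- if (is.null(precursor_mz)) {
    vapply(df$transition_mz, mean, 0)
  } else rep_len(as.numeric(precursor_mz), n)
  df
}

#' Generate a random synthetic assay's ground truth
#'
#' Draws peptides uniformly across the gradient with log-uniform apex fluxes
#' spanning `flux_range` (4 orders of magnitude by default, as in real
#' targeted assays) and 4-8 transitions each.
#'
#' @param n_peptides Number of peptides.
#' @param gradient Gradient `[t0, t1]`, minutes.
#' @param fwhm LC peak FWHM, minutes.
#' @param flux_range Apex flux range, charges/second (log-uniform).
#' @param n_proteins Number of proteins the peptides are spread over.
#' @param seed RNG seed.
#' @return A [ground_truth_peaks()] data frame.
#' @export
simulate_ground_truth <- function(n_peptides = 100, gradient = c(2, 32),
                                  fwhm = 0.15, flux_range = c(1e3, 1e7),
                                  n_proteins = ceiling(n_peptides / 3),
                                  seed = 1L) {
  set.seed(seed)
  rt <- sort(stats::runif(n_peptides, gradient[1], gradient[2]))
  ntr <- sample(4:8, n_peptides, replace = TRUE)
  base_flux <- exp(stats::runif(n_peptides, log(flux_range[1]),
                                log(flux_range[2])))
  trans <- lapply(ntr, function(k) sort(stats::runif(k, 300, 1300)))
  flux <- mapply(function(k, f) {
    f * stats::rbeta(k, 2, 2)  # relative transition intensities
  }, ntr, base_flux, SIMPLIFY = FALSE)
  ground_truth_peaks(
    peptide = sprintf("PEP%03d", seq_len(n_peptides)),
    rt_true = rt, fwhm = fwhm, transition_mz = trans, flux = flux,
    charge = sample(2:3, n_peptides, replace = TRUE),
    protein_id = sprintf("PROT%03d",
                         sample(seq_len(n_proteins), n_peptides,
                                replace = TRUE))
  )
}

#' Retention-time drift models
#'
#' Returns a continuous function `drift(t)` giving the retention-time shift
#' (minutes) of an analyte whose reference elution time is `t`.
#'
#' @param kind One of `"none"`, `"linear"` (shift ramps linearly from 0 to
#'   `magnitude` across the gradient), `"piecewise"` (linear interpolation
#'   through `knots`), `"smooth"` (seeded smooth random drift reaching about
#'   `magnitude` via a monotone-time spline through jittered knots).
#' @param magnitude Maximum shift, minutes.
#' @param gradient Gradient `[t0, t1]`, minutes.
#' @param knots For `"piecewise"`: data frame with `time` and `shift`.
#' @param seed Seed for `"smooth"`.
#' @return Function of time returning the shift in minutes.
#' @export
#' @examples
#' d <- drift_model("linear", magnitude = 1.5, gradient = c(0, 30))
#' d(c(0, 15, 30))
drift_model <- function(kind = c("none", "linear", "piecewise", "smooth"),
                        magnitude = 1, gradient = c(0, 30), knots = NULL,
                        seed = 1L) {
  kind <- match.arg(kind)
  t0 <- gradient[1]
  t1 <- gradient[2]
  switch(kind,
    none = function(t) rep(0, length(t)),
    linear = function(t) magnitude * pmin(1, pmax(0, (t - t0) / (t1 - t0))),
    piecewise = {
      stopifnot(!is.null(knots), all(c("time", "shift") %in% names(knots)))
      function(t) stats::approx(knots$time, knots$shift, xout = t,
                                rule = 2)$y
    },
    smooth = {
      set.seed(seed)
      kt <- seq(t0, t1, length.out = 6)
      ks <- magnitude * seq(0, 1, length.out = 6) +
        stats::rnorm(6, sd = 0.1 * magnitude)
      ks[1] <- 0
      sf <- stats::splinefun(kt, ks, method = "natural")
      function(t) sf(pmin(t1, pmax(t0, t)))
    }
  )
}

# Gaussian flux profile at times t for one transition
.gauss_flux <- function(t, apex_flux, rt, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  apex_flux * exp(-(t - rt)^2 / (2 * sigma^2))
}

#' Simulate a scheduled acquisition run
#'
#' Produces, for every scheduled target, a chromatogram whose scans follow
#' the assay cycle: at each cycle tick inside the (statically scheduled)
#' window the AGC model sets the injection time from the target's total
#' incoming flux, each transition's ion count is drawn from
#' `Poisson(flux(t) * IT)`, and the recorded intensity is `ions / IT`.
#' Retention times are displaced by the drift model. Reproducible under a
#' fixed seed.
#'
#' @param peaks A [ground_truth_peaks()] table.
#' @param schedule Scheduled targets (same peptides) with
#'   `window_start`/`window_end`; pass `NULL` to cover each peak's
#'   `rt_true +/- 3 * fwhm`.
#' @param timing_model An [instrument_timing_model()].
#' @param cycle_time_s Assay cycle time, seconds.
#' @param max_it_s Maximum injection time per scan, seconds (a static
#'   stand-in for the dynamic allocation; default the gate maximum).
#' @param drift A [drift_model()] function (default none).
#' @param seed RNG seed.
#' @return Named list (by peptide) of [chromatogram()]s, each with extra
#'   fields `ions` (per-scan summed ion counts) and `per_transition` (scans
#'   x transitions ion-count matrix).
#' @export
simulate_run <- function(peaks, schedule = NULL,
                         timing_model = instrument_timing_model(),
                         cycle_time_s = 1, max_it_s = NULL,
                         drift = drift_model("none"), seed = 1L) {
  set.seed(seed)
  if (is.null(max_it_s)) max_it_s <- timing_model$gate_max_it_s
  out <- vector("list", nrow(peaks))
  names(out) <- peaks$peptide
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    if (is.null(schedule)) {
      w <- c(p$rt_true - 3 * p$fwhm, p$rt_true + 3 * p$fwhm)
    } else {
      j <- match(p$peptide, schedule$peptide)
      if (is.na(j)) next
      w <- c(schedule$window_start[j], schedule$window_end[j])
    }
    times <- seq(w[1], w[2], by = cycle_time_s / 60)
    apex <- p$rt_true + drift(p$rt_true)
    flux <- sapply(seq_along(p$transition_mz[[1]]), function(k) {
      .gauss_flux(times, p$flux[[1]][k], apex, p$fwhm)
    })
    flux <- matrix(flux, nrow = length(times))
    total_flux <- rowSums(flux)
    it <- agc_injection_time(total_flux, timing_model$agc_target_ions,
                             max_it_s, timing_model)
    ions <- matrix(stats::rpois(length(flux), lambda = flux * it),
                   nrow = length(times))
    intens <- rowSums(ions) / it
    ch <- chromatogram(times, intens, injection_times = it)
    ch$ions <- rowSums(ions)
    ch$per_transition <- ions
    out[[i]] <- ch
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Simulate a precursor-level spectrum stream (for alignment)
#'
#' Generates MS1-like spectra on a regular time grid: each peptide
#' contributes a Gaussian elution profile at its precursor m/z, with apex
#' positions displaced by the drift model. Used to build reference maps and
#' to exercise the real-time shift estimator.
#'
#' @param peaks A [ground_truth_peaks()] table.
#' @param times Spectrum times, minutes (uniform grid).
#' @param drift A [drift_model()] function.
#' @param noise_sd Additive intensity noise SD, as a fraction of the largest
#'   apex flux (default 0: noiseless).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return Data frame with columns `time`, `mz`, `intensity` (long format),
#'   suitable for [build_reference()].
#' @export
simulate_spectrum_stream <- function(peaks, times, drift = drift_model("none"),
                                     noise_sd = 0, seed = 1L) {
  if (noise_sd > 0) set.seed(seed)
  apex <- peaks$rt_true + drift(peaks$rt_true)
  total_flux <- vapply(peaks$flux, sum, 0)
  res <- lapply(seq_along(times), function(i) {
    t <- times[i]
    intens <- .gauss_flux(t, total_flux, apex, peaks$fwhm)
    keep <- intens > max(total_flux) * 1e-6
    if (!any(keep)) {
      # keep the time grid uniform: an empty spectrum is a zero-intensity row
      return(data.frame(time = t, mz = peaks$precursor_mz[1], intensity = 0))
    }
    data.frame(time = t, mz = peaks$precursor_mz[keep],
               intensity = intens[keep])
  })
  out <- do.call(rbind, res)
  if (noise_sd > 0) {
    out$intensity <- pmax(0, out$intensity +
                            stats::rnorm(nrow(out),
                                         sd = noise_sd * max(total_flux)))
  }
  rownames(out) <- NULL
  out
}

#' Simulate total ions collected by SRM versus PRM for one precursor
#'
#' Under SRM the `n_transitions` product ions are monitored serially: each
#' receives a dwell of `cycle / N` minus the switching overhead. Under PRM
#' all products are accumulated together in a single event whose injection
#' time is the cycle minus one switching overhead. Ion counts are Poisson
#' draws from the Gaussian elution flux integrated scan by scan; the ratio of
#' PRM to SRM total ions approaches N at zero overhead and exceeds N when
#' dwell times approach the switching overhead.
#'
#' @param n_transitions Number of product ions, `>= 1`.
#' @param cycle_time_s Cycle time, seconds.
#' @param apex_flux Apex flux per transition, charges/second.
#' @param fwhm LC peak FWHM, minutes.
#' @param timing_model An [instrument_timing_model()] (supplies the
#'   switching overhead).
#' @param switching_overhead_ms Override for the SRM switching overhead.
#' @param seed RNG seed.
#' @return List with `srm_ions`, `prm_ions`, `ratio`, `dwell_ms`,
#'   `prm_it_ms`.
#' @export
simulate_srm_vs_prm <- function(n_transitions, cycle_time_s,
                                apex_flux = 1e4, fwhm = 0.15,
                                timing_model = instrument_timing_model(),
                                switching_overhead_ms =
                                  timing_model$srm_switching_overhead_ms,
                                seed = 1L) {
  stopifnot(n_transitions >= 1)
  set.seed(seed)
  dwell_ms <- srm_dwell(cycle_time_s, n_transitions, switching_overhead_ms)
  prm_it_ms <- cycle_time_s * 1000 - switching_overhead_ms
  rt <- 10
  times <- seq(rt - 3 * fwhm, rt + 3 * fwhm, by = cycle_time_s / 60)
  flux <- .gauss_flux(times, apex_flux, rt, fwhm)
  srm <- sum(stats::rpois(length(times) * n_transitions,
                          lambda = rep(flux, n_transitions) *
                            dwell_ms / 1000))
  # PRM accumulates every transition for the full injection time
  prm <- sum(stats::rpois(length(times) * n_transitions,
                          lambda = rep(flux, n_transitions) *
                            prm_it_ms / 1000))
  list(srm_ions = srm, prm_ions = prm, ratio = prm / srm,
       dwell_ms = dwell_ms, prm_it_ms = prm_it_ms)
}

#' Simulate a serial dilution series
#'
#' Scales each transition's expected ion yield by the dilution-level
#' fraction, adds a constant matrix-background yield, and draws replicate
#' areas with Poisson counting noise plus multiplicative lognormal noise of
#' the stated CV (LC/ESI variability).
#'
#' @param peaks A [ground_truth_peaks()] table; each transition's expected
#'   ion yield at full concentration is `flux * it_s * n_scans` integrated
#'   over the peak (summarized here as `flux * yield_factor`).
#' @param levels Dilution amounts, descending; 0 is a blank.
#' @param replicates Replicates per level (default 3).
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param background_ions Expected background ions per transition integration
#'   (default 25).
#' @param yield_factor Converts apex flux (charges/s) to expected integrated
#'   ions at the highest level (default 0.01 s-equivalent accumulation).
#' @param seed RNG seed.
#' @return Data frame with columns `peptide`, `transition`, `level`,
#'   `replicate`, `area` (areas in ion-count units).
#' @export
simulate_dilution_series <- function(peaks, levels, replicates = 3L,
                                     noise_cv = 0.05, background_ions = 25,
                                     yield_factor = 0.01, seed = 1L) {
  stopifnot(all(diff(levels) <= 0) || all(diff(levels) >= 0),
            noise_cv >= 0, replicates >= 1)
  set.seed(seed)
  top <- max(levels)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    mzs <- p$transition_mz[[1]]
    fl <- p$flux[[1]]
    for (k in seq_along(mzs)) {
      expected_full <- fl[k] * yield_factor
      for (lev in levels) {
        frac <- if (top > 0) lev / top else 0
        mu <- expected_full * frac + background_ions
        counts <- stats::rpois(replicates, mu)
        noise <- if (noise_cv > 0) {
          stats::rlnorm(replicates, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        } else rep(1, replicates)
        for (r in seq_len(replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = p$peptide,
            transition = sprintf("%s_%.1f", p$peptide, mzs[k]),
            level = lev, replicate = r,
            area = counts[r] * noise[r]
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive a synthetic transition-level report from ground truth
#'
#' Integrates each transition's Gaussian flux over the peak into an area,
#' adds background and multiplicative noise, and formats the result as the
#' transition report consumed by [filter_transitions()] - letting the whole
#' filtering/design pipeline run on simulated data.
#'
#' @param peaks A [ground_truth_peaks()] table.
#' @param noise_cv Multiplicative noise CV on areas (default 0.1).
#' @param background_frac Background area as a fraction of a transition's
#'   area at apex flux 1e4 charges/s equivalent (default constant background
#'   of 5 intensity-minutes).
#' @param file_name Report file name field.
#' @param seed RNG seed.
#' @return Transition-report data frame (canonical columns).
#' @export
simulate_transition_report <- function(peaks, noise_cv = 0.1,
                                       background_frac = 0.02,
                                       file_name = "synthetic_run",
                                       seed = 1L) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    mzs <- p$transition_mz[[1]]
    fl <- p$flux[[1]]
    sigma <- p$fwhm / (2 * sqrt(2 * log(2)))
    base <- peak_base_width(p$fwhm)
    for (k in seq_along(mzs)) {
      area <- fl[k] * sigma * sqrt(2 * pi)  # integrated flux, charges*min
      noisy <- area * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      bg <- background_frac * max(fl) * sigma * sqrt(2 * pi)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p$protein_id, peptide = p$peptide,
        precursor_charge = p$charge, precursor_mz = p$precursor_mz,
        product_mz = mzs[k], fragment_label = sprintf("y%d", k + 2L),
        label_type = "light", area = noisy, background = bg,
        fwhm = p$fwhm, rt = p$rt_true,
        start_time = p$rt_true - base / 2, end_time = p$rt_true + base / 2,
        file_name = file_name
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
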