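#' Instrument timing model for a quadrupole/linear-ion-trap PRM instrument
#'
#' Bundles the constants that determine acquisition timing and ion counting:
#' the analyzer's standard scan rates, per-scan overhead, SRM switching
#' overhead, the AGC ion target, the injection-time gate linearity range, and
#' the in-peak ion capacity.
#'
#' @param scan_rates Available mass-analysis rates in kDa/s (numerically equal
#'   to Th/ms for singly charged ions). Default `c(33, 67, 125, 200)`.
#' @param per_scan_overhead_ms Fixed time per scan not spent scanning the mass
#'   range (isolation, activation, transfer, analyzer reset), milliseconds.
#'   Default 4.7, calibrated so the model reproduces the reference acquisition
#'   rates of ~70 Hz for a 1200 Th range at 125 kDa/s and ~175 Hz for a 200 Th
#'   range at 200 kDa/s.
#' @param transfer_overhead_ms The portion of the per-scan overhead during
#'   which ion accumulation for the next scan cannot proceed even with
#'   pipelined accumulation/analysis, milliseconds. Default 2.3, calibrated to
#'   an accumulation duty cycle of ~85\% at a 65 Hz acquisition rate.
#' @param srm_switching_overhead_ms Hardware switching overhead between serial
#'   SRM transitions, milliseconds. Default 1.0.
#' @param agc_target_ions Automatic gain control target charges per spectrum.
#'   Default 1e4.
#' @param gate_min_it_s,gate_max_it_s Injection-time gate linearity limits in
#'   seconds. Defaults 3e-6 and 0.3.
#' @param max_ions_per_peak In-spectrum ion capacity before saturation.
#'   Default 25000.
#'
#' @return An object of class `instrument_timing_model` (a named list).
#' @seealso [scan_period()], [srm_dwell()], [agc_injection_time()],
#'   [dynamic_max_injection_times()], [accumulation_duty_cycle()]
#' @export
#' @examples
#' m <- instrument_timing_model()
#' scan_period(1200, 125, model = m)
instrument_timing_model <- function(scan_rates = c(33, 67, 125, 200),
                                    per_scan_overhead_ms = 4.7,
                                    transfer_overhead_ms = 2.3,
                                    srm_switching_overhead_ms = 1.0,
                                    agc_target_ions = 1e4,
                                    gate_min_it_s = 3e-6,
                                    gate_max_it_s = 0.3,
                                    max_ions_per_peak = 25000) {
  stopifnot(
    length(scan_rates) >= 1, all(scan_rates > 0),
    per_scan_overhead_ms >= 0,
    transfer_overhead_ms >= 0,
    transfer_overhead_ms <= per_scan_overhead_ms,
    srm_switching_overhead_ms >= 0,
    agc_target_ions > 0,
    gate_min_it_s > 0, gate_max_it_s > gate_min_it_s,
    max_ions_per_peak > 0
  )
  structure(
    list(
      scan_rates = sort(scan_rates),
      per_scan_overhead_ms = per_scan_overhead_ms,
      transfer_overhead_ms = transfer_overhead_ms,
      srm_switching_overhead_ms = srm_switching_overhead_ms,
      agc_target_ions = agc_target_ions,
      gate_min_it_s = gate_min_it_s,
      gate_max_it_s = gate_max_it_s,
      max_ions_per_peak = max_ions_per_peak
    ),
    class = "instrument_timing_model"
  )
}

#' @export
print.instrument_timing_model <- function(x, ...) {
  cat("Instrument timing model\n")
  cat("  scan rates (kDa/s):   ", paste(x$scan_rates, collapse = ", "), "\n")
  cat("  per-scan overhead:    ", x$per_scan_overhead_ms, "ms",
      sprintf("(%.1f ms non-pipelined)", x$transfer_overhead_ms), "\n")
  cat("  SRM switching:        ", x$srm_switching_overhead_ms, "ms\n")
  cat("  AGC target:           ", format(x$agc_target_ions, big.mark = ","),
      "charges/spectrum\n")
  cat("  gate linearity:       ",
      format(x$gate_min_it_s, scientific = TRUE), "-",
      x$gate_max_it_s, "s\n")
  cat("  in-peak ion capacity: ", format(x$max_ions_per_peak, big.mark = ","),
      "ions\n")
  invisible(x)
}

#' Scan period and acquisition rate for a mass-analysis scan
#'
#' The time to acquire one ion-trap mass-analysis scan is the time to sweep
#' the scan range at the chosen analysis rate plus a fixed per-scan overhead:
#' `period_ms = width / rate + overhead` with the rate in Th/ms (numerically
#' kDa/s for singly charged ions).
#'
#' @param scan_range_width Scan range width in Th, `>= 0`. Vectorized.
#' @param scan_rate Analysis rate in kDa/s; must be one of the model's
#'   standard rates.
#' @param model An [instrument_timing_model()].
#' @param overhead_ms Per-scan overhead, milliseconds; defaults to the
#'   model's.
#'
#' @return A list with `period_ms` and `rate_hz` (= 1000 / period_ms), each
#'   the length of `scan_range_width`.
#' @export
#' @examples
#' scan_period(1400 - 200, 125)  # ~70 Hz full peptide product range
#' scan_period(200, 200)         # ~175 Hz small range
scan_period <- function(scan_range_width, scan_rate,
                        model = instrument_timing_model(),
                        overhead_ms = model$per_scan_overhead_ms) {
  stopifnot(all(scan_range_width >= 0), length(scan_rate) == 1)
  if (!scan_rate %in% model$scan_rates) {
    stop("unknown scan rate ", scan_rate, " kDa/s; valid rates: ",
         paste(model$scan_rates, collapse = ", "), call. = FALSE)
  }
  period <- scan_range_width / scan_rate + overhead_ms
  list(period_ms = period, rate_hz = 1000 / period)
}

#' SRM dwell time at a given cycle time and transition concurrency
#'
#' On a triple quadrupole, `n` concurrent transitions monitored serially
#' within one cycle each receive `cycle / n` minus the hardware switching
#' overhead. A non-positive dwell is an infeasibility error that carries the
#' minimum feasible cycle time.
#'
#' @param cycle_time_s Cycle time in seconds, `> 0`.
#' @param n_concurrent_transitions Number of concurrent transitions, `>= 1`.
#' @param switching_overhead_ms Per-transition switching overhead,
#'   milliseconds.
#'
#' @return Dwell time in milliseconds.
#' @export
#' @examples
#' srm_dwell(1.5, 624)  # 1.404 ms: a triple quadrupole near its limit
srm_dwell <- function(cycle_time_s, n_concurrent_transitions,
                      switching_overhead_ms = 1.0) {
  stopifnot(cycle_time_s > 0, n_concurrent_transitions >= 1,
            switching_overhead_ms >= 0)
  dwell <- cycle_time_s * 1000 / n_concurrent_transitions -
    switching_overhead_ms
  if (dwell <= 0) {
    min_cycle <- n_concurrent_transitions * switching_overhead_ms / 1000
    stop_infeasible(
      sprintf(paste0("non-positive SRM dwell (%.3f ms) at cycle %.3f s with ",
                     "%d concurrent transitions; cycle time must exceed %.3f s"),
              dwell, cycle_time_s, n_concurrent_transitions, min_cycle),
      min_cycle_s = min_cycle
    )
  }
  dwell
}

#' AGC injection time for a given ion flux
#'
#' Automatic gain control sets the injection (gate) time so that an ideally
#' constant number of ions enters the trap per spectrum:
#' `IT = target_ions / flux`, clipped to the gate's linearity range and to the
#' scan's maximum injection time. Zero flux receives the maximum.
#'
#' @param flux Incoming ion flux, charges/second, `>= 0`. Vectorized.
#' @param target_ions AGC target, charges per spectrum.
#' @param max_it_s Maximum injection time available for this scan, seconds.
#' @param model An [instrument_timing_model()] supplying the gate limits.
#'
#' @return Injection time(s) in seconds, always within
#'   `[gate_min_it_s, min(max_it_s, gate_max_it_s)]`.
#' @export
#' @examples
#' agc_injection_time(1e6, 1e4, 0.1)   # 0.01 s
#' agc_injection_time(1e3, 1e4, 0.05)  # clipped at 0.05 s
agc_injection_time <- function(flux,
                               target_ions = model$agc_target_ions,
                               max_it_s = model$gate_max_it_s,
                               model = instrument_timing_model()) {
  stopifnot(all(flux >= 0), target_ions > 0, max_it_s > 0)
  hi <- min(max_it_s, model$gate_max_it_s)
  it <- ifelse(flux == 0, hi, target_ions / flux)
  pmin(pmax(it, model$gate_min_it_s), hi)
}

#' Dynamic maximum injection-time allocation across concurrent targets
#'
#' At the start of a cycle the mass-analysis-limited time of the active
#' targets is compared to the cycle time; the surplus is distributed to the
#' targets' maximum injection times inverse-proportionally to their (prior)
#' abundances, so less abundant targets receive more injection time. Because
#' ion accumulation for one scan is pipelined with mass analysis of the
#' previous scan, a target's usable maximum injection time is its own
#' analysis slot plus its surplus share.
#'
#' @param analysis_times_ms Per-target mass-analysis times (scan periods),
#'   milliseconds.
#' @param abundances Per-target prior abundances (e.g. areas from a reference
#'   run). Zero or missing abundances are treated as the smallest positive
#'   abundance in the set (so unknown targets receive the largest share); if
#'   all are missing, shares are equal.
#' @param cycle_time_s Cycle time, seconds. Must be at least the summed
#'   analysis time, else an infeasibility error carrying the minimum feasible
#'   cycle time is raised.
#'
#' @return A data frame with columns `analysis_time_ms`, `extra_ms`
#'   (surplus share) and `max_it_ms` (their sum). `sum(extra_ms)` equals the
#'   surplus exactly and `extra_ms * abundance` is constant across targets.
#' @export
#' @examples
#' dynamic_max_injection_times(c(10, 10), c(1, 3), cycle_time_s = 0.028)
dynamic_max_injection_times <- function(analysis_times_ms, abundances,
                                        cycle_time_s) {
  n <- length(analysis_times_ms)
  stopifnot(n >= 1, all(analysis_times_ms >= 0), cycle_time_s > 0,
            length(abundances) == n)
  total_ms <- sum(analysis_times_ms)
  if (total_ms > cycle_time_s * 1000) {
    stop_infeasible(
      sprintf(paste0("summed analysis time %.3f ms exceeds cycle %.3f ms; ",
                     "minimum feasible cycle time is %.6f s"),
              total_ms, cycle_time_s * 1000, total_ms / 1000),
      min_cycle_s = total_ms / 1000
    )
  }
  surplus <- cycle_time_s * 1000 - total_ms
  a <- as.numeric(abundances)
  bad <- !is.finite(a) | a <= 0
  if (all(bad)) {
    w <- rep(1 / n, n)
  } else {
    a[bad] <- min(a[!bad])
    inv <- 1 / a
    w <- inv / sum(inv)
  }
  extra <- surplus * w
  data.frame(
    analysis_time_ms = analysis_times_ms,
    extra_ms = extra,
    max_it_ms = analysis_times_ms + extra
  )
}

#' Estimate the number of ions in a spectrum
#'
#' On linear-ion-trap data the number of charges in a spectrum is estimated
#' as the spectral total ion current multiplied by the injection time in
#' seconds, assuming singly charged ions (a reasonable assumption for
#' bottom-up MS/MS fragments).
#'
#' @param tic Spectral total ion current (intensity, i.e. charges/second).
#' @param injection_time_s Injection time, seconds. Vectorized with `tic`.
#' @return Estimated charges per spectrum.
#' @export
#' @examples
#' ions_per_spectrum(5e5, 0.02)  # 1e4
ions_per_spectrum <- function(tic, injection_time_s) {
  stopifnot(all(tic >= 0), all(injection_time_s >= 0))
  tic * injection_time_s
}

#' Minimum ions for a target counting-statistics precision
#'
#' Poisson counting statistics bound the relative standard deviation of an
#' ion-count measurement by `1/sqrt(N)`; achieving a relative standard
#' deviation `rsd` therefore requires at least `ceil(1 / rsd^2)` ions
#' integrated over the LC peak. At the conventional 20% precision bound this
#' is 25 ions.
#'
#' @param rsd Target relative standard deviation as a fraction, in `(0, 1]`.
#' @return Minimum number of ions (integer).
#' @export
#' @examples
#' min_ions_for_rsd(0.20)  # 25
min_ions_for_rsd <- function(rsd) {
  if (!is.numeric(rsd) || any(rsd <= 0) || any(rsd > 1)) {
    stop("rsd must be in (0, 1]", call. = FALSE)
  }
  as.integer(ceiling(1 / rsd^2 - 1e-9))
}

#' Accumulation duty cycle of the pipelined acquisition model
#'
#' With ion accumulation pipelined against mass analysis of the previous
#' scan, the fraction of wall time spent accumulating ions is limited only by
#' the non-pipelined portion of the per-scan overhead:
#' `duty = 1 - transfer_overhead / period`.
#'
#' @param rate_hz Acquisition rate, Hz. Vectorized.
#' @param model An [instrument_timing_model()].
#' @return Accumulation duty cycle as a fraction in `[0, 1]`.
#' @export
#' @examples
#' accumulation_duty_cycle(65)  # ~0.85
accumulation_duty_cycle <- function(rate_hz,
                                    model = instrument_timing_model()) {
  stopifnot(all(rate_hz > 0))
  period <- 1000 / rate_hz
  pmax(0, 1 - model$transfer_overhead_ms / period)
}
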