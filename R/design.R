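#' Construct a scheduled-target table
#'
#' A light validating constructor for the data frame used by the scheduling
#' functions. `transitions` is a list column of product m/z vectors.
#'
#' @param peptide Character. @param charge Integer precursor charge.
#' @param precursor_mz Precursor m/z, Th.
#' @param rt_center Scheduled retention-time center, minutes.
#' @param transitions List of numeric product m/z vectors, one per target.
#' @param abundance Prior abundance (e.g. reference-run summed area).
#' @param protein_id Protein accession (optional).
#' @return Data frame with one row per target.
#' @export
scheduled_targets <- function(peptide, charge, precursor_mz, rt_center,
                              transitions, abundance = NA_real_,
                              protein_id = NA_character_) {
  n <- length(peptide)
  stopifnot(length(charge) %in% c(1L, n),
            length(precursor_mz) %in% c(1L, n),
            length(rt_center) == n, length(transitions) == n)
  df <- data.frame(
    peptide = as.character(peptide),
    charge = rep_len(as.integer(charge), n),
    precursor_mz = rep_len(as.numeric(precursor_mz), n),
    rt_center = as.numeric(rt_center),
    abundance = rep_len(as.numeric(abundance), n),
    protein_id = rep_len(as.character(protein_id), n)
  )
  df$transitions <- lapply(transitions, as.numeric)
  df$n_transitions <- lengths(df$transitions)
  df
}

#' Assign scheduled acquisition windows around retention-time centers
#'
#' Each target's window is `rt_center +/- width/2`, clipped to the gradient.
#' Targets eluting in the first or last `edge_zone` fraction of the gradient
#' receive a widened window (`width * (1 + edge_widening)`), compensating for
#' the larger retention-time variability at the gradient edges. Centers
#' outside the gradient are clipped with a warning.
#'
#' @param targets Scheduled-target data frame with `rt_center`.
#' @param nominal_width Nominal window width, minutes, `> 0`.
#' @param gradient Gradient time range `[t0, t1]`, minutes.
#' @param edge_widening Fractional widening applied in the edge zones
#'   (default 0.5, i.e. +50\%).
#' @param edge_zone Fraction of the gradient counted as an edge (default 0.1).
#' @return `targets` with columns `window_start` and `window_end` added.
#' @export
assign_windows <- function(targets, nominal_width, gradient,
                           edge_widening = 0.5, edge_zone = 0.1) {
  stopifnot(nominal_width > 0, length(gradient) == 2,
            gradient[1] < gradient[2], edge_widening >= 0,
            edge_zone >= 0, edge_zone <= 0.5)
  rt <- targets$rt_center
  if (any(rt < gradient[1] | rt > gradient[2])) {
    warning("rt_center outside gradient for ",
            sum(rt < gradient[1] | rt > gradient[2]),
            " target(s); windows clipped to the gradient edge", call. = FALSE)
  }
  span <- gradient[2] - gradient[1]
  in_edge <- rt < gradient[1] + edge_zone * span |
    rt > gradient[2] - edge_zone * span
  width <- ifelse(in_edge, nominal_width * (1 + edge_widening), nominal_width)
  rtc <- pmin(pmax(rt, gradient[1]), gradient[2])
  targets$window_start <- pmax(gradient[1], rtc - width / 2)
  targets$window_end <- pmin(gradient[2], rtc + width / 2)
  targets
}

#' Assay concurrency as a function of retention time
#'
#' Counts, on a regular time grid, how many targets' acquisition windows
#' contain each grid point (half-open membership `[start, end)` so window
#' boundaries are not double-counted) and the summed number of their
#' transitions.
#'
#' @param targets Scheduled targets with `window_start`/`window_end` and,
#'   optionally, `n_transitions` (defaults to 1 per target).
#' @param grid_step Grid step, minutes (default 1 second).
#' @return Object of class `concurrency_profile`: list with `time`,
#'   `concurrent_precursors`, `concurrent_transitions`, the max of each and
#'   the times where the maxima occur.
#' @export
concurrency_profile <- function(targets, grid_step = 1 / 60) {
  stopifnot(all(c("window_start", "window_end") %in% names(targets)),
            grid_step > 0)
  ntr <- if ("n_transitions" %in% names(targets)) {
    targets$n_transitions
  } else rep(1L, nrow(targets))
  grid <- seq(min(targets$window_start), max(targets$window_end),
              by = grid_step)
  inwin <- outer(grid, targets$window_start, ">=") &
    outer(grid, targets$window_end, "<")
  prec <- as.integer(rowSums(inwin))
  trans <- as.integer(inwin %*% ntr)
  structure(
    list(
      time = grid,
      concurrent_precursors = prec,
      concurrent_transitions = trans,
      max_precursors = max(prec),
      max_transitions = max(trans),
      t_max_precursors = grid[which.max(prec)],
      t_max_transitions = grid[which.max(trans)]
    ),
    class = "concurrency_profile"
  )
}

#' @export
print.concurrency_profile <- function(x, ...) {
  cat(sprintf(
    "Concurrency profile: %d grid points, max %d precursors (%.2f min), max %d transitions (%.2f min)\n",
    length(x$time), x$max_precursors, x$t_max_precursors,
    x$max_transitions, x$t_max_transitions))
  invisible(x)
}

#' @export
plot.concurrency_profile <- function(x, ...) {
  graphics::plot(x$time, x$concurrent_precursors, type = "s",
                 xlab = "retention time (min)",
                 ylab = "concurrent precursors", ...)
  invisible(x)
}

#' @export
as.data.frame.concurrency_profile <- function(x, ...) {
  data.frame(time = x$time,
             concurrent_precursors = x$concurrent_precursors,
             concurrent_transitions = x$concurrent_transitions)
}

#' Cycle time required for a target points-per-peak sampling rate
#'
#' A Gaussian LC peak of the given FWHM has an estimated base width of
#' `fwhm * 2.547`; sampling it `points_per_peak` times (6 approximates the
#' Nyquist criterion) requires a cycle no longer than
#' `fwhm * 2.547 * 60 / points_per_peak` seconds.
#'
#' @param peak_fwhm LC peak FWHM, minutes, `> 0`.
#' @param points_per_peak Required acquisition points across the base width.
#' @return Required cycle time, seconds.
#' @export
#' @examples
#' required_cycle_time(0.1, 6)  # 2.547 s
required_cycle_time <- function(peak_fwhm, points_per_peak = 6) {
  stopifnot(all(peak_fwhm > 0), points_per_peak >= 1)
  peak_base_width(peak_fwhm) * 60 / points_per_peak
}

#' Minimal per-target scan ranges and analysis rates
#'
#' Shrinks each target's scan range to its transitions plus a pad, clipped to
#' the instrument's mass range, and assigns the faster 125 kDa/s analysis
#' rate to targets whose resulting range is narrow (`<= fast_width`), keeping
#' the default (better-resolution) rate otherwise.
#'
#' @param targets Scheduled targets with a `transitions` list column.
#' @param pad Pad added on each side of the transition span, Th (default 5).
#' @param instrument_range Instrument scan range limits, Th.
#' @param fast_width Maximum width assigned the fast rate, Th (default 600).
#' @param fast_rate,default_rate Analysis rates, kDa/s.
#' @return `targets` with `scan_low`, `scan_high` and `scan_rate` columns.
#' @export
optimize_scan_ranges <- function(targets, pad = 5,
                                 instrument_range = c(200, 1500),
                                 fast_width = 600,
                                 fast_rate = 125, default_rate = 67) {
  stopifnot("transitions" %in% names(targets),
            all(lengths(targets$transitions) >= 1), pad >= 0)
  lo <- vapply(targets$transitions, min, 0) - pad
  hi <- vapply(targets$transitions, max, 0) + pad
  targets$scan_low <- pmax(instrument_range[1], lo)
  targets$scan_high <- pmin(instrument_range[2], hi)
  width <- targets$scan_high - targets$scan_low
  targets$scan_rate <- ifelse(width <= fast_width, fast_rate, default_rate)
  targets
}

# per-target scan periods (ms) used by feasibility and splitting
.target_periods <- function(targets, model) {
  rate <- if ("scan_rate" %in% names(targets)) {
    targets$scan_rate
  } else rep(max(model$scan_rates), nrow(targets))
  width <- targets$scan_high - targets$scan_low
  width / rate + model$per_scan_overhead_ms
}

#' Cycle-time feasibility of a scheduled assay
#'
#' At each grid point the mass-analysis time of the concurrent targets
#' (sum of their scan periods) is compared with the required cycle time; the
#' assay is feasible iff the requirement is met everywhere. Where it is, the
#' surplus is distributed per [dynamic_max_injection_times()] and each
#' target's minimum available maximum injection time across its window is
#' reported.
#'
#' @param targets Scheduled targets with windows, scan ranges and (optional)
#'   `scan_rate` and `abundance` columns.
#' @param timing_model An [instrument_timing_model()].
#' @param cycle_requirement_s Required cycle time, seconds (e.g. from
#'   [required_cycle_time()]).
#' @param grid_step Time grid step, minutes.
#' @return Object of class `feasibility_report`: list with `profile` (data
#'   frame: time, n_precursors, total_period_ms, surplus_ms, feasible),
#'   `per_target` (peptide, min_max_it_ms), `feasible` flag and
#'   `min_cycle_required_s` (the max summed period).
#' @export
feasibility_report <- function(targets, timing_model = instrument_timing_model(),
                               cycle_requirement_s, grid_step = 1 / 60) {
  stopifnot(all(c("window_start", "window_end", "scan_low", "scan_high")
                %in% names(targets)),
            cycle_requirement_s > 0)
  periods <- .target_periods(targets, timing_model)
  grid <- seq(min(targets$window_start), max(targets$window_end),
              by = grid_step)
  inwin <- outer(grid, targets$window_start, ">=") &
    outer(grid, targets$window_end, "<")
  total <- as.numeric(inwin %*% periods)
  surplus <- cycle_requirement_s * 1000 - total
  abund <- if ("abundance" %in% names(targets)) {
    targets$abundance
  } else rep(NA_real_, nrow(targets))
  min_it <- rep(Inf, nrow(targets))
  for (g in seq_along(grid)) {
    act <- which(inwin[g, ])
    if (!length(act) || surplus[g] < 0) next
    alloc <- dynamic_max_injection_times(periods[act], abund[act],
                                         cycle_requirement_s)
    min_it[act] <- pmin(min_it[act], alloc$max_it_ms)
  }
  min_it[!is.finite(min_it)] <- NA_real_
  structure(
    list(
      profile = data.frame(
        time = grid, n_precursors = as.integer(rowSums(inwin)),
        total_period_ms = total, surplus_ms = surplus,
        feasible = total <= cycle_requirement_s * 1000
      ),
      per_target = data.frame(peptide = targets$peptide,
                              min_max_it_ms = min_it),
      feasible = all(total <= cycle_requirement_s * 1000),
      min_cycle_required_s = max(total) / 1000,
      cycle_requirement_s = cycle_requirement_s
    ),
    class = "feasibility_report"
  )
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat(sprintf(
    "Assay %s at a %.3f s cycle (minimum required cycle: %.3f s)\n",
    if (x$feasible) "FEASIBLE" else "INFEASIBLE",
    x$cycle_requirement_s, x$min_cycle_required_s))
  if (x$feasible) {
    cat(sprintf("  min available max injection time: %.2f ms\n",
                min(x$per_target$min_max_it_ms, na.rm = TRUE)))
  }
  invisible(x)
}

#' Balanced-load precursor selection: the best N peptides per protein
#'
#' For each protein, keeps the top `n_per_protein` precursors by the rank
#' key (default: summed qualifying-transition area, descending). Ties are
#' broken deterministically by higher transition count, then lexicographic
#' peptide sequence, so the result is invariant to input ordering.
#'
#' @param precursors Data frame with `protein_id`, `peptide` and the rank-key
#'   column; `n_transitions` (or `n_qualifying`) is used for tie-breaking
#'   when present.
#' @param n_per_protein Number of precursors kept per protein.
#' @param rank_key Name of the ranking column (default `"total_area"`,
#'   falling back to `"abundance"` or `"area"` if absent).
#' @return The selected rows, ordered by protein then rank.
#' @export
balanced_load <- function(precursors, n_per_protein, rank_key = NULL) {
  stopifnot(n_per_protein >= 1, "protein_id" %in% names(precursors))
  if (is.null(rank_key)) {
    rank_key <- intersect(c("total_area", "abundance", "area"),
                          names(precursors))[1]
    if (is.na(rank_key)) stop("no rank-key column found", call. = FALSE)
  }
  ntr <- if ("n_transitions" %in% names(precursors)) {
    precursors$n_transitions
  } else if ("n_qualifying" %in% names(precursors)) {
    precursors$n_qualifying
  } else rep(0L, nrow(precursors))
  ord <- order(precursors$protein_id,
               -precursors[[rank_key]],
               -ntr,
               precursors$peptide)
  sel <- precursors[ord, , drop = FALSE]
  keep <- stats::ave(rep(1L, nrow(sel)), sel$protein_id,
                     FUN = seq_along) <= n_per_protein
  out <- sel[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split an oversubscribed target set into multiple feasible assays
#'
#' Finds the smallest number of assays `k` such that a round-robin
#' assignment of the targets in retention-time order (target `i` to assay
#' `i mod k`) makes every assay feasible at the required cycle time. Every
#' input target appears in exactly one output assay.
#'
#' @inheritParams feasibility_report
#' @param cycle_requirement_s Required cycle time, seconds.
#' @param max_assays Upper bound on the number of assays tried.
#' @return List of scheduled-target data frames, each feasible.
#' @export
split_assays <- function(targets, timing_model = instrument_timing_model(),
                         cycle_requirement_s, grid_step = 1 / 60,
                         max_assays = 16L) {
  stopifnot(nrow(targets) >= 1)
  periods <- .target_periods(targets, timing_model)
  alone_bad <- periods > cycle_requirement_s * 1000
  if (any(alone_bad)) {
    stop("target(s) infeasible even alone: ",
         paste(targets$peptide[alone_bad], collapse = ", "), call. = FALSE)
  }
  ord <- order(targets$rt_center, targets$peptide)
  sorted <- targets[ord, , drop = FALSE]
  for (k in seq_len(max_assays)) {
    groups <- ((seq_len(nrow(sorted)) - 1L) %% k) + 1L
    assays <- lapply(seq_len(k), function(i) {
      a <- sorted[groups == i, , drop = FALSE]
      rownames(a) <- NULL
      a
    })
    ok <- vapply(assays, function(a) {
      feasibility_report(a, timing_model, cycle_requirement_s,
                         grid_step)$feasible
    }, TRUE)
    if (all(ok)) return(assays)
  }
  stop("no feasible split within ", max_assays, " assays", call. = FALSE)
}
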