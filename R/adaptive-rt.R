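#' Build a compressed reference map from a spectrum stream
#'
#' Bins each reference spectrum (MS1 or narrow-window DIA) to fixed-width m/z
#' bins and retains only the top-K most intense bins per spectrum, producing a
#' compact time-by-m/z matrix that can be serialized
#' ([write_reference_map()]) and compared with incoming spectra in real time
#' to estimate retention-time shifts.
#'
#' @param stream A data frame with columns `time` (minutes), `mz` (Th) and
#'   `intensity`, long format (one row per peak), or a list of spectra, each
#'   `list(time =, mz =, intensity =)`. Times must be increasing and (for
#'   serialization) uniformly spaced.
#' @param bin_width m/z bin width, Th (default 1.0).
#' @param top_k Bins retained per spectrum (default 50); all others zeroed.
#' @param peak_fwhm Typical LC peak FWHM of the assay, minutes (used by
#'   [update_active_windows()] for the update period and buffer).
#' @return Object of class `reference_map` with fields `time_grid`,
#'   `mz_bin_width`, `bin_lo`, `matrix` (rows = times, cols = m/z bins),
#'   `top_k`, `peak_fwhm`.
#' @export
build_reference <- function(stream, bin_width = 1.0, top_k = 50L,
                            peak_fwhm = 0.2) {
  stopifnot(bin_width > 0, top_k >= 1, peak_fwhm > 0)
  if (is.data.frame(stream)) {
    stopifnot(all(c("time", "mz", "intensity") %in% names(stream)))
    if (nrow(stream) == 0) stop("empty spectrum stream", call. = FALSE)
    times <- sort(unique(stream$time))
    spectra <- split(stream[c("mz", "intensity")], stream$time)
  } else {
    if (length(stream) == 0) stop("empty spectrum stream", call. = FALSE)
    times <- vapply(stream, `[[`, 0, "time")
    stopifnot(all(diff(times) > 0))
    spectra <- lapply(stream, function(s) s[c("mz", "intensity")])
  }
  bins_all <- floor(unlist(lapply(spectra, `[[`, "mz")) / bin_width)
  bin_lo <- min(bins_all)
  n_bins <- max(bins_all) - bin_lo + 1L
  mat <- matrix(0, nrow = length(times), ncol = n_bins)
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    b <- floor(s$mz / bin_width) - bin_lo + 1L
    v <- tapply(s$intensity, b, sum)
    bu <- as.integer(names(v))
    v <- as.numeric(v)
    if (length(v) > top_k) {
      keep <- order(v, decreasing = TRUE)[seq_len(top_k)]
      bu <- bu[keep]
      v <- v[keep]
    }
    mat[i, bu] <- v
  }
  structure(
    list(time_grid = as.numeric(times), mz_bin_width = bin_width,
         bin_lo = as.integer(bin_lo), matrix = mat,
         top_k = as.integer(top_k), peak_fwhm = peak_fwhm),
    class = "reference_map"
  )
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf(
    "Reference map: %d spectra (%.2f-%.2f min), %d m/z bins of %.2g Th, top-%d, %d nonzeros\n",
    nrow(x$matrix), min(x$time_grid), max(x$time_grid), ncol(x$matrix),
    x$mz_bin_width, x$top_k, sum(x$matrix != 0)))
  invisible(x)
}

#' Initialize a retention-time alignment state
#'
#' @param current_shift Initial shift estimate, minutes.
#' @return Object of class `alignment_state` with an empty estimate history,
#'   `current_shift`, `uncertainty` 0 and `low_confidence` FALSE.
#' @export
alignment_state <- function(current_shift = 0) {
  structure(
    list(
      estimates = data.frame(time = numeric(0), shift = numeric(0),
                             score = numeric(0)),
      current_shift = current_shift,
      uncertainty = 0,
      low_confidence = FALSE,
      recent = NULL  # rolling block of recently observed binned spectra
    ),
    class = "alignment_state"
  )
}

#' @export
print.alignment_state <- function(x, ...) {
  cat(sprintf(
    "Alignment state: shift %.3f min (uncertainty %.3f), %d updates%s\n",
    x$current_shift, x$uncertainty, nrow(x$estimates),
    if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

# bin one observed spectrum onto the reference's bin axis
.bin_spectrum <- function(mz, intensity, map) {
  v <- numeric(ncol(map$matrix))
  b <- floor(mz / map$mz_bin_width) - map$bin_lo + 1L
  ok <- b >= 1L & b <= length(v)
  if (any(ok)) {
    agg <- tapply(intensity[ok], b[ok], sum)
    v[as.integer(names(agg))] <- agg
  }
  v
}

#' Update the retention-time shift estimate from an observed spectrum
#'
#' Maintains a rolling block of the most recent `block_n` observed spectra
#' (binned like the reference) and compares it, by cosine similarity on the
#' flattened block, against reference blocks ending at each reference time
#' within `(t - current_shift) +/- search_half_width`. Matching a short block
#' rather than a single spectrum uses the temporal elution pattern, which
#' disambiguates regions where one analyte dominates (a single spectrum's
#' cosine similarity is scale-invariant and therefore flat along one
#' analyte's elution). The raw shift is `t - argmax`; the reported shift is
#' the median of the last `smooth_n` raw shifts and the uncertainty their
#' median absolute deviation. If every similarity falls below
#' `similarity_floor` the state is returned unchanged (apart from the
#' spectrum buffer) with its `low_confidence` flag set.
#'
#' @param reference A `reference_map`.
#' @param time Observed run time of the spectrum, minutes.
#' @param mz,intensity The observed spectrum.
#' @param state An `alignment_state` (from [alignment_state()] or a previous
#'   call).
#' @param search_half_width Half width of the reference search window,
#'   minutes (default 2).
#' @param block_n Recent spectra compared jointly (default 5).
#' @param smooth_n Raw shifts in the median smoother (default 5).
#' @param similarity_floor Minimum acceptable cosine similarity (default 0.1).
#' @return The updated `alignment_state`.
#' @export
estimate_shift <- function(reference, time, mz, intensity, state,
                           search_half_width = 2, block_n = 5L,
                           smooth_n = 5L, similarity_floor = 0.1) {
  stopifnot(inherits(reference, "reference_map"),
            inherits(state, "alignment_state"),
            search_half_width > 0, block_n >= 1)
  obs <- .bin_spectrum(mz, intensity, reference)
  state$recent <- rbind(state$recent, obs)
  if (nrow(state$recent) > block_n) {
    state$recent <- state$recent[
      (nrow(state$recent) - block_n + 1L):nrow(state$recent), , drop = FALSE]
  }
  block <- state$recent
  w <- nrow(block)
  nobs <- sqrt(sum(block^2))
  center <- time - state$current_shift
  rows <- which(abs(reference$time_grid - center) <= search_half_width &
                  seq_along(reference$time_grid) >= w)
  if (!length(rows) || nobs == 0) {
    state$low_confidence <- TRUE
    return(state)
  }
  # dot products of every reference row with every block row, then summed
  # along the block diagonal to get the flattened-block inner product
  D <- reference$matrix %*% t(block)  # n_times x w
  sim <- vapply(rows, function(j) {
    idx <- (j - w + 1L):j
    num <- sum(D[cbind(idx, seq_len(w))])
    den <- sqrt(sum(reference$matrix[idx, , drop = FALSE]^2)) * nobs
    if (den == 0) 0 else num / den
  }, 0)
  best_sim <- max(sim)
  if (best_sim < similarity_floor) {
    state$low_confidence <- TRUE
    return(state)
  }
  # among near-ties, take the candidate closest to the current shift
  cand <- rows[sim >= best_sim - 1e-9]
  raw_shifts <- time - reference$time_grid[cand]
  raw_shift <- raw_shifts[which.min(abs(raw_shifts - state$current_shift))]
  state$estimates <- rbind(
    state$estimates,
    data.frame(time = time, shift = raw_shift, score = best_sim)
  )
  recent <- utils::tail(state$estimates$shift, smooth_n)
  state$current_shift <- stats::median(recent)
  state$uncertainty <- stats::mad(recent, constant = 1)
  state$low_confidence <- FALSE
  state
}

#' Active target set under the current retention-time shift
#'
#' Shifts every scheduled window by the current shift estimate and widens it
#' on each side by a buffer of `max(uncertainty, peak_fwhm * 2.547)` (around
#' one LC base peak width), then reports which targets are active at `now`.
#' The natural cadence for calling this is 3.5 updates per LC base peak
#' width, i.e. every `peak_fwhm * 2.547 / 3.5` minutes (see
#' [rt_update_period()]).
#'
#' @param schedule Scheduled targets with `window_start`/`window_end`.
#' @param state An `alignment_state`.
#' @param peak_fwhm Typical LC peak FWHM, minutes.
#' @param now Current run time, minutes.
#' @return Logical vector: is each target active at `now`?
#' @export
update_active_windows <- function(schedule, state, peak_fwhm, now) {
  stopifnot(inherits(state, "alignment_state"), peak_fwhm > 0)
  buffer <- max(state$uncertainty, peak_base_width(peak_fwhm))
  lo <- schedule$window_start + state$current_shift - buffer
  hi <- schedule$window_end + state$current_shift + buffer
  now >= lo & now <= hi
}

#' Scheduled-window update period
#'
#' The active-target set is re-evaluated 3.5 times per LC base peak width.
#'
#' @param peak_fwhm Typical LC peak FWHM, minutes.
#' @param updates_per_peak Updates per base peak width (default 3.5).
#' @return Update period, minutes.
#' @export
rt_update_period <- function(peak_fwhm, updates_per_peak = 3.5) {
  stopifnot(peak_fwhm > 0, updates_per_peak > 0)
  peak_base_width(peak_fwhm) / updates_per_peak
}
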