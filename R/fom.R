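#' Replicate coefficient of variation
#'
#' Sample standard deviation divided by the mean. The conventional replicate
#' quality filter in targeted proteomics rejects peptides with CV above 0.3
#' across validation injections (and uses 0.2 as the quantifiable-level
#' criterion in dilution series).
#'
#' @param areas At least two finite values with a positive mean.
#' @return CV as a fraction. A non-positive mean yields `NA` with a warning.
#' @export
#' @examples
#' replicate_cv(c(10, 12))
replicate_cv <- function(areas) {
  areas <- areas[is.finite(areas)]
  if (length(areas) < 2) {
    stop("need at least 2 finite replicate values", call. = FALSE)
  }
  m <- mean(areas)
  if (m <= 0) {
    warning("non-positive mean; CV undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::sd(areas) / m
}

#' Acquisition points per LC peak
#'
#' The number of acquisition cycles sampling one peak, estimated
#' conservatively from the peak's FWHM: `fwhm * 2.547 / sampling_interval`.
#' Using the base-width estimate rather than integration bounds avoids the
#' overestimation that integration bounds wider than the peak produce.
#'
#' @param fwhm Peak FWHM, minutes, `> 0`.
#' @param sampling_interval Time between acquisitions of the same target
#'   (the cycle time), minutes, `> 0`.
#' @return Points per peak.
#' @export
#' @examples
#' points_per_peak(0.1, 0.04245)  # 6
points_per_peak <- function(fwhm, sampling_interval) {
  stopifnot(all(fwhm > 0), all(sampling_interval > 0))
  peak_base_width(fwhm) / sampling_interval
}

#' Fit a bilinear (hinge) calibration model and estimate the LOD
#'
#' Fits `response(x) = b + s * max(0, x - k)` to level/response pairs by
#' least squares over a grid of candidate knots (the measured levels plus a
#' 10x refinement between each adjacent pair), with the slope constrained
#' non-negative. The limit of detection is the turning point `k`: below it
#' the response is indistinguishable from the flat baseline `b`.
#'
#' @param levels Amounts (attomole or dilution fraction), `>= 4` distinct
#'   values including the low/blank region.
#' @param responses Mean responses at each level (same length).
#' @param refine Refinement points inserted between adjacent levels
#'   (default 10).
#' @return Object of class `bilinear_fit` with components `baseline`,
#'   `slope`, `knot`, `lod` (= knot), `fitted`, `residuals`, `sse`,
#'   `degenerate` (TRUE when the responses carry no turning point and the
#'   LOD is undefined), plus the data. Methods: `print`, `coef`, `predict`,
#'   `residuals`, `fitted`, `plot`.
#' @export
#' @examples
#' x <- c(0, 1, 2, 5, 10, 20, 50)
#' y <- pmax(10, 10 + 2 * (x - 5))
#' fit_bilinear_lod(x, y)
fit_bilinear_lod <- function(levels, responses, refine = 10L) {
  stopifnot(length(levels) == length(responses),
            length(unique(levels)) >= 4, all(is.finite(responses)))
  ord <- order(levels)
  x <- as.numeric(levels)[ord]
  y <- as.numeric(responses)[ord]
  if (max(y) - min(y) < .Machine$double.eps * max(1, abs(max(y)))) {
    warning("responses are constant; no turning point, LOD undefined",
            call. = FALSE)
    fit <- structure(
      list(baseline = y[1], slope = 0, knot = NA_real_, lod = NA_real_,
           fitted = rep(y[1], length(y)), residuals = y - y[1], sse = 0,
           degenerate = TRUE, levels = x, responses = y),
      class = "bilinear_fit")
    return(fit)
  }
  ux <- sort(unique(x))
  knots <- unique(sort(unlist(lapply(seq_len(length(ux) - 1), function(i) {
    seq(ux[i], ux[i + 1], length.out = refine + 2L)
  }))))
  best <- NULL
  for (k in knots) {
    h <- pmax(0, x - k)
    vh <- sum((h - mean(h))^2)
    if (vh > 0) {
      s <- sum((h - mean(h)) * (y - mean(y))) / vh
      if (s < 0) s <- 0
    } else {
      s <- 0
    }
    b <- mean(y) - s * mean(h)
    res <- y - (b + s * h)
    sse <- sum(res^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(baseline = b, slope = s, knot = k, sse = sse)
    }
  }
  fitted <- best$baseline + best$slope * pmax(0, x - best$knot)
  structure(
    list(baseline = best$baseline, slope = best$slope, knot = best$knot,
         lod = best$knot, fitted = fitted, residuals = y - fitted,
         sse = best$sse, degenerate = FALSE, levels = x, responses = y),
    class = "bilinear_fit"
  )
}

#' @export
print.bilinear_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Bilinear calibration fit: degenerate (constant response), LOD undefined\n")
  } else {
    cat(sprintf(
      "Bilinear calibration fit: baseline %.4g, slope %.4g, LOD (turning point) %.4g\n",
      x$baseline, x$slope, x$lod))
  }
  invisible(x)
}

#' @export
coef.bilinear_fit <- function(object, ...) {
  c(baseline = object$baseline, slope = object$slope, knot = object$knot)
}

#' @export
predict.bilinear_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$levels else as.numeric(newdata)
  if (object$degenerate) return(rep(object$baseline, length(x)))
  object$baseline + object$slope * pmax(0, x - object$knot)
}

#' @export
residuals.bilinear_fit <- function(object, ...) object$residuals

#' @export
fitted.bilinear_fit <- function(object, ...) object$fitted

#' @export
plot.bilinear_fit <- function(x, ...) {
  graphics::plot(x$levels, x$responses, xlab = "amount",
                 ylab = "response", ...)
  xs <- seq(min(x$levels), max(x$levels), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  if (!x$degenerate) graphics::abline(v = x$lod, lty = 2)
  invisible(x)
}

#' Estimate the limit of quantification from a dilution series
#'
#' Scanning the dilution levels from highest to lowest on the summed-subset
#' responses, the LOQ candidate is the lowest level such that every level at
#' or above it has a replicate CV at most `cv_threshold` and a mean response
#' above the bilinear baseline. The reported LOQ is then the smallest
#' measured level that satisfies the candidate and exceeds twice the LOD, so
#' `LOQ >= 2 * LOD` always holds in the output.
#'
#' @param series Data frame with columns `level`, `replicate`, `area`
#'   (summed over the chosen transition subset).
#' @param fit A `bilinear_fit` for the same summed response (supplies the
#'   baseline and LOD).
#' @param lod Limit of detection; defaults to `fit$lod`.
#' @param cv_threshold Maximum acceptable replicate CV (default 0.2).
#' @return List with `loq` (`NA` if no level qualifies, with attribute
#'   `flag = "no-qualifying-level"`), `candidate`, and `per_level` (data
#'   frame: level, mean, cv, qualifies).
#' @export
estimate_loq <- function(series, fit, lod = fit$lod, cv_threshold = 0.2) {
  stopifnot(all(c("level", "replicate", "area") %in% names(series)))
  lev <- sort(unique(series$level), decreasing = TRUE)
  means <- vapply(lev, function(l) mean(series$area[series$level == l]), 0)
  cvs <- vapply(lev, function(l) {
    a <- series$area[series$level == l]
    if (length(a) < 2) return(NA_real_)
    suppressWarnings(replicate_cv(a))
  }, 0)
  ok <- !is.na(cvs) & cvs <= cv_threshold & means > fit$baseline
  # walk down from the top level while every level above still qualifies
  candidate <- NA_real_
  for (i in seq_along(lev)) {
    if (!ok[i]) break
    candidate <- lev[i]
  }
  per_level <- data.frame(level = lev, mean = means, cv = cvs,
                          qualifies = ok)
  if (is.na(candidate)) {
    loq <- NA_real_
    attr(loq, "flag") <- "no-qualifying-level"
    return(list(loq = loq, candidate = candidate, per_level = per_level))
  }
  eligible <- lev[lev >= candidate]
  if (!is.na(lod)) eligible <- eligible[eligible > 2 * lod]
  if (!length(eligible)) {
    loq <- NA_real_
    attr(loq, "flag") <- "no-qualifying-level"
  } else {
    loq <- min(eligible)
  }
  list(loq = loq, candidate = candidate, per_level = per_level)
}

# figures of merit for one transition subset: summed response -> LOD, LOQ
.subset_fom <- function(series, transitions, cv_threshold) {
  sub <- series[series$transition %in% transitions, , drop = FALSE]
  summed <- stats::aggregate(area ~ level + replicate, data = sub, FUN = sum)
  means <- stats::aggregate(area ~ level, data = summed, FUN = mean)
  fit <- suppressWarnings(fit_bilinear_lod(means$level, means$area))
  lq <- estimate_loq(summed, fit, cv_threshold = cv_threshold)
  list(fit = fit, lod = fit$lod, loq = lq$loq, per_level = lq$per_level)
}

#' Choose the transition subset giving the lowest LOQ
#'
#' Evaluates transition subsets of size at least `min_size` on their summed
#' dilution-curve response and returns the subset minimizing the LOQ (ties
#' broken by lower LOD, then fewer transitions, then lexicographic transition
#' names). All subsets are enumerated exhaustively when there are at most
#' `exhaustive_max` transitions; beyond that a greedy backward elimination
#' from the full set is used.
#'
#' @param series Data frame with columns `transition`, `level`, `replicate`,
#'   `area` (one peptide's dilution series).
#' @param min_size Minimum subset size (default 3).
#' @param cv_threshold Replicate CV threshold for the LOQ rule (default 0.2).
#' @param exhaustive_max Largest transition count enumerated exhaustively
#'   (default 12).
#' @param peptide Optional peptide label carried into the result.
#' @return Object of class `fom_result`: list with `peptide`,
#'   `chosen_transitions`, `lod`, `loq`, `fit` (the `bilinear_fit` of the
#'   chosen subset) and `per_level` (levels, means, CVs of the chosen
#'   subset). `loq >= 2 * lod` holds whenever both are defined.
#' @export
optimize_transition_subset <- function(series, min_size = 3L,
                                       cv_threshold = 0.2,
                                       exhaustive_max = 12L,
                                       peptide = NA_character_) {
  stopifnot(all(c("transition", "level", "replicate", "area")
                %in% names(series)))
  trans <- sort(unique(as.character(series$transition)))
  if (length(trans) < min_size) {
    stop("need at least ", min_size, " transitions, got ", length(trans),
         call. = FALSE)
  }
  series$transition <- as.character(series$transition)

  score <- function(subset) {
    fom <- .subset_fom(series, subset, cv_threshold)
    list(subset = subset, fom = fom,
         key = c(ifelse(is.na(fom$loq), Inf, fom$loq),
                 ifelse(is.na(fom$lod), Inf, fom$lod),
                 length(subset)))
  }
  better <- function(a, b) {
    # TRUE if a beats b
    for (i in 1:3) {
      if (a$key[i] < b$key[i] - 1e-12) return(TRUE)
      if (a$key[i] > b$key[i] + 1e-12) return(FALSE)
    }
    paste(a$subset, collapse = ",") < paste(b$subset, collapse = ",")
  }

  best <- NULL
  if (length(trans) <= exhaustive_max) {
    for (sz in seq(min_size, length(trans))) {
      combs <- utils::combn(trans, sz, simplify = FALSE)
      for (cc in combs) {
        cand <- score(cc)
        if (is.null(best) || better(cand, best)) best <- cand
      }
    }
  } else {
    current <- trans
    best <- score(current)
    while (length(current) > min_size) {
      round_best <- NULL
      for (drop in current) {
        cand <- score(setdiff(current, drop))
        if (is.null(round_best) || better(cand, round_best)) {
          round_best <- cand
        }
      }
      current <- round_best$subset
      if (better(round_best, best)) best <- round_best
    }
  }
  structure(
    list(peptide = peptide, chosen_transitions = best$subset,
         lod = best$fom$lod, loq = best$fom$loq, fit = best$fom$fit,
         per_level = best$fom$per_level),
    class = "fom_result"
  )
}

#' @export
print.fom_result <- function(x, ...) {
  cat(sprintf(
    "Figures of merit%s: LOD %.4g, LOQ %s, %d transitions (%s)\n",
    if (is.na(x$peptide)) "" else paste0(" for ", x$peptide),
    x$lod, ifelse(is.na(x$loq), "undefined", format(x$loq, digits = 4)),
    length(x$chosen_transitions),
    paste(x$chosen_transitions, collapse = ", ")))
  invisible(x)
}

#' Align integration boundaries of low-concentration replicates
#'
#' At low dilution levels automated peak picking loses the peak; this aligns
#' each target (low-concentration) run to a reference (high-concentration)
#' run by cross-correlating their summed-transition traces within
#' `+/- max_lag` minutes and applying the best lag to the reference
#' integration boundaries. If the correlation peak falls below
#' `correlation_floor` the reference boundaries are copied unshifted and the
#' peptide is flagged.
#'
#' @param reference Named list: peptide -> summed-transition
#'   [chromatogram()] of the reference run.
#' @param target Named list: peptide -> summed-transition chromatogram of
#'   the run to align.
#' @param ref_boundaries Data frame with `peptide`, `min_start_time`,
#'   `max_end_time` (reference integration bounds, minutes).
#' @param file_name File name written into the output boundary list.
#' @param max_lag Maximum lag searched, minutes (default 2).
#' @param correlation_floor Minimum acceptable peak correlation (default
#'   0.25).
#' @return Data frame of class `peak_boundaries` with columns `file_name`,
#'   `peptide`, `min_start_time`, `max_end_time`, `lag` and `flagged`.
#' @export
align_integration_boundaries <- function(reference, target, ref_boundaries,
                                         file_name = "aligned",
                                         max_lag = 2,
                                         correlation_floor = 0.25) {
  stopifnot(all(c("peptide", "min_start_time", "max_end_time")
                %in% names(ref_boundaries)))
  out <- ref_boundaries
  out$file_name <- file_name
  out$lag <- 0
  out$flagged <- FALSE
  for (i in seq_len(nrow(out))) {
    pep <- out$peptide[i]
    ref <- reference[[pep]]
    tgt <- target[[pep]]
    if (is.null(ref) || is.null(tgt)) {
      out$flagged[i] <- TRUE
      next
    }
    dt <- stats::median(diff(ref$times))
    lags <- seq(-max_lag, max_lag, by = dt)
    best_r <- -Inf
    best_lag <- 0
    ref_sd <- stats::sd(ref$intensities)
    tgt_sd <- stats::sd(tgt$intensities)
    if (is.na(ref_sd) || ref_sd == 0 || is.na(tgt_sd) || tgt_sd == 0) {
      out$flagged[i] <- TRUE
      next
    }
    for (lag in lags) {
      # target shifted back by lag should overlay the reference
      shifted <- stats::approx(tgt$times - lag, tgt$intensities,
                               xout = ref$times, rule = 1)$y
      ok <- !is.na(shifted)
      if (sum(ok) < 4 || stats::sd(shifted[ok]) == 0) next
      r <- stats::cor(shifted[ok], ref$intensities[ok])
      if (!is.na(r) && r > best_r) {
        best_r <- r
        best_lag <- lag
      }
    }
    if (!is.finite(best_r) || best_r < correlation_floor) {
      out$flagged[i] <- TRUE
      next
    }
    out$lag[i] <- best_lag
    out$min_start_time[i] <- ref_boundaries$min_start_time[i] + best_lag
    out$max_end_time[i] <- ref_boundaries$max_end_time[i] + best_lag
  }
  out <- out[c("file_name", "peptide", "min_start_time", "max_end_time",
               "lag", "flagged")]
  class(out) <- c("peak_boundaries", "data.frame")
  out
}
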