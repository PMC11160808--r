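#' Transition-quality filter thresholds
#'
#' The six transition-quality rules applied before assay construction:
#' absolute area, relative area (fraction of the precursor's largest
#' transition), signal-to-background, correlation to the median transition,
#' LC base peak width, and retention-time range; plus the minimum number of
#' qualifying transitions a precursor needs to be accepted.
#'
#' Defaults are deliberately permissive while still exercising every rule;
#' all are overridable.
#'
#' @param min_area Minimum absolute integrated area (intensity x min).
#' @param min_relative_area Minimum area as a fraction of the precursor's
#'   largest transition area, in `[0, 1]`.
#' @param min_signal_to_background Minimum area/background ratio. A zero
#'   background is treated as infinite signal-to-background (rule passes).
#' @param min_correlation Minimum Pearson correlation to the precursor's
#'   point-wise median transition trace, in `[-1, 1]`.
#' @param base_width_range Allowed LC base peak width `fwhm * 2.547`,
#'   `[min, max]` minutes.
#' @param rt_range Allowed retention-time range, `[min, max]` minutes.
#' @param min_qualifying_transitions Minimum number of passing transitions
#'   for a precursor to qualify (typically 3).
#' @return An object of class `filter_thresholds`.
#' @export
#' @examples
#' filter_thresholds(min_area = 1000, min_correlation = 0.9)
filter_thresholds <- function(min_area = 0,
                              min_relative_area = 0.05,
                              min_signal_to_background = 3,
                              min_correlation = 0.8,
                              base_width_range = c(0.02, 1.0),
                              rt_range = c(0, Inf),
                              min_qualifying_transitions = 3L) {
  stopifnot(
    min_area >= 0,
    min_relative_area >= 0, min_relative_area <= 1,
    min_signal_to_background >= 0,
    min_correlation >= -1, min_correlation <= 1,
    length(base_width_range) == 2, base_width_range[1] <= base_width_range[2],
    length(rt_range) == 2, rt_range[1] <= rt_range[2],
    min_qualifying_transitions >= 1
  )
  structure(
    list(
      min_area = min_area,
      min_relative_area = min_relative_area,
      min_signal_to_background = min_signal_to_background,
      min_correlation = min_correlation,
      base_width_range = base_width_range,
      rt_range = rt_range,
      min_qualifying_transitions = as.integer(min_qualifying_transitions)
    ),
    class = "filter_thresholds"
  )
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Transition filter thresholds\n")
  cat("  min area:            ", x$min_area, "\n")
  cat("  min relative area:   ", x$min_relative_area, "\n")
  cat("  min S/B:             ", x$min_signal_to_background, "\n")
  cat("  min correlation:     ", x$min_correlation, "\n")
  cat("  base width range:    ", paste(x$base_width_range, collapse = " - "),
      "min\n")
  cat("  RT range:            ", paste(x$rt_range, collapse = " - "), "min\n")
  cat("  min qualifying trans:", x$min_qualifying_transitions, "\n")
  invisible(x)
}

#' Pearson correlation of each transition trace to the median trace
#'
#' For a set of co-eluting transition chromatograms on a shared time grid,
#' computes the point-wise median trace and each transition's Pearson
#' correlation against it. A constant trace (or a constant median) has an
#' undefined correlation and is reported as 0 with a warning.
#'
#' @param traces Numeric matrix (rows = time points, columns = transitions,
#'   at least 2) or a list of [chromatogram()]s on identical time grids.
#' @return Numeric vector of correlations in `[-1, 1]`, one per transition.
#' @export
#' @examples
#' tt <- seq(0, 1, by = 0.05)
#' g <- exp(-(tt - 0.5)^2 / 0.02)
#' correlation_to_median(cbind(g, 2 * g, 0.5 * g))
correlation_to_median <- function(traces) {
  if (is.list(traces) && !is.data.frame(traces)) {
    stopifnot(all(vapply(traces, inherits, TRUE, "chromatogram")))
    t0 <- traces[[1]]$times
    ok <- vapply(traces, function(ch) isTRUE(all.equal(ch$times, t0)), TRUE)
    if (!all(ok)) stop("traces must share one time grid", call. = FALSE)
    traces <- vapply(traces, `[[`, numeric(length(t0)), "intensities")
  }
  traces <- as.matrix(traces)
  if (ncol(traces) < 2) stop("need at least 2 traces", call. = FALSE)
  med <- apply(traces, 1, stats::median)
  sds <- apply(traces, 2, stats::sd)
  if (stats::sd(med) == 0) {
    warning("median trace is constant; correlations undefined, returning 0",
            call. = FALSE)
    return(rep(0, ncol(traces)))
  }
  r <- rep(0, ncol(traces))
  if (any(sds == 0)) {
    warning("constant trace(s); correlation undefined, returning 0",
            call. = FALSE)
  }
  nz <- sds > 0
  r[nz] <- as.numeric(stats::cor(traces[, nz, drop = FALSE], med))
  r
}

.precursor_key <- function(records) {
  paste(records$peptide, records$precursor_charge, records$label_type,
        records$file_name, sep = "\r")
}

#' Apply the transition-quality rules to a transition report
#'
#' Every transition record receives a verdict; the rules are evaluated
#' independently so a failing record lists all rules it violates:
#' \describe{
#'   \item{min_area}{`area >= min_area`}
#'   \item{min_relative_area}{`area / max(area)` within the precursor
#'     (peptide, charge, label type, file) `>= min_relative_area`}
#'   \item{min_signal_to_background}{`area / background >= threshold`;
#'     `background == 0` passes (infinite S/B)}
#'   \item{min_correlation}{Pearson r to the precursor's median trace
#'     `>= min_correlation`; skipped with a warning when `traces` is `NULL`}
#'   \item{base_width}{`fwhm * 2.547` within `base_width_range`}
#'   \item{rt_range}{`rt` within `rt_range`}
#' }
#' Missing values fail the corresponding rule.
#'
#' @param records Transition report data frame
#'   (see [read_transition_report()]).
#' @param traces Optional named list keyed by
#'   `paste(peptide, precursor_charge, label_type, file_name, sep = "/")`,
#'   each element a matrix of co-eluting transition traces whose columns are
#'   named by `product_mz`. `NULL` skips the correlation rule.
#' @param thresholds A [filter_thresholds()] object.
#' @return The input records with added columns `passed` (logical) and
#'   `failed_rules` (list of character vectors; empty iff passed), classed
#'   `filter_verdicts`.
#' @export
filter_transitions <- function(records, traces = NULL,
                               thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  n <- nrow(records)
  fails <- vector("list", n)
  add_fail <- function(bad, rule) {
    for (i in which(bad)) fails[[i]] <<- c(fails[[i]], rule)
    fails
  }

  area <- records$area
  fails <- add_fail(is.na(area) | area < thresholds$min_area, "min_area")

  key <- .precursor_key(records)
  max_area <- stats::ave(ifelse(is.na(area), 0, area), key,
                         FUN = function(x) max(x, na.rm = TRUE))
  rel <- ifelse(max_area > 0, area / max_area, 1)
  fails <- add_fail(is.na(rel) | rel < thresholds$min_relative_area,
                    "min_relative_area")

  bg <- records$background
  sb <- ifelse(is.na(bg) | is.na(area), NA_real_,
               ifelse(bg == 0, Inf, area / bg))
  fails <- add_fail(is.na(sb) | sb < thresholds$min_signal_to_background,
                    "min_signal_to_background")

  if (!is.null(traces)) {
    r <- rep(NA_real_, n)
    pub_key <- paste(records$peptide, records$precursor_charge,
                     records$label_type, records$file_name, sep = "/")
    for (k in unique(pub_key)) {
      idx <- which(pub_key == k)
      tr <- traces[[k]]
      if (is.null(tr) || ncol(tr) < 2) next
      cols <- match(as.character(records$product_mz[idx]), colnames(tr))
      rr <- suppressWarnings(correlation_to_median(tr))
      r[idx] <- rr[cols]
    }
    fails <- add_fail(is.na(r) | r < thresholds$min_correlation,
                      "min_correlation")
  } else {
    warning("no traces supplied; correlation rule skipped", call. = FALSE)
  }

  bw <- peak_base_width(records$fwhm)
  fails <- add_fail(is.na(bw) | bw < thresholds$base_width_range[1] |
                      bw > thresholds$base_width_range[2], "base_width")

  rt <- records$rt
  fails <- add_fail(is.na(rt) | rt < thresholds$rt_range[1] |
                      rt > thresholds$rt_range[2], "rt_range")

  fails <- lapply(fails, function(x) if (is.null(x)) character(0) else x)
  out <- records
  out$passed <- lengths(fails) == 0
  out$failed_rules <- fails
  class(out) <- c("filter_verdicts", class(records))
  out
}

#' Summarize per-rule rejection counts
#'
#' @param object A `filter_verdicts` object from [filter_transitions()].
#' @param ... Unused.
#' @return Named integer vector of rejection counts per rule (invisibly),
#'   printed with totals.
#' @export
summary.filter_verdicts <- function(object, ...) {
  rules <- unlist(object$failed_rules)
  counts <- if (length(rules)) table(rules) else table(character(0))
  cat(sprintf("%d / %d transitions passed\n",
              sum(object$passed), nrow(object)))
  if (length(counts)) {
    for (r in names(counts)) cat(sprintf("  %-26s %d\n", r, counts[[r]]))
  }
  invisible(as.integer(counts))
}

#' Qualify precursors by their number of passing transitions
#'
#' A precursor (peptide, charge, label type) is accepted if it has at least
#' `min_qualifying_transitions` passing transitions (typically 3); accepted
#' precursors carry only their passing transitions.
#'
#' @param verdicts A `filter_verdicts` object from [filter_transitions()].
#' @param min_qualifying_transitions Minimum passing-transition count.
#' @return A list of class `qualified_precursors` with elements
#'   \describe{
#'     \item{precursors}{data frame: peptide, precursor_charge, label_type,
#'       protein_id, precursor_mz, rt, fwhm, n_qualifying, total_area}
#'     \item{transitions}{the passing transition records of accepted
#'       precursors}
#'   }
#' @export
qualify_precursors <- function(verdicts, min_qualifying_transitions = 3L) {
  stopifnot(min_qualifying_transitions >= 1)
  key <- paste(verdicts$peptide, verdicts$precursor_charge,
               verdicts$label_type, sep = "\r")
  npass <- tapply(verdicts$passed, key, sum)
  accepted_keys <- names(npass)[npass >= min_qualifying_transitions]
  keep <- verdicts$passed & key %in% accepted_keys
  trans <- as.data.frame(verdicts)[keep, , drop = FALSE]
  trans$failed_rules <- NULL
  trans$passed <- NULL
  rownames(trans) <- NULL
  if (nrow(trans)) {
    kk <- paste(trans$peptide, trans$precursor_charge, trans$label_type,
                sep = "\r")
    first <- !duplicated(kk)
    prec <- data.frame(
      peptide = trans$peptide[first],
      precursor_charge = trans$precursor_charge[first],
      label_type = trans$label_type[first],
      protein_id = trans$protein_id[first],
      precursor_mz = trans$precursor_mz[first],
      rt = as.numeric(tapply(trans$rt, kk, stats::median))[match(kk[first], sort(unique(kk)))],
      fwhm = as.numeric(tapply(trans$fwhm, kk, stats::median, na.rm = TRUE))[match(kk[first], sort(unique(kk)))],
      n_qualifying = as.integer(tapply(rep(1L, nrow(trans)), kk, sum))[match(kk[first], sort(unique(kk)))],
      total_area = as.numeric(tapply(trans$area, kk, sum))[match(kk[first], sort(unique(kk)))]
    )
    rownames(prec) <- NULL
  } else {
    prec <- data.frame(
      peptide = character(0), precursor_charge = integer(0),
      label_type = character(0), protein_id = character(0),
      precursor_mz = numeric(0), rt = numeric(0), fwhm = numeric(0),
      n_qualifying = integer(0), total_area = numeric(0)
    )
  }
  structure(list(precursors = prec, transitions = trans),
            class = "qualified_precursors")
}

#' @export
print.qualified_precursors <- function(x, ...) {
  cat(sprintf("%d qualified precursors, %d qualifying transitions\n",
              nrow(x$precursors), nrow(x$transitions)))
  invisible(x)
}
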