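#' Chromatogram container
#'
#' A single extracted chromatogram: a strictly increasing time axis with
#' non-negative intensities and, optionally, the per-scan injection times used
#' to acquire it (needed for ion counting).
#'
#' @param times Scan times, minutes, strictly increasing.
#' @param intensities Intensities (charges/second), same length, `>= 0`.
#' @param injection_times Optional per-scan injection times, seconds.
#' @return An object of class `chromatogram`.
#' @export
#' @examples
#' chromatogram(c(1, 2, 3), c(0, 10, 0))
chromatogram <- function(times, intensities, injection_times = NULL) {
  stopifnot(
    length(times) == length(intensities),
    all(diff(times) > 0),
    all(intensities >= 0)
  )
  if (!is.null(injection_times)) {
    stopifnot(length(injection_times) == length(times),
              all(injection_times >= 0))
  }
  structure(
    list(times = as.numeric(times), intensities = as.numeric(intensities),
         injection_times = injection_times),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram: %d scans, %.3f-%.3f min, apex %.4g at %.3f min\n",
              length(x$times), min(x$times), max(x$times),
              max(x$intensities), x$times[which.max(x$intensities)]))
  invisible(x)
}

# Canonical transition-report columns and their on-disk dialect. The dialect
# is modeled on a Skyline custom report; the alias table lets reports written
# with Skyline-style headers be read without renaming.
.TRANSITION_COLUMNS <- c(
  "protein_id", "peptide", "precursor_charge", "precursor_mz", "product_mz",
  "fragment_label", "label_type", "area", "background", "fwhm", "rt",
  "start_time", "end_time", "file_name"
)
.TRANSITION_NUMERIC <- c(
  "precursor_charge", "precursor_mz", "product_mz", "area", "background",
  "fwhm", "rt", "start_time", "end_time"
)

#' Column aliases accepted by [read_transition_report()]
#'
#' Maps common report-header spellings (Skyline-style custom report headers)
#' to the canonical column names. Matching is case-insensitive and ignores
#' spaces and punctuation.
#'
#' @return Named character vector: names are alias spellings, values are
#'   canonical column names.
#' @export
transition_column_aliases <- function() {
  c(
    "protein"                  = "protein_id",
    "proteinname"              = "protein_id",
    "peptidemodifiedsequence"  = "peptide",
    "modifiedsequence"         = "peptide",
    "precursorcharge"          = "precursor_charge",
    "precursormz"              = "precursor_mz",
    "productmz"                = "product_mz",
    "fragmention"              = "fragment_label",
    "isotopelabeltype"         = "label_type",
    "totalarea"                = "area",
    "totalbackground"          = "background",
    "maxfwhm"                  = "fwhm",
    "bestretentiontime"        = "rt",
    "retentiontime"            = "rt",
    "minstarttime"             = "start_time",
    "maxendtime"               = "end_time",
    "filename"                 = "file_name"
  )
}

.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a transition-level quantitative report
#'
#' Reads a CSV report with one row per precursor-to-product transition,
#' carrying the quantitative metadata used for transition filtering and assay
#' design (areas, backgrounds, peak widths, retention times, integration
#' boundaries). Canonical column names are
#' `protein_id, peptide, precursor_charge, precursor_mz, product_mz,
#' fragment_label, label_type, area, background, fwhm, rt, start_time,
#' end_time, file_name`; Skyline-style spellings are accepted via
#' [transition_column_aliases()]. Unknown columns are ignored. Empty numeric
#' cells become `NA`.
#'
#' @param path Path to the CSV file.
#' @param aliases Alias table, see [transition_column_aliases()].
#' @return A data frame with the canonical columns, one row per transition.
#' @export
read_transition_report <- function(path,
                                   aliases = transition_column_aliases()) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  hdr <- .norm_header(names(raw))
  canon <- ifelse(hdr %in% names(aliases), aliases[hdr], hdr)
  # direct canonical spellings (with or without underscores) also match
  canon_direct <- match(hdr, .norm_header(.TRANSITION_COLUMNS))
  canon[!is.na(canon_direct)] <- .TRANSITION_COLUMNS[canon_direct[!is.na(canon_direct)]]
  missing <- setdiff(.TRANSITION_COLUMNS, canon)
  if (length(missing)) {
    stop("transition report ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- raw[match(.TRANSITION_COLUMNS, canon)]
  names(out) <- .TRANSITION_COLUMNS
  for (col in .TRANSITION_NUMERIC) {
    v <- out[[col]]
    empty <- is.na(v) | v == "" | toupper(v) == "NA"
    num <- suppressWarnings(as.numeric(v))
    bad <- !empty & is.na(num)
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                   v[which(bad)[1]], col, which(bad)[1] + 1L, path),
           call. = FALSE)
    }
    out[[col]] <- num
  }
  out$precursor_charge <- as.integer(out$precursor_charge)
  out$label_type <- tolower(out$label_type)
  rownames(out) <- NULL
  out
}

#' Write a transition-level report
#'
#' Writes the canonical CSV dialect read back by [read_transition_report()]
#' (UTF-8, "." decimal separator, LF line endings). Numeric values are
#' written with full precision so a write/read round trip is lossless.
#'
#' @param records Data frame of transition records (canonical columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_report <- function(records, path) {
  stopifnot(all(.TRANSITION_COLUMNS %in% names(records)))
  out <- records[.TRANSITION_COLUMNS]
  for (col in .TRANSITION_NUMERIC) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], digits = 15, trim = TRUE,
                                scientific = FALSE))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write a scheduled target list
#'
#' Exports scheduled targets as the CSV consumed by an instrument-method
#' template: columns `Compound, PrecursorMz, Charge, WindowStart, WindowEnd,
#' ScanRangeLow, ScanRangeHigh, NCE, MaxInjectionTime`. Windows are minutes
#' (3+ decimals), the scan range is Th, NCE is percent (default 30) and the
#' maximum injection time is milliseconds. Duplicate compound names are
#' disambiguated with a charge suffix (warning).
#'
#' @param targets Data frame of scheduled targets with columns `peptide`,
#'   `charge`, `precursor_mz`, `window_start`, `window_end`, `scan_low`,
#'   `scan_high` and optionally `max_it_ms`.
#' @param path Output path.
#' @param nce Normalized collision energy, percent. Default 30.
#' @param default_max_it_ms Maximum injection time used when the targets
#'   carry none, milliseconds.
#' @return `path`, invisibly.
#' @export
write_target_list <- function(targets, path, nce = 30,
                              default_max_it_ms = 100) {
  need <- c("peptide", "charge", "precursor_mz", "window_start",
            "window_end", "scan_low", "scan_high")
  stopifnot(all(need %in% names(targets)))
  n <- nrow(targets)
  header <- c("Compound", "PrecursorMz", "Charge", "WindowStart", "WindowEnd",
              "ScanRangeLow", "ScanRangeHigh", "NCE", "MaxInjectionTime")
  if (n == 0) {
    writeLines(paste(header, collapse = ","), path)
    return(invisible(path))
  }
  stopifnot(all(targets$window_start < targets$window_end),
            all(targets$scan_low < targets$scan_high))
  compound <- as.character(targets$peptide)
  if (anyDuplicated(compound)) {
    dup <- compound %in% compound[duplicated(compound)]
    compound[dup] <- paste0(compound[dup], "+", targets$charge[dup])
    if (anyDuplicated(compound)) {
      compound <- make.unique(compound, sep = "#")
    }
    warning("duplicate compound names disambiguated with charge suffix",
            call. = FALSE)
  }
  max_it <- if ("max_it_ms" %in% names(targets)) {
    ifelse(is.na(targets$max_it_ms), default_max_it_ms, targets$max_it_ms)
  } else rep(default_max_it_ms, n)
  rows <- sprintf("%s,%.4f,%d,%.4f,%.4f,%.4f,%.4f,%.1f,%.3f",
                  compound, targets$precursor_mz,
                  as.integer(targets$charge),
                  targets$window_start, targets$window_end,
                  targets$scan_low, targets$scan_high,
                  nce, max_it)
  writeLines(c(paste(header, collapse = ","), rows), path)
  invisible(path)
}

#' Read a scheduled target list written by [write_target_list()]
#'
#' @param path Path to the CSV.
#' @return Data frame with columns `peptide, precursor_mz, charge,
#'   window_start, window_end, scan_low, scan_high, nce, max_it_ms`.
#' @export
read_target_list <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("Compound", "PrecursorMz", "Charge", "WindowStart",
                "WindowEnd", "ScanRangeLow", "ScanRangeHigh", "NCE",
                "MaxInjectionTime")
  if (!identical(names(df), expected)) {
    stop("not a prmforge target list: ", path, call. = FALSE)
  }
  data.frame(
    peptide = as.character(df$Compound),
    precursor_mz = df$PrecursorMz,
    charge = as.integer(df$Charge),
    window_start = df$WindowStart,
    window_end = df$WindowEnd,
    scan_low = df$ScanRangeLow,
    scan_high = df$ScanRangeHigh,
    nce = df$NCE,
    max_it_ms = df$MaxInjectionTime
  )
}

#' Write a peak integration-boundary list
#'
#' Writes the Skyline peak-boundary CSV dialect with the exact header
#' `FileName,MinStartTime,MaxEndTime,PeptideModifiedSequence`; times are
#' minutes with 4 decimals.
#'
#' @param boundaries Data frame with columns `file_name`, `peptide`,
#'   `min_start_time`, `max_end_time`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary_list <- function(boundaries, path) {
  header <- "FileName,MinStartTime,MaxEndTime,PeptideModifiedSequence"
  if (nrow(boundaries) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  stopifnot(all(c("file_name", "peptide", "min_start_time", "max_end_time")
                %in% names(boundaries)),
            all(boundaries$min_start_time < boundaries$max_end_time))
  rows <- sprintf("%s,%.4f,%.4f,%s",
                  boundaries$file_name, boundaries$min_start_time,
                  boundaries$max_end_time, boundaries$peptide)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a peak integration-boundary list
#'
#' @param path Path to a boundary CSV in the dialect of
#'   [write_boundary_list()].
#' @return Data frame with columns `file_name, peptide, min_start_time,
#'   max_end_time`.
#' @export
read_boundary_list <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("FileName", "MinStartTime", "MaxEndTime",
                "PeptideModifiedSequence")
  if (!identical(names(df), expected)) {
    stop("not a peak-boundary list: ", path, call. = FALSE)
  }
  data.frame(
    file_name = as.character(df$FileName),
    peptide = as.character(df$PeptideModifiedSequence),
    min_start_time = df$MinStartTime,
    max_end_time = df$MaxEndTime
  )
}

#' Serialize a reference map to a text file
#'
#' The on-disk format is two-part: the first line is a JSON header (time-grid
#' origin/step/length, m/z bin width, bin offset and count, top-K, typical
#' peak FWHM); the remaining lines are tab-separated `row, col, value`
#' triplets of the non-zero matrix entries (1-based indices).
#'
#' @param map A [build_reference()] object of class `reference_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_reference_map()]
#' @export
write_reference_map <- function(map, path) {
  stopifnot(inherits(map, "reference_map"))
  g <- map$time_grid
  header <- jsonlite::toJSON(list(
    format = "prmforge-reference-map", version = 1L,
    t0 = g[1], dt = if (length(g) > 1) g[2] - g[1] else 0,
    n_times = length(g),
    mz_bin_width = map$mz_bin_width, bin_lo = map$bin_lo,
    n_bins = ncol(map$matrix), top_k = map$top_k,
    peak_fwhm = map$peak_fwhm
  ), auto_unbox = TRUE, digits = NA)
  nz <- which(map$matrix != 0, arr.ind = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(as.character(header), con)
  if (nrow(nz)) {
    writeLines(sprintf("%d\t%d\t%.10g", nz[, 1], nz[, 2],
                       map$matrix[nz]), con)
  }
  invisible(path)
}

#' Read a serialized reference map
#'
#' @param path Path written by [write_reference_map()].
#' @return An object of class `reference_map`.
#' @export
read_reference_map <- function(path) {
  lines <- readLines(path)
  h <- jsonlite::fromJSON(lines[1])
  if (!identical(h$format, "prmforge-reference-map")) {
    stop("not a prmforge reference map: ", path, call. = FALSE)
  }
  mat <- matrix(0, nrow = h$n_times, ncol = h$n_bins)
  if (length(lines) > 1) {
    trip <- utils::read.table(text = lines[-1], sep = "\t",
                              col.names = c("row", "col", "value"))
    mat[cbind(trip$row, trip$col)] <- trip$value
  }
  structure(
    list(
      time_grid = h$t0 + h$dt * (seq_len(h$n_times) - 1),
      mz_bin_width = h$mz_bin_width,
      bin_lo = h$bin_lo,
      matrix = mat,
      top_k = h$top_k,
      peak_fwhm = h$peak_fwhm
    ),
    class = "reference_map"
  )
}
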