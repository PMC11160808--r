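.CONFIG_KEYS <- c(
  "seed", "out_dir", "report", "simulate", "thresholds", "timing",
  "points_per_peak", "window_width", "edge_widening", "edge_zone",
  "gradient", "balanced_n", "split", "cycle_time_s", "dilution",
  "fom_peptides", "verbosity"
)

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a named list; unknown keys are rejected.
#' See [run_pipeline()] for the keys.
#'
#' @param config Path to a YAML file or a named list.
#' @return The validated config list with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(
    seed = 1L, report = NULL,
    simulate = list(n_peptides = 60, fwhm = 0.15),
    thresholds = list(), timing = list(),
    points_per_peak = 6, window_width = 0.6,
    edge_widening = 0.5, edge_zone = 0.1,
    gradient = c(2, 32), balanced_n = NULL, split = TRUE,
    cycle_time_s = NULL, dilution = list(),
    fom_peptides = 3L, verbosity = 1L
  )
  out <- utils::modifyList(defaults, config)
  if (is.null(out$out_dir)) stop("config requires out_dir", call. = FALSE)
  out$gradient <- as.numeric(unlist(out$gradient))
  stopifnot(length(out$gradient) == 2, out$gradient[1] < out$gradient[2],
            out$window_width > 0, out$points_per_peak >= 1)
  out
}

#' Run the full assay-design pipeline
#'
#' Chains the stages filter -> design -> simulate -> figures of merit on
#' either a supplied transition report or a simulated one, writing all
#' artifacts to `config$out_dir` and returning a machine-readable summary.
#' Deterministic for a fixed `seed`.
#'
#' Config keys (YAML or list): `seed`, `out_dir`, `report` (optional CSV
#' path; when absent a synthetic report is generated from `simulate`:
#' `n_peptides`, `fwhm`), `thresholds` ([filter_thresholds()] overrides),
#' `timing` ([instrument_timing_model()] overrides), `points_per_peak`,
#' `window_width` (minutes), `edge_widening`, `edge_zone`, `gradient`
#' (`[t0, t1]` minutes), `balanced_n` (optional best-N-per-protein
#' selection), `split` (split infeasible assays, default TRUE),
#' `cycle_time_s` (override the points-per-peak-derived cycle), `dilution`
#' (`levels`, `replicates`, `noise_cv`), `fom_peptides` (how many peptides
#' get dilution-curve figures of merit), `verbosity`.
#'
#' Artifacts written: `report.csv` (when simulated), `targets_assay<k>.csv`,
#' `concurrency.csv`, `foms.csv`, `summary.json`.
#'
#' @param config Path to a YAML config or a named list
#'   (see [load_run_config()]).
#' @return Summary list (invisibly): per-stage counts, feasibility, assay
#'   count, FOM table.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) {
    if (cfg$verbosity > 0) message(sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  summary <- list(seed = cfg$seed)

  # --- inputs -----------------------------------------------------------
  peaks <- NULL
  report <- stage("input", {
    if (!is.null(cfg$report)) {
      read_transition_report(cfg$report)
    } else {
      sim <- cfg$simulate
      # the stage block is a promise evaluated in this function's frame,
      # so plain assignment lands here
      peaks <- simulate_ground_truth(
        n_peptides = sim$n_peptides %||% 60,
        gradient = cfg$gradient,
        fwhm = sim$fwhm %||% 0.15,
        seed = cfg$seed
      )
      rep <- simulate_transition_report(peaks, seed = cfg$seed + 1L)
      write_transition_report(rep, file.path(cfg$out_dir, "report.csv"))
      rep
    }
  })
  summary$transitions_in <- nrow(report)
  log_msg("input: %d transitions, %d precursors", nrow(report),
          length(unique(paste(report$peptide, report$precursor_charge))))

  # --- filter -----------------------------------------------------------
  qualified <- stage("filter", {
    thr <- do.call(filter_thresholds, cfg$thresholds)
    verdicts <- suppressWarnings(filter_transitions(report, NULL, thr))
    summary$transitions_passed <- sum(verdicts$passed)
    qualify_precursors(verdicts, thr$min_qualifying_transitions)
  })
  summary$precursors_qualified <- nrow(qualified$precursors)
  log_msg("filter: %d transitions passed, %d precursors qualified",
          summary$transitions_passed, summary$precursors_qualified)
  if (summary$precursors_qualified == 0) {
    stop("stage 'filter' failed: no precursor qualified", call. = FALSE)
  }

  # --- design -----------------------------------------------------------
  model <- do.call(instrument_timing_model, cfg$timing)
  design <- stage("design", {
    prec <- qualified$precursors
    if (!is.null(cfg$balanced_n)) {
      prec <- balanced_load(prec, cfg$balanced_n)
    }
    tr <- qualified$transitions
    key <- paste(tr$peptide, tr$precursor_charge, tr$label_type)
    pkey <- paste(prec$peptide, prec$precursor_charge, prec$label_type)
    targets <- scheduled_targets(
      peptide = prec$peptide, charge = prec$precursor_charge,
      precursor_mz = prec$precursor_mz, rt_center = prec$rt,
      transitions = lapply(pkey, function(k) tr$product_mz[key == k]),
      abundance = prec$total_area, protein_id = prec$protein_id
    )
    targets <- assign_windows(targets, cfg$window_width, cfg$gradient,
                              cfg$edge_widening, cfg$edge_zone)
    targets <- optimize_scan_ranges(targets)
    fwhm_typ <- stats::median(qualified$transitions$fwhm, na.rm = TRUE)
    cycle <- cfg$cycle_time_s %||%
      required_cycle_time(fwhm_typ, cfg$points_per_peak)
    feas <- feasibility_report(targets, model, cycle)
    utils::write.csv(as.data.frame(concurrency_profile(targets)),
                     file.path(cfg$out_dir, "concurrency.csv"),
                     row.names = FALSE)
    assays <- if (feas$feasible) {
      list(targets)
    } else if (isTRUE(cfg$split)) {
      split_assays(targets, model, cycle)
    } else {
      list(targets)
    }
    list(targets = targets, cycle = cycle, feasible = feas$feasible,
         min_cycle = feas$min_cycle_required_s, assays = assays)
  })
  summary$cycle_time_s <- design$cycle
  summary$feasible_single_assay <- design$feasible
  summary$min_cycle_required_s <- design$min_cycle
  summary$n_assays <- length(design$assays)
  for (k in seq_along(design$assays)) {
    write_target_list(design$assays[[k]],
                      file.path(cfg$out_dir,
                                sprintf("targets_assay%d.csv", k)))
  }
  log_msg("design: cycle %.3f s, %s, %d assay(s)", design$cycle,
          if (design$feasible) "feasible" else "infeasible as one assay",
          summary$n_assays)

  # --- figures of merit (simulated dilution series) ---------------------
  if (!is.null(peaks) && cfg$fom_peptides > 0) {
    foms <- stage("foms", {
      dil <- cfg$dilution
      levels <- dil$levels %||% (100 / 3^(0:6))
      levels <- c(sort(as.numeric(levels), decreasing = TRUE), 0)
      pep_sel <- intersect(peaks$peptide, design$targets$peptide)
      pep_sel <- utils::head(pep_sel, cfg$fom_peptides)
      series <- simulate_dilution_series(
        peaks[peaks$peptide %in% pep_sel, , drop = FALSE],
        levels = levels,
        replicates = dil$replicates %||% 3L,
        noise_cv = dil$noise_cv %||% 0.05,
        seed = cfg$seed + 2L
      )
      res <- lapply(pep_sel, function(pp) {
        optimize_transition_subset(series[series$peptide == pp, ],
                                   peptide = pp)
      })
      data.frame(
        peptide = pep_sel,
        lod = vapply(res, function(r) r$lod, 0),
        loq = vapply(res, function(r) ifelse(is.na(r$loq), NA_real_, r$loq), 0),
        n_transitions = vapply(res, function(r) length(r$chosen_transitions),
                               0L),
        transitions = vapply(res, function(r) {
          paste(r$chosen_transitions, collapse = ";")
        }, "")
      )
    })
    utils::write.csv(foms, file.path(cfg$out_dir, "foms.csv"),
                     row.names = FALSE)
    summary$foms <- foms
    log_msg("foms: %d peptides, median LOD %.3g, median LOQ %.3g",
            nrow(foms), stats::median(foms$lod, na.rm = TRUE),
            stats::median(foms$loq, na.rm = TRUE))
  }

  jsonlite::write_json(
    summary[setdiff(names(summary), "foms")],
    file.path(cfg$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(summary)
}
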