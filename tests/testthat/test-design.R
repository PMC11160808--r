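simple_targets <- function(centers, ntr = 5L) {
  scheduled_targets(
    peptide = sprintf("P%03d", seq_along(centers)), charge = 2L,
    precursor_mz = 500, rt_center = centers,
    transitions = replicate(length(centers),
                            seq(400, 800, length.out = ntr),
                            simplify = FALSE)
  )
}

test_that("windows are centered, clipped, and widened at the gradient edges", {
  tg <- simple_targets(c(15, 0.5, 29.5, 2))
  w <- assign_windows(tg, 0.6, c(0, 30), edge_widening = 0.5,
                      edge_zone = 0.1)
  # mid-gradient: center +/- width/2
  expect_equal(c(w$window_start[1], w$window_end[1]), c(14.7, 15.3))
  # edge zones (first/last 3 min): width 0.6 * 1.5 = 0.9
  expect_equal(w$window_end[2] - w$window_start[2], 0.9)
  expect_equal(w$window_end[3] - w$window_start[3], 0.9)
  expect_equal(w$window_end[4] - w$window_start[4], 0.9)
  # clipping at the gradient start
  tg0 <- simple_targets(0)
  w0 <- assign_windows(tg0, 0.6, c(0, 30))
  expect_equal(w0$window_start, 0)
})

test_that("centers outside the gradient are clipped with a warning", {
  tg <- simple_targets(c(15, 31))
  expect_warning(w <- assign_windows(tg, 0.6, c(0, 30)), "clipped")
  expect_lte(w$window_end[2], 30)
  expect_lt(w$window_start[2], w$window_end[2])
})

test_that("concurrency of disjoint and identical windows", {
  tg <- simple_targets(c(5, 10, 15))
  tg <- assign_windows(tg, 0.6, c(0, 30), edge_widening = 0)
  expect_equal(concurrency_profile(tg)$max_precursors, 1L)

  tg10 <- simple_targets(rep(12, 10), ntr = 4L)
  tg10 <- assign_windows(tg10, 0.6, c(0, 30), edge_widening = 0)
  prof <- concurrency_profile(tg10)
  expect_equal(prof$max_precursors, 10L)
  expect_equal(prof$max_transitions, 40L)
})

test_that("concurrency profile equals the brute-force interval count", {
  win <- make_random_windows(200, seed = 14)
  prof <- concurrency_profile(win, grid_step = 0.05)
  oracle <- brute_force_concurrency(win, prof$time)
  expect_identical(prof$concurrent_precursors, oracle$precursors)
  expect_identical(prof$concurrent_transitions, oracle$transitions)
})

test_that("window membership is half-open: no double counting at boundaries", {
  win <- data.frame(window_start = c(10, 10.6), window_end = c(10.6, 11.2),
                    n_transitions = c(1L, 1L))
  prof <- concurrency_profile(win, grid_step = 0.1)
  expect_equal(max(prof$concurrent_precursors), 1L)
})

test_that("required cycle time follows the base-width / points-per-peak rule", {
  expect_equal(required_cycle_time(0.1, 6), 2.547, tolerance = 1e-9)
  expect_equal(required_cycle_time(0.1, 1), 0.1 * 2.547 * 60)
  expect_equal(required_cycle_time(0.2, 12), required_cycle_time(0.1, 6))
})

test_that("scan ranges shrink to the transitions and pick the fast rate", {
  tg <- scheduled_targets("A", 2L, 600, 15,
                          transitions = list(c(400.2, 800.4)))
  o <- optimize_scan_ranges(tg)
  expect_equal(c(o$scan_low, o$scan_high), c(395.2, 805.4))
  expect_equal(o$scan_rate, 125)

  one <- optimize_scan_ranges(scheduled_targets("B", 2L, 600, 15,
                                                transitions = list(777)))
  expect_equal(one$scan_high - one$scan_low, 10)

  wide <- optimize_scan_ranges(scheduled_targets("C", 2L, 600, 15,
                                                 transitions = list(c(350, 1250))))
  expect_gt(wide$scan_high - wide$scan_low, 600)
  expect_equal(wide$scan_rate, 67)

  clip <- optimize_scan_ranges(scheduled_targets("D", 2L, 600, 15,
                                                 transitions = list(c(202, 1498))))
  expect_equal(c(clip$scan_low, clip$scan_high), c(200, 1500))
})

test_that("feasibility: n identical targets with period p fit iff n*p <= cycle", {
  m <- instrument_timing_model()
  tg <- simple_targets(rep(12, 8))
  tg <- assign_windows(tg, 0.6, c(0, 30), edge_widening = 0)
  tg <- optimize_scan_ranges(tg)
  p <- (tg$scan_high[1] - tg$scan_low[1]) / tg$scan_rate[1] +
    m$per_scan_overhead_ms
  just <- feasibility_report(tg, m, cycle_requirement_s = 8 * p / 1000 + 1e-6)
  expect_true(just$feasible)
  expect_equal(just$min_cycle_required_s, 8 * p / 1000, tolerance = 1e-9)
  tight <- feasibility_report(tg, m, cycle_requirement_s = 8 * p / 1000 - 1e-4)
  expect_false(tight$feasible)
  # a single target is feasible at any sane cycle
  single <- feasibility_report(tg[1, ], m, cycle_requirement_s = 0.5)
  expect_true(single$feasible)
})

test_that("feasibility report matches per-point recomputation on a random assay", {
  set.seed(15)
  m <- instrument_timing_model()
  tg <- simple_targets(runif(40, 1, 29))
  tg <- assign_windows(tg, runif(1, 0.4, 1.2), c(0, 30))
  tg <- optimize_scan_ranges(tg)
  fr <- feasibility_report(tg, m, cycle_requirement_s = 1, grid_step = 0.1)
  periods <- (tg$scan_high - tg$scan_low) / tg$scan_rate +
    m$per_scan_overhead_ms
  for (g in seq(1, nrow(fr$profile), by = 7)) {
    t <- fr$profile$time[g]
    act <- which(t >= tg$window_start & t < tg$window_end)
    expect_equal(fr$profile$total_period_ms[g], sum(periods[act]))
    expect_equal(fr$profile$n_precursors[g], length(act))
  }
})

test_that("removing a target never makes a feasible assay infeasible", {
  set.seed(16)
  tg <- simple_targets(runif(30, 1, 29))
  tg <- assign_windows(tg, 0.8, c(0, 30))
  tg <- optimize_scan_ranges(tg)
  m <- instrument_timing_model()
  cyc <- feasibility_report(tg, m, 1)$min_cycle_required_s + 1e-6
  expect_true(feasibility_report(tg, m, cyc)$feasible)
  for (drop in sample(30, 5)) {
    expect_true(feasibility_report(tg[-drop, ], m, cyc)$feasible)
  }
})

test_that("balanced load keeps the top-N peptides per protein, deterministically", {
  prec <- data.frame(
    protein_id = c("A", "A", "A", "A", "A", "B"),
    peptide = c("P1", "P2", "P3", "P4", "P5", "Q1"),
    total_area = c(10, 50, 30, 50, 20, 5),
    n_transitions = c(3L, 4L, 3L, 3L, 3L, 3L)
  )
  top2 <- balanced_load(prec, 2)
  # P2 and P4 tie on area; P2 wins on transition count
  expect_setequal(top2$peptide[top2$protein_id == "A"], c("P2", "P4"))
  expect_equal(top2$peptide[1], "P2")
  expect_equal(top2$peptide[top2$protein_id == "B"], "Q1")

  # N larger than available keeps everything
  expect_equal(nrow(balanced_load(prec, 10)), 6)

  # equal areas resolve lexicographically and survive permutation
  prec$total_area <- 7
  prec$n_transitions <- 3L
  a <- balanced_load(prec, 2)
  b <- balanced_load(prec[sample(nrow(prec)), ], 2)
  expect_equal(a$peptide, b$peptide)
  expect_equal(a$peptide[a$protein_id == "A"], c("P1", "P2"))
})

test_that("splitting returns one assay when everything fits", {
  tg <- simple_targets(c(5, 15, 25))
  tg <- assign_windows(tg, 0.6, c(0, 30))
  tg <- optimize_scan_ranges(tg)
  out <- split_assays(tg, cycle_requirement_s = 1)
  expect_length(out, 1)
})

test_that("a 2x oversubscribed uniform load splits into 2 feasible assays", {
  m <- instrument_timing_model()
  tg <- simple_targets(rep(12, 10))
  tg <- assign_windows(tg, 0.6, c(0, 30), edge_widening = 0)
  tg <- optimize_scan_ranges(tg)
  p <- (tg$scan_high[1] - tg$scan_low[1]) / tg$scan_rate[1] +
    m$per_scan_overhead_ms
  cyc <- 5.5 * p / 1000  # room for 5 of the 10 concurrent targets
  out <- split_assays(tg, m, cyc)
  expect_length(out, 2)
  for (a in out) expect_true(feasibility_report(a, m, cyc)$feasible)
})

test_that("splitting partitions the input (disjoint cover)", {
  set.seed(17)
  tg <- simple_targets(sort(runif(40, 1, 29)))
  tg <- assign_windows(tg, 1.5, c(0, 30))
  tg <- optimize_scan_ranges(tg)
  m <- instrument_timing_model()
  cyc <- feasibility_report(tg, m, 1)$min_cycle_required_s / 2.5
  out <- split_assays(tg, m, cyc)
  all_peps <- unlist(lapply(out, `[[`, "peptide"))
  expect_setequal(all_peps, tg$peptide)
  expect_equal(length(all_peps), nrow(tg))
})

test_that("a target infeasible even alone is reported by name", {
  tg <- simple_targets(10)
  tg <- assign_windows(tg, 0.6, c(0, 30))
  tg <- optimize_scan_ranges(tg)
  expect_error(split_assays(tg, cycle_requirement_s = 0.001), "P001")
})
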