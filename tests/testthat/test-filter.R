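test_that("correlation to median: identical traces give r = 1, a negated trace -1", {
  g <- make_gaussian_traces(3, scales = c(1, 1, 1))
  expect_equal(correlation_to_median(g), rep(1, 3), tolerance = 1e-12)

  tr <- make_gaussian_traces(3, scales = c(1, 1, -1))
  r <- correlation_to_median(tr)
  expect_equal(r[1:2], c(1, 1), tolerance = 1e-12)
  expect_equal(r[3], -1, tolerance = 1e-12)
})

test_that("correlation to median matches a direct Pearson computation", {
  set.seed(31)
  tr <- matrix(rlnorm(41 * 5), nrow = 41, ncol = 5) +
    make_gaussian_traces(5, scales = runif(5, 1, 10))
  r <- correlation_to_median(tr)
  med <- apply(tr, 1, median)
  direct <- vapply(1:5, function(j) {
    x <- tr[, j]
    sum((x - mean(x)) * (med - mean(med))) /
      sqrt(sum((x - mean(x))^2) * sum((med - mean(med))^2))
  }, 0)
  expect_equal(r, direct, tolerance = 1e-12)
})

test_that("constant traces yield r = 0 with a warning", {
  tr <- cbind(make_gaussian_traces(1), rep(2, 41), make_gaussian_traces(1))
  expect_warning(r <- correlation_to_median(tr), "constant")
  expect_equal(r[2], 0)
})

test_that("permissive thresholds pass everything; rule failures are named", {
  df <- make_transition_df()
  thr <- filter_thresholds(min_area = 0, min_relative_area = 0,
                           min_signal_to_background = 0,
                           base_width_range = c(0, Inf),
                           rt_range = c(0, Inf))
  v <- suppressWarnings(filter_transitions(df, NULL, thr))
  expect_true(all(v$passed))
  expect_true(all(lengths(v$failed_rules) == 0))

  thr2 <- filter_thresholds(min_area = 100, min_relative_area = 0,
                            min_signal_to_background = 0,
                            base_width_range = c(0, Inf))
  df2 <- df
  df2$area[1] <- 10
  v2 <- suppressWarnings(filter_transitions(df2, NULL, thr2))
  expect_false(v2$passed[1])
  expect_true("min_area" %in% v2$failed_rules[[1]])
})

test_that("zero background counts as infinite signal-to-background", {
  df <- make_transition_df()  # row 2 has background 0
  thr <- filter_thresholds(min_signal_to_background = 1e6,
                           min_relative_area = 0,
                           base_width_range = c(0, Inf))
  v <- suppressWarnings(filter_transitions(df, NULL, thr))
  expect_false("min_signal_to_background" %in% v$failed_rules[[2]])
  expect_true("min_signal_to_background" %in% v$failed_rules[[1]])
})

test_that("a constructed 10-record table matches hand-enumerated verdicts", {
  df <- do.call(rbind, replicate(10, make_transition_df()[1, ],
                                 simplify = FALSE))
  df$product_mz <- 500.1 + seq_len(10)  # keep uniqueness
  df$area <- c(1000, 40, 1000, 1000, 1000, 1000, 1000, 1000, 2, 1000)
  df$background <- c(10, 10, 500, 10, 10, 10, 10, 10, 10, 10)
  df$fwhm <- c(0.1, 0.1, 0.1, 2.0, 0.001, 0.1, 0.1, 0.1, 0.1, NA)
  df$rt <- c(12.5, 12.5, 12.5, 12.5, 12.5, 50, -1, 12.5, 12.5, 12.5)
  thr <- filter_thresholds(min_area = 100, min_relative_area = 0.05,
                           min_signal_to_background = 3,
                           base_width_range = c(0.02, 1.0),
                           rt_range = c(0, 40))
  v <- suppressWarnings(filter_transitions(df, NULL, thr))
  # hand enumeration: max area = 1000 within the single precursor group
  expected <- list(
    character(0),
    c("min_area", "min_relative_area"),  # 40 < 100 and 40/1000 < 0.05
    "min_signal_to_background",          # 1000/500 = 2 < 3
    "base_width",                        # 2.0 * 2.547 > 1.0
    "base_width",                        # 0.001 * 2.547 < 0.02
    "rt_range",                          # 50 > 40
    "rt_range",                          # -1 < 0
    character(0),
    c("min_area", "min_relative_area", "min_signal_to_background"),
    "base_width"                         # missing fwhm fails its rule
  )
  for (i in 1:10) expect_setequal(v$failed_rules[[i]], expected[[i]])
  expect_equal(v$passed, lengths(expected) == 0)
})

test_that("the largest transition of a precursor always passes relative area", {
  set.seed(8)
  df <- make_transition_df()[rep(1, 6), ]
  df$product_mz <- 500 + 1:6
  for (k in 1:20) {
    df$area <- rlnorm(6, 5, 2)
    thr <- filter_thresholds(min_relative_area = runif(1),
                             min_signal_to_background = 0,
                             base_width_range = c(0, Inf))
    v <- suppressWarnings(filter_transitions(df, NULL, thr))
    imax <- which.max(df$area)
    expect_false("min_relative_area" %in% v$failed_rules[[imax]])
  }
})

test_that("verdicts are invariant to row permutation", {
  set.seed(9)
  pk <- simulate_ground_truth(10, seed = 9)
  df <- simulate_transition_report(pk, seed = 10)
  thr <- filter_thresholds(min_area = 100, min_signal_to_background = 5)
  v1 <- suppressWarnings(filter_transitions(df, NULL, thr))
  perm <- sample(nrow(df))
  v2 <- suppressWarnings(filter_transitions(df[perm, ], NULL, thr))
  expect_equal(v2$passed, v1$passed[perm])
})

test_that("tightening any single threshold never grows the accepted set", {
  pk <- simulate_ground_truth(15, seed = 21)
  df <- simulate_transition_report(pk, noise_cv = 0.3, seed = 22)
  base <- filter_thresholds(min_area = 10, min_relative_area = 0.02,
                            min_signal_to_background = 2,
                            base_width_range = c(0.02, 1),
                            rt_range = c(0, 40))
  accepted <- function(thr) {
    v <- suppressWarnings(filter_transitions(df, NULL, thr))
    q <- qualify_precursors(v, thr$min_qualifying_transitions)
    paste(q$precursors$peptide, q$precursors$precursor_charge)
  }
  a0 <- accepted(base)
  tighter <- list(
    filter_thresholds(min_area = 1e4, min_relative_area = 0.02,
                      min_signal_to_background = 2,
                      base_width_range = c(0.02, 1), rt_range = c(0, 40)),
    filter_thresholds(min_area = 10, min_relative_area = 0.5,
                      min_signal_to_background = 2,
                      base_width_range = c(0.02, 1), rt_range = c(0, 40)),
    filter_thresholds(min_area = 10, min_relative_area = 0.02,
                      min_signal_to_background = 50,
                      base_width_range = c(0.02, 1), rt_range = c(0, 40)),
    filter_thresholds(min_area = 10, min_relative_area = 0.02,
                      min_signal_to_background = 2,
                      base_width_range = c(0.02, 1), rt_range = c(5, 20)),
    filter_thresholds(min_area = 10, min_relative_area = 0.02,
                      min_signal_to_background = 2,
                      base_width_range = c(0.02, 1), rt_range = c(0, 40),
                      min_qualifying_transitions = 5)
  )
  for (thr in tighter) expect_true(all(accepted(thr) %in% a0))
})

test_that("precursor qualification needs the minimum transition count", {
  df <- make_transition_df()
  thr <- filter_thresholds(min_area = 600, min_relative_area = 0,
                           min_signal_to_background = 0,
                           base_width_range = c(0, Inf))
  v <- suppressWarnings(filter_transitions(df, NULL, thr))
  # AAAK: areas 1000, 2000, 500 -> 2 passing; CCCR: 1500 -> 1 passing
  q3 <- qualify_precursors(v, 3)
  expect_equal(nrow(q3$precursors), 0)
  q1 <- qualify_precursors(v, 1)
  expect_setequal(q1$precursors$peptide, c("AAAK", "CCCR"))
  expect_equal(q1$precursors$n_qualifying[q1$precursors$peptide == "AAAK"], 2L)
  # accepted precursors carry only passing transitions
  expect_false(500 %in% q1$transitions$area)
})

test_that("qualification matches a brute-force recount on 50 random precursors", {
  set.seed(33)
  n_prec <- 50
  rows <- do.call(rbind, lapply(seq_len(n_prec), function(i) {
    k <- sample(2:8, 1)
    df <- make_transition_df()[rep(1, k), ]
    df$peptide <- sprintf("PEP%02d", i)
    df$product_mz <- 400 + seq_len(k)
    df$area <- rlnorm(k, 6, 1.5)
    df
  }))
  thr <- filter_thresholds(min_area = 400, min_relative_area = 0,
                           min_signal_to_background = 0,
                           base_width_range = c(0, Inf))
  v <- suppressWarnings(filter_transitions(rows, NULL, thr))
  q <- qualify_precursors(v, 3)
  # independent recount straight off the raw table
  expected <- names(which(tapply(rows$area >= 400, rows$peptide, sum) >= 3))
  expect_setequal(q$precursors$peptide, expected)
})

test_that("correlation rule filters transitions against the median trace", {
  df <- make_transition_df()[1:3, ]
  tt <- seq(0, 1, length.out = 41)
  good <- exp(-(tt - 0.5)^2 / 0.02)
  bad <- exp(-(tt - 0.15)^2 / 0.005)  # co-isolated interference peak
  traces <- list(`AAAK/2/light/run1` = cbind(`500.1` = good, `600.2` = good,
                                             `700.3` = bad))
  thr <- filter_thresholds(min_relative_area = 0, min_correlation = 0.8,
                           min_signal_to_background = 0,
                           base_width_range = c(0, Inf))
  v <- filter_transitions(df, traces, thr)
  expect_true(v$passed[1] && v$passed[2])
  expect_true("min_correlation" %in% v$failed_rules[[3]])
})
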