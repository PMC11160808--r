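test_that("replicate CV is sd/mean with the documented edge cases", {
  expect_equal(replicate_cv(c(5, 5, 5)), 0)
  expect_equal(replicate_cv(c(10, 12)), sqrt(2) / 11)
  expect_equal(round(replicate_cv(c(10, 12)), 4), 0.1286)
  expect_error(replicate_cv(7), "at least 2")
  expect_warning(cv <- replicate_cv(c(-5, 3)), "mean")
  expect_true(is.na(cv))
})

test_that("points per peak uses the 2.547 base-width estimate", {
  expect_equal(peak_base_width(1.0), 2.547)
  expect_equal(points_per_peak(0.1, 0.04245), 6, tolerance = 1e-4)
  bw <- peak_base_width(0.1)
  expect_equal(points_per_peak(0.1, bw), 1)
})

test_that("bilinear fit recovers a noiseless hinge exactly", {
  x <- c(0, 1, 2, 5, 10, 20, 50)
  y <- pmax(10, 10 + 2 * (x - 5))
  fit <- fit_bilinear_lod(x, y)
  expect_equal(fit$lod, 5, tolerance = 1e-9)
  expect_equal(fit$baseline, 10, tolerance = 1e-9)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_lt(fit$sse, 1e-18)
  expect_equal(coef(fit), c(baseline = 10, slope = 2, knot = 5))
  expect_equal(predict(fit, c(0, 5, 30)), c(10, 10, 60))
})

test_that("a strictly linear curve through the blank puts the LOD at/below the lowest level", {
  x <- c(0, 1, 2, 5, 10, 20, 50)
  y <- 3 * x
  fit <- fit_bilinear_lod(x, y)
  expect_lte(fit$lod, 1)
})

test_that("constant responses are flagged degenerate with undefined LOD", {
  x <- c(0, 1, 2, 5)
  expect_warning(fit <- fit_bilinear_lod(x, rep(4, 4)), "constant")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$lod))
})

test_that("bilinear knot recovery tolerates 5% noise (seeded trials)", {
  hits <- 0
  for (s in 1:40) {
    ser <- make_bilinear_series(noise_cv = 0.05, seed = s)
    means <- aggregate(area ~ level, ser, mean)
    fit <- fit_bilinear_lod(means$level, means$area)
    # within one level spacing of the true knot at 5 (bracketed by 2 and 10)
    if (fit$lod >= 2 && fit$lod <= 10) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)
})

test_that("LOQ is the lowest CV-qualified level above baseline and 2xLOD", {
  lv <- c(0, 1, 2, 5, 10, 20, 50)
  clean <- make_bilinear_series(levels = lv, baseline = 10, slope = 20,
                                knot = 0.5, noise_cv = 0.01, seed = 2)
  means <- aggregate(area ~ level, clean, mean)
  fit <- fit_bilinear_lod(means$level, means$area)
  res <- estimate_loq(clean, fit)
  # tiny LOD: the lowest nonzero level qualifies
  expect_equal(res$loq, min(lv[lv > 0 & lv > 2 * fit$lod]))

  # a candidate below 2xLOD is promoted to the smallest level above it
  fit2 <- fit
  fit2$lod <- 3  # pretend a larger turning point
  res2 <- estimate_loq(clean, fit2, lod = 3)
  expect_gt(res2$loq, 6)
  expect_equal(res2$loq, 10)
})

test_that("a CV break at a mid level pushes the LOQ above that level", {
  lv <- c(0, 1, 2, 5, 10, 20, 50)
  ser <- make_bilinear_series(levels = lv, baseline = 5, slope = 20,
                              knot = 0.5, noise_cv = 0.01, seed = 3)
  # wreck the replicates at level 5
  idx <- ser$level == 5
  ser$area[idx] <- c(10, 500, 5000)
  means <- aggregate(area ~ level, ser, mean)
  fit <- fit_bilinear_lod(means$level, means$area)
  res <- estimate_loq(ser, fit)
  expect_gt(res$loq, 5)
})

test_that("no qualifying level yields a flagged undefined LOQ", {
  lv <- c(0, 1, 2, 5)
  ser <- do.call(rbind, lapply(lv, function(l) {
    data.frame(level = l, replicate = 1:3, area = c(1, 100, 10000))
  }))
  means <- aggregate(area ~ level, ser, mean)
  fit <- suppressWarnings(fit_bilinear_lod(means$level, means$area))
  res <- estimate_loq(ser, fit)
  expect_true(is.na(res$loq))
  expect_equal(attr(res$loq, "flag"), "no-qualifying-level")
})

test_that("subset optimization drops pure-noise transitions and matches enumeration", {
  lv <- c(0, 1, 2, 5, 10, 20, 50)
  series <- make_multitransition_series(lv, n_clean = 3, n_noise = 2,
                                        seed = 41)
  clean_tr <- c("clean01", "clean02", "clean03")
  res <- optimize_transition_subset(series)
  expect_setequal(res$chosen_transitions, clean_tr)

  # independent exhaustive enumeration oracle (lexicographic on loq, lod, size)
  all_tr <- sort(unique(series$transition))
  lex_less <- function(a, b) {
    for (i in seq_along(a)) {
      if (a[i] < b[i] - 1e-12) return(TRUE)
      if (a[i] > b[i] + 1e-12) return(FALSE)
    }
    FALSE
  }
  best <- NULL
  for (sz in 3:5) {
    for (cc in combn(all_tr, sz, simplify = FALSE)) {
      sub <- series[series$transition %in% cc, ]
      summed <- aggregate(area ~ level + replicate, sub, sum)
      means <- aggregate(area ~ level, summed, mean)
      fit <- suppressWarnings(fit_bilinear_lod(means$level, means$area))
      lq <- estimate_loq(summed, fit)
      key <- c(ifelse(is.na(lq$loq), Inf, lq$loq),
               ifelse(is.na(fit$lod), Inf, fit$lod), sz)
      if (is.null(best) || lex_less(key, best$key)) {
        best <- list(subset = cc, key = key)
      }
    }
  }
  expect_setequal(res$chosen_transitions, best$subset)
})

test_that("with exactly 3 transitions the only admissible subset is returned", {
  lv <- c(0, 1, 2, 5, 10)
  series <- do.call(rbind, lapply(c("a", "b", "c"), function(tr) {
    s <- make_bilinear_series(levels = lv, seed = match(tr, letters))
    s$transition <- tr
    s
  }))
  res <- optimize_transition_subset(series)
  expect_setequal(res$chosen_transitions, c("a", "b", "c"))
  expect_error(optimize_transition_subset(series[series$transition != "c", ]),
               "at least 3")
})

test_that("LOQ >= 2x LOD holds on series with a real turning point", {
  lv <- c(100 / 3^(0:6), 0)
  checked <- 0
  for (s in 1:8) {
    series <- make_multitransition_series(lv, n_clean = 4, baseline = 50,
                                          slope = 40, knot = lv[5],
                                          noise_cv = 0.05, seed = 600 + s)
    res <- optimize_transition_subset(series)
    if (!is.na(res$loq) && !is.na(res$lod) && res$lod > 0) {
      expect_gte(res$loq, 2 * res$lod)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 0)
})

test_that("greedy elimination (many transitions) does no worse than the full set", {
  lv <- c(0, 1, 2, 5, 10, 20, 50)
  series <- make_multitransition_series(lv, n_clean = 4, n_noise = 9,
                                        seed = 46)
  res <- optimize_transition_subset(series)  # 13 transitions -> greedy
  full <- prmforge:::.subset_fom(series, sort(unique(series$transition)), 0.2)
  loq_or_inf <- function(x) ifelse(is.na(x), Inf, x)
  expect_lte(loq_or_inf(res$loq), loq_or_inf(full$loq))
})

test_that("boundary alignment recovers a constructed delay", {
  tt <- seq(9, 13, by = 0.02)
  base <- exp(-(tt - 10.5)^2 / (2 * 0.1^2))
  ref <- list(PEP1 = chromatogram(tt, base))
  tgt_same <- list(PEP1 = chromatogram(tt, base))
  tgt_delayed <- list(PEP1 = chromatogram(tt, exp(-(tt - 10.8)^2 /
                                                    (2 * 0.1^2))))
  tgt_flat <- list(PEP1 = chromatogram(tt, rep(1, length(tt))))
  rb <- data.frame(peptide = "PEP1", min_start_time = 10.2,
                   max_end_time = 10.8)

  same <- align_integration_boundaries(ref, tgt_same, rb)
  expect_equal(same$lag, 0)
  expect_equal(same$min_start_time, 10.2)

  del <- align_integration_boundaries(ref, tgt_delayed, rb)
  expect_equal(del$lag, 0.3, tolerance = 0.021)
  expect_equal(del$min_start_time, 10.5, tolerance = 0.021)
  expect_false(del$flagged)

  flat <- align_integration_boundaries(ref, tgt_flat, rb)
  expect_true(flat$flagged)
  expect_equal(flat$min_start_time, 10.2)
})
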