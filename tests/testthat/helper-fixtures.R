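# Shared fixtures, built in code.

# a small, fully populated transition report
make_transition_df <- function() {
  data.frame(
    protein_id = c("P1", "P1", "P1", "P2"),
    peptide = c("AAAK", "AAAK", "AAAK", "CCCR"),
    precursor_charge = c(2L, 2L, 2L, 3L),
    precursor_mz = c(400.5, 400.5, 400.5, 512.3),
    product_mz = c(500.1, 600.2, 700.3, 650.4),
    fragment_label = c("y4", "y5", "y6", "y5"),
    label_type = "light",
    area = c(1000, 2000, 500, 1500),
    background = c(10, 0, 50, 30),
    fwhm = c(0.1, 0.1, 0.1, 0.12),
    rt = c(12.5, 12.5, 12.5, 18.2),
    start_time = c(12.3, 12.3, 12.3, 18.0),
    end_time = c(12.7, 12.7, 12.7, 18.4),
    file_name = "run1",
    stringsAsFactors = FALSE
  )
}

# gaussian traces on a shared grid; ncol = number of transitions
make_gaussian_traces <- function(n = 3, scales = rep(1, n), center = 0.5,
                                 sd = 0.1, npts = 41) {
  tt <- seq(0, 1, length.out = npts)
  sapply(scales, function(s) s * exp(-(tt - center)^2 / (2 * sd^2)))
}

# random scheduled windows over a gradient
make_random_windows <- function(n, gradient = c(0, 30), width = 0.6,
                                seed = 1) {
  set.seed(seed)
  centers <- runif(n, gradient[1], gradient[2])
  data.frame(
    peptide = sprintf("P%03d", seq_len(n)),
    rt_center = centers,
    window_start = centers - width / 2,
    window_end = centers + width / 2,
    n_transitions = sample(3:8, n, replace = TRUE)
  )
}

# brute-force interval counting oracle (O(n * grid))
brute_force_concurrency <- function(windows, grid) {
  prec <- integer(length(grid))
  trans <- integer(length(grid))
  for (g in seq_along(grid)) {
    inside <- logical(nrow(windows))
    for (i in seq_len(nrow(windows))) {
      inside[i] <- grid[g] >= windows$window_start[i] &&
        grid[g] < windows$window_end[i]
    }
    prec[g] <- sum(inside)
    trans[g] <- sum(windows$n_transitions[inside])
  }
  list(precursors = prec, transitions = trans)
}

# multi-transition dilution series: n_clean transitions share a bilinear
# mean with the given knot; n_noise transitions are erratic background
# (lognormal with large dispersion) that wrecks replicate CVs
make_multitransition_series <- function(levels = c(0, 1, 2, 5, 10, 20, 50),
                                        n_clean = 3, n_noise = 0,
                                        baseline = 20, slope = 30, knot = 1,
                                        noise_cv = 0.03, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_clean)) {
    s <- make_bilinear_series(levels, baseline, slope, knot,
                              noise_cv = noise_cv, seed = seed + i)
    s$transition <- sprintf("clean%02d", i)
    rows[[length(rows) + 1L]] <- s
  }
  set.seed(seed + 500)
  for (i in seq_len(n_noise)) {
    s <- do.call(rbind, lapply(levels, function(l) {
      data.frame(level = l, replicate = 1:3,
                 area = rlnorm(3, log(2000), 1.5))
    }))
    s$transition <- sprintf("noise%02d", i)
    rows[[length(rows) + 1L]] <- s
  }
  do.call(rbind, rows)
}

# dilution series with a known bilinear mean structure:
# response(x) = baseline + slope * max(0, x - knot), multiplicative noise
make_bilinear_series <- function(levels = c(0, 1, 2, 5, 10, 20, 50),
                                 baseline = 10, slope = 2, knot = 5,
                                 replicates = 3, noise_cv = 0.05,
                                 seed = 1) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  do.call(rbind, lapply(levels, function(l) {
    mu <- baseline + slope * max(0, l - knot)
    data.frame(level = l, replicate = seq_len(replicates),
               area = mu * rlnorm(replicates, -sdlog^2 / 2, sdlog))
  }))
}
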