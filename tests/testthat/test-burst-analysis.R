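test_that("moving-average smoothing reproduces brute-force window means", {
  x <- rep(2.5, 1000)
  sm <- smooth_trace(x, dt = 10)
  expect_true(all(abs(sm$value - 2.5) < 1e-12))
  # 10 ms output step
  expect_equal(unique(diff(sm$t)), 10)
  # brute-force windowed mean on a random trace
  set.seed(7)
  x <- rnorm(2000)
  sm <- smooth_trace(x, dt = 10, window_ms = 400, step_ms = 10)
  i <- 50
  ci <- sm$t[i] / 10 + 1
  brute <- mean(x[(ci - 20):(ci + 20)])
  expect_equal(sm$value[i], brute, tolerance = 1e-12)
  # unit impulse spreads into a boxcar of window width
  imp <- c(rep(0, 500), 1, rep(0, 500))
  smi <- smooth_trace(imp, dt = 10)
  expect_equal(max(smi$value), 1 / 41, tolerance = 1e-12)
  expect_equal(sum(smi$value > 0) * 10, 410, tolerance = 10)
  expect_error(smooth_trace(rnorm(10), dt = 10), "shorter")
  expect_error(smooth_trace(rnorm(100), dt = 20), "sampled")
})

test_that("percentile thresholds follow the linear-interpolation convention", {
  ramp <- seq(0, 1, length.out = 100001)
  th <- percentile_thresholds(ramp)
  expect_equal(unname(th["upper"]), 0.75, tolerance = 1e-4)
  expect_equal(unname(th["lower"]), 0.65, tolerance = 1e-4)
  thc <- percentile_thresholds(rep(0.4, 50))
  expect_equal(unname(thc["upper"]), unname(thc["lower"]))
  set.seed(8)
  x <- rexp(500)
  expect_equal(unname(percentile_thresholds(x)["upper"]),
               unname(quantile(x, 0.75, type = 7)))
  expect_error(percentile_thresholds(numeric(0)), "empty")
})

test_that("dual-threshold crossing detects planted bursts", {
  # trapezoidal bump crossing upper at ~1 s and falling below lower at ~4 s
  t <- seq(0, 6000, by = 10)
  up <- 0.5; lo <- 0.4
  val <- approx(c(0, 900, 1100, 3900, 4100, 6000),
                c(0.1, 0.1, 0.8, 0.8, 0.1, 0.1), xout = t)$y
  b <- detect_lfp_bursts(t, val, up, lo)
  expect_equal(nrow(b), 1)
  expect_equal(b$length, 3000, tolerance = 150)
  # trace never crossing the upper threshold: no bursts
  b0 <- detect_lfp_bursts(t, rep(0.3, length(t)), up, lo)
  expect_equal(nrow(b0), 0)
  # two disjoint bumps
  val2 <- approx(c(0, 500, 700, 1500, 1700, 3000, 3200, 4000, 4200, 6000),
                 c(0, 0, 1, 1, 0, 0, 1, 1, 0, 0), xout = t)$y
  b2 <- detect_lfp_bursts(t, val2, up, lo)
  expect_equal(nrow(b2), 2)
  expect_true(all(b2$offset > b2$onset))
  # a burst still open at the end of the trace is discarded
  val3 <- c(rep(0, 300), seq(0, 1, length.out = 301))
  b3 <- detect_lfp_bursts(seq_along(val3), val3, up, lo)
  expect_equal(nrow(b3), 0)
  expect_error(detect_lfp_bursts(t, val, 0.4, 0.5), "upper >= lower")
})

test_that("raising the upper threshold never increases the burst count", {
  set.seed(9)
  t <- seq(0, 2e5, by = 10)
  val <- as.numeric(stats::filter(rnorm(length(t)), rep(1 / 41, 41),
                                  sides = 2))
  val[is.na(val)] <- 0
  counts <- sapply(c(0.1, 0.2, 0.3, 0.4), function(u)
    nrow(detect_lfp_bursts(t, val, u, 0.05)))
  expect_true(all(diff(counts) <= 0))
})

test_that("burst statistics summarise lengths and flag the empty case", {
  b <- tibble::tibble(length = c(1, 2, 9))
  st <- burst_statistics(b, cutoff_s = 5)
  expect_equal(st$mean, 4)
  expect_equal(st$median, 2)
  expect_equal(st$frac_short, 2 / 3)
  expect_equal(sum(st$histogram$count), 3)
  one <- burst_statistics(tibble::tibble(length = 2.5))
  expect_equal(one$mean, one$median)
  none <- burst_statistics(tibble::tibble(length = numeric(0)))
  expect_true(is.na(none$mean) && is.na(none$frac_short))
  expect_equal(none$n, 0L)
  # brute-force recomputation on a large sample
  set.seed(10)
  len <- rexp(1000, 0.3)
  stl <- burst_statistics(tibble::tibble(length = len), cutoff_s = 5)
  expect_equal(stl$frac_short, mean(len < 5))
  expect_equal(stl$mean, mean(len))
  # right-skewed lengths: mean above median
  expect_gt(stl$mean, stl$median)
})

test_that("rank tests separate distinct samples and not identical ones", {
  set.seed(11)
  same <- rexp(40)
  expect_gt(compare_burst_lengths(same, same), 0.9)
  a <- rnorm(50, 1, 0.1); b <- rnorm(50, 10, 0.1)
  expect_lt(compare_burst_lengths(a, b), 1e-3)
  expect_error(compare_burst_lengths(numeric(0), a), "nonempty")
  # permutation p-value on tiny samples matches exhaustive enumeration
  x <- c(1.2, 3.4, 2.2); y <- c(5.1, 6.3, 4.4, 7.0)
  p_perm <- compare_burst_lengths(x, y, method = "permutation",
                                  n_perm = 1e5)
  rk <- rank(c(x, y)); obs <- sum(rk[1:3]); mu <- 3 * 8 / 2
  idx <- utils::combn(7, 3)
  stats <- colSums(matrix(rk[idx], nrow = 3))
  p_exact <- mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
  expect_equal(p_perm, p_exact)
  # rank test agrees in direction with clearly separated samples
  expect_lt(compare_burst_lengths(a, b, method = "permutation",
                                  n_perm = 2000), 0.01)
})

test_that("detected bursts are disjoint, ordered and within the window", {
  set.seed(12)
  t <- seq(0, 1e5, by = 10)
  val <- abs(as.numeric(stats::filter(rnorm(length(t)), rep(1 / 81, 81),
                                      sides = 2)))
  val[is.na(val)] <- 0
  th <- percentile_thresholds(val)
  b <- detect_lfp_bursts(t, val, th["upper"], th["lower"])
  if (nrow(b) > 1) {
    expect_true(all(b$onset[-1] > b$offset[-nrow(b)]))
  }
  expect_lte(sum(b$length), max(t) - min(t))
  expect_true(all(b$length > 0))
})
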