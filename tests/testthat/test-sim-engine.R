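# Integration-level behaviour on small, fast networks (N = 20, seconds of
# simulated time). The full-scale study conditions live in the acceptance
# suite.

test_that("same seed gives bitwise-identical summaries", {
  cfg <- tiny_sim(K = 0)
  a <- simulate_network(cfg)
  b <- simulate_network(cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$final_state, b$final_state)
})

test_that("K = 0 leaves the trajectory identical to the stimulation-free run", {
  base <- simulate_network(tiny_sim("cDBS", K = 0))
  for (mode in c("aDBS", "cpLDF", "apLDF")) {
    s <- simulate_network(tiny_sim(mode, K = 0))
    expect_identical(s$final_state, base$final_state)
    expect_equal(s$series$lfp, base$series$lfp)
  }
})

test_that("continuous DBS amplitude is constant K after the ramp", {
  cfg <- tiny_sim("cDBS", K = 1.5, t_total = 3000, t_stim_on = 1000,
                  T_ramp = 500)
  s <- simulate_network(cfg)
  post <- s$series$t > 1600
  expect_true(all(s$series$A[post] == 1.5))
  expect_true(all(s$series$gate[post] == 1))
  # during the ramp the amplitude grows toward K
  mid <- s$series$t > 1050 & s$series$t < 1450
  expect_true(all(s$series$A[mid] < 1.5))
  expect_true(all(diff(s$series$A[mid]) >= -1e-12))
  pre <- s$series$t < 1000
  expect_true(all(s$series$A[pre] == 0))
})

test_that("administered stimulation equals K * T_on exactly for gated DBS", {
  cfg <- tiny_sim("aDBS", K = 1.3, t_total = 5000, t_stim_on = 1000,
                  Th_on = 0.016, Th_off = 0.008)
  s <- simulate_network(cfg)
  w <- which(s$series$t >= 1500)
  expect_equal(administered_stimulation(s$series$S[w]),
               1.3 * stimulation_time_fraction(s$series$gate[w]),
               tolerance = 1e-12)
})

test_that("adaptive modes with thresholds at -Inf behave as continuous", {
  ca <- tiny_sim("aDBS", K = 1, t_total = 4000, t_stim_on = 1000,
                 Th_on = -Inf, Th_off = -Inf)
  s <- simulate_network(ca)
  w <- which(s$series$t >= 1500)
  expect_equal(stimulation_time_fraction(s$series$gate[w]), 1)
  cc <- tiny_sim("cDBS", K = 1, t_total = 4000, t_stim_on = 1000)
  sc <- simulate_network(cc)
  # post-onset amplitude traces agree once the adaptive gate has latched on
  expect_equal(s$series$A[w], sc$series$A[w])
})

test_that("gate trace is piecewise constant and toggles only at maxima", {
  cfg <- tiny_sim("aDBS", K = 1.2, t_total = 6000, t_stim_on = 1000,
                  Th_on = 0.016, Th_off = 0.008)
  s <- simulate_network(cfg)
  g <- s$series$gate
  expect_true(all(g %in% c(0L, 1L)))
  expect_true(all(g[s$series$t < 1000] == 0L))
})

test_that("LDF modes record S = K (x(t - tau) - x(t)) and vanish at tau = 0", {
  cfg0 <- tiny_sim("cpLDF", K = 7, tau = 0, t_total = 3000, t_stim_on = 1000)
  s0 <- simulate_network(cfg0)
  expect_true(all(abs(s0$series$S) < 1e-12))
  cfg <- tiny_sim("cpLDF", K = 7, tau = 60, t_total = 3000, t_stim_on = 1000)
  s <- simulate_network(cfg)
  w <- which(s$series$t > 1200)
  # recorded S matches the delayed-difference law applied to recorded x
  i <- w[seq(1, length(w), by = 47)]
  lag <- 60 / cfg$rec_dt
  expect_equal(s$series$S[i],
               7 * (s$series$x[i - lag] - s$series$x[i]),
               tolerance = 2e-3)
})

test_that("engine RHS matches the R reference on an uncoupled cell", {
  skip_if_not_installed("deSolve")
  netc <- network_config(N = 3, g_stn_gpe = 0, g_gpe_stn = 0,
                         I_app_sd = 0, eps_sd = 0)
  cfg <- simulation_config(network = netc,
                           controller = controller_config("cDBS", K = 0),
                           t_total = 200, t_stim_on = 150, t_skip = 10,
                           dt = 0.01)
  y0v <- c(v = -58, Ca = 0.3, n = 0.05, h = 0.6, r = 0.2)
  st <- rep(0, 36)
  st[1:3] <- y0v[["v"]]; st[4:6] <- y0v[["Ca"]]; st[7:9] <- y0v[["n"]]
  st[10:12] <- y0v[["h"]]; st[13:15] <- y0v[["r"]]
  # GPe block: steady benign state
  st[19:21] <- -65; st[22:24] <- 0.2; st[25:27] <- 0.1
  st[28:30] <- 0.8; st[31:33] <- 0.5
  out <- simulate_network(cfg, state = st)
  f <- function(t, y, parms) {
    list(unname(cell_rhs(structure(y, class = c("neuron_state", "numeric")),
                         netc$stn)))
  }
  ref <- deSolve::lsoda(y0v, c(0, 200), f, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(out$final_state[1], unname(ref[2, "v"]), tolerance = 1e-3)
})

test_that("halving dt changes the summary less than across-seed spread", {
  run_dt <- function(dt) {
    cfg <- tiny_sim(K = 0, t_total = 4000, t_stim_on = 3000)
    cfg$dt <- dt
    simulate_network(cfg)$summary$R_mean
  }
  r1 <- run_dt(0.05)
  r2 <- run_dt(0.025)
  seeds <- sapply(c(11, 22, 33), function(sd) {
    simulate_network(tiny_sim(K = 0, t_total = 4000, t_stim_on = 3000,
                              seed = sd))$summary$R_mean
  })
  expect_lt(abs(r1 - r2), max(2 * stats::sd(seeds), 0.1))
})

test_that("protocol averaging reproduces the brute-force mean of runs", {
  cfg <- tiny_sim("aDBS", K = 1, t_total = 3000, t_stim_on = 1500)
  pr <- run_protocol(cfg, n_ramp_runs = 3)
  expect_equal(nrow(pr$runs), 3)
  expect_equal(pr$summary$R_mean, mean(pr$runs$R_mean))
  expect_equal(pr$summary$T_on, mean(pr$runs$T_on))
  expect_gte(pr$summary$R_sd, 0)
  # ramps evenly spaced over the requested range
  expect_equal(pr$runs$T_ramp, c(0, 1000, 2000))
  expect_error(run_protocol(cfg, n_ramp_runs = 1), ">= 2")
})

test_that("continuous modes give T_on = 1 regardless of ramp", {
  cfg <- tiny_sim("cDBS", K = 1, t_total = 3000, t_stim_on = 1500)
  pr <- run_protocol(cfg, n_ramp_runs = 2)
  expect_equal(pr$summary$T_on, 1)
})

test_that("a sweep row equals an independent protocol run", {
  cfg <- tiny_sim("cDBS", K = 1, t_total = 3000, t_stim_on = 1500)
  grid <- data.frame(K = c(0.5, 1), GW = c(0, 2))
  sw <- sweep_protocol(cfg, grid, n_ramp_runs = 2)
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$feasible))
  cfg1 <- cfg
  cfg1$controller$K <- 0.5
  pr1 <- run_protocol(cfg1, n_ramp_runs = 2)
  expect_equal(sw$R_mean[1], pr1$summary$R_mean)
  # infeasible geometry is flagged, not computed
  sw2 <- sweep_protocol(cfg, data.frame(K = 1, GW = 8), n_ramp_runs = 2)
  expect_false(sw2$feasible[1])
  expect_error(sweep_protocol(cfg, data.frame()), "empty")
})

test_that("sweeps resume from a progress file", {
  withr::with_tempfile("f", fileext = ".csv", {
    cfg <- tiny_sim("cDBS", K = 1, t_total = 3000, t_stim_on = 1500)
    grid <- data.frame(K = c(0.5, 1))
    s1 <- sweep_protocol(cfg, grid[1, , drop = FALSE], n_ramp_runs = 2,
                         file = f)
    expect_true(file.exists(f))
    s2 <- sweep_protocol(cfg, grid, n_ramp_runs = 2, file = f)
    expect_equal(nrow(s2), 2)
    expect_equal(s2$R_mean[1], s1$R_mean[1])
  })
})

test_that("tidiers and plots expose the run in tidy form", {
  s <- simulate_network(tiny_sim(K = 0, t_total = 2000, t_stim_on = 1500))
  td <- tidy(s)
  expect_true(all(c("t", "signal", "value") %in% names(td)))
  expect_setequal(unique(td$signal), c("lfp", "x", "R", "gate", "S", "A"))
  gl <- glance(s)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("R_mean", "T_on", "S_abs_mean") %in% names(gl)))
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})
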