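test_that("sigmoid activation matches its closed form and limits", {
  expect_equal(sigmoid_activation(-30, -30, 10), 0.5)
  expect_equal(sigmoid_activation(-30, -30, -3.1), 0.5)
  expect_equal(sigmoid_activation(-20, -30, 10), 1 / (1 + exp(-1)))
  expect_equal(sigmoid_activation(1e4, -30, 10), 1, tolerance = 1e-12)
  expect_equal(sigmoid_activation(-1e4, -30, 10), 0, tolerance = 1e-12)
  v <- seq(-100, 20, by = 1)
  expect_true(all(diff(sigmoid_activation(v, -30, 10)) > 0))
  expect_true(all(diff(sigmoid_activation(v, -58, -12)) < 0))
  expect_error(sigmoid_activation(0, 0, 0), "nonzero")
})

test_that("voltage time constant interpolates between its asymptotes", {
  # midpoint with the subthalamic n-gate constants
  expect_equal(voltage_time_constant(-80, 1, 100, -80, -26), 51)
  expect_equal(voltage_time_constant(1e4, 1, 100, -80, -26), 1,
               tolerance = 1e-6)
  expect_equal(voltage_time_constant(-1e4, 1, 100, -80, -26), 101,
               tolerance = 1e-6)
  tv <- voltage_time_constant(seq(-120, 40, 5), 1, 100, -80, -26)
  expect_true(all(tv >= 1 & tv <= 101))
  # constant parameterisation used by the pallidal r gate
  expect_equal(voltage_time_constant(c(-80, 0), 30, 0, 0, 1), c(30, 30))
  expect_error(voltage_time_constant(0, -1, 100, -80, -26), "positive")
})

test_that("b_inf vanishes at r = 0 and is monotone against sigma_b's sign", {
  expect_equal(b_inf(0, 0.4, -0.1), 0)
  expect_equal(b_inf(0, 0.25, -0.07), 0)
  expect_equal(b_inf(0.4, 0.4, -0.1), 0.5 - 1 / (1 + exp(4)))
  r <- seq(0, 1, by = 0.02)
  expect_true(all(diff(b_inf(r, 0.4, -0.1)) > 0))   # increasing for sigma < 0
  expect_true(all(diff(b_inf(r, 0.4, 0.1)) < 0))
  expect_error(b_inf(0.5, 0.4, 0), "nonzero")
})

test_that("membrane currents vanish at reversal potentials and zero gates", {
  p <- stn_params()
  st <- neuron_state(v = p$v_L, Ca = 0.2, n = 0.3, h = 0.4, r = 0.2)
  cur <- membrane_currents(st, p)
  expect_equal(cur$value[cur$current == "I_L"], 0)
  st0 <- neuron_state(v = -55, Ca = 0, n = 0, h = 0.4, r = 0.2)
  cur0 <- membrane_currents(st0, stn_params())
  expect_equal(cur0$value[cur0$current == "I_AHP"], 0)
  expect_equal(cur0$value[cur0$current == "I_K"], 0)
  # population-specific low-threshold calcium current
  g <- gpe_params()
  stg <- neuron_state(v = -50, Ca = 0.1, n = 0.2, h = 0.5, r = 0)
  curg <- membrane_currents(stg, g)
  expect_equal(curg$value[curg$current == "I_T"], 0) # r = 0 for GPe
  expect_error(membrane_currents(st, modifyList(p, list(pop = "STR"))))
})

test_that("cell_rhs reduces correctly in degenerate settings", {
  # zero all conductances: v' = I_app / C_m
  p <- stn_params(g_L = 0, g_K = 0, g_Na = 0, g_T = 0, g_Ca = 0, g_AHP = 0)
  st <- neuron_state(v = -60, Ca = 0.5, n = 0.2, h = 0.5, r = 0.1)
  d <- cell_rhs(st, p, I_syn = 0, I_stim = 0)
  expect_equal(d[["v"]], p$I_app / p$C_m)
  # with I_Ca = I_T = 0: Ca' = -eps * k_Ca * Ca
  expect_equal(d[["Ca"]], -p$eps * p$k_Ca * 0.5)
  expect_error(cell_rhs(structure(c(v = NaN, Ca = 0, n = 0, h = 0, r = 0),
                                  class = "neuron_state"), p),
               "non-finite")
})

test_that("gating variables remain in [0, 1] along network trajectories", {
  cfg <- tiny_sim(N = 5, t_total = 1500, t_stim_on = 1200)
  s <- simulate_network(cfg)
  y <- s$final_state
  N <- 5
  gates <- c(y[(2 * N + 1):(5 * N)], y[(8 * N + 1):(11 * N)])
  expect_true(all(gates >= 0 & gates <= 1))
  ca <- c(y[(N + 1):(2 * N)], y[(7 * N + 1):(8 * N)])
  expect_true(all(ca >= 0))
})

test_that("single-cell trajectory agrees with an adaptive reference solver", {
  skip_if_not_installed("deSolve")
  p <- stn_params(I_app = 25) # tonically spiking for a nontrivial trajectory
  y0 <- c(v = -62, Ca = 0.2, n = 0.1, h = 0.5, r = 0.1)
  f <- function(t, y, parms) {
    st <- structure(y, class = c("neuron_state", "numeric"))
    list(unname(cell_rhs(st, p)))
  }
  ref <- deSolve::lsoda(y0, c(0, 100), f, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  # C++ fixed-step path: isolated cell inside an uncoupled N=3 ring
  run_net <- function(dt) {
    cfg <- simulation_config(
      network = network_config(N = 3, g_stn_gpe = 0, g_gpe_stn = 0,
                               I_app_mean = 25, I_app_sd = 0, eps_sd = 0),
      controller = controller_config("cDBS", K = 0),
      t_total = 100, t_stim_on = 99, t_skip = 0, dt = dt, rec_dt = 1)
    st <- rep(0, 36)
    st[1:3] <- y0[["v"]]; st[4:6] <- y0[["Ca"]]
    st[7:9] <- y0[["n"]]; st[10:12] <- y0[["h"]]; st[13:15] <- y0[["r"]]
    simulate_network(cfg, state = st)$final_state[1]
  }
  v_ref <- ref[nrow(ref), "v"]
  err_050 <- abs(run_net(0.05) - v_ref)
  err_025 <- abs(run_net(0.025) - v_ref)
  err_0125 <- abs(run_net(0.0125) - v_ref)
  expect_lt(err_0125, 1e-4)
  # fixed-step error shrinks (or stays at the floor) as dt decreases
  expect_lte(err_025, err_050 + 1e-8)
})

test_that("the subthalamic cell is excitable at rest and tonic when driven", {
  run_iso <- function(I) {
    cfg <- simulation_config(
      network = network_config(N = 3, g_stn_gpe = 0, g_gpe_stn = 0,
                               I_app_mean = I, I_app_sd = 0, eps_sd = 0),
      controller = controller_config("cDBS", K = 0),
      t_total = 1000, t_stim_on = 900, t_skip = 0)
    length(simulate_network(cfg)$spikes[[1]])
  }
  # near-threshold quiescence at the network operating point, repetitive
  # firing under a modest extra drive
  expect_lte(run_iso(10), 2)
  expect_gt(run_iso(25), 5)
})

test_that("parameter constructors validate their invariants", {
  expect_error(stn_params(g_L = -1), "conductances")
  expect_error(stn_params(C_m = 0), "C_m")
  expect_error(stn_params(sigma_n = 0), "sigma")
  expect_error(stn_params(nonsense = 1), "unknown")
  d <- dump_default_params()
  expect_setequal(unique(d$population), c("STN", "GPe"))
  expect_true(all(c("g_L", "eps", "theta_b") %in% d$parameter))
})
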