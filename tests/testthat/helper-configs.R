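# Small configurations used across tests; all seeded and fast.

tiny_sim <- function(mode = "cDBS", K = 0, N = 20, t_total = 3000,
                     t_stim_on = 1000, GW = 0, seed = 7, ...) {
  simulation_config(
    network = network_config(N = N, seed = seed),
    controller = controller_config(mode, K = K, ...),
    pulse = pulse_train_config(GW = GW),
    t_total = t_total, t_stim_on = t_stim_on,
    t_skip = min(500, (t_total - t_stim_on) / 2),
    ic_seed = seed
  )
}
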