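# canonical toy study systems used across the suite

dw_pot <- function(...) potential_spec("double_well_1d", ...)
dw_eng <- function(...) engine_params(...)
dw_states <- function(edge = 0.9) default_states_1d(edge)

# brute-force shooting estimate of the committor on a grid (independent
# oracle used against the analytic formula and the learned model)
shoot_grid <- function(grid, n_shots, pot = dw_pot(), eng = dw_eng(),
                       states = dw_states(), seed = 1) {
  set.seed(seed)
  vapply(grid, function(x0) {
    sample_committor(phase_point(x0), eng, pot, states, n_shots)$p_hat
  }, numeric(1))
}

# small trained net on 1D logistic data, shared by a few tests
fit_linear_net <- function(data, epochs = 2000, lr = 0.05, seed = 1) {
  net <- committor_net(ncol(feature_cols(data)), build_pyramid(1, 0),
                       seed = seed)
  train_committor(net, data, epochs = epochs, learning_rate = lr)
}

feature_cols <- function(data) {
  data[setdiff(names(data), c("chain_id", "step_index", "s", "n_A", "n_B"))]
}
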