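# Shared fixtures: all synthetic, built in code.

default_acq <- acq_params()

# Constant-input concentration grid including t = 0 (the analytic closed
# forms for constant input assume the input switches on at t = 0).
const_grid <- seq(0, 1460, by = 73)

make_const_cp <- function(c = 2, t = const_grid) conc_curve(t, rep(c, length(t)))

# Fine-grid extended Parker VIF over the full acquisition window.
make_fine_vif <- function(dt = 0.1, t_end = 1460, p = vif_params()) {
  t <- seq(0, t_end, by = dt)
  conc_curve(t, extended_parker_vif(t / 60, p))
}

# Signal curve with a given enhancement time course.
make_signal_from_enh <- function(times, E, S0 = 100) {
  signal_curve(times, S0 * (1 + E), baseline = S0)
}
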