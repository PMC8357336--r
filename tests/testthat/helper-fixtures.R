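# Shared fixtures built in code.

# Ideal three-phase sinusoid stack with known DC/AC ground truth.
ideal_stack <- function(n = 64, a0 = 100, a1 = 10, f = 9, pitch_um = 20,
                        phi = 0.3) {
  x_mm <- (seq_len(n) - (n + 1) / 2) * pitch_um / 1000
  mk <- function(ph) {
    a0 + a1 * matrix(cos(2 * pi * f * x_mm + phi + ph), n, n)
  }
  phase_stack(mk(0), mk(2 * pi / 3), mk(4 * pi / 3), f = f,
              pitch_um = pitch_um)
}

# Small, fast Monte Carlo run reused across tests.
fast_hg_run <- function(n_photons = 1e5, musp = 1, mua = 0.01,
                        depth_cutoff = 1.2, seed = 101, ...) {
  pf <- phase_function("henyey-greenstein", g_R = 0.9)
  med <- medium_from_musp(musp, mua, pf)
  run_simulation(n_photons, med, depth_cutoff = depth_cutoff, seed = seed,
                 ...)
}

# Hand-built detection-bin object.
manual_bins <- function(x_n, B_n, delta_x) {
  list(x_n = x_n, delta_x = delta_x, B_n = B_n, n_bins = length(x_n))
}

# Hand-built photon-record table for depth-quantile tests.
manual_records <- function(exit_x, weight, depth_um, accepted = TRUE) {
  data.frame(exit_x_mm = exit_x, weight = weight, max_depth_um = depth_um,
             accepted = accepted)
}
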