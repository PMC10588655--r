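# Shared fixtures. Everything is generated in code; no data files.

default_tc <- tissue_constants()
default_ase <- ase_protocol()
default_asl <- asl_protocol()
default_priors <- prior_spec()

# noise-free tau-series at a given truth (s0 = 1)
make_ase_signal <- function(oef, dbv, proto = default_ase,
                            const = default_tc) {
  total_signal(voxel_state(1, oef, dbv), const, proto, proto$taus)
}

# oef implied by (r2p, dbv) truth pair and vice versa
truth_r2p <- function(oef, dbv, const = default_tc, b0 = 3) {
  dbv * delta_omega(oef, const, b0)
}

# small noiseless phantom for pipeline-level tests
tiny_spec <- function(seed = 1, n_subjects = 2, grid = c(16, 16, 16), ...) {
  default_table_spec(seed = seed, n_subjects = n_subjects,
                     grid_shape = grid, sd_scale = 0,
                     snr_ase = Inf, snr_asl = Inf, ...)
}
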