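# Shared fixtures, built in code.

# A recording covering `n_cycles` oscillation cycles.
make_rec <- function(f0 = 100, n_cycles = 30, fs = 4000, ...) {
  generate_recording(recording_spec(
    f0 = f0, fs = fs, n_frames = ceiling((n_cycles + 2) * fs / f0), ...))
}

# Extract the GAW_T perturbation features of a recording.
pert_of <- function(rec) {
  cyc <- detect_cycles(rec$gaw_total, rec$fs)
  suppressWarnings(perturbation_features(cycle_series(rec$gaw_total, cyc)))
}

# Small two-group feature table with one informative column among noise.
make_noise_table <- function(seed, n_per_class = 30, n_noise = 9,
                             delta = 4) {
  set.seed(seed)
  X <- cbind(inf = c(rnorm(n_per_class, 0), rnorm(n_per_class, delta)),
             matrix(rnorm(2 * n_per_class * n_noise), ncol = n_noise))
  colnames(X) <- c("inf", paste0("noise", seq_len(n_noise)))
  tab <- tibble::as_tibble(X)
  tab$group <- rep(c("N_F", "FD_F"), each = n_per_class)
  tab
}

# Strictly separable 1-D classification problem (disjoint supports).
make_separable <- function(seed, n_per_class = 30, gap = 1) {
  set.seed(seed)
  X <- cbind(x = c(runif(n_per_class, 0, 1),
                   runif(n_per_class, 1 + gap, 2 + gap)))
  y <- factor(rep(c("healthy", "disordered"), each = n_per_class),
              levels = c("healthy", "disordered"))
  list(X = X, y = y)
}

# Lazily computed, cached perturbation cohort (shared across test blocks).
.pv_cache <- new.env(parent = emptyenv())
get_perturbation_cohort <- function() {
  if (is.null(.pv_cache$cohort)) {
    .pv_cache$cohort <- sample_perturbation_cohort(n = 100, n_cycles = 200,
                                                   seed = 1)
  }
  .pv_cache$cohort
}
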