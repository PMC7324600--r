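#' Pulse-shape specification for one vocal fold
#'
#' The glottal pulse is piecewise linear with a flat plateau: a closed
#' segment, a linear rise (opening), a plateau at peak displacement, and a
#' linear fall (closing). This makes the shape quotients analytically
#' controllable: the speed quotient (closing/opening duration) equals
#' `speed_quotient` and the plateau quotient (fraction of the open phase at
#' >= 90% of peak) equals `plateau_fraction`.
#'
#' @param open_quotient Fraction of the cycle during which the fold is open,
#'   in (0, 1].
#' @param speed_quotient Target ratio of closing to opening duration (> 0).
#' @param plateau_fraction Fraction of the open phase at >= 90% of peak, in
#'   \[0, 1). Values below 0.1 are not representable by a piecewise-linear
#'   pulse (the 10% ramp tails alone occupy 0.1); they yield a pure triangle
#'   whose measured plateau quotient is 0.1.
#' @param amplitude Peak displacement, arbitrary area units (> 0).
#' @return A `pv_pulse` list with the requested fields plus the internal ramp
#'   fractions `q_open`, `q_flat`, `q_close` (fractions of the open phase)
#'   and the realised plateau quotient `pq_true`.
#' @export
#' @examples
#' pulse_shape(open_quotient = 0.6, speed_quotient = 0.8)
pulse_shape <- function(open_quotient = 0.6, speed_quotient = 0.8,
                        plateau_fraction = 0.3, amplitude = 1) {
  check_scalar(open_quotient, "open_quotient", 0, 1, lo_open = TRUE)
  check_scalar(speed_quotient, "speed_quotient", 0, Inf, lo_open = TRUE)
  check_scalar(plateau_fraction, "plateau_fraction", 0, 1, hi_open = TRUE)
  check_scalar(amplitude, "amplitude", 0, Inf, lo_open = TRUE)
  q_flat <- max(0, (plateau_fraction - 0.1) / 0.9)
  q_open <- (1 - q_flat) / (1 + speed_quotient)
  q_close <- speed_quotient * q_open
  structure(
    list(open_quotient = open_quotient, speed_quotient = speed_quotient,
         plateau_fraction = plateau_fraction, amplitude = amplitude,
         q_open = q_open, q_flat = q_flat, q_close = q_close,
         pq_true = q_flat + 0.1 * (1 - q_flat)),
    class = "pv_pulse"
  )
}

#' Specification of a synthetic glottal recording
#'
#' Defines the kinematics of a simulated pair of vocal folds: fundamental
#' frequency, cycle-to-cycle period and amplitude perturbation (calibrated so
#' the *extracted* jitter and shimmer match the targets in expectation),
#' additive broadband noise at a controlled harmonics-to-noise ratio,
#' left-right phase shift and amplitude asymmetry, and anterior-posterior
#' opening/closing delays that control the Phonovibrogram contour angles.
#'
#' Period perturbation is i.i.d. multiplicative Gaussian,
#' `T_k = T0 * (1 + delta_k)` with `sd(delta) = (jitter_pct/100) * sqrt(pi)/2`,
#' so that `E|T_k - T_{k-1}| / mean(T)` equals the jitter target (for i.i.d.
#' normal increments `E|X_k - X_{k-1}| = 2 sigma / sqrt(pi)`). Amplitude
#' perturbation is i.i.d. lognormal on the dB scale,
#' `A_k = A0 * 10^(e_k/20)` with `sd(e) = shimmer_db * sqrt(pi)/2`, so the
#' mean absolute dB shimmer equals the target exactly in expectation.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param fs Sampling (frame) rate in Hz; default 4000.
#' @param n_frames Number of frames; default 1000 (250 ms at 4000 Hz). Must
#'   cover at least 3 cycles.
#' @param jitter_pct_target Target extracted Jit(%) in percent (>= 0).
#' @param shimmer_db_target Target extracted mean dB shimmer (>= 0).
#' @param snr_db_target Target harmonics-to-noise energy ratio of `gaw_total`
#'   in dB, or `NULL` for a noise-free recording.
#' @param phase_shift Left-right phase shift as a fraction of the cycle
#'   (right minus left, signed; positive = right fold lags).
#' @param lr_amplitude_ratio Right/left peak-amplitude ratio (> 0).
#' @param ap_delay_open,ap_delay_close Fraction of the cycle by which the
#'   opening (closing) sweeps from the fold tips to the mid-fold (signed;
#'   0 = simultaneous along the fold).
#' @param n_positions Number of contour sample positions per fold (even,
#'   >= 8); default 64.
#' @param pulse_left,pulse_right [pulse_shape()] per fold; `pulse_right`
#'   defaults to `pulse_left`.
#' @param seed Integer seed; every recording is bit-reproducible given it.
#' @return A `pv_recording_spec` list.
#' @export
recording_spec <- function(f0 = 120, fs = 4000, n_frames = 1000,
                           jitter_pct_target = 0, shimmer_db_target = 0,
                           snr_db_target = NULL, phase_shift = 0,
                           lr_amplitude_ratio = 1,
                           ap_delay_open = 0, ap_delay_close = 0,
                           n_positions = 64,
                           pulse_left = pulse_shape(),
                           pulse_right = NULL, seed = 1L) {
  check_scalar(f0, "f0", 0, Inf, lo_open = TRUE)
  check_scalar(fs, "fs", 0, Inf, lo_open = TRUE)
  if (fs <= 2 * f0) abort_field("fs", "must exceed 2 * f0")
  check_scalar(n_frames, "n_frames", 3, Inf)
  if (n_frames < 3 * fs / f0) {
    abort_field("n_frames", "must cover at least 3 oscillation cycles")
  }
  check_scalar(jitter_pct_target, "jitter_pct_target", 0, Inf)
  check_scalar(shimmer_db_target, "shimmer_db_target", 0, Inf)
  check_scalar(snr_db_target, "snr_db_target", allow_null = TRUE)
  check_scalar(phase_shift, "phase_shift", -0.5, 0.5)
  check_scalar(lr_amplitude_ratio, "lr_amplitude_ratio", 0, Inf,
               lo_open = TRUE)
  check_scalar(n_positions, "n_positions", 8, Inf)
  if (n_positions %% 2 != 0) abort_field("n_positions", "must be even")
  if (!inherits(pulse_left, "pv_pulse")) {
    abort_field("pulse_left", "must be a pulse_shape()")
  }
  if (is.null(pulse_right)) pulse_right <- pulse_left
  if (!inherits(pulse_right, "pv_pulse")) {
    abort_field("pulse_right", "must be a pulse_shape() or NULL")
  }
  for (p in list(pulse_left, pulse_right)) {
    c0 <- (1 - p$open_quotient) / 2
    check_scalar(ap_delay_open, "ap_delay_open", -c0, c0)
    check_scalar(ap_delay_close, "ap_delay_close", -c0, c0)
    if (abs(ap_delay_close - ap_delay_open) >= 0.9 * p$open_quotient) {
      abort_field("ap_delay_close",
                  "opening/closing delays would collapse the open phase")
    }
  }
  check_scalar(seed, "seed")
  structure(
    list(f0 = f0, fs = fs, n_frames = as.integer(n_frames),
         jitter_pct_target = jitter_pct_target,
         shimmer_db_target = shimmer_db_target,
         snr_db_target = snr_db_target, phase_shift = phase_shift,
         lr_amplitude_ratio = lr_amplitude_ratio,
         ap_delay_open = ap_delay_open, ap_delay_close = ap_delay_close,
         n_positions = as.integer(n_positions),
         pulse_left = pulse_left, pulse_right = pulse_right,
         seed = as.integer(seed)),
    class = "pv_recording_spec"
  )
}

# Evaluate the pulse at relative open-phase positions `rel` (matrix ok).
pulse_value <- function(rel, pulse) {
  v <- pmin(rel / pulse$q_open, 1, (1 - rel) / pulse$q_close)
  v[!is.finite(v)] <- 0
  pmax(v, 0)
}

#' Generate a synthetic glottal recording
#'
#' Builds per-fold displacement matrices `D_s(p, t) = A_{s,k} g(p) v(u)`
#' where `g(p)` is a half-sine amplitude envelope along the fold (maximum at
#' mid-fold), `v` is the piecewise-linear pulse of [pulse_shape()], and the
#' pulse onset/offset at position `p` is delayed by
#' `ap_delay * (1 - |p - mid| / (P/2))` cycles, so the fold opens/closes in a
#' "zipper" from the tips towards the mid-fold when the delay is positive.
#' The partial glottal area waveforms are the rectangle-rule integral of the
#' displacement over position, and `gaw_total = gaw_left + gaw_right`
#' exactly. Broadband Gaussian noise, when requested, is added to the 1-D GAW
#' signals (split equally between the left and right waveform so the total
#' remains the exact sum), scaled so the harmonics-to-noise energy ratio of
#' `gaw_total` equals `snr_db_target`.
#'
#' @param spec A [recording_spec()].
#' @return A `pv_recording`: list with `disp_left`, `disp_right`
#'   (`n_positions x n_frames` matrices, posterior at row 1), `gaw_left`,
#'   `gaw_right`, `gaw_total`, `fs`, and `truth` (the spec).
#' @export
#' @examples
#' rec <- generate_recording(recording_spec(f0 = 100, n_frames = 400))
#' length(rec$gaw_total)
generate_recording <- function(spec) {
  if (!inherits(spec, "pv_recording_spec")) {
    abort("`spec` must be a recording_spec()", class = "phonovibe_error")
  }
  with_seed(spec$seed, {
    P <- spec$n_positions
    n <- spec$n_frames
    T0 <- spec$fs / spec$f0                    # frames per cycle
    sigma_T <- spec$jitter_pct_target / 100 * sqrt(pi) / 2
    sigma_A <- spec$shimmer_db_target * sqrt(pi) / 2   # dB

    # Peak epochs: the perturbed periods are the peak-to-peak intervals, so
    # the extremum-based cycle estimators see exactly the generated
    # perturbation sequence. Each pulse is a self-contained unit of fixed
    # duration T0 centred on its epoch; only the epoch spacing is jittered.
    # The period floor keeps adjacent pulses from overlapping.
    per_floor <- max(0.2, spec$pulse_left$open_quotient + 0.05,
                     spec$pulse_right$open_quotient + 0.05)
    n_cyc <- ceiling(n / (T0 * 0.7)) + 6L
    periods <- T0 * pmax(per_floor, 1 + rnorm(n_cyc, 0, sigma_T))
    while (sum(periods) < n + 3 * T0) {
      periods <- c(periods, T0 * pmax(per_floor, 1 + rnorm(10L, 0, sigma_T)))
    }
    amps <- 10^(rnorm(length(periods) + 1L, 0, sigma_A) / 20)
    epochs <- c(0, cumsum(periods))            # continuous frame time

    g <- sin(pi * (seq_len(P) - 0.5) / P)      # half-sine envelope
    h <- abs(seq_len(P) - (P + 1) / 2) / (P / 2)  # 1 at tips, ~0 mid-fold
    lag_frac <- 1 - h                          # delay grows tip -> mid

    side_matrix <- function(pulse, amp_scale, phase_off) {
      c0 <- (1 - pulse$open_quotient) / 2
      a_p <- c0 + spec$ap_delay_open * lag_frac
      b_p <- c0 + pulse$open_quotient + spec$ap_delay_close * lag_frac
      # peak centre in pulse-local coordinates
      c_pk <- c0 + pulse$open_quotient * (pulse$q_open + pulse$q_flat / 2)
      disp <- matrix(0, nrow = P, ncol = n)
      x <- seq_len(n) - 1
      span <- range(c(a_p, b_p))
      for (j in seq_along(epochs)) {
        q_j <- epochs[j] + phase_off * T0      # this side's peak epoch
        lo <- q_j + (span[1] - c_pk) * T0
        hi <- q_j + (span[2] - c_pk) * T0
        cols <- which(x > lo & x < hi)
        if (length(cols) == 0L) next
        w <- (x[cols] - q_j) / T0 + c_pk       # pulse-local coordinate
        rel <- (matrix(w, nrow = P, ncol = length(cols), byrow = TRUE) -
                  a_p) / (b_p - a_p)
        disp[, cols] <- disp[, cols] +
          (amps[j] * amp_scale * pulse$amplitude) * g * pulse_value(rel, pulse)
      }
      disp
    }

    disp_left <- side_matrix(spec$pulse_left, 1, 0)
    disp_right <- side_matrix(spec$pulse_right, spec$lr_amplitude_ratio,
                              spec$phase_shift)
    gaw_left <- colSums(disp_left)
    gaw_right <- colSums(disp_right)

    if (!is.null(spec$snr_db_target)) {
      gaw_total <- gaw_left + gaw_right
      p_sig <- mean((gaw_total - mean(gaw_total))^2)
      noise_var <- p_sig / 10^(spec$snr_db_target / 10)
      gaw_left <- gaw_left + rnorm(n, 0, sqrt(noise_var / 2))
      gaw_right <- gaw_right + rnorm(n, 0, sqrt(noise_var / 2))
    }

    structure(
      list(disp_left = disp_left, disp_right = disp_right,
           gaw_left = gaw_left, gaw_right = gaw_right,
           gaw_total = gaw_left + gaw_right,
           fs = spec$fs, truth = spec),
      class = "pv_recording"
    )
  })
}

#' @export
print.pv_recording <- function(x, ...) {
  cat(sprintf(
    "<pv_recording> %d frames @ %g Hz, %d positions/fold, f0 = %g Hz\n",
    length(x$gaw_total), x$fs, nrow(x$disp_left), x$truth$f0))
  invisible(x)
}

#' Specification of a synthetic cohort
#'
#' @param n_per_group Named integer vector or list: recordings per group
#'   label (all counts > 0).
#' @param params Named list (one entry per group, or a single unnamed
#'   template applied to all groups) of [recording_spec()] field overrides.
#'   Each field is either a scalar (held fixed) or a length-2 numeric
#'   `c(lo, hi)` sampled uniformly per recording.
#' @param seed Integer seed.
#' @return A `pv_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group, params = list(), seed = 1L) {
  n_per_group <- unlist(n_per_group)
  if (length(n_per_group) == 0L || is.null(names(n_per_group)) ||
      any(!nzchar(names(n_per_group)))) {
    abort_field("n_per_group", "must be a named vector of group counts")
  }
  if (any(n_per_group <= 0)) abort_field("n_per_group", "counts must be > 0")
  known <- names(formals(recording_spec))
  flat <- if (length(params) > 0L && is.null(names(params))) params[[1]] else params
  entries <- if (!is.null(names(flat)) && all(names(flat) %in% names(n_per_group))) {
    unlist(unname(flat), recursive = FALSE)
  } else flat
  bad <- setdiff(names(entries), known)
  if (length(bad) > 0L) {
    abort_field("params", paste("unknown recording_spec field(s):",
                                paste(bad, collapse = ", ")))
  }
  structure(list(n_per_group = n_per_group, params = params,
                 seed = as.integer(seed)),
            class = "pv_cohort_spec")
}

#' Generate a cohort of synthetic recordings
#'
#' Draws per-recording parameters from the per-group distributions of the
#' [cohort_spec()], generates each recording with its own derived seed, and
#' returns one row per recording. Deterministic under the cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @param keep_recordings Keep the `pv_recording` objects in a list column
#'   (default `TRUE`). With `FALSE` only the sampled ground-truth parameters
#'   are returned (useful when recordings are consumed streamingly).
#' @return Tibble with columns `subject_id`, `group`, `recording` (list of
#'   `pv_recording`), and one column per sampled ground-truth field.
#' @export
generate_cohort <- function(spec, keep_recordings = TRUE) {
  if (!inherits(spec, "pv_cohort_spec")) {
    abort("`spec` must be a cohort_spec()", class = "phonovibe_error")
  }
  groups <- names(spec$n_per_group)
  per_group_params <- function(g) {
    if (length(spec$params) == 0L) return(list())
    if (!is.null(names(spec$params)) && g %in% names(spec$params)) {
      spec$params[[g]]
    } else if (is.null(names(spec$params)) ||
               !any(names(spec$params) %in% groups)) {
      spec$params
    } else {
      list()
    }
  }
  rows <- list()
  idx <- 0L
  with_seed(spec$seed, {
    for (g in groups) {
      overrides <- per_group_params(g)
      for (i in seq_len(spec$n_per_group[[g]])) {
        idx <- idx + 1L
        drawn <- lapply(overrides, function(v) {
          if (is.numeric(v) && length(v) == 2L) runif(1, v[1], v[2]) else v
        })
        drawn$seed <- derive_seed(spec$seed, idx)
        rs <- do.call(recording_spec, drawn)
        truth <- drawn[setdiff(names(drawn), "seed")]
        rows[[idx]] <- c(
          list(subject_id = sprintf("S%04d", idx), group = g,
               recording = if (keep_recordings) list(generate_recording(rs))
                           else list(NULL),
               spec = list(rs)),
          truth[vapply(truth, is.numeric, logical(1))]
        )
      }
    }
  })
  out <- bind_rows(lapply(rows, as_tibble))
  if (!keep_recordings) out$recording <- NULL
  out
}

#' Sample a subject-level feature table from printed group statistics
#'
#' Draws independent Gaussian values per parameter and group from a
#' mean/standard-deviation table (default: the published per-group statistics
#' of the 12 final parameters, [hsv2_group_stats()]), truncated to each
#' parameter's valid domain: angle and dB parameters are unconstrained,
#' bounded arbitrary-unit indices are clipped to \[0, 1.5\] (the signed phase
#' shift to \[-0.5, 0.5\]), and Std-type parameters are clipped at 0.
#' Marginal statistics only are emulated; parameters are drawn independently
#' within a subject.
#'
#' @param stats Tibble with columns `group`, `parameter`, `mean`, `sd`.
#' @param n_per_group Named vector of subjects per group, or a single count
#'   applied to every group in `stats`.
#' @param seed Integer seed.
#' @return Feature table tibble: `subject_id`, `group`, `sex`, `age`, then
#'   one column per parameter.
#' @export
#' @examples
#' tab <- sample_feature_table(n_per_group = 10, seed = 1)
#' dplyr::count(tab, group)
sample_feature_table <- function(stats = hsv2_group_stats(), n_per_group,
                                 seed = 1L) {
  reg <- parameter_registry()
  unknown <- setdiff(unique(stats$parameter), reg$name)
  if (length(unknown) > 0L) {
    abort_field("stats", paste("unknown parameter name(s):",
                               paste(unknown, collapse = ", ")))
  }
  if (any(stats$sd < 0)) abort_field("stats", "sd must be >= 0")
  groups <- unique(stats$group)
  if (is.null(names(n_per_group))) {
    if (length(n_per_group) != 1L) {
      abort_field("n_per_group", "must be named or a single count")
    }
    n_per_group <- setNames(rep(as.integer(n_per_group), length(groups)),
                            groups)
  }
  if (any(n_per_group <= 0)) abort_field("n_per_group", "counts must be > 0")

  clip_bounds <- function(p) {
    r <- reg[reg$name == p, ]
    if (r$units %in% c("deg", "dB", "Hz", "s", "%")) return(c(-Inf, Inf))
    if (r$statistic == "Std") return(c(0, Inf))
    if (r$name == "PhA_Mean") return(c(-0.5, 0.5))
    if (is.finite(r$domain_hi) && r$domain_hi <= 1.5) return(c(0, 1.5))
    c(r$domain_lo, r$domain_hi)
  }

  with_seed(seed, {
    rows <- list()
    sid <- 0L
    for (g in names(n_per_group)) {
      gstats <- stats[stats$group == g, ]
      if (nrow(gstats) == 0L) {
        abort_field("n_per_group", sprintf("group `%s` absent from stats", g))
      }
      n <- n_per_group[[g]]
      healthy <- grepl("^N", g)
      vals <- lapply(seq_len(nrow(gstats)), function(i) {
        b <- clip_bounds(gstats$parameter[i])
        pmin(pmax(rnorm(n, gstats$mean[i], gstats$sd[i]), b[1]), b[2])
      })
      names(vals) <- gstats$parameter
      age <- pmin(pmax(round(rnorm(n, if (healthy) 25 else 45,
                                   if (healthy) 4 else 12)), 18), 85)
      rows[[g]] <- as_tibble(c(
        list(subject_id = sprintf("%s%04d", g, seq_len(n) + sid),
             group = rep(g, n),
             sex = rep(if (grepl("_F$", g)) "F"
                       else if (grepl("_M$", g)) "M" else NA_character_, n),
             age = age),
        vals
      ))
      sid <- sid + n
    }
    bind_rows(rows)
  })
}

#' Write / read a recording as a plain-text bundle
#'
#' Persists a `pv_recording` as a directory of CSV matrices plus a JSON
#' ground-truth spec, and reads it back.
#'
#' @param rec A `pv_recording`.
#' @param path Directory to create/read.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `pv_recording`.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(rec$disp_left, file.path(path, "disp_left.csv"),
            row.names = FALSE)
  write.csv(rec$disp_right, file.path(path, "disp_right.csv"),
            row.names = FALSE)
  write.csv(data.frame(gaw_left = rec$gaw_left, gaw_right = rec$gaw_right,
                       gaw_total = rec$gaw_total),
            file.path(path, "gaw.csv"), row.names = FALSE)
  truth <- rec$truth
  truth$pulse_left <- unclass(truth$pulse_left)
  truth$pulse_right <- unclass(truth$pulse_right)
  jsonlite::write_json(c(list(fs = rec$fs), unclass(truth)),
                       file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  truth <- jsonlite::read_json(file.path(path, "truth.json"),
                               simplifyVector = TRUE)
  gaw <- utils::read.csv(file.path(path, "gaw.csv"))
  structure(
    list(
      disp_left = as.matrix(utils::read.csv(file.path(path, "disp_left.csv"))),
      disp_right = as.matrix(utils::read.csv(file.path(path, "disp_right.csv"))),
      gaw_left = gaw$gaw_left, gaw_right = gaw$gaw_right,
      gaw_total = gaw$gaw_total, fs = truth$fs,
      truth = truth
    ),
    class = "pv_recording"
  )
}

#' Perturbation-feature cohort for the redundancy screen
#'
#' Generates the cohort design used to demonstrate the redundancy of the
#' jitter and shimmer parameter families: recordings with jitter targets
#' uniform in 0.5-5%, mean-dB-shimmer targets uniform in 0.1-1 dB and
#' fundamental frequency uniform in 100-300 Hz, each long enough for about
#' 200 oscillation cycles, with no additive noise. For every recording the
#' period- and amplitude-perturbation parameters are extracted.
#'
#' @param n Number of recordings; default 100.
#' @param n_cycles Oscillation cycles per recording; default 200.
#' @param seed Integer seed.
#' @return Tibble with the ground-truth targets (`f0_true`, `jitter_true`,
#'   `shimmer_true`) and the extracted parameters `Jit_pct`, `PPQ3`,
#'   `PPQ5`, `PPQ11`, `APQ3`, `APQ5`, `APQ11`, `MShim`.
#' @export
sample_perturbation_cohort <- function(n = 100L, n_cycles = 200L,
                                       seed = 1L) {
  params <- c("Jit_pct", "PPQ3", "PPQ5", "PPQ11",
              "APQ3", "APQ5", "APQ11", "MShim")
  with_seed(seed, {
    draws <- tibble(
      f0_true = runif(n, 100, 300),
      jitter_true = runif(n, 0.5, 5),
      shimmer_true = runif(n, 0.1, 1),
      rec_seed = vapply(seq_len(n), function(i) derive_seed(seed, i),
                        integer(1))
    )
  })
  feats <- pmap(draws, function(f0_true, jitter_true, shimmer_true,
                                rec_seed) {
    spec <- recording_spec(
      f0 = f0_true, fs = 4000,
      n_frames = ceiling((n_cycles + 2) * 4000 / f0_true),
      jitter_pct_target = jitter_true, shimmer_db_target = shimmer_true,
      seed = rec_seed)
    rec <- generate_recording(spec)
    cyc <- detect_cycles(rec$gaw_total, rec$fs)
    p <- suppressWarnings(perturbation_features(
      cycle_series(rec$gaw_total, cyc)))
    as_tibble(as.list(p[params]))
  })
  dplyr::bind_cols(draws[c("f0_true", "jitter_true", "shimmer_true")],
                   bind_rows(feats))
}
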