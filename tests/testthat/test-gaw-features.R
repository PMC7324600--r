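# Constructed triangular pulse train with known peaks and amplitudes.
pulse_train <- function(amps, period = 40L, half = 10L) {
  n <- period * (length(amps) + 1L)
  x <- numeric(n)
  for (k in seq_along(amps)) {
    pk <- period * k
    idx <- (pk - half):(pk + half)
    x[idx] <- amps[k] * pmax(0, 1 - abs(idx - pk) / half)
  }
  x
}

test_that("cycle series recovers constructed periods, amplitudes, landmarks", {
  x <- pulse_train(rep(c(1.0, 1.1), 10))
  cyc <- detect_cycles(x, fs = 4000)
  ser <- cycle_series(x, cyc)
  expect_true(all(abs(ser$T - 0.01) < 1e-9))
  expect_true(all(abs(ser$A - rep_len(c(1.0, 1.1), nrow(ser))[1:nrow(ser)])
                  < 1e-9) ||
                all(abs(ser$A - rep_len(c(1.1, 1.0), nrow(ser))[1:nrow(ser)])
                    < 1e-9))
  # symmetric triangles: opening equals closing
  ok <- !is.na(ser$opening)
  expect_true(all(abs(ser$opening[ok] - ser$closing[ok]) < 1e-6))
})

test_that("perturbation formulas match hand-evaluated oracles", {
  mk <- function(T, A) tibble::tibble(T = T, A = A, E = A^2,
                                      opening = NA, plateau = NA,
                                      closing = NA, open_span = NA)
  per <- mk(rep(0.01, 15), rep(2, 15))
  p0 <- suppressWarnings(perturbation_features(per))
  expect_equal(p0[["Jit_pct"]], 0)
  expect_equal(p0[["MShim"]], 0)
  expect_equal(p0[["PPQ3"]], 0)
  expect_equal(p0[["APQ11"]], 0)

  alt <- mk(rep(c(40, 42), 7)[1:14] / 4000, rep(1, 14))
  expect_equal(suppressWarnings(perturbation_features(alt))[["Jit_pct"]],
               100 * 2 / 41, tolerance = 1e-10)

  sh <- mk(rep(0.01, 14), rep(c(1.0, 1.1), 7))
  expect_equal(suppressWarnings(perturbation_features(sh))[["MShim"]],
               20 * log10(1.1), tolerance = 1e-10)

  expect_error(perturbation_features(mk(rep(0.01, 2), rep(1, 2))),
               "at least 3")
})

test_that("11-point quotients need 12 cycles, others stay defined", {
  short <- tibble::tibble(T = rep(0.01, 8), A = rep(1, 8), E = rep(1, 8),
                          opening = NA, plateau = NA, closing = NA,
                          open_span = NA)
  w <- capture_warnings(p <- perturbation_features(short))
  expect_length(w, 3L)
  expect_match(w, "11", all = TRUE)
  expect_true(is.na(p[["PPQ11"]]))
  expect_true(is.na(p[["APQ11"]]))
  expect_false(is.na(p[["PPQ5"]]))
})

test_that("relative perturbation measures are amplitude-scale invariant", {
  rec <- make_rec(f0 = 130, n_cycles = 30, jitter_pct_target = 2,
                  shimmer_db_target = 0.5, seed = 4)
  x <- rec$gaw_total
  rel <- c("Jit_pct", "RAP_K", "PPQ3", "PPQ5", "PPQ11", "PPF",
           "APQ3", "APQ5", "APQ11", "APF", "MShim",
           "EPQ3", "EPQ5", "EPQ11", "EPF", "vAm", "F0_Mean", "F0_Std")
  f <- function(sig) {
    cyc <- detect_cycles(sig, 4000)
    suppressWarnings(perturbation_features(cycle_series(sig, cyc)))
  }
  expect_equal(f(x)[rel], f(7.3 * x)[rel], tolerance = 1e-9)
  expect_gt(f(x)[["Jit_pct"]], 0)
})

test_that("shape quotients follow the constructed pulse geometry", {
  # asymmetric pulses: opening 30 frames, closing 10
  n <- 50L * 12L
  x <- numeric(n)
  for (k in 1:11) {
    pk <- 50L * k
    ramp_up <- (pk - 30L):pk
    ramp_dn <- pk:(pk + 10L)
    x[ramp_up + 1L] <- (ramp_up - (pk - 30L)) / 30
    x[ramp_dn + 1L] <- pmax(x[ramp_dn + 1L], (pk + 10L - ramp_dn) / 10)
  }
  cyc <- detect_cycles(x, fs = 4000)
  q <- suppressWarnings(quotients(cycle_series(x, cyc)))
  expect_equal(q[["SQ_Mean"]], 1 / 3, tolerance = 0.02)
  expect_lt(q[["SQ_Std"]], 1e-6)

  # plateau ordering: square-like pulses have higher PQ than triangles
  sq_rec <- make_rec(f0 = 100, n_cycles = 20,
                     pulse_left = pulse_shape(plateau_fraction = 0.7))
  tri_rec <- make_rec(f0 = 100, n_cycles = 20,
                      pulse_left = pulse_shape(plateau_fraction = 0))
  pq <- function(r) {
    suppressWarnings(quotients(cycle_series(
      r$gaw_total, detect_cycles(r$gaw_total, r$fs))))[["PQ_Mean"]]
  }
  expect_gt(pq(sq_rec), pq(tri_rec))
})

test_that("generator shape targets are recovered from the GAW", {
  rec <- make_rec(f0 = 120, n_cycles = 60, seed = 2,
                  pulse_left = pulse_shape(open_quotient = 0.6,
                                           speed_quotient = 0.8,
                                           plateau_fraction = 0.3))
  q <- suppressWarnings(quotients(cycle_series(
    rec$gaw_total, detect_cycles(rec$gaw_total, rec$fs))))
  expect_equal(q[["SQ_Mean"]], 0.8, tolerance = 0.08)
  expect_equal(q[["PQ_Mean"]], 0.3, tolerance = 0.03)
  expect_equal(q[["OQ_Mean"]], 0.6, tolerance = 0.03)
})

test_that("snr_k caps on noiseless harmonic signals and tracks noise power", {
  t <- 0:1999
  x <- sin(2 * pi * 100 * t / 4000)
  cyc <- detect_cycles(x, 4000)
  v <- snr_k(x, cyc)
  expect_equal(as.numeric(v), 60)
  expect_true(attr(v, "capped"))

  # doubling the noise power lowers SNR_K by ~3 dB
  est <- function(target) {
    mean(vapply(1:10, function(s) {
      r <- make_rec(f0 = 120, n_cycles = 28, snr_db_target = target,
                    seed = s)
      as.numeric(snr_k(r$gaw_total, detect_cycles(r$gaw_total, r$fs)))
    }, numeric(1)))
  }
  expect_equal(est(14) - est(14 - 10 * log10(2)), 10 * log10(2),
               tolerance = 0.35)

  expect_error(snr_k(x[1:150], detect_cycles(x[1:150], 4000)),
               "at least 10")
})

test_that("symmetry features satisfy identity, shift and cancellation cases", {
  # identity
  rec <- make_rec(f0 = 100, n_cycles = 15)
  maxc <- detect_cycles(rec$gaw_total, rec$fs)
  minc <- detect_cycles(rec$gaw_total, rec$fs, mode = "minimum")
  s <- symmetry_features(rec$gaw_left, rec$gaw_right, maxc, minc)
  expect_equal(s[["PhA_Mean"]], 0)
  expect_equal(s[["PhAI_Mean"]], 0)
  expect_equal(s[["AmSI_Mean"]], 1)
  expect_equal(s[["WaSI_Mean"]], 1)

  # constructed quarter-cycle shift of the right fold
  rec2 <- make_rec(f0 = 100, n_cycles = 30, phase_shift = 0.25, seed = 1)
  maxc2 <- detect_cycles(rec2$gaw_total, rec2$fs)
  minc2 <- detect_cycles(rec2$gaw_total, rec2$fs, mode = "minimum")
  s2 <- symmetry_features(rec2$gaw_left, rec2$gaw_right, maxc2, minc2)
  expect_equal(s2[["PhA_Mean"]], 0.25, tolerance = 0.02)
  expect_equal(s2[["PhAI_Mean"]], 0.25, tolerance = 0.02)

  # alternating +0.1/-0.1 lags cancel in PhA but not PhAI
  period <- 40L; n <- period * 22L; half <- 8L
  l <- numeric(n); r <- numeric(n)
  for (k in 1:20) {
    pk <- period * k
    lag <- if (k %% 2 == 0) 4L else -4L     # 0.1 cycle
    il <- (pk - half):(pk + half)
    l[il] <- pmax(l[il], 1 - abs(il - pk) / half)
    ir <- il + lag
    r[ir] <- pmax(r[ir], 1 - abs(ir - pk - lag) / half)
  }
  minc3 <- detect_cycles(l + r, 4000, mode = "minimum",
                         prominence_frac = 0.05)
  s3 <- symmetry_features(l, r, detect_cycles(l + r, 4000), minc3)
  expect_lt(abs(s3[["PhA_Mean"]]), 0.02)
  expect_equal(s3[["PhAI_Mean"]], 0.1, tolerance = 0.02)
})

test_that("swapping folds negates signed symmetry and keeps indices", {
  rec <- make_rec(f0 = 110, n_cycles = 25, phase_shift = 0.15,
                  lr_amplitude_ratio = 0.8, seed = 3)
  maxc <- detect_cycles(rec$gaw_total, rec$fs)
  minc <- detect_cycles(rec$gaw_total, rec$fs, mode = "minimum")
  a <- symmetry_features(rec$gaw_left, rec$gaw_right, maxc, minc)
  b <- symmetry_features(rec$gaw_right, rec$gaw_left, maxc, minc)
  expect_equal(a[["PhA_Mean"]], -b[["PhA_Mean"]], tolerance = 1e-6)
  expect_equal(a[["AmS_Mean"]], -b[["AmS_Mean"]], tolerance = 1e-9)
  expect_equal(a[["PhAI_Mean"]], b[["PhAI_Mean"]], tolerance = 1e-9)
  expect_equal(a[["AmSI_Mean"]], b[["AmSI_Mean"]], tolerance = 1e-9)
  # bounded ranges
  expect_true(a[["PhA_Mean"]] > -0.5 && a[["PhA_Mean"]] <= 0.5)
  expect_true(a[["AmSI_Mean"]] >= 0 && a[["AmSI_Mean"]] <= 1)
})

test_that("the full feature vector covers the registry", {
  reg <- parameter_registry()
  expect_equal(nrow(reg), 91L)
  expect_equal(sum(reg$family == "GAW_T"), 41L)
  expect_equal(sum(reg$family == "GAW_symmetry"), 18L)
  expect_equal(sum(reg$family == "PVG"), 32L)
  expect_identical(reg$name[reg$cycle_mode == "minimum"],
                   c("PhA_Mean", "PhA_Std", "PhAI_Mean", "PhAI_Std"))

  rec <- make_rec(f0 = 100, n_cycles = 20, seed = 1)
  v <- compute_feature_vector(rec)
  expect_identical(names(v), reg$name)
  expect_false(anyNA(v))

  # short recording: the 11-point family is NA, the rest defined
  rec8 <- make_rec(f0 = 100, n_cycles = 8, seed = 1)
  v8 <- compute_feature_vector(rec8)
  expect_true(all(is.na(v8[c("PPQ11", "APQ11", "EPQ11")])))
  expect_false(is.na(v8[["PPQ5"]]))
})
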