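#' Extraction settings for vibration-parameter computation
#'
#' Collects the numerical knobs of the feature extractors. All thresholds are
#' relative, so extraction is invariant to uniform amplitude scaling.
#'
#' @param prominence_frac Peak prominence threshold for cycle detection, as a
#'   fraction of the signal range (default 0.10).
#' @param f0_bounds Plausible f0 range in Hz for cycle spacing, default
#'   `c(50, 1000)`.
#' @param open_frac Threshold (fraction of signal excursion) above which the
#'   glottis counts as open when locating pulses; default 0.02.
#' @param plateau_level Fraction of the pulse peak defining the plateau and
#'   the opening/closing landmarks; default 0.9.
#' @param pvg_eps_frac Displacement threshold for PVG onset/offset detection,
#'   as a fraction of each position's maximum excursion; default 0.05.
#' @param snr_max_harmonics Number of harmonics summed by [snr_k()] (max 8).
#' @param snr_cap Cap in dB for the harmonics-to-noise ratio; default 60.
#' @param detect_smooth Width (odd number of frames) of the moving average
#'   applied to `gaw_total` before cycle *detection* in
#'   [compute_feature_vector()]; broadband noise otherwise seeds spurious
#'   extrema. All measurements are still taken on the raw signal. 0
#'   disables smoothing; default 7.
#' @return A `pv_config` list.
#' @export
feature_config <- function(prominence_frac = 0.10, f0_bounds = c(50, 1000),
                           open_frac = 0.02, plateau_level = 0.9,
                           pvg_eps_frac = 0.05, snr_max_harmonics = 8,
                           snr_cap = 60, detect_smooth = 7L) {
  structure(list(prominence_frac = prominence_frac, f0_bounds = f0_bounds,
                 open_frac = open_frac, plateau_level = plateau_level,
                 pvg_eps_frac = pvg_eps_frac,
                 snr_max_harmonics = snr_max_harmonics, snr_cap = snr_cap,
                 detect_smooth = as.integer(detect_smooth)),
            class = "pv_config")
}

# moving-average smoothing for cycle detection; edges keep raw values
smooth_for_detection <- function(x, w) {
  if (w <= 1L) return(x)
  xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  xs
}

# Sub-frame instant of the extremum whose integer index is `b`:
# midpoint of the two linear-interpolated crossings of the mid-level between
# local base and peak. Falls back to `b` when a crossing cannot be located.
# Integer frame indices quantize peak instants to the 250 us frame grid;
# at typical f0 this quantization alone would inflate extracted jitter, so
# periods and phase lags are measured on these refined instants instead.
# The 50% level keeps both bracketing samples on the same monotone flank,
# where linear interpolation of a piecewise-linear pulse is exact.
refine_extremum <- function(x, b, lo, hi, base, level_frac = 0.5) {
  lvl <- base + level_frac * (x[b] - base)
  i <- b
  while (i > lo && x[i - 1L] >= lvl) i <- i - 1L
  t_left <- if (i > lo && x[i - 1L] < lvl) cross_time(x, i - 1L, lvl) else NA
  j <- b
  while (j < hi && x[j + 1L] >= lvl) j <- j + 1L
  t_right <- if (j < hi && x[j + 1L] < lvl) cross_time(x, j, lvl) else NA
  if (is.na(t_left) || is.na(t_right)) return(as.numeric(b))
  (t_left + t_right) / 2
}

# Refined instants for all boundaries of a cycle set (maximum mode assumed;
# pass -x for minima).
refine_boundaries <- function(x, cycles) {
  b <- cycles$boundaries
  n <- length(x)
  base <- min(x)
  vapply(seq_along(b), function(i) {
    lo <- if (i == 1L) 1L else b[i - 1L]
    hi <- if (i == length(b)) n else b[i + 1L]
    refine_extremum(x, b[i], lo, hi, base)
  }, numeric(1))
}

#' Per-cycle series of periods, amplitudes, energies and pulse landmarks
#'
#' For each cycle: period `T` (seconds, from sub-frame-refined extremum
#' spacing), peak amplitude `A`, energy `E` (sum of squared samples), and the
#' opening / plateau / closing durations (frames) of the glottal pulse
#' contained in the cycle. Pulse landmarks are located on the open phase:
#' opening runs from the open-phase start to the first crossing of 90% of the
#' pulse peak, the plateau is the contiguous >= 90% span containing the peak,
#' and closing runs from the last 90% crossing to the open-phase end; all
#' landmark times are linearly interpolated between frames.
#'
#' @param gaw Signal vector (typically `gaw_total`).
#' @param cycles A `pv_cycles` from [detect_cycles()].
#' @param config A [feature_config()].
#' @return A `pv_cycle_series` tibble with one row per cycle: `T`, `A`, `E`,
#'   `opening`, `plateau`, `closing`, `open_span` (frames; `NA` when the
#'   cycle holds no complete pulse).
#' @export
cycle_series <- function(gaw, cycles, config = feature_config()) {
  if (n_cycles(cycles) < 3L) {
    abort("need at least 3 cycles", class = "phonovibe_error")
  }
  b <- cycles$boundaries
  K <- n_cycles(cycles)
  x <- gaw
  sgn_x <- if (cycles$mode == "minimum") -x else x
  refined <- refine_boundaries(sgn_x, cycles)
  periods <- diff(refined) / cycles$fs

  # For maximum-based cycles the defining peak is the cycle's own pulse;
  # taking the plain segment max instead would mix in the front of the next
  # pulse's plateau and halve the extracted shimmer.
  A <- E <- numeric(K)
  for (k in seq_len(K)) {
    seg <- x[b[k]:(b[k + 1L] - 1L)]
    A[k] <- if (cycles$mode == "maximum") x[b[k]] else max(seg)
    E[k] <- sum(seg^2)
  }

  # pulse landmarks over the whole signal, then assigned to cycles
  minv <- min(x)
  thr <- minv + config$open_frac * (max(x) - minv)
  open <- x > thr
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  opening <- plateau <- closing <- open_span <- rep(NA_real_, K)
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]
    if (s == 1L || e == length(x)) next       # partial pulse at the edge
    pk_rel <- which.max(x[s:e])
    pk <- s + pk_rel - 1L
    peak <- x[pk]
    lvl <- minv + config$plateau_level * (peak - minv)
    t_on <- cross_time(x, s - 1L, thr)
    t_off <- cross_time(x, e, thr)
    iu <- pk
    while (iu > s && x[iu - 1L] >= lvl) iu <- iu - 1L
    t_up <- if (x[iu - 1L] < lvl) cross_time(x, iu - 1L, lvl) else t_on
    id <- pk
    while (id < e && x[id + 1L] >= lvl) id <- id + 1L
    t_dn <- if (x[id + 1L] < lvl) cross_time(x, id, lvl) else t_off
    mid <- (t_on + t_off) / 2
    k <- findInterval(mid, b)
    if (k < 1L || k > K) next
    if (!is.na(open_span[k]) && open_span[k] >= t_off - t_on) next
    opening[k] <- t_up - t_on
    plateau[k] <- t_dn - t_up
    closing[k] <- t_off - t_dn
    open_span[k] <- t_off - t_on
  }

  structure(
    tibble(T = periods, A = A, E = E, opening = opening, plateau = plateau,
           closing = closing, open_span = open_span),
    class = c("pv_cycle_series", "tbl_df", "tbl", "data.frame"),
    fs = cycles$fs, mode = cycles$mode
  )
}

moving_average <- function(x, k) {
  stats::filter(x, rep(1 / k, k), sides = 2)
}

point_quotient <- function(x, k) {
  if (length(x) < k + 1L) return(NA_real_)
  ma <- as.numeric(moving_average(x, k))
  ok <- !is.na(ma)
  100 * mean(abs(x[ok] - ma[ok])) / mean(x)
}

#' Perturbation parameters from a per-cycle series
#'
#' Standard voice-perturbation definitions over the per-cycle periods `T`,
#' amplitudes `A` and energies `E`:
#' * `XP[Mean]`/`XP[Std]`: moments of the absolute consecutive differences
#'   `|X_k - X_{k-1}|` (TP in seconds, AP/EP in signal units);
#' * `Jit(%)` `= 100 mean|T_k - T_{k-1}| / mean T`;
#' * `RAP_K`: 3-point relative average perturbation
#'   `100 mean|T_k - (T_{k-1}+T_k+T_{k+1})/3| / mean T`;
#' * `PPQk`/`APQk`/`EPQk` (k = 3, 5, 11): `100 mean|X_j - MA_k(X)_j| /
#'   mean X` with a centred k-point moving average;
#' * `PPF`/`APF`/`EPF`: `100 mean|X_k - X_{k-1}| / mean X` over consecutive
#'   differences;
#' * `MShim` `= mean|20 log10(A_{k+1}/A_k)|` in dB;
#' * `F0[Mean]`/`F0[Std]`: moments of the per-cycle rate `1/T_k`;
#' * amplitude/energy magnitudes `A[Mean]`, `A[Std]`, `E[Mean]`, `E[Std]`
#'   and the amplitude variation coefficient `vAm = 100 sd(A)/mean(A)`.
#'
#' The 11-point quotients need at least 12 cycles; shorter series yield `NA`
#' with a warning rather than a silently degraded estimate.
#'
#' @param series A [cycle_series()].
#' @return Named numeric vector (partial parameter vector).
#' @export
perturbation_features <- function(series) {
  if (nrow(series) < 3L) {
    abort("need at least 3 cycles", class = "phonovibe_error")
  }
  out <- c()
  f0 <- 1 / series$T
  out["F0_Mean"] <- mean(f0)
  out["F0_Std"] <- sd(f0)
  for (nm in c("T", "A", "E")) {
    x <- series[[nm]]
    pre <- c(T = "TP", A = "AP", E = "EP")[[nm]]
    d <- abs(diff(x))
    out[paste0(pre, "_Mean")] <- mean(d)
    out[paste0(pre, "_Std")] <- sd(d)
    qpre <- c(T = "PPQ", A = "APQ", E = "EPQ")[[nm]]
    for (k in c(3L, 5L, 11L)) {
      q <- point_quotient(x, k)
      if (is.na(q) && k == 11L) {
        warn(sprintf("fewer than 12 cycles: %s11 undefined", qpre))
      }
      out[paste0(qpre, k)] <- q
    }
    out[paste0(c(T = "PPF", A = "APF", E = "EPF")[[nm]])] <-
      100 * mean(d) / mean(x)
  }
  out["Jit_pct"] <- 100 * mean(abs(diff(series$T))) / mean(series$T)
  Tn <- series$T
  if (length(Tn) >= 3L) {
    ma3 <- as.numeric(moving_average(Tn, 3L))
    ok <- !is.na(ma3)
    out["RAP_K"] <- 100 * mean(abs(Tn[ok] - ma3[ok])) / mean(Tn)
  } else {
    out["RAP_K"] <- NA_real_
  }
  out["MShim"] <- mean(abs(20 * log10(series$A[-1] / head(series$A, -1))))
  out["A_Mean"] <- mean(series$A)
  out["A_Std"] <- sd(series$A)
  out["E_Mean"] <- mean(series$E)
  out["E_Std"] <- sd(series$E)
  out["vAm"] <- 100 * sd(series$A) / mean(series$A)
  out
}

#' Shape-quotient parameters from pulse landmarks
#'
#' Per-cycle quotients of the glottal pulse: speed quotient
#' `SQ = closing / opening` duration, plateau quotient `PQ = plateau /
#' open-phase` duration, open quotient `OQ = open-phase / period`, speed
#' index `SI = (closing - opening)/(closing + opening)`, and closing/opening
#' quotients relative to the period. Cycles with a zero opening duration are
#' skipped with a warning.
#'
#' @param series A [cycle_series()].
#' @return Named numeric vector with `[Mean]` and `[Std]` entries for SQ,
#'   PQ, OQ, SI, ClQ, OpQ.
#' @export
quotients <- function(series) {
  fs <- attr(series, "fs")
  ok <- !is.na(series$open_span)
  zero_open <- ok & series$opening <= 0
  if (any(zero_open)) {
    warn(sprintf("%d cycle(s) with zero opening duration skipped",
                 sum(zero_open)))
  }
  ok <- ok & !zero_open
  s <- series[ok, ]
  per_frames <- s$T * fs
  vals <- list(
    SQ = s$closing / s$opening,
    PQ = s$plateau / s$open_span,
    OQ = s$open_span / per_frames,
    SI = (s$closing - s$opening) / (s$closing + s$opening),
    ClQ = s$closing / per_frames,
    OpQ = s$opening / per_frames
  )
  out <- c()
  for (nm in names(vals)) {
    out[paste0(nm, "_Mean")] <- if (length(vals[[nm]]) > 0) mean(vals[[nm]]) else NA_real_
    out[paste0(nm, "_Std")] <- if (length(vals[[nm]]) > 1) sd(vals[[nm]]) else NA_real_
  }
  out
}

#' Harmonics-to-noise energy ratio of a GAW spectrum, in dB
#'
#' The mean-removed, Hann-windowed spectrum is split into harmonic bands
#' (one bin either side of the local spectral peak near each multiple of the
#' fundamental, up to `snr_max_harmonics` harmonics below Nyquist) and a
#' residual. The broadband-noise floor, estimated from the non-harmonic bins
#' between 0.5 f0 and the last harmonic, is subtracted from the harmonic
#' bands (and credited to the residual) so the returned ratio
#' `10 log10(E_harm / E_residual)` is an unbiased estimate of the
#' harmonics-to-noise energy ratio. The value is capped at
#' `snr_cap` dB; a vanishing residual returns the cap with attribute
#' `capped = TRUE`.
#'
#' @param gaw Signal vector.
#' @param cycles A `pv_cycles` (provides f0 = 1 / mean period).
#' @param config A [feature_config()].
#' @return dB value (scalar), possibly with attribute `capped`.
#' @export
snr_k <- function(gaw, cycles, config = feature_config()) {
  if (n_cycles(cycles) < 10L) {
    abort("need at least 10 cycles to estimate SNR_K",
          class = "phonovibe_error")
  }
  fs <- cycles$fs
  n <- length(gaw)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  X <- fft((gaw - mean(gaw)) * w)
  pow <- Mod(X[2:(floor(n / 2) + 1L)])^2       # bins 1..n/2 (cycles/signal)
  bin_hz <- fs / n

  band_set <- function(f0, K) {
    harm_bins <- integer(0)
    for (k in seq_len(K)) {
      centre0 <- round(k * f0 / bin_hz)
      lo <- max(1L, centre0 - 2L); hi <- min(length(pow), centre0 + 2L)
      centre <- lo + which.max(pow[lo:hi]) - 1L
      harm_bins <- c(harm_bins,
                     max(1L, centre - 1L):min(length(pow), centre + 1L))
    }
    unique(harm_bins)
  }

  # Fundamental from the spectrum itself: broadband noise can corrupt
  # time-domain cycle boundaries, so the strongest bin in the plausible
  # f0 band seeds a subharmonic comb check (the strongest partial may be a
  # higher harmonic); the cycle-based estimate is only a fallback.
  f_lo <- max(config$f0_bounds[1], 2 * bin_hz)
  f_hi <- min(config$f0_bounds[2], fs / 2 - bin_hz)
  search <- max(1L, floor(f_lo / bin_hz)):ceiling(f_hi / bin_hz)
  f_max <- search[which.max(pow[search])] * bin_hz
  if (!is.finite(f_max) || f_max <= 0) {
    f_max <- fs / mean(diff(refine_boundaries(
      if (cycles$mode == "minimum") -gaw else gaw, cycles)))
  }
  cand <- f_max / seq_len(4L)
  cand <- cand[cand >= 0.8 * f_lo]
  cand_energy <- vapply(cand, function(f) {
    K <- max(1L, min(config$snr_max_harmonics, floor((fs / 2 - f / 2) / f)))
    sum(pow[band_set(f, K)])
  }, numeric(1))
  f0 <- max(cand[cand_energy >= 0.95 * max(cand_energy)])

  K <- min(config$snr_max_harmonics, floor((fs / 2 - f0 / 2) / f0))
  if (K < 1L) abort("f0 too close to Nyquist", class = "phonovibe_error")
  harm_bins <- band_set(f0, K)
  # residual over the whole spectrum above 0.5 f0 (bins below carry the
  # smeared remnant of mean removal); broadband noise outside the harmonic
  # search range is noise all the same
  range_bins <- max(1L, floor(0.5 * f0 / bin_hz)):length(pow)
  noise_bins <- setdiff(range_bins, harm_bins)
  floor_est <- if (length(noise_bins) > 0L) mean(pow[noise_bins]) else 0

  e_tot <- sum(pow[range_bins])
  e_band <- sum(pow[intersect(harm_bins, range_bins)])
  nb <- length(intersect(harm_bins, range_bins))
  e_harm <- max(e_band - nb * floor_est, 0)
  e_res <- e_tot - e_band + nb * floor_est
  capped <- FALSE
  if (e_res <= 0 || e_harm / e_res > 10^(config$snr_cap / 10)) {
    val <- config$snr_cap
    capped <- TRUE
  } else if (e_harm == 0) {
    val <- -config$snr_cap
  } else {
    val <- 10 * log10(e_harm / e_res)
  }
  attr(val, "capped") <- capped
  val
}

#' Left-right symmetry parameters from the partial GAWs
#'
#' Computes, per cycle:
#' * `PhA` (minimum-based cycles): signed lag of the right peak instant
#'   relative to the left, in cycle fractions, wrapped to (-0.5, 0.5];
#'   `PhAI` uses its absolute value. Peak instants are sub-frame refined.
#' * `AmS` (signed) and `AmSI` (index): per-cycle peak-amplitude asymmetry
#'   `(A_R - A_L)/max(A_R, A_L)` and `min(A_L, A_R)/max(A_L, A_R)`;
#' * `DyRS`/`DyRSI`: the same on the per-cycle dynamic range (max - min);
#' * `SpA`/`SpAI`: the same on the per-cycle energy;
#' * `WaSI`: per-cycle zero-lag normalized cross-correlation (Pearson) of
#'   the two waveforms.
#' Cycles that are flat on either side are skipped.
#'
#' @param gaw_left,gaw_right Partial GAW vectors sharing the frame clock.
#' @param max_cycles,min_cycles `pv_cycles` in maximum and minimum mode
#'   (minimum-based cycles are required by the phase-shift parameters; pass
#'   `NULL` to obtain `NA` for those).
#' @return Named numeric vector of the 18 symmetry parameters.
#' @export
symmetry_features <- function(gaw_left, gaw_right, max_cycles,
                              min_cycles = NULL) {
  stopifnot(length(gaw_left) == length(gaw_right))
  out <- setNames(rep(NA_real_, 18L), c(
    "PhA_Mean", "PhA_Std", "PhAI_Mean", "PhAI_Std",
    "AmS_Mean", "AmS_Std", "AmSI_Mean", "AmSI_Std",
    "DyRS_Mean", "DyRS_Std", "DyRSI_Mean", "DyRSI_Std",
    "SpA_Mean", "SpA_Std", "SpAI_Mean", "SpAI_Std",
    "WaSI_Mean", "WaSI_Std"))

  pair_stats <- function(l, r) {
    mx <- pmax(l, r)
    keep <- mx > 0
    list(signed = (r[keep] - l[keep]) / mx[keep],
         index = pmin(l[keep], r[keep]) / mx[keep])
  }

  b <- max_cycles$boundaries
  K <- n_cycles(max_cycles)
  A_L <- A_R <- R_L <- R_R <- E_L <- E_R <- wasi <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    il <- b[k]:(b[k + 1L] - 1L)
    l <- gaw_left[il]; r <- gaw_right[il]
    if (diff(range(l)) == 0 || diff(range(r)) == 0) next
    A_L[k] <- max(l); A_R[k] <- max(r)
    R_L[k] <- diff(range(l)); R_R[k] <- diff(range(r))
    E_L[k] <- sum(l^2); E_R[k] <- sum(r^2)
    wasi[k] <- cor(l, r)
  }
  ok <- !is.na(A_L)
  if (any(ok)) {
    am <- pair_stats(A_L[ok], A_R[ok])
    dy <- pair_stats(R_L[ok], R_R[ok])
    sp <- pair_stats(E_L[ok], E_R[ok])
    out["AmS_Mean"] <- mean(am$signed); out["AmS_Std"] <- sd(am$signed)
    out["AmSI_Mean"] <- mean(am$index); out["AmSI_Std"] <- sd(am$index)
    out["DyRS_Mean"] <- mean(dy$signed); out["DyRS_Std"] <- sd(dy$signed)
    out["DyRSI_Mean"] <- mean(dy$index); out["DyRSI_Std"] <- sd(dy$index)
    out["SpA_Mean"] <- mean(sp$signed); out["SpA_Std"] <- sd(sp$signed)
    out["SpAI_Mean"] <- mean(sp$index); out["SpAI_Std"] <- sd(sp$index)
    out["WaSI_Mean"] <- mean(wasi[ok]); out["WaSI_Std"] <- sd(wasi[ok])
  }

  if (!is.null(min_cycles)) {
    bm <- min_cycles$boundaries
    lags <- c()
    for (k in seq_len(n_cycles(min_cycles))) {
      il <- bm[k]:(bm[k + 1L] - 1L)
      l <- gaw_left[il]; r <- gaw_right[il]
      if (diff(range(l)) == 0 || diff(range(r)) == 0) next
      pl <- il[1] - 1L + which.max(l)
      pr <- il[1] - 1L + which.max(r)
      tl <- refine_extremum(gaw_left, pl, il[1], il[length(il)], min(l))
      tr <- refine_extremum(gaw_right, pr, il[1], il[length(il)], min(r))
      lag <- (tr - tl) / length(il)
      lags <- c(lags, lag - ceiling(lag - 0.5))
    }
    if (length(lags) > 0L) {
      out["PhA_Mean"] <- mean(lags); out["PhA_Std"] <- sd(lags)
      out["PhAI_Mean"] <- mean(abs(lags)); out["PhAI_Std"] <- sd(abs(lags))
    }
  }
  out
}

#' Compute the full 91-parameter vector of a recording
#'
#' Runs cycle detection on `gaw_total` in both extremum modes, transfers the
#' boundaries to the partial GAWs and the PVG, and evaluates every registry
#' entry: perturbation, quotient and noise parameters on `GAW_T`, symmetry
#' parameters on `GAW_L`/`GAW_R`, and contour-angle parameters on the PVG.
#' Parameters whose preconditions fail (e.g. 11-point quotients with fewer
#' than 12 cycles) are `NA`; the function errors only when no cycles can be
#' detected at all.
#'
#' @param recording A `pv_recording`.
#' @param registry The parameter registry (defaults to
#'   [parameter_registry()]).
#' @param config A [feature_config()].
#' @return Named numeric vector of length `nrow(registry)` in registry
#'   order.
#' @export
#' @examples
#' rec <- generate_recording(recording_spec(f0 = 100, n_frames = 600))
#' v <- compute_feature_vector(rec)
#' v[c("Jit_pct", "MShim", "PhA_Mean")]
compute_feature_vector <- function(recording,
                                   registry = parameter_registry(),
                                   config = feature_config()) {
  gaw <- recording$gaw_total
  gaw_s <- smooth_for_detection(gaw, config$detect_smooth)
  max_cycles <- detect_cycles(gaw_s, recording$fs, "maximum",
                              config$prominence_frac, config$f0_bounds)
  min_cycles <- tryCatch(
    detect_cycles(gaw_s, recording$fs, "minimum",
                  config$prominence_frac, config$f0_bounds),
    phonovibe_error = function(e) NULL)

  vec <- setNames(rep(NA_real_, nrow(registry)), registry$name)
  series <- cycle_series(gaw, max_cycles, config)
  pert <- suppressWarnings(perturbation_features(series))
  vec[names(pert)] <- pert
  qt <- suppressWarnings(quotients(series))
  vec[names(qt)] <- qt
  if (n_cycles(max_cycles) >= 10L) {
    vec["SNR_K_Mean"] <- as.numeric(snr_k(gaw, max_cycles, config))
  }
  sym <- symmetry_features(recording$gaw_left, recording$gaw_right,
                           transfer_cycles(max_cycles,
                                           length(recording$gaw_left)),
                           if (!is.null(min_cycles)) {
                             transfer_cycles(min_cycles,
                                             length(recording$gaw_left))
                           })
  vec[names(sym)] <- sym

  pvg <- build_pvg(recording)
  pvg_cycles <- transfer_cycles(max_cycles, ncol(pvg$disp_left))
  ang <- tryCatch({
    edges <- opening_closing_edges(pvg, pvg_cycles, config$pvg_eps_frac)
    angles <- contour_angles(edges, pvg_cycles, nrow(pvg$disp_left))
    c(angle_means(angles), angle_symmetry(angles))
  }, phonovibe_error = function(e) NULL)
  if (!is.null(ang)) vec[names(ang)] <- ang

  vec[registry$name]
}

#' Extract a feature table from a cohort of recordings
#'
#' Applies [compute_feature_vector()] to every recording and binds the
#' results with the cohort metadata into a subjects x parameters tibble, the
#' input format of the pruning and selection stages.
#'
#' @param cohort Tibble from [generate_cohort()] (needs a `recording` list
#'   column), or a bare list of `pv_recording` objects.
#' @param registry,config Passed to [compute_feature_vector()].
#' @return Feature-table tibble: `subject_id`, `group` (if available), then
#'   one column per registry parameter.
#' @export
extract_features <- function(cohort, registry = parameter_registry(),
                             config = feature_config()) {
  if (is.data.frame(cohort)) {
    recs <- cohort$recording
    meta <- cohort[intersect(c("subject_id", "group"), names(cohort))]
  } else {
    recs <- cohort
    meta <- tibble(subject_id = sprintf("S%04d", seq_along(recs)))
  }
  feats <- map(recs, compute_feature_vector, registry = registry,
               config = config)
  bind_cols(meta, as_tibble(do.call(rbind, feats)))
}

#' @importFrom dplyr bind_cols
NULL
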