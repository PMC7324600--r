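#' Detect extremum-based oscillation cycles on a GAW signal
#'
#' Cycle boundaries are sufficiently distinct local extrema of the requested
#' kind: maxima (each cycle runs from one distinct local maximum to just
#' before the next) or minima. "Sufficiently distinct" means topographic
#' prominence of at least `prominence_frac` times the signal range; candidate
#' extrema closer together than one period at `f0_bounds[2]` are thinned by
#' dropping the weaker (less prominent) one, and gaps longer than one period
#' at `f0_bounds[1]` are left as-is (they simply produce long cycles that the
#' plausibility check flags). Detection is invariant to affine rescaling of
#' the signal. Boundaries are 1-based frame indices; cycle `k` spans
#' `[boundary_k, boundary_{k+1})` and the trailing partial cycle is
#' discarded.
#'
#' @param gaw Numeric signal vector (finite, length >= 3).
#' @param fs Sampling rate in Hz.
#' @param mode `"maximum"` or `"minimum"`.
#' @param prominence_frac Minimum prominence as a fraction of the signal
#'   range; default 0.10.
#' @param f0_bounds Plausible fundamental-frequency range in Hz; default
#'   `c(50, 1000)`.
#' @return A `pv_cycles` object: list with `mode`, `boundaries` (strictly
#'   increasing integer frame indices), `fs`.
#' @export
#' @examples
#' x <- sin(2 * pi * 100 * (0:999) / 4000)
#' cyc <- detect_cycles(x, fs = 4000)
#' n_cycles(cyc)
detect_cycles <- function(gaw, fs, mode = c("maximum", "minimum"),
                          prominence_frac = 0.10, f0_bounds = c(50, 1000)) {
  mode <- match.arg(mode)
  if (length(gaw) < 3L || !all(is.finite(gaw))) {
    abort("`gaw` must be a finite signal of length >= 3",
          class = "phonovibe_error")
  }
  x <- if (mode == "minimum") -gaw else gaw
  rng <- diff(range(x))
  if (rng == 0) abort("no cycles detected", class = "phonovibe_error")

  cand <- local_maxima(x)
  prom <- peak_prominence(x, cand)
  keep <- prom >= prominence_frac * rng
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) >= 2L) {
    min_gap <- fs / f0_bounds[2]
    repeat {
      gaps <- diff(cand)
      viol <- which(gaps < min_gap)
      if (length(viol) == 0L) break
      i <- viol[1]
      drop <- if (prom[i] < prom[i + 1L]) i else i + 1L
      cand <- cand[-drop]; prom <- prom[-drop]
      if (length(cand) < 2L) break
    }
  }
  if (length(cand) < 2L) {
    abort("no cycles detected", class = "phonovibe_error")
  }
  new_cycles(mode, cand, fs, length(gaw))
}

new_cycles <- function(mode, boundaries, fs, n_frames) {
  boundaries <- as.integer(boundaries)
  if (length(boundaries) < 2L || any(diff(boundaries) <= 0L)) {
    abort("cycle boundaries must be >= 2 strictly increasing indices",
          class = "phonovibe_error")
  }
  if (boundaries[1] < 1L || boundaries[length(boundaries)] > n_frames) {
    abort("cycle boundary outside the signal", class = "phonovibe_error")
  }
  structure(list(mode = mode, boundaries = boundaries, fs = fs,
                 n_frames = as.integer(n_frames)),
            class = "pv_cycles")
}

#' @export
print.pv_cycles <- function(x, ...) {
  cat(sprintf("<pv_cycles> %s-based, %d cycles, fs = %g Hz\n",
              x$mode, n_cycles(x), x$fs))
  invisible(x)
}

#' Number of complete cycles in a cycle set
#' @param cycles A `pv_cycles` object.
#' @return Integer count (boundaries minus one).
#' @export
n_cycles <- function(cycles) length(cycles$boundaries) - 1L

# Indices of local maxima; runs of equal values (plateaus) contribute the
# centre sample of the run.
local_maxima <- function(x) {
  n <- length(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == k || r$values[i + 1L] < r$values[i]
    if (left_ok && right_ok && !(i == 1L && i == k)) {
      if (i == 1L || i == k) next  # edge plateaus are not interior maxima
      out <- c(out, as.integer(floor((starts[i] + ends[i]) / 2)))
    }
  }
  out
}

# Topographic prominence of peaks at indices `peaks` in signal `x`:
# height above the higher of the two lowest valleys separating the peak from
# the nearest higher terrain (or the signal edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p)]
    higher_l <- which(left > h)
    lo_l <- min(left[(max(higher_l, 0L) + 1L):p])
    right <- x[p:length(x)]
    higher_r <- which(right > h)
    hi_r <- if (length(higher_r) > 0L) min(higher_r) else length(right)
    lo_r <- min(right[1:hi_r])
    h - max(lo_l, lo_r)
  }, numeric(1))
}

#' Transfer cycle boundaries to another signal of the same frame clock
#'
#' The GAW_T cycle boundaries are conferred unchanged to GAW_L, GAW_R and
#' the PVG; only the target length is validated.
#'
#' @param cycles A `pv_cycles` object.
#' @param target_length Length (frames) of the target signal.
#' @return A `pv_cycles` with identical boundaries.
#' @export
transfer_cycles <- function(cycles, target_length) {
  if (max(cycles$boundaries) > target_length) {
    abort("cycle boundary beyond target signal length",
          class = "phonovibe_error")
  }
  new_cycles(cycles$mode, cycles$boundaries, cycles$fs,
             as.integer(target_length))
}

#' Serialize / deserialize a cycle set to JSON
#' @param cycles A `pv_cycles` object.
#' @param path File path.
#' @return `cycles_to_json` returns `path` invisibly; `cycles_from_json`
#'   returns a `pv_cycles`. Boundaries are stored as 1-based frame indices.
#' @export
cycles_to_json <- function(cycles, path) {
  jsonlite::write_json(
    list(mode = cycles$mode, fs = cycles$fs, n_frames = cycles$n_frames,
         index_base = 1L, boundaries = cycles$boundaries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cycles_to_json
#' @export
cycles_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_cycles(j$mode, j$boundaries, j$fs, j$n_frames)
}
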