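#' Build a Phonovibrogram from a recording
#'
#' The Phonovibrogram (PVG) depicts the per-position displacement of both
#' vocal-fold contours from the glottal midline over time in one image. Here
#' it is the identity mapping of the generator's displacement matrices into
#' the PVG coordinate convention: row 1 = posterior end, last row = anterior
#' end, columns = frames.
#'
#' @param recording A `pv_recording` with displacement matrices.
#' @return A `pv_pvg`: list with `disp_left`, `disp_right`
#'   (`n_positions x n_frames`, nonnegative), `fs`.
#' @export
build_pvg <- function(recording) {
  if (is.null(recording$disp_left) || is.null(recording$disp_right)) {
    abort("recording carries no displacement matrices",
          class = "phonovibe_error")
  }
  stopifnot(all(dim(recording$disp_left) == dim(recording$disp_right)))
  structure(list(disp_left = recording$disp_left,
                 disp_right = recording$disp_right, fs = recording$fs),
            class = "pv_pvg")
}

#' Render a PVG as a single image matrix
#'
#' Stacks the left fold (flipped so its anterior end meets the image centre)
#' above the right fold, giving the conventional `2P x n_frames` PVG image.
#'
#' @param pvg A `pv_pvg`.
#' @return Numeric matrix `2 * n_positions x n_frames`.
#' @export
pvg_image <- function(pvg) {
  rbind(pvg$disp_left[rev(seq_len(nrow(pvg$disp_left))), , drop = FALSE],
        pvg$disp_right)
}

#' Export a PVG image as 16-bit grayscale TIFF
#'
#' Displacements are scaled to the full 16-bit range; the scale factor is
#' returned invisibly so values can be recovered up to quantization.
#'
#' @param pvg A `pv_pvg`.
#' @param path Output file path.
#' @return Invisibly, the scale factor used.
#' @export
write_pvg_tiff <- function(pvg, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the `tiff` package is required for TIFF export",
          class = "phonovibe_error")
  }
  img <- pvg_image(pvg)
  sc <- max(img)
  if (sc == 0) sc <- 1
  tiff::writeTIFF(img / sc, path, bits.per.sample = 16L)
  invisible(sc)
}

#' Per-cycle opening and closing edges of the PVG
#'
#' For each cycle, fold and contour position, frames are classified open
#' when the displacement exceeds `eps_frac` times that position's maximum
#' excursion. In minimum-based cycles (closed at both ends) the opening
#' edge is the first open frame and the closing edge the last. In
#' maximum-based cycles - which start at the fully open peak, close in the
#' middle and reopen towards the next peak - the closing edge is the last
#' frame of the first open run and the opening edge the first frame of the
#' last open run. Positions whose overall excursion is negligible (below
#' 1e-3 of the fold-wide maximum) or that never open in a cycle are marked
#' absent. Cycles in which every position is absent are skipped with a
#' warning.
#'
#' @param pvg A `pv_pvg`.
#' @param cycles A `pv_cycles` on the same frame clock.
#' @param eps_frac Relative displacement threshold; default 0.05.
#' @return A `pv_edges`: list with `onset` and `offset`
#'   (`n_positions x 2 x n_cycles` arrays, folds ordered left, right; `NA`
#'   marks absent positions), `boundaries`.
#' @export
opening_closing_edges <- function(pvg, cycles, eps_frac = 0.05) {
  if (n_cycles(cycles) < 1L) {
    abort("need at least one full cycle", class = "phonovibe_error")
  }
  P <- nrow(pvg$disp_left)
  K <- n_cycles(cycles)
  b <- cycles$boundaries
  onset <- offset <- array(NA_real_, dim = c(P, 2L, K))
  folds <- list(pvg$disp_left, pvg$disp_right)
  for (f in 1:2) {
    D <- folds[[f]]
    pos_max <- apply(D, 1, max)
    absent <- pos_max < 1e-3 * max(pos_max)
    thr <- eps_frac * pos_max
    max_mode <- cycles$mode == "maximum"
    for (k in seq_len(K)) {
      cols <- b[k]:(b[k + 1L] - 1L)
      seg <- D[, cols, drop = FALSE]
      for (p in seq_len(P)) {
        if (absent[p]) next
        open <- seg[p, ] > thr[p]
        if (!any(open)) next
        if (max_mode) {
          if (all(open)) next                # never closes in this cycle
          r <- rle(open)
          ends <- cumsum(r$lengths)
          first_run <- which(r$values)[1]
          last_run <- tail(which(r$values), 1)
          offset[p, f, k] <- ends[first_run]
          onset[p, f, k] <- ends[last_run] - r$lengths[last_run] + 1L
        } else {
          onset[p, f, k] <- which(open)[1]
          offset[p, f, k] <- tail(which(open), 1)
        }
      }
    }
  }
  empty <- vapply(seq_len(K), function(k) all(is.na(onset[, , k])),
                  logical(1))
  if (any(empty)) {
    warn(sprintf("%d cycle(s) with no supra-threshold positions skipped",
                 sum(empty)))
  }
  if (all(empty)) {
    abort("no cycle has supra-threshold positions", class = "phonovibe_error")
  }
  structure(list(onset = onset, offset = offset, boundaries = b,
                 skipped = empty),
            class = "pv_edges")
}

# region definitions: posterior half = rows 1..P/2, anterior = rows
# (P/2 + 1)..P; the tip-adjacent end of each half is the coordinate origin
# and the mid-fold end is 1 (half-fold units).
region_rows <- function(P) {
  list(A = (P %/% 2 + 1L):P, P = 1L:(P %/% 2))
}

region_u <- function(P) {
  list(A = (P - ((P %/% 2 + 1L):P)) / (P / 2),
       P = ((1L:(P %/% 2)) - 1L) / (P / 2))
}

#' Contour angles from PVG opening/closing edges
#'
#' For each cycle, fold (L/R), phase (O = opening via onsets, C = closing
#' via offsets) and fold half (A = anterior, P = posterior), the edge frame
#' is regressed on contour position by least squares. Coordinates are
#' normalized - position in half-fold units running from the fold tip
#' towards the mid-fold, time in cycle lengths - and the angle is
#' `atan2(delta_position, delta_time)` in degrees, so zero time spread
#' (simultaneous opening/closing) gives exactly 90 degrees and an opening
#' sweeping tip-to-mid over a quarter cycle gives `atan2(1, 0.25)` = 75.96
#' degrees. A region needs at least 3 valid positions in a cycle, otherwise
#' that cycle's angle is absent.
#'
#' @param edges A `pv_edges` from [opening_closing_edges()].
#' @param cycles The matching `pv_cycles`.
#' @param n_positions Contour positions per fold.
#' @return A `pv_angles`: array `[n_cycles, 2 folds, 4 regions]` with
#'   dimnames `fold = c("L", "R")`, `region = c("OA", "OP", "CA", "CP")`,
#'   angles in degrees.
#' @export
contour_angles <- function(edges, cycles, n_positions) {
  valid_k <- which(!edges$skipped)
  if (length(valid_k) < 3L) {
    abort("need edges from at least 3 cycles", class = "phonovibe_error")
  }
  P <- n_positions
  K <- dim(edges$onset)[3]
  rows <- region_rows(P)
  us <- region_u(P)
  b <- edges$boundaries
  regions <- c("OA", "OP", "CA", "CP")
  ang <- array(NA_real_, dim = c(K, 2L, 4L),
               dimnames = list(NULL, fold = c("L", "R"), region = regions))
  for (k in seq_len(K)) {
    if (edges$skipped[k]) next
    cyc_len <- b[k + 1L] - b[k]
    for (f in 1:2) {
      for (ri in seq_along(regions)) {
        rg <- regions[ri]
        half <- substr(rg, 2, 2)
        src <- if (substr(rg, 1, 1) == "O") edges$onset else edges$offset
        tvals <- src[rows[[half]], f, k]
        u <- us[[half]]
        ok <- !is.na(tvals)
        if (sum(ok) < 3L) next
        t_frac <- (tvals[ok] - 1) / cyc_len
        uu <- u[ok]
        slope <- if (var(uu) == 0) 0 else
          sum((uu - mean(uu)) * (t_frac - mean(t_frac))) / sum((uu - mean(uu))^2)
        ang[k, f, ri] <- atan2(1, slope) * 180 / pi
      }
    }
  }
  structure(ang, class = "pv_angles")
}

#' Per-parameter means and stds of contour angles
#'
#' @param angles A `pv_angles` array.
#' @return Named vector `CA_<fold>_<region>_<Mean|Std>` (16 entries).
#' @export
angle_means <- function(angles) {
  out <- c()
  for (f in c("L", "R")) {
    for (rg in c("OA", "OP", "CA", "CP")) {
      v <- angles[, f, rg]
      v <- v[!is.na(v)]
      out[sprintf("CA_%s_%s_Mean", f, rg)] <-
        if (length(v) > 0) mean(v) else NA_real_
      out[sprintf("CA_%s_%s_Std", f, rg)] <-
        if (length(v) > 1) sd(v) else NA_real_
    }
  }
  out
}

#' Contour-angle symmetry parameters
#'
#' Per cycle and region X: the signed ratio `CAS^X = CA_L / CA_R` and the
#' bounded index `CASI^X = min(CA_L, CA_R) / max(CA_L, CA_R)`; means and
#' standard deviations are taken across cycles. Cycles missing either fold's
#' angle are excluded for that region. Swapping the folds inverts CAS and
#' leaves CASI unchanged.
#'
#' @param angles A `pv_angles` array.
#' @return Named vector `CAS_<region>_<Mean|Std>`, `CASI_<region>_<Mean|Std>`
#'   (16 entries).
#' @export
angle_symmetry <- function(angles) {
  out <- c()
  for (rg in c("OA", "OP", "CA", "CP")) {
    l <- angles[, "L", rg]; r <- angles[, "R", rg]
    ok <- !is.na(l) & !is.na(r) & r != 0
    cas <- l[ok] / r[ok]
    casi <- pmin(l[ok], r[ok]) / pmax(l[ok], r[ok])
    out[sprintf("CAS_%s_Mean", rg)] <- if (any(ok)) mean(cas) else NA_real_
    out[sprintf("CAS_%s_Std", rg)] <- if (sum(ok) > 1) sd(cas) else NA_real_
    out[sprintf("CASI_%s_Mean", rg)] <- if (any(ok)) mean(casi) else NA_real_
    out[sprintf("CASI_%s_Std", rg)] <- if (sum(ok) > 1) sd(casi) else NA_real_
  }
  out
}
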