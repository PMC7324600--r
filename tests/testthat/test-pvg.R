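test_that("the PVG image mirrors symmetric folds and keeps zeros", {
  rec <- make_rec(f0 = 100, n_cycles = 8)
  pvg <- build_pvg(rec)
  img <- pvg_image(pvg)
  P <- nrow(pvg$disp_left)
  expect_equal(img[1:P, ], pvg$disp_left[P:1, ])
  expect_equal(img[(P + 1):(2 * P), ], pvg$disp_right)

  zero <- rec
  zero$disp_left[] <- 0
  zero$disp_right[] <- 0
  expect_true(all(pvg_image(build_pvg(zero)) == 0))

  norec <- rec
  norec$disp_left <- NULL
  expect_error(build_pvg(norec), "displacement")
})

test_that("PVG TIFF export round-trips within quantization tolerance", {
  skip_if_not_installed("tiff")
  rec <- make_rec(f0 = 120, n_cycles = 5)
  pvg <- build_pvg(rec)
  f <- tempfile(fileext = ".tif")
  sc <- write_pvg_tiff(pvg, f)
  back <- tiff::readTIFF(f) * sc
  expect_equal(dim(back), dim(pvg_image(pvg)))
  expect_lt(max(abs(back - pvg_image(pvg))), sc / 2^15)
  unlink(f)
})

test_that("edges detect simultaneous and linearly delayed opening", {
  rec <- make_rec(f0 = 100, n_cycles = 10)
  cyc <- transfer_cycles(detect_cycles(rec$gaw_total, rec$fs),
                         ncol(rec$disp_left))
  ed <- opening_closing_edges(build_pvg(rec), cyc)
  on1 <- ed$onset[, 1, 2]
  expect_lte(diff(range(on1, na.rm = TRUE)), 1)

  # anterior-to-mid delay: onset spread along the fold ~ delay in frames
  d <- 0.12
  rec2 <- make_rec(f0 = 100, n_cycles = 10, ap_delay_open = d,
                   pulse_left = pulse_shape(open_quotient = 0.5))
  cyc2 <- transfer_cycles(detect_cycles(rec2$gaw_total, rec2$fs),
                          ncol(rec2$disp_left))
  ed2 <- opening_closing_edges(build_pvg(rec2), cyc2)
  on2 <- ed2$onset[, 1, 2]
  expect_equal(diff(range(on2, na.rm = TRUE)), d * 40, tolerance = 3)
})

test_that("contour angles follow the stated normalization exactly", {
  # constructed edge geometry, no generator involved
  P <- 16L; K <- 4L; cyc_len <- 100L
  onset <- offset <- array(NA_real_, dim = c(P, 2L, K))
  u <- c((1:(P / 2) - 1) / (P / 2),          # posterior, tip -> mid
         (P - ((P / 2 + 1):P)) / (P / 2))    # anterior, tip -> mid
  for (k in seq_len(K)) {
    onset[, 1, k] <- 1 + 0.25 * cyc_len * u  # sweep over 25% of the cycle
    onset[, 2, k] <- 10                      # simultaneous
    offset[, 1, k] <- 60
    offset[, 2, k] <- 60 + 0.1 * cyc_len * u
  }
  edges <- structure(list(onset = onset, offset = offset,
                          boundaries = seq(1L, by = cyc_len,
                                           length.out = K + 1L),
                          skipped = rep(FALSE, K)),
                     class = "pv_edges")
  cycles <- detect_cycles(rep(cos(2 * pi * (0:((K + 1) * cyc_len)) /
                                    cyc_len), 1), fs = 4000,
                          f0_bounds = c(10, 1000))
  ang <- contour_angles(edges, cycles, P)
  expect_equal(ang[1, "L", "OA"], atan2(1, 0.25) * 180 / pi,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ang[1, "R", "OA"], 90, ignore_attr = TRUE)
  expect_equal(ang[1, "R", "OP"], 90, ignore_attr = TRUE)
  expect_equal(ang[1, "L", "CA"], 90, ignore_attr = TRUE)
  expect_equal(ang[1, "R", "CP"], atan2(1, 0.1) * 180 / pi,
               tolerance = 1e-6, ignore_attr = TRUE)
  # identical cycles: zero spread
  m <- angle_means(ang)
  expect_equal(m[["CA_L_OA_Std"]], 0)
})

test_that("angle symmetry ratios follow direct arithmetic and swap rules", {
  K <- 5L
  ang <- array(NA_real_, dim = c(K, 2L, 4L),
               dimnames = list(NULL, fold = c("L", "R"),
                               region = c("OA", "OP", "CA", "CP")))
  ang[, "L", ] <- 100
  ang[, "R", ] <- 80
  s <- angle_symmetry(structure(ang, class = "pv_angles"))
  expect_equal(s[["CAS_OA_Mean"]], 1.25)
  expect_equal(s[["CASI_OA_Mean"]], 0.8)
  expect_equal(s[["CAS_CA_Std"]], 0)

  swapped <- ang
  swapped[, "L", ] <- 80
  swapped[, "R", ] <- 100
  s2 <- angle_symmetry(structure(swapped, class = "pv_angles"))
  expect_equal(s2[["CAS_OA_Mean"]], 1 / s[["CAS_OA_Mean"]])
  expect_equal(s2[["CASI_OA_Mean"]], s[["CASI_OA_Mean"]])
})

test_that("CASI is bounded by 1 with equality iff angles match", {
  rec <- make_rec(f0 = 110, n_cycles = 12, ap_delay_open = 0.06,
                  jitter_pct_target = 2, seed = 8,
                  pulse_left = pulse_shape(open_quotient = 0.5))
  v <- compute_feature_vector(rec)
  for (rg in c("OA", "OP", "CA", "CP")) {
    expect_lte(v[[sprintf("CASI_%s_Mean", rg)]], 1)
  }
  sym <- compute_feature_vector(make_rec(f0 = 110, n_cycles = 12))
  expect_equal(sym[["CASI_OA_Mean"]], 1)
})

test_that("angles are invariant to displacement scaling", {
  rec <- make_rec(f0 = 100, n_cycles = 10, ap_delay_open = 0.1,
                  pulse_left = pulse_shape(open_quotient = 0.5))
  sc <- rec
  sc$disp_left <- 5 * sc$disp_left
  sc$disp_right <- 5 * sc$disp_right
  cyc <- transfer_cycles(detect_cycles(rec$gaw_total, rec$fs),
                         ncol(rec$disp_left))
  a1 <- contour_angles(opening_closing_edges(build_pvg(rec), cyc), cyc,
                       nrow(rec$disp_left))
  a2 <- contour_angles(opening_closing_edges(build_pvg(sc), cyc), cyc,
                       nrow(rec$disp_left))
  expect_equal(unclass(a1), unclass(a2))
})

test_that("anterior-posterior delays map monotonically onto contour angles", {
  sweep <- vapply(c(0, 0.04, 0.08, 0.12, 0.16), function(d) {
    rec <- make_rec(f0 = 100, n_cycles = 10, ap_delay_open = d,
                    pulse_left = pulse_shape(open_quotient = 0.5))
    compute_feature_vector(rec)[["CA_L_OA_Mean"]]
  }, numeric(1))
  expect_equal(sweep[1], 90)
  expect_true(all(diff(sweep) < 0))
})
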