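#' The 91-parameter vibration-parameter registry
#'
#' Every quantitative parameter the package extracts from a glottal recording
#' is declared here, split into three families: 41 parameters computed from
#' the total glottal area waveform (`GAW_T`), 18 left-right symmetry
#' parameters computed from the partial waveforms `GAW_L`/`GAW_R`, and 32
#' Phonovibrogram (PVG) contour-angle parameters. The registry is data-driven:
#' downstream code (feature extraction, pruning, selection) consumes the
#' registry rather than hard-coded parameter lists, so a definition can be
#' amended in one place.
#'
#' Almost all parameters are computed on maximum-based oscillation cycles;
#' the four phase-shift parameters (`PhA_Mean`, `PhA_Std`, `PhAI_Mean`,
#' `PhAI_Std`) require minimum-based cycles because the oscillation peak must
#' lie in the cycle interior.
#'
#' `domain_lo`/`domain_hi` give each parameter's valid range; they are used to
#' truncate Gaussian draws in [sample_feature_table()].
#'
#' @return A tibble with one row per parameter: `name` (syntactic column
#'   key), `label` (display form), `family` (`"GAW_T"`, `"GAW_symmetry"`,
#'   `"PVG"`), `signal_type` (`"GAW"` or `"PVG"`, as used by subset
#'   screens), `statistic` (`"Mean"`, `"Std"` or `"scalar"`), `cycle_mode`,
#'   `units`, `domain_lo`, `domain_hi`, `description`.
#' @export
#' @examples
#' reg <- parameter_registry()
#' table(reg$family)
parameter_registry <- function() {
  row <- function(name, label, family, statistic, cycle_mode, units,
                  lo, hi, description) {
    tibble(
      name = name, label = label, family = family,
      signal_type = if (family == "PVG") "PVG" else "GAW",
      statistic = statistic, cycle_mode = cycle_mode, units = units,
      domain_lo = lo, domain_hi = hi, description = description
    )
  }
  per <- function(name, label, units, description) {
    # perturbation magnitudes: nonnegative
    row(name, label, "GAW_T", "scalar", "maximum", units, 0, Inf, description)
  }

  gaw <- bind_rows(
    row("F0_Mean", "F0 [Mean]", "GAW_T", "Mean", "maximum", "Hz", 0, Inf,
        "Mean fundamental frequency, from per-cycle periods"),
    row("F0_Std", "F0 [Std]", "GAW_T", "Std", "maximum", "Hz", 0, Inf,
        "Standard deviation of per-cycle fundamental frequency"),
    per("TP_Mean", "TP [Mean]", "s",
        "Mean absolute cycle-to-cycle period difference"),
    per("TP_Std", "TP [Std]", "s",
        "Std of absolute cycle-to-cycle period differences"),
    per("Jit_pct", "Jit(%)", "%",
        "Relative jitter: 100 * mean|T_k - T_{k-1}| / mean T"),
    per("RAP_K", "RAP_K", "%",
        "3-point relative average perturbation of the period"),
    per("PPQ3", "PPQ3", "%", "3-point period perturbation quotient"),
    per("PPQ5", "PPQ5", "%", "5-point period perturbation quotient"),
    per("PPQ11", "PPQ11", "%", "11-point period perturbation quotient"),
    per("PPF", "PPF", "%",
        "Period perturbation factor over consecutive differences"),
    per("AP_Mean", "AP [Mean]", "a.u.",
        "Mean absolute cycle-to-cycle amplitude difference"),
    per("AP_Std", "AP [Std]", "a.u.",
        "Std of absolute cycle-to-cycle amplitude differences"),
    per("MShim", "MShim", "dB",
        "Mean absolute dB shimmer: mean|20 log10(A_{k+1}/A_k)|"),
    per("APQ3", "APQ3", "%", "3-point amplitude perturbation quotient"),
    per("APQ5", "APQ5", "%", "5-point amplitude perturbation quotient"),
    per("APQ11", "APQ11", "%", "11-point amplitude perturbation quotient"),
    per("APF", "APF", "%",
        "Amplitude perturbation factor over consecutive differences"),
    per("EP_Mean", "EP [Mean]", "a.u.",
        "Mean absolute cycle-to-cycle energy difference"),
    per("EP_Std", "EP [Std]", "a.u.",
        "Std of absolute cycle-to-cycle energy differences"),
    per("EPQ3", "EPQ3", "%", "3-point energy perturbation quotient"),
    per("EPQ5", "EPQ5", "%", "5-point energy perturbation quotient"),
    per("EPQ11", "EPQ11", "%", "11-point energy perturbation quotient"),
    per("EPF", "EPF", "%",
        "Energy perturbation factor over consecutive differences"),
    row("OQ_Mean", "OQ [Mean]", "GAW_T", "Mean", "maximum", "a.u.", 0, 1,
        "Mean open quotient (open-phase duration / period)"),
    row("OQ_Std", "OQ [Std]", "GAW_T", "Std", "maximum", "a.u.", 0, Inf,
        "Std of per-cycle open quotient"),
    row("SQ_Mean", "SQ [Mean]", "GAW_T", "Mean", "maximum", "a.u.", 0, Inf,
        "Mean speed quotient (closing / opening duration)"),
    row("SQ_Std", "SQ [Std]", "GAW_T", "Std", "maximum", "a.u.", 0, Inf,
        "Std of per-cycle speed quotient"),
    row("PQ_Mean", "PQ [Mean]", "GAW_T", "Mean", "maximum", "a.u.", 0, 1,
        "Mean plateau quotient (>=90%-of-peak span / open phase)"),
    row("PQ_Std", "PQ [Std]", "GAW_T", "Std", "maximum", "a.u.", 0, Inf,
        "Std of per-cycle plateau quotient"),
    row("SI_Mean", "SI [Mean]", "GAW_T", "Mean", "maximum", "a.u.", -1, 1,
        "Mean speed index (closing - opening)/(closing + opening)"),
    row("SI_Std", "SI [Std]", "GAW_T", "Std", "maximum", "a.u.", 0, Inf,
        "Std of per-cycle speed index"),
    row("ClQ_Mean", "ClQ [Mean]", "GAW_T", "Mean", "maximum", "a.u.", 0, 1,
        "Mean closing quotient (closing duration / period)"),
    row("ClQ_Std", "ClQ [Std]", "GAW_T", "Std", "maximum", "a.u.", 0, Inf,
        "Std of per-cycle closing quotient"),
    row("OpQ_Mean", "OpQ [Mean]", "GAW_T", "Mean", "maximum", "a.u.", 0, 1,
        "Mean opening quotient (opening duration / period)"),
    row("OpQ_Std", "OpQ [Std]", "GAW_T", "Std", "maximum", "a.u.", 0, Inf,
        "Std of per-cycle opening quotient"),
    row("A_Mean", "A [Mean]", "GAW_T", "Mean", "maximum", "a.u.", 0, Inf,
        "Mean per-cycle peak amplitude of GAW_T"),
    row("A_Std", "A [Std]", "GAW_T", "Std", "maximum", "a.u.", 0, Inf,
        "Std of per-cycle peak amplitude"),
    row("E_Mean", "E [Mean]", "GAW_T", "Mean", "maximum", "a.u.", 0, Inf,
        "Mean per-cycle signal energy"),
    row("E_Std", "E [Std]", "GAW_T", "Std", "maximum", "a.u.", 0, Inf,
        "Std of per-cycle signal energy"),
    row("vAm", "vAm", "GAW_T", "scalar", "maximum", "%", 0, Inf,
        "Coefficient of variation of peak amplitude, percent"),
    row("SNR_K_Mean", "SNR_K [Mean]", "GAW_T", "scalar", "maximum", "dB",
        -Inf, Inf,
        "Harmonics-to-noise energy ratio of the GAW_T spectrum")
  )

  symrow <- function(name, label, statistic, cycle_mode, lo, hi, description) {
    row(name, label, "GAW_symmetry", statistic, cycle_mode, "a.u.", lo, hi,
        description)
  }
  sym <- bind_rows(
    symrow("PhA_Mean", "PhA [Mean]", "Mean", "minimum", -0.5, 0.5,
           "Mean signed left-right phase shift, cycle fractions"),
    symrow("PhA_Std", "PhA [Std]", "Std", "minimum", 0, Inf,
           "Std of signed left-right phase shift"),
    symrow("PhAI_Mean", "PhAI [Mean]", "Mean", "minimum", 0, 0.5,
           "Mean absolute left-right phase shift"),
    symrow("PhAI_Std", "PhAI [Std]", "Std", "minimum", 0, Inf,
           "Std of absolute left-right phase shift"),
    symrow("AmS_Mean", "AmS [Mean]", "Mean", "maximum", -1, 1,
           "Mean signed amplitude asymmetry (A_R - A_L)/max(A_R, A_L)"),
    symrow("AmS_Std", "AmS [Std]", "Std", "maximum", 0, Inf,
           "Std of signed amplitude asymmetry"),
    symrow("AmSI_Mean", "AmSI [Mean]", "Mean", "maximum", 0, 1,
           "Mean amplitude symmetry index min(A_L,A_R)/max(A_L,A_R)"),
    symrow("AmSI_Std", "AmSI [Std]", "Std", "maximum", 0, Inf,
           "Std of amplitude symmetry index"),
    symrow("DyRS_Mean", "DyRS [Mean]", "Mean", "maximum", -1, 1,
           "Mean signed dynamic-range asymmetry"),
    symrow("DyRS_Std", "DyRS [Std]", "Std", "maximum", 0, Inf,
           "Std of signed dynamic-range asymmetry"),
    symrow("DyRSI_Mean", "DyRSI [Mean]", "Mean", "maximum", 0, 1,
           "Mean dynamic-range symmetry index"),
    symrow("DyRSI_Std", "DyRSI [Std]", "Std", "maximum", 0, Inf,
           "Std of dynamic-range symmetry index"),
    symrow("SpA_Mean", "SpA [Mean]", "Mean", "maximum", -1, 1,
           "Mean signed per-cycle energy asymmetry"),
    symrow("SpA_Std", "SpA [Std]", "Std", "maximum", 0, Inf,
           "Std of signed per-cycle energy asymmetry"),
    symrow("SpAI_Mean", "SpAI [Mean]", "Mean", "maximum", 0, 1,
           "Mean per-cycle energy symmetry index"),
    symrow("SpAI_Std", "SpAI [Std]", "Std", "maximum", 0, Inf,
           "Std of per-cycle energy symmetry index"),
    symrow("WaSI_Mean", "WaSI [Mean]", "Mean", "maximum", -1, 1,
           "Mean per-cycle zero-lag waveform correlation of GAW_L and GAW_R"),
    symrow("WaSI_Std", "WaSI [Std]", "Std", "maximum", 0, Inf,
           "Std of per-cycle zero-lag waveform correlation")
  )

  sides <- c(L = "left", R = "right")
  regions <- c(OA = "opening, anterior half", OP = "opening, posterior half",
               CA = "closing, anterior half", CP = "closing, posterior half")
  pvg <- list()
  for (s in names(sides)) {
    for (rg in names(regions)) {
      for (st in c("Mean", "Std")) {
        nm <- sprintf("CA_%s_%s_%s", s, rg, st)
        lab <- sprintf("CA^%s,%s [%s]", s, rg, st)
        pvg[[nm]] <- row(
          nm, lab, "PVG", st, "maximum", "deg",
          if (st == "Std") 0 else 0, if (st == "Std") Inf else 180,
          sprintf("%s of the %s fold contour angle (%s); 90 deg = simultaneous",
                  st, sides[[s]], regions[[rg]])
        )
      }
    }
  }
  for (rg in names(regions)) {
    for (st in c("Mean", "Std")) {
      nm <- sprintf("CAS_%s_%s", rg, st)
      pvg[[nm]] <- row(
        nm, sprintf("CAS^%s [%s]", rg, st), "PVG", st, "maximum", "a.u.",
        if (st == "Std") 0 else 0, Inf,
        sprintf("%s of signed contour-angle ratio CA_L/CA_R (%s)",
                st, regions[[rg]])
      )
      nmi <- sprintf("CASI_%s_%s", rg, st)
      pvg[[nmi]] <- row(
        nmi, sprintf("CASI^%s [%s]", rg, st), "PVG", st, "maximum", "a.u.",
        0, if (st == "Std") Inf else 1,
        sprintf("%s of contour-angle symmetry index min/max (%s)",
                st, regions[[rg]])
      )
    }
  }
  out <- bind_rows(gaw, sym, bind_rows(pvg))
  stopifnot(nrow(out) == 91L, !anyDuplicated(out$name))
  out
}

#' Final 12-parameter subset reported for healthy vs functionally dysphonic voices
#'
#' Registry names of the 12-parameter subset (`HSV_2`): means of SNR_K, PhA
#' and five contour-angle/symmetry parameters, plus standard deviations of
#' SQ, PQ and three contour angles.
#'
#' @return Character vector of 12 registry `name`s.
#' @export
hsv2_parameters <- function() {
  c("SNR_K_Mean", "PhA_Mean",
    "CA_L_OP_Mean", "CA_R_CA_Mean", "CAS_OA_Mean", "CASI_OA_Mean",
    "CASI_CA_Mean",
    "SQ_Std", "PQ_Std", "CA_L_CA_Std", "CA_R_CA_Std", "CA_R_CP_Std")
}

#' Published per-group statistics of the final parameter subset
#'
#' Mean and standard deviation of the 12 `HSV_2` parameters in the four
#' clinical groups (healthy/disordered x female/male) of the source cohort,
#' used to calibrate [sample_feature_table()].
#'
#' @return Tibble with columns `group` (`N_F`, `FD_F`, `N_M`, `FD_M`),
#'   `parameter` (registry name), `mean`, `sd`.
#' @export
hsv2_group_stats <- function() {
  p <- c("CA_L_OP_Mean", "CA_R_CA_Mean", "CAS_OA_Mean", "CASI_OA_Mean",
         "CASI_CA_Mean", "CA_L_CA_Std", "CA_R_CA_Std", "CA_R_CP_Std",
         "SNR_K_Mean", "PhA_Mean", "SQ_Std", "PQ_Std")
  stats <- list(
    N_F  = list(c(100.8, 12.9), c(87.6, 5.9), c(0.976, 0.141),
                c(0.883, 0.070), c(0.934, 0.035), c(3.4, 1.7), c(3.4, 1.8),
                c(6.6, 4.3), c(11.2, 1.4), c(-0.031, 0.080),
                c(0.151, 0.065), c(0.047, 0.011)),
    FD_F = list(c(99.9, 15.8), c(87.7, 9.4), c(1.001, 0.154),
                c(0.880, 0.073), c(0.904, 0.061), c(4.3, 3.0), c(4.4, 2.1),
                c(6.5, 5.1), c(10.5, 1.6), c(0.001, 0.113),
                c(0.174, 0.085), c(0.052, 0.014)),
    N_M  = list(c(96.9, 17.2), c(83.1, 9.1), c(0.995, 0.084),
                c(0.933, 0.045), c(0.921, 0.044), c(2.9, 1.6), c(3.1, 1.5),
                c(5.3, 6.5), c(11.1, 1.3), c(-0.001, 0.078),
                c(0.155, 0.057), c(0.043, 0.013)),
    FD_M = list(c(80.9, 16.3), c(78.5, 8.6), c(1.020, 0.103),
                c(0.923, 0.049), c(0.902, 0.048), c(4.0, 1.7), c(3.3, 1.0),
                c(2.9, 2.1), c(11.0, 1.4), c(-0.011, 0.092),
                c(0.165, 0.100), c(0.051, 0.018))
  )
  bind_rows(lapply(names(stats), function(g) {
    tibble(
      group = g, parameter = p,
      mean = map_dbl(stats[[g]], 1),
      sd = map_dbl(stats[[g]], 2)
    )
  }))
}
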