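#' Pearson correlation matrix of a feature table
#'
#' Pairwise Pearson correlation coefficients (PCC) between all parameters,
#' pooled over all subjects regardless of group - so only relations that are
#' consistent across healthy and disordered groups register as redundancy.
#' Constant columns have undefined correlations; they are flagged and
#' excluded from redundancy grouping.
#'
#' @param table Feature-table tibble (metadata columns `subject_id`,
#'   `group`, `sex`, `age` are ignored).
#' @return A `pv_corr`: list with `pcc` (symmetric matrix, unit diagonal),
#'   `constant` (names of constant columns), `n` (subjects).
#' @export
correlation_matrix <- function(table) {
  X <- feature_matrix(table)
  if (nrow(X) < 3L) {
    abort("need at least 3 subjects", class = "phonovibe_error")
  }
  constant <- colnames(X)[apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || diff(range(v)) == 0
  })]
  pcc <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  diag(pcc) <- 1
  structure(list(pcc = pcc, constant = constant, n = nrow(X)),
            class = "pv_corr")
}

feature_matrix <- function(table) {
  meta <- c("subject_id", "group", "sex", "age")
  cols <- setdiff(names(table), meta)
  X <- as.matrix(table[cols])
  storage.mode(X) <- "double"
  X
}

#' Prune redundant parameters by very-high correlation
#'
#' Parameters correlated "very high" (|PCC| >= `very_high`, default 0.9) are
#' grouped by connected components of the thresholded correlation graph; one
#' representative per component is kept, chosen from an explicit priority
#' list (defaulting to the conventional representatives of the known
#' redundancy families: MShim for the shimmer family, Jit(%) for the jitter
#' family, EPF, PhAI\[Mean\], AmSI\[Std\], PhAI\[Std\], SpAI\[Std\],
#' CASI^CA\[Std\]) and otherwise by registry order. On top of the threshold
#' rule, `manual_removals` drops parameters that are only "high"-correlated
#' (0.7 <= |PCC| < 0.9) with a retained parameter; the default removes
#' TP\[Std\] (keeping F0\[Std\]), DyRS\[Mean\] (keeping AmS\[Mean\]) and
#' DyRSI\[Mean\] (keeping AmSI\[Mean\]). Every decision is recorded in a
#' ledger with its reason.
#'
#' @param table Feature-table tibble.
#' @param very_high Correlation threshold for redundancy; default 0.9.
#' @param manual_removals Character vector of additional parameters to
#'   remove.
#' @param priority Character vector of preferred representatives (first
#'   match in a component wins).
#' @return A `pv_prune`: list with `kept`, `discarded`, `ledger` (tibble:
#'   parameter, action, component, representative, reason), `components`,
#'   `corr` (the `pv_corr`), and `table` (the reduced feature table).
#' @export
prune_redundant <- function(table, very_high = 0.9,
                            manual_removals = c("TP_Std", "DyRS_Mean",
                                                "DyRSI_Mean"),
                            priority = c("MShim", "Jit_pct", "EPF",
                                         "PhAI_Mean", "AmSI_Std",
                                         "PhAI_Std", "SpAI_Std",
                                         "CASI_CA_Std")) {
  corr <- correlation_matrix(table)
  params <- colnames(corr$pcc)
  missing_priority <- setdiff(priority, params)
  if (length(missing_priority) > 0L) {
    abort(sprintf("priority parameters not in table: %s",
                  paste(missing_priority, collapse = ", ")),
          class = "phonovibe_error")
  }
  manual_removals <- intersect(manual_removals, params)

  usable <- setdiff(params, corr$constant)
  idx <- match(usable, params)
  pm <- abs(corr$pcc[idx, idx, drop = FALSE])
  p <- length(usable)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (p > 1L) {
    for (i in seq_len(p - 1L)) {
      hits <- which(!is.na(pm[i, ]) & pm[i, ] >= very_high)
      for (j in hits[hits > i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(p), find, integer(1))
  comp_ids <- unique(roots)
  components <- lapply(comp_ids, function(r) usable[roots == r])
  components <- components[vapply(components, length, integer(1)) > 1L]

  ledger <- list()
  discarded <- character(0)
  for (ci in seq_along(components)) {
    comp <- components[[ci]]
    rep_ <- intersect(priority, comp)
    rep_ <- if (length(rep_) > 0L) rep_[1] else comp[1]
    for (m in setdiff(comp, rep_)) {
      discarded <- c(discarded, m)
      ledger[[length(ledger) + 1L]] <- tibble(
        parameter = m, action = "discard", component = ci,
        representative = rep_,
        reason = sprintf("|PCC| >= %.2f with %s (component of %d)",
                         very_high, rep_, length(comp)))
    }
    ledger[[length(ledger) + 1L]] <- tibble(
      parameter = rep_, action = "keep", component = ci,
      representative = rep_,
      reason = if (rep_ %in% priority) "priority representative"
               else "first in registry order")
  }
  for (m in setdiff(manual_removals, discarded)) {
    discarded <- c(discarded, m)
    ledger[[length(ledger) + 1L]] <- tibble(
      parameter = m, action = "discard", component = NA_integer_,
      representative = NA_character_,
      reason = "manual removal (high 0.7 <= |PCC| < 0.9 with a kept parameter)")
  }
  kept <- setdiff(params, discarded)
  reduced <- table[c(intersect(c("subject_id", "group", "sex", "age"),
                               names(table)), kept)]
  structure(list(kept = kept, discarded = discarded,
                 ledger = bind_rows(ledger), components = components,
                 corr = corr, table = reduced),
            class = "pv_prune")
}

#' @export
print.pv_prune <- function(x, ...) {
  cat(sprintf("<pv_prune> %d kept, %d discarded (%d redundancy groups)\n",
              length(x$kept), length(x$discarded), length(x$components)))
  invisible(x)
}

#' @export
tidy.pv_prune <- function(x, ...) x$ledger

#' Screen parameters for correlation with subject age
#'
#' Pearson correlation of each parameter with age, with the two-sided
#' p-value for rho = 0 and the 95% confidence interval from the Fisher
#' z-transform (as given by [stats::cor.test()]). A correlation is flagged
#' negligible when |PCC| <= 0.3.
#'
#' @param table Feature-table tibble.
#' @param ages Numeric vector of subject ages (positive, one per row);
#'   defaults to the table's `age` column.
#' @return A `pv_agescreen` tibble: `parameter`, `pcc`, `p_value`,
#'   `ci_lo`, `ci_hi`, `negligible`.
#' @export
age_screen <- function(table, ages = table$age) {
  if (is.null(ages) || any(is.na(ages)) || any(ages <= 0)) {
    abort_field("ages", "must be positive, one per subject")
  }
  X <- feature_matrix(table)
  if (nrow(X) != length(ages)) {
    abort_field("ages", "length must match the number of subjects")
  }
  if (nrow(X) < 4L) {
    abort("need at least 4 subjects for a confidence interval",
          class = "phonovibe_error")
  }
  rows <- lapply(colnames(X), function(p) {
    v <- X[, p]
    ok <- !is.na(v)
    if (sum(ok) < 4L || diff(range(v[ok])) == 0) {
      return(tibble(parameter = p, pcc = NA_real_, p_value = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_, negligible = NA))
    }
    ct <- cor.test(v[ok], ages[ok], method = "pearson", conf.level = 0.95)
    tibble(parameter = p, pcc = unname(ct$estimate),
           p_value = ct$p.value,
           ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
           negligible = abs(unname(ct$estimate)) <= 0.3)
  })
  structure(bind_rows(rows),
            class = c("pv_agescreen", "tbl_df", "tbl", "data.frame"))
}

#' Scatter plot of a parameter against subject age
#'
#' Convenience helper for the visual part of the age screen.
#'
#' @param table Feature-table tibble with an `age` column.
#' @param parameter Column name to plot.
#' @return A ggplot object.
#' @export
plot_age_relation <- function(table, parameter) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$age, y = .data[[parameter]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "age (years)", y = parameter)
}

#' Export a pruning report to CSV and JSON
#' @param prune A `pv_prune`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_prune_report <- function(prune, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ledger_csv <- file.path(dir, "prune_ledger.csv")
  write.csv(prune$ledger, ledger_csv, row.names = FALSE)
  json <- file.path(dir, "prune_report.json")
  jsonlite::write_json(
    list(kept = prune$kept, discarded = prune$discarded,
         constant = prune$corr$constant,
         components = prune$components),
    json, auto_unbox = FALSE, digits = NA)
  invisible(c(ledger_csv, json))
}
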