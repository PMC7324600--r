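# Five-step boosted-stump parameter-selection protocol over a feature table:
# (1) pick the boosting algorithm (performance + random-feature sanity),
# (2) pick the number of stumps, (3)/(4) per-comparison stepwise selection
# along the feature-importance ranking, (5) combine the per-comparison sets.

comparison_data <- function(table, groups) {
  rows <- table$group %in% groups
  X <- feature_matrix(table[rows, ])
  keep <- colnames(X)[apply(X, 2, function(v) all(is.finite(v)))]
  list(X = X[, keep, drop = FALSE],
       y = factor(table$group[rows], levels = groups))
}

# Healthy-vs-disordered comparisons implied by the group labels: pairs
# N_<suffix> vs FD_<suffix>; with exactly two groups, that single pair.
default_comparisons <- function(groups) {
  groups <- unique(groups)
  out <- list()
  for (s in unique(sub("^(N|FD)_", "", groups))) {
    n <- paste0("N_", s); d <- paste0("FD_", s)
    if (n %in% groups && d %in% groups) out[[s]] <- c(n, d)
  }
  if (length(out) == 0L && length(groups) == 2L) {
    out[["all"]] <- sort(groups)
  }
  if (length(out) == 0L) {
    abort("cannot derive healthy-vs-disordered comparisons from group labels",
          class = "phonovibe_error")
  }
  out
}

#' Step 1: compare boosting algorithms and their random-feature sensitivity
#'
#' Evaluates AdaBoost, LogitBoost and RUSBoost on every comparison, with and
#' without two injected random parameters (one standard normal, one
#' uniform). An algorithm is unsuitable if either random parameter reaches a
#' normalized feature importance above 0.5; among the suitable ones the
#' winner has the highest mean of AUC and ACC averaged over comparisons and
#' over the with/without-random runs.
#'
#' @param table Feature-table tibble with a `group` column.
#' @param comparisons Named list of length-2 group-label vectors; default
#'   derived from the group labels (healthy `N_*` vs disordered `FD_*` per
#'   suffix).
#' @param algorithms Algorithms to compare.
#' @param n_stumps,k,repeats,seed Training and cross-validation settings.
#' @return A `pv_step1`: list with `results` (one row per algorithm x
#'   comparison x random-injection), `winner`, `unsuitable`.
#' @export
step1_compare_algorithms <- function(table,
                                     comparisons = default_comparisons(table$group),
                                     algorithms = c("AdaBoost", "LogitBoost",
                                                    "RUSBoost"),
                                     n_stumps = 100L, k = 10L, repeats = 2L,
                                     seed = 1L) {
  rows <- list()
  rand_fi <- list()
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    cname <- names(comparisons)[ci]
    cd <- comparison_data(table, cmp)
    Xr <- with_seed(derive_seed(seed, ci), cbind(
      cd$X,
      RAND_N = rnorm(nrow(cd$X)),
      RAND_U = runif(nrow(cd$X))))
    for (alg in algorithms) {
      cfg <- boost_config(alg, n_stumps = n_stumps,
                          seed = derive_seed(seed, ci * 10L))
      for (with_random in c(FALSE, TRUE)) {
        Xu <- if (with_random) Xr else cd$X
        cv <- crossval_evaluate(Xu, cd$y, cfg, k = k, repeats = repeats,
                                seed = derive_seed(seed, ci * 100L))
        g <- glance(cv)
        fi_rand <- NA_real_
        if (with_random) {
          fit <- train_boost(Xr, cd$y, cfg)
          fi <- feature_importance(fit)
          fi_rand <- max(fi$normalized[fi$feature %in% c("RAND_N", "RAND_U")])
          rand_fi[[paste(cname, alg)]] <- fi_rand
        }
        rows[[length(rows) + 1L]] <- tibble(
          comparison = cname, algorithm = alg, with_random = with_random,
          auc = g$auc, acc = g$acc, max_random_fi = fi_rand)
      }
    }
  }
  results <- bind_rows(rows)
  by_alg <- results |>
    group_by(.data$algorithm) |>
    summarise(score = mean((.data$auc + .data$acc) / 2),
              max_random_fi = max(.data$max_random_fi, na.rm = TRUE),
              .groups = "drop")
  unsuitable <- by_alg$algorithm[by_alg$max_random_fi > 0.5]
  ok <- by_alg[!(by_alg$algorithm %in% unsuitable), ]
  winner <- if (nrow(ok) > 0) ok$algorithm[which.max(ok$score)] else NA_character_
  structure(list(results = results, winner = winner,
                 unsuitable = unsuitable),
            class = "pv_step1")
}

#' @export
print.pv_step1 <- function(x, ...) {
  cat(sprintf("<pv_step1> winner: %s%s\n", x$winner,
              if (length(x$unsuitable) > 0)
                paste0(" (unsuitable: ",
                       paste(x$unsuitable, collapse = ", "), ")") else ""))
  invisible(x)
}

#' Step 2: sweep the number of stumps
#'
#' Cross-validated AUC and ACC of models with increasing stump counts
#' (evaluated as nested prefixes of one boosting run per fold). The chosen
#' size is the smallest whose AUC, averaged over comparisons, lies within
#' `tol` of the curve maximum; a manual override is supported.
#'
#' @param table Feature-table tibble.
#' @param algorithm Boosting algorithm (normally the Step-1 winner).
#' @param sizes Stump counts to evaluate; a coarse grid is fine.
#' @param comparisons As in [step1_compare_algorithms()].
#' @param tol AUC tolerance for "no further improvement"; default 0.005.
#' @param override Optional manual stump count.
#' @param k,repeats,seed Cross-validation settings.
#' @return A `pv_sweep`: `curve` (per comparison and size), `chosen`.
#' @export
step2_stump_sweep <- function(table, algorithm,
                              sizes = c(1, 10, 25, 50, 100, 200, 300, 400, 500),
                              comparisons = default_comparisons(table$group),
                              tol = 0.005, override = NULL, k = 10L,
                              repeats = 2L, seed = 1L) {
  curves <- list()
  for (ci in seq_along(comparisons)) {
    cd <- comparison_data(table, comparisons[[ci]])
    cfg <- boost_config(algorithm, n_stumps = max(sizes),
                        seed = derive_seed(seed, ci))
    cv <- crossval_sweep(cd$X, cd$y, cfg, sizes, k = k, repeats = repeats,
                         seed = derive_seed(seed, ci * 100L))
    cv$comparison <- names(comparisons)[ci]
    curves[[ci]] <- cv
  }
  curve <- bind_rows(curves)
  pooled <- curve |>
    group_by(.data$size) |>
    summarise(auc = mean(.data$auc_mean), .groups = "drop")
  chosen <- if (!is.null(override)) as.integer(override) else {
    min(pooled$size[pooled$auc >= max(pooled$auc) - tol])
  }
  structure(list(curve = curve, chosen = chosen, tol = tol),
            class = "pv_sweep")
}

#' @export
autoplot.pv_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curve, c("auc_mean", "acc_mean"),
                           names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$value,
                                  colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen, linetype = 2) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "number of stumps", y = NULL)
}

#' Steps 3/4: stepwise parameter selection along the importance ranking
#'
#' Features are ranked by normalized feature importance from one full-data
#' fit; nested models containing the 1, 2, ..., p top-ranked features are
#' evaluated by repeated cross-validation, and the chosen size is the
#' smallest whose AUC lies within `tol` of the maximum over sizes - a model
#' that is as good as the best but smaller.
#'
#' @param table Feature-table tibble.
#' @param comparison Length-2 vector of group labels (healthy first).
#' @param algorithm Boosting algorithm.
#' @param n_stumps Stumps per model (the Step-2 choice).
#' @param tol AUC tolerance; default 0.005.
#' @param max_size Cap on the number of nested models (default: all).
#' @param k,repeats,seed Cross-validation settings.
#' @return A `pv_stepwise`: `ranking` (pv_importance), `curve` (size,
#'   parameter added, AUC/ACC mean and sd), `chosen_size`, `chosen_subset`.
#' @export
stepwise_select <- function(table, comparison, algorithm, n_stumps = 100L,
                            tol = 0.005, max_size = NULL, k = 10L,
                            repeats = 2L, seed = 1L) {
  cd <- comparison_data(table, comparison)
  cfg <- boost_config(algorithm, n_stumps = n_stumps,
                      seed = derive_seed(seed, 1L))
  fit <- train_boost(cd$X, cd$y, cfg)
  ranking <- feature_importance(fit)
  order_names <- ranking$feature
  p <- if (is.null(max_size)) length(order_names) else
    min(max_size, length(order_names))
  rows <- list()
  # one shared partition seed: nested sizes are compared on the same folds,
  # so size-to-size AUC differences are paired rather than resampled
  part_seed <- derive_seed(seed, 100L)
  for (s in seq_len(p)) {
    sub <- order_names[seq_len(s)]
    cv <- crossval_evaluate(cd$X[, sub, drop = FALSE], cd$y, cfg, k = k,
                            repeats = repeats, seed = part_seed)
    g <- glance(cv)
    sm <- cv$summary
    rows[[s]] <- tibble(size = s, parameter_added = order_names[s],
                        auc_mean = g$auc,
                        auc_sd = sm$sd[sm$measure == "auc"],
                        acc_mean = g$acc,
                        acc_sd = sm$sd[sm$measure == "acc"])
  }
  curve <- bind_rows(rows)
  chosen_size <- min(curve$size[curve$auc_mean >= max(curve$auc_mean) - tol])
  structure(list(ranking = ranking, curve = curve,
                 chosen_size = chosen_size,
                 chosen_subset = order_names[seq_len(chosen_size)],
                 comparison = comparison, tol = tol),
            class = "pv_stepwise")
}

#' @export
print.pv_stepwise <- function(x, ...) {
  cat(sprintf("<pv_stepwise> %s vs %s: %d of %d parameters kept\n",
              x$comparison[1], x$comparison[2], x$chosen_size,
              nrow(x$curve)))
  invisible(x)
}

#' @export
autoplot.pv_stepwise <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curve, c("auc_mean", "acc_mean"),
                           names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$value,
                                  colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_size, linetype = 2) +
    ggplot2::labs(x = "number of included parameters", y = NULL)
}

#' Step 5: combine the per-comparison parameter sets
#'
#' Evaluates candidate subsets - the union of the per-comparison choices,
#' each comparison's own set, the PVG-only and GAW-only members of the
#' union, any user-supplied subsets, and optionally the intermediate sets of
#' a greedy backward pass from the union - on every comparison, and picks as
#' final set the smallest whose worst-case (minimum over comparisons) AUC is
#' within `tol` of the best worst-case AUC.
#'
#' @param stepwise_list Named list of `pv_stepwise` results, one per
#'   comparison.
#' @param table Feature-table tibble.
#' @param comparisons Named list of group pairs matching `stepwise_list`.
#' @param algorithm,n_stumps,k,repeats,seed Model settings.
#' @param extra_subsets Named list of additional character vectors.
#' @param greedy Run the greedy backward pass (default TRUE).
#' @param tol Worst-case-AUC tolerance; default 0.01.
#' @param registry Parameter registry (classifies GAW vs PVG members).
#' @return A `pv_combine`: `table` (one row per candidate with per-
#'   comparison AUC/ACC and `min_auc`), `final_subset`, `final_name`.
#' @export
step5_combine <- function(stepwise_list, table,
                          comparisons = default_comparisons(table$group),
                          algorithm = "LogitBoost", n_stumps = 100L,
                          extra_subsets = list(), greedy = TRUE, tol = 0.01,
                          k = 10L, repeats = 2L, seed = 1L,
                          registry = parameter_registry()) {
  all_params <- setdiff(names(table), c("subject_id", "group", "sex", "age"))
  union_set <- unique(unlist(map(stepwise_list, "chosen_subset")))
  sets <- list(union = union_set)
  for (nm in names(stepwise_list)) {
    sets[[paste0("only_", nm)]] <- stepwise_list[[nm]]$chosen_subset
  }
  sig <- setNames(registry$signal_type, registry$name)
  pvg_only <- union_set[!is.na(sig[union_set]) & sig[union_set] == "PVG"]
  gaw_only <- union_set[!is.na(sig[union_set]) & sig[union_set] == "GAW"]
  if (length(pvg_only) > 0) sets[["pvg_only"]] <- pvg_only
  if (length(gaw_only) > 0) sets[["gaw_only"]] <- gaw_only
  for (nm in names(extra_subsets)) sets[[nm]] <- extra_subsets[[nm]]

  bad <- setdiff(unique(unlist(sets)), all_params)
  if (length(bad) > 0L) {
    abort(sprintf("subset contains unknown parameter(s): %s",
                  paste(bad, collapse = ", ")), class = "phonovibe_error")
  }

  # all candidates are compared on the same partitions per comparison
  eval_subset <- function(sub, off) {
    per <- list()
    for (ci in seq_along(comparisons)) {
      cd <- comparison_data(table, comparisons[[ci]])
      cfg <- boost_config(algorithm, n_stumps = n_stumps,
                          seed = derive_seed(seed, ci))
      cv <- crossval_evaluate(cd$X[, sub, drop = FALSE], cd$y, cfg, k = k,
                              repeats = repeats,
                              seed = derive_seed(seed, 500L + ci))
      g <- glance(cv)
      per[[names(comparisons)[ci]]] <- c(auc = g$auc, acc = g$acc)
    }
    per
  }

  rows <- list()
  add_row <- function(name, sub, per) {
    r <- tibble(candidate = name, n = length(sub),
                parameters = paste(sub, collapse = ";"))
    for (nm in names(per)) {
      r[[paste0("auc_", nm)]] <- per[[nm]][["auc"]]
      r[[paste0("acc_", nm)]] <- per[[nm]][["acc"]]
    }
    r$min_auc <- min(map_dbl(per, "auc"))
    rows[[length(rows) + 1L]] <<- r
  }
  off <- 0L
  subsets_eval <- list()
  for (nm in names(sets)) {
    off <- off + 1L
    per <- eval_subset(sets[[nm]], off)
    add_row(nm, sets[[nm]], per)
    subsets_eval[[nm]] <- sets[[nm]]
  }

  if (greedy && length(union_set) > 2L) {
    current <- union_set
    best_min <- max(map_dbl(rows, ~ .x$min_auc))
    repeat {
      if (length(current) <= 2L) break
      trial <- map(seq_along(current), function(i) current[-i])
      scores <- numeric(length(trial))
      pers <- list()
      for (i in seq_along(trial)) {
        off <- off + 1L
        pers[[i]] <- eval_subset(trial[[i]], off)
        scores[i] <- min(map_dbl(pers[[i]], "auc"))
      }
      i_best <- which.max(scores)
      if (scores[i_best] < best_min - tol) break
      current <- trial[[i_best]]
      nm <- sprintf("greedy_%d", length(current))
      add_row(nm, current, pers[[i_best]])
      subsets_eval[[nm]] <- current
      best_min <- max(best_min, scores[i_best])
    }
  }

  tab <- bind_rows(rows)
  best_min_auc <- max(tab$min_auc)
  eligible <- tab$min_auc >= best_min_auc - tol
  final_idx <- which(eligible)[order(tab$n[eligible])][1]
  structure(list(table = tab,
                 final_subset = subsets_eval[[tab$candidate[final_idx]]],
                 final_name = tab$candidate[final_idx], tol = tol),
            class = "pv_combine")
}

#' @export
print.pv_combine <- function(x, ...) {
  cat(sprintf("<pv_combine> final set `%s` (%d parameters)\n",
              x$final_name, length(x$final_subset)))
  invisible(x)
}
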