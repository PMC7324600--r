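#' Run the full parameter-selection pipeline
#'
#' Executes, from a single config: cohort construction (sampling a feature
#' table from group statistics, generating and extracting synthetic
#' recordings, or loading a CSV), correlation-based redundancy pruning, the
#' age screen on the disordered groups, and the five selection steps
#' (algorithm comparison, stump-count sweep, per-comparison stepwise
#' selection, subset combination). Every stage is seeded from the config
#' seed, so the run - including all written reports - is byte-reproducible.
#'
#' @param config A named list or the path of a YAML file. Recognised
#'   entries (all optional unless noted):
#' \describe{
#'   \item{seed}{integer; default 1.}
#'   \item{out_dir}{directory for CSV/JSON artifacts; nothing is written
#'     when omitted.}
#'   \item{cohort}{list; either `type: "table"` with `n_per_group`
#'     (sampled via [sample_feature_table()]), `type: "recordings"` with
#'     `n_per_group` and `params` (via [generate_cohort()] +
#'     [extract_features()]), or `file:` a feature-table CSV.}
#'   \item{cv}{`k` (default 5) and `repeats` (default 2).}
#'   \item{prune}{`very_high` threshold (default 0.9).}
#'   \item{step1}{`n_stumps` (default 50).}
#'   \item{step2}{`sizes` grid and `tol` (defaults `c(1,10,25,50,100,200,300)`,
#'     0.005).}
#'   \item{stepwise}{`tol` (default 0.005), `max_size`.}
#'   \item{step5}{`greedy` (default TRUE), `tol` (default 0.01),
#'     `subsets` (named list of extra candidates).}
#' }
#' @return A `pv_report`: list with `table`, `prune`, `age_screen`,
#'   `step1`, `step2`, `stepwise` (named per comparison), `combine`,
#'   `final_subset`, `config`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(
#'   seed = 7,
#'   cohort = list(type = "table", n_per_group = 15),
#'   cv = list(k = 5, repeats = 1),
#'   step2 = list(sizes = c(1, 10, 25, 50))))
#' rep$final_subset
#' }
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "phonovibe_error")
    }
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  cv_k <- config$cv$k %||% 5L
  cv_rep <- config$cv$repeats %||% 2L

  # --- cohort -------------------------------------------------------------
  cohort <- config$cohort %||% list(type = "table", n_per_group = 15)
  if (!is.null(cohort$file)) {
    if (!file.exists(cohort$file)) {
      abort(sprintf("feature table not found: %s", cohort$file),
            class = "phonovibe_error")
    }
    table <- as_tibble(utils::read.csv(cohort$file, check.names = FALSE))
  } else if ((cohort$type %||% "table") == "table") {
    npg <- cohort$n_per_group %||% 15
    table <- sample_feature_table(n_per_group = unlist(npg),
                                  seed = derive_seed(seed, 1L))
  } else if (cohort$type == "recordings") {
    cs <- cohort_spec(cohort$n_per_group, cohort$params %||% list(),
                      seed = derive_seed(seed, 1L))
    table <- extract_features(generate_cohort(cs))
    table$sex <- ifelse(grepl("_F$", table$group), "F",
                        ifelse(grepl("_M$", table$group), "M",
                               NA_character_))
  } else {
    abort_field("cohort$type", "must be 'table' or 'recordings'")
  }
  comparisons <- default_comparisons(table$group)

  # --- prune + age screen ---------------------------------------------------
  params_present <- setdiff(names(table),
                            c("subject_id", "group", "sex", "age"))
  pr_defaults <- formals(prune_redundant)
  prune <- prune_redundant(
    table,
    very_high = config$prune$very_high %||% 0.9,
    manual_removals = intersect(eval(pr_defaults$manual_removals),
                                params_present),
    priority = intersect(eval(pr_defaults$priority), params_present))
  pruned_table <- prune$table

  age <- NULL
  if ("age" %in% names(table)) {
    fd_groups <- grep("^FD_", unique(table$group), value = TRUE)
    screens <- list()
    for (g in if (length(fd_groups) > 0) fd_groups else unique(table$group)) {
      sc <- age_screen(pruned_table[pruned_table$group == g, ])
      sc$group <- g
      screens[[g]] <- sc
    }
    age <- bind_rows(screens)
  }

  # --- selection steps ------------------------------------------------------
  s1 <- step1_compare_algorithms(
    pruned_table, comparisons,
    n_stumps = config$step1$n_stumps %||% 50L,
    k = cv_k, repeats = cv_rep, seed = derive_seed(seed, 2L))
  algorithm <- s1$winner

  s2 <- step2_stump_sweep(
    pruned_table, algorithm,
    sizes = config$step2$sizes %||% c(1, 10, 25, 50, 100, 200, 300),
    comparisons = comparisons,
    tol = config$step2$tol %||% 0.005,
    k = cv_k, repeats = cv_rep, seed = derive_seed(seed, 3L))

  stepwise <- list()
  for (ci in seq_along(comparisons)) {
    stepwise[[names(comparisons)[ci]]] <- stepwise_select(
      pruned_table, comparisons[[ci]], algorithm,
      n_stumps = s2$chosen,
      tol = config$stepwise$tol %||% 0.005,
      max_size = config$stepwise$max_size,
      k = cv_k, repeats = cv_rep, seed = derive_seed(seed, 4L + ci))
  }

  comb <- step5_combine(
    stepwise, pruned_table, comparisons, algorithm,
    n_stumps = s2$chosen,
    extra_subsets = config$step5$subsets %||% list(),
    greedy = config$step5$greedy %||% TRUE,
    tol = config$step5$tol %||% 0.01,
    k = cv_k, repeats = cv_rep, seed = derive_seed(seed, 10L))

  report <- structure(
    list(table = table, prune = prune, age_screen = age, step1 = s1,
         step2 = s2, stepwise = stepwise, combine = comb,
         final_subset = comb$final_subset,
         comparisons = comparisons,
         config = c(config, list(seed = seed, algorithm = algorithm,
                                 n_stumps = s2$chosen))),
    class = "pv_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write all pipeline reports to a directory
#'
#' Emits the feature table, pruning ledger and report, age screen,
#' algorithm-comparison table, stump-sweep curve, per-comparison stepwise
#' curves, the candidate-combination table and the final subset, as CSV and
#' JSON. Rewriting the same report produces byte-identical files.
#'
#' @param report A `pv_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  wcsv(report$table, "feature_table.csv")
  write_prune_report(report$prune, dir)
  if (!is.null(report$age_screen)) wcsv(report$age_screen, "age_screen.csv")
  wcsv(report$step1$results, "step1_results.csv")
  wcsv(report$step2$curve, "step2_curve.csv")
  for (nm in names(report$stepwise)) {
    wcsv(report$stepwise[[nm]]$curve, sprintf("stepwise_%s.csv", nm))
    wcsv(report$stepwise[[nm]]$ranking, sprintf("importance_%s.csv", nm))
  }
  wcsv(report$combine$table, "combinations.csv")
  jsonlite::write_json(
    list(seed = report$config$seed,
         algorithm = report$config$algorithm,
         n_stumps = report$config$n_stumps,
         comparisons = report$comparisons,
         chosen_sizes = lapply(report$stepwise, function(s) s$chosen_size),
         final_candidate = report$combine$final_name,
         final_subset = report$final_subset),
    file.path(dir, "final_subset.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pv_report <- function(x, ...) {
  cat("<pv_report>\n")
  cat(sprintf("  cohort: %d subjects, %d parameters\n", nrow(x$table),
              length(setdiff(names(x$table),
                             c("subject_id", "group", "sex", "age")))))
  cat(sprintf("  pruned: %d discarded -> %d kept\n",
              length(x$prune$discarded), length(x$prune$kept)))
  cat(sprintf("  algorithm: %s, %d stumps\n", x$config$algorithm,
              x$config$n_stumps))
  for (nm in names(x$stepwise)) {
    cat(sprintf("  stepwise %s: %d parameters\n", nm,
                x$stepwise[[nm]]$chosen_size))
  }
  cat(sprintf("  final subset (%s): %s\n", x$combine$final_name,
              paste(x$final_subset, collapse = ", ")))
  invisible(x)
}
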