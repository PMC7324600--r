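test_that("step 1 evaluates algorithms and flags random-feature abuse", {
  tab <- make_noise_table(1, n_per_class = 30, n_noise = 3)
  s1 <- step1_compare_algorithms(tab, n_stumps = 30, k = 5, repeats = 1,
                                 seed = 1)
  expect_s3_class(s1$results, "tbl_df")
  expect_equal(nrow(s1$results), 6L)   # 3 algorithms x with/without random
  expect_true(s1$winner %in% c("AdaBoost", "LogitBoost", "RUSBoost"))
  withr <- s1$results[s1$results$with_random, ]
  expect_true(all(withr$max_random_fi < 0.1))
  expect_true(all(withr$auc > 0.9))
})

test_that("step 1 finds no meaningful separation on pure noise", {
  set.seed(2)
  tab <- tibble::as_tibble(matrix(rnorm(60 * 4), ncol = 4,
                                  dimnames = list(NULL, paste0("p", 1:4))))
  tab$group <- rep(c("N_F", "FD_F"), each = 30)
  s1 <- step1_compare_algorithms(tab, n_stumps = 20, k = 5, repeats = 1,
                                 seed = 3)
  expect_true(all(abs(s1$results$auc - 0.5) < 0.15))
})

test_that("the stump sweep saturates and picks a small deterministic size", {
  tab <- make_noise_table(3, n_per_class = 25, n_noise = 2)
  s2 <- step2_stump_sweep(tab, "LogitBoost", sizes = c(1, 5, 20, 50),
                          k = 5, repeats = 1, seed = 2)
  expect_gte(max(s2$curve$auc_mean), 0.95)
  expect_lte(s2$chosen, 50)
  s2b <- step2_stump_sweep(tab, "LogitBoost", sizes = c(1, 5, 20, 50),
                           k = 5, repeats = 1, seed = 2)
  expect_identical(s2$curve, s2b$curve)
  s2c <- step2_stump_sweep(tab, "LogitBoost", sizes = c(1, 5, 20, 50),
                           k = 5, repeats = 1, seed = 2, override = 37)
  expect_equal(s2c$chosen, 37L)
})

test_that("stepwise selection recovers a single informative feature", {
  tab <- make_noise_table(4)
  sw <- stepwise_select(tab, c("N_F", "FD_F"), "LogitBoost", n_stumps = 40,
                        k = 5, repeats = 1, seed = 4)
  expect_identical(sw$chosen_subset, "inf")
  expect_equal(sw$ranking$feature[1], "inf")
  expect_equal(nrow(sw$curve), 10L)
  expect_true(all(c("auc_mean", "auc_sd", "acc_mean", "acc_sd") %in%
                    names(sw$curve)))

  one <- tab[c("inf", "group")]
  sw1 <- stepwise_select(one, c("N_F", "FD_F"), "LogitBoost",
                         n_stumps = 20, k = 5, repeats = 1, seed = 1)
  expect_equal(nrow(sw1$curve), 1L)
  expect_equal(sw1$chosen_size, 1L)
})

test_that("step 5 combines disjoint informative sets across sexes", {
  set.seed(6)
  n <- 25
  tab <- tibble::tibble(
    f_feat = c(rnorm(n, 0), rnorm(n, 4), rnorm(2 * n, 2)),
    m_feat = c(rnorm(2 * n, 2), rnorm(n, 0), rnorm(n, 4)),
    noise = rnorm(4 * n),
    group = rep(c("N_F", "FD_F", "N_M", "FD_M"), each = n)
  )
  fake <- list(F = list(chosen_subset = "f_feat"),
               M = list(chosen_subset = "m_feat"))
  comb <- step5_combine(fake, tab, algorithm = "LogitBoost",
                        n_stumps = 30, greedy = FALSE, k = 5, repeats = 1,
                        seed = 2)
  expect_true(all(c("f_feat", "m_feat") %in% comb$final_subset))
  expect_true(all(c("auc_F", "auc_M", "acc_F", "acc_M", "min_auc") %in%
                    names(comb$table)))
  expect_gte(nrow(comb$table), 3L)

  expect_error(
    step5_combine(fake, tab, algorithm = "LogitBoost", n_stumps = 10,
                  extra_subsets = list(bad = "NOT_A_COL"), greedy = FALSE,
                  k = 5, repeats = 1),
    "unknown parameter")
})

test_that("greedy backward never worsens the worst-case AUC", {
  tab <- make_noise_table(7, n_per_class = 25, n_noise = 4)
  fake <- list(F = list(chosen_subset = c("inf", "noise1", "noise2")))
  comb <- step5_combine(fake, tab, comparisons = list(F = c("N_F", "FD_F")),
                        algorithm = "LogitBoost", n_stumps = 30,
                        greedy = TRUE, k = 5, repeats = 1, seed = 3)
  union_auc <- comb$table$min_auc[comb$table$candidate == "union"]
  expect_gte(max(comb$table$min_auc), union_auc)
  expect_gte(comb$table$min_auc[comb$table$candidate == comb$final_name],
             max(comb$table$min_auc) - comb$tol)
})

test_that("the pipeline runs end-to-end from a config and is seeded", {
  cfg <- list(seed = 5,
              cohort = list(type = "table", n_per_group = 12),
              cv = list(k = 4, repeats = 1),
              step1 = list(n_stumps = 20),
              step2 = list(sizes = c(1, 10, 25)),
              stepwise = list(max_size = 6),
              step5 = list(greedy = FALSE))
  rep <- run_pipeline(cfg)
  expect_s3_class(rep, "pv_report")
  expect_true(length(rep$final_subset) >= 1)
  expect_true(all(rep$final_subset %in% names(rep$table)))
  expect_named(rep$stepwise, c("F", "M"))
  expect_true(all(rep$age_screen$group %in% c("FD_F", "FD_M")))

  d <- tempfile()
  write_report(rep, d)
  expect_true(file.exists(file.path(d, "final_subset.json")))
  expect_true(file.exists(file.path(d, "combinations.csv")))
  unlink(d, recursive = TRUE)

  expect_error(run_pipeline("no/such/config.yaml"), "not found")
  expect_error(run_pipeline(list(cohort = list(file = "no/such.csv"))),
               "not found")
})

test_that("pipeline configs load from YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9",
               "cohort:", "  type: table", "  n_per_group: 12",
               "cv: {k: 4, repeats: 1}",
               "step1: {n_stumps: 15}",
               "step2: {sizes: [1, 10]}",
               "stepwise: {max_size: 4}",
               "step5: {greedy: false}"), f)
  rep <- run_pipeline(f)
  expect_s3_class(rep, "pv_report")
  unlink(f)
})

test_that("recording-based cohorts flow through feature extraction", {
  cs <- cohort_spec(
    c(N_F = 4, FD_F = 4),
    params = list(
      N_F = list(f0 = c(180, 240), n_frames = 1200),
      FD_F = list(f0 = c(180, 240), n_frames = 1200,
                  jitter_pct_target = c(2, 4), phase_shift = c(0.1, 0.2))),
    seed = 21)
  tab <- extract_features(generate_cohort(cs))
  expect_equal(nrow(tab), 8L)
  expect_true(all(parameter_registry()$name %in% names(tab)))
  fd <- tab$group == "FD_F"
  expect_gt(mean(tab$Jit_pct[fd]), mean(tab$Jit_pct[!fd]))
  expect_gt(mean(tab$PhAI_Mean[fd]), mean(tab$PhAI_Mean[!fd]))
})
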