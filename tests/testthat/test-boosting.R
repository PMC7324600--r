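test_that("stump search matches brute force and stated tie rules", {
  X <- matrix(c(0, 1, 2, 3), ncol = 1)
  st <- fit_stump(X, c(-1, -1, 1, 1), rep(0.25, 4), "class")
  expect_equal(st$threshold, 1.5)
  expect_equal(st$left, -1)
  expect_equal(st$right, 1)
  expect_gt(st$gain, 0)

  # brute-force oracle on random data: enumerate all feature/midpoint pairs
  set.seed(3)
  Xr <- matrix(rnorm(40), ncol = 2)
  y <- sample(c(-1, 1), 20, replace = TRUE)
  w <- runif(20); w <- w / sum(w)
  st2 <- fit_stump(Xr, y, w, "class")
  brute <- Inf
  for (j in 1:2) {
    xs <- sort(unique(Xr[, j]))
    for (i in seq_len(length(xs) - 1)) {
      thr <- (xs[i] + xs[i + 1]) / 2
      for (sl in c(-1, 1)) for (sr in c(-1, 1)) {
        pred <- ifelse(Xr[, j] <= thr, sl, sr)
        brute <- min(brute, sum(w[pred != y]))
      }
    }
  }
  parent <- (sum(w) - abs(sum(w * y))) / 2
  expect_equal(st2$gain, parent - brute, tolerance = 1e-12)

  # duplicated feature columns: tie broken to the lower index
  Xd <- cbind(Xr[, 1], Xr[, 1])
  st3 <- fit_stump(Xd, y, w, "class")
  expect_equal(st3$feature, 1L)

  # degenerate input
  st4 <- fit_stump(matrix(1, 5, 2), c(1, 1, -1, -1, 1), rep(0.2, 5),
                   "class")
  expect_true(is.na(st4$feature))
  expect_equal(st4$gain, 0)
  expect_error(fit_stump(Xr, y, rep(0, 20)), "weights")
})

test_that("labels independent of X give near-zero stump gain", {
  set.seed(11)
  n <- 500
  X <- matrix(rnorm(2 * n), ncol = 2)
  y <- rep(c(-1, 1), n / 2)
  st <- fit_stump(X, y, rep(1 / n, n), "class")
  parent <- (1 - abs(mean(y))) / 2
  expect_lt(st$gain / parent, 0.15)
})

test_that("all three algorithms separate separable data and are seeded", {
  d <- make_separable(1)
  for (alg in c("AdaBoost", "LogitBoost", "RUSBoost")) {
    fit <- train_boost(d$X, d$y, boost_config(alg, n_stumps = 50, seed = 2))
    expect_equal(mean(predict(fit, d$X, "label") == d$y), 1,
                 info = alg)
  }
  f1 <- train_boost(d$X, d$y, boost_config("RUSBoost", n_stumps = 20,
                                           seed = 7))
  f2 <- train_boost(d$X, d$y, boost_config("RUSBoost", n_stumps = 20,
                                           seed = 7))
  expect_identical(f1$stumps, f2$stumps)
  expect_error(train_boost(d$X, factor(rep("a", nrow(d$X)))),
               "two classes")
})

test_that("LogitBoost training log-loss is non-increasing", {
  set.seed(4)
  X <- cbind(a = c(rnorm(40, 0), rnorm(40, 1.5)), b = rnorm(80))
  y <- factor(rep(c("h", "d"), each = 40), levels = c("h", "d"))
  fit <- train_boost(X, y, boost_config("LogitBoost", n_stumps = 150))
  expect_true(all(diff(fit$train_logloss) <= 1e-12))
})

test_that("prediction scores behave additively with sane defaults", {
  d <- make_separable(2)
  fit <- train_boost(d$X, d$y, boost_config("AdaBoost", n_stumps = 10))
  expect_error(predict(fit, cbind(d$X, d$X)), "mismatch")

  sc0 <- predict(fit, d$X, "score", n_stumps = 0)
  expect_true(all(sc0 == 0))
  expect_equal(as.character(unique(predict(fit, d$X, "label",
                                           n_stumps = 0))),
               "healthy")                      # default class at score 0

  sc1 <- predict(fit, d$X, "score", n_stumps = 1)
  expect_length(unique(sc1), 2L)

  # separable training data: scores perfectly ordered by class
  fit50 <- train_boost(d$X, d$y, boost_config("AdaBoost", n_stumps = 50))
  sc <- predict(fit50, d$X, "score")
  expect_true(min(sc[d$y == "disordered"]) > max(sc[d$y == "healthy"]))
})

test_that("feature importance concentrates mass and sums over duplicates", {
  d <- make_separable(3)
  fit <- train_boost(d$X, d$y, boost_config("LogitBoost", n_stumps = 30))
  fi <- feature_importance(fit)
  expect_equal(fi$normalized[1], 1)
  expect_equal(fi$feature[1], "x")

  set.seed(5)
  X1 <- cbind(inf = c(rnorm(40, 0), rnorm(40, 3)), n1 = rnorm(80))
  y <- factor(rep(c("h", "d"), each = 40), levels = c("h", "d"))
  f_single <- train_boost(X1, y, boost_config("LogitBoost", n_stumps = 60))
  fi_single <- feature_importance(f_single)
  Xd <- cbind(X1[, 1, drop = FALSE], dup = X1[, 1], n1 = X1[, 2])
  f_dup <- train_boost(Xd, y, boost_config("LogitBoost", n_stumps = 60))
  fi_dup <- feature_importance(f_dup)
  sum_dup <- sum(fi_dup$raw[fi_dup$feature %in% c("inf", "dup")])
  expect_equal(sum_dup, fi_single$raw[fi_single$feature == "inf"],
               tolerance = 0.1)
})

test_that("injected random features earn negligible importance", {
  set.seed(6)
  X <- cbind(inf = c(runif(50, 0, 1), runif(50, 2, 3)),
             rand_n = rnorm(100), rand_u = runif(100))
  y <- factor(rep(c("h", "d"), each = 50), levels = c("h", "d"))
  for (alg in c("AdaBoost", "LogitBoost")) {
    fi <- feature_importance(train_boost(X, y, boost_config(alg,
                                                            n_stumps = 100)))
    expect_lt(max(fi$normalized[fi$feature != "inf"]), 0.1)
  }
  # per-round undersampling gives RUSBoost noisier splits; the suitability
  # bar is the 0.5 flag threshold
  fi_rus <- feature_importance(train_boost(X, y, boost_config("RUSBoost",
                                                              n_stumps = 100)))
  expect_lt(max(fi_rus$normalized[fi_rus$feature != "inf"]), 0.5)
})

test_that("cross-validation reports chance level on shuffled labels", {
  # permutation null: averaged over shuffled-label datasets
  aucs <- vapply(1:6, function(ds) {
    set.seed(ds)
    X <- matrix(rnorm(200 * 3), ncol = 3)
    y <- factor(rep(c("h", "d"), each = 100), levels = c("h", "d"))
    cv <- crossval_evaluate(X, y, boost_config("LogitBoost", n_stumps = 30),
                            k = 10, repeats = 2, seed = 1)
    cv$summary$mean[cv$summary$measure == "auc"]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  d <- make_separable(8, n_per_class = 40)
  cv2 <- crossval_evaluate(d$X, d$y, boost_config("LogitBoost",
                                                  n_stumps = 30),
                           k = 10, repeats = 1, seed = 1)
  expect_equal(cv2$summary$mean[cv2$summary$measure == "auc"], 1)
  expect_equal(cv2$summary$mean[cv2$summary$measure == "acc"], 1)

  cv3 <- crossval_evaluate(d$X, d$y, boost_config("LogitBoost",
                                                  n_stumps = 10),
                           k = 5, repeats = 1, seed = 3)
  cv4 <- crossval_evaluate(d$X, d$y, boost_config("LogitBoost",
                                                  n_stumps = 10),
                           k = 5, repeats = 1, seed = 3)
  expect_identical(cv3$summary, cv4$summary)
  expect_error(crossval_evaluate(d$X[1:45, , drop = FALSE], d$y[1:45],
                                 k = 10), "smaller k")
})

test_that("AdaBoost matches a reference boosted-stump implementation", {
  skip_if_not_installed("xgboost")
  diffs <- vapply(1:3, function(s) {
    set.seed(s)
    Xtr <- matrix(rnorm(40 * 3), ncol = 3)
    Xtr[, 1] <- Xtr[, 1] + rep(c(0, 2), each = 20)
    ytr <- factor(rep(c("h", "d"), each = 20), levels = c("h", "d"))
    set.seed(s + 50)
    Xte <- matrix(rnorm(200 * 3), ncol = 3)
    Xte[, 1] <- Xte[, 1] + rep(c(0, 2), each = 100)
    yte <- factor(rep(c("h", "d"), each = 100), levels = c("h", "d"))

    fit <- train_boost(Xtr, ytr, boost_config("AdaBoost", n_stumps = 100,
                                              learning_rate = 0.1))
    acc_ours <- mean(predict(fit, Xte, "label") == yte)
    bst <- xgboost::xgboost(x = Xtr, y = factor(as.integer(ytr == "d")),
                            max_depth = 1, learning_rate = 0.1,
                            nrounds = 100, verbosity = 0, nthread = 1)
    ref <- as.integer(as.character(predict(bst, Xte, type = "class")))
    acc_ref <- mean(ref == as.integer(yte == "d"))
    abs(acc_ours - acc_ref)
  }, numeric(1))
  expect_lt(max(diffs), 0.05 + 1e-9)
})

test_that("RUSBoost approaches AdaBoost under balanced classes", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    X <- cbind(a = c(rnorm(30, 0), rnorm(30, 1.5)), b = rnorm(60))
    y <- factor(rep(c("h", "d"), each = 30), levels = c("h", "d"))
    va <- vapply(c("AdaBoost", "RUSBoost"), function(alg) {
      cv <- crossval_evaluate(X, y, boost_config(alg, n_stumps = 30),
                              k = 5, repeats = 1, seed = s)
      cv$summary$mean[cv$summary$measure == "auc"]
    }, numeric(1))
    va["AdaBoost"] - va["RUSBoost"]
  }, numeric(1))
  expect_lt(abs(mean(aucs)), 0.05)
})

test_that("tidy and glance surfaces expose the fit", {
  d <- make_separable(9)
  fit <- train_boost(d$X, d$y, boost_config("LogitBoost", n_stumps = 15))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 15L)
  g <- glance(fit)
  expect_equal(g$algorithm, "LogitBoost")
  ens <- jsonlite::toJSON(td, digits = NA)
  expect_true(nchar(ens) > 0)
})
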