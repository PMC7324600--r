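#' Configuration for boosted decision stumps
#'
#' Depth-1 trees ("stumps") are boosted with one of three algorithms:
#' AdaBoost (exponential reweighting), LogitBoost (Newton steps on the
#' binomial log-likelihood, suited to hardly separable classes) or RUSBoost
#' (AdaBoost with per-round random undersampling of the majority class,
#' suited to imbalanced cohorts). Stumps are used instead of deeper trees to
#' avoid overfitting; shrinkage (`learning_rate = 0.1`) and a uniform class
#' prior (initial observation weights `1/(2 n_class)`) follow the same
#' rationale on imbalanced clinical group sizes.
#'
#' @param algorithm `"LogitBoost"`, `"AdaBoost"` or `"RUSBoost"`.
#' @param n_stumps Number of boosting rounds (>= 1).
#' @param learning_rate Shrinkage in (0, 1]; default 0.1.
#' @param prior `"uniform"` (default; initial weights `1/(2 n_class)`) or
#'   `"empirical"` (`1/n`).
#' @param seed Integer seed (drives the RUSBoost subsampling; training is
#'   deterministic given it).
#' @return A `pv_boost_config`.
#' @export
boost_config <- function(algorithm = c("LogitBoost", "AdaBoost", "RUSBoost"),
                         n_stumps = 100L, learning_rate = 0.1,
                         prior = c("uniform", "empirical"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  prior <- match.arg(prior)
  check_scalar(n_stumps, "n_stumps", 1, Inf)
  check_scalar(learning_rate, "learning_rate", 0, 1, lo_open = TRUE)
  structure(list(algorithm = algorithm, n_stumps = as.integer(n_stumps),
                 learning_rate = learning_rate, prior = prior,
                 seed = as.integer(seed)),
            class = "pv_boost_config")
}

#' Fit a single decision stump
#'
#' Exhaustive search over all features and all midpoints between adjacent
#' distinct observed values, minimizing the weighted squared error (for a
#' numeric working response, LogitBoost's base problem) or the weighted
#' misclassification (for labels in -1/+1, AdaBoost's base problem). The
#' recorded `gain` is the criterion reduction relative to the best constant
#' prediction, hence always >= 0. Ties are broken towards the lowest feature
#' index, then the lowest threshold. If every feature is constant a
#' degenerate single-value stump with zero gain is returned.
#'
#' @param X Numeric matrix (subjects x features).
#' @param y Response: numeric working response (`type = "ls"`) or -1/+1
#'   labels (`type = "class"`).
#' @param weights Nonnegative observation weights, not all zero.
#' @param type `"ls"` or `"class"`.
#' @return A list: `feature` (column index, `NA` if degenerate),
#'   `threshold`, `left`, `right` (leaf values; `x <= threshold` goes left),
#'   `gain`.
#' @export
fit_stump <- function(X, y, weights, type = c("ls", "class")) {
  type <- match.arg(type)
  if (any(weights < 0) || sum(weights) <= 0) {
    abort_field("weights", "must be nonnegative and not all zero")
  }
  n <- nrow(X); p <- ncol(X)
  w <- weights
  best <- NULL
  totW <- sum(w)
  if (type == "ls") {
    totWY <- sum(w * y)
    parent_pred <- totWY / totW
    parent_crit <- sum(w * (y - parent_pred)^2)
  } else {
    S <- sum(w * y)
    parent_crit <- (totW - abs(S)) / 2
  }
  for (j in seq_len(p)) {
    ord <- order(X[, j])
    xs <- X[ord, j]
    valid <- which(xs[-n] < xs[-1L])
    if (length(valid) == 0L) next
    ws <- w[ord]; ys <- y[ord]
    cumW <- cumsum(ws)
    if (type == "ls") {
      cumWY <- cumsum(ws * ys)
      wl <- cumW[valid]; wr <- totW - wl
      sl <- cumWY[valid]; sr <- sum(ws * ys) - sl
      crit <- sum(ws * ys^2) - sl^2 / wl - sr^2 / wr
      crit[wl <= 0 | wr <= 0] <- Inf
    } else {
      cumS <- cumsum(ws * ys)
      sl <- cumS[valid]; sr <- sum(ws * ys) - sl
      crit <- (totW - abs(sl) - abs(sr)) / 2
    }
    i_best <- which.min(crit)
    if (is.null(best) || crit[i_best] < best$crit - 1e-12) {
      i <- valid[i_best]
      if (type == "ls") {
        wl <- cumW[i]; wr <- totW - wl
        sl <- cumsum(ws * ys)[i]; sr <- sum(ws * ys) - sl
        left <- sl / wl; right <- sr / wr
      } else {
        sl <- cumsum(ws * ys)[i]; sr <- sum(ws * ys) - sl
        left <- if (sl > 0) 1 else -1
        right <- if (sr > 0) 1 else -1
      }
      best <- list(feature = j, threshold = (xs[i] + xs[i + 1L]) / 2,
                   left = left, right = right, crit = crit[i_best])
    }
  }
  if (is.null(best)) {
    const <- if (type == "ls") sum(w * y) / totW else {
      if (sum(w * y) > 0) 1 else -1
    }
    return(list(feature = NA_integer_, threshold = NA_real_,
                left = const, right = const, gain = 0))
  }
  list(feature = best$feature, threshold = best$threshold,
       left = best$left, right = best$right,
       gain = max(parent_crit - best$crit, 0))
}

stump_predict <- function(stump, X) {
  if (is.na(stump$feature)) return(rep(stump$left, nrow(X)))
  ifelse(X[, stump$feature] <= stump$threshold, stump$left, stump$right)
}

#' Train a boosted-stump ensemble
#'
#' @param X Numeric matrix or data frame of features (subjects x features).
#' @param y Two-level factor (second level = positive / disordered class) or
#'   a vector coercible to one.
#' @param config A [boost_config()].
#' @return A `pv_ensemble`: list with `stumps` (tibble: `feature` index,
#'   `feature_name`, `threshold`, `left`, `right` - leaf contributions
#'   already scaled by stage weight and shrinkage - and `gain`), `config`,
#'   `levels`, `feature_names`, `train_logloss` (LogitBoost only).
#' @export
#' @examples
#' X <- matrix(c(0, 1, 2, 3), ncol = 1)
#' y <- factor(c("a", "a", "b", "b"))
#' fit <- train_boost(X, y, boost_config("AdaBoost", n_stumps = 5))
#' predict(fit, X)
train_boost <- function(X, y, config = boost_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.factor(y)
  if (nlevels(y) != 2L || any(table(y) == 0L)) {
    abort("`y` must contain exactly two classes", class = "phonovibe_error")
  }
  yy <- ifelse(y == levels(y)[2], 1, -1)
  n <- nrow(X)
  n_by <- table(y)[y]
  obs_w <- if (config$prior == "uniform") 1 / (2 * as.numeric(n_by))
           else rep(1 / n, n)
  obs_w <- obs_w / sum(obs_w)
  lr <- config$learning_rate
  M <- config$n_stumps
  stumps <- vector("list", M)
  train_logloss <- NULL

  with_seed(config$seed, {
    if (config$algorithm == "LogitBoost") {
      y01 <- (yy + 1) / 2
      Fx <- rep(0, n)
      p_hat <- rep(0.5, n)
      train_logloss <- numeric(M)
      for (m in seq_len(M)) {
        p_hat <- pmin(pmax(p_hat, 1e-10), 1 - 1e-10)
        wvar <- p_hat * (1 - p_hat)
        z <- pmin(pmax((y01 - p_hat) / wvar, -4), 4)
        w <- obs_w * pmax(wvar, 1e-10)
        st <- fit_stump(X, z, w, type = "ls")
        contrib <- 0.5 * lr * stump_predict(st, X)
        Fx <- Fx + contrib
        p_hat <- 1 / (1 + exp(-2 * Fx))
        stumps[[m]] <- tibble(
          feature = st$feature, threshold = st$threshold,
          left = 0.5 * lr * st$left, right = 0.5 * lr * st$right,
          gain = st$gain)
        pc <- pmin(pmax(p_hat, 1e-10), 1 - 1e-10)
        train_logloss[m] <- -sum(obs_w * (y01 * log(pc) +
                                            (1 - y01) * log(1 - pc)))
      }
    } else {
      rus <- config$algorithm == "RUSBoost"
      d <- obs_w
      minority <- names(which.min(table(y)))
      for (m in seq_len(M)) {
        d <- d / sum(d)
        if (rus) {
          idx_min <- which(y == minority)
          idx_maj <- which(y != minority)
          sub <- c(idx_min,
                   if (length(idx_maj) > length(idx_min)) {
                     sample(idx_maj, length(idx_min))
                   } else idx_maj)
          st <- fit_stump(X[sub, , drop = FALSE], yy[sub], d[sub],
                          type = "class")
        } else {
          st <- fit_stump(X, yy, d, type = "class")
        }
        pred <- stump_predict(st, X)
        err <- sum(d[pred != yy])
        err <- pmin(pmax(err, 1e-10), 1 - 1e-10)
        alpha <- 0.5 * lr * log((1 - err) / err)
        d <- d * exp(-alpha * yy * pred)
        stumps[[m]] <- tibble(
          feature = st$feature, threshold = st$threshold,
          left = alpha * st$left, right = alpha * st$right,
          gain = st$gain)
      }
    }
  })
  stumps <- bind_rows(stumps)
  stumps$feature_name <- colnames(X)[stumps$feature]
  structure(list(stumps = stumps, config = config, levels = levels(y),
                 feature_names = colnames(X),
                 n_features = ncol(X),
                 train_logloss = train_logloss),
            class = "pv_ensemble")
}

#' Prediction scores and class labels from a stump ensemble
#'
#' Scores are the additive stump sum; labels take the positive (second)
#' class when the score exceeds 0. Any strictly increasing transform of the
#' scores leaves the ROC - hence the AUC - unchanged.
#'
#' @param object A `pv_ensemble`.
#' @param newdata Feature matrix or data frame with the training feature
#'   count.
#' @param type `"score"`, `"label"` or `"both"`.
#' @param n_stumps Use only the first `n_stumps` stumps (default all);
#'   exposes the nested prefix models of a boosting run.
#' @param ... Unused.
#' @return Numeric scores, factor labels, or a tibble with both.
#' @export
predict.pv_ensemble <- function(object, newdata, type = c("score", "label",
                                                          "both"),
                                n_stumps = NULL, ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$n_features) {
    abort(sprintf("feature count mismatch: ensemble expects %d, got %d",
                  object$n_features, ncol(X)), class = "phonovibe_error")
  }
  st <- object$stumps
  if (!is.null(n_stumps)) st <- st[seq_len(min(n_stumps, nrow(st))), ]
  scores <- rep(0, nrow(X))
  for (m in seq_len(nrow(st))) {
    scores <- scores + if (is.na(st$feature[m])) st$left[m] else
      ifelse(X[, st$feature[m]] <= st$threshold[m], st$left[m], st$right[m])
  }
  labels <- factor(object$levels[(scores > 0) + 1L], levels = object$levels)
  switch(type, score = scores, label = labels,
         both = tibble(score = scores, label = labels))
}

#' Feature importance of a stump ensemble
#'
#' Per feature, the sum of the recorded split-criterion reductions divided
#' by the number of stumps, then normalized so the most important feature
#' scores 1. Features never split on score 0.
#'
#' @param ensemble A `pv_ensemble`.
#' @return A `pv_importance` tibble: `feature`, `raw`, `normalized`, sorted
#'   by decreasing importance with ties in training feature order.
#' @export
feature_importance <- function(ensemble) {
  nm <- ensemble$feature_names
  raw <- setNames(rep(0, length(nm)), nm)
  ok <- !is.na(ensemble$stumps$feature)
  agg <- tapply(ensemble$stumps$gain[ok],
                ensemble$stumps$feature_name[ok], sum)
  raw[names(agg)] <- agg / nrow(ensemble$stumps)
  norm <- if (max(raw) > 0) raw / max(raw) else raw
  out <- tibble(feature = nm, raw = unname(raw), normalized = unname(norm))
  out <- out[order(-out$raw), ]
  structure(out, class = c("pv_importance", class(tibble())))
}

#' @export
tidy.pv_ensemble <- function(x, ...) x$stumps

#' @export
glance.pv_ensemble <- function(x, ...) {
  tibble(algorithm = x$config$algorithm, n_stumps = nrow(x$stumps),
         learning_rate = x$config$learning_rate,
         n_features_used = length(unique(stats::na.omit(x$stumps$feature))),
         final_train_logloss = if (is.null(x$train_logloss)) NA_real_
                               else tail(x$train_logloss, 1))
}

#' @export
print.pv_ensemble <- function(x, ...) {
  cat(sprintf("<pv_ensemble> %s, %d stumps over %d features\n",
              x$config$algorithm, nrow(x$stumps), x$n_features))
  invisible(x)
}

#' @export
autoplot.pv_importance <- function(object, top = 10, ...) {
  d <- head(object, top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$normalized, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "normalized feature importance", y = NULL)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

classification_measures <- function(scores, truth, positive) {
  pos <- truth == positive
  pred_pos <- scores > 0
  c(auc = auc_mw(scores, pos),
    acc = mean(pred_pos == pos),
    sensitivity = if (any(pos)) mean(pred_pos[pos]) else NA_real_,
    specificity = if (any(!pos)) mean(!pred_pos[!pos]) else NA_real_)
}

#' Repeated stratified cross-validated performance
#'
#' Stratified k-fold cross-validation, repeated with fresh seeded
#' partitions to wash out the influence of any single random split. The
#' AUC is computed per test fold from the ensemble scores (Mann-Whitney
#' formulation) and then averaged over folds and repeats; accuracy,
#' sensitivity (disordered correctly flagged) and specificity (healthy
#' correctly cleared) use the score threshold 0.
#'
#' @param X Feature matrix or data frame.
#' @param y Two-level factor (second level = positive class).
#' @param config A [boost_config()].
#' @param k Folds (default 10); every class must have at least `k` members.
#' @param repeats Partition repetitions (default 10).
#' @param seed Integer seed for the partitions.
#' @return A `pv_cv`: list with `summary` (tibble: `measure`, `mean`, `sd`)
#'   and `folds` (per-fold measures).
#' @export
crossval_evaluate <- function(X, y, config = boost_config(), k = 10L,
                              repeats = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (min(table(y)) < k) {
    abort(sprintf(
      "smallest class (n = %d) has fewer members than k = %d; use smaller k",
      min(table(y)), k), class = "phonovibe_error")
  }
  rows <- list()
  for (r in seq_len(repeats)) {
    fold <- with_seed(derive_seed(seed, r), stratified_folds(y, k))
    for (f in seq_len(k)) {
      test <- fold == f
      cfg <- config
      cfg$seed <- derive_seed(seed, r * 1000L + f)
      fit <- train_boost(X[!test, , drop = FALSE], y[!test], cfg)
      sc <- predict(fit, X[test, , drop = FALSE], type = "score")
      rows[[length(rows) + 1L]] <- c(repeat_ = r, fold = f,
                                     classification_measures(
                                       sc, y[test], levels(y)[2]))
    }
  }
  folds <- as_tibble(do.call(rbind, rows))
  summary <- tibble(
    measure = c("auc", "acc", "sensitivity", "specificity"),
    mean = map_dbl(c("auc", "acc", "sensitivity", "specificity"),
                   ~ mean(folds[[.x]], na.rm = TRUE)),
    sd = map_dbl(c("auc", "acc", "sensitivity", "specificity"),
                 ~ sd(folds[[.x]], na.rm = TRUE)))
  structure(list(summary = summary, folds = folds, k = k,
                 repeats = repeats, config = config),
            class = "pv_cv")
}

#' @export
tidy.pv_cv <- function(x, ...) x$summary

#' @export
glance.pv_cv <- function(x, ...) {
  s <- x$summary
  tibble(auc = s$mean[s$measure == "auc"],
         acc = s$mean[s$measure == "acc"],
         sensitivity = s$mean[s$measure == "sensitivity"],
         specificity = s$mean[s$measure == "specificity"],
         k = x$k, repeats = x$repeats, algorithm = x$config$algorithm)
}

#' @export
print.pv_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pv_cv> %s, %d-fold x %d: AUC %.3f (sd %.3f), ACC %.3f\n",
              x$config$algorithm, x$k, x$repeats,
              s$mean[s$measure == "auc"], s$sd[s$measure == "auc"],
              s$mean[s$measure == "acc"]))
  invisible(x)
}

# Cross-validated AUC/ACC of the nested prefix models of one boosting run:
# trains the full-size ensemble once per fold and scores every requested
# prefix size. Shared by the stump-count sweep.
crossval_sweep <- function(X, y, config, sizes, k = 10L, repeats = 2L,
                           seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  sizes <- sort(unique(as.integer(sizes)))
  acc_auc <- array(NA_real_, dim = c(repeats * k, length(sizes), 2L))
  row <- 0L
  for (r in seq_len(repeats)) {
    fold <- with_seed(derive_seed(seed, r), stratified_folds(y, k))
    for (f in seq_len(k)) {
      row <- row + 1L
      test <- fold == f
      cfg <- config
      cfg$n_stumps <- max(sizes)
      cfg$seed <- derive_seed(seed, r * 1000L + f)
      fit <- train_boost(X[!test, , drop = FALSE], y[!test], cfg)
      Xt <- X[test, , drop = FALSE]
      st <- fit$stumps
      scores <- rep(0, nrow(Xt))
      si <- 1L
      for (m in seq_len(nrow(st))) {
        scores <- scores + if (is.na(st$feature[m])) st$left[m] else
          ifelse(Xt[, st$feature[m]] <= st$threshold[m],
                 st$left[m], st$right[m])
        if (si <= length(sizes) && m == sizes[si]) {
          ms <- classification_measures(scores, y[test], levels(y)[2])
          acc_auc[row, si, 1] <- ms["auc"]
          acc_auc[row, si, 2] <- ms["acc"]
          si <- si + 1L
        }
      }
    }
  }
  tibble(size = sizes,
         auc_mean = apply(acc_auc[, , 1, drop = FALSE], 2, mean),
         auc_sd = apply(acc_auc[, , 1, drop = FALSE], 2, sd),
         acc_mean = apply(acc_auc[, , 2, drop = FALSE], 2, mean),
         acc_sd = apply(acc_auc[, , 2, drop = FALSE], 2, sd))
}
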