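# The anesthetic-concentration predictor: quantile transform -> mutual-
# information feature selection -> RBF support-vector classifier (whose
# prediction is appended as an extra feature) -> RBF support-vector
# regressor, trained and evaluated by resampled 2/3-1/3 splits with 3-fold
# inner grid search.

#' Hyper-parameter grids
#'
#' `default_spec_grid()` spans the regimes the quantile-transform / RBF
#' family needs; `reduced_spec_grid()` is a small grid for resampled runs at
#' desk scale. `gamma = "scale"` is the kernel-width heuristic
#' `1 / (n_features * var(X))`.
#'
#' @return named list of candidate values for `n_quantiles`,
#'   `select_percentile`, `C`, `gamma`, `epsilon`.
#' @export
default_spec_grid <- function() {
  list(n_quantiles = c(10, 100, 1000),
       select_percentile = c(25, 50, 75, 100),
       C = c(0.1, 1, 10, 100),
       gamma = list("scale", 0.01, 0.1, 1),
       epsilon = c(0.01, 0.1, 0.5))
}

#' @rdname default_spec_grid
#' @export
reduced_spec_grid <- function() {
  list(n_quantiles = 100,
       select_percentile = c(50, 100),
       C = c(1, 10),
       gamma = list("scale"),
       epsilon = c(0.01, 0.1))
}

# ---- quantile transform -----------------------------------------------------

fit_quantile_transform <- function(X, n_quantiles = 100) {
  probs <- seq(0, 1, length.out = max(2L, min(n_quantiles, nrow(X))))
  refs <- lapply(seq_len(ncol(X)), function(j)
    stats::quantile(X[, j], probs, type = 7, names = FALSE))
  structure(list(refs = refs, probs = probs), class = "quantile_transform")
}

apply_quantile_transform <- function(qt, X) {
  out <- matrix(0.5, nrow(X), ncol(X))
  colnames(out) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    r <- qt$refs[[j]]
    if (diff(range(r)) <= 0) next
    xj <- pmin(pmax(X[, j], r[1]), r[length(r)])
    out[, j] <- stats::approx(r, qt$probs, xout = xj, rule = 2,
                              ties = max)$y
  }
  out
}

# ---- mutual-information feature scores --------------------------------------

# quantile-binned plug-in mutual information (nats); ranking-only use
mutual_information <- function(x, y, n_bins = 8) {
  disc <- function(v) {
    u <- unique(v)
    if (length(u) <= n_bins) return(match(v, sort(u)))
    br <- unique(stats::quantile(v, seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3) return(rep(1L, length(v)))
    cut(v, br, include.lowest = TRUE, labels = FALSE)
  }
  tb <- table(disc(x), disc(y))
  p <- tb / sum(tb)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

select_features <- function(X, y, percentile, n_bins = 8) {
  if (percentile <= 0 || percentile > 100)
    stop("invalid parameter: select_percentile must be in (0, 100]")
  scores <- vapply(seq_len(ncol(X)), function(j)
    mutual_information(X[, j], y, n_bins), numeric(1))
  k <- max(1L, ceiling(percentile / 100 * ncol(X)))
  sort(order(scores, decreasing = TRUE)[seq_len(k)])
}

resolve_gamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(X))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else as.numeric(gamma)
}

# ---- pipeline ---------------------------------------------------------------

# stratified-ish fold ids, deterministic given the RNG state
fold_ids <- function(n, k) sample(rep_len(seq_len(k), n))

# fit the binary anesthetized/awake classifier on already-transformed,
# selected features; degenerate single-class input yields a constant model
fit_clf <- function(Xs, ybin, C, gamma) {
  if (nlevels(droplevels(ybin)) < 2)
    return(list(constant = as.numeric(as.character(ybin[1]))))
  g <- resolve_gamma(gamma, Xs)
  e1071::svm(Xs, ybin, type = "C-classification", kernel = "radial",
             cost = C, gamma = g, scale = FALSE)
}

predict_clf <- function(clf, Xs) {
  if (!is.null(clf$constant)) return(rep(clf$constant, nrow(Xs)))
  as.numeric(as.character(stats::predict(clf, Xs)))
}

# full pipeline fit; the classifier feature on training rows is the 3-fold
# out-of-fold prediction, so the regressor never sees in-sample classifier
# output
fit_depth_pipeline <- function(X, y, spec, inner_folds = 3) {
  qt <- fit_quantile_transform(X, spec$n_quantiles)
  Xt <- apply_quantile_transform(qt, X)
  sel <- select_features(Xt, y, spec$select_percentile)
  Xs <- Xt[, sel, drop = FALSE]
  ybin <- factor(as.integer(y > 0), levels = c(0, 1))
  clf <- fit_clf(Xs, ybin, spec$C_clf, spec$gamma_clf)
  oof <- rep(NA_real_, nrow(Xs))
  if (is.null(clf$constant)) {
    ids <- fold_ids(nrow(Xs), inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- ids != f
      cf <- fit_clf(Xs[tr, , drop = FALSE], droplevels(ybin[tr]),
                    spec$C_clf, spec$gamma_clf)
      oof[!tr] <- predict_clf(cf, Xs[!tr, , drop = FALSE])
    }
  } else {
    oof <- rep(clf$constant, nrow(Xs))
  }
  Xr <- cbind(Xs, clf_feat = oof)
  g <- resolve_gamma(spec$gamma, Xr)
  reg <- e1071::svm(Xr, y, type = "eps-regression", kernel = "radial",
                    cost = spec$C, gamma = g, epsilon = spec$epsilon,
                    scale = FALSE)
  structure(list(qt = qt, sel = sel, clf = clf, reg = reg, spec = spec),
            class = "depth_pipeline")
}

# transformed regressor input for new rows (classifier feature appended)
pipeline_features <- function(object, X) {
  Xt <- apply_quantile_transform(object$qt, X)
  Xs <- Xt[, object$sel, drop = FALSE]
  cbind(Xs, clf_feat = predict_clf(object$clf, Xs))
}

#' @export
predict.depth_pipeline <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$reg, pipeline_features(object, newdata)))
}

# ---- tuning -----------------------------------------------------------------

expand_grid_list <- function(...) {
  g <- expand.grid(..., stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# two-stage 3-fold grid search: classifier hyper-parameters by accuracy,
# then the remaining pipeline by regressor R^2 (classifier feature computed
# in-sample per fold during tuning for tractability)
tune_depth_pipeline <- function(X, y, grid, inner_folds = 3) {
  n <- nrow(X)
  ids <- fold_ids(n, inner_folds)
  ybin <- factor(as.integer(y > 0), levels = c(0, 1))
  mid_q <- grid$n_quantiles[ceiling(length(grid$n_quantiles) / 2)]

  clf_combos <- expand_grid_list(C = grid$C, gamma = grid$gamma)
  acc <- vapply(clf_combos, function(cb) {
    mean(vapply(seq_len(inner_folds), function(f) {
      tr <- ids != f
      if (nlevels(droplevels(ybin[tr])) < 2) return(NA_real_)
      qt <- fit_quantile_transform(X[tr, , drop = FALSE], mid_q)
      Xt_tr <- apply_quantile_transform(qt, X[tr, , drop = FALSE])
      Xt_te <- apply_quantile_transform(qt, X[!tr, , drop = FALSE])
      cf <- fit_clf(Xt_tr, droplevels(ybin[tr]), cb$C, cb$gamma[[1]])
      mean(predict_clf(cf, Xt_te) == (as.integer(y[!tr] > 0)))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best_clf <- clf_combos[[which.max(acc)]]

  reg_combos <- expand_grid_list(n_quantiles = grid$n_quantiles,
                                 select_percentile = grid$select_percentile,
                                 C = grid$C, gamma = grid$gamma,
                                 epsilon = grid$epsilon)
  r2 <- vapply(reg_combos, function(cb) {
    mean(vapply(seq_len(inner_folds), function(f) {
      tr <- ids != f
      qt <- fit_quantile_transform(X[tr, , drop = FALSE], cb$n_quantiles)
      Xt_tr <- apply_quantile_transform(qt, X[tr, , drop = FALSE])
      Xt_te <- apply_quantile_transform(qt, X[!tr, , drop = FALSE])
      sel <- select_features(Xt_tr, y[tr], cb$select_percentile)
      Xs_tr <- Xt_tr[, sel, drop = FALSE]
      Xs_te <- Xt_te[, sel, drop = FALSE]
      cf <- fit_clf(Xs_tr, droplevels(factor(as.integer(y[tr] > 0),
                                             levels = c(0, 1))),
                    best_clf$C, best_clf$gamma[[1]])
      Xr_tr <- cbind(Xs_tr, clf_feat = predict_clf(cf, Xs_tr))
      Xr_te <- cbind(Xs_te, clf_feat = predict_clf(cf, Xs_te))
      g <- resolve_gamma(cb$gamma[[1]], Xr_tr)
      reg <- e1071::svm(Xr_tr, y[tr], type = "eps-regression",
                        kernel = "radial", cost = cb$C, gamma = g,
                        epsilon = cb$epsilon, scale = FALSE)
      evaluate_metrics(y[!tr], as.numeric(stats::predict(reg, Xr_te)))$R2
    }, numeric(1)))
  }, numeric(1))
  best <- reg_combos[[which.max(r2)]]
  list(n_quantiles = best$n_quantiles,
       select_percentile = best$select_percentile,
       C = best$C, gamma = best$gamma[[1]], epsilon = best$epsilon,
       C_clf = best_clf$C, gamma_clf = best_clf$gamma[[1]],
       inner_r2 = max(r2))
}

# ---- metrics ----------------------------------------------------------------

#' Regression evaluation metrics
#'
#' Coefficient of determination `R^2 = 1 - SS_res / SS_tot` and the median
#' absolute error between true and predicted concentration.
#'
#' @param true,predicted equal-length numeric vectors (length >= 2).
#' @return list with `R2` and `median_abs_error`.
#' @export
evaluate_metrics <- function(true, predicted) {
  if (length(true) != length(predicted)) stop("invalid parameter: unequal lengths")
  if (length(true) < 2) stop("invalid parameter: need >= 2 observations")
  ss_res <- sum((true - predicted)^2)
  ss_tot <- sum((true - mean(true))^2)
  list(R2 = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
       median_abs_error = as.numeric(stats::median(abs(true - predicted))))
}

# ---- resampled training -----------------------------------------------------

table_xy <- function(table) {
  fc <- feature_cols(table)
  if (is.null(fc)) stop("invalid parameter: not a feature_table")
  X <- as.matrix(table[, fc, drop = FALSE])
  if (any(!is.finite(X))) stop("invalid parameter: non-finite feature values")
  list(X = X, y = table$concentration,
       groups = if ("subject_id" %in% names(table)) table$subject_id else NULL)
}

# one train/test split of row indices; group_by_subject keeps a subject's
# rows on one side
split_rows <- function(n, test_fraction, groups, group_by_subject) {
  if (group_by_subject && !is.null(groups)) {
    gs <- unique(groups)
    te_g <- sample(gs, max(1, round(length(gs) * test_fraction)))
    which(groups %in% te_g)
  } else {
    sample.int(n, max(1, round(n * test_fraction)))
  }
}

#' Resampled training and evaluation of the depth predictor
#'
#' The table is iteratively (`n_iterations`) divided into a training set
#' (2/3 of the rows) and a held-out set (1/3); all pipeline hyper-parameters
#' are tuned by 3-fold grid search on the training part only, the pipeline
#' is refit on the full training part, and performance is assessed on the
#' held-out rows. Splits that leave a single distinct label in training are
#' redrawn.
#'
#' @param table a `feature_table` with a `concentration` label column.
#' @param spec_grid hyper-parameter grid, see [default_spec_grid()].
#' @param n_iterations number of outer resampling iterations.
#' @param test_fraction held-out fraction of rows per iteration.
#' @param inner_folds folds of the inner grid-search CV.
#' @param seed master seed; per-iteration seeds are derived from it, so a
#'   fixed seed gives identical splits, chosen hyper-parameters and metrics.
#' @param group_by_subject split at the subject level instead of row level.
#' @return a `model_result`: `per_iteration` data frame (`iteration`, `R2`,
#'   `median_abs_error`, chosen hyper-parameters), `predictions` data frame
#'   (`iteration`, `row`, `true`, `predicted`) and `summary` with pooled R^2
#'   and pooled median absolute error over all held-out predictions.
#' @export
train_evaluate <- function(table, spec_grid = reduced_spec_grid(),
                           n_iterations = 100, test_fraction = 1 / 3,
                           inner_folds = 3, seed = 1,
                           group_by_subject = FALSE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("invalid parameter: test_fraction must be in (0, 1)")
  d <- table_xy(table)
  if (length(unique(d$y)) < 2) stop("invalid parameter: need >= 2 distinct labels")
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max %/% 2, n_iterations)
  per_iter <- vector("list", n_iterations)
  preds <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    set.seed(iter_seeds[it])
    te <- split_rows(nrow(d$X), test_fraction, d$groups, group_by_subject)
    tries <- 0
    while (length(unique(d$y[-te])) < 2 && tries < 10) {
      te <- split_rows(nrow(d$X), test_fraction, d$groups, group_by_subject)
      tries <- tries + 1
    }
    spec <- tune_depth_pipeline(d$X[-te, , drop = FALSE], d$y[-te],
                                spec_grid, inner_folds)
    fit <- fit_depth_pipeline(d$X[-te, , drop = FALSE], d$y[-te], spec,
                              inner_folds)
    pr <- predict(fit, d$X[te, , drop = FALSE])
    met <- evaluate_metrics(d$y[te], pr)
    per_iter[[it]] <- data.frame(
      iteration = it, R2 = met$R2, median_abs_error = met$median_abs_error,
      n_quantiles = spec$n_quantiles,
      select_percentile = spec$select_percentile, C = spec$C,
      epsilon = spec$epsilon, C_clf = spec$C_clf)
    preds[[it]] <- data.frame(iteration = it, row = te, true = d$y[te],
                              predicted = pr)
  }
  predictions <- do.call(rbind, preds)
  pooled <- evaluate_metrics(predictions$true, predictions$predicted)
  structure(list(per_iteration = do.call(rbind, per_iter),
                 predictions = predictions, summary = pooled),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %d iteration(s)\n", nrow(x$per_iteration)))
  cat(sprintf("  pooled R^2 = %.3f, pooled median |error| = %.3f\n",
              x$summary$R2, x$summary$median_abs_error))
  invisible(x)
}

#' Binary anesthetized/awake classification
#'
#' Trains the same quantile-transform -> feature-selection -> RBF-SVM
#' classifier on the binary label `concentration > 0` with resampled
#' held-out accuracy; optionally scores a table recorded under a different
#' anesthetic than the training table (transfer test).
#'
#' @inheritParams train_evaluate
#' @param transfer_table optional second `feature_table` to score with a
#'   classifier fitted on all rows of `table`.
#' @return list with `per_iteration` accuracies, `accuracy` (their mean) and,
#'   when requested, `transfer_accuracy`.
#' @export
classify_anesthetized <- function(table, spec_grid = reduced_spec_grid(),
                                  n_iterations = 20, test_fraction = 1 / 3,
                                  inner_folds = 3, seed = 1,
                                  transfer_table = NULL) {
  d <- table_xy(table)
  ybin <- as.integer(d$y > 0)
  if (length(unique(ybin)) < 2)
    stop("invalid parameter: single-class input (no concentration contrast)")
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max %/% 2, n_iterations)
  fit_one <- function(X, y) {
    ids <- fold_ids(nrow(X), inner_folds)
    combos <- expand_grid_list(C = spec_grid$C, gamma = spec_grid$gamma)
    acc <- vapply(combos, function(cb) {
      mean(vapply(seq_len(inner_folds), function(f) {
        tr <- ids != f
        if (length(unique(y[tr])) < 2) return(NA_real_)
        qt <- fit_quantile_transform(X[tr, , drop = FALSE],
                                     spec_grid$n_quantiles[1])
        cf <- fit_clf(apply_quantile_transform(qt, X[tr, , drop = FALSE]),
                      factor(y[tr], levels = c(0, 1)), cb$C, cb$gamma[[1]])
        mean(predict_clf(cf, apply_quantile_transform(
          qt, X[!tr, , drop = FALSE])) == y[!tr])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    best <- combos[[which.max(acc)]]
    qt <- fit_quantile_transform(X, spec_grid$n_quantiles[1])
    clf <- fit_clf(apply_quantile_transform(qt, X),
                   factor(y, levels = c(0, 1)), best$C, best$gamma[[1]])
    list(qt = qt, clf = clf)
  }
  accs <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    set.seed(iter_seeds[it])
    te <- sample.int(nrow(d$X), max(1, round(nrow(d$X) * test_fraction)))
    tries <- 0
    while (length(unique(ybin[-te])) < 2 && tries < 10) {
      te <- sample.int(nrow(d$X), max(1, round(nrow(d$X) * test_fraction)))
      tries <- tries + 1
    }
    m <- fit_one(d$X[-te, , drop = FALSE], ybin[-te])
    accs[it] <- mean(predict_clf(
      m$clf, apply_quantile_transform(m$qt, d$X[te, , drop = FALSE])) ==
        ybin[te])
  }
  out <- list(per_iteration = accs, accuracy = mean(accs))
  if (!is.null(transfer_table)) {
    dt <- table_xy(transfer_table)
    set.seed(seed)
    m <- fit_one(d$X, ybin)
    out$transfer_accuracy <- mean(predict_clf(
      m$clf, apply_quantile_transform(m$qt, dt$X)) == as.integer(dt$y > 0))
  }
  out
}

#' Age-stratified depth models
#'
#' Either three separate regressors with 2 and 4 months as age cut-offs, or
#' a single model over all subjects with age appended as an input feature.
#'
#' @param table combined `feature_table` with an `age_months` column.
#' @param cutoffs_months age cut-offs (months).
#' @param mode `"three_models"` or `"single_model_with_age"`.
#' @param ... passed to [train_evaluate()].
#' @return `three_models`: named list of `model_result`s, one per age group;
#'   `single_model_with_age`: one `model_result`.
#' @export
train_age_stratified <- function(table, cutoffs_months = c(2, 4),
                                 mode = c("three_models",
                                          "single_model_with_age"), ...) {
  mode <- match.arg(mode)
  if (!"age_months" %in% names(table))
    stop("invalid parameter: table needs an age_months column")
  if (mode == "single_model_with_age") {
    fc <- feature_cols(table)
    tab <- table
    tab$age_feature <- tab$age_months
    attr(tab, "feature_cols") <- c(fc, "age_feature")
    class(tab) <- class(table)
    return(train_evaluate(tab, ...))
  }
  grp <- cut(table$age_months, breaks = c(-Inf, cutoffs_months, Inf),
             labels = c(sprintf("0-%g", cutoffs_months[1]),
                        sprintf("%g-%g", cutoffs_months[1], cutoffs_months[2]),
                        sprintf("%g+", cutoffs_months[2])), right = TRUE)
  present <- levels(grp)[tabulate(grp, nbins = nlevels(grp)) > 0]
  out <- lapply(present, function(g) {
    sub <- table[grp == g, , drop = FALSE]
    attr(sub, "feature_cols") <- feature_cols(table)
    class(sub) <- class(table)
    train_evaluate(sub, ...)
  })
  stats::setNames(out, present)
}

#' Small-training-set robustness
#'
#' Same resampled pipeline but training on a small fraction of the rows
#' (20% by default) and testing on the remainder.
#'
#' @inheritParams train_evaluate
#' @param train_fraction fraction of rows used for training, in (0, 1).
#' @return a `model_result`.
#' @export
train_fraction_robustness <- function(table, train_fraction = 0.2,
                                      spec_grid = reduced_spec_grid(),
                                      n_iterations = 20, inner_folds = 3,
                                      seed = 1, group_by_subject = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("invalid parameter: train_fraction must be in (0, 1)")
  train_evaluate(table, spec_grid = spec_grid, n_iterations = n_iterations,
                 test_fraction = 1 - train_fraction,
                 inner_folds = inner_folds, seed = seed,
                 group_by_subject = group_by_subject)
}
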