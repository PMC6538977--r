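# Depth-prediction pipeline: metrics, tuning, resampled evaluation,
# age stratification and the decision-space map.

small_grid <- function() {
  list(n_quantiles = 50, select_percentile = 100, C = 10,
       gamma = list("scale"), epsilon = c(0.01, 0.1))
}

test_that("evaluation metrics match their definitions", {
  expect_identical(evaluate_metrics(1:5, 1:5)$R2, 1)
  expect_identical(evaluate_metrics(1:5, 1:5)$median_abs_error, 0)
  expect_equal(evaluate_metrics(c(1, 2, 3, 4), rep(2.5, 4))$R2, 0)
  true <- c(0.5, 1.2, 2.0, 2.8, 3.1); pred <- c(0.7, 1.0, 2.5, 2.5, 3.0)
  m <- evaluate_metrics(true, pred)
  expect_equal(m$R2, 1 - sum((true - pred)^2) / sum((true - mean(true))^2))
  expect_equal(m$median_abs_error, median(abs(true - pred)))
  expect_error(evaluate_metrics(1:3, 1:4), "unequal")
  expect_error(evaluate_metrics(1, 1), ">= 2")
})

test_that("quantile transform maps to [0,1] and handles constants", {
  set.seed(1)
  X <- cbind(rnorm(60), rep(3, 60), rexp(60))
  qt <- anesdepth:::fit_quantile_transform(X, 20)
  Z <- anesdepth:::apply_quantile_transform(qt, X)
  expect_true(all(Z >= 0 & Z <= 1))
  expect_true(all(Z[, 2] == 0.5))            # constant column
  # monotone: order preserved within a column
  expect_identical(order(Z[, 1]), order(X[, 1]))
  # out-of-range values clip to the boundaries
  Z2 <- anesdepth:::apply_quantile_transform(qt, cbind(100, 3, -5))
  expect_identical(as.vector(Z2), c(1, 0.5, 0))
})

test_that("mutual-information scores rank informative features first", {
  set.seed(2)
  y <- sample(c(0, 1, 2, 3), 300, replace = TRUE)
  X <- cbind(good = y + rnorm(300, 0, 0.2), junk = rnorm(300))
  mi_good <- anesdepth:::mutual_information(X[, 1], y)
  mi_junk <- anesdepth:::mutual_information(X[, 2], y)
  expect_gt(mi_good, mi_junk + 0.2)
  expect_identical(anesdepth:::select_features(X, y, 50), 1L)
  expect_identical(anesdepth:::select_features(X, y, 100), c(1L, 2L))
})

test_that("a perfect feature yields near-perfect pooled recovery", {
  set.seed(3)
  conc <- sample(c(0, 1, 2, 3), 150, replace = TRUE)
  tab <- toy_feature_table(data.frame(exact = conc, junk = rnorm(150)), conc)
  mr <- train_evaluate(tab, spec_grid = small_grid(), n_iterations = 5, seed = 4)
  expect_gte(mr$summary$R2, 0.99)
  expect_lte(mr$summary$median_abs_error, 0.05)
})

test_that("permuted labels give a null-level pooled score", {
  tab <- toy_separable_table(150, seed = 5)
  set.seed(6)
  tab$concentration <- sample(tab$concentration)
  mr <- train_evaluate(tab, spec_grid = small_grid(), n_iterations = 5, seed = 7)
  expect_lte(mr$summary$R2, 0.05)
})

test_that("training is deterministic given the master seed", {
  tab <- toy_separable_table(100, seed = 8)
  a <- train_evaluate(tab, spec_grid = small_grid(), n_iterations = 3, seed = 9)
  b <- train_evaluate(tab, spec_grid = small_grid(), n_iterations = 3, seed = 9)
  expect_identical(a$per_iteration, b$per_iteration)
  expect_identical(a$predictions, b$predictions)
  c_ <- train_evaluate(tab, spec_grid = small_grid(), n_iterations = 3, seed = 10)
  expect_false(identical(a$predictions$predicted, c_$predictions$predicted))
})

test_that("fitted transforms ignore held-out labels (no leakage)", {
  tab <- toy_separable_table(90, seed = 11)
  d <- anesdepth:::table_xy(tab)
  tr <- 1:60; te <- 61:90
  fit_with <- function(y_test) {
    set.seed(12)
    spec <- anesdepth:::tune_depth_pipeline(d$X[tr, ], d$y[tr], small_grid(), 3)
    set.seed(13)
    anesdepth:::fit_depth_pipeline(d$X[tr, ], d$y[tr], spec, 3)
  }
  f1 <- fit_with(d$y[te])
  f2 <- fit_with(sample(d$y[te]))
  expect_identical(predict(f1, d$X[te, ]), predict(f2, d$X[te, ]))
})

test_that("the classifier separates anesthetized bins and transfers", {
  tab <- toy_separable_table(140, seed = 14)
  cl <- classify_anesthetized(tab, spec_grid = small_grid(),
                              n_iterations = 5, seed = 15)
  expect_gte(cl$accuracy, 0.95)
  # transfer to an independent cohort with the same suppression structure
  tab2 <- toy_separable_table(80, seed = 16)
  cl2 <- classify_anesthetized(tab, spec_grid = small_grid(),
                               n_iterations = 3, seed = 17,
                               transfer_table = tab2)
  expect_gt(cl2$transfer_accuracy, 0.8)
  # single-class input is rejected
  tab0 <- tab; tab0$concentration <- rep(2, nrow(tab0))
  expect_error(classify_anesthetized(tab0, small_grid()), "single-class")
})

test_that("age stratification splits groups and the single mode adds a column", {
  tabs <- lapply(1:3, function(g) {
    t <- toy_separable_table(60, seed = 20 + g)
    t$age_months <- c(1, 3, 5)[g]
    t$subject_id <- paste0("g", g)
    t
  })
  tab <- bind_feature_tables(tabs)
  strat <- train_age_stratified(tab, spec_grid = small_grid(),
                                n_iterations = 3, seed = 21)
  expect_named(strat, c("0-2", "2-4", "4+"))
  # only populated groups are trained
  expect_named(train_age_stratified(tabs[[2]], spec_grid = small_grid(),
                                    n_iterations = 2, seed = 30), "2-4")
  for (m in strat) expect_gt(m$summary$R2, 0.5)
  # all subjects in one group reduces to plain train_evaluate
  one <- tabs[[1]]
  solo <- train_age_stratified(one, spec_grid = small_grid(),
                               n_iterations = 3, seed = 22)[["0-2"]]
  plain <- train_evaluate(one, spec_grid = small_grid(),
                          n_iterations = 3, seed = 22)
  expect_identical(solo$summary, plain$summary)
  single <- train_age_stratified(tab, mode = "single_model_with_age",
                                 spec_grid = small_grid(),
                                 n_iterations = 3, seed = 23)
  expect_gt(single$summary$R2, 0.5)
})

test_that("small-training-fraction mode behaves like a learning curve", {
  tab <- toy_separable_table(150, seed = 24)
  expect_error(train_fraction_robustness(tab, train_fraction = 1), "train_fraction")
  expect_error(train_fraction_robustness(tab, train_fraction = 0), "train_fraction")
  r_small <- train_fraction_robustness(tab, 0.2, spec_grid = small_grid(),
                                       n_iterations = 4, seed = 25)
  r_big <- train_evaluate(tab, spec_grid = small_grid(),
                          n_iterations = 4, seed = 25)
  # more training data should not hurt on average
  expect_gte(r_big$summary$R2, r_small$summary$R2 - 0.05)
  expect_gt(r_small$summary$R2, 0.5)
})

test_that("the package SVR agrees with an independent kernel implementation", {
  skip_if_not_installed("kernlab")
  set.seed(26)
  conc <- sample(c(0, 1, 2, 3), 120, replace = TRUE)
  X <- cbind(a = conc + rnorm(120, 0, 0.2), b = rnorm(120))
  fit_e <- e1071::svm(X, conc, type = "eps-regression", kernel = "radial",
                      cost = 10, gamma = 0.5, epsilon = 0.1, scale = FALSE)
  fit_k <- kernlab::ksvm(X, conc, type = "eps-svr",
                         kernel = "rbfdot",
                         kpar = list(sigma = 0.5), C = 10, epsilon = 0.1,
                         scaled = FALSE)
  p_e <- as.numeric(predict(fit_e, X))
  p_k <- as.numeric(kernlab::predict(fit_k, X))
  expect_gt(cor(p_e, p_k), 0.99)
  expect_lt(mean(abs(p_e - p_k)), 0.15)
})

test_that("decision-space map embeds rows and paints Voronoi cells", {
  tab <- toy_separable_table(60, seed = 27)
  pipe <- fit_pipeline(tab, spec_grid = small_grid(), seed = 28)
  map <- decision_space_map(pipe, tab, seed = 29, perplexity = 8, grid_n = 25)
  expect_identical(nrow(map$coords), 60L)
  expect_identical(nrow(map$grid), 625L)
  # identical feature rows land on coincident coordinates
  tab2 <- tab
  tab2[2, feature_cols(tab2)] <- tab2[1, feature_cols(tab2)]
  map2 <- decision_space_map(pipe, tab2, seed = 29, perplexity = 8, grid_n = 10)
  expect_identical(map2$coords[1, c("x", "y")], map2$coords[2, c("x", "y")],
                   ignore_attr = TRUE)
  # nearest-grid-cell value equals the point's own prediction
  i <- 7
  d2 <- (map$grid$x - map$coords$x[i])^2 + (map$grid$y - map$coords$y[i])^2
  near <- which.min(d2)
  own <- which.min((map$coords$x - map$grid$x[near])^2 +
                     (map$coords$y - map$grid$y[near])^2)
  expect_equal(map$grid$value[near], map$coords$predicted[own])
  expect_error(decision_space_map(pipe, tab[1:5, ], seed = 1), ">= 10")
})
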