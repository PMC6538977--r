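# 2-D visualization of the regressor decision space: exact t-SNE embedding
# of the pipeline's feature rows with a nearest-neighbor (Voronoi) map of
# predicted depth over the plane.

# exact t-SNE (O(n^2)); adequate for the row counts of per-minute feature
# tables. Duplicate rows are embedded once and share coordinates.
tsne_embed <- function(X, perplexity = 10, max_iter = 300, seed = 1) {
  key <- apply(X, 1, paste, collapse = "\r")
  uk <- !duplicated(key)
  Xu <- X[uk, , drop = FALSE]
  n <- nrow(Xu)
  if (n < 4) stop("too few distinct points for an embedding")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 1) stop("fewer points than the perplexity requires")
  D2 <- as.matrix(stats::dist(Xu))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(sp) + beta * sum(di * p) / sp
      p <- p / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- 4       # early exaggeration
  mom <- 0.5
  upd <- matrix(0, n, 2)
  for (iter in seq_len(max_iter)) {
    if (iter == 51) gain <- 1
    if (iter == 21) mom <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (gain * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    upd <- mom * upd - 100 * grad
    Y <- Y + upd
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y[match(key, key[uk]), , drop = FALSE]
}

#' Decision-space map of a fitted depth pipeline
#'
#' Embeds the pipeline's (transformed) feature rows in 2-D with t-SNE and
#' approximates the decision space by a Voronoi tessellation: every point of
#' a regular grid over the plane takes the predicted depth of its nearest
#' embedded row (k-nearest regression on the embedding coordinates).
#'
#' @param pipeline a fitted `depth_pipeline` (internal fit of
#'   [train_evaluate()]; obtain one via [fit_pipeline()]).
#' @param table a `feature_table` with the rows to embed (>= 10).
#' @param seed RNG seed of the embedding.
#' @param perplexity t-SNE perplexity.
#' @param k neighbors of the background regression (1 = Voronoi cells).
#' @param grid_n background grid resolution per axis.
#' @return a `decision_space_map`: `coords` (x, y, predicted, true per row)
#'   and `grid` (x, y, value).
#' @export
decision_space_map <- function(pipeline, table, seed = 1, perplexity = 10,
                               k = 1, grid_n = 60) {
  d <- table_xy(table)
  if (nrow(d$X) < 10) stop("invalid parameter: need >= 10 points")
  Xr <- pipeline_features(pipeline, d$X)
  Y <- tsne_embed(Xr, perplexity = perplexity, seed = seed)
  pred <- predict(pipeline, d$X)
  gx <- seq(min(Y[, 1]), max(Y[, 1]), length.out = grid_n)
  gy <- seq(min(Y[, 2]), max(Y[, 2]), length.out = grid_n)
  grid <- expand.grid(x = gx, y = gy)
  d2 <- outer(grid$x, Y[, 1], `-`)^2 + outer(grid$y, Y[, 2], `-`)^2
  grid$value <- apply(d2, 1, function(row) {
    mean(pred[order(row)[seq_len(k)]])
  })
  structure(list(coords = data.frame(x = Y[, 1], y = Y[, 2],
                                     predicted = pred, true = d$y),
                 grid = grid),
            class = "decision_space_map")
}

#' Fit one depth pipeline on a whole table
#'
#' Tunes on the full table (3-fold) and fits; used for the decision-space
#' map and for transfer scoring.
#'
#' @param table a `feature_table`.
#' @param spec_grid hyper-parameter grid.
#' @param inner_folds grid-search folds.
#' @param seed RNG seed.
#' @return a fitted `depth_pipeline`.
#' @export
fit_pipeline <- function(table, spec_grid = reduced_spec_grid(),
                         inner_folds = 3, seed = 1) {
  d <- table_xy(table)
  set.seed(seed)
  spec <- tune_depth_pipeline(d$X, d$y, spec_grid, inner_folds)
  fit_depth_pipeline(d$X, d$y, spec, inner_folds)
}

#' @export
plot.decision_space_map <- function(x, ...) {
  pal <- grDevices::hcl.colors(64, "viridis")
  gx <- sort(unique(x$grid$x)); gy <- sort(unique(x$grid$y))
  z <- matrix(x$grid$value, length(gx), length(gy))
  graphics::image(gx, gy, z, col = pal, xlab = "t-SNE 1", ylab = "t-SNE 2",
                  main = "Predicted anesthetic depth", ...)
  rng <- range(c(x$coords$true, x$grid$value))
  ci <- pmax(1, pmin(64, 1 + round(63 * (x$coords$true - rng[1]) /
                                     max(1e-12, diff(rng)))))
  graphics::points(x$coords$x, x$coords$y, pch = 21, bg = pal[ci])
  invisible(x)
}
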