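# Group-level climate-driver importance: gradient-boosted trees (binary
# logistic) on binary group suitability, inverse-frequency class weighting,
# 70/30 split, fivefold stratified CV for hyperparameter choice, and Gain
# importance summarized as fold mean +/- sd.

#' Assemble a group-level design
#'
#' Rows are all cells finite in the mask and every predictor, or a seeded
#' stratified uniform sample of `sample_cap` cells preserving the class
#' proportions. Class weights are inverse to class frequency.
#'
#' @param suitable_mask Binary [raster_layer()] (group suitable/unsuitable).
#' @param climate_stack Stack of predictor layers.
#' @param variables Predictor layer names (nonempty).
#' @param sample_cap Maximum number of rows (default 100000).
#' @param seed Integer seed for the subsample.
#' @return A `group_design` list: `x` (matrix), `y` (0/1), `weights`,
#'   `variables`.
#' @export
assemble_design <- function(suitable_mask, climate_stack, variables,
                            sample_cap = 100000, seed = 1) {
  if (length(variables) == 0) stop("variables must be nonempty")
  if (!grid_equal(suitable_mask$grid, climate_stack$grid))
    stop_grid_mismatch("mask and stack")
  vals <- stack_values_at(climate_stack,
                          seq_len(climate_stack$grid$nrows *
                                    climate_stack$grid$ncols))
  vals <- vals[, variables, drop = FALSE]
  y <- as.vector(suitable_mask$values)
  ok <- is.finite(y) & rowSums(!is.finite(vals)) == 0
  vals <- vals[ok, , drop = FALSE]
  y <- as.integer(y[ok] > 0)
  if (length(unique(y)) < 2)
    stop("mask has a single class over the finite cells")
  if (length(y) > sample_cap) {
    with_seed(seed, {
      n1 <- round(sample_cap * mean(y))
      i1 <- sample(which(y == 1), n1)
      i0 <- sample(which(y == 0), sample_cap - n1)
      keep <- sort(c(i1, i0))
    })
    vals <- vals[keep, , drop = FALSE]
    y <- y[keep]
  }
  freq <- c(mean(y == 0), mean(y == 1))
  w <- ifelse(y == 1, 1 / freq[2], 1 / freq[1])
  w <- w / mean(w)
  structure(list(x = vals, y = y, weights = w, variables = variables),
            class = "group_design")
}

# Stratified fold assignment (1..k), deterministic under the current RNG.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.xgb_fit <- function(x, y, w, params, xval, yval, nrounds = 500,
                     patience = 20) {
  dtr <- xgboost::xgb.DMatrix(x, label = y, weight = w, nthread = 1)
  dva <- xgboost::xgb.DMatrix(xval, label = yval, nthread = 1)
  m <- xgboost::xgb.train(
    params = c(params, list(objective = "binary:logistic",
                            eval_metric = "logloss", nthread = 1)),
    data = dtr, nrounds = nrounds, evals = list(val = dva),
    early_stopping_rounds = patience, verbose = 0)
  best <- xgboost::xgb.attributes(m)$best_iteration
  list(model = m, best_iteration = if (is.null(best)) nrounds
       else as.integer(best))
}

.gain_vector <- function(model, variables) {
  imp <- xgboost::xgb.importance(model = model)
  g <- stats::setNames(rep(0, length(variables)), variables)
  if (!is.null(imp) && nrow(imp)) g[imp$Feature] <- imp$Gain
  if (sum(g) > 0) g <- g / sum(g)
  g
}

#' Fit the group-level gradient-boosted classifier
#'
#' 70/30 stratified train/test split; within the training partition, each
#' hyperparameter combination is scored by fivefold stratified CV (accuracy
#' on the held-out fold, boosting stopped early against it). Selection
#' maximizes mean fold accuracy, breaking ties toward lower fold variability
#' and then toward shallower/fewer trees. The chosen configuration is refit
#' on the full training partition and Overall Accuracy reported on the 30%
#' test split. Gain importances are per-fold normalized to sum 1, reported
#' as mean +/- sd.
#'
#' @param design An [assemble_design()] object.
#' @param split Training fraction (default 0.7).
#' @param cv_folds Stratified folds within training (default 5).
#' @param grid Data.frame of hyperparameters (`max_depth`, `eta`,
#'   `subsample`); default `{2,3,4} x {0.05, 0.1} x {0.8}`.
#' @param nrounds_max,patience Boosting-round cap (500) and early-stopping
#'   patience (20).
#' @param seed Integer seed (splits, folds, subsampling).
#' @return An `importance_report`: `importance` (data.frame `variable`,
#'   `gain_mean`, `gain_sd`), `overall_accuracy`, `chosen` hyperparameters,
#'   `fold_accuracy`, `model`.
#' @export
fit_gbt <- function(design, split = 0.7, cv_folds = 5, grid = NULL,
                    nrounds_max = 500, patience = 20, seed = 1) {
  if (is.null(grid))
    grid <- expand.grid(max_depth = c(2L, 3L, 4L), eta = c(0.05, 0.1),
                        subsample = 0.8)
  x <- design$x; y <- design$y; w <- design$weights
  with_seed(derive_seed(seed, "gbt"), {
    tr <- sort(unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, round(split * length(idx)))
    })))
    te <- setdiff(seq_along(y), tr)
    fold <- stratified_folds(y[tr], cv_folds)
    if (min(table(fold, y[tr])) < 1) stop("degenerate fold with a single class")

    score <- lapply(seq_len(nrow(grid)), function(gi) {
      params <- list(max_depth = grid$max_depth[gi], eta = grid$eta[gi],
                     subsample = grid$subsample[gi],
                     seed = derive_seed(seed, "xgb", gi))
      accs <- numeric(cv_folds); iters <- numeric(cv_folds)
      gains <- matrix(0, cv_folds, length(design$variables),
                      dimnames = list(NULL, design$variables))
      for (f in seq_len(cv_folds)) {
        itr <- tr[fold != f]; iva <- tr[fold == f]
        fit <- .xgb_fit(x[itr, , drop = FALSE], y[itr], w[itr], params,
                        x[iva, , drop = FALSE], y[iva],
                        nrounds = nrounds_max, patience = patience)
        pred <- stats::predict(fit$model, x[iva, , drop = FALSE]) > 0.5
        accs[f] <- mean(pred == (y[iva] == 1))
        iters[f] <- fit$best_iteration
        gains[f, ] <- .gain_vector(fit$model, design$variables)
      }
      list(acc_mean = mean(accs), acc_sd = stats::sd(accs),
           iters = mean(iters), gains = gains, params = params,
           depth = grid$max_depth[gi])
    })

    acc_means <- vapply(score, `[[`, 0, "acc_mean")
    acc_sds <- vapply(score, `[[`, 0, "acc_sd")
    depths <- vapply(score, `[[`, 0, "depth")
    iters <- vapply(score, `[[`, 0, "iters")
    ord <- order(-acc_means, acc_sds, depths, iters)
    best <- score[[ord[1]]]

    refit <- .xgb_fit(x[tr, , drop = FALSE], y[tr], w[tr], best$params,
                      x[te, , drop = FALSE], y[te],
                      nrounds = max(1L, round(best$iters)), patience = 10000)
    pred <- stats::predict(refit$model, x[te, , drop = FALSE]) > 0.5
    overall_accuracy <- mean(pred == (y[te] == 1))

    rep <- importance_cv(best$gains)
    structure(list(importance = rep, overall_accuracy = overall_accuracy,
                   chosen = best$params, fold_accuracy = c(
                     mean = best$acc_mean, sd = best$acc_sd),
                   model = refit$model),
              class = "importance_report")
  })
}

#' Summarize per-fold gain importances
#'
#' @param fold_gains Matrix (folds x variables) of gain importances; each
#'   row is normalized to sum 1 before averaging.
#' @return Data.frame with `variable`, `gain_mean`, `gain_sd`; the means sum
#'   to 1.
#' @export
importance_cv <- function(fold_gains) {
  if (nrow(fold_gains) < 2) stop("need at least 2 folds")
  rs <- rowSums(fold_gains)
  rs[rs == 0] <- 1
  norm <- fold_gains / rs
  data.frame(variable = colnames(fold_gains),
             gain_mean = colMeans(norm),
             gain_sd = apply(norm, 2, stats::sd),
             row.names = NULL)
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> overall accuracy %.4f (folds %.4f +/- %.4f)\n",
              x$overall_accuracy, x$fold_accuracy["mean"],
              x$fold_accuracy["sd"]))
  top <- x$importance[order(-x$importance$gain_mean), ][1:min(5, nrow(x$importance)), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-10s %.4f +/- %.4f\n", top$variable[i],
                top$gain_mean[i], top$gain_sd[i]))
  invisible(x)
}
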