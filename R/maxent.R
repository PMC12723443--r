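# Presence-background maximum-entropy modelling. The fitted distribution is
# the Gibbs density q_lambda(x) = exp(lambda . f(x)) / Z over the background
# sample; fitting minimizes the L1-penalized negative presence log-likelihood
#   -(1/m) sum_presences lambda . f(x) + log Z + sum_j beta_j |lambda_j|
# by cyclic coordinate descent with soft-thresholding, tracking per-update
# gain improvements for percent-contribution accounting.

#' Build a MaxEnt feature set
#'
#' Features are derived from stack layers after min-max scaling to `[0, 1]`
#' over the background cells (values outside the background range are clamped
#' at prediction time). Supported classes: `linear` (scaled value),
#' `quadratic` (its square) and `hinge` (forward hinges
#' `max(0, (v - k) / (1 - k))` with knots at background quantiles).
#' Zero-variance features are dropped.
#'
#' @param stack Environmental [raster_stack()].
#' @param background_cells Integer cell indices of the background sample.
#' @param classes Subset of `c("linear", "quadratic", "hinge")`.
#' @param variables Layer names to use (default: all continuous layers).
#' @param n_hinge Hinge knots per variable (default 10, at quantiles).
#' @return A `maxent_features` object.
#' @export
build_features <- function(stack, background_cells,
                           classes = c("linear", "quadratic", "hinge"),
                           variables = NULL, n_hinge = 10) {
  classes <- match.arg(classes, several.ok = TRUE)
  if (length(background_cells) == 0) stop("background sample is empty")
  if (is.null(variables))
    variables <- names(stack)[vapply(stack$layers, function(l)
      l$kind == "continuous", logical(1))]
  bg <- stack_values_at(stack, background_cells)[, variables, drop = FALSE]
  defs <- list()
  scaling <- list()
  for (v in variables) {
    x <- bg[, v]
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo) next  # constant layer
    scaling[[v]] <- c(lo = lo, hi = hi)
    if ("linear" %in% classes)
      defs[[length(defs) + 1L]] <- list(variable = v, transform = "linear",
                                        knot = NA_real_)
    if ("quadratic" %in% classes)
      defs[[length(defs) + 1L]] <- list(variable = v, transform = "quadratic",
                                        knot = NA_real_)
    if ("hinge" %in% classes) {
      s <- (x - lo) / (hi - lo)
      knots <- unique(stats::quantile(s, probs = seq_len(n_hinge) /
                                        (n_hinge + 1), names = FALSE))
      knots <- knots[knots < 1 - 1e-9]
      for (k in knots)
        defs[[length(defs) + 1L]] <- list(variable = v, transform = "hinge",
                                          knot = k)
    }
  }
  if (length(defs) == 0) stop("all layers are constant over the background")
  fs <- structure(list(definitions = defs, scaling = scaling,
                       variables = names(scaling)),
                  class = "maxent_features")
  # drop features constant over the background (e.g. hinge above all values)
  Fm <- feature_matrix(fs, bg_values = bg)
  keep <- apply(Fm, 2, function(col) max(col) - min(col) > 1e-12)
  fs$definitions <- fs$definitions[keep]
  if (length(fs$definitions) == 0)
    stop("all features are constant over the background")
  fs
}

#' Evaluate the feature matrix at cells
#'
#' @param features A [build_features()] object.
#' @param stack Stack providing the source layers (or pass `bg_values`).
#' @param cells Cell indices at which to evaluate.
#' @param bg_values Optional precomputed value matrix (cells x variables).
#' @return Numeric matrix, rows = cells, columns = features in `[0, 1]` over
#'   the background.
#' @export
feature_matrix <- function(features, stack = NULL, cells = NULL,
                           bg_values = NULL) {
  if (is.null(bg_values)) {
    if (is.null(stack) || is.null(cells))
      stop("supply either bg_values or stack + cells")
    miss <- setdiff(features$variables, names(stack))
    if (length(miss)) stop("missing layer(s): ", paste(miss, collapse = ", "))
    bg_values <- stack_values_at(stack, cells)[, features$variables,
                                               drop = FALSE]
  }
  scaled <- vapply(features$variables, function(v) {
    s <- features$scaling[[v]]
    pmin(pmax((bg_values[, v] - s["lo"]) / (s["hi"] - s["lo"]), 0), 1)
  }, numeric(nrow(bg_values)))
  if (nrow(bg_values) == 1L)
    scaled <- matrix(scaled, nrow = 1, dimnames = list(NULL, features$variables))
  out <- vapply(features$definitions, function(d) {
    s <- scaled[, d$variable]
    switch(d$transform,
           linear = s,
           quadratic = s^2,
           hinge = pmax(0, (s - d$knot) / (1 - d$knot)))
  }, numeric(nrow(bg_values)))
  if (nrow(bg_values) == 1L) out <- matrix(out, nrow = 1)
  colnames(out) <- vapply(features$definitions, function(d)
    if (d$transform == "hinge")
      sprintf("%s:hinge:%0.4f", d$variable, d$knot)
    else paste(d$variable, d$transform, sep = ":"), "")
  out
}

# Default per-feature regularization, beta_class(m) interpolated over the
# presence count times sqrt(var(f)/m), after the published MaxEnt default
# scheme; scaled by beta_multiplier.
default_beta <- function(features, F_pres, beta_multiplier = 1) {
  m <- nrow(F_pres)
  interp <- function(xs, ys) {
    if (m <= xs[1]) return(ys[1])
    if (m >= xs[length(xs)]) return(ys[length(ys)])
    stats::approx(xs, ys, xout = m)$y
  }
  cls <- vapply(features$definitions, function(d)
    if (d$transform == "hinge") "hinge" else "lq", "")
  b_lq <- interp(c(10, 30, 100), c(1.0, 0.6, 0.05))
  b_h <- 0.5
  s2 <- pmax(apply(F_pres, 2, stats::var), 1e-4)
  base <- ifelse(cls == "hinge", b_h, b_lq)
  beta_multiplier * base * sqrt(s2 / m)
}

#' Fit a presence-background maximum-entropy model
#'
#' @param features A [build_features()] object (its scaling defines the
#'   background distribution support).
#' @param stack Environmental stack.
#' @param presence_cells,background_cells Cell indices (>= 5 presences).
#' @param beta_multiplier Scales the default L1 regularization weights.
#' @param max_iter Maximum coordinate-descent cycles.
#' @param tol Convergence tolerance on the per-cycle objective change.
#' @return A `maxent_model` with elements `lambda`, `log_partition`,
#'   `entropy`, `beta`, `feature_set`, `gain` (regularized training gain over
#'   the uniform model), `var_gain` (per-variable summed positive objective
#'   improvements) and `converged`.
#' @export
maxent_fit <- function(features, stack, presence_cells, background_cells,
                       beta_multiplier = 1, max_iter = 500, tol = 1e-6) {
  if (length(presence_cells) < 5) stop("need at least 5 presence cells")
  F_bg <- feature_matrix(features, stack, background_cells)
  F_pres <- feature_matrix(features, stack, presence_cells)
  maxent_fit_matrices(features, F_pres, F_bg, beta_multiplier, max_iter, tol)
}

# Core optimizer on precomputed feature matrices; the cyclic coordinate
# descent itself is compiled (src/maxent_cd.cpp).
maxent_fit_matrices <- function(features, F_pres, F_bg, beta_multiplier = 1,
                                max_iter = 500, tol = 1e-6) {
  n <- nrow(F_bg); p <- ncol(F_bg); m <- nrow(F_pres)
  beta <- default_beta(features, F_pres, beta_multiplier)
  fbar <- colMeans(F_pres)
  cd <- .maxent_cd(F_bg, fbar, beta, as.integer(max_iter), tol)
  if (!cd$converged)
    warning("maxent_fit: not converged after ", max_iter, " cycles")
  lambda <- cd$lambda
  var_of <- vapply(features$definitions, `[[`, "", "variable")
  var_gain <- vapply(split(cd$feat_gain, factor(var_of,
                                                levels = features$variables)),
                     sum, 0)
  logZ <- cd$log_partition
  eta <- as.vector(F_bg %*% lambda)
  q <- exp(eta - logZ)
  H <- -sum(q * ifelse(q > 0, log(q), 0))
  gain <- sum(fbar * lambda) - logZ + log(n) - sum(beta * abs(lambda))
  structure(list(lambda = stats::setNames(lambda, colnames(F_bg)),
                 log_partition = logZ, entropy = H, beta = beta,
                 feature_set = features, gain = gain, var_gain = var_gain,
                 n_background = n, n_presence = m, converged = cd$converged,
                 objective = cd$objective),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features, %d presences, %d background; gain %.4f, entropy %.4f%s\n",
    length(x$lambda), x$n_presence, x$n_background, x$gain, x$entropy,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Logistic suitability prediction
#'
#' Per cell, the raw density `q = exp(lambda . f) / Z` (Z over the fitting
#' background) is transformed to `P = q e^H / (1 + q e^H)`, the calibration
#' under which a cell with typical presence characteristics scores 0.5.
#'
#' @param model A fitted [maxent_fit()] model.
#' @param stack Stack providing all source layers.
#' @param cells Optional cell subset; default all cells.
#' @return A [raster_layer()] in `[0, 1]`; nodata propagates.
#' @export
predict_logistic <- function(model, stack, cells = NULL) {
  g <- stack$grid
  all_cells <- is.null(cells)
  if (all_cells) cells <- seq_len(g$nrows * g$ncols)
  vals <- stack_values_at(stack, cells)[, model$feature_set$variables,
                                        drop = FALSE]
  ok <- rowSums(!is.finite(vals)) == 0
  eta <- rep(NA_real_, length(cells))
  if (any(ok)) {
    Fm <- feature_matrix(model$feature_set, bg_values = vals[ok, , drop = FALSE])
    eta[ok] <- as.vector(Fm %*% model$lambda)
  }
  logq <- eta - model$log_partition
  P <- stats::plogis(logq + model$entropy)
  if (!all_cells) return(P)
  m <- matrix(NA_real_, g$nrows, g$ncols)
  m[cells] <- P
  raster_layer(m, g, name = "suitability")
}

#' Percent contribution per variable
#'
#' Positive objective-improvement increments accumulated during fitting are
#' summed per source variable and normalized to 100.
#'
#' @param model A fitted [maxent_fit()] model.
#' @return Named numeric vector summing to 100 (all zero, with a warning,
#'   for a degenerate zero-gain fit).
#' @export
percent_contribution <- function(model) {
  vg <- model$var_gain
  tot <- sum(vg)
  if (tot <= 0) {
    warning("degenerate fit: no positive gain improvements")
    return(vg * 0)
  }
  100 * vg / tot
}

#' Jackknife training gains per variable
#'
#' For each variable, the regularized training gain of a model fitted with
#' only that variable's features (`with_only`) and with all features except
#' them (`without`). Gains are relative to the uniform background model
#' (gain 0); a single-variable `without` model is the uniform model.
#'
#' @param features A [build_features()] object (>= 2 variables for a
#'   meaningful `without`).
#' @param stack Environmental stack.
#' @param presence_cells,background_cells Cell indices.
#' @param beta_multiplier,max_iter,tol As [maxent_fit()].
#' @return Data.frame with columns `variable`, `with_only`, `without`.
#' @export
jackknife_gain <- function(features, stack, presence_cells, background_cells,
                           beta_multiplier = 1, max_iter = 500, tol = 1e-6) {
  F_bg <- feature_matrix(features, stack, background_cells)
  F_pres <- feature_matrix(features, stack, presence_cells)
  vars <- features$variables
  var_of <- vapply(features$definitions, `[[`, "", "variable")
  sub_fit <- function(keep) {
    if (!any(keep)) return(0)
    fs <- features
    fs$definitions <- features$definitions[keep]
    fs$variables <- unique(var_of[keep])
    fit <- maxent_fit_matrices(fs, F_pres[, keep, drop = FALSE],
                               F_bg[, keep, drop = FALSE],
                               beta_multiplier, max_iter, tol)
    fit$gain
  }
  data.frame(
    variable = vars,
    with_only = vapply(vars, function(v) sub_fit(var_of == v), 0),
    without = vapply(vars, function(v) sub_fit(var_of != v), 0),
    row.names = NULL)
}

#' Rank-based AUC with tie correction
#'
#' The Mann-Whitney estimator: the probability that a random presence score
#' exceeds a random background score, ties credited 0.5.
#'
#' @param presence_scores,background_scores Nonempty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0 || length(background_scores) == 0)
    stop("score vectors must be nonempty")
  np <- length(presence_scores); nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Replicate subsample evaluation of one species
#'
#' Per replicate: a fresh uniform background sample from valid cells, a
#' random presence split (`train_fraction` train, remainder test), a fit on
#' the training presences, and the AUC of test presences against the
#' background. The final suitability map is the mean of the replicate
#' logistic maps. Species with `auc_mean <= auc_min` or `cv >= cv_max` are
#' flagged `excluded`.
#'
#' @param stack Environmental stack.
#' @param presence_cells Unique presence cell indices (>= 8).
#' @param n_background Background sample size per replicate (default 10000,
#'   capped at the number of valid cells).
#' @param train_fraction Training share of presences (default 0.75).
#' @param n_replicates Number of replicates (default 10).
#' @param seed Integer seed (replicate seeds derive from it).
#' @param classes,variables,n_hinge,beta_multiplier Passed to
#'   [build_features()] / [maxent_fit()].
#' @param auc_min,cv_max Reliability thresholds (defaults 0.90 and 0.15).
#' @param do_jackknife Also compute jackknife gains on the first replicate.
#' @param species Label used in messages.
#' @return An `eval_report` list: `auc_mean`, `auc_sd`, `cv`, `auc`,
#'   `contributions` (replicate-mean percent contribution), `jackknife`,
#'   `mean_map`, `excluded`, `n_replicates`, `train_fraction`.
#' @export
evaluate_subsample <- function(stack, presence_cells, n_background = 10000,
                               train_fraction = 0.75, n_replicates = 10,
                               seed = 1,
                               classes = c("linear", "quadratic", "hinge"),
                               variables = NULL, n_hinge = 10,
                               beta_multiplier = 1,
                               auc_min = 0.90, cv_max = 0.15,
                               do_jackknife = FALSE, species = "species") {
  presence_cells <- unique(presence_cells)
  if (length(presence_cells) < 8)
    stop("too few presence cells for ", species,
         " (need >= 8, have ", length(presence_cells), ")")
  valid <- finite_cells(stack)
  nbg <- min(n_background, length(valid))
  g <- stack$grid
  aucs <- numeric(n_replicates)
  contribs <- NULL
  jk <- NULL
  mean_map <- matrix(0, g$nrows, g$ncols)
  for (r in seq_len(n_replicates)) {
    rep_out <- with_seed(derive_seed(seed, "rep", r), {
      bg <- sample(valid, nbg)
      ntr <- max(1, floor(train_fraction * length(presence_cells)))
      tr_idx <- sample(seq_along(presence_cells), ntr)
      train <- presence_cells[tr_idx]
      test <- presence_cells[-tr_idx]
      if (length(test) == 0) test <- train
      fs <- build_features(stack, bg, classes = classes,
                           variables = variables, n_hinge = n_hinge)
      fit <- maxent_fit(fs, stack, train, bg,
                        beta_multiplier = beta_multiplier)
      map <- predict_logistic(fit, stack)
      list(auc = auc_rank(map$values[test], map$values[bg]),
           contrib = percent_contribution(fit), map = map$values,
           fs = fs, fit = fit, train = train, bg = bg)
    })
    aucs[r] <- rep_out$auc
    contribs <- rbind(contribs, rep_out$contrib)
    mean_map <- mean_map + rep_out$map / n_replicates
    if (do_jackknife && r == 1)
      jk <- jackknife_gain(rep_out$fs, stack, rep_out$train, rep_out$bg,
                           beta_multiplier = beta_multiplier)
  }
  auc_mean <- mean(aucs); auc_sd <- stats::sd(aucs)
  cv <- if (auc_mean > 0) auc_sd / auc_mean else Inf
  structure(list(
    species = species, auc = aucs, auc_mean = auc_mean, auc_sd = auc_sd,
    cv = cv, n_replicates = n_replicates, train_fraction = train_fraction,
    contributions = colMeans(contribs), jackknife = jk,
    mean_map = raster_layer(mean_map, g, name = paste0("suit_", species)),
    excluded = (auc_mean <= auc_min) || (cv >= cv_max),
    auc_min = auc_min, cv_max = cv_max),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: AUC %.3f +/- %.3f (CV %.3f, %d reps)%s\n",
              x$species, x$auc_mean, x$auc_sd, x$cv, x$n_replicates,
              if (x$excluded) " [EXCLUDED]" else ""))
  invisible(x)
}
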