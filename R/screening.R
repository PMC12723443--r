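# Two-step predictor selection: removal of zero-contribution layers, then
# iterative pairwise Pearson filtering (|r| >= threshold) at occurrence
# points, keeping the higher-contribution member of each offending pair.

#' Pearson correlation matrix at occurrence cells
#'
#' Correlations are computed over the layer values at the distinct occupied
#' cells of the occurrence set. A layer with zero variance at those points
#' has undefined correlations; its pairs are reported `NA` (with a warning)
#' and treated as `|r| = 0` by [select_variables()].
#'
#' @param stack Environmental [raster_stack()].
#' @param occ Occurrence data.frame; snapped to the stack grid if no `cell`
#'   column is present.
#' @param variables Layer names (default: all continuous layers).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_at_points <- function(stack, occ, variables = NULL) {
  if (is.null(variables))
    variables <- names(stack)[vapply(stack$layers, function(l)
      l$kind == "continuous", logical(1))]
  if (is.null(occ$cell)) occ <- snap_occurrences(occ, stack$grid)
  cells <- unique(occ$cell)
  vals <- stack_values_at(stack, cells)[, variables, drop = FALSE]
  vals <- vals[rowSums(!is.finite(vals)) == 0, , drop = FALSE]
  if (nrow(vals) < 3) stop("need at least 3 occurrence cells with finite values")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance layer(s) at occurrence points: ",
            paste(variables[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(vals))
  diag(r) <- 1
  r
}

#' Two-step variable screening
#'
#' Step one drops every layer with zero percent contribution. Step two
#' repeatedly finds the remaining pair with the largest `|r| >= r_threshold`
#' and drops its lower-contribution member (tie: the later in input order),
#' until no pair reaches the threshold. `NA` correlations are treated as 0.
#'
#' @param contributions Named numeric vector of percent contributions
#'   covering all layers (e.g. from a preliminary all-variable
#'   [maxent_fit()] via [percent_contribution()]).
#' @param correlation Square symmetric correlation matrix over the same
#'   layers (e.g. [pearson_at_points()]).
#' @param r_threshold Absolute correlation threshold in `(0, 1]`
#'   (default 0.8).
#' @return A `screening_result` list: `kept` (names), `dropped` (data.frame
#'   `name`, `reason`), `correlation`, `contributions`.
#' @export
select_variables <- function(contributions, correlation, r_threshold = 0.8) {
  if (r_threshold <= 0 || r_threshold > 1)
    stop("r_threshold must be in (0, 1]")
  vars <- names(contributions)
  if (is.null(vars) || !all(vars %in% rownames(correlation)))
    stop("contributions must be named and covered by the correlation matrix")
  correlation <- correlation[vars, vars, drop = FALSE]
  dropped <- data.frame(name = character(0), reason = character(0))
  zero <- vars[contributions == 0]
  if (length(zero))
    dropped <- rbind(dropped, data.frame(name = zero,
                                         reason = "zero_contribution"))
  kept <- setdiff(vars, zero)
  absr <- abs(correlation)
  absr[!is.finite(absr)] <- 0
  repeat {
    if (length(kept) < 2) break
    sub <- absr[kept, kept, drop = FALSE]
    diag(sub) <- 0
    mx <- max(sub)
    if (mx < r_threshold) break
    idx <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- kept[idx[1]]; b <- kept[idx[2]]
    # drop the lower-contribution member; tie -> the later in input order
    drop_name <- if (contributions[a] < contributions[b]) a
    else if (contributions[b] < contributions[a]) b
    else kept[max(idx)]
    keep_name <- setdiff(c(a, b), drop_name)
    dropped <- rbind(dropped, data.frame(
      name = drop_name, reason = paste0("correlated_with:", keep_name)))
    kept <- setdiff(kept, drop_name)
  }
  structure(list(kept = kept, dropped = dropped,
                 correlation = correlation, contributions = contributions,
                 r_threshold = r_threshold),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> kept %d of %d layers (|r| < %.2f): %s\n",
              length(x$kept), length(x$contributions), x$r_threshold,
              paste(x$kept, collapse = ", ")))
  if (nrow(x$dropped))
    cat("  dropped:", paste(sprintf("%s (%s)", x$dropped$name,
                                    x$dropped$reason), collapse = "; "), "\n")
  invisible(x)
}

#' Screening ledger as a data.frame
#'
#' One row per input layer: its contribution, whether it was kept, and the
#' drop reason if not.
#'
#' @param x A [select_variables()] result.
#' @return A data.frame (`name`, `contribution`, `kept`, `reason`).
#' @export
screening_table <- function(x) {
  vars <- names(x$contributions)
  reason <- stats::setNames(rep("", length(vars)), vars)
  reason[x$dropped$name] <- x$dropped$reason
  data.frame(name = vars,
             contribution = as.numeric(x$contributions),
             kept = vars %in% x$kept,
             reason = as.character(reason), row.names = NULL)
}
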