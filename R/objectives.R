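#' Confusion counts at a threshold
#'
#' An instance is predicted positive iff its score strictly exceeds the
#' threshold, so `t = 1` is the all-negative classifier and `t = 0` is
#' all-positive except for exact-zero scores.
#'
#' @param scores Numeric vector of classifier scores in `[0, 1]`.
#' @param labels Labels in -1/+1 (or 0/1).
#' @param threshold Decision threshold in `[0, 1]`.
#' @return Named integer vector `(TP, FP, TN, FN)`.
#' @examples
#' confusion(c(0.9, 0.8, 0.4, 0.2), c(1, -1, 1, -1), 0.5)
#' @export
confusion <- function(scores, labels, threshold) {
  if (length(scores) != length(labels))
    stop_momep("`scores` and `labels` must have equal length", "momep_input_error")
  if (any(!is.finite(scores)))
    stop_momep("`scores` must be finite", "momep_input_error")
  pos <- labels > 0
  pred <- scores > threshold
  c(TP = sum(pred & pos), FP = sum(pred & !pos),
    TN = sum(!pred & !pos), FN = sum(!pred & pos))
}

#' Confusion-based metrics
#'
#' Accuracy is the fraction of correctly classified instances; sensitivity
#' the accuracy of the (minority) positive class; specificity the accuracy
#' of the (majority) negative class; `gmean()` their geometric mean, the
#' imbalance-robust summary. When a class is empty its accuracy is 0 by
#' convention, which keeps every objective total and penalizes degenerate
#' splits.
#'
#' @param counts Named vector from [confusion()].
#' @return A value in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  unname((counts["TP"] + counts["TN"]) / n)
}

#' @rdname accuracy
#' @export
sensitivity <- function(counts) {
  np <- counts["TP"] + counts["FN"]
  if (np == 0) return(0)
  unname(counts["TP"] / np)
}

#' @rdname accuracy
#' @export
specificity <- function(counts) {
  nn <- counts["TN"] + counts["FP"]
  if (nn == 0) return(0)
  unname(counts["TN"] / nn)
}

#' @rdname accuracy
#' @export
gmean <- function(counts) sqrt(sensitivity(counts) * specificity(counts))

#' Threshold grid
#'
#' The pre-established decision thresholds swept by the threshold-dependent
#' measures. The default is 10 equally spaced values 0.05, 0.15, ..., 0.95.
#'
#' @param thresholds Strictly increasing values in `[0, 1]`.
#' @return The validated numeric vector.
#' @export
threshold_grid <- function(thresholds = seq(0.05, 0.95, by = 0.1)) {
  if (length(thresholds) == 0 || any(thresholds < 0 | thresholds > 1) ||
      is.unsorted(thresholds, strictly = TRUE))
    stop_momep("thresholds must be strictly increasing values in [0, 1]",
               "momep_config_error")
  thresholds
}

# TP-rate and FP-rate of one score vector at every threshold of the grid
roc_points <- function(scores, labels, grid) {
  pos <- labels > 0
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tpr <- fpr <- numeric(length(grid))
  for (i in seq_along(grid)) {
    pred <- scores > grid[i]
    tpr[i] <- if (n_pos > 0) sum(pred & pos) / n_pos else 0
    fpr[i] <- if (n_neg > 0) sum(pred & !pos) / n_neg else 0
  }
  list(tpr = tpr, fpr = fpr)
}

#' AUC over a threshold grid
#'
#' ROC points are computed at every grid threshold, anchored at (0, 0) and
#' (1, 1), sorted by FP rate, and integrated by the trapezoid rule.
#'
#' @inheritParams confusion
#' @param grid A [threshold_grid()].
#' @return AUC value in `[0, 1]`.
#' @export
auc_over_thresholds <- function(scores, labels, grid = threshold_grid()) {
  rp <- roc_points(scores, labels, grid)
  fpr <- c(0, rp$fpr, 1)
  tpr <- c(0, rp$tpr, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Histogram of TP rates over fixed FP-rate bins
#'
#' The ROC curve re-expressed as a histogram: the `[0, 1]` FP-rate axis is
#' cut into `n_bins` equal-width bins (last bin right-closed); every grid
#' threshold contributes its TP rate to the bin containing its FP rate, and
#' each bin reports the mean of the TP rates it received (empty bins are 0).
#'
#' @inheritParams auc_over_thresholds
#' @param n_bins Number of FP-rate bins.
#' @return Numeric vector of length `n_bins`.
#' @export
histo_tp_rates <- function(scores, labels, grid = threshold_grid(), n_bins = 10) {
  if (n_bins < 1) stop_momep("`n_bins` must be >= 1", "momep_config_error")
  rp <- roc_points(scores, labels, grid)
  bin <- pmin(floor(rp$fpr * n_bins) + 1L, n_bins)
  out <- numeric(n_bins)
  for (b in unique(bin)) out[b] <- mean(rp$tpr[bin == b])
  out
}

#' Objective-combination model specification
#'
#' The four models couple an X measure (the scalar that picks the best
#' sub-expression inside a chromosome) with a Y objective vector (what
#' NSGA-II maximizes for that best sub-expression):
#' * A: average accuracy over the grid & the per-threshold accuracies;
#' * B: AUC over the grid & the TP-rate histogram bins;
#' * C: geometric mean at a single threshold & (sensitivity, specificity);
#' * D: average of per-threshold geometric means & those geometric means.
#'
#' Model C is defined on a single threshold (default 0.5); the others use
#' the full [threshold_grid()].
#'
#' @param model `"A"`, `"B"`, `"C"` or `"D"`.
#' @param grid Threshold grid; for model C it must hold a single value.
#' @param n_bins FP-rate bins for model B's histogram objectives.
#' @return An object of class `momep_model`.
#' @export
model_spec <- function(model = c("A", "B", "C", "D"), grid = NULL, n_bins = 10) {
  model <- match.arg(model)
  if (is.null(grid)) grid <- if (model == "C") 0.5 else threshold_grid()
  grid <- threshold_grid(grid)
  if (model == "C" && length(grid) != 1)
    stop_momep("model C uses a single threshold", "momep_config_error")
  x_measure <- c(A = "AvgAcc", B = "AUC", C = "GM", D = "avgGM")[[model]]
  y_name <- c(A = "Accs", B = "HistoTPFNrates", C = "PosNegAcc",
              D = "GMPosNegAccs")[[model]]
  n_obj <- switch(model, A = length(grid), B = as.integer(n_bins), C = 2L,
                  D = length(grid))
  structure(list(id = model, x_measure = x_measure, y_objectives = y_name,
                 grid = grid, n_bins = as.integer(n_bins),
                 n_objectives = n_obj),
            class = "momep_model")
}

#' @export
print.momep_model <- function(x, ...) {
  cat(sprintf("<momep_model> %s: X = %s, Y = %s (%d objectives), %d thresholds\n",
              x$id, x$x_measure, x$y_objectives, x$n_objectives, length(x$grid)))
  invisible(x)
}

# per-threshold metric matrices for an L x n score matrix; used to compute
# X values for all genes at once
threshold_metrics <- function(scores, labels, grid) {
  pos <- as.numeric(labels > 0)
  neg <- 1 - pos
  n_pos <- sum(pos); n_neg <- sum(neg); n <- length(labels)
  L <- nrow(scores)
  acc <- sens <- spec <- matrix(0, L, length(grid))
  for (j in seq_along(grid)) {
    pred <- scores > grid[j]
    tp <- as.numeric(pred %*% pos)
    fp <- as.numeric(pred %*% neg)
    acc[, j] <- (tp + (n_neg - fp)) / n
    sens[, j] <- if (n_pos > 0) tp / n_pos else 0
    spec[, j] <- if (n_neg > 0) (n_neg - fp) / n_neg else 0
  }
  list(acc = acc, sens = sens, spec = spec)
}

#' X values of every gene in a chromosome's outputs
#'
#' Computes the model's X measure for each gene's score row.
#'
#' @param outputs An `mep_gene_outputs` from [evaluate_chromosome()], or a
#'   numeric `L x n` score matrix.
#' @param labels Instance labels in -1/+1.
#' @param spec A [model_spec()].
#' @return Numeric vector of length `L`.
#' @export
x_values <- function(outputs, labels, spec) {
  scores <- if (inherits(outputs, "mep_gene_outputs")) outputs$scores else outputs
  tm <- threshold_metrics(scores, labels, spec$grid)
  switch(spec$x_measure,
    AvgAcc = rowMeans(tm$acc),
    GM = sqrt(tm$sens[, 1] * tm$spec[, 1]),
    avgGM = rowMeans(sqrt(tm$sens * tm$spec)),
    AUC = vapply(seq_len(nrow(scores)), function(i) {
      auc_over_thresholds(scores[i, ], labels, spec$grid)
    }, numeric(1)))
}

#' Best-gene selection by the X measure
#'
#' @inheritParams x_values
#' @return Index of the maximizing gene; ties go to the lowest index.
#' @export
x_measure <- function(outputs, labels, spec) {
  which.max(x_values(outputs, labels, spec))
}

#' Y objective vector of a score row
#'
#' @param scores Score vector of the selected best gene.
#' @param labels Instance labels in -1/+1.
#' @param spec A [model_spec()].
#' @return Numeric vector of length `spec$n_objectives`, all components in
#'   `[0, 1]` and maximized.
#' @export
y_objectives <- function(scores, labels, spec) {
  tm <- threshold_metrics(matrix(scores, nrow = 1), labels, spec$grid)
  y <- switch(spec$id,
    A = as.numeric(tm$acc),
    B = histo_tp_rates(scores, labels, spec$grid, spec$n_bins),
    C = c(tm$sens[1, 1], tm$spec[1, 1]),
    D = as.numeric(sqrt(tm$sens * tm$spec)))
  if (!is.null(spec$objective_index)) y[spec$objective_index] else y
}

#' Single-criterion variant of a model
#'
#' Restricts the model's Y vector to one component, turning the
#' multi-objective search into a single-criterion search. This is how the
#' plain-voting baseline is built: one independent optimization per
#' objective, each evolving a specialist for that criterion, combined by
#' majority vote afterwards.
#'
#' @param spec A [model_spec()].
#' @param j Objective component to keep (1-based).
#' @return A `momep_model` with a single objective.
#' @export
select_objective <- function(spec, j = 1) {
  if (j < 1 || j > spec$n_objectives)
    stop_momep("`j` must index an objective of the model", "momep_config_error")
  spec$objective_index <- as.integer(j)
  spec$n_objectives <- 1L
  spec
}

#' Per-classifier metric dump
#'
#' Serializable summary of one score vector under one model: confusion
#' counts and metrics per threshold, the X value and the Y vector.
#'
#' @inheritParams y_objectives
#' @return A list ready for [jsonlite::toJSON()].
#' @export
classifier_metrics <- function(scores, labels, spec) {
  per_t <- lapply(spec$grid, function(t) {
    cts <- confusion(scores, labels, t)
    list(threshold = t, counts = as.list(cts), accuracy = accuracy(cts),
         sensitivity = sensitivity(cts), specificity = specificity(cts),
         gmean = gmean(cts))
  })
  list(model = spec$id, thresholds = spec$grid, per_threshold = per_t,
       x_value = x_values(matrix(scores, 1), labels, spec)[1],
       y = y_objectives(scores, labels, spec))
}
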