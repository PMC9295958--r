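#' Fisher's discriminant ratio (F1)
#'
#' Per feature `f`: `(mean_pos - mean_neg)^2 / (var_pos + var_neg)` with
#' population variances; F1 aggregates over features with the maximum
#' (higher = easier problem). Features with zero pooled variance and zero
#' mean gap contribute 0. The mean aggregation is available because the
#' max-vs-mean choice cannot be settled from small published values alone.
#'
#' @param data Feature table with a `label` column; both classes required.
#' @param aggregate `"max"` (default) or `"mean"`.
#' @return Non-negative scalar.
#' @export
complexity_f1 <- function(data, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  ds <- as_labeled_dataset(data)
  if (ds$n_positive == 0 || ds$n_negative == 0)
    stop_momep("both classes must be present", "momep_data_error")
  pos <- ds$features[ds$labels == 1L, , drop = FALSE]
  neg <- ds$features[ds$labels == -1L, , drop = FALSE]
  pvar <- function(x) mean((x - mean(x))^2)
  ratios <- vapply(seq_len(ncol(ds$features)), function(j) {
    gap <- (mean(pos[, j]) - mean(neg[, j]))^2
    denom <- pvar(pos[, j]) + pvar(neg[, j])
    if (denom == 0) {
      if (gap == 0) 0 else Inf
    } else gap / denom
  }, numeric(1))
  if (aggregate == "max") max(ratios) else mean(ratios)
}

#' Class separability (N2)
#'
#' Ratio of the summed distances to the nearest same-class neighbour over
#' the summed distances to the nearest other-class neighbour (Euclidean,
#' self excluded). Lower values mean tighter, better-separated classes.
#'
#' @param data Feature table with a `label` column; each class needs at
#'   least two members.
#' @return Non-negative scalar.
#' @export
complexity_n2 <- function(data) {
  ds <- as_labeled_dataset(data)
  if (sum(ds$labels == 1L) < 2 || sum(ds$labels == -1L) < 2)
    stop_momep("each class needs at least two members", "momep_data_error")
  d <- as.matrix(stats::dist(ds$features))
  diag(d) <- Inf
  same <- outer(ds$labels, ds$labels, "==")
  intra <- vapply(seq_len(nrow(d)), function(i) min(d[i, same[i, ]]), numeric(1))
  inter <- vapply(seq_len(nrow(d)), function(i) min(d[i, !same[i, ]]), numeric(1))
  sum(intra) / sum(inter)
}

#' Average points per dimension (T2)
#'
#' `n / (m + 1)` by default — the denominator counts the label column as a
#' dimension, the convention consistent with the published per-split values
#' for six-feature moment tables (e.g. 212 training points over 6 features
#' giving 30.2857). The bare `n / m` form is available via
#' `include_label_dim = FALSE`.
#'
#' @param data Feature table with a `label` column, or an instance count
#'   `n` when `m` is given.
#' @param m Feature count (only when `data` is a count).
#' @param include_label_dim Count the label as an extra dimension.
#' @return Positive scalar.
#' @examples
#' complexity_t2(212, m = 6) # 30.2857
#' @export
complexity_t2 <- function(data, m = NULL, include_label_dim = TRUE) {
  if (is.numeric(data) && length(data) == 1) {
    n <- data
    if (is.null(m)) stop_momep("`m` is required when `data` is a count",
                               "momep_input_error")
  } else {
    ds <- as_labeled_dataset(data)
    n <- nrow(ds$features)
    m <- ncol(ds$features)
  }
  if (m < 1) stop_momep("`m` must be at least 1", "momep_config_error")
  n / (m + if (include_label_dim) 1 else 0)
}

#' Data-complexity report
#'
#' All three measures for a training split and, optionally, a test split,
#' in the layout of a per-problem complexity table: F1 (higher = simpler),
#' N2 (lower = simpler), T2 (higher = simpler, reported to 4 decimals when
#' printed).
#'
#' @param train Feature table of the training split.
#' @param test Optional feature table of the test split.
#' @param ... Passed to [complexity_f1()].
#' @return A tibble with columns `split`, `n`, `m`, `F1`, `N2`, `T2`.
#' @export
complexity_report <- function(train, test = NULL, ...) {
  one <- function(d, split) {
    ds <- as_labeled_dataset(d)
    tibble::tibble(split = split, n = nrow(ds$features), m = ncol(ds$features),
                   F1 = complexity_f1(d, ...), N2 = complexity_n2(d),
                   T2 = complexity_t2(d))
  }
  out <- one(train, "train")
  if (!is.null(test)) out <- dplyr::bind_rows(out, one(test, "test"))
  out
}
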