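#' Majority vote over a label matrix
#'
#' Combines the 0/1 predictions of `r` voters (rows) on `TS` instances
#' (columns). The default rule is the floor formula
#' `floor(1/2 + (sum - 1/2) / r)`, which returns 1 iff strictly more than
#' half the voters predict 1 — even-`r` ties resolve to 0. The alternative
#' `"ties_positive"` rule resolves even ties to 1 instead.
#'
#' @param lm Numeric/integer matrix of 0/1 votes, voters in rows.
#' @param rule `"floor"` (default) or `"ties_positive"`.
#' @return Integer 0/1 vector of length `ncol(lm)`.
#' @examples
#' majority_vote(rbind(c(1, 0), c(1, 0), c(0, 1)))
#' @export
majority_vote <- function(lm, rule = c("floor", "ties_positive")) {
  rule <- match.arg(rule)
  if (!is.matrix(lm) || nrow(lm) < 1 || !all(lm %in% c(0, 1)))
    stop_momep("`lm` must be a 0/1 matrix with at least one row", "momep_input_error")
  r <- nrow(lm)
  s <- colSums(lm)
  if (rule == "floor") {
    as.integer(floor(1 / 2 + (s - 1 / 2) / r))
  } else {
    as.integer(s >= r / 2)
  }
}

#' Train/test split
#'
#' Seeded shuffle into two-thirds training and one-third testing
#' (`round(2n/3)` training instances unless `train_size` overrides it,
#' e.g. to mirror a published split). Stratification preserves the class
#' ratio to within one instance.
#'
#' @param data Feature table with a `label` column, `n >= 3`.
#' @param seed Integer seed.
#' @param stratified Preserve the class ratio in both parts.
#' @param train_size Optional explicit training-set size.
#' @return List with tibbles `train` and `test` (disjoint, exhaustive).
#' @export
split_data <- function(data, seed = 1, stratified = TRUE, train_size = NULL) {
  n <- nrow(data)
  if (n < 3) stop_momep("need at least 3 instances to split", "momep_data_error")
  target <- if (is.null(train_size)) round(2 * n / 3) else as.integer(train_size)
  if (target < 1 || target >= n)
    stop_momep("`train_size` must leave both parts non-empty", "momep_data_error")
  set.seed(as.integer(seed))
  if (stratified && "label" %in% names(data)) {
    pos <- which(data$label > 0)
    neg <- which(data$label <= 0)
    k_pos <- round(target * length(pos) / n)
    k_pos <- min(max(k_pos, 0L), length(pos))
    k_neg <- target - k_pos
    idx <- c(sample(pos, k_pos), sample(neg, k_neg))
  } else {
    idx <- sample.int(n, target)
  }
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Vote a Pareto front over a dataset
#'
#' The electorate is every (classifier, threshold) pair: each front member
#' casts one 0/1 vote per grid threshold, so a front of `p` classifiers on
#' a `t`-threshold grid has `r = p * t` voters. The ensemble's accuracy
#' comes from the majority label; its score for the AUC sweep is the vote
#' fraction (an artifact convention: voting yields labels while AUC needs
#' scores).
#'
#' @param front A `momep_front`.
#' @param data Feature table with labels (the test set).
#' @param fs Function set used in training.
#' @param rule Tie rule passed to [majority_vote()].
#' @return List with `accuracy`, `auc` (`NA` for single-threshold model C),
#'   `labels` (0/1 predictions), `vote_fraction` and the label matrix `lm`.
#' @export
vote_front <- function(front, data, fs = mep_function_set(), rule = "floor") {
  ds <- as_labeled_dataset(data)
  grid <- front$spec$grid
  lm <- do.call(rbind, lapply(seq_along(front$solutions), function(i) {
    sc <- solution_scores(front, i, ds, fs)
    do.call(rbind, lapply(grid, function(t) as.integer(sc > t)))
  }))
  pred <- majority_vote(lm, rule)
  truth <- as.integer(ds$labels > 0)
  frac <- colMeans(lm)
  auc <- if (length(grid) > 1) auc_over_thresholds(frac, ds$labels, grid) else NA_real_
  list(accuracy = mean(pred == truth), auc = auc, labels = pred,
       vote_fraction = frac, lm = lm)
}

# union of fronts re-filtered to the mutually non-dominated subset
general_front <- function(fronts) {
  solutions <- do.call(c, lapply(fronts, `[[`, "solutions"))
  solutions <- solutions[!duplicated(vapply(solutions, `[[`, character(1), "key"))]
  objs <- do.call(rbind, lapply(solutions, `[[`, "objectives"))
  keep <- dominance_ranks(objs) == 0L
  structure(list(solutions = dedup_front(solutions[keep]), spec = fronts[[1]]$spec,
                 m = fronts[[1]]$m, config = list()),
            class = "momep_front")
}

#' Run the full evaluation protocol
#'
#' Per run: a seeded two-thirds/one-third split, one evolutionary run on
#' the training part, and Pareto-front voting over the test part at all
#' grid thresholds; accuracy and AUC are averaged over runs. Afterwards the
#' per-run fronts are pooled into the general Pareto front (the
#' non-dominated subset of the union), which is voted over each run's test
#' set to give the "optimal" accuracy/AUC.
#'
#' @param data Feature table with a `label` column.
#' @param spec A [model_spec()].
#' @param n_runs Number of independent runs, at least 1.
#' @param seed Master seed; each run derives its own sub-seed.
#' @param stratified,train_size Passed to [split_data()].
#' @param ... Passed to [evolve()] (population size, generations, ...).
#' @return An object of class `momep_protocol`: per-run results, averaged
#'   and general-front ("optimal") metrics, and the general front itself.
#' @export
run_protocol <- function(data, spec = model_spec("A"), n_runs = 5, seed = 1,
                         stratified = TRUE, train_size = NULL, ...) {
  if (n_runs < 1) stop_momep("`n_runs` must be at least 1", "momep_config_error")
  runs <- lapply(seq_len(n_runs), function(r) {
    rs <- child_seed(seed, r)
    parts <- split_data(data, seed = rs, stratified = stratified,
                        train_size = train_size)
    front <- evolve(parts$train, spec, seed = rs, ...)
    vote <- vote_front(front, parts$test)
    list(front = front, test = parts$test,
         accuracy = vote$accuracy, auc = vote$auc)
  })
  per_run <- tibble::tibble(
    run = seq_len(n_runs),
    front_size = vapply(runs, function(r) length(r$front$solutions), integer(1)),
    accuracy = vapply(runs, `[[`, numeric(1), "accuracy"),
    auc = vapply(runs, `[[`, numeric(1), "auc"))

  gf <- general_front(lapply(runs, `[[`, "front"))
  gf_votes <- lapply(runs, function(r) vote_front(gf, r$test))
  opt_acc <- mean(vapply(gf_votes, `[[`, numeric(1), "accuracy"))
  opt_auc <- mean(vapply(gf_votes, `[[`, numeric(1), "auc"))

  structure(list(per_run = per_run,
                 avg_accuracy = mean(per_run$accuracy),
                 avg_auc = mean(per_run$auc),
                 opt_accuracy = opt_acc, opt_auc = opt_auc,
                 general_front = gf, spec = spec, n_runs = n_runs),
            class = "momep_protocol")
}

#' @export
print.momep_protocol <- function(x, ...) {
  cat(sprintf("<momep_protocol> model %s, %d runs\n", x$spec$id, x$n_runs))
  cat(sprintf("  average voted test accuracy: %.4f (AUC %s)\n", x$avg_accuracy,
              ifelse(is.na(x$avg_auc), "-", sprintf("%.4f", x$avg_auc))))
  cat(sprintf("  general-front (optimal) accuracy: %.4f (AUC %s); front size %d\n",
              x$opt_accuracy,
              ifelse(is.na(x$opt_auc), "-", sprintf("%.4f", x$opt_auc)),
              length(x$general_front$solutions)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.momep_protocol <- function(x, ...) x$per_run

#' @exportS3Method generics::glance
glance.momep_protocol <- function(x, ...) {
  tibble::tibble(model = x$spec$id, n_runs = x$n_runs,
                 avg_accuracy = x$avg_accuracy, avg_auc = x$avg_auc,
                 opt_accuracy = x$opt_accuracy, opt_auc = x$opt_auc,
                 general_front_size = length(x$general_front$solutions))
}

#' Compare plain voting against simultaneous multi-objective search
#'
#' Both strategies consider the same objectives on the same train/test
#' split. The voting arm evolves one single-criterion specialist per
#' objective component (independent runs) and pools all specialists into a
#' voting ensemble; the multi-objective arm evolves all objectives
#' simultaneously and votes the resulting Pareto front. Each arm is
#' repeated `n_runs` times and its test accuracies are averaged. For a
#' single-objective model the two arms coincide (and, with matched seeds,
#' return equal accuracies).
#'
#' @inheritParams run_protocol
#' @return A tibble with one row per strategy (`voting`, `mo`) and its
#'   voted test accuracy.
#' @export
compare_voting_vs_mo <- function(data, spec = model_spec("A"), n_runs = 1,
                                 seed = 1, stratified = TRUE, ...) {
  parts <- split_data(data, seed = seed, stratified = stratified)

  acc_voting <- vapply(seq_len(n_runs), function(r) {
    rs <- child_seed(seed, r)
    fronts <- lapply(seq_len(spec$n_objectives), function(j) {
      evolve(parts$train, select_objective(spec, j), seed = child_seed(rs, j), ...)
    })
    pool <- fronts[[1]]
    pool$solutions <- do.call(c, lapply(fronts, `[[`, "solutions"))
    pool$solutions <- pool$solutions[!duplicated(
      vapply(pool$solutions, `[[`, character(1), "key"))]
    vote_front(pool, parts$test)$accuracy
  }, numeric(1))

  acc_mo <- vapply(seq_len(n_runs), function(r) {
    rs <- child_seed(seed, r)
    front <- evolve(parts$train, spec, seed = child_seed(rs, 1), ...)
    vote_front(front, parts$test)$accuracy
  }, numeric(1))

  tibble::tibble(strategy = c("voting", "mo"),
                 accuracy = c(mean(acc_voting), mean(acc_mo)),
                 n_runs = n_runs)
}
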