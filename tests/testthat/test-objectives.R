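test_that("confusion counts partition the sample at any threshold", {
  expect_equal(confusion(c(0.9, 0.8, 0.4, 0.2), c(1, -1, 1, -1), 0.5),
               c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  # t = 1: nothing is predicted positive
  c1 <- confusion(c(0.9, 0.8, 0.4), c(1, 1, -1), 1)
  expect_equal(unname(c1[c("TP", "FP")]), c(0L, 0L))
  # oracle scores equal to the 0/1 labels give a perfect confusion
  labs <- c(1, -1, 1, -1, -1)
  cp <- confusion(as.numeric(labs > 0), labs, 0.5)
  expect_equal(unname(cp[c("FP", "FN")]), c(0L, 0L))
  expect_error(confusion(c(0.1, 0.2), c(1, -1, 1), 0.5), class = "momep_input_error")
})

test_that("accuracy, sensitivity, specificity follow their formulas", {
  cts <- c(TP = 3, FP = 1, TN = 2, FN = 2)
  expect_equal(accuracy(cts), 5 / 8)
  expect_equal(sensitivity(cts), 3 / 5)
  expect_equal(specificity(cts), 2 / 3)
  perfect <- c(TP = 4, FP = 0, TN = 6, FN = 0)
  expect_equal(c(accuracy(perfect), sensitivity(perfect), specificity(perfect)),
               c(1, 1, 1))
  # empty-class conventions
  expect_equal(sensitivity(c(TP = 0, FP = 1, TN = 3, FN = 0)), 0)
  expect_equal(specificity(c(TP = 2, FP = 0, TN = 0, FN = 1)), 0)
  expect_equal(gmean(c(TP = 4, FP = 2, TN = 2, FN = 1)), sqrt(0.8 * 0.5))
})

test_that("accuracy is the class-weighted mean of sensitivity and specificity", {
  set.seed(2)
  for (i in 1:50) {
    cts <- c(TP = sample(0:20, 1), FP = sample(0:20, 1),
             TN = sample(0:20, 1), FN = sample(0:20, 1))
    n <- sum(cts)
    if (n == 0) next
    np <- cts["TP"] + cts["FN"]; nn <- cts["TN"] + cts["FP"]
    expect_equal(accuracy(cts),
                 unname((np * sensitivity(cts) + nn * specificity(cts)) / n))
  }
})

test_that("threshold-sweep AUC matches the pair-counting oracle on a dense grid", {
  dense <- threshold_grid(seq(0.001, 0.999, length.out = 999))
  expect_equal(auc_over_thresholds(c(0.9, 0.8, 0.4, 0.2), c(1, 1, -1, -1), dense), 1)
  expect_equal(auc_over_thresholds(rep(0.7, 6), c(1, -1, 1, -1, 1, -1), dense), 0.5)

  set.seed(77)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    scores <- round(runif(n), 2)
    labels <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_over_thresholds(scores, labels, dense),
                 oracle_auc(scores, labels), tolerance = 5e-3)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  dense <- threshold_grid(seq(0.001, 0.999, length.out = 999))
  set.seed(13)
  scores <- round(runif(30), 2)  # 2-dp scores are fully resolved by the grid
  labels <- sample(c(-1, 1), 30, replace = TRUE)
  a1 <- auc_over_thresholds(scores, labels, dense)
  a2 <- auc_over_thresholds(sqrt(scores), labels, dense)
  expect_lt(abs(a1 - a2), 5e-3)
})

test_that("TP-rate histogram bins average correctly", {
  # thresholds yielding FP rates (0.1, 0.2, 0.6, 0.6) and TP rates
  # (0.5, 0.7, 0.9, 1.0) with 2 bins -> (0.6, 0.95); build such a dataset:
  # 10 negatives, 10 positives with chosen score patterns
  scores <- c(rep(0.9, 5), rep(0.75, 2), rep(0.6, 2), 0.4,     # positives
              0.85, 0.75, rep(0.6, 4), rep(0.1, 4))            # negatives
  labels <- c(rep(1, 10), rep(-1, 10))
  grid <- c(0.3, 0.5, 0.7, 0.8)
  h <- histo_tp_rates(scores, labels, grid, n_bins = 2)
  expect_equal(h, c(mean(c(0.5, 0.7)), mean(c(0.9, 1.0))))

  # single threshold, single bin: the output is that threshold's TP rate
  expect_equal(histo_tp_rates(scores, labels, 0.5, n_bins = 1), 0.9)

  # perfect classifier on a dense grid: the FP-rate-0 bin holds TP rate 1
  dense <- seq(0.01, 0.99, by = 0.01)
  hp <- histo_tp_rates(c(1, 1, 0.05, 0.05), c(1, 1, -1, -1), dense, n_bins = 10)
  expect_equal(hp[1], 1)
  expect_equal(hp[10], 1)  # all-positive thresholds land in the last bin
})

test_that("model specs pair X measures with Y objectives as published", {
  a <- model_spec("A"); b <- model_spec("B"); cc <- model_spec("C"); d <- model_spec("D")
  expect_equal(a$x_measure, "AvgAcc"); expect_equal(a$n_objectives, 10L)
  expect_equal(b$x_measure, "AUC");    expect_equal(b$n_objectives, 10L)
  expect_equal(cc$x_measure, "GM");    expect_equal(cc$n_objectives, 2L)
  expect_equal(d$x_measure, "avgGM");  expect_equal(d$n_objectives, 10L)
  expect_equal(cc$grid, 0.5)
  expect_error(model_spec("C", grid = c(0.3, 0.5)), class = "momep_config_error")
})

test_that("x_measure picks the dominant gene under every model", {
  labels <- c(rep(1, 6), rep(-1, 6))
  perfect <- c(rep(0.9, 6), rep(0.1, 6))
  flat <- rep(0.5, 12)
  scores <- rbind(flat, perfect, flat)
  for (mod in c("A", "B", "C", "D")) {
    expect_equal(x_measure(scores, labels, model_spec(mod)), 2)
  }
  # ties resolve to the lowest index
  same <- rbind(flat, flat, flat)
  expect_equal(x_measure(same, labels, model_spec("A")), 1)
  # GM arithmetic: sens 0.8, spec 0.5 -> sqrt(0.4)
  cts <- confusion(c(0.9, 0.9, 0.9, 0.9, 0.1, 0.7, 0.7, 0.2, 0.2),
                   c(1, 1, 1, 1, 1, -1, -1, -1, -1), 0.5)
  expect_equal(gmean(cts), sqrt(0.8 * 0.5))
})

test_that("y_objectives have the right shape, range and degenerate values", {
  labels <- c(rep(1, 5), rep(-1, 5))
  scores <- runif(10)
  for (mod in c("A", "B", "D")) {
    y <- y_objectives(scores, labels, model_spec(mod))
    expect_length(y, model_spec(mod)$n_objectives)
    expect_true(all(y >= 0 & y <= 1))
  }
  # perfect classifier, model C -> (1, 1)
  yC <- y_objectives(c(rep(0.9, 5), rep(0.1, 5)), labels, model_spec("C"))
  expect_equal(yC, c(1, 1))
  # degenerate all-positive classifier has GM 0 (spec factor annihilates)
  yD <- y_objectives(rep(0.99, 10), labels, model_spec("D"))
  expect_true(all(yD == 0))
  # single-criterion restriction picks one component
  y1 <- y_objectives(scores, labels, select_objective(model_spec("A"), 3))
  expect_equal(y1, y_objectives(scores, labels, model_spec("A"))[3])
})

test_that("classifier metric dumps serialize to JSON and back", {
  labels <- c(1, 1, -1, -1)
  m <- classifier_metrics(c(0.8, 0.6, 0.4, 0.2), labels, model_spec("C"))
  js <- jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$x_value, m$x_value)
  expect_equal(back$per_threshold$accuracy, m$per_threshold[[1]]$accuracy)
})
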