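test_that("wins/ties/losses count row winners correctly", {
  tab <- rbind(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))
  colnames(tab) <- c("a", "b", "c")
  wtl <- wins_ties_losses(tab)
  expect_equal(wtl$wins, c(1L, 1L, 1L))

  dominant <- cbind(a = c(5, 6, 7), b = c(1, 2, 3))
  expect_equal(wins_ties_losses(dominant)$wins, c(3L, 0L))
  expect_equal(wins_ties_losses(dominant)$losses, c(0L, 3L))

  same <- cbind(a = c(1, 2), b = c(1, 2))
  expect_equal(wins_ties_losses(same)$ties, c(2L, 2L))
  expect_equal(wins_ties_losses(same)$win_pct, c(0, 0))
})

test_that("the sign test uses the normal quantile and exact binomial tail", {
  st <- sign_test(9, 12, alpha = 0.05)
  expect_equal(st$z_alpha, qnorm(0.95))
  expect_equal(round(st$z_alpha, 3), 1.645)
  expect_equal(st$threshold, 6 + qnorm(0.95) * sqrt(12) / 2)
  expect_equal(st$p, 299 / 4096)
  # rejection iff ncw >= 9 for nc = 12 at alpha = 0.05
  expect_false(sign_test(8, 12)$reject)
  expect_true(sign_test(9, 12)$reject)

  # exact binomial p decreases monotonically in ncw
  ps <- vapply(0:12, function(w) sign_test(w, 12)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(sign_test(13, 12), class = "momep_input_error")
})

test_that("Wilcoxon rank sums and exact p match enumeration", {
  w <- wilcoxon_signed_rank(c(2, 1, 3, 4))
  expect_equal(w$r_minus, 0)
  expect_equal(w$T, 0)
  # symmetric differences balance the sums
  ws <- wilcoxon_signed_rank(c(2, -2, 5, -5))
  expect_equal(ws$r_plus, ws$r_minus)
  # N = 5 all positive: one-sided exact p = 1/32
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p, 1 / 32)
  # all-zero differences: T = N(N+1)/4 and p = 1
  w0 <- wilcoxon_signed_rank(rep(0, 6))
  expect_equal(w0$T, 6 * 7 / 4)
  expect_equal(w0$p, 1)

  # rank conservation: R+ + R- = N(N+1)/2
  set.seed(3)
  for (i in 1:25) {
    d <- round(rnorm(10), 1)
    w <- wilcoxon_signed_rank(d)
    expect_equal(w$r_plus + w$r_minus, 10 * 11 / 2)
  }
})

test_that("the convolution null matches full 2^N enumeration, zeros and ties included", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- sample(c(-3, -2, -1, 0, 1, 2, 3), n, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(d)$p, oracle_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("exact and normal-approximate Wilcoxon p agree for N = 20", {
  set.seed(5)
  for (i in 1:10) {
    d <- rnorm(20)
    p_exact <- wilcoxon_signed_rank(d, exact_limit = 25)$p
    p_norm <- wilcoxon_signed_rank(d, exact_limit = 10)$p
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("Friedman statistic matches its definition and an independent check", {
  same <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(friedman_rank_test(same)$chi2, 0)

  perfect <- rbind(c(3, 2, 1), c(3, 2, 1), c(3, 2, 1))
  expect_equal(friedman_rank_test(perfect)$chi2, 6)

  set.seed(9)
  for (i in 1:100) {
    tab <- matrix(rnorm(4 * 8), 8, 4)
    fr <- friedman_rank_test(tab)
    expect_equal(fr$chi2, oracle_friedman_chi2(tab), tolerance = 1e-12)
    expect_equal(sum(fr$avg_ranks), 4 * 5 / 2)
  }

  # base R's friedman.test as an independent cross-check (no ties case)
  tab <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(friedman_rank_test(tab)$chi2,
               unname(stats::friedman.test(tab)$statistic), tolerance = 1e-10)

  # rank-based: invariant to strictly monotone transforms of each row
  tab2 <- t(apply(tab, 1, function(r) exp(r)))
  expect_equal(friedman_rank_test(tab)$chi2, friedman_rank_test(tab2)$chi2)
})

test_that("Iman-Davenport follows Eq arithmetic and flags its pole", {
  expect_equal(iman_davenport(0, 10, 4)$F_F, 0)
  expect_equal(iman_davenport(6, 4, 3)$F_F, 9)
  expect_error(iman_davenport(8, 4, 3), class = "momep_degenerate_error")
  fr <- friedman_rank_test(rbind(c(3, 2, 1), c(3, 2, 1), c(2, 3, 1), c(1, 2, 3)))
  id <- iman_davenport(fr)
  expect_equal(id$df1, 2)
  expect_equal(id$df2, 6)
})

test_that("Nemenyi critical differences use the tabled constants", {
  nm <- nemenyi(c(A = 1.2, B = 2.0, C = 3.1, D = 3.7), n_ds = 12, alpha = 0.05)
  expect_equal(nm$q_alpha, 2.569)
  expect_equal(nm$cd, 2.569 * sqrt(20 / 72))
  # k = 2 reduces to the z scaling
  nm2 <- nemenyi(c(a = 1.2, b = 1.8), n_ds = 10, alpha = 0.05)
  expect_equal(nm2$q_alpha, 1.960)
  expect_equal(nm2$cd, 1.960 * sqrt(6 / 60))
  # equal average ranks are never flagged
  nm3 <- nemenyi(c(a = 2, b = 2, c = 2), n_ds = 5)
  expect_false(any(nm3$pairs$significant))
  expect_error(nemenyi(setNames(1:11, letters[1:11]), n_ds = 5),
               class = "momep_config_error")
  expect_error(nemenyi(c(a = 1, b = 2), n_ds = 5, alpha = 0.01),
               class = "momep_config_error")
  expect_s3_class(autoplot(nm), "ggplot")
})

test_that("CD-diagram groups are the maximal non-separated runs", {
  # CD = 2.569 * sqrt(20/72) ~ 1.354: A-B-D form one group, B-D-C another
  nm <- nemenyi(c(A = 1.5, B = 2.75, C = 3, D = 2.75), n_ds = 12, alpha = 0.05)
  named <- lapply(nm$groups, function(g) sort(names(nm$avg_ranks)[g]))
  expect_true(list(c("A", "B", "D")) %in% named ||
                any(vapply(named, identical, logical(1), c("A", "B", "D"))))
  expect_true(any(vapply(named, identical, logical(1), c("B", "C", "D"))))
  expect_length(named, 2)
})

test_that("the full battery flags a dominant algorithm and stays quiet on ties", {
  n_ds <- 12
  set.seed(10)
  base <- matrix(runif(n_ds * 4, 0.4, 0.6), n_ds, 4,
                 dimnames = list(NULL, LETTERS[1:4]))
  dominant <- base
  dominant[, 1] <- dominant[, 1] + 0.5  # A strictly best everywhere
  dominant[, 4] <- dominant[, 4] - 0.5  # D strictly worst
  rep_dom <- full_comparison(list(acc = dominant))
  m <- rep_dom$measures$acc
  expect_true(m$friedman$reject)
  expect_false(is.null(m$nemenyi))
  ad <- m$nemenyi$pairs[m$nemenyi$pairs$a == "A" & m$nemenyi$pairs$b == "D", ]
  expect_true(ad$significant)

  flat <- matrix(rep(1:n_ds, 4), n_ds, 4, dimnames = list(NULL, LETTERS[1:4]))
  rep_flat <- full_comparison(list(acc = flat))
  td <- tidy(rep_flat)
  expect_false(any(td$significant[td$test %in% c("friedman", "wilcoxon")]))

  expect_error(full_comparison(list(a = dominant,
                                    b = dominant[, c(2, 1, 3, 4)])),
               class = "momep_input_error")
})

test_that("comparison reports round-trip through JSON", {
  set.seed(2)
  tab <- matrix(runif(24), 6, 4, dimnames = list(NULL, LETTERS[1:4]))
  rep_ <- full_comparison(list(acc = tab, auc = tab + 0.1))
  path <- withr::local_tempfile(fileext = ".json")
  write_comparison(rep_, path)
  back <- read_comparison(path)
  expect_equal(as.data.frame(back), as.data.frame(tidy(rep_)))
})
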