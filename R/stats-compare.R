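#' Wins, ties and losses
#'
#' For each problem (row) of a performance table the algorithm with the
#' largest value wins; exactly equal maxima tie among the algorithms that
#' share them; everyone else loses.
#'
#' @param table Numeric matrix or data frame, problems in rows and
#'   algorithms in columns (all values maximized).
#' @return A tibble with per-algorithm `wins`, `ties`, `losses` and their
#'   percentages of the problem count.
#' @export
wins_ties_losses <- function(table) {
  tab <- as.matrix(table)
  validate_performance_table(tab)
  k <- ncol(tab)
  algs <- colnames(tab) %||% paste0("alg", seq_len(k))
  w <- t_ <- l <- integer(k)
  for (i in seq_len(nrow(tab))) {
    best <- max(tab[i, ])
    at_best <- tab[i, ] == best
    if (sum(at_best) == 1) {
      w[at_best] <- w[at_best] + 1L
      l[!at_best] <- l[!at_best] + 1L
    } else {
      t_[at_best] <- t_[at_best] + 1L
      l[!at_best] <- l[!at_best] + 1L
    }
  }
  n <- nrow(tab)
  tibble::tibble(algorithm = algs, wins = w, ties = t_, losses = l,
                 win_pct = 100 * w / n, tie_pct = 100 * t_ / n,
                 loss_pct = 100 * l / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_performance_table <- function(tab) {
  if (!is.matrix(tab) || ncol(tab) < 2 || nrow(tab) < 1 || !all(is.finite(tab)))
    stop_momep("performance table needs >= 2 algorithms, >= 1 problem, finite values",
               "momep_input_error")
  invisible(TRUE)
}

#' Sign test on win counts
#'
#' Under the null that two algorithms perform equally well, each wins about
#' `nc / 2` of `nc` comparisons. The null is rejected when the win count
#' `ncw` (ties counted as wins for the first algorithm, per the
#' "better or the same" convention; `ties = "half"` counts them half each)
#' reaches `nc/2 + z_alpha * sqrt(nc) / 2`. The p-value is the exact
#' binomial tail `P(X >= ncw)`, `X ~ Binomial(nc, 1/2)`.
#'
#' @param ncw Number of wins (including ties) of the first algorithm.
#' @param nc Total number of comparisons.
#' @param alpha Significance level.
#' @return An object of class `momep_sign_test`.
#' @examples
#' sign_test(9, 12) # p = 299/4096
#' @export
sign_test <- function(ncw, nc, alpha = 0.05) {
  if (ncw < 0 || ncw > nc) stop_momep("`ncw` must lie in [0, nc]", "momep_input_error")
  z <- qnorm(1 - alpha)
  threshold <- nc / 2 + z * sqrt(nc) / 2
  p <- pbinom(ncw - 1, nc, 0.5, lower.tail = FALSE)
  structure(list(ncw = ncw, nc = nc, alpha = alpha, z_alpha = z,
                 threshold = threshold, reject = ncw >= threshold, p = p),
            class = "momep_sign_test")
}

#' @export
print.momep_sign_test <- function(x, ...) {
  cat(sprintf("Sign test: ncw = %d of nc = %d, threshold %.3f (z = %.3f), p = %.4g%s\n",
              x$ncw, x$nc, x$threshold, x$z_alpha, x$p,
              if (x$reject) " *" else ""))
  invisible(x)
}

# counts wins of algorithm a over b across the rows of a table,
# ties counted as wins (or half wins) for a
count_wins <- function(tab, a, b, ties = c("win", "half")) {
  ties <- match.arg(ties)
  gt <- sum(tab[, a] > tab[, b])
  eq <- sum(tab[, a] == tab[, b])
  if (ties == "win") gt + eq else gt + eq / 2
}

#' Wilcoxon signed-ranks test
#'
#' Ranks the absolute paired differences ascending (ties get average
#' ranks); `R+` sums the ranks of positive differences, `R-` of negative
#' ones, and zero differences contribute half their rank to each sum.
#' `T = min(R+, R-)`. For `N <= exact_limit` the one-sided p-value
#' `P(R <= T)` is exact, from the null distribution of the signed rank sum
#' over all sign assignments of the nonzero differences (computed by
#' convolution); beyond that the normal approximation
#' `z = (T - N(N+1)/4) / sqrt(N(N+1)(2N+1)/24)` is used.
#'
#' @param diffs Numeric vector of paired performance differences.
#' @param exact_limit Largest `N` for which the exact null is computed.
#' @return An object of class `momep_wilcoxon`: `r_plus`, `r_minus`, `T`,
#'   `N`, `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(diffs, exact_limit = 25) {
  N <- length(diffs)
  if (N < 1) stop_momep("`diffs` must be non-empty", "momep_input_error")
  rk <- rank(abs(diffs))
  r_plus <- sum(rk[diffs > 0]) + sum(rk[diffs == 0]) / 2
  r_minus <- sum(rk[diffs < 0]) + sum(rk[diffs == 0]) / 2
  T_ <- min(r_plus, r_minus)
  if (N <= exact_limit) {
    p <- wilcoxon_exact_p(rk[diffs != 0], sum(rk[diffs == 0]) / 2, T_)
    method <- "exact"
  } else {
    z <- (T_ - N * (N + 1) / 4) / sqrt(N * (N + 1) * (2 * N + 1) / 24)
    p <- pnorm(z)
    method <- "normal"
  }
  structure(list(r_plus = r_plus, r_minus = r_minus, T = T_, N = N,
                 p = p, method = method),
            class = "momep_wilcoxon")
}

# one-sided P(R <= T_obs) where R = base + sum of a random subset of
# `ranks` (each included with prob 1/2). Ranks may be half-integers from
# tie averaging, so everything is doubled onto an integer lattice.
wilcoxon_exact_p <- function(ranks, base, T_obs) {
  if (length(ranks) == 0) return(1)
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1)  # index s+1 holds P(2 * subset sum = s)
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), dist[seq_len(total + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  sums <- (seq_along(dist) - 1) / 2 + base
  sum(dist[sums <= T_obs + 1e-9])
}

#' @export
print.momep_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-ranks: R+ = %.1f, R- = %.1f, T = %.1f, N = %d, p = %.4g (%s)\n",
              x$r_plus, x$r_minus, x$T, x$N, x$p, x$method))
  invisible(x)
}

#' Friedman rank test
#'
#' Ranks the algorithms within each problem (rank 1 = best performance,
#' ties averaged) and tests whether the mean ranks `R_j` could have arisen
#' under equal performance:
#' `chi2_F = 12 N / (k (k+1)) * (sum R_j^2 - k (k+1)^2 / 4)`,
#' referred to a chi-squared distribution with `k - 1` degrees of freedom.
#' An explicit `critical` value may be supplied (e.g. an exact-table value)
#' in place of the chi-squared quantile.
#'
#' @param table Performance matrix/data frame, problems x algorithms,
#'   larger is better.
#' @param alpha Significance level.
#' @param critical Optional critical value overriding the chi-squared
#'   quantile at `k - 1` degrees of freedom.
#' @return An object of class `momep_friedman`: `avg_ranks`, `chi2`, `df`,
#'   `critical`, `reject`, `p`.
#' @export
friedman_rank_test <- function(table, alpha = 0.05, critical = NULL) {
  tab <- as.matrix(table)
  validate_performance_table(tab)
  if (nrow(tab) < 2)
    stop_momep("the Friedman test needs at least 2 problems", "momep_input_error")
  k <- ncol(tab)
  N <- nrow(tab)
  ranks <- t(apply(tab, 1, function(row) rank(-row)))
  avg <- colMeans(ranks)
  chi2 <- 12 * N / (k * (k + 1)) * (sum(avg^2) - k * (k + 1)^2 / 4)
  crit <- critical %||% qchisq(1 - alpha, df = k - 1)
  structure(list(avg_ranks = setNames(avg, colnames(tab) %||% paste0("alg", 1:k)),
                 chi2 = chi2, df = k - 1L, critical = crit,
                 reject = chi2 > crit,
                 p = stats::pchisq(chi2, df = k - 1, lower.tail = FALSE),
                 k = k, n_ds = N, alpha = alpha),
            class = "momep_friedman")
}

#' @export
print.momep_friedman <- function(x, ...) {
  cat(sprintf("Friedman: chi2_F = %.4f (df = %d), critical %.4f, p = %.4g%s\n",
              x$chi2, x$df, x$critical, x$p, if (x$reject) " *" else ""))
  print(round(x$avg_ranks, 3))
  invisible(x)
}

#' Iman-Davenport correction of the Friedman statistic
#'
#' `F_F = (N_ds - 1) chi2_F / (N_ds (k - 1) - chi2_F)`, referred to the
#' F distribution with `k - 1` and `(k - 1)(N_ds - 1)` degrees of freedom.
#' A less conservative companion to the Friedman test.
#'
#' @param chi2 Friedman statistic (or a `momep_friedman` object).
#' @param n_ds Number of problems.
#' @param k Number of algorithms.
#' @param alpha Significance level.
#' @return List with `F_F`, degrees of freedom, `critical`, `reject`, `p`.
#' @export
iman_davenport <- function(chi2, n_ds, k, alpha = 0.05) {
  if (inherits(chi2, "momep_friedman")) {
    n_ds <- chi2$n_ds; k <- chi2$k; chi2 <- chi2$chi2
  }
  denom <- n_ds * (k - 1) - chi2
  if (denom <= 0)
    stop_momep("degenerate statistic: chi2 reaches its upper bound N(k-1)",
               "momep_degenerate_error")
  ff <- (n_ds - 1) * chi2 / denom
  df1 <- k - 1
  df2 <- (k - 1) * (n_ds - 1)
  crit <- stats::qf(1 - alpha, df1, df2)
  list(F_F = ff, df1 = df1, df2 = df2, critical = crit, reject = ff > crit,
       p = stats::pf(ff, df1, df2, lower.tail = FALSE))
}

# Critical q constants for the Nemenyi test (Studentized range / sqrt(2)),
# k = 2..10
NEMENYI_Q <- list(
  "0.05" = c(1.960, 2.343, 2.569, 2.728, 2.850, 2.949, 3.031, 3.102, 3.164),
  "0.1"  = c(1.645, 2.052, 2.291, 2.459, 2.589, 2.693, 2.780, 2.855, 2.920))

#' Nemenyi post-hoc test and critical-difference diagram data
#'
#' Two algorithms differ significantly when their average Friedman ranks
#' differ by at least `CDf = q_alpha * sqrt(k (k+1) / (6 N_ds))`. Returns
#' the flagged pairs and the data behind a critical-difference diagram:
#' algorithms placed at their average ranks plus the maximal groups of
#' algorithms whose rank span stays below `CDf` (drawn as connecting
#' segments).
#'
#' @param avg_ranks Named numeric vector of average ranks (or a
#'   `momep_friedman` object).
#' @param n_ds Number of problems.
#' @param alpha 0.05 or 0.10.
#' @return An object of class `momep_nemenyi`.
#' @export
nemenyi <- function(avg_ranks, n_ds, alpha = 0.05) {
  if (inherits(avg_ranks, "momep_friedman")) {
    n_ds <- avg_ranks$n_ds
    avg_ranks <- avg_ranks$avg_ranks
  }
  k <- length(avg_ranks)
  if (k < 2 || k > 10)
    stop_momep("Nemenyi constants are tabled for k in 2..10", "momep_config_error")
  key <- as.character(alpha)
  if (!key %in% names(NEMENYI_Q))
    stop_momep("`alpha` must be 0.05 or 0.10", "momep_config_error")
  q <- NEMENYI_Q[[key]][k - 1]
  cdf <- q * sqrt(k * (k + 1) / (6 * n_ds))
  algs <- names(avg_ranks) %||% paste0("alg", seq_len(k))
  pairs <- t(combn(k, 2))
  sig <- tibble::tibble(
    a = algs[pairs[, 1]], b = algs[pairs[, 2]],
    rank_a = unname(avg_ranks[pairs[, 1]]),
    rank_b = unname(avg_ranks[pairs[, 2]]),
    diff = abs(unname(avg_ranks[pairs[, 1]]) - unname(avg_ranks[pairs[, 2]])))
  sig$significant <- sig$diff >= cdf

  ord <- order(avg_ranks)
  sorted <- avg_ranks[ord]
  groups <- list()
  for (i in seq_len(k)) {
    members <- which(sorted - sorted[i] < cdf & sorted >= sorted[i])
    grp <- ord[members]
    if (length(grp) > 1) groups[[length(groups) + 1]] <- grp
  }
  # keep only maximal groups (dedupe first: identical groups must not
  # knock each other out of the subset filter)
  groups <- unique(groups)
  if (length(groups)) {
    keep <- vapply(seq_along(groups), function(i) {
      !any(vapply(seq_along(groups), function(j) {
        i != j && all(groups[[i]] %in% groups[[j]])
      }, logical(1)))
    }, logical(1))
    groups <- groups[keep]
  }
  structure(list(q_alpha = q, cd = cdf, alpha = alpha, k = k, n_ds = n_ds,
                 avg_ranks = setNames(as.numeric(avg_ranks), algs),
                 pairs = sig, groups = groups),
            class = "momep_nemenyi")
}

#' @export
print.momep_nemenyi <- function(x, ...) {
  cat(sprintf("Nemenyi: q = %.3f, CD = %.4f (k = %d, N = %d, alpha = %g)\n",
              x$q_alpha, x$cd, x$k, x$n_ds, x$alpha))
  flagged <- x$pairs[x$pairs$significant, ]
  if (nrow(flagged) == 0) {
    cat("  no significant pairs\n")
  } else {
    for (i in seq_len(nrow(flagged)))
      cat(sprintf("  %s vs %s: |%.3f - %.3f| = %.3f\n", flagged$a[i], flagged$b[i],
                  flagged$rank_a[i], flagged$rank_b[i], flagged$diff[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.momep_nemenyi <- function(x, ...) x$pairs

#' Critical-difference diagram
#'
#' Demsar-style visualization: algorithms are placed on a rank axis at
#' their average Friedman ranks; horizontal segments connect groups whose
#' performance does not differ by the critical difference.
#'
#' @param object A `momep_nemenyi` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.momep_nemenyi <- function(object, ...) {
  ranks <- sort(object$avg_ranks)
  pts <- tibble::tibble(algorithm = names(ranks), rank = unname(ranks),
                        y = 0.3 + 0.15 * (seq_along(ranks) %% 2))
  segs <- if (length(object$groups)) {
    dplyr::bind_rows(lapply(seq_along(object$groups), function(g) {
      r <- object$avg_ranks[object$groups[[g]]]
      tibble::tibble(xmin = min(r), xmax = max(r), y = -0.12 * g)
    }))
  } else {
    tibble::tibble(xmin = numeric(0), xmax = numeric(0), y = numeric(0))
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$rank, y = 0)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(y = .data$y, label = .data$algorithm),
                       size = 3.2) +
    ggplot2::annotate("segment", x = min(pts$rank), xend = min(pts$rank) + object$cd,
                      y = 0.62, yend = 0.62, linewidth = 1) +
    ggplot2::annotate("text", x = min(pts$rank) + object$cd / 2, y = 0.72,
                      label = sprintf("CD = %.3f", object$cd), size = 3) +
    ggplot2::scale_y_continuous(limits = c(-0.15 * max(1, length(object$groups)) - 0.1, 0.85)) +
    ggplot2::labs(x = "average rank (1 = best)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (nrow(segs)) {
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$xmin, xend = .data$xmax, y = .data$y, yend = .data$y),
      linewidth = 1.2, inherit.aes = FALSE)
  }
  p
}

#' Full non-parametric comparison battery
#'
#' Runs, per performance measure: wins/ties/losses, the sign test and the
#' Wilcoxon signed-ranks test for every algorithm pair, the Friedman test,
#' its Iman-Davenport correction, and — whenever Friedman rejects — the
#' Nemenyi post-hoc with critical-difference data. Statistics with
#' `p < alpha` are flagged.
#'
#' @param tables Named list of performance tables (problems x algorithms);
#'   all tables must share the same algorithm columns.
#' @param alpha Significance level.
#' @param ties Tie handling for the sign test's win counts.
#' @return An object of class `momep_comparison`.
#' @export
full_comparison <- function(tables, alpha = 0.05, ties = "win") {
  if (!is.list(tables) || is.null(names(tables)))
    stop_momep("`tables` must be a named list of performance tables",
               "momep_input_error")
  algs <- colnames(as.matrix(tables[[1]]))
  for (tb in tables) {
    if (!identical(colnames(as.matrix(tb)), algs))
      stop_momep("all tables must share the same algorithm columns",
                 "momep_input_error")
  }
  measures <- lapply(names(tables), function(nm) {
    tab <- as.matrix(tables[[nm]])
    validate_performance_table(tab)
    k <- ncol(tab)
    pairs <- t(combn(k, 2))
    pair_tests <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      ncw <- count_wins(tab, a, b, ties)
      list(a = colnames(tab)[a], b = colnames(tab)[b],
           sign = sign_test(ncw, nrow(tab), alpha),
           wilcoxon = wilcoxon_signed_rank(tab[, a] - tab[, b]))
    })
    fr <- friedman_rank_test(tab, alpha)
    id <- tryCatch(iman_davenport(fr, alpha = alpha),
                   momep_degenerate_error = function(e) NULL)
    nem <- if (fr$reject) nemenyi(fr, alpha = alpha) else NULL
    list(measure = nm, wtl = wins_ties_losses(tab), pairs = pair_tests,
         friedman = fr, iman_davenport = id, nemenyi = nem)
  })
  structure(list(measures = setNames(measures, names(tables)), alpha = alpha),
            class = "momep_comparison")
}

#' @export
print.momep_comparison <- function(x, ...) {
  for (m in x$measures) {
    cat("==", m$measure, "==\n")
    print(m$friedman)
    if (!is.null(m$nemenyi)) print(m$nemenyi)
  }
  invisible(x)
}

#' Tidy a comparison report
#'
#' @param x A `momep_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per (measure, test, pair) and its
#'   statistic, p-value and significance flag.
#' @exportS3Method generics::tidy
tidy.momep_comparison <- function(x, ...) {
  rows <- list()
  for (m in x$measures) {
    for (pt in m$pairs) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        measure = m$measure, test = "sign",
        pair = paste(pt$a, "vs", pt$b),
        statistic = pt$sign$ncw, p = pt$sign$p,
        significant = pt$sign$p < x$alpha)
      rows[[length(rows) + 1]] <- tibble::tibble(
        measure = m$measure, test = "wilcoxon",
        pair = paste(pt$a, "vs", pt$b),
        statistic = pt$wilcoxon$T, p = pt$wilcoxon$p,
        significant = pt$wilcoxon$p < x$alpha)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      measure = m$measure, test = "friedman", pair = "all",
      statistic = m$friedman$chi2, p = m$friedman$p,
      significant = m$friedman$reject)
    if (!is.null(m$iman_davenport)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        measure = m$measure, test = "iman_davenport", pair = "all",
        statistic = m$iman_davenport$F_F, p = m$iman_davenport$p,
        significant = m$iman_davenport$reject)
    }
  }
  dplyr::bind_rows(rows)
}

#' Write / read a comparison report as JSON
#'
#' The tidy form of the report round-trips losslessly.
#'
#' @param x A `momep_comparison`.
#' @param path File path.
#' @return `write_comparison()` the path invisibly; `read_comparison()` a
#'   tibble equal to `tidy(x)`.
#' @export
write_comparison <- function(x, path) {
  jsonlite::write_json(tidy(x), path, digits = NA)
  invisible(path)
}

#' @rdname write_comparison
#' @export
read_comparison <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}
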