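#' Pareto dominance (maximization)
#'
#' `u` dominates `v` iff `u` is at least as good componentwise and strictly
#' better somewhere.
#'
#' @param u,v Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(u, v) {
  if (length(u) != length(v))
    stop_momep("objective vectors must have equal length", "momep_input_error")
  all(u >= v) && any(u > v)
}

#' Dominance-count ranks
#'
#' The fitness used by the search: each solution's rank is the number of
#' other solutions that dominate it, so non-dominated solutions have the
#' best rank of 0. (This is a dominance *count*, not front-peeling; the two
#' coincide on the rank-0 set, which is what a run returns.)
#'
#' @param objs Numeric matrix, one row per solution, or a list of objective
#'   vectors.
#' @return Integer vector of ranks.
#' @export
dominance_ranks <- function(objs) {
  if (is.list(objs)) objs <- do.call(rbind, objs)
  if (!is.matrix(objs) || nrow(objs) == 0)
    stop_momep("`objs` must be a non-empty matrix or list", "momep_input_error")
  n <- nrow(objs)
  ranks <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(objs[j, ], objs[i, ])) ranks[i] <- ranks[i] + 1L
    }
  }
  ranks
}

#' Crowding distances
#'
#' Diversity score over a set of mutually comparable solutions: on each
#' objective a solution's contribution is the mean of its distances to the
#' nearest other value at-or-below and at-or-above it (exact duplicates
#' therefore contribute 0); the crowding distance is the mean over
#' objectives. Solutions holding an extreme value on any objective with
#' non-zero range get `+Inf`, preserving the spread of the front; sets of
#' at most two solutions are all `+Inf`. Objectives with zero range
#' contribute 0.
#'
#' @param objs Numeric matrix (rows = solutions) or list of vectors.
#' @return Numeric vector of crowding distances (possibly `Inf`).
#' @export
crowding_distances <- function(objs) {
  if (is.list(objs)) objs <- do.call(rbind, objs)
  if (!is.matrix(objs) || nrow(objs) < 1)
    stop_momep("at least one solution is required", "momep_input_error")
  n <- nrow(objs); k <- ncol(objs)
  if (n <= 2) return(rep(Inf, n))
  contrib <- matrix(0, n, k)
  extreme <- rep(FALSE, n)
  for (j in seq_len(k)) {
    v <- objs[, j]
    rng <- max(v) - min(v)
    if (rng == 0) next
    extreme <- extreme | v == max(v) | v == min(v)
    for (i in seq_len(n)) {
      others <- v[-i]
      lower <- others[others <= v[i]]
      upper <- others[others >= v[i]]
      d_lo <- if (length(lower)) v[i] - max(lower) else NA_real_
      d_hi <- if (length(upper)) min(upper) - v[i] else NA_real_
      contrib[i, j] <- mean(c(d_lo, d_hi), na.rm = TRUE)
    }
  }
  out <- rowMeans(contrib)
  out[extreme] <- Inf
  out
}

# evaluate one chromosome under a model: best gene, x value, objectives
evaluate_individual <- function(chrom, ds, spec, fs) {
  outputs <- evaluate_chromosome(chrom, ds, fs)
  xv <- x_values(outputs, ds$labels, spec)
  best <- which.max(xv)
  list(chromosome = chrom, best_gene = best, x_value = xv[best],
       objectives = y_objectives(outputs$scores[best, ], ds$labels, spec),
       key = paste(format_chromosome(chrom), collapse = ";"))
}

# duplicate objective vectors are kept in the population during the search
# but collapse to one representative (lowest genome key) in a reported front
dedup_front <- function(solutions) {
  if (length(solutions) <= 1) return(solutions)
  keys <- vapply(solutions, `[[`, character(1), "key")
  solutions <- solutions[order(keys, method = "radix")]
  obj_key <- vapply(solutions, function(s) {
    paste(sprintf("%.15g", s$objectives), collapse = ",")
  }, character(1))
  solutions[!duplicated(obj_key)]
}

# total preorder used for truncation and tournaments: rank ascending,
# crowding descending, then genome serialization order (radix = byte-wise,
# so the ordering does not depend on the session locale)
selection_order <- function(ranks, crowding, keys) {
  order(ranks, -crowding, keys, method = "radix")
}

#' Evolve a Pareto front of MEP classifiers
#'
#' Elitist (mu + lambda) NSGA-II style loop: every generation builds
#' `population_size` offspring by binary tournament on (dominance rank,
#' crowding distance), one-point crossover and per-gene mutation; parent
#' and offspring populations are merged and the best `population_size`
#' individuals by (rank ascending, crowding descending, genome order)
#' survive. Each individual is evaluated by picking its best sub-expression
#' under the model's X measure and scoring that sub-expression's Y
#' objective vector. The run returns the final non-dominated set.
#'
#' @param data Feature table (tibble with `f1..fm` and `label`) or
#'   `momep_dataset`; both classes must be present.
#' @param spec A [model_spec()].
#' @param population_size Even population size.
#' @param generations Number of generations, at least 1.
#' @param crossover_prob Probability a parent pair is recombined.
#' @param mutation_prob Per-gene mutation probability.
#' @param L Genome length.
#' @param fs An [mep_function_set()].
#' @param constant_range Range of random constant terminals.
#' @param tournament_size Tournament size for parent selection.
#' @param seed Integer seed; fixed seeds give identical fronts.
#' @return An object of class `momep_front`: list with `solutions` (each a
#'   chromosome + best gene + objective vector), `spec`, and the run
#'   configuration.
#' @examples
#' d <- sim_features(n = 60, m = 4, class_mean_shift = c(3, 0, 0, 0), seed = 1)
#' f <- evolve(d, model_spec("C"), population_size = 20, generations = 5, seed = 1)
#' length(f$solutions)
#' @export
evolve <- function(data, spec = model_spec("A"), population_size = 100,
                   generations = 100, crossover_prob = 0.9,
                   mutation_prob = 0.05, L = 30, fs = mep_function_set(),
                   constant_range = c(-1, 1), tournament_size = 2, seed = 1) {
  ds <- as_labeled_dataset(data)
  if (ds$n_positive == 0 || ds$n_negative == 0)
    stop_momep("both classes must be present in the training data",
               "momep_data_error")
  if (population_size %% 2 != 0)
    stop_momep("`population_size` must be even", "momep_config_error")
  if (generations < 1)
    stop_momep("`generations` must be at least 1", "momep_config_error")
  m <- ncol(ds$features)
  set.seed(as.integer(seed))

  pop <- lapply(seq_len(population_size), function(i) {
    evaluate_individual(random_chromosome(L, m, fs, constant_range), ds, spec, fs)
  })

  rank_pool <- function(pool) {
    objs <- do.call(rbind, lapply(pool, `[[`, "objectives"))
    ranks <- dominance_ranks(objs)
    crowd <- rep(0, length(pool))
    for (r in unique(ranks)) {
      idx <- which(ranks == r)
      crowd[idx] <- crowding_distances(objs[idx, , drop = FALSE])
    }
    list(ranks = ranks, crowd = crowd,
         keys = vapply(pool, `[[`, character(1), "key"))
  }

  info <- rank_pool(pop)
  for (gen in seq_len(generations)) {
    pick <- function() {
      cand <- sample.int(length(pop), tournament_size)
      cand[selection_order(info$ranks[cand], info$crowd[cand],
                           info$keys[cand])[1]]
    }
    offspring <- vector("list", population_size)
    i <- 1L
    while (i <= population_size) {
      pa <- pop[[pick()]]$chromosome
      pb <- pop[[pick()]]$chromosome
      kids <- if (runif(1) < crossover_prob) crossover(pa, pb) else list(pa, pb)
      for (kid in kids) {
        if (i > population_size) break
        kid <- mutate_chromosome(kid, mutation_prob, fs, constant_range)
        offspring[[i]] <- evaluate_individual(kid, ds, spec, fs)
        i <- i + 1L
      }
    }
    pool <- c(pop, offspring)
    pinfo <- rank_pool(pool)
    keep <- selection_order(pinfo$ranks, pinfo$crowd, pinfo$keys)[seq_len(population_size)]
    pop <- pool[keep]
    info <- list(ranks = pinfo$ranks[keep], crowd = pinfo$crowd[keep],
                 keys = pinfo$keys[keep])
  }

  front <- pop[info$ranks == 0]
  front <- dedup_front(front)
  structure(list(solutions = front, spec = spec, m = m,
                 config = list(population_size = population_size,
                               generations = generations,
                               crossover_prob = crossover_prob,
                               mutation_prob = mutation_prob, L = L,
                               tournament_size = tournament_size,
                               seed = seed)),
            class = "momep_front")
}

#' @export
print.momep_front <- function(x, ...) {
  cat(sprintf("<momep_front> model %s: %d non-dominated classifiers (%d objectives)\n",
              x$spec$id, length(x$solutions), x$spec$n_objectives))
  invisible(x)
}

#' Tidy a Pareto front
#'
#' @param x A `momep_front`.
#' @param ... Unused.
#' @return A tibble with one row per front member: `classifier`,
#'   `best_gene`, `x_value` and objective columns `obj_1..obj_k`.
#' @exportS3Method generics::tidy
tidy.momep_front <- function(x, ...) {
  objs <- do.call(rbind, lapply(x$solutions, `[[`, "objectives"))
  colnames(objs) <- paste0("obj_", seq_len(ncol(objs)))
  dplyr::bind_cols(
    tibble::tibble(classifier = seq_along(x$solutions),
                   best_gene = vapply(x$solutions, `[[`, integer(1), "best_gene"),
                   x_value = vapply(x$solutions, `[[`, numeric(1), "x_value")),
    tibble::as_tibble(objs))
}

#' @exportS3Method generics::glance
glance.momep_front <- function(x, ...) {
  tibble::tibble(model = x$spec$id, n_classifiers = length(x$solutions),
                 n_objectives = x$spec$n_objectives,
                 best_x = max(vapply(x$solutions, `[[`, numeric(1), "x_value")))
}

#' Plot a Pareto front in objective space
#'
#' Two-objective fronts are drawn as a scatter; higher-dimensional fronts
#' as parallel coordinates over the objectives.
#'
#' @param object A `momep_front`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.momep_front <- function(object, ...) {
  td <- tidy(object)
  k <- object$spec$n_objectives
  if (k == 2) {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$obj_1, y = .data$obj_2)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "objective 1", y = "objective 2",
                    title = sprintf("Pareto front (model %s)", object$spec$id)) +
      ggplot2::theme_minimal()
  } else {
    long <- tidyr::pivot_longer(td, dplyr::starts_with("obj_"),
                                names_to = "objective", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$objective, y = .data$value,
                                       group = .data$classifier)) +
      ggplot2::geom_line(alpha = 0.6) +
      ggplot2::labs(title = sprintf("Pareto front (model %s)", object$spec$id),
                    x = NULL, y = "objective value") +
      ggplot2::theme_minimal()
  }
}

#' Scores of a front member on new data
#'
#' @param front A `momep_front`.
#' @param i Index of the front member.
#' @param data Feature table or `momep_dataset`.
#' @param fs Function set used in training.
#' @return Numeric score vector in `[0, 1]`.
#' @export
solution_scores <- function(front, i, data, fs = mep_function_set()) {
  sol <- front$solutions[[i]]
  evaluate_chromosome(sol$chromosome, data, fs)$scores[sol$best_gene, ]
}

#' Write / read a front archive
#'
#' JSON-lines archive: one line per classifier holding the serialized
#' genome, the best-gene index and the objective vector; a header line
#' records the model and feature count. Round-trips losslessly.
#'
#' @param front A `momep_front`.
#' @param path File path.
#' @return `write_front()` the path invisibly; `read_front()` a
#'   `momep_front`.
#' @export
write_front <- function(front, path) {
  header <- jsonlite::toJSON(list(model = front$spec$id, m = front$m,
                                  grid = front$spec$grid,
                                  n_bins = front$spec$n_bins),
                             auto_unbox = TRUE, digits = NA)
  lines <- vapply(front$solutions, function(s) {
    jsonlite::toJSON(list(genome = format_chromosome(s$chromosome),
                          best_gene = s$best_gene, x_value = s$x_value,
                          objectives = s$objectives),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_front
#' @export
read_front <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  spec <- model_spec(header$model, grid = header$grid, n_bins = header$n_bins)
  solutions <- lapply(lines[-1], function(line) {
    rec <- jsonlite::fromJSON(line)
    chrom <- parse_chromosome(rec$genome, header$m)
    list(chromosome = chrom, best_gene = as.integer(rec$best_gene),
         x_value = rec$x_value, objectives = as.numeric(rec$objectives),
         key = paste(format_chromosome(chrom), collapse = ";"))
  })
  structure(list(solutions = solutions, spec = spec, m = as.integer(header$m),
                 config = list()),
            class = "momep_front")
}
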