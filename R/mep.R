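#' MEP function set
#'
#' The operator vocabulary available to internal genes. All operators are
#' total on the reals: division is protected (returns the numerator when the
#' denominator's magnitude falls below `1e-12`). The default set is
#' `{+, -, *, /, min, max}`; the set is configurable because classification
#' problems differ in the algebra they need.
#'
#' @param operators Character vector of operator symbols drawn from the
#'   registry: `"+", "-", "*", "/", "min", "max"`.
#' @return An object of class `mep_function_set`.
#' @export
mep_function_set <- function(operators = c("+", "-", "*", "/", "min", "max")) {
  registry <- list(
    "+"   = function(a, b) a + b,
    "-"   = function(a, b) a - b,
    "*"   = function(a, b) a * b,
    "/"   = function(a, b) ifelse(abs(b) < 1e-12, a, a / b),
    "min" = function(a, b) pmin(a, b),
    "max" = function(a, b) pmax(a, b))
  bad <- setdiff(operators, names(registry))
  if (length(bad) || length(operators) == 0)
    stop_momep("unknown or empty operator set", "momep_config_error")
  structure(list(symbols = operators, funs = registry[operators],
                 arity = setNames(rep(2L, length(operators)), operators)),
            class = "mep_function_set")
}

# raw values are clamped to this magnitude after every gene so that
# evaluation stays total (no Inf/NaN can propagate into the sigmoid)
MEP_CLAMP <- 1e6

random_gene <- function(i, m, fs, constant_range, terminal_prob, const_prob) {
  if (i == 1L || runif(1) < terminal_prob) {
    if (runif(1) < const_prob) {
      list(type = "const", value = runif(1, constant_range[1], constant_range[2]))
    } else {
      list(type = "feature", index = sample.int(m, 1))
    }
  } else {
    symbol <- sample(fs$symbols, 1)
    list(type = "op", symbol = symbol,
         args = sample.int(i - 1L, fs$arity[[symbol]], replace = TRUE))
  }
}

#' Random MEP chromosome
#'
#' A chromosome is an ordered list of `L` genes. Each gene is either a
#' terminal (a feature reference or a real constant) or an operator whose
#' operand indices strictly precede it, so every gene is the root of a valid
#' sub-expression and one genome encodes `L` candidate classifiers. `L`
#' bounds the classifier size, which is what keeps evolved models readable.
#'
#' @param L Genome length (number of genes), at least 1.
#' @param m Number of input features.
#' @param fs An [mep_function_set()].
#' @param constant_range Range for random constant terminals.
#' @param terminal_prob Probability that a gene beyond the first is a
#'   terminal.
#' @param const_prob Probability that a terminal is a constant rather than a
#'   feature.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `mep_chromosome`.
#' @export
random_chromosome <- function(L, m, fs = mep_function_set(),
                              constant_range = c(-1, 1),
                              terminal_prob = 0.3, const_prob = 0.2,
                              seed = NULL) {
  if (L < 1) stop_momep("`L` must be at least 1", "momep_config_error")
  if (m < 1) stop_momep("`m` must be at least 1", "momep_config_error")
  if (!is.null(seed)) set.seed(as.integer(seed))
  genes <- lapply(seq_len(L), random_gene, m = m, fs = fs,
                  constant_range = constant_range,
                  terminal_prob = terminal_prob, const_prob = const_prob)
  new_chromosome(genes, m)
}

new_chromosome <- function(genes, m) {
  structure(list(genes = genes, m = as.integer(m)), class = "mep_chromosome")
}

#' Validate a chromosome's structural invariants
#'
#' Checks that gene 1 is a terminal, that every operator gene references
#' only earlier genes, and that feature indices are in range.
#'
#' @param chrom An `mep_chromosome`.
#' @return `TRUE` invisibly; invalid chromosomes raise an error.
#' @export
validate_chromosome <- function(chrom) {
  stopifnot(inherits(chrom, "mep_chromosome"))
  for (i in seq_along(chrom$genes)) {
    g <- chrom$genes[[i]]
    if (i == 1L && g$type == "op")
      stop_momep("gene 1 must be a terminal", "momep_chromosome_error")
    if (g$type == "op" && any(g$args >= i | g$args < 1))
      stop_momep("operator operands must strictly precede the gene",
                 "momep_chromosome_error")
    if (g$type == "feature" && (g$index < 1 || g$index > chrom$m))
      stop_momep("feature index out of range", "momep_chromosome_error")
  }
  invisible(TRUE)
}

#' @export
print.mep_chromosome <- function(x, ...) {
  cat("<mep_chromosome> L =", length(x$genes), ", m =", x$m, "\n")
  cat(format_chromosome(x), sep = "\n")
  invisible(x)
}

#' Serialize / parse a chromosome
#'
#' Line-oriented text format, one gene per line: `i: Fk` for a feature
#' terminal, `i: c=<value>` for a constant (printed at full precision, so
#' the round-trip is lossless) and `i: op(j,l)` for an operator gene.
#'
#' @param chrom An `mep_chromosome`.
#' @param lines Character vector as produced by `format_chromosome()`.
#' @param m Feature count of the parsed chromosome.
#' @return `format_chromosome()` a character vector of `L` lines;
#'   `parse_chromosome()` an `mep_chromosome`.
#' @export
format_chromosome <- function(chrom) {
  vapply(seq_along(chrom$genes), function(i) {
    g <- chrom$genes[[i]]
    body <- switch(g$type,
      feature = paste0("F", g$index),
      const = sprintf("c=%.17g", g$value),
      op = sprintf("%s(%s)", g$symbol, paste(g$args, collapse = ",")))
    sprintf("%d: %s", i, body)
  }, character(1))
}

#' @rdname format_chromosome
#' @export
parse_chromosome <- function(lines, m) {
  genes <- lapply(lines, function(line) {
    body <- sub("^\\s*\\d+:\\s*", "", line)
    if (grepl("^F\\d+$", body)) {
      list(type = "feature", index = as.integer(sub("^F", "", body)))
    } else if (grepl("^c=", body)) {
      list(type = "const", value = as.numeric(sub("^c=", "", body)))
    } else {
      symbol <- sub("\\(.*$", "", body)
      args <- as.integer(strsplit(gsub("^.*\\(|\\)$", "", body), ",")[[1]])
      list(type = "op", symbol = symbol, args = args)
    }
  })
  chrom <- new_chromosome(genes, m)
  validate_chromosome(chrom)
  chrom
}

#' Coerce a feature table to the internal labeled-dataset form
#'
#' @param data A tibble/data frame with feature columns and a `label`
#'   column in -1/+1 (0/1 is accepted and mapped), or an already-coerced
#'   `momep_dataset`.
#' @return A `momep_dataset`: list with `features` (n x m matrix), `labels`
#'   (-1/+1), `n_positive`, `n_negative`.
#' @export
as_labeled_dataset <- function(data) {
  if (inherits(data, "momep_dataset")) return(data)
  if (!is.data.frame(data) || !"label" %in% names(data))
    stop_momep("`data` must be a data frame with a `label` column", "momep_input_error")
  feats <- as.matrix(data[setdiff(names(data), "label")])
  if (ncol(feats) < 1) stop_momep("at least one feature column is required",
                                  "momep_input_error")
  if (anyNA(feats)) stop_momep("features must not contain missing values",
                               "momep_input_error")
  labels <- ifelse(data$label > 0, 1L, -1L)
  structure(list(features = feats, labels = labels,
                 n_positive = sum(labels == 1L),
                 n_negative = sum(labels == -1L)),
            class = "momep_dataset")
}

#' Evaluate every sub-expression of a chromosome on a dataset
#'
#' One forward pass computes the raw value of all `L` genes on all `n`
#' instances; the sigmoid maps every raw row into `[0, 1]` so each gene's
#' score row is a complete candidate classifier. Raw values are clamped to
#' a large finite magnitude so evaluation is total.
#'
#' @param chrom An `mep_chromosome`.
#' @param data A feature table or `momep_dataset`.
#' @param fs The [mep_function_set()] the chromosome's operators come from.
#' @return An object of class `mep_gene_outputs`: list with `raw` and
#'   `scores`, both `L x n` matrices.
#' @export
evaluate_chromosome <- function(chrom, data, fs = mep_function_set()) {
  ds <- as_labeled_dataset(data)
  n <- nrow(ds$features)
  L <- length(chrom$genes)
  raw <- matrix(0, L, n)
  for (i in seq_len(L)) {
    g <- chrom$genes[[i]]
    row <- switch(g$type,
      feature = {
        if (g$index > ncol(ds$features))
          stop_momep("chromosome references a feature beyond `m`",
                     "momep_chromosome_error")
        ds$features[, g$index]
      },
      const = rep(g$value, n),
      op = fs$funs[[g$symbol]](raw[g$args[1], ], raw[g$args[2], ]))
    raw[i, ] <- pmin(pmax(row, -MEP_CLAMP), MEP_CLAMP)
  }
  structure(list(raw = raw, scores = sigmoid(raw)), class = "mep_gene_outputs")
}

#' One-point crossover
#'
#' Exchanges the gene tails of two equal-length parents at a random cut.
#' Because operand references are positional and always point backwards,
#' offspring are valid by construction.
#'
#' @param parent_a,parent_b `mep_chromosome`s of equal length.
#' @param seed Optional integer seed.
#' @return List of two offspring chromosomes.
#' @export
crossover <- function(parent_a, parent_b, seed = NULL) {
  La <- length(parent_a$genes); Lb <- length(parent_b$genes)
  if (La != Lb) stop_momep("parents must have equal length", "momep_input_error")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cut <- sample(0:(La - 1L), 1)
  head_a <- parent_a$genes[seq_len(cut)]
  head_b <- parent_b$genes[seq_len(cut)]
  tail_a <- parent_a$genes[setdiff(seq_len(La), seq_len(cut))]
  tail_b <- parent_b$genes[setdiff(seq_len(Lb), seq_len(cut))]
  list(new_chromosome(c(head_a, tail_b), parent_a$m),
       new_chromosome(c(head_b, tail_a), parent_b$m))
}

#' Per-gene mutation
#'
#' Each gene is independently resampled with probability `per_gene_prob`;
#' resampled operator genes choose operands only among earlier positions,
#' so mutation preserves validity.
#'
#' @param chrom An `mep_chromosome`.
#' @param per_gene_prob Per-gene resampling probability in `[0, 1]`.
#' @param fs An [mep_function_set()].
#' @param constant_range,terminal_prob,const_prob As in
#'   [random_chromosome()].
#' @param seed Optional integer seed.
#' @return The mutated `mep_chromosome`.
#' @export
mutate_chromosome <- function(chrom, per_gene_prob = 0.05,
                              fs = mep_function_set(),
                              constant_range = c(-1, 1),
                              terminal_prob = 0.3, const_prob = 0.2,
                              seed = NULL) {
  stopifnot(per_gene_prob >= 0, per_gene_prob <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  genes <- chrom$genes
  hit <- runif(length(genes)) < per_gene_prob
  for (i in which(hit)) {
    genes[[i]] <- random_gene(i, chrom$m, fs, constant_range,
                              terminal_prob, const_prob)
  }
  new_chromosome(genes, chrom$m)
}
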