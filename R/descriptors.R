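#' Statistical moments of a grayscale image
#'
#' The six-component intensity descriptor used as the smallest classifier
#' input: mean, standard deviation, skewness, kurtosis, minimum and maximum
#' of the pixel intensities. Moments are population moments (divide by the
#' pixel count); kurtosis is excess kurtosis, so a Gaussian intensity field
#' gives 0. Zero-variance images return skewness 0 and kurtosis 0 by
#' convention.
#'
#' @param image Numeric matrix of intensities in `[0, 255]`.
#' @return Named numeric vector
#'   `(mean, sd, skewness, kurtosis, min, max)`.
#' @examples
#' compute_moments(matrix(c(0, 0, 0, 255), 2, 2))
#' @export
compute_moments <- function(image) {
  if (!is.matrix(image) || length(image) == 0)
    stop_momep("`image` must be a non-empty matrix", "momep_input_error")
  px <- as.numeric(image)
  mu <- mean(px)
  v <- mean((px - mu)^2)
  s <- sqrt(v)
  if (v > 0) {
    skew <- mean((px - mu)^3) / s^3
    kurt <- mean((px - mu)^4) / v^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean = mu, sd = s, skewness = skew, kurtosis = kurt,
    min = min(px), max = max(px))
}

#' HOG parameter set
#'
#' Parameters of the histogram-of-oriented-gradients descriptor. The
#' full-scale mammogram parameterisation (720 x 1152 window, 16 x 16 block,
#' 8 x 8 cell, 2 x 2 stride, 8 bins) is available by passing those values;
#' the default window is 64 x 64, a size at which the descriptor remains
#' informative while staying cheap to compute.
#'
#' @param window,block,cell,block_stride `(height, width)` integer pairs in
#'   pixels; `block` must be divisible by `cell` and `window` by
#'   `block_stride`.
#' @param n_bins Number of unsigned orientation bins over `[0, pi)`.
#' @param norm Block normalization, `"L2"` or `"L1"`.
#' @param gamma Apply square-root gamma normalization to intensities first.
#' @return An object of class `hog_params`.
#' @export
hog_params <- function(window = c(64, 64), block = c(16, 16), cell = c(8, 8),
                       block_stride = c(8, 8), n_bins = 8,
                       norm = c("L2", "L1"), gamma = TRUE) {
  norm <- match.arg(norm)
  window <- as.integer(window); block <- as.integer(block)
  cell <- as.integer(cell); block_stride <- as.integer(block_stride)
  if (any(block %% cell != 0))
    stop_momep("`block` must be divisible by `cell`", "momep_config_error")
  if (any(window %% block_stride != 0))
    stop_momep("`window` must be divisible by `block_stride`", "momep_config_error")
  if (n_bins < 2) stop_momep("`n_bins` must be >= 2", "momep_config_error")
  if (any(window < block))
    stop_momep("`window` must be at least one block", "momep_config_error")
  structure(list(window = window, block = block, cell = cell,
                 block_stride = block_stride, n_bins = as.integer(n_bins),
                 norm = norm, gamma = gamma),
            class = "hog_params")
}

#' Descriptor length implied by a HOG parameterisation
#'
#' Closed form: blocks per window (per block stride) x cells per block x
#' orientation bins.
#'
#' @param params An [hog_params()] object.
#' @return Integer descriptor length.
#' @export
hog_length <- function(params) {
  nb <- (params$window - params$block) %/% params$block_stride + 1L
  cells <- prod(params$block %/% params$cell)
  as.integer(prod(nb) * cells * params$n_bins)
}

# central-difference gradients with replicated borders
image_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  right <- img[, pmin(seq_len(w) + 1L, w), drop = FALSE]
  left <- img[, pmax(seq_len(w) - 1L, 1L), drop = FALSE]
  down <- img[pmin(seq_len(h) + 1L, h), , drop = FALSE]
  up <- img[pmax(seq_len(h) - 1L, 1L), , drop = FALSE]
  list(gx = right - left, gy = down - up)
}

#' Histogram of oriented gradients
#'
#' Pipeline: optional square-root gamma normalization, `[-1, 0, 1]`
#' central-difference gradients (replicated borders), gradient magnitude and
#' unsigned orientation in `[0, pi)`, per-cell `n_bins`-bin histograms with
#' linear interpolation between adjacent bin centres (centres at
#' `k * pi / n_bins`, wrap-around), per-block concatenation normalized by
#' the configured norm with an additive stabilizer, concatenation over all
#' block-stride positions. Images that do not match the window are resized
#' to it (bilinear).
#'
#' @param image Numeric intensity matrix.
#' @param params An [hog_params()] object.
#' @return Numeric descriptor vector of length [hog_length()].
#' @examples
#' img <- matrix(runif(64 * 64, 0, 255), 64, 64)
#' length(compute_hog(img, hog_params()))
#' @export
compute_hog <- function(image, params = hog_params()) {
  stopifnot(inherits(params, "hog_params"))
  wh <- params$window[1]; ww <- params$window[2]
  if (nrow(image) != wh || ncol(image) != ww) {
    image <- matrix(EBImage::imageData(
      EBImage::resize(EBImage::Image(image), w = wh, h = ww)), wh, ww)
  }
  if (params$gamma) image <- sqrt(pmax(image, 0))

  g <- image_gradients(image)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ori <- atan2(g$gy, g$gx) %% pi  # unsigned orientation in [0, pi)

  nb <- params$n_bins
  bin_w <- pi / nb
  pos <- ori / bin_w              # continuous bin position, centres at integers
  lo <- floor(pos)
  w_hi <- pos - lo
  lo <- matrix((as.integer(lo) %% nb) + 1L, nrow(pos), ncol(pos))
  hi <- (lo %% nb) + 1L

  cell_hist <- function(rows, cols) {
    m <- as.vector(mag[rows, cols])
    h1 <- as.vector(tapply(m * (1 - as.vector(w_hi[rows, cols])),
                           factor(as.vector(lo[rows, cols]), levels = 1:nb), sum))
    h2 <- as.vector(tapply(m * as.vector(w_hi[rows, cols]),
                           factor(as.vector(hi[rows, cols]), levels = 1:nb), sum))
    h1[is.na(h1)] <- 0; h2[is.na(h2)] <- 0
    h1 + h2
  }

  eps <- 1e-6
  bh <- params$block[1]; bw <- params$block[2]
  ch <- params$cell[1]; cw <- params$cell[2]
  ys <- seq(1L, wh - bh + 1L, by = params$block_stride[1])
  xs <- seq(1L, ww - bw + 1L, by = params$block_stride[2])
  out <- vector("list", length(ys) * length(xs))
  k <- 0L
  for (y0 in ys) {
    for (x0 in xs) {
      block <- numeric(0)
      for (cy in seq(0L, bh - ch, by = ch)) {
        for (cx in seq(0L, bw - cw, by = cw)) {
          block <- c(block, cell_hist(y0 + cy + seq_len(ch) - 1L,
                                      x0 + cx + seq_len(cw) - 1L))
        }
      }
      block <- if (params$norm == "L2") {
        block / sqrt(sum(block^2) + eps^2)
      } else {
        block / (sum(abs(block)) + eps)
      }
      k <- k + 1L
      out[[k]] <- block
    }
  }
  unlist(out, use.names = FALSE)
}

#' Extract a feature table from an image set
#'
#' Applies one descriptor to every image of a set and returns the tidy
#' feature table (`f1..fm` plus `label`) consumed by the training and
#' complexity functions.
#'
#' @param x A `momep_image_set`.
#' @param descriptor `"moments"`, `"hog"` or `"kd"`.
#' @param params Descriptor parameters ([hog_params()] or [kd_params()]);
#'   ignored for moments.
#' @param basis A fitted [kd_fit()] basis, required for `"kd"`.
#' @return A tibble with one row per image.
#' @export
extract_features <- function(x, descriptor = c("moments", "hog", "kd"),
                             params = NULL, basis = NULL) {
  stopifnot(inherits(x, "momep_image_set"))
  descriptor <- match.arg(descriptor)
  rows <- switch(descriptor,
    moments = lapply(x$images, compute_moments),
    hog = {
      if (is.null(params)) params <- hog_params()
      lapply(x$images, compute_hog, params = params)
    },
    kd = {
      if (is.null(basis)) stop_momep("`basis` is required for kernel descriptors",
                                     "momep_state_error")
      lapply(x$images, compute_kdes, basis = basis)
    })
  feat <- do.call(rbind, rows)
  colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  dplyr::mutate(tibble::as_tibble(feat), label = x$labels)
}
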