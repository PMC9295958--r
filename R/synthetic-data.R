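#' Simulate a labeled feature table
#'
#' Draws `n` instances from two spherical multivariate Gaussians that differ
#' by `class_mean_shift`, the stand-in used throughout the package for a
#' descriptor table extracted from real mammograms. The positive class is
#' shifted by `class_mean_shift`; both classes share the standard deviation
#' `class_sd`. Labels follow the -1/+1 on-disk convention (-1 healthy,
#' +1 pathological).
#'
#' @param n Number of instances (rows).
#' @param m Number of features (columns `f1..fm`).
#' @param class_mean_shift Numeric vector of length `m` (or a scalar,
#'   recycled) giving the positive-class mean shift per feature.
#' @param class_sd Common within-class standard deviation, `> 0`.
#' @param positive_fraction Fraction of positive instances in `(0, 1)`;
#'   the positive count is exactly `round(n * positive_fraction)`.
#' @param seed Integer seed; equal seeds give identical tables.
#'
#' @return A tibble with columns `f1..fm` and `label` (integer -1/+1).
#'
#' @examples
#' sim_features(n = 10, m = 3, class_mean_shift = c(2, 0, 0), seed = 1)
#' @export
sim_features <- function(n, m, class_mean_shift = 0, class_sd = 1,
                         positive_fraction = 0.5, seed = 1) {
  if (m <= 0) stop_momep("`m` must be a positive feature count", "momep_config_error")
  if (n < 2) stop_momep("`n` must be at least 2", "momep_config_error")
  if (class_sd <= 0) stop_momep("`class_sd` must be > 0", "momep_config_error")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop_momep("`positive_fraction` must lie strictly in (0, 1)", "momep_config_error")
  if (length(class_mean_shift) == 1) class_mean_shift <- rep(class_mean_shift, m)
  if (length(class_mean_shift) != m)
    stop_momep("`class_mean_shift` must have length `m`", "momep_config_error")

  set.seed(as.integer(seed))
  n_pos <- round(n * positive_fraction)
  labels <- rep(-1L, n)
  labels[sample.int(n, n_pos)] <- 1L
  x <- matrix(rnorm(n * m, sd = class_sd), nrow = n, ncol = m)
  x[labels == 1L, ] <- sweep(x[labels == 1L, , drop = FALSE], 2, class_mean_shift, "+")
  colnames(x) <- paste0("f", seq_len(m))
  dplyr::mutate(tibble::as_tibble(x), label = labels)
}

#' Simulate a labeled grayscale image set
#'
#' Generates seeded synthetic 8-bit grayscale images: a Gaussian-noise
#' background (optionally smoothed to give the noise a spatial grain) to
#' which, for positive images only, a Gaussian-blurred disc of shifted
#' intensity is added at a random position. The additive blurred disc is
#' deliberately the simplest lesion model that leaves a signature in
#' statistical moments, gradient histograms and kernel descriptors alike.
#'
#' @param n_images Number of images, at least 2.
#' @param image_height,image_width Image size in pixels.
#' @param positive_fraction Fraction of positive (lesion-bearing) images in
#'   `(0, 1)`; exactly `round(n_images * positive_fraction)` are positive.
#' @param background_mean,background_sd Background intensity mean and
#'   standard deviation on the 0-255 scale.
#' @param lesion_intensity_shift Peak additive intensity of the lesion disc;
#'   `0` makes positives statistically identical to negatives.
#' @param lesion_radius Disc radius in pixels; must be smaller than half the
#'   smaller image dimension.
#' @param texture_grain Smoothing scale (Gaussian sigma, pixels) applied to
#'   the background noise; `0` leaves white noise.
#' @param seed Integer seed. Each image draws from its own sub-stream so the
#'   set is reproducible image-by-image.
#'
#' @return An object of class `momep_image_set`: a list with `images` (list
#'   of height x width matrices, intensities in `[0, 255]`) and `labels`
#'   (integer -1/+1 vector).
#'
#' @examples
#' imgs <- sim_images(n_images = 4, image_height = 32, image_width = 32,
#'                    lesion_radius = 6, seed = 7)
#' length(imgs$images)
#' @export
sim_images <- function(n_images, image_height = 128, image_width = 128,
                       positive_fraction = 0.5, background_mean = 100,
                       background_sd = 10, lesion_intensity_shift = 40,
                       lesion_radius = 16, texture_grain = 0, seed = 1) {
  if (n_images < 2) stop_momep("`n_images` must be at least 2", "momep_config_error")
  if (image_height < 1 || image_width < 1)
    stop_momep("image dimensions must be positive", "momep_config_error")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop_momep("`positive_fraction` must lie strictly in (0, 1)", "momep_config_error")
  if (lesion_radius >= min(image_height, image_width) / 2)
    stop_momep("`lesion_radius` must be < min(height, width) / 2", "momep_config_error")

  set.seed(as.integer(seed))
  n_pos <- round(n_images * positive_fraction)
  labels <- rep(-1L, n_images)
  labels[sample.int(n_images, n_pos)] <- 1L

  images <- lapply(seq_len(n_images), function(i) {
    set.seed(child_seed(seed, i))
    img <- matrix(rnorm(image_height * image_width, background_mean, background_sd),
                  nrow = image_height, ncol = image_width)
    if (texture_grain > 0) img <- gaussian_blur(img, texture_grain)
    if (labels[i] == 1L && lesion_intensity_shift != 0) {
      r <- lesion_radius
      cy <- runif(1, r + 1, image_height - r)
      cx <- runif(1, r + 1, image_width - r)
      d2 <- outer(seq_len(image_height), seq_len(image_width),
                  function(y, x) (y - cy)^2 + (x - cx)^2)
      disc <- (d2 <= r^2) * 1
      disc <- gaussian_blur(disc, max(r / 4, 0.5))
      img <- img + lesion_intensity_shift * disc
    }
    pmin(pmax(img, 0), 255)
  })

  structure(list(images = images, labels = labels,
                 height = image_height, width = image_width),
            class = "momep_image_set")
}

#' @export
print.momep_image_set <- function(x, ...) {
  cat(sprintf("<momep_image_set> %d images (%d x %d), %d positive / %d negative\n",
              length(x$images), x$height, x$width,
              sum(x$labels == 1L), sum(x$labels == -1L)))
  invisible(x)
}

# Gaussian blur on a plain matrix; EBImage does the filtering, we keep the
# matrix container. sigma <= 0 is the identity.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  out <- EBImage::gblur(EBImage::Image(mat), sigma = sigma)
  matrix(EBImage::imageData(out), nrow = nrow(mat), ncol = ncol(mat))
}

#' Write / read a feature table as CSV
#'
#' Feature tables travel as plain CSV with the header `f1..fm,label` and
#' labels -1/+1, the on-disk convention used by every front-end in the
#' package.
#'
#' @param data Tibble with feature columns and a `label` column.
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(data, path) {
  stopifnot("label" %in% names(data))
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  if (!"label" %in% names(out))
    stop_momep("feature table must contain a `label` column", "momep_input_error")
  out$label <- as.integer(out$label)
  out
}

#' Write an image set as 8-bit PNG files plus a label CSV
#'
#' @param x A `momep_image_set`.
#' @param dir Output directory (created if missing). Images become
#'   `img_0001.png`, ... and labels `labels.csv` (columns `file,label`).
#' @return The directory, invisibly.
#' @export
write_image_set <- function(x, dir) {
  stopifnot(inherits(x, "momep_image_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("img_%04d.png", seq_along(x$images))
  for (i in seq_along(x$images)) {
    png::writePNG(x$images[[i]] / 255, file.path(dir, files[i]))
  }
  write.csv(data.frame(file = files, label = x$labels),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(dir) {
  lab <- read.csv(file.path(dir, "labels.csv"))
  images <- lapply(lab$file, function(f) {
    px <- png::readPNG(file.path(dir, f))
    if (length(dim(px)) == 3) px <- px[, , 1]
    px * 255
  })
  structure(list(images = images, labels = as.integer(lab$label),
                 height = nrow(images[[1]]), width = ncol(images[[1]])),
            class = "momep_image_set")
}

#' Run a generator from a YAML configuration file
#'
#' Keys of the YAML file match the argument names of [sim_features()] or
#' [sim_images()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @param kind `"features"` or `"images"`.
#' @return The generated feature tibble or `momep_image_set`.
#' @export
sim_from_config <- function(path, kind = c("features", "images")) {
  kind <- match.arg(kind)
  # keep 1.1-style boolean scalars (y/n/yes/no) as literal strings so that
  # the field name `n` survives as a key
  keep <- function(x) x
  cfg <- yaml::read_yaml(path, handlers = list("bool#no" = keep, "bool#yes" = keep))
  fun <- if (kind == "features") sim_features else sim_images
  bad <- setdiff(names(cfg), names(formals(fun)))
  if (length(bad))
    stop_momep(paste0("unknown configuration keys: ", paste(bad, collapse = ", ")),
               "momep_config_error")
  do.call(fun, cfg)
}
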