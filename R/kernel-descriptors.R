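#' Gradient kernel-descriptor parameters
#'
#' Parameters of the single-level gradient match-kernel descriptor. A patch
#' is summarised by its per-pixel gradients; the similarity of two patches
#' is a match kernel — a sum over pixel pairs of the product of the
#' normalized gradient magnitudes with Gaussian kernels over gradient
#' orientation (as unit vectors) and normalized pixel position. Patch
#' embeddings against a sampled basis (a Nystroem-style finite-dimensional
#' approximation) are averaged over a grid of patches and compacted by
#' kernel PCA to `kdesdim` components.
#'
#' Defaults follow the published mammogram configuration where one is
#' stated: `kdesdim = 200`, `contrast = 0.8`, `grid_size = 8`,
#' `patch_size = 16`. The basis size and kernel bandwidths are free
#' parameters of this construction.
#'
#' @param kdesdim Output dimensionality; must not exceed `basis_size`.
#' @param contrast Gradient-normalization constant: magnitudes are divided
#'   by `sqrt(mean(m^2) + contrast^2)` within each patch.
#' @param grid_size Lattice step (pixels) between patch origins.
#' @param patch_size Patch side (pixels); must exceed `grid_size`.
#' @param basis_size Number of basis patches sampled when fitting.
#' @param kernel_bandwidths Named pair `c(orientation =, position =)` of
#'   Gaussian bandwidths (standard deviations).
#' @return An object of class `kd_params`.
#' @export
kd_params <- function(kdesdim = 200, contrast = 0.8, grid_size = 8,
                      patch_size = 16, basis_size = 300,
                      kernel_bandwidths = c(orientation = 0.5, position = 0.3)) {
  if (kdesdim > basis_size)
    stop_momep("`kdesdim` must not exceed `basis_size`", "momep_config_error")
  if (patch_size <= grid_size)
    stop_momep("`patch_size` must exceed `grid_size`", "momep_config_error")
  if (any(kernel_bandwidths <= 0))
    stop_momep("kernel bandwidths must be positive", "momep_config_error")
  structure(list(kdesdim = as.integer(kdesdim), contrast = contrast,
                 grid_size = as.integer(grid_size),
                 patch_size = as.integer(patch_size),
                 basis_size = as.integer(basis_size),
                 kernel_bandwidths = kernel_bandwidths),
            class = "kd_params")
}

# per-patch gradient features: normalized magnitude weights, orientation
# unit vectors and positions scaled to [0, 1]^2
kd_patch_features <- function(patch, params) {
  g <- image_gradients(patch)
  m <- sqrt(as.vector(g$gx)^2 + as.vector(g$gy)^2)
  mw <- m / sqrt(mean(m^2) + params$contrast^2)
  theta <- atan2(as.vector(g$gy), as.vector(g$gx))
  n <- nrow(patch)
  idx <- expand.grid(row = seq_len(nrow(patch)), col = seq_len(ncol(patch)))
  list(mw = mw,
       ov = cbind(cos(theta), sin(theta)),
       z = cbind((idx$row - 1) / max(nrow(patch) - 1, 1),
                 (idx$col - 1) / max(ncol(patch) - 1, 1)))
}

sqdist <- function(a, b) {
  # pairwise squared Euclidean distances between rows of a and b
  d <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

#' Gradient match kernel between two patches
#'
#' @param patch_a,patch_b Intensity matrices of equal size.
#' @param params A [kd_params()] object.
#' @return Scalar kernel value (non-negative).
#' @export
kd_match_kernel <- function(patch_a, patch_b, params = kd_params()) {
  fa <- kd_patch_features(patch_a, params)
  fb <- kd_patch_features(patch_b, params)
  kd_match_kernel_feats(fa, fb, params)
}

kd_match_kernel_feats <- function(fa, fb, params) {
  so <- params$kernel_bandwidths[["orientation"]]
  sp <- params$kernel_bandwidths[["position"]]
  ko <- exp(-sqdist(fa$ov, fb$ov) / (2 * so^2))
  kp <- exp(-sqdist(fa$z, fb$z) / (2 * sp^2))
  sum((fa$mw %o% fb$mw) * ko * kp)
}

#' Fit a kernel-descriptor basis on a training image set
#'
#' Samples `basis_size` patches uniformly at random (seeded) from the
#' training images, embeds each patch against the basis through the match
#' kernel, and fits the kernel-PCA compaction (centering + eigenvectors of
#' the embedding covariance) used by [compute_kdes()].
#'
#' @param x A `momep_image_set` of training images.
#' @param params A [kd_params()] object.
#' @param seed Integer seed for the patch sample.
#' @return An object of class `momep_kd_basis`.
#' @export
kd_fit <- function(x, params = kd_params(), seed = 1) {
  stopifnot(inherits(x, "momep_image_set"))
  ps <- params$patch_size
  if (x$height < ps || x$width < ps)
    stop_momep("images are smaller than `patch_size`", "momep_config_error")
  set.seed(as.integer(seed))
  patches <- lapply(seq_len(params$basis_size), function(i) {
    img <- x$images[[sample.int(length(x$images), 1)]]
    y0 <- sample.int(nrow(img) - ps + 1L, 1)
    x0 <- sample.int(ncol(img) - ps + 1L, 1)
    img[y0 + seq_len(ps) - 1L, x0 + seq_len(ps) - 1L]
  })
  feats <- lapply(patches, kd_patch_features, params = params)
  emb <- kd_embed(feats, feats, params)
  center <- colMeans(emb)
  ec <- eigen(stats::cov(emb), symmetric = TRUE)
  structure(list(params = params, patch_features = feats,
                 center = center, rotation = ec$vectors,
                 eigenvalues = ec$values),
            class = "momep_kd_basis")
}

# rows: patch feature list to embed; cols: basis patch features
kd_embed <- function(feats, basis_feats, params) {
  out <- matrix(0, length(feats), length(basis_feats))
  for (i in seq_along(feats)) {
    for (j in seq_along(basis_feats)) {
      out[i, j] <- kd_match_kernel_feats(feats[[i]], basis_feats[[j]], params)
    }
  }
  out
}

#' Kernel descriptor of an image
#'
#' Embeds every patch on the `grid_size` lattice against the fitted basis,
#' averages the patch embeddings and projects the centred average onto the
#' leading `kdesdim` kernel-PCA components of the basis fit.
#'
#' @param image Numeric intensity matrix, at least one patch large.
#' @param basis A fitted [kd_fit()] object.
#' @return Numeric vector of length `kdesdim`.
#' @export
compute_kdes <- function(image, basis) {
  if (!inherits(basis, "momep_kd_basis") || is.null(basis$rotation))
    stop_momep("`basis` must be a fitted `momep_kd_basis`", "momep_state_error")
  params <- basis$params
  ps <- params$patch_size
  if (nrow(image) < ps || ncol(image) < ps)
    stop_momep("image is smaller than `patch_size`", "momep_input_error")
  ys <- seq(1L, nrow(image) - ps + 1L, by = params$grid_size)
  xs <- seq(1L, ncol(image) - ps + 1L, by = params$grid_size)
  feats <- list()
  for (y0 in ys) for (x0 in xs) {
    feats[[length(feats) + 1L]] <-
      kd_patch_features(image[y0 + seq_len(ps) - 1L, x0 + seq_len(ps) - 1L], params)
  }
  emb <- kd_embed(feats, basis$patch_features, params)
  avg <- colMeans(emb)
  as.numeric((avg - basis$center) %*% basis$rotation[, seq_len(params$kdesdim), drop = FALSE])
}
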