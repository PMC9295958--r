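test_that("moments match their definitions on known and random images", {
  expect_equal(compute_moments(matrix(5, 3, 3)),
               c(mean = 5, sd = 0, skewness = 0, kurtosis = 0, min = 5, max = 5))
  two <- compute_moments(matrix(c(0, 1), 1, 2))
  expect_equal(unname(two[c("mean", "sd", "skewness", "min", "max")]),
               c(0.5, 0.5, 0, 0, 1))

  set.seed(31)
  for (i in 1:50) {
    img <- matrix(runif(64, 0, 255), 8, 8)
    expect_equal(compute_moments(img), oracle_moments(img), tolerance = 1e-12)
  }
  expect_equal(compute_moments(matrix(c(0, 0, 0, 255), 2, 2))[["mean"]], 63.75)
})

test_that("moments are permutation invariant and internally ordered", {
  set.seed(5)
  img <- matrix(runif(100, 0, 255), 10, 10)
  shuf <- matrix(sample(as.numeric(img)), 10, 10)
  expect_equal(compute_moments(img), compute_moments(shuf))
  m <- compute_moments(img)
  expect_true(m["min"] <= m["mean"] && m["mean"] <= m["max"])
  expect_gte(m[["sd"]], 0)
  expect_error(compute_moments(matrix(numeric(0), 0, 0)), class = "momep_input_error")
})

test_that("HOG length follows the closed form for several parameterisations", {
  expect_equal(hog_length(hog_params(window = c(64, 64), block = c(16, 16),
                                     cell = c(8, 8), block_stride = c(8, 8),
                                     n_bins = 8)), 7 * 7 * 4 * 8)
  expect_equal(hog_length(hog_params(window = c(32, 32), block = c(16, 16),
                                     cell = c(8, 8), block_stride = c(16, 16),
                                     n_bins = 9)), 2 * 2 * 4 * 9)
  expect_equal(hog_length(hog_params(window = c(48, 24), block = c(8, 8),
                                     cell = c(4, 4), block_stride = c(8, 8),
                                     n_bins = 6)), 6 * 3 * 4 * 6)
  p <- hog_params(window = c(64, 64))
  img <- matrix(runif(64^2, 0, 255), 64, 64)
  expect_length(compute_hog(img, p), hog_length(p))
})

test_that("uniform images give the zero descriptor; step edges one bin per cell", {
  p <- hog_params(window = c(32, 32), block = c(16, 16), cell = c(8, 8),
                  block_stride = c(16, 16), n_bins = 8)
  expect_equal(compute_hog(matrix(77, 32, 32), p), rep(0, hog_length(p)))

  # vertical step edge: gradient is horizontal, analytic orientation 0
  step <- cbind(matrix(0, 32, 16), matrix(255, 32, 16))
  desc <- compute_hog(step, hog_params(window = c(32, 32), block = c(16, 16),
                                       cell = c(8, 8), block_stride = c(16, 16),
                                       n_bins = 8, gamma = FALSE))
  bins <- matrix(desc, nrow = 8)  # columns = cells, rows = orientation bins
  nonzero_cells <- which(colSums(bins) > 0)
  expect_gt(length(nonzero_cells), 0)
  for (cell in nonzero_cells) {
    expect_equal(which(bins[, cell] > 0), 1)  # all mass in the bin of orientation 0
  }
})

test_that("HOG gradient stage ignores constant intensity offsets", {
  set.seed(8)
  img <- matrix(sample(0:200, 32 * 32, replace = TRUE), 32, 32)
  p <- hog_params(window = c(32, 32), block = c(16, 16), cell = c(8, 8),
                  block_stride = c(16, 16), n_bins = 8, gamma = FALSE)
  expect_equal(compute_hog(img, p), compute_hog(img + 40, p))
})

test_that("L2-normalized blocks have norm at most 1", {
  set.seed(12)
  img <- matrix(runif(64^2, 0, 255), 64, 64)
  p <- hog_params()
  desc <- compute_hog(img, p)
  block_len <- prod(p$block %/% p$cell) * p$n_bins
  blocks <- matrix(desc, nrow = block_len)
  norms <- sqrt(colSums(blocks^2))
  expect_true(all(norms <= 1 + 1e-9))
})

test_that("the gradient match kernel is symmetric, PSD and maximal on the diagonal", {
  params <- kd_params(kdesdim = 5, grid_size = 4, patch_size = 8, basis_size = 5)
  set.seed(14)
  patches <- lapply(1:10, function(i) matrix(runif(64, 0, 255), 8, 8))
  gram <- matrix(0, 10, 10)
  for (i in 1:10) for (j in i:10) {
    gram[i, j] <- gram[j, i] <- kd_match_kernel(patches[[i]], patches[[j]], params)
  }
  expect_equal(gram, t(gram))
  expect_true(all(eigen(gram, symmetric = TRUE, only.values = TRUE)$values >= -1e-8))
  # kernel Cauchy-Schwarz: k(a,b) <= sqrt(k(a,a) k(b,b))
  for (i in 1:10) for (j in 1:10) {
    expect_lte(gram[i, j], sqrt(gram[i, i] * gram[j, j]) + 1e-9)
  }
})

test_that("full-rank KPCA is an isometry of the basis embedding", {
  imgs <- sim_images(n_images = 4, image_height = 24, image_width = 24,
                     lesion_radius = 4, seed = 3)
  params <- kd_params(kdesdim = 5, grid_size = 4, patch_size = 8, basis_size = 5)
  basis <- kd_fit(imgs, params, seed = 2)
  desc <- lapply(imgs$images, compute_kdes, basis = basis)
  expect_true(all(vapply(desc, length, integer(1)) == 5))
  # deterministic given (image, basis)
  expect_identical(desc[[1]], compute_kdes(imgs$images[[1]], basis))

  # with kdesdim == basis_size the projection matrix is orthogonal, so the
  # descriptor is an isometry of the centred average-patch embedding
  expect_equal(crossprod(basis$rotation), diag(5), tolerance = 1e-8)
  raw <- do.call(rbind, lapply(imgs$images, function(im) {
    feats <- momep:::kd_patch_features  # embed one image without the PCA step
    ps <- params$patch_size
    ys <- seq(1, nrow(im) - ps + 1, by = params$grid_size)
    xs <- seq(1, ncol(im) - ps + 1, by = params$grid_size)
    fl <- list()
    for (y0 in ys) for (x0 in xs) {
      fl[[length(fl) + 1]] <- feats(im[y0 + seq_len(ps) - 1, x0 + seq_len(ps) - 1], params)
    }
    colMeans(momep:::kd_embed(fl, basis$patch_features, params))
  }))
  expect_equal(as.matrix(dist(raw)), as.matrix(dist(do.call(rbind, desc))),
               tolerance = 1e-8)
})

test_that("unfitted or undersized inputs are rejected", {
  params <- kd_params(kdesdim = 3, grid_size = 4, patch_size = 8, basis_size = 3)
  fake <- structure(list(rotation = NULL), class = "momep_kd_basis")
  expect_error(compute_kdes(matrix(0, 16, 16), fake), class = "momep_state_error")
  imgs <- sim_images(n_images = 3, image_height = 24, image_width = 24,
                     lesion_radius = 4, seed = 1)
  basis <- kd_fit(imgs, params, seed = 1)
  expect_error(compute_kdes(matrix(0, 4, 4), basis), class = "momep_input_error")
})

test_that("extract_features returns a tidy labeled table for each descriptor", {
  imgs <- sim_images(n_images = 6, image_height = 32, image_width = 32,
                     lesion_radius = 6, seed = 5)
  mom <- extract_features(imgs, "moments")
  expect_named(mom, c(paste0("f", 1:6), "label"))
  expect_identical(mom$label, imgs$labels)

  p <- hog_params(window = c(32, 32), block = c(16, 16), cell = c(8, 8),
                  block_stride = c(16, 16), n_bins = 4)
  hog <- extract_features(imgs, "hog", params = p)
  expect_equal(ncol(hog) - 1L, hog_length(p))

  expect_error(extract_features(imgs, "kd"), class = "momep_state_error")
})
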