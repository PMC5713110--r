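test_that("PCA matches an independent eigendecomposition and is orthonormal", {
  set.seed(6)
  X <- matrix(rnorm(6 * 4), 6, 4)
  m <- pca_fit(X, n_components = 4L)
  expect_equal(crossprod(m$loadings), diag(4), tolerance = 1e-8)
  # oracle: SVD-based prcomp
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(m$eigenvalues, unname(p$sdev^2), tolerance = 1e-8)
  expect_equal(abs(m$loadings), abs(unname(p$rotation)), tolerance = 1e-8)
  expect_true(all(diff(m$explained_variance_ratio) <= 1e-12))
  expect_true(all(m$explained_variance_ratio >= 0 &
                    m$explained_variance_ratio <= 1))
  expect_lte(sum(m$explained_variance_ratio), 1 + 1e-12)
})

test_that("PCA on collinear points concentrates variance in PC1", {
  t <- c(-2, -1, 0.5, 3)
  X <- cbind(t, 2 * t)                       # rank-1: points on a line
  m <- pca_fit(X, n_components = 2L)
  expect_equal(m$explained_variance_ratio[1L], 1, tolerance = 1e-12)
  expect_equal(m$explained_variance_ratio[2L], 0, tolerance = 1e-12)
  expect_error(pca_fit(X[1, , drop = FALSE]), "at least 2")
})

test_that("PC score images project masked pixels and background to the minimum", {
  set.seed(10)
  amp <- matrix(runif(16, -1, 1), 4, 4)
  direction <- c(1, 2, 3)
  cube <- hypercube(outer(amp, direction) + 0.5, c(500, 600, 700),
                    calibrated = TRUE)
  mask <- matrix(TRUE, 4, 4); mask[1, 1] <- FALSE
  imgs <- pc_score_images(cube, mask, n = 2L)
  expect_length(imgs, 2L)
  # rank-1 cube: PC1 scores reproduce the amplitude pattern up to affine sign
  sc <- imgs[[1]][mask]
  a <- amp[mask]
  expect_equal(abs(cor(sc, a)), 1, tolerance = 1e-8)
  expect_equal(imgs[[1]][1, 1], min(imgs[[1]]))

  # pixels equal to the training mean score zero
  flat <- hypercube(array(rep(c(0.1, 0.2, 0.3), each = 16), c(4, 4, 3)),
                    c(500, 600, 700), calibrated = TRUE)
  model <- pca_fit(matrix(rnorm(30) + rep(c(0.1, 0.2, 0.3), each = 10),
                          10, 3, byrow = FALSE), 2L)
  model$center <- c(0.1, 0.2, 0.3)
  z <- pc_score_images(flat, matrix(TRUE, 4, 4), model = model)
  expect_equal(unique(as.vector(z[[1]])), 0, tolerance = 1e-12)
})

test_that("quantization bins linearly into equal-width gray levels", {
  expect_equal(unique(as.vector(quantize(matrix(3.7, 5, 5), 8))), 0L)
  expect_equal(sort(unique(as.vector(
    quantize(matrix(c(2, 9), 2, 2), 2)))), c(0L, 1L))
  ramp <- matrix(0:255, 16, 16)
  q <- quantize(ramp, 8)
  expect_equal(as.vector(table(q)), rep(32L, 8L))
  withNA <- matrix(c(1, 2, NA, 4), 2, 2)
  expect_equal(is.na(quantize(withNA, 4)), is.na(withNA))
})

test_that("GLCM counts pixel pairs per offset, symmetric and normalized", {
  cfg2 <- glcm_config(levels = 2L)
  const <- matrix(0L, 3, 3)
  g <- glcm(const, cfg2, angle = 0)
  expect_equal(g$p, matrix(c(1, 0, 0, 0), 2, 2))

  checker <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  gc <- glcm(checker, cfg2, angle = 0)
  expect_equal(gc$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # unnormalized counts conserve the number of valid pairs
  cfgu <- glcm_config(levels = 4L, symmetric = FALSE, normalize = FALSE)
  set.seed(3)
  img <- matrix(sample(0:3, 30, TRUE), 5, 6)
  for (a in c(0, 45, 90, 135)) {
    gu <- glcm(img, cfgu, angle = a)
    npairs <- switch(as.character(a), "0" = 5 * 5, "45" = 4 * 5,
                     "90" = 4 * 6, "135" = 4 * 5)
    expect_equal(sum(gu$p), npairs)
  }
  expect_error(glcm(matrix(0L, 1, 1), cfg2, angle = 0), "smaller than")
  expect_error(glcm(matrix(5L, 3, 3), cfg2), "0..levels-1")
})

test_that("GLCM equals the pair-counting double-loop oracle at all angles", {
  set.seed(14)
  for (rep in 1:3) {
    img <- matrix(sample(0:5, 36, TRUE), 6, 6)
    img[sample(36, 4)] <- NA                  # off-ROI pixels excluded
    for (a in c(0, 45, 90, 135)) {
      cfg <- glcm_config(levels = 6L, distance = 1L)
      expect_equal(glcm(img, cfg, angle = a)$p,
                   oracle_glcm(img, 6L, 1L, a),
                   tolerance = 1e-12)
    }
  }
})

test_that("descriptors follow their closed forms on degenerate and uniform GLCMs", {
  d <- glcm_descriptors(glcm(matrix(0L, 4, 4), glcm_config(levels = 4L)))
  expect_equal(d[["contrast"]], 0)
  expect_equal(d[["dissimilarity"]], 0)
  expect_equal(d[["variance"]], 0)
  expect_equal(d[["homogeneity"]], 1)
  expect_equal(d[["entropy"]], 0)
  expect_equal(d[["second_moment"]], 1)
  expect_equal(d[["correlation"]], 1)  # perfectly predictable pairs

  L <- 4L
  u <- glcm_descriptors(matrix(1 / L^2, L, L))
  expect_equal(u[["entropy"]], log(L^2))
  expect_equal(u[["second_moment"]], 1 / L^2)

  chk <- glcm_descriptors(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(chk[["contrast"]], 1)
  expect_equal(chk[["dissimilarity"]], 1)
  expect_equal(chk[["homogeneity"]], 0.5)
  expect_equal(chk[["mean"]], 0.5)
  expect_equal(chk[["correlation"]], -1)

  expect_error(glcm_descriptors(matrix(1, 2, 2)), "normalized")
  expect_equal(glcm_descriptors(matrix(1 / 16, 4, 4),
                                entropy_base = "log2")[["entropy"]],
               log2(16))
})

test_that("descriptors are invariant to image transposition (symmetric mode)", {
  # reflection across the main diagonal swaps the horizontal and vertical
  # offsets (0 <-> 90); each diagonal offset maps to its own reverse, which
  # symmetric counting already includes, so 45 and 135 are individually fixed
  set.seed(21)
  img <- matrix(sample(0:7, 48, TRUE), 6, 8)
  cfg <- glcm_config(levels = 8L)
  for (pair in list(c(0, 90), c(90, 0), c(45, 45), c(135, 135))) {
    a <- glcm_descriptors(glcm(img, cfg, angle = pair[1]))
    b <- glcm_descriptors(glcm(t(img), cfg, angle = pair[2]))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("texture_vector yields 16 deterministic, texture-sensitive features", {
  cfg <- tiny_scene_config()
  lc <- generate_scene(4, cfg, seed = 13)
  cal <- calibrate_cube(lc$cube, lc$white, lc$dark)
  tv <- texture_vector(cal, lc$roi_mask)
  expect_length(tv, 16L)
  expect_equal(names(tv)[1:2], c("mean_pc1", "variance_pc1"))
  expect_equal(names(tv)[9], "mean_pc2")
  expect_identical(tv, texture_vector(cal, lc$roi_mask))
  expect_true(tv[["homogeneity_pc1"]] > 0 && tv[["homogeneity_pc1"]] <= 1)
  expect_true(tv[["second_moment_pc1"]] > 0 && tv[["second_moment_pc1"]] <= 1)
  expect_gte(tv[["contrast_pc1"]], 0)
  expect_true(abs(tv[["correlation_pc1"]]) <= 1)
})

test_that("texture regression reports a consistent R/R^2 pair", {
  set.seed(30)
  F <- matrix(rnorm(40 * 16), 40, 16)
  y <- round(3 + 0.5 * F[, 1] * 0)           # constant labels edge: skip
  y <- sample(0:5, 40, TRUE)
  r <- texture_di_regression(F, y)
  expect_equal(r$R^2, r$R2, tolerance = 1e-12)

  # labels exactly linear in one feature -> perfect fit
  y2 <- F[, 3]
  r2 <- texture_di_regression(F, y2)
  expect_equal(r2$R2, 1, tolerance = 1e-10)

  # permuted labels: R2 concentrates near the p/(N-1) chance level
  set.seed(31)
  r2s <- replicate(30, texture_di_regression(F, sample(y))$R2)
  expect_lt(mean(r2s), 3 * 16 / 39)
  expect_gt(mean(r2s), 16 / 39 / 3)
})
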