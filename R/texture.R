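#' Principal component analysis (covariance eigendecomposition)
#'
#' Mean-centered PCA by eigendecomposition of the sample covariance matrix.
#' Components are ordered by decreasing eigenvalue; each loading's sign is
#' fixed so its largest-magnitude element is positive, making score images
#' reproducible. For data of rank below `n_components`, explained-variance
#' ratios beyond the rank are 0.
#'
#' @param X Numeric `N x K` matrix (rows = observations: ROI pixels or
#'   sample spectra).
#' @param n_components Number of components to keep, `<= min(N, K)`.
#' @return Object of class `pca_model`: `loadings` (`K x C`, orthonormal
#'   columns), `explained_variance_ratio`, `eigenvalues`, `center`.
#' @export
pca_fit <- function(X, n_components = min(dim(X))) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n < 2L) stopf("PCA needs at least 2 observations")
  if (n_components < 1L || n_components > min(n, k)) {
    stopf("`n_components` must be in 1..min(N, K) = %d", min(n, k))
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  S <- crossprod(Xc) / (n - 1)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  evr <- if (total > 0) vals / total else rep(0, k)
  keep <- seq_len(n_components)
  L <- e$vectors[, keep, drop = FALSE]
  for (j in seq_len(ncol(L))) {            # deterministic sign convention
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  structure(list(loadings = L,
                 explained_variance_ratio = evr[keep],
                 eigenvalues = vals[keep],
                 center = center),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d variables; explained: %s\n",
              ncol(x$loadings), nrow(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Principal-component score images of a cube
#'
#' Projects every ROI pixel's (centered) spectrum onto the first `n` PCA
#' loadings, producing `n` gray-scale score images. Off-mask pixels are set
#' to the minimum score of the component (background). When no model is
#' supplied, PCA is fitted to the cube's own ROI pixels — the per-image
#' workflow used when each sample is analyzed independently.
#'
#' @param cube A calibrated [hypercube()].
#' @param mask Logical `lines x samples` ROI mask.
#' @param model Optional [pca_fit()] model on a matching band count.
#' @param n Number of score images (default 2: PC1 and PC2).
#' @return List of `n` numeric `lines x samples` matrices.
#' @export
pc_score_images <- function(cube, mask, model = NULL, n = 2L) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == d[1:2])) stopf("mask shape must match the cube")
  keep <- which(as.vector(mask))
  if (length(keep) == 0L) stopf("ROI mask is empty")
  px <- cube_pixels(cube)[keep, , drop = FALSE]
  if (is.null(model)) model <- pca_fit(px, n_components = n)
  if (nrow(model$loadings) != d[3L]) {
    stopf("PCA model was fitted on %d bands, cube has %d",
          nrow(model$loadings), d[3L])
  }
  if (n > ncol(model$loadings)) stopf("model holds only %d components", ncol(model$loadings))
  scores <- sweep(px, 2L, model$center) %*% model$loadings[, seq_len(n), drop = FALSE]
  lapply(seq_len(n), function(j) {
    img <- matrix(min(scores[, j]), d[1L], d[2L])
    img[keep] <- scores[, j]
    img
  })
}

#' GLCM configuration
#'
#' @param distance Pixel offset distance `D >= 1`.
#' @param angles Offset directions in degrees, subset of `{0, 45, 90, 135}`.
#'   Descriptors from [texture_vector()] are averaged over these angles.
#' @param levels Number of gray levels `>= 2` used for quantization.
#' @param symmetric Count each pair in both orders (adds the transpose).
#' @param normalize Normalize counts to relative frequencies summing to 1.
#' @param entropy_base Logarithm base for the entropy descriptor:
#'   `"natural"` (default) or `"log2"`.
#' @return Object of class `glcm_config`.
#' @export
glcm_config <- function(distance = 1L, angles = c(0, 45, 90, 135),
                        levels = 64L, symmetric = TRUE, normalize = TRUE,
                        entropy_base = c("natural", "log2")) {
  if (distance < 1L) stopf("`distance` must be >= 1")
  if (levels < 2L) stopf("`levels` must be >= 2")
  if (!all(angles %in% c(0, 45, 90, 135))) {
    stopf("`angles` must be a subset of {0, 45, 90, 135}")
  }
  structure(list(distance = as.integer(distance), angles = as.numeric(angles),
                 levels = as.integer(levels), symmetric = isTRUE(symmetric),
                 normalize = isTRUE(normalize),
                 entropy_base = match.arg(entropy_base)),
            class = "glcm_config")
}

#' Quantize a gray-scale image
#'
#' Linear min-max binning into `levels` equal-width gray levels `0 ..
#' levels - 1`. A constant image maps to level 0. `NA` pixels (outside the
#' ROI) stay `NA` and are later excluded from pair counting.
#'
#' @param image Numeric matrix; finite values (plus optional `NA`s).
#' @param levels Number of gray levels.
#' @return Integer matrix with values in `0 .. levels - 1` (and `NA`s).
#' @export
quantize <- function(image, levels = 64L) {
  if (any(is.infinite(image))) stopf("image must be finite")
  r <- range(image, na.rm = TRUE)
  if (r[1L] == r[2L]) {
    q <- image
    q[!is.na(q)] <- 0L
    storage.mode(q) <- "integer"
    return(q)
  }
  q <- floor((image - r[1L]) / (r[2L] - r[1L]) * levels)
  q[q == levels] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),     # (row, col) displacement
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stopf("unsupported angle %s", angle))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of gray levels `(g(x), g(x + offset))` over all pixel
#' positions where both ends are inside the image and not `NA`, for the
#' offset defined by `cfg$distance` and a single angle. In symmetric mode the
#' transpose is added; with `normalize` the matrix is scaled to sum to 1.
#'
#' @param img Integer matrix of gray levels in `0 .. levels - 1`, `NA`
#'   allowed for excluded (off-ROI) pixels.
#' @param cfg A [glcm_config()]; its first angle is used unless `angle` is
#'   given.
#' @param angle Offset direction in degrees.
#' @return Object of class `glcm_matrix`: `p` (`levels x levels`), `n_pairs`,
#'   `config`, `angle`.
#' @export
glcm <- function(img, cfg = glcm_config(), angle = cfg$angles[1L]) {
  L <- cfg$levels
  d <- cfg$distance
  if (any(img >= L, na.rm = TRUE) || any(img < 0, na.rm = TRUE)) {
    stopf("image values must lie in 0..levels-1")
  }
  off <- glcm_offset(angle, d)
  nr <- nrow(img); nc <- ncol(img)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- rows[rows + off[1L] >= 1L & rows + off[1L] <= nr]
  c1 <- cols[cols + off[2L] >= 1L & cols + off[2L] <= nc]
  if (length(r1) == 0L || length(c1) == 0L) {
    stopf("image is smaller than the pixel offset")
  }
  a <- img[r1, c1, drop = FALSE]
  b <- img[r1 + off[1L], c1 + off[2L], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  counts <- matrix(0, L, L)
  if (any(ok)) {
    tab <- tabulate(a[ok] * L + b[ok] + 1L, nbins = L * L)
    counts <- matrix(tab, L, L, byrow = TRUE)  # rows: first pixel level
  }
  n_pairs <- sum(ok)
  if (cfg$symmetric) counts <- counts + t(counts)
  p <- counts
  if (cfg$normalize && sum(counts) > 0) p <- counts / sum(counts)
  structure(list(p = p, n_pairs = n_pairs, config = cfg, angle = angle),
            class = "glcm_matrix")
}

#' Haralick-style descriptors of a normalized GLCM
#'
#' With `p(i, j)` the normalized co-occurrence frequencies over 0-based gray
#' levels and `mu_i, mu_j, sigma_i, sigma_j` the marginal means and SDs:
#' mean `= sum i p`, variance `= sum (i - mu_i)^2 p`, homogeneity
#' `= sum p / (1 + (i - j)^2)`, contrast `= sum (i - j)^2 p`, dissimilarity
#' `= sum |i - j| p`, entropy `= -sum p log p` (over `p > 0`), second moment
#' `= sum p^2`, correlation `= sum (i - mu_i)(j - mu_j) p / (sigma_i
#' sigma_j)`. A zero-variance (constant-image) GLCM has perfectly predictable
#' pairs, so its correlation is defined as 1.
#'
#' @param P A normalized [glcm()] matrix (or a plain matrix summing to 1).
#' @param entropy_base `"natural"` or `"log2"`.
#' @return Named numeric vector of the 8 descriptors.
#' @export
glcm_descriptors <- function(P, entropy_base = NULL) {
  if (inherits(P, "glcm_matrix")) {
    if (is.null(entropy_base)) entropy_base <- P$config$entropy_base
    P <- P$p
  }
  if (is.null(entropy_base)) entropy_base <- "natural"
  if (abs(sum(P) - 1) > 1e-8) stopf("GLCM must be normalized (sum to 1)")
  L <- nrow(P)
  i <- matrix(0:(L - 1L), L, L)
  j <- t(i)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  lev <- 0:(L - 1L)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj_)
  var_i <- sum((lev - mu_i)^2 * pi_); var_j <- sum((lev - mu_j)^2 * pj_)
  lg <- if (entropy_base == "log2") log2 else log
  pos <- P > 0
  corr <- if (var_i > 0 && var_j > 0) {
    sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j)
  } else 1
  c(mean = mu_i,
    variance = var_i,
    homogeneity = sum(P / (1 + (i - j)^2)),
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    entropy = -sum(P[pos] * lg(P[pos])),
    second_moment = sum(P^2),
    correlation = corr)
}

#' 16-feature GLCM texture vector of a cube
#'
#' The texture signature of one sample: PC1 and PC2 score images are computed
#' over the ROI (per-cube PCA unless a model is given), cropped to the ROI
#' bounding box, min-max quantized to `cfg$levels` gray levels, and the 8
#' GLCM descriptors are computed per angle in `cfg$angles` (off-ROI pairs
#' excluded) and averaged over angles. PC1's 8 descriptors come first, then
#' PC2's.
#'
#' @param cube A calibrated [hypercube()].
#' @param mask Logical ROI mask.
#' @param model Optional [pca_fit()] model; default fits per cube.
#' @param cfg A [glcm_config()].
#' @return Named numeric vector of 16 values
#'   (`mean_pc1 .. correlation_pc1, mean_pc2 .. correlation_pc2`).
#' @export
texture_vector <- function(cube, mask, model = NULL, cfg = glcm_config()) {
  mask <- as.matrix(mask)
  imgs <- pc_score_images(cube, mask, model = model, n = 2L)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  submask <- mask[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]
  out <- lapply(seq_along(imgs), function(k) {
    img <- imgs[[k]][rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]
    img[!submask] <- NA
    q <- quantize(img, cfg$levels)
    per_angle <- vapply(cfg$angles,
                        function(a) glcm_descriptors(glcm(q, cfg, angle = a)),
                        numeric(8L))
    rowMeans(per_angle)
  })
  v <- c(out[[1L]], out[[2L]])
  names(v) <- paste0(rep(names(out[[1L]]), 2L),
                     rep(c("_pc1", "_pc2"), each = 8L))
  v
}

#' Multiple linear regression of infestation degree on texture features
#'
#' Quantifies how much ordinal infestation information the 16 GLCM features
#' carry: fits DI ~ texture by OLS (via [mlr_fit()]) and reports the multiple
#' correlation coefficient R and the coefficient of determination R^2.
#'
#' @param features Numeric `N x 16` texture feature matrix.
#' @param labels Integer DI labels `0..5`, length `N`.
#' @return List with `R`, `R2` and the underlying `mlr_model`.
#' @export
texture_di_regression <- function(features, labels) {
  features <- as.matrix(features)
  y <- as.numeric(labels)
  if (nrow(features) <= ncol(features) + 1L) {
    stopf("need more samples than features + 1")
  }
  fit <- mlr_fit(features, y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(R = sqrt(max(r2, 0)), R2 = r2, model = fit)
}
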