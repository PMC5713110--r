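#' One SPA variable chain
#'
#' Phase 1 of the successive projections algorithm (SPA). Starting from one
#' column of the `N x K` data matrix, each iteration projects every remaining
#' column onto the orthogonal complement of the span of the columns already
#' in the chain and appends the column with the largest projected norm. This
#' is the classic collinearity-minimizing forward selection used for
#' characteristic-wavelength selection in spectroscopy.
#'
#' Projections are maintained by sequential Gram-Schmidt deflation: after a
#' column is chosen, its (already orthogonalized) direction is removed from
#' all remaining columns, which is equivalent to projecting onto the
#' orthogonal complement of the whole chosen span. Ties in projected norm
#' break toward the lowest column index. If every remaining projected norm is
#' numerically zero (columns in the chosen span), the chain truncates early
#' with a warning.
#'
#' @param X Numeric `N x K` matrix (samples x variables).
#' @param start Starting variable index in `1..K`.
#' @param M Maximum chain length; capped at `min(N - 1, K)` by the caller
#'   convention of SPA (projections vanish beyond rank).
#' @param tol Relative tolerance declaring a projected norm zero.
#' @return Integer vector of selected variable indices, beginning with
#'   `start`, of length at most `M`.
#' @export
spa_chain <- function(X, start, M = min(nrow(X) - 1L, ncol(X)), tol = 1e-10) {
  X <- as.matrix(X)
  K <- ncol(X)
  if (start < 1L || start > K) stopf("`start` must be in 1..%d", K)
  M <- min(M, K)
  chain <- integer(M)
  chain[1L] <- start
  if (M == 1L) return(chain)
  R <- X                                   # residuals after deflation
  norm_ref <- max(colSums(X^2))
  z <- R[, start]
  for (i in 2:M) {
    zz <- sum(z^2)
    if (zz > 0) R <- R - z %*% (crossprod(z, R) / zz)
    R[, chain[seq_len(i - 1L)]] <- 0
    norms <- colSums(R^2)
    if (max(norms) <= tol * norm_ref) {
      warning(sprintf("SPA chain from %d truncated at length %d: remaining columns lie in the chosen span", start, i - 1L),
              call. = FALSE)
      return(chain[seq_len(i - 1L)])
    }
    j <- which.max(norms)                  # ties -> lowest index
    chain[i] <- j
    z <- R[, j]
  }
  chain
}

#' All SPA chains
#'
#' Runs [spa_chain()] from every possible starting variable, giving the `K`
#' candidate chains of Phase 1.
#'
#' @inheritParams spa_chain
#' @return List of `K` integer chains.
#' @export
spa_all_chains <- function(X, M = min(nrow(X) - 1L, ncol(X)), tol = 1e-10) {
  lapply(seq_len(ncol(X)), function(k) spa_chain(X, k, M = M, tol = tol))
}

#' Ordinary least-squares multiple linear regression
#'
#' Fits `y ~ 1 + Xsub` by OLS. Rank-deficient designs fall back to the
#' minimum-norm solution (via the pseudoinverse) and are flagged.
#'
#' @param Xsub Numeric `N x p` predictor matrix.
#' @param y Numeric response of length `N`.
#' @return Object of class `mlr_model`: list with `coefficients` (intercept
#'   first), `fitted`, `residuals`, and `rank_deficient`.
#' @export
mlr_fit <- function(Xsub, y) {
  Xsub <- as.matrix(Xsub)
  if (nrow(Xsub) != length(y)) stopf("nrow(Xsub) must equal length(y)")
  if (!all(is.finite(Xsub)) || !all(is.finite(y))) stopf("non-finite values in MLR input")
  A <- cbind(`(intercept)` = 1, Xsub)
  fit <- stats::lm.fit(A, y)
  deficient <- fit$rank < ncol(A)
  if (deficient) {
    s <- svd(A)
    pos <- s$d > max(dim(A)) * .Machine$double.eps * s$d[1L]
    coef <- s$v[, pos, drop = FALSE] %*%
      ((crossprod(s$u[, pos, drop = FALSE], y)) / s$d[pos])
    coef <- drop(coef)
    names(coef) <- colnames(A)
  } else {
    coef <- fit$coefficients
  }
  fitted <- drop(A %*% coef)
  structure(list(coefficients = coef, fitted = fitted,
                 residuals = y - fitted, rank_deficient = deficient),
            class = "mlr_model")
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(cbind(1, newdata) %*% object$coefficients)
}

#' Root mean square error
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) == 0L) {
    stopf("`pred` and `obs` must have equal positive length")
  }
  sqrt(mean((pred - obs)^2))
}

#' SPA Phase 2: subset choice by validation RMSE
#'
#' Evaluates every chain prefix of every candidate size: an MLR model is fit
#' on the calibration set using the prefix variables and scored by RMSE on
#' the validation set; the global minimizer wins. Ties break toward the
#' smaller subset, then the earlier chain.
#'
#' @param chains List of integer chains from [spa_all_chains()].
#' @param Xcal,ycal Calibration predictors and numeric response (here the
#'   ordinal DI index 0-5).
#' @param Xval,yval Validation predictors/response.
#' @param size_range Integer vector of subset sizes to evaluate.
#' @param wavelengths Optional wavelength axis (nm) used to report the
#'   selected wavelengths.
#' @return Object of class `spa_result`: `selected_indices` (in selection
#'   order), `selected_wavelengths`, `rmse_by_size` (minimum validation RMSE
#'   at each evaluated size), `best_size` and `best_rmse`.
#' @export
spa_phase2 <- function(chains, Xcal, ycal, Xval, yval,
                       size_range = 1:30, wavelengths = NULL) {
  if (length(size_range) == 0L) stopf("`size_range` must be non-empty")
  Xcal <- as.matrix(Xcal); Xval <- as.matrix(Xval)
  size_range <- sort(unique(as.integer(size_range)))
  M <- min(nrow(Xcal) - 1L, ncol(Xcal))
  if (any(size_range < 1L) || any(size_range > M)) {
    stopf("`size_range` must lie in 1..%d", M)
  }
  cache <- new.env(parent = emptyenv())
  # RMSE tie tolerance on the response scale: prefixes whose validation RMSEs
  # agree to ~10 significant digits count as tied, and ties go to the
  # smaller subset, then the earlier chain.
  eps <- 1e-10 * (stats::sd(yval) + abs(mean(yval)) + 1e-30)
  best <- list(rmse = Inf, size = NA_integer_, subset = NULL)
  rmse_by_size <- rep(Inf, length(size_range))
  names(rmse_by_size) <- size_range
  for (chain in chains) {
    for (si in seq_along(size_range)) {
      m <- size_range[si]
      if (m > length(chain)) next
      prefix <- chain[seq_len(m)]
      key <- paste(sort(prefix), collapse = ",")
      r <- cache[[key]]
      if (is.null(r)) {
        fit <- mlr_fit(Xcal[, prefix, drop = FALSE], ycal)
        r <- rmse(predict(fit, Xval[, prefix, drop = FALSE]), yval)
        cache[[key]] <- r
      }
      if (r < rmse_by_size[si]) rmse_by_size[si] <- r
      if (r < best$rmse - eps ||
          (abs(r - best$rmse) <= eps && m < best$size)) {
        best <- list(rmse = r, size = m, subset = prefix)
      }
    }
  }
  rmse_by_size <- rmse_by_size[is.finite(rmse_by_size)]
  structure(list(selected_indices = best$subset,
                 selected_wavelengths = if (is.null(wavelengths)) NULL else
                   wavelengths[best$subset],
                 rmse_by_size = rmse_by_size,
                 best_size = best$size, best_rmse = best$rmse),
            class = "spa_result")
}

#' @export
print.spa_result <- function(x, ...) {
  cat(sprintf("<spa_result> %d variables selected (validation RMSE %.4f)\n",
              x$best_size, x$best_rmse))
  if (!is.null(x$selected_wavelengths)) {
    cat("  wavelengths (nm):",
        paste(round(sort(x$selected_wavelengths), 1), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Characteristic-wavelength selection by SPA
#'
#' Convenience wrapper running both SPA phases: chains from every start
#' variable (Phase 1), then MLR/RMSE subset choice on a validation set
#' (Phase 2). The response is the numeric DI index, matching the ordinal
#' severity structure of the grading problem.
#'
#' @inheritParams spa_phase2
#' @param center Mean-center columns before the projection phase
#'   (default `FALSE`).
#' @return An `spa_result`; see [spa_phase2()].
#' @export
spa_select <- function(Xcal, ycal, Xval, yval, size_range = 1:30,
                       wavelengths = NULL, center = FALSE) {
  Xcal <- as.matrix(Xcal); Xval <- as.matrix(Xval)
  M <- min(nrow(Xcal) - 1L, ncol(Xcal))
  size_range <- size_range[size_range <= M]
  if (length(size_range) == 0L) stopf("no feasible subset size below %d", M)
  Xp <- if (center) scale(Xcal, center = TRUE, scale = FALSE) else Xcal
  chains <- spa_all_chains(Xp, M = max(size_range))
  spa_phase2(chains, Xcal, ycal, Xval, yval, size_range = size_range,
             wavelengths = wavelengths)
}
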