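# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs. These deliberately use the most explicit
# formulation available (explicit projector matrices, double loops,
# exhaustive enumeration, finite differences) rather than sharing code with
# the implementation under test.

# SPA step oracle: the next variable maximizes ||P x_j|| where P is the
# explicit projector onto the orthogonal complement of the chosen columns.
oracle_spa_chain <- function(X, start, M) {
  K <- ncol(X)
  chain <- start
  while (length(chain) < M) {
    A <- X[, chain, drop = FALSE]
    P <- diag(nrow(X)) - A %*% solve(crossprod(A)) %*% t(A)
    norms <- rep(-Inf, K)
    for (j in setdiff(seq_len(K), chain)) norms[j] <- sum((P %*% X[, j])^2)
    chain <- c(chain, which.max(norms))
  }
  chain
}

# GLCM oracle: double loop over every pixel position.
oracle_glcm <- function(img, levels, d, angle, symmetric = TRUE,
                        normalize = TRUE) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) {
    for (cc in seq_len(ncol(img))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
      a <- img[r, cc]; b <- img[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

# Kennard-Stone oracle: step-by-step enumeration with explicit loops.
oracle_kennard_stone <- function(X, n_cal) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  best <- c(NA, NA); bestd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand_best <- NA; cand_d <- -Inf
    for (i in setdiff(seq_len(n), sel)) {
      mind <- Inf
      for (s in sel) mind <- min(mind, D[i, s])
      if (mind > cand_d) { cand_d <- mind; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

# Central finite-difference gradient of the BPNN epoch loss.
oracle_fd_gradients <- function(w, X, T, h = 1e-6) {
  loss <- function(w) stemborer:::bpnn_loss(w, X, T)
  out <- w
  for (nm in c("W1", "b1", "W2", "b2")) {
    g <- w[[nm]]
    for (i in seq_along(g)) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      g[i] <- (loss(wp) - loss(wm)) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}

# Small, fast scene configuration shared by texture/pipeline tests.
tiny_scene_config <- function(...) {
  args <- utils::modifyList(
    list(n_bands = 48L, image_shape = c(24L, 24L),
         class_counts = rep(2L, 6), seed = 7L),
    list(...))
  do.call(scene_config, args)
}
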