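# Stain separation and color normalization in optical-density space.
#
# Model: per-pixel OD vector v (3) ~ W %*% c, with W a 3x2 nonnegative
# stain matrix (unit-norm columns: hematoxylin-like, eosin-like) and c the
# nonnegative per-stain concentrations. W is estimated by sparse NMF
# (multiplicative updates with an L1 penalty on concentrations);
# concentrations are then re-solved by cyclic coordinate descent on the
# L1-penalized nonnegative least-squares problem, which is deterministic
# and resolves degenerate (single-stain) fits onto the first column.

# Default H&E absorption directions (Ruifrok-style), unit-normalized.
default_stain_matrix <- function() {
  w <- cbind(h = c(0.650, 0.704, 0.286), e = c(0.072, 0.990, 0.105))
  sweep(w, 2, sqrt(colSums(w^2)), "/")
}

#' Convert an 8-bit RGB image to optical density
#'
#' `OD = -log10((I + 1) / 256)` per channel: 0 at full background
#' (I = 255), strictly decreasing in intensity, and exactly inverted by
#' [od_to_rgb()].
#'
#' @param image numeric array `H x W x 3`, values in `[0, 255]`.
#' @return numeric array `H x W x 3` of nonnegative optical densities.
#' @export
rgb_to_od <- function(image) -log10((image + 1) / 256)

#' Convert optical density back to 8-bit RGB
#'
#' Inverse of [rgb_to_od()]: `I = round(256 * 10^(-OD) - 1)`, clipped to
#' `[0, 255]`.
#'
#' @param od numeric array of nonnegative optical densities.
#' @return numeric array of 8-bit values, same shape.
#' @export
od_to_rgb <- function(od) pmin(pmax(round(256 * 10^(-od) - 1), 0), 255)

# Deterministic initialization for the stain dictionary: project the OD
# point cloud onto its top-2 principal plane and take the robust angular
# extremes (1st/99th percentile) as initial stain directions. Permutation
# invariant (covariance and quantiles only); NA on degenerate input.
init_stain_extremes <- function(V) {
  if (ncol(V) < 3) return(matrix(NA_real_, 3, 2))
  e <- eigen(tcrossprod(V - rowMeans(V)) / ncol(V), symmetric = TRUE)$vectors[, 1:2]
  proj <- crossprod(e, V)                       # 2 x n
  for (j in 1:2) if (mean(proj[j, ]) < 0) { e[, j] <- -e[, j]; proj[j, ] <- -proj[j, ] }
  phi <- atan2(proj[2, ], proj[1, ])
  q <- quantile(phi, c(0.01, 0.99), names = FALSE)
  W <- cbind(e %*% c(cos(q[1]), sin(q[1])), e %*% c(cos(q[2]), sin(q[2])))
  W <- pmax(W, 0)
  if (any(colSums(W) == 0)) return(matrix(NA_real_, 3, 2))
  W
}

# Solve min_{C >= 0} ||V - W C||^2/2 + lambda * sum(C) by cyclic coordinate
# descent, vectorized across pixels. V: 3 x n, W: 3 x k. Returns k x n.
solve_concentrations <- function(V, W, lambda = 0, iters = 60L) {
  k <- ncol(W)
  n <- ncol(V)
  C <- matrix(0, k, n)
  wtv <- crossprod(W, V)          # k x n
  wtw <- crossprod(W)             # k x k
  for (it in seq_len(iters)) {
    for (j in seq_len(k)) {
      resid_j <- wtv[j, ] - wtw[j, -j, drop = FALSE] %*% C[-j, , drop = FALSE]
      C[j, ] <- pmax(0, (resid_j - lambda) / wtw[j, j])
    }
  }
  C
}

#' Estimate a two-stain model from an image
#'
#' Fits the stain matrix by sparse non-negative matrix factorization of
#' the foreground optical-density pixels: deterministic initialization at
#' the robust angular extremes of the OD point cloud, then alternating
#' minimization of `||V - W C||^2 / 2 + sparsity * sum(C)` over `W >= 0`
#' (unit-norm columns) and `C >= 0`; a seeded random initialization is the
#' fallback on degenerate input. Concentrations are finally re-solved by
#' plain nonnegative least squares given the fitted dictionary, matching
#' the solve [normalize_image()] renders with.
#' Foreground = pixels whose maximum-channel OD exceeds
#' `od_threshold`. Columns are ordered so column 1 is the more
#' blue-absorbing (hematoxylin-like) stain, i.e. the one with the larger
#' red-channel OD coefficient. The per-stain concentration scale is the
#' 99th percentile of each stain's concentration over all pixels.
#'
#' @param image numeric array `H x W x 3`, values in `[0, 255]`.
#' @param od_threshold foreground threshold on max-channel OD.
#' @param sparsity L1 penalty weight on concentrations.
#' @param seed integer seed for the fallback initialization.
#' @param iters number of alternating-minimization iterations.
#' @return a `stain_model`: list with `stain_matrix` (3 x 2, unit-norm
#'   nonnegative columns) and `concentration_scale` (length 2).
#' @export
estimate_stain_model <- function(image, od_threshold = 0.15, sparsity = 0.1,
                                 seed = 0L, iters = 30L) {
  od <- rgb_to_od(image)
  V_all <- t(matrix(od, ncol = 3))                   # 3 x npix
  fg <- which(pmax(V_all[1, ], V_all[2, ], V_all[3, ]) > od_threshold)
  if (length(fg) < 100)
    stopf("only %d foreground pixels above OD %.3g; lower od_threshold",
          length(fg), od_threshold)
  V <- V_all[, fg, drop = FALSE]
  eps <- 1e-12
  W <- init_stain_extremes(V)
  if (anyNA(W)) W <- with_seed(seed, matrix(runif(6, 0.1, 1), 3, 2))
  W <- sweep(W, 2, pmax(sqrt(colSums(W^2)), eps), "/")
  # Alternating minimization: exact L1-prox nonnegative coding step, then
  # Mairal-style block-coordinate dictionary update (nonnegative, columns
  # renormalized to unit norm). A short unpenalized pass follows, removing
  # the L1 shrinkage bias from the dictionary (debiasing polish).
  dict_pass <- function(W, lambda, n_it) {
    for (it in seq_len(n_it)) {
      C <- solve_concentrations(V, W, lambda, iters = 30L)
      A <- tcrossprod(C)
      B <- tcrossprod(V, C)
      for (j in 1:2) {
        if (A[j, j] < eps) next
        u <- pmax((B[, j] - W %*% A[, j] + A[j, j] * W[, j]) / A[j, j], 0)
        nrm <- sqrt(sum(u^2))
        if (nrm > eps) W[, j] <- u / nrm
      }
    }
    W
  }
  W <- dict_pass(W, sparsity, iters)
  # Degenerate (single-stain) input: columns near-collinear (genuine H&E
  # pairs sit near 0.8) or one stain essentially unused under the sparse
  # code. Collapse onto the dominant column; otherwise debias-polish.
  usage <- rowSums(solve_concentrations(V, W, sparsity))
  if (sum(W[, 1] * W[, 2]) > 0.995 || min(usage) < 0.01 * max(usage)) {
    j <- which.max(usage)
    W <- W[, c(j, 3 - j), drop = FALSE]
    C <- rbind(solve_concentrations(V_all, W[, 1, drop = FALSE], 0), 0)
  } else {
    W <- dict_pass(W, 0, max(10L, iters %/% 3))
    if (W[1, 1] < W[1, 2]) W <- W[, 2:1, drop = FALSE]
    # concentration scales: unpenalized solve over ALL pixels -- the same
    # solve normalize_image re-renders with, keeping transfer idempotent
    C <- solve_concentrations(V_all, W, 0)
  }
  scale <- apply(C, 1, quantile, probs = 0.99, names = FALSE)
  new_stain_model(W, scale)
}

new_stain_model <- function(stain_matrix, concentration_scale) {
  stopifnot(all(dim(stain_matrix) == c(3, 2)), all(stain_matrix >= 0),
            length(concentration_scale) == 2)
  structure(list(stain_matrix = unname(stain_matrix),
                 concentration_scale = as.numeric(concentration_scale)),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>\n  stain matrix (columns: hematoxylin-like, eosin-like):\n")
  print(round(x$stain_matrix, 4))
  cat("  concentration scale (99th pct):", round(x$concentration_scale, 4), "\n")
  invisible(x)
}

#' Serialize / read a stain model as JSON
#' @param model a `stain_model`.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `stain_model` (read).
#' @export
write_stain_model <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(stain_matrix = model$stain_matrix,
                            concentration_scale = model$concentration_scale),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_stain_model
#' @export
read_stain_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_stain_model(x$stain_matrix, x$concentration_scale)
}

#' Normalize an image's stain appearance to a target
#'
#' Decomposes the source image into concentrations under the source stain
#' matrix, rescales each stain's concentrations by
#' `target_scale / source_scale`, and re-renders with the target stain
#' matrix through the Beer-Lambert law. Structural (concentration)
#' information is preserved; background (zero-OD) pixels stay background.
#'
#' @param source numeric array `H x W x 3`, values in `[0, 255]`.
#' @param source_model `stain_model` estimated from `source`.
#' @param target_model `stain_model` of the reference appearance.
#' @param sparsity L1 penalty when re-solving source concentrations;
#'   0 (plain nonnegative least squares) keeps re-rendering unbiased, so
#'   normalizing to the source's own model is an identity up to rounding.
#' @return numeric array `H x W x 3`, values in `[0, 255]`.
#' @export
normalize_image <- function(source, source_model, target_model, sparsity = 0) {
  if (any(source_model$concentration_scale <= 0))
    stopf("degenerate source stain: zero concentration scale")
  d <- dim(source)
  V <- t(matrix(rgb_to_od(source), ncol = 3))
  C <- solve_concentrations(V, source_model$stain_matrix, sparsity)
  C <- C * (target_model$concentration_scale / source_model$concentration_scale)
  od_new <- t(target_model$stain_matrix %*% C)
  array(od_to_rgb(od_new), d)
}
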