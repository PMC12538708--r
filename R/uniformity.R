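#' Contiguity weight matrix on a regular grid
#'
#' Binary spatial weights between grid tiles: rook contiguity links the 4
#' edge neighbors, queen contiguity additionally links the 4 diagonal
#' neighbors. Boundary tiles simply have fewer neighbors. Tiles are indexed
#' row-major from the top-left, matching [grid_proportions()]. Weights are
#' not row-standardized: Moran's I already normalizes by the total weight
#' `S0`.
#'
#' @param n_rows,n_cols Grid dimensions; the grid must have at least 2
#'   tiles.
#' @param scheme `"queen"` (default) or `"rook"`.
#' @return A list of class `weight_matrix`: `w` (N x N 0/1 matrix,
#'   symmetric, zero diagonal), `n_rows`, `n_cols`, `scheme`, `S0`.
#' @examples
#' build_weights(2, 2, "rook")$S0  # 8
#' @export
build_weights <- function(n_rows, n_cols, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  stopifnot(n_rows >= 1, n_cols >= 1)
  n <- n_rows * n_cols
  if (n < 2) rlang::abort("grid must have at least 2 tiles")
  offsets <- if (scheme == "rook") {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))[-5, ]
  }
  idx <- function(r, c) (r - 1) * n_cols + c
  w <- matrix(0, n, n)
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      rr <- r + offsets[, 1]
      cc <- c + offsets[, 2]
      ok <- rr >= 1 & rr <= n_rows & cc >= 1 & cc <= n_cols
      w[idx(r, c), idx(rr[ok], cc[ok])] <- 1
    }
  }
  structure(list(w = w, n_rows = n_rows, n_cols = n_cols,
                 scheme = scheme, S0 = sum(w)),
            class = "weight_matrix")
}

#' Moran's I spatial autocorrelation
#'
#' Computes global Moran's I on tile values `x_i`:
#' \deqn{I = \frac{N \sum_i \sum_j w_{ij} (x_i - \bar x)(x_j - \bar x)}
#'            {S_0 \sum_i (x_i - \bar x)^2}}
#' with \eqn{S_0 = \sum_i \sum_j w_{ij}}. Values near 1 indicate clustering,
#' near -1 dispersion, and near 0 spatial randomness — i.e. a uniform,
#' well-singulated seed spread. Under random relabeling the expectation is
#' `-1/(N-1)`.
#'
#' Constant tile values leave the statistic undefined (0/0) and raise an
#' error rather than returning 0, because downstream analysis interprets
#' magnitudes.
#'
#' An optional permutation test (an extension beyond plain scoring, flagged
#' in the output) relabels tile values at random and reports the two-sided
#' add-one-corrected p-value
#' `(1 + #{|I_perm| >= |I_obs|}) / (1 + n_perm)`.
#'
#' @param values A [grid_proportions()] tibble (row-major tile order) or a
#'   plain numeric vector of length `N`.
#' @param W A [build_weights()] object matching `N`; if `NULL`, queen
#'   weights are built from the grid attributes of `values`.
#' @param n_perm Number of permutations (0 = no test).
#' @param seed Integer seed for the permutation draw.
#' @param scheme Weight scheme used when `W` is `NULL`.
#' @return A list of class `moran_result`: `I`, `N`, `S0`,
#'   `expected_I_null` (= -1/(N-1)), and when `n_perm > 0` also `p_perm`,
#'   `n_perm`.
#' @examples
#' W <- build_weights(2, 2, "rook")
#' morans_i(c(1, -1, -1, 1), W)$I  # checkerboard: -1
#' @export
morans_i <- function(values, W = NULL, n_perm = 0, seed = 1,
                     scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  if (inherits(values, "grid_proportions")) {
    if (is.null(W)) {
      W <- build_weights(attr(values, "n_rows"), attr(values, "n_cols"), scheme)
    }
    x <- values$proportion[order(values$row, values$col)]
  } else {
    x <- as.numeric(values)
    if (is.null(W)) rlang::abort("W is required when values is a plain vector")
  }
  stopifnot(inherits(W, "weight_matrix"))
  n <- length(x)
  if (n != nrow(W$w)) rlang::abort("length(values) must equal the weight matrix dimension")
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) {
    rlang::abort("Moran's I is undefined: all tile values are equal (zero variance)")
  }
  moran_stat <- function(z) n * drop(z %*% W$w %*% z) / (W$S0 * sum(z^2))
  I <- moran_stat(z)
  res <- list(I = I, N = n, S0 = W$S0, expected_I_null = -1 / (n - 1))
  if (n_perm > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    perm <- vapply(seq_len(n_perm), function(k) moran_stat(sample(z)), numeric(1))
    res$p_perm <- (1 + sum(abs(perm) >= abs(I))) / (1 + n_perm)
    res$n_perm <- n_perm
    res$perm_values <- perm
  }
  structure(res, class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.5f (N = %d, S0 = %g, E[I|null] = %.5f)\n",
              x$I, x$N, x$S0, x$expected_I_null))
  if (!is.null(x$p_perm)) {
    cat(sprintf("two-sided permutation p = %.4f (%d permutations)\n",
                x$p_perm, x$n_perm))
  }
  invisible(x)
}

#' @rdname morans_i
#' @param x A `moran_result`.
#' @param ... Unused.
#' @method tidy moran_result
#' @export
tidy.moran_result <- function(x, ...) {
  tibble::tibble(statistic = x$I, n_tiles = x$N, s0 = x$S0,
                 null_expectation = x$expected_I_null,
                 p_perm = if (is.null(x$p_perm)) NA_real_ else x$p_perm,
                 n_perm = if (is.null(x$n_perm)) NA_integer_ else x$n_perm)
}

#' @rdname morans_i
#' @method glance moran_result
#' @export
glance.moran_result <- function(x, ...) tidy.moran_result(x, ...)

#' Score a scene end to end
#'
#' Convenience wrapper: ground-truth (or segmented) mask -> grid proportions
#' -> Moran's I. This is the per-image uniformity score the virtual Taguchi
#' experiment aggregates.
#'
#' @param scene A [render_scene()] result.
#' @param n_rows,n_cols Grid dimensions (default 6 x 8 = 48 tiles).
#' @param scheme Contiguity scheme.
#' @param use_segmentation If `TRUE`, segment `scene$image` with
#'   [default_hsv_thresholds()] instead of using the ground-truth mask.
#' @return A `moran_result`.
#' @export
score_scene <- function(scene, n_rows = 6, n_cols = 8,
                        scheme = c("queen", "rook"), use_segmentation = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(scene, "seed_scene"))
  mask <- if (use_segmentation) {
    if (is.null(scene$image)) rlang::abort("scene has no RGB image to segment")
    thr <- default_hsv_thresholds()
    hsv_segment(scene$image, thr$h, thr$s, thr$v)
  } else {
    scene$mask
  }
  gp <- grid_proportions(mask,
                         tile_w_px = ncol(mask) %/% n_cols,
                         tile_h_px = nrow(mask) %/% n_rows)
  morans_i(gp, scheme = scheme)
}
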