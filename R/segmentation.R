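#' Unsharp-mask sharpening
#'
#' Classic unsharp masking applied per channel:
#' `clip(x + amount * (x - gaussian_blur(x, radius)))`. Used as a
#' noise-suppression step before HSV thresholding; with `amount = 0` the
#' image is returned untouched.
#'
#' @param image Height x width x 3 RGB array in \[0, 1\], or a single-channel
#'   matrix.
#' @param radius Gaussian blur sigma in pixels (> 0).
#' @param amount Strength of the high-frequency boost (>= 0).
#' @return Array/matrix of the same shape, clipped to \[0, 1\].
#' @export
unsharp_sharpen <- function(image, radius = 2, amount = 1) {
  if (radius <= 0) rlang::abort("radius must be > 0")
  if (amount < 0) rlang::abort("amount must be >= 0")
  blur1 <- function(m) {
    # Gaussian kernel truncated at 3 sigma, clamped to the image extent
    br <- 2 * ceiling(3 * radius) + 1
    lim <- min(dim(m)) - 1
    if (lim %% 2 == 0) lim <- lim - 1
    EBImage::gblur(m, sigma = radius, radius = min(br, lim))
  }
  if (is.matrix(image)) {
    out <- image + amount * (image - blur1(image))
    return(pmin(pmax(out, 0), 1))
  }
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    rlang::abort("image must be an RGB array (h x w x 3) or a matrix")
  }
  if (amount == 0) return(image)
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- image[, , ch] + amount * (image[, , ch] - blur1(image[, , ch]))
  }
  pmin(pmax(out, 0), 1)
}

#' HSV threshold segmentation
#'
#' Converts an RGB frame to HSV (all three channels scaled to \[0, 1\]) and
#' marks a pixel as seed when hue, saturation and value each fall inside
#' their interval. The hue interval may wrap around 0 (give `h_range` with
#' `h_range[1] > h_range[2]`), since seed hues can straddle red.
#'
#' There are no magic default thresholds for user-supplied images; the
#' shipped [default_hsv_thresholds()] are tuned to the synthetic palette
#' only.
#'
#' @param image RGB array (h x w x 3) in \[0, 1\].
#' @param h_range,s_range,v_range Length-2 numeric intervals in \[0, 1\].
#' @return An integer 0/1 matrix (class `binary_mask`) with attribute
#'   `hsv_convention = "h,s,v in [0,1]; h wraps"`.
#' @examples
#' thr <- default_hsv_thresholds()
#' img <- array(0.5, dim = c(4, 4, 3))
#' hsv_segment(img, thr$h, thr$s, thr$v)
#' @export
hsv_segment <- function(image, h_range, s_range, v_range) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    rlang::abort("image must be an RGB array (h x w x 3)")
  }
  check_interval <- function(r, name, wrap = FALSE) {
    if (length(r) != 2 || any(r < 0) || any(r > 1)) {
      rlang::abort(paste0(name, " must be a length-2 interval within [0, 1]"))
    }
    if (!wrap && r[1] > r[2]) rlang::abort(paste0(name, " is empty (lo > hi)"))
  }
  check_interval(h_range, "h_range", wrap = TRUE)
  check_interval(s_range, "s_range")
  check_interval(v_range, "v_range")

  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
  in_h <- if (h_range[1] <= h_range[2]) {
    h >= h_range[1] & h <= h_range[2]
  } else {
    h >= h_range[1] | h <= h_range[2]  # wraparound through 0
  }
  keep <- in_h & s >= s_range[1] & s <= s_range[2] & v >= v_range[1] & v <= v_range[2]
  mask <- matrix(as.integer(keep), nrow = d[1], ncol = d[2])
  structure(mask, class = c("binary_mask", class(mask)),
            hsv_convention = "h,s,v in [0,1]; h wraps")
}

#' Default HSV thresholds for the synthetic palette
#'
#' Selects the warm yellow-to-brown seed hues of the default palette and
#' rejects the near-white belt background by its low saturation.
#'
#' @return A list with elements `h`, `s`, `v` (length-2 intervals).
#' @export
default_hsv_thresholds <- function() {
  list(h = c(0.02, 0.25), s = c(0.15, 1), v = c(0.03, 1))
}

#' Grid-binned seed-pixel proportions
#'
#' Partitions a binary mask into equal tiles and reports the seed-pixel
#' fraction of each tile. With the 3840 x 2160 frame and the default
#' 480 x 360 tiles this yields the 6 x 8 = 48 regions whose fractions are
#' the observations entering Moran's I. Tiles are traversed row-major from
#' the top-left; partial tiles are refused.
#'
#' @param mask 0/1 matrix (rows = image height).
#' @param tile_w_px,tile_h_px Tile width/height in pixels; must divide the
#'   mask width/height exactly.
#' @return A tibble of class `grid_proportions` with columns `row`, `col`,
#'   `proportion` (row-major order) and attributes `n_rows`, `n_cols`,
#'   `tile_w_px`, `tile_h_px`.
#' @examples
#' m <- matrix(0L, 36, 48); m[1:18, 1:24] <- 1L
#' grid_proportions(m, tile_w_px = 24, tile_h_px = 18)
#' @export
grid_proportions <- function(mask, tile_w_px = 480, tile_h_px = 360) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0L, 1L))) rlang::abort("mask values must be 0/1")
  h <- nrow(mask); w <- ncol(mask)
  if (h %% tile_h_px != 0 || w %% tile_w_px != 0) {
    rlang::abort(sprintf(
      "mask %d x %d is not divisible into %d x %d tiles (no partial tiles)",
      w, h, tile_w_px, tile_h_px))
  }
  n_rows <- h %/% tile_h_px
  n_cols <- w %/% tile_w_px
  row_grp <- rep(seq_len(n_rows), each = tile_h_px)
  col_grp <- rep(seq_len(n_cols), each = tile_w_px)
  by_row <- rowsum(mask, row_grp)                  # n_rows x w
  counts <- t(rowsum(t(by_row), col_grp))          # n_rows x n_cols
  out <- tibble::tibble(
    row = rep(seq_len(n_rows), each = n_cols),
    col = rep(seq_len(n_cols), times = n_rows),
    proportion = as.vector(t(counts)) / (tile_w_px * tile_h_px)
  )
  structure(out, class = c("grid_proportions", class(out)),
            n_rows = n_rows, n_cols = n_cols,
            tile_w_px = tile_w_px, tile_h_px = tile_h_px)
}
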