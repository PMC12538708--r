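#' Render a layout to an RGB frame and ground-truth mask
#'
#' Each seed is drawn as a filled rotated ellipse (semi-axes = length/2 and
#' width/2, scaled by `px_per_mm`) with per-pixel Gaussian color jitter; the
#' ground-truth mask is the union of the ellipse footprints. Overlapping
#' seeds therefore merge in the mask, which deliberately mimics the
#' occlusion the physical dispenser suffers when seeds adhere. Rendering is
#' bit-reproducible from the layout (the color-jitter stream is derived from
#' the scene seed).
#'
#' @param layout A [sample_layout()] result.
#' @param palette Seed palette supplying per-class colors; must cover every
#'   class present in the layout.
#' @param background A [background_model()].
#' @param image If `FALSE`, skip the RGB raster (mask and counts only) —
#'   useful when only ground-truth uniformity is needed.
#' @param max_pixels Guard on raster size (width x height in pixels).
#' @return A list of class `seed_scene`: `image` (height x width x 3 array
#'   in \[0, 1\], or `NULL`), `mask` (height x width 0/1 integer matrix,
#'   origin top-left), `counts` (tibble of per-class seed counts),
#'   `px_per_mm`.
#' @examples
#' p <- process_params("poisson", mix_counts = c(soybean = 5))
#' lay <- sample_layout(p, seed = 3, belt_width_mm = 60, belt_height_mm = 40,
#'                      px_per_mm = 4)
#' sc <- render_scene(lay)
#' dim(sc$mask)
#' @export
render_scene <- function(layout, palette = seed_palette(),
                         background = background_model(),
                         image = TRUE, max_pixels = 5e7) {
  stopifnot(inherits(layout, "layout_scene"), inherits(background, "background_model"))
  validate_palette(palette)
  px_per_mm <- attr(layout, "px_per_mm")
  if (is.null(px_per_mm) || px_per_mm <= 0) rlang::abort("layout has no positive px_per_mm")
  w_px <- round(attr(layout, "belt_width_mm") * px_per_mm)
  h_px <- round(attr(layout, "belt_height_mm") * px_per_mm)
  if (w_px * h_px > max_pixels) {
    rlang::abort(sprintf("raster %d x %d exceeds max_pixels = %g", w_px, h_px, max_pixels))
  }
  missing <- setdiff(unique(layout$class_label), palette$class_label)
  if (length(missing) > 0) {
    rlang::abort(paste0("palette missing class(es) present in layout: ",
                        paste(missing, collapse = ", ")))
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(attr(layout, "color_seed") %||% (attr(layout, "seed") + 1L))

  mask <- matrix(0L, nrow = h_px, ncol = w_px)
  img <- NULL
  if (image) {
    img <- array(0, dim = c(h_px, w_px, 3))
    for (ch in 1:3) {
      img[, , ch] <- background$color[ch] +
        if (background$sd > 0) stats::rnorm(h_px * w_px, 0, background$sd) else 0
    }
    if (background$diamond) {
      cols <- matrix(rep(seq_len(w_px), each = h_px), nrow = h_px)
      rows <- matrix(rep(seq_len(h_px), times = w_px), nrow = h_px)
      p <- background$diamond_period_px
      lines <- ((rows + cols) %% p < 2) | ((rows - cols) %% p < 2)
      for (ch in 1:3) img[, , ch] <- img[, , ch] - background$diamond_depth * lines
    }
  }

  # pixel centers in mm; row r covers y in [(r-1)/s, r/s)
  for (i in seq_len(nrow(layout))) {
    a <- layout$length_mm[i] / 2
    b <- layout$width_mm[i] / 2
    cx <- layout$x_mm[i]; cy <- layout$y_mm[i]
    th <- layout$theta_rad[i]
    r0 <- max(1L, floor((cy - a) * px_per_mm - 1) + 1L)
    r1 <- min(h_px, ceiling((cy + a) * px_per_mm + 1))
    c0 <- max(1L, floor((cx - a) * px_per_mm - 1) + 1L)
    c1 <- min(w_px, ceiling((cx + a) * px_per_mm + 1))
    if (r1 < r0 || c1 < c0) next
    pxx <- (seq(c0, c1) - 0.5) / px_per_mm - cx
    pyy <- (seq(r0, r1) - 0.5) / px_per_mm - cy
    dx <- matrix(rep(pxx, each = length(pyy)), nrow = length(pyy))
    dy <- matrix(rep(pyy, times = length(pxx)), nrow = length(pyy))
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    inside <- (u^2 + v^2) <= 1
    if (!any(inside)) next
    sub <- mask[r0:r1, c0:c1]
    sub[inside] <- 1L
    mask[r0:r1, c0:c1] <- sub
    if (image) {
      j <- match(layout$class_label[i], palette$class_label)
      base <- c(palette$color_r[j], palette$color_g[j], palette$color_b[j])
      sd <- palette$color_sd[j]
      n_in <- sum(inside)
      ridx <- rep(seq(r0, r1), times = length(pxx))[inside]
      cidx <- rep(seq(c0, c1), each = length(pyy))[inside]
      for (ch in 1:3) {
        val <- base[ch] + if (sd > 0) stats::rnorm(n_in, 0, sd) else 0
        img[cbind(ridx, cidx, ch)] <- val
      }
    }
  }
  if (image) img[] <- pmin(pmax(img, 0), 1)

  counts <- dplyr::count(tibble::as_tibble(layout[, "class_label", drop = FALSE]),
                         .data$class_label, name = "n")
  structure(list(image = img, mask = mask, counts = counts, px_per_mm = px_per_mm),
            class = "seed_scene")
}

#' @export
print.seed_scene <- function(x, ...) {
  cat(sprintf("<seed_scene> %d x %d px, %d seeds (%s image)\n",
              ncol(x$mask), nrow(x$mask), sum(x$counts$n),
              if (is.null(x$image)) "no" else "with"))
  invisible(x)
}
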