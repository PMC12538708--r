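#' Default seed palette
#'
#' Mean seed dimensions and rendering colors for the three seed classes
#' handled by the spreading device: imported soybeans and the two quarantine
#' ragweed species *Ambrosia trifida* and *Ambrosia artemisiifolia*.
#' Dimensions are caliper means over ~500 seeds per class (length x width of
#' the seed silhouette in mm). Colors are flat RGB means in \[0, 1\] with a
#' per-pixel Gaussian jitter sd, chosen so the three classes and the
#' near-white belt background separate cleanly in HSV space.
#'
#' @param classes Character vector of class labels to keep (default all
#'   three).
#' @return A tibble with one row per seed class and columns `class_label`,
#'   `length_mm`, `width_mm`, `color_r`, `color_g`, `color_b`, `color_sd`.
#' @examples
#' seed_palette()
#' @export
seed_palette <- function(classes = c("soybean", "a_trifida", "a_artemisiifolia")) {
  pal <- tibble::tibble(
    class_label = c("soybean", "a_trifida", "a_artemisiifolia"),
    length_mm   = c(7.65, 7.57, 3.22),
    width_mm    = c(6.52, 4.57, 2.84),
    color_r     = c(0.83, 0.54, 0.35),
    color_g     = c(0.69, 0.38, 0.24),
    color_b     = c(0.22, 0.20, 0.13),
    color_sd    = c(0.03, 0.03, 0.03)
  )
  unknown <- setdiff(classes, pal$class_label)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown seed class(es): ", paste(unknown, collapse = ", ")))
  }
  pal <- pal[match(classes, pal$class_label), , drop = FALSE]
  validate_palette(pal)
  pal
}

validate_palette <- function(pal) {
  stopifnot(
    is.data.frame(pal),
    all(c("class_label", "length_mm", "width_mm",
          "color_r", "color_g", "color_b", "color_sd") %in% names(pal))
  )
  if (anyDuplicated(pal$class_label)) {
    rlang::abort("seed palette class labels must be unique")
  }
  if (any(pal$width_mm <= 0) || any(pal$length_mm < pal$width_mm)) {
    rlang::abort("seed dimensions must satisfy length_mm >= width_mm > 0")
  }
  if (any(pal$color_sd < 0)) rlang::abort("color_sd must be nonnegative")
  invisible(pal)
}

#' Background model for rendered scenes
#'
#' The belt background is near-white; the optional diamond texture emulates
#' the patterned conveyor belts used on the physical device (periodic darker
#' diagonal lines).
#'
#' @param color RGB triple in \[0, 1\].
#' @param sd Per-pixel Gaussian jitter sd.
#' @param diamond Logical; overlay a diamond lattice texture.
#' @param diamond_period_px,diamond_depth Period (pixels) and darkening of
#'   the texture lines.
#' @return A list of class `background_model`.
#' @export
background_model <- function(color = c(0.94, 0.93, 0.90), sd = 0.01,
                             diamond = FALSE, diamond_period_px = 40,
                             diamond_depth = 0.06) {
  stopifnot(length(color) == 3, all(color >= 0), all(color <= 1), sd >= 0)
  structure(
    list(color = color, sd = sd, diamond = diamond,
         diamond_period_px = diamond_period_px, diamond_depth = diamond_depth),
    class = "background_model"
  )
}
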