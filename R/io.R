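#' Read and write scene artifacts
#'
#' Scenes are exchanged as 8-bit PNGs (RGB image; 0/255 mask), placement
#' ground truth as CSV and count summaries as JSON.
#'
#' @param scene A [render_scene()] result.
#' @param layout The [sample_layout()] the scene came from.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_scene <- function(scene, layout, dir, prefix = "scene") {
  stopifnot(inherits(scene, "seed_scene"), inherits(layout, "layout_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  if (!is.null(scene$image)) {
    p <- file.path(dir, paste0(prefix, "_image.png"))
    png::writePNG(scene$image, p)
    paths["image"] <- p
  }
  p <- file.path(dir, paste0(prefix, "_mask.png"))
  png::writePNG(scene$mask * 1.0, p)
  paths["mask"] <- p
  p <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(
    data.frame(class = layout$class_label, x_mm = layout$x_mm, y_mm = layout$y_mm,
               len_mm = layout$length_mm, wid_mm = layout$width_mm,
               theta_rad = layout$theta_rad),
    p, row.names = FALSE)
  paths["truth"] <- p
  p <- file.path(dir, paste0(prefix, "_counts.json"))
  jsonlite::write_json(stats::setNames(as.list(scene$counts$n), scene$counts$class_label),
                       p, auto_unbox = TRUE)
  paths["counts"] <- p
  invisible(paths)
}

#' @rdname write_scene
#' @param path A mask PNG path.
#' @return `read_mask_png()`: a 0/1 integer matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow = nrow(m))
}

#' Read/write grid proportions as CSV
#'
#' @param gp A [grid_proportions()] tibble.
#' @param path CSV path with columns `row`, `col`, `proportion`.
#' @export
write_proportions_csv <- function(gp, path) {
  stopifnot(inherits(gp, "grid_proportions"))
  utils::write.csv(tibble::as_tibble(gp)[, c("row", "col", "proportion")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportions_csv
#' @export
read_proportions_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("row", "col", "proportion") %in% names(df)))
  out <- tibble::as_tibble(df[order(df$row, df$col), ])
  structure(out, class = c("grid_proportions", class(out)),
            n_rows = max(df$row), n_cols = max(df$col))
}
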