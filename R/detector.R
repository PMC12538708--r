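#' Stochastic detector model
#'
#' A count-level stand-in for the real-time detection model running on the
#' device: each true seed is detected independently with a per-class recall,
#' a detected seed may be relabeled according to a confusion matrix, and
#' spurious detections arrive as a Poisson stream per image.
#'
#' @param recall Named vector of per-class detection probabilities in
#'   \[0, 1\].
#' @param fp_rate_per_image Expected false positives per image (Poisson).
#' @param confusion Square matrix of label-transfer probabilities with
#'   dimnames = classes; rows (true class) must sum to 1. Default identity.
#' @param fp_class_probs Distribution of false-positive labels over classes;
#'   default uniform.
#' @return A list of class `detector_model`.
#' @examples
#' detector_model(recall = c(soybean = 0.96, a_trifida = 0.96))
#' @export
detector_model <- function(recall, fp_rate_per_image = 0,
                           confusion = NULL, fp_class_probs = NULL) {
  if (is.null(names(recall)) || any(recall < 0) || any(recall > 1)) {
    rlang::abort("recall must be a named vector of probabilities in [0, 1]")
  }
  classes <- names(recall)
  if (is.null(confusion)) {
    confusion <- diag(length(classes))
    dimnames(confusion) <- list(classes, classes)
  }
  stopifnot(is.matrix(confusion),
            identical(rownames(confusion), classes),
            identical(colnames(confusion), classes))
  if (any(abs(rowSums(confusion) - 1) > 1e-8) || any(confusion < 0)) {
    rlang::abort("each confusion row must be a probability distribution")
  }
  if (is.null(fp_class_probs)) {
    fp_class_probs <- stats::setNames(rep(1 / length(classes), length(classes)), classes)
  }
  stopifnot(fp_rate_per_image >= 0, abs(sum(fp_class_probs) - 1) < 1e-8)
  structure(list(recall = recall, fp_rate_per_image = fp_rate_per_image,
                 confusion = confusion, fp_class_probs = fp_class_probs),
            class = "detector_model")
}

#' Simulate per-class detection counts for a layout
#'
#' @param layout A [sample_layout()] result.
#' @param det A [detector_model()]; recall must be defined for every class
#'   present in the layout.
#' @param seed Optional integer seed; defaults to the layout's own detection
#'   sub-stream so the full scene pipeline stays reproducible from one scene
#'   seed.
#' @return A tibble with columns `class_label`, `true_count`,
#'   `detected_count`.
#' @examples
#' p <- process_params("poisson", mix_counts = c(soybean = 50))
#' lay <- sample_layout(p, seed = 9, belt_width_mm = 100, belt_height_mm = 100)
#' simulate_detections(lay, detector_model(recall = c(soybean = 1)))
#' @export
simulate_detections <- function(layout, det, seed = NULL) {
  stopifnot(inherits(layout, "layout_scene"), inherits(det, "detector_model"))
  classes <- names(det$recall)
  missing <- setdiff(unique(layout$class_label), classes)
  if (length(missing) > 0) {
    rlang::abort(paste0("detector recall undefined for class(es): ",
                        paste(missing, collapse = ", ")))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(if (is.null(seed)) attr(layout, "detection_seed") else as.integer(seed))

  detected <- stats::setNames(integer(length(classes)), classes)
  true <- stats::setNames(integer(length(classes)), classes)
  tab <- table(factor(layout$class_label, levels = classes))
  true[names(tab)] <- as.integer(tab)

  for (cl in classes) {
    n_det <- stats::rbinom(1, true[cl], det$recall[cl])
    if (n_det > 0) {
      labels <- sample(classes, n_det, replace = TRUE, prob = det$confusion[cl, ])
      t2 <- table(factor(labels, levels = classes))
      detected <- detected + as.integer(t2)
    }
  }
  n_fp <- stats::rpois(1, det$fp_rate_per_image)
  if (n_fp > 0) {
    fp <- sample(classes, n_fp, replace = TRUE, prob = det$fp_class_probs)
    detected <- detected + as.integer(table(factor(fp, levels = classes)))
  }
  tibble::tibble(class_label = classes,
                 true_count = as.integer(true),
                 detected_count = as.integer(detected))
}
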