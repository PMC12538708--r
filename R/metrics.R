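#' Seed-counting verification metrics
#'
#' Per-class detection accuracy and leakage from ground-truth vs. detected
#' counts, plus the sample composition. Accuracy is
#' `100 * min(detected, true) / true` — overcounts are capped so accuracy
#' never exceeds 100% and accuracy + leakage = 100 exactly. Composition is
#' each class's share of all true seeds (weed + soybean; the denominator is
#' flagged in the output attribute `composition_denominator`).
#'
#' @param counts A data frame with columns `class_label`, `true_count`,
#'   `detected_count` (e.g. from [simulate_detections()]); an optional
#'   `mass_g` column is carried through.
#' @return A tibble of class `metrics_report` with per-class `accuracy_pct`,
#'   `leakage_pct`, `composition_pct`, and attribute
#'   `average_accuracy_pct` (unweighted mean over classes).
#' @examples
#' compute_metrics(data.frame(class_label = c("soybean", "a_trifida"),
#'                            true_count = c(2000, 100),
#'                            detected_count = c(1920, 95)))
#' @export
compute_metrics <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("class_label", "true_count", "detected_count")
  if (!all(need %in% names(counts))) {
    rlang::abort(paste0("counts need columns: ", paste(need, collapse = ", ")))
  }
  if (any(counts$true_count <= 0)) {
    rlang::abort("true_count must be > 0 for every reported class")
  }
  if (any(counts$detected_count < 0)) rlang::abort("detected_count must be >= 0")
  total_true <- sum(counts$true_count)
  out <- counts |>
    dplyr::mutate(
      accuracy_pct = 100 * pmin(.data$detected_count, .data$true_count) / .data$true_count,
      leakage_pct = 100 - .data$accuracy_pct,
      composition_pct = 100 * .data$true_count / total_true
    )
  structure(out, class = unique(c("metrics_report", class(out))),
            average_accuracy_pct = mean(out$accuracy_pct),
            composition_denominator = "all true seeds (weed + soybean)")
}

#' @rdname compute_metrics
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x),
                 average_accuracy_pct = attr(x, "average_accuracy_pct"),
                 total_true = sum(x$true_count),
                 total_detected = sum(x$detected_count))
}

#' Check sample composition against the quarantine protocol
#'
#' The verification protocol spikes each 500 +/- 10 g soybean sample
#' (~2000 +/- 40 seeds) with weed seeds at a mass ratio of 1 +/- 0.05% and
#' a count ratio of 5 +/- 0.5% relative to the soybeans (e.g. 100 +/- 10
#' *A. trifida* seeds, 5 +/- 1 g). This checks a count table against those
#' tolerances, per weed class.
#'
#' @param counts A data frame with `class_label`, `true_count` and, for the
#'   mass check, `mass_g`.
#' @param crop_class The reference (crop) class; ratios are weed / crop.
#' @param count_target,count_tol Count-ratio target and tolerance in
#'   percent (default 5 +/- 0.5).
#' @param mass_target,mass_tol Mass-ratio target and tolerance in percent
#'   (default 1 +/- 0.05); checked only when masses are present.
#' @return A tibble with one row per (weed class, constraint):
#'   `class_label`, `constraint`, `ratio_pct`, `target_pct`, `tol_pct`,
#'   `pass`.
#' @examples
#' check_composition(data.frame(class_label = c("soybean", "a_trifida"),
#'                              true_count = c(2000, 100)))
#' @export
check_composition <- function(counts, crop_class = "soybean",
                              count_target = 5, count_tol = 0.5,
                              mass_target = 1, mass_tol = 0.05) {
  counts <- tibble::as_tibble(counts)
  if (!crop_class %in% counts$class_label) {
    rlang::abort(paste0("crop class '", crop_class, "' absent from counts"))
  }
  crop <- counts[counts$class_label == crop_class, ]
  weeds <- counts[counts$class_label != crop_class, ]
  if (nrow(weeds) == 0) rlang::abort("no weed classes to check")
  out <- weeds |>
    dplyr::transmute(class_label = .data$class_label,
                     constraint = "count_ratio",
                     ratio_pct = 100 * .data$true_count / crop$true_count,
                     target_pct = count_target, tol_pct = count_tol)
  if ("mass_g" %in% names(counts) && !anyNA(counts$mass_g)) {
    out <- dplyr::bind_rows(out, weeds |>
      dplyr::transmute(class_label = .data$class_label,
                       constraint = "mass_ratio",
                       ratio_pct = 100 * .data$mass_g / crop$mass_g,
                       target_pct = mass_target, tol_pct = mass_tol))
  }
  dplyr::mutate(out, pass = abs(.data$ratio_pct - .data$target_pct) <= .data$tol_pct)
}
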