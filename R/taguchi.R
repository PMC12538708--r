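#' Taguchi designs and run sets
#'
#' A Taguchi design is a balanced orthogonal-array design: a tibble with a
#' `run` column plus one column per factor holding level labels, where every
#' (factor, level) pair occurs equally often. [taguchi_l18()] returns the
#' 18-run array used to optimize the seed-spreading device, with one
#' 2-level factor (seed-socket arrangement) and five 3-level factors
#' (spreading-roller speed, conveyor-motor speed, seed-box inclination,
#' drop-chute inclination, conveyor-belt type).
#'
#' @param design A data frame with a `run` column and factor columns.
#' @return A tibble of class `taguchi_design` with attribute `factors`
#'   (named list of level labels per factor).
#' @examples
#' taguchi_l18()
#' @export
taguchi_design <- function(design) {
  design <- tibble::as_tibble(design)
  if (!"run" %in% names(design)) rlang::abort("design needs a 'run' column")
  fac_cols <- setdiff(names(design), "run")
  if (length(fac_cols) == 0) rlang::abort("design has no factor columns")
  design[fac_cols] <- lapply(design[fac_cols], as.character)
  factors <- lapply(design[fac_cols], function(col) unique(col))
  for (f in fac_cols) {
    tab <- table(design[[f]])
    if (length(unique(tab)) != 1) {
      rlang::abort(sprintf("design is unbalanced in factor '%s'", f))
    }
  }
  structure(design, class = c("taguchi_design", class(design)), factors = factors)
}

#' @rdname taguchi_design
#' @export
taguchi_l18 <- function() {
  path <- system.file("extdata", "l18_design.csv", package = "seedspread",
                      mustWork = TRUE)
  taguchi_design(utils::read.csv(path, colClasses = "character"))
}

#' Attach replicate observations to a design
#'
#' Bundles per-run replicate responses (here: per-image Moran's I values)
#' with the design, and summarizes each run by its mean response and its
#' smaller-the-better S/N ratio.
#'
#' @param design A [taguchi_design()].
#' @param observations A data frame with columns `run` and `response` (one
#'   row per replicate observation; a `replicate` column is allowed and
#'   ignored).
#' @return A list of class `taguchi_runset`: `design`, `observations`,
#'   `runs` (tibble with `run`, `m`, `run_mean`, `run_sn`).
#' @export
taguchi_runset <- function(design, observations) {
  stopifnot(inherits(design, "taguchi_design"))
  observations <- tibble::as_tibble(observations)
  if (!all(c("run", "response") %in% names(observations))) {
    rlang::abort("observations need 'run' and 'response' columns")
  }
  missing <- setdiff(design$run, observations$run)
  if (length(missing) > 0) {
    rlang::abort(paste0("runs without observations: ", paste(missing, collapse = ", ")))
  }
  runs <- observations |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(m = dplyr::n(),
                     run_mean = mean(.data$response),
                     run_sn = sn_smaller_better(.data$response),
                     .groups = "drop")
  runs <- dplyr::left_join(tibble::tibble(run = design$run), runs, by = "run")
  structure(list(design = design, observations = observations, runs = runs),
            class = "taguchi_runset")
}

#' Smaller-the-better signal-to-noise ratio
#'
#' `S/N = -10 log10( (1/m) * sum(Y_i^2) )` in dB, the Taguchi
#' characteristic for responses whose ideal value is zero — here Moran's I,
#' where 0 means a spatially uniform spread. Larger S/N means responses
#' closer to zero and more stable. All-zero observations give `+Inf`.
#'
#' @param observations Numeric vector of replicate responses (length >= 1).
#' @return S/N in dB.
#' @examples
#' sn_smaller_better(0.1)            # 20
#' sn_smaller_better(c(0.1, 0.2, 0.3))
#' @export
sn_smaller_better <- function(observations) {
  if (length(observations) < 1) rlang::abort("at least one observation required")
  msq <- mean(observations^2)
  if (msq == 0) return(Inf)
  -10 * log10(msq)
}

#' Response table: level means and S/N per factor
#'
#' For every factor and level, averages the run means (and per-run S/N)
#' over the runs at that level. Delta = max - min across levels measures a
#' factor's influence; factors get dense ranks by descending delta (ties
#' share the smaller rank).
#'
#' @param x A [taguchi_runset()], or a data frame already holding
#'   `factor`, `level`, `n_runs`, `mean`, `sn` columns (e.g. the shipped
#'   [device_response_table()]).
#' @return A tibble of class `response_table` with columns `factor`,
#'   `level`, `n_runs`, `mean`, `sn`, and attributes `grand_mean`,
#'   `grand_sn`, `ranks` (see [response_ranks()]).
#' @export
response_table <- function(x) {
  if (inherits(x, "taguchi_runset")) {
    design <- x$design
    runs <- x$runs
    fac_cols <- setdiff(names(design), "run")
    long <- design |>
      dplyr::left_join(runs, by = "run") |>
      tidyr::pivot_longer(dplyr::all_of(fac_cols),
                          names_to = "factor", values_to = "level")
    rt <- long |>
      dplyr::group_by(.data$factor, .data$level) |>
      dplyr::summarise(n_runs = dplyr::n(),
                       mean = mean(.data$run_mean),
                       sn = mean(.data$run_sn), .groups = "drop")
    # preserve design factor and level order
    lvl_order <- attr(design, "factors")
    rt <- dplyr::arrange(rt, match(.data$factor, fac_cols),
                         purrr::map2_int(.data$factor, .data$level,
                                         ~ match(.y, lvl_order[[.x]])))
    grand_mean <- mean(runs$run_mean)
    grand_sn <- mean(runs$run_sn)
  } else {
    rt <- tibble::as_tibble(x)
    need <- c("factor", "level", "n_runs", "mean", "sn")
    if (!all(need %in% names(rt))) {
      rlang::abort(paste0("response table needs columns: ", paste(need, collapse = ", ")))
    }
    # each factor's occurrence-weighted level means average to the grand
    # mean, so the first factor suffices to recover it
    f1 <- rt$factor == rt$factor[1]
    grand_mean <- stats::weighted.mean(rt$mean[f1], rt$n_runs[f1])
    grand_sn <- stats::weighted.mean(rt$sn[f1], rt$n_runs[f1])
  }
  rt <- structure(rt, class = unique(c("response_table", class(rt))),
                  grand_mean = grand_mean, grand_sn = grand_sn)
  attr(rt, "ranks") <- response_ranks(rt)
  rt
}

#' Delta-based factor ranks
#'
#' @param rt A [response_table()].
#' @return A tibble with `factor`, `delta_mean`, `delta_sn`, `rank_mean`,
#'   `rank_sn` (dense ranks, 1 = largest delta).
#' @export
response_ranks <- function(rt) {
  stopifnot(all(c("factor", "level", "mean", "sn") %in% names(rt)))
  tibble::as_tibble(rt) |>
    dplyr::group_by(factor = .data$factor) |>
    dplyr::summarise(delta_mean = max(.data$mean) - min(.data$mean),
                     delta_sn = max(.data$sn) - min(.data$sn),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$factor, unique(rt$factor))) |>
    dplyr::mutate(rank_mean = dplyr::dense_rank(dplyr::desc(.data$delta_mean)),
                  rank_sn = dplyr::dense_rank(dplyr::desc(.data$delta_sn)))
}

#' Published response table of the spreading-device optimization
#'
#' Level means and smaller-the-better S/N ratios of Moran's I from the
#' physical device's L18 optimization experiment, shipped as a package
#' fixture. Useful as a worked reference input for [response_ranks()],
#' [optimal_levels()] and [anova_from_levels()].
#'
#' @return A [response_table()] tibble.
#' @examples
#' device_response_table()
#' @export
device_response_table <- function() {
  path <- system.file("extdata", "device_response_table.csv",
                      package = "seedspread", mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c(factor = "character", level = "character"))
  response_table(tibble::as_tibble(df))
}

#' Per-factor sums of squares from level means
#'
#' The Taguchi between-level sum of squares for one factor:
#' `SS_f = sum_v n_v * (mean_v - grand_mean)^2`, where `n_v` is the number
#' of runs at level `v` (9 for the 2-level factor, 6 for 3-level factors in
#' an L18). `DOF = l - 1`, `MS = SS / DOF`.
#'
#' @param rt A [response_table()].
#' @param response `"mean"` (run means) or `"sn"` (per-run S/N).
#' @param n_runs_total Total runs in the design (for the occurrence check);
#'   default inferred from the first factor.
#' @return A tibble with `factor`, `dof`, `ss`, `ms`.
#' @export
anova_from_levels <- function(rt, response = c("mean", "sn"),
                              n_runs_total = NULL) {
  response <- match.arg(response)
  stopifnot(inherits(rt, "response_table") || is.data.frame(rt))
  rt <- tibble::as_tibble(rt)
  val <- rt[[response]]
  total_per_factor <- tapply(rt$n_runs, rt$factor, sum)
  if (is.null(n_runs_total)) n_runs_total <- unname(total_per_factor[1])
  if (any(total_per_factor != n_runs_total)) {
    rlang::abort("level occurrences are inconsistent with the design size")
  }
  rt |>
    dplyr::mutate(.value = val) |>
    dplyr::group_by(factor = .data$factor) |>
    dplyr::summarise(
      dof = dplyr::n() - 1L,
      ss = {
        gm <- stats::weighted.mean(.data$.value, .data$n_runs)
        sum(.data$n_runs * (.data$.value - gm)^2)
      },
      .groups = "drop") |>
    dplyr::mutate(ms = .data$ss / .data$dof) |>
    dplyr::arrange(match(.data$factor, unique(rt$factor)))
}

#' ANOVA of a Taguchi run set
#'
#' Partitions the between-run variation of the chosen response (run means
#' or per-run S/N) into per-factor sums of squares plus residual error.
#' `SS_total = sum_runs (y_run - grand)^2`; the error SS is the remainder
#' (floored at 0) with `DOF_err = (runs - 1) - sum(l_f - 1)` — 6 for the
#' L18 with these six factors. `F = MS_factor / MS_err`; p-values are the
#' upper tail of the F distribution, uncorrected, judged against 0.05.
#'
#' @param runset A [taguchi_runset()].
#' @param response `"mean"` or `"sn"`.
#' @return A tibble of class `anova_table` with columns `source`, `dof`,
#'   `ss`, `ms`, `f`, `p` — one row per factor plus `error` and `total`
#'   rows.
#' @export
taguchi_anova <- function(runset, response = c("mean", "sn")) {
  response <- match.arg(response)
  stopifnot(inherits(runset, "taguchi_runset"))
  rt <- response_table(runset)
  y <- if (response == "mean") runset$runs$run_mean else runset$runs$run_sn
  n_runs <- nrow(runset$runs)
  grand <- mean(y)
  fac <- anova_from_levels(rt, response = response, n_runs_total = n_runs)
  ss_total <- sum((y - grand)^2)
  dof_err <- (n_runs - 1L) - sum(fac$dof)
  if (dof_err <= 0) rlang::abort("no residual degrees of freedom for the error term")
  ss_err <- max(0, ss_total - sum(fac$ss))
  ms_err <- ss_err / dof_err
  f_val <- if (ms_err > 0) fac$ms / ms_err else rep(Inf, nrow(fac))
  p_val <- if (ms_err > 0) {
    stats::pf(f_val, fac$dof, dof_err, lower.tail = FALSE)
  } else {
    rep(0, nrow(fac))
  }
  out <- dplyr::bind_rows(
    tibble::tibble(source = fac$factor, dof = fac$dof, ss = fac$ss,
                   ms = fac$ms, f = f_val, p = p_val),
    tibble::tibble(source = "error", dof = dof_err, ss = ss_err,
                   ms = ms_err, f = NA_real_, p = NA_real_),
    tibble::tibble(source = "total", dof = n_runs - 1L, ss = ss_total,
                   ms = NA_real_, f = NA_real_, p = NA_real_)
  )
  structure(out, class = unique(c("anova_table", class(out))), response = response)
}

#' Optimal factor levels
#'
#' Two selection rules, reported side by side and not adjudicated:
#' * mean rule — the level whose mean Moran's I is closest to zero
#'   (best average uniformity);
#' * S/N rule — the level with the highest smaller-the-better S/N
#'   (most stable uniformity).
#' Ties are broken by the lowest level index and flagged.
#'
#' @param rt A [response_table()].
#' @param mean_rule Currently only `"closest_to_zero"`.
#' @param sn_rule Currently only `"maximize"`.
#' @return A tibble with `factor`, `level_by_mean`, `tie_mean`,
#'   `level_by_sn`, `tie_sn`.
#' @examples
#' optimal_levels(device_response_table())
#' @export
optimal_levels <- function(rt, mean_rule = "closest_to_zero", sn_rule = "maximize") {
  mean_rule <- match.arg(mean_rule)
  sn_rule <- match.arg(sn_rule)
  tibble::as_tibble(rt) |>
    dplyr::group_by(factor = .data$factor) |>
    dplyr::summarise(
      level_by_mean = .data$level[which.min(abs(.data$mean))],
      tie_mean = sum(abs(.data$mean) == min(abs(.data$mean))) > 1,
      level_by_sn = .data$level[which.max(.data$sn)],
      tie_sn = sum(.data$sn == max(.data$sn)) > 1,
      .groups = "drop") |>
    dplyr::arrange(match(.data$factor, unique(rt$factor)))
}
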