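#' Map design factor levels to simulator knobs
#'
#' The virtual experiment replaces the physical dispenser with the scene
#' simulator, so each L18 factor combination must be translated into
#' point-process parameters. The default map encodes a declared, simple
#' mechanism: each factor level contributes a "clumping score"; the total
#' score selects the placement regime — low scores give a hard-core
#' (well-singulated) layout, intermediate scores complete spatial
#' randomness, high scores a Thomas cluster layout with tighter clusters as
#' the score grows. The speed factors dominate the score, mirroring their
#' dominant ranks in the device study; the remaining factors contribute
#' little.
#'
#' @param scores Named list of per-factor named numeric vectors
#'   (level -> score contribution). Defaults cover the L18 factors.
#' @param hardcore_radius_mm Center spacing of the singulated regime; the
#'   default follows the dispenser's ~14 mm socket pitch, which separates
#'   seed centers by roughly one and a half soybean lengths.
#' @param hardcore_max,poisson_max Score cut points between regimes.
#' @return A function `f(levels)` taking a named character vector of factor
#'   levels and returning a [process_params()] skeleton (without
#'   `mix_counts`, which the experiment adds per replicate group).
#' @export
default_knob_map <- function(scores = NULL, hardcore_radius_mm = 12,
                             hardcore_max = 0.25, poisson_max = 0.55) {
  if (is.null(scores)) {
    scores <- list(
      socket_arrangement = c(deflection = 0.05, `non-deflection` = 0),
      roller_speed = c(`50` = 0, `150` = 0.25, `250` = 0.55),
      motor_speed = c(`50` = 0.55, `150` = 0.25, `250` = 0),
      box_inclination = c(`20` = 0.03, `30` = 0.02, `40` = 0),
      chute_inclination = c(`60` = 0, `70` = 0.03, `80` = 0.02),
      belt_type = c(`1` = 0.06, `2` = 0.03, `3` = 0)
    )
  }
  force(hardcore_radius_mm); force(hardcore_max); force(poisson_max)
  function(levels) {
    s <- 0
    for (f in names(levels)) {
      if (!is.null(scores[[f]])) {
        contrib <- scores[[f]][[levels[[f]]]]
        if (is.null(contrib) || is.na(contrib)) {
          rlang::abort(sprintf("knob map has no score for %s = %s", f, levels[[f]]))
        }
        s <- s + contrib
      }
    }
    if (s <= hardcore_max) {
      list(process = "hardcore", hardcore_radius_mm = hardcore_radius_mm)
    } else if (s <= poisson_max) {
      list(process = "poisson")
    } else {
      list(process = "thomas",
           cluster_parent_intensity = 3e-4,
           cluster_sd_mm = max(6, 40 * (1.1 - s)))
    }
  }
}

#' Configuration of the virtual spreading experiment
#'
#' Defaults reproduce the device study's protocol at full scale: a
#' 384 x 216 mm field imaged at 10 px/mm (3840 x 2160 frames), 100 images
#' per run, three replicate sample groups per run (soybeans only, +1%
#' *A. artemisiifolia* by count, +1% *A. trifida*), a 6 x 8 scoring grid
#' with queen weights. Examples and tests scale these down explicitly.
#'
#' @param knob_map Factor-level translation, see [default_knob_map()].
#' @param images_per_run Scenes per run and replicate group (>= 1).
#' @param soybeans_per_frame Soybean count per frame.
#' @param weed_fraction Weed count fraction of the spiked groups.
#' @param belt_width_mm,belt_height_mm,px_per_mm Scene geometry.
#' @param n_rows,n_cols,scheme Uniformity grid and weights.
#' @param segment If `TRUE`, score scenes through rendering + HSV
#'   segmentation; if `FALSE` (default), score the ground-truth mask —
#'   equivalent on synthetic scenes and much faster.
#' @param seed Master seed for the whole experiment.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(knob_map = default_knob_map(),
                              images_per_run = 100,
                              soybeans_per_frame = 200,
                              weed_fraction = 0.01,
                              belt_width_mm = 384, belt_height_mm = 216,
                              px_per_mm = 10,
                              n_rows = 6, n_cols = 8,
                              scheme = c("queen", "rook"),
                              segment = FALSE, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(is.function(knob_map), images_per_run >= 1, soybeans_per_frame >= 1)
  structure(list(knob_map = knob_map, images_per_run = as.integer(images_per_run),
                 soybeans_per_frame = as.integer(soybeans_per_frame),
                 weed_fraction = weed_fraction,
                 belt_width_mm = belt_width_mm, belt_height_mm = belt_height_mm,
                 px_per_mm = px_per_mm, n_rows = n_rows, n_cols = n_cols,
                 scheme = scheme, segment = segment, seed = as.integer(seed)),
            class = "experiment_config")
}

experiment_groups <- function(cfg) {
  n <- cfg$soybeans_per_frame
  w <- max(1L, round(cfg$weed_fraction * n))
  list(
    soy_only = c(soybean = n),
    plus_artemisiifolia = c(soybean = n, a_artemisiifolia = w),
    plus_trifida = c(soybean = n, a_trifida = w)
  )
}

#' Run the virtual Taguchi spreading experiment
#'
#' For every design run and replicate group, generates `images_per_run`
#' scenes from the knob-mapped point process, scores each scene's Moran's I
#' on the ground-truth (or segmented) mask, aggregates per run, and returns
#' the full Taguchi analysis. Per-scene seeds are drawn once from the
#' master seed (a single seeded draw of one sub-seed per scene, indexed
#' run-major), so the whole experiment — and any single scene, via the
#' manifest — is reproducible.
#'
#' @param design A [taguchi_design()] (default the L18 array).
#' @param config An [experiment_config()].
#' @return A list of class `virtual_experiment`: `runset`
#'   ([taguchi_runset()]), `response` ([response_table()]), `ranks`,
#'   `optimal` ([optimal_levels()]), `anova_mean`, `anova_sn`
#'   ([taguchi_anova()]), and `manifest` (tibble: run, group, image,
#'   scene_seed, process, moran_i).
#' @examples
#' \donttest{
#' cfg <- experiment_config(images_per_run = 1, soybeans_per_frame = 40,
#'                          belt_width_mm = 96, belt_height_mm = 54,
#'                          px_per_mm = 2, seed = 7)
#' vx <- run_virtual_experiment(taguchi_l18(), cfg)
#' vx$optimal
#' }
#' @export
run_virtual_experiment <- function(design = taguchi_l18(), config = experiment_config()) {
  stopifnot(inherits(design, "taguchi_design"), inherits(config, "experiment_config"))
  fac_cols <- setdiff(names(design), "run")
  groups <- experiment_groups(config)
  n_scenes <- nrow(design) * length(groups) * config$images_per_run

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n_scenes)

  manifest <- vector("list", n_scenes)
  k <- 0L
  for (i in seq_len(nrow(design))) {
    levels <- as.list(design[i, fac_cols])
    knobs <- config$knob_map(levels)
    for (g in seq_along(groups)) {
      for (img in seq_len(config$images_per_run)) {
        k <- k + 1L
        params <- do.call(process_params, c(knobs, list(mix_counts = groups[[g]])))
        lay <- sample_layout(params, seed = scene_seeds[k],
                             belt_width_mm = config$belt_width_mm,
                             belt_height_mm = config$belt_height_mm,
                             px_per_mm = config$px_per_mm)
        scene <- render_scene(lay, image = config$segment)
        mi <- score_scene(scene, n_rows = config$n_rows, n_cols = config$n_cols,
                          scheme = config$scheme,
                          use_segmentation = config$segment)
        manifest[[k]] <- tibble::tibble(
          run = design$run[i], group = names(groups)[g], image = img,
          scene_seed = scene_seeds[k], process = params$process, moran_i = mi$I)
      }
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  obs <- dplyr::transmute(manifest, run = .data$run, response = .data$moran_i)
  runset <- taguchi_runset(design, obs)
  rt <- response_table(runset)
  structure(list(runset = runset, response = rt,
                 ranks = response_ranks(rt), optimal = optimal_levels(rt),
                 anova_mean = taguchi_anova(runset, "mean"),
                 anova_sn = taguchi_anova(runset, "sn"),
                 manifest = manifest, config = config),
            class = "virtual_experiment")
}

#' @export
print.virtual_experiment <- function(x, ...) {
  cat(sprintf("<virtual_experiment> %d runs x %d groups x %d images\n",
              nrow(x$runset$design), length(unique(x$manifest$group)),
              x$config$images_per_run))
  cat("optimal levels:\n")
  print(x$optimal)
  invisible(x)
}

#' @rdname run_virtual_experiment
#' @param x A `virtual_experiment`.
#' @param ... Unused.
#' @method tidy virtual_experiment
#' @export
tidy.virtual_experiment <- function(x, ...) x$manifest

#' @rdname run_virtual_experiment
#' @method glance virtual_experiment
#' @export
glance.virtual_experiment <- function(x, ...) {
  tibble::tibble(n_runs = nrow(x$runset$design),
                 n_scenes = nrow(x$manifest),
                 grand_mean_moran = mean(x$runset$runs$run_mean),
                 grand_mean_sn = mean(x$runset$runs$run_sn))
}
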