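#' Point-process parameters for seed layouts
#'
#' Describes how seed centers are placed on the virtual belt. Three regimes
#' span the continuum the physical dispenser produces, from clumped and
#' occluded to well singulated:
#' * `"poisson"` — complete spatial randomness (independent uniform centers);
#' * `"hardcore"` — sequential inhibition: every pair of centers at least
#'   `hardcore_radius_mm` apart, emulating a well-singulated spread;
#' * `"thomas"` — a Thomas-type cluster process: Poisson parents, Gaussian
#'   offspring dispersion, emulating seed adhesion and clumping.
#'
#' Counts are taken from `mix_counts` when given (exact per-class counts,
#' e.g. `c(soybean = 2000, a_trifida = 100)` for the 5% count-ratio
#' protocol); otherwise the total count is Poisson with mean
#' `intensity_per_mm2 * belt area` and classes are drawn uniformly.
#'
#' @param process One of `"poisson"`, `"hardcore"`, `"thomas"`.
#' @param intensity_per_mm2 Expected seeds per mm^2 when `mix_counts` is
#'   absent.
#' @param hardcore_radius_mm Minimum center-to-center distance (hardcore
#'   only; must be 0 otherwise).
#' @param cluster_parent_intensity Parents per mm^2 (thomas only).
#' @param cluster_mean_children Mean offspring per parent, used when
#'   `mix_counts` is absent (thomas only).
#' @param cluster_sd_mm Gaussian dispersion of offspring around parents
#'   (thomas only).
#' @param mix_counts Named integer vector of exact per-class counts, or
#'   `NULL`.
#' @return A list of class `process_params`.
#' @examples
#' process_params("hardcore", hardcore_radius_mm = 9,
#'                mix_counts = c(soybean = 100))
#' @export
process_params <- function(process = c("poisson", "hardcore", "thomas"),
                           intensity_per_mm2 = 0,
                           hardcore_radius_mm = 0,
                           cluster_parent_intensity = 0,
                           cluster_mean_children = 0,
                           cluster_sd_mm = 0,
                           mix_counts = NULL) {
  process <- match.arg(process)
  stopifnot(intensity_per_mm2 >= 0, hardcore_radius_mm >= 0,
            cluster_parent_intensity >= 0, cluster_mean_children >= 0,
            cluster_sd_mm >= 0)
  if (process != "hardcore" && hardcore_radius_mm != 0) {
    rlang::abort("hardcore_radius_mm must be 0 unless process = 'hardcore'")
  }
  if (process == "thomas" && is.null(mix_counts) &&
      (cluster_parent_intensity <= 0 || cluster_mean_children <= 0)) {
    rlang::abort("thomas process without mix_counts needs positive cluster_parent_intensity and cluster_mean_children")
  }
  if (!is.null(mix_counts)) {
    if (is.null(names(mix_counts)) || any(!nzchar(names(mix_counts)))) {
      rlang::abort("mix_counts must be a named vector of per-class counts")
    }
    if (any(mix_counts < 0) || any(mix_counts != round(mix_counts))) {
      rlang::abort("mix_counts must be nonnegative integers")
    }
  }
  structure(
    list(process = process,
         intensity_per_mm2 = intensity_per_mm2,
         hardcore_radius_mm = hardcore_radius_mm,
         cluster_parent_intensity = cluster_parent_intensity,
         cluster_mean_children = cluster_mean_children,
         cluster_sd_mm = cluster_sd_mm,
         mix_counts = mix_counts),
    class = "process_params"
  )
}

# Deterministic sub-stream seeds so placement, color jitter and detection
# draws are independent yet all reproducible from one scene seed.
scene_substreams <- function(seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  list(placement = s[1], color = s[2], detection = s[3])
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Sample a seed layout on the virtual belt
#'
#' Draws seed centers from the configured point process, assigns classes,
#' sizes and orientations, and returns the ground-truth placement table.
#' By default centers are confined to the belt interior inset by each seed's
#' semi-major axis, so no seed is clipped at the frame edge; set
#' `edge_clip = TRUE` to allow centers anywhere on the belt.
#'
#' The layout is bit-reproducible from `(params, specs, seed, belt
#' geometry)`: the same inputs always give the identical placement table.
#'
#' @param params A [process_params()] object.
#' @param specs Seed palette tibble, see [seed_palette()].
#' @param seed Integer scene seed.
#' @param belt_width_mm,belt_height_mm Belt field of view in mm (defaults
#'   384 x 216, imaged at 10 px/mm as a 3840 x 2160 frame).
#' @param px_per_mm Raster scale carried to [render_scene()].
#' @param edge_clip Allow seeds to overlap the frame edge.
#' @param max_tries Rejection budget per seed for the hardcore process;
#'   exceeding it raises an infeasible-packing error rather than silently
#'   returning fewer seeds.
#' @return A tibble of class `layout_scene` with columns `class_label`,
#'   `x_mm`, `y_mm`, `length_mm`, `width_mm`, `theta_rad` and attributes
#'   `belt_width_mm`, `belt_height_mm`, `px_per_mm`, `seed`.
#' @examples
#' p <- process_params("poisson", mix_counts = c(soybean = 40, a_trifida = 2))
#' sample_layout(p, seed = 1)
#' @export
sample_layout <- function(params, specs = seed_palette(), seed,
                          belt_width_mm = 384, belt_height_mm = 216,
                          px_per_mm = 10, edge_clip = FALSE,
                          max_tries = 200L) {
  stopifnot(inherits(params, "process_params"),
            belt_width_mm > 0, belt_height_mm > 0, px_per_mm > 0)
  validate_palette(specs)
  streams <- scene_substreams(seed)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(streams$placement)

  area <- belt_width_mm * belt_height_mm
  if (!is.null(params$mix_counts)) {
    missing <- setdiff(names(params$mix_counts), specs$class_label)
    if (length(missing) > 0) {
      rlang::abort(paste0("mix_counts classes absent from palette: ",
                          paste(missing, collapse = ", ")))
    }
    classes <- rep(names(params$mix_counts), times = params$mix_counts)
  } else {
    n <- stats::rpois(1, params$intensity_per_mm2 * area)
    classes <- if (n > 0) sample(specs$class_label, n, replace = TRUE) else character(0)
  }
  n <- length(classes)
  idx <- match(classes, specs$class_label)
  semi_major <- specs$length_mm[idx] / 2
  inset <- if (edge_clip) rep(0, n) else semi_major

  feasible_check <- function() {
    if (params$process == "hardcore" && n > 1) {
      # crude packing bound: disks of radius r/2 must fit the belt area
      r <- params$hardcore_radius_mm
      if (n * pi * (r / 2)^2 > area) {
        rlang::abort("infeasible hardcore packing: requested count exceeds the belt's packing capacity")
      }
    }
  }
  feasible_check()

  xy <- switch(params$process,
    poisson  = place_uniform(n, belt_width_mm, belt_height_mm, inset),
    hardcore = place_hardcore(n, belt_width_mm, belt_height_mm, inset,
                              params$hardcore_radius_mm, max_tries),
    thomas   = place_thomas(n, belt_width_mm, belt_height_mm, inset, params)
  )

  layout <- tibble::tibble(
    class_label = classes,
    x_mm = xy$x, y_mm = xy$y,
    length_mm = specs$length_mm[idx],
    width_mm = specs$width_mm[idx],
    theta_rad = if (n > 0) stats::runif(n, 0, pi) else numeric(0)
  )
  structure(layout,
            class = c("layout_scene", class(layout)),
            belt_width_mm = belt_width_mm, belt_height_mm = belt_height_mm,
            px_per_mm = px_per_mm, seed = as.integer(seed),
            color_seed = streams$color, detection_seed = streams$detection,
            process = params$process)
}

place_uniform <- function(n, w, h, inset) {
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  list(x = stats::runif(n, inset, w - inset),
       y = stats::runif(n, inset, h - inset))
}

place_hardcore <- function(n, w, h, inset, radius, max_tries) {
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, inset[i], w - inset[i])
      cy <- stats::runif(1, inset[i], h - inset[i])
      if (i == 1 ||
          all((x[seq_len(i - 1)] - cx)^2 + (y[seq_len(i - 1)] - cy)^2 >= radius^2)) {
        x[i] <- cx; y[i] <- cy; placed <- TRUE
        break
      }
    }
    if (!placed) {
      rlang::abort(sprintf(
        "infeasible hardcore packing: seed %d of %d not placed after %d tries (radius %.1f mm)",
        i, n, max_tries, radius))
    }
  }
  list(x = x, y = y)
}

place_thomas <- function(n, w, h, inset, params) {
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  n_par <- stats::rpois(1, max(params$cluster_parent_intensity * w * h, 1e-12))
  if (n_par == 0) n_par <- 1L  # condition on at least one parent when seeds are required
  px <- stats::runif(n_par, 0, w)
  py <- stats::runif(n_par, 0, h)
  parent <- sample.int(n_par, n, replace = TRUE)
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      cx <- px[parent[i]] + stats::rnorm(1, 0, params$cluster_sd_mm)
      cy <- py[parent[i]] + stats::rnorm(1, 0, params$cluster_sd_mm)
      if (cx >= inset[i] && cx <= w - inset[i] && cy >= inset[i] && cy <= h - inset[i]) break
      if (try == 100) {  # parent too close to the edge: fall back to uniform
        cx <- stats::runif(1, inset[i], w - inset[i])
        cy <- stats::runif(1, inset[i], h - inset[i])
      }
    }
    x[i] <- cx; y[i] <- cy
  }
  list(x = x, y = y)
}

#' @export
print.layout_scene <- function(x, ...) {
  cat(sprintf("<layout_scene> %d seeds on %.0f x %.0f mm belt (%s process, seed %d)\n",
              nrow(x), attr(x, "belt_width_mm"), attr(x, "belt_height_mm"),
              attr(x, "process") %||% "?", attr(x, "seed")))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
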