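# Small-scale scene builders shared across tests. Desk-scale geometry:
# a quarter-size belt at 2 px/mm keeps rendering fast while preserving the
# 6 x 8 grid structure.

small_layout <- function(process = "poisson", seed = 1,
                         counts = c(soybean = 60),
                         belt_w = 192, belt_h = 108, px = 2, ...) {
  p <- process_params(process, mix_counts = counts, ...)
  sample_layout(p, seed = seed, belt_width_mm = belt_w, belt_height_mm = belt_h,
                px_per_mm = px)
}

scene_moran <- function(layout) {
  score_scene(render_scene(layout, image = FALSE))$I
}

# Independent O(N^2) double-loop evaluation of Moran's I
moran_brute <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
    }
  }
  n * num / (sum(w) * sum((x - xb)^2))
}
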