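test_that("empty process yields an empty placement list", {
  p <- process_params("poisson", intensity_per_mm2 = 0)
  lay <- sample_layout(p, seed = 1, belt_width_mm = 100, belt_height_mm = 100)
  expect_equal(nrow(lay), 0)
  sc <- render_scene(lay)
  expect_true(all(sc$mask == 0))
  expect_equal(nrow(sc$counts), 0)
})

test_that("poisson intensity controls the mean count", {
  lambda_a <- 0.002 * 100 * 100  # intensity * area = 20
  p <- process_params("poisson", intensity_per_mm2 = 0.002)
  counts <- vapply(1:200, function(k) {
    nrow(sample_layout(p, seed = 100 + k, belt_width_mm = 100,
                       belt_height_mm = 100, edge_clip = TRUE))
  }, numeric(1))
  expect_lt(abs(mean(counts) - lambda_a), 3 * sqrt(lambda_a))
})

test_that("mix_counts are honored exactly and give the protocol count ratio", {
  lay <- small_layout(counts = c(soybean = 2000, a_trifida = 100),
                      belt_w = 384, belt_h = 216)
  tab <- table(lay$class_label)
  expect_equal(unname(tab[["soybean"]]), 2000)
  expect_equal(unname(tab[["a_trifida"]]), 100)
  sc <- render_scene(lay, image = FALSE)
  n <- setNames(sc$counts$n, sc$counts$class_label)
  expect_equal(100 * n[["a_trifida"]] / n[["soybean"]], 5.0)
})

test_that("hardcore layouts respect the minimum pairwise distance", {
  for (seed in 1:5) {
    lay <- small_layout("hardcore", seed = seed, counts = c(soybean = 50),
                        hardcore_radius_mm = 10)
    d <- as.matrix(dist(cbind(lay$x_mm, lay$y_mm)))
    diag(d) <- Inf
    expect_gte(min(d), 10)
  }
})

test_that("infeasible hardcore packing raises an explicit error", {
  p <- process_params("hardcore", hardcore_radius_mm = 30,
                      mix_counts = c(soybean = 200))
  expect_error(
    sample_layout(p, seed = 1, belt_width_mm = 100, belt_height_mm = 100),
    "infeasible"
  )
})

test_that("layouts, renders and detections are bit-identical under a fixed seed", {
  lay1 <- small_layout(seed = 42, counts = c(soybean = 30, a_trifida = 2))
  lay2 <- small_layout(seed = 42, counts = c(soybean = 30, a_trifida = 2))
  expect_identical(as.data.frame(lay1), as.data.frame(lay2))
  sc1 <- render_scene(lay1)
  sc2 <- render_scene(lay2)
  expect_identical(sc1$image, sc2$image)
  expect_identical(sc1$mask, sc2$mask)
  det <- detector_model(recall = c(soybean = 0.9, a_trifida = 0.9))
  expect_identical(simulate_detections(lay1, det), simulate_detections(lay2, det))
})

test_that("a single rendered soybean matches the ellipse-area oracle", {
  spec <- seed_palette("soybean")
  lay <- tibble::tibble(class_label = "soybean", x_mm = 50, y_mm = 50,
                        length_mm = spec$length_mm, width_mm = spec$width_mm,
                        theta_rad = 0.7)
  lay <- structure(lay, class = c("layout_scene", class(lay)),
                   belt_width_mm = 100, belt_height_mm = 100,
                   px_per_mm = 10, seed = 1L, color_seed = 2L)
  sc <- render_scene(lay, image = FALSE)
  expected_px <- pi * (spec$length_mm * 10 / 2) * (spec$width_mm * 10 / 2)
  expect_lt(abs(sum(sc$mask) - expected_px) / expected_px, 0.02)
})

test_that("rendered per-class counts equal layout counts", {
  lay <- small_layout(counts = c(soybean = 25, a_trifida = 4, a_artemisiifolia = 4))
  sc <- render_scene(lay, image = FALSE)
  expect_equal(sort(sc$counts$n), sort(as.integer(table(lay$class_label))))
})

test_that("perfect and degenerate detectors behave as configured", {
  lay <- small_layout(counts = c(soybean = 40, a_trifida = 5))
  perfect <- detector_model(recall = c(soybean = 1, a_trifida = 1))
  d <- simulate_detections(lay, perfect)
  expect_equal(d$detected_count, d$true_count)
  blind <- detector_model(recall = c(soybean = 0, a_trifida = 1))
  d2 <- simulate_detections(lay, blind)
  expect_equal(d2$detected_count[d2$class_label == "soybean"], 0L)
  expect_error(simulate_detections(lay, detector_model(recall = c(soybean = 1))),
               "undefined")
})

test_that("detection counts follow the binomial oracle", {
  lay <- small_layout(counts = c(soybean = 2000), belt_w = 384, belt_h = 216)
  det <- detector_model(recall = c(soybean = 0.96))
  fr <- vapply(1:500, function(k) {
    d <- simulate_detections(lay, det, seed = 7000 + k)
    d$detected_count / d$true_count
  }, numeric(1))
  se <- sqrt(0.96 * 0.04 / 2000)
  expect_lt(abs(mean(fr) - 0.96), 3 * se)
})

test_that("confusion rows reroute labels", {
  lay <- small_layout(counts = c(soybean = 500, a_trifida = 500),
                      belt_w = 384, belt_h = 216)
  conf <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE,
                 dimnames = list(c("soybean", "a_trifida"),
                                 c("soybean", "a_trifida")))
  det <- detector_model(recall = c(soybean = 1, a_trifida = 1), confusion = conf)
  d <- simulate_detections(lay, det)
  expect_equal(d$detected_count[d$class_label == "a_trifida"], 1000L)
  expect_equal(d$detected_count[d$class_label == "soybean"], 0L)
})
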