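test_that("implant extraction recovers the phantom footprint", {
  ph <- small_phantom("cube", designed_bi = 0.5, seed = 3)
  imp <- segment_implant(ph$image, small_stage1())
  expect_gte(iou(imp$mask, ph$footprint), 0.90)
  # no-noise render: area within 5% of ground truth
  expect_lte(abs(imp$area_px / sum(ph$footprint) - 1), 0.05)
})

test_that("a flat background image fails segmentation with a stage name", {
  expect_error(segment_implant(matrix(0.08, 120, 120)),
               "segmentation failed.*mean-threshold")
})

test_that("implant extraction is deterministic and stays inside closing(union)", {
  ph <- small_phantom("gyroid", designed_bi = 0.4, seed = 6)
  img <- add_noise(ph$image, 0.02, seed = 8)
  cfg <- small_stage1()
  a <- segment_implant(img, cfg)
  b <- segment_implant(img, cfg)
  expect_identical(a$mask, b$mask)

  # no pixels invented outside the closed union of the two evidence masks
  gray <- to_grayscale(img)
  mmask <- mean_threshold(gray)
  edges <- sobel_edges(gray * mmask)
  wmask <- sliding_window_classify(
    edges, window = cfg$window, stride = cfg$stride,
    edge_threshold = cfg$edge_frac * max(edges),
    min_edge_count = ceiling(cfg$min_edge_frac * cfg$window^2))
  envelope <- morphological_close(mmask | wmask, cfg$close_radius,
                                  cfg$close_shape)
  expect_false(any(a$mask & !envelope))
})

test_that("implant-mask IoU degrades monotonically with noise", {
  ph <- small_phantom("cube", designed_bi = 0.5, seed = 3)
  ious <- vapply(c(0, 0.02, 0.05), function(s) {
    iou(segment_implant(add_noise(ph$image, s, seed = 5),
                        small_stage1())$mask, ph$footprint)
  }, numeric(1))
  expect_true(all(diff(ious) <= 1e-12))
})

test_that("hole detection: empty pores found, filled pores yield no holes", {
  ph0 <- small_phantom("cube", designed_bi = 0, seed = 4)
  holes <- detect_holes(ph0$image, ph0$footprint)
  expect_gte(iou(holes, ph0$hole), 0.90)

  ph1 <- small_phantom("cube", designed_bi = 1, seed = 4)
  h1 <- suppressWarnings(detect_holes(ph1$image, ph1$footprint))
  pore_area <- sum(ph1$bone) + sum(ph1$hole)
  expect_lte(sum(h1), 0.02 * pore_area)
})

test_that("hole detection on a solid implant returns an empty mask", {
  ph <- small_phantom("solid", seed = 2)
  expect_warning(h <- detect_holes(ph$image, ph$footprint), "seed")
  expect_false(any(h))
})

test_that("roughness rule: flat regions are metal, high-frequency texture is bone", {
  cfg <- stage2_config(roughness_threshold = 0.3, bone_opening = 0L,
                       bone_intensity_max = NULL, neighborhood = 5L)
  all_mask <- matrix(TRUE, 20, 20)

  flat <- matrix(0.6, 20, 20)
  r <- classify_roughness(flat, all_mask, cfg)
  expect_identical(r$metal, all_mask)
  expect_false(any(r$bone))

  # 1-px vertical stripes: Roberts magnitude is sqrt(2)*delta ~ 0.57 everywhere
  stripes <- matrix(rep(c(0.3, 0.7), 10), 20, 20, byrow = TRUE)[, 1:20]
  stripes <- matrix(rep(c(0.3, 0.7), length.out = 20), 20, 20, byrow = TRUE)
  r2 <- classify_roughness(stripes, all_mask, cfg)
  expect_identical(r2$bone, all_mask)
  expect_false(any(r2$metal))
})

test_that("roughness split localizes a flat/textured boundary within the window", {
  set.seed(81)
  img <- matrix(0.8, 40, 60)
  img[, 31:60] <- stats::runif(40 * 30, 0.35, 0.75)   # textured right half
  cfg <- stage2_config(roughness_threshold = 0.1, bone_opening = 0L,
                       bone_intensity_max = NULL, neighborhood = 5L)
  r <- classify_roughness(img, matrix(TRUE, 40, 60), cfg)
  expect_false(any(r$bone[, 1:25]))    # flat side, clear of the boundary
  expect_true(all(r$bone[, 36:60]))    # textured side, clear of the boundary
})

test_that("raising the roughness threshold never adds bone pixels", {
  ph <- small_phantom("cube", designed_bi = 0.6, seed = 5)
  remaining <- ph$footprint & !ph$hole
  prev <- NULL
  for (thr in c(0.05, 0.1, 0.2, 0.4)) {
    cfg <- stage2_config(roughness_threshold = thr, bone_opening = 0L,
                         bone_intensity_max = NULL)
    cur <- classify_roughness(ph$image, remaining, cfg)$bone
    if (!is.null(prev)) expect_true(all(prev | !cur))
    prev <- cur
  }
})

test_that("texture partition tiles the implant region and is accurate per class", {
  # nominal scale: 60 px pores (600 um at 10 um/px)
  ph <- render_phantom(lattice_phantom("cube", designed_bi = 0.5, seed = 7))
  img <- add_noise(ph$image, 0.02, seed = 9)
  seg <- segment_textures(img, ph$footprint)

  un <- seg$implant_metal | seg$bone | seg$holes
  expect_identical(un, ph$footprint)
  expect_false(any(seg$implant_metal & seg$bone))
  expect_false(any(seg$implant_metal & seg$holes))
  expect_false(any(seg$bone & seg$holes))

  # per-class pixel accuracy vs ground truth
  expect_gte(sum(seg$bone & ph$bone) / sum(ph$bone), 0.90)
  expect_gte(sum(seg$holes & ph$hole) / sum(ph$hole), 0.90)
  expect_gte(sum(seg$implant_metal & ph$metal) / sum(ph$metal), 0.90)
})

test_that("texture partition of a solid implant is all metal", {
  ph <- small_phantom("solid", seed = 2)
  seg <- suppressWarnings(segment_textures(ph$image, ph$footprint))
  expect_identical(seg$implant_metal, ph$footprint)
  expect_false(any(seg$bone))
  expect_false(any(seg$holes))
})

test_that("texture partition is bit-identical across reruns", {
  ph <- small_phantom("voronoi", designed_bi = 0.3, seed = 8)
  img <- add_noise(ph$image, 0.02, seed = 10)
  a <- segment_textures(img, ph$footprint)
  b <- segment_textures(img, ph$footprint)
  expect_identical(a$implant_metal, b$implant_metal)
  expect_identical(a$bone, b$bone)
  expect_identical(a$holes, b$holes)
})
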