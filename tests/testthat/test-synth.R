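test_that("a straight synthetic tube matches the capsule closed form", {
  m <- generate_worm_mask(120, 12, curvature = 0, seed = 1)
  sh <- measure_shapes(label_components(m))
  L <- 120; w <- 12
  cont <- (2 * L + pi * w - 2 * w) / (4 * sqrt(L * w - w^2 + pi * w^2 / 4))
  expect_gt(sh$worminess, 1.45)
  expect_lt(sh$worminess, 1.75)
  expect_equal(sh$worminess, cont, tolerance = 0.05)
  # area matches the capsule allowing the closed-inclusion rasterization
  # convention (pixel centres within the half-width add ~1 px of width)
  expect_gte(sh$area_px, (L - w) * w + pi * w^2 / 4)
  expect_lte(sh$area_px, (L - w + 1) * (w + 1) + pi * (w + 1)^2 / 4)
})

test_that("worm mask generation validates input and is seed-deterministic", {
  expect_error(generate_worm_mask(10, 10, seed = 1))
  expect_error(generate_worm_mask(20, 2, seed = 1))
  m1 <- generate_worm_mask(80, 10, 0.15, seed = 42)
  m2 <- generate_worm_mask(80, 10, 0.15, seed = 42)
  expect_identical(m1, m2)
  expect_false(identical(m1, generate_worm_mask(80, 10, 0.15, seed = 43)))
})

test_that("worm mask generation leaves the global RNG stream alone", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_worm_mask(60, 8, 0.1, seed = 5))
  expect_identical(runif(3), before)
})

test_that("plates are seed-reproducible with non-touching planted worms", {
  sp <- plate_spec(image_size = c(400L, 400L), n_worms = 6L,
                   worm_length = 80, worm_width = 10, seed = 11)
  a <- generate_plate(sp); b <- generate_plate(sp)
  expect_identical(a$bf$pixels, b$bf$pixels)
  expect_identical(a$fl$pixels, b$fl$pixels)
  expect_identical(a$truth$labels, b$truth$labels)

  # every planted worm exists and worms stay separate even after 1 px
  # dilation on each side (>= 3 px gap)
  lab <- a$truth$labels
  expect_equal(max(lab), 6L)
  expect_true(all(tabulate(lab[lab > 0], 6) > 0))
  grown <- EBImage::dilate(lab > 0, EBImage::makeBrush(3, "box"))
  expect_equal(attr(label_components(grown > 0), "n_objects"), 6L)
})

test_that("noise-free plates plant exact intensities", {
  sp <- plate_spec(image_size = c(300L, 300L), n_worms = 1L,
                   worm_length = 70, worm_width = 9,
                   conditions = c(x = 500), worm_mean_jitter = 0,
                   background_fl = 50, noise_sd = 0,
                   n_round_debris = 0L, n_specks = 0L, seed = 2)
  pl <- generate_plate(sp)
  inside <- pl$fl$pixels[pl$truth$labels > 0]
  outside <- pl$fl$pixels[pl$truth$labels == 0]
  expect_true(all(inside == 500))
  expect_true(all(outside == 50))

  empty <- generate_plate(plate_spec(image_size = c(200L, 200L),
                                     n_worms = 0L, n_round_debris = 0L,
                                     n_specks = 0L, seed = 3))
  expect_equal(max(empty$truth$labels), 0L)
  expect_equal(mean(empty$fl$pixels), 500, tolerance = 0.01)
})

test_that("detection scoring is exact on forced cases", {
  pl <- generate_plate(plate_spec(image_size = c(300L, 300L), n_worms = 3L,
                                  worm_length = 60, worm_width = 8,
                                  n_round_debris = 0L, n_specks = 0L,
                                  seed = 4))
  truth <- pl$truth
  # detections identical to truth
  ev <- evaluate_detection(truth$labels, truth, iou_threshold = 0.6)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$iou, rep(1, 3))

  # no detections at all
  ev0 <- evaluate_detection(matrix(0L, 300, 300), truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 0)
  expect_false(ev0$precision_defined)

  # truth plus one spurious blob: precision = n/(n+1)
  det <- truth$labels
  det[5:14, 5:14] <- 99L
  ev1 <- evaluate_detection(det, truth)
  expect_equal(ev1$recall, 1)
  expect_equal(ev1$precision, 3 / 4)
})

test_that("condition ordering and scaled agreement hold on one suite", {
  suite <- synthetic_condition_suite(seed = 5, image_size = c(500L, 500L),
                                     n_worms = 6L, worm_length = 90,
                                     worm_width = 9)
  cfg <- worm_config()
  cond_means <- c(); rec <- c(); planted <- c()
  for (cond in names(suite)) {
    pl <- suite[[cond]]
    res <- quiet(run_image(pl$bf, pl$fl, cfg, pair_id = cond))
    ev <- evaluate_detection(res, pl$truth)
    expect_equal(ev$recall, 1)
    expect_equal(ev$precision, 1)
    m <- res$measurements
    cond_means <- c(cond_means, mean(m$mean_fl_bgsub))
    mt <- ev$matches[order(ev$matches$detected_label), ]
    rec <- c(rec, m$mean_fl_bgsub[order(m$label)])
    planted <- c(planted, pl$truth$worm_means[mt$true_worm] -
                           pl$truth$background_fl)
  }
  expect_true(all(diff(cond_means) > 0))  # strictly increasing conditions
  expect_gt(cor(minmax_scale(rec), minmax_scale(planted)), 0.99)
})

test_that("a synthetic folder is complete and readable back", {
  d <- withr::local_tempdir()
  paths <- quiet(write_synthetic_batch(
    d, seed = 1, conditions = c(lo = 800, hi = 3000),
    image_size = c(300L, 300L), n_worms = 3L, worm_length = 70,
    worm_width = 9))
  expect_true(all(file.exists(paths)))
  expect_length(grep("_BF\\.tif$", paths), 2L)
  key <- read_condition_key(file.path(d, "key.csv"))
  expect_equal(sort(unname(key)), c("hi", "lo"))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(length(truth$plates), 2L)
  expect_equal(length(truth$plates[[1]]$worm_means), 3L)
})
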