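test_that("worminess formula matches hand arithmetic and the circle value", {
  # ideal circle at several radii: sqrt(pi)/2, printed 0.89
  for (r in c(1, 10, 333)) {
    w <- worminess(2 * pi * r, pi * r^2)
    expect_equal(w, sqrt(pi) / 2, tolerance = 1e-12)
    expect_equal(round(w, 2), 0.89)
  }
  expect_equal(worminess(4, 1), 1)
  expect_equal(worminess(220, 1000), 220 / (4 * sqrt(1000)), tolerance = 1e-12)
  expect_equal(round(worminess(220, 1000), 4), 1.7393)
  expect_error(worminess(0, 10), "positive")
  expect_error(worminess(10, -1), "positive")
})

test_that("measured shapes hit the known geometry of disks and rectangles", {
  disk <- measure_shapes(label_components(disk_mask(100)))
  expect_equal(nrow(disk), 1L)
  expect_gt(disk$worminess, 0.85)
  expect_lt(disk$worminess, 0.95)
  expect_equal(disk$area_px, sum(disk_mask(100)))

  sq <- measure_shapes(label_components(rect_mask(50, 50)))
  expect_equal(sq$worminess, 1.0, tolerance = 0.05)

  rect <- measure_shapes(label_components(rect_mask(100, 10)))
  expect_equal(rect$worminess, 220 / (4 * sqrt(1000)), tolerance = 0.08)

  # centroid, bbox and border flag of a known square
  m <- rect_mask(10, 10, margin = 3)
  s <- measure_shapes(label_components(m))
  expect_equal(c(s$centroid_row, s$centroid_col), c(8.5, 8.5))
  expect_equal(c(s$bbox_min_row, s$bbox_max_row), c(4L, 13L))
  expect_false(s$touches_border)
  mb <- matrix(TRUE, 4, 6)
  expect_true(measure_shapes(label_components(mb))$touches_border)
})

test_that("Crofton estimator reproduces the standard configuration LUT", {
  # frozen oracle values computed from the reference 4-direction LUT
  expect_equal(crofton_perimeter(disk_mask(100)), 630.0640295604787,
               tolerance = 1e-10)
  expect_equal(crofton_perimeter(rect_mask(100, 10)), 207.4623580385348,
               tolerance = 1e-10)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(crofton_perimeter(one), 2.681517061334488, tolerance = 1e-10)
  L <- matrix(FALSE, 6, 6); L[2:5, 2] <- TRUE; L[5, 2:5] <- TRUE
  expect_equal(crofton_perimeter(L), 13.502870081686932, tolerance = 1e-10)
  # both estimators available through measure_shapes
  cro <- measure_shapes(label_components(disk_mask(50)), estimator = "crofton")
  expect_equal(cro$perimeter_px, crofton_perimeter(disk_mask(50)))
  expect_equal(attr(cro, "perimeter_estimator"), "crofton")
})

test_that("worminess is scale invariant across rasterization scales", {
  ws <- sapply(c(50, 100, 200), function(r) {
    measure_shapes(label_components(disk_mask(r)))$worminess
  })
  expect_lt(diff(range(ws)) / mean(ws), 0.03)
  # same for a 10:1 rectangle at three scales
  wr <- sapply(c(1, 2, 4), function(k) {
    measure_shapes(label_components(rect_mask(100 * k, 10 * k)))$worminess
  })
  expect_lt(diff(range(wr)) / mean(wr), 0.03)
})

test_that("worminess grows strictly with rectangle aspect ratio", {
  ws <- sapply(1:5, function(w) {
    measure_shapes(label_components(rect_mask(20 * w, 20)))$worminess
  })
  expect_true(all(diff(ws) > 0))
  # continuous form (2w+2)/(4 sqrt(w)) tracks the measurement
  cont <- (2 * (1:5) + 2) / (4 * sqrt(1:5))
  expect_equal(ws, cont, tolerance = 0.06)
})

test_that("no convex blob scores below the discrete circle floor", {
  set.seed(21)
  n_per <- 500
  ws <- numeric(0)
  for (i in seq_len(n_per)) {
    a <- runif(1, 8, 28); b <- runif(1, 8, 28)
    ws <- c(ws, measure_shapes(label_components(
      ellipse_mask(a, b, runif(1, 0, pi))))$worminess)
  }
  for (i in seq_len(n_per)) {
    ws <- c(ws, measure_shapes(label_components(
      convex_blob_mask(12, runif(1, 10, 25))))$worminess)
  }
  expect_length(ws, 1000L)
  expect_gte(min(ws), 0.85)
  # the minimum sits near the disk value
  expect_lt(min(ws), 0.95)
})

test_that("worminess and size filters respect inclusive bounds and conserve objects", {
  shapes <- data.frame(label = 1:3, worminess = c(0.92, 1.74, 2.50),
                       area_px = c(50, 500, 5000))
  fw <- filter_worminess(shapes)
  expect_equal(fw$kept$worminess, 1.74)
  expect_equal(fw$removed$worminess, c(0.92, 2.50))

  fb <- filter_worminess(data.frame(label = 1L, worminess = 1.5, area_px = 10))
  expect_equal(nrow(fb$kept), 1L)  # boundary value kept (inclusive)
  fb <- filter_worminess(data.frame(label = 1L, worminess = 2.1, area_px = 10))
  expect_equal(nrow(fb$kept), 1L)

  fs <- filter_size(shapes, 400)
  expect_equal(fs$kept$area_px, c(500, 5000))
  expect_equal(nrow(filter_size(shapes, 1)$removed), 0L)

  e <- filter_worminess(shapes[0, ])
  expect_equal(nrow(e$kept) + nrow(e$removed), 0L)

  # composition: every object lands in exactly one bucket
  set.seed(2)
  big <- data.frame(label = 1:50, worminess = runif(50, 0.8, 2.6),
                    area_px = sample(10:2000, 50))
  f1 <- filter_worminess(big)
  f2 <- filter_size(f1$kept, 300)
  expect_equal(nrow(f2$kept) + nrow(f2$removed) + nrow(f1$removed), 50L)
  expect_error(filter_worminess(big, 2.0, 1.5))
})
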