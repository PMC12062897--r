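test_that("config validation fills defaults and catches mistakes", {
  cfg <- validate_config(list(input_dir = "imgs"))
  expect_s3_class(cfg, "worm_config")
  expect_equal(cfg$worminess_lo, 1.5)
  expect_equal(cfg$worminess_hi, 2.1)
  expect_equal(cfg$blur_sigma, 2)
  expect_equal(cfg$polarity, "dark")
  expect_false(cfg$exclude_border)

  expect_error(validate_config(list(input_dir = "imgs", worminess_lo = 2.5,
                                    worminess_hi = 2.0)), "worminess_lo")
  expect_error(validate_config(list(input_dir = "imgs", wormness_lo = 1.0)),
               "unknown key")
  expect_error(validate_config(list()), "input_dir")
  expect_error(worm_config(contrast_low_pct = 60))
})

test_that("one image runs the stages in the canonical order", {
  pl <- tiny_plate()
  res <- quiet(run_image(pl$bf, pl$fl, worm_config(), pair_id = "t"))
  expect_equal(res$stages,
               c("contrast", "illumination", "blur", "threshold", "clean",
                 "label", "measure_shapes", "filter_worminess", "filter_size",
                 "background", "measure_fluorescence", "overlay"))
})

test_that("planted worms are kept while debris and specks are rejected", {
  pl <- tiny_plate()
  res <- quiet(run_image(pl$bf, pl$fl, worm_config(), pair_id = "t"))
  expect_equal(nrow(res$measurements), 5L)  # worms only
  # the two round debris are removed by worminess, near the circle score
  rej <- res$shapes[res$shapes$filter_status == "removed_worminess", ]
  expect_equal(nrow(rej), 2L)
  expect_true(all(rej$worminess < 1.5))
  expect_true(all(abs(rej$worminess - sqrt(pi) / 2) < 0.1))
  # specks never survive cleanup: every candidate object is worm or debris
  expect_equal(nrow(res$shapes), 7L)
  # recovered intensities track the planted ones
  ev <- evaluate_detection(res, pl$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_true(all(ev$iou >= 0.6))
})

test_that("degenerate images follow the per-image error contract", {
  blank <- worm_image(matrix(500, 64, 64), 16)
  res <- quiet(run_image(blank, blank, worm_config(), pair_id = "blank"))
  expect_equal(nrow(res$measurements), 0L)
  expect_equal(res$background$n_background_px, 64L * 64L)

  bf <- worm_image(matrix(0, 10, 10), 8)
  fl <- worm_image(matrix(0, 10, 12), 8)
  expect_error(quiet(run_image(bf, fl, worm_config(), pair_id = "x")),
               "mismatch")
})

write_tiny_batch <- function(d, seeds = 1:2) {
  for (s in seeds) {
    pl <- tiny_plate(seed = s)
    save_image(pl$bf, file.path(d, sprintf("img%02d_BF.tif", s)))
    save_image(pl$fl, file.path(d, sprintf("img%02d_Fl.tif", s)))
  }
  key <- data.frame(filename = sprintf("img%02d_BF.tif", seeds),
                    condition = paste0("cond", seeds))
  write.csv(key, file.path(d, "key.csv"), row.names = FALSE)
}

test_that("the batch driver joins conditions and writes combined outputs", {
  d <- withr::local_tempdir()
  write_tiny_batch(d)
  cfg <- validate_config(list(input_dir = d, key_path = file.path(d, "key.csv"),
                              output_dir = file.path(d, "out")))
  res <- quiet(run_batch(cfg))
  expect_equal(res$n_failed, 0L)
  expect_equal(sort(unique(res$measurements$condition)), c("cond1", "cond2"))
  expect_equal(nrow(res$measurements), 10L)  # 5 worms x 2 images
  expect_true(file.exists(file.path(d, "out", "measurements.csv")))
  expect_true(file.exists(file.path(d, "out", "run.log")))
  expect_length(grep("overlay\\.png$", res$manifest), 2L)

  # no key: condition column empty, batch still succeeds
  cfg2 <- validate_config(list(input_dir = d,
                               output_dir = file.path(d, "out2")))
  res2 <- quiet(run_batch(cfg2))
  expect_true(all(res2$measurements$condition == ""))
})

test_that("a corrupt image is skipped without affecting the others", {
  d <- withr::local_tempdir()
  write_tiny_batch(d)
  ref <- quiet(run_batch(validate_config(
    list(input_dir = d, output_dir = file.path(d, "o1")))))

  writeLines("not a tiff", file.path(d, "img99_BF.tif"))
  writeLines("not a tiff", file.path(d, "img99_Fl.tif"))
  res <- quiet(run_batch(validate_config(
    list(input_dir = d, output_dir = file.path(d, "o2")))))
  expect_equal(res$n_failed, 1L)
  expect_equal(sum(res$images$status == "ok"), 2L)
  # isolation: surviving measurements identical to the clean run
  expect_equal(res$measurements[res$measurements$pair_id != "img99", ],
               ref$measurements)

  expect_error(quiet(run_batch(validate_config(
    list(input_dir = withr::local_tempdir())))), "no image pairs")
})
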