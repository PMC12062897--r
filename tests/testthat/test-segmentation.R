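test_that("Otsu matches an exhaustive between-class-variance search", {
  set.seed(11)
  for (i in 1:20) {
    # random 8-bit histogram: mixture of two blurred modes + uniform floor
    counts <- as.integer(runif(256, 0, 5))
    for (m in 1:2) {
      mu <- sample(20:235, 1); s <- runif(1, 3, 25)
      counts <- counts + as.integer(2000 * exp(-((0:255 - mu)^2) / (2 * s^2)))
    }
    vals <- histogram_to_values(counts)
    expect_identical(otsu_threshold(vals)$bin, otsu_brute(counts))
  }
})

test_that("thresholding separates a bimodal field with dark foreground", {
  set.seed(3)
  x <- matrix(c(rnorm(3000, 0.1, 0.02), rnorm(7000, 0.8, 0.03)), 100, 100)
  x <- pmin(pmax(x, 0), 1)
  mask <- threshold_binary(x, polarity = "dark")
  dark <- x < 0.45
  expect_identical(mask, dark)
  # bright polarity is the complement
  expect_identical(threshold_binary(x, polarity = "bright"), !dark)
})

test_that("degenerate threshold inputs behave per contract", {
  expect_message(m <- threshold_binary(matrix(0.5, 10, 10)), "constant")
  expect_false(any(m))
  two <- matrix(c(0, 1), 1, 2)
  m2 <- threshold_binary(two, polarity = "dark")
  expect_identical(as.vector(m2), c(TRUE, FALSE))
})

test_that("clean_mask fills small holes, keeps big ones, drops specks", {
  m <- matrix(FALSE, 60, 60)
  m[6:55, 6:55] <- TRUE
  m[20:21, 20:21] <- FALSE           # 4 px hole
  area0 <- sum(m)
  out <- clean_mask(m, max_hole_area = 10, min_speck_area = 5)
  expect_equal(sum(out), area0 + 4)  # hole filled, nothing else changed

  big <- matrix(FALSE, 60, 60)
  big[6:55, 6:55] <- TRUE
  big[20:29, 20:29] <- FALSE         # 100 px hole > cutoff
  expect_identical(clean_mask(big, max_hole_area = 10, min_speck_area = 1), big)

  speck <- matrix(FALSE, 30, 30)
  speck[4:13, 4:13] <- TRUE
  speck[25, 25:26] <- TRUE           # 2 px speck
  out <- clean_mask(speck, max_hole_area = 10, min_speck_area = 5)
  expect_equal(sum(out), 100)
  expect_false(any(out[25, ]))
})

test_that("clean_mask is idempotent and conserves pixel accounting", {
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(runif(2500) < 0.45, 50, 50)
    once <- clean_mask(m, 20, 8)
    expect_identical(clean_mask(once, 20, 8), once)
  }
  # conservation: foreground after = before + filled - removed, computed
  # from the labeled pieces themselves
  m <- matrix(FALSE, 40, 40)
  m[5:30, 5:30] <- TRUE; m[10:11, 10:12] <- FALSE  # 6 px hole
  m[36, 36] <- TRUE                                 # 1 px speck
  out <- clean_mask(m, 10, 4)
  expect_equal(sum(out), sum(m) + 6 - 1)
})

test_that("component labeling is deterministic and connectivity-aware", {
  m <- matrix(FALSE, 20, 20)
  m[3:6, 3:6] <- TRUE
  m[12:15, 12:15] <- TRUE
  lab <- label_components(m)
  expect_equal(attr(lab, "n_objects"), 2L)
  # raster-scan order: the upper-left square is object 1
  expect_equal(lab[3, 3], 1L)
  expect_equal(lab[12, 12], 2L)

  expect_equal(attr(label_components(matrix(FALSE, 5, 5)), "n_objects"), 0L)

  diag2 <- matrix(FALSE, 5, 5)
  diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_equal(attr(label_components(diag2, 8), "n_objects"), 1L)
  expect_equal(attr(label_components(diag2, 4), "n_objects"), 2L)
})

test_that("4-connectivity labeling agrees with EBImage bwlabel", {
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.4, 30, 30)
    ours <- label_components(m, 4)
    theirs <- EBImage::bwlabel(m)  # bwlabel is 4-connectivity
    expect_equal(attr(ours, "n_objects"), max(theirs))
    # same partition (labels may be permuted): compare co-membership
    expect_equal(length(unique(paste(ours[m], theirs[m]))),
                 attr(ours, "n_objects"))
  }
})
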