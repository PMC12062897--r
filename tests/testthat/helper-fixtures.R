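# Shared fixtures and independent oracles, all built in code.

# rasterized disk: pixel centres within radius r of the centre
disk_mask <- function(r, margin = 5) {
  n <- 2 * (r + margin) + 1
  ctr <- r + margin + 1
  g <- seq_len(n)
  outer(g, g, function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

rect_mask <- function(h, w, margin = 5) {
  m <- matrix(FALSE, h + 2 * margin, w + 2 * margin)
  m[margin + seq_len(h), margin + seq_len(w)] <- TRUE
  m
}

# axis-angle filled ellipse (a convex blob family for the worminess floor)
ellipse_mask <- function(a, b, theta, margin = 4) {
  n <- 2 * ceiling(max(a, b)) + 2 * margin + 1
  ctr <- (n + 1) / 2
  g <- seq_len(n)
  ii <- outer(g, g, function(i, j) i - ctr)
  jj <- outer(g, g, function(i, j) j - ctr)
  u <- ii * cos(theta) + jj * sin(theta)
  v <- -ii * sin(theta) + jj * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# filled convex polygon from the convex hull of random points (even-odd
# point-in-polygon rasterization)
convex_blob_mask <- function(n_pts = 10, radius = 15, margin = 3) {
  ang <- runif(n_pts, 0, 2 * pi)
  rad <- radius * sqrt(runif(n_pts, 0.4, 1))
  px <- rad * cos(ang); py <- rad * sin(ang)
  h <- grDevices::chull(px, py)
  vx <- px[h]; vy <- py[h]
  n <- 2 * ceiling(radius) + 2 * margin + 1
  ctr <- (n + 1) / 2
  g <- seq_len(n) - ctr
  gx <- rep(g, times = n); gy <- rep(g, each = n)
  inside <- rep(FALSE, n * n)
  nv <- length(vx)
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vy[i] > gy) != (vy[j] > gy)) &
      (gx < (vx[j] - vx[i]) * (gy - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, n, n)
}

# independent Otsu oracle: plain exhaustive loop over all split points of
# an explicit histogram (never the package's vectorized code path)
otsu_brute <- function(counts) {
  n <- length(counts)
  vals <- seq_len(n) - 1
  tot <- sum(counts)
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(n - 1)) {
    w0 <- sum(counts[1:k]); w1 <- tot - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(vals[1:k] * counts[1:k]) / w0
    m1 <- sum(vals[(k + 1):n] * counts[(k + 1):n]) / w1
    v <- (w0 / tot) * (w1 / tot) * (m0 - m1)^2
    if (v > best) { best <- v; best_k <- k }
  }
  best_k
}

# expand a histogram into pixel values on the [0,1) bin grid
histogram_to_values <- function(counts, n_bins = 256) {
  rep((seq_along(counts) - 0.5) / n_bins, times = counts)
}

# small deterministic synthetic pair used by several tests
tiny_plate <- function(seed = 7, ...) {
  generate_plate(plate_spec(
    image_size = c(420L, 420L), n_worms = 5L, worm_length = 90,
    worm_width = 9, n_round_debris = 2L, debris_radius = 14,
    n_specks = 3L, seed = seed, ...))
}

quiet <- function(expr) suppressMessages(expr)
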