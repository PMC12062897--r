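# Brightfield preparation before thresholding. All three steps operate on
# (and return) plain numeric matrices on a normalized [0,1] working scale;
# the fluorescence channel is never preprocessed.

#' Percentile contrast stretch to the \[0,1\] working scale
#'
#' Linearly rescales so the `low_pct` percentile maps to 0 and `high_pct`
#' to 1, clipping beyond the percentiles. Raw-integer input is accepted:
#' the stretch itself normalizes the scale.
#'
#' @param img [worm_image] or numeric matrix.
#' @param low_pct,high_pct percentiles in \[0,100\], `low_pct < high_pct`.
#' @return numeric matrix in \[0,1\].
#' @export
enhance_contrast <- function(img, low_pct = 1, high_pct = 99) {
  px <- as_pixels(img)
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  q <- quantile(px, c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    wq_warn("contrast stretch skipped: image effectively constant")
    scale_max <- if (inherits(img, "worm_image")) 2^img$bit_depth - 1
                 else max(1, max(px))
    return(px / scale_max)
  }
  out <- (px - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Gaussian smoothing with reflective padding. EBImage::filter2 is
# FFT-based with circular wrap; padding by the kernel half-width with
# mirrored image content makes the wrap read reflected pixels instead,
# avoiding dark rims at the borders.
gaussian_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  hw <- ceiling(3 * sigma)
  nr <- nrow(px); nc <- ncol(px)
  ri <- c(pmin(hw:1, nr), seq_len(nr), nr + 1 - pmin(seq_len(hw), nr))
  ci <- c(pmin(hw:1, nc), seq_len(nc), nc + 1 - pmin(seq_len(hw), nc))
  padded <- px[ri, ci]
  if (hw <= 15L) {
    # small kernels: separable shift-and-add beats the FFT route
    w <- exp(-((-hw:hw)^2) / (2 * sigma^2)); w <- w / sum(w)
    np <- nrow(padded); mp <- ncol(padded)
    out <- matrix(0, np - 2L * hw, mp)
    for (k in -hw:hw)
      out <- out + w[k + hw + 1L] * padded[(1L + hw + k):(np - hw + k), ]
    res <- matrix(0, np - 2L * hw, mp - 2L * hw)
    for (k in -hw:hw)
      res <- res + w[k + hw + 1L] * out[, (1L + hw + k):(mp - hw + k)]
    return(res)
  }
  sm <- EBImage::gblur(padded, sigma = sigma, radius = 2L * hw + 1L)
  as.matrix(sm)[hw + seq_len(nr), hw + seq_len(nc)]
}

# block-mean downsampling by integer factor (edge-replicated to a
# multiple of ds)
downsample_mean <- function(px, ds) {
  nr <- nrow(px); nc <- ncol(px)
  nr2 <- ceiling(nr / ds) * ds; nc2 <- ceiling(nc / ds) * ds
  if (nr2 > nr || nc2 > nc)
    px <- px[c(seq_len(nr), rep(nr, nr2 - nr)),
             c(seq_len(nc), rep(nc, nc2 - nc)), drop = FALSE]
  m <- matrix(colMeans(matrix(px, ds)), nr2 / ds)  # rows pooled
  t(matrix(colMeans(matrix(t(m), ds)), nc2 / ds))  # cols pooled
}

# separable bilinear interpolation of a coarse grid (cell centres at
# (i - 0.5) * ds) back to the full H x W grid
bilinear_upsample <- function(coarse, H, W, ds) {
  weights <- function(n_out, n_in) {
    pos <- (seq_len(n_out) - 0.5) / ds + 0.5  # fine centre in coarse units
    pos <- pmin(pmax(pos, 1), n_in)
    lo <- pmin(floor(pos), n_in - 1L); frac <- pos - lo
    if (n_in == 1L) { lo <- rep(1L, n_out); frac <- rep(0, n_out) }
    Wm <- matrix(0, n_out, n_in)
    Wm[cbind(seq_len(n_out), lo)] <- 1 - frac
    Wm[cbind(seq_len(n_out), pmin(lo + 1L, n_in))] <-
      Wm[cbind(seq_len(n_out), pmin(lo + 1L, n_in))] + frac
    Wm
  }
  weights(H, nrow(coarse)) %*% coarse %*% t(weights(W, ncol(coarse)))
}

#' Correct non-uniform illumination
#'
#' Divides (default) or subtracts a smooth background estimate obtained by
#' very wide Gaussian smoothing of the image itself, then renormalizes so
#' the output median equals the input median. Division suits the
#' multiplicative shading of transmitted-light optics; `mode = "subtract"`
#' is available for additive shading.
#'
#' @param img numeric matrix on the \[0,1\] working scale.
#' @param illum_sigma background scale in pixels; default 1/8 of the
#'   shorter image side. Must be much larger than worm-scale detail.
#' @param mode `"divide"` or `"subtract"`.
#' @return numeric matrix in \[0,1\].
#' @export
correct_illumination <- function(img, illum_sigma = NULL, mode = c("divide", "subtract")) {
  px <- as_pixels(img)
  mode <- match.arg(mode)
  if (is.null(illum_sigma)) illum_sigma <- min(dim(px)) / 8
  if (illum_sigma <= 0) return(px)
  # the background varies over >> 16 px scales, so estimate it on a
  # decimated grid and interpolate back: same smooth field, much cheaper
  if (illum_sigma >= 16) {
    ds <- max(2L, min(8L, floor(illum_sigma / 8)))
    coarse <- gaussian_blur(downsample_mean(px, ds), illum_sigma / ds)
    bg <- bilinear_upsample(coarse, nrow(px), ncol(px), ds)
  } else {
    bg <- gaussian_blur(px, illum_sigma)
  }
  med_in <- median(px)
  if (mode == "divide") {
    eps <- 1e-6
    if (any(bg < eps)) {
      wq_warn("illumination estimate near zero; guarded by epsilon")
      bg <- pmax(bg, eps)
    }
    out <- px / bg
  } else {
    out <- px - bg
  }
  med_out <- median(out)
  if (mode == "divide") {
    out <- if (med_out > 0) out * (med_in / med_out) else out
  } else {
    out <- out + (med_in - med_out)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Slight Gaussian blur
#'
#' Evens out the light/dark mottling within each worm so that a single
#' threshold can separate whole worms from the background. `sigma = 0` is
#' the identity.
#'
#' @param img numeric matrix on the \[0,1\] working scale.
#' @param sigma blur width in pixels (default 2, "slight").
#' @return numeric matrix in \[0,1\].
#' @export
blur_image <- function(img, sigma = 2) {
  px <- as_pixels(img)
  stopifnot(sigma >= 0)
  if (sigma == 0) return(px)
  out <- gaussian_blur(px, sigma)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Full brightfield preprocessing: contrast, illumination, blur
#'
#' Applies the three steps in that fixed order and returns the \[0,1\]
#' matrix used for thresholding.
#'
#' @param img [worm_image] or matrix (raw brightfield).
#' @param cfg a [worm_config()] (only its preprocessing fields are used).
#' @return numeric matrix in \[0,1\].
#' @export
preprocess_brightfield <- function(img, cfg = worm_config()) {
  px <- enhance_contrast(img, cfg$contrast_low_pct, cfg$contrast_high_pct)
  px <- correct_illumination(px, cfg$illum_sigma, cfg$illum_mode)
  blur_image(px, cfg$blur_sigma)
}
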