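# Thresholding of the preprocessed brightfield, mask cleanup, and
# connected-component labeling.

#' Otsu threshold of a \[0,1\] image
#'
#' Maximizes between-class variance over a fixed-width histogram. Ties are
#' broken toward the lowest bin, so the result is fully deterministic.
#'
#' @param px numeric vector or matrix in \[0,1\].
#' @param n_bins histogram bins (default 256, the 8-bit convention).
#' @return list with `threshold` (upper edge of the last background bin,
#'   i.e. `bin / n_bins`) and `bin` (1-based index of the last class-0 bin).
#' @export
otsu_threshold <- function(px, n_bins = 256L) {
  v <- as.numeric(px)
  v <- v[!is.na(v)]
  bins <- pmin(n_bins - 1L, pmax(0L, as.integer(floor(v * n_bins))))
  h <- tabulate(bins + 1L, n_bins)
  tot <- sum(h)
  mids <- seq_len(n_bins) - 1  # bin values 0..n_bins-1
  w0 <- cumsum(h)
  m0 <- cumsum(h * mids)
  mt <- m0[n_bins]
  # split after bin k: class0 = bins 1..k, class1 = rest
  k <- seq_len(n_bins - 1L)
  w1 <- tot - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- m0[k][valid] / w0[k][valid]
  mu1 <- (mt - m0[k][valid]) / w1[valid]
  bcv[valid] <- (w0[k][valid] / tot) * (w1[valid] / tot) * (mu0 - mu1)^2
  if (!any(valid)) return(list(threshold = NA_real_, bin = NA_integer_))
  best <- which.max(bcv)  # lowest index on ties
  list(threshold = best / n_bins, bin = best)
}

#' Threshold the brightfield into a binary foreground mask
#'
#' @param img numeric matrix on the \[0,1\] working scale (preprocessed
#'   brightfield).
#' @param polarity `"dark"` if worms read darker than the background (the
#'   default for backlit brightfield), `"bright"` otherwise.
#' @param method `"otsu"` or `"fixed"`.
#' @param value threshold in \[0,1\] when `method = "fixed"`.
#' @return logical matrix, `TRUE` = candidate worm/debris foreground.
#' @export
threshold_binary <- function(img, polarity = c("dark", "bright"),
                             method = c("otsu", "fixed"), value = NULL) {
  px <- as_pixels(img)
  polarity <- match.arg(polarity)
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(is.numeric(value), length(value) == 1L)
    thr <- value
  } else {
    if (diff(range(px)) == 0) {
      wq_warn("constant image: threshold undefined, returning empty mask")
      return(matrix(FALSE, nrow(px), ncol(px)))
    }
    thr <- otsu_threshold(px)$threshold
  }
  if (polarity == "dark") px < thr else px >= thr
}

#' Fill small holes and remove small specks
#'
#' Background regions fully enclosed by foreground with area at most
#' `max_hole_area` are filled first; isolated foreground components with
#' area below `min_speck_area` are then removed. The operation is
#' idempotent.
#'
#' @param mask logical matrix.
#' @param max_hole_area largest hole (px^2) that gets filled.
#' @param min_speck_area smallest foreground component (px^2) kept.
#' @param connectivity foreground connectivity (4 or 8); holes use the
#'   complementary connectivity.
#' @return logical matrix.
#' @export
clean_mask <- function(mask, max_hole_area = 100, min_speck_area = 20,
                       connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  # holes: background components not touching the image border, labeled
  # with the connectivity dual to the foreground's
  bg_conn <- if (connectivity == 8) 4L else 8L
  bg_lab <- .cc_label(!mask, bg_conn)
  if (attr(bg_lab, "n_objects") > 0L) {
    border <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                       bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
    areas <- tabulate(bg_lab, attr(bg_lab, "n_objects"))
    fill <- setdiff(which(areas <= max_hole_area), border)
    if (length(fill)) mask[bg_lab %in% fill] <- TRUE
  }
  fg_lab <- .cc_label(mask, as.integer(connectivity))
  if (attr(fg_lab, "n_objects") > 0L) {
    areas <- tabulate(fg_lab, attr(fg_lab, "n_objects"))
    drop <- which(areas < min_speck_area)
    if (length(drop)) mask[fg_lab %in% drop] <- FALSE
  }
  mask
}

#' Label connected foreground components
#'
#' Deterministic labeling: components are numbered in raster-scan order of
#' their first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8; thin diagonal worm sections must
#'   not fragment).
#' @return integer matrix (0 = background, 1..n = objects) with attribute
#'   `n_objects`.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  .cc_label(mask, as.integer(connectivity))
}
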