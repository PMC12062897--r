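# Fluorescence measurement under transferred masks, and per-image
# background estimation. All statistics are computed on RAW fluorescence
# intensities; brightfield preprocessing never touches this channel.

#' Per-image fluorescence background from the step-2 mask
#'
#' The background is the arithmetic mean of the fluorescence over every
#' pixel NOT in the thresholded-and-cleaned foreground ("step-2" mask) --
#' i.e. the complement of ALL candidate objects, including debris that the
#' worminess/size filters later remove. Using the step-2 mask (not the
#' post-filter mask) keeps non-fluorescent debris out of the background
#' estimate.
#'
#' @param fluor [worm_image] or numeric matrix (raw fluorescence).
#' @param step2_mask logical matrix from [clean_mask()].
#' @return list with `background_fl` and `n_background_px`.
#' @export
background_mean <- function(fluor, step2_mask) {
  px <- as_pixels(fluor)
  stopifnot(identical(dim(px), dim(step2_mask)))
  bg <- px[!step2_mask]
  if (length(bg) == 0L)
    stop("no background pixels: the whole image thresholded as foreground")
  list(background_fl = mean(bg), n_background_px = length(bg))
}

#' Measure per-worm fluorescence under kept masks
#'
#' For each kept object: mean and population standard deviation (divide by
#' n) of the raw fluorescence under its mask, joined with its geometry, and
#' the background-subtracted mean. `worm_number` is assigned in label order
#' and matches the number drawn on the QC overlay. Negative
#' background-subtracted means are reported as-is.
#'
#' @param fluor [worm_image] or numeric matrix (raw fluorescence).
#' @param labels integer label matrix (step-2 labeling).
#' @param shapes data.frame of KEPT objects (subset of [measure_shapes()]
#'   rows; its `label` column addresses `labels`).
#' @param bg list from [background_mean()].
#' @param pair_id,condition provenance strings carried into the output.
#' @return data.frame, one row per kept worm: `pair_id`, `worm_number`,
#'   `label` (component label behind the worm number), `condition`,
#'   `mean_fl`, `sd_fl`, `area_px`, `perimeter_px`, `worminess`,
#'   `background_fl`, `mean_fl_bgsub`.
#' @export
measure_fluorescence <- function(fluor, labels, shapes, bg,
                                 pair_id = "", condition = "") {
  px <- as_pixels(fluor)
  stopifnot(identical(dim(px), dim(labels)))
  n <- nrow(shapes)
  if (n == 0L) {
    wq_log("no kept objects; empty measurement set")
    return(data.frame(pair_id = character(0), worm_number = integer(0),
                      label = integer(0),
                      condition = character(0), mean_fl = numeric(0),
                      sd_fl = numeric(0), area_px = numeric(0),
                      perimeter_px = numeric(0), worminess = numeric(0),
                      background_fl = numeric(0), mean_fl_bgsub = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(shapes$label)
  shapes <- shapes[ord, , drop = FALSE]
  means <- numeric(n); sds <- numeric(n)
  for (k in seq_len(n)) {
    v <- px[labels == shapes$label[k]]
    if (length(v) == 0L)
      stop("internal consistency error: label ", shapes$label[k],
           " has no pixels")
    means[k] <- mean(v)
    sds[k] <- sqrt(mean((v - means[k])^2))  # population SD
  }
  data.frame(
    pair_id = pair_id,
    worm_number = seq_len(n),
    label = shapes$label,
    condition = condition,
    mean_fl = means,
    sd_fl = sds,
    area_px = shapes$area_px,
    perimeter_px = shapes$perimeter_px,
    worminess = shapes$worminess,
    background_fl = bg$background_fl,
    mean_fl_bgsub = means - bg$background_fl,
    stringsAsFactors = FALSE)
}

#' Min-max scale a set of intensities to \[0,1\]
#'
#' `(v - min) / (max - min)`; used to compare quantifications of the same
#' image made with different methods on a common 0-1 scale.
#'
#' @param values numeric vector, length >= 2 with `max > min`.
#' @return numeric vector in \[0,1\].
#' @export
minmax_scale <- function(values) {
  if (length(values) < 2L) stop("need at least two values to scale")
  r <- range(values)
  if (r[1] == r[2]) stop("cannot min-max scale a constant set of values")
  (values - r[1]) / (r[2] - r[1])
}
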