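# Synthetic ground-truth plates: dark elongated tubes on a bright,
# unevenly lit brightfield background, matched fluorescence images with
# planted per-worm means, round debris (low worminess) and sub-threshold
# specks. Everything is driven by one integer seed, and the generated
# truth lets detection and intensity recovery be scored offline.

#' Specification of a synthetic field of view
#'
#' Defaults describe a typical plate at >= 35x magnification: 20 separated
#' adult worms (~120 px long, ~12 px wide, aspect ratio ~10), two round
#' non-fluorescent debris particles and three sub-threshold specks, on a
#' 16-bit brightfield with a 0.8-1.2x multiplicative illumination ramp and
#' moderate sensor noise.
#'
#' @param image_size c(H, W) in pixels.
#' @param n_worms worms to place (pairwise gap >= 3 px, never touching).
#' @param worm_length,worm_width nominal tube size, px (each jittered
#'   +/-10% per worm).
#' @param curvature maximum bend amplitude as a fraction of length.
#' @param min_gap minimum pairwise separation between planted objects, px
#'   (>= 3). The default (8 px, about two thirds of a worm width) mirrors
#'   worms that have genuinely been pushed apart; separations near the
#'   blur scale would read as touching.
#' @param conditions named numeric vector: condition label -> planted mean
#'   fluorescence; worms are assigned round-robin when several are given.
#' @param worm_mean_jitter per-worm multiplicative jitter of the planted
#'   mean (fraction).
#' @param background_fl planted fluorescence background level.
#' @param noise_sd additive Gaussian noise SD on the fluorescence image.
#' @param illumination_gradient c(lo, hi) multiplicative ramp across the
#'   brightfield.
#' @param n_round_debris,debris_radius round debris count and radius, px.
#' @param debris_fl fluorescence of debris pixels (default 0:
#'   non-fluorescent, darker than the background glow).
#' @param n_specks sub-threshold 2x2 specks.
#' @param bf_level brightfield background intensity before the ramp.
#' @param bf_worm_contrast,bf_debris_contrast multiplicative darkening of
#'   worm / debris pixels in the brightfield.
#' @param bf_noise_sd brightfield additive noise SD.
#' @param mottled add light/dark within-worm texture to the brightfield
#'   (emulates worm transparency; stresses the blur step).
#' @param bit_depth output bit depth (8 or 16).
#' @param seed integer seed; fully determines the plate.
#' @return list of class `plate_spec`.
#' @export
plate_spec <- function(image_size = c(1000L, 1000L),
                       n_worms = 20L,
                       worm_length = 120,
                       worm_width = 12,
                       curvature = 0.2,
                       min_gap = 8,
                       conditions = c(ctrl = 3000),
                       worm_mean_jitter = 0.05,
                       background_fl = 500,
                       noise_sd = 50,
                       illumination_gradient = c(0.8, 1.2),
                       n_round_debris = 2L,
                       debris_radius = 15,
                       debris_fl = 0,
                       n_specks = 3L,
                       bf_level = 40000,
                       bf_worm_contrast = 0.45,
                       bf_debris_contrast = 0.5,
                       bf_noise_sd = 800,
                       mottled = FALSE,
                       bit_depth = 16L,
                       seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 64L),
            worm_length > worm_width, worm_width >= 3,
            curvature >= 0, min_gap >= 3, length(conditions) >= 1L,
            !is.null(names(conditions)),
            noise_sd >= 0, length(illumination_gradient) == 2L)
  structure(mget(names(formals(plate_spec)), environment()),
            class = "plate_spec")
}

# Sinusoidal midline of given arc length: low-order sine bend, uniformly
# scaled so the polyline length equals `target` (the cap-centre to
# cap-centre distance), rotated by theta and shifted to `origin`.
worm_midline <- function(target, amplitude, n_arches, phase, theta = 0,
                         origin = c(0, 0), n_pts = 81L) {
  t <- seq(0, 1, length.out = n_pts)
  x <- t * target
  y <- amplitude * sin(pi * n_arches * t + phase)
  y <- y - mean(y)
  len <- sum(sqrt(diff(x)^2 + diff(y)^2))
  x <- x * (target / len); y <- y * (target / len)
  x <- x - mean(x)
  r <- x * sin(theta) + y * cos(theta)
  c2 <- x * cos(theta) - y * sin(theta)
  cbind(row = r + origin[1], col = c2 + origin[2])
}

# exact squared distance from every pixel centre of a window to the
# midline polyline (point-to-segment, not point-to-vertex, so the tube
# boundary is not thinned by vertex spacing)
midline_dist2 <- function(pts, rows, cols) {
  grid_r <- rep(rows, times = length(cols))
  grid_c <- rep(cols, each = length(rows))
  d2min <- rep(Inf, length(grid_r))
  n <- nrow(pts)
  for (k in seq_len(n - 1L)) {
    vr <- pts[k + 1L, 1] - pts[k, 1]; vc <- pts[k + 1L, 2] - pts[k, 2]
    L2 <- vr * vr + vc * vc
    if (L2 == 0) next
    t <- ((grid_r - pts[k, 1]) * vr + (grid_c - pts[k, 2]) * vc) / L2
    t[t < 0] <- 0; t[t > 1] <- 1
    dr <- grid_r - (pts[k, 1] + t * vr); dc <- grid_c - (pts[k, 2] + t * vc)
    d2 <- dr * dr + dc * dc
    lt <- d2 < d2min
    d2min[lt] <- d2[lt]
  }
  list(row = grid_r, col = grid_c, d2 = d2min)
}

tube_pixels <- function(pts, radius, rows, cols) {
  d <- midline_dist2(pts, rows, cols)
  keep <- d$d2 <= radius^2
  cbind(row = d$row[keep], col = d$col[keep])
}

#' Generate a single synthetic worm mask
#'
#' A filled tube of the given width along a random low-order sinusoidal
#' midline with total tip-to-tip length `length`. For a straight tube the
#' shape is a capsule (stadium), whose continuous worminess is
#' `(2L + pi*w - 2w) / (4 * sqrt(Lw - w^2 + pi*w^2/4))`. If rasterization
#' deviates far from the expected capsule area (a self-intersecting bend),
#' the bend is reduced and the draw retried.
#'
#' @param length tip-to-tip length, px (`length > width`).
#' @param width tube width, px (>= 3).
#' @param curvature bend amplitude as a fraction of length.
#' @param seed integer seed; the same seed reproduces the same mask.
#' @return logical matrix tightly cropped around the worm (1 px margin).
#' @export
generate_worm_mask <- function(length, width, curvature = 0.1, seed = 1L) {
  stopifnot(length > width, width >= 3, curvature >= 0)
  with_seed(seed, {
    n_arches <- sample(1:2, 1L)
    phase <- runif(1, 0, 2 * pi)
    expected <- (length - width) * width + pi * width^2 / 4
    curv <- curvature
    repeat {
      pts <- worm_midline(length - width, curv * length, n_arches, phase)
      lim_r <- range(pts[, 1]); lim_c <- range(pts[, 2])
      pad <- width / 2 + 1
      rows <- seq(floor(lim_r[1] - pad), ceiling(lim_r[2] + pad))
      cols <- seq(floor(lim_c[1] - pad), ceiling(lim_c[2] + pad))
      pix <- tube_pixels(pts, width / 2, rows, cols)
      if (nrow(pix) <= 1.2 * expected || curv < 1e-3) break
      curv <- curv * 0.7
      wq_warn("worm bend self-intersects; retrying with curvature ", round(curv, 3))
    }
    mask <- matrix(FALSE, base::length(rows), base::length(cols))
    mask[cbind(match(pix[, 1], rows), match(pix[, 2], cols))] <- TRUE
    mask
  })
}

#' Suite of worm masks with per-seed size and bend draws
#'
#' Mask `i` is generated with seed `seeds[i]`, width drawn uniformly from
#' `width_range` and curvature from `[0, curvature_max]` under the same
#' seed, so the whole suite is reproducible.
#'
#' @param seeds integer vector of seeds (default 1:50).
#' @param length tip-to-tip length, px.
#' @param width_range c(lo, hi) tube width range, px.
#' @param curvature_max maximum bend fraction.
#' @return list of logical mask matrices.
#' @export
worm_mask_suite <- function(seeds = 1:50, length = 120,
                            width_range = c(10, 15), curvature_max = 0.2) {
  lapply(seeds, function(s) {
    draw <- with_seed(s, c(runif(1, width_range[1], width_range[2]),
                           runif(1, 0, curvature_max)))
    generate_worm_mask(length, draw[1], draw[2], seed = s)
  })
}

#' Generate a synthetic brightfield/fluorescence plate pair
#'
#' Worms are placed with a minimum 3 px pairwise gap (the pipeline assumes
#' non-touching worms). The brightfield is a bright background times a
#' horizontal illumination ramp, with worms, debris and specks rendered
#' darker, plus Gaussian noise. The fluorescence image holds the planted
#' background everywhere, the planted per-worm mean on worm pixels and
#' `debris_fl` on debris, plus noise. Noise fields, worm placement, debris
#' and specks each consume an independent sub-stream of the seed, so e.g.
#' adding debris does not move the worms or change the noise.
#'
#' @param spec a [plate_spec()].
#' @return list with `bf`, `fl` ([worm_image]s) and `truth` (list:
#'   `labels` matrix, `worm_means`, `worm_condition`, `background_fl`,
#'   `debris_mask`, `spec`).
#' @export
generate_plate <- function(spec = plate_spec()) {
  stopifnot(inherits(spec, "plate_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  sub <- with_seed(spec$seed, sample.int(2^31 - 2, 6L))

  labels <- matrix(0L, H, W)
  occupancy <- matrix(FALSE, H, W)
  margin <- ceiling(spec$worm_length / 2) + 4
  worm_widths <- numeric(spec$n_worms)

  with_seed(sub[1], {
    for (i in seq_len(spec$n_worms)) {
      placed <- FALSE
      for (attempt in seq_len(300L)) {
        len <- spec$worm_length * runif(1, 0.9, 1.1)
        wid <- spec$worm_width * runif(1, 0.9, 1.1)
        curv <- runif(1, 0, spec$curvature)
        theta <- runif(1, 0, pi)
        n_arches <- sample(1:2, 1L)
        phase <- runif(1, 0, 2 * pi)
        ctr <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
        pts <- worm_midline(len - wid, curv * len, n_arches, phase,
                            theta, ctr)
        if (min(pts[, 1]) < wid + 4 || max(pts[, 1]) > H - wid - 4 ||
            min(pts[, 2]) < wid + 4 || max(pts[, 2]) > W - wid - 4) next
        pad <- wid / 2 + spec$min_gap + 1
        rows <- max(1, floor(min(pts[, 1]) - pad)):min(H, ceiling(max(pts[, 1]) + pad))
        cols <- max(1, floor(min(pts[, 2]) - pad)):min(W, ceiling(max(pts[, 2]) + pad))
        d <- midline_dist2(pts, rows, cols)
        gap <- d$d2 <= (wid / 2 + spec$min_gap)^2
        gap_pix <- cbind(d$row[gap], d$col[gap])
        if (any(occupancy[gap_pix])) next
        tube <- d$d2 <= (wid / 2)^2
        pix <- cbind(d$row[tube], d$col[tube])
        labels[pix] <- i
        occupancy[pix] <- TRUE
        worm_widths[i] <- wid
        placed <- TRUE
        break
      }
      if (!placed)
        stop("cannot place ", spec$n_worms, " non-touching worms in a ",
             H, "x", W, " field; use fewer or smaller worms")
    }
  })

  # round-robin condition assignment and per-worm planted means
  n_cond <- length(spec$conditions)
  cond_idx <- ((seq_len(spec$n_worms) - 1L) %% n_cond) + 1L
  worm_condition <- names(spec$conditions)[cond_idx]
  worm_means <- with_seed(sub[6], {
    base <- unname(spec$conditions[cond_idx])
    base * (1 + spec$worm_mean_jitter * runif(spec$n_worms, -1, 1))
  })

  disk_pixels <- function(ctr, r) {
    rows <- seq(max(1, floor(ctr[1] - r - 1)), min(H, ceiling(ctr[1] + r + 1)))
    cols <- seq(max(1, floor(ctr[2] - r - 1)), min(W, ceiling(ctr[2] + r + 1)))
    gr <- rep(rows, times = length(cols)); gc <- rep(cols, each = length(rows))
    keep <- (gr - ctr[1])^2 + (gc - ctr[2])^2 <= r^2
    cbind(gr[keep], gc[keep])
  }

  debris_mask <- matrix(FALSE, H, W)
  with_seed(sub[4], {
    for (i in seq_len(spec$n_round_debris)) {
      for (attempt in seq_len(300L)) {
        r <- spec$debris_radius * runif(1, 0.8, 1.2)
        ctr <- c(runif(1, r + 5, H - r - 5), runif(1, r + 5, W - r - 5))
        gap <- disk_pixels(ctr, r + spec$min_gap)
        if (any(occupancy[gap])) next
        pix <- disk_pixels(ctr, r)
        debris_mask[pix] <- TRUE
        occupancy[pix] <- TRUE
        break
      }
    }
  })

  speck_mask <- matrix(FALSE, H, W)
  with_seed(sub[5], {
    for (i in seq_len(spec$n_specks)) {
      for (attempt in seq_len(300L)) {
        ctr <- floor(c(runif(1, 5, H - 6), runif(1, 5, W - 6)))
        rows <- ctr[1] + 0:1; cols <- ctr[2] + 0:1
        box <- as.matrix(expand.grid(ctr[1] + (-3:4), ctr[2] + (-3:4)))
        if (any(occupancy[box])) next
        speck_mask[rows, cols] <- TRUE
        occupancy[rows, cols] <- TRUE
        break
      }
    }
  })

  maxval <- 2^spec$bit_depth - 1
  ramp <- matrix(seq(spec$illumination_gradient[1],
                     spec$illumination_gradient[2], length.out = W),
                 H, W, byrow = TRUE)
  bf <- spec$bf_level * ramp
  worm_sel <- labels > 0L
  bf[worm_sel] <- bf[worm_sel] * spec$bf_worm_contrast
  if (spec$mottled) {
    tex <- with_seed(sub[6] + 1L,
                     gaussian_blur(matrix(runif(H * W), H, W), 3))
    tex <- 1 + 0.8 * (tex - mean(tex)) / max(1e-9, stats::sd(tex)) * 0.45
    bf[worm_sel] <- bf[worm_sel] * pmax(0.15, tex[worm_sel])
  }
  bf[debris_mask] <- spec$bf_level * ramp[debris_mask] * spec$bf_debris_contrast
  bf[speck_mask] <- spec$bf_level * ramp[speck_mask] * spec$bf_worm_contrast
  if (spec$bf_noise_sd > 0)
    bf <- bf + with_seed(sub[2], matrix(rnorm(H * W, 0, spec$bf_noise_sd), H, W))
  bf <- round(pmin(pmax(bf, 0), maxval))

  fl <- matrix(spec$background_fl, H, W)
  if (any(worm_sel)) fl[worm_sel] <- worm_means[labels[worm_sel]]
  fl[debris_mask] <- spec$debris_fl
  if (spec$noise_sd > 0)
    fl <- fl + with_seed(sub[3], matrix(rnorm(H * W, 0, spec$noise_sd), H, W))
  fl <- round(pmin(pmax(fl, 0), maxval))

  attr(labels, "n_objects") <- spec$n_worms
  list(
    bf = worm_image(bf, bit_depth = spec$bit_depth,
                    source_path = "<synthetic brightfield>"),
    fl = worm_image(fl, bit_depth = spec$bit_depth,
                    source_path = "<synthetic fluorescence>"),
    truth = list(labels = labels, worm_means = worm_means,
                 worm_condition = worm_condition,
                 background_fl = spec$background_fl,
                 debris_mask = debris_mask, spec = spec))
}

#' Default increasing-condition suite of synthetic plates
#'
#' One single-condition plate per condition (as on a real slide, where
#' each image holds one treatment), with strictly increasing planted
#' fluorescence means; plate `k` uses seed `seed * 100 + k`.
#'
#' @param seed base integer seed.
#' @param conditions named numeric vector of planted condition means, in
#'   the order they should increase.
#' @param ... further arguments passed to [plate_spec()].
#' @return named list (condition -> output of [generate_plate()]).
#' @export
synthetic_condition_suite <- function(seed = 1L,
                                      conditions = c(c1 = 1200, c2 = 2400,
                                                     c3 = 4000, c4 = 6000),
                                      ...) {
  out <- list()
  for (k in seq_along(conditions)) {
    sp <- plate_spec(conditions = conditions[k],
                     seed = seed * 100L + k, ...)
    out[[names(conditions)[k]]] <- generate_plate(sp)
  }
  out
}

#' Score detections against synthetic ground truth
#'
#' Greedy one-to-one matching of detected objects to true worms by
#' descending intersection-over-union; a match counts when IoU reaches
#' `iou_threshold`. Intensity RMSE compares each matched worm's
#' background-subtracted mean against its planted contrast (planted mean
#' minus planted background).
#'
#' @param detection a `worm_quant` from [run_image()], or an integer label
#'   matrix restricted to kept objects.
#' @param truth truth list from [generate_plate()].
#' @param measurements needed only when `detection` is a bare matrix.
#' @param iou_threshold minimum IoU for a match (default 0.6).
#' @return list: `n_true`, `n_detected`, `iou` (per true worm, best
#'   overlap), `recall`, `precision`, `precision_defined`,
#'   `intensity_rmse`, `matches` (data.frame true_worm/detected_label/iou).
#' @export
evaluate_detection <- function(detection, truth, measurements = NULL,
                               iou_threshold = 0.6) {
  if (inherits(detection, "worm_quant")) {
    measurements <- detection$measurements
    kept_labels <- detection$shapes$label[detection$shapes$filter_status == "kept"]
    det <- detection$labels
    det[!(det %in% kept_labels)] <- 0L
  } else det <- detection
  stopifnot(identical(dim(det), dim(truth$labels)))

  det_ids <- sort(setdiff(unique(as.integer(det)), 0L))
  n_det <- length(det_ids)
  n_true <- max(0L, max(truth$labels))
  det_re <- match(det, c(0L, det_ids)) - 1L  # relabel 1..n_det
  dim(det_re) <- dim(det)

  idx <- which(truth$labels > 0L | det_re > 0L)
  tl <- truth$labels[idx]; dl <- det_re[idx]
  area_t <- tabulate(tl, n_true)
  area_d <- tabulate(dl, n_det)
  both <- tl > 0L & dl > 0L
  pairs <- data.frame(t = integer(0), d = integer(0), inter = integer(0))
  if (any(both)) {
    key <- (tl[both] - 1L) * n_det + dl[both]
    cnt <- tabulate(key, n_true * n_det)
    nz <- which(cnt > 0L)
    pairs <- data.frame(t = ((nz - 1L) %/% n_det) + 1L,
                        d = ((nz - 1L) %% n_det) + 1L,
                        inter = cnt[nz])
  }
  pairs$iou <- if (nrow(pairs))
    pairs$inter / (area_t[pairs$t] + area_d[pairs$d] - pairs$inter) else numeric(0)

  pairs <- pairs[order(-pairs$iou), , drop = FALSE]
  used_t <- logical(n_true); used_d <- logical(max(1L, n_det))
  m_t <- integer(0); m_d <- integer(0); m_iou <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    if (pairs$iou[k] < iou_threshold) break
    t <- pairs$t[k]; d <- pairs$d[k]
    if (used_t[t] || used_d[d]) next
    used_t[t] <- TRUE; used_d[d] <- TRUE
    m_t <- c(m_t, t); m_d <- c(m_d, d); m_iou <- c(m_iou, pairs$iou[k])
  }
  iou_per_true <- numeric(n_true)
  for (k in seq_len(nrow(pairs)))
    iou_per_true[pairs$t[k]] <- max(iou_per_true[pairs$t[k]], pairs$iou[k])

  rmse <- NA_real_
  if (length(m_t) && !is.null(measurements) && nrow(measurements)) {
    det_lab <- det_ids[m_d]
    rows <- match(det_lab, measurements$label)
    ok <- !is.na(rows)
    if (any(ok)) {
      est <- measurements$mean_fl_bgsub[rows[ok]]
      planted <- truth$worm_means[m_t[ok]] - truth$background_fl
      rmse <- sqrt(mean((est - planted)^2))
    }
  }
  list(n_true = n_true, n_detected = n_det,
       iou = iou_per_true,
       recall = if (n_true > 0) length(m_t) / n_true else NA_real_,
       precision = if (n_det > 0) length(m_t) / n_det else 0,
       precision_defined = n_det > 0,
       intensity_rmse = rmse,
       matches = data.frame(true_worm = m_t, detected_label = det_ids[m_d],
                            iou = m_iou))
}

#' Write a ready-to-run synthetic input folder
#'
#' One BF/Fl TIFF pair per condition plus `key.csv` and a `truth.json`
#' summary (per-worm planted means, centroids and areas; synthetic stand-in
#' data, labelled as such in the JSON).
#'
#' @param out_dir destination folder (created if needed).
#' @param seed base seed.
#' @param conditions named numeric vector of planted condition means.
#' @param ... further [plate_spec()] arguments.
#' @return character vector of written paths.
#' @export
write_synthetic_batch <- function(out_dir, seed = 1L,
                                  conditions = c(c1 = 1200, c2 = 2400,
                                                 c3 = 4000, c4 = 6000),
                                  ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  suite <- synthetic_condition_suite(seed = seed, conditions = conditions, ...)
  manifest <- character(0)
  key <- data.frame(filename = character(0), condition = character(0))
  truth_all <- list(description = "synthetic ground truth (generated data)",
                    seed = seed, plates = list())
  for (cond in names(suite)) {
    pl <- suite[[cond]]
    stem <- paste0("plate_", cond)
    bf_path <- file.path(out_dir, paste0(stem, "_BF.tif"))
    fl_path <- file.path(out_dir, paste0(stem, "_Fl.tif"))
    save_image(pl$bf, bf_path); save_image(pl$fl, fl_path)
    manifest <- c(manifest, bf_path, fl_path)
    key <- rbind(key, data.frame(filename = basename(bf_path), condition = cond))
    lab <- pl$truth$labels
    n <- max(lab)
    idx <- which(lab > 0L)
    rows <- ((idx - 1L) %% nrow(lab)) + 1L; colsx <- ((idx - 1L) %/% nrow(lab)) + 1L
    truth_all$plates[[stem]] <- list(
      condition = cond,
      background_fl = pl$truth$background_fl,
      worm_means = pl$truth$worm_means,
      worm_area_px = as.numeric(tabulate(lab[idx], n)),
      centroid_row = as.numeric(tapply(rows, lab[idx], mean)),
      centroid_col = as.numeric(tapply(colsx, lab[idx], mean)))
  }
  key_path <- file.path(out_dir, "key.csv")
  write.csv(key, key_path, row.names = FALSE)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth_all, truth_path, auto_unbox = TRUE, digits = NA)
  c(manifest, key_path, truth_path)
}
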