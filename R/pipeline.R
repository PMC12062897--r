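# The per-image pipeline and the batch driver.

#' Run the full pipeline on one brightfield/fluorescence pair
#'
#' Stage order is fixed: preprocess (contrast, illumination, blur) ->
#' threshold -> clean -> label -> measure shapes -> worminess filter ->
#' size filter -> background from the step-2 mask -> fluorescence
#' measurement -> overlay. The run is deterministic for fixed inputs and
#' configuration.
#'
#' @param bf,fluor [worm_image]s (or a one-row pairing data.frame in `bf`,
#'   see `pair`); dimensions must agree.
#' @param cfg a [worm_config()].
#' @param pair_id,condition provenance strings for the output tables.
#' @return object of class `worm_quant`: list with `measurements`,
#'   `background`, `shapes` (all candidates with `filter_status` in
#'   kept/removed_worminess/removed_size), `overlay`, `step2_mask`,
#'   `labels`, `stages` (executed stage names), `pair_id`, `condition`.
#' @export
run_image <- function(bf, fluor, cfg = worm_config(), pair_id = "image",
                      condition = "") {
  if (is.data.frame(bf)) {
    pair <- bf
    pair_id <- pair$pair_id[1]
    condition <- if (!is.null(pair$condition)) pair$condition[1] else ""
    bf <- load_image(pair$brightfield_path[1], channel = cfg$channel_index)
    fluor <- load_image(pair$fluorescence_path[1], channel = cfg$channel_index)
  }
  if (!identical(dim(as_pixels(bf)), dim(as_pixels(fluor))))
    stop("brightfield/fluorescence dimension mismatch for ", pair_id)
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  note("contrast")
  px <- enhance_contrast(bf, cfg$contrast_low_pct, cfg$contrast_high_pct)
  note("illumination")
  px <- correct_illumination(px, cfg$illum_sigma, cfg$illum_mode)
  note("blur")
  px <- blur_image(px, cfg$blur_sigma)

  note("threshold")
  raw_mask <- threshold_binary(px, polarity = cfg$polarity,
                               method = cfg$threshold_method,
                               value = cfg$threshold_value)
  note("clean")
  step2 <- clean_mask(raw_mask, cfg$max_hole_area, cfg$min_speck_area,
                      cfg$connectivity)
  note("label")
  labels <- label_components(step2, cfg$connectivity)

  note("measure_shapes")
  shapes <- measure_shapes(labels, estimator = cfg$perimeter_estimator)
  if (cfg$exclude_border && nrow(shapes)) {
    dropped <- shapes$touches_border
    if (any(dropped))
      wq_log(pair_id, ": excluding ", sum(dropped), " border object(s)")
    shapes_in <- shapes[!dropped, , drop = FALSE]
  } else shapes_in <- shapes

  note("filter_worminess")
  fw <- filter_worminess(shapes_in, cfg$worminess_lo, cfg$worminess_hi)
  note("filter_size")
  fs <- filter_size(fw$kept, cfg$min_area, cfg$max_area)
  kept <- fs$kept

  status <- rep("kept", nrow(shapes))
  status[shapes$label %in% fw$removed$label] <- "removed_worminess"
  status[shapes$label %in% fs$removed$label] <- "removed_size"
  if (cfg$exclude_border && any(shapes$touches_border))
    status[shapes$touches_border] <- "removed_border"
  shapes$filter_status <- status

  note("background")
  bg <- background_mean(fluor, step2)
  note("measure_fluorescence")
  meas <- measure_fluorescence(fluor, labels, kept, bg,
                               pair_id = pair_id, condition = condition)
  note("overlay")
  kept_ord <- kept[order(kept$label), , drop = FALSE]
  kept_ord$worm_number <- seq_len(nrow(kept_ord))
  style <- overlay_style(alpha = cfg$overlay_alpha,
                         font_scale = cfg$overlay_font_scale)
  overlay <- render_overlay(
    bf, labels, kept_ord, style,
    rejected = if (cfg$debug_overlays)
      shapes[shapes$filter_status != "kept", , drop = FALSE] else NULL)

  structure(list(
    pair_id = pair_id, condition = condition,
    measurements = meas,
    background = c(list(pair_id = pair_id), bg),
    shapes = shapes,
    overlay = overlay,
    step2_mask = step2,
    labels = labels,
    stages = stages,
    config = cfg), class = "worm_quant")
}

#' @export
print.worm_quant <- function(x, ...) {
  tab <- table(factor(x$shapes$filter_status,
                      levels = c("kept", "removed_worminess", "removed_size",
                                 "removed_border")))
  cat(sprintf("<worm_quant> %s: %d worm(s) kept of %d candidate object(s)\n",
              x$pair_id, tab[["kept"]], nrow(x$shapes)))
  cat(sprintf("  removed: %d by worminess, %d by size%s\n",
              tab[["removed_worminess"]], tab[["removed_size"]],
              if (tab[["removed_border"]] > 0)
                sprintf(", %d at border", tab[["removed_border"]]) else ""))
  cat(sprintf("  background: %.2f over %d px\n",
              x$background$background_fl, x$background$n_background_px))
  invisible(x)
}

#' @export
summary.worm_quant <- function(object, ...) {
  m <- object$measurements
  cat(sprintf("Image %s (%s): %d worms\n", object$pair_id,
              if (nzchar(object$condition)) object$condition else "no condition",
              nrow(m)))
  if (nrow(m)) {
    cat(sprintf("  mean_fl_bgsub: min %.1f, median %.1f, max %.1f\n",
                min(m$mean_fl_bgsub), median(m$mean_fl_bgsub),
                max(m$mean_fl_bgsub)))
    cat(sprintf("  worminess: %.2f-%.2f; area: %d-%d px\n",
                min(m$worminess), max(m$worminess),
                as.integer(min(m$area_px)), as.integer(max(m$area_px))))
  }
  invisible(m)
}

#' @export
plot.worm_quant <- function(x, ...) {
  op <- par(mar = c(0, 0, 2, 0)); on.exit(par(op))
  plot.new()
  plot.window(c(0, 1), c(0, 1), asp = dim(x$overlay)[1] / dim(x$overlay)[2])
  rasterImage(x$overlay, 0, 0, 1, 1)
  graphics::title(main = x$pair_id)
  invisible(x)
}

#' Run the batch pipeline over a folder of paired images
#'
#' Pairs channels, joins conditions from the key file, runs [run_image()]
#' per pair (a failing image is logged and skipped, never fatal to the
#' batch), writes combined outputs via [write_outputs()] plus a `run.log`,
#' and reports a summary.
#'
#' @param cfg a [worm_config()] with `input_dir` set, or a named list
#'   accepted by [validate_config()].
#' @return object of class `worm_batch`: `measurements`, `backgrounds`,
#'   `shapes`, `images` (per-image status data.frame), `manifest`,
#'   `n_failed`.
#' @export
run_batch <- function(cfg) {
  if (!inherits(cfg, "worm_config")) cfg <- validate_config(cfg)
  if (is.null(cfg$input_dir)) stop("config error: input_dir is required")
  if (!dir.exists(cfg$input_dir)) stop("input directory not found: ", cfg$input_dir)
  if (is.null(cfg$output_dir))
    cfg$output_dir <- file.path(cfg$input_dir, "wormquant_out")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  .wq_env$logfile <- file.path(cfg$output_dir, "run.log")
  on.exit(.wq_env$logfile <- NULL)

  conditions <- NULL
  if (!is.null(cfg$key_path)) {
    conditions <- read_condition_key(cfg$key_path, cfg$bf_pattern, cfg$fl_pattern)
  } else wq_log("no condition key supplied; condition column left empty")

  pairs <- pair_channels(cfg$input_dir, cfg$bf_pattern, cfg$fl_pattern,
                         conditions)
  if (nrow(pairs) == 0L)
    stop("batch error: no image pairs found in ", cfg$input_dir)

  meas <- list(); bgs <- list(); shp <- list(); overlays <- list()
  status <- character(nrow(pairs)); err <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$pair_id[i]
    res <- tryCatch(run_image(pairs[i, , drop = FALSE], cfg = cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- "failed"; err[i] <- conditionMessage(res)
      wq_warn("image ", pid, " failed: ", err[i])
      next
    }
    status[i] <- "ok"
    wq_log(pid, ": ", nrow(res$measurements), " worm(s) kept of ",
           nrow(res$shapes), " object(s)")
    meas[[pid]] <- res$measurements
    bgs[[pid]] <- as.data.frame(res$background)
    s <- res$shapes; if (nrow(s)) s <- cbind(pair_id = pid, s)
    shp[[pid]] <- s
    overlays[[pid]] <- res$overlay
  }

  measurements <- do.call(rbind, c(meas, list(make.row.names = FALSE)))
  if (is.null(measurements))
    measurements <- measure_fluorescence(matrix(0, 1, 1),
                                         matrix(0L, 1, 1),
                                         data.frame(), list(background_fl = 0))
  backgrounds <- do.call(rbind, c(bgs, list(make.row.names = FALSE)))
  if (is.null(backgrounds))
    backgrounds <- data.frame(pair_id = character(0),
                              background_fl = numeric(0),
                              n_background_px = integer(0))
  shapes <- do.call(rbind, c(Filter(nrow, shp), list(make.row.names = FALSE)))

  manifest <- write_outputs(measurements, backgrounds, cfg$output_dir,
                            overlays = overlays, shapes = shapes)

  n_failed <- sum(status == "failed")
  wq_log("batch done: ", sum(status == "ok"), " image(s) processed, ",
         n_failed, " failed; ", nrow(measurements), " worm(s) measured")
  structure(list(
    measurements = measurements,
    backgrounds = backgrounds,
    shapes = shapes,
    images = data.frame(pair_id = pairs$pair_id, status = status,
                        error = err, stringsAsFactors = FALSE),
    manifest = manifest,
    n_failed = n_failed,
    config = cfg), class = "worm_batch")
}

#' @export
print.worm_batch <- function(x, ...) {
  cat(sprintf("<worm_batch> %d image(s): %d ok, %d failed; %d worm(s) measured\n",
              nrow(x$images), sum(x$images$status == "ok"), x$n_failed,
              nrow(x$measurements)))
  if (!is.null(x$shapes) && nrow(x$shapes)) {
    tab <- table(x$shapes$filter_status)
    cat("  objects:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  outputs:", dirname(x$manifest[1]), "\n")
  invisible(x)
}

#' @export
summary.worm_batch <- function(object, ...) {
  m <- object$measurements
  if (!nrow(m)) { cat("no measurements\n"); return(invisible(m)) }
  agg <- aggregate(mean_fl_bgsub ~ condition, data = m, FUN = mean)
  names(agg)[2] <- "mean_of_mean_fl_bgsub"
  agg$n_worms <- aggregate(mean_fl_bgsub ~ condition, data = m, FUN = length)[, 2]
  print(agg, row.names = FALSE)
  invisible(agg)
}
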