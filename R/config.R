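# Pipeline configuration: every tunable with its documented default.

#' Pipeline configuration
#'
#' Collects every adjustable parameter of the pipeline with its default.
#' The worminess band defaults to the worm range `[1.5, 2.1]`.
#'
#' @param input_dir folder of paired images (required for [run_batch()]).
#' @param output_dir destination folder (default `<input_dir>/wormquant_out`).
#' @param key_path optional condition-key CSV (`filename,condition`).
#' @param bf_pattern,fl_pattern channel-suffix regexes for pairing.
#' @param contrast_low_pct,contrast_high_pct percentile stretch bounds.
#' @param illum_sigma illumination-estimate scale, px (`NULL` = 1/8 of the
#'   shorter image side).
#' @param illum_mode `"divide"` (multiplicative shading) or `"subtract"`.
#' @param blur_sigma slight-blur width, px.
#' @param polarity `"dark"` (worms darker than background) or `"bright"`.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value fixed threshold in \[0,1\] when method is fixed.
#' @param max_hole_area largest filled hole, px^2.
#' @param min_speck_area smallest kept foreground component, px^2.
#' @param connectivity component connectivity, 4 or 8.
#' @param worminess_lo,worminess_hi inclusive worminess band.
#' @param min_area,max_area object size filter, px^2.
#' @param exclude_border drop objects touching the image border.
#' @param channel_index optional channel to take from RGB input (RGB is
#'   otherwise rejected).
#' @param perimeter_estimator `"contour"` or `"crofton"`.
#' @param debug_overlays also tint rejected objects grey on overlays.
#' @param overlay_alpha,overlay_font_scale overlay styling.
#' @param seed integer seed for any stochastic fixture use.
#' @return list of class `worm_config`.
#' @export
worm_config <- function(input_dir = NULL,
                        output_dir = NULL,
                        key_path = NULL,
                        bf_pattern = "_bf$",
                        fl_pattern = "_fl$",
                        contrast_low_pct = 1,
                        contrast_high_pct = 99,
                        illum_sigma = NULL,
                        illum_mode = "divide",
                        blur_sigma = 2,
                        polarity = "dark",
                        threshold_method = "otsu",
                        threshold_value = NULL,
                        max_hole_area = 100,
                        min_speck_area = 20,
                        connectivity = 8,
                        worminess_lo = 1.5,
                        worminess_hi = 2.1,
                        min_area = 100,
                        max_area = Inf,
                        exclude_border = FALSE,
                        channel_index = NULL,
                        perimeter_estimator = "contour",
                        debug_overlays = FALSE,
                        overlay_alpha = 0.5,
                        overlay_font_scale = 2,
                        seed = 1L) {
  cfg <- structure(
    mget(names(formals(worm_config)), environment(), ifnotfound = list(NULL)),
    class = "worm_config")
  check_config(cfg)
  cfg
}

check_config <- function(cfg) {
  with(cfg, {
    stopifnot(contrast_low_pct >= 0, contrast_low_pct < 50,
              contrast_high_pct > 50, contrast_high_pct <= 100,
              contrast_low_pct < contrast_high_pct)
    if (!(worminess_lo > 0 && worminess_lo < worminess_hi))
      stop("config error: worminess_lo must be in (0, worminess_hi)")
    stopifnot(min_area >= 1, blur_sigma >= 0,
              connectivity %in% c(4, 8),
              polarity %in% c("dark", "bright"),
              threshold_method %in% c("otsu", "fixed"),
              illum_mode %in% c("divide", "subtract"),
              perimeter_estimator %in% c("contour", "crofton"))
    if (threshold_method == "fixed" && is.null(threshold_value))
      stop("config error: threshold_method 'fixed' needs threshold_value")
  })
  invisible(cfg)
}

#' Validate a raw configuration mapping
#'
#' Turns a plain named list (e.g. parsed from a YAML file or CLI flags)
#' into a fully-defaulted [worm_config()]. Unknown keys are an error, so
#' typos never silently fall back to defaults; `input_dir` is required.
#'
#' @param raw named list of configuration values.
#' @return a `worm_config`.
#' @export
validate_config <- function(raw = list()) {
  known <- names(formals(worm_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$input_dir))
    stop("config error: input_dir is required")
  cfg <- do.call(worm_config, raw)
  if (is.null(cfg$output_dir))
    cfg$output_dir <- file.path(cfg$input_dir, "wormquant_out")
  cfg
}

#' @export
print.worm_config <- function(x, ...) {
  cat("<worm_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "<auto>" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
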