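# QC overlay rendering and table output.

#' Overlay rendering style
#'
#' @param alpha tint opacity in (0, 1].
#' @param palette ordered vector of >= 8 colours; colours cycle by
#'   worm_number.
#' @param font_scale integer pixel scale of the 3x5 digit glyphs.
#' @param number_color colour of the drawn worm numbers.
#' @return list of class `overlay_style`.
#' @export
overlay_style <- function(alpha = 0.5,
                          palette = c("#E41A1C", "#377EB8", "#4DAF4A",
                                      "#984EA3", "#FF7F00", "#FFFF33",
                                      "#A65628", "#F781BF"),
                          font_scale = 2L, number_color = "#FFFFFF") {
  stopifnot(alpha > 0, alpha <= 1, length(palette) >= 8L, font_scale >= 1L)
  structure(list(alpha = alpha, palette = palette,
                 font_scale = as.integer(font_scale),
                 number_color = number_color),
            class = "overlay_style")
}

# 3x5 digit bitmaps, one string row per scanline.
.digit_font <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "010", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111"))

# stamp an integer onto an RGB array centred at (row, col)
draw_number <- function(rgb, number, row, col, scale, color) {
  digits <- strsplit(as.character(number), "")[[1]]
  gw <- 3L * scale; gh <- 5L * scale; gap <- scale
  total_w <- length(digits) * gw + (length(digits) - 1L) * gap
  r0 <- round(row - gh / 2); c0 <- round(col - total_w / 2)
  colv <- col2rgb(color)[, 1] / 255
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  for (d in seq_along(digits)) {
    glyph <- .digit_font[[digits[d]]]
    for (gr in 1:5) {
      bits <- strsplit(glyph[gr], "")[[1]] == "1"
      for (gc in 1:3) {
        if (!bits[gc]) next
        rr <- r0 + (gr - 1L) * scale + seq_len(scale) - 1L
        cc <- c0 + (d - 1L) * (gw + gap) + (gc - 1L) * scale + seq_len(scale) - 1L
        rr <- rr[rr >= 1 & rr <= nr]; cc <- cc[cc >= 1 & cc <= nc]
        if (length(rr) && length(cc)) for (ch in 1:3) rgb[rr, cc, ch] <- colv[ch]
      }
    }
  }
  rgb
}

#' Render the colour-coded QC overlay
#'
#' The original brightfield is promoted to RGB; each kept object is tinted
#' with its cycling palette colour at the style's opacity and its worm
#' number is stamped at the object centroid. Pixels outside kept objects
#' are the unmodified brightfield. A machine-readable sidecar
#' (worm_number, centroid, colour) is attached as attribute `sidecar` so QC
#' tooling need not read the rendered digits.
#'
#' @param bf [worm_image] or matrix (raw brightfield).
#' @param labels integer label matrix.
#' @param shapes data.frame of kept objects, rows in worm-number order
#'   (column `label` addresses `labels`; `worm_number` optional, defaults
#'   to row order).
#' @param style an [overlay_style()].
#' @param rejected optional data.frame of removed objects to outline in a
#'   reserved grey "rejected" tint (debug aid).
#' @return H x W x 3 numeric array in \[0,1\] with attribute `sidecar`.
#' @export
render_overlay <- function(bf, labels, shapes, style = overlay_style(),
                           rejected = NULL) {
  px <- as_pixels(bf)
  gray <- px / max(1, if (inherits(bf, "worm_image")) 2^bf$bit_depth - 1 else max(px))
  rgb <- array(gray, dim = c(dim(gray), 3L))
  a <- style$alpha
  if (!is.null(rejected) && nrow(rejected)) {
    rejcol <- col2rgb("#666666")[, 1] / 255
    sel <- labels %in% rejected$label
    for (ch in 1:3)
      rgb[, , ch][sel] <- (1 - a) * rgb[, , ch][sel] + a * rejcol[ch]
  }
  n <- nrow(shapes)
  worm_no <- if (!is.null(shapes$worm_number)) shapes$worm_number else seq_len(n)
  colors <- style$palette[((worm_no - 1L) %% length(style$palette)) + 1L]
  if (n > 0L) {
    max_lab <- max(shapes$label)
    row_of <- rep(NA_integer_, max_lab)
    row_of[shapes$label] <- seq_len(n)
    idx <- which(labels > 0L)
    k <- row_of[labels[idx]]
    ok <- !is.na(k)
    idx <- idx[ok]; k <- k[ok]
    colmat <- col2rgb(colors) / 255  # 3 x n
    npx <- prod(dim(labels))
    for (ch in 1:3) {
      at <- idx + (ch - 1L) * npx
      rgb[at] <- (1 - a) * rgb[at] + a * colmat[ch, k]
    }
  }
  for (k in seq_len(n)) {
    rgb <- draw_number(rgb, worm_no[k], shapes$centroid_row[k],
                       shapes$centroid_col[k], style$font_scale,
                       style$number_color)
  }
  attr(rgb, "sidecar") <- data.frame(
    worm_number = worm_no,
    label = shapes$label,
    centroid_row = shapes$centroid_row,
    centroid_col = shapes$centroid_col,
    color = colors,
    stringsAsFactors = FALSE)
  rgb
}

#' Write batch outputs: combined CSVs, overlays and sidecars
#'
#' Writes `measurements.csv` (one row per kept worm, ordered by pair_id
#' then worm_number), `backgrounds.csv` (one row per image), optionally
#' `shapes.csv` (all candidate objects with their filter status), one
#' overlay PNG plus JSON sidecar per image. Writability is checked before
#' anything is written, so a bad output directory never leaves a partial
#' combined CSV.
#'
#' @param measurements data.frame as from [measure_fluorescence()]
#'   (possibly row-bound across images).
#' @param backgrounds data.frame with columns `pair_id`, `background_fl`,
#'   `n_background_px`.
#' @param out_dir output directory (created if missing).
#' @param overlays optional named list (pair_id -> overlay array from
#'   [render_overlay()]).
#' @param shapes optional combined per-object shape table.
#' @return character vector of written paths (the file manifest).
#' @export
write_outputs <- function(measurements, backgrounds, out_dir,
                          overlays = NULL, shapes = NULL) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory not writable: ", out_dir)
  manifest <- character(0)

  ord <- order(measurements$pair_id, measurements$worm_number)
  measurements <- measurements[ord, , drop = FALSE]
  p <- file.path(out_dir, "measurements.csv")
  write.csv(measurements, p, row.names = FALSE)
  manifest <- c(manifest, p)

  backgrounds <- backgrounds[order(backgrounds$pair_id), , drop = FALSE]
  p <- file.path(out_dir, "backgrounds.csv")
  write.csv(backgrounds, p, row.names = FALSE)
  manifest <- c(manifest, p)

  if (!is.null(shapes)) {
    p <- file.path(out_dir, "shapes.csv")
    write.csv(shapes[order(shapes$pair_id, shapes$label), , drop = FALSE],
              p, row.names = FALSE)
    manifest <- c(manifest, p)
  }
  for (pid in names(overlays)) {
    ov <- overlays[[pid]]
    p <- file.path(out_dir, paste0(pid, "_overlay.png"))
    png::writePNG(ov, p)
    manifest <- c(manifest, p)
    sc <- attr(ov, "sidecar")
    if (!is.null(sc)) {
      p2 <- file.path(out_dir, paste0(pid, "_overlay.json"))
      jsonlite::write_json(sc, p2, dataframe = "rows", digits = NA)
      manifest <- c(manifest, p2)
    }
  }
  manifest
}
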