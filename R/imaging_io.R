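#' Single-channel raster image
#'
#' A `worm_image` is a plain intensity matrix plus bit-depth metadata.
#' Pixel values are kept in native integer units (0 .. 2^bit_depth - 1);
#' nothing in the reader rescales intensities.
#'
#' @param pixels numeric matrix of intensities (rows = image rows).
#' @param bit_depth integer, 8 or 16.
#' @param source_path optional provenance string.
#' @return An object of class `worm_image` with fields `pixels`,
#'   `bit_depth`, `source_path`.
#' @export
worm_image <- function(pixels, bit_depth = 16L, source_path = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix (single channel)")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (any(pixels < 0 | pixels > 2^bit_depth - 1, na.rm = TRUE))
    stop("intensities outside [0, 2^bit_depth - 1]")
  structure(
    list(pixels = pixels, bit_depth = bit_depth,
         source_path = source_path),
    class = "worm_image")
}

#' @export
print.worm_image <- function(x, ...) {
  cat(sprintf("<worm_image> %d x %d px, %d-bit, range [%s, %s]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              format(min(x$pixels)), format(max(x$pixels))))
  if (!is.na(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' @export
dim.worm_image <- function(x) dim(x$pixels)

# Accept either a worm_image or a bare matrix in pipeline internals.
as_pixels <- function(img) {
  if (inherits(img, "worm_image")) img$pixels
  else if (is.matrix(img) && is.numeric(img)) img
  else stop("expected a worm_image or a numeric matrix")
}

#' Load a grayscale TIFF or PNG preserving native bit depth
#'
#' Intensities are returned as raw integers on the native scale (a 16-bit
#' TIFF pixel of 40000 stays 40000). Multi-channel input is rejected unless
#' `channel` selects one plane; silent averaging would mix fluorescence
#' channels.
#'
#' @param path file path; format decided by extension (.tif/.tiff/.png).
#' @param channel optional 1-based channel index to extract from RGB input.
#' @return A [worm_image].
#' @export
load_image <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) stop("cannot decode TIFF ", path, ": ",
                                             conditionMessage(e)))
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else if (ext == "png") {
    arr <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("cannot decode PNG ", path, ": ",
                                             conditionMessage(e)))
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else stop("unsupported image format '", ext, "' (TIFF or PNG expected): ", path)
  bits <- if (bits <= 8) 8L else 16L

  if (length(dim(arr)) == 3L) {
    if (is.null(channel))
      stop("multi-channel image and no channel selection configured: ", path)
    if (channel < 1L || channel > dim(arr)[3L])
      stop("channel index ", channel, " out of range for ", path)
    arr <- arr[, , channel]
  }
  # readTIFF/readPNG return [0,1] doubles; recover native integer scale
  px <- matrix(round(as.numeric(arr) * (2^bits - 1)),
               dim(arr)[1], dim(arr)[2])
  worm_image(px, bit_depth = bits, source_path = path)
}

#' Save a raster image
#'
#' TIFF preserves both 8- and 16-bit depths; PNG output is 8-bit.
#'
#' @param img a [worm_image].
#' @param path destination (.tif/.tiff or .png).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "worm_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- img$pixels / (2^img$bit_depth - 1)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = img$bit_depth)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else stop("unsupported output format: ", ext)
  invisible(path)
}

# Strip a channel suffix from a file name to get the pair stem.
pair_stem <- function(fname, pattern) {
  stem <- tools::file_path_sans_ext(basename(fname))
  sub(pattern, "", stem, ignore.case = TRUE)
}

#' Pair brightfield and fluorescence files in a directory
#'
#' Files are matched by shared stem after stripping the channel suffix.
#' Default patterns follow the `*_BF.*` / `*_Fl.*` convention
#' (case-insensitive); both are overridable regexes. Unmatched files are
#' reported with a warning, never silently dropped.
#'
#' @param directory folder containing the images.
#' @param bf_pattern,fl_pattern regexes identifying (and stripped to stem)
#'   the brightfield / fluorescence channel suffix.
#' @param conditions optional named character vector (stem -> condition), as
#'   returned by [read_condition_key()].
#' @return data.frame with columns `pair_id`, `brightfield_path`,
#'   `fluorescence_path`, `condition`, sorted by `pair_id`.
#' @export
pair_channels <- function(directory,
                          bf_pattern = "_bf$",
                          fl_pattern = "_fl$",
                          conditions = NULL) {
  if (!dir.exists(directory)) stop("directory not found: ", directory)
  files <- list.files(directory, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  stems <- tools::file_path_sans_ext(basename(files))
  is_bf <- grepl(bf_pattern, stems, ignore.case = TRUE)
  is_fl <- grepl(fl_pattern, stems, ignore.case = TRUE)

  bf_files <- files[is_bf & !is_fl]
  fl_files <- files[is_fl & !is_bf]
  other <- files[!(is_bf | is_fl) | (is_bf & is_fl)]
  if (length(other))
    wq_warn("files matching neither (or both) channel patterns ignored: ",
            paste(basename(other), collapse = ", "))

  bf_stems <- pair_stem(bf_files, bf_pattern)
  fl_stems <- pair_stem(fl_files, fl_pattern)

  dup_fl <- fl_stems[duplicated(fl_stems)]
  if (length(dup_fl)) {
    bad <- unique(dup_fl)
    stop("ambiguous pairing: multiple fluorescence candidates for stem(s) ",
         paste(bad, collapse = ", "), " [",
         paste(basename(fl_files[fl_stems %in% bad]), collapse = ", "), "]")
  }
  dup_bf <- bf_stems[duplicated(bf_stems)]
  if (length(dup_bf))
    stop("ambiguous pairing: multiple brightfield candidates for stem(s) ",
         paste(unique(dup_bf), collapse = ", "))

  common <- intersect(bf_stems, fl_stems)
  unmatched <- c(setdiff(bf_stems, fl_stems), setdiff(fl_stems, bf_stems))
  if (length(unmatched))
    wq_warn("unmatched channel files for stem(s): ",
            paste(sort(unmatched), collapse = ", "))

  common <- sort(common)
  cond <- rep("", length(common))
  if (!is.null(conditions) && length(common)) {
    hit <- match(common, names(conditions))
    cond <- ifelse(is.na(hit), "", unname(conditions[hit]))
    if (anyNA(hit))
      wq_warn("no condition in key for stem(s): ",
              paste(common[is.na(hit)], collapse = ", "))
  }
  data.frame(
    pair_id = common,
    brightfield_path = bf_files[match(common, bf_stems)],
    fluorescence_path = fl_files[match(common, fl_stems)],
    condition = cond,
    stringsAsFactors = FALSE)
}

#' Read the condition-key table
#'
#' CSV with a header row and columns `filename` and `condition`; the
#' filename column may carry a channel suffix and/or extension, which are
#' stripped to the pair stem.
#'
#' @param path CSV path.
#' @param bf_pattern,fl_pattern channel-suffix regexes stripped when
#'   reducing filenames to stems.
#' @return named character vector: stem -> condition label.
#' @export
read_condition_key <- function(path, bf_pattern = "_bf$", fl_pattern = "_fl$") {
  if (!file.exists(path)) stop("condition key not found: ", path)
  key <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(key) == 0L) return(stats::setNames(character(0), character(0)))
  names(key) <- tolower(names(key))
  if (!all(c("filename", "condition") %in% names(key)))
    stop("condition key needs 'filename' and 'condition' columns: ", path)
  stems <- tools::file_path_sans_ext(basename(key$filename))
  stems <- sub(bf_pattern, "", stems, ignore.case = TRUE)
  stems <- sub(fl_pattern, "", stems, ignore.case = TRUE)
  cond <- as.character(key$condition)
  agg <- tapply(cond, stems, function(v) unique(v), simplify = FALSE)
  bad <- names(agg)[vapply(agg, length, 1L) > 1L]
  if (length(bad))
    stop("conflicting conditions in key for stem(s): ",
         paste(bad, collapse = ", "))
  stats::setNames(vapply(agg, `[[`, "", 1L), names(agg))
}
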