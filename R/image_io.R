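#' Marker codes for Live/Dead stained frames
#'
#' Each confocal frame carries exactly one fluorescence marker: SYTO9 stains
#' viable cells green, propidium iodide (PI) stains membrane-compromised
#' (non-viable) cells red. Marker strings are matched case-insensitively;
#' `"green"`, `"syto9"` and `"green_syto9"` map to `GREEN_SYTO9`, and
#' `"red"`, `"pi"` and `"red_pi"` map to `RED_PI`.
#'
#' @param x character vector of marker labels.
#' @return character vector with elements `"GREEN_SYTO9"` or `"RED_PI"`.
#' @examples
#' parse_marker(c("green", "RED", "Green_SYTO9"))
#' @export
parse_marker <- function(x) {
  key <- tolower(trimws(as.character(x)))
  map <- c(
    green = "GREEN_SYTO9", syto9 = "GREEN_SYTO9", green_syto9 = "GREEN_SYTO9",
    red = "RED_PI", pi = "RED_PI", red_pi = "RED_PI"
  )
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown marker label(s): ", paste(sQuote(bad), collapse = ", "),
         " (expected GREEN_SYTO9 or RED_PI, case-insensitive)", call. = FALSE)
  }
  out
}

#' Construct a confocal image object
#'
#' A `confocal_image` is one 8-bit RGB frame carrying a single Live/Dead
#' marker, together with its sample metadata. Pixel intensities are stored as
#' integers on the native 0--255 scale: the downstream brightness histogram is
#' defined on 8-bit levels, so no rescaling is ever applied.
#'
#' @param pixels integer array `H x W x 3` with values in `[0, 255]`
#'   (red, green, blue planes).
#' @param sample_id short sample key (e.g. `"CNT"`, `"TCS"`).
#' @param time_h exposure time in hours (non-negative).
#' @param marker marker label, see [parse_marker()].
#' @param source_path optional path the frame was read from.
#' @return an object of class `confocal_image`.
#' @export
confocal_image <- function(pixels, sample_id, time_h, marker,
                           source_path = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel intensities must be integers in [0, 255]", call. = FALSE)
  if (!is.numeric(time_h) || length(time_h) != 1L || is.na(time_h) || time_h < 0)
    stop("'time_h' must be a single non-negative number", call. = FALSE)
  structure(
    list(
      pixels = pixels,
      sample_id = as.character(sample_id),
      time_h = as.numeric(time_h),
      marker = parse_marker(marker),
      source_path = as.character(source_path)
    ),
    class = "confocal_image"
  )
}

#' @export
print.confocal_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("confocal_image: %d x %d, sample %s @ %g h, marker %s\n",
              d[1], d[2], x$sample_id, x$time_h, x$marker))
  invisible(x)
}

# Decode a raster file to an H x W x {1,2,3,4} double array in [0,1] plus its
# stored bit depth. Only lossless containers are accepted: JPEG artifacts
# perturb the zero-brightness count that anchors the histogram normalization.
read_raster <- function(path) {
  if (!file.exists(path))
    stop("cannot read image ", sQuote(path), ": file does not exist",
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) stop("cannot read image ", sQuote(path),
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
    depth <- attr(arr, "bits.per.sample")
  } else if (ext == "png") {
    arr <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("cannot read image ", sQuote(path),
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
    depth <- attr(arr, "info")$bit.depth
  } else {
    stop("unsupported image format ", sQuote(ext), " for ", sQuote(path),
         ": only lossless 8-bit RGB TIFF or PNG are accepted", call. = FALSE)
  }
  if (is.null(depth)) depth <- NA_integer_
  list(values = arr, depth = as.integer(depth[1]))
}

#' Read one confocal frame from disk
#'
#' Reads an 8-bit RGB TIFF or PNG exactly as stored: no rescaling, no gamma.
#' Non-8-bit files raise an explicit unsupported-depth error rather than being
#' silently converted, because the brightness histogram is defined on the
#' native 0--255 levels. An RGBA alpha plane is discarded with a warning.
#'
#' @inheritParams confocal_image
#' @param path path to a TIFF or PNG file.
#' @return a [confocal_image()].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(0, c(2, 2, 3)), f)
#' img <- read_confocal(f, "CNT", 24, "green")
#' range(img$pixels)
#' @export
read_confocal <- function(path, sample_id, time_h, marker) {
  ras <- read_raster(path)
  if (!is.na(ras$depth) && ras$depth != 8L)
    stop("unsupported bit depth (", ras$depth, ") in ", sQuote(path),
         ": only 8-bit images are supported, no silent conversion is applied",
         call. = FALSE)
  arr <- ras$values
  if (length(dim(arr)) == 2L)
    stop("image ", sQuote(path), " is single-plane (grayscale); ",
         "an RGB frame with the marker in its colour plane is required",
         call. = FALSE)
  if (dim(arr)[3] == 4L) {
    warning("discarding alpha plane of RGBA image ", sQuote(path),
            call. = FALSE)
    arr <- arr[, , 1:3, drop = FALSE]
  }
  if (dim(arr)[3] != 3L)
    stop("image ", sQuote(path), " has ", dim(arr)[3],
         " planes; expected RGB", call. = FALSE)
  px <- array(as.integer(round(arr * 255)), dim(arr))  # drop decoder attrs
  confocal_image(px, sample_id, time_h, marker, source_path = path)
}

#' Write a confocal frame to disk
#'
#' Lossless 8-bit output; a written-then-read frame is pixel-identical to the
#' original. Format is chosen from the file extension (`.tif`/`.tiff`/`.png`).
#'
#' @param image a [confocal_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confocal <- function(image, path) {
  stopifnot(inherits(image, "confocal_image"))
  ext <- tolower(tools::file_ext(path))
  arr <- image$pixels / 255
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L, compression = "none")
  } else if (ext == "png") {
    png::writePNG(arr, path)
  } else {
    stop("unsupported output format ", sQuote(ext),
         ": use .tif, .tiff or .png", call. = FALSE)
  }
  invisible(path)
}

#' Read and validate a sample manifest
#'
#' The manifest is a CSV with header `sample_id,time_h,marker,path` listing
#' every frame of the dataset. Frames are grouped by
#' `(sample_id, time_h, marker)`; each group must contain 1--4 images,
#' mirroring how stained-sample datasets are assembled (one to four frames
#' per stained sample per marker). Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path path to the manifest CSV.
#' @param check_paths if `TRUE` (default) every listed file must exist.
#' @return a `data.frame` of class `sample_manifest` with columns
#'   `sample_id`, `time_h`, `marker`, `path`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path))
    stop("manifest ", sQuote(path), " does not exist", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_h", "marker", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  df <- df[, need]
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  as_sample_manifest(df, check_paths = check_paths)
}

#' Validate a manifest data frame
#'
#' @param df data.frame with columns `sample_id`, `time_h`, `marker`, `path`.
#' @inheritParams read_manifest
#' @return the validated `sample_manifest`.
#' @export
as_sample_manifest <- function(df, check_paths = TRUE) {
  df$sample_id <- as.character(df$sample_id)
  df$time_h <- as.numeric(df$time_h)
  if (anyNA(df$time_h) || any(df$time_h < 0))
    stop("manifest 'time_h' must be non-negative numbers", call. = FALSE)
  df$marker <- parse_marker(df$marker)
  sizes <- stats::aggregate(list(n = seq_len(nrow(df))),
                            by = df[c("sample_id", "time_h", "marker")],
                            FUN = length)
  bad <- sizes[sizes$n < 1L | sizes$n > 4L, , drop = FALSE]
  if (nrow(bad) > 0L) {
    key <- sprintf("(%s, %g h, %s): %d images",
                   bad$sample_id, bad$time_h, bad$marker, bad$n)
    stop("each (sample_id, time_h, marker) group must hold 1-4 images; ",
         "offending group(s): ", paste(key, collapse = "; "), call. = FALSE)
  }
  if (check_paths) {
    miss <- !file.exists(df$path)
    if (any(miss))
      stop("manifest lists missing file(s): ",
           paste(sQuote(utils::head(df$path[miss], 5)), collapse = ", "),
           call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Check that the declared marker matches the dominant colour plane
#'
#' Advisory consistency check: warns when the declared marker's colour plane
#' carries less total intensity than the opposite plane (e.g. a frame declared
#' GREEN_SYTO9 whose red plane is brighter overall). The marker is always
#' taken from the manifest, never inferred from pixels.
#'
#' @param image a [confocal_image()].
#' @return `TRUE` (consistent) or `FALSE` (warned), invisibly.
#' @export
check_marker_consistency <- function(image) {
  stopifnot(inherits(image, "confocal_image"))
  red <- sum(as.numeric(image$pixels[, , 1]))
  green <- sum(as.numeric(image$pixels[, , 2]))
  declared <- if (image$marker == "GREEN_SYTO9") green else red
  other <- if (image$marker == "GREEN_SYTO9") red else green
  ok <- declared >= other
  if (!ok)
    warning(sprintf(
      "frame %s (sample %s, %g h) declared %s but the opposite colour plane has higher total intensity",
      image$source_path, image$sample_id, image$time_h, image$marker),
      call. = FALSE)
  invisible(ok)
}
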