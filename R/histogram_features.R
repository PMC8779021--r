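#' Dark-normalized brightness histogram of the V channel
#'
#' Counts the occurrence of each of the 256 brightness levels of the V plane
#' and divides every count by the number of zero-brightness (dark) pixels.
#' Confocal frames of clustered bacteria are mostly dark background, so the
#' dark-pixel count acts as a per-frame exposure/density normalizer: frames
#' of different bacterial density become directly comparable, and tiling a
#' frame with itself leaves every normalized entry unchanged.
#'
#' A frame with no zero-brightness pixel has no normalization anchor and is
#' rejected with an error rather than silently patched: such a frame does not
#' conform to the expected image character (large dark areas between
#' clusters).
#'
#' @param hsv an `hsv_image` from [rgb_to_hsv_image()].
#' @return an object of class `brightness_histogram`: list with `counts`
#'   (integer, length 256, `counts[v + 1]` = number of pixels at level `v`),
#'   `zero_count`, `normalized` (`counts / zero_count`), `n_pixels`, and the
#'   frame metadata.
#' @examples
#' px <- array(0L, c(4, 4, 3))
#' px[1, 1:4, 2] <- 200L
#' h <- brightness_histogram(rgb_to_hsv_image(confocal_image(px, "CNT", 24, "green")))
#' h$zero_count; h$normalized[201]
#' @export
brightness_histogram <- function(hsv) {
  stopifnot(inherits(hsv, "hsv_image"))
  counts <- tabulate(as.integer(hsv$v) + 1L, nbins = 256L)
  zero <- counts[1]
  if (zero == 0L)
    stop("zero-brightness normalization undefined: frame ",
         sQuote(hsv$source_path), " has no dark (V = 0) pixel; ",
         "confocal frames are expected to contain dark background",
         call. = FALSE)
  structure(
    list(counts = counts, zero_count = zero, normalized = counts / zero,
         n_pixels = length(hsv$v),
         sample_id = hsv$sample_id, time_h = hsv$time_h,
         marker = hsv$marker, source_path = hsv$source_path),
    class = "brightness_histogram"
  )
}

#' Bin layout over the nonzero brightness levels
#'
#' The 255 nonzero levels `V = 1..255` are partitioned into `n_bins`
#' contiguous bins of as-equal-as-possible width using floor-based edges:
#' bin `b` (0-based) covers `V` in
#' `[1 + floor(255 b / n_bins), 1 + floor(255 (b + 1) / n_bins) - 1]`.
#' Level `V = 0` is never binned: it is the normalizer, not signal.
#'
#' @param n_bins number of bins, in `[1, 255]`.
#' @return data.frame with columns `bin` (1-based), `v_lo`, `v_hi`.
#' @examples
#' head(brightness_bins(127))
#' @export
brightness_bins <- function(n_bins = 127L) {
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 1L || n_bins > 255L)
    stop("'n_bins' must be a single integer in [1, 255]", call. = FALSE)
  b <- 0:(n_bins - 1L)
  data.frame(
    bin = b + 1L,
    v_lo = 1L + as.integer(floor(255 * b / n_bins)),
    v_hi = 1L + as.integer(floor(255 * (b + 1L) / n_bins)) - 1L
  )
}

#' Extract the per-frame viability feature from a brightness histogram
#'
#' Two feature definitions are supported, both computed on the dark-normalized
#' histogram with the `V = 0` level excluded:
#'
#' * `"max_binned"` (default, `n_bins = 127`): the nonzero levels are grouped
#'   into `n_bins` contiguous bins (see [brightness_bins()]); each bin's
#'   content is the sum of the normalized entries it covers; the feature is
#'   the maximum bin content. Ties are immaterial: only the value is used.
#' * `"sum_all"`: the sum of all normalized entries over `V = 1..255`.
#'
#' `max_binned` with `n_bins = 1` equals `sum_all`; with `n_bins = 255` it is
#' the largest single normalized entry. The two definitions rank samples very
#' similarly in practice, so the binned maximum is a robustness default rather
#' than a sensitive tuning knob.
#'
#' @param hist a [brightness_histogram()].
#' @param method `"max_binned"` or `"sum_all"` (case-insensitive).
#' @param n_bins number of bins for `"max_binned"`, in `[1, 255]`.
#' @return an object of class `viability_feature`: list with `value`,
#'   `method`, `n_bins` (`NA` for `sum_all`), and the frame metadata.
#' @examples
#' px <- array(0L, c(4, 4, 3)); px[1, 1:4, 2] <- 200L
#' h <- brightness_histogram(rgb_to_hsv_image(confocal_image(px, "S", 0, "green")))
#' extract_feature(h)$value          # 4/12
#' extract_feature(h, "sum_all")$value
#' @export
extract_feature <- function(hist, method = c("max_binned", "sum_all"),
                            n_bins = 127L) {
  stopifnot(inherits(hist, "brightness_histogram"))
  method <- match.arg(tolower(method[1]), c("max_binned", "sum_all"))
  if (method == "max_binned") {
    bins <- brightness_bins(n_bins)
    content <- vapply(seq_len(nrow(bins)), function(i) {
      sum(hist$normalized[(bins$v_lo[i]:bins$v_hi[i]) + 1L])
    }, numeric(1))
    value <- max(content)
    nb <- as.integer(n_bins)
  } else {
    value <- sum(hist$normalized[2:256])
    nb <- NA_integer_
  }
  structure(
    list(value = value, method = method, n_bins = nb,
         sample_id = hist$sample_id, time_h = hist$time_h,
         marker = hist$marker, source_path = hist$source_path),
    class = "viability_feature"
  )
}

#' Dump a brightness histogram to CSV
#'
#' Writes one row per brightness level `v = 0..255` with columns
#' `v,count,normalized`. By convention `normalized[v] = count[v] /
#' count[0]`, so the `v = 0` row always has `normalized = 1`.
#'
#' @param hist a [brightness_histogram()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "brightness_histogram"))
  df <- data.frame(v = 0:255, count = hist$counts,
                   normalized = hist$normalized)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
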