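#' Advisory frame quality score (brightness x focus)
#'
#' Operationalizes "brightest and best focus" frame selection as a
#' deterministic score: the mean V brightness (scaled to `[0, 1]`) multiplied
#' by the Tenengrad gradient energy (mean squared Sobel gradient magnitude of
#' `V / 255`). All-dark frames and perfectly flat frames score 0; blurring a
#' frame lowers its score. The score is advisory only -- it ranks candidate
#' frames for reporting or when more than four are available; frames listed
#' in a manifest are never silently dropped.
#'
#' @param hsv an `hsv_image` from [rgb_to_hsv_image()].
#' @return a single non-negative number.
#' @export
quality_score <- function(hsv) {
  stopifnot(inherits(hsv, "hsv_image"))
  v <- hsv$v / 255
  mv <- mean(v)
  if (nrow(v) < 3L || ncol(v) < 3L) return(0)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  conv3 <- function(m, k) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0, nr - 2L, nc - 2L)
    for (i in 1:3) for (j in 1:3)
      out <- out + k[i, j] * m[i:(nr - 3L + i), j:(nc - 3L + j)]
    out
  }
  gx <- conv3(v, kx)
  gy <- conv3(v, t(kx))
  mv * mean(gx^2 + gy^2)
}

#' Per-sample viable/non-viable ratio from per-frame features
#'
#' Aggregates the 1--4 green-frame (SYTO9) features and the 1--4 red-frame
#' (PI) features of one stained sample by arithmetic mean, and returns their
#' quotient. Green and red frames are unpaired captures of the same stained
#' sample, so the ratio is formed between aggregated marker features, not
#' averaged over frame pairs. Higher ratios indicate a healthier population.
#'
#' @param green_feats,red_feats lists of [extract_feature()] results (a single
#'   `viability_feature` is also accepted), 1--4 per marker, all computed with
#'   the same method and bin count.
#' @return an object of class `viability_ratio`: list with `sample_id`,
#'   `time_h`, `green_feature`, `red_feature`, `ratio`, `n_green`, `n_red`.
#' @examples
#' px <- array(0L, c(4, 4, 3)); px[1, 1:2, 2] <- 180L
#' f <- extract_feature(brightness_histogram(rgb_to_hsv_image(
#'   confocal_image(px, "CNT", 24, "green"))))
#' px2 <- px[, , c(2, 1, 3)]  # same pattern painted red
#' g <- extract_feature(brightness_histogram(rgb_to_hsv_image(
#'   confocal_image(px2, "CNT", 24, "red"))))
#' sample_ratio(list(f), list(g))$ratio  # 1: identical brightness pattern
#' @export
sample_ratio <- function(green_feats, red_feats) {
  as_feat_list <- function(x, side) {
    if (inherits(x, "viability_feature")) x <- list(x)
    if (!is.list(x) || !all(vapply(x, inherits, logical(1), "viability_feature")))
      stop("'", side, "' must be a list of viability_feature objects",
           call. = FALSE)
    if (length(x) < 1L || length(x) > 4L)
      stop("1-4 features per marker are required (got ", length(x),
           " for ", side, ")", call. = FALSE)
    x
  }
  green_feats <- as_feat_list(green_feats, "green_feats")
  red_feats <- as_feat_list(red_feats, "red_feats")
  all_feats <- c(green_feats, red_feats)
  meth <- unique(vapply(all_feats, `[[`, character(1), "method"))
  nb <- unique(vapply(all_feats, `[[`, integer(1), "n_bins"))
  if (length(meth) != 1L || length(nb) != 1L)
    stop("all features must share one method and bin count", call. = FALSE)
  sid <- unique(vapply(all_feats, `[[`, character(1), "sample_id"))
  th <- unique(vapply(all_feats, `[[`, numeric(1), "time_h"))
  if (length(sid) != 1L || length(th) != 1L)
    stop("all features must come from one (sample_id, time_h)", call. = FALSE)
  gf <- mean(vapply(green_feats, `[[`, numeric(1), "value"))
  rf <- mean(vapply(red_feats, `[[`, numeric(1), "value"))
  if (rf == 0)
    stop("undefined viable/non-viable ratio for (", sid, ", ", th,
         " h): no detectable dead-cell signal (red feature is 0)",
         call. = FALSE)
  structure(
    list(sample_id = sid, time_h = th,
         green_feature = gf, red_feature = rf, ratio = gf / rf,
         n_green = length(green_feats), n_red = length(red_feats),
         method = meth, n_bins = nb),
    class = "viability_ratio"
  )
}

#' @export
print.viability_ratio <- function(x, ...) {
  cat(sprintf("viability_ratio: %s @ %g h: %.4g (green %.4g / red %.4g)\n",
              x$sample_id, x$time_h, x$ratio, x$green_feature, x$red_feature))
  invisible(x)
}

#' @export
as.data.frame.viability_ratio <- function(x, ...) {
  data.frame(sample_id = x$sample_id, time_h = x$time_h,
             n_green = x$n_green, n_red = x$n_red,
             green_feature = x$green_feature, red_feature = x$red_feature,
             ratio = x$ratio, stringsAsFactors = FALSE)
}

#' Long-form table of ratios over the sample x time grid
#'
#' Arranges per-sample ratios on the full `sample_id x time_h` grid, the
#' data behind a radial (polar) chart of viable/non-viable proportion per
#' reactor over exposure time. Missing grid cells are emitted as explicit
#' `NA`s; duplicate `(sample_id, time_h)` entries are an error.
#'
#' @param ratios a data.frame with columns `sample_id`, `time_h`, `ratio`
#'   (e.g. the `ratios` element of [quantify_manifest()]), or a list of
#'   [sample_ratio()] results.
#' @return data.frame with columns `sample_id`, `time_h`, `ratio` covering
#'   the full grid, ordered by sample then time.
#' @export
radial_chart_table <- function(ratios) {
  if (is.list(ratios) && !is.data.frame(ratios))
    ratios <- do.call(rbind, lapply(ratios, as.data.frame))
  stopifnot(all(c("sample_id", "time_h", "ratio") %in% names(ratios)))
  key <- paste(ratios$sample_id, ratios$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    d <- ratios[duplicated(key), c("sample_id", "time_h"), drop = FALSE]
    stop("duplicate (sample_id, time_h) entries: ",
         paste(sprintf("(%s, %g h)", d$sample_id, d$time_h), collapse = ", "),
         call. = FALSE)
  }
  grid <- expand.grid(time_h = sort(unique(ratios$time_h)),
                      sample_id = unique(ratios$sample_id),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("sample_id", "time_h")]
  idx <- match(paste(grid$sample_id, grid$time_h, sep = "\r"), key)
  grid$ratio <- ratios$ratio[idx]
  rownames(grid) <- NULL
  grid
}

#' Radial chart of viable/non-viable ratios
#'
#' Polar rendering of [radial_chart_table()]: one angular sector per sample,
#' one coloured trace per exposure time. Requires ggplot2.
#'
#' @param tbl output of [radial_chart_table()].
#' @return a ggplot object.
#' @export
plot_radial_ratios <- function(tbl) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_radial_ratios() requires the ggplot2 package", call. = FALSE)
  tbl$time <- factor(tbl$time_h)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$sample_id, y = .data$ratio,
                                    group = .data$time, colour = .data$time)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "viable / non-viable ratio",
                  colour = "time (h)") +
    ggplot2::theme_minimal()
}
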