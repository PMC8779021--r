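#' Convert an RGB confocal frame to HSV
#'
#' Standard hexcone conversion. The brightness plane is the per-pixel channel
#' maximum, `V = max(R, G, B)`, kept as integers on the 8-bit 0--255 scale:
#' this is what makes green (SYTO9) and red (PI) frames directly comparable,
#' because V is invariant under any permutation of the colour planes, unlike
#' perceptual luma, under which a red object appears dimmer than a green one
#' of equal brightness. Only V is consumed downstream; hue (degrees in
#' `[0, 360)`) and saturation (in `[0, 1]`, with `S = 0` where `V = 0`) are
#' exposed for diagnostics.
#'
#' @param image a [confocal_image()].
#' @return an object of class `hsv_image`: list with matrices `h`, `s`,
#'   integer matrix `v`, and the source metadata (`sample_id`, `time_h`,
#'   `marker`, `source_path`).
#' @examples
#' px <- array(0L, c(2, 2, 3))
#' px[1, 1, 2] <- 200L  # one pure-green pixel
#' hsv <- rgb_to_hsv_image(confocal_image(px, "CNT", 24, "green"))
#' hsv$v
#' @export
rgb_to_hsv_image <- function(image) {
  stopifnot(inherits(image, "confocal_image"))
  d2 <- dim(image$pixels)[1:2]
  r <- image$pixels[, , 1]; dim(r) <- d2
  g <- image$pixels[, , 2]; dim(g) <- d2
  b <- image$pixels[, , 3]; dim(b) <- d2
  v <- pmax(r, g, b)
  m <- pmin(r, g, b)
  ch <- v - m
  rr <- r; gg <- g; bb <- b; chn <- ch # numeric copies for division
  storage.mode(rr) <- storage.mode(gg) <- storage.mode(bb) <- "double"
  storage.mode(chn) <- "double"
  h <- ifelse(ch == 0L, 0,
       ifelse(v == r, ((gg - bb) / chn) %% 6,
       ifelse(v == g, (bb - rr) / chn + 2,
                      (rr - gg) / chn + 4))) * 60
  s <- ifelse(v == 0L, 0, chn / ifelse(v == 0L, 1, v))
  storage.mode(v) <- "integer"
  structure(
    list(h = h, s = s, v = v,
         sample_id = image$sample_id, time_h = image$time_h,
         marker = image$marker, source_path = image$source_path),
    class = "hsv_image"
  )
}

#' @export
print.hsv_image <- function(x, ...) {
  cat(sprintf("hsv_image: %d x %d, sample %s @ %g h, marker %s, V in [%d, %d]\n",
              nrow(x$v), ncol(x$v), x$sample_id, x$time_h, x$marker,
              min(x$v), max(x$v)))
  invisible(x)
}
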