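# Run code under a temporary RNG state so simulation is reproducible from a
# seed without trampling the caller's random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Parameterize a synthetic Live/Dead image pair
#'
#' Defines the full, seeded parameterization of one simulated stained sample:
#' a green (SYTO9/live) frame and a red (PI/dead) frame with known ground
#' truth. Cells follow a Thomas-type cluster process -- cluster centers drawn
#' uniformly over the frame, cells assigned to clusters multinomially and
#' offset isotropically -- and each cell is rendered as an additive Gaussian
#' spot whose peak is drawn from a normal distribution clipped to `[1, 255]`.
#' This reproduces the character of real confocal frames: sparse bright
#' clustered spots on a predominantly dark background.
#'
#' @param width,height frame size in pixels (native confocal frames are
#'   1024 x 1024).
#' @param n_live,n_dead ground-truth cell counts for the green and red frame.
#' @param n_clusters number of cluster centers per frame.
#' @param cluster_spread standard deviation (px) of cell offsets around their
#'   cluster center.
#' @param spot_sigma Gaussian spot width (px) per cell.
#' @param peak_mean,peak_sd peak-brightness distribution on the 0--255 scale;
#'   draws are clipped to `[1, 255]`.
#' @param background_level constant background added to every plane (8-bit
#'   scale; default 0, matching dark confocal background).
#' @param noise_sd standard deviation of additive Gaussian noise (8-bit
#'   scale) applied to every plane of both frames; default 0.
#' @param seed integer seed; the pair is bit-reproducible from it.
#' @return an object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(width = 1024L, height = 1024L,
                           n_live = 200L, n_dead = 200L,
                           n_clusters = 25L, cluster_spread = 15,
                           spot_sigma = 2.5, peak_mean = 180, peak_sd = 40,
                           background_level = 0, noise_sd = 0, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_live = as.integer(n_live), n_dead = as.integer(n_dead),
               n_clusters = as.integer(n_clusters),
               cluster_spread = as.numeric(cluster_spread),
               spot_sigma = as.numeric(spot_sigma),
               peak_mean = as.numeric(peak_mean),
               peak_sd = as.numeric(peak_sd),
               background_level = as.numeric(background_level),
               noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (spec$width < 1L || spec$height < 1L)
    stop("frame size must be at least 1 x 1", call. = FALSE)
  if (spec$n_live < 0L || spec$n_dead < 0L)
    stop("cell counts must be non-negative", call. = FALSE)
  if (spec$n_clusters < 1L)
    stop("'n_clusters' must be positive", call. = FALSE)
  if (spec$spot_sigma <= 0)
    stop("'spot_sigma' must be positive", call. = FALSE)
  if (spec$noise_sd < 0 || spec$cluster_spread < 0 || spec$peak_sd < 0)
    stop("'noise_sd', 'cluster_spread' and 'peak_sd' must be non-negative",
         call. = FALSE)
  if (spec$background_level < 0 || spec$background_level > 255)
    stop("'background_level' must be on the 8-bit scale [0, 255]",
         call. = FALSE)
  class(spec) <- "synthetic_spec"
  spec
}

# Additive Gaussian-spot rendering on a float canvas; each cell contributes
# over a +/- 4 sigma window, clipped at the frame edges.
render_spots <- function(width, height, x, y, peak, sigma) {
  img <- matrix(0, nrow = height, ncol = width)
  r <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    xs <- max(1L, floor(x[i]) - r):min(width, ceiling(x[i]) + r)
    ys <- max(1L, floor(y[i]) - r):min(height, ceiling(y[i]) + r)
    if (xs[1] > width || ys[1] > height || xs[length(xs)] < 1L ||
        ys[length(ys)] < 1L) next
    gx <- exp(-(xs - x[i])^2 / (2 * sigma^2))
    gy <- exp(-(ys - y[i])^2 / (2 * sigma^2))
    img[ys, xs] <- img[ys, xs] + peak[i] * outer(gy, gx)
  }
  img
}

# One marker scene: cluster centers, multinomial cluster assignment,
# Gaussian offsets, clipped-normal peaks. Returns the float signal canvas
# and the planted cell coordinates.
draw_scene <- function(spec, n_cells) {
  cx <- stats::runif(spec$n_clusters, 1, spec$width)
  cy <- stats::runif(spec$n_clusters, 1, spec$height)
  if (n_cells == 0L)
    return(list(signal = matrix(0, spec$height, spec$width),
                x = numeric(0), y = numeric(0)))
  cl <- sample.int(spec$n_clusters, n_cells, replace = TRUE)
  x <- cx[cl] + stats::rnorm(n_cells, 0, spec$cluster_spread)
  y <- cy[cl] + stats::rnorm(n_cells, 0, spec$cluster_spread)
  peak <- pmin(255, pmax(1, stats::rnorm(n_cells, spec$peak_mean,
                                         spec$peak_sd)))
  list(signal = render_spots(spec$width, spec$height, x, y, peak,
                             spec$spot_sigma),
       x = x, y = y)
}

quantize_plane <- function(signal, spec) {
  plane <- signal + spec$background_level
  if (spec$noise_sd > 0)
    plane <- plane + matrix(stats::rnorm(length(plane), 0, spec$noise_sd),
                            nrow(plane), ncol(plane))
  p <- as.integer(round(pmin(255, pmax(0, plane))))
  array(p, dim(signal))
}

#' Simulate one green/red confocal frame pair with known ground truth
#'
#' The green frame renders `n_live` cells into its green plane; the red frame
#' independently renders `n_dead` cells into its red plane (green and red
#' frames of a stained sample are unpaired captures, so the two scenes are
#' independent draws). Off-marker planes contain only background and noise.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param sample_id,time_h metadata stamped on both frames.
#' @return list with elements `green` and `red` ([confocal_image()]s),
#'   `n_live`, `n_dead`, and `live_xy` / `dead_xy` (planted cell coordinate
#'   matrices, columns `x`, `y`).
#' @examples
#' pair <- simulate_pair(synthetic_spec(width = 64, height = 64,
#'   n_live = 20, n_dead = 10, seed = 7), sample_id = "SYN", time_h = 24)
#' max(pair$green$pixels[, , 2])
#' @export
simulate_pair <- function(spec, sample_id = "SYN", time_h = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    live <- draw_scene(spec, spec$n_live)
    dead <- draw_scene(spec, spec$n_dead)
    for (s in list(live, dead)) {
      dark <- mean(s$signal + spec$background_level < 0.5)
      if (dark < 0.01)
        warning("fewer than 1% dark pixels in a noise-free render: ",
                "the zero-brightness normalization anchor is degenerating",
                call. = FALSE)
    }
    zero <- matrix(0, spec$height, spec$width)
    gpix <- array(0L, c(spec$height, spec$width, 3))
    gpix[, , 1] <- quantize_plane(zero, spec)
    gpix[, , 2] <- quantize_plane(live$signal, spec)
    gpix[, , 3] <- quantize_plane(zero, spec)
    rpix <- array(0L, c(spec$height, spec$width, 3))
    rpix[, , 1] <- quantize_plane(dead$signal, spec)
    rpix[, , 2] <- quantize_plane(zero, spec)
    rpix[, , 3] <- quantize_plane(zero, spec)
    list(
      green = confocal_image(gpix, sample_id, time_h, "GREEN_SYTO9"),
      red = confocal_image(rpix, sample_id, time_h, "RED_PI"),
      n_live = spec$n_live, n_dead = spec$n_dead,
      live_xy = cbind(x = live$x, y = live$y),
      dead_xy = cbind(x = dead$x, y = dead$y)
    )
  })
}

#' Simulate a full panel of samples with planted live/dead ratios
#'
#' Builds a radial-chart-style validation panel: for every planted ratio `r`,
#' exposure time and replicate, one frame pair is simulated with
#' `n_live = round(total_cells * r / (1 + r))` and
#' `n_dead = total_cells - n_live`, so the total cell count is constant and
#' only the live/dead split varies. Frames are written as 8-bit TIFFs along
#' with a manifest CSV (`manifest.csv`) and a ground-truth CSV
#' (`truth.csv`, columns `sample_id,time_h,n_live,n_dead,planted_ratio`).
#' Each replicate is an independently seeded sample (`sample_id` =
#' `"R<ratio>_rep<k>"`); per-pair seeds are derived deterministically from
#' `seed`.
#'
#' @param out_dir directory to write into (created if needed).
#' @param ratios planted live/dead ratios, all positive.
#' @param times exposure times in hours.
#' @param replicates replicate pairs per (ratio, time).
#' @param total_cells total cells per pair (live + dead).
#' @param base a [synthetic_spec()] supplying frame size and rendering
#'   parameters; its `n_live`/`n_dead`/`seed` are overridden per pair.
#' @param seed master seed for the panel.
#' @return list with `manifest` (a `sample_manifest`), `truth` (data.frame),
#'   and the paths `manifest_path`, `truth_path`.
#' @export
simulate_panel <- function(out_dir, ratios = c(0.25, 0.5, 1, 2, 4),
                           times = c(24, 48, 72), replicates = 3L,
                           total_cells = 400L, base = synthetic_spec(),
                           seed = 1L) {
  stopifnot(inherits(base, "synthetic_spec"))
  if (any(ratios <= 0)) stop("planted ratios must be positive", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(replicate = seq_len(replicates), time_h = times,
                      ratio = ratios, KEEP.OUT.ATTRS = FALSE)
  pair_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max, nrow(grid)))
  rows <- vector("list", nrow(grid))
  truth <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- grid$ratio[i]
    n_live <- as.integer(round(total_cells * r / (1 + r)))
    n_dead <- as.integer(total_cells) - n_live
    sid <- sprintf("R%s_rep%d", format(r, trim = TRUE), grid$replicate[i])
    spec <- base
    spec$n_live <- n_live
    spec$n_dead <- n_dead
    spec$seed <- pair_seeds[i]
    pair <- simulate_pair(spec, sample_id = sid, time_h = grid$time_h[i])
    gfile <- sprintf("%s_t%g_green.tif", sid, grid$time_h[i])
    rfile <- sprintf("%s_t%g_red.tif", sid, grid$time_h[i])
    write_confocal(pair$green, file.path(out_dir, gfile))
    write_confocal(pair$red, file.path(out_dir, rfile))
    rows[[i]] <- data.frame(
      sample_id = sid, time_h = grid$time_h[i],
      marker = c("GREEN_SYTO9", "RED_PI"), path = c(gfile, rfile),
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      sample_id = sid, time_h = grid$time_h[i],
      n_live = n_live, n_dead = n_dead, planted_ratio = r,
      stringsAsFactors = FALSE)
  }
  manifest_df <- do.call(rbind, rows)
  truth_df <- do.call(rbind, truth)
  manifest_path <- file.path(out_dir, "manifest.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(manifest_df, manifest_path, row.names = FALSE)
  utils::write.csv(truth_df, truth_path, row.names = FALSE)
  manifest <- manifest_df
  manifest$path <- file.path(out_dir, manifest$path)
  list(manifest = as_sample_manifest(manifest), truth = truth_df,
       manifest_path = manifest_path, truth_path = truth_path)
}
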