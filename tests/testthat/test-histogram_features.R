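hsv_of <- function(img) rgb_to_hsv_image(img)

toy_frame <- function(levels) {
  # 4x4 frame whose green plane holds the given nonzero levels
  px <- array(0L, c(4, 4, 3))
  px[, , 2][seq_along(levels)] <- as.integer(levels)
  confocal_image(px, "TOY", 0, "green")
}

test_that("toy histograms match hand counts", {
  h0 <- brightness_histogram(hsv_of(toy_frame(integer(0))))
  expect_identical(h0$counts[1], 16L)
  expect_equal(h0$normalized[1], 1)
  expect_true(all(h0$counts[-1] == 0L))
  expect_identical(sum(h0$counts), 16L)

  h <- brightness_histogram(hsv_of(toy_frame(rep(200L, 4))))
  expect_identical(h$counts[1], 12L)
  expect_identical(h$counts[201], 4L)
  expect_equal(h$normalized[201], 1 / 3)
  expect_identical(sum(h$counts), 16L)
})

test_that("a frame with no dark pixel is a normalization error", {
  px <- array(7L, c(4, 4, 3))
  expect_error(brightness_histogram(hsv_of(confocal_image(px, "S", 0, "green"))),
               "zero-brightness normalization undefined")
})

test_that("single-level histograms give the hand-computed feature", {
  h <- brightness_histogram(hsv_of(toy_frame(rep(200L, 4))))
  expect_equal(extract_feature(h, "max_binned", 127)$value, 1 / 3)
  expect_equal(extract_feature(h, "sum_all")$value, 1 / 3)
})

test_that("binned features match the brute-force binning oracle", {
  set.seed(31)
  for (rep in 1:20) {
    img <- sparse_frame(16, 16, n_bright = 20)
    h <- brightness_histogram(hsv_of(img))
    for (nb in c(127L, 63L, 200L)) {
      expect_equal(extract_feature(h, "max_binned", nb)$value,
                   oracle_max_binned(h$normalized, nb))
    }
  }
})

test_that("bin edges partition 1..255 with as-equal-as-possible widths", {
  for (nb in c(1L, 2L, 63L, 127L, 255L)) {
    b <- brightness_bins(nb)
    expect_identical(b$v_lo[1], 1L)
    expect_identical(b$v_hi[nb], 255L)
    if (nb > 1L) expect_identical(b$v_lo[-1], b$v_hi[-nb] + 1L)
    w <- b$v_hi - b$v_lo + 1L
    expect_lte(diff(range(w)), 1L)
  }
  expect_error(brightness_bins(0), "n_bins")
  expect_error(brightness_bins(256), "n_bins")
})

test_that("degenerate bin counts collapse to the documented equivalences", {
  set.seed(32)
  img <- sparse_frame(16, 16, n_bright = 30)
  h <- brightness_histogram(hsv_of(img))
  expect_equal(extract_feature(h, "max_binned", 1)$value,
               extract_feature(h, "sum_all")$value)
  expect_equal(extract_feature(h, "max_binned", 255)$value,
               max(h$normalized[2:256]))
})

test_that("tiling a frame leaves normalized entries and features unchanged", {
  set.seed(33)
  img <- sparse_frame(16, 16, n_bright = 12)
  tiled_px <- array(0L, c(16, 32, 3))
  tiled_px[, 1:16, ] <- img$pixels
  tiled_px[, 17:32, ] <- img$pixels
  tiled <- confocal_image(tiled_px, img$sample_id, img$time_h, img$marker)
  h1 <- brightness_histogram(hsv_of(img))
  h2 <- brightness_histogram(hsv_of(tiled))
  expect_identical(h2$counts, 2L * h1$counts)
  expect_identical(h2$zero_count, 2L * h1$zero_count)
  expect_identical(h2$normalized, h1$normalized)
  expect_identical(extract_feature(h2, "max_binned", 127)$value,
                   extract_feature(h1, "max_binned", 127)$value)
  expect_identical(extract_feature(h2, "sum_all")$value,
                   extract_feature(h1, "sum_all")$value)
})

test_that("brightening a dark pixel reduces zero_count and never lowers sum_all", {
  set.seed(34)
  img <- sparse_frame(16, 16, n_bright = 12)
  h1 <- brightness_histogram(hsv_of(img))
  px <- img$pixels
  dark <- which(px[, , 2] == 0L & px[, , 1] == 0L & px[, , 3] == 0L)[1]
  plane <- px[, , 2]; plane[dark] <- 150L; px[, , 2] <- plane
  h2 <- brightness_histogram(hsv_of(confocal_image(px, "S", 0, "green")))
  expect_identical(h2$zero_count, h1$zero_count - 1L)
  expect_gt(extract_feature(h2, "sum_all")$value,
            extract_feature(h1, "sum_all")$value - 1e-15)
})

test_that("the histogram CSV dump has one row per brightness level", {
  set.seed(35)
  h <- brightness_histogram(hsv_of(sparse_frame()))
  f <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(h, f)
  df <- read.csv(f)
  expect_identical(nrow(df), 256L)
  expect_identical(df$v, 0:255)
  expect_equal(df$normalized[1], 1)
  expect_identical(sum(df$count), h$n_pixels)
})
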