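test_that("bright-focus suppression replaces only over-cap pixels", {
  p <- suppression_params(500, 100)
  img <- matrix(c(10, 499, 500, 1000), 2, 2)
  out <- suppress_bright_foci(img, p)
  expect_equal(out, matrix(c(10, 499, 500, 100), 2, 2))
  # entirely below cap: unchanged
  expect_equal(suppress_bright_foci(matrix(1:4, 2), p), matrix(1:4, 2))
  expect_error(suppression_params(100, 100), "strictly below")
  # property: never raises a pixel, never alters pixels <= cap
  set.seed(10)
  for (i in 1:20) {
    img <- matrix(runif(100, 0, 1000), 10)
    out <- suppress_bright_foci(img, p)
    expect_true(all(out <= img))
    expect_identical(out[img <= 500], img[img <= 500])
  }
})

test_that("Otsu equals the exhaustive pixel-partition maximizer", {
  # uniform 0..255 ladder
  v <- matrix(rep(0:255, 4), 32, 32)
  thr <- otsu_threshold(v)
  orc <- oracle_otsu(v)
  expect_equal(sum(v <= thr), orc$n_lower)
  # separability: two-value image
  tv <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  thr2 <- otsu_threshold(tv)
  expect_gte(thr2, 10); expect_lt(thr2, 200)
  # random 8-bit fixtures, several distributions
  set.seed(11)
  for (i in 1:25) {
    img <- switch(1 + i %% 3,
                  matrix(sample(0:255, 400, replace = TRUE), 20),
                  matrix(pmin(255, pmax(0, round(c(rnorm(200, 60, 20),
                                                   rnorm(200, 180, 25))))), 20),
                  matrix(sample(c(0:40, 200:255), 400, replace = TRUE), 20))
    thr <- otsu_threshold(img)
    orc <- oracle_otsu(img)
    expect_equal(sum(img <= thr), orc$n_lower, info = paste("fixture", i))
  }
  expect_error(otsu_threshold(matrix(5, 3, 3)), "constant")
})

test_that("Otsu separates a two-component Gaussian mixture almost perfectly", {
  set.seed(12)
  lab <- rep(c(0, 1), each = 2000)
  v <- c(rnorm(2000, 20, 5), rnorm(2000, 180, 5))
  thr <- otsu_threshold(v)
  miscls <- mean((v > thr) != lab)
  expect_lt(miscls, 0.001)
})

test_that("suppression keeps the Otsu threshold between the tissue modes", {
  set.seed(13)
  # bimodal nuclei scene with very bright foci at 5000
  v <- c(runif(700, 8, 12), runif(280, 95, 105), runif(20, 4900, 5100))
  p <- suppression_params(500, 100)
  thr_s <- otsu_threshold(suppress_bright_foci(matrix(v, 25, 40), p))
  # threshold separates background from nuclei: foreground = nuclei + foci
  expect_equal(mean(v > thr_s), 0.3, tolerance = 1e-9)
  # without suppression the outliers dominate and only the foci survive
  thr_raw <- otsu_threshold(matrix(v, 25, 40))
  expect_equal(mean(v > thr_raw), 0.02, tolerance = 1e-9)
})

test_that("combined channel image is the blurred sum, matching a dense oracle", {
  set.seed(14)
  a <- matrix(runif(24 * 20, 0, 50), 24, 20)
  b <- matrix(runif(24 * 20, 0, 50), 24, 20)
  mov <- movie_from_two_channels(list(a), list(b))
  got <- combined_channel_image(mov, c("a", "b"), blur_sigma_px = 2)[[1]]
  want <- oracle_conv2_replicate(a + b, oracle_gauss_kernel2(2))
  expect_equal(got, want, tolerance = 1e-6)
  # zero channel: blurred other channel; constant pair: constant sum
  movz <- movie_from_two_channels(list(a), list(matrix(0, 24, 20)))
  expect_equal(combined_channel_image(movz, 1:2, 2)[[1]],
               oracle_conv2_replicate(a, oracle_gauss_kernel2(2)),
               tolerance = 1e-6)
  movc <- movie_from_two_channels(list(matrix(3, 16, 16)),
                                  list(matrix(4, 16, 16)))
  expect_equal(combined_channel_image(movc, 1:2, 2)[[1]],
               matrix(7, 16, 16), tolerance = 1e-10)
})

test_that("combined-territory segmentation labels each nucleus and warns on blank frames", {
  # 8 disks -> 8 labeled objects
  cy <- rep(c(15, 40, 65, 90), 2)
  cx <- rep(c(20, 50), each = 4)
  f <- disk_image(105, 70, cy, cx, 8, level = 100, bg = 10)
  mov <- movie_from_two_channels(list(f / 2), list(f / 2))
  masks <- segment_combined_territory(mov, 1:2)
  expect_equal(max(masks[[1]]$labels), 8)
  expect_equal(masks[[1]]$kind, "combined_territory")
  # blank frame: empty mask plus warning
  blank <- movie_from_two_channels(list(matrix(0, 20, 20)),
                                   list(matrix(0, 20, 20)))
  expect_warning(mb <- segment_combined_territory(blank, 1:2), "empty")
  expect_equal(max(mb[[1]]$labels), 0)
})

test_that("watershed nucleus segmentation splits touching disks and filters borders", {
  # two disks overlapping by ~20% of radius -> 2 labels
  r <- 12
  f <- disk_image(80, 80, c(40, 40), c(28, 28 + 1.8 * r), r,
                  level = 100, bg = 5)
  m <- segment_nuclei_rpb3(f, blur_sigma_px = 1.5, dilation_radius_px = 2)
  expect_equal(max(m$labels), 2)
  # single isolated disk: 1 label, dilated area >= raw disk area
  f1 <- disk_image(64, 64, 32, 32, 10, level = 100, bg = 5)
  m1 <- segment_nuclei_rpb3(f1)
  expect_equal(max(m1$labels), 1)
  expect_gte(sum(m1$labels > 0), sum(f1 > 50))
  # disk on the image edge is removed by the border filter
  fe <- disk_image(64, 64, c(32, 2), c(32, 32), 10, level = 100, bg = 5)
  me <- segment_nuclei_rpb3(fe)
  expect_equal(max(me$labels), 1)
  cen <- mask_centroids(me)
  expect_equal(round(cen$y), 32)
})

test_that("mask helpers report contiguous labels, areas and centroids", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L
  lab[7:9, 6:9] <- 2L
  fm <- frame_mask(lab, 1, "nuclei")
  expect_equal(unname(mask_areas(fm)), c(9L, 12L))
  cen <- mask_centroids(fm)
  expect_equal(cen$y, c(3, 8))
  expect_equal(cen$x, c(3, 7.5))
  expect_error(frame_mask(matrix(c(0L, 2L), 1, 2), 1, "nuclei"),
               "contiguous")
})
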