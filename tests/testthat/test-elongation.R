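test_that("DoG response equals the dense two-pass oracle", {
  set.seed(50)
  img <- matrix(runif(22 * 18, 0, 100), 22, 18)
  got <- dog_response(img, c(1.6, 2.6))
  want <- oracle_conv2_replicate(img, oracle_gauss_kernel2(1.6)) -
    oracle_conv2_replicate(img, oracle_gauss_kernel2(2.6))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("DoG spot detection is accurate and quiet on blank frames", {
  set.seed(51)
  noise <- matrix(rnorm(80 * 80, 30, 2), 80)
  expect_equal(nrow(detect_transcription_spots(noise)), 0)
  f <- noise + gauss_spot(80, 80, 44.4, 25.6, 20, 2)
  d <- detect_transcription_spots(f)
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$y - 44.4)^2 + (d$x - 25.6)^2), 1)
})

test_that("gap closing bridges up to max_gap missing frames, splitting beyond", {
  mk_det <- function(frames) data.frame(frame = frames, y = 50, x = 50)
  # continuous track: 1 track, no gaps
  t0 <- link_spots(mk_det(1:10), max_gap = 5, img_dim = c(100, 100))
  expect_equal(length(unique(t0$track_id)), 1)
  expect_equal(nrow(track_gaps(t0)), 0)
  # absent exactly 5 consecutive frames: one track with one recorded gap
  f5 <- c(1:4, 10:14)
  t5 <- link_spots(mk_det(f5), max_gap = 5, img_dim = c(100, 100))
  expect_equal(length(unique(t5$track_id)), 1)
  g <- track_gaps(t5)
  expect_equal(g$length, 5)
  expect_equal(g$start_frame, 5)
  # absent 6 frames: two tracks
  f6 <- c(1:4, 11:14)
  t6 <- link_spots(mk_det(f6), max_gap = 5, img_dim = c(100, 100))
  expect_equal(length(unique(t6$track_id)), 2)
  # boundary behaviour matches the exhaustive single-spot linker
  set.seed(52)
  for (i in 1:10) {
    frames <- sort(sample(1:30, 12))
    tk <- link_spots(mk_det(frames), max_gap = 3, img_dim = c(100, 100))
    orc <- oracle_split_by_gap(frames, 3)
    orc <- orc[vapply(orc, length, 1L) >= 2]    # single-frame tracks dropped
    expect_equal(length(unique(tk$track_id)), length(orc))
  }
})

test_that("single-frame and border-hugging tracks are discarded", {
  det <- rbind(data.frame(frame = 1:5, y = 50, x = 50),
               data.frame(frame = 3, y = 20, x = 80),     # single frame
               data.frame(frame = 1:5, y = 5, x = 30))    # near border
  tk <- link_spots(det, max_gap = 5, border_margin = 8,
                   img_dim = c(100, 100))
  expect_equal(length(unique(tk$track_id)), 1)
  expect_equal(unique(round(tk$y)), 50)
})

test_that("jittered multi-locus linking assigns frames to the right locus", {
  set.seed(53)
  n_loci <- 10; nf <- 40
  cy <- runif(n_loci, 20, 140); cx <- runif(n_loci, 20, 140)
  # enforce separation
  while (min(dist(cbind(cy, cx))) < 15) {
    cy <- runif(n_loci, 20, 140); cx <- runif(n_loci, 20, 140)
  }
  rows <- list()
  for (k in seq_len(n_loci)) {
    y <- cy[k] + cumsum(rnorm(nf, 0, 0.5))
    x <- cx[k] + cumsum(rnorm(nf, 0, 0.5))
    present <- runif(nf) > 0.1                 # 10% dropout
    rows[[k]] <- data.frame(frame = which(present), y = y[present],
                            x = x[present], truth = k)
  }
  det <- do.call(rbind, rows)
  tk <- link_spots(det[order(det$frame), c("frame", "y", "x")],
                   max_gap = 5, max_disp_px = 5, border_margin = 0)
  # map each detection back to its ground-truth locus by position
  assign_truth <- function(y, x) which.min((cy - y)^2 + (cx - x)^2)
  tk$truth <- mapply(assign_truth, tk$y, tk$x)
  # majority vote per track, then fraction of correctly assigned frames
  correct <- 0
  for (id in unique(tk$track_id)) {
    tt <- tk$truth[tk$track_id == id]
    correct <- correct + max(table(tt))
  }
  expect_gte(correct / nrow(tk), 0.95)
})

test_that("window quantification equals the pixel-loop oracle and skips gaps", {
  set.seed(54)
  ny <- 60; nx <- 60
  fa <- replicate(4, matrix(runif(ny * nx, 0, 100), ny), simplify = FALSE)
  fb <- replicate(4, matrix(runif(ny * nx, 0, 100), ny), simplify = FALSE)
  mov <- movie_from_two_channels(fa, fb, channels = c("mcp", "pcp"))
  det <- data.frame(frame = c(1, 2, 4), y = c(30, 31, 30.4),
                    x = c(25, 25.6, 26))
  tk <- link_spots(det, max_gap = 5, border_margin = 8, img_dim = c(ny, nx))
  tk <- quantify_track(tk, mov, "mcp", "pcp", half_width = 8)
  for (i in seq_len(nrow(tk))) {
    f <- tk$frame[i]
    expect_equal(tk$mcp_intensity[i],
                 oracle_window_mean(fa[[f]], round(tk$y[i]),
                                    round(tk$x[i]), 8), tolerance = 1e-12)
    expect_equal(tk$pcp_intensity[i],
                 oracle_window_mean(fb[[f]], round(tk$y[i]),
                                    round(tk$x[i]), 8), tolerance = 1e-12)
  }
  # cumulative sums run over quantified frames only (gap frame 3 skipped)
  expect_equal(tk$cumulative_mcp, cumsum(tk$mcp_intensity))
  # constant channel: intensity c at every frame
  movc <- movie_from_two_channels(list(matrix(7, 40, 40)),
                                  list(matrix(3, 40, 40)),
                                  channels = c("mcp", "pcp"))
  tkc <- structure(data.frame(track_id = 1L, frame = 1L, y = 20, x = 20),
                   class = c("spot_tracks", "data.frame"))
  tkc <- quantify_track(tkc, movc, "mcp", "pcp")
  expect_equal(tkc$mcp_intensity, 7)
  expect_equal(tkc$pcp_intensity, 3)
})

test_that("a 3-px displaced spot keeps over 90% of its windowed signal", {
  # analytic oracle for the 17x17 window with PSF sd 2 px
  frac_centered <- oracle_gauss_window_fraction(0, 0, 8, 2)
  frac_displaced <- oracle_gauss_window_fraction(3, 0, 8, 2)
  expect_gt(frac_displaced / frac_centered, 0.9)
  # and the measured window means agree with the analytic prediction
  ny <- 51; nx <- 51
  spot <- gauss_spot(ny, nx, 26, 26, 100, 2)
  mov <- movie_from_two_channels(list(spot), list(spot),
                                 channels = c("mcp", "pcp"))
  centred <- oracle_window_mean(spot, 26, 26, 8)
  displaced <- oracle_window_mean(spot, 29, 26, 8)
  expect_gt(displaced / centred, 0.9)
  expect_equal(displaced / centred, frac_displaced / frac_centered,
               tolerance = 0.01)
})

test_that("track sorting is lexicographic and matches the brute-force oracle", {
  set.seed(55)
  mk_tracks <- function(first, pcp) {
    do.call(rbind, lapply(seq_along(first), function(i)
      data.frame(track_id = i, frame = first[i] + 0:1, y = 30, x = 30,
                 mcp_intensity = 1, pcp_intensity = pcp[i] / 2,
                 cumulative_mcp = 1:2, cumulative_pcp = pcp[i] / 2 * (1:2))))
  }
  # same appearance time: descending total PCP
  tk <- structure(mk_tracks(c(2, 2, 2), c(5, 9, 1)),
                  class = c("spot_tracks", "data.frame"))
  srt <- sort_tracks(tk)
  expect_equal(attr(srt, "track_summary")$total_pcp, c(9, 5, 1))
  # distinct appearance times dominate regardless of PCP
  tk2 <- structure(mk_tracks(c(5, 1, 3), c(100, 1, 50)),
                   class = c("spot_tracks", "data.frame"))
  srt2 <- sort_tracks(tk2)
  expect_equal(attr(srt2, "track_summary")$first_frame, c(1, 3, 5))
  # random set against the oracle
  first <- sample(1:4, 8, replace = TRUE)
  pcp <- round(runif(8, 0, 20), 3)
  tk3 <- structure(mk_tracks(first, pcp),
                   class = c("spot_tracks", "data.frame"))
  srt3 <- sort_tracks(tk3)
  orc <- oracle_sort_order(first, pcp)
  expect_equal(attr(srt3, "track_summary")$first_frame, first[orc])
  expect_equal(attr(srt3, "track_summary")$total_pcp, pcp[orc])
})

test_that("montages tile the tracks row-wise with blank gap tiles", {
  set.seed(56)
  fa <- replicate(3, matrix(runif(60 * 60, 0, 10), 60), simplify = FALSE)
  fb <- replicate(3, matrix(runif(60 * 60, 0, 10), 60), simplify = FALSE)
  mov <- movie_from_two_channels(fa, fb, channels = c("mcp", "pcp"))
  det <- data.frame(frame = c(1, 3), y = c(30, 30), x = c(30, 30))
  tk <- link_spots(det, max_gap = 5, border_margin = 8, img_dim = c(60, 60))
  tk <- quantify_track(tk, mov, "mcp", "pcp")
  expect_warning(mt <- render_montage(tk, mov, "mcp", "pcp", n_top = 50),
                 "only 1")
  expect_equal(dim(mt$mcp), c(17, 3 * 17))
  # tile content equals the direct crop oracle
  expect_equal(mt$mcp[1:17, 1:17], fa[[1]][22:38, 22:38])
  # gap frame 2 is blank
  expect_true(all(mt$mcp[, 18:34] == 0))
  expect_equal(mt$mcp[, 35:51], fa[[3]][22:38, 22:38])
})

test_that("cumulative scatter reports per-track totals and rank correlation", {
  tk <- do.call(rbind, lapply(1:5, function(i)
    data.frame(track_id = i, frame = 1:4, y = 30, x = 30,
               mcp_intensity = i, pcp_intensity = 0,
               cumulative_mcp = i * (1:4), cumulative_pcp = 0)))
  sc <- cumulative_scatter(tk)
  expect_equal(sc$table$cumulative_mcp, (1:5) * 4)
  expect_true(all(sc$table$cumulative_pcp == 0))   # all points on the x-axis
  tk$pcp_intensity <- tk$mcp_intensity * 2
  tk$cumulative_pcp <- tk$cumulative_mcp * 2
  sc2 <- cumulative_scatter(tk)
  expect_equal(sc2$rank_correlation, 1)
})

test_that("the four elongation defect classes are recovered from schedules", {
  noise_sd <- 1
  mk <- function(id, frames, mcp, pcp) data.frame(
    track_id = id, frame = frames, y = 30, x = 30, mcp_intensity = mcp,
    pcp_intensity = pcp, cumulative_mcp = cumsum(mcp),
    cumulative_pcp = cumsum(pcp))
  tk <- rbind(
    mk(1, 1:30, rep(20, 30), c(rep(0, 10), rep(20, 20))),  # normal
    mk(2, 1:6, rep(20, 6), rep(0, 6)),                     # transient, no 3'
    mk(3, 1:30, rep(c(35, 2), 15), rep(0, 30)),            # unstable, no 3'
    mk(4, 1:30, rep(20, 30), c(rep(0, 22), rep(6, 8))),    # delayed / low
    mk(5, 1:30, rep(20, 30), rep(0, 30)))                  # stable, no 3'
  cls <- classify_elongation_defects(tk, noise_sd = noise_sd, k = 5)
  expect_equal(cls$class, c("normal", "transient_no_pcp", "unstable_no_pcp",
                            "delayed_low_pcp", "stable_no_pcp"))
})
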