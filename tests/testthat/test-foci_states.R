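test_that("stationary nuclei track one-to-one; incomplete nuclei are discarded", {
  pos <- replicate(10, data.frame(y = c(10, 25), x = c(10, 25)),
                   simplify = FALSE)
  masks <- masks_from_positions(pos, 40, 40, 4)
  tr <- track_nuclei(masks)
  expect_equal(length(unique(tr$nucleus_id)), 2)
  expect_true(all(table(tr$nucleus_id) == 10))
  # each retained track keeps one label per frame
  expect_true(all(tapply(tr$label, paste(tr$nucleus_id, tr$frame),
                         length) == 1))
  # a nucleus absent in one frame is excluded from the retained set
  pos2 <- pos
  pos2[[5]] <- pos2[[5]][1, , drop = FALSE]
  tr2 <- track_nuclei(masks_from_positions(pos2, 40, 40, 4))
  expect_equal(length(unique(tr2$nucleus_id)), 1)
  # the interrupted nucleus yields two incomplete fragments, both dropped
  expect_equal(attr(tr2, "n_discarded"), 2)
})

test_that("drifting nuclei are linked with perfect identity", {
  # 2 px/frame drift, known identities
  base <- data.frame(y = c(12, 12, 30), x = c(10, 34, 22))
  pos <- lapply(0:7, function(t) data.frame(y = base$y + 2 * t,
                                            x = base$x))
  masks <- masks_from_positions(pos, 60, 50, 4)
  tr <- track_nuclei(masks, max_disp_px = 4)
  expect_equal(length(unique(tr$nucleus_id)), 3)
  for (id in unique(tr$nucleus_id)) {
    xs <- tr$x[tr$nucleus_id == id]
    expect_equal(length(unique(round(xs))), 1)   # x constant per true nucleus
    ys <- tr$y[tr$nucleus_id == id]
    expect_equal(diff(range(ys)), 14, tolerance = 0.5)
  }
  expect_error(track_nuclei(masks[1]), "at least two")
})

test_that("LoG detection finds synthetic spots at sub-pixel accuracy", {
  set.seed(40)
  mask <- frame_mask(matrix(1L, 64, 64), 1, "nuclei")
  noise_sd <- 2
  # blank (pure noise) frame: no detections
  blank <- matrix(rnorm(64 * 64, 50, noise_sd), 64)
  expect_equal(nrow(detect_mcp_foci(blank, mask)), 0)
  # constant frame: degenerate but safe
  expect_equal(nrow(detect_mcp_foci(matrix(0, 64, 64), mask)), 0)
  # single Gaussian spot at SNR 10: exactly 1 detection within 1 px
  f <- blank + gauss_spot(64, 64, 30.3, 41.7, 10 * noise_sd, 2)
  d <- detect_mcp_foci(f, mask)
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$y - 30.3)^2 + (d$x - 41.7)^2), 1.5)
  # two spots 15 px apart: 2 detections
  f2 <- blank + gauss_spot(64, 64, 30, 20, 10 * noise_sd, 2) +
    gauss_spot(64, 64, 30, 35, 10 * noise_sd, 2)
  expect_equal(nrow(detect_mcp_foci(f2, mask)), 2)
  # detections outside the mask land in the orphan log
  part <- matrix(0L, 64, 64); part[1:32, ] <- 1L
  d3 <- detect_mcp_foci(f, frame_mask(part, 1, "nuclei"))
  expect_equal(nrow(d3), 1)
  d4 <- detect_mcp_foci(f2 - gauss_spot(64, 64, 30, 20, 10 * noise_sd, 2),
                        frame_mask(1L - part, 1, "nuclei"))
  expect_equal(nrow(d4), 0)
  expect_equal(nrow(attr(d4, "orphans")), 1)
})

test_that("state assignment reproduces scheduled ON intervals and transitions", {
  pos <- replicate(12, data.frame(y = 10, x = 10), simplify = FALSE)
  tr <- track_nuclei(masks_from_positions(pos, 20, 20, 4))
  # foci present frames 3..10 only
  det <- data.frame(frame = 3:10, nucleus = 1L)
  st <- assign_states(tr, det)
  expect_equal(st$transitions$frame, c(3L, 11L))
  expect_equal(st$transitions$type, c("off_to_on", "on_to_off"))
  expect_equal(sum(st$states$state == "ON"), 8)
  # never any focus: all OFF, empty transition list
  st0 <- assign_states(tr, det[0, ])
  expect_true(all(st0$states$state == "OFF"))
  expect_equal(nrow(st0$transitions), 0)
  # invariant to detection order within frames
  det2 <- data.frame(frame = c(5, 3, 10, 4, 6:9), nucleus = 1L)
  st2 <- assign_states(tr, det2)
  expect_equal(st2$states$state, st$states$state)
  # optional smoothing removes short blips
  blip <- data.frame(frame = c(2, 6, 7, 8), nucleus = 1L)
  sts <- assign_states(tr, blip, min_consecutive = 2)
  expect_equal(sts$transitions$frame, c(6L, 9L))
})

test_that("cumulative curves follow their definitions and invariants", {
  pos <- replicate(10, data.frame(y = c(8, 8, 22, 22), x = c(8, 22, 8, 22)),
                   simplify = FALSE)
  tr <- track_nuclei(masks_from_positions(pos, 30, 30, 3))
  # all four nuclei ON from frame 5, stay ON
  det <- do.call(rbind, lapply(5:10, function(f)
    data.frame(frame = f, nucleus = 1:4)))
  cv <- cumulative_transition_curves(assign_states(tr, det), 1, 20)
  expect_equal(cv$pct_appeared, c(0, 0, 0, 0, rep(100, 6)))
  expect_true(all(cv$pct_disappeared == 0))
  # half the nuclei turn ON then OFF: disappearance plateaus at 50
  det2 <- rbind(do.call(rbind, lapply(3:10, function(f)
    data.frame(frame = f, nucleus = 1:2))),
    do.call(rbind, lapply(3:5, function(f)
      data.frame(frame = f, nucleus = 3:4))))
  cv2 <- cumulative_transition_curves(assign_states(tr, det2), 1, 20)
  expect_equal(max(cv2$pct_disappeared), 50)
  expect_equal(max(cv2$pct_appeared), 100)
  # property: monotone, bounded, disappearance <= appearance (random states)
  set.seed(41)
  for (i in 1:10) {
    det_r <- data.frame(frame = sample(1:10, 12, replace = TRUE),
                        nucleus = sample(1:4, 12, replace = TRUE))
    cvr <- cumulative_transition_curves(assign_states(tr, det_r), 1, 20)
    expect_true(all(diff(cvr$pct_appeared) >= 0))
    expect_true(all(diff(cvr$pct_disappeared) >= 0))
    expect_true(all(cvr$pct_disappeared <= cvr$pct_appeared))
    expect_true(all(cvr$pct_appeared <= 100 & cvr$pct_appeared >= 0))
  }
})

test_that("appearance half-time interpolates the 50% crossing", {
  curves <- structure(data.frame(frame = 1:5, time_s = seq(0, 80, 20),
                                 pct_appeared = c(0, 20, 60, 90, 100),
                                 pct_disappeared = 0),
                      class = c("CumulativeCurves", "data.frame"))
  # crosses 50 between 20 s (20%) and 40 s (60%)
  expect_equal(appearance_halftime(curves), 20 + 30 / 40 * 20)
})
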