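# Programmatic fixtures: all test images are built in code.

disk_image <- function(ny, nx, cy, cx, r, level = 100, bg = 0) {
  img <- matrix(bg, ny, nx)
  for (k in seq_along(cy)) {
    d <- sqrt(outer((seq_len(ny) - cy[k])^2, (seq_len(nx) - cx[k])^2, `+`))
    img[d <= r[min(k, length(r))]] <- level
  }
  img
}

gauss_spot <- function(ny, nx, cy, cx, amp, sd) {
  d2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, `+`)
  amp * exp(-d2 / (2 * sd^2))
}

# single-channel projected movie from a list of frame matrices
movie_from_frames <- function(frames, channel = "ch1", interval = 20) {
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  data <- array(0, dim = c(length(frames), 1, ny, nx))
  for (t in seq_along(frames)) data[t, 1, , ] <- frames[[t]]
  projected_movie(data, frame_interval_s = interval, channel_names = channel)
}

# two-channel projected movie from two parallel frame lists
movie_from_two_channels <- function(frames_a, frames_b,
                                    channels = c("a", "b"), interval = 20) {
  ny <- nrow(frames_a[[1]]); nx <- ncol(frames_a[[1]])
  data <- array(0, dim = c(length(frames_a), 2, ny, nx))
  for (t in seq_along(frames_a)) {
    data[t, 1, , ] <- frames_a[[t]]
    data[t, 2, , ] <- frames_b[[t]]
  }
  projected_movie(data, frame_interval_s = interval,
                  channel_names = channels)
}

# labeled mask list from per-frame disk positions (one disk per nucleus)
masks_from_positions <- function(pos_list, ny, nx, r, kind = "nuclei") {
  lapply(seq_along(pos_list), function(t) {
    p <- pos_list[[t]]
    lab <- matrix(0L, ny, nx)
    for (k in seq_len(nrow(p))) {
      d <- sqrt(outer((seq_len(ny) - p$y[k])^2, (seq_len(nx) - p$x[k])^2,
                      `+`))
      lab[d <= r] <- k
    }
    frame_mask(lab, t, kind)
  })
}
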