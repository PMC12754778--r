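#' Difference-of-Gaussians response
#'
#' `G_sigma1 * I - G_sigma2 * I` with `sigma1 < sigma2`: a band-pass filter
#' whose maxima mark diffraction-limited spots. Separable Gaussian
#' convolution with replicate boundary.
#'
#' @param frame numeric matrix.
#' @param sigma_pair `c(sigma1, sigma2)` in pixels, default `c(1.6, 2.6)`.
#' @return response matrix.
#' @export
dog_response <- function(frame, sigma_pair = c(1.6, 2.6)) {
  stopifnot(length(sigma_pair) == 2L, sigma_pair[1] < sigma_pair[2])
  gaussian_blur(frame, sigma_pair[1]) - gaussian_blur(frame, sigma_pair[2])
}

#' Detect transcription spots by difference of Gaussians
#'
#' Local maxima of the [dog_response()] above a threshold (default
#' `threshold_k` times the robust 1.4826-MAD noise SD of the response),
#' refined to sub-pixel precision by the local intensity centroid of the
#' positive response in a 3x3 neighbourhood.
#'
#' @param frame numeric matrix (MCP channel, one frame).
#' @inheritParams dog_response
#' @param threshold absolute response threshold; `NULL` for the k-MAD rule.
#' @param threshold_k multiplier for the automatic threshold (default 5).
#' @return data frame with columns `y`, `x` (sub-pixel), `response`.
#' @export
detect_transcription_spots <- function(frame, sigma_pair = c(1.6, 2.6),
                                       threshold = NULL, threshold_k = 5) {
  resp <- dog_response(frame, sigma_pair)
  # the outermost pixel ring carries replicate-boundary filter artifacts
  interior <- border_band_mask(dim(frame), 2L)
  if (is.null(threshold)) threshold <- threshold_k * mad(resp[interior])
  resp_s <- resp
  resp_s[!interior] <- -Inf
  mx <- cpp_local_max(resp_s, threshold)
  idx <- which(mx, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(y = numeric(0), x = numeric(0), response = numeric(0)))
  ny <- nrow(frame); nxp <- ncol(frame)
  refine <- function(i, j) {
    ys <- max(1, i - 1):min(ny, i + 1)
    xs <- max(1, j - 1):min(nxp, j + 1)
    w <- pmax(resp[ys, xs, drop = FALSE], 0)
    if (sum(w) == 0) return(c(i, j))
    c(sum(outer(ys, rep(1, length(xs))) * w) / sum(w),
      sum(outer(rep(1, length(ys)), xs) * w) / sum(w))
  }
  ref <- t(mapply(refine, idx[, 1], idx[, 2]))
  data.frame(y = ref[, 1], x = ref[, 2],
             response = resp[cbind(idx[, 1], idx[, 2])])
}

#' Link spot detections into tracks with gap closing
#'
#' Greedy nearest-neighbour linking with memory: a track whose spot went
#' undetected may be resumed after up to `max_gap` consecutive missing
#' frames (the boundary is exact: absent exactly `max_gap` frames resumes
#' the track, absent `max_gap + 1` starts a new one). After linking, tracks
#' spanning a single frame and tracks with any detection within
#' `border_margin` pixels of the X-Y image border are discarded, so every
#' quantification window fits inside the image.
#'
#' @param detections data frame with columns `frame`, `y`, `x` (all frames
#'   concatenated, e.g. from [detect_transcription_spots()]).
#' @param max_gap maximum number of consecutive missing frames bridged
#'   (default 5).
#' @param max_disp_px spatial gate per link (default 5).
#' @param border_margin exclusion margin in pixels (default 8, half the
#'   17x17 quantification window); set 0 to disable.
#' @param img_dim `c(ny, nx)`; required when `border_margin > 0`.
#' @return An object of class `spot_tracks`: data frame with columns
#'   `track_id`, `frame`, `y`, `x`, ordered by track then frame; track ids
#'   are numbered by time of first appearance.
#' @export
link_spots <- function(detections, max_gap = 5L, max_disp_px = 5,
                       border_margin = 8L, img_dim = NULL) {
  if (border_margin > 0 && is.null(img_dim))
    stop("img_dim is required when border_margin > 0")
  det <- detections[order(detections$frame), , drop = FALSE]
  tracks <- list()   # each: list(rows = df rows, last_y, last_x, last_f)
  for (f in sort(unique(det$frame))) {
    df <- det[det$frame == f, , drop = FALSE]
    cand <- which(vapply(tracks, function(tr)
      f - tr$last_f - 1L <= max_gap && f > tr$last_f, logical(1)))
    d <- if (length(cand) && nrow(df)) {
      py <- vapply(tracks[cand], `[[`, numeric(1), "last_y")
      px <- vapply(tracks[cand], `[[`, numeric(1), "last_x")
      sqrt(outer(py, df$y, `-`)^2 + outer(px, df$x, `-`)^2)
    } else matrix(numeric(0), length(cand), nrow(df))
    m <- greedy_match(d, max_disp_px)
    for (i in seq_along(cand)) {
      if (is.na(m[i])) next
      tr <- tracks[[cand[i]]]
      j <- m[i]
      tr$frames <- c(tr$frames, f)
      tr$y <- c(tr$y, df$y[j]); tr$x <- c(tr$x, df$x[j])
      tr$last_y <- df$y[j]; tr$last_x <- df$x[j]; tr$last_f <- f
      tracks[[cand[i]]] <- tr
    }
    if (nrow(df)) {
      unmatched <- setdiff(seq_len(nrow(df)), m[!is.na(m)])
      for (j in unmatched)
        tracks[[length(tracks) + 1L]] <- list(frames = f, y = df$y[j],
                                              x = df$x[j], last_y = df$y[j],
                                              last_x = df$x[j], last_f = f)
    }
  }
  keep <- vapply(tracks, function(tr) length(tr$frames) >= 2L, logical(1))
  if (border_margin > 0) {
    inb <- vapply(tracks, function(tr)
      all(tr$y > border_margin & tr$y <= img_dim[1] - border_margin &
          tr$x > border_margin & tr$x <= img_dim[2] - border_margin),
      logical(1))
    keep <- keep & inb
  }
  tracks <- tracks[keep]
  if (!length(tracks))
    return(structure(data.frame(track_id = integer(0), frame = integer(0),
                                y = numeric(0), x = numeric(0)),
                     max_gap = max_gap, class = c("spot_tracks",
                                                  "data.frame")))
  first_f <- vapply(tracks, function(tr) tr$frames[1], numeric(1))
  tracks <- tracks[order(first_f)]
  out <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track_id = i, frame = tr$frames, y = tr$y, x = tr$x)
  }))
  structure(out, max_gap = max_gap, max_disp_px = max_disp_px,
            border_margin = border_margin,
            class = c("spot_tracks", "data.frame"))
}

#' Gap structure of spot tracks
#'
#' @param tracks a [link_spots()] result.
#' @return data frame with one row per gap: `track_id`, `start_frame`
#'   (first missing frame), `length`.
#' @export
track_gaps <- function(tracks) {
  rows <- list()
  for (id in unique(tracks$track_id)) {
    f <- sort(tracks$frame[tracks$track_id == id])
    d <- diff(f)
    g <- which(d > 1)
    if (length(g))
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = id, start_frame = f[g] + 1L, length = d[g] - 1L)
  }
  if (!length(rows))
    return(data.frame(track_id = integer(0), start_frame = integer(0),
                      length = integer(0)))
  do.call(rbind, rows)
}

#' Quantify both reporter channels along spot tracks
#'
#' At each detection, the mean intensity over a `(2*half_width+1)`-square
#' window (17x17 by default) centred on the rounded MCP spot position is
#' measured in both channels; the large window tolerates the slight
#' displacement of the 3' reporter focus from the MCP spot. Gap frames are
#' not interpolated; cumulative sums run over quantified frames only.
#'
#' @param tracks a [link_spots()] result.
#' @param movie a [projected_movie()] containing both channels.
#' @param mcp_channel,pcp_channel channel indices or names.
#' @param half_width half window size (default 8, i.e. a 17x17 square).
#' @return `tracks` with columns `mcp_intensity`, `pcp_intensity`,
#'   `cumulative_mcp`, `cumulative_pcp` added.
#' @export
quantify_track <- function(tracks, movie, mcp_channel, pcp_channel,
                           half_width = 8L) {
  stopifnot(inherits(movie, "ProjectedMovie"))
  d <- dim(movie$data)
  n <- nrow(tracks)
  mcp <- numeric(n); pcp <- numeric(n)
  for (i in seq_len(n)) {
    yi <- round(tracks$y[i]); xi <- round(tracks$x[i])
    ys <- (yi - half_width):(yi + half_width)
    xs <- (xi - half_width):(xi + half_width)
    if (ys[1] < 1 || xs[1] < 1 || ys[length(ys)] > d[3] ||
        xs[length(xs)] > d[4])
      stop("quantification window clipped by image border at track ",
           tracks$track_id[i], ", frame ", tracks$frame[i],
           "; border filtering should have removed this track")
    mcp[i] <- mean(get_frame(movie, tracks$frame[i], mcp_channel)[ys, xs])
    pcp[i] <- mean(get_frame(movie, tracks$frame[i], pcp_channel)[ys, xs])
  }
  tracks$mcp_intensity <- mcp
  tracks$pcp_intensity <- pcp
  tracks$cumulative_mcp <- NA_real_
  tracks$cumulative_pcp <- NA_real_
  for (id in unique(tracks$track_id)) {
    sel <- which(tracks$track_id == id)
    sel <- sel[order(tracks$frame[sel])]
    tracks$cumulative_mcp[sel] <- cumsum(tracks$mcp_intensity[sel])
    tracks$cumulative_pcp[sel] <- cumsum(tracks$pcp_intensity[sel])
  }
  attr(tracks, "half_width") <- half_width
  tracks
}

#' Sort tracks by first appearance, then total 3' signal
#'
#' Stable lexicographic sort: ascending frame of first appearance, ties
#' broken by descending total PCP intensity.
#'
#' @param tracks a quantified [quantify_track()] result.
#' @return `tracks` with rows reordered and track ids renumbered in the new
#'   order; attribute `track_summary` holds one row per track
#'   (`track_id`, `first_frame`, `total_pcp`).
#' @export
sort_tracks <- function(tracks) {
  if (is.null(tracks$pcp_intensity))
    stop("tracks must be quantified before sorting")
  ids <- unique(tracks$track_id)
  first_f <- vapply(ids, function(id)
    min(tracks$frame[tracks$track_id == id]), numeric(1))
  tot_pcp <- vapply(ids, function(id)
    sum(tracks$pcp_intensity[tracks$track_id == id]), numeric(1))
  ord <- order(first_f, -tot_pcp)
  new_id <- setNames(seq_along(ids), ids[ord])
  out <- do.call(rbind, lapply(seq_along(ord), function(i) {
    tr <- tracks[tracks$track_id == ids[ord[i]], , drop = FALSE]
    tr$track_id <- i
    tr[order(tr$frame), , drop = FALSE]
  }))
  rownames(out) <- NULL
  for (a in c("max_gap", "max_disp_px", "border_margin", "half_width"))
    attr(out, a) <- attr(tracks, a)
  attr(out, "track_summary") <- data.frame(
    track_id = seq_along(ord), first_frame = first_f[ord],
    total_pcp = tot_pcp[ord])
  class(out) <- class(tracks)
  out
}

#' Render a two-channel track montage
#'
#' One row per track (top `n_top` in the current order), one column per
#' movie frame; each tile is the `(2*half_width+1)`-square crop around the
#' spot position in that frame, blank where the track has no detection.
#' Channels are rendered as separate matrices with shared per-channel
#' scaling recorded.
#'
#' @param tracks a sorted, quantified track collection.
#' @param movie a [projected_movie()].
#' @param mcp_channel,pcp_channel channel indices or names.
#' @param n_top number of tracks displayed (clamped, with a warning, to the
#'   number available; default 50).
#' @param half_width tile half size (default 8).
#' @return An object of class `Montage`: list with `mcp` and `pcp` tile-grid
#'   matrices (`n_tracks*17 x n_frames*17`), `row_order`, `tile_px`,
#'   `scaling` (per-channel display maxima).
#' @export
render_montage <- function(tracks, movie, mcp_channel, pcp_channel,
                           n_top = 50L, half_width = 8L) {
  stopifnot(inherits(movie, "ProjectedMovie"))
  ids <- unique(tracks$track_id)
  if (n_top > length(ids)) {
    warning("requested ", n_top, " tracks but only ", length(ids),
            " available")
    n_top <- length(ids)
  }
  ids <- ids[seq_len(n_top)]
  d <- dim(movie$data)
  w <- 2L * half_width + 1L
  nt <- d[1]
  grid <- function(channel) {
    g <- matrix(0, n_top * w, nt * w)
    for (r in seq_along(ids)) {
      tr <- tracks[tracks$track_id == ids[r], , drop = FALSE]
      for (k in seq_len(nrow(tr))) {
        f <- tr$frame[k]
        yi <- round(tr$y[k]); xi <- round(tr$x[k])
        tile <- get_frame(movie, f, channel)[
          (yi - half_width):(yi + half_width),
          (xi - half_width):(xi + half_width)]
        g[((r - 1L) * w + 1L):(r * w), ((f - 1L) * w + 1L):(f * w)] <- tile
      }
    }
    g
  }
  m <- grid(mcp_channel); p <- grid(pcp_channel)
  structure(list(mcp = m, pcp = p, row_order = ids, tile_px = w,
                 scaling = c(mcp = max(m), pcp = max(p))),
            class = "Montage")
}

#' Cumulative MCP versus PCP intensity per track
#'
#' End-of-movie cumulative sums per track for the 5' (MCP) and 3' (PCP)
#' reporters, plus their Spearman rank correlation: positively correlated
#' totals indicate normal elongation, a PCP plateau indicates premature
#' termination.
#'
#' @param tracks a quantified track collection.
#' @return list with `table` (one row per track: `track_id`,
#'   `cumulative_mcp`, `cumulative_pcp`), `rank_correlation`, and
#'   `per_frame` (the full cumulative series).
#' @export
cumulative_scatter <- function(tracks) {
  if (is.null(tracks$cumulative_pcp))
    stop("tracks must be quantified first")
  ids <- unique(tracks$track_id)
  tab <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    data.frame(track_id = id,
               cumulative_mcp = tr$cumulative_mcp[nrow(tr)],
               cumulative_pcp = tr$cumulative_pcp[nrow(tr)])
  }))
  rho <- if (nrow(tab) >= 3)
    suppressWarnings(cor(tab$cumulative_mcp, tab$cumulative_pcp,
                         method = "spearman")) else NA_real_
  list(table = tab, rank_correlation = rho,
       per_frame = tracks[, c("track_id", "frame", "cumulative_mcp",
                              "cumulative_pcp")])
}

#' Classify elongation defects from dual-reporter tracks
#'
#' PCP is considered "acquired" when `pcp_intensity` exceeds
#' `k * noise_sd` in at least two consecutive frames. Tracks are then
#' classed as: `normal` (PCP acquired within `max_normal_delay_frames` of
#' first appearance); `delayed_low_pcp` (acquired later); and, for tracks
#' that never acquire PCP, `transient_no_pcp` (span shorter than
#' `min_stable_frames`), `unstable_no_pcp` (long span but MCP coefficient
#' of variation above `cv_threshold`) or `stable_no_pcp`. The thresholds
#' are package additions for automated classification of the defect
#' categories otherwise read off montages by eye.
#'
#' @param tracks a quantified track collection.
#' @param noise_sd robust per-pixel noise SD of the PCP channel (a.u.).
#' @param k PCP acquisition threshold multiplier (default 5).
#' @param min_stable_frames minimum span counted as stable (default 10).
#' @param max_normal_delay_frames latest normal PCP onset relative to track
#'   start (default 15 frames, ~5 min at 20 s/frame).
#' @param cv_threshold MCP coefficient-of-variation bound (default 0.5).
#' @return data frame with `track_id`, `class`, `pcp_delay_frames`, `span`.
#' @export
classify_elongation_defects <- function(tracks, noise_sd, k = 5,
                                        min_stable_frames = 10L,
                                        max_normal_delay_frames = 15L,
                                        cv_threshold = 0.5) {
  if (is.null(tracks$pcp_intensity))
    stop("tracks must be quantified first")
  ids <- unique(tracks$track_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    above <- tr$frame[tr$pcp_intensity > k * noise_sd]
    acq <- if (length(above) >= 2) above[which(diff(above) == 1)[1]] else NA
    span <- max(tr$frame) - min(tr$frame) + 1L
    delay <- if (is.na(acq)) NA_integer_ else acq - min(tr$frame)
    cls <- if (!is.na(acq)) {
      if (delay <= max_normal_delay_frames) "normal" else "delayed_low_pcp"
    } else if (span < min_stable_frames) {
      "transient_no_pcp"
    } else {
      cv <- sd(tr$mcp_intensity) / mean(tr$mcp_intensity)
      if (is.finite(cv) && cv > cv_threshold) "unstable_no_pcp"
      else "stable_no_pcp"
    }
    data.frame(track_id = id, class = cls, pcp_delay_frames = delay,
               span = span)
  }))
  rownames(out) <- NULL
  out
}
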