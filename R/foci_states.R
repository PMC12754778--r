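# logical mask that is TRUE away from a border band of the given width
border_band_mask <- function(d, width) {
  m <- matrix(FALSE, d[1], d[2])
  m[(width + 1):(d[1] - width), (width + 1):(d[2] - width)] <- TRUE
  m
}

# Greedy nearest-neighbour one-to-one matching: returns, for each row of
# `d` (n_a x n_b distance matrix), the matched column or NA. Pairs are taken
# in ascending distance order; pairs beyond `gate` are never matched.
greedy_match <- function(d, gate) {
  n_a <- nrow(d); n_b <- ncol(d)
  match_a <- rep(NA_integer_, n_a)
  if (n_a == 0 || n_b == 0) return(match_a)
  ok <- which(d <= gate)
  if (!length(ok)) return(match_a)
  ord <- ok[order(d[ok])]
  used_b <- logical(n_b)
  used_a <- logical(n_a)
  for (idx in ord) {
    i <- ((idx - 1L) %% n_a) + 1L
    j <- ((idx - 1L) %/% n_a) + 1L
    if (used_a[i] || used_b[j]) next
    match_a[i] <- j
    used_a[i] <- TRUE
    used_b[j] <- TRUE
  }
  match_a
}

#' Track nuclei across a movie
#'
#' Centroids are linked frame-to-frame by greedy nearest-neighbour matching
#' within a maximum displacement (default: half the median nucleus
#' equivalent diameter). Only nuclei detected in every frame are retained;
#' each retained track maps to exactly one mask label per frame.
#'
#' @param masks list of [frame_mask()] objects (>= 2 frames).
#' @param max_disp_px maximum centroid displacement per frame; `NULL` for
#'   the automatic gate.
#' @return An object of class `nucleus_tracks`: data frame with columns
#'   `nucleus_id`, `frame`, `y`, `x`, `label`; attribute `n_frames`.
#' @export
track_nuclei <- function(masks, max_disp_px = NULL) {
  nt <- length(masks)
  if (nt < 2) stop("need at least two frames to track")
  cents <- lapply(masks, mask_centroids)
  if (is.null(max_disp_px)) {
    areas <- unlist(lapply(cents, `[[`, "area_px"))
    if (!length(areas)) stop("no objects to track")
    max_disp_px <- median(sqrt(areas / pi))   # half the equivalent diameter
  }
  c1 <- cents[[1]]
  tracks <- lapply(seq_len(nrow(c1)), function(i)
    list(y = c1$y[i], x = c1$x[i], label = c1$label[i], start = 1L))
  for (t in seq_len(nt)[-1]) {
    ct <- cents[[t]]
    live <- which(vapply(tracks, function(tr)
      length(tr$label) == t - tr$start, logical(1)))
    d <- if (length(live) && nrow(ct)) {
      py <- vapply(tracks[live], function(tr) tr$y[length(tr$y)], numeric(1))
      px <- vapply(tracks[live], function(tr) tr$x[length(tr$x)], numeric(1))
      sqrt(outer(py, ct$y, `-`)^2 + outer(px, ct$x, `-`)^2)
    } else matrix(numeric(0), length(live), nrow(ct))
    m <- greedy_match(d, max_disp_px)
    for (i in seq_along(live)) {
      if (is.na(m[i])) next
      tr <- tracks[[live[i]]]
      j <- m[i]
      tr$y <- c(tr$y, ct$y[j]); tr$x <- c(tr$x, ct$x[j])
      tr$label <- c(tr$label, ct$label[j])
      tracks[[live[i]]] <- tr
    }
    if (nrow(ct)) {
      unmatched <- setdiff(seq_len(nrow(ct)), m[!is.na(m)])
      for (j in unmatched)
        tracks[[length(tracks) + 1L]] <- list(y = ct$y[j], x = ct$x[j],
                                              label = ct$label[j], start = t)
    }
  }
  complete <- vapply(tracks, function(tr)
    tr$start == 1L && length(tr$label) == nt, logical(1))
  if (!any(complete))
    stop("no nucleus was detected across all ", nt,
         " frames; tracking produced no complete tracks")
  keep <- tracks[complete]
  out <- do.call(rbind, lapply(seq_along(keep), function(i) {
    tr <- keep[[i]]
    data.frame(nucleus_id = i, frame = seq_len(nt), y = tr$y, x = tr$x,
               label = tr$label)
  }))
  structure(out, n_frames = nt, max_disp_px = max_disp_px,
            n_discarded = sum(!complete),
            class = c("nucleus_tracks", "data.frame"))
}

#' Detect reporter foci by Laplacian of Gaussian
#'
#' LoG response (`sigma^2 * -Laplacian(G_sigma * I)`) computed over a
#' geometric ladder of scales. Each scale's response is divided by its own
#' robust noise SD (1.4826 MAD), so responses are expressed in noise-SD
#' units and comparable across scales; the per-pixel maximum over scales is
#' then searched for 8-neighbourhood local maxima above `threshold_k`
#' noise SDs, restricted to the (dilated) nucleus masks.
#'
#' @param frame numeric matrix (reporter channel, one frame).
#' @param nucleus_mask a [frame_mask()]; detections are assigned to the
#'   nucleus whose label they fall in. Detections outside all nuclei are
#'   returned in the `orphans` attribute, not assigned.
#' @param sigma_range `c(min, max)` LoG sigmas in pixels (default 1.5-4).
#' @param n_scales scales in the ladder (default 4).
#' @param threshold detection threshold in noise-SD units; `NULL` uses
#'   `threshold_k`.
#' @param threshold_k multiplier for the automatic threshold (default 5).
#' @return data frame with columns `y`, `x`, `response` (noise-SD units),
#'   `sigma`, `radius_estimate_px`, `nucleus`; attribute `orphans`.
#' @export
detect_mcp_foci <- function(frame, nucleus_mask, sigma_range = c(1.5, 4),
                            n_scales = 4L, threshold = NULL,
                            threshold_k = 5) {
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_scales))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  labels0 <- if (inherits(nucleus_mask, "FrameMask")) nucleus_mask$labels
             else nucleus_mask
  # the replicate-boundary Laplacian inflates the outermost pixel ring;
  # keep a 2-px band out of both the noise estimate and the maxima search
  interior <- border_band_mask(dim(frame), 2L)
  inmask <- labels0 > 0 & interior
  resp <- NULL; best_s <- NULL
  for (s in sigmas) {
    r <- -s^2 * cpp_conv2(gaussian_blur(frame, s), lap)
    # noise-SD units per scale; photon noise is higher inside nuclei, so
    # the robust SD is estimated where detection actually happens
    denom <- if (any(inmask)) mad(r[inmask]) else mad(r[interior])
    if (denom == 0) denom <- mad(r[interior])
    if (denom == 0) denom <- sd(r[interior])
    if (!is.finite(denom) || denom == 0) {
      resp <- matrix(0, nrow(r), ncol(r))
      best_s <- matrix(s, nrow(r), ncol(r))
      break
    }
    r <- r / denom
    if (is.null(resp)) {
      resp <- r; best_s <- matrix(s, nrow(r), ncol(r))
    } else {
      upd <- r > resp
      resp[upd] <- r[upd]; best_s[upd] <- s
    }
  }
  if (is.null(threshold)) threshold <- threshold_k
  resp[!interior] <- -Inf
  mx <- cpp_local_max(resp, threshold)
  idx <- which(mx, arr.ind = TRUE)
  det <- data.frame(y = as.numeric(idx[, 1]), x = as.numeric(idx[, 2]),
                    response = resp[mx], sigma = best_s[mx])
  det$radius_estimate_px <- det$sigma * sqrt(2)
  labels <- if (inherits(nucleus_mask, "FrameMask")) nucleus_mask$labels
            else nucleus_mask
  det$nucleus <- labels[cbind(idx[, 1], idx[, 2])]
  orphans <- det[det$nucleus == 0, , drop = FALSE]
  det <- det[det$nucleus > 0, , drop = FALSE]
  rownames(det) <- NULL
  structure(det, orphans = orphans, threshold = threshold)
}

#' Assign per-nucleus ON/OFF transcriptional states
#'
#' A nucleus is ON in a frame iff at least one reporter focus lies inside
#' its mask in that frame. Optional temporal smoothing removes ON runs
#' shorter than `min_consecutive` frames (default 1 = off). Transitions are
#' recorded at the first frame of the new state.
#'
#' @param tracks a [track_nuclei()] result.
#' @param detections data frame with columns `frame` and `nucleus` (mask
#'   label), e.g. rbind of per-frame [detect_mcp_foci()] results with a
#'   `frame` column added.
#' @param min_consecutive minimum ON run length kept.
#' @return An object of class `state_series`: list with `states` (data
#'   frame `nucleus_id`, `frame`, `state`) and `transitions` (data frame
#'   `nucleus_id`, `frame`, `type` in `"off_to_on"`/`"on_to_off"`).
#' @export
assign_states <- function(tracks, detections, min_consecutive = 1L) {
  stopifnot(inherits(tracks, "nucleus_tracks"))
  nt <- attr(tracks, "n_frames")
  ids <- unique(tracks$nucleus_id)
  states <- list(); trans <- list()
  for (id in ids) {
    tr <- tracks[tracks$nucleus_id == id, ]
    on <- logical(nt)
    for (t in seq_len(nt)) {
      lab <- tr$label[tr$frame == t]
      on[t] <- any(detections$frame == t & detections$nucleus == lab)
    }
    if (min_consecutive > 1L && any(on)) {
      r <- rle(on)
      r$values[r$values & r$lengths < min_consecutive] <- FALSE
      on <- inverse.rle(r)
    }
    states[[length(states) + 1L]] <-
      data.frame(nucleus_id = id, frame = seq_len(nt),
                 state = ifelse(on, "ON", "OFF"))
    ch <- which(diff(on) != 0) + 1L
    if (length(ch))
      trans[[length(trans) + 1L]] <-
        data.frame(nucleus_id = id, frame = ch,
                   type = ifelse(on[ch], "off_to_on", "on_to_off"))
  }
  structure(list(
    states = do.call(rbind, states),
    transitions = if (length(trans)) do.call(rbind, trans) else
      data.frame(nucleus_id = integer(0), frame = integer(0),
                 type = character(0)),
    n_frames = nt, nucleus_ids = ids
  ), class = "state_series")
}

#' Cumulative focus appearance/disappearance curves
#'
#' `pct_appeared[t]`: cumulative percentage of retained nuclei whose first
#' OFF-to-ON transition occurred at or before `t` (counting from S-phase
#' entry). `pct_disappeared[t]`: cumulative percentage that, after first
#' turning ON, had an ON-to-OFF transition at or before `t`. Both curves
#' are non-decreasing and bounded by construction, and disappearance never
#' exceeds appearance.
#'
#' @param states an [assign_states()] result.
#' @param s_phase_start_frame frame defined as S-phase entry (default 1).
#' @param frame_interval_s seconds between frames (default 20).
#' @return data frame with columns `frame`, `time_s`, `pct_appeared`,
#'   `pct_disappeared`; attribute `n_nuclei`.
#' @export
cumulative_transition_curves <- function(states, s_phase_start_frame = 1L,
                                         frame_interval_s = 20) {
  stopifnot(inherits(states, "state_series"))
  ids <- states$nucleus_ids
  n <- length(ids)
  if (n == 0) stop("zero retained nuclei")
  nt <- states$n_frames
  tr <- states$transitions
  tr <- tr[tr$frame >= s_phase_start_frame, , drop = FALSE]
  first_on <- rep(NA_integer_, n)
  lost_at <- rep(NA_integer_, n)
  for (i in seq_along(ids)) {
    ti <- tr[tr$nucleus_id == ids[i], ]
    on <- ti$frame[ti$type == "off_to_on"]
    if (!length(on)) next
    first_on[i] <- min(on)
    off <- ti$frame[ti$type == "on_to_off" & ti$frame > first_on[i]]
    if (length(off)) lost_at[i] <- min(off)
  }
  frames <- s_phase_start_frame:nt
  pct_app <- vapply(frames, function(t)
    100 * sum(!is.na(first_on) & first_on <= t) / n, numeric(1))
  pct_dis <- vapply(frames, function(t)
    100 * sum(!is.na(lost_at) & lost_at <= t) / n, numeric(1))
  structure(data.frame(
    frame = frames,
    time_s = (frames - s_phase_start_frame) * frame_interval_s,
    pct_appeared = pct_app,
    pct_disappeared = pct_dis
  ), n_nuclei = n, class = c("CumulativeCurves", "data.frame"))
}

#' Appearance half-time of a cumulative curve
#'
#' Linear interpolation of the time at which `pct_appeared` first crosses
#' half its final value (NA if the curve never reaches it).
#'
#' @param curves a [cumulative_transition_curves()] result.
#' @return time in seconds.
#' @export
appearance_halftime <- function(curves) {
  y <- curves$pct_appeared
  target <- max(y) / 2
  if (max(y) == 0) return(NA_real_)
  i <- which(y >= target)[1]
  if (i == 1) return(curves$time_s[1])
  t0 <- curves$time_s[i - 1]; t1 <- curves$time_s[i]
  y0 <- y[i - 1]; y1 <- y[i]
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}
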