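#' Per-frame intensity statistics inside a mask sequence
#'
#' For each frame, the arithmetic mean, population variance (divide by N)
#' and maximum of the channel's intensities over all mask pixels
#' (`labels > 0`). Frames with an empty mask are recorded as missing (`NA`),
#' never zero, so segmentation dropouts cannot masquerade as signal minima.
#'
#' @param movie a [projected_movie()].
#' @param masks list of [frame_mask()] objects, one per frame.
#' @param channel channel index or name.
#' @param cycle_label optional label (e.g. `"NC13"`) carried into the result.
#' @return An object of class `HubTimeSeries`: data frame with columns
#'   `frame`, `time_s`, `mean`, `variance`, `max`, plus attributes
#'   `channel`, `mask_kind`, `cycle_label`.
#' @export
mask_intensity_series <- function(movie, masks, channel,
                                  cycle_label = NA_character_) {
  stopifnot(inherits(movie, "ProjectedMovie"))
  nt <- dim(movie$data)[1]
  if (length(masks) != nt) stop("need exactly one mask per frame")
  tm <- frame_times(movie)
  out <- data.frame(frame = seq_len(nt), time_s = tm, mean = NA_real_,
                    variance = NA_real_, max = NA_real_)
  for (t in seq_len(nt)) {
    px <- get_frame(movie, t, channel)[masks[[t]]$labels > 0]
    if (length(px) == 0) next
    out$mean[t] <- mean(px)
    out$variance[t] <- pop_var(px)
    out$max[t] <- max(px)
  }
  structure(out,
            channel = if (is.character(channel)) channel else
              movie$channel_names[channel],
            mask_kind = masks[[1]]$kind,
            cycle_label = cycle_label,
            variance_kind = "population",
            class = c("HubTimeSeries", "data.frame"))
}

#' Temporal peaks of mean and variance within a time window
#'
#' Returns the maximum of each statistic restricted to frames inside the
#' window (typically the 2-min interval following kinase recruitment at
#' S-phase entry), with the time at which it occurs; ties are broken toward
#' the earliest time. Missing frames are ignored.
#'
#' @param series a [mask_intensity_series()] result.
#' @param window numeric `c(start_s, end_s)`; frames with
#'   `start_s <= time_s <= end_s` are considered.
#' @param cycle_label optional label for the summary.
#' @return An object of class `PeakSummary`: list with `peak_mean`,
#'   `t_peak_mean`, `peak_variance`, `t_peak_variance`, `window`,
#'   `cycle_label`.
#' @export
extract_temporal_peaks <- function(series, window,
                                   cycle_label = attr(series, "cycle_label")) {
  stopifnot(inherits(series, "HubTimeSeries"), length(window) == 2L)
  sel <- series$time_s >= window[1] & series$time_s <= window[2]
  if (!any(sel)) stop("window contains no frames")
  s <- series[sel, ]
  pick <- function(v) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    i <- which.max(v)    # first maximum = earliest time
    c(v[i], s$time_s[i])
  }
  pm <- pick(s$mean); pv <- pick(s$variance)
  structure(list(peak_mean = pm[1], t_peak_mean = pm[2],
                 peak_variance = pv[1], t_peak_variance = pv[2],
                 window = window, cycle_label = cycle_label),
            class = "PeakSummary")
}

#' @export
print.PeakSummary <- function(x, ...) {
  cat(sprintf(
    "PeakSummary%s: mean %.3g at %.0f s; variance %.3g at %.0f s (window %.0f..%.0f s)\n",
    if (is.na(x$cycle_label)) "" else paste0(" [", x$cycle_label, "]"),
    x$peak_mean, x$t_peak_mean, x$peak_variance, x$t_peak_variance,
    x$window[1], x$window[2]))
  invisible(x)
}

#' Per-nucleus intensity samples at selected frames
#'
#' One sample per (nucleus, frame, channel): mean and maximum intensity
#' within that nucleus's mask, suitable for pooling across embryos and for
#' box-plot comparisons between treatments.
#'
#' @param movie a [projected_movie()].
#' @param masks list of [frame_mask()] objects, one per frame of `movie`.
#' @param frames frames at which to sample.
#' @param channels channel indices or names (default all).
#' @param treatment,embryo_id labels attached to every sample.
#' @return data frame with columns `nucleus_id`, `frame`, `channel`,
#'   `mean_intensity`, `max_intensity`, `treatment`, `embryo_id`.
#' @export
per_nucleus_intensities <- function(movie, masks, frames,
                                    channels = movie$channel_names,
                                    treatment = NA_character_,
                                    embryo_id = NA_character_) {
  stopifnot(inherits(movie, "ProjectedMovie"))
  nt <- dim(movie$data)[1]
  if (any(frames < 1 | frames > nt)) stop("requested frame absent from movie")
  rows <- list()
  for (t in frames) {
    labels <- masks[[t]]$labels
    k <- max(labels)
    if (k == 0) next
    for (ch in channels) {
      img <- get_frame(movie, t, ch)
      px <- img[labels > 0]
      lab <- labels[labels > 0]
      mu <- tapply(px, lab, mean)
      mx <- tapply(px, lab, max)
      ids <- as.integer(names(mu))
      rows[[length(rows) + 1L]] <- data.frame(
        nucleus_id = ids, frame = t,
        channel = if (is.character(ch)) ch else movie$channel_names[ch],
        mean_intensity = as.numeric(mu), max_intensity = as.numeric(mx),
        treatment = treatment, embryo_id = embryo_id)
    }
  }
  if (!length(rows))
    return(data.frame(nucleus_id = integer(0), frame = integer(0),
                      channel = character(0), mean_intensity = numeric(0),
                      max_intensity = numeric(0), treatment = character(0),
                      embryo_id = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare per-nucleus intensities between two treatments
#'
#' Two-sided Mann-Whitney U test with Bonferroni correction on the chosen
#' statistic (per-nucleus mean or maximum intensity), plus the box-plot
#' summary (median, quartiles, 1.5 IQR whiskers) of each group.
#'
#' @param samples_a,samples_b [per_nucleus_intensities()] data frames (one
#'   treatment each); may pool several embryos.
#' @param statistic `"max"` (default, hub enrichment) or `"mean"`.
#' @param channel restrict to one channel name (required if several present).
#' @param n_comparisons Bonferroni m for the family this comparison is part
#'   of.
#' @return list with the `RankTestResult` (`test`), group `box_summary`s and
#'   group sizes.
#' @export
compare_treatments <- function(samples_a, samples_b,
                               statistic = c("max", "mean"), channel = NULL,
                               n_comparisons = 1L) {
  statistic <- match.arg(statistic)
  col <- paste0(statistic, "_intensity")
  pull <- function(s) {
    if (!is.null(channel)) s <- s[s$channel == channel, ]
    s[[col]]
  }
  a <- pull(samples_a); b <- pull(samples_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least two samples")
  test <- mann_whitney_u(a, b, n_comparisons = n_comparisons)
  list(test = test, statistic = statistic, channel = channel,
       box_a = box_summary(a), box_b = box_summary(b),
       n_a = length(a), n_b = length(b),
       median_a = median(a), median_b = median(b))
}
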