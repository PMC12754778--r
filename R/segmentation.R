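#' Bright-focus suppression parameters
#'
#' Pixels above `cap_threshold` are replaced by `replacement_value` before
#' blurring and thresholding, so that a handful of very bright sub-nuclear
#' foci (HLBs, hubs) cannot dominate the Otsu histogram and pull the
#' threshold above the nucleoplasmic mode.
#'
#' @param cap_threshold intensity above which pixels are replaced.
#' @param replacement_value constant substituted for capped pixels; must be
#'   strictly below `cap_threshold`.
#' @param blur_sigma_px Gaussian blur sigma (pixels) applied after
#'   suppression, before thresholding.
#' @return An object of class `SuppressionParams`.
#' @export
suppression_params <- function(cap_threshold, replacement_value,
                               blur_sigma_px = 2) {
  if (!(replacement_value < cap_threshold))
    stop("replacement_value must be strictly below cap_threshold")
  if (blur_sigma_px <= 0) stop("blur_sigma_px must be positive")
  structure(list(cap_threshold = cap_threshold,
                 replacement_value = replacement_value,
                 blur_sigma_px = blur_sigma_px),
            class = "SuppressionParams")
}

#' Automatic suppression parameters from an image
#'
#' The cap is set to a high percentile of the frame's intensities (default
#' 99.5), and the replacement value to the median of sub-cap pixels inside a
#' provisional Otsu foreground, which keeps suppressed pixels in the
#' foreground class.
#'
#' @param image numeric matrix.
#' @param cap_percentile percentile (0-100) defining the cap.
#' @inheritParams suppression_params
#' @return A [suppression_params()] object.
#' @export
auto_suppression_params <- function(image, cap_percentile = 99.5,
                                    blur_sigma_px = 2) {
  v <- as.numeric(image)
  cap <- as.numeric(quantile(v, cap_percentile / 100, names = FALSE))
  capped <- pmin(v, cap)
  thr <- tryCatch(otsu_threshold(capped), error = function(e) NA_real_)
  fg <- if (is.na(thr)) v[v <= cap] else v[v > thr & v <= cap]
  if (length(fg) == 0) fg <- v[v <= cap]
  rep_val <- median(fg)
  if (!(rep_val < cap)) rep_val <- if (is.na(thr)) cap * (1 - 1e-9) else thr
  suppression_params(cap, rep_val, blur_sigma_px)
}

#' Replace over-bright pixels with a constant
#'
#' `out[y,x] = replacement_value` where `in[y,x] > cap_threshold`, else
#' unchanged. Applied before blurring/thresholding. Never raises a pixel and
#' never touches pixels at or below the cap.
#'
#' @param image numeric matrix.
#' @param p a [suppression_params()] object.
#' @return numeric matrix of the same size.
#' @export
suppress_bright_foci <- function(image, p) {
  stopifnot(inherits(p, "SuppressionParams"))
  image[image > p$cap_threshold] <- p$replacement_value
  image
}

#' Otsu threshold over a 256-bin histogram
#'
#' Exhaustively maximises the between-class variance over the 255 cuts of a
#' 256-bin histogram spanning the image's intensity range. Per-bin sums of
#' the actual pixel values (not bin centres) are used, so the chosen
#' partition is exactly the between-class-variance maximiser among the
#' bin-boundary partitions; ties are broken toward the lowest threshold.
#' The returned value is the largest pixel intensity in the lower class, so
#' `image <= threshold` reproduces the foreground/background split exactly.
#'
#' @param image numeric matrix (or vector) with at least two distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold intensity; pixels `> threshold` are foreground.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  v <- v[!is.na(v)]
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("constant image: Otsu threshold is undefined")
  w <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(as.integer(floor((v - rng[1]) / w)) + 1L, n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  sums <- numeric(n_bins)
  rs <- rowsum(v, bin)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  cum_n <- cumsum(cnt)
  cum_s <- cumsum(sums)
  n <- length(v)
  total <- cum_s[n_bins]
  k <- seq_len(n_bins - 1L)
  w0 <- cum_n[k]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- ifelse(valid, cum_s[k] / w0, 0)
  mu1 <- ifelse(valid, (total - cum_s[k]) / w1, 0)
  bcv <- as.numeric(w0) * as.numeric(w1) * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  kbest <- which.max(bcv)   # first maximum = lowest qualifying threshold
  max(v[bin <= kbest])
}

#' Combined two-channel image for territory segmentation
#'
#' Per frame, the pixel-wise sum of two channels followed by Gaussian
#' blurring: chromosome territories and nuclei are visible in either
#' channel, and the sum improves mask stability when one channel is dim.
#'
#' @param movie a [projected_movie()].
#' @param channels length-2 vector of channel indices or names.
#' @param blur_sigma_px Gaussian sigma in pixels.
#' @return list of numeric matrices, one per frame.
#' @export
combined_channel_image <- function(movie, channels, blur_sigma_px = 2) {
  stopifnot(inherits(movie, "ProjectedMovie"), length(channels) == 2L)
  lapply(seq_len(dim(movie$data)[1]), function(t) {
    s <- get_frame(movie, t, channels[1]) + get_frame(movie, t, channels[2])
    gaussian_blur(s, blur_sigma_px)
  })
}

#' Per-frame labeled mask
#'
#' @param labels integer matrix, 0 = background, k > 0 = object id
#'   (contiguous from 1).
#' @param frame_index frame the mask belongs to.
#' @param kind `"combined_territory"` or `"nuclei"`.
#' @param params list recording the thresholds/sigmas used.
#' @return An object of class `FrameMask`.
#' @export
frame_mask <- function(labels, frame_index, kind = c("combined_territory",
                                                     "nuclei"),
                       params = list()) {
  kind <- match.arg(kind)
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0)) stop("labels must be non-negative")
  u <- sort(unique(labels[labels > 0]))
  if (length(u) && !identical(u, seq_along(u)))
    stop("object ids must be contiguous from 1")
  structure(list(labels = labels, frame_index = frame_index, kind = kind,
                 params = params),
            class = "FrameMask")
}

#' @export
print.FrameMask <- function(x, ...) {
  cat(sprintf("FrameMask (%s): frame %d, %d object(s), %d x %d px\n",
              x$kind, x$frame_index, max(x$labels), nrow(x$labels),
              ncol(x$labels)))
  invisible(x)
}

# relabel objects contiguously from 1, dropping ids in `drop`
relabel_mask <- function(labels, drop = integer()) {
  u <- setdiff(sort(unique(labels[labels > 0])), drop)
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(u)) out[labels == u[i]] <- i
  out
}

# ids of objects with any pixel on the image border
border_label_ids <- function(labels) {
  unique(c(labels[1, ], labels[nrow(labels), ],
           labels[, 1], labels[, ncol(labels)]))
}

#' Object areas of a labeled mask
#'
#' @param mask a [frame_mask()] (or plain label matrix).
#' @return named integer vector of pixel areas, one per object id.
#' @export
mask_areas <- function(mask) {
  labels <- if (inherits(mask, "FrameMask")) mask$labels else mask
  k <- max(labels)
  if (k == 0) return(setNames(integer(0), character(0)))
  setNames(tabulate(labels[labels > 0], nbins = k), seq_len(k))
}

#' Object centroids of a labeled mask
#'
#' @param mask a [frame_mask()] (or plain label matrix).
#' @return data frame with columns `label`, `y`, `x`, `area_px`.
#' @export
mask_centroids <- function(mask) {
  labels <- if (inherits(mask, "FrameMask")) mask$labels else mask
  k <- max(labels)
  if (k == 0)
    return(data.frame(label = integer(0), y = numeric(0), x = numeric(0),
                      area_px = integer(0)))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  data.frame(
    label = seq_len(k),
    y = as.numeric(tapply(idx[, 1], lab, mean)),
    x = as.numeric(tapply(idx[, 2], lab, mean)),
    area_px = as.integer(tabulate(lab, nbins = k))
  )
}

#' Segment the combined chromosome/nucleus territory
#'
#' Per frame: sum of the two channels, bright-focus suppression, Gaussian
#' blur, Otsu threshold, connected-component labeling. Empty frames yield an
#' empty mask with a warning.
#'
#' @param movie a [projected_movie()].
#' @param channels length-2 vector of channel indices or names.
#' @param p optional [suppression_params()]; by default derived per frame
#'   with [auto_suppression_params()].
#' @param cap_percentile used for automatic suppression.
#' @param blur_sigma_px Gaussian sigma.
#' @return list of [frame_mask()] objects, kind `"combined_territory"`.
#' @export
segment_combined_territory <- function(movie, channels, p = NULL,
                                       cap_percentile = 99.5,
                                       blur_sigma_px = 2) {
  stopifnot(inherits(movie, "ProjectedMovie"), length(channels) == 2L)
  nt <- dim(movie$data)[1]
  lapply(seq_len(nt), function(t) {
    img <- get_frame(movie, t, channels[1]) + get_frame(movie, t, channels[2])
    pp <- if (is.null(p))
      tryCatch(auto_suppression_params(img, cap_percentile, blur_sigma_px),
               error = function(e) NULL) else p
    sup <- if (is.null(pp)) img else suppress_bright_foci(img, pp)
    b <- gaussian_blur(sup, blur_sigma_px)
    thr <- tryCatch(otsu_threshold(b), error = function(e) NA_real_)
    if (is.na(thr) || !any(b > thr)) {
      warning("frame ", t, ": empty territory mask")
      return(frame_mask(matrix(0L, nrow(b), ncol(b)), t,
                        "combined_territory",
                        params = list(threshold = thr)))
    }
    lab <- as_matrix(EBImage::bwlabel(b > thr))
    frame_mask(relabel_mask(lab), t, "combined_territory",
               params = list(threshold = thr,
                             cap_threshold = if (is.null(pp)) NA_real_ else pp$cap_threshold,
                             blur_sigma_px = blur_sigma_px))
  })
}

#' Segment nuclei with dilation, watershed and filtering
#'
#' The nuclear-channel workflow: suppress especially bright sub-nuclear
#' signal, Gaussian blur, Otsu threshold, dilate the mask (to capture
#' reporter foci at the nuclear periphery), split touching nuclei by a
#' watershed on the distance transform, then remove objects smaller than
#' `min_area_px` and objects touching the X-Y image borders.
#'
#' @param frame numeric matrix (one frame of the nuclear channel).
#' @param p optional [suppression_params()]; automatic by default.
#' @param cap_percentile percentile for automatic suppression.
#' @param blur_sigma_px Gaussian sigma (default 2).
#' @param dilation_radius_px disc radius for mask dilation (default 3).
#' @param min_area_px minimum object area kept (default 50).
#' @param watershed_tolerance minimum distance-map depth separating two
#'   objects; default a quarter of the distance-map maximum (a merge-proof
#'   nucleus radius estimate), nucleus-radius-scaled seeding that still
#'   splits pairs overlapping by ~20% of a radius.
#' @param frame_index stored in the returned mask.
#' @return A [frame_mask()] of kind `"nuclei"`.
#' @export
segment_nuclei_rpb3 <- function(frame, p = NULL, cap_percentile = 99.5,
                                blur_sigma_px = 2, dilation_radius_px = 3L,
                                min_area_px = 50L,
                                watershed_tolerance = NULL,
                                frame_index = 1L) {
  pp <- if (is.null(p))
    tryCatch(auto_suppression_params(frame, cap_percentile, blur_sigma_px),
             error = function(e) NULL) else p
  sup <- if (is.null(pp)) frame else suppress_bright_foci(frame, pp)
  b <- gaussian_blur(sup, blur_sigma_px)
  thr <- tryCatch(otsu_threshold(b), error = function(e) NA_real_)
  empty <- frame_mask(matrix(0L, nrow(b), ncol(b)), frame_index, "nuclei",
                      params = list(threshold = thr))
  if (is.na(thr) || !any(b > thr)) return(empty)
  bin <- matrix(as.numeric(b > thr), nrow(b), ncol(b))
  if (dilation_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_radius_px) + 1L,
                                shape = "disc")
    bin <- as_matrix(EBImage::dilate(bin, brush))
  }
  dm <- as_matrix(EBImage::distmap(bin))
  if (is.null(watershed_tolerance)) {
    # the distance-map maximum estimates the (dilated) nucleus radius even
    # when touching nuclei merge into one component
    watershed_tolerance <- max(1, max(dm) / 4)
  }
  lab <- as_matrix(EBImage::watershed(dm, tolerance = watershed_tolerance,
                                      ext = 1L))
  k <- max(lab)
  if (k == 0) return(empty)
  areas <- tabulate(lab[lab > 0], nbins = k)
  drop <- unique(c(which(areas < min_area_px), border_label_ids(lab)))
  frame_mask(relabel_mask(lab, drop = drop), frame_index, "nuclei",
             params = list(threshold = thr,
                           cap_threshold = if (is.null(pp)) NA_real_ else pp$cap_threshold,
                           blur_sigma_px = blur_sigma_px,
                           dilation_radius_px = dilation_radius_px,
                           min_area_px = min_area_px,
                           watershed_tolerance = watershed_tolerance))
}

#' Export a mask sequence as label TIFF and object CSV
#'
#' Masks are written as one 16-bit label TIFF per frame plus a per-object
#' CSV (`frame, label, centroid_y, centroid_x, area_px`).
#'
#' @param masks list of [frame_mask()] objects.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths of the written files, invisibly.
#' @export
export_masks <- function(masks, dir, prefix = "mask") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  rows <- list()
  for (m in masks) {
    pth <- file.path(dir, sprintf("%s_f%04d.tif", prefix, m$frame_index))
    tiff::writeTIFF(m$labels / 65535, pth, bits.per.sample = 16L)
    paths <- c(paths, pth)
    cen <- mask_centroids(m)
    if (nrow(cen))
      rows[[length(rows) + 1L]] <- cbind(frame = m$frame_index, cen)
  }
  csv <- file.path(dir, paste0(prefix, "_objects.csv"))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), label = integer(0), y = numeric(0),
               x = numeric(0), area_px = integer(0))
  write.csv(tab, csv, row.names = FALSE)
  invisible(c(paths, csv))
}

#' Write a mask-outline overlay TIFF
#'
#' One float page per frame: the chosen channel scaled to \[0, 1\] with the
#' nucleus mask boundaries burned in at full intensity, for visual QC of
#' segmentation against the reporter signal.
#'
#' @param movie a [projected_movie()].
#' @param masks list of [frame_mask()] objects, one per frame.
#' @param channel channel index or name shown under the outlines.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_overlay <- function(movie, masks, channel, path) {
  stopifnot(inherits(movie, "ProjectedMovie"))
  nt <- dim(movie$data)[1]
  hi <- max(movie$data[, if (is.character(channel))
    match(channel, movie$channel_names) else channel, , ])
  pages <- lapply(seq_len(nt), function(t) {
    img <- get_frame(movie, t, channel) / max(hi, 1e-9)
    fg <- masks[[t]]$labels > 0
    er <- as_matrix(EBImage::erode(matrix(as.numeric(fg), nrow(fg)),
                                   EBImage::makeBrush(3, "box"))) > 0
    img[fg & !er] <- 1
    pmin(img, 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

# EBImage returns Image objects; strip to plain matrix
as_matrix <- function(x) {
  m <- EBImage::imageData(x)
  matrix(as.numeric(m), nrow(m), ncol(m))
}
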