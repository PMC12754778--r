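#' Construct a multi-channel time-lapse Z-stack movie
#'
#' `MovieStack` is the package's raw-data container: a 5-D non-negative
#' intensity array indexed `(time, z, channel, y, x)` plus acquisition
#' metadata. All downstream analysis consumes the maximum-intensity
#' projection produced by [max_project()].
#'
#' @param data 5-D numeric array with dimensions `(T, Z, C, Y, X)`.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param z_step_um axial step between Z slices in micrometres (default 0.5,
#'   the acquisition step the pipeline assumes).
#' @param frame_interval_s time between frames in seconds (default 20).
#' @param channel_names character vector naming the channels, length equal to
#'   the channel dimension.
#' @param time_origin_frame optional integer frame index defined as the start
#'   of S phase; used to report times relative to S-phase entry.
#' @return An object of class `MovieStack`.
#' @seealso [read_movie()], [max_project()]
#' @export
movie_stack <- function(data, pixel_size_um = 1, z_step_um = 0.5,
                        frame_interval_s = 20, channel_names = NULL,
                        time_origin_frame = NULL) {
  if (!is.array(data) || length(dim(data)) != 5L)
    stop("`data` must be a 5-D array (T, Z, C, Y, X)")
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  if (pixel_size_um <= 0 || z_step_um <= 0 || frame_interval_s <= 0)
    stop("pixel_size_um, z_step_um and frame_interval_s must be positive")
  nc <- dim(data)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel_names length must equal the channel dimension")
  structure(list(
    data = data,
    pixel_size_um = pixel_size_um,
    z_step_um = z_step_um,
    frame_interval_s = frame_interval_s,
    channel_names = channel_names,
    time_origin_frame = time_origin_frame
  ), class = "MovieStack")
}

#' @export
print.MovieStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("MovieStack: %d frames, %d z, %d channel(s) [%s], %d x %d px\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              d[4], d[5]))
  cat(sprintf("  frame interval %.1f s, z step %.2f um, pixel %.3f um\n",
              x$frame_interval_s, x$z_step_um, x$pixel_size_um))
  invisible(x)
}

#' Read a multi-page TIFF movie
#'
#' Pages are mapped onto the `(T, Z, C)` axes according to `axis_order`, the
#' explicit page-major ordering (slowest-varying axis first). Axis sizes that
#' cannot be inferred unambiguously from the page count must be given;
#' the function fails rather than guessing.
#'
#' @param path path to a multi-page (OME-)TIFF.
#' @param axis_order permutation of `"TZC"` giving the page ordering,
#'   slowest-varying axis first. Default `"TZC"` (channel varies fastest).
#' @param n_t,n_z,n_c axis sizes. `n_t = NULL` infers T from the page count
#'   divided by `n_z * n_c`; a non-integer ratio is an error.
#' @param intensity_scale factor by which 32-bit float pages were normalised
#'   at write time (see [write_movie()]); ignored for integer TIFFs.
#' @inheritParams movie_stack
#' @return A [movie_stack()] object. Integer TIFF data are read as stored
#'   (no 0-1 rescaling).
#' @export
read_movie <- function(path, axis_order = "TZC", n_t = NULL, n_z = 1L,
                       n_c = 1L, pixel_size_um = 1, z_step_um = 0.5,
                       frame_interval_s = 20, channel_names = NULL,
                       time_origin_frame = NULL, intensity_scale = 65535) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # integer pages come back rescaled to [0,1]: undo that; float pages are
  # stored normalised by intensity_scale (see write_movie)
  pages <- lapply(pages, function(p) {
    bps <- attr(p, "bits.per.sample")
    if (is.null(bps)) bps <- 16L
    if (bps == 32L) p * intensity_scale else round(p * (2^bps - 1))
  })
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("only single-sample (grayscale) TIFF pages are supported")
  np <- length(pages)
  if (is.null(n_t)) {
    if (np %% (n_z * n_c) != 0)
      stop("page count ", np, " is not a multiple of n_z * n_c = ", n_z * n_c,
           "; axis mapping is ambiguous")
    n_t <- np %/% (n_z * n_c)
  }
  if (n_t * n_z * n_c != np)
    stop("n_t * n_z * n_c = ", n_t * n_z * n_c,
         " does not match page count ", np)
  ax <- strsplit(toupper(axis_order), "")[[1]]
  if (length(ax) != 3L || !setequal(ax, c("T", "Z", "C")))
    stop("axis_order must be a permutation of \"TZC\"")
  sizes <- c(T = n_t, Z = n_z, C = n_c)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, dim = c(n_t, n_z, n_c, ny, nx))
  # page index for (t,z,c): mixed-radix number in the declared axis order
  ord_sizes <- sizes[ax]
  for (p in seq_len(np)) {
    idx0 <- p - 1L
    pos <- integer(3)                 # position along ax[1], ax[2], ax[3]
    pos[3] <- idx0 %% ord_sizes[3]
    pos[2] <- (idx0 %/% ord_sizes[3]) %% ord_sizes[2]
    pos[1] <- idx0 %/% (ord_sizes[3] * ord_sizes[2])
    names(pos) <- ax
    pg <- pages[[p]]
    if (!is.numeric(pg)) stop("non-numeric pixel data in page ", p)
    data[pos["T"] + 1L, pos["Z"] + 1L, pos["C"] + 1L, , ] <- pg
  }
  movie_stack(data, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
              frame_interval_s = frame_interval_s,
              channel_names = channel_names,
              time_origin_frame = time_origin_frame)
}

#' Write a movie stack as a multi-page TIFF
#'
#' Pages are written in `"TZC"` order (channel fastest). Integer modes
#' (8/16 bit) store values as-is and round-trip exactly through
#' [read_movie()]; 32-bit float mode stores `value / intensity_scale`
#' (TIFF float storage is only defined on \[0, 1\]), which [read_movie()]
#' undoes given the same scale.
#'
#' @param stack a [movie_stack()] object.
#' @param path output path.
#' @param bits_per_sample 8, 16 or 32.
#' @param intensity_scale normalisation factor for 32-bit float output;
#'   intensities must not exceed it.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path, bits_per_sample = 16L,
                        intensity_scale = 65535) {
  stopifnot(inherits(stack, "MovieStack"))
  if (!bits_per_sample %in% c(8L, 16L, 32L))
    stop("bits_per_sample must be 8, 16 or 32")
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2] * d[3])
  p <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    pg <- stack$data[t, z, ch, , ]
    if (bits_per_sample < 32L) {
      mx <- 2^bits_per_sample - 1
      if (any(pg != round(pg)) || any(pg > mx))
        stop("integer TIFF export requires integer data within [0, ", mx, "]")
      pg <- pg / mx
    } else {
      if (any(pg > intensity_scale))
        stop("float TIFF export requires intensities <= intensity_scale (",
             intensity_scale, ")")
      pg <- pg / intensity_scale
    }
    pages[[p]] <- pg
    p <- p + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Construct a projected movie directly
#'
#' Container for 4-D `(T, C, Y, X)` projected data, the input of every
#' analysis stage. Normally produced by [max_project()]; this constructor
#' exists for synthetic 2-D data.
#'
#' @param data 4-D numeric array `(T, C, Y, X)`.
#' @param provenance list recording the processing steps applied so far.
#' @inheritParams movie_stack
#' @return An object of class `ProjectedMovie`.
#' @export
projected_movie <- function(data, pixel_size_um = 1, frame_interval_s = 20,
                            channel_names = NULL, time_origin_frame = NULL,
                            provenance = list()) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4-D array (T, C, Y, X)")
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  nc <- dim(data)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel_names length must equal the channel dimension")
  structure(list(
    data = data,
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s,
    channel_names = channel_names,
    time_origin_frame = time_origin_frame,
    provenance = provenance
  ), class = "ProjectedMovie")
}

#' @export
print.ProjectedMovie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ProjectedMovie: %d frames, %d channel(s) [%s], %d x %d px\n",
              d[1], d[2], paste(x$channel_names, collapse = ", "), d[3], d[4]))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "op"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' Maximum-intensity projection along Z
#'
#' `out[t, c, y, x] = max_z in[t, z, c, y, x]`. Metadata are carried over
#' (minus the Z step); the operation is recorded in provenance.
#'
#' @param stack a [movie_stack()] object with at least one Z slice.
#' @return A [projected_movie()].
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "MovieStack"))
  d <- dim(stack$data)
  out <- array(0, dim = d[c(1, 3, 4, 5)])
  for (t in seq_len(d[1])) for (ch in seq_len(d[3])) {
    if (d[2] == 1L) {
      out[t, ch, , ] <- stack$data[t, 1, ch, , ]
    } else {
      sl <- stack$data[t, , ch, , , drop = FALSE]
      dim(sl) <- d[c(2, 4, 5)]
      out[t, ch, , ] <- apply(sl, c(2, 3), max)
    }
  }
  projected_movie(out, pixel_size_um = stack$pixel_size_um,
                  frame_interval_s = stack$frame_interval_s,
                  channel_names = stack$channel_names,
                  time_origin_frame = stack$time_origin_frame,
                  provenance = list(list(op = "max_project", n_z = d[2])))
}

# Ball (hemisphere) structuring element: heights sqrt(r^2 - d^2), NA outside
ball_se <- function(radius) {
  r <- floor(radius)
  g <- seq(-r, r)
  d2 <- outer(g^2, g^2, `+`)
  h <- suppressWarnings(sqrt(radius^2 - d2))
  h[d2 > radius^2] <- NA_real_
  h
}

block_min <- function(img, s) {
  ny <- nrow(img); nx <- ncol(img)
  by <- ceiling(ny / s); bx <- ceiling(nx / s)
  # replicate-pad to a multiple of s
  ri <- pmin(rep(seq_len(by * s), length.out = by * s), ny)
  ci <- pmin(seq_len(bx * s), nx)
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(Inf, by, bx)
  for (dy in seq_len(s)) for (dx in seq_len(s)) {
    out <- pmin(out, pad[seq(dy, by * s, by = s), seq(dx, bx * s, by = s),
                         drop = FALSE])
  }
  out
}

enlarge_bilinear <- function(small, ny, nx, s) {
  # block centres of the shrunk grid sit at (i-1)*s + (s+1)/2 in the original
  yy <- (seq_len(ny) - (s + 1) / 2) / s + 1
  xx <- (seq_len(nx) - (s + 1) / 2) / s + 1
  yy <- pmin(pmax(yy, 1), nrow(small))
  xx <- pmin(pmax(xx, 1), ncol(small))
  y0 <- pmin(floor(yy), nrow(small) - 1L); y0[nrow(small) == 1] <- 1L
  x0 <- pmin(floor(xx), ncol(small) - 1L); x0[ncol(small) == 1] <- 1L
  y1 <- pmin(y0 + 1L, nrow(small)); x1 <- pmin(x0 + 1L, ncol(small))
  fy <- yy - y0; fx <- xx - x0
  small[y0, x0, drop = FALSE] * ((1 - fy) %o% (1 - fx)) +
    small[y1, x0, drop = FALSE] * (fy %o% (1 - fx)) +
    small[y0, x1, drop = FALSE] * ((1 - fy) %o% fx) +
    small[y1, x1, drop = FALSE] * (fy %o% fx)
}

#' Rolling-ball background estimate of a single image
#'
#' Grayscale morphological opening with a ball (hemisphere) structuring
#' element of the given radius: the surface traced by a ball rolling under
#' the intensity landscape. For radii above 16 px the image is min-pooled by
#' a shrink factor (4 up to radius 64, 8 beyond), the ball rolled at reduced
#' scale and the background bilinearly enlarged, trading sub-percent accuracy
#' for speed on large radii.
#'
#' @param img numeric matrix `(Y, X)`.
#' @param radius ball radius in pixels (>= 1, smaller than the image extent).
#' @return background matrix, everywhere `<= img`.
#' @export
rolling_ball_background <- function(img, radius) {
  if (radius < 1) stop("radius must be >= 1")
  if (radius >= min(dim(img)))
    stop("rolling-ball radius (", radius, ") exceeds image extent")
  s <- if (radius <= 16) 1L else if (radius <= 64) 4L else 8L
  if (s == 1L) {
    se <- ball_se(radius)
    bg <- cpp_gray_morph(cpp_gray_morph(img, se, TRUE), se, FALSE)
  } else {
    small <- block_min(img, s)
    se <- ball_se(radius / s)
    op <- cpp_gray_morph(cpp_gray_morph(small, se, TRUE), se, FALSE)
    bg <- enlarge_bilinear(op, nrow(img), ncol(img), s)
  }
  pmin(bg, img)
}

#' Rolling-ball background subtraction
#'
#' Subtracts a [rolling_ball_background()] estimate from every frame and
#' channel independently, clamping negative residuals to zero. The radius is
#' recorded in provenance.
#'
#' @param movie a [projected_movie()].
#' @param rolling_ball_radius_px ball radius in pixels (default 50).
#' @return the background-subtracted [projected_movie()].
#' @export
subtract_background <- function(movie, rolling_ball_radius_px = 50L) {
  stopifnot(inherits(movie, "ProjectedMovie"))
  d <- dim(movie$data)
  out <- movie
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    img <- movie$data[t, ch, , ]
    bg <- rolling_ball_background(img, rolling_ball_radius_px)
    out$data[t, ch, , ] <- pmax(img - bg, 0)
  }
  out$provenance <- c(out$provenance,
                      list(list(op = "subtract_background",
                                rolling_ball_radius_px = rolling_ball_radius_px)))
  out
}

#' Crop a spatial subregion of a projected movie
#'
#' All time and channel planes are cropped identically. The crop offset is
#' recorded in provenance so coordinates can be mapped back with
#' [map_to_original()].
#'
#' @param movie a [projected_movie()].
#' @param region named numeric vector `c(y, x, height, width)`: 1-based
#'   top-left corner and size.
#' @return the cropped [projected_movie()].
#' @export
crop_interior <- function(movie, region) {
  stopifnot(inherits(movie, "ProjectedMovie"))
  y <- region[["y"]]; x <- region[["x"]]
  h <- region[["height"]]; w <- region[["width"]]
  d <- dim(movie$data)
  if (y < 1 || x < 1 || h < 1 || w < 1 || y + h - 1 > d[3] || x + w - 1 > d[4])
    stop("crop rectangle out of bounds")
  out <- movie
  out$data <- movie$data[, , y:(y + h - 1), x:(x + w - 1), drop = FALSE]
  out$provenance <- c(out$provenance,
                      list(list(op = "crop", offset_y = y - 1L,
                                offset_x = x - 1L)))
  out
}

#' Map cropped coordinates back to the original frame
#'
#' Adds up the crop offsets recorded in provenance.
#'
#' @param movie a (possibly repeatedly) cropped [projected_movie()].
#' @param coords data frame with columns `y` and `x` in the movie's current
#'   coordinate system.
#' @return `coords` with `y`, `x` translated to original-frame coordinates.
#' @export
map_to_original <- function(movie, coords) {
  stopifnot(inherits(movie, "ProjectedMovie"))
  oy <- 0L; ox <- 0L
  for (st in movie$provenance) {
    if (identical(st$op, "crop")) {
      oy <- oy + st$offset_y
      ox <- ox + st$offset_x
    }
  }
  coords$y <- coords$y + oy
  coords$x <- coords$x + ox
  coords
}

#' Extract a single frame/channel image
#'
#' @param movie a [projected_movie()].
#' @param frame frame index (1-based).
#' @param channel channel index or name.
#' @return numeric matrix `(Y, X)`.
#' @export
get_frame <- function(movie, frame, channel = 1L) {
  stopifnot(inherits(movie, "ProjectedMovie"))
  if (is.character(channel)) {
    channel <- match(channel, movie$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  d <- dim(movie$data)
  if (frame < 1 || frame > d[1]) stop("frame out of range")
  movie$data[frame, channel, , ]
}

#' Frame times in seconds
#'
#' Times are relative to `time_origin_frame` (S-phase entry) when set,
#' otherwise to the first frame.
#'
#' @param movie a [projected_movie()].
#' @return numeric vector of length `T`.
#' @export
frame_times <- function(movie) {
  stopifnot(inherits(movie, "ProjectedMovie"))
  origin <- if (is.null(movie$time_origin_frame)) 1L else movie$time_origin_frame
  (seq_len(dim(movie$data)[1]) - origin) * movie$frame_interval_s
}
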