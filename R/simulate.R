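#' Synthetic movie scene specification
#'
#' Describes a scene for [simulate_movie()]: image geometry, nuclei and
#' their drift, channels, point-spread function and the noise model
#' (Poisson photon noise plus Gaussian read noise). The seed fully
#' determines the rendered movie.
#'
#' Channel names determine what is rendered into them: `"rpb3"`, `"brd4"`,
#' `"cdc7"` are nuclear-protein channels (nucleoplasmic fill plus any
#' scheduled hub foci); `"mcp"` and `"pcp"` are reporter channels (faint
#' diffuse nucleoplasmic background, heavily smoothed, plus scheduled
#' transcription spots).
#'
#' @param width,height image size in pixels (default 160, a ~35 um field
#'   at the default pixel size, holding ~10 blastoderm nuclei).
#' @param n_frames number of time points.
#' @param n_z Z slices per time point (default 3); the focal plane is the
#'   middle slice, out-of-focus slices are attenuated by a Gaussian axial
#'   profile of width `defocus_sigma_um`.
#' @param n_nuclei number of nuclei.
#' @param nucleus_radius_px,nucleus_radius_sd mean and SD of nucleus radii.
#' @param drift_sd_px per-frame random-walk displacement SD of each nucleus.
#' @param channels channel names (see Details).
#' @param bg_level extracellular background intensity (a.u.).
#' @param nucleoplasm_level nucleoplasmic intensity in nuclear-protein
#'   channels.
#' @param reporter_nucleoplasm_level faint diffuse level of unbound coat
#'   protein in reporter channels.
#' @param psf_sd_px Gaussian PSF sigma for foci and spots.
#' @param edge_sigma_px width of the nuclear edge (linear roll-off).
#' @param spot_snr amplitude of reporter spots and hub foci, in units of
#'   the local per-pixel noise SD (default 10).
#' @param photon_scale photons per intensity unit for Poisson noise
#'   (`Inf` disables photon noise).
#' @param read_noise_sd Gaussian read noise SD (a.u.).
#' @param mitosis_frames frames rendered as mitotic: nuclei shrink to 60%
#'   radius, approximating chromosome condensation.
#' @param frame_interval_s,pixel_size_um,z_step_um acquisition metadata.
#' @param defocus_sigma_um axial extent of the foreground signal.
#' @param time_origin_frame frame defined as S-phase entry.
#' @param seed integer RNG seed; all stochastic choices of the simulation
#'   are drawn from this single stream in documented order.
#' @return An object of class `SceneSpec`.
#' @export
scene_spec <- function(width = 160L, height = 160L, n_frames = 40L,
                       n_z = 3L, n_nuclei = 10L, nucleus_radius_px = 11,
                       nucleus_radius_sd = 1, drift_sd_px = 0.3,
                       channels = c("rpb3", "mcp"), bg_level = 20,
                       nucleoplasm_level = 60,
                       reporter_nucleoplasm_level = 10, psf_sd_px = 1.5,
                       edge_sigma_px = 1, spot_snr = 10,
                       photon_scale = 1, read_noise_sd = 2,
                       mitosis_frames = integer(0),
                       frame_interval_s = 20, pixel_size_um = 0.22,
                       z_step_um = 0.5, defocus_sigma_um = 0.6,
                       time_origin_frame = 1L, seed = 1L) {
  stopifnot(width > 0, height > 0, n_frames >= 1, n_z >= 1, n_nuclei >= 0,
            nucleus_radius_px > 0, nucleus_radius_sd >= 0,
            drift_sd_px >= 0, read_noise_sd >= 0, spot_snr >= 0)
  structure(as.list(environment()), class = "SceneSpec")
}

# per-pixel noise SD at a given clean intensity level
sim_noise_sd <- function(spec, level) {
  pois_var <- if (is.infinite(spec$photon_scale)) 0 else level / spec$photon_scale
  sqrt(pois_var + spec$read_noise_sd^2)
}

# amplitude reference: one noise SD, floored at 1 a.u. so that noise-free
# renders still carry foci/spots of amplitude spot_snr
sim_amp_ref <- function(spec, level) max(sim_noise_sd(spec, level), 1)

#' Hub (focus) schedule
#'
#' One row per (nucleus, channel) focus: the frame it appears, the frame it
#' disperses (exclusive), its amplitude in local-noise-SD units, and its
#' sub-nuclear position as a fraction of the nucleus radius (`NA` = drawn
#' at render time).
#'
#' @param nucleus_id,channel,appearance_frame,dispersal_frame,amplitude_snr
#'   vectors (recycled) defining the schedule.
#' @param rel_y,rel_x sub-nuclear offsets in units of nucleus radius.
#' @return data frame of class `HubSchedule`.
#' @export
hub_schedule <- function(nucleus_id, channel, appearance_frame,
                         dispersal_frame, amplitude_snr,
                         rel_y = NA_real_, rel_x = NA_real_) {
  out <- data.frame(nucleus_id = nucleus_id, channel = channel,
                    appearance_frame = appearance_frame,
                    dispersal_frame = dispersal_frame,
                    amplitude_snr = amplitude_snr,
                    rel_y = rel_y, rel_x = rel_x)
  if (any(out$appearance_frame >= out$dispersal_frame))
    stop("appearance_frame must precede dispersal_frame")
  class(out) <- c("HubSchedule", "data.frame")
  out
}

#' Transcription spot schedule
#'
#' One locus per row: the frame its 5' (MCP) signal turns ON, the frame it
#' turns OFF (`NA` = stays ON), the 3' (PCP) onset delay and attenuation,
#' a per-frame dropout probability (detection realism), and its elongation
#' class.
#'
#' @param nucleus_id nucleus carrying the locus.
#' @param onset_frame first ON frame of the MCP signal.
#' @param off_frame first frame after the MCP signal ends (`NA` = never).
#' @param pcp_delay_frames elongation delay between 5' and 3' signal onset.
#' @param pcp_attenuation multiplicative factor on the PCP amplitude.
#' @param pcp_never logical: locus never acquires PCP (elongation failure).
#' @param dropout_prob per-frame probability that an ON spot is not
#'   rendered (transient undetectability).
#' @param class elongation class label; `NULL` derives it from the other
#'   fields.
#' @return data frame of class `SpotSchedule`, one row per locus.
#' @export
spot_schedule <- function(nucleus_id, onset_frame, off_frame = NA_integer_,
                          pcp_delay_frames = 10L, pcp_attenuation = 1,
                          pcp_never = FALSE, dropout_prob = 0,
                          class = NULL) {
  out <- data.frame(nucleus_id = nucleus_id, onset_frame = onset_frame,
                    off_frame = off_frame,
                    pcp_delay_frames = pcp_delay_frames,
                    pcp_attenuation = pcp_attenuation,
                    pcp_never = pcp_never, dropout_prob = dropout_prob)
  out$locus_id <- seq_len(nrow(out))
  if (is.null(class)) {
    class <- ifelse(out$pcp_never,
                    ifelse(is.na(out$off_frame), "stable_no_pcp",
                           "transient_no_pcp"),
                    ifelse(out$pcp_attenuation < 1 |
                             out$pcp_delay_frames > 12, "delayed_low_pcp",
                           "normal"))
  }
  out$class <- class
  structure(out, class = c("SpotSchedule", "data.frame"))
}

#' Named perturbation regimes
#'
#' Parameter bundles emulating the study's perturbation contrasts, each
#' differing from `control` only in the stated directions. The magnitudes
#' are synthetic calibrations (the source data report directions, not
#' printed distributions):
#' \describe{
#'   \item{control}{hub foci appear at S-phase entry and disperse after
#'     ~2 min; reporter spots turn ON synchronously within ~4 min, rarely
#'     turn OFF, and all acquire the 3' signal after a 10-frame (~3.3 min)
#'     elongation delay.}
#'   \item{cdc7i_like}{kinase foci attenuated and delayed, bookmark foci
#'     persist longer; spot onset delayed and desynchronised, frequent
#'     early loss, a fraction of loci never acquire PCP and the rest
#'     acquire it late and attenuated.}
#'   \item{cbp_kd_like}{hub amplitudes zero (no bookmarks).}
#'   \item{jq1_like}{bookmark-reader foci strongly attenuated; kinase foci
#'     delayed.}
#' }
#'
#' @param name regime name.
#' @param spec a [scene_spec()]; schedules are drawn deterministically from
#'   `spec$seed`.
#' @return list with elements `hubs` (a [hub_schedule()]) and `spots`
#'   (a [spot_schedule()]).
#' @export
make_regime <- function(name = c("control", "cdc7i_like", "cbp_kd_like",
                                 "jq1_like"), spec) {
  name <- match.arg(name)
  stopifnot(inherits(spec, "SceneSpec"))
  n <- spec$n_nuclei
  nf <- spec$n_frames
  set.seed(spec$seed + 1000003L)     # schedule stream, separate from render
  pars <- switch(name,
    control = list(brd4_amp = 10, brd4_disp = 7L, cdc7_amp = 10,
                   cdc7_app = 1L, cdc7_disp = 7L,
                   onset_lo = 3L, onset_hi = 12L, loss_frac = 0.1,
                   loss_after_lo = 6L, loss_after_hi = 15L,
                   pcp_never_frac = 0, pcp_delay = 10L, pcp_att = 1,
                   dropout = 0),
    cdc7i_like = list(brd4_amp = 10, brd4_disp = 15L, cdc7_amp = 3,
                      cdc7_app = 6L, cdc7_disp = 12L,
                      onset_lo = 8L, onset_hi = 28L, loss_frac = 0.45,
                      loss_after_lo = 3L, loss_after_hi = 10L,
                      pcp_never_frac = 0.4, pcp_delay = 15L, pcp_att = 0.3,
                      dropout = 0),
    cbp_kd_like = list(brd4_amp = 0, brd4_disp = 7L, cdc7_amp = 0,
                       cdc7_app = 1L, cdc7_disp = 7L,
                       onset_lo = 3L, onset_hi = 12L, loss_frac = 0.1,
                       loss_after_lo = 6L, loss_after_hi = 15L,
                       pcp_never_frac = 0, pcp_delay = 10L, pcp_att = 1,
                       dropout = 0),
    jq1_like = list(brd4_amp = 2.5, brd4_disp = 7L, cdc7_amp = 8,
                    cdc7_app = 4L, cdc7_disp = 10L,
                    onset_lo = 3L, onset_hi = 12L, loss_frac = 0.1,
                    loss_after_lo = 6L, loss_after_hi = 15L,
                    pcp_never_frac = 0, pcp_delay = 10L, pcp_att = 1,
                    dropout = 0))
  ids <- seq_len(n)
  hubs <- rbind(
    hub_schedule(ids, "brd4", 1L, min(pars$brd4_disp, nf + 1L),
                 pars$brd4_amp),
    hub_schedule(ids, "cdc7", min(pars$cdc7_app, nf),
                 min(pars$cdc7_disp, nf + 1L), pars$cdc7_amp))
  class(hubs) <- c("HubSchedule", "data.frame")
  onset <- sample(pars$onset_lo:pars$onset_hi, n, replace = TRUE)
  lose <- runif(n) < pars$loss_frac
  off <- ifelse(lose, onset + sample(pars$loss_after_lo:pars$loss_after_hi,
                                     n, replace = TRUE), NA_integer_)
  never <- runif(n) < pars$pcp_never_frac
  spots <- spot_schedule(ids, pmin(onset, nf), pmin(off, nf + 1L),
                         pcp_delay_frames = pars$pcp_delay,
                         pcp_attenuation = pars$pcp_att,
                         pcp_never = never, dropout_prob = pars$dropout)
  list(hubs = hubs, spots = spots, name = name)
}

# linear-edge disk weight on a local patch; returns list(rows, cols, w)
disk_patch <- function(cy, cx, r, edge, ny, nx) {
  ys <- max(1L, floor(cy - r - 2)):min(ny, ceiling(cy + r + 2))
  xs <- max(1L, floor(cx - r - 2)):min(nx, ceiling(cx + r + 2))
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  w <- pmin(pmax((r + 0.5 - d) / max(edge, 1e-6), 0), 1)
  list(ys = ys, xs = xs, w = w)
}

gauss_patch <- function(cy, cx, sd, ny, nx, extent = 4) {
  ys <- max(1L, floor(cy - extent * sd)):min(ny, ceiling(cy + extent * sd))
  xs <- max(1L, floor(cx - extent * sd)):min(nx, ceiling(cx + extent * sd))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  list(ys = ys, xs = xs, w = exp(-d2 / (2 * sd^2)))
}

#' Render a synthetic movie with ground truth
#'
#' Renders drifting nuclei (linear-edge disks), scheduled hub foci and
#' dual-channel transcription spots (2-D Gaussians of the PSF width),
#' applies Poisson photon noise then Gaussian read noise, and returns both
#' the 5-D movie stack and a machine-readable ground-truth record. The
#' output is fully determined by `spec$seed`; random draws happen in a
#' fixed order (nucleus placement, radii, drift, hub offsets, spot offsets,
#' dropout, pixel noise).
#'
#' @param spec a [scene_spec()].
#' @param hubs optional [hub_schedule()].
#' @param spots optional [spot_schedule()].
#' @return list with elements `stack` (a [movie_stack()]) and `truth`
#'   (class `GroundTruth`: nucleus positions per frame, absolute hub and
#'   spot schedules, true state series, noise-free per-spot intensities and
#'   noise levels).
#' @export
simulate_movie <- function(spec, hubs = NULL, spots = NULL) {
  stopifnot(inherits(spec, "SceneSpec"))
  if (!is.null(hubs) && nrow(hubs) &&
      any(!hubs$nucleus_id %in% seq_len(spec$n_nuclei)))
    stop("hub schedule references nonexistent nuclei")
  if (!is.null(spots) && nrow(spots) &&
      any(!spots$nucleus_id %in% seq_len(spec$n_nuclei)))
    stop("spot schedule references nonexistent nuclei")
  ny <- spec$height; nx <- spec$width
  n <- spec$n_nuclei; nf <- spec$n_frames; nzs <- spec$n_z
  chs <- spec$channels
  set.seed(spec$seed)

  # 1. nucleus placement: rejection sampling with margin and min separation
  margin <- spec$nucleus_radius_px + 8
  min_sep <- 2.4 * spec$nucleus_radius_px
  cy <- numeric(0); cx <- numeric(0)
  tries <- 0L
  while (length(cy) < n && tries < 20000L) {
    tries <- tries + 1L
    py <- runif(1, margin, ny - margin)
    px <- runif(1, margin, nx - margin)
    if (!length(cy) || all(sqrt((cy - py)^2 + (cx - px)^2) >= min_sep)) {
      cy <- c(cy, py); cx <- c(cx, px)
    }
  }
  if (length(cy) < n)
    stop("could not place ", n, " nuclei at this density; ",
         "reduce n_nuclei or enlarge the image")
  # 2. radii
  radii <- pmax(3, rnorm(n, spec$nucleus_radius_px, spec$nucleus_radius_sd))
  # 3. drift: reflected cumulative random walk
  posy <- matrix(0, nf, n); posx <- matrix(0, nf, n)
  posy[1, ] <- cy; posx[1, ] <- cx
  if (nf > 1) for (t in 2:nf) {
    posy[t, ] <- posy[t - 1, ] + rnorm(n, 0, spec$drift_sd_px)
    posx[t, ] <- posx[t - 1, ] + rnorm(n, 0, spec$drift_sd_px)
    posy[t, ] <- pmin(pmax(posy[t, ], margin), ny - margin)
    posx[t, ] <- pmin(pmax(posx[t, ], margin), nx - margin)
  }
  # 4. hub sub-nuclear offsets
  if (!is.null(hubs) && nrow(hubs)) {
    for (i in seq_len(nrow(hubs))) {
      if (is.na(hubs$rel_y[i]) || is.na(hubs$rel_x[i])) {
        a <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * 0.4
        hubs$rel_y[i] <- rr * sin(a); hubs$rel_x[i] <- rr * cos(a)
      }
    }
  }
  # 5. spot sub-nuclear offsets (fixed relative position, moves with nucleus)
  if (!is.null(spots) && nrow(spots)) {
    a <- runif(nrow(spots), 0, 2 * pi)
    rr <- sqrt(runif(nrow(spots))) * 0.5
    spots$rel_y <- rr * sin(a); spots$rel_x <- rr * cos(a)
    # 6. dropout draws, one per locus x frame (shared by both channels)
    drop_mat <- matrix(runif(nrow(spots) * nf), nrow(spots), nf) <
      spots$dropout_prob
  }

  nuclear_chs <- intersect(chs, c("rpb3", "brd4", "cdc7"))
  noise_nuc <- sim_noise_sd(spec, spec$bg_level + spec$nucleoplasm_level)
  noise_rep <- sim_noise_sd(spec, spec$bg_level +
                              spec$reporter_nucleoplasm_level)
  amp_nuc <- sim_amp_ref(spec, spec$bg_level + spec$nucleoplasm_level)
  amp_rep <- sim_amp_ref(spec, spec$bg_level +
                           spec$reporter_nucleoplasm_level)
  zc <- (nzs + 1) / 2
  fz <- exp(-0.5 * (((seq_len(nzs) - zc) * spec$z_step_um) /
                      spec$defocus_sigma_um)^2)

  mcp_amp <- spec$spot_snr * amp_rep
  truth_nuc <- list(); truth_spot <- list()
  data <- array(0, dim = c(nf, nzs, length(chs), ny, nx))

  for (t in seq_len(nf)) {
    rad_t <- if (t %in% spec$mitosis_frames) 0.6 * radii else radii
    for (ci in seq_along(chs)) {
      ch <- chs[ci]
      fg <- matrix(0, ny, nx)
      if (ch %in% nuclear_chs) {
        for (k in seq_len(n)) {
          p <- disk_patch(posy[t, k], posx[t, k], rad_t[k],
                          spec$edge_sigma_px, ny, nx)
          fg[p$ys, p$xs] <- fg[p$ys, p$xs] + spec$nucleoplasm_level * p$w
        }
        if (!is.null(hubs) && nrow(hubs)) {
          hh <- hubs[hubs$channel == ch & hubs$appearance_frame <= t &
                       hubs$dispersal_frame > t, , drop = FALSE]
          for (i in seq_len(nrow(hh))) {
            k <- hh$nucleus_id[i]
            hy <- posy[t, k] + hh$rel_y[i] * rad_t[k]
            hx <- posx[t, k] + hh$rel_x[i] * rad_t[k]
            g <- gauss_patch(hy, hx, spec$psf_sd_px, ny, nx)
            fg[g$ys, g$xs] <- fg[g$ys, g$xs] +
              hh$amplitude_snr[i] * amp_nuc * g$w
          }
        }
      } else {
        # reporter channel: diffuse unbound coat protein, heavily smoothed
        for (k in seq_len(n)) {
          p <- disk_patch(posy[t, k], posx[t, k], rad_t[k],
                          spec$edge_sigma_px, ny, nx)
          fg[p$ys, p$xs] <- fg[p$ys, p$xs] +
            spec$reporter_nucleoplasm_level * p$w
        }
        fg <- gaussian_blur(fg, 3)
        if (!is.null(spots) && nrow(spots)) {
          for (i in seq_len(nrow(spots))) {
            k <- spots$nucleus_id[i]
            on_mcp <- t >= spots$onset_frame[i] &&
              (is.na(spots$off_frame[i]) || t < spots$off_frame[i])
            on_pcp <- !spots$pcp_never[i] &&
              t >= spots$onset_frame[i] + spots$pcp_delay_frames[i] &&
              (is.na(spots$off_frame[i]) || t < spots$off_frame[i])
            rendered <- !drop_mat[i, t]
            amp <- if (ch == "mcp") {
              if (on_mcp && rendered) mcp_amp else 0
            } else {
              if (on_pcp && rendered) mcp_amp * spots$pcp_attenuation[i]
              else 0
            }
            sy <- posy[t, k] + spots$rel_y[i] * rad_t[k]
            sx <- posx[t, k] + spots$rel_x[i] * rad_t[k]
            if (amp > 0) {
              g <- gauss_patch(sy, sx, spec$psf_sd_px, ny, nx)
              fg[g$ys, g$xs] <- fg[g$ys, g$xs] + amp * g$w
            }
            if (ch == "mcp")
              truth_spot[[length(truth_spot) + 1L]] <- data.frame(
                frame = t, locus_id = spots$locus_id[i], nucleus_id = k,
                y = sy, x = sx, mcp_on = on_mcp, pcp_on = on_pcp,
                rendered = rendered && on_mcp,
                mcp_amp = if (on_mcp) mcp_amp else 0,
                pcp_amp = if (on_pcp) mcp_amp * spots$pcp_attenuation[i]
                          else 0)
          }
        }
      }
      for (z in seq_len(nzs)) {
        clean <- spec$bg_level + fz[z] * fg
        noisy <- if (is.infinite(spec$photon_scale)) clean else
          rpois(length(clean), clean * spec$photon_scale) /
            spec$photon_scale
        if (spec$read_noise_sd > 0)
          noisy <- noisy + rnorm(length(clean), 0, spec$read_noise_sd)
        data[t, z, ci, , ] <- matrix(pmax(noisy, 0), ny, nx)
      }
    }
    truth_nuc[[t]] <- data.frame(frame = t, nucleus_id = seq_len(n),
                                 y = posy[t, ], x = posx[t, ],
                                 radius = rad_t)
  }

  state_truth <- NULL
  if (!is.null(spots) && nrow(spots)) {
    state_truth <- do.call(rbind, lapply(seq_len(nrow(spots)), function(i) {
      on <- seq_len(nf) >= spots$onset_frame[i] &
        (is.na(spots$off_frame[i]) | seq_len(nf) < spots$off_frame[i])
      data.frame(nucleus_id = spots$nucleus_id[i], frame = seq_len(nf),
                 state = ifelse(on, "ON", "OFF"))
    }))
  }

  truth <- structure(list(
    nuclei = do.call(rbind, truth_nuc),
    hubs = hubs,
    spots = spots,
    spot_frames = if (length(truth_spot)) do.call(rbind, truth_spot)
                  else NULL,
    state_truth = state_truth,
    noise_sd = c(nuclear = noise_nuc, reporter = noise_rep),
    spot_amplitude = mcp_amp,
    seed = spec$seed
  ), class = "GroundTruth")

  stack <- movie_stack(data, pixel_size_um = spec$pixel_size_um,
                       z_step_um = spec$z_step_um,
                       frame_interval_s = spec$frame_interval_s,
                       channel_names = chs,
                       time_origin_frame = spec$time_origin_frame)
  list(stack = stack, truth = truth)
}

#' Write a ground-truth record as JSON
#'
#' @param truth a `GroundTruth` from [simulate_movie()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
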