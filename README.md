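# hubtrack

Quantification of transcriptional hubs and live transcription-reporter
dynamics in time-lapse confocal movies of early *Drosophila* embryos.

During the rapid nuclear division cycles of the syncytial blastoderm,
bromodomain protein Brd4 marks select loci through mitosis ("mitotic
bookmarks"), the replication-initiation kinase Cdc7/DDK transiently
co-clusters with these marks at S-phase entry ("early-replicating hubs"),
and stem-loop reporters (MS2/MCP in the 5′UTR, PP7/PCP in the 3′UTR) make
transcription initiation and completed elongation visible as
diffraction-limited fluorescent spots. `hubtrack` implements the image
quantification that turns such movies into numbers:

- **Preparation** — maximum-intensity projection of T×Z×C×Y×X TIFF stacks,
  rolling-ball background subtraction (ball structuring element, default
  radius 50 px), interior cropping with coordinate-mapping provenance.
- **Segmentation** — Otsu thresholding (exhaustive 256-bin between-class
  variance maximisation, exact lowest-threshold tie-break) after
  *bright-focus suppression* (pixels above a cap are replaced by a
  sub-cap constant so hubs and histone-locus bodies cannot distort the
  histogram), on either the summed two-channel "territory" image or the
  nuclear channel with dilation, distance-transform watershed splitting
  and small/border object filtering.
- **Hub dynamics** — per-frame mean / population-variance / maximum
  intensity inside masks; temporal peaks of mean and variance within a
  declared window (e.g. the 2-minute interval after kinase recruitment);
  per-nucleus samples pooled across embryos and compared between
  treatments by a two-sided Mann–Whitney U test with Bonferroni
  correction and 1.5 IQR box summaries.
- **ON/OFF state kinetics** — nucleus tracking (greedy nearest-neighbour,
  full-movie completeness requirement), multiscale Laplacian-of-Gaussian
  focus detection with per-scale noise normalisation, presence-based
  per-nucleus ON/OFF states, and cumulative appearance/disappearance
  curves relative to S-phase entry.
- **Dual-reporter elongation** — difference-of-Gaussians spot detection
  with sub-pixel refinement, nearest-neighbour linking with gap closing
  (≤ 5 missing frames), 17×17-pixel window quantification of both
  channels centred on the MCP spot, appearance/PCP-total track sorting,
  montages, cumulative MCP-vs-PCP scatter and elongation-defect
  classification.
- **Synthetic movies** — a seeded generator that renders drifting nuclei,
  scheduled hub foci and dual-channel reporter spots under Poisson +
  Gaussian read noise, together with machine-readable ground truth, plus
  named perturbation regimes (`control`, `cdc7i_like`, `cbp_kd_like`,
  `jq1_like`) so every stage is testable without raw imaging data.

## Worked example

Simulate a control-regime movie and recover the transcription kinetics:

```r
library(hubtrack)

spec   <- scene_spec(n_frames = 30, n_z = 1, n_nuclei = 10,
                     channels = c("rpb3", "mcp"), spot_snr = 8, seed = 42)
regime <- make_regime("control", spec)
sim    <- simulate_movie(spec, spots = regime$spots)
sim$stack
#> MovieStack: 30 frames, 1 z, 2 channel(s) [rpb3, mcp], 160 x 160 px
#>   frame interval 20.0 s, z step 0.50 um, pixel 0.220 um

movie <- subtract_background(max_project(sim$stack),
                             rolling_ball_radius_px = 50)
masks <- lapply(1:30, function(t)
  segment_nuclei_rpb3(get_frame(movie, t, "rpb3"), frame_index = t))
masks[[1]]
#> FrameMask (nuclei): frame 1, 10 object(s), 160 x 160 px

tracks <- track_nuclei(masks)
detections <- do.call(rbind, lapply(1:30, function(t) {
  d <- detect_mcp_foci(get_frame(movie, t, "mcp"), masks[[t]])
  if (nrow(d)) cbind(frame = t, d) else NULL
}))
states <- assign_states(tracks, detections)
curves <- cumulative_transition_curves(states, s_phase_start_frame = 1,
                                       frame_interval_s = 20)
appearance_halftime(curves) / 60
#> [1] 1.888889
tail(curves$pct_appeared, 1); tail(curves$pct_disappeared, 1)
#> [1] 100
#> [1] 0
```

Half of the simulated nuclei have switched ON within ~1.9 minutes of
S-phase entry, all ten are ON by the end of the movie, and none lose
their focus — the synchronous-activation behaviour the control regime
encodes. `curves` holds the full cumulative percentage curves
(`time_s`, `pct_appeared`, `pct_disappeared`); the per-frame detection
table carries sub-pixel positions, LoG responses in noise-SD units and
the nucleus each focus was assigned to.

The same movie analysed end-to-end from a configuration:

```r
run_workflow(list(workflow = "mcp-states", input = sim$stack,
                  out_dir = "out/states",
                  nuclear_channel = "rpb3", mcp_channel = "mcp"))
```

writes `nucleus_tracks.csv`, `detections.csv`, `states.csv`,
`cumulative_curves.csv`, a mask-overlay TIFF, the full parameter set and
a checksummed manifest. A shell entry point with the same workflows
lives at `inst/scripts/hubtrack.R`.

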