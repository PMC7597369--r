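# holotrack

Analysis of live-cell **two-color single-molecule tracking (SMT)** of
chromatin-binding proteins, built around the assembly and disassembly of
the DNA polymerase delta (Pol δ) – PCNA holoenzyme. In these experiments
two interleaved camera channels follow sparsely labeled PCNA (the DNA
sliding clamp) and Pol δ in S-phase nuclei at ~0.75 Hz per channel
(1.34 s frame interval, 84 nm pixels). Each immobile fluorescent spot is a
chromatin-binding event; the questions are *how long* molecules stay
bound, *in which order* clamp and polymerase arrive and leave when they
meet, and *where* binding recurs.

The package is for microscopists and computational biologists who have
either raw two-channel TIFF stacks or pre-localized track tables and want
a reproducible, tested pipeline for:

- **Localization and linking** — spots are fit with a 2D Gaussian PSF
  model (`localize_frame()`); localizations are linked into tracks by
  per-frame optimal bipartite assignment gated at
  r<sub>max</sub>(Δt) = √(4·D<sub>max</sub>·Δt) with D<sub>max</sub> =
  0.05 µm²/s, bridging blinking gaps up to 5 s (`link_tracks()`); tracks
  outside the nuclear ROI are excluded (`filter_nuclear_tracks()`).
- **Colocalization and binding order** — a Pol δ track lasting > 1.34 s
  that overlaps a PCNA track in time and sits within 47 nm of it (distance
  of time-averaged positions over the overlap window) is a colocalization
  event (`detect_colocalizations()`). Arrival and departure order are
  classified against a one-frame simultaneity tolerance, with bootstrap
  errors (1,000 iterations) and assembly/disassembly pathway quadrants;
  a positional-randomization null quantifies chance colocalization
  (`randomize_positions()`).
- **Residence-time kinetics** — survival curves S(t) = 1 − CDF of track
  durations are fit with exponential mixtures
  S(t) = Σᵢ fᵢ·exp(−(t−t₀)/τᵢ), k = 1–3, separating the short-lived T1
  (< 1.7 s) and stable T2 populations; model choice is by corrected AIC
  on the duration likelihood (`fit_exponential_mixture()`,
  `select_model()`). Photobleaching constants are estimated from the
  global bound-signal decay and interact with residence times through
  1/τ<sub>obs</sub> = 1/τ<sub>true</sub> + 1/τ<sub>bleach</sub>.
- **Binding hubs** — event maps expanded 10× (8.4 nm pixels) are raster
  scanned with a pinned 168 nm octagon window; contiguous windows holding
  ≥ 3 events become hubs, normalized as hubs per 1,000 binding events,
  and revisit latencies within hubs are fit with 1–3 exponential
  components (`scan_octagon()`, `label_hubs()`, `hub_latencies()`).
- **Synthetic ground truth** — a generator (`sim_config()`,
  `generate_truth()`, `emit_tracks()`, `render_movie()`) plants known
  residence mixtures, paired events with configurable order statistics,
  hubs with a three-component latency mixture, sparse labeling,
  photobleaching, localization noise and blinking, so every stage can be
  validated by parameter recovery.

`run_pipeline()` orchestrates everything and emits CSV tables, a JSON
report and figures (`make_figures()`).

## Worked example

Simulate one nucleus at the default acquisition conditions (512×512 px,
84 nm pixels, 985 frames per channel at 1.34 s, 2,000 events per
channel) and run the main analyses:

```r
library(holotrack)

cfg   <- sim_config(seed = 42)
truth <- generate_truth(cfg)
tab   <- emit_tracks(truth, cfg)
trk   <- tracks_from_table(tab, cfg$frame_interval_s, cfg$movie_length_frames)
pold  <- channel_tracks(trk, "pold")
pcna  <- channel_tracks(trk, "pcna")

ev <- detect_colocalizations(pold, pcna)   # 47 nm, > 1.34 s defaults
colocalization_frequency(ev)
#> events: 8 of 425 qualifying tracks -> 1.88 %

fit_residence_times(residence_times(trk, "pold"), k_max = 2)
#> 2-component exponential survival fit (n = 1192, mle, rss = 0.0002331)
#>   component 1: f = 0.818, tau = 0.933 s
#>   component 2: f = 0.182, tau = 11.7 s
#>   T1 = 0.933 s (81.8%), T2 = 11.7 s (18.2%)

m    <- expand_map(pold, field_size_px = cfg$field_size_px)
hubs <- label_hubs(scan_octagon(m))
hubs_per_1000(hubs, nrow(pold))
#> hubs: 26 -> 21.8 per 1000 events
```

The colocalization frequency (~1.9% of qualifying Pol δ tracks, all
arrivals clamp-first in this small draw), the recovered residence
mixture (T1 below a second for transient probing, T2 ≈ 12 s for stable
binding; the stable share is inflated above the generator's 4%
background because planted hub events are long-lived by construction),
and the hub rate (~22 per 1,000 events) are the three headline readouts
of the pipeline. Censored tracks (touching the movie start/end) are
excluded from the kinetic fits automatically.

To analyze your own data instead, write per-nucleus track tables in the
`track_id, channel, frame, t_s, x_nm, y_nm, intensity` format (channels
`pold`/`pcna`) and call
`run_pipeline(run_config(...), mode = "analyze", cells = <paths>)`, or
start from TIFF stacks with `track_movie(read_movie(...))`.

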