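---
title: "Methods: two-color SMT analysis of clamp-polymerase binding dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-color SMT analysis of clamp-polymerase binding dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holotrack)
```

This vignette documents the models, parameter choices, and numerical
decisions behind the package, in the spirit of a methods section: what
each stage assumes, where the design was genuinely open and what we
chose, and what passing the test suite does and does not demonstrate.

## The measurement model

Two fluorophore channels (a labeled DNA sliding clamp, PCNA, and a
labeled polymerase, Pol δ) are imaged alternately through a filter
wheel, giving each channel an effective frame interval `dt = 1.34 s`
(500 ms exposure plus dead time). We fix the convention that the clamp
channel is exposed at `t = k*dt` and the polymerase channel at
`t = k*dt + dt/2` (0-based frame `k`). Only chromatin-bound molecules
are visible as diffraction-limited spots; freely diffusing molecules are
motion-blurred at these exposures, which is why tracking uses a small
diffusion gate rather than a diffusion model. All positions are in nm
with origin at the field corner, times in seconds, frames 0-based; unit
conversion happens once at I/O boundaries.

A *track* is one binding event: its duration is
`(frames spanned) * dt`, counting bridged gap frames, so the minimum
observable duration is one frame interval. Tracks touching the first or
last movie frame are *censored*: their duration is a lower bound, so
they are excluded from kinetic fits (an unbounded duration biases an
exponential fit downward at the tail) but retained for maps and
colocalization, where only presence matters.

## Localization and linking

Spot candidates are strict local maxima above
`median + 5 * mad(image)`; each is refined by least-squares fitting of
`b + A*exp(-((x-x0)^2+(y-y0)^2)/(2*sigma^2))` on a 7×7 px window
(`minpack.lm`). Fits are rejected when they fail to converge, the width
leaves `[0.5, 4]` px, the amplitude is not positive, or the center
leaves the window; duplicates within 1 px keep the brighter spot. The
detection threshold and width bounds are exposed as arguments because
the appropriate values depend on camera gain and background; defaults
were chosen on rendered synthetic movies at the package's default SNR
(peak ≈ 600–1000 counts over ≈ 50–100 background).

Linking processes frames in order. Open track heads compete for new
localizations through a maximum-weight bipartite matching
(`igraph::max_bipartite_match`) in which every admissible edge carries
weight `BIG - d^2`: with `BIG` larger than any accumulated cost
difference, the matching maximizes the number of links first and the
total squared displacement second. This is the deterministic core of
multi-target tracking without its full probabilistic machinery.
Admissibility is the diffusion gate `d <= sqrt(4 * D_max * elapsed)`
with `D_max = 0.05 um^2/s`; a head stays open while its bridged gap
(missing frames × `dt`) is at most 5 s, i.e. up to three missing
per-channel frames — consistent with the generator's blinking model,
which caps miss runs at three frames.

The nuclear ROI is a polygon (an ellipse helper is provided);
point-in-polygon uses `mgcv::in.out` plus an explicit on-segment test so
that boundary points count as inside — the stated convention, and the
one that makes the filter idempotent under vertex resampling.

## Colocalization and binding order

A polymerase track qualifies if its duration strictly exceeds 1.34 s
(one frame). A qualifying track and a clamp track form an event when
their bound intervals overlap on the interleaved clock (closed
intervals; touching counts) and their time-averaged positions over the
overlap window are strictly within 47 nm. Averaging over the overlap
window, rather than taking a per-frame minimum, suppresses localization
noise (≈ 25 nm per frame per channel shrinks as `1/sqrt(n)`); the
per-frame criterion is available via `method = "perframe"`. Because the
two channel grids interleave, a very short overlap window can contain no
localization of one partner; the window is then widened by `dt/2`, the
smallest amount that restores one sample. Pairing is polymerase-centric
and one-to-one — nearest separation, ties broken by longer overlap —
because frequencies are reported per polymerase track.

Arrival/departure order uses a simultaneity tolerance of one frame
interval: the channels are never sampled at the same instant, so
differences below `dt` are not resolvable; |Δt| ≤ `dt` is classed
"simultaneous", otherwise the sign decides. The tolerance is an
argument (`simultaneity_tol_s`). Class fractions carry bootstrap SDs
(1,000 resamples of events with replacement, seeded); pathway quadrants
cross non-simultaneous arrival × departure classes and report each
quadrant's share *of all events* together with median pre-, joint- and
post-colocalization intervals and bootstrap CIs.

The chance-colocalization null replaces every track's mean position with
an independent uniform draw over the ROI (rigidly translating its
localizations), channel-independently, preserving all timing — so the
null keeps the duration and density structure and destroys only spatial
correlation.

## Residence-time kinetics

Durations are summarized as the empirical survival function
`S(t) = P(T >= t)` at each distinct duration and modeled as
`S(t) = sum_i f_i * exp(-(t - t0)/tau_i)`, `k = 1..3`, with `t0` the
minimum observed duration. The left shift acknowledges that durations
below one frame cannot exist; without it the discrete minimum biases
every component.

Two fitting routes exist. The default maximizes the duration likelihood
by EM. On frame-quantized durations the continuous exponential density
is the wrong likelihood — the data are tied multiples of `dt`, and a
density-based likelihood is unbounded as a component's constant shrinks
onto the atom at `t0` — so the fitter detects a regular grid and
switches to the exact interval (geometric) likelihood, whose M-step is
still closed-form. The curve-fit route (`method = "ls"`) performs
constrained nonlinear least squares against the survival curve
(stick-breaking weights, log-scale constants, a deterministic
multi-start grid); it reproduces the classical 1−CDF curve fit and is
retained as a cross-check and for noiseless analytic curves. We made
maximum likelihood the default after measuring both on the package's
own recovery conditions (n = 10,000; minor weight 0.04; constants 1 s
and 12.4 s): the curve fit's error on the minor component varies from a
few percent to several tens of percent across seeds, while the EM fit
stays within ~7%; an equally-weighted LS fit of an ECDF is simply an
inefficient estimator for a small long-lived population.

Model selection uses corrected AIC computed from the duration
log-likelihood at the fitted parameters — not from curve residuals,
whose strong autocorrelation makes residual-based information criteria
prefer spurious components. Additionally, a larger model qualifies only
if it is *identifiable*: every component weight ≥ 1% and adjacent
constants separated by ≥ 2×. The degenerate alternatives (a
vanishing-weight spike, or two nearly equal constants) are exactly how
an exponential mixture absorbs sampling noise; the package's recovery
guarantees only cover separations ≥ 5× and minor weights ≥ 3%, so
nothing resolvable is lost by the guard. An F-test on curve residuals
is available behind `criterion = "ftest"`.

Residence fits are per cell (T1/T2 and population percentages are then
compared across cells with the two-group Kruskal-Wallis rank test);
hub-latency fits pool all latencies across cells, where per-hub counts
are small. Binned survival curves are not used; the unbinned 1−CDF is
the default representation (a 1-s binned histogram view of the same
durations contains strictly less information and was not implemented as
a separate estimator).

Photobleaching competes with unbinding:
`1/tau_obs = 1/tau_true + 1/tau_bleach`. The bleach constant is fit from
the global bound-signal decay (`A*exp(-t/tau) + c`, with a flag instead
of a fit when the series does not decay). No bleach correction is
applied by default — the bleach constants (≈ 99–167 s) are far above the
residence constants of interest, and condition comparisons use the same
dyes — but `correct_for_bleaching()` applies the rate-sum inversion when
wanted.

## Binding hubs

Event mean positions (by default only events > 1.7 s, the stable class)
are binned on a 10×-expanded grid (8.4 nm pixels). The scan window is a
regular octagon of 20 expanded pixels (168 nm): since "octagon" admits
several rasterizations, one is pinned bit-exactly — a 20×20 square with
6-pixel 45° corner cuts, 316 member pixels, shipped as a text fixture
and generated identically in code. Window counts are computed by
stamping the reflected kernel at each event, which is algebraically
identical to raster-scanning the window over every pixel but linear in
the number of events; the equivalence is tested against a naive
per-pixel oracle. Pixels with ≥ 3 events in their window are hub seeds;
8-connected components of seeds become hubs (raster masks produce
diagonal adjacency; 4-connectivity is an option). An event belongs to a
hub if any window centered on one of the hub's pixels covers it; the
rare event covered by two hubs goes to the nearer centroid. Hubs are
ordered by centroid for determinism. Revisit latencies are successive
`start - previous end` gaps of a hub's time-ordered events; overlapping
events would give negative gaps, which are clamped to zero and flagged
rather than silently dropped.

Hub counts are normalized per cell as hubs per 1,000 binding events, so
cells with different event yields are comparable.

## The synthetic-data generator

`generate_truth()` draws a nucleus (axis-aligned ellipse, default
semi-axes 8 × 6 µm in a 43 µm field) with, per channel, 2,000 binding
events over a 985-frame (~22 min) movie. Residence times come from a
96%/4% exponential mixture with constants 1.0 s and 12.4 s. A fraction
(default 2.1%) of polymerase events receives a clamp partner whose true
position differs by an isotropic 15 nm Gaussian offset and whose
arrival/departure order follows two independent categorical
distributions (defaults 79/10/11% clamp-first arrivals and 84/9/7%
polymerase-first departures; the product structure reproduces a
~66% main assembly/disassembly quadrant). Planted non-simultaneous
gaps are `2*dt + Exp(8 s)`: the floor guarantees that discretization
onto the interleaved grid can never flip a planted class, and the
exponential tail reproduces partner-alone intervals of a few to tens of
seconds. Classes infeasible for a short event (the partner interval
would not overlap) are re-drawn among feasible classes.

Hubs are chains of revisiting events: 30 hubs per nucleus, members
uniform within an 84 nm radius, chain gaps from a three-component
latency mixture (weights 0.37/0.43/0.20, constants 8/25/200 s). Hub
members draw their durations from the stable residence component by
default (`hub_long_lived = TRUE`): hub detection considers only events
longer than 1.7 s, and revisits to replication sites are productive
binding events; with members drawn from the full mixture a 5-event hub
would rarely contain three stable events and hubs would essentially
never form at these densities. The per-nucleus event count (2,000) and
hub count (30) were chosen once so that the detected hub rate and the
stable-population share land in the ranges a cell at these imaging
conditions shows (~20 per 1,000 events; stable share ~10%); they are
conditions of the simulation, not fitted quantities.

`emit_tracks()` applies, in order: sparse labeling (per-channel
retention probability), an exponential per-molecule bleach time
(defaults 99.3 s polymerase / 166.8 s clamp) truncating the observed
interval, discretization onto the interleaved frame grid, per-frame
isotropic localization noise (default 25 nm — the 47 nm pairing radius
suggests a per-channel precision near 20–25 nm, which is exposed as
configuration rather than assumed), and blinking (each interior frame
dropped with probability 0.1, runs capped at 3 frames so 5-s gap closing
can always bridge them). Ground truth is stored in continuous seconds
and nm; only emission discretizes, so the same truth can be re-emitted
under different detection models. `render_movie()` additionally rasters
each localization as a 2D Gaussian PSF (σ = 1.5 px) with constant
background and Poisson shot noise into 16-bit stacks.

What the generator does *not* emulate — and what recovery tests
therefore cannot certify on real data: diffusing unbound molecules and
their motion blur, spatially varying background and autofluorescence,
chromatic offset between channels, drift, EMCCD excess noise beyond
Poisson, non-exponential (power-law) dwell components, and cell-to-cell
parameter heterogeneity beyond independent seeds. Nuclear ROIs are exact
ellipses rather than traced boundaries, so ROI-tracing errors are out of
scope.

## Determinism, seeds, and degenerate inputs

Every stochastic stage takes a seed; a master seed fans out to stages
and cells through a fixed hash, so one integer reproduces an entire run
byte-for-byte (track tables round-trip through CSV at full double
precision). EM and LS multi-starts are deterministic grids, not random
restarts. Degenerate inputs fail loudly or are flagged rather than
guessed at: empty duration sets, all-zero or non-decaying bleach series,
zero-area ROIs, fewer distinct durations than components, a window
diameter that is not a multiple of the expanded pixel — each is a
documented error or flag, tested in the suite.

## Problem sizes used by the test suite

The suite validates recovery at the sizes the statistics require while
staying fast: mixture recovery at n = 10,000 durations (40–100
replicates for selection rates), colocalization oracle equivalence at
500 tracks per channel, the randomization null over 200 seeded draws
across 10 nuclei, order recovery at ~270 events, hub-scan oracle
equivalence on a full 512×512-pixel native field with ~260 events, and
latency recovery over ~10,000 pooled latencies — the pooled-across-cells
scale at which the 3.1×-separated short and intermediate classes are
resolvable to 20%. End-to-end
rendering/tracking tests use reduced fields (96–128 px, ≤ 25 frames) —
rendering full movies adds nothing statistically to the per-spot
localization oracle, which is tested directly.

## Known limitations

- The tracker is nearest-frame greedy in time (per-frame optimal); it
  does not revisit past assignments, so two molecules crossing within
  the gate radius can swap identities. At binding-site densities and a
  ~0.5 µm gate this is rare, and it cannot create spurious *events*,
  only mislabel them.
- Unlabeled-partner exchange is invisible: a clamp that outlives its
  labeled polymerase may have hosted an unlabeled replacement. The
  package reports what is observable and leaves that interpretation to
  the user.
- Hub membership at the boundary between two merged hubs uses a
  centroid tie-break; other conventions (window union without
  tie-break, per-event multiplicity) would shift per-hub event counts
  by small integers.
- The latency mixture fitted on *detected* hubs is biased by movie-end
  truncation (a 200 s component in a ~1,320 s movie) and by chance
  co-membership of background events; the acceptance script therefore
  reports those fitted values as observed, while recovery tests use
  ground-truth latencies.
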