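test_that("a constructed overlapping pair yields the expected intervals", {
  # PCNA bound [0, 30], pold bound [10, 14], co-positioned (times in s)
  tab <- rbind(
    data.frame(track_id = 1L, channel = "pcna", frame = 1:31, t_s = 0:30,
               x_nm = 5000, y_nm = 5000, intensity = 1),
    data.frame(track_id = 2L, channel = "pold", frame = 11:15, t_s = 10:14,
               x_nm = 5000, y_nm = 5000, intensity = 1))
  trk <- tracks_from_table(tab, frame_interval_s = 1, n_frames = 1000L)
  ev <- detect_colocalizations(channel_tracks(trk, "pold"),
                               channel_tracks(trk, "pcna"),
                               radius_nm = 47, min_pold_s = 1.34)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$coloc_s, 4)
  expect_equal(ev$pre_s, 10)
  expect_equal(ev$post_s, 16)
  expect_equal(ev$arrival, "pcna_first")
  expect_equal(ev$departure, "pold_first")
})

test_that("pairs beyond the radius or below minimum duration are rejected", {
  dt <- 1.34
  spec <- data.frame(channel = c("pcna", "pold"), t0 = c(0, 0.67),
                     n = c(20, 20), x = c(5000, 5100), y = 5000)
  trk <- make_tracks(spec, dt = dt)
  expect_equal(nrow(detect_colocalizations(channel_tracks(trk, "pold"),
                                           channel_tracks(trk, "pcna"))), 0)
  # same place but single-frame polymerase track: 1.34 s is not > 1.34 s
  spec2 <- data.frame(channel = c("pcna", "pold"), t0 = c(0, 0.67),
                      n = c(20, 1), x = 5000, y = 5000)
  trk2 <- make_tracks(spec2, dt = dt)
  expect_equal(nrow(detect_colocalizations(channel_tracks(trk2, "pold"),
                                           channel_tracks(trk2, "pcna"))), 0)
})

test_that("detection equals the brute-force pair scan on random tracks", {
  cfg <- sim_config(n_events_per_channel = 150L, coloc_fraction = 0.3,
                    hub_count = 0L, residence_weights = c(0.3, 0.7),
                    residence_tau_s = c(1, 12), seed = 51L)
  tab <- emit_tracks(generate_truth(cfg), cfg)
  trk <- tracks_from_table(tab, cfg$frame_interval_s,
                           cfg$movie_length_frames)
  pold <- channel_tracks(trk, "pold"); pcna <- channel_tracks(trk, "pcna")
  ev <- detect_colocalizations(pold, pcna)
  ora <- oracle_coloc(pold, pcna)
  expect_equal(nrow(ev), nrow(ora))
  expect_equal(ev$pold_track, ora$pold_track)
  expect_equal(ev$pcna_track, ora$pcna_track)
  expect_equal(ev$sep_nm, ora$sep_nm, tolerance = 1e-9)
})

test_that("shrinking radius or raising minimum duration never adds events", {
  cfg <- sim_config(n_events_per_channel = 200L, coloc_fraction = 0.4,
                    hub_count = 0L, seed = 52L)
  tab <- emit_tracks(generate_truth(cfg), cfg)
  trk <- tracks_from_table(tab, cfg$frame_interval_s,
                           cfg$movie_length_frames)
  pold <- channel_tracks(trk, "pold"); pcna <- channel_tracks(trk, "pcna")
  n_events <- function(r, md) nrow(detect_colocalizations(pold, pcna, r, md))
  radii <- c(150, 47, 20, 5)
  counts_r <- vapply(radii, n_events, 0, md = 1.34)
  expect_true(all(diff(counts_r) <= 0))
  mds <- c(0, 1.34, 4, 10)
  counts_m <- vapply(mds, function(m) n_events(47, m), 0)
  expect_true(all(diff(counts_m) <= 0))
})

test_that("swapping channel labels swaps the order classes", {
  cfg <- sim_config(n_events_per_channel = 150L, coloc_fraction = 0.6,
                    residence_weights = c(0.2, 0.8),
                    residence_tau_s = c(1, 15), hub_count = 0L, seed = 53L)
  tab <- emit_tracks(generate_truth(cfg), cfg)
  trk <- tracks_from_table(tab, cfg$frame_interval_s,
                           cfg$movie_length_frames)
  pold <- channel_tracks(trk, "pold"); pcna <- channel_tracks(trk, "pcna")
  ev <- detect_colocalizations(pold, pcna, min_pold_s = 0)
  # swap roles: feed pcna tracks as the "polymerase" side
  swapped <- detect_colocalizations(pcna, pold, min_pold_s = 0)
  # the same physical pairs seen from the other side invert the classes
  key1 <- paste(ev$pold_track, ev$pcna_track)
  key2 <- paste(swapped$pcna_track, swapped$pold_track)
  common <- intersect(key1, key2)
  expect_gt(length(common), 0.8 * nrow(ev))
  i1 <- match(common, key1); i2 <- match(common, key2)
  flip <- c(pcna_first = "pold_first", pold_first = "pcna_first",
            simultaneous = "simultaneous")
  expect_equal(unname(flip[ev$arrival[i1]]), swapped$arrival[i2])
  expect_equal(unname(flip[ev$departure[i1]]), swapped$departure[i2])
})

test_that("mismatched coordinate frames are refused", {
  spec <- data.frame(channel = c("pcna", "pold"), t0 = c(0, 0.67),
                     n = c(5, 5), x = 5000, y = 5000)
  trk <- make_tracks(spec)
  a <- channel_tracks(trk, "pold"); b <- channel_tracks(trk, "pcna")
  attr(a, "pixel_size_nm") <- 84; attr(b, "pixel_size_nm") <- 107
  expect_error(detect_colocalizations(a, b), "mismatched")
})

test_that("colocalization frequency is a simple percentage with guards", {
  ev <- structure(data.frame(event_id = 1:2), class = c("coloc_events",
                                                        "data.frame"))
  expect_equal(colocalization_frequency(ev, 100), 2)
  expect_error(colocalization_frequency(ev, 0), "positive count")
})
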