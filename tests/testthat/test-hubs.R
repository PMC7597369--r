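events_df <- function(x_nm, y_nm, start_t = seq_along(x_nm),
                      end_t = start_t + 1) {
  data.frame(track_id = seq_along(x_nm), mean_x = x_nm, mean_y = y_nm,
             start_t = start_t, end_t = end_t,
             duration_s = end_t - start_t + 1.34)
}

test_that("the pinned octagon kernel matches its shipped fixture", {
  k <- octagon_kernel(20)
  fx <- as.matrix(read.table(system.file("extdata",
                                         "octagon_kernel_20.txt",
                                         package = "holotrack")))
  expect_equal(unname(matrix(as.integer(k), 20, 20)), unname(fx))
  expect_equal(sum(k), 316)
  expect_error(octagon_kernel(15), "even")
})

test_that("map expansion bins positions at a tenth of a pixel", {
  ev <- events_df(c(84, 0, 4299.9), c(84, 0, 10))
  m <- expand_map(ev, min_duration_s = 0, field_size_px = c(64L, 64L))
  expect_equal(m$events$ix, c(10L, 0L, 511L))
  expect_equal(m$events$iy, c(10L, 0L, 1L))
  expect_equal(m$pixel_size_nm, 8.4)
  # duration filter: only events > 1.7 s survive by default
  ev2 <- events_df(c(100, 200), c(100, 200))
  ev2$duration_s <- c(1.34, 2.68)
  m2 <- expand_map(ev2, field_size_px = c(64L, 64L))
  expect_equal(nrow(m2$events), 1)
  # empty input
  m0 <- expand_map(ev[0, ], min_duration_s = 0)
  expect_equal(nrow(scan_octagon(m0)$pixels), 0)
})

test_that("octagon scanning counts events exactly (oracle equivalence)", {
  set.seed(101)
  # random field with clusters and background on a 64 x 64 px native grid
  n_bg <- 60
  xs <- runif(n_bg, 100, 5200); ys <- runif(n_bg, 100, 5200)
  # a planted 3-event cluster and a 2-event pair
  xs <- c(xs, 2600 + c(0, 20, -15), 4000 + c(0, 25))
  ys <- c(ys, 2600 + c(10, -5, 0), 4000 + c(5, -10))
  m <- expand_map(events_df(xs, ys), min_duration_s = 0,
                  field_size_px = c(64L, 64L))
  mask <- scan_octagon(m, 168, 3)
  counts_ora <- naive_window_counts(m$events, mask$pixels, mask$kernel)
  expect_equal(mask$pixels$count, counts_ora)
  # every pixel absent from the sparse count list has zero events in its
  # window: verify on a random sample of absent pixels
  absent <- data.frame(ix = sample(0:639, 200), iy = sample(0:639, 200))
  key <- paste(mask$pixels$ix, mask$pixels$iy)
  absent <- absent[!paste(absent$ix, absent$iy) %in% key, ]
  expect_true(all(naive_window_counts(m$events, absent, mask$kernel) == 0))
})

test_that("three events in a window seed a hub; two never do", {
  # 3 events on one expanded pixel
  m3 <- expand_map(events_df(rep(1000, 3), rep(1000, 3)),
                   min_duration_s = 0, field_size_px = c(32L, 32L))
  mask3 <- scan_octagon(m3)
  expect_true(any(mask3$seed))
  # the seed region is exactly the kernel footprint
  expect_equal(sum(mask3$seed), 316)
  m2 <- expand_map(events_df(c(1000, 1008), c(1000, 1000)),
                   min_duration_s = 0, field_size_px = c(32L, 32L))
  expect_false(any(scan_octagon(m2)$seed))
})

test_that("hub labeling matches a flood-fill oracle and orders hubs", {
  flood_fill_components <- function(ix, iy) {
    key <- paste(ix, iy)
    lab <- rep(NA_integer_, length(ix)); cur <- 0L
    for (s in seq_along(ix)) {
      if (!is.na(lab[s])) next
      cur <- cur + 1L
      queue <- s
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        if (!is.na(lab[p])) next
        lab[p] <- cur
        nb <- which(abs(ix - ix[p]) <= 1 & abs(iy - iy[p]) <= 1 &
                      is.na(lab))
        queue <- c(queue, nb)
      }
    }
    lab
  }
  set.seed(102)
  # two tight clusters 1 um apart plus sparse background
  xs <- c(1000 + runif(3, -20, 20), 2000 + runif(4, -20, 20),
          runif(25, 100, 5200))
  ys <- c(1000 + runif(3, -20, 20), 1000 + runif(4, -20, 20),
          runif(25, 100, 5200))
  m <- expand_map(events_df(xs, ys), min_duration_s = 0,
                  field_size_px = c(64L, 64L))
  mask <- scan_octagon(m)
  hubs <- label_hubs(mask)
  seeds <- mask$pixels[mask$seed, ]
  ora <- flood_fill_components(seeds$ix, seeds$iy)
  expect_equal(nrow(hubs$hubs), max(ora))
  expect_gte(nrow(hubs$hubs), 2)
  # ordered by centroid
  expect_true(!is.unsorted(hubs$hubs$centroid_x_nm))
  # one 6-event cluster gives one hub with all members
  m6 <- expand_map(events_df(3000 + runif(6, -30, 30),
                             3000 + runif(6, -30, 30)),
                   min_duration_s = 0, field_size_px = c(64L, 64L))
  h6 <- label_hubs(scan_octagon(m6))
  expect_equal(nrow(h6$hubs), 1)
  expect_equal(h6$hubs$n_events, 6)
})

test_that("adding an event never destroys a hub (monotonicity)", {
  set.seed(103)
  xs <- 2000 + runif(3, -25, 25); ys <- 2000 + runif(3, -25, 25)
  base <- events_df(xs, ys)
  m1 <- expand_map(base, min_duration_s = 0, field_size_px = c(48L, 48L))
  mask1 <- scan_octagon(m1)
  h1 <- label_hubs(mask1)
  extra <- events_df(c(xs, 3500), c(ys, 600))
  m2 <- expand_map(extra, min_duration_s = 0, field_size_px = c(48L, 48L))
  mask2 <- scan_octagon(m2)
  # counts never decrease on the original pixels
  k1 <- paste(mask1$pixels$ix, mask1$pixels$iy)
  k2 <- paste(mask2$pixels$ix, mask2$pixels$iy)
  idx <- match(k1, k2)
  expect_true(all(mask2$pixels$count[idx] >= mask1$pixels$count))
  expect_gte(nrow(label_hubs(mask2)$hubs), nrow(h1$hubs))
})

test_that("whole-pixel translations shift hubs identically", {
  set.seed(104)
  xs <- 2000 + runif(4, -30, 30); ys <- 2500 + runif(4, -30, 30)
  m1 <- expand_map(events_df(xs, ys), min_duration_s = 0,
                   field_size_px = c(64L, 64L))
  h1 <- label_hubs(scan_octagon(m1))
  shift <- 25 * 8.4  # whole number of expanded pixels
  m2 <- expand_map(events_df(xs + shift, ys + shift), min_duration_s = 0,
                   field_size_px = c(64L, 64L))
  h2 <- label_hubs(scan_octagon(m2))
  expect_equal(nrow(h2$hubs), nrow(h1$hubs))
  expect_equal(h2$hubs$centroid_x_nm, h1$hubs$centroid_x_nm + shift)
  expect_equal(h2$hubs$n_events, h1$hubs$n_events)
})

test_that("hub rate normalization and latency extraction", {
  expect_equal(hubs_per_1000(11L, 500), 22)
  expect_equal(hubs_per_1000(0L, 100), 0)
  expect_error(hubs_per_1000(3L, 0), "positive count")
  # latencies: bound [0,2] and [12,14] -> 10; then gaps 10 and 20
  h <- data.frame(start_t = c(0, 12), end_t = c(2, 14))
  expect_equal(hub_latencies(h)$latency_s, 10)
  h3 <- data.frame(start_t = c(0, 12, 34), end_t = c(2, 14, 40))
  expect_equal(hub_latencies(h3)$latency_s, c(10, 20))
  # overlapping events clamp to zero and are flagged
  hov <- data.frame(start_t = c(0, 3), end_t = c(5, 8))
  lat <- hub_latencies(hov)
  expect_equal(lat$latency_s, 0)
  expect_true(lat$clamped)
  expect_equal(nrow(hub_latencies(data.frame(start_t = 1, end_t = 2))), 0)
})

test_that("uniform fields produce fewer hubs than hub-planted fields", {
  cfg_hub <- sim_config(n_events_per_channel = 800L, hub_count = 15L,
                        hub_events_mean = 10,
                        residence_weights = c(0.3, 0.7),
                        residence_tau_s = c(1, 12),
                        coloc_fraction = 0, seed = 105L)
  cfg_uni <- sim_config(n_events_per_channel = 800L, hub_count = 0L,
                        residence_weights = c(0.3, 0.7),
                        residence_tau_s = c(1, 12),
                        coloc_fraction = 0, seed = 105L)
  rate <- function(cfg) {
    tab <- emit_tracks(generate_truth(cfg), cfg)
    trk <- tracks_from_table(tab, cfg$frame_interval_s,
                             cfg$movie_length_frames)
    pold <- channel_tracks(trk, "pold")
    m <- expand_map(pold, field_size_px = cfg$field_size_px)
    hubs <- label_hubs(scan_octagon(m))
    hubs_per_1000(hubs, max(nrow(pold), 1))
  }
  expect_gt(rate(cfg_hub), rate(cfg_uni))
})
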