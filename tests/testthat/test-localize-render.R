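gauss_image <- function(nx, ny, x0_px, y0_px, amp = 800, sigma = 1.5,
                        bg = 10) {
  # x0_px in continuous pixel coordinates (pixel i spans [i-1, i))
  jx <- seq_len(nx) - 0.5
  jy <- seq_len(ny) - 0.5
  bg + amp * exp(-outer((jx - x0_px)^2, (jy - y0_px)^2, "+") / (2 * sigma^2))
}

test_that("noiseless sub-pixel positions are recovered to 0.02 px", {
  img <- gauss_image(64, 64, 31.3, 40.7)
  out <- localize_frame(img, detect_threshold = 100)
  expect_equal(nrow(out), 1)
  expect_lt(abs(out$x_px - 31.3), 0.02)
  expect_lt(abs(out$y_px - 40.7), 0.02)
  expect_lt(abs(out$sigma_nm / 84 - 1.5), 0.05)
})

test_that("flat frames and bad pixels are handled", {
  expect_equal(nrow(localize_frame(matrix(10, 32, 32))), 0)
  m <- matrix(10, 32, 32); m[5, 5] <- NA
  expect_error(localize_frame(m), "finite")
})

test_that("rendering puts the brightest pixel at the true position", {
  cfg <- sim_config(field_size_px = c(48L, 48L), movie_length_frames = 2L,
                    n_events_per_channel = 0L, hub_count = 0L, seed = 41L)
  # one stationary pold event, deterministic rendering
  tab <- data.frame(track_id = 1L, channel = "pold", frame = 0L,
                    t_s = 0.67, x_nm = 20.3 * 84, y_nm = 31.6 * 84,
                    intensity = 1000)
  class(tab) <- c("smt_loc_table", "data.frame")
  mov <- render_movie(tab, cfg, poisson_noise = FALSE)
  img <- mov$stacks$pold[[1]]
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(21, 32))  # 1-based pixel of (20.3, 31.6)
  # empty channel is pure background
  expect_true(all(mov$stacks$pcna[[1]] == 100))
  # out-of-field positions clip with a warning
  tab2 <- tab; tab2$x_nm <- -50
  expect_warning(render_movie(tab2, cfg, poisson_noise = FALSE), "clipped")
})

test_that("localization precision under shot noise matches a Monte-Carlo oracle", {
  set.seed(42)
  # oracle: repeated single-spot fits at the same SNR
  one_err <- function() {
    x0 <- 16 + runif(1); y0 <- 16 + runif(1)
    img <- matrix(stats::rpois(48 * 48,
                               gauss_image(48, 48, x0, y0, amp = 600,
                                           bg = 50)), 48, 48)
    out <- localize_frame(img, detect_threshold = 150)
    if (nrow(out) != 1) return(NA_real_)
    sqrt((out$x_px - x0)^2 + (out$y_px - y0)^2)
  }
  errs <- replicate(80, one_err())
  expect_lt(mean(is.na(errs)), 0.05)       # detection is near-certain
  rmse <- sqrt(mean(errs^2, na.rm = TRUE))
  # theoretical localization precision is ~ sigma/sqrt(N) ~ 0.03 px at
  # this SNR; the Monte-Carlo estimate must sit in a sane band around it
  expect_lt(rmse, 0.15)
  expect_gt(rmse, 0.005)
})

test_that("rendered movies can be re-localized and re-tracked end to end", {
  cfg <- sim_config(field_size_px = c(96L, 96L), movie_length_frames = 25L,
                    n_events_per_channel = 12L, hub_count = 0L,
                    coloc_fraction = 0,
                    nucleus_semiaxes_nm = c(3500, 3000),
                    residence_weights = c(0, 1),
                    residence_tau_s = c(1, 12),
                    label_fraction = c(pold = 1, pcna = 1),
                    bleach_tau_s = c(pold = Inf, pcna = Inf),
                    loc_noise_sigma_nm = 0, blink_gap_prob = 0, seed = 43L)
  truth <- generate_truth(cfg)
  tab <- emit_tracks(truth, cfg)
  mov <- render_movie(tab, cfg, poisson_noise = TRUE)
  trk <- track_movie(mov, cfg$frame_interval_s)
  # >= 95% of rendered polymerase localizations are re-localized within
  # one pixel on their frame
  locs_r <- track_locs(trk)
  locs_r <- locs_r[locs_r$channel == "pold", ]
  pold_tab <- tab[tab$channel == "pold", ]
  hit <- vapply(seq_len(nrow(pold_tab)), function(i) {
    sel <- locs_r$frame == pold_tab$frame[i]
    any(sqrt((locs_r$x_nm[sel] - pold_tab$x_nm[i])^2 +
               (locs_r$y_nm[sel] - pold_tab$y_nm[i])^2) < 84)
  }, TRUE)
  expect_gte(mean(hit), 0.95)
  # and most emitted tracks come back as tracks near their true position
  emitted <- tracks_from_table(tab, cfg$frame_interval_s,
                               cfg$movie_length_frames)
  pold_e <- emitted[emitted$channel == "pold", ]
  pold_r <- trk[trk$channel == "pold", ]
  matched <- vapply(seq_len(nrow(pold_e)), function(i) {
    d <- sqrt((pold_r$mean_x - pold_e$mean_x[i])^2 +
                (pold_r$mean_y - pold_e$mean_y[i])^2)
    any(d < 2 * 84)
  }, TRUE)
  expect_gte(mean(matched), 0.75)
})

test_that("movies round-trip through TIFF + sidecar", {
  cfg <- sim_config(field_size_px = c(32L, 32L), movie_length_frames = 2L,
                    n_events_per_channel = 3L, hub_count = 0L,
                    nucleus_semiaxes_nm = c(1200, 1000), seed = 44L)
  tab <- emit_tracks(generate_truth(cfg), cfg)
  mov <- render_movie(tab, cfg, poisson_noise = FALSE)
  dir <- withr::local_tempdir()
  write_movie(mov, dir, "demo")
  back <- read_movie(dir, "demo")
  expect_equal(names(back$stacks), names(mov$stacks))
  expect_equal(back$stacks$pold[[1]], mov$stacks$pold[[1]], tolerance = 1)
  expect_equal(back$pixel_size_nm, mov$pixel_size_nm)
})
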