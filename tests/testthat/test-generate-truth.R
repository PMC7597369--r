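test_that("degenerate one-component mixture gives exponential durations", {
  cfg <- clean_config(n_events_per_channel = 10000L,
                      residence_weights = c(1, 0),
                      residence_tau_s = c(1, 12.4), seed = 2L)
  truth <- generate_truth(cfg)
  d <- truth$duration_s[truth$channel == "pold"]
  # Exp(1): mean 1, SE 1/sqrt(n)
  expect_lt(abs(mean(d) - 1), 3 / sqrt(length(d)))
  expect_true(all(truth$population[truth$channel == "pold"] == 1L))
})

test_that("no hubs requested means no event carries a hub id", {
  truth <- generate_truth(clean_config(seed = 3L))
  expect_true(all(is.na(truth$hub_id)))
})

test_that("durations follow the two-component mixture (KS vs oracle)", {
  cfg <- clean_config(n_events_per_channel = 10000L, seed = 1L)
  truth <- generate_truth(cfg)
  d <- truth$duration_s[truth$channel == "pold"]
  set.seed(99)
  ref <- oracle_mixture(10000L, c(0.96, 0.04), c(1, 12.4))
  ks <- suppressWarnings(stats::ks.test(d, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("hub structure: membership radius and latency mixture", {
  cfg <- sim_config(n_events_per_channel = 3000L, hub_count = 150L,
                    hub_events_mean = 8, coloc_fraction = 0,
                    movie_length_frames = 3000L, seed = 4L)
  truth <- generate_truth(cfg)
  hub_ev <- truth[!is.na(truth$hub_id), ]
  expect_gt(nrow(hub_ev), 450)
  # members lie within hub_radius of their hub center (pairwise bound 2r)
  for (h in unique(hub_ev$hub_id)[1:20]) {
    m <- hub_ev[hub_ev$hub_id == h, ]
    dmax <- max(dist(cbind(m$x_nm, m$y_nm)))
    expect_lte(dmax, 2 * cfg$hub_radius_nm + 1e-9)
  }
  # within-hub start-time gaps are latency draws from the 3-exp mixture
  lats <- unlist(lapply(split(hub_ev, hub_ev$hub_id), function(m) {
    m <- m[order(m$start_s), ]
    m$start_s[-1] - (m$start_s[-nrow(m)] + m$duration_s[-nrow(m)])
  }))
  expect_true(all(lats > 0))
  set.seed(123)
  ref <- oracle_mixture(length(lats), cfg$latency_weights, cfg$latency_tau_s)
  ks <- suppressWarnings(stats::ks.test(lats, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted partners share position and link symmetrically", {
  cfg <- sim_config(n_events_per_channel = 400L, coloc_fraction = 0.5,
                    residence_weights = c(0.2, 0.8),
                    residence_tau_s = c(1, 15), hub_count = 0L, seed = 5L)
  truth <- generate_truth(cfg)
  paired <- truth[!is.na(truth$partner_id), ]
  expect_gt(nrow(paired), 100)
  idx <- match(paired$partner_id, truth$event_id)
  # symmetry
  expect_equal(truth$partner_id[idx], paired$event_id)
  # shared position up to the configured offset scale (5 sigma bound)
  d <- sqrt((paired$x_nm - truth$x_nm[idx])^2 +
              (paired$y_nm - truth$y_nm[idx])^2)
  expect_true(all(d < 5 * sqrt(2) * cfg$coloc_offset_scale_nm))
  # durations nonnegative everywhere
  expect_true(all(truth$duration_s >= 0))
})

test_that("planted order labels follow the configured distribution", {
  cfg <- sim_config(n_events_per_channel = 2000L, coloc_fraction = 1,
                    residence_weights = c(0, 1), residence_tau_s = c(1, 20),
                    hub_count = 0L, seed = 6L)
  truth <- generate_truth(cfg)
  lab <- truth[truth$channel == "pold" & !is.na(truth$arrival_class), ]
  n <- nrow(lab)
  for (cls in names(cfg$arrival_probs)) {
    p <- cfg$arrival_probs[[cls]]
    obs <- mean(lab$arrival_class == cls)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
  for (cls in names(cfg$departure_probs)) {
    p <- cfg$departure_probs[[cls]]
    obs <- mean(lab$departure_class == cls)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})
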