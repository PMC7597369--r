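dt <- 1.34

loc_row <- function(frame, x, y = 0) {
  data.frame(channel = "pold", frame = frame, t_s = frame * dt + dt / 2,
             x_nm = x, y_nm = y, intensity = 1000)
}

test_that("a stationary spot across frames becomes one track", {
  locs <- do.call(rbind, lapply(0:4, loc_row, x = 5000))
  trk <- link_tracks(locs, frame_interval_s = dt, n_frames = 100L)
  expect_equal(nrow(trk), 1)
  expect_equal(trk$n_locs, 5)
  expect_equal(trk$duration_s, 5 * dt)
})

test_that("gap closing bridges up to but not beyond the 5 s limit", {
  # 2 missing frames: 2 * 1.34 = 2.68 s <= 5 s -> bridged
  locs <- do.call(rbind, lapply(c(0:2, 5:7), loc_row, x = 5000))
  trk <- link_tracks(locs, frame_interval_s = dt, n_frames = 100L)
  expect_equal(nrow(trk), 1)
  expect_equal(trk$duration_s, 8 * dt)  # spans frames 0..7
  # 4 missing frames: 5.36 s > 5 s -> two tracks
  locs2 <- do.call(rbind, lapply(c(0:2, 7:9), loc_row, x = 5000))
  trk2 <- link_tracks(locs2, frame_interval_s = dt, n_frames = 100L)
  expect_equal(nrow(trk2), 2)
})

test_that("the gating radius separates distant simultaneous spots", {
  # two spots 5 um apart: far beyond r_max = sqrt(4 * 0.05 um^2/s * 1.34 s)
  locs <- rbind(do.call(rbind, lapply(0:3, loc_row, x = 1000)),
                do.call(rbind, lapply(0:3, loc_row, x = 6000)))
  trk <- link_tracks(locs, frame_interval_s = dt, n_frames = 100L)
  expect_equal(nrow(trk), 2)
  expect_true(all(trk$n_locs == 4))
})

test_that("empty input yields an empty track set, not an error", {
  trk <- link_tracks(loc_row(0, 0)[0, ], frame_interval_s = dt)
  expect_equal(nrow(trk), 0)
})

test_that("linking matches an exhaustive small-instance assignment oracle", {
  # brute-force per-frame assignment: enumerate all injective admissible
  # matchings, pick max cardinality then min total squared displacement
  oracle_link <- function(locs, d_nm2, max_gap_s) {
    frames <- sort(unique(locs$frame))
    track_id <- integer(nrow(locs))
    head_row <- integer(0); head_track <- integer(0); next_id <- 1L
    for (f in frames) {
      rows <- which(locs$frame == f)
      tnow <- locs$t_s[rows[1]]
      if (length(head_row)) {
        openh <- (f - locs$frame[head_row] - 1L) * dt <= max_gap_s
        head_row <- head_row[openh]; head_track <- head_track[openh]
      }
      assigned <- rep(NA_integer_, length(rows))
      if (length(head_row)) {
        dtv <- tnow - locs$t_s[head_row]
        gate2 <- 4 * d_nm2 * dtv
        cost <- outer(seq_along(head_row), seq_along(rows),
                      Vectorize(function(i, j)
                        (locs$x_nm[head_row[i]] - locs$x_nm[rows[j]])^2 +
                          (locs$y_nm[head_row[i]] - locs$y_nm[rows[j]])^2))
        adm <- sweep(cost, 1, gate2, "<=")
        best <- NULL
        # enumerate all assignments col -> row or NA
        combos <- expand.grid(rep(list(c(NA_integer_,
                                         seq_along(head_row))),
                                  length(rows)))
        for (r in seq_len(nrow(combos))) {
          a <- as.integer(combos[r, ])
          used <- a[!is.na(a)]
          if (anyDuplicated(used)) next
          okadm <- all(vapply(seq_along(a), function(j)
            is.na(a[j]) || adm[a[j], j], TRUE))
          if (!okadm) next
          card <- sum(!is.na(a))
          tot <- sum(vapply(seq_along(a), function(j)
            if (is.na(a[j])) 0 else cost[a[j], j], 0))
          sc <- c(card, -tot)
          if (is.null(best) || sc[1] > best$sc[1] ||
              (sc[1] == best$sc[1] && sc[2] > best$sc[2]))
            best <- list(a = a, sc = sc)
        }
        assigned <- best$a
      }
      for (j in seq_along(rows)) {
        if (!is.na(assigned[j])) {
          hi <- assigned[j]
          track_id[rows[j]] <- head_track[hi]
          head_row[hi] <- rows[j]
        } else {
          track_id[rows[j]] <- next_id
          head_row <- c(head_row, rows[j])
          head_track <- c(head_track, next_id)
          next_id <- next_id + 1L
        }
      }
    }
    track_id
  }
  partition_key <- function(id) {
    # canonical labels by first appearance
    match(id, unique(id))
  }
  for (s in 1:6) {
    set.seed(100 + s)
    nfr <- 4L
    locs <- do.call(rbind, lapply(0:(nfr - 1), function(f) {
      n <- sample(0:4, 1)
      if (n == 0) return(NULL)
      data.frame(channel = "pold", frame = f, t_s = f * dt + dt / 2,
                 x_nm = runif(n, 0, 2500), y_nm = runif(n, 0, 2500),
                 intensity = 1)
    }))
    if (is.null(locs) || nrow(locs) == 0) next
    trk <- link_tracks(locs, frame_interval_s = dt, n_frames = nfr)
    mine <- track_locs(trk)
    mine <- mine[order(mine$frame, mine$x_nm), ]
    loc2 <- locs[order(locs$frame, locs$x_nm), ]
    ora <- oracle_link(loc2, 0.05e6, 5)
    expect_equal(partition_key(mine$track_id), partition_key(ora),
                 info = sprintf("seed %d", 100 + s))
  }
})

test_that("linking recovers ground-truth tracks and is translation invariant", {
  cfg <- clean_config(n_events_per_channel = 50L,
                      residence_weights = c(0, 1),
                      residence_tau_s = c(1, 20),
                      loc_noise_sigma_nm = 25, seed = 15L)
  truth <- generate_truth(cfg)
  tab <- emit_tracks(truth, cfg)
  pold <- tab[tab$channel == "pold", ]
  relink <- link_tracks(pold[, setdiff(names(pold), "track_id")],
                        frame_interval_s = cfg$frame_interval_s,
                        n_frames = cfg$movie_length_frames)
  got <- track_locs(relink)
  # per-localization pair Jaccard between recovered and true partitions
  key <- paste(got$frame, round(got$x_nm, 6))
  truekey <- paste(pold$frame, round(pold$x_nm, 6))
  ids_true <- pold$track_id[match(key, truekey)]
  pairs <- function(id) {
    out <- character(0)
    for (g in split(seq_along(id), id))
      if (length(g) > 1) {
        cmb <- combn(sort(g), 2)
        out <- c(out, paste(cmb[1, ], cmb[2, ]))
      }
    out
  }
  p1 <- pairs(got$track_id); p2 <- pairs(ids_true)
  jacc <- length(intersect(p1, p2)) / length(union(p1, p2))
  expect_gte(jacc, 0.95)
  # no two tracks share a localization
  expect_false(any(duplicated(paste(got$frame, got$x_nm, got$y_nm))))
  # global translation does not change the partition
  shifted <- pold
  shifted$x_nm <- shifted$x_nm + 5000
  shifted$y_nm <- shifted$y_nm + 3000
  relink2 <- link_tracks(shifted[, setdiff(names(shifted), "track_id")],
                         frame_interval_s = cfg$frame_interval_s,
                         n_frames = cfg$movie_length_frames)
  got2 <- track_locs(relink2)
  expect_equal(got$track_id, got2$track_id)
})
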