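# Frame linking, consecutive-frame confirmation, overlap suppression,
# manual-correction accounting and the correction-rate QC metric.

fake_dets <- function(frame, cx, cy, r, score = 1) {
  data.frame(detection_id = seq_along(cx), frame_index = frame,
             cx_px = cx, cy_px = cy, radius_px = r, score = score)
}

test_that("static detections link into one track per circle", {
  det <- do.call(rbind, lapply(0:4, function(f) {
    fake_dets(f, c(20, 80), c(30, 60), c(10, 12))
  }))
  tracks <- link_frames(det, match_tol_px = 5)
  expect_length(tracks, 2)
  expect_true(all(vapply(tracks, `[[`, integer(1), "max_run") == 5))
})

test_that("detections separated in time and space stay unlinked", {
  det <- rbind(fake_dets(0, 20, 20, 10), fake_dets(3, 90, 90, 10))
  tracks <- link_frames(det, match_tol_px = 5)
  expect_length(tracks, 2)
})

test_that("greedy linking matches brute-force optimal assignment", {
  # 3 well-separated circles, 10 jittered frames, jitter <= tol/4; the
  # oracle enumerates all frame-to-frame permutations and picks the one
  # minimizing total center distance.
  base <- data.frame(cx = c(30, 100, 60), cy = c(30, 40, 100), r = c(10, 12, 9))
  tol <- 8
  det <- ivmorph:::with_seed(42, do.call(rbind, lapply(0:9, function(f) {
    d <- fake_dets(f, base$cx + rnorm(3, 0, tol / 8),
                   base$cy + rnorm(3, 0, tol / 8), base$r)
    d$circle <- seq_len(3)  # hidden identity, ignored by link_frames
    d
  })))
  perms <- function(v) if (length(v) == 1) list(v) else {
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  frames <- split(det, det$frame_index)
  oracle_label <- list(seq_len(3))  # track label of detection i in frame f
  for (f in 2:10) {
    prev <- frames[[f - 1]]; cur <- frames[[f]]
    best <- NULL; best_cost <- Inf
    for (p in perms(seq_len(3))) {
      cost <- sum(sqrt((prev$cx_px - cur$cx_px[p])^2 +
                         (prev$cy_px - cur$cy_px[p])^2))
      if (cost < best_cost) { best_cost <- cost; best <- p }
    }
    lab <- integer(3); lab[best] <- oracle_label[[f - 1]]
    oracle_label[[f]] <- lab
  }
  tracks <- link_frames(det, match_tol_px = tol)
  expect_length(tracks, 3)
  for (tr in tracks) {
    expect_equal(tr$frames, 0:9)
    # all members of a greedy track carry one oracle label
    labs <- vapply(seq_len(10), function(f) {
      di <- which(frames[[f]]$cx_px == tr$members$cx_px[f])
      oracle_label[[f]][di]
    }, integer(1))
    expect_equal(length(unique(labs)), 1)
  }
  expect_error(link_frames(det, match_tol_px = -1), "match_tol_px")
})

test_that("confirmation equals the longest-consecutive-run oracle", {
  brute_longest <- function(frames) {
    frames <- sort(unique(frames))
    best <- 0
    for (i in seq_along(frames)) {
      for (j in i:length(frames)) {
        if (identical(frames[i:j], seq(frames[i], frames[i] + (j - i)))) {
          best <- max(best, j - i + 1)
        }
      }
    }
    best
  }
  ivmorph:::with_seed(99, {
    for (rep in 1:100) {
      present <- sort(sample(0:9, sample(1:10, 1)))
      k_min <- sample(1:5, 1)
      det <- fake_dets(present, rep(50, length(present)),
                       rep(50, length(present)), rep(10, length(present)))
      tracks <- link_frames(det, match_tol_px = 5)
      expect_length(tracks, 1)
      confirmed <- confirm_tracks(tracks, k_min)
      expect_equal(length(confirmed) == 1, brute_longest(present) >= k_min)
    }
  })
})

test_that("confirm_tracks with k_min = 1 is the identity on tracks", {
  det <- fake_dets(c(0, 2, 5), rep(40, 3), rep(40, 3), rep(10, 3))
  tracks <- link_frames(det, match_tol_px = 5)
  confirmed <- confirm_tracks(tracks, 1L)
  expect_equal(length(confirmed), length(tracks))
  expect_equal(confirmed[[1]]$members$frame_index,
               tracks[[1]]$members$frame_index)
})

test_that("overlap suppression keeps the best of overlapping circles", {
  disjoint <- data.frame(cx_px = c(10, 60), cy_px = c(10, 60),
                         radius_px = c(5, 5), score = c(0.9, 0.8))
  expect_equal(nrow(suppress_overlaps(disjoint)), 2)

  concentric <- data.frame(cx_px = c(30, 30), cy_px = c(30, 30),
                           radius_px = c(10, 12), score = c(0.7, 0.9))
  kept <- suppress_overlaps(concentric)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)
})

test_that("overlap suppression is idempotent on random circle sets", {
  ivmorph:::with_seed(7, {
    for (rep in 1:100) {
      n <- sample(1:20, 1)
      x <- data.frame(cx_px = runif(n, 0, 200), cy_px = runif(n, 0, 200),
                      radius_px = runif(n, 3, 40), score = runif(n))
      once <- suppress_overlaps(x)
      expect_lte(nrow(once), n)
      expect_identical(suppress_overlaps(once), once)
    }
  })
})

test_that("manual corrections update the set and the ledger counts", {
  auto <- fake_dets(0, seq(20, 200, by = 10), seq(20, 200, by = 10),
                    rep(8, 19))[1:18, ]
  auto$source <- "auto"
  no_edit <- apply_corrections(auto)
  expect_equal(nrow(no_edit$circles), 18)
  expect_equal(no_edit$ledger$n_manual, 0)

  plus1 <- apply_corrections(auto,
                             additions = data.frame(cx_px = 300, cy_px = 300,
                                                    radius_px = 9))
  expect_equal(nrow(plus1$circles), 19)
  expect_equal(plus1$ledger$n_auto_retained, 18)
  expect_equal(plus1$ledger$n_manual, 1)
  expect_equal(sum(plus1$circles$source == "manual"), 1)

  auto12 <- auto[1:12, ]
  minus1 <- apply_corrections(auto12, removal_ids = 3L)
  expect_equal(nrow(minus1$circles), 11)
  expect_equal(minus1$ledger$n_auto_retained, 11)
  expect_equal(minus1$ledger$n_manual, 1)
  expect_error(apply_corrections(auto12, removal_ids = 99L), "unknown removal")
})

test_that("the correction rate reproduces its defining formula", {
  expect_equal(manual_correction_rate(list(n_auto_retained = 18,
                                           n_manual = 1)), 5.26)
  expect_equal(manual_correction_rate(list(n_auto_retained = 11,
                                           n_manual = 4)), 26.67)
  expect_equal(manual_correction_rate(list(n_auto_retained = 40,
                                           n_manual = 0)), 0)
  expect_error(manual_correction_rate(list(n_auto_retained = 0,
                                           n_manual = 0)), "undefined")
  # bounded in [0, 100] and strictly increasing in n_manual
  rates <- vapply(0:10, function(m) {
    manual_correction_rate(list(n_auto_retained = 15, n_manual = m))
  }, numeric(1))
  expect_true(all(rates >= 0 & rates <= 100))
  expect_true(all(diff(rates) > 0))
  expect_true(all((rates == 0) == (0:10 == 0)))
})

test_that("diameter histograms bin on aligned left-closed edges", {
  h <- diameter_histogram(c(600, 600, 600), 10)
  expect_equal(h$breaks, c(600, 610))
  expect_equal(h$counts, 3L)

  h0 <- diameter_histogram(numeric(0), 10)
  expect_equal(sum(h0$counts), 0)

  draws <- ivmorph:::with_seed(5, runif(1000, 550, 690 - 1e-9))
  h1 <- diameter_histogram(draws, 10)
  expect_equal(length(h1$counts), 14)
  expect_equal(sum(h1$counts), 1000)
  expect_error(diameter_histogram(c(1, 2), 0), "bin_width")
})

test_that("confirmed detection on a jittered sequence recovers the scene", {
  spec <- scene_spec(320, 320,
                     circles = data.frame(cx_px = c(70, 200, 120),
                                          cy_px = c(80, 90, 240),
                                          radius_px = c(25, 30, 20),
                                          contrast = c(-90, -110, -70)),
                     noise_sd = 3, seed = 12)
  sq <- render_sequence(spec, 5, jitter_sd_px = 0.5)
  params <- hough_params(15, 35)
  det <- do.call(rbind, lapply(seq_along(sq$frames), function(f) {
    d <- detect_circles(sq$frames[[f]], params)
    if (nrow(d)) d$frame_index <- f - 1L
    d
  }))
  tracks <- confirm_tracks(link_frames(det, match_tol_px = 5), 3L)
  circ <- suppress_overlaps(track_circles(tracks))
  m <- match_detections(circ, render_scene(spec)$truth)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(m$n_fp, 0)
})
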