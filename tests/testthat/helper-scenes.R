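# Shared fixtures: randomized non-overlapping disk scenes with ground truth
# and a greedy matching of detections to truth.

random_disk_scene <- function(seed, size_px = 320, n_max = 8,
                              r_range = c(12, 30), contrast_range = c(50, 120),
                              noise_max = 5) {
  ivmorph:::with_seed(seed, {
    n <- sample(seq_len(n_max), 1)
    circ <- data.frame(cx_px = numeric(0), cy_px = numeric(0),
                       radius_px = numeric(0), contrast = numeric(0))
    tries <- 0
    while (nrow(circ) < n && tries < 400) {
      tries <- tries + 1
      r <- stats::runif(1, r_range[1], r_range[2])
      cx <- stats::runif(1, r + 4, size_px - r - 4)
      cy <- stats::runif(1, r + 4, size_px - r - 4)
      if (nrow(circ)) {
        d <- sqrt((circ$cx_px - cx)^2 + (circ$cy_px - cy)^2)
        if (any(d < circ$radius_px + r + 10)) next
      }
      circ <- rbind(circ, data.frame(cx_px = cx, cy_px = cy, radius_px = r,
                                     contrast = -stats::runif(1,
                                                              contrast_range[1],
                                                              contrast_range[2])))
    }
    scene_spec(size_px, size_px, circles = circ,
               noise_sd = stats::runif(1, 0, noise_max), seed = seed)
  })
}

# Greedy 1:1 matching of detections to truth by nearest center.
match_detections <- function(det, truth, tol_px = 5) {
  used <- integer(0)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((det$cx_px - truth$cx_px[i])^2 + (det$cy_px - truth$cy_px[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_px) {
      used <- c(used, j)
      rows[[length(rows) + 1]] <- data.frame(
        truth_id = i, det_id = j, center_err = d[j],
        radius_err = abs(det$radius_px[j] - truth$radius_px[i]))
    }
  }
  list(pairs = if (length(rows)) do.call(rbind, rows) else
    data.frame(truth_id = integer(0), det_id = integer(0),
               center_err = numeric(0), radius_err = numeric(0)),
    n_fp = nrow(det) - length(used), n_fn = nrow(truth) - length(rows))
}

# Recovery experiment over seeded scenes; returns aggregate metrics.
recovery_metrics <- function(seeds, params = hough_params(10, 33), ...) {
  tp <- 0; fp <- 0; fn <- 0; errs_c <- c(); errs_r <- c()
  for (s in seeds) {
    sc <- render_scene(random_disk_scene(s, ...))
    det <- detect_circles(sc$image, params)
    m <- match_detections(det, sc$truth)
    tp <- tp + nrow(m$pairs); fp <- fp + m$n_fp; fn <- fn + m$n_fn
    errs_c <- c(errs_c, m$pairs$center_err)
    errs_r <- c(errs_r, m$pairs$radius_err)
  }
  list(recall = tp / (tp + fn), precision = tp / (tp + fp),
       max_center_err = max(errs_c), max_radius_err = max(errs_r))
}

# Calibration model with a known scale, for tests that need one.
unit_calibration <- function(um_per_px = 1) {
  fit_calibration(c(0, 100, 200), 100 * um_per_px)
}
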