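# End-to-end synthetic pipeline: simulate an IVM experiment with known
# ground truth, image every dish, run calibration -> detection -> temporal
# QC -> diameter selection -> endpoint summaries -> statistics, and write
# all artifacts. GVBD is never inferred from images: the simulated human
# scores are ingested as data, exactly as stereomicroscope calls would be.

#' Simulate per-oocyte ground truth for an IVM experiment
#'
#' Draws initial diameters from a truncated normal inside the stage III
#' selection window, per-oocyte diameter changes from group-specific
#' normals, and GVBD calls from group-specific Bernoulli rates. Group
#' effects default to a DHP-responsive pattern with non-monotonic-like
#' suppression across the BTBPE doses.
#'
#' @param groups Character vector of group labels, or a data frame with
#'   columns `group`, `gvbd_p`, `delta_mean_um` to override the effects.
#' @param dishes_per_group,oocytes_per_dish Design sizes.
#' @param seed Integer seed.
#' @param d_initial_mean_um,d_initial_sd_um,window_um Truncated-normal
#'   parameters for initial diameters.
#' @param delta_sd_um Per-oocyte SD of the diameter change.
#' @return A data frame of oocyte records (`oocyte_id`, `dish_id`, `group`,
#'   `d_initial_um`, `d_final_um`, `gvbd`).
#' @export
simulate_ivm_experiment <- function(groups = NULL, dishes_per_group = 3L,
                                    oocytes_per_dish = 30L, seed = 1L,
                                    d_initial_mean_um = 620,
                                    d_initial_sd_um = 30,
                                    window_um = c(550, 690),
                                    delta_sd_um = 8) {
  effects <- default_group_effects()
  if (is.null(groups)) {
    groups <- effects
  } else if (is.character(groups)) {
    abort_if(!all(groups %in% effects$group),
             "no default effects for group(s): ",
             paste(setdiff(groups, effects$group), collapse = ", "),
             "; pass a data frame with gvbd_p and delta_mean_um")
    groups <- effects[match(groups, effects$group), ]
  } else {
    groups <- as.data.frame(groups)
    abort_if(!all(c("group", "gvbd_p", "delta_mean_um") %in% names(groups)),
             "group table needs group, gvbd_p, delta_mean_um")
  }
  with_seed(seed, {
    rows <- list()
    for (gi in seq_len(nrow(groups))) {
      g <- groups$group[gi]
      for (d in seq_len(dishes_per_group)) {
        n <- oocytes_per_dish
        u <- stats::runif(n, stats::pnorm(window_um[1], d_initial_mean_um,
                                          d_initial_sd_um),
                          stats::pnorm(window_um[2], d_initial_mean_um,
                                       d_initial_sd_um))
        d0 <- stats::qnorm(u, d_initial_mean_um, d_initial_sd_um)
        delta <- stats::rnorm(n, groups$delta_mean_um[gi], delta_sd_um)
        gv <- stats::runif(n) < groups$gvbd_p[gi]
        rows[[length(rows) + 1]] <- data.frame(
          oocyte_id = sprintf("%s_d%d_o%02d", g, d, seq_len(n)),
          dish_id = sprintf("%s_dish%d", g, d), group = g,
          d_initial_um = d0, d_final_um = d0 + delta, gvbd = gv,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Group effect defaults: DHP induces maturation (high GVBD, ~+20 um
# diameter gain); the hormone-free control barely matures; BTBPE doses
# suppress both endpoints without strict dose proportionality.
default_group_effects <- function() {
  data.frame(group = c("noDHP", "DHP", "BTBPE_1nM", "BTBPE_10nM",
                       "BTBPE_100nM", "BTBPE_1000nM"),
             gvbd_p = c(0.05, 0.85, 0.45, 0.55, 0.65, 0.35),
             delta_mean_um = c(2, 20, 8, 10, 14, 6),
             stringsAsFactors = FALSE)
}

# Lay the oocytes of one dish out on a grid so disks never overlap;
# positions are deterministic. Returns the scene circle table plus image
# dimensions.
dish_layout <- function(d_um, um_per_px, contrast, max_extra_um = 40) {
  n <- length(d_um)
  r_px <- d_um / 2 / um_per_px
  cell <- 2 * ceiling(max(r_px) + max_extra_um / 2 / um_per_px) + 14
  ncol_grid <- ceiling(sqrt(n * 1.2))
  nrow_grid <- ceiling(n / ncol_grid)
  ix <- (seq_len(n) - 1) %% ncol_grid
  iy <- (seq_len(n) - 1) %/% ncol_grid
  circles <- data.frame(
    cx_px = cell / 2 + ix * cell + ((seq_len(n) * 7) %% 5) - 2,
    cy_px = cell / 2 + iy * cell + ((seq_len(n) * 3) %% 5) - 2,
    radius_px = r_px, contrast = contrast)
  list(circles = circles, width_px = ncol_grid * cell,
       height_px = nrow_grid * cell)
}

# Detect circles in one dish image sequence and return confirmed,
# overlap-filtered representative circles.
detect_dish <- function(frames, params, k_min, match_tol_px) {
  dets <- lapply(seq_along(frames), function(f) {
    d <- detect_circles(frames[[f]], params)
    if (nrow(d)) d$frame_index <- f - 1L
    d
  })
  all_det <- do.call(rbind, dets)
  if (is.null(all_det) || !nrow(all_det)) {
    return(structure(empty_detections(),
                     class = c("ivm_detections", "data.frame")))
  }
  if (length(frames) == 1) {
    return(suppress_overlaps(dets[[1]]))
  }
  tracks <- confirm_tracks(link_frames(all_det, match_tol_px), k_min)
  suppress_overlaps(track_circles(tracks))
}

# Match detected circles to true circles by nearest center within tol.
# Returns per-truth-row index into detections (NA = miss) and the
# false-positive detection rows.
match_to_truth <- function(detections, truth, tol_px) {
  m <- rep(NA_integer_, nrow(truth))
  if (nrow(detections)) {
    for (i in seq_len(nrow(truth))) {
      d <- sqrt((detections$cx_px - truth$cx_px[i])^2 +
                  (detections$cy_px - truth$cy_px[i])^2)
      d[seq_len(nrow(detections)) %in% m] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= tol_px) m[i] <- j
    }
  }
  list(match = m, false_pos = setdiff(seq_len(nrow(detections)), m))
}

#' Run the full synthetic IVM pipeline
#'
#' Executes calibrate -> detect -> temporal QC -> diameter selection ->
#' (ingest GVBD scores) -> dish summaries -> statistics on a simulated
#' experiment, writing all intermediate CSV/JSON artifacts plus a QC report
#' (diameter histogram, manual correction rate) to `out_dir`. Misses and
#' false positives of the detector relative to ground truth are converted
#' into the manual additions/removals an operator would perform, so the
#' correction ledger is meaningful. Every artifact carries the config hash;
#' outputs contain no timestamps, so a rerun with the same config and seed
#' reproduces identical bytes.
#'
#' @param config A config list (see [default_run_config()],
#'   [read_run_config()]); `config$out_dir` may be overridden by `out_dir`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `status` (0 on success), `paths` of the
#'   written artifacts, `dishes`, `qc` and `report`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  abort_if(is.null(out_dir), "an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  log_lines <- c(sprintf("config_hash=%s", hash),
                 sprintf("seed=%d", as.integer(config$seed)))
  logf <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- "calibrate"
  result <- tryCatch({
    # --- calibration ---------------------------------------------------
    calcfg <- config$calibration
    mspec <- micrometer_spec(calcfg$width_px, calcfg$height_px,
                             calcfg$spacing_um, calcfg$um_per_px,
                             line_width_px = calcfg$line_width_px,
                             noise_sd = calcfg$noise_sd,
                             seed = derive_seed(config$seed, 1L))
    mic <- render_micrometer(mspec)
    cal <- calibrate_from_image(mic$image, calcfg$spacing_um,
                                magnification_label = calcfg$label)
    cal$created_at <- NULL  # run artifacts stay timestamp-free
    write_calibration(cal, file.path(out_dir, "calibration.json"))
    logf("calibrate: %d rulings, %.5f um/px (rms %.4f um)",
         cal$n_lines, cal$um_per_px, cal$rms_residual_um)

    # --- simulate ground truth -----------------------------------------
    stage <- "simulate"
    des <- config$design
    truth <- simulate_ivm_experiment(des$groups, des$dishes_per_group,
                                     des$oocytes_per_dish,
                                     seed = derive_seed(config$seed, 2L),
                                     window_um = config$selection_window_um)
    logf("simulate: %d oocytes in %d dishes", nrow(truth),
         length(unique(truth$dish_id)))

    # --- per-dish imaging, detection, QC -------------------------------
    stage <- "detect"
    um <- cal$um_per_px
    dcfg <- config$detection
    r_lo <- max(3, floor(config$selection_window_um[1] / (2 * um)) -
                  dcfg$radius_margin_px)
    r_hi <- ceiling((config$selection_window_um[2] + 40) / (2 * um)) +
      dcfg$radius_margin_px
    params <- hough_params(r_lo, r_hi,
                           gradient_low = dcfg$gradient_low,
                           gradient_high = dcfg$gradient_high,
                           accumulator_threshold = dcfg$accumulator_threshold,
                           accumulator_downscale = dcfg$accumulator_downscale)
    match_tol <- config$qc$match_tol_px %||% max(5, 0.1 * r_lo)
    dish_ids <- unique(truth$dish_id)
    oocyte_rows <- list()
    qc_rows <- list()
    for (dish in dish_ids) {
      rec <- truth[truth$dish_id == dish, , drop = FALSE]
      lay <- dish_layout(rec$d_initial_um, um, config$imaging$contrast)
      dseed <- derive_seed(config$seed, 3L, match(dish, dish_ids))
      spec <- scene_spec(lay$width_px, lay$height_px,
                         circles = lay$circles,
                         noise_sd = config$imaging$noise_sd,
                         edge_softness_px = config$imaging$edge_softness_px,
                         seed = dseed)
      seq_pre <- render_sequence(spec, config$qc$n_frames,
                                 config$qc$jitter_sd_px)
      auto <- detect_dish(seq_pre$frames, params, config$qc$k_min, match_tol)
      mt <- match_to_truth(auto, lay$circles, tol_px = 10)
      additions <- lay$circles[is.na(mt$match),
                               c("cx_px", "cy_px", "radius_px"), drop = FALSE]
      corr <- apply_corrections(auto,
                                additions = if (nrow(additions)) additions,
                                removal_ids = auto$detection_id[mt$false_pos])
      # measured initial diameter per oocyte (manual additions carry the
      # operator's measurement, i.e. the true circle)
      d0_px <- ifelse(is.na(mt$match), lay$circles$radius_px,
                      auto$radius_px[mt$match])
      rec$d_initial_meas_um <- px_to_um(2 * d0_px, cal)

      # post-incubation re-measurement: same field, grown radii, one frame
      lay_post <- lay
      lay_post$circles$radius_px <- rec$d_final_um / 2 / um
      spec_post <- scene_spec(lay$width_px, lay$height_px,
                              circles = lay_post$circles,
                              noise_sd = config$imaging$noise_sd,
                              edge_softness_px = config$imaging$edge_softness_px,
                              seed = derive_seed(dseed, 4L))
      post_img <- render_scene(spec_post)$image
      auto_post <- detect_dish(list(post_img), params, 1L, match_tol)
      mt_post <- match_to_truth(auto_post, lay_post$circles, tol_px = 10)
      rec$d_final_meas_um <- px_to_um(
        2 * ifelse(is.na(mt_post$match), NA_real_,
                   auto_post$radius_px[mt_post$match]), cal)
      oocyte_rows[[dish]] <- rec
      qc_rows[[dish]] <- data.frame(
        dish_id = dish, n_auto = corr$ledger$n_auto_retained,
        n_manual = corr$ledger$n_manual,
        correction_rate_percent = manual_correction_rate(corr$ledger),
        stringsAsFactors = FALSE)
      logf("detect: dish %s auto=%d manual=%d rate=%.2f%%", dish,
           corr$ledger$n_auto_retained, corr$ledger$n_manual,
           manual_correction_rate(corr$ledger))
    }
    measured <- do.call(rbind, oocyte_rows)
    qc_table <- do.call(rbind, qc_rows)
    rownames(measured) <- rownames(qc_table) <- NULL

    # --- diameter selection --------------------------------------------
    stage <- "select"
    w <- config$selection_window_um
    in_window <- measured$d_initial_meas_um >= w[1] &
      measured$d_initial_meas_um < w[2]
    logf("select: %d/%d oocytes inside [%g, %g) um", sum(in_window),
         nrow(measured), w[1], w[2])
    oocytes <- data.frame(oocyte_id = measured$oocyte_id,
                          dish_id = measured$dish_id,
                          group = measured$group,
                          d_initial_um = measured$d_initial_meas_um,
                          d_final_um = measured$d_final_meas_um,
                          gvbd = measured$gvbd,  # ingested human scores
                          stringsAsFactors = FALSE)[in_window, , drop = FALSE]
    write_oocyte_table(oocytes, file.path(out_dir, "oocytes.csv"), hash)

    # --- QC report ------------------------------------------------------
    stage <- "qc"
    hist <- diameter_histogram(oocytes$d_initial_um, 10)
    overall_rate <- manual_correction_rate(list(
      n_auto_retained = sum(qc_table$n_auto),
      n_manual = sum(qc_table$n_manual)))
    qc <- list(per_dish = qc_table,
               overall = list(n_auto = sum(qc_table$n_auto),
                              n_manual = sum(qc_table$n_manual),
                              correction_rate_percent = overall_rate),
               diameter_histogram = list(breaks = hist$breaks,
                                         counts = hist$counts),
               config_hash = hash)
    jsonlite::write_json(qc, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_csv_hashed(qc_table, file.path(out_dir, "qc_per_dish.csv"), hash)

    # --- summaries and statistics ---------------------------------------
    stage <- "summarize"
    dishes <- withCallingHandlers(
      summarize_dishes(oocytes, expected_n = des$oocytes_per_dish),
      warning = function(wc) {
        logf("summarize: %s", conditionMessage(wc))
        invokeRestart("muffleWarning")
      })
    out_dishes <- dishes
    out_dishes$mean_delta_um <- fmt_um(out_dishes$mean_delta_um)
    out_dishes$gvbd_rate_percent <- round(out_dishes$gvbd_rate_percent, 2)
    write_csv_hashed(out_dishes, file.path(out_dir, "dish_summaries.csv"),
                     hash)
    stage <- "stats"
    report <- withCallingHandlers(
      run_analysis(dishes),
      warning = function(wc) {
        logf("stats: %s", conditionMessage(wc))
        invokeRestart("muffleWarning")
      })
    jsonlite::write_json(list(config_hash = hash,
                              results = report_to_list(report)),
                         file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "stats_report.txt"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    list(status = 0L,
         paths = file.path(out_dir, c("calibration.json", "oocytes.csv",
                                      "qc_report.json", "qc_per_dish.csv",
                                      "dish_summaries.csv",
                                      "stats_report.json", "stats_report.txt",
                                      "run_log.txt")),
         dishes = dishes, qc = qc, report = report)
  }, error = function(e) {
    writeLines(c(log_lines, sprintf("ERROR at stage %s: %s", stage,
                                    conditionMessage(e))),
               file.path(out_dir, "run_log.txt"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
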