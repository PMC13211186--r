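# Cross-frame reliability rules: detections are linked into tracks, retained
# only when consistently identified across consecutive frames, overlapping
# detections are filtered, and manual corrections are accounted for in a
# ledger whose summary is the manual correction rate
# N_manual / (N_auto + N_manual) * 100%.

#' Link per-frame detections into tracks
#'
#' Frame-to-frame greedy matching by ascending center distance: a detection
#' joins the nearest open track whose last center lies within `match_tol_px`
#' and whose radius differs by at most 20%; unmatched detections open new
#' tracks. Deterministic for a fixed input.
#'
#' @param detections A data frame of detections from consecutive frames with
#'   columns `frame_index` (0-based, consecutive), `cx_px`, `cy_px`,
#'   `radius_px` and optionally `score`.
#' @param match_tol_px Maximum center distance for a frame-to-frame link
#'   (>= 0).
#' @return An object of class `ivm_tracks`: a list of tracks, each with
#'   `track_id`, `members` (the linked detection rows), `frames`,
#'   `max_run` (longest consecutive-frame run) and `representative`
#'   (median center/radius over members).
#' @export
link_frames <- function(detections, match_tol_px) {
  abort_if(!is_number(match_tol_px) || match_tol_px < 0,
           "'match_tol_px' must be >= 0")
  detections <- as.data.frame(detections)
  if (!"score" %in% names(detections)) detections$score <- NA_real_
  tracks <- list()           # each: list(members = data.frame, last = row)
  frames <- sort(unique(detections$frame_index))
  for (f in frames) {
    dets <- detections[detections$frame_index == f, , drop = FALSE]
    if (!nrow(dets)) next
    if (!length(tracks)) {
      tracks <- lapply(seq_len(nrow(dets)), function(i) {
        list(members = dets[i, , drop = FALSE])
      })
      next
    }
    last <- do.call(rbind, lapply(tracks, function(tr) {
      utils::tail(tr$members, 1)[, c("cx_px", "cy_px", "radius_px")]
    }))
    dist <- outer(last$cx_px, dets$cx_px, `-`)^2 +
      outer(last$cy_px, dets$cy_px, `-`)^2
    dist <- sqrt(dist)
    rad_ok <- abs(outer(last$radius_px, dets$radius_px, `-`)) <=
      0.2 * last$radius_px
    cand <- which(dist <= match_tol_px & rad_ok, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dist[cand], cand[, 1], cand[, 2])
      used_tr <- logical(length(tracks)); used_det <- logical(nrow(dets))
      for (k in ord) {
        ti <- cand[k, 1]; di <- cand[k, 2]
        if (used_tr[ti] || used_det[di]) next
        used_tr[ti] <- TRUE; used_det[di] <- TRUE
        tracks[[ti]]$members <- rbind(tracks[[ti]]$members,
                                      dets[di, , drop = FALSE])
      }
    } else {
      used_det <- logical(nrow(dets))
    }
    for (di in which(!used_det)) {
      tracks[[length(tracks) + 1]] <- list(members = dets[di, , drop = FALSE])
    }
  }
  tracks <- lapply(seq_along(tracks), function(i) {
    finish_track(tracks[[i]]$members, i)
  })
  structure(tracks, class = "ivm_tracks")
}

longest_run <- function(frames) {
  frames <- sort(unique(frames))
  n <- length(frames)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  r <- rle(diff(frames) == 1)
  if (!any(r$values)) return(1L)
  max(r$lengths[r$values]) + 1L
}

finish_track <- function(members, id) {
  members <- members[order(members$frame_index), , drop = FALSE]
  rownames(members) <- NULL
  list(track_id = id, members = members, frames = members$frame_index,
       max_run = longest_run(members$frame_index),
       representative = data.frame(
         cx_px = stats::median(members$cx_px),
         cy_px = stats::median(members$cy_px),
         radius_px = stats::median(members$radius_px),
         score = stats::median(members$score)))
}

#' @export
print.ivm_tracks <- function(x, ...) {
  cat(sprintf("ivm_tracks: %d track(s)\n", length(x)))
  invisible(x)
}

#' Confirm tracks by consecutive-frame persistence
#'
#' Retains tracks whose longest run of consecutive frames is at least
#' `k_min`; the representative circle is recomputed from the members lying
#' in qualifying runs only. `confirm_tracks(x, 1)` is the identity.
#'
#' @param tracks An `ivm_tracks` object from [link_frames()].
#' @param k_min Minimum consecutive-frame run length (positive integer).
#' @return An `ivm_tracks` object with the confirmed tracks.
#' @export
confirm_tracks <- function(tracks, k_min = 3L) {
  abort_if(!is_count(k_min), "'k_min' must be a positive integer")
  out <- list()
  for (tr in tracks) {
    if (tr$max_run < k_min) next
    fr <- sort(unique(tr$members$frame_index))
    grp <- cumsum(c(1, diff(fr) != 1))
    ok_frames <- unlist(lapply(split(fr, grp),
                               function(g) if (length(g) >= k_min) g))
    members <- tr$members[tr$members$frame_index %in% ok_frames, ,
                          drop = FALSE]
    conf <- finish_track(members, tr$track_id)
    out[[length(out) + 1]] <- conf
  }
  structure(out, class = "ivm_tracks")
}

#' Representative circles of a track set
#'
#' @param tracks An `ivm_tracks` object.
#' @return An `ivm_detections`-style data frame with one row per track
#'   (median center/radius, median score), `source = "auto"`.
#' @export
track_circles <- function(tracks) {
  if (!length(tracks)) return(structure(empty_detections(),
                                        class = c("ivm_detections",
                                                  "data.frame")))
  rep <- do.call(rbind, lapply(tracks, `[[`, "representative"))
  out <- data.frame(detection_id = vapply(tracks, `[[`, integer(1),
                                          "track_id"),
                    cx_px = rep$cx_px, cy_px = rep$cy_px,
                    radius_px = rep$radius_px,
                    score = ifelse(is.na(rep$score), 1, rep$score),
                    frame_index = 0L, source = "auto",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("ivm_detections", "data.frame"))
}

#' Filter overlapping detections
#'
#' Greedy score-ordered suppression: circles are processed in descending
#' score (ties by lower `cy_px` then `cx_px`); a circle is discarded when its
#' center lies within the radius of an already-kept circle, or when its
#' center distance to a kept circle is less than half the sum of the two
#' radii. The result is sorted by descending score; the operation never
#' increases the count and is idempotent.
#'
#' @param circles A data frame with `cx_px`, `cy_px`, `radius_px`, `score`.
#' @return The retained circles, sorted by descending score.
#' @export
suppress_overlaps <- function(circles) {
  circles <- as.data.frame(circles)
  abort_if(!"score" %in% names(circles), "circles must carry scores")
  if (!nrow(circles)) return(circles)
  ord <- order(-circles$score, circles$cy_px, circles$cx_px)
  circles <- circles[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(circles))) {
    if (length(keep)) {
      d <- sqrt((circles$cx_px[keep] - circles$cx_px[i])^2 +
                  (circles$cy_px[keep] - circles$cy_px[i])^2)
      bad <- d < circles$radius_px[keep] |
        d < 0.5 * (circles$radius_px[keep] + circles$radius_px[i])
      if (any(bad)) next
    }
    keep <- c(keep, i)
  }
  out <- circles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply manual corrections to automatic detections
#'
#' Reproduces the operator interventions of the sorting workflow: removal of
#' false-positive circles and addition of missed ones. The final circle set
#' is `(auto - removals) + additions`, with additions tagged
#' `source = "manual"`. The returned ledger counts `n_auto_retained`
#' (automatic detections not removed) and
#' `n_manual = n_additions + n_removals`.
#'
#' @param auto An `ivm_detections` data frame with a `detection_id` column.
#' @param additions Data frame of manually added circles (`cx_px`, `cy_px`,
#'   `radius_px`; `score` optional), or `NULL`.
#' @param removal_ids Integer ids of auto detections to remove, or `NULL`.
#' @return A list with `circles` (final set) and `ledger` (class
#'   `ivm_ledger`).
#' @export
apply_corrections <- function(auto, additions = NULL, removal_ids = NULL) {
  auto <- as.data.frame(auto)
  removal_ids <- unique(as.integer(removal_ids %||% integer(0)))
  unknown <- setdiff(removal_ids, auto$detection_id)
  abort_if(length(unknown) > 0,
           "unknown removal id(s): ", paste(unknown, collapse = ", "))
  retained <- auto[!auto$detection_id %in% removal_ids, , drop = FALSE]
  n_add <- 0L
  if (!is.null(additions) && nrow(as.data.frame(additions))) {
    additions <- as.data.frame(additions)
    need <- c("cx_px", "cy_px", "radius_px")
    abort_if(!all(need %in% names(additions)),
             "additions need columns ", paste(need, collapse = ", "))
    if (!"score" %in% names(additions)) additions$score <- NA_real_
    n_add <- nrow(additions)
    add <- data.frame(detection_id = max(c(0L, auto$detection_id)) +
                        seq_len(n_add),
                      cx_px = additions$cx_px, cy_px = additions$cy_px,
                      radius_px = additions$radius_px,
                      score = additions$score, frame_index = 0L,
                      source = "manual", stringsAsFactors = FALSE)
    final <- rbind(retained[names(add)], add)
  } else {
    additions <- NULL
    final <- retained
  }
  rownames(final) <- NULL
  ledger <- structure(list(additions = additions, removals = removal_ids,
                           n_auto_retained = nrow(retained),
                           n_manual = n_add + length(removal_ids)),
                      class = "ivm_ledger")
  list(circles = structure(final, class = c("ivm_detections", "data.frame")),
       ledger = ledger)
}

#' @export
print.ivm_ledger <- function(x, ...) {
  cat(sprintf("correction ledger: %d auto retained, %d manual (%d added, %d removed)\n",
              x$n_auto_retained, x$n_manual,
              if (is.null(x$additions)) 0L else nrow(x$additions),
              length(x$removals)))
  if (x$n_auto_retained + x$n_manual > 0) {
    cat(sprintf("manual correction rate: %.2f%%\n",
                manual_correction_rate(x)))
  }
  invisible(x)
}

#' Manual correction rate
#'
#' The workflow's detector-reliability QC metric:
#' `100 * N_manual / (N_auto + N_manual)`, where `N_auto` counts automatic
#' detections retained after removals and `N_manual` counts manual
#' interventions (additions plus removals). Reported to two decimals.
#'
#' @param ledger An `ivm_ledger`, or a list with `n_auto_retained` and
#'   `n_manual`.
#' @return The rate in percent, rounded to two decimals.
#' @examples
#' manual_correction_rate(list(n_auto_retained = 18, n_manual = 1))  # 5.26
#' manual_correction_rate(list(n_auto_retained = 11, n_manual = 4))  # 26.67
#' @export
manual_correction_rate <- function(ledger) {
  n_auto <- ledger$n_auto_retained
  n_manual <- ledger$n_manual
  abort_if(!is_number(n_auto) || !is_number(n_manual) ||
             n_auto < 0 || n_manual < 0,
           "ledger counts must be non-negative numbers")
  abort_if(n_auto + n_manual == 0,
           "undefined rate: no detections and no corrections")
  round(100 * n_manual / (n_auto + n_manual), 2)
}

#' Diameter histogram
#'
#' Left-closed bins aligned to multiples of `bin_width_um`, covering the data
#' range contiguously; counts sum to the input length. Empty input yields an
#' empty histogram.
#'
#' @param diameters_um Numeric vector of diameters in micrometers.
#' @param bin_width_um Bin width (> 0).
#' @return A list with `breaks` (bin edges, length `n_bins + 1`) and
#'   `counts`.
#' @export
diameter_histogram <- function(diameters_um, bin_width_um) {
  abort_if(!is_number(bin_width_um) || bin_width_um <= 0,
           "'bin_width_um' must be > 0")
  if (!length(diameters_um)) {
    return(list(breaks = numeric(0), counts = integer(0)))
  }
  idx <- floor(diameters_um / bin_width_um)
  bins <- seq(min(idx), max(idx))
  counts <- vapply(bins, function(b) sum(idx == b), integer(1))
  list(breaks = c(bins, max(bins) + 1) * bin_width_um, counts = counts)
}
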