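# Diameter-based stage classification and per-oocyte / per-dish endpoints.
# Zebrafish follicle stages by diameter: stage III is broadly ~340-690 um;
# the sorting workflow uses a stricter late-vitellogenic window of
# 550-690 um to avoid overlap with stage IV (690-730 um) and stage V
# (730-750 um). All windows are half-open [lo, hi), except the uppermost,
# which is closed at its upper bound.

#' Stage windows for zebrafish follicles
#'
#' @param scheme `"broad"` (stage III from 340 um) or `"strict"` (the
#'   550-690 um late-vitellogenic selection window).
#' @return A data frame of class `ivm_stage_windows` with columns `stage`,
#'   `lo_um`, `hi_um`, ascending and non-overlapping; the scheme name is
#'   carried as an attribute.
#' @export
stage_windows <- function(scheme = c("broad", "strict")) {
  scheme <- match.arg(scheme)
  lo3 <- if (scheme == "broad") 340 else 550
  make_stage_windows(data.frame(stage = c("III", "IV", "V"),
                                lo_um = c(lo3, 690, 730),
                                hi_um = c(690, 730, 750)), scheme)
}

#' Validate a custom stage-window table
#'
#' @param windows Data frame with `stage`, `lo_um`, `hi_um`.
#' @param scheme Scheme label.
#' @return An `ivm_stage_windows` object.
#' @export
make_stage_windows <- function(windows, scheme = "custom") {
  windows <- as.data.frame(windows)
  need <- c("stage", "lo_um", "hi_um")
  abort_if(!all(need %in% names(windows)),
           "windows need columns ", paste(need, collapse = ", "))
  windows <- windows[order(windows$lo_um), need]
  abort_if(any(windows$lo_um >= windows$hi_um), "each window needs lo < hi")
  if (nrow(windows) > 1) {
    abort_if(any(windows$hi_um[-nrow(windows)] > windows$lo_um[-1]),
             "stage windows overlap")
  }
  rownames(windows) <- NULL
  structure(windows, scheme = scheme,
            class = c("ivm_stage_windows", "data.frame"))
}

#' Classify diameters into follicle stages
#'
#' Each diameter maps to the unique window containing it under the
#' half-open convention `[lo, hi)`; the uppermost window is right-closed, so
#' 750 um still classifies as stage V under the default schemes. Boundary
#' values such as 690 and 730 um go to the upper stage.
#'
#' @param diameter_um Positive numeric vector of diameters.
#' @param windows An `ivm_stage_windows` object (default broad scheme).
#' @return Character vector of stage labels; `NA` outside all windows.
#' @export
classify_stage <- function(diameter_um, windows = stage_windows("broad")) {
  abort_if(!inherits(windows, "ivm_stage_windows"),
           "'windows' must come from stage_windows()/make_stage_windows()")
  abort_if(any(diameter_um <= 0), "diameters must be positive")
  n <- nrow(windows)
  out <- rep(NA_character_, length(diameter_um))
  for (i in seq_len(n)) {
    hit <- diameter_um >= windows$lo_um[i] &
      (diameter_um < windows$hi_um[i] |
         (i == n & diameter_um == windows$hi_um[i]))
    out[hit] <- windows$stage[i]
  }
  out
}

#' Per-oocyte diameter change
#'
#' `delta = d_final_um - d_initial_um` (signed), per oocyte.
#'
#' @param records A data frame of oocyte records with `oocyte_id`,
#'   `d_initial_um`, `d_final_um`.
#' @return Numeric vector of diameter changes in micrometers.
#' @export
compute_delta <- function(records) {
  records <- as.data.frame(records)
  abort_if(!all(c("oocyte_id", "d_initial_um", "d_final_um") %in%
                  names(records)),
           "records need oocyte_id, d_initial_um, d_final_um")
  missing <- is.na(records$d_final_um) | is.na(records$d_initial_um)
  abort_if(any(missing), "missing diameter for oocyte(s): ",
           paste(records$oocyte_id[missing], collapse = ", "))
  records$d_final_um - records$d_initial_um
}

#' Summarise one culture dish
#'
#' The culture dish is the experimental unit. Mean diameter change is the
#' arithmetic mean of per-oocyte deltas; oocytes lacking a post-incubation
#' measurement are excluded from the mean (their ids are attached as the
#' `excluded_delta` attribute) but still enter the GVBD denominator when
#' scored. The GVBD rate is the percentage of matured oocytes among scored
#' oocytes in the dish.
#'
#' @param records Oocyte records for a single dish (`dish_id`, `group`,
#'   `d_initial_um`, `d_final_um`, `gvbd`).
#' @return A one-row data frame of class `ivm_dish_summary`: `dish_id`,
#'   `group`, `n_oocytes`, `mean_delta_um`, `gvbd_rate_percent`.
#' @export
summarize_dish <- function(records) {
  records <- as.data.frame(records)
  abort_if(nrow(records) < 1, "need at least one oocyte record")
  abort_if(length(unique(records$dish_id)) != 1,
           "records mix dish ids: ",
           paste(unique(records$dish_id), collapse = ", "))
  has_delta <- !is.na(records$d_final_um) & !is.na(records$d_initial_um)
  mean_delta <- if (any(has_delta)) {
    mean(compute_delta(records[has_delta, , drop = FALSE]))
  } else NA_real_
  scored <- !is.na(records$gvbd)
  gvbd_rate <- if (any(scored)) {
    100 * sum(records$gvbd[scored]) / sum(scored)
  } else NA_real_
  out <- data.frame(dish_id = records$dish_id[1],
                    group = records$group[1],
                    n_oocytes = nrow(records),
                    mean_delta_um = mean_delta,
                    gvbd_rate_percent = gvbd_rate,
                    stringsAsFactors = FALSE)
  attr(out, "excluded_delta") <- records$oocyte_id[!has_delta]
  structure(out, class = c("ivm_dish_summary", "data.frame"))
}

#' Summarise all dishes of an experiment
#'
#' Applies [summarize_dish()] per dish and warns when a dish deviates from
#' the declared design size (default 30 oocytes per dish).
#'
#' @param records Oocyte records for the whole experiment.
#' @param expected_n Declared oocytes per dish; `NULL` disables the check.
#' @return A data frame with one row per dish.
#' @export
summarize_dishes <- function(records, expected_n = 30L) {
  records <- as.data.frame(records)
  out <- do.call(rbind, lapply(split(records, records$dish_id), function(r) {
    s <- summarize_dish(r)
    if (!is.null(expected_n) && s$n_oocytes != expected_n) {
      warning(sprintf("dish %s has %d oocytes (declared %d)",
                      s$dish_id, s$n_oocytes, expected_n), call. = FALSE)
    }
    s
  }))
  rownames(out) <- NULL
  out[order(out$group, out$dish_id), ]
}
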