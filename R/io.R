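# File formats: PNG/TIFF images (8/16-bit grayscale), CSV tables (comma,
# UTF-8, mandatory header, "." decimal; micrometer values serialized at
# 0.1 um precision), JSON reports and YAML run configuration. CSV artifacts
# written by the pipeline carry the run's config hash in a leading comment
# line.

#' Load a PNG or TIFF image
#'
#' Returns the image in native integer grey levels with a `bit_depth`
#' attribute; no silent downcast of 16-bit data. 3-channel images are
#' returned as arrays (see [to_grayscale()]).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix (or `h x w x 3` array) of grey levels.
#' @export
load_image <- function(path) {
  abort_if(!file.exists(path), "no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      x <- tryCatch(png::readPNG(path),
                    error = function(e) stop("cannot read PNG '", path, "': ",
                                             conditionMessage(e),
                                             call. = FALSE))
      # readPNG rescales to [0,1]; recover the integer code. 16-bit files
      # are detected by codes that are not multiples of 1/255.
      v255 <- x * 255
      if (max(abs(v255 - round(v255))) > 1e-3) {
        x <- round(x * 65535); attr(x, "bit_depth") <- 16L
      } else {
        x <- round(v255); attr(x, "bit_depth") <- 8L
      }
      x
    },
    tif = ,
    tiff = {
      x <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                    error = function(e) stop("cannot read TIFF '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
      info <- attr(x, "bits.per.sample") %||% 8L
      y <- x
      attributes(y) <- list(dim = dim(x))
      storage.mode(y) <- "double"
      attr(y, "bit_depth") <- as.integer(info)
      y
    },
    stop("unsupported image format '", ext, "' for file: ", path,
         call. = FALSE)
  )
  if (length(dim(img)) == 3 && dim(img)[3] %in% c(2L, 4L)) {
    img <- img[, , seq_len(dim(img)[3] - 1), drop = FALSE]  # drop alpha
    if (dim(img)[3] == 1) img <- img[, , 1]
  }
  img
}

#' Save a grayscale image as PNG or TIFF
#'
#' Writes integer grey levels losslessly: PNG for 8-bit images, TIFF for
#' 8- or 16-bit. Round trip through [load_image()] is bit-identical.
#'
#' @param image Numeric matrix of grey levels with an optional `bit_depth`
#'   attribute (default 8).
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  depth <- attr(image, "bit_depth") %||% 8L
  abort_if(!depth %in% c(8L, 16L), "'bit_depth' must be 8 or 16")
  vmax <- 2^depth - 1
  abort_if(min(image) < 0 || max(image) > vmax,
           "image values outside the declared bit range")
  ext <- tolower(tools::file_ext(path))
  norm <- unclass(image) / vmax
  attr(norm, "bit_depth") <- NULL
  if (ext == "png") {
    abort_if(depth != 8L, "use TIFF for 16-bit output")
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = depth)
  } else {
    stop("unsupported image format '", ext, "' for file: ", path,
         call. = FALSE)
  }
  invisible(path)
}

fmt_um <- function(x) round(x, 1)  # 0.1 um serialization precision

#' Write detections to CSV
#'
#' Columns: `frame`, `cx_px`, `cy_px`, `radius_px`, `diameter_um` (when a
#' calibration is given), `score`, `source`.
#'
#' @param detections An `ivm_detections` data frame.
#' @param path Output CSV path.
#' @param cal Optional `ivm_calibration` used to add `diameter_um`.
#' @param config_hash Optional hash string recorded in a leading comment.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path, cal = NULL,
                                 config_hash = NULL) {
  out <- data.frame(frame = detections$frame_index,
                    cx_px = round(detections$cx_px, 3),
                    cy_px = round(detections$cy_px, 3),
                    radius_px = round(detections$radius_px, 3),
                    diameter_um = if (!is.null(cal)) {
                      fmt_um(px_to_um(2 * detections$radius_px, cal))
                    } else NA_real_,
                    score = round(detections$score, 4),
                    source = detections$source)
  write_csv_hashed(out, path, config_hash)
}

write_csv_hashed <- function(df, path, config_hash = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config_hash)) {
    writeLines(paste0("# config_hash=", config_hash), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an oocyte endpoint table
#'
#' Expects a CSV with mandatory columns `oocyte_id`, `dish_id`, `group`,
#' `d_initial_um`, `d_final_um`, `gvbd`. `d_final_um` may be empty
#' (oocyte lost before re-measurement); `gvbd` accepts only
#' `true`/`false`/`1`/`0` (case-insensitive) or empty for unscored. Schema
#' violations are collected and reported with line numbers.
#'
#' @param path CSV path.
#' @return A data frame of typed oocyte records.
#' @export
read_oocyte_table <- function(path) {
  abort_if(!file.exists(path), "no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         fileEncoding = "UTF-8")
  need <- c("oocyte_id", "dish_id", "group", "d_initial_um", "d_final_um",
            "gvbd")
  missing <- setdiff(need, names(raw))
  abort_if(length(missing) > 0,
           "missing mandatory column(s): ", paste(missing, collapse = ", "))
  problems <- character(0)
  line <- seq_len(nrow(raw)) + 1L  # header on line 1
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  d0 <- num_or_na(raw$d_initial_um)
  d1 <- ifelse(raw$d_final_um == "", NA, num_or_na(raw$d_final_um))
  bad <- which(is.na(d0) | d0 <= 0)
  if (length(bad)) problems <- c(problems, paste0(
    "line ", line[bad], ": d_initial_um must be a positive number"))
  bad <- which(raw$d_final_um != "" & (is.na(d1) | num_or_na(raw$d_final_um) <= 0))
  if (length(bad)) problems <- c(problems, paste0(
    "line ", line[bad], ": d_final_um must be a positive number or empty"))
  gv_low <- tolower(trimws(raw$gvbd))
  gv <- rep(NA, nrow(raw))
  gv[gv_low %in% c("true", "1")] <- TRUE
  gv[gv_low %in% c("false", "0")] <- FALSE
  bad <- which(!gv_low %in% c("true", "false", "1", "0", ""))
  if (length(bad)) problems <- c(problems, paste0(
    "line ", line[bad], ": gvbd must be true/false/1/0 (got '",
    raw$gvbd[bad], "')"))
  dup <- duplicated(paste(raw$dish_id, raw$oocyte_id))
  if (any(dup)) problems <- c(problems, paste0(
    "line ", line[dup], ": duplicate oocyte_id '", raw$oocyte_id[dup],
    "' within dish '", raw$dish_id[dup], "'"))
  abort_if(length(problems) > 0,
           "invalid oocyte table '", path, "':\n  ",
           paste(problems, collapse = "\n  "))
  data.frame(oocyte_id = raw$oocyte_id, dish_id = raw$dish_id,
             group = raw$group, d_initial_um = d0, d_final_um = d1,
             gvbd = gv, stringsAsFactors = FALSE)
}

#' Write an oocyte endpoint table
#'
#' @param records Oocyte records data frame.
#' @param path Output CSV path.
#' @param config_hash Optional hash recorded in a leading comment.
#' @return `path`, invisibly.
#' @export
write_oocyte_table <- function(records, path, config_hash = NULL) {
  out <- records
  out$d_initial_um <- fmt_um(out$d_initial_um)
  out$d_final_um <- fmt_um(out$d_final_um)
  out$gvbd <- ifelse(is.na(out$gvbd), "",
                     ifelse(out$gvbd, "true", "false"))
  write_csv_hashed(out, path, config_hash)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated config list (see [validate_run_config()]).
#' @export
read_run_config <- function(path) {
  abort_if(!file.exists(path), "no such config file: ", path)
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a pipeline run configuration
#'
#' Fills defaults and checks the schema before any computation. See
#' [default_run_config()] for the full field list.
#'
#' @param config A named list.
#' @return The completed config list.
#' @export
validate_run_config <- function(config) {
  abort_if(!is.list(config), "config must be a named list")
  def <- default_run_config()
  unknown <- setdiff(names(config), names(def))
  abort_if(length(unknown) > 0,
           "unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(def)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- def[[nm]]
    } else if (is.list(def[[nm]])) {
      sub_unknown <- setdiff(names(config[[nm]]), names(def[[nm]]))
      abort_if(length(sub_unknown) > 0, "unknown config field(s) in '", nm,
               "': ", paste(sub_unknown, collapse = ", "))
      for (sub in names(def[[nm]])) {
        if (is.null(config[[nm]][[sub]])) config[[nm]][[sub]] <- def[[nm]][[sub]]
      }
    }
  }
  abort_if(!is_number(config$seed), "config$seed must be a number")
  cal <- config$calibration
  abort_if(!is_number(cal$spacing_um) || cal$spacing_um <= 0,
           "calibration$spacing_um must be positive")
  abort_if(!is_number(cal$um_per_px) || cal$um_per_px <= 0,
           "calibration$um_per_px must be positive")
  w <- config$selection_window_um
  abort_if(length(w) != 2 || w[1] >= w[2],
           "selection_window_um must be c(lo, hi), lo < hi")
  abort_if(!is_count(config$qc$k_min), "qc$k_min must be a positive integer")
  d <- config$design
  abort_if(!is_count(d$dishes_per_group) || !is_count(d$oocytes_per_dish),
           "design sizes must be positive integers")
  abort_if(length(d$groups) < 2, "design needs >= 2 groups")
  config
}

#' Default pipeline configuration
#'
#' The defaults mirror the study design: six groups (hormone-free control,
#' DHP positive control, DHP + BTBPE at 1/10/100/1000 nM), three dishes per
#' group, 30 oocytes per dish, a 550-690 um stage III selection window, and
#' three consecutive confirmation frames.
#'
#' @return A named list.
#' @export
default_run_config <- function() {
  list(seed = 1L,
       calibration = list(spacing_um = 200, um_per_px = 8,
                          width_px = 600L, height_px = 120L,
                          line_width_px = 3, noise_sd = 2,
                          label = "4x"),
       detection = list(radius_margin_px = 5, accumulator_threshold = 0.3,
                        gradient_low = 10, gradient_high = 30,
                        accumulator_downscale = 1L),
       selection_window_um = c(550, 690),
       qc = list(k_min = 3L, match_tol_px = NULL, n_frames = 3L,
                 jitter_sd_px = 0.3),
       design = list(groups = c("noDHP", "DHP", "BTBPE_1nM", "BTBPE_10nM",
                                "BTBPE_100nM", "BTBPE_1000nM"),
                     dishes_per_group = 3L, oocytes_per_dish = 30L),
       imaging = list(noise_sd = 3, contrast = -90, edge_softness_px = 2),
       out_dir = NULL)
}

# Hash of the canonical JSON serialization of a config list.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
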