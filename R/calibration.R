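# Pixel-to-micrometer calibration from a stage-micrometer image: detect dark
# rulings with sub-pixel localisation, then fit the known cumulative ruling
# distance against detected position. A fresh model is fit per magnification
# setting and whenever imaging conditions change.

#' Detect micrometer rulings
#'
#' Projects mean intensity perpendicular to the rulings, finds
#' prominence-filtered minima (dark lines) and refines each to sub-pixel
#' precision by local parabolic interpolation.
#'
#' @param image Grayscale numeric matrix of a stage-micrometer target.
#' @param axis `"x"` if the rulings are vertical lines (positions measured
#'   along the x axis), `"y"` otherwise.
#' @param min_depth Minimum dip depth in grey levels for a line to count;
#'   guards against reading noise as rulings.
#' @return Sorted numeric vector of 0-based sub-pixel line positions.
#' @export
detect_rulings <- function(image, axis = c("x", "y"), min_depth = 10) {
  axis <- match.arg(axis)
  image <- to_grayscale(image)
  profile <- if (axis == "x") colMeans(image) else rowMeans(image)
  baseline <- stats::quantile(profile, 0.9, names = FALSE)
  depth <- baseline - profile
  dmax <- max(depth)
  abort_if(dmax < min_depth,
           "fewer than 2 rulings found; re-image the micrometer target")
  above <- depth >= 0.5 * dmax
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pos <- c()
  for (k in which(runs$values)) {
    seg <- starts[k]:ends[k]
    i <- seg[which.max(depth[seg])]
    p <- i
    if (i > 1 && i < length(depth)) {
      a <- depth[i - 1]; b <- depth[i]; c <- depth[i + 1]
      den <- a - 2 * b + c
      if (den < 0) p <- i + 0.5 * (a - c) / den
    }
    pos <- c(pos, p - 1)  # 0-based
  }
  abort_if(length(pos) < 2,
           "fewer than 2 rulings found; re-image the micrometer target")
  sort(pos)
}

#' Fit a pixel-to-micrometer calibration model
#'
#' Least-squares fit of the known cumulative ruling distance
#' `(i - 1) * spacing_um` against detected line position; the slope is the
#' scale in micrometers per pixel (a single physical parameter — the
#' intercept only absorbs the phase of the first ruling).
#'
#' @param line_positions_px Strictly increasing line positions in pixels
#'   (length >= 2).
#' @param spacing_um Known ruling interval in micrometers.
#' @param magnification_label Free-text label of the magnification setting.
#' @return An object of class `ivm_calibration` with fields `um_per_px`,
#'   `magnification_label`, `rms_residual_um`, `n_lines` and `created_at`.
#' @export
fit_calibration <- function(line_positions_px, spacing_um,
                            magnification_label = "") {
  p <- as.numeric(line_positions_px)
  abort_if(length(p) < 2, "need at least 2 line positions")
  abort_if(any(diff(p) <= 0), "line positions must be strictly increasing")
  abort_if(!is_number(spacing_um) || spacing_um <= 0,
           "'spacing_um' must be positive")
  d <- (seq_along(p) - 1) * spacing_um
  fit <- stats::lm(d ~ p)
  slope <- unname(stats::coef(fit)[2])
  abort_if(!is.finite(slope) || slope <= 0,
           "degenerate calibration fit (non-positive scale)")
  structure(list(um_per_px = slope,
                 magnification_label = magnification_label,
                 rms_residual_um = sqrt(mean(stats::resid(fit)^2)),
                 n_lines = length(p),
                 created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "ivm_calibration")
}

#' @export
print.ivm_calibration <- function(x, ...) {
  cat(sprintf("calibration [%s]: %.6g um/px from %d rulings (rms %.3g um)\n",
              x$magnification_label, x$um_per_px, x$n_lines,
              x$rms_residual_um))
  invisible(x)
}

#' Convert a pixel length to micrometers
#'
#' Linear, origin-preserving conversion `length_px * um_per_px`.
#'
#' @param length_px Non-negative length(s) in pixels.
#' @param model An `ivm_calibration`.
#' @return Length(s) in micrometers.
#' @export
px_to_um <- function(length_px, model) {
  abort_if(!inherits(model, "ivm_calibration"),
           "'model' must be an ivm_calibration")
  abort_if(any(length_px < 0), "lengths must be non-negative")
  length_px * model$um_per_px
}

#' Calibrate directly from a micrometer image
#'
#' Convenience wrapper: [detect_rulings()] then [fit_calibration()].
#'
#' @inheritParams detect_rulings
#' @inheritParams fit_calibration
#' @return An `ivm_calibration`.
#' @export
calibrate_from_image <- function(image, spacing_um, axis = "x",
                                 magnification_label = "") {
  fit_calibration(detect_rulings(image, axis), spacing_um,
                  magnification_label)
}

#' Write / read a calibration model as JSON
#'
#' @param model An `ivm_calibration`.
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the model.
#' @export
write_calibration <- function(model, path) {
  abort_if(!inherits(model, "ivm_calibration"),
           "'model' must be an ivm_calibration")
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  abort_if(is.null(x$um_per_px) || x$um_per_px <= 0,
           "invalid calibration file: ", path)
  structure(x[c("um_per_px", "magnification_label", "rms_residual_um",
                "n_lines", "created_at")], class = "ivm_calibration")
}
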