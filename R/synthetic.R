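# Synthetic scene generation: bright-field-like images of circular oocytes
# and stage-micrometer ruling targets, with exact ground truth.
#
# Coordinate convention (used package-wide): pixel indices are 0-based and a
# circle center is expressed in pixel-center coordinates, so the center of
# the top-left pixel is (0, 0). Images are stored as numeric matrices with
# rows = y and columns = x, values in integer grey levels clipped to the bit
# range.

#' Specify a synthetic oocyte scene
#'
#' Describes a grayscale scene of disk-shaped objects on a uniform
#' background, emulating a bright-field view of oocytes in a sorting dish.
#' The default polarity is a bright background with darker disks (negative
#' `contrast`), but contrast is signed per circle so either polarity can be
#' generated.
#'
#' @param width_px,height_px Image size in pixels (positive integers).
#' @param background_level Background grey value within the bit range.
#' @param circles A data frame with columns `cx_px`, `cy_px`, `radius_px`,
#'   `contrast` (grey-level offset of the disk interior relative to the
#'   background; negative for dark disks). May have zero rows.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   grey levels (>= 0).
#' @param edge_softness_px Width in pixels of the linear intensity ramp at a
#'   disk rim; 0 gives a hard edge.
#' @param bit_depth Image bit depth, 8 or 16.
#' @param seed Integer seed making the rendered noise reproducible.
#' @return An object of class `scene_spec`.
#' @seealso [render_scene()], [render_sequence()]
#' @export
scene_spec <- function(width_px, height_px, background_level = 200,
                       circles = empty_circles(), noise_sd = 0,
                       edge_softness_px = 2, bit_depth = 8L, seed = 1L) {
  abort_if(!is_count(width_px) || !is_count(height_px),
           "image dimensions must be positive integers")
  abort_if(!bit_depth %in% c(8L, 16L), "'bit_depth' must be 8 or 16")
  vmax <- 2^bit_depth - 1
  abort_if(!is_number(background_level) || background_level < 0 ||
             background_level > vmax,
           "'background_level' must lie in [0, ", vmax, "]")
  abort_if(!is_number(noise_sd) || noise_sd < 0, "'noise_sd' must be >= 0")
  abort_if(!is_number(edge_softness_px) || edge_softness_px < 0,
           "'edge_softness_px' must be >= 0")
  circles <- as_circle_table(circles)
  if (nrow(circles)) {
    abort_if(any(circles$radius_px < 3), "circle radius_px must be >= 3")
    inside <- circles$cx_px >= 0 & circles$cx_px <= width_px - 1 &
      circles$cy_px >= 0 & circles$cy_px <= height_px - 1
    abort_if(!all(inside), "all circle centers must lie inside the image")
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 background_level = background_level,
                 circles = circles, noise_sd = noise_sd,
                 edge_softness_px = edge_softness_px,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

empty_circles <- function() {
  data.frame(cx_px = numeric(0), cy_px = numeric(0), radius_px = numeric(0),
             contrast = numeric(0))
}

as_circle_table <- function(circles) {
  circles <- as.data.frame(circles)
  need <- c("cx_px", "cy_px", "radius_px", "contrast")
  abort_if(!all(need %in% names(circles)),
           "'circles' needs columns ", paste(need, collapse = ", "))
  circles[need]
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene_spec: %dx%d px, %d circle(s), noise sd %.3g, seed %d\n",
              x$width_px, x$height_px, nrow(x$circles), x$noise_sd, x$seed))
  invisible(x)
}

# Render disk coverage into `img` (modified copy returned). Coverage at a
# pixel is 1 inside the disk, 0 outside, with a linear ramp of width
# `softness` centered on the rim.
add_disks <- function(img, circles, softness) {
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(nrow(circles))) {
    cx <- circles$cx_px[i]; cy <- circles$cy_px[i]
    r <- circles$radius_px[i]; a <- circles$contrast[i]
    pad <- ceiling(r + softness / 2 + 1)
    x0 <- max(0, floor(cx - pad)); x1 <- min(w - 1, ceiling(cx + pad))
    y0 <- max(0, floor(cy - pad)); y1 <- min(h - 1, ceiling(cy + pad))
    xs <- x0:x1; ys <- y0:y1
    dx <- xs - cx; dy <- ys - cy
    d <- sqrt(outer(dy^2, dx^2, `+`))
    cov <- if (softness > 0) {
      pmin(1, pmax(0, (r + softness / 2 - d) / softness))
    } else {
      (d <= r) * 1
    }
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + a * cov
  }
  img
}

finalize_image <- function(img, spec) {
  vmax <- 2^spec$bit_depth - 1
  img <- round(pmax(pmin(img, vmax), 0))
  attr(img, "bit_depth") <- spec$bit_depth
  img
}

#' Render a synthetic scene
#'
#' Renders the scene described by a [scene_spec()] and returns the image
#' together with its exact ground truth. Rendering is deterministic for a
#' fixed spec (including seed).
#'
#' @param spec A `scene_spec`.
#' @return A list with elements `image` (numeric matrix, grey levels, with a
#'   `bit_depth` attribute) and `truth` (data frame `id`, `cx_px`, `cy_px`,
#'   `radius_px`, one row per circle in spec order).
#' @export
render_scene <- function(spec) {
  abort_if(!inherits(spec, "scene_spec"), "'spec' must be a scene_spec")
  img <- matrix(spec$background_level, spec$height_px, spec$width_px)
  img <- add_disks(img, spec$circles, spec$edge_softness_px)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                              nrow(img), ncol(img)))
    img <- img + noise
  }
  truth <- data.frame(id = seq_len(nrow(spec$circles)),
                      cx_px = spec$circles$cx_px,
                      cy_px = spec$circles$cy_px,
                      radius_px = spec$circles$radius_px)
  list(image = finalize_image(img, spec), truth = truth)
}

#' Render a multi-frame sequence with center jitter
#'
#' Emulates consecutive live frames of the same field: each frame perturbs
#' every circle center by independent Gaussian jitter (radius held fixed).
#' Pixel noise is identical across frames for a given spec seed, so with
#' `jitter_sd_px = 0` all frames are bit-identical to [render_scene()].
#' Jittered centers are clamped to the image bounds.
#'
#' @param spec A `scene_spec`.
#' @param n_frames Number of frames (>= 1).
#' @param jitter_sd_px Per-axis standard deviation of the center jitter in
#'   pixels (>= 0).
#' @return A list with `frames` (list of images) and `truth` (data frame
#'   `frame`, `id`, `cx_px`, `cy_px`, `radius_px`; frames indexed from 0).
#' @export
render_sequence <- function(spec, n_frames, jitter_sd_px = 0) {
  abort_if(!inherits(spec, "scene_spec"), "'spec' must be a scene_spec")
  abort_if(!is_count(n_frames), "'n_frames' must be a positive integer")
  abort_if(!is_number(jitter_sd_px) || jitter_sd_px < 0,
           "'jitter_sd_px' must be >= 0")
  k <- nrow(spec$circles)
  jit <- with_seed(derive_seed(spec$seed, 7L),
                   array(stats::rnorm(n_frames * k * 2, 0, jitter_sd_px),
                         dim = c(n_frames, k, 2)))
  frames <- vector("list", n_frames)
  truths <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    sp <- spec
    if (k) {
      sp$circles$cx_px <- pmin(spec$width_px - 1,
                               pmax(0, spec$circles$cx_px + jit[f, , 1]))
      sp$circles$cy_px <- pmin(spec$height_px - 1,
                               pmax(0, spec$circles$cy_px + jit[f, , 2]))
    }
    out <- render_scene(sp)
    frames[[f]] <- out$image
    truths[[f]] <- cbind(frame = f - 1L, out$truth)
  }
  list(frames = frames, truth = do.call(rbind, truths))
}

#' Specify a stage-micrometer ruling target
#'
#' Describes a calibration image of parallel dark rulings at a known physical
#' pitch, as imaged at a true scale of `um_per_px`. Lines are rendered with a
#' Gaussian intensity profile (sigma = `line_width_px / 2`) so that sub-pixel
#' localisation is well-posed; the first ruling is placed at half the pixel
#' pitch from the image edge.
#'
#' @param width_px,height_px Image size in pixels.
#' @param spacing_um Ruling interval in micrometers.
#' @param um_per_px True scale in micrometers per pixel.
#' @param line_width_px Nominal line width in pixels (>= 1).
#' @param orientation `"vertical"` (lines perpendicular to the x axis) or
#'   `"horizontal"`.
#' @param background_level,line_depth Background grey value and depth of the
#'   ruling dip in grey levels.
#' @param noise_sd,bit_depth,seed As in [scene_spec()].
#' @return An object of class `micrometer_spec`.
#' @export
micrometer_spec <- function(width_px, height_px, spacing_um, um_per_px,
                            line_width_px = 3, orientation = c("vertical",
                                                               "horizontal"),
                            background_level = 220, line_depth = 120,
                            noise_sd = 0, bit_depth = 8L, seed = 1L) {
  orientation <- match.arg(orientation)
  abort_if(!is_count(width_px) || !is_count(height_px),
           "image dimensions must be positive integers")
  abort_if(!is_number(spacing_um) || spacing_um <= 0,
           "'spacing_um' must be positive")
  abort_if(!is_number(um_per_px) || um_per_px <= 0,
           "'um_per_px' must be positive")
  abort_if(!is_number(line_width_px) || line_width_px < 1,
           "'line_width_px' must be >= 1")
  spacing_px <- spacing_um / um_per_px
  abort_if(spacing_px < 2 * line_width_px,
           "rulings are not resolvable: spacing_um/um_per_px must be >= ",
           "2 * line_width_px")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 spacing_um = spacing_um, um_per_px = um_per_px,
                 line_width_px = line_width_px, orientation = orientation,
                 background_level = background_level, line_depth = line_depth,
                 noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "micrometer_spec")
}

#' Render a stage-micrometer target
#'
#' @param spec A [micrometer_spec()].
#' @return A list with `image` and `positions_px`, the exact (possibly
#'   sub-pixel) 0-based coordinates of the rendered ruling centers along the
#'   axis perpendicular to the lines. True positions are independent of the
#'   noise realisation.
#' @export
render_micrometer <- function(spec) {
  abort_if(!inherits(spec, "micrometer_spec"), "'spec' must be a micrometer_spec")
  spacing_px <- spec$spacing_um / spec$um_per_px
  extent <- if (spec$orientation == "vertical") spec$width_px else spec$height_px
  positions <- seq(spacing_px / 2, extent - 1, by = spacing_px)
  abort_if(length(positions) < 2,
           "image too small to hold two rulings at this spacing")
  coord <- 0:(extent - 1)
  sigma <- spec$line_width_px / 2
  dip <- rowSums(vapply(positions, function(p) {
    exp(-((coord - p)^2) / (2 * sigma^2))
  }, numeric(length(coord))))
  profile <- spec$background_level - spec$line_depth * pmin(1, dip)
  img <- if (spec$orientation == "vertical") {
    matrix(profile, spec$height_px, spec$width_px, byrow = TRUE)
  } else {
    matrix(profile, spec$height_px, spec$width_px)
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                              nrow(img), ncol(img)))
    img <- img + noise
  }
  list(image = finalize_image(img, spec), positions_px = positions)
}
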