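# Circle detection: grayscale conversion and a gradient-voting circle Hough
# transform. The transform is implemented as a described operator so it can
# be validated against generator ground truth: Sobel gradients -> hysteresis
# edge map -> per-radius voting along +/- gradient direction -> accumulator
# peaks -> non-maximum suppression -> algebraic (Kasa) sub-pixel refinement.

#' Convert an image to grayscale
#'
#' 3-channel images are combined with the standard luminance weights
#' (0.299, 0.587, 0.114); single-channel input is returned unchanged.
#'
#' @param image A numeric matrix (grayscale) or an `h x w x 3` array.
#' @return A numeric matrix.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3) {
    out <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    attr(out, "bit_depth") <- attr(image, "bit_depth")
    return(out)
  }
  stop("unsupported image: expected 1 or 3 channels", call. = FALSE)
}

#' Parameters for the circle Hough transform
#'
#' @param r_min_px,r_max_px Radius search range in pixels; `r_min_px >= 3`.
#'   In the sorting workflow these hold the user-defined diameter window,
#'   converted to pixels with the current calibration.
#' @param radius_step_px Radius sampling step (>= 1).
#' @param gradient_low,gradient_high Hysteresis thresholds on gradient
#'   magnitude, in grey levels per pixel (`low <= high`).
#' @param accumulator_threshold Minimum normalized accumulator vote fraction
#'   in `[0, 1]`; 1 corresponds to the theoretical vote count of a complete
#'   circle rim.
#' @param min_center_dist_px Minimum separation between reported centers;
#'   defaults to `r_min_px`.
#' @param accumulator_downscale Integer accumulator downscale factor (>= 1).
#' @param min_arc_coverage Minimum fraction of a candidate's circumference
#'   (in 10-degree sectors) that must hold radially-oriented edge pixels;
#'   rejects arc artifacts that vote like small circles tangent to a large
#'   rim.
#' @return An object of class `hough_params`.
#' @export
hough_params <- function(r_min_px, r_max_px, radius_step_px = 1,
                         gradient_low = 10, gradient_high = 30,
                         accumulator_threshold = 0.3,
                         min_center_dist_px = r_min_px,
                         accumulator_downscale = 1L,
                         min_arc_coverage = 0.5) {
  abort_if(!is_number(r_min_px) || r_min_px < 3, "'r_min_px' must be >= 3")
  abort_if(!is_number(r_max_px) || r_max_px < r_min_px,
           "empty radius range: need r_min_px <= r_max_px")
  abort_if(!is_number(radius_step_px) || radius_step_px < 1,
           "'radius_step_px' must be >= 1")
  abort_if(!is_number(gradient_low) || !is_number(gradient_high) ||
             gradient_low <= 0 || gradient_high < gradient_low,
           "need 0 < gradient_low <= gradient_high")
  abort_if(!is_number(accumulator_threshold) || accumulator_threshold <= 0 ||
             accumulator_threshold > 1,
           "'accumulator_threshold' must be in (0, 1]")
  abort_if(!is_number(min_center_dist_px) || min_center_dist_px < 0,
           "'min_center_dist_px' must be >= 0")
  abort_if(!is_count(accumulator_downscale),
           "'accumulator_downscale' must be a positive integer")
  abort_if(!is_number(min_arc_coverage) || min_arc_coverage < 0 ||
             min_arc_coverage > 1, "'min_arc_coverage' must be in [0, 1]")
  structure(list(r_min_px = r_min_px, r_max_px = r_max_px,
                 radius_step_px = radius_step_px,
                 gradient_low = gradient_low, gradient_high = gradient_high,
                 accumulator_threshold = accumulator_threshold,
                 min_center_dist_px = min_center_dist_px,
                 accumulator_downscale = as.integer(accumulator_downscale),
                 min_arc_coverage = min_arc_coverage),
            class = "hough_params")
}

# Neighbour access with zero padding: n[y, x] = m[y + dy, x + dx].
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys - dy, xs - dx] <- m[ys, xs]
  out
}

# One pass of separable binomial ([1 2 1]/4) smoothing.
smooth3 <- function(m) {
  m <- (shift_mat(m, -1, 0) + 2 * m + shift_mat(m, 1, 0)) / 4
  (shift_mat(m, 0, -1) + 2 * m + shift_mat(m, 0, 1)) / 4
}

# Sobel gradients, normalized to grey levels per pixel.
sobel_gradients <- function(img) {
  gx <- (shift_mat(img, -1, 1) + 2 * shift_mat(img, 0, 1) +
           shift_mat(img, 1, 1)) -
    (shift_mat(img, -1, -1) + 2 * shift_mat(img, 0, -1) +
       shift_mat(img, 1, -1))
  gy <- (shift_mat(img, 1, -1) + 2 * shift_mat(img, 1, 0) +
           shift_mat(img, 1, 1)) -
    (shift_mat(img, -1, -1) + 2 * shift_mat(img, -1, 0) +
       shift_mat(img, -1, 1))
  gx <- gx / 4; gy <- gy / 4
  mag <- sqrt(gx^2 + gy^2)
  # border responses use zero padding; invalidate them
  mag[c(1, nrow(mag)), ] <- 0
  mag[, c(1, ncol(mag))] <- 0
  list(gx = gx, gy = gy, mag = mag)
}

# Hysteresis edge selection: pixels with mag >= low that are 8-connected to a
# pixel with mag >= high. Returns a logical vector over pixels
# (column-major).
hysteresis_edges <- function(mag, low, high) {
  h <- nrow(mag)
  weak <- as.vector(mag >= low)
  visited <- as.vector(mag >= high)
  frontier <- which(visited)
  if (!length(frontier)) return(visited)
  offs <- c(-1, 1, -h, h, -h - 1, -h + 1, h - 1, h + 1)
  npix <- length(weak)
  while (length(frontier)) {
    nb <- rep(frontier, times = length(offs)) +
      rep(offs, each = length(frontier))
    nb <- nb[nb >= 1 & nb <= npix]
    nb <- unique(nb[weak[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

# 3x3 box sum of an accumulator matrix.
pool3 <- function(m) {
  m <- shift_mat(m, -1, 0) + m + shift_mat(m, 1, 0)
  shift_mat(m, 0, -1) + m + shift_mat(m, 0, 1)
}

empty_detections <- function() {
  data.frame(detection_id = integer(0), cx_px = numeric(0),
             cy_px = numeric(0), radius_px = numeric(0), score = numeric(0),
             frame_index = integer(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Detect circular objects with the circle Hough transform
#'
#' Gradient-voting circle detection: (1) 3x3 Sobel derivative kernels give
#' gradient magnitude and direction (after one binomial smoothing pass);
#' (2) an edge map is extracted by hysteresis thresholding; (3) for each
#' radius in the search range, edge pixels vote along both gradient
#' directions into a center accumulator; (4) pooled local accumulator maxima
#' with normalized votes at or above `accumulator_threshold` become
#' candidates; (5) candidates closer than `min_center_dist_px` are reduced to
#' the highest-scoring one (ties broken by lower `cy_px`, then lower
#' `cx_px`, then smaller radius). Surviving candidates are refined to
#' sub-pixel center and radius by an algebraic least-squares circle fit on
#' their rim edge pixels. Output is sorted by descending score and is
#' deterministic for fixed input.
#'
#' @param image A grayscale numeric matrix (see [to_grayscale()]).
#' @param params A [hough_params()] object.
#' @return A data frame of class `ivm_detections` with columns
#'   `detection_id`, `cx_px`, `cy_px`, `radius_px`, `score`, `frame_index`
#'   (0 here; set by callers for sequences) and `source` (`"auto"`).
#' @export
detect_circles <- function(image, params) {
  abort_if(!inherits(params, "hough_params"), "'params' must be hough_params")
  image <- to_grayscale(image)
  abort_if(min(dim(image)) < 2 * params$r_min_px,
           "image smaller than (2 * r_min_px)^2")
  img <- smooth3(image)
  g <- sobel_gradients(img)
  edge <- hysteresis_edges(g$mag, params$gradient_low, params$gradient_high)
  idx <- which(edge)
  if (!length(idx)) return(structure(empty_detections(),
                                     class = c("ivm_detections", "data.frame")))
  h <- nrow(img); w <- ncol(img)
  ex <- (idx - 1) %/% h   # 0-based x
  ey <- (idx - 1) %% h    # 0-based y
  m <- g$mag[idx]
  ux <- g$gx[idx] / m; uy <- g$gy[idx] / m
  ds <- params$accumulator_downscale
  hd <- ceiling(h / ds); wd <- ceiling(w / ds)
  radii <- seq(params$r_min_px, params$r_max_px, by = params$radius_step_px)
  cands <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    votes <- numeric(hd * wd)
    for (s in c(-1, 1)) {
      qx <- round((ex + s * r * ux) / ds)
      qy <- round((ey + s * r * uy) / ds)
      ok <- qx >= 0 & qx <= wd - 1 & qy >= 0 & qy <= hd - 1
      bin <- qx[ok] * hd + qy[ok] + 1
      votes <- votes + tabulate(bin, nbins = hd * wd)
    }
    acc <- pool3(matrix(votes, hd, wd))
    thr <- params$accumulator_threshold * 2 * pi * r
    hit <- which(acc >= thr)
    if (!length(hit)) next
    # keep only local maxima of the pooled accumulator
    is_max <- rep(TRUE, length(hit))
    hy <- (hit - 1) %% hd; hx <- (hit - 1) %/% hd
    for (off in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                     c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
      ny <- hy + off[1]; nx <- hx + off[2]
      inb <- ny >= 0 & ny < hd & nx >= 0 & nx < wd
      v <- rep(-Inf, length(hit))
      v[inb] <- acc[nx[inb] * hd + ny[inb] + 1]
      is_max <- is_max & acc[hit] >= v
    }
    hit <- hit[is_max]
    if (!length(hit)) next
    cands[[k]] <- data.frame(cx_px = ((hit - 1) %/% hd) * ds,
                             cy_px = ((hit - 1) %% hd) * ds,
                             radius_px = r,
                             score = pmin(1, acc[hit] / (2 * pi * r)))
  }
  cand <- do.call(rbind, cands)
  if (is.null(cand) || !nrow(cand)) {
    return(structure(empty_detections(),
                     class = c("ivm_detections", "data.frame")))
  }
  cand <- cand[order(-cand$score, cand$cy_px, cand$cx_px, cand$radius_px), ,
               drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(keep)) { keep <- i; next }
    d <- sqrt((cand$cx_px[keep] - cand$cx_px[i])^2 +
                (cand$cy_px[keep] - cand$cy_px[i])^2)
    if (all(d >= params$min_center_dist_px)) keep <- c(keep, i)
  }
  cand <- cand[keep, , drop = FALSE]
  ref <- refine_circles(cand, ex, ey, ux, uy, params$min_arc_coverage)
  out <- data.frame(detection_id = seq_len(nrow(ref)),
                    cx_px = ref$cx_px, cy_px = ref$cy_px,
                    radius_px = ref$radius_px, score = ref$score,
                    frame_index = 0L, source = "auto",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("ivm_detections", "data.frame"))
}

# Verification and sub-pixel refinement. For each candidate, the rim
# support is the set of edge pixels in an annulus around the candidate
# whose gradient is roughly radial; candidates whose support covers too few
# 10-degree sectors of the circumference are arc artifacts and are dropped.
# Survivors are refined by an algebraic (Kasa) least-squares circle fit on
# their support, falling back to the accumulator estimate when the fit is
# unsupported or drifts.
refine_circles <- function(cand, ex, ey, ux, uy, min_arc_coverage = 0.5) {
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    dx <- ex - cand$cx_px[i]; dy <- ey - cand$cy_px[i]
    d <- sqrt(dx^2 + dy^2)
    sel <- abs(d - cand$radius_px[i]) <= 2.5 & d > 1
    if (sum(sel) < 8) next
    radial <- abs(ux[sel] * dx[sel] / d[sel] + uy[sel] * dy[sel] / d[sel])
    sel2 <- which(sel)[radial > 0.6]
    if (length(sel2) < 8) next
    sectors <- unique(floor((atan2(ey[sel2] - cand$cy_px[i],
                                   ex[sel2] - cand$cx_px[i]) + pi) /
                              (2 * pi) * 36))
    if (length(sectors) < ceiling(min_arc_coverage * 36)) next
    keep[i] <- TRUE
    x <- ex[sel2]; y <- ey[sel2]
    A <- cbind(2 * x, 2 * y, 1)
    fit <- tryCatch(qr.solve(A, x^2 + y^2), error = function(e) NULL)
    if (is.null(fit)) next
    r2 <- fit[3] + fit[1]^2 + fit[2]^2
    if (r2 <= 0) next
    rr <- sqrt(r2)
    drift <- sqrt((fit[1] - cand$cx_px[i])^2 + (fit[2] - cand$cy_px[i])^2)
    if (drift <= 3 && abs(rr - cand$radius_px[i]) <= 3) {
      cand$cx_px[i] <- fit[1]; cand$cy_px[i] <- fit[2]; cand$radius_px[i] <- rr
    }
  }
  cand[keep, , drop = FALSE]
}

#' Filter detections by physical diameter
#'
#' Keeps detections whose diameter `2 * radius_px * um_per_px` falls in the
#' half-open window `[lo, hi)`; input order is preserved. The stage III
#' sorting window used in the oocyte workflow is 550-690 um.
#'
#' @param detections An `ivm_detections` data frame.
#' @param window_um Numeric `c(lo, hi)` in micrometers, `lo < hi`.
#' @param cal An `ivm_calibration` model (see [fit_calibration()]).
#' @return The retained subset of `detections`.
#' @export
filter_by_diameter <- function(detections, window_um, cal) {
  abort_if(length(window_um) != 2 || !is.numeric(window_um) ||
             window_um[1] >= window_um[2],
           "'window_um' must be c(lo, hi) with lo < hi")
  abort_if(!inherits(cal, "ivm_calibration"), "'cal' must be an ivm_calibration")
  d_um <- 2 * detections$radius_px * cal$um_per_px
  detections[d_um >= window_um[1] & d_um < window_um[2], , drop = FALSE]
}
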