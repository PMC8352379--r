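#' Circular region-of-interest specification
#'
#' A fixed circular pixel set over which per-frame temperature statistics are
#' computed. Membership follows the pixel-center rule: a pixel `(r, c)`
#' belongs to the ROI when its center lies at Euclidean distance at most
#' `diameter / 2` from the ROI center (inclusive boundary).
#'
#' @param center `(row, col)` center pixel.
#' @param diameter ROI diameter in pixels (default 30, the conventional
#'   hotspot ROI for this assay).
#' @param frame_dim `(rows, cols)` of the frames the ROI must fit in.
#' @return An object of class `roi_spec` with the enumerated `member_pixels`
#'   (two-column matrix of row, col).
#' @export
roi_spec <- function(center, diameter = 30, frame_dim) {
  stopifnot(length(center) == 2, diameter >= 1, length(frame_dim) == 2)
  radius <- diameter / 2
  if (center[1] - radius < 1 - 0.5 || center[1] + radius > frame_dim[1] + 0.5 ||
      center[2] - radius < 1 - 0.5 || center[2] + radius > frame_dim[2] + 0.5) {
    stop("ROI does not fit inside the frame")
  }
  rr <- max(1, ceiling(center[1] - radius)):min(frame_dim[1], floor(center[1] + radius))
  cc <- max(1, ceiling(center[2] - radius)):min(frame_dim[2], floor(center[2] + radius))
  grid <- expand.grid(row = rr, col = cc)
  d2 <- (grid$row - center[1])^2 + (grid$col - center[2])^2
  members <- as.matrix(grid[d2 <= radius^2 + 1e-9, , drop = FALSE])
  if (nrow(members) == 0) stop("ROI contains no pixels")
  structure(
    list(center = as.numeric(center), diameter = diameter,
         member_pixels = members),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> center (%g, %g), diameter %g px, %d member pixels\n",
              x$center[1], x$center[2], x$diameter, nrow(x$member_pixels)))
  invisible(x)
}

#' Locate the hotspot ROI in a thermograph stack
#'
#' Places a fixed circular ROI at the pixel attaining the global maximum
#' temperature over all frames at or after laser-on — the hotspot that the
#' operator would select as "encompassing the maximum temperature values".
#' Ties are broken by the first occurrence in (frame, row, col) order. If the
#' maximum pixel lies nearer than one radius to a frame edge, the center is
#' shifted minimally inward so the full circle fits, keeping the member-pixel
#' count identical across recordings.
#'
#' @param stack a [thermal_stack()].
#' @param diameter ROI diameter in pixels (default 30).
#' @return A [roi_spec()].
#' @export
locate_roi <- function(stack, diameter = 30) {
  stopifnot(inherits(stack, "thermal_stack"))
  d <- dim(stack$frames)
  radius <- diameter / 2
  if (d[2] < diameter || d[3] < diameter)
    stop("frame is smaller than the ROI diameter")
  sub <- stack$frames[stack$laser_on_index:d[1], , , drop = FALSE]
  # first maximum in (frame, row, col) order; array storage is
  # frame-fastest so search per frame
  best <- c(Inf, NA, NA)  # value sentinel replaced on first frame
  best_val <- -Inf
  for (k in seq_len(dim(sub)[1])) {
    f <- sub[k, , ]
    m <- max(f)
    if (m > best_val) {
      idx <- which(f == m, arr.ind = TRUE)
      # first in (row, col) lexicographic order
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      best <- idx[1, ]
      best_val <- m
    }
  }
  # shift minimally inward to the nearest integer center that fits; integer
  # centers keep the member-pixel count identical across recordings
  center <- as.numeric(best)
  center[1] <- min(max(center[1], ceiling(radius + 0.5)), floor(d[2] - radius + 0.5))
  center[2] <- min(max(center[2], ceiling(radius + 0.5)), floor(d[3] - radius + 0.5))
  roi_spec(center, diameter, frame_dim = d[2:3])
}

#' Reduce a thermograph stack to an ROI temperature trace
#'
#' Computes, for every frame, the arithmetic mean and the population SD of
#' the temperatures over the ROI member pixels. Times are derived from the
#' frame period and laser-on index (t = 0 at laser-on; earlier frames carry
#' negative times).
#'
#' @param stack a [thermal_stack()].
#' @param roi a [roi_spec()].
#' @param animal_id,wavelength,injection metadata stored in the trace.
#' @return A [temperature_trace()].
#' @export
roi_trace <- function(stack, roi, animal_id = stack$source_id,
                      wavelength = NA_real_, injection = NA_character_) {
  stopifnot(inherits(stack, "thermal_stack"), inherits(roi, "roi_spec"))
  d <- dim(stack$frames)
  mp <- roi$member_pixels
  if (nrow(mp) == 0) stop("ROI member set is empty")
  if (max(mp[, 1]) > d[2] || max(mp[, 2]) > d[3]) stop("ROI exceeds frame bounds")
  flat <- matrix(stack$frames, nrow = d[1])  # (frame) x (row*col), column-major
  cols <- (mp[, 2] - 1) * d[2] + mp[, 1]
  vals <- flat[, cols, drop = FALSE]
  means <- rowMeans(vals)
  centered <- vals - means  # recycles by column in column-major order
  sds <- sqrt(rowMeans(centered^2))
  temperature_trace(
    times = stack_times(stack), temp_mean = means, temp_sd = sds,
    animal_id = animal_id, wavelength = wavelength, injection = injection
  )
}
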