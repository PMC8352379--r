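#' Thermograph stack container
#'
#' A time-ordered stack of temperature-calibrated infrared frames. Frames are
#' stored as a 3-D numeric array indexed `(frame, row, col)` with values in
#' degrees C. Time is anchored at laser-on: frame `laser_on_index` is the
#' first frame of the exposure (t = 0); earlier frames carry negative times.
#'
#' @param frames 3-D numeric array `(frame, row, col)` of temperatures in
#'   degrees C; all values finite.
#' @param frame_period_s seconds between consecutive frames (> 0).
#' @param laser_on_index 1-based index of the first exposed frame.
#' @param source_id free-text identifier of the recording.
#' @return An object of class `thermal_stack`.
#' @export
thermal_stack <- function(frames, frame_period_s, laser_on_index = 1L,
                          source_id = "") {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (!all(is.finite(frames))) stop("thermal_stack frames must be finite")
  if (frame_period_s <= 0) stop("frame_period_s must be positive")
  laser_on_index <- as.integer(laser_on_index)
  if (laser_on_index < 1L || laser_on_index > dim(frames)[1])
    stop("laser_on_index must index a frame of the stack")
  structure(
    list(frames = frames, frame_period_s = frame_period_s,
         laser_on_index = laser_on_index, source_id = as.character(source_id)),
    class = "thermal_stack"
  )
}

#' @export
print.thermal_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<thermal_stack> %d frames of %dx%d px, %.4g s/frame, laser-on at frame %d%s\n",
    d[1], d[2], d[3], x$frame_period_s, x$laser_on_index,
    if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Frame times of a thermograph stack
#'
#' @param stack a [thermal_stack()].
#' @return Times in seconds relative to laser-on, one per frame.
#' @export
stack_times <- function(stack) {
  (seq_len(dim(stack$frames)[1]) - stack$laser_on_index) * stack$frame_period_s
}

#' ROI temperature trace container
#'
#' Per-frame ROI mean and spatial SD temperature for one animal, with times
#' in seconds relative to laser-on.
#'
#' @param times strictly increasing times, s.
#' @param temp_mean ROI mean temperatures, degrees C.
#' @param temp_sd ROI spatial SDs, degrees C (non-negative).
#' @param animal_id animal identifier.
#' @param wavelength laser wavelength of the treatment group, nm.
#' @param injection injection arm, `"GNR"` or `"saline"`.
#' @return An object of class `temperature_trace`.
#' @export
temperature_trace <- function(times, temp_mean, temp_sd = rep(0, length(times)),
                              animal_id = "", wavelength = NA_real_,
                              injection = NA_character_) {
  if (length(times) != length(temp_mean) || length(times) != length(temp_sd))
    stop("times, temp_mean and temp_sd must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(temp_sd < 0)) stop("temp_sd must be non-negative")
  structure(
    list(times = as.numeric(times), temp_mean = as.numeric(temp_mean),
         temp_sd = as.numeric(temp_sd), animal_id = as.character(animal_id),
         wavelength = as.numeric(wavelength), injection = as.character(injection)),
    class = "temperature_trace"
  )
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf(
    "<temperature_trace> %s (%g nm, %s): %d points, t in [%.2f, %.2f] s, T in [%.2f, %.2f] C\n",
    x$animal_id, x$wavelength, x$injection, length(x$times),
    min(x$times), max(x$times), min(x$temp_mean), max(x$temp_mean)))
  invisible(x)
}

#' @export
as.data.frame.temperature_trace <- function(x, ...) {
  data.frame(
    time_s = x$times, temp_mean_C = x$temp_mean, temp_sd_C = x$temp_sd,
    animal_id = x$animal_id,
    group = paste0(x$wavelength, "_", x$injection)
  )
}

#' Write a thermograph stack as a radiometric multi-page TIFF
#'
#' Stores one 16-bit greyscale page per frame, with the linear temperature
#' calibration (`temp_C = counts * scale + offset`), frame period and
#' laser-on index recorded in a JSON sidecar (`<path>.json`). With the
#' default `scale` of 0.01 degrees C per count the round trip is lossless for
#' stacks quantized at 0.01 degrees C (the simulator default).
#'
#' @param stack a [thermal_stack()].
#' @param path output TIFF path.
#' @param scale degrees C per count (default 0.01).
#' @param offset temperature at count 0, degrees C; default just below the
#'   stack minimum.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, scale = 0.01, offset = NULL) {
  stopifnot(inherits(stack, "thermal_stack"), scale > 0)
  rng <- range(stack$frames)
  if (is.null(offset)) offset <- floor(rng[1])
  counts_max <- (rng[2] - offset) / scale
  if (rng[1] < offset || counts_max > 65535)
    stop("temperature range does not fit the 16-bit count range; adjust scale/offset")
  pages <- lapply(seq_len(dim(stack$frames)[1]), function(k) {
    round((stack$frames[k, , ] - offset) / scale) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(scale = scale, offset = offset,
               frame_period_s = stack$frame_period_s,
               laser_on_index = stack$laser_on_index,
               source_id = stack$source_id, units = "C")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a thermograph stack from a multi-page TIFF
#'
#' Accepts either 32-bit float pages already calibrated in degrees C, or
#' 16-bit integer count pages with a linear calibration
#' (`temp_C = counts * scale + offset`) supplied in the JSON metadata
#' sidecar. Integer pages without a resolvable calibration are an error; the
#' reader never guesses units.
#'
#' @param path TIFF path.
#' @param metadata_path JSON sidecar path; default `<path>.json` if present.
#' @return A [thermal_stack()].
#' @export
read_stack <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(metadata_path)) {
    cand <- paste0(path, ".json")
    if (file.exists(cand)) metadata_path <- cand
  }
  meta <- if (!is.null(metadata_path)) jsonlite::read_json(metadata_path) else list()

  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE)  # float pages
  )
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged TIFF: pages differ in size")

  integer_counts <- is.integer(pages[[1]])
  if (integer_counts) {
    missing <- setdiff(c("scale", "offset"), names(meta))
    if (length(missing) > 0)
      stop("integer count pages need calibration metadata; missing key(s): ",
           paste(missing, collapse = ", "))
  }
  frames <- array(NA_real_, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    frames[k, , ] <- if (integer_counts)
      as.numeric(p) * meta$scale + meta$offset else as.numeric(p)
  }
  thermal_stack(
    frames,
    frame_period_s = if (!is.null(meta$frame_period_s)) meta$frame_period_s else 1,
    laser_on_index = if (!is.null(meta$laser_on_index)) meta$laser_on_index else 1L,
    source_id = if (!is.null(meta$source_id)) meta$source_id else basename(path)
  )
}

#' Write temperature traces to CSV
#'
#' One row per (animal, frame) with the canonical header
#' `time_s,temp_mean_C,temp_sd_C,animal_id,group`; group is encoded as
#' `<wavelength>_<injection>`.
#'
#' @param traces a [temperature_trace()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "temperature_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read temperature traces from CSV
#'
#' Expects the header written by [write_traces()]. Rows are grouped by
#' `animal_id` and sorted by time; duplicate or non-monotone times within an
#' animal are an error naming the offender.
#'
#' @param path CSV path.
#' @return Named list of [temperature_trace()] objects, one per animal.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "temp_mean_C", "temp_sd_C", "animal_id", "group")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("trace CSV is missing column(s): ", paste(missing, collapse = ", "))
  out <- list()
  for (id in unique(df$animal_id)) {
    rows <- df[df$animal_id == id, ]
    rows <- rows[order(rows$time_s), ]
    if (anyDuplicated(rows$time_s))
      stop("duplicate time points for animal ", id)
    grp <- strsplit(rows$group[1], "_", fixed = TRUE)[[1]]
    out[[id]] <- temperature_trace(
      times = rows$time_s, temp_mean = rows$temp_mean_C,
      temp_sd = rows$temp_sd_C, animal_id = id,
      wavelength = suppressWarnings(as.numeric(grp[1])),
      injection = if (length(grp) > 1) paste(grp[-1], collapse = "_") else NA_character_
    )
  }
  out
}

#' Write result tables as CSV with a schema-version header
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if needed).
#' @param schema_version integer written as a `#`-comment first line.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, dir, schema_version = 1L) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# pttherm results schema_version=%d", schema_version), con)
    utils::write.csv(tables[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a result table written by [write_results()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
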