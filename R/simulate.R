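# RNG discipline: all simulation entry points take an explicit seed and run
# under a local RNG state, restoring .Random.seed on exit so library code
# never perturbs the caller's stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a per-animal substream seed from a global seed
#'
#' Stable string hash of `(group label, animal index)` folded with the global
#' seed, kept below 2^31 so it is a valid R seed. Adding animals or groups to
#' a design does not perturb the draws of existing ones.
#'
#' @param seed global integer seed.
#' @param group group label, e.g. `"808_GNR"`.
#' @param index 1-based animal index within the group.
#' @return An integer seed in `[0, 2^31)`.
#' @export
animal_seed <- function(seed, group, index) {
  key <- paste0(group, "#", index)
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 7919) %% 2147483647)
}

# Truncated-normal draw of one animal's (t0, tinf, tau): redraw until the
# physical constraints tau > tau_floor and tinf > t0 hold. The printed
# group SDs (up to 12.3 s on tau) make unconstrained draws occasionally
# nonphysical.
draw_animal_params <- function(params, tau_floor = 1, max_attempts = 100L) {
  for (i in seq_len(max_attempts)) {
    t0 <- stats::rnorm(1, params$t0_mean, params$t0_sd)
    tinf <- stats::rnorm(1, params$tinf_mean, params$tinf_sd)
    tau <- stats::rnorm(1, params$tau_mean, params$tau_sd)
    if (tau > tau_floor && tinf > t0) {
      return(list(t0 = t0, tinf = tinf, tau = tau))
    }
  }
  stop(sprintf(
    "could not draw physical parameters (tau > %g s, tinf > t0) in %d attempts",
    tau_floor, max_attempts))
}

#' Simulate a hotspot-ROI temperature trace for one animal
#'
#' Draws per-animal `(t0, tinf, tau)` from the group distributions
#' (truncated at `tau > 1` s and `tinf > t0`), evaluates the first-order
#' heating curve at the camera frame times `t = k / frame_rate`,
#' `k = 0..floor(exposure_s * frame_rate)`, and adds iid Gaussian noise to
#' the ROI-mean channel. The noise SD is
#' `camera$noise_sd / sqrt(effective_roi_pixels)`: with the default
#' `effective_roi_pixels = 1` the ROI mean fluctuates at the full per-pixel
#' noise scale, modeling camera noise that is strongly correlated across the
#' pixels of a small ROI (frame-level drift dominates), which is the regime
#' consistent with sub-degree fit residuals on ROI-averaged traces.
#'
#' @param params one row of [default_group_params()] (or a list with fields
#'   `t0_mean`, `t0_sd`, `tinf_mean`, `tinf_sd`, `tau_mean`, `tau_sd`, and
#'   optionally `wavelength`, `injection`).
#' @param camera a [camera_model()].
#' @param exposure_s laser exposure duration, s (default 90).
#' @param seed integer seed; required for reproducibility.
#' @param effective_roi_pixels effective number of independent pixels in the
#'   ROI average (default 1, fully correlated noise).
#' @param animal_id identifier stored in the trace.
#' @return A [temperature_trace()] with attribute `"truth"` holding the drawn
#'   `(t0, tinf, tau)`.
#' @examples
#' p <- default_group_params()[1, ]
#' tr <- simulate_trace(p, camera_model(noise_sd = 0), seed = 1)
#' head(as.data.frame(tr))
#' @export
simulate_trace <- function(params, camera = camera_model(), exposure_s = 90,
                           seed = NULL, effective_roi_pixels = 1,
                           animal_id = "sim") {
  stopifnot(exposure_s > 0, effective_roi_pixels >= 1)
  if (is.null(seed)) stop("simulate_trace() requires an explicit seed")
  with_local_seed(seed, {
    truth <- draw_animal_params(params)
    times <- seq(0, floor(exposure_s * camera$frame_rate)) / camera$frame_rate
    temp <- first_order_temperature(times, truth$t0, truth$tinf, truth$tau)
    sd_trace <- camera$noise_sd / sqrt(effective_roi_pixels)
    if (sd_trace > 0) temp <- temp + stats::rnorm(length(temp), 0, sd_trace)
    temp <- temp + camera$bias
    tr <- temperature_trace(
      times = times, temp_mean = temp, temp_sd = rep(0, length(temp)),
      animal_id = animal_id,
      wavelength = if (!is.null(params$wavelength)) params$wavelength else NA_real_,
      injection = if (!is.null(params$injection)) params$injection else NA_character_
    )
    attr(tr, "truth") <- truth
    tr
  })
}

#' Render a synthetic thermograph stack for one animal
#'
#' Renders frames of a scene in which every pixel outside the body footprint
#' sits at ambient temperature, pixels inside the body sit at baseline skin
#' temperature, and an isotropic Gaussian hotspot heats up following the
#' first-order curve once the laser switches on:
#' `frame(r, c, t) = body + (T(t) - T0) * exp(-d^2 / (2 sigma^2)) + noise`,
#' quantized at the camera readout step. Frames recorded before laser-on
#' (`scene$pre_exposure_s`) carry no heating term. The hottest pixel (the
#' beam center) therefore follows the heating curve exactly up to noise and
#' quantization.
#'
#' @inheritParams simulate_trace
#' @param scene a [scene_spec()].
#' @return A [thermal_stack()] with attribute `"truth"` holding the drawn
#'   `(t0, tinf, tau)`.
#' @export
simulate_stack <- function(params, camera = camera_model(),
                           scene = scene_spec(camera), seed = NULL,
                           animal_id = "sim") {
  if (is.null(seed)) stop("simulate_stack() requires an explicit seed")
  bm <- scene$body_mask
  if (bm$rows[1] < 1 || bm$rows[2] > camera$height ||
      bm$cols[1] < 1 || bm$cols[2] > camera$width) {
    stop("body footprint exceeds the camera frame")
  }
  with_local_seed(seed, {
    truth <- draw_animal_params(params)
    body_temp <- if (is.null(scene$body_temp)) truth$t0 else scene$body_temp
    n_pre <- floor(scene$pre_exposure_s * camera$frame_rate)
    n_total <- floor((scene$pre_exposure_s + scene$exposure_s) * camera$frame_rate)
    h <- camera$height; w <- camera$width

    base <- matrix(scene$ambient_temp, h, w)
    in_body <- matrix(FALSE, h, w)
    in_body[bm$rows[1]:bm$rows[2], bm$cols[1]:bm$cols[2]] <- TRUE
    base[in_body] <- body_temp

    d2 <- outer((seq_len(h) - scene$hotspot_center[1])^2,
                (seq_len(w) - scene$hotspot_center[2])^2, "+")
    kernel <- exp(-d2 / (2 * scene$hotspot_sigma^2))
    kernel[!in_body] <- 0

    frames <- array(NA_real_, dim = c(n_total, h, w))
    times <- (seq_len(n_total) - 1 - n_pre) / camera$frame_rate
    for (k in seq_len(n_total)) {
      t <- times[k]
      heat <- if (t >= 0)
        (first_order_temperature(t, truth$t0, truth$tinf, truth$tau) - truth$t0)
      else 0
      f <- base + heat * kernel + camera$bias
      if (camera$noise_sd > 0) f <- f + matrix(stats::rnorm(h * w, 0, camera$noise_sd), h, w)
      if (camera$quantization_step > 0)
        f <- round(f / camera$quantization_step) * camera$quantization_step
      frames[k, , ] <- f
    }
    st <- thermal_stack(frames, frame_period_s = 1 / camera$frame_rate,
                        laser_on_index = n_pre + 1L, source_id = animal_id)
    attr(st, "truth") <- truth
    st
  })
}

#' Simulate a full cohort of temperature traces
#'
#' Simulates every animal of a multi-group design (by default the eight-group
#' wavelength-by-injection layout of [default_group_params()]), deriving each
#' animal's RNG substream from the global seed with [animal_seed()].
#'
#' @param params data frame of group parameter rows (see
#'   [default_group_params()]).
#' @inheritParams simulate_trace
#' @return A list with `traces` (list of [temperature_trace()]) and
#'   `manifest` (data frame of ground-truth `t0`, `tinf`, `tau`, and the
#'   substream seed per animal, for parameter-recovery diagnostics).
#' @export
simulate_cohort <- function(params = default_group_params(),
                            camera = camera_model(), exposure_s = 90,
                            seed = 1, effective_roi_pixels = 1) {
  traces <- list()
  rows <- list()
  for (g in seq_len(nrow(params))) {
    p <- params[g, ]
    glab <- paste0(p$wavelength, "_", p$injection)
    for (i in seq_len(p$n_animals)) {
      s <- animal_seed(seed, glab, i)
      id <- sprintf("%s_a%d", glab, i)
      tr <- simulate_trace(p, camera, exposure_s, seed = s,
                           effective_roi_pixels = effective_roi_pixels,
                           animal_id = id)
      truth <- attr(tr, "truth")
      traces[[id]] <- tr
      rows[[id]] <- data.frame(
        animal_id = id, wavelength = p$wavelength, injection = p$injection,
        t0_true = truth$t0, tinf_true = truth$tinf, tau_true = truth$tau,
        seed = s
      )
    }
  }
  list(traces = traces, manifest = do.call(rbind, c(rows, make.row.names = FALSE)))
}
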