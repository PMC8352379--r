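#' First-order step-response temperature model
#'
#' Temperature of a laser-heated tumor surface under the step response of a
#' first-order thermal system:
#' \deqn{T(t) = (T_0 - T_\infty)\, e^{-t/\tau} + T_\infty}
#' where \eqn{T_0} is the initial temperature, \eqn{T_\infty} the steady-state
#' temperature and \eqn{\tau} the thermal time constant (the time needed to
#' reach \eqn{1 - e^{-1} \approx 63.2\%} of the total temperature span).
#'
#' @param t times in seconds (laser-on at `t = 0`); vectorized.
#' @param t0 initial temperature, degrees C.
#' @param tinf steady-state temperature, degrees C.
#' @param tau thermal time constant, seconds; must be positive.
#' @return Temperatures in degrees C, same length as `t`.
#' @examples
#' first_order_temperature(40, t0 = 30, tinf = 70, tau = 40)  # 70 - 40/e
#' @export
first_order_temperature <- function(t, t0, tinf, tau) {
  stopifnot(is.numeric(t), length(tau) == 1L, tau > 0)
  (t0 - tinf) * exp(-t / tau) + tinf
}

#' Steady-state temperature implied by an observed end-of-exposure maximum
#'
#' Inverts the first-order model at the end of the exposure: given the
#' temperature `tmax` reached after `exposure_s` seconds of heating from `t0`
#' with time constant `tau`, returns the asymptote `tinf` such that
#' `first_order_temperature(exposure_s, t0, tinf, tau) == tmax`.
#' Used to seed simulation parameters from reported group-mean maximum
#' temperatures, which are measured at the end of a finite exposure rather
#' than at steady state.
#'
#' @param tmax temperature at the end of the exposure, degrees C.
#' @param t0 initial temperature, degrees C.
#' @param tau thermal time constant, s.
#' @param exposure_s exposure duration, s (default 90).
#' @return Steady-state temperature, degrees C.
#' @export
tinf_from_tmax <- function(tmax, t0, tau, exposure_s = 90) {
  stopifnot(all(tau > 0), exposure_s > 0)
  a <- exp(-exposure_s / tau)
  (tmax - t0 * a) / (1 - a)
}

#' Default simulation parameters for the eight-group study design
#'
#' Returns per-group distributions for the simulated cohort: four
#' near-infrared laser wavelengths (808, 940, 975, 1064 nm) crossed with two
#' intratumoral injection arms (gold nanorods `"GNR"` vs saline `"saline"`),
#' four animals per group. Group means and SDs of the initial temperature
#' `t0`, the thermal time constant `tau` and the end-of-exposure maximum
#' temperature `tmax` encode the reported outcomes of an in-vivo photothermal
#' ablation study of subcutaneous 4T1 breast tumors; the steady-state
#' temperature `tinf` is derived from (`tmax`, `t0`, `tau`) by
#' [tinf_from_tmax()] at a 90 s exposure. The `provenance` column marks each
#' row's time-constant value as `"reported"` (printed group mean) or
#' `"derived"` (implied by a printed reduction relative to the control arm).
#'
#' Initial-temperature SDs (1 degree C) and the `tau`/`tmax` SDs of arms for
#' which no spread was printed are modeling choices, documented in the
#' package vignette.
#'
#' @param exposure_s exposure used to convert `tmax` to `tinf`, s (default 90).
#' @return A data frame with one row per group and columns `wavelength`,
#'   `injection`, `n_animals`, `t0_mean`, `t0_sd`, `tinf_mean`, `tinf_sd`,
#'   `tau_mean`, `tau_sd`, `tmax_mean`, `tmax_sd`, `dt_mean`, `provenance`.
#' @examples
#' p <- default_group_params()
#' subset(p, injection == "saline", c(wavelength, tau_mean, tau_sd))
#' @export
default_group_params <- function(exposure_s = 90) {
  wl <- c(808, 940, 975, 1064)
  gnr <- data.frame(
    wavelength = wl,
    injection  = "GNR",
    tmax_mean  = c(68, 69, 84, 69),
    tmax_sd    = c(2, 3, 9, 3),
    dt_mean    = c(39, 40, 55, 40),
    # GNR tau at 940 nm is a reported group mean; 808/1064 nm follow from a
    # ~33 s reduction vs the matched controls, 975 nm from a ~7 s reduction.
    tau_mean   = c(67.8 - 33, 35.4, 38.3 - 7, 66.9 - 33),
    tau_sd     = c(1.8, 9.8, 5.1, 4.8),
    provenance = c("derived", "reported", "derived", "derived")
  )
  sal <- data.frame(
    wavelength = wl,
    injection  = "saline",
    tmax_mean  = c(52, 64, 79, 56),
    tmax_sd    = c(1, 3, 3, 1),
    dt_mean    = c(22, 33, 50, 26),
    tau_mean   = c(67.8, 57.7, 38.3, 66.9),
    tau_sd     = c(1.8, 12.3, 5.1, 4.8),
    provenance = "reported"
  )
  p <- rbind(gnr, sal)
  p$n_animals <- 4L
  p$t0_mean <- p$tmax_mean - p$dt_mean
  p$t0_sd <- 1
  p$tinf_mean <- tinf_from_tmax(p$tmax_mean, p$t0_mean, p$tau_mean, exposure_s)
  p$tinf_sd <- p$tmax_sd
  stopifnot(all(p$tinf_mean > p$t0_mean), all(p$tau_mean > 0))
  p[c("wavelength", "injection", "n_animals", "t0_mean", "t0_sd",
      "tinf_mean", "tinf_sd", "tau_mean", "tau_sd",
      "tmax_mean", "tmax_sd", "dt_mean", "provenance")]
}

#' Reported group temperature changes and heating efficiencies
#'
#' The published per-wavelength mean temperature changes (`dt_gnr`,
#' `dt_saline`, degrees C) for nanorod-injected tumors and saline controls,
#' together with the heating efficiency printed alongside them
#' (`he_printed`). These serve as reference inputs for recomputing the
#' heating efficiency; see [check_printed_he()] for consistency flags.
#'
#' @return Data frame with columns `wavelength`, `dt_gnr`, `dt_saline`,
#'   `he_printed`.
#' @export
printed_heating_table <- function() {
  data.frame(
    wavelength = c(808, 940, 975, 1064),
    dt_gnr     = c(39, 40, 55, 40),
    dt_saline  = c(22, 33, 50, 26),
    he_printed = c(1.8, 1.2, 1.2, 1.6)
  )
}

#' Camera acquisition model for simulated thermography
#'
#' Describes the infrared camera used to render synthetic thermograph
#' stacks: frame rate, frame geometry, per-pixel noise, systematic bias and
#' quantization of the temperature readout. Defaults emulate a research-grade
#' long-wave IR camera (640 x 480 native, here down-scaled for desk-size
#' simulations) acquiring at 6 frames/s with about +/-2 degrees C absolute
#' accuracy and sub-degree temporal noise.
#'
#' @param frame_rate frames per second (default 6).
#' @param width,height frame size in pixels (default 160 x 120; use
#'   640 x 480 for full-scale frames).
#' @param noise_sd SD of Gaussian temperature noise per pixel, degrees C
#'   (default 0.7).
#' @param bias systematic temperature offset, degrees C (default 0; the
#'   absolute-accuracy band of the emulated camera is +/-2 degrees C).
#' @param quantization_step readout quantization, degrees C (default 0.01).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(frame_rate = 6, width = 160L, height = 120L,
                         noise_sd = 0.7, bias = 0, quantization_step = 0.01) {
  stopifnot(frame_rate > 0, width >= 1, height >= 1,
            noise_sd >= 0, quantization_step >= 0)
  structure(
    list(frame_rate = frame_rate, width = as.integer(width),
         height = as.integer(height), noise_sd = noise_sd, bias = bias,
         quantization_step = quantization_step),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %dx%d px, %.3g fps, noise %.2f C, bias %+.2f C, q %.3g C\n",
              x$width, x$height, x$frame_rate, x$noise_sd, x$bias,
              x$quantization_step))
  invisible(x)
}

#' Scene geometry for simulated thermograph stacks
#'
#' Spatial layout rendered by [simulate_stack()]: an ambient background, a
#' rectangular body (mouse flank) footprint at baseline skin temperature, and
#' an isotropic Gaussian heating hotspot inside it whose peak follows the
#' first-order heating curve. The hotspot spatial scale is set so a laser
#' beam of roughly 0.8 cm diameter spans a plausible pixel extent at the
#' default frame size.
#'
#' @param camera a [camera_model()]; supplies frame dimensions for defaults.
#' @param ambient_temp background temperature outside the body, degrees C.
#' @param body_temp baseline skin temperature inside the body footprint,
#'   degrees C, or `NULL` to use each simulated animal's drawn initial
#'   temperature (keeps the hotspot-peak trace exactly on the heating curve).
#' @param body_mask list with integer ranges `rows` and `cols` delimiting the
#'   rectangular body footprint; default central 80% of the frame.
#' @param hotspot_center `(row, col)` of the beam center; default the center
#'   of the body footprint.
#' @param hotspot_sigma Gaussian SD of the heating profile, pixels.
#' @param exposure_s laser exposure duration, s (default 90).
#' @param pre_exposure_s baseline recording before laser-on, s (default 5).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(camera = camera_model(), ambient_temp = 24,
                       body_temp = NULL, body_mask = NULL,
                       hotspot_center = NULL, hotspot_sigma = 8,
                       exposure_s = 90, pre_exposure_s = 5) {
  stopifnot(exposure_s > 0, pre_exposure_s >= 0, hotspot_sigma > 0)
  if (is.null(body_mask)) {
    body_mask <- list(
      rows = c(ceiling(camera$height * 0.1), floor(camera$height * 0.9)),
      cols = c(ceiling(camera$width * 0.1), floor(camera$width * 0.9))
    )
  }
  if (is.null(hotspot_center)) {
    hotspot_center <- c(round(mean(body_mask$rows)), round(mean(body_mask$cols)))
  }
  if (hotspot_center[1] < body_mask$rows[1] || hotspot_center[1] > body_mask$rows[2] ||
      hotspot_center[2] < body_mask$cols[1] || hotspot_center[2] > body_mask$cols[2]) {
    stop("hotspot_center must lie inside the body footprint")
  }
  structure(
    list(ambient_temp = ambient_temp, body_temp = body_temp,
         body_mask = body_mask, hotspot_center = as.integer(hotspot_center),
         hotspot_sigma = hotspot_sigma, exposure_s = exposure_s,
         pre_exposure_s = pre_exposure_s),
    class = "scene_spec"
  )
}
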