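#' Per-animal thermal summary of an exposure
#'
#' Reduces one ROI trace to the quantities tabulated per animal: the maximum
#' ROI-mean temperature over the exposure window (`tmax`), the temperature at
#' laser-on (`t_initial`, nearest sample to t = 0), and their difference
#' (`delta_t`). For monotone first-order heating `tmax` coincides with the
#' end-of-exposure temperature; taking the maximum is robust to end-of-trace
#' dips.
#'
#' @param trace a [temperature_trace()].
#' @param exposure_s end of the window, s; default the last observed time.
#' @return A list with `tmax`, `t_initial`, `delta_t` (degrees C).
#' @export
animal_thermal_summary <- function(trace, exposure_s = NULL) {
  stopifnot(inherits(trace, "temperature_trace"))
  if (is.null(exposure_s)) exposure_s <- max(trace$times)
  keep <- trace$times >= 0 & trace$times <= exposure_s
  if (!any(keep)) stop("trace has no points in the exposure window")
  t <- trace$times[keep]
  y <- trace$temp_mean[keep]
  t_initial <- y[which.min(abs(t))]
  tmax <- max(y)
  list(tmax = tmax, t_initial = t_initial, delta_t = tmax - t_initial)
}

#' Effective temperature enhancement
#'
#' Percent excess of the nanorod-group mean maximum temperature over the
#' saline-control mean maximum temperature at the same wavelength:
#' \deqn{\tilde T_{enh} = \frac{T_i - T_{PBS,i}}{T_{PBS,i}} \cdot 100}
#' The formula is anchored at the control temperature on the Celsius scale
#' (it is not invariant under a common temperature offset); it is applied
#' exactly as conventionally defined.
#'
#' @param t_gnr nanorod-group mean maximum temperature, degrees C.
#' @param t_pbs saline-control mean maximum temperature, degrees C (> 0).
#' @return Enhancement in percent.
#' @examples
#' effective_temperature_enhancement(68, 52)  # ~30.8%
#' @export
effective_temperature_enhancement <- function(t_gnr, t_pbs) {
  if (any(t_pbs <= 0))
    stop("control temperature must be positive: the enhancement is anchored at the saline-group temperature")
  (t_gnr - t_pbs) / t_pbs * 100
}

#' Heating efficiency
#'
#' Ratio of the mean maximum temperature change of nanorod-injected tumors
#' to that of irradiated saline controls at the same wavelength. Being a
#' ratio of temperature changes it is invariant under a common temperature
#' offset.
#'
#' @param dt_gnr nanorod-group mean temperature change, degrees C.
#' @param dt_saline saline-group mean temperature change, degrees C (> 0).
#' @return Dimensionless efficiency.
#' @examples
#' heating_efficiency(39, 22)  # ~1.77, rounds to 1.8
#' @export
heating_efficiency <- function(dt_gnr, dt_saline) {
  if (any(dt_saline <= 0)) stop("control temperature change must be positive")
  dt_gnr / dt_saline
}

#' Recompute heating efficiencies from the reported temperature changes
#'
#' Recomputes `HE = dt_gnr / dt_saline` from [printed_heating_table()] and
#' flags rows where the value rounded to one decimal disagrees with the
#' efficiency printed next to those temperature changes (such disagreement
#' arises when a table was computed from unrounded group values).
#'
#' @param table data frame as returned by [printed_heating_table()].
#' @return The table with added columns `he_recomputed` (full precision),
#'   `he_rounded`, and `rounding_inconsistent`.
#' @export
check_printed_he <- function(table = printed_heating_table()) {
  table$he_recomputed <- heating_efficiency(table$dt_gnr, table$dt_saline)
  table$he_rounded <- round(table$he_recomputed, 1)
  table$rounding_inconsistent <- table$he_rounded != table$he_printed
  table
}

#' Group-level summaries and enhancement metrics
#'
#' Aggregates per-animal results into per-group (wavelength x injection)
#' means and SDs of `tmax`, `delta_t` and `tau`, and derives per-wavelength
#' enhancement metrics (effective temperature enhancement and heating
#' efficiency) from the group means. Wavelengths missing one injection arm
#' yield group summaries but no enhancement entry (a warning is recorded);
#' single-animal groups get SD 0 with a warning.
#'
#' @param per_animal data frame with one row per animal and columns
#'   `animal_id`, `wavelength`, `injection` (`"GNR"` / `"saline"`), `tmax`,
#'   `delta_t`, and optionally `tau`.
#' @return A list with data frames `groups` (columns `wavelength`,
#'   `injection`, `n`, `tmax_mean`, `tmax_sd`, `delta_t_mean`, `delta_t_sd`,
#'   `tau_mean`, `tau_sd`) and `enhancement` (columns `wavelength`, `t_gnr`,
#'   `t_pbs`, `dt_gnr`, `dt_saline`, `t_enh`, `he`), plus a character vector
#'   `warnings`.
#' @export
summarize_groups <- function(per_animal) {
  required <- c("wavelength", "injection", "tmax", "delta_t")
  missing <- setdiff(required, names(per_animal))
  if (length(missing) > 0)
    stop("per_animal is missing column(s): ", paste(missing, collapse = ", "))
  if (!"tau" %in% names(per_animal)) per_animal$tau <- NA_real_
  warnings <- character(0)

  sd0 <- function(x) if (length(x) <= 1) 0 else stats::sd(x)
  key <- interaction(per_animal$wavelength, per_animal$injection, drop = TRUE)
  groups <- do.call(rbind, lapply(split(per_animal, key), function(g) {
    data.frame(
      wavelength = g$wavelength[1], injection = g$injection[1],
      n = nrow(g),
      tmax_mean = mean(g$tmax), tmax_sd = sd0(g$tmax),
      delta_t_mean = mean(g$delta_t), delta_t_sd = sd0(g$delta_t),
      tau_mean = mean(g$tau, na.rm = TRUE), tau_sd = sd0(g$tau[!is.na(g$tau)])
    )
  }))
  rownames(groups) <- NULL
  groups <- groups[order(groups$wavelength, groups$injection), ]
  if (any(groups$n == 1))
    warnings <- c(warnings, sprintf(
      "single-animal group(s): %s",
      paste(with(groups[groups$n == 1, ], paste0(wavelength, "_", injection)),
            collapse = ", ")))

  enh <- list()
  for (wl in unique(groups$wavelength)) {
    g_gnr <- groups[groups$wavelength == wl & groups$injection == "GNR", ]
    g_sal <- groups[groups$wavelength == wl & groups$injection == "saline", ]
    if (nrow(g_gnr) == 1 && nrow(g_sal) == 1) {
      enh[[as.character(wl)]] <- data.frame(
        wavelength = wl,
        t_gnr = g_gnr$tmax_mean, t_pbs = g_sal$tmax_mean,
        dt_gnr = g_gnr$delta_t_mean, dt_saline = g_sal$delta_t_mean,
        t_enh = effective_temperature_enhancement(g_gnr$tmax_mean, g_sal$tmax_mean),
        he = heating_efficiency(g_gnr$delta_t_mean, g_sal$delta_t_mean)
      )
    } else {
      warnings <- c(warnings, sprintf(
        "wavelength %s nm lacks one injection arm; no enhancement metrics", wl))
    }
  }
  enhancement <- if (length(enh) > 0) do.call(rbind, c(enh, make.row.names = FALSE))
  else data.frame(wavelength = numeric(0), t_gnr = numeric(0),
                  t_pbs = numeric(0), dt_gnr = numeric(0),
                  dt_saline = numeric(0), t_enh = numeric(0), he = numeric(0))
  for (msg in warnings) warning(msg, call. = FALSE)
  list(groups = groups, enhancement = enhancement, warnings = warnings)
}
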