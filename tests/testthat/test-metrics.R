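test_that("effective temperature enhancement follows its defining formula", {
  expect_equal(effective_temperature_enhancement(68, 52), 16 / 52 * 100)
  expect_equal(round(effective_temperature_enhancement(68, 52), 2), 30.77)
  expect_equal(round(effective_temperature_enhancement(69, 64), 2), 7.81)
  expect_equal(effective_temperature_enhancement(55, 55), 0)
  expect_error(effective_temperature_enhancement(68, 0), "positive")
  # strictly increasing in the nanorod temperature, anchored at the control
  expect_true(effective_temperature_enhancement(69, 52) >
                effective_temperature_enhancement(68, 52))
  # not invariant under a common offset (absolute-Celsius anchored)
  expect_false(isTRUE(all.equal(effective_temperature_enhancement(78, 62),
                                effective_temperature_enhancement(68, 52))))
})

test_that("heating efficiency is a ratio of temperature changes", {
  expect_equal(round(heating_efficiency(39, 22), 1), 1.8)
  expect_equal(round(heating_efficiency(40, 33), 1), 1.2)
  expect_equal(heating_efficiency(26, 26), 1)
  expect_error(heating_efficiency(39, 0), "positive")
  expect_true(heating_efficiency(40, 22) > heating_efficiency(39, 22))
  # invariant under a common temperature offset (differences cancel)
  expect_equal(heating_efficiency((68 + 5) - (29 + 5), (52 + 5) - (30 + 5)),
               heating_efficiency(68 - 29, 52 - 30))
})

test_that("recomputed efficiencies flag the inconsistent reference rows", {
  chk <- check_printed_he()
  expect_equal(chk$rounding_inconsistent,
               c(FALSE, FALSE, TRUE, TRUE))  # 808, 940 ok; 975, 1064 flagged
  expect_equal(chk$he_rounded, c(1.8, 1.2, 1.1, 1.5))
})

test_that("per-animal thermal summaries use max-over-window semantics", {
  tr <- temperature_trace(seq(0, 90, by = 10),
                          c(29, 45, 55, 61, 64, 66, 67, 67.5, 67.8, 68))
  s <- animal_thermal_summary(tr)
  expect_equal(s$tmax, 68)
  expect_equal(s$t_initial, 29)
  expect_equal(s$delta_t, 39)

  flat <- temperature_trace(0:9, rep(40, 10))
  expect_equal(animal_thermal_summary(flat)$delta_t, 0)

  # a peak before the end wins over the final value
  peaky <- temperature_trace(0:4, c(30, 50, 70, 60, 55))
  expect_equal(animal_thermal_summary(peaky)$tmax, 70)

  # delta_t can never exceed the full excursion of the trace
  expect_lte(s$delta_t, s$tmax - min(tr$temp_mean))
})

test_that("group summaries aggregate and degrade gracefully", {
  per_animal <- data.frame(
    animal_id = sprintf("a%d", 1:10),
    wavelength = c(rep(808, 8), 940, 940),
    injection = c(rep("GNR", 4), rep("saline", 4), "GNR", "saline"),
    tmax = c(66, 68, 68, 70, 51, 52, 52, 53, 69, 64),
    delta_t = c(37, 39, 39, 41, 21, 22, 22, 23, 40, 33),
    tau = c(33, 34, 36, 37, 66, 67, 69, 70, 35, 58)
  )
  res <- suppressWarnings(summarize_groups(per_animal))
  g <- res$groups
  expect_equal(g$tmax_mean[g$wavelength == 808 & g$injection == "GNR"], 68)
  expect_equal(g$n[g$wavelength == 940 & g$injection == "GNR"], 1)
  expect_equal(g$tmax_sd[g$wavelength == 940 & g$injection == "GNR"], 0)
  expect_true(any(grepl("single-animal", res$warnings)))

  e <- res$enhancement
  expect_equal(nrow(e), 2)
  expect_equal(e$he[e$wavelength == 808], 39 / 22 * (4 / 4), tolerance = 1e-12)
  expect_equal(e$t_enh[e$wavelength == 808],
               effective_temperature_enhancement(68, 52))

  # a wavelength missing one arm yields a summary but no enhancement row
  partial <- per_animal[per_animal$injection == "GNR" | per_animal$wavelength == 808, ]
  res2 <- suppressWarnings(summarize_groups(partial))
  expect_false(940 %in% res2$enhancement$wavelength)
  expect_true(any(grepl("940", res2$warnings)))
})
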