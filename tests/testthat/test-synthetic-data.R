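test_that("default group parameters encode the eight-group design", {
  p <- default_group_params()
  expect_equal(nrow(p), 8L)
  expect_setequal(p$wavelength, c(808, 940, 975, 1064))
  expect_setequal(p$injection, c("GNR", "saline"))
  expect_true(all(p$n_animals == 4L))
  expect_true(all(p$tinf_mean > p$t0_mean))
  expect_true(all(p$tau_mean > 0))
  expect_true(all(p$tau_sd >= 0))

  sal808 <- p[p$wavelength == 808 & p$injection == "saline", ]
  expect_equal(sal808$tau_mean, 67.8)
  expect_equal(sal808$tau_sd, 1.8)
  gnr940 <- p[p$wavelength == 940 & p$injection == "GNR", ]
  expect_equal(gnr940$tau_mean, 35.4)
  expect_equal(gnr940$tau_sd, 9.8)
  # derived nanorod time constants: ~33 s below the matched control at
  # 808/1064 nm, ~7 s below at 975 nm
  expect_equal(p$tau_mean[p$wavelength == 808 & p$injection == "GNR"], 67.8 - 33)
  expect_equal(p$tau_mean[p$wavelength == 1064 & p$injection == "GNR"], 66.9 - 33)
  expect_equal(p$tau_mean[p$wavelength == 975 & p$injection == "GNR"], 38.3 - 7)
  expect_equal(p$provenance[p$wavelength == 940 & p$injection == "GNR"], "reported")
})

test_that("tinf_from_tmax inverts the forward model at the end of exposure", {
  for (tau in c(20, 35, 68)) {
    tinf <- tinf_from_tmax(68, 29, tau, exposure_s = 90)
    expect_gt(tinf, 68)
    expect_equal(first_order_temperature(90, 29, tinf, tau), 68, tolerance = 1e-12)
  }
})

test_that("noiseless simulated traces follow the closed-form heating curve", {
  # direct closed-form values of the forward model
  expect_equal(first_order_temperature(40, 30, 70, 40), 70 - 40 * exp(-1),
               tolerance = 1e-12)
  expect_equal(first_order_temperature(0, 30, 70, 40), 30)

  cam <- camera_model(noise_sd = 0)
  tr <- simulate_trace(fixed_params(30, 70, 40), cam, exposure_s = 90, seed = 11)
  truth <- attr(tr, "truth")
  expect_equal(truth$t0, 30)
  expect_equal(tr$temp_mean[1], 30)
  k <- which(tr$times == 40)
  expect_equal(tr$temp_mean[k], 70 - 40 * exp(-1), tolerance = 1e-12)
  expect_equal(length(tr$times), floor(90 * 6) + 1)

  # strictly increasing and bounded above by the asymptote
  expect_true(all(diff(tr$temp_mean) > 0))
  expect_true(all(tr$temp_mean < 70))
})

test_that("trace simulation is deterministic given a seed", {
  p <- default_group_params()[2, ]
  a <- simulate_trace(p, camera_model(), seed = 42)
  b <- simulate_trace(p, camera_model(), seed = 42)
  expect_identical(a, b)
  c <- simulate_trace(p, camera_model(), seed = 43)
  expect_false(identical(a$temp_mean, c$temp_mean))
})

test_that("sampled time constants match the group distribution in ensemble", {
  p <- default_group_params()
  p <- p[p$wavelength == 940 & p$injection == "saline", ]  # widest printed SD
  cam <- camera_model(noise_sd = 0)
  taus <- vapply(seq_len(200), function(i) {
    tr <- simulate_trace(p, cam, exposure_s = 2, seed = animal_seed(5, "ens", i))
    attr(tr, "truth")$tau
  }, 0)
  se_mean <- p$tau_sd / sqrt(200)
  se_sd <- p$tau_sd / sqrt(2 * 200)
  expect_lt(abs(mean(taus) - p$tau_mean), 3 * se_mean)
  expect_lt(abs(sd(taus) - p$tau_sd), 3 * se_sd)
})

test_that("nonphysical group parameters exhaust the resampling cap", {
  # an impossible constraint set: tinf below t0 with zero spread
  p <- fixed_params(50, 40, 30)
  expect_error(simulate_trace(p, camera_model(), seed = 1),
               "could not draw physical parameters")
})

test_that("rendered stacks have the expected geometry and null behavior", {
  cam <- camera_model(noise_sd = 0, width = 160L, height = 120L)
  sc <- scene_spec(cam, exposure_s = 90, pre_exposure_s = 5)
  # negligible heating amplitude: every in-mask pixel stays at body temp
  st0 <- simulate_stack(fixed_params(31, 31 + 1e-9, 40), cam, sc, seed = 2)
  expect_equal(dim(st0$frames), c(570, 120, 160))  # floor(95 s * 6 fps) frames
  bm <- sc$body_mask
  inside <- st0$frames[, bm$rows[1]:bm$rows[2], bm$cols[1]:bm$cols[2]]
  expect_true(all(inside == 31))
  outside <- st0$frames[, 1:(bm$rows[1] - 1), ]
  expect_true(all(outside == sc$ambient_temp))

  # hotspot-center pixel follows the closed-form curve up to quantization
  st <- simulate_stack(fixed_params(31, 70, 40), cam, sc, seed = 2)
  ctr <- sc$hotspot_center
  px <- st$frames[, ctr[1], ctr[2]]
  times <- stack_times(st)
  expected <- ifelse(times >= 0, first_order_temperature(times, 31, 70, 40), 31)
  expect_lt(max(abs(px - expected)), cam$quantization_step / 2 + 1e-9)

  # spatial maximum sits at the hotspot center in the noiseless case
  last <- st$frames[570, , ]
  expect_equal(as.integer(which(last == max(last), arr.ind = TRUE)[1, ]),
               as.integer(ctr))
})

test_that("a hotspot outside the body footprint is rejected", {
  cam <- camera_model()
  expect_error(scene_spec(cam, hotspot_center = c(1, 1)),
               "inside the body footprint")
})
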