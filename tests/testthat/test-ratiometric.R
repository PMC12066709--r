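# Ratiometric imaging: frame averaging, ratio, calibration, rate maps.

test_that("frame averaging is the per-pixel mean and reduces noise", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(average_frames(rep(list(img), 10)), img)
  expect_identical(average_frames(list(matrix(0, 2, 2), matrix(2, 2, 2))),
                   matrix(1, 2, 2))
  expect_error(average_frames(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "shape")
  set.seed(8)
  stack <- replicate(10, matrix(rnorm(32 * 32), 32), simplify = FALSE)
  ratio <- var(as.vector(average_frames(stack))) /
    mean(vapply(stack, function(m) var(as.vector(m)), 0))
  expect_gt(ratio, 1 / 14)
  expect_lt(ratio, 1 / 7)
})

test_that("ratio computation guards against reference-channel dropouts", {
  g <- matrix(2, 3, 3)
  expect_equal(compute_ratio(g, g), matrix(1, 3, 3))
  expect_equal(compute_ratio(2 * g, g), matrix(2, 3, 3))
  g0 <- g; g0[2, 2] <- 0
  r <- compute_ratio(g, g0)
  expect_true(is.na(r[2, 2]))
  expect_equal(sum(is.na(r)), 1L)
})

test_that("Stern-Volmer calibration recovers known parameters", {
  cal <- reference_calibration(R0 = 2, Ksv = 0.02)
  expect_equal(cal$R0, 2, tolerance = 0.01)
  expect_equal(cal$K_sv, 0.02, tolerance = 0.01)
  # zero-O2 point maps to R0 exactly in the fitted prediction
  expect_equal(o2_to_ratio(cal, 0), cal$R0)
  # inverse consistency over the calibrated range
  o2 <- seq(0, 300, by = 10)
  expect_equal(ratio_to_o2(cal, o2_to_ratio(cal, o2)), o2,
               tolerance = 1e-8)
  # two-site model with f = 1 collapses onto the simple model
  two <- structure(list(model = "two-site", R0 = 2, K_sv = 0.02, f = 1),
                   class = "calibration_curve")
  expect_equal(o2_to_ratio(two, o2), 2 / (1 + 0.02 * o2))
  # a noisy two-site target is recovered by the two-site fit
  o2c <- seq(0, 300, by = 25)
  tab <- data.frame(o2_umol_L = o2c,
                    ratio = 1.8 * (0.9 / (1 + 0.03 * o2c) + 0.1))
  fit2 <- fit_calibration(tab, model = "two-site")
  expect_equal(fit2$R0, 1.8, tolerance = 0.02)
  expect_equal(fit2$f, 0.9, tolerance = 0.02)
  expect_equal(ratio_to_o2(fit2, o2_to_ratio(fit2, o2)), o2,
               tolerance = 1e-6)
  # non-monotone tables are rejected
  bad <- data.frame(o2_umol_L = c(0, 50, 100), ratio = c(2, 1.5, 1.6))
  expect_error(fit_calibration(bad), "monotone")
})

test_that("rate maps are exact on clean stacks and linear in time", {
  cal <- reference_calibration()
  spec <- synthetic_spec(noise_cv = 0, frame_times_h = c(0, 1, 2))
  # identical frames give a zero rate everywhere
  still <- make_ratio_series(matrix(0, 12, 12), cal, spec)
  expect_equal(max(abs(rate_map(still, cal, 0, 2)$rate)), 0,
               tolerance = 1e-10)
  # scaling the interval and the concentration change leaves rates fixed
  stack <- make_ratio_series(matrix(-26, 12, 12), cal, spec)
  r1 <- rate_map(stack, cal, 0, 1)$rate
  r2 <- rate_map(stack, cal, 0, 2)$rate
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_error(rate_map(stack, cal, 1, 1), "t1")
})

test_that("outlier spikes are removed without disturbing their neighbours", {
  cal <- reference_calibration()
  spec <- synthetic_spec(noise_cv = 0, frame_times_h = c(0, 1))
  stack <- make_ratio_series(matrix(-26, 15, 15), cal, spec)
  # inject a +1e4 umol/L/h spike at one pixel of the later frame
  spike_o2 <- matrix(-26, 15, 15); spike_o2[8, 8] <- 1e4 - 26
  stack$frames[[2]]$red <- o2_to_ratio(cal, pmax(100 + spike_o2, 0)) *
    stack$frames[[2]]$green
  rm1 <- rate_map(stack, cal, 0, 1)
  expect_equal(rm1$rate[8, 8], -26, tolerance = 1e-6)
  neigh <- rm1$rate[6:10, 6:10]
  expect_lt(max(abs(neigh + 26)) / 26, 0.05)
})

test_that("patch statistics split phototroph and heterotroph pixels", {
  # constructed field whose whole-map quartiles are -46 and +12
  vals <- c(-46, -46, -20, 12, 12)
  rate <- matrix(vals, 1, 5)
  rmap <- structure(list(rate = rate,
                         valid_mask = matrix(TRUE, 1, 5),
                         chl_mask = matrix(c(FALSE, FALSE, FALSE, TRUE,
                                             TRUE), 1, 5)),
                    class = "rate_map")
  st <- patch_statistics(rmap)
  all_row <- st[st$class == "all", ]
  expect_equal(all_row$q25, -46)
  expect_equal(all_row$q75, 12)
  expect_equal(st$median[st$class == "chl_positive"], 12)
  expect_equal(st$median[st$class == "chl_negative"], -46)
  # single-class maps report the other class as absent
  rmap$chl_mask[] <- TRUE
  st1 <- patch_statistics(rmap)
  expect_false("chl_negative" %in% st1$class)
})

test_that("class medians recover the generating rates on synthetic maps", {
  cal <- reference_calibration()
  spec <- synthetic_spec(seed = 21, noise_cv = 0.02, frame_times_h = c(0, 1))
  truth <- matrix(-26, 40, 40)
  chl <- matrix(FALSE, 40, 40); chl[, 28:40] <- TRUE
  truth[chl] <- 19
  stack <- make_ratio_series(truth, cal, spec)
  rm1 <- rate_map(stack, cal, 0, 1, chl_image = 1 * chl,
                  chl_threshold = 0.5)
  st <- patch_statistics(rm1)
  expect_equal(st$median[st$class == "chl_positive"], 19, tolerance = 0.1)
  expect_equal(st$median[st$class == "chl_negative"], -26, tolerance = 0.1)
})

test_that("median filter and Otsu threshold behave on known inputs", {
  m <- matrix(0, 7, 7); m[4, 4] <- 100
  expect_equal(median_filter2(m, 5), matrix(0, 7, 7))
  expect_equal(median_filter2(matrix(3, 4, 4), 3), matrix(3, 4, 4))
  bimodal <- c(rnorm(300, 10, 1), rnorm(300, 50, 1))
  thr <- otsu_threshold(matrix(bimodal, 30))
  expect_gt(thr, 15); expect_lt(thr, 45)
})

test_that("filtered rate maps stay within 15% RMS up to 5% channel noise", {
  cal <- reference_calibration()
  spec <- synthetic_spec(seed = 31, noise_cv = 0.05, frame_times_h = c(0, 1))
  # four 12-column bands, wider than the 5x5 filter support
  truth <- matrix(rep(c(-46, -26, 0, 19), each = 12 * 48), 48, 48)
  stack <- make_ratio_series(truth, cal, spec)
  rm1 <- rate_map(stack, cal, 0, 1)
  rms <- sqrt(mean((rm1$rate - truth)^2))
  expect_lt(rms / sqrt(mean(truth^2)), 0.15)
})
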