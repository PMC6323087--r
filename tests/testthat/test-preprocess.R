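test_that("resample: identity, bin arithmetic, peak-area preservation", {
  axis <- seq(900, 910, 0.1)
  ds <- spectra_dataset(mz_axis = axis,
                        intensities = rbind(dnorm(axis, 905, 0.3)),
                        coords = data.frame(x = 0, y = 0),
                        mass_range = c(900, 910))
  expect_identical(resample(ds, 0.1), ds)

  # (4000 - 800)/0.1 + 1 = 32001 bins on the peptide default
  one <- spectra_dataset(mz_axis = c(800, 4000), intensities = rbind(c(0, 0)),
                         coords = data.frame(x = 0, y = 0))
  expect_equal(length(resample(one, 0.1)$mz_axis), 32001L)

  half <- resample(ds, 0.05)
  area <- function(d) sum((d$intensities[1, -1] + d$intensities[1, -ncol(d$intensities)]) / 2 *
                            diff(d$mz_axis))
  expect_lt(abs(area(half) / area(ds) - 1), 0.01)

  expect_error(resample(ds, 20), "larger than the mass range")
  expect_error(resample(ds, 0), "> 0")
})

test_that("resample handles heterogeneous per-pixel axes", {
  ds <- spectra_dataset(mz_list = list(c(900, 901, 902), c(900.5, 901.5)),
                        intensity_list = list(c(1, 2, 3), c(4, 5)),
                        coords = data.frame(x = 0:1, y = 0),
                        mass_range = c(900, 902))
  expect_false(is_common_grid(ds))
  rs <- resample(ds, 0.5)
  expect_true(is_common_grid(rs))
  expect_equal(rs$intensities[1, 1], 1)     # exact grid point
  expect_equal(rs$intensities[2, 2], 4)     # 900.5 preserved
})

test_that("baseline: flat, all-zero, ramp and pure-baseline contracts", {
  axis <- seq(800, 900, 0.1)
  flat <- spectra_dataset(mz_axis = axis,
                          intensities = rbind(rep(3, length(axis))),
                          coords = data.frame(x = 0, y = 0),
                          mass_range = c(800, 900))
  bc <- baseline_correct(flat, 5)
  expect_equal(max(abs(bc$dataset$intensities)), 0)
  expect_true(all(abs(bc$baselines - 3) < 1e-12))

  zero <- flat; zero$intensities[] <- 0
  expect_equal(max(abs(baseline_correct(zero, 5)$dataset$intensities)), 0)

  ramp <- 2 + 0.01 * (axis - 800)
  peak <- dnorm(axis, 850, 0.3) * 40
  ds <- spectra_dataset(mz_axis = axis, intensities = rbind(ramp + peak),
                        coords = data.frame(x = 0, y = 0),
                        mass_range = c(800, 900))
  rec <- sum(baseline_correct(ds, 5)$dataset$intensities[1, abs(axis - 850) <= 1.5]) * 0.1
  expect_lt(abs(rec / 40 - 1), 0.02)

  pure <- spectra_dataset(mz_axis = axis,
                          intensities = rbind(10 * exp(-(axis - 800) / 40)),
                          coords = data.frame(x = 0, y = 0),
                          mass_range = c(800, 900))
  bcp <- baseline_correct(pure, 5)
  expect_lt(sum(bcp$dataset$intensities) / sum(pure$intensities), 0.05)

  expect_error(baseline_correct(ds, 0), "> 0")
})

test_that("outlier flagging: trivial, extreme pixel, invariances", {
  mk <- function(tics) {
    spectra_dataset(mz_axis = c(900, 900.1, 900.2),
                    intensities = outer(tics, c(0.25, 0.5, 0.25)),
                    coords = data.frame(x = seq_along(tics) - 1L, y = 0L),
                    mass_range = c(800, 4000))
  }
  expect_identical(flag_outlier_spectra(mk(rep(7, 50))), integer(0))

  set.seed(11)
  tics <- exp(rnorm(1000, 0, 0.1))
  tics[137] <- median(tics) * 100
  ds <- mk(tics)
  fl <- flag_outlier_spectra(ds)
  expect_true(137 %in% fl)

  ds2 <- ds; ds2$intensities <- ds$intensities * 123.4
  expect_identical(flag_outlier_spectra(ds2), fl)

  perm <- sample(1000)
  dsp <- mk(tics[perm])
  expect_identical(sort(perm[flag_outlier_spectra(dsp)]), fl)

  expect_error(flag_outlier_spectra(mk(rep(1, 5))), "at least 10")
})

test_that("outlier recall on a phantom with planted 10x/0.1x outliers", {
  map <- make_phantom(c(32, 32), 0.4, seed = 2)
  lib <- make_component_library(10, c(800, 930), frac_discriminatory = 0.2,
                                seed = 3)
  syn <- synthesize_dataset(map, lib, noise_sd = 0.02, baseline_amp = 0.1,
                            mz_jitter_sd = 0, tic_spread = 0.15,
                            outlier_rate = 0.02, seed = 4)
  bc <- baseline_correct(syn$dataset)
  fl <- flag_outlier_spectra(bc$dataset)
  expect_gte(mean(syn$truth$outlier_pixels %in% fl), 0.9)
})

test_that("alignment: identical spectra, constructed lag, planted jitter", {
  axis <- seq(900, 950, 0.1)
  base <- dnorm(axis, 920, 0.3) * 50 + dnorm(axis, 940, 0.25) * 30
  same <- spectra_dataset(mz_axis = axis,
                          intensities = matrix(base, 10, length(axis), byrow = TRUE),
                          coords = data.frame(x = 0:9, y = 0),
                          mass_range = c(900, 950))
  expect_true(all(align_to_average(same, 1)$shifts == 0))

  shifted <- same
  shifted$intensities[3, ] <- c(rep(0, 3), base[1:(length(base) - 3)])
  al <- align_to_average(shifted, 1)
  expect_equal(al$shifts[3], -3L)
  expect_true(all(al$shifts[-3] == 0))

  expect_error(align_to_average(same, 20), "10%")

  map <- make_phantom(c(16, 16), 0.4, seed = 2)
  lib <- make_component_library(15, c(800, 1000), frac_discriminatory = 0,
                                seed = 3)
  syn <- synthesize_dataset(map, lib, noise_sd = 0, baseline_amp = 0,
                            mz_jitter_sd = 0.2, tic_spread = 0,
                            outlier_rate = 0, seed = 5)
  al2 <- align_to_average(syn$dataset, 1)
  resid <- al2$shifts + syn$truth$shifts / 0.1
  expect_gt(sd(syn$truth$shifts / 0.1), 1.5)   # planted ~2-bin jitter
  expect_lt(sd(resid), 1)
})

test_that("TIC normalization and the average spectrum", {
  ds <- spectra_dataset(mz_axis = c(900, 900.1),
                        intensities = rbind(c(1, 1), c(3, 1)),
                        coords = data.frame(x = 0:1, y = 0),
                        mass_range = c(800, 4000))
  tn <- tic_normalize(ds)
  expect_equal(rowSums(tn$intensities), c(3, 3))
  expect_equal(tn$intensities[2, 1] / tn$intensities[2, 2], 3)
  expect_equal(tic_normalize(tn)$intensities, tn$intensities)

  zero <- ds; zero$intensities[2, ] <- 0
  expect_error(tic_normalize(zero), "zero-TIC pixel")

  one <- drop_pixels(ds, 2L)
  expect_equal(average_spectrum(one)$intensity, ds$intensities[1, ])
  two <- ds; two$intensities <- rbind(c(0, 0), c(2, 2))
  expect_equal(average_spectrum(two)$intensity, c(1, 1))

  big <- tiny_dataset(100, mz = seq(900, 901, 0.1))
  expect_identical(average_spectrum(big)$intensity, colMeans(big$intensities))
})

test_that("full chain is an identity (up to TIC scale) on a clean phantom", {
  map <- make_phantom(c(12, 12), 0.4, seed = 2)
  lib <- make_component_library(10, c(800, 930), frac_discriminatory = 0.2,
                                seed = 4)
  syn <- synthesize_dataset(map, lib, noise_sd = 0, baseline_amp = 0,
                            mz_jitter_sd = 0, tic_spread = 0,
                            outlier_rate = 0, seed = 6)
  pp <- preprocess(syn$dataset, roi = syn$roi)
  keep <- setdiff(seq_len(n_pixels(syn$dataset)), pp$report$outlier_indices)
  tic_in <- rowSums(syn$dataset$intensities[keep, ])
  scaled <- syn$dataset$intensities[keep, ] * (mean(tic_in) / tic_in)
  expect_lt(max(abs(pp$dataset$intensities - scaled)) / max(scaled), 1e-3)
  expect_true(all(pp$report$shift_per_pixel == 0))
  # mask stays aligned after outlier removal
  expect_equal(length(pp$roi), n_pixels(pp$dataset))
})
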