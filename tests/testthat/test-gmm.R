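synthetic_average <- function(centres, sds, weights, range, step = 0.1) {
  mz <- seq(range[1], range[2], step)
  y <- numeric(length(mz))
  for (j in seq_along(centres))
    y <- y + weights[j] * dnorm(mz, centres[j], sds[j])
  structure(list(mz = mz, intensity = y), class = "average_spectrum")
}

test_that("fit_gmm recovers planted peaks", {
  avg <- synthetic_average(1000, 0.3, 50, c(995, 1005))
  m <- fit_gmm(avg)
  top <- which.max(m$components$weight)
  expect_lt(abs(m$components$mean[top] - 1000), 0.05)
  expect_lt(abs(m$components$sd[top] - 0.3), 0.05)

  avg3 <- synthetic_average(c(990, 1000, 1010), c(0.3, 0.25, 0.35),
                            c(40, 80, 20), c(985, 1015))
  m3 <- fit_gmm(avg3)
  surv <- m3$components$mean[surviving_components(m3)]
  for (ctr in c(990, 1000, 1010))
    expect_lt(min(abs(surv - ctr)), 0.1)

  expect_error(fit_gmm(structure(list(mz = 1:10, intensity = rep(0, 10)),
                                 class = "average_spectrum")), "all zero")
})

test_that("EM log-likelihood traces are non-decreasing", {
  avg <- synthetic_average(c(990, 991, 1005), c(0.3, 0.3, 0.3),
                           c(50, 25, 40), c(985, 1010))
  m <- fit_gmm(avg)
  for (tr in m$ll_trace)
    expect_true(all(diff(tr) > -1e-6 * (abs(tr[-length(tr)]) + 1)))
})

test_that("filter_components flags by SD and amplitude without deleting", {
  m <- msidiscrim:::new_gmm_model(mean = c(900, 910, 920),
                                  sd = c(0.3, 3, 0.3),
                                  weight = c(0.45, 0.45, 0.1))
  f <- filter_components(m, sd_max = 1, weight_min = 0)
  expect_identical(f$filter_reason, c(NA, "high_variance", NA))
  expect_equal(nrow(f$components), 3L)

  same <- msidiscrim:::new_gmm_model(rep(c(900, 910), 1) + c(0, 0),
                                     sd = c(0.3, 0.3), weight = c(0.5, 0.5))
  expect_false(any(filter_components(same, sd_max = Inf,
                                     weight_min = 1)$filtered_out))
  expect_false(any(filter_components(m, sd_max = Inf,
                                     weight_min = 0)$filtered_out))

  # low-amplitude flagging: amplitude = weight / sd
  la <- filter_components(m, sd_max = Inf, weight_min = 0.5)
  expect_true(la$filtered_out[2])   # broad peak has tiny apex
})

test_that("merge_skewed maps satellites leftward with the dominance rule", {
  # isolated components: identity map
  m0 <- msidiscrim:::new_gmm_model(c(900, 950), c(0.3, 0.3), c(0.5, 0.5))
  expect_identical(merge_skewed(m0)$merge_map, 1:2)

  # major + two satellites at +1.003 / +2.006 with decaying weights
  m <- msidiscrim:::new_gmm_model(c(900, 901.003, 902.006, 950),
                                  sd = rep(0.3, 4),
                                  weight = c(0.4, 0.2, 0.1, 0.3))
  g <- merge_skewed(m)
  expect_identical(g$merge_map, c(1L, 1L, 1L, 4L))
  expect_equal(sum(surviving_components(g)), 2L)

  # equal amplitudes: dominance not met, no merge
  eq <- msidiscrim:::new_gmm_model(c(900, 901), c(0.3, 0.3), c(0.5, 0.5))
  expect_identical(merge_skewed(eq)$merge_map, 1:2)

  # filtered components take no part
  mf <- filter_components(m, sd_max = Inf, weight_min = 0)
  mf$filtered_out[1] <- TRUE
  gf <- merge_skewed(mf)
  expect_identical(gf$merge_map[2], 2L)  # nearest major (1) is filtered
})

test_that("quantification matches the Gaussian self-overlap closed form", {
  sdv <- 0.3
  axis <- seq(995, 1005, 0.05)
  m <- msidiscrim:::new_gmm_model(1000, sdv, 1)
  ds <- spectra_dataset(mz_axis = axis,
                        intensities = rbind(dnorm(axis, 1000, sdv)),
                        coords = data.frame(x = 0, y = 0),
                        mass_range = c(995, 1005))
  ab <- quantify_abundances(m, ds)
  expect_lt(abs(ab$abundances[1, 1] - 1 / (2 * sdv * sqrt(pi))), 1e-4)

  # exact linearity and pixel permutation equivariance
  ds2 <- ds
  ds2$intensities <- ds$intensities * 2
  expect_equal(quantify_abundances(m, ds2)$abundances,
               ab$abundances * 2)

  multi <- spectra_dataset(mz_axis = axis,
                           intensities = rbind(dnorm(axis, 1000, sdv),
                                               2 * dnorm(axis, 1000, sdv),
                                               3 * dnorm(axis, 1000, sdv)),
                           coords = data.frame(x = 0:2, y = 0),
                           mass_range = c(995, 1005))
  q1 <- quantify_abundances(m, multi)$abundances
  perm <- multi
  perm$intensities <- multi$intensities[c(3, 1, 2), ]
  q2 <- quantify_abundances(m, perm)$abundances
  expect_equal(q2[1, ], q1[1, c(3, 1, 2)])

  bad <- spectra_dataset(mz_axis = seq(1200, 1210, 0.1),
                         intensities = matrix(1, 1, 101),
                         coords = data.frame(x = 0, y = 0),
                         mass_range = c(800, 4000))
  expect_error(quantify_abundances(m, bad), "do not match")
})

test_that("noise-free phantom quantification correlates with planted truth", {
  map <- make_phantom(c(10, 10), 0.4, seed = 1)
  lib <- make_component_library(12, c(800, 950), frac_discriminatory = 0.3,
                                skew_fraction = 0, seed = 2)
  syn <- synthesize_dataset(map, lib, noise_sd = 0, baseline_amp = 0,
                            mz_jitter_sd = 0, tic_spread = 0,
                            outlier_rate = 0, seed = 3)
  m <- fit_gmm(average_spectrum(syn$dataset))
  ft <- quantify_abundances(m, syn$dataset)
  for (j in seq_len(12)) {
    k <- which.min(abs(ft$component_ids - lib$components$mz[j]))
    expect_gt(cor(ft$abundances[k, ], syn$truth$abundances[, j]), 0.99)
  }
})

test_that("filter-then-merge equals merge-then-filter when independent", {
  m <- msidiscrim:::new_gmm_model(c(900, 901.003, 920, 950),
                                  sd = c(0.3, 0.3, 5, 0.3),
                                  weight = c(0.5, 0.2, 0.2, 0.1))
  a <- merge_skewed(filter_components(m, sd_max = 1, weight_min = 0))
  b <- filter_components(merge_skewed(m), sd_max = 1, weight_min = 0)
  expect_identical(surviving_components(a), surviving_components(b))
})
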