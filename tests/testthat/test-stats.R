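test_that("coefficient of variation per component and group", {
  tb <- feature_table(component_ids = c(900, 910),
                      abundances = rbind(rep(5, 6), c(1, 2, 3, 1, 2, 3)))
  mask <- roi_mask(rep(c("cancer", "epithelium"), each = 3))
  cv <- cv_per_component(tb, mask)
  expect_equal(cv$cv_all[1], 0)
  expect_equal(cv$cv_cancer[2], 0.5)       # sd({1,2,3}) = 1, mean = 2
  expect_equal(cv$cv_epithelium[2], 0.5)

  zero <- feature_table(component_ids = 900,
                        abundances = rbind(rep(0, 6)))
  expect_true(is.na(cv_per_component(zero, mask)$cv_all[1]))
})

test_that("planted per-region CVs are recovered on a phantom", {
  map <- make_phantom(c(32, 32), 0.5, seed = 1)   # 512 per region
  lib <- make_component_library(8, c(800, 904), frac_discriminatory = 0,
                                cv_cancer = 0.4, cv_epithelium = 0.3, seed = 2)
  syn <- synthesize_feature_table(map, lib, seed = 3)
  cv <- cv_per_component(syn$table, syn$roi)
  expect_lt(abs(mean(cv$cv_cancer) / 0.4 - 1), 0.1)
  expect_lt(abs(mean(cv$cv_epithelium) / 0.3 - 1), 0.1)
})

test_that("Lilliefors test is calibrated and detects non-normality", {
  # type-I: ~5% rejections at alpha 0.05 on normal samples of n = 100
  rej <- msidiscrim:::with_seed(515151, {
    vapply(seq_len(1000), function(b)
      lilliefors_test(rnorm(100))$p.value < 0.05, logical(1))
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.075)
  # gross non-normality is caught
  x <- msidiscrim:::with_seed(9, rexp(200))
  expect_lt(lilliefors_test(x)$p.value, 0.01)
  expect_error(lilliefors_test(rnorm(4)), ">= 5")
})

test_that("F screen agrees with var.test and handles equal variances", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x + 10                                # identical variances
  tb <- feature_table(component_ids = 900, abundances = rbind(c(x, y)))
  mask <- roi_mask(rep(c("cancer", "epithelium"), each = 6))
  sc <- distribution_screens(tb, mask)
  expect_equal(sc$f_test_p[1], 1)

  set.seed(3)
  a <- rnorm(50, sd = 1); b <- rnorm(50, sd = 3)
  tb2 <- feature_table(component_ids = 900, abundances = rbind(c(a, b)))
  mask2 <- roi_mask(rep(c("cancer", "epithelium"), each = 50))
  sc2 <- distribution_screens(tb2, mask2)
  expect_lt(sc2$f_test_p[1], 0.001)
  # independent oracle
  expect_equal(sc2$f_test_p[1], var.test(a, b)$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney: exact branch, ties, and the spec example", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p.value, 0.1)            # 2/20 arrangements as extreme

  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
})

test_that("exact Mann-Whitney equals enumeration for all sizes <= 6", {
  cases <- msidiscrim:::with_seed(616161, {
    lapply(seq_len(25), function(i) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      list(x = round(rnorm(n1), 6), y = round(rnorm(n2, 0.5), 6))
    })
  })
  for (cs in cases) {
    got <- mann_whitney(cs$x, cs$y)
    expect_equal(got$p.value, mw_enumeration_p(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  ps <- msidiscrim:::with_seed(717171, {
    lapply(seq_len(50), function(i) runif(sample(1:200, 1))^sample(1:3, 1))
  })
  for (p in ps) expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-15)
})

test_that("robust Cohen's d: classical limit, symmetry, invariance", {
  expect_equal(cohens_d_robust(rep(1:5, 2), rep(1:5, 2), 0.2), 0)

  x <- 1:10; y <- 3:12
  classical <- (mean(x) - mean(y)) /
    sqrt(((9 * var(x)) + (9 * var(y))) / 18)
  expect_equal(cohens_d_robust(x, y, trim = 0), classical, tolerance = 1e-12)

  set.seed(5)
  a <- rlnorm(40); b <- rlnorm(40, 0.5)
  expect_equal(cohens_d_robust(a, b), -cohens_d_robust(b, a))
  expect_equal(cohens_d_robust(3 * a + 2, 3 * b + 2), cohens_d_robust(a, b),
               tolerance = 1e-12)
  expect_error(cohens_d_robust(1:3, 1:10), ">= 5")
  expect_warning(d <- cohens_d_robust(rep(1, 6), rep(2, 6)), "infinite")
  expect_true(is.infinite(d))
})

test_that("effect categories honour the 0.5/0.8/1.2 cuts", {
  expect_equal(as.character(effect_category(0.49)), "negligible")
  expect_equal(as.character(effect_category(0.5)), "negligible")
  expect_equal(as.character(effect_category(0.51)), "medium")
  expect_equal(as.character(effect_category(0.8)), "medium")
  expect_equal(as.character(effect_category(1.2)), "large")
  expect_equal(as.character(effect_category(-1.3)), "very_large")
})

test_that("similarity index contracts and domain ordering", {
  v <- c(5, 3, 2, 1)
  expect_equal(similarity_index(v, v, c(1, 2, 4)), rep(1, 3))
  a <- c(1, 0, 2, 0); b <- c(0, 3, 0, 1)
  expect_equal(similarity_index(a, b, 4), 0)
  expect_error(similarity_index(a, b, 5), "exceeds")

  # domain with smaller planted effects has the higher similarity curve
  map <- make_phantom(c(20, 20), 0.5, seed = 1)
  lib_pep <- make_component_library(30, c(800, 1180), frac_discriminatory = 0.6,
                                    effect_size_range = c(1.5, 2.5),
                                    skew_fraction = 0, seed = 2)
  lib_lip <- make_component_library(30, c(800, 1180), frac_discriminatory = 0.6,
                                    effect_size_range = c(0.2, 0.4),
                                    skew_fraction = 0, seed = 2)
  curves <- lapply(list(lib_pep, lib_lip), function(lib) {
    syn <- synthesize_feature_table(map, lib, seed = 3)
    ic <- syn$roi == "cancer"
    ma <- colMeans(syn$abundances[ic, ])
    mb <- colMeans(syn$abundances[!ic, ])
    similarity_index(ma, mb, c(5, 10, 20, 30))
  })
  expect_true(all(curves[[2]] > curves[[1]]))
})

test_that("compare_components assembles coherent records", {
  tq <- quick_table(n_components = 8, n_side = 12, frac = 0.5,
                    d_range = c(1.5, 1.5), seed = 11)
  eff <- compare_components(tq$table, tq$roi, screens = TRUE)
  expect_equal(nrow(eff), 8L)
  expect_true(all(eff$p_adj >= eff$p_raw - 1e-15))
  expect_true(all(eff$p_raw >= 0 & eff$p_adj <= 1))
  disc <- tq$lib$components$discriminatory
  expect_true(all(eff$significant[disc]))
  expect_true(all(abs(eff$d[disc]) > 0.8))
  # category consistent with |d|
  expect_identical(as.character(eff$category), as.character(effect_category(eff$d)))
})
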