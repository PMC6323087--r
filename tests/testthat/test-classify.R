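test_that("validation metrics identities on reference rate pairs", {
  # constructed confusion realizing sensitivity 78.7 / specificity 90.7
  truth <- rep(c(TRUE, FALSE), each = 1000)
  pred <- c(rep(TRUE, 787), rep(FALSE, 213), rep(TRUE, 93), rep(FALSE, 907))
  m <- validation_metrics(truth, pred)
  expect_equal(m$sensitivity, 78.7)
  expect_equal(m$specificity, 90.7)
  expect_equal(m$weighted_accuracy, 84.7)
  expect_equal(m$f_measure,
               2 * m$precision * m$sensitivity / (m$precision + m$sensitivity))

  pred2 <- c(rep(TRUE, 560), rep(FALSE, 440), rep(TRUE, 176), rep(FALSE, 824))
  m2 <- validation_metrics(truth, pred2)
  expect_equal(m2$sensitivity, 56.0)
  expect_equal(m2$specificity, 82.4)
  expect_equal(m2$weighted_accuracy, 69.2)

  perfect <- validation_metrics(truth, truth)
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  accuracy = 100, weighted_accuracy = 100,
                                  precision = 100, f_measure = 100))
})

test_that("random validation balances, splits and reproduces deterministically", {
  tq <- quick_table(n_components = 12, n_side = 16, frac = 0.3,
                    d_range = c(1.5, 2), seed = 21, cancer_fraction = 0.2)
  runs <- run_random_validation(tq$table, tq$roi, n_iter = 6, seed = 5)
  lab <- as.character(tq$roi)
  for (r in runs) {
    expect_length(intersect(r$train, r$test), 0)
    tb <- table(lab[r$train])
    expect_lte(abs(tb[["cancer"]] - tb[["epithelium"]]), 1)
  }
  runs2 <- run_random_validation(tq$table, tq$roi, n_iter = 6, seed = 5)
  expect_identical(lapply(runs, `[[`, "signature"),
                   lapply(runs2, `[[`, "signature"))
  expect_identical(runs[[3]]$test_metrics, runs2[[3]]$test_metrics)

  small <- roi_mask(c(rep("cancer", 5), rep("epithelium",
                                            length(tq$roi) - 5)))
  expect_error(run_random_validation(tq$table, small, 1, 1),
               "fewer than 10")
})

test_that("a perfectly separating feature is selected first", {
  set.seed(31)
  n <- 120
  lab <- rep(c("cancer", "epithelium"), each = n / 2)
  noise <- matrix(rexp(n * 30), nrow = 30)
  signal <- ifelse(lab == "cancer", 10, 1) * exp(rnorm(n, 0, 0.05))
  tb <- feature_table(component_ids = c(850.5, sort(runif(30, 900, 1200))),
                      abundances = rbind(signal, noise))
  runs <- run_random_validation(tb, roi_mask(lab), n_iter = 1, seed = 2)
  expect_equal(runs[[1]]$signature[1], 850.5)
})

test_that("feature scoring follows the accuracy x position-weight formula", {
  mk_run <- function(sig, wacc) {
    structure(list(iteration = 1, train = 1:2, test = 3:4,
                   signature = sig,
                   test_metrics = list(weighted_accuracy = wacc)),
              class = "validation_run")
  }
  runs <- list(mk_run(c(900, 910), 100), mk_run(c(910, 900), 80))
  sc <- score_and_rank_features(runs, c(900, 910, 920))
  # 900: 1.0 * 1 + 0.8 * 0.5 = 1.4 ; 910: 1.0 * 0.5 + 0.8 * 1 = 1.3
  expect_equal(sc$score[sc$component_id == 900], 1.4)
  expect_equal(sc$score[sc$component_id == 910], 1.3)
  expect_equal(sc$score[sc$component_id == 920], 0)
  expect_equal(sc$rank[sc$component_id == 920], 3L)
  expect_identical(sc$rank, 1:3)

  # feature always first with 100% accuracy scores n_iter
  always <- lapply(1:7, function(i) mk_run(c(950, 960), 100))
  sca <- score_and_rank_features(always, c(950, 960))
  expect_equal(sca$score[sca$component_id == 950], 7)
})

test_that("knee rule on constructed curves", {
  expect_equal(msidiscrim:::knee_point(c(10, 9, 8, 1, 0.9, 0.8, 0.7, 0.6, 0.5)), 3L)
  expect_equal(msidiscrim:::knee_point(rep(4, 10)), 1L)
  expect_equal(msidiscrim:::knee_point(c(5, 1)), 1L)
})

test_that("probability maps: logistic identity, symmetry, region contrast", {
  tq <- quick_table(n_components = 10, n_side = 12, frac = 0.4,
                    d_range = c(1.5, 2), seed = 41)
  zero <- structure(list(signature = tq$table$component_ids[1:2],
                         coefficients = c(0, 0, 0), transform = "log1p"),
                    class = "msi_classifier")
  pm <- probability_map(zero, tq$table)
  expect_true(all(pm$probability == 0.5))
  expect_equal(dim(pm$image), c(12, 12))

  model <- train_classifier(tq$table, tq$roi,
                            tq$table$component_ids[1:5], seed = 3)
  p1 <- probability_map(model, tq$table)$probability
  flipped <- model
  flipped$coefficients <- -model$coefficients
  p2 <- probability_map(flipped, tq$table)$probability
  expect_equal(p1, 1 - p2, tolerance = 1e-12)

  # mean probability higher in the true cancer region
  sig <- tq$lib$components$mz[tq$lib$components$discriminatory]
  model2 <- train_classifier(tq$table, tq$roi, sig, seed = 3)
  p <- probability_map(model2, tq$table)$probability
  expect_gt(mean(p[tq$roi == "cancer"]), mean(p[tq$roi == "epithelium"]))
})

test_that("signature feature correlations", {
  set.seed(51)
  n <- 1000
  f1 <- rnorm(n); f2 <- f1; f3 <- rnorm(n)
  tb <- feature_table(component_ids = c(900, 910, 920),
                      abundances = rbind(f1, f2, f3) + 10)
  fc <- feature_correlations(tb, c(900, 910, 920), min_effect = 0.5)
  dup <- fc[fc$id_a == 900 & fc$id_b == 910, ]
  expect_equal(dup$r, 1)
  expect_true(dup$reported)
  ind <- fc[fc$id_b == 920, ]
  expect_false(any(ind$reported))

  # null calibration: ~5% of pairs significant before adjustment
  set.seed(52)
  X <- matrix(rnorm(1000 * 15), nrow = 15)
  tbn <- feature_table(component_ids = 900 + 1:15, abundances = X)
  fcn <- feature_correlations(tbn, tbn$component_ids, min_effect = 0)
  expect_lt(abs(mean(fcn$p < 0.05) - 0.05), 0.05)

  const <- feature_table(component_ids = c(1, 2),
                         abundances = rbind(rep(1, 10), rnorm(10)))
  fc2 <- feature_correlations(const, c(1, 2))
  expect_true(is.na(fc2$r[1]))
  expect_error(feature_correlations(tb, 900), ">= 2")
})

test_that("classifier JSON round trip and evaluation on separable data", {
  tq <- quick_table(n_components = 8, n_side = 12, frac = 0.5,
                    d_range = c(4, 4), seed = 61)
  sig <- tq$lib$components$mz[tq$lib$components$discriminatory]
  model <- train_classifier(tq$table, tq$roi, sig, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(model, path)
  m2 <- load_classifier(path)
  expect_equal(m2$coefficients, model$coefficients)
  expect_equal(m2$signature, model$signature)
  m <- evaluate_classifier(m2, tq$table, tq$roi)
  expect_gt(m$weighted_accuracy, 95)
})

test_that("signature size lands near the planted feature count", {
  # 5 strong planted features among 45 noise; scaled to 2 seeds x 20
  # iterations to keep the default run fast (the acceptance-scale version
  # behaves identically)
  map <- make_phantom(c(24, 24), 0.4, seed = 71)
  sizes <- integer(2)
  for (s in 1:2) {
    lib <- make_component_library(50, c(800, 1200), frac_discriminatory = 0.1,
                                  effect_size_range = c(1.5, 2.5),
                                  skew_fraction = 0, seed = 80 + s)
    syn <- synthesize_feature_table(map, lib, seed = 90 + s)
    runs <- run_random_validation(syn$table, syn$roi, n_iter = 20,
                                  seed = 95 + s)
    sc <- score_and_rank_features(runs, syn$table$component_ids)
    sizes[s] <- select_signature(sc, syn$table, syn$roi, seed = 95 + s)$size
  }
  expect_true(all(sizes >= 4 & sizes <= 7))
})
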