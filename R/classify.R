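# Cancer-vs-epithelium spectral classifier: multiple random validation with
# class-balancing downsampling, BIC-guided forward stepwise logistic
# signatures, feature scoring/ranking, knee-rule signature sizing, final
# validation metrics, probability maps and signature correlations.

# logistic regression by IRLS with a small ridge so that perfectly
# separable phantoms do not blow up the weights
fit_logistic <- function(X, y, ridge = 1e-8, max_iter = 60) {
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X, X * w) + diag(ridge, p)
    beta_new <- drop(solve(A, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  list(beta = beta, ll = sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

logistic_bic <- function(fit, n) -2 * fit$ll + length(fit$beta) * log(n)

# forward stepwise selection minimizing BIC; returns indices in selection
# order (first = most important)
stepwise_bic <- function(X, y, max_size = 15L) {
  n <- nrow(X)
  one <- matrix(1, n, 1)
  best_bic <- logistic_bic(fit_logistic(one, y), n)
  selected <- integer(0)
  remaining <- seq_len(ncol(X))
  while (length(selected) < max_size && length(remaining)) {
    bics <- vapply(remaining, function(j) {
      Xj <- cbind(one, X[, c(selected, j), drop = FALSE])
      logistic_bic(fit_logistic(Xj, y), n)
    }, numeric(1))
    k <- which.min(bics)
    if (bics[k] >= best_bic - 1e-9) break
    best_bic <- bics[k]
    selected <- c(selected, remaining[k])
    remaining <- remaining[-k]
  }
  selected
}

#' Validation metrics from predictions
#'
#' Cancer is the positive class. All values are percentages.
#' `weighted_accuracy` is the mean of sensitivity and specificity;
#' `f_measure` the harmonic mean of precision and sensitivity.
#'
#' @param truth Logical (or factor-like) vector, `TRUE`/`"cancer"` =
#'   positive.
#' @param predicted Logical vector of positive predictions.
#' @return List of sensitivity, specificity, accuracy, weighted_accuracy,
#'   precision, f_measure (all in `[0, 100]`).
#' @export
validation_metrics <- function(truth, predicted) {
  truth <- if (is.logical(truth)) truth else truth == "cancer"
  tp <- sum(truth & predicted); fn <- sum(truth & !predicted)
  tn <- sum(!truth & !predicted); fp <- sum(!truth & predicted)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  fm <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(sensitivity = sens, specificity = spec,
       accuracy = 100 * (tp + tn) / length(truth),
       weighted_accuracy = (sens + spec) / 2,
       precision = prec, f_measure = fm)
}

# match signature m/z values to table component ids, tolerant of the tiny
# precision loss of text serialization
match_components <- function(signature, ids) {
  idx <- vapply(signature, function(s) {
    k <- which.min(abs(ids - s))
    if (abs(ids[k] - s) <= 1e-6 * max(1, abs(s))) k else NA_integer_
  }, integer(1))
  if (anyNA(idx)) abort_msi("signature component(s) absent from table")
  idx
}

# feature design matrix: pixels x components on a log scale (stabilizes
# the IRLS against the heavy right tail of abundances)
design_matrix <- function(table) t(log1p(pmax(table$abundances, 0)))

#' Multiple random validation of stepwise logistic classifiers
#'
#' Per iteration: a stratified 50/50 pixel split; the training half is
#' randomly downsampled to equal class counts; a forward stepwise logistic
#' regression grows the signature while BIC improves; metrics are computed
#' on the untouched test half at threshold 0.5.
#'
#' @param table A [feature_table()].
#' @param mask A [roi_mask()] with both classes (minority >= 10 pixels).
#' @param n_iter Number of random-validation iterations (50 by
#'   convention).
#' @param seed Master seed; the whole run is deterministic given it.
#' @param max_signature Cap on the per-iteration signature size.
#' @return List of `validation_run` objects: `iteration`, `train`/`test`
#'   pixel indices, `signature` (component ids in selection order),
#'   `test_metrics`.
#' @export
run_random_validation <- function(table, mask, n_iter = 50L, seed = 1,
                                  max_signature = 15L) {
  stopifnot(inherits(table, "feature_table"))
  check_two_groups(mask)
  if (n_iter < 1) abort_msi("n_iter must be >= 1")
  ic <- which(mask == "cancer"); ie <- which(mask == "epithelium")
  if (min(length(ic), length(ie)) < 10)
    abort_msi("minority class has fewer than 10 pixels")
  X <- design_matrix(table)
  y_all <- as.character(mask) == "cancer"
  with_seed(seed, lapply(seq_len(n_iter), function(it) {
    tr_c <- sample(ic, floor(length(ic) / 2))
    tr_e <- sample(ie, floor(length(ie) / 2))
    test <- setdiff(c(ic, ie), c(tr_c, tr_e))
    m <- min(length(tr_c), length(tr_e))
    train <- c(if (length(tr_c) > m) sample(tr_c, m) else tr_c,
               if (length(tr_e) > m) sample(tr_e, m) else tr_e)
    sel <- stepwise_bic(X[train, , drop = FALSE], y_all[train], max_signature)
    fit <- fit_logistic(cbind(1, X[train, sel, drop = FALSE]), y_all[train])
    prob <- stats::plogis(drop(cbind(1, X[test, sel, drop = FALSE]) %*% fit$beta))
    structure(list(iteration = it, train = sort(train), test = sort(test),
                   signature = table$component_ids[sel],
                   signature_idx = sel,
                   test_metrics = validation_metrics(y_all[test], prob >= 0.5)),
              class = "validation_run")
  }))
}

#' Score and rank features over validation runs
#'
#' score(f) = sum over runs whose signature contains f of
#' (test weighted accuracy as a fraction) x (positional weight
#' `(L - pos + 1)/L` for a signature of length L: first feature 1, last
#' 1/L). Features never selected score 0. Ties are broken by ascending
#' component m/z.
#'
#' @param runs List from [run_random_validation()].
#' @param component_ids All candidate component ids (so unselected
#'   features appear with score 0); defaults to the union over signatures.
#' @return Data frame `component_id`, `score`, `rank`, ordered by rank.
#' @export
score_and_rank_features <- function(runs, component_ids = NULL) {
  if (!length(runs)) abort_msi("need at least one validation run")
  if (is.null(component_ids))
    component_ids <- sort(unique(unlist(lapply(runs, `[[`, "signature"))))
  score <- stats::setNames(numeric(length(component_ids)),
                           fmt_full(component_ids))
  for (r in runs) {
    L <- length(r$signature)
    if (!L) next
    wacc <- r$test_metrics$weighted_accuracy / 100
    for (pos in seq_len(L)) {
      key <- fmt_full(r$signature[pos])
      score[key] <- score[key] + wacc * (L - pos + 1) / L
    }
  }
  ord <- order(-score, component_ids)
  data.frame(component_id = component_ids[ord],
             score = unname(score[ord]),
             rank = seq_along(ord))
}

# knee of a non-increasing score curve: normalize both axes to [0, 1] and
# take the point of maximum (signed) elevation above the first-to-last
# chord; degenerate (flat or all-below) curves give 1
knee_point <- function(scores) {
  K <- length(scores)
  if (K < 3) return(1L)
  rng <- max(scores) - min(scores)
  if (rng <= 0) return(1L)
  yn <- (scores - min(scores)) / rng
  xn <- (seq_len(K) - 1) / (K - 1)
  elev <- yn - (1 - xn)
  if (max(elev[-c(1, K)]) <= 0) return(1L)
  which.max(replace(elev, c(1, K), -Inf))
}

#' Select the final signature size
#'
#' The knee of the score-vs-rank curve (maximum distance to the chord on
#' the normalized curve), advanced to the performance plateau when that is
#' larger: classifiers are retrained with the top-k features for k = 1..K
#' and the plateau point is the first k whose weighted accuracy is within
#' 0.5 percentage points of the curve maximum.
#'
#' @param scores Data frame from [score_and_rank_features()].
#' @param table,mask Pooled training data used for the retraining curve.
#' @param seed Seed for the balancing downsample during retraining.
#' @param max_k Cap on the examined signature sizes (default 30).
#' @return List: `signature` (component ids, by rank), `size`, `knee`,
#'   `plateau`, `performance` (weighted accuracy per k).
#' @export
select_signature <- function(scores, table, mask, seed = 1, max_k = 30L) {
  if (!nrow(scores)) abort_msi("empty score table")
  ranked <- scores$component_id[scores$score > 0]
  if (!length(ranked)) ranked <- scores$component_id
  K <- min(length(ranked), max_k)
  knee <- knee_point(scores$score[seq_len(min(nrow(scores), max_k))])
  X <- design_matrix(table)
  y <- as.character(mask) == "cancer"
  idx <- match_components(ranked[seq_len(K)], table$component_ids)
  perf <- with_seed(seed, {
    # repeated stratified 50/50 holdouts (train balanced, evaluate on the
    # untouched half), averaged: the stability analysis smoothing the
    # performance curve so noise features cannot set a late maximum
    ic <- which(y); ie <- which(!y)
    reps <- vapply(seq_len(5L), function(rep) {
      tr_c <- sample(ic, floor(length(ic) / 2))
      tr_e <- sample(ie, floor(length(ie) / 2))
      test <- setdiff(c(ic, ie), c(tr_c, tr_e))
      m <- min(length(tr_c), length(tr_e))
      bal <- c(if (length(tr_c) > m) sample(tr_c, m) else tr_c,
               if (length(tr_e) > m) sample(tr_e, m) else tr_e)
      vapply(seq_len(K), function(k) {
        Xb <- cbind(1, X[bal, idx[seq_len(k)], drop = FALSE])
        fit <- fit_logistic(Xb, y[bal])
        prob <- stats::plogis(
          drop(cbind(1, X[test, idx[seq_len(k)], drop = FALSE]) %*% fit$beta))
        validation_metrics(y[test], prob >= 0.5)$weighted_accuracy
      }, numeric(1))
    }, numeric(K))
    rowMeans(reps)
  })
  plateau <- which(perf >= max(perf) - 0.5)[1]
  size <- max(knee, plateau)
  size <- min(size, K)
  list(signature = ranked[seq_len(size)], size = size,
       knee = knee, plateau = plateau, performance = perf)
}

#' Train the final classifier on a fixed signature
#'
#' Training pixels are downsampled to equal class counts, then a logistic
#' model is fitted on the signature components.
#'
#' @param table,mask Training data.
#' @param signature Component ids (m/z values present in the table).
#' @param seed Seed for the balancing downsample.
#' @return A `msi_classifier`: signature, coefficients (intercept first),
#'   training metadata.
#' @export
train_classifier <- function(table, mask, signature, seed = 1) {
  check_two_groups(mask)
  idx <- match_components(signature, table$component_ids)
  X <- design_matrix(table)
  y <- as.character(mask) == "cancer"
  with_seed(seed, {
    ic <- which(y); ie <- which(!y)
    m <- min(length(ic), length(ie))
    bal <- c(sample(ic, m), sample(ie, m))
    fit <- fit_logistic(cbind(1, X[bal, idx, drop = FALSE]), y[bal])
    structure(list(signature = signature, coefficients = fit$beta,
                   transform = "log1p", seed = seed),
              class = "msi_classifier")
  })
}

#' @export
print.msi_classifier <- function(x, ...) {
  cat("<msi_classifier> ", length(x$signature), " components; intercept ",
      signif(x$coefficients[1], 4), "\n", sep = "")
  invisible(x)
}

classifier_probabilities <- function(model, table) {
  idx <- match_components(model$signature, table$component_ids)
  X <- design_matrix(table)
  stats::plogis(drop(cbind(1, X[, idx, drop = FALSE]) %*% model$coefficients))
}

#' Evaluate a classifier on labelled pixels
#'
#' @param model A `msi_classifier`.
#' @param table A [feature_table()] quantified with the same components.
#' @param mask A [roi_mask()] containing both classes.
#' @param threshold Probability cut for calling cancer (default 0.5).
#' @return [validation_metrics()] list.
#' @export
evaluate_classifier <- function(model, table, mask, threshold = 0.5) {
  check_two_groups(mask)
  prob <- classifier_probabilities(model, table)
  lab <- which(mask != "unassigned")
  validation_metrics(as.character(mask)[lab] == "cancer",
                     prob[lab] >= threshold)
}

#' Per-pixel cancer probability map
#'
#' @param model A `msi_classifier`.
#' @param table A [feature_table()] carrying pixel coordinates.
#' @param mask Optional [roi_mask()]; `unassigned` pixels are rendered as
#'   `NA` in the image.
#' @return List: `probability` (per retained pixel), `image` (matrix on
#'   the raster grid, `NA` outside tissue / unassigned).
#' @export
probability_map <- function(model, table, mask = NULL) {
  prob <- classifier_probabilities(model, table)
  coords <- table$coords
  if (is.null(coords)) abort_msi("feature table carries no coordinates")
  img <- matrix(NA_real_, max(coords$y) + 1L, max(coords$x) + 1L)
  keep <- if (is.null(mask)) rep(TRUE, length(prob)) else mask != "unassigned"
  img[cbind(coords$y + 1L, coords$x + 1L)[keep, , drop = FALSE]] <- prob[keep]
  list(probability = prob, image = img)
}

#' Pairwise Pearson correlations among signature features
#'
#' All pairs get r and a two-sided p; reported pairs must pass the
#' BH-adjusted significance level and the absolute-correlation floor.
#'
#' @param table A [feature_table()].
#' @param signature Component ids (>= 2).
#' @param alpha Significance level on BH-adjusted p-values.
#' @param min_effect Minimum |r| to report (default 0.5, "high effect").
#' @return Data frame of pairs: `id_a`, `id_b`, `r`, `p`, `p_adj`,
#'   `reported` (`NA` r for constant features).
#' @export
feature_correlations <- function(table, signature, alpha = 0.05,
                                 min_effect = 0.5) {
  if (length(signature) < 2) abort_msi("signature must have >= 2 components")
  idx <- match_components(signature, table$component_ids)
  X <- t(table$abundances[idx, , drop = FALSE])
  n <- nrow(X)
  pairs <- utils::combn(length(signature), 2)
  r <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- X[, pairs[1, k]]; b <- X[, pairs[2, k]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      r[k] <- NA_real_; p[k] <- NA_real_
    } else {
      r[k] <- stats::cor(a, b)
      tstat <- r[k] * sqrt((n - 2) / max(1 - r[k]^2, 1e-300))
      p[k] <- 2 * stats::pt(-abs(tstat), n - 2)
    }
  }
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- bh_adjust(p[ok])
  data.frame(id_a = signature[pairs[1, ]], id_b = signature[pairs[2, ]],
             r = r, p = p, p_adj = p_adj,
             reported = !is.na(r) & p_adj < alpha & abs(r) >= min_effect)
}

#' Save / load a classifier as JSON
#'
#' @param model A `msi_classifier`.
#' @param path File path.
#' @return `load_classifier()` returns the model.
#' @export
save_classifier <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "msi_classifier")
}
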