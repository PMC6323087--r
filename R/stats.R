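# Comparative statistics for molecular components: dispersion, normality /
# variance screens, cancer-vs-epithelium testing with multiplicity control,
# robust effect sizes, and the mean-spectrum similarity index.

#' Coefficient of variation per component
#'
#' CV = sample standard deviation / mean, per component, overall and within
#' each ROI. Components with zero mean get `NA` (flagged undefined).
#'
#' @param table A [feature_table()].
#' @param mask A [roi_mask()] aligned with the table's pixels.
#' @return Data frame: `component_id`, `cv_all`, `cv_cancer`,
#'   `cv_epithelium`.
#' @export
cv_per_component <- function(table, mask) {
  stopifnot(inherits(table, "feature_table"), length(mask) == ncol(table$abundances))
  check_two_groups(mask)
  grp_cv <- function(cols) {
    if (length(cols) < 2) return(rep(NA_real_, nrow(table$abundances)))
    a <- table$abundances[, cols, drop = FALSE]
    mu <- rowMeans(a)
    s <- apply(a, 1, stats::sd)
    ifelse(mu > 0, s / mu, NA_real_)
  }
  data.frame(component_id = table$component_ids,
             cv_all = grp_cv(which(mask != "unassigned")),
             cv_cancer = grp_cv(which(mask == "cancer")),
             cv_epithelium = grp_cv(which(mask == "epithelium")))
}

# ---- Lilliefors normality test ---------------------------------------------
# KS statistic against a normal with estimated mean/SD; the null (which is
# not the plain KS null because parameters are estimated) is built by Monte
# Carlo and cached per sample size.

lilliefors_null_env <- new.env(parent = emptyenv())

lilliefors_stat <- function(x) {
  n <- length(x)
  x <- sort(x)
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  p <- stats::pnorm(x, m, s)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

lilliefors_null <- function(n, B = 500L) {
  key <- paste0("n", n, "_B", B)
  tab <- lilliefors_null_env[[key]]
  if (is.null(tab)) {
    tab <- with_seed(2000029L + (n %% 99991L), {
      vapply(seq_len(B), function(b) lilliefors_stat(stats::rnorm(n)),
             numeric(1))
    })
    lilliefors_null_env[[key]] <- tab
  }
  tab
}

#' Lilliefors test for normality
#'
#' @param x Numeric sample (n >= 5).
#' @param B Monte-Carlo null replicates (cached per sample size).
#' @return List with `statistic` and `p.value` (`NA` for degenerate input).
#' @export
lilliefors_test <- function(x, B = 500L) {
  if (length(x) < 5) abort_msi("Lilliefors test needs >= 5 observations")
  stat <- lilliefors_stat(x)
  if (is.na(stat)) return(list(statistic = NA_real_, p.value = NA_real_))
  null <- lilliefors_null(length(x), B)
  list(statistic = stat,
       p.value = (1 + sum(null >= stat)) / (length(null) + 1))
}

#' Normality and variance-homogeneity screens
#'
#' Per component: Lilliefors test of abundance normality across the tissue
#' (all labelled pixels pooled) and a two-sided variance-ratio F test
#' between the cancer and epithelium groups. Both are descriptive screens;
#' they do not gate the rank test.
#'
#' @inheritParams cv_per_component
#' @return Data frame: `component_id`, `lilliefors_p`, `f_test_p`
#'   (`NA` where degenerate).
#' @export
distribution_screens <- function(table, mask) {
  stopifnot(inherits(table, "feature_table"))
  check_two_groups(mask)
  ic <- which(mask == "cancer"); ie <- which(mask == "epithelium")
  if (length(ic) < 5 || length(ie) < 5)
    abort_msi("distribution screens need >= 5 pixels per group")
  both <- c(ic, ie)
  lp <- fp <- numeric(nrow(table$abundances))
  for (j in seq_len(nrow(table$abundances))) {
    a <- table$abundances[j, ]
    lp[j] <- lilliefors_test(a[both])$p.value
    v1 <- stats::var(a[ic]); v2 <- stats::var(a[ie])
    if (v1 == 0 || v2 == 0) {
      fp[j] <- NA_real_
    } else {
      f <- v1 / v2
      p <- stats::pf(f, length(ic) - 1, length(ie) - 1)
      fp[j] <- min(1, 2 * min(p, 1 - p))
    }
  }
  data.frame(component_id = table$component_ids,
             lilliefors_p = lp, f_test_p = fp)
}

# ---- Mann-Whitney U with Benjamini-Hochberg --------------------------------

#' Mann-Whitney U test (two-sided)
#'
#' Exact null (via the Wilcoxon distribution) when both groups have at most
#' 8 observations and no ties occur; otherwise the tie-corrected normal
#' approximation with continuity correction. The reported `u` counts pairs
#' where `x` exceeds `y` (ties counted half).
#'
#' @param x,y Numeric samples.
#' @return List with `u` and `p.value`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort_msi("both groups must be nonempty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (n1 <= 8 && n2 <= 8 && !has_ties) {
    u_min <- min(u, n1 * n2 - u)
    p <- min(1, 2 * stats::pwilcox(u_min, n1, n2))
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) /
                                (nn * (nn - 1)))
    if (sigma2 <= 0) return(list(u = u, p.value = 1))
    z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-z)
  }
  list(u = u, p.value = min(1, p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of raw p-values (one family).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Per-component Mann-Whitney tests with BH correction
#'
#' Two-sided Mann-Whitney U per component between cancer and epithelium
#' pixels, Benjamini-Hochberg adjusted across all components of the table
#' (one molecular domain = one family).
#'
#' @inheritParams cv_per_component
#' @param alpha Significance level applied to the adjusted p-values.
#' @return Data frame: `component_id`, `u_stat`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
mw_bh_test <- function(table, mask, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  check_two_groups(mask)
  ic <- which(mask == "cancer"); ie <- which(mask == "epithelium")
  res <- t(vapply(seq_len(nrow(table$abundances)), function(j) {
    mw <- mann_whitney(table$abundances[j, ic], table$abundances[j, ie])
    c(mw$u, mw$p.value)
  }, numeric(2)))
  p_adj <- bh_adjust(res[, 2])
  data.frame(component_id = table$component_ids,
             u_stat = res[, 1], p_raw = res[, 2], p_adj = p_adj,
             significant = p_adj < alpha)
}

# ---- robust Cohen's d -------------------------------------------------------

winsorized_var <- function(x, trim) {
  n <- length(x)
  k <- floor(trim * n)
  xs <- sort(x)
  if (k > 0) {
    xs[seq_len(k)] <- xs[k + 1]
    xs[(n - k + 1):n] <- xs[n - k]
  }
  stats::var(xs)
}

#' Robust Cohen's d (trimmed means, pooled Winsorized SD)
#'
#' d = (trimmed mean of `x` - trimmed mean of `y`) divided by the pooled
#' Winsorized standard deviation (group Winsorized variances weighted by
#' group size - 1). With `trim = 0` this is the classical pooled-SD
#' Cohen's d. The sign convention in the pipeline is cancer minus
#' epithelium.
#'
#' @param x,y Numeric samples, each of size >= 5.
#' @param trim Trim fraction in `[0, 0.5)` (default 0.2).
#' @return The effect size (`Inf` with a warning when the pooled SD is 0).
#' @export
cohens_d_robust <- function(x, y, trim = 0.2) {
  if (length(x) < 5 || length(y) < 5)
    abort_msi("each group needs >= 5 observations")
  check_scalar_number(trim, "trim", 0, 0.5, strict_upper = TRUE)
  tmx <- mean(x, trim = trim)
  tmy <- mean(y, trim = trim)
  n1 <- length(x); n2 <- length(y)
  pooled <- ((n1 - 1) * winsorized_var(x, trim) +
             (n2 - 1) * winsorized_var(y, trim)) / (n1 + n2 - 2)
  if (pooled <= 0) {
    if (tmx == tmy) return(0)
    warning("zero pooled Winsorized SD; effect size infinite")
    return(sign(tmx - tmy) * Inf)
  }
  (tmx - tmy) / sqrt(pooled)
}

#' Effect-size category
#'
#' Thresholds 0.5 / 0.8 / 1.2 on |d| ("above" is strict: the boundary
#' belongs to the lower category).
#'
#' @param d Effect size(s), finite.
#' @return Factor with levels negligible, medium, large, very_large.
#' @export
effect_category <- function(d) {
  a <- abs(d)
  lv <- c("negligible", "medium", "large", "very_large")
  factor(ifelse(a <= 0.5, "negligible",
         ifelse(a <= 0.8, "medium",
         ifelse(a <= 1.2, "large", "very_large"))), levels = lv)
}

# ---- similarity index -------------------------------------------------------

#' Similarity index between two mean component vectors
#'
#' Components are ranked by their mean abundance across both groups; the
#' similarity at `top_n` is the cosine similarity of the square-root
#' transformed abundances over the `top_n` top-ranked components.
#'
#' @param mean_a,mean_b Component-level mean abundance vectors (same
#'   length, nonnegative).
#' @param top_n Number of top components (single value or vector; each
#'   must not exceed the component count).
#' @return Numeric similarity in `[0, 1]` per `top_n` value (`NA` when a
#'   restricted vector is all zero).
#' @export
similarity_index <- function(mean_a, mean_b, top_n) {
  stopifnot(length(mean_a) == length(mean_b))
  if (any(top_n > length(mean_a)))
    abort_msi("top_n exceeds component count")
  ord <- order((mean_a + mean_b) / 2, decreasing = TRUE)
  vapply(top_n, function(k) {
    ia <- sqrt(mean_a[ord[seq_len(k)]])
    ib <- sqrt(mean_b[ord[seq_len(k)]])
    na <- sqrt(sum(ia^2)); nb <- sqrt(sum(ib^2))
    if (na == 0 || nb == 0) return(NA_real_)
    sum(ia * ib) / (na * nb)
  }, numeric(1))
}

#' Full comparative analysis of a feature table
#'
#' Runs the dispersion, screening, testing and effect-size stages and
#' assembles one record per component.
#'
#' @inheritParams mw_bh_test
#' @param trim Trim fraction for the robust effect size.
#' @param screens Run the (slower) Lilliefors/F screens (default TRUE).
#' @return Data frame of per-component records (class `effect_records`):
#'   CVs, screen p-values, U statistic, raw/adjusted p, robust d and its
#'   category.
#' @export
compare_components <- function(table, mask, alpha = 0.05, trim = 0.2,
                               screens = TRUE) {
  cv <- cv_per_component(table, mask)
  mw <- mw_bh_test(table, mask, alpha)
  ic <- which(mask == "cancer"); ie <- which(mask == "epithelium")
  d <- vapply(seq_len(nrow(table$abundances)), function(j)
    cohens_d_robust(table$abundances[j, ic], table$abundances[j, ie], trim),
    numeric(1))
  out <- data.frame(cv,
                    u_stat = mw$u_stat, p_raw = mw$p_raw, p_adj = mw$p_adj,
                    significant = mw$significant,
                    d = d, category = effect_category(d))
  if (screens) {
    sc <- distribution_screens(table, mask)
    out$lilliefors_p <- sc$lilliefors_p
    out$f_test_p <- sc$f_test_p
  }
  class(out) <- c("effect_records", "data.frame")
  out
}
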