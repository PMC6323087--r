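# Phantom generator: imaging datasets with known region structure, known
# molecular components and known (robust-d) effect sizes, so that every
# downstream stage can be tested against planted ground truth.

# ---- population moments of the log-normal, trimmed/Winsorized ---------------
# Quantile quadrature on a fine probability grid; deterministic, no sampling.
# Used to express planted effect sizes directly in the robust Cohen's d
# metric computed by the comparative-statistics stage.

pop_robust_stats_lnorm <- function(sdlog, trim = 0.2, K = 20000L) {
  p <- (seq_len(K) - 0.5) / K
  q <- stats::qlnorm(p, meanlog = 0, sdlog = sdlog)
  inner <- p > trim & p < 1 - trim
  tm <- mean(q[inner])
  qw <- pmin(pmax(q, stats::qlnorm(trim, 0, sdlog)),
             stats::qlnorm(1 - trim, 0, sdlog))
  wm <- mean(qw)
  wv <- mean((qw - wm)^2)
  list(tmean = tm, wvar = wv)
}

# Multiplier m on the cancer median realizing robust Cohen's d = target
# between LN(log m, s_c) and LN(0, s_e) groups (equal sizes).
solve_effect_multiplier <- function(target_d, sdlog_cancer, sdlog_epithelium,
                                    trim = 0.2) {
  sc <- pop_robust_stats_lnorm(sdlog_cancer, trim)
  se <- pop_robust_stats_lnorm(sdlog_epithelium, trim)
  if (sc$wvar <= 0 && se$wvar <= 0) {
    if (target_d != 0)
      abort_msi("zero CV in both regions cannot realize a finite effect size")
    return(1)
  }
  dfun <- function(m)
    (m * sc$tmean - se$tmean) / sqrt((m^2 * sc$wvar + se$wvar) / 2)
  d_hi <- dfun(1e6); d_lo <- dfun(1e-6)
  if (target_d >= d_hi || target_d <= d_lo)
    abort_msi("target effect size ", target_d,
              " is not achievable with the given CVs (range ",
              round(d_lo, 2), " .. ", round(d_hi, 2), ")")
  stats::uniroot(function(lm) dfun(exp(lm)) - target_d,
                 lower = log(1e-6), upper = log(1e6), tol = 1e-12)$root |> exp()
}

# ---- region map -------------------------------------------------------------

#' Generate a phantom region map
#'
#' Places a connected, approximately circular cancer blob inside an
#' epithelium field on a raster grid (optionally surrounded by a background
#' margin). The cancer pixel count is exactly `round(cancer_fraction * n)`
#' of the tissue pixels: the blob is the set of tissue pixels nearest to a
#' randomly chosen interior centre.
#'
#' @param shape Integer grid dimensions `c(nrow, ncol)`, both >= 4.
#' @param cancer_fraction Fraction of tissue pixels labelled cancer,
#'   strictly in (0, 1).
#' @param seed Integer seed; the map is deterministic given `(shape,
#'   cancer_fraction, seed)`.
#' @param background_margin Width (pixels) of a background ring carrying no
#'   tissue; default 0 (whole grid is tissue).
#' @return A character matrix of `"cancer"`, `"epithelium"`, `"background"`.
#' @export
make_phantom <- function(shape, cancer_fraction, seed,
                         background_margin = 0L) {
  if (length(shape) != 2L || any(shape < 4))
    abort_msi("shape must be two dimensions, each >= 4")
  check_scalar_number(cancer_fraction, "cancer_fraction", 0, 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  m <- as.integer(background_margin)
  if (2 * m >= min(nr, nc) - 2) abort_msi("background_margin too large")
  map <- matrix("background", nr, nc)
  rows <- (1 + m):(nr - m); cols <- (1 + m):(nc - m)
  map[rows, cols] <- "epithelium"
  tissue <- which(map != "background", arr.ind = TRUE)
  n_tissue <- nrow(tissue)
  k <- round(cancer_fraction * n_tissue)
  k <- max(1L, min(n_tissue - 1L, k))
  with_seed(seed, {
    # centre drawn from the central half of the tissue so the blob stays
    # compact rather than clipped by the border
    cr <- stats::runif(1, m + nr * 0.25, nr - m - nr * 0.25 + 1)
    cc <- stats::runif(1, m + nc * 0.25, nc - m - nc * 0.25 + 1)
    d2 <- (tissue[, 1] - cr)^2 + (tissue[, 2] - cc)^2
    sel <- order(d2, tissue[, 1], tissue[, 2])[seq_len(k)]
    map[tissue[sel, , drop = FALSE]] <- "cancer"
  })
  map
}

# ---- component library ------------------------------------------------------

#' Generate a library of planted molecular components
#'
#' Component centres are laid out with a guaranteed minimum separation of
#' 4 peak SDs (even spacing with random jitter). A chosen fraction of
#' components is made discriminatory: their cancer-region median is scaled
#' by a multiplier solved so that the *robust* Cohen's d (20% trimmed mean /
#' pooled Winsorized SD) between the two regions hits the drawn target; the
#' sign of the shift is random. A chosen fraction carries 1-3 right-side
#' satellites with ~1.003 Da spacing and geometrically decaying weights,
#' emulating unresolved isotope envelopes.
#'
#' @param n_components Number of components (>= 1).
#' @param mass_range `(low, high)` in Da.
#' @param frac_discriminatory Fraction of components given a planted effect.
#' @param effect_size_range `(d_min, d_max)` robust Cohen's d targets.
#' @param skew_fraction Fraction of components given isotope satellites.
#' @param seed Integer seed.
#' @param peak_sd Gaussian peak SD in Da (default 0.3).
#' @param cv_cancer,cv_epithelium Planted per-region coefficients of
#'   variation of component abundance (log-normal; defaults 0.4 / 0.3,
#'   dispersion higher within cancer).
#' @param base_abundance Median abundance scale (arbitrary units).
#' @param trim Trim fraction used when calibrating planted effects (0.2,
#'   matching the downstream robust d).
#' @param min_separation Minimum centre-to-centre distance in Da; defaults
#'   to 4 peak SDs. Envelope phantoms exercising the satellite-merge rule
#'   should raise it above the satellite span (~3.2 Da) so whole envelopes
#'   stay disjoint and satellites remain attributable.
#' @return A `component_truth` object.
#' @export
make_component_library <- function(n_components, mass_range,
                                   frac_discriminatory = 0.25,
                                   effect_size_range = c(0.5, 2),
                                   skew_fraction = 0.3, seed = 1,
                                   peak_sd = 0.3,
                                   cv_cancer = 0.4, cv_epithelium = 0.3,
                                   base_abundance = 100, trim = 0.2,
                                   min_separation = NULL) {
  if (n_components < 1) abort_msi("n_components must be >= 1")
  width <- diff(mass_range)
  if (width <= 0) abort_msi("mass_range must be increasing")
  spacing <- width / n_components
  min_sep <- if (is.null(min_separation)) 4 * peak_sd else min_separation
  if (spacing < min_sep * 1.05)
    abort_msi("cannot place ", n_components, " components with >= ",
              min_sep, " Da separation in ", width,
              " Da; use fewer components")
  sdlog_c <- sqrt(log(1 + cv_cancer^2))
  sdlog_e <- sqrt(log(1 + cv_epithelium^2))
  with_seed(seed, {
    base_grid <- mass_range[1] + (seq_len(n_components) - 0.5) * spacing
    jit_amp <- (spacing - min_sep * 1.02) / 2
    mz <- base_grid + stats::runif(n_components, -jit_amp, jit_amp)
    base <- stats::rlnorm(n_components, log(base_abundance), 0.5)
    disc <- rep(FALSE, n_components)
    target_d <- rep(0, n_components)
    mult <- rep(1, n_components)
    n_disc <- round(frac_discriminatory * n_components)
    if (n_disc > 0) {
      idx <- sample.int(n_components, n_disc)
      disc[idx] <- TRUE
      mag <- stats::runif(n_disc, effect_size_range[1], effect_size_range[2])
      sgn <- sample(c(-1, 1), n_disc, replace = TRUE)
      target_d[idx] <- sgn * mag
      mult[idx] <- vapply(target_d[idx], solve_effect_multiplier,
                          numeric(1), sdlog_c, sdlog_e, trim)
    }
    n_skew <- round(skew_fraction * n_components)
    sat <- data.frame(component = character(0), offset = numeric(0),
                      rel_weight = numeric(0))
    ids <- sprintf("C%04d", seq_len(n_components))
    n_sats <- integer(n_components)
    if (n_skew > 0) {
      sidx <- sample.int(n_components, n_skew)
      for (j in sidx) {
        k <- sample.int(3L, 1L)
        n_sats[j] <- k
        sat <- rbind(sat, data.frame(component = ids[j],
                                     offset = 1.003 * seq_len(k),
                                     rel_weight = 0.5^seq_len(k)))
      }
    }
    comps <- data.frame(
      id = ids, mz = mz, sd = peak_sd,
      mean_cancer = base * mult, mean_epithelium = base,
      sdlog_cancer = sdlog_c, sdlog_epithelium = sdlog_e,
      cv_cancer = cv_cancer, cv_epithelium = cv_epithelium,
      discriminatory = disc, target_d = target_d,
      n_satellites = n_sats, stringsAsFactors = FALSE)
    structure(list(components = comps, satellites = sat,
                   params = list(mass_range = mass_range, peak_sd = peak_sd,
                                 trim = trim, seed = seed)),
              class = "component_truth")
  })
}

#' @export
print.component_truth <- function(x, ...) {
  cat("<component_truth> ", nrow(x$components), " components in ",
      x$params$mass_range[1], "-", x$params$mass_range[2], " Da; ",
      sum(x$components$discriminatory), " discriminatory, ",
      sum(x$components$n_satellites > 0), " with satellites\n", sep = "")
  invisible(x)
}

# Draw one abundance matrix (pixel x component) for the given region labels.
draw_abundances <- function(labels, comps) {
  n_px <- length(labels); n_c <- nrow(comps)
  a <- matrix(0, n_px, n_c)
  is_can <- labels == "cancer"
  for (j in seq_len(n_c)) {
    mu <- ifelse(is_can, comps$mean_cancer[j], comps$mean_epithelium[j])
    s <- ifelse(is_can, comps$sdlog_cancer[j], comps$sdlog_epithelium[j])
    a[, j] <- stats::rlnorm(n_px, log(mu), s)
  }
  a
}

# tissue pixel coordinates (0-based, row-major by y then x) of a region map
tissue_coords <- function(region_map) {
  idx <- which(region_map != "background", arr.ind = TRUE)
  coords <- data.frame(x = idx[, 2] - 1L, y = idx[, 1] - 1L,
                       label = region_map[idx])
  coords[order(coords$y, coords$x), , drop = FALSE]
}

default_grid_step <- function(domain) if (domain == "peptide") 0.1 else 0.05

mz_grid <- function(mass_range, grid_step) {
  n <- floor(diff(mass_range) / grid_step + 1e-9) + 1
  mass_range[1] + (seq_len(n) - 1) * grid_step
}

#' Synthesize a phantom MSI dataset
#'
#' Builds one spectrum per tissue pixel: the sum over library components of
#' a Gaussian peak envelope (centre plus right-side satellites) scaled by a
#' log-normal abundance around the pixel's region median, plus a smooth
#' decaying baseline and nonnegative noise, globally shifted in m/z by a
#' per-pixel calibration error and scaled by a per-pixel TIC factor.
#' Outlier pixels get their TIC multiplied by >= 10 or <= 0.1.
#'
#' @param region_map Matrix from [make_phantom()].
#' @param component_truth From [make_component_library()].
#' @param noise_sd Additive noise SD relative to the tallest mean-spectrum
#'   peak; in `[0, 1)`.
#' @param baseline_amp Baseline amplitude on the same relative scale.
#' @param mz_jitter_sd SD (Da) of the per-pixel global m/z shift.
#' @param tic_spread Log-normal SD of the per-pixel TIC factor.
#' @param outlier_rate Bernoulli rate of planted TIC-outlier pixels.
#' @param seed Integer seed.
#' @param grid_step m/z bin width; default 0.1 Da (peptide) / 0.05 Da (lipid).
#' @param domain Overrides the domain inferred from the mass range.
#' @param specimen_id Dataset label.
#' @return A list with `dataset` ([spectra_dataset()]), `roi`
#'   ([roi_mask()]) and `truth` (a `phantom_truth` list recording every
#'   planted quantity: region map, component truth, abundance matrix,
#'   per-pixel shifts and TIC factors, outlier pixel indices).
#' @export
synthesize_dataset <- function(region_map, component_truth,
                               noise_sd = 0.05, baseline_amp = 0.1,
                               mz_jitter_sd = 0.1, tic_spread = 0.15,
                               outlier_rate = 0.01, seed = 1,
                               grid_step = NULL, domain = NULL,
                               specimen_id = "phantom") {
  for (nm in c("noise_sd", "baseline_amp", "tic_spread", "outlier_rate"))
    check_scalar_number(get(nm), nm, 0, 1, strict_upper = TRUE)
  check_scalar_number(mz_jitter_sd, "mz_jitter_sd", 0)
  comps <- component_truth$components
  mass_range <- component_truth$params$mass_range
  if (is.null(domain))
    domain <- if (mass_range[1] >= 600) "peptide" else "lipid"
  if (is.null(grid_step)) grid_step <- default_grid_step(domain)
  axis <- mz_grid(mass_range, grid_step)
  nbin <- length(axis)
  tc <- tissue_coords(region_map)
  n_px <- nrow(tc)
  if (n_px < 1) abort_msi("region map has no tissue pixels")

  with_seed(seed, {
    a <- draw_abundances(tc$label, comps)

    # unit-area envelope density of each component on the grid
    dens <- matrix(0, nrow(comps), nbin)
    for (j in seq_len(nrow(comps))) {
      ctr <- comps$mz[j]; psd <- comps$sd[j]
      sj <- component_truth$satellites[
        component_truth$satellites$component == comps$id[j], , drop = FALSE]
      centers <- c(ctr, ctr + sj$offset)
      wts <- c(1, sj$rel_weight); wts <- wts / sum(wts)
      for (k in seq_along(centers)) {
        lo <- max(1L, findInterval(centers[k] - 6 * psd, axis))
        hi <- min(nbin, findInterval(centers[k] + 6 * psd, axis) + 1L)
        idx <- lo:hi
        dens[j, idx] <- dens[j, idx] +
          wts[k] * stats::dnorm(axis[idx], centers[k], psd)
      }
    }
    clean <- a %*% dens
    ref <- max(colMeans(clean))

    shifts <- if (mz_jitter_sd > 0)
      stats::rnorm(n_px, 0, mz_jitter_sd) else rep(0, n_px)
    if (mz_jitter_sd > 0) {
      for (p in seq_len(n_px))
        clean[p, ] <- stats::approx(axis, clean[p, ], xout = axis - shifts[p],
                                    yleft = 0, yright = 0)$y
    }
    if (baseline_amp > 0) {
      shape <- exp(-3 * (axis - mass_range[1]) / diff(mass_range))
      amp <- baseline_amp * ref * stats::runif(n_px, 0.8, 1.2)
      clean <- clean + outer(amp, shape)
    }
    if (noise_sd > 0)
      clean <- clean + abs(matrix(stats::rnorm(n_px * nbin, 0, noise_sd * ref),
                                  n_px, nbin))

    tic_factor <- if (tic_spread > 0)
      exp(stats::rnorm(n_px, 0, tic_spread)) else rep(1, n_px)
    out_px <- integer(0)
    if (outlier_rate > 0) {
      out_px <- which(stats::runif(n_px) < outlier_rate)
      if (length(out_px)) {
        up <- stats::runif(length(out_px)) < 0.5
        fac <- ifelse(up, 10^stats::runif(length(out_px), 1, 1.3),
                      10^-stats::runif(length(out_px), 1, 1.3))
        tic_factor[out_px] <- tic_factor[out_px] * fac
      }
    }
    ints <- clean * tic_factor

    ds <- spectra_dataset(mz_axis = axis, intensities = ints,
                          coords = tc[c("x", "y")],
                          specimen_id = specimen_id, domain = domain,
                          mass_range = mass_range)
    roi <- roi_mask(ifelse(tc$label == "cancer", "cancer", "epithelium"))
    truth <- structure(list(
      region_map = region_map, component_truth = component_truth,
      abundances = a, shifts = shifts, tic_factor = tic_factor,
      outlier_pixels = out_px, coords = tc[c("x", "y")],
      params = list(noise_sd = noise_sd, baseline_amp = baseline_amp,
                    mz_jitter_sd = mz_jitter_sd, tic_spread = tic_spread,
                    outlier_rate = outlier_rate, seed = seed,
                    grid_step = grid_step)), class = "phantom_truth")
    list(dataset = ds, roi = roi, truth = truth)
  })
}

#' Synthesize a feature table directly (no spectra)
#'
#' Fast path for testing the segmentation, statistics and classification
#' stages: draws the per-pixel component abundances of a phantom without
#' rendering spectra, so the result is exactly what a noise-free
#' quantification would recover.
#'
#' @inheritParams synthesize_dataset
#' @return A list with `table` ([feature_table()]), `roi` ([roi_mask()])
#'   and `abundances` (the pixel x component truth matrix).
#' @export
synthesize_feature_table <- function(region_map, component_truth, seed = 1,
                                     domain = NULL) {
  comps <- component_truth$components
  if (is.null(domain))
    domain <- if (component_truth$params$mass_range[1] >= 600)
      "peptide" else "lipid"
  tc <- tissue_coords(region_map)
  with_seed(seed, {
    a <- draw_abundances(tc$label, comps)
    tbl <- feature_table(component_ids = comps$mz, abundances = t(a),
                         domain = domain, coords = tc[c("x", "y")])
    roi <- roi_mask(ifelse(tc$label == "cancer", "cancer", "epithelium"))
    list(table = tbl, roi = roi, abundances = a)
  })
}
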