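# Gaussian mixture modelling of the cohort average spectrum: peak detection,
# component filtering, isotope-envelope (right-skew) merging, and per-pixel
# quantification of the surviving "molecular components".

new_gmm_model <- function(mean, sd, weight, params = list()) {
  ord <- order(mean)
  comps <- data.frame(mean = mean[ord], sd = sd[ord], weight = weight[ord])
  # collapse numerically identical means so the order is strict
  if (nrow(comps) > 1) {
    dup <- c(FALSE, diff(comps$mean) < 1e-9)
    if (any(dup)) {
      grp <- cumsum(!dup)
      comps <- do.call(rbind, lapply(split(comps, grp), function(d)
        data.frame(mean = d$mean[1], sd = stats::weighted.mean(d$sd, d$weight),
                   weight = sum(d$weight))))
    }
  }
  structure(list(components = comps,
                 filtered_out = rep(FALSE, nrow(comps)),
                 filter_reason = rep(NA_character_, nrow(comps)),
                 merge_map = seq_len(nrow(comps)),
                 params = params),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat("<gmm_model> ", nrow(x$components), " components (",
      sum(surviving_components(x)), " surviving, ",
      sum(x$filtered_out), " filtered, ",
      sum(x$merge_map != seq_along(x$merge_map)), " merged)\n", sep = "")
  invisible(x)
}

#' Surviving components of a mixture model
#'
#' A component survives when it is neither filtered out nor merged into a
#' left neighbour.
#'
#' @param model A `gmm_model`.
#' @return Logical vector over components.
#' @export
surviving_components <- function(model) {
  !model$filtered_out & model$merge_map == seq_along(model$merge_map)
}

# component amplitude: density apex height (weight / sd up to 1/sqrt(2*pi))
component_amplitude <- function(model)
  model$components$weight / model$components$sd

# weighted EM for a 1-d Gaussian mixture over binned data
# x: bin centres, w: nonnegative bin weights (sum ~ effective sample size)
em_gauss_mix <- function(x, w, mu0, sd0, pi0, sd_floor,
                         max_iter = 300, tol = 1e-8) {
  k <- length(mu0)
  mu <- mu0; sd <- pmax(sd0, sd_floor); pi_ <- pi0 / sum(pi0)
  W <- sum(w)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      pi_[j] * stats::dnorm(x, mu[j], sd[j]), numeric(length(x)))
    dens <- matrix(dens, ncol = k)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(w * log(tot))
    ll_trace <- c(ll_trace, ll)
    r <- dens / tot
    nj <- colSums(w * r)
    keep <- nj > 1e-10 * W
    if (!all(keep)) {
      mu <- mu[keep]; sd <- sd[keep]; pi_ <- pi_[keep]
      pi_ <- pi_ / sum(pi_)
      k <- sum(keep)
      if (k == 0) break
      next
    }
    mu <- colSums(w * r * x) / nj
    sd <- sqrt(pmax(colSums(w * r * (x - rep(mu, each = length(x)))^2) / nj,
                    sd_floor^2))
    pi_ <- nj / W
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sd = sd, pi = pi_, ll = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, k = k)
}

# contiguous above-threshold signal regions, merged across small gaps
signal_regions <- function(y, thr, gap_bins) {
  above <- y > thr
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  merged <- list(seg[1, ])
  if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
    last <- merged[[length(merged)]]
    if (seg[i, 1] - last[2] - 1L <= gap_bins)
      merged[[length(merged)]] <- c(last[1], seg[i, 2])
    else merged[[length(merged) + 1L]] <- seg[i, ]
  }
  merged
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(which.max(y))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Fit a Gaussian mixture model to the average spectrum
#'
#' The average spectrum is treated as a sample-weighted density over m/z.
#' Contiguous above-threshold signal regions are modelled independently by
#' expectation-maximization with peak-maxima initialization; the component
#' count per region is chosen by a BIC sweep around the number of local
#' maxima. Region models are concatenated into one ordered mixture whose
#' weights reflect each region's share of total ion current.
#'
#' @param avg An `average_spectrum` (from [average_spectrum()]), or a list
#'   with numeric `mz` and `intensity`.
#' @param max_components Upper bound on components per region (default 12).
#' @param seed Integer seed (the fit is deterministic; the seed guards any
#'   fallback re-initialization).
#' @param signal_rel Signal threshold relative to the tallest bin
#'   (default 5e-4; the noise pedestal estimate usually dominates).
#' @param gap_da Gap (Da) below threshold tolerated inside one region
#'   (default 1.0, so isotope envelopes stay in one region).
#' @return A `gmm_model`: ordered components `(mean, sd, weight)`, filter
#'   flags (all `FALSE`), identity merge map, and per-region log-likelihood
#'   traces in `$ll_trace` (each non-decreasing).
#' @export
fit_gmm <- function(avg, max_components = 12, seed = 1,
                    signal_rel = 5e-4, gap_da = 1.0) {
  x <- avg$mz; y <- avg$intensity
  if (length(x) < 3) abort_msi("average spectrum too short")
  if (all(y <= 0)) abort_msi("average spectrum is all zero")
  step <- x[2] - x[1]
  # threshold above both a fraction of the tallest peak and the noise
  # pedestal (median + 5 MAD of the mostly-signal-free bins)
  floor_est <- stats::median(y) + 5 * stats::mad(y)
  thr <- max(signal_rel * max(y), floor_est)
  regs <- signal_regions(y, thr, gap_bins = max(1L, round(gap_da / step)))
  # pad each region so peak tails are inside
  pad <- max(2L, round(0.5 / step))  # extend regions ~0.5 Da for tails
  total_w <- sum(y[y > thr])
  mu_all <- sd_all <- w_all <- numeric(0)
  traces <- list()
  with_seed(seed, for (rg in regs) {
    i0 <- max(1L, rg[1] - pad); i1 <- min(length(x), rg[2] + pad)
    xs <- x[i0:i1]; ys <- y[i0:i1]
    wsum <- sum(ys)
    if (wsum <= 0) next
    # intensities act as pseudo-counts (TOF intensities scale with ion
    # counts), so the BIC sample size is the region's total intensity
    w <- ys
    W <- wsum
    mx <- local_maxima(ys)
    mx <- mx[ys[mx] > thr]
    if (!length(mx)) mx <- which.max(ys)
    n_max <- length(mx)
    # peak width from the half-height span of the tallest maximum
    top <- mx[which.max(ys[mx])]
    half <- ys[top] / 2
    wl <- top; while (wl > 1 && ys[wl - 1] >= half && ys[wl - 1] < ys[wl]) wl <- wl - 1L
    wr <- top; while (wr < length(ys) && ys[wr + 1] >= half && ys[wr + 1] < ys[wr]) wr <- wr + 1L
    sd_est <- max(step, (wr - wl + 1) * step / 2.355)
    region_bic <- function(fit) -2 * fit$ll + (3 * fit$k - 1) * log(W)
    # base fit at the visible maxima
    mu0 <- xs[sort(mx)]
    fit <- em_gauss_mix(xs, w, mu0, rep(sd_est, length(mu0)),
                        ys[sort(mx)] + 1e-12, sd_floor = step / 2)
    if (fit$k == 0) next
    best <- fit; best_bic <- region_bic(fit)
    # every above-threshold local maximum is direct evidence of a peak, so
    # the component count is floored at the maxima count; the BIC sweep
    # only arbitrates additional shoulder components.
    # grow greedily: add a component at the residual maximum, refit
    cur <- fit
    for (k in seq_len(min(max_components, n_max + 8) - fit$k)) {
      if (cur$k >= max_components) break
      f_model <- rowSums(vapply(seq_len(cur$k), function(j)
        cur$pi[j] * stats::dnorm(xs, cur$mu[j], cur$sd[j]),
        numeric(length(xs))))
      resid <- w - W * f_model / max(sum(f_model), 1e-300)
      jmax <- which.max(resid)
      if (resid[jmax] <= 0) break
      cur <- em_gauss_mix(xs, w, c(cur$mu, xs[jmax]),
                          c(cur$sd, min(sd_est, stats::median(cur$sd))),
                          c(cur$pi * W, max(sum(pmax(resid, 0)), 1e-6)),
                          sd_floor = step / 2)
      if (cur$k == 0) break
      bic <- region_bic(cur)
      if (bic < best_bic) { best <- cur; best_bic <- bic }
    }
    mu_all <- c(mu_all, best$mu)
    sd_all <- c(sd_all, best$sd)
    w_all <- c(w_all, best$pi * wsum)
    traces[[length(traces) + 1L]] <- best$ll_trace
  })
  if (!length(mu_all)) abort_msi("no signal regions found")
  w_all <- w_all / sum(w_all)
  model <- new_gmm_model(mu_all, sd_all, w_all,
                         params = list(signal_rel = signal_rel,
                                       gap_da = gap_da, step = step,
                                       mz_range = range(x), seed = seed))
  model$ll_trace <- traces
  model
}

#' Flag high-variance / low-amplitude components
#'
#' Flags are annotations only; no component is deleted. Amplitude is the
#' component's density apex height (weight / sd up to a constant).
#'
#' @param model A `gmm_model`.
#' @param sd_max Components with `sd > sd_max` are flagged `high_variance`.
#' @param weight_min Components with amplitude below `weight_min` times the
#'   maximum amplitude are flagged `low_amplitude` (0 disables).
#' @return The annotated model.
#' @export
filter_components <- function(model, sd_max = Inf, weight_min = 0) {
  stopifnot(inherits(model, "gmm_model"))
  if (!is.numeric(sd_max) || sd_max <= 0) abort_msi("sd_max must be > 0")
  if (!is.numeric(weight_min) || weight_min < 0)
    abort_msi("weight_min must be >= 0")
  amp <- component_amplitude(model)
  hv <- model$components$sd > sd_max
  la <- amp < weight_min * max(amp)
  model$filtered_out <- hv | la
  model$filter_reason <- ifelse(hv, "high_variance",
                                ifelse(la, "low_amplitude", NA_character_))
  model
}

#' Merge right-skew (isotope-satellite) components leftward
#'
#' A component is a right satellite when its mean lies within
#' `envelope_window` to the right of a larger-amplitude surviving major and
#' its amplitude is below `dominance_ratio` of that major's. Satellites map
#' (transitively, always leftward) onto the major component. Filtered-out
#' components take no part in merging.
#'
#' @param model A `gmm_model` (after [filter_components()], or directly
#'   after [fit_gmm()]).
#' @param envelope_window Window in Da (default 3.1, covering the +1/+2/+3
#'   isotope satellites of singly charged species).
#' @param dominance_ratio Amplitude ratio below which the right neighbour
#'   counts as a satellite (default 0.9).
#' @return The model with an updated merge map.
#' @export
merge_skewed <- function(model, envelope_window = 3.1, dominance_ratio = 0.9) {
  stopifnot(inherits(model, "gmm_model"))
  comps <- model$components
  amp <- component_amplitude(model)
  mm <- seq_len(nrow(comps))
  active <- which(!model$filtered_out)
  for (j in active) {
    left <- active[active < j & comps$mean[j] - comps$mean[active] <= envelope_window]
    if (!length(left)) next
    majors <- left[mm[left] == left]          # already-resolved majors
    for (i in rev(majors)) {                  # nearest major first
      if (amp[j] < dominance_ratio * amp[i]) { mm[j] <- i; break }
    }
  }
  model$merge_map <- mm
  model
}

#' Quantify component abundances in every pixel
#'
#' The abundance of surviving component c in pixel p is the inner product
#' of the pixel spectrum with the component's unit-area Gaussian density
#' (satellite densities are folded into their merge target, weighted by
#' mixture weight), times the grid step:
#' `abundance(c, p) = sum_bins spectrum_p * phi_c * step`. Exactly linear
#' in the spectrum.
#'
#' @param model A `gmm_model` with >= 1 surviving component.
#' @param dataset Common-grid [spectra_dataset()] on the grid the model was
#'   fitted on.
#' @return A [feature_table()] (components x pixels), component ids = the
#'   surviving centre m/z values.
#' @export
quantify_abundances <- function(model, dataset) {
  stopifnot(inherits(model, "gmm_model"),
            inherits(dataset, "spectra_dataset"))
  if (!is_common_grid(dataset))
    abort_msi("dataset must be on a common grid")
  axis <- dataset$mz_axis
  surv <- which(surviving_components(model))
  if (!length(surv)) abort_msi("no surviving components")
  if (min(model$components$mean) < min(axis) - 1e-6 ||
      max(model$components$mean) > max(axis) + 1e-6)
    abort_msi("model and dataset m/z grids do not match")
  step <- axis[2] - axis[1]
  nbin <- length(axis)
  D <- matrix(0, length(surv), nbin)
  for (s in seq_along(surv)) {
    grp <- which(model$merge_map == surv[s] & !model$filtered_out)
    wts <- model$components$weight[grp]
    wts <- wts / sum(wts)
    for (gi in seq_along(grp)) {
      mu <- model$components$mean[grp[gi]]
      sdv <- model$components$sd[grp[gi]]
      lo <- max(1L, findInterval(mu - 8 * sdv, axis))
      hi <- min(nbin, findInterval(mu + 8 * sdv, axis) + 1L)
      D[s, lo:hi] <- D[s, lo:hi] + wts[gi] * stats::dnorm(axis[lo:hi], mu, sdv)
    }
  }
  ab <- D %*% t(dataset$intensities) * step
  feature_table(component_ids = model$components$mean[surv],
                abundances = ab, domain = dataset$domain,
                coords = dataset$coords)
}
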