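# Hartigan & Hartigan's dip statistic for unimodality, with a Monte-Carlo
# calibrated test under the uniform null (the least favourable unimodal
# distribution). Used as the stopping rule of the divisive segmentation.

#' Dip statistic of a sample
#'
#' The maximum difference between the empirical distribution function and
#' the closest unimodal distribution function. For every candidate mode
#' position j the minimal one-sided sup-error of a convex (left) fit is
#' half the largest deviation of the empirical upper step values above the
#' greatest convex minorant of the lower step values over points 1..j
#' (mirrored with the least concave majorant on the right); the dip is the
#' minimum over j of the larger one-sided error. Both hull passes are
#' incremental, so the whole computation is one left-to-right and one
#' right-to-left sweep.
#'
#' @param x Numeric sample (n >= 4 for a meaningful value).
#' @return The dip statistic (0 when all values coincide).
#' @details The statistic equals the definitional minimum sup-distance to a
#'   unimodal distribution function (verified against a brute-force
#'   feasibility search); implementations based on the classical AS 217
#'   order-statistic interpolation can differ by O(1/n). The Monte-Carlo
#'   null of [dip_test()] is built from this same statistic, so the test is
#'   exactly calibrated.
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 2 || !any(x != x[1])) return(0)
  tb <- table(x)
  xs <- as.numeric(names(tb))
  cnt <- as.integer(tb)
  m <- length(xs)
  cum <- cumsum(cnt)
  lo <- (cum - cnt) / n   # F(x_i-): value just below x_i
  hi <- cum / n           # F(x_i): value at x_i

  # Left pass: interior misfit of a convex (left-of-mode) fit up to point j
  # = max_{i<j} (hi_i - gcm_j(xs_i)), gcm_j the greatest convex minorant of
  # {(xs_i, lo_i): i <= j}. A mode AT point j additionally pays the full
  # step cnt_j/n there (the fit must pass through the jump continuously);
  # a mode in the gap (j, j+1) avoids that but extends the hull with the
  # point (xs_{j+1}, hi_j).
  Dl <- numeric(m)    # mode at point j
  Dlg <- rep(Inf, m)  # mode in gap (j, j+1)
  st <- c(1L)         # hull vertex stack (indices into xs)
  md <- c(cnt[1] / n) # max deviation frozen at each vertex
  gap_dev <- function(st, md, xstar, ystar, ys_hull, dev_of) {
    # deviation after virtually extending the hull with (xstar, ystar)
    k <- length(st)
    while (k >= 2L) {
      a <- st[k - 1L]; b <- st[k]
      if ((ystar - ys_hull[b]) * (xs[b] - xs[a]) >
          (ys_hull[b] - ys_hull[a]) * (xstar - xs[b])) break
      k <- k - 1L
    }
    v <- st[k]
    dev <- md[k]
    jj <- which(xs > xs[v] & xs < xstar)
    if (length(jj)) {
      fit <- ys_hull[v] + (xs[jj] - xs[v]) * (ystar - ys_hull[v]) /
        (xstar - xs[v])
      dev <- max(dev, max(dev_of(jj, fit)))
    }
    dev
  }
  Dl[1] <- cnt[1] / n
  Dlg[1] <- if (m > 1)
    gap_dev(st, md, xs[2], hi[1], lo, function(jj, fit) hi[jj] - fit) else Inf
  for (j in seq_len(m)[-1]) {
    while (length(st) >= 2L) {
      k <- length(st)
      a <- st[k - 1L]; b <- st[k]
      # pop b while it violates convexity against the incoming point j
      if ((lo[j] - lo[b]) * (xs[b] - xs[a]) >
          (lo[b] - lo[a]) * (xs[j] - xs[b])) break
      st <- st[-k]; md <- md[-k]
    }
    v <- st[length(st)]
    dev <- md[length(md)]
    if (j - v > 1L) {
      ii <- (v + 1L):(j - 1L)
      fit <- lo[v] + (xs[ii] - xs[v]) * (lo[j] - lo[v]) / (xs[j] - xs[v])
      dev <- max(dev, max(hi[ii] - fit))
    }
    dev <- max(dev, cnt[j] / n)   # a continuous fit pays the full step here
    st <- c(st, j); md <- c(md, dev)
    Dl[j] <- dev
    if (j < m)
      Dlg[j] <- gap_dev(st, md, xs[j + 1], hi[j], lo,
                        function(jj, fit) hi[jj] - fit)
  }

  # Right pass, mirrored: least concave majorant of {(xs_i, hi_i): i >= j},
  # misfit against the uppers lo_i.
  Dr <- numeric(m)
  Drg <- rep(Inf, m)  # mode in gap (j, j+1), paired with right part from j+1
  st <- c(m); md <- c(cnt[m] / n)
  gap_dev_r <- function(st, md, xstar, ystar) {
    k <- length(st)
    while (k >= 2L) {
      a <- st[k - 1L]; b <- st[k]
      if ((hi[b] - ystar) * (xs[a] - xs[b]) >
          (hi[a] - hi[b]) * (xs[b] - xstar)) break
      k <- k - 1L
    }
    v <- st[k]
    dev <- md[k]
    jj <- which(xs > xstar & xs < xs[v])
    if (length(jj)) {
      fit <- ystar + (xs[jj] - xstar) * (hi[v] - ystar) / (xs[v] - xstar)
      dev <- max(dev, max(fit - lo[jj]))
    }
    dev
  }
  Dr[m] <- cnt[m] / n
  if (m > 1) Drg[m - 1] <- gap_dev_r(st, md, xs[m - 1], lo[m])
  for (j in rev(seq_len(m))[-1]) {
    while (length(st) >= 2L) {
      k <- length(st)
      a <- st[k - 1L]; b <- st[k]
      if ((hi[b] - hi[j]) * (xs[a] - xs[b]) >
          (hi[a] - hi[b]) * (xs[b] - xs[j])) break
      st <- st[-k]; md <- md[-k]
    }
    v <- st[length(st)]
    dev <- md[length(md)]
    if (v - j > 1L) {
      ii <- (j + 1L):(v - 1L)
      fit <- hi[j] + (xs[ii] - xs[j]) * (hi[v] - hi[j]) / (xs[v] - xs[j])
      dev <- max(dev, max(fit - lo[ii]))
    }
    dev <- max(dev, cnt[j] / n)
    st <- c(st, j); md <- c(md, dev)
    Dr[j] <- dev
    if (j > 1) Drg[j - 1] <- gap_dev_r(st, md, xs[j - 1], lo[j])
  }

  cand <- min(pmax(Dl, Dr))
  if (m > 1) cand <- min(cand, min(pmax(Dlg[-m], Drg[-m])))
  max(cand, 1 / n) / 2
}

# Monte-Carlo null table of dip statistics for uniform samples of size n,
# cached per (n, B); deterministic (internal seed derived from n).
dip_null_env <- new.env(parent = emptyenv())

dip_null_table <- function(n, B = 200L) {
  key <- paste0("n", n, "_B", B)
  tab <- dip_null_env[[key]]
  if (is.null(tab)) {
    tab <- with_seed(1000003L + (n %% 99991L), {
      vapply(seq_len(B), function(b) dip_statistic(stats::runif(n)),
             numeric(1))
    })
    dip_null_env[[key]] <- tab
  }
  tab
}

#' Dip test p-value (uniform-null Monte Carlo)
#'
#' @param x Numeric sample.
#' @param B Monte-Carlo replicates (default 200).
#' @return List with `statistic` and `p.value`.
#' @export
dip_test <- function(x, B = 200L) {
  stat <- dip_statistic(x)
  null <- dip_null_table(length(x[is.finite(x)]), B)
  list(statistic = stat, p.value = (1 + sum(null >= stat)) / (length(null) + 1))
}
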