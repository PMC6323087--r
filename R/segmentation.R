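# Unsupervised molecular-image segmentation: recursive (divisive) 2-means
# with data-driven stopping (minimum cluster size, unimodal intra-cluster
# distance distribution).

#' Unimodality stopping check
#'
#' Computes the Euclidean distances of member pixels to their centroid and
#' dip-tests that distance distribution. Returns `TRUE` ("stop, this node
#' is coherent") when the test fails to reject unimodality at `alpha`.
#' Samples larger than `max_n` are thinned to evenly spaced order
#' statistics before testing (the dip depends on distributional shape, not
#' sample size, and the Monte-Carlo null is cached per size).
#'
#' @param pixels Numeric matrix, one row per pixel (abundance rows).
#' @param alpha Significance level (default 0.05).
#' @param max_n Size cap for the dip computation (default 512); larger
#'   nodes are randomly subsampled (deterministically) so the cached
#'   iid-uniform null stays valid.
#' @return `TRUE` to stop splitting, `FALSE` otherwise.
#' @export
unimodality_check <- function(pixels, alpha = 0.05, max_n = 512L) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 4) abort_msi("unimodality check needs >= 4 pixels")
  ctr <- colMeans(pixels)
  d <- sqrt(rowSums((pixels - rep(ctr, each = nrow(pixels)))^2))
  if (max(d) - min(d) < 1e-12 * (abs(max(d)) + 1e-300)) return(TRUE)
  if (length(d) > max_n)
    d <- with_seed(3000017L + length(d) %% 9973L,
                   d[sample.int(length(d), max_n)])
  dip_test(d)$p.value >= alpha
}

# k-means++ seeding followed by Lloyd iterations, best of `nstart` restarts
kmeans2 <- function(xm, nstart = 10L) {
  n <- nrow(xm)
  best <- NULL
  for (s in seq_len(nstart)) {
    c1 <- xm[sample.int(n, 1L), ]
    d2 <- rowSums((xm - rep(c1, each = n))^2)
    if (all(d2 == 0)) return(list(cluster = rep(1L, n)))
    c2 <- xm[sample.int(n, 1L, prob = d2 / sum(d2)), ]
    km <- suppressWarnings(
      stats::kmeans(xm, centers = rbind(c1, c2), iter.max = 50L,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Divisive k-means segmentation of a molecular image
#'
#' Recursively splits the pixel set by 2-means (k-means++ seeding, 10
#' restarts, Euclidean metric on log-transformed abundances). At each node
#' the features are filtered locally: components whose within-node
#' coefficient of variation falls below the node median CV are dropped
#' before clustering. Splitting stops when a node holds fewer than
#' `min_cluster_frac` of all pixels or when its intra-cluster distance
#' distribution is unimodal ([unimodality_check()]).
#'
#' @param table A [feature_table()] with >= 2 pixels.
#' @param min_cluster_frac Minimum cluster size as a fraction of all pixels
#'   (default 0.01, i.e. 1% of the tissue).
#' @param seed Integer seed (segmentation is deterministic given it).
#' @param alpha Dip-test significance for the unimodality stop.
#' @return A `segmentation_result`: `cluster_id` (per-pixel integer
#'   labels), `split_tree` (data frame of nodes with sizes, depths and stop
#'   reasons), `summary` (see [summarize_segments()]).
#' @export
divik_segment <- function(table, min_cluster_frac = 0.01, seed = 1,
                          alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (ncol(table$abundances) < 2) abort_msi("need at least 2 pixels")
  check_scalar_number(min_cluster_frac, "min_cluster_frac", 0, 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  xm <- t(log1p(table$abundances))    # pixels x components, log scale
  n <- nrow(xm)
  min_size <- min_cluster_frac * n
  cluster <- integer(n)
  nodes <- list()
  next_cluster <- 0L

  recurse <- function(idx, depth, node_id) {
    size <- length(idx)
    stop_reason <- NULL
    if (size < max(min_size, 4)) {
      stop_reason <- "too_small"
    } else {
      sub <- xm[idx, , drop = FALSE]
      # the stop rule sees the node's full distance distribution
      if (unimodality_check(sub, alpha)) {
        stop_reason <- "unimodal"
      } else {
        # local feature filtering for the split: keep components whose
        # within-node CV (linear scale) is at or above the node median
        a <- table$abundances[, idx, drop = FALSE]
        mu <- rowMeans(a)
        cv <- ifelse(mu > 0,
                     sqrt(pmax(rowMeans(a^2) - mu^2, 0)) / mu, 0)
        keep <- cv >= stats::median(cv)
        if (!any(keep)) keep <- rep(TRUE, length(keep))
        km <- kmeans2(sub[, keep, drop = FALSE])
        if (length(unique(km$cluster)) < 2L) {
          stop_reason <- "unimodal"
        } else {
          nodes[[length(nodes) + 1L]] <<- data.frame(
            node = node_id, size = size, depth = depth,
            stop_reason = "split", stringsAsFactors = FALSE)
          recurse(idx[km$cluster == 1L], depth + 1L, 2L * node_id)
          recurse(idx[km$cluster == 2L], depth + 1L, 2L * node_id + 1L)
          return(invisible())
        }
      }
    }
    next_cluster <<- next_cluster + 1L
    cluster[idx] <<- next_cluster
    nodes[[length(nodes) + 1L]] <<- data.frame(
      node = node_id, size = size, depth = depth,
      stop_reason = stop_reason, stringsAsFactors = FALSE)
    invisible()
  }
  with_seed(seed, recurse(seq_len(n), 0L, 1L))
  res <- structure(list(cluster_id = cluster,
                        split_tree = do.call(rbind, nodes),
                        coords = table$coords),
                   class = "segmentation_result")
  res$summary <- summarize_segments(res)
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  s <- x$summary
  cat("<segmentation_result> ", s$n_clusters, " clusters; avg ",
      s$avg_size_pct, "%, largest ", s$largest_size_pct, "%\n", sep = "")
  invisible(x)
}

#' Cluster-size summary of a segmentation
#'
#' @param result A `segmentation_result`.
#' @return List with `n_clusters`, `avg_size_pct` and `largest_size_pct`
#'   (percentages of all pixels, reported to 2 decimals).
#' @export
summarize_segments <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  sizes <- table(result$cluster_id)
  n <- length(result$cluster_id)
  list(n_clusters = length(sizes),
       avg_size_pct = round(100 * mean(sizes) / n, 2),
       largest_size_pct = round(100 * max(sizes) / n, 2))
}

# Adjusted Rand index between two labelings (used by tests and phantom
# audits; exported because recovering a planted region map is a first-class
# phantom measurement).

#' Adjusted Rand index
#'
#' @param a,b Two labelings of the same items.
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
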