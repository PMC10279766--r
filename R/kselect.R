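#' Mean silhouette width of a clustering
#'
#' The standard silhouette: for point i with mean intra-cluster distance a
#' (excluding itself) and b the minimum over other clusters of the mean
#' distance to that cluster's members, s(i) = (b - a) / max(a, b). Points
#' in singleton clusters contribute s(i) = 0, as do points for which both
#' a and b are zero. Distances are plain Euclidean.
#'
#' @param x coordinates accepted by [as_points()], or an `iso_kmeans`
#'   object (then `cluster` may be omitted).
#' @param cluster integer cluster assignment, or an `iso_kmeans` object.
#' @return mean silhouette width in \[-1, 1\], with the per-point widths in
#'   attribute `widths`.
#' @export
silhouette_mean <- function(x, cluster = NULL) {
  if (inherits(x, "iso_kmeans")) {
    pts <- x$points
    cl <- unname(x$cluster)
  } else {
    pts <- as_points(x)
    cl <- if (inherits(cluster, "iso_kmeans")) {
      unname(cluster$cluster)
    } else {
      as.integer(cluster)
    }
  }
  n <- nrow(pts)
  if (length(cl) != n) stop("assignment length does not match point count")
  ids <- unique(cl)
  if (length(ids) < 2L) stop("silhouette requires at least two clusters")
  D <- as.matrix(stats::dist(pts))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(cl == cl[i]), i)
    if (!length(own)) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(ids, cl[i]),
                    function(j) mean(D[i, cl == j]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  structure(mean(s), widths = s)
}

#' Gap statistic for choosing the number of clusters
#'
#' Tibshirani-style gap statistic with a uniform reference distribution
#' over the axis-aligned bounding box of the data:
#' `Gap(k) = mean_b log(WSS*_b(k)) - log(WSS(k))`, with standard error
#' `s_k = sd_b(log WSS*) * sqrt(1 + 1/B)`. The chosen k is the smallest k
#' in the grid with `Gap(k) >= Gap(k+1) - s_(k+1)` (the one-standard-error
#' rule), falling back to the largest k in the grid.
#'
#' @param x coordinates accepted by [as_points()].
#' @param k_grid ascending integer grid of cluster counts.
#' @param B number of uniform reference data sets; >= 10.
#' @param n_init k-means restarts per fit (default 10; the reference fits
#'   dominate the cost, and planted-structure decisions are insensitive to
#'   more restarts at these problem sizes).
#' @param seed integer seed; fixing it makes the result bit-reproducible.
#' @param scale standardise axes first.
#' @return data frame with columns `k`, `logW`, `gap`, `se`, carrying the
#'   chosen k in attribute `chosen_k`.
#' @export
gap_statistic <- function(x, k_grid = 1:8, B = 50, n_init = 10,
                          seed = NULL, scale = FALSE) {
  pts <- as_points(x, scale = scale)
  if (B < 10) stop("B must be >= 10")
  if (nrow(unique(pts)) < 2L) {
    stop("degenerate data: all points are identical")
  }
  with_seed(seed, {
    logW <- log(vapply(.wss_scan(pts, k_grid, n_init), `[[`, 0, "wss"))
    if (any(!is.finite(logW))) {
      stop("zero within-cluster dispersion on the k_grid; reduce its ",
           "largest k below the number of distinct points")
    }
    rng <- apply(pts, 2, range)
    n <- nrow(pts)
    logWstar <- matrix(NA_real_, B, length(k_grid))
    for (b in seq_len(B)) {
      ref <- vapply(seq_len(ncol(pts)),
                    function(j) stats::runif(n, rng[1, j], rng[2, j]),
                    numeric(n))
      logWstar[b, ] <- log(vapply(.wss_scan(ref, k_grid, n_init),
                                  `[[`, 0, "wss"))
    }
    gap <- colMeans(logWstar) - logW
    se <- apply(logWstar, 2, stats::sd) * sqrt(1 + 1 / B)
    m <- length(k_grid)
    chosen <- k_grid[m]
    for (i in seq_len(m - 1L)) {
      if (gap[i] >= gap[i + 1L] - se[i + 1L]) {
        chosen <- k_grid[i]
        break
      }
    }
    out <- data.frame(k = k_grid, logW = logW, gap = gap, se = se)
    attr(out, "chosen_k") <- chosen
    attr(out, "B") <- B
    out
  })
}

#' Select the number of trophic guilds
#'
#' Runs the three standard diagnostics for the number of k-means clusters
#' on the same point set — the elbow (maximum curvature of the WSS curve),
#' the mean silhouette width (maximised over k >= 2), and the gap statistic
#' with its one-standard-error rule — and resolves disagreement by majority
#' vote, with ties going to the smallest k. All three per-k curves are
#' reported so the vote is transparent.
#'
#' @param x coordinates accepted by [as_points()].
#' @param k_grid ascending integer grid of cluster counts (default 1:8).
#' @param n_init k-means restarts per k for the WSS/silhouette scan.
#' @param B reference sets for the gap statistic.
#' @param gap_n_init restarts per fit inside the gap statistic.
#' @param seed integer seed (one seed drives the whole selection).
#' @param scale standardise axes first (recorded in the report).
#' @return object of class `iso_kselect`: `table` (per-k `wss`,
#'   `silhouette`, `gap`, `gap_se`), `chosen` (per-method and `consensus`),
#'   `k_grid`, `scaled`, `seed`.
#' @export
select_k <- function(x, k_grid = 1:8, n_init = 100, B = 50,
                     gap_n_init = 10, seed = NULL, scale = FALSE) {
  pts <- as_points(x, scale = scale)
  res <- with_seed(seed, {
    models <- .wss_scan(pts, k_grid, n_init)
    wss <- vapply(models, `[[`, 0, "wss")
    sil <- vapply(models, function(m) {
      if (m$k >= 2L) as.numeric(silhouette_mean(m)) else NA_real_
    }, 0)
    gap <- gap_statistic(pts, k_grid = k_grid, B = B, n_init = gap_n_init,
                         seed = NULL)
    list(wss = wss, sil = sil, gap = gap)
  })
  chosen_elbow <- .elbow_choice(k_grid, res$wss)
  chosen_sil <- if (all(is.na(res$sil))) NA_integer_ else
    k_grid[which.max(res$sil)]
  chosen_gap <- attr(res$gap, "chosen_k")
  votes <- c(elbow = chosen_elbow, silhouette = chosen_sil,
             gap = chosen_gap)
  votes_ok <- votes[!is.na(votes)]
  tab <- table(votes_ok)
  consensus <- min(as.integer(names(tab)[tab == max(tab)]))
  structure(
    list(
      table = data.frame(k = k_grid, wss = res$wss, silhouette = res$sil,
                         gap = res$gap$gap, gap_se = res$gap$se),
      chosen = list(elbow = chosen_elbow, silhouette = chosen_sil,
                    gap = chosen_gap, consensus = consensus),
      k_grid = k_grid, scaled = attr(pts, "scaled"), seed = seed
    ),
    class = "iso_kselect"
  )
}

#' @export
print.iso_kselect <- function(x, ...) {
  cat("Cluster-count selection (",
      if (isTRUE(x$scaled)) "standardised" else "raw per-mil",
      " axes)\n", sep = "")
  tab <- x$table
  tab$wss <- round_half_up(tab$wss, 3)
  tab$silhouette <- round_half_up(tab$silhouette, 3)
  tab$gap <- round_half_up(tab$gap, 3)
  tab$gap_se <- round_half_up(tab$gap_se, 3)
  print(tab, row.names = FALSE)
  cat("chosen k — elbow:", x$chosen$elbow,
      " silhouette:", x$chosen$silhouette,
      " gap:", x$chosen$gap,
      " consensus:", x$chosen$consensus, "\n")
  invisible(x)
}
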