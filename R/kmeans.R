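#' Coerce input to an isotope coordinate matrix
#'
#' Accepts a two-column numeric matrix, a group-summary data frame
#' (columns `mean_d13C`, `mean_d15N`) or a measurement data frame (columns
#' `d13C`, `d15N`) and returns an n x 2 matrix of (d13C, d15N) coordinates,
#' with labels as row names when available. Optionally standardises each
#' axis to zero mean and unit variance; the flag is recorded in the
#' `"scaled"` attribute so reports can state whether raw per-mil values
#' were clustered.
#'
#' @param x matrix or data frame as described.
#' @param scale standardise the axes (default `FALSE`: cluster raw per-mil
#'   values).
#' @return numeric matrix with attribute `scaled`.
#' @export
as_points <- function(x, scale = FALSE) {
  if (is.matrix(x)) {
    pts <- x
  } else if (is.data.frame(x)) {
    if (all(c("mean_d13C", "mean_d15N") %in% names(x))) {
      pts <- cbind(d13C = x$mean_d13C, d15N = x$mean_d15N)
    } else if (all(c("d13C", "d15N") %in% names(x))) {
      pts <- cbind(d13C = x$d13C, d15N = x$d15N)
    } else {
      stop("cannot interpret 'x' as isotope coordinates")
    }
    if ("label" %in% names(x)) rownames(pts) <- x$label
  } else {
    stop("'x' must be a matrix or data frame of coordinates")
  }
  storage.mode(pts) <- "double"
  if (nrow(pts) < 1L) stop("at least one point is required")
  if (!all(is.finite(pts))) stop("non-finite coordinates")
  if (isTRUE(scale)) {
    pts <- base::scale(pts)
    attr(pts, "scaled:center") <- NULL
    attr(pts, "scaled:scale") <- NULL
  }
  attr(pts, "scaled") <- isTRUE(scale)
  pts
}

# squared Euclidean distances between rows of x and rows of centers
.dist2 <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to the squared distance to the nearest chosen centre
.kmeanspp <- function(pts, k) {
  n <- nrow(pts)
  centers <- pts[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2min <- do.call(pmin, as.data.frame(.dist2(pts, centers)))
    i <- if (sum(d2min) <= 0) {
      sample.int(n, 1L)
    } else {
      sample.int(n, 1L, prob = d2min)
    }
    centers <- rbind(centers, pts[i, , drop = FALSE])
  }
  centers
}

# Lloyd iterations from given centres; returns a converged solution in
# which every point sits in its nearest cluster (ties to the lowest index)
# and every centre is the mean of its members. Empty clusters are repaired
# by re-seeding on the point farthest from its current centre.
.lloyd <- function(pts, centers, max_iter = 100, tol = 1e-10) {
  n <- nrow(pts)
  k <- nrow(centers)
  assign_prev <- integer(0)
  it <- 0L
  repeat {
    d2 <- .dist2(pts, centers)
    cl <- max.col(-d2, ties.method = "first")
    repeat {
      empty <- setdiff(seq_len(k), unique(cl))
      if (!length(empty)) break
      far <- which.max(d2[cbind(seq_len(n), cl)])
      centers[empty[1L], ] <- pts[far, ]
      d2 <- .dist2(pts, centers)
      cl <- max.col(-d2, ties.method = "first")
    }
    if (identical(cl, assign_prev) || it >= max_iter) break
    new_centers <- centers
    for (j in seq_len(k)) {
      new_centers[j, ] <- colMeans(pts[cl == j, , drop = FALSE])
    }
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    assign_prev <- cl
    it <- it + 1L
    if (shift < tol) {
      d2 <- .dist2(pts, centers)
      cl <- max.col(-d2, ties.method = "first")
      break
    }
  }
  wss_i <- d2[cbind(seq_len(n), cl)]
  withinss <- vapply(seq_len(k), function(j) sum(wss_i[cl == j]), 0)
  list(centers = centers, assign = cl, wss = sum(wss_i),
       withinss = withinss, iter = it)
}

#' Fit k-means to isotope coordinates
#'
#' Lloyd's algorithm from k-means++ seeding, keeping the best of `n_init`
#' restarts by total within-cluster sum of squares (squared Euclidean
#' distance in per-mil squared). Deterministic given `seed`; empty clusters
#' are repaired by re-seeding on the point farthest from its centre.
#'
#' @param x coordinates accepted by [as_points()].
#' @param k number of clusters; `1 <= k <=` number of distinct points.
#' @param n_init number of k-means++ restarts (default 100).
#' @param seed integer seed; required for reproducibility, `NULL` uses the
#'   current RNG stream.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param tol centroid-shift convergence threshold (per mil).
#' @param scale standardise axes before clustering (default `FALSE`).
#' @param extra_inits optional list of k x 2 centre matrices to try in
#'   addition to the random restarts (used internally for warm starts).
#' @return object of class `iso_kmeans`: `k`, `centers`, `cluster` (named
#'   1-based assignment), `wss`, `withinss`, `iterations`, `n_init`,
#'   `seed`, `scaled`, and the `points` matrix used.
#' @examples
#' pts <- rbind(matrix(rnorm(10, 0, .1), 5), matrix(rnorm(10, 5, .1), 5))
#' m <- kmeans_fit(pts, 2, n_init = 10, seed = 1)
#' m$k
#' @export
kmeans_fit <- function(x, k, n_init = 100, seed = NULL, max_iter = 100,
                       tol = 1e-10, scale = FALSE, extra_inits = NULL) {
  pts <- as_points(x, scale = scale)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be a single positive integer")
  }
  k <- as.integer(k)
  n_distinct <- nrow(unique(pts))
  if (k > n_distinct) {
    stop("k (", k, ") exceeds the number of distinct points (",
         n_distinct, ")")
  }
  fit <- with_seed(seed, {
    if (k == 1L) {
      ctr <- matrix(colMeans(pts), 1L, ncol(pts),
                    dimnames = list(NULL, colnames(pts)))
      wss_i <- .dist2(pts, ctr)[, 1L]
      list(centers = ctr, assign = rep(1L, nrow(pts)), wss = sum(wss_i),
           withinss = sum(wss_i), iter = 0L)
    } else {
      best <- NULL
      for (i in seq_len(n_init)) {
        cand <- .lloyd(pts, .kmeanspp(pts, k), max_iter, tol)
        if (is.null(best) || cand$wss < best$wss) best <- cand
      }
      for (ctr in extra_inits) {
        cand <- .lloyd(pts, ctr, max_iter, tol)
        if (cand$wss < best$wss) best <- cand
      }
      best
    }
  })
  structure(
    list(k = k, centers = fit$centers,
         cluster = stats::setNames(fit$assign, rownames(pts)),
         wss = fit$wss, withinss = fit$withinss, iterations = fit$iter,
         n_init = n_init, seed = seed, scaled = attr(pts, "scaled"),
         points = pts),
    class = "iso_kmeans"
  )
}

#' @export
print.iso_kmeans <- function(x, ...) {
  cat("k-means fit: k =", x$k, "on", nrow(x$points), "points",
      if (isTRUE(x$scaled)) "(standardised axes)" else "(raw per-mil axes)",
      "\n")
  cat("  total WSS:", format(x$wss), " cluster sizes:",
      paste(tabulate(x$cluster, x$k), collapse = ", "), "\n")
  invisible(x)
}

# greedily extend a centre set to k centres with farthest-point choices;
# Lloyd started from this configuration can only lower the WSS of the
# smaller solution, guaranteeing a non-increasing WSS curve across k
.farthest_augment <- function(pts, centers, k) {
  while (nrow(centers) < k) {
    d2min <- do.call(pmin, as.data.frame(.dist2(pts, centers)))
    centers <- rbind(centers, pts[which.max(d2min), , drop = FALSE])
  }
  centers
}

# fit every k in an ascending grid, warm-starting each k from the previous
# best solution augmented with farthest points (consumes the current RNG
# stream; wrap in with_seed for determinism)
.wss_scan <- function(pts, k_grid, n_init, max_iter = 100, tol = 1e-10) {
  if (is.unsorted(k_grid, strictly = TRUE)) {
    stop("k_grid must be sorted ascending without duplicates")
  }
  models <- vector("list", length(k_grid))
  prev <- NULL
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    extra <- if (!is.null(prev) && prev$k < k) {
      list(.farthest_augment(pts, prev$centers, k))
    } else {
      NULL
    }
    models[[i]] <- kmeans_fit(pts, k, n_init = n_init, seed = NULL,
                              max_iter = max_iter, tol = tol,
                              extra_inits = extra)
    prev <- models[[i]]
  }
  models
}

#' Within-cluster sum-of-squares curve and elbow suggestion
#'
#' Fits k-means for every k in `k_grid` and returns the WSS curve. The
#' curve is guaranteed non-increasing in k (each fit is warm-started from
#' the previous one in addition to its random restarts). The elbow
#' suggestion is the k maximising the second difference of the log-WSS
#' curve — the point of maximum relative-drop curvature, a documented
#' heuristic (on the raw curve the first large drop dominates whenever the
#' one-cluster dispersion is large, regardless of structure). It needs at
#' least three grid points.
#'
#' @param x coordinates accepted by [as_points()].
#' @param k_grid ascending integer grid of cluster counts.
#' @param n_init restarts per k.
#' @param seed integer seed for reproducibility.
#' @param scale standardise axes first.
#' @return data frame with columns `k` and `wss`, with attribute
#'   `elbow_k` (the suggestion, `NA` if the grid is too short) and
#'   attribute `models` (the fitted `iso_kmeans` objects).
#' @export
elbow_wss <- function(x, k_grid = 1:8, n_init = 100, seed = NULL,
                      scale = FALSE) {
  pts <- as_points(x, scale = scale)
  models <- with_seed(seed, .wss_scan(pts, k_grid, n_init))
  wss <- vapply(models, `[[`, 0, "wss")
  out <- data.frame(k = k_grid, wss = wss)
  attr(out, "elbow_k") <- .elbow_choice(k_grid, wss)
  attr(out, "models") <- models
  out
}

.elbow_choice <- function(k_grid, wss) {
  m <- length(k_grid)
  if (m < 3L) return(NA_integer_)
  # curvature of the log curve; zero WSS (k = n distinct points) guarded
  lw <- log(pmax(wss, 1e-12 * max(wss, 1)))
  inner <- 2:(m - 1L)
  d2 <- lw[inner - 1L] - 2 * lw[inner] + lw[inner + 1L]
  k_grid[inner[which.max(d2)]]
}
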