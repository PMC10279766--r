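# Independent oracles and small data builders used across the suite.

# build a measurement table from parallel vectors
make_measurements <- function(label, d13C, d15N, compartment = "fauna",
                              depth_m = NA_real_) {
  data.frame(
    sample_id = paste0("s", seq_along(d13C)),
    label = label, compartment = compartment, depth_m = depth_m,
    n_replicates = 1L, d13C = d13C, d15N = d15N,
    stringsAsFactors = FALSE
  )
}

# exhaustive-search k-means oracle: minimum WSS over every assignment of
# n points to k clusters (empty clusters never beat non-empty ones, so
# enumerating all k^n label vectors covers the optimum)
brute_force_kmeans <- function(pts, k) {
  n <- nrow(pts)
  stopifnot(n <= 8)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best_wss <- Inf
  best_assign <- NULL
  for (r in seq_len(nrow(grid))) {
    asg <- grid[r, ]
    wss <- 0
    for (j in unique(asg)) {
      m <- pts[asg == j, , drop = FALSE]
      ctr <- colMeans(m)
      wss <- wss + sum(sweep(m, 2, ctr)^2)
    }
    if (wss < best_wss) {
      best_wss <- wss
      best_assign <- asg
    }
  }
  list(wss = best_wss, assign = best_assign)
}

# two partitions describe the same grouping up to label permutation
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# hand-rolled silhouette oracle (independent loop-based formulation)
silhouette_oracle <- function(pts, cl) {
  n <- nrow(pts)
  ed <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(sapply(own, ed, i = i))
    b <- Inf
    for (j in setdiff(unique(cl), cl[i])) {
      b <- min(b, mean(sapply(which(cl == j), ed, i = i)))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# four well-separated planted centres (all pairwise distances >= 10;
# deliberately irregular — on a perfectly symmetric square the k = 2
# partition removes exactly the uniform-reference share of dispersion and
# no k-selection heuristic can see past it)
blob_centers4 <- rbind(c(0, 0), c(11, 2), c(3, 12), c(14, 13))

# isotropic Gaussian blobs around given centres
make_blobs <- function(centers, n_per = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
}
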