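#' Total isotopic ranges of a food web
#'
#' The extent (max minus min) of the group mean values along each isotope
#' axis, over all groups including the particulate organic matter pools.
#'
#' @param groups data frame of group summaries.
#' @return named vector `c(c_range, n_range)` in per mil.
#' @examples
#' isotopic_ranges(angola_reef_groups()) # 9.65 and 19.9
#' @export
isotopic_ranges <- function(groups) {
  if (!is.data.frame(groups) || nrow(groups) == 0L) {
    stop("at least one group is required")
  }
  c(c_range = diff(range(groups$mean_d13C)),
    n_range = diff(range(groups$mean_d15N)))
}

#' Distance between two cluster centroids in isotope space
#'
#' Per-axis differences of the mean stable isotope ratios of two guild
#' summaries, returned as absolute magnitudes with the direction (sign of
#' `j - i`) recorded in the `direction` attribute.
#'
#' @param summary_i,summary_j one-row data frames (or named lists) with
#'   `mean_d13C` and `mean_d15N`.
#' @return named vector `c(d13C, d15N)` of absolute per-mil differences.
#' @examples
#' cluster_distance(list(mean_d13C = -21.57, mean_d15N = 4.83),
#'                  list(mean_d13C = -18.70, mean_d15N = 12.90))
#' @export
cluster_distance <- function(summary_i, summary_j) {
  pick <- function(s, f) {
    v <- s[[f]]
    if (is.null(v) || !length(v)) stop("missing field '", f, "'")
    as.numeric(v[1])
  }
  dc <- pick(summary_j, "mean_d13C") - pick(summary_i, "mean_d13C")
  dn <- pick(summary_j, "mean_d15N") - pick(summary_i, "mean_d15N")
  structure(c(d13C = abs(dc), d15N = abs(dn)),
            direction = c(d13C = sign(dc), d15N = sign(dn)))
}

#' Convert a d15N difference to trophic levels
#'
#' Divides a d15N gap by the per-step trophic enrichment factor. By
#' construction this is consistent with [trophic_position()]:
#' `TP(x) - TP(y) = gap_to_trophic_levels(x - y)`.
#'
#' @param delta_d15N per-mil d15N difference(s).
#' @param tef a [tef_config()] (or a single d15N enrichment value).
#' @return dimensionless number of trophic levels.
#' @examples
#' gap_to_trophic_levels(8.07) # 2.37 at 2 dp
#' @export
gap_to_trophic_levels <- function(delta_d15N, tef = tef_config()) {
  tef <- as_tef(tef)
  delta_d15N / tef$tef_n
}

#' Pearson correlation between the two isotope axes
#'
#' Product-moment correlation with the usual Student-t test:
#' `t = r * sqrt((n - 2) / (1 - r^2))`, two-sided p from a t distribution
#' with n - 2 degrees of freedom (computed via [stats::cor.test()]). The
#' display value of p is floored at the conventional `< 2.2e-16`.
#'
#' @param x,y numeric vectors of equal length (n >= 3), e.g. d13C and d15N.
#' @return list with `r`, `t_stat`, `df`, `p`, `p_display`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("at least 3 observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  p <- ct$p.value
  list(
    r = unname(ct$estimate),
    t_stat = unname(ct$statistic),
    df = n - 2L,
    p = p,
    p_display = if (p < 2.2e-16) "< 2.2e-16" else
      format(p, digits = 4),
    n = n
  )
}

#' Whole-web summary metrics
#'
#' Bundles the web-level quantities: total isotopic ranges, the d13C/d15N
#' Pearson correlation across group means, and — when a guild summary is
#' supplied — all pairwise inter-guild centroid distances with their d15N
#' gaps converted to trophic levels.
#'
#' @param groups data frame of group summaries (all compartments).
#' @param guilds optional guild summary from [summarize_clusters()].
#' @param tef a [tef_config()].
#' @return object of class `web_metrics`: `c_range`, `n_range`, `pearson`,
#'   `cluster_distances` (data frame or `NULL`), `n_obs`.
#' @export
web_metrics <- function(groups, guilds = NULL, tef = tef_config()) {
  tef <- as_tef(tef)
  rng <- isotopic_ranges(groups)
  pear <- pearson_correlation(groups$mean_d13C, groups$mean_d15N)
  dists <- NULL
  if (!is.null(guilds) && nrow(guilds) >= 2L) {
    pairs <- utils::combn(guilds$cluster, 2)
    dists <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]
      j <- pairs[2, p]
      d <- cluster_distance(guilds[guilds$cluster == i, ],
                            guilds[guilds$cluster == j, ])
      data.frame(cluster_i = i, cluster_j = j,
                 delta_d13C = d[["d13C"]], delta_d15N = d[["d15N"]],
                 trophic_levels = gap_to_trophic_levels(d[["d15N"]], tef))
    }))
  }
  structure(
    list(c_range = rng[["c_range"]], n_range = rng[["n_range"]],
         pearson = pear, cluster_distances = dists, n_obs = nrow(groups)),
    class = "web_metrics"
  )
}

#' @export
print.web_metrics <- function(x, ...) {
  cat("Food-web metrics over", x$n_obs, "groups\n")
  cat("  isotopic ranges:", round_half_up(x$c_range), "per mil (d13C),",
      round_half_up(x$n_range), "per mil (d15N)\n")
  cat("  Pearson r(d13C, d15N) =", round_half_up(x$pearson$r),
      " p", if (startsWith(x$pearson$p_display, "<")) "" else "=",
      x$pearson$p_display, "\n")
  if (!is.null(x$cluster_distances)) {
    cat("  inter-guild distances:\n")
    d <- x$cluster_distances
    d[3:5] <- lapply(d[3:5], round_half_up)
    print(d, row.names = FALSE)
  }
  invisible(x)
}
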