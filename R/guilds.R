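#' Summarise trophic guilds
#'
#' Per-cluster summary statistics over member group means: n, mean and
#' sample standard deviation of each isotope axis, mean and standard
#' deviation of the members' trophic positions (where available — the
#' particulate organic matter cluster has none), and the member labels.
#' Clusters are relabelled 1..k by ascending mean d15N, so cluster 1 is
#' the baseline-like (POM) guild and the highest-d15N guild comes last.
#'
#' @param groups data frame of group summaries, in the same row order as
#'   the points the clustering was fitted to.
#' @param model an `iso_kmeans` fit, or an integer cluster assignment of
#'   the same length as `nrow(groups)`.
#' @param tp optional trophic position table from [tp_table()]; matched to
#'   members by label.
#' @return data frame with columns `cluster`, `n`, `mean_d13C`, `sd_d13C`,
#'   `mean_d15N`, `sd_d15N`, `mean_tp`, `sd_tp`, `members`; the relabelled
#'   per-group assignment is in attribute `assignment` (named by label).
#' @examples
#' groups <- angola_reef_groups()
#' published <- angola_reef_clusters()
#' asg <- published$cluster[match(groups$label, published$label)]
#' summarize_clusters(groups, asg, tp_table(groups, 4.23))
#' @export
summarize_clusters <- function(groups, model, tp = NULL) {
  cl <- if (inherits(model, "iso_kmeans")) {
    unname(model$cluster)
  } else {
    as.integer(model)
  }
  if (length(cl) != nrow(groups)) {
    stop("assignment length does not match the number of groups")
  }
  ids <- sort(unique(cl))
  m15 <- vapply(ids, function(j) mean(groups$mean_d15N[cl == j]), 0)
  ord <- ids[order(m15)]
  new <- match(cl, ord)
  k <- length(ids)
  rows <- lapply(seq_len(k), function(g) {
    mem <- groups[new == g, , drop = FALSE]
    tpv <- if (!is.null(tp) && nrow(tp)) {
      tp$tp[match(mem$label, tp$label)]
    } else {
      rep(NA_real_, nrow(mem))
    }
    tpv_ok <- tpv[!is.na(tpv)]
    data.frame(
      cluster = g,
      n = nrow(mem),
      mean_d13C = mean(mem$mean_d13C),
      sd_d13C = sample_sd(mem$mean_d13C),
      mean_d15N = mean(mem$mean_d15N),
      sd_d15N = sample_sd(mem$mean_d15N),
      mean_tp = if (length(tpv_ok)) mean(tpv_ok) else NA_real_,
      sd_tp = sample_sd(tpv_ok),
      members = paste(mem$label, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "assignment") <- stats::setNames(new, groups$label)
  out
}
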