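#' Convert raw isotope ratios to delta notation
#'
#' Computes the per-mil deviation of a sample's heavy/light isotope ratio
#' (13C/12C or 15N/14N) from the international reference standard (VPDB for
#' carbon, atmospheric N2 for nitrogen):
#' \deqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000}
#' Exact arithmetic, no rounding.
#'
#' @param r_sample dimensionless heavy/light isotope ratio of the sample;
#'   strictly positive.
#' @param r_standard dimensionless ratio of the reference standard; strictly
#'   positive. Recycled against `r_sample`.
#' @return per-mil delta value(s).
#' @examples
#' delta_from_ratios(0.0112372, 0.0112372)        # 0
#' delta_from_ratios(0.98 * 0.0112372, 0.0112372) # -20
#' @export
delta_from_ratios <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard)) {
    stop("isotope ratios must be numeric")
  }
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0)) {
    stop("isotope ratios must be finite and strictly positive")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Validate a table of isotope measurements
#'
#' Checks and normalises a flat table of calibrated isotope observations.
#' Required columns: `sample_id`, `label`, `compartment`, `d13C`, `d15N`;
#' optional: `depth_m` (non-negative metres, may be missing) and
#' `n_replicates` (positive integer, default 1). The compartment must be one
#' of `fauna`, `spom`, `spom_trap`, `sediment`. Delta values must be finite;
#' values outside the plausibility window (-60 to 10 per mil for d13C, -20
#' to 40 per mil for d15N) raise a warning but are kept.
#'
#' @param x data frame of measurements.
#' @return the validated data frame with `depth_m` and `n_replicates`
#'   columns filled in.
#' @export
validate_measurements <- function(x) {
  if (!is.data.frame(x)) stop("measurements must be a data.frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("sample_id", "label", "compartment", "d13C", "d15N")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("missing measurement columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0L) stop("no measurements supplied")
  if (!"depth_m" %in% names(x)) x$depth_m <- NA_real_
  if (!"n_replicates" %in% names(x)) x$n_replicates <- 1L
  x$depth_m <- suppressWarnings(as.numeric(x$depth_m))
  x$d13C <- as.numeric(x$d13C)
  x$d15N <- as.numeric(x$d15N)
  bad_comp <- !x$compartment %in% iso_compartments
  if (any(bad_comp)) {
    stop("unknown compartment(s): ",
         paste(unique(x$compartment[bad_comp]), collapse = ", "),
         " (expected one of ", paste(iso_compartments, collapse = ", "), ")")
  }
  if (any(!is.finite(x$d13C)) || any(!is.finite(x$d15N))) {
    stop("d13C and d15N must be finite")
  }
  if (any(x$n_replicates < 1)) stop("n_replicates must be >= 1")
  if (any(!is.na(x$depth_m) & x$depth_m < 0)) stop("depth_m must be >= 0")
  out_c <- x$d13C < -60 | x$d13C > 10
  if (any(out_c)) {
    warning(sum(out_c), " d13C value(s) outside the plausibility window ",
            "[-60, 10] per mil")
  }
  out_n <- x$d15N < -20 | x$d15N > 40
  if (any(out_n)) {
    warning(sum(out_n), " d15N value(s) outside the plausibility window ",
            "[-20, 40] per mil")
  }
  x
}

#' Read isotope measurements from CSV
#'
#' Reads a UTF-8 CSV with header
#' `sample_id,label,compartment,depth_m,n_replicates,d13C,d15N` (missing
#' depth allowed as empty field; lines starting with `#` are comments) and
#' validates it with [validate_measurements()].
#'
#' @param path path to the CSV file.
#' @return validated data frame of measurements.
#' @export
read_measurements <- function(path) {
  validate_measurements(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  )
}

#' Aggregate measurements into group-level summaries
#'
#' Collapses sample-level measurements to one row per label: the arithmetic
#' mean and the sample (n-1) standard deviation of each isotope axis, with
#' `n` the number of contributing measurements (each measurement counted
#' once, unweighted by its `n_replicates`). The standard deviation is absent
#' (`NA`) for single-measurement groups. A label spanning more than one
#' compartment triggers a warning and is assigned the most frequent one.
#'
#' @param measurements data frame accepted by [validate_measurements()].
#' @return data frame with columns `label`, `compartment`, `depth_m`, `n`,
#'   `mean_d13C`, `sd_d13C`, `mean_d15N`, `sd_d15N`, one row per label in
#'   order of first appearance.
#' @export
aggregate_groups <- function(measurements) {
  m <- validate_measurements(measurements)
  labs <- unique(m$label)
  rows <- lapply(labs, function(lb) {
    g <- m[m$label == lb, , drop = FALSE]
    comp <- unique(g$compartment)
    if (length(comp) > 1L) {
      warning("label '", lb, "' mixes compartments (",
              paste(comp, collapse = ", "), "); using the most frequent")
      tab <- table(factor(g$compartment, levels = comp))
      comp <- names(tab)[which.max(tab)]
    }
    data.frame(
      label = lb,
      compartment = comp,
      depth_m = if (all(is.na(g$depth_m))) NA_real_ else
        mean(g$depth_m, na.rm = TRUE),
      n = nrow(g),
      mean_d13C = mean(g$d13C),
      sd_d13C = sample_sd(g$d13C),
      mean_d15N = mean(g$d15N),
      sd_d15N = sample_sd(g$d15N),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Pool group summaries
#'
#' Pools several group-level summaries into one: by default the unweighted
#' mean and sample standard deviation over the member groups' mean values
#' (group-level statistics, not replicate-weighted). This is the convention
#' used to pool particulate organic matter pools into a food-web baseline.
#' Weighting by the groups' `n` is available but off by default.
#'
#' @param groups data frame of group summaries (from [aggregate_groups()]
#'   or equivalent, needing columns `mean_d13C` and `mean_d15N`).
#' @param weighted if `TRUE`, weight each group's mean by its `n`.
#' @return one-row data frame with `n_groups`, `mean_d13C`, `sd_d13C`,
#'   `mean_d15N`, `sd_d15N`. Standard deviations are `NA` for a single
#'   group.
#' @examples
#' g <- data.frame(mean_d13C = c(-22.46, -21.89, -21.73, -21.40),
#'                 mean_d15N = c(3.97, 2.00, 5.32, 5.61))
#' pool_groups(g) # mean d15N 4.225 -> printed 4.23
#' @export
pool_groups <- function(groups, weighted = FALSE) {
  if (!is.data.frame(groups)) stop("groups must be a data.frame")
  if (nrow(groups) == 0L) stop("cannot pool an empty set of groups")
  w <- if (weighted) {
    if (!"n" %in% names(groups)) stop("weighted pooling needs an 'n' column")
    as.numeric(groups$n)
  } else {
    rep(1, nrow(groups))
  }
  pool_axis <- function(v) {
    m <- stats::weighted.mean(v, w)
    s <- if (length(v) < 2L) NA_real_ else
      sqrt(sum(w * (v - m)^2) / (sum(w) - 1))
    c(mean = m, sd = s)
  }
  c13 <- pool_axis(groups$mean_d13C)
  n15 <- pool_axis(groups$mean_d15N)
  data.frame(
    n_groups = nrow(groups),
    mean_d13C = c13[["mean"]], sd_d13C = c13[["sd"]],
    mean_d15N = n15[["mean"]], sd_d15N = n15[["sd"]]
  )
}
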