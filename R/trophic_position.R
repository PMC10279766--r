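#' Trophic enrichment factor configuration
#'
#' Per-trophic-step isotopic enrichment of a consumer relative to its diet.
#' The defaults are the values standardly assumed for marine food webs:
#' 3.4 per mil for d15N (used by the trophic position equation) and about
#' 1 per mil for d13C (used by the simulator and web metrics only).
#'
#' @param tef_n per-mil d15N enrichment per trophic step; must be > 0.
#' @param tef_c per-mil d13C enrichment per trophic step; must be >= 0.
#' @return an object of class `tef_config`.
#' @export
tef_config <- function(tef_n = 3.4, tef_c = 1.0) {
  if (!is.numeric(tef_n) || length(tef_n) != 1L || !is.finite(tef_n) ||
      tef_n <= 0) {
    stop("tef_n must be a single positive number")
  }
  if (!is.numeric(tef_c) || length(tef_c) != 1L || !is.finite(tef_c) ||
      tef_c < 0) {
    stop("tef_c must be a single non-negative number")
  }
  structure(list(tef_n = tef_n, tef_c = tef_c), class = "tef_config")
}

as_tef <- function(tef) {
  if (inherits(tef, "tef_config")) return(tef)
  if (is.numeric(tef) && length(tef) == 1L) return(tef_config(tef_n = tef))
  stop("tef must be a tef_config() or a single d15N enrichment value")
}

#' Build a food-web baseline from particulate organic matter groups
#'
#' Selects the baseline groups (by default the suspended particulate
#' organic matter compartments, `spom` and `spom_trap`), pools their
#' group-level d15N means with [pool_groups()] (unweighted), and records
#' the trophic level lambda occupied by the baseline (default 1, a primary
#' producer / primary consumer food source).
#'
#' @param groups data frame of group summaries (see [aggregate_groups()]).
#' @param compartments compartments to select when `labels` is `NULL`.
#' @param labels optional explicit group labels overriding the compartment
#'   filter.
#' @param lambda trophic level of the baseline; >= 1.
#' @return an object of class `iso_baseline` with elements `mean_d15N`,
#'   `sd_d15N`, `lambda` and `members`.
#' @examples
#' b <- build_baseline(angola_reef_groups())
#' round_half_up(b$mean_d15N) # 4.23
#' @export
build_baseline <- function(groups, compartments = c("spom", "spom_trap"),
                           labels = NULL, lambda = 1) {
  if (!is.numeric(lambda) || lambda < 1) stop("lambda must be >= 1")
  sel <- if (!is.null(labels)) {
    groups$label %in% labels
  } else {
    groups$compartment %in% compartments
  }
  if (!any(sel)) {
    stop("baseline selector matched no groups (",
         if (!is.null(labels)) {
           paste0("labels: ", paste(labels, collapse = ", "))
         } else {
           paste0("compartments: ", paste(compartments, collapse = ", "))
         }, ")")
  }
  pooled <- pool_groups(groups[sel, , drop = FALSE])
  structure(
    list(mean_d15N = pooled$mean_d15N, sd_d15N = pooled$sd_d15N,
         lambda = lambda, members = groups$label[sel]),
    class = "iso_baseline"
  )
}

#' @export
print.iso_baseline <- function(x, ...) {
  cat("Isotopic baseline: d15N =", round_half_up(x$mean_d15N),
      if (!is.na(x$sd_d15N)) paste0("+/- ", round_half_up(x$sd_d15N)) else "",
      "per mil, lambda =", x$lambda, "\n")
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

as_baseline <- function(baseline, lambda = 1) {
  if (inherits(baseline, "iso_baseline")) return(baseline)
  if (is.numeric(baseline) && length(baseline) == 1L) {
    return(structure(list(mean_d15N = baseline, sd_d15N = NA_real_,
                          lambda = lambda, members = character()),
                     class = "iso_baseline"))
  }
  stop("baseline must be an iso_baseline or a single d15N value")
}

#' Baseline-referenced trophic position
#'
#' The continuous trophic position of a consumer relative to an isotopic
#' baseline:
#' \deqn{TP = \lambda + (\delta^{15}N - \delta^{15}N_{baseline}) / TEF}
#' Full precision; round for display with [round_half_up()].
#'
#' @param d15N consumer d15N value(s), per mil.
#' @param baseline an [build_baseline()] result, or a single baseline d15N
#'   value (then taken at lambda = 1).
#' @param tef a [tef_config()] (or a single d15N enrichment value).
#' @return trophic position(s), dimensionless.
#' @examples
#' trophic_position(11.56, 4.23)                # 3.16 at 2 dp
#' trophic_position(20.83, 4.23)                # 5.88 at 2 dp
#' @export
trophic_position <- function(d15N, baseline, tef = tef_config()) {
  b <- as_baseline(baseline)
  tef <- as_tef(tef)
  b$lambda + (d15N - b$mean_d15N) / tef$tef_n
}

#' Trophic position uncertainty
#'
#' Linear error propagation of the consumer's d15N standard deviation
#' through the trophic position equation, with the baseline and the
#' enrichment factor treated as fixed: `sd_d15N / tef_n`. Optionally the
#' baseline d15N standard deviation is added in quadrature
#' (`sqrt(sd^2 + baseline_sd^2) / tef_n`); this fuller propagation is off
#' by default because published trophic position uncertainties follow the
#' simple rule.
#'
#' @param sd_d15N consumer d15N standard deviation(s); >= 0, `NA` allowed
#'   (propagates to `NA`).
#' @param tef a [tef_config()] (or a single d15N enrichment value).
#' @param baseline_sd optional baseline d15N standard deviation to add in
#'   quadrature.
#' @return trophic position standard deviation(s).
#' @examples
#' tp_uncertainty(2.59) # 0.76 at 2 dp
#' @export
tp_uncertainty <- function(sd_d15N, tef = tef_config(), baseline_sd = NULL) {
  tef <- as_tef(tef)
  if (any(sd_d15N < 0, na.rm = TRUE)) stop("sd_d15N must be >= 0")
  if (is.null(baseline_sd) || is.na(baseline_sd)) {
    sd_d15N / tef$tef_n
  } else {
    if (baseline_sd < 0) stop("baseline_sd must be >= 0")
    sqrt(sd_d15N^2 + baseline_sd^2) / tef$tef_n
  }
}

#' Trophic position table for consumer groups
#'
#' Computes one trophic position estimate per fauna group; particulate
#' organic matter groups (the baseline side of the web) get no trophic
#' position and are excluded. Output rows follow the input order.
#'
#' @param groups data frame of group summaries (see [aggregate_groups()]).
#' @param baseline an [build_baseline()] result or a single baseline d15N.
#' @param tef a [tef_config()].
#' @param include_baseline_sd if `TRUE`, add the baseline d15N variance in
#'   quadrature when propagating uncertainty (default `FALSE`).
#' @return data frame with columns `label`, `n`, `mean_d15N`, `sd_d15N`,
#'   `mean_d13C`, `sd_d13C`, `tp`, `tp_sd` (fauna groups only; zero rows if
#'   there are none).
#' @examples
#' groups <- angola_reef_groups()
#' tp <- tp_table(groups, baseline = 4.23)
#' round_half_up(tp$tp[tp$label == "Madr"]) # 2.85
#' @export
tp_table <- function(groups, baseline, tef = tef_config(),
                     include_baseline_sd = FALSE) {
  b <- as_baseline(baseline)
  tef <- as_tef(tef)
  fauna <- groups[groups$compartment == "fauna", , drop = FALSE]
  bsd <- if (include_baseline_sd) b$sd_d15N else NULL
  data.frame(
    label = fauna$label,
    n = fauna$n,
    mean_d15N = fauna$mean_d15N,
    sd_d15N = fauna$sd_d15N,
    mean_d13C = fauna$mean_d13C,
    sd_d13C = fauna$sd_d13C,
    tp = trophic_position(fauna$mean_d15N, b, tef),
    tp_sd = tp_uncertainty(fauna$sd_d15N, tef, baseline_sd = bsd),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Trophic position sensitivity to the enrichment factor
#'
#' Recomputes trophic positions across a grid of d15N enrichment factors
#' (literature values span roughly 3.4 to 5.0 per mil), a quick scan of how
#' strongly conclusions depend on the assumed TEF.
#'
#' @param d15N consumer d15N value(s).
#' @param baseline an [build_baseline()] result or a single baseline d15N.
#' @param tef_values numeric vector of d15N enrichment factors.
#' @return matrix of trophic positions, one row per consumer, one column
#'   per TEF value.
#' @export
tef_scan <- function(d15N, baseline, tef_values = seq(3.4, 5.0, by = 0.4)) {
  out <- vapply(tef_values,
                function(f) trophic_position(d15N, baseline, tef_config(f)),
                numeric(length(d15N)))
  out <- matrix(out, nrow = length(d15N),
                dimnames = list(names(d15N), paste0("tef_", tef_values)))
  out
}
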