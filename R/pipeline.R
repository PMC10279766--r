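#' Run the full trophic analysis pipeline
#'
#' Orchestrates the whole analysis on one input table: aggregation (if
#' sample-level measurements are supplied), baseline construction, the
#' trophic position table, selection of the number of guilds (unless `k`
#' is fixed), k-means clustering, guild summaries and web metrics. Every
#' default taken is logged with `message()`; artifacts are written as CSV
#' and JSON when `out_dir` is given, together with a run manifest
#' capturing the configuration. Re-running with identical configuration
#' and input yields byte-identical outputs.
#'
#' @param input path to a CSV, or a data frame: either sample-level
#'   measurements (see [read_measurements()]) or group-level summaries
#'   (columns `label`, `compartment`, `n`, `mean_d13C`, ..., as from
#'   [aggregate_groups()]).
#' @param k fixed number of clusters; `NULL` (default) selects it with
#'   [select_k()].
#' @param k_grid grid for k selection.
#' @param n_init k-means restarts.
#' @param B gap-statistic reference sets.
#' @param seed integer seed; required (clustering always runs).
#' @param scale standardise the axes before clustering (default `FALSE`,
#'   i.e. raw per-mil values; the choice is recorded in the outputs).
#' @param lambda trophic level of the baseline.
#' @param tef a [tef_config()].
#' @param baseline_compartments compartments pooled into the baseline.
#' @param out_dir optional directory for report artifacts
#'   (`tp_table.csv`, `clusters.csv`, `cluster_summary.csv`,
#'   `kselect.csv`, `web_metrics.json`, `run_manifest.json`).
#' @param quiet suppress progress messages.
#' @return object of class `iso_pipeline`: `groups`, `baseline`, `tp`,
#'   `kselect` (or `NULL`), `model`, `guilds`, `metrics`, `config`.
#' @examples
#' res <- run_pipeline(angola_reef_groups(), k = 4, seed = 1, quiet = TRUE)
#' res$guilds$mean_tp
#' @export
run_pipeline <- function(input, k = NULL, k_grid = 1:8, n_init = 100,
                         B = 50, seed = NULL, scale = FALSE, lambda = 1,
                         tef = tef_config(),
                         baseline_compartments = c("spom", "spom_trap"),
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.null(seed)) stop("a seed is required (clustering is stochastic)")
  tef <- as_tef(tef)
  dat <- if (is.character(input)) {
    say("reading ", input)
    utils::read.csv(input, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    as.data.frame(input)
  }
  groups <- if (all(c("mean_d13C", "mean_d15N") %in% names(dat))) {
    say("input interpreted as group-level summaries (", nrow(dat),
        " groups)")
    dat
  } else {
    say("aggregating ", nrow(dat), " measurements")
    aggregate_groups(dat)
  }
  baseline <- build_baseline(groups, compartments = baseline_compartments,
                             lambda = lambda)
  say("baseline: d15N = ", round_half_up(baseline$mean_d15N),
      " per mil (lambda = ", lambda, ") from ",
      paste(baseline$members, collapse = ", "))
  if (!any(groups$compartment == "fauna")) {
    warning("no fauna groups: the trophic position table is empty")
  }
  tpt <- tp_table(groups, baseline, tef)
  say("trophic positions computed for ", nrow(tpt), " fauna groups ",
      "(TEF = ", tef$tef_n, " per mil)")
  kselect <- NULL
  if (is.null(k)) {
    kselect <- select_k(groups, k_grid = k_grid, n_init = n_init, B = B,
                        seed = seed, scale = scale)
    k <- kselect$chosen$consensus
    say("k selection: elbow = ", kselect$chosen$elbow,
        ", silhouette = ", kselect$chosen$silhouette,
        ", gap = ", kselect$chosen$gap, " -> consensus k = ", k)
  } else {
    say("k fixed to ", k)
  }
  model <- kmeans_fit(groups, k, n_init = n_init, seed = seed,
                      scale = scale)
  say("k-means: ", if (isTRUE(model$scaled)) "standardised" else
    "raw per-mil", " axes, n_init = ", n_init, ", WSS = ",
    round_half_up(model$wss, 3))
  guilds <- summarize_clusters(groups, model, tpt)
  metrics <- web_metrics(groups, guilds, tef)
  res <- structure(
    list(groups = groups, baseline = baseline, tp = tpt,
         kselect = kselect, model = model, guilds = guilds,
         metrics = metrics,
         config = list(k = k, k_grid = k_grid, n_init = n_init, B = B,
                       seed = seed, scale = scale, lambda = lambda,
                       tef_n = tef$tef_n, tef_c = tef$tef_c,
                       baseline_compartments = baseline_compartments)),
    class = "iso_pipeline"
  )
  if (!is.null(out_dir)) {
    write_pipeline(res, out_dir)
    say("artifacts written to ", out_dir)
  }
  res
}

#' Write pipeline artifacts
#'
#' Emits the machine-readable report bundle of a pipeline run: the trophic
#' position table, per-group cluster assignments, the guild summary, the
#' per-k selection diagnostics (when k was selected), the web metrics as
#' JSON (full precision plus two-decimal display copies) and a run
#' manifest with the configuration and package version. Numeric CSVs keep
#' full precision.
#'
#' @param res an `iso_pipeline` result.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(res, out_dir) {
  if (!inherits(res, "iso_pipeline")) stop("res must be an iso_pipeline")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$tp, file.path(out_dir, "tp_table.csv"),
                   row.names = FALSE)
  asg <- attr(res$guilds, "assignment")
  utils::write.csv(
    data.frame(label = names(asg), cluster = unname(asg)),
    file.path(out_dir, "clusters.csv"), row.names = FALSE
  )
  utils::write.csv(
    res$guilds[c("cluster", "n", "mean_d13C", "sd_d13C", "mean_d15N",
                 "sd_d15N", "mean_tp", "sd_tp", "members")],
    file.path(out_dir, "cluster_summary.csv"), row.names = FALSE
  )
  if (!is.null(res$kselect)) {
    utils::write.csv(res$kselect$table,
                     file.path(out_dir, "kselect.csv"), row.names = FALSE)
  }
  m <- res$metrics
  jsonlite::write_json(
    list(
      c_range = m$c_range, n_range = m$n_range, n_obs = m$n_obs,
      pearson = m$pearson, cluster_distances = m$cluster_distances,
      display = list(c_range = round_half_up(m$c_range),
                     n_range = round_half_up(m$n_range),
                     pearson_r = round_half_up(m$pearson$r))
    ),
    file.path(out_dir, "web_metrics.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  jsonlite::write_json(
    c(res$config,
      list(package = "isoweb",
           version = as.character(utils::packageVersion("isoweb")))),
    file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.iso_pipeline <- function(x, ...) {
  cat("Trophic analysis pipeline —", nrow(x$groups), "groups,",
      nrow(x$tp), "fauna\n")
  print(x$baseline)
  if (!is.null(x$kselect)) {
    cat("consensus k =", x$config$k, "(elbow ", x$kselect$chosen$elbow,
        ", silhouette ", x$kselect$chosen$silhouette, ", gap ",
        x$kselect$chosen$gap, ")\n", sep = "")
  } else {
    cat("k fixed to", x$config$k, "\n")
  }
  g <- x$guilds
  g[3:8] <- lapply(g[3:8], round_half_up)
  print(g, row.names = FALSE)
  print(x$metrics)
  invisible(x)
}
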