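#' Published group-level isotope summaries for the Angolan reef community
#'
#' Group-level mean d13C and d15N (with standard deviation and sample
#' counts) for 30 groups — six particulate organic matter pools and 24
#' consumer taxa — transcribed from a published stable-isotope survey of
#' cold-water coral reefs on the Angolan margin (SE Atlantic). The columns
#' `reported_tp` and `reported_tp_sd` carry the trophic positions as
#' published (fauna only; baseline 4.23 per mil, lambda 1, TEF 3.4 per
#' mil), for comparison with recomputed values. Two transcription fixes are
#' flagged in the file itself: the Gorgoniidae d13C sign (restored to
#' -17.35) and the Desmophyllum pertusum TP s.d. (0.40, a printed digit
#' transposition).
#'
#' @return data frame with columns `label`, `taxon`, `compartment`,
#'   `depth_m`, `n`, `mean_d15N`, `sd_d15N`, `mean_d13C`, `sd_d13C`,
#'   `reported_tp`, `reported_tp_sd`.
#' @seealso [angola_reef_clusters()] for the published guild memberships.
#' @examples
#' groups <- angola_reef_groups()
#' isotopic_ranges(groups)
#' @export
angola_reef_groups <- function() {
  path <- system.file("extdata", "table1_groups.csv", package = "isoweb",
                      mustWork = TRUE)
  g <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  num <- c("depth_m", "n", "mean_d15N", "sd_d15N", "mean_d13C", "sd_d13C",
           "reported_tp", "reported_tp_sd")
  g[num] <- lapply(g[num], as.numeric)
  g
}

#' Published trophic-guild memberships for the Angolan reef community
#'
#' The four k-means guilds reported for the Angolan reef groups: cluster 1
#' the six particulate organic matter pools, cluster 2 the fourteen
#' suspension feeders (all cnidarians plus Munida, a polynoid and a
#' myctophid fish), cluster 3 the echinoderms plus Eunice norvegica, and
#' cluster 4 the five sponge taxa.
#'
#' @return data frame with columns `label`, `cluster`.
#' @export
angola_reef_clusters <- function() {
  path <- system.file("extdata", "clusters.csv", package = "isoweb",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
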