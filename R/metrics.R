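#' Fish-community metric quartiles by habitat
#'
#' Summarizes overall abundance density (individuals per 100 m2, all
#' species pooled) and species richness per habitat by their 0.25, 0.5 and
#' 0.75 quartiles (linear-interpolation convention), with an all-habitat
#' `Overall` row. Habitats without stations are omitted.
#'
#' @param stations labeled station data frame.
#' @param fish long-form fish count table (`station_id`, `species`,
#'   `family`, `rotation`, `count`).
#' @param observed_area observed surface area in m2 per station.
#' @return Data frame of class `habitat_metric_summary`: `habitat`,
#'   `n_stations`, `density_q25/q50/q75`, `richness_q25/q50/q75`.
#' @export
summarize_metrics <- function(stations, fish, observed_area = 78.5) {
  if (!"habitat" %in% names(stations) || all(is.na(stations$habitat))) {
    stop("summarize_metrics() needs labeled stations", call. = FALSE)
  }
  fs <- station_fish_summaries(fish, observed_area = observed_area)
  merged <- merge(stations[, c("station_id", "habitat")], fs,
                  by = "station_id", all.x = TRUE)
  merged$total_density[is.na(merged$total_density)] <- 0
  merged$species_richness[is.na(merged$species_richness)] <- 0L
  merged <- merged[!is.na(merged$habitat), , drop = FALSE]

  qrow <- function(sub, label) {
    qd <- stats::quantile(sub$total_density, c(.25, .5, .75), type = 7L)
    qr <- stats::quantile(sub$species_richness, c(.25, .5, .75), type = 7L)
    data.frame(habitat = label, n_stations = nrow(sub),
               density_q25 = qd[[1L]], density_q50 = qd[[2L]],
               density_q75 = qd[[3L]],
               richness_q25 = qr[[1L]], richness_q50 = qr[[2L]],
               richness_q75 = qr[[3L]], stringsAsFactors = FALSE)
  }
  habitats <- intersect(habitat_levels(), unique(merged$habitat))
  out <- do.call(rbind, c(
    lapply(habitats, function(h) qrow(merged[merged$habitat == h, ], h)),
    list(qrow(merged, "Overall"))))
  rownames(out) <- NULL
  class(out) <- c("habitat_metric_summary", "data.frame")
  out
}

#' Family frequency by habitat
#'
#' Frequency of each fish family — the percentage of stations where the
#' family is present (any positive count) — per habitat and overall.
#' Families whose overall frequency does not exceed `min_overall_pct`
#' (default 1%) are dropped; a floor of 0 retains every observed family.
#'
#' @param stations labeled station data frame.
#' @param fish long-form fish count table with a `family` column.
#' @param min_overall_pct overall-frequency floor in percent.
#' @return Data frame of class `family_frequency_table`: `family`, one
#'   column per habitat, and `Overall`, all in percent of stations.
#' @export
family_frequencies <- function(stations, fish, min_overall_pct = 1) {
  if (!"habitat" %in% names(stations) || all(is.na(stations$habitat))) {
    stop("family_frequencies() needs labeled stations", call. = FALSE)
  }
  if (!"family" %in% names(fish)) {
    stop("fish table needs a family column", call. = FALSE)
  }
  stations <- stations[!is.na(stations$habitat), , drop = FALSE]
  habitats <- intersect(habitat_levels(), unique(stations$habitat))
  present <- fish[fish$count > 0 & !is.na(fish$family), , drop = FALSE]
  fam_station <- unique(present[, c("station_id", "family")])
  fam_station <- fam_station[fam_station$station_id %in% stations$station_id, ,
                             drop = FALSE]
  families <- sort(unique(fam_station$family))
  if (!length(families)) {
    out <- data.frame(family = character(), stringsAsFactors = FALSE)
    for (h in c(habitats, "Overall")) out[[h]] <- numeric()
    class(out) <- c("family_frequency_table", "data.frame")
    return(out)
  }
  hab_of <- stats::setNames(stations$habitat, stations$station_id)
  freq <- function(fam, ids) {
    if (!length(ids)) return(NA_real_)
    with_fam <- unique(fam_station$station_id[fam_station$family == fam])
    100 * sum(ids %in% with_fam) / length(ids)
  }
  rows <- lapply(families, function(fam) {
    r <- data.frame(family = fam, stringsAsFactors = FALSE)
    for (h in habitats) {
      r[[h]] <- freq(fam, stations$station_id[stations$habitat == h])
    }
    r$Overall <- freq(fam, stations$station_id)
    r
  })
  out <- do.call(rbind, rows)
  out <- out[out$Overall > min_overall_pct, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("family_frequency_table", "data.frame")
  out
}

#' Habitat-effect tests for community metrics (convenience wrapper)
#'
#' Thin, non-core convenience around standard model fits: a Gamma GLM for
#' overall density (zero densities are dropped with a note, as a Gamma
#' response must be positive) and a negative-binomial GLM for species
#' richness, each with habitat as the only covariate. No bespoke inference
#' is performed; interpret through the returned model objects.
#'
#' @param stations labeled station data frame.
#' @param fish long-form fish count table.
#' @param observed_area observed surface area in m2.
#' @return List with elements `density` (Gamma `glm`) and `richness`
#'   (`MASS::glm.nb` fit).
#' @export
habitat_effect_tests <- function(stations, fish, observed_area = 78.5) {
  if (!requireNamespace("MASS", quietly = TRUE)) {
    stop("habitat_effect_tests() needs the MASS package", call. = FALSE)
  }
  fs <- station_fish_summaries(fish, observed_area = observed_area)
  merged <- merge(stations[, c("station_id", "habitat")], fs,
                  by = "station_id")
  merged <- merged[!is.na(merged$habitat), , drop = FALSE]
  pos <- merged$total_density > 0
  if (any(!pos)) {
    message(sum(!pos), " station(s) with zero density dropped from the ",
            "Gamma density model")
  }
  list(
    density = stats::glm(total_density ~ habitat,
                         data = merged[pos, , drop = FALSE],
                         family = stats::Gamma(link = "log")),
    richness = MASS::glm.nb(species_richness ~ habitat, data = merged))
}
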