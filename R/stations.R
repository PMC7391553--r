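#' Habitat and station vocabulary
#'
#' `habitat_levels()` returns the five habitat types of the typology.
#' `attribute_names()` returns the names of the station-level habitat
#' attributes; with `composites = TRUE` the derived composite attributes are
#' appended. Composites are always computed from the base covers, never
#' stored: `algae` = erect_algae + algal_turf, `hard_coral` = live_coral +
#' dead_coral, `hard_substrate` = debris + boulder + rock + slab, and
#' `slab_boulder_rock` = slab + boulder + rock.
#'
#' @param composites logical; append composite attribute names?
#' @return Character vector of names.
#' @export
habitat_levels <- function() {
  c("Seagrass", "Macroalgae", "Sandy", "Debris", "Live Coral")
}

#' @rdname habitat_levels
#' @export
attribute_names <- function(composites = FALSE) {
  base <- c("depth", "topography", "complexity",
            "sand", "debris", "boulder", "rock", "slab",
            "live_coral", "dead_coral", "erect_algae", "algal_turf",
            "seagrass")
  if (composites) c(base, names(composite_attributes())) else base
}

# Composite attribute -> base covers it sums.
composite_attributes <- function() {
  list(
    algae            = c("erect_algae", "algal_turf"),
    hard_coral       = c("live_coral", "dead_coral"),
    hard_substrate   = c("debris", "boulder", "rock", "slab"),
    slab_boulder_rock = c("slab", "boulder", "rock")
  )
}

substrate_attributes <- function() c("sand", "debris", "boulder", "rock", "slab")

biotic_attributes <- function() {
  c("live_coral", "dead_coral", "erect_algae", "algal_turf", "seagrass")
}

# Station CSV column dictionary: CSV/in-memory column -> plain attribute name.
station_attribute_columns <- function() {
  c(depth = "depth_m", topography = "topography", complexity = "complexity",
    sand = "sand_pc", debris = "debris_pc", boulder = "boulder_pc",
    rock = "rock_pc", slab = "slab_pc", live_coral = "live_coral_pc",
    dead_coral = "dead_coral_pc", erect_algae = "erect_algae_pc",
    algal_turf = "algal_turf_pc", seagrass = "seagrass_pc")
}

station_mandatory_columns <- function() {
  c("station_id", "site", "zone", unname(station_attribute_columns()))
}

#' Extract plain-named attribute values from a station table
#'
#' Station tables use the CSV column dictionary (`depth_m`, `sand_pc`, ...).
#' `station_attributes()` returns a data frame with plain attribute names
#' (`depth`, `sand`, ...), optionally with the derived composites appended.
#' `attribute_values()` returns a single attribute (base or composite) as a
#' numeric vector.
#'
#' @param stations station data frame (see [read_stations()] for the schema).
#' @param composites logical; append composite attributes?
#' @param attribute attribute name, base or composite.
#' @return `station_attributes()`: a data frame, one row per station;
#'   `attribute_values()`: a numeric vector.
#' @export
station_attributes <- function(stations, composites = FALSE) {
  cols <- station_attribute_columns()
  missing <- setdiff(unname(cols), names(stations))
  if (length(missing)) {
    stop("station table is missing attribute column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- stations[, unname(cols), drop = FALSE]
  names(out) <- names(cols)
  if (composites) {
    for (cmp in names(composite_attributes())) {
      out[[cmp]] <- rowSums(out[, composite_attributes()[[cmp]], drop = FALSE])
    }
  }
  out
}

#' @rdname station_attributes
#' @export
attribute_values <- function(stations, attribute) {
  comps <- composite_attributes()
  attrs <- station_attributes(stations)
  if (attribute %in% names(attrs)) return(attrs[[attribute]])
  if (attribute %in% names(comps)) {
    return(rowSums(attrs[, comps[[attribute]], drop = FALSE]))
  }
  stop("unknown attribute: ", attribute, call. = FALSE)
}

# Zero-row station frame with the canonical schema.
empty_station_frame <- function() {
  cols <- station_mandatory_columns()
  out <- data.frame(station_id = character(), site = character(),
                    zone = character(), stringsAsFactors = FALSE)
  for (col in setdiff(cols, names(out))) out[[col]] <- numeric()
  out$habitat <- character()
  out
}

#' Validate a station table
#'
#' Checks the station schema and the profile invariants: every percent cover
#' in \[0, 100\], ordinal topography/complexity scores in \[1, 5\], the five
#' substrate covers (sand, debris, boulder, rock, slab) summing to 100
#' within `tolerance`, and — when `biotic_check` is on — the five biotic
#' overlay covers summing to at most 100 + `tolerance`. Habitat labels, when
#' present, must be one of [habitat_levels()] (`NA` = unlabeled).
#'
#' Substrate-sum violations reflect annotation rounding and are warnings by
#' default; under `strict = TRUE` any problem is an error.
#'
#' @param stations station data frame.
#' @param tolerance allowed slack on the substrate sum, in percentage
#'   points (default 0.5).
#' @param strict logical; escalate problems to errors?
#' @param biotic_check logical; also check that biotic overlay covers sum to
#'   at most 100? Overlays share the observed area, so overlap (e.g. turf on
#'   dead coral) keeps this a soft constraint, on by default.
#' @return Invisibly, a data frame of problems (`station_id`, `problem`);
#'   zero rows when the table is clean.
#' @export
validate_stations <- function(stations, tolerance = 0.5, strict = FALSE,
                              biotic_check = TRUE) {
  if (!is.data.frame(stations)) stop("`stations` must be a data frame", call. = FALSE)
  missing <- setdiff(station_mandatory_columns(), names(stations))
  if (length(missing)) {
    stop("station table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  probs <- list()
  note <- function(ids, what) {
    if (length(ids)) probs[[length(probs) + 1L]] <<-
        data.frame(station_id = as.character(ids), problem = what,
                   stringsAsFactors = FALSE)
  }
  if (nrow(stations) == 0L) {
    report <- data.frame(station_id = character(), problem = character())
    return(invisible(report))
  }
  ids <- as.character(stations$station_id)

  for (col in unname(station_attribute_columns())) {
    v <- stations[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      note(ids[is.na(v) & !is.na(stations[[col]])],
           paste0("non-numeric value in ", col))
    }
    note(ids[is.na(v)], paste0("missing value in ", col))
  }

  attrs <- station_attributes(stations)
  for (a in c(substrate_attributes(), biotic_attributes())) {
    bad <- !is.na(attrs[[a]]) & (attrs[[a]] < 0 | attrs[[a]] > 100)
    note(ids[bad], paste0(a, " cover outside [0, 100]"))
  }
  for (a in c("topography", "complexity")) {
    bad <- !is.na(attrs[[a]]) & (attrs[[a]] < 1 | attrs[[a]] > 5)
    note(ids[bad], paste0(a, " score outside [1, 5]"))
  }
  bad <- !is.na(attrs$depth) & attrs$depth < 0
  note(ids[bad], "negative depth")

  ssum <- rowSums(attrs[, substrate_attributes(), drop = FALSE])
  bad <- !is.na(ssum) & abs(ssum - 100) > tolerance
  note(ids[bad], sprintf("substrate covers sum to %.6g, not 100", ssum[bad]))

  if (biotic_check) {
    bsum <- rowSums(attrs[, biotic_attributes(), drop = FALSE])
    bad <- !is.na(bsum) & bsum > 100 + tolerance
    note(ids[bad], sprintf("biotic overlay covers sum to %.6g > 100", bsum[bad]))
  }

  if ("habitat" %in% names(stations)) {
    h <- stations$habitat
    bad <- !is.na(h) & !(h %in% habitat_levels())
    note(ids[bad], sprintf("unknown habitat label '%s'", h[bad]))
  }

  report <- if (length(probs)) do.call(rbind, probs) else
    data.frame(station_id = character(), problem = character())
  if (nrow(report)) {
    msg <- paste0("station validation found ", nrow(report), " problem(s), e.g. ",
                  report$station_id[1L], ": ", report$problem[1L])
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(report)
}

#' Read and write station tables
#'
#' Station CSV schema: one row per station with columns `station_id`,
#' `site`, `zone` (`coastal` or `remote`), `depth_m`, `topography`,
#' `complexity`, the five substrate percent covers `sand_pc`, `debris_pc`,
#' `boulder_pc`, `rock_pc`, `slab_pc`, the five biotic overlay covers
#' `live_coral_pc`, `dead_coral_pc`, `erect_algae_pc`, `algal_turf_pc`,
#' `seagrass_pc`, and an optional `habitat` label. Unknown columns are
#' preserved as opaque extras. Numeric fields round-trip at 6 significant
#' digits.
#'
#' @param path file path.
#' @param stations station data frame.
#' @param validate logical; run [validate_stations()] after reading?
#' @param strict escalate validation problems to errors (see
#'   [validate_stations()]).
#' @return `read_stations()`: the station data frame; `write_stations()`:
#'   `path`, invisibly.
#' @export
read_stations <- function(path, validate = TRUE, strict = FALSE) {
  stations <- utils::read.csv(path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  missing <- setdiff(station_mandatory_columns(), names(stations))
  if (length(missing)) {
    stop("station file ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"habitat" %in% names(stations)) stations$habitat <- NA_character_
  stations$station_id <- as.character(stations$station_id)
  if (nrow(stations) && validate) {
    validate_stations(stations, strict = strict)
  }
  stations
}

#' @rdname read_stations
#' @export
write_stations <- function(stations, path) {
  out <- stations
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], signif, digits = 6L)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Aggregate per-frame habitat annotations to a rotation profile
#'
#' Each station rotation is annotated on six contiguous 60-degree frames;
#' the station-level value of every habitat attribute is the arithmetic mean
#' of its six per-frame values. The substrate-sum invariant is re-checked
#' after averaging (the mean of per-frame compositions is itself a
#' composition).
#'
#' @param frames data frame of exactly 6 rows (one per frame) with plain
#'   attribute columns ([attribute_names()]).
#' @param tolerance substrate-sum slack in percentage points.
#' @param station_id optional id used in error messages.
#' @return One-row data frame of frame-averaged attributes.
#' @export
aggregate_habitat_frames <- function(frames, tolerance = 0.5,
                                     station_id = NULL) {
  if (!is.data.frame(frames)) stop("`frames` must be a data frame", call. = FALSE)
  if (nrow(frames) != 6L) {
    stop("a rotation has exactly 6 frames, got ", nrow(frames), call. = FALSE)
  }
  missing <- setdiff(attribute_names(), names(frames))
  if (length(missing)) {
    stop("frame table is missing attribute(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prof <- as.data.frame(as.list(colMeans(frames[, attribute_names()])))
  ssum <- sum(prof[, substrate_attributes()])
  if (abs(ssum - 100) > tolerance) {
    stop("substrate covers sum to ", signif(ssum, 6L), ", not 100",
         if (!is.null(station_id)) paste0(" (station ", station_id, ")"),
         call. = FALSE)
  }
  prof
}

#' Summarize fish counts for one station
#'
#' Per-species abundance is the mean count over the (nominally three)
#' rotations; density rescales abundance from the observed area (default
#' 78.5 m2, a 5-m radius around the camera) to individuals per 100 m2.
#' Species richness is the number of species seen in any rotation.
#'
#' @param counts data frame with columns `species`, `rotation`, `count` and
#'   optionally `family`; one row per species x rotation (absent rows count
#'   as zero).
#' @param observed_area observed surface area in m2 (default 78.5).
#' @param n_rotations nominal number of rotations (default 3); fewer
#'   observed rotations are allowed with a warning and the station is
#'   flagged as degraded.
#' @return A list with `species` (data frame: `species`, `family`,
#'   `mean_count`, `density`), `species_richness`, `total_density`,
#'   `families` (character vector of families present) and `degraded`.
#' @export
summarize_fish <- function(counts, observed_area = 78.5, n_rotations = 3L) {
  stopifnot(is.data.frame(counts), observed_area > 0)
  need <- c("species", "rotation", "count")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    stop("fish counts are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(counts$count < 0)) stop("negative fish counts", call. = FALSE)
  rotations <- sort(unique(counts$rotation))
  degraded <- length(rotations) > 0L && length(rotations) < n_rotations
  if (degraded) {
    warning("only ", length(rotations), " of ", n_rotations,
            " rotations observed; station flagged as degraded", call. = FALSE)
  }
  n_rot <- max(length(rotations), 1L)
  if (nrow(counts) == 0L) {
    sp <- data.frame(species = character(), family = character(),
                     mean_count = numeric(), density = numeric())
    return(list(species = sp, species_richness = 0L, total_density = 0,
                families = character(), degraded = degraded))
  }
  fam <- if ("family" %in% names(counts)) counts$family else
    rep(NA_character_, nrow(counts))
  tot <- tapply(counts$count, counts$species, sum)
  keep <- names(tot)[tot > 0]               # species seen in any rotation
  fam_of <- tapply(as.character(fam), counts$species, function(f) f[1L])
  mean_count <- tot / n_rot                 # absent rotations count as zero
  sp <- data.frame(species = names(tot),
                   family = unname(fam_of[names(tot)]),
                   mean_count = unname(mean_count),
                   density = unname(mean_count) / observed_area * 100,
                   stringsAsFactors = FALSE)
  sp <- sp[sp$species %in% keep, , drop = FALSE]
  sp <- sp[order(sp$species), , drop = FALSE]
  rownames(sp) <- NULL
  list(species = sp,
       species_richness = nrow(sp),
       total_density = sum(sp$density),
       families = sort(unique(stats::na.omit(sp$family))),
       degraded = degraded)
}

#' Per-station fish summaries for a long-form count table
#'
#' Applies [summarize_fish()] to each station of a long-form fish table
#' (`station_id`, `species`, `family`, `rotation`, `count`).
#'
#' @param fish long-form fish count data frame.
#' @param observed_area observed surface area in m2 per station.
#' @return Data frame with one row per station: `station_id`,
#'   `total_density`, `species_richness`, `degraded`.
#' @export
station_fish_summaries <- function(fish, observed_area = 78.5) {
  stopifnot(is.data.frame(fish))
  if (!"station_id" %in% names(fish)) {
    stop("fish table needs a station_id column", call. = FALSE)
  }
  ids <- unique(as.character(fish$station_id))
  rows <- lapply(ids, function(id) {
    s <- summarize_fish(fish[fish$station_id == id, , drop = FALSE],
                        observed_area = observed_area)
    data.frame(station_id = id, total_density = s$total_density,
               species_richness = s$species_richness, degraded = s$degraded,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(station_id = character(), total_density = numeric(),
               species_richness = integer(), degraded = logical())
  rownames(out) <- NULL
  out
}
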