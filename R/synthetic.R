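#' Habitat archetypes for synthetic station generation
#'
#' An archetype holds the generative parameters of one habitat type: mean
#' proportions and a Dirichlet concentration for the five-part substrate
#' composition (sand, debris, boulder, rock, slab; draws sum to 100
#' exactly), truncated-normal location/spread for each biotic overlay cover
#' and for depth, continuous ordinal scores for topography and complexity on
#' \[1, 5\] (frame-averaged semantics), the archetypical attribute with its
#' guaranteed minimum (default 15%), and per-family fish occurrence
#' probabilities and abundance scales.
#'
#' `default_archetypes()` returns the packaged parameterization of the five
#' habitats (Seagrass, Macroalgae, Sandy, Debris, Live Coral). The `overlap`
#' level widens all spreads and flattens the substrate concentration to
#' create a between-habitat continuum.
#'
#' @param overlap one of `"low"`, `"medium"`, `"high"`.
#' @return Named list of archetype objects (class `habitat_archetype`).
#' @export
default_archetypes <- function(overlap = c("low", "medium", "high")) {
  overlap <- match.arg(overlap)
  widen <- switch(overlap, low = 1, medium = 1.8, high = 2.6)
  flatten <- switch(overlap, low = 1, medium = 3, high = 8)

  arch <- function(habitat, substrate, conc, biotic, depth, topography,
                   complexity, archetype_attribute, fish_probs, fish_scales) {
    structure(list(
      habitat = habitat,
      substrate = substrate / sum(substrate),
      substrate_conc = conc / flatten,
      biotic = data.frame(attribute = biotic_attributes(),
                          mean = biotic[, 1L], sd = biotic[, 2L] * widen),
      depth = c(mean = depth[1L], sd = depth[2L] * widen),
      topography = c(mean = topography[1L], sd = topography[2L] * widen),
      complexity = c(mean = complexity[1L], sd = complexity[2L] * widen),
      archetype_attribute = archetype_attribute,
      archetype_min = 15,
      fish = data.frame(family = names(fish_probs), prob = unname(fish_probs),
                        scale = unname(fish_scales[names(fish_probs)]))
    ), class = "habitat_archetype")
  }

  # rows: live_coral, dead_coral, erect_algae, algal_turf, seagrass
  bio <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE)

  scales <- c(Acanthuridae = 6, Scaridae = 5, Labridae = 5,
              Chaetodontidae = 3, Lethrinidae = 3, Mullidae = 2.5,
              Balistidae = 2, Dasyatidae = 1, Elapidae = 1,
              Carcharhinidae = 1, Pomacentridae = 10, Siganidae = 2)
  pr <- function(...) c(...)

  list(
    Seagrass = arch(
      "Seagrass",
      substrate = c(sand = .88, debris = .05, boulder = .01, rock = .02, slab = .04),
      conc = 60,
      biotic = bio(2, 2,   1, 1,   4, 3,   3, 2.5,   65, 16),
      depth = c(8, 4), topography = c(1.4, .3), complexity = c(1.5, .35),
      archetype_attribute = "seagrass",
      fish_probs = pr(Acanthuridae = .25, Scaridae = .30, Labridae = .50,
                      Chaetodontidae = .15, Lethrinidae = .65, Mullidae = .55,
                      Balistidae = .50, Dasyatidae = .20, Elapidae = .18,
                      Carcharhinidae = .02, Pomacentridae = .35, Siganidae = .40),
      fish_scales = scales),
    Macroalgae = arch(
      "Macroalgae",
      substrate = c(sand = .72, debris = .09, boulder = .03, rock = .05, slab = .11),
      conc = 60,
      biotic = bio(2, 2,   1.5, 1.5,   58, 14,   6, 4,   3, 3),
      depth = c(10, 4), topography = c(1.5, .3), complexity = c(1.6, .35),
      archetype_attribute = "erect_algae",
      fish_probs = pr(Acanthuridae = .30, Scaridae = .30, Labridae = .55,
                      Chaetodontidae = .20, Lethrinidae = .70, Mullidae = .60,
                      Balistidae = .55, Dasyatidae = .15, Elapidae = .15,
                      Carcharhinidae = .02, Pomacentridae = .40, Siganidae = .40),
      fish_scales = scales),
    Sandy = arch(
      "Sandy",
      substrate = c(sand = .86, debris = .06, boulder = .02, rock = .02, slab = .04),
      conc = 60,
      biotic = bio(4, 3.5,   2, 2,   2.5, 2.5,   6, 5,   0.8, 1),
      depth = c(14, 6), topography = c(1.3, .25), complexity = c(1.4, .3),
      archetype_attribute = "sand",
      fish_probs = pr(Acanthuridae = .70, Scaridae = .60, Labridae = .70,
                      Chaetodontidae = .50, Lethrinidae = .50, Mullidae = .50,
                      Balistidae = .45, Dasyatidae = .25, Elapidae = .20,
                      Carcharhinidae = .05, Pomacentridae = .60, Siganidae = .20),
      fish_scales = scales),
    Debris = arch(
      "Debris",
      substrate = c(sand = .18, debris = .55, boulder = .08, rock = .08, slab = .11),
      conc = 55,
      biotic = bio(5, 4,   6, 4,   2, 2,   10, 6,   0.2, .5),
      depth = c(12, 5), topography = c(1.9, .45), complexity = c(2.1, .4),
      archetype_attribute = "debris",
      fish_probs = pr(Acanthuridae = .85, Scaridae = .80, Labridae = .85,
                      Chaetodontidae = .70, Lethrinidae = .35, Mullidae = .30,
                      Balistidae = .35, Dasyatidae = .03, Elapidae = .05,
                      Carcharhinidae = .15, Pomacentridae = .85, Siganidae = .15),
      fish_scales = scales),
    `Live Coral` = arch(
      "Live Coral",
      substrate = c(sand = .14, debris = .10, boulder = .12, rock = .34, slab = .30),
      conc = 50,
      biotic = bio(58, 12,   15, 7,   2, 2,   9, 5,   0.2, .5),
      depth = c(12, 6), topography = c(3.2, .6), complexity = c(3.4, .5),
      archetype_attribute = "live_coral",
      fish_probs = pr(Acanthuridae = .90, Scaridae = .85, Labridae = .90,
                      Chaetodontidae = .85, Lethrinidae = .30, Mullidae = .25,
                      Balistidae = .30, Dasyatidae = .02, Elapidae = .04,
                      Carcharhinidae = .18, Pomacentridae = .95, Siganidae = .10),
      fish_scales = scales)
  )
}

# One substrate composition draw: Dirichlet scaled to sum exactly 100.
draw_substrate <- function(archetype) {
  alpha <- archetype$substrate * archetype$substrate_conc
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha             # degenerate guard
  out <- 100 * g / sum(g)
  names(out) <- names(archetype$substrate)
  out
}

# One full station profile draw (plain attribute names).
draw_profile <- function(archetype) {
  sub <- draw_substrate(archetype)
  bio <- archetype$biotic
  overlay <- stats::setNames(
    vapply(seq_len(nrow(bio)), function(i) {
      rtruncnorm(1L, bio$mean[i], bio$sd[i], 0, 100)
    }, numeric(1L)), bio$attribute)
  # biotic overlays share the observed area; rescale if draws exceed it
  if (sum(overlay) > 100) overlay <- overlay * 100 / sum(overlay)
  prof <- c(
    depth = rtruncnorm(1L, archetype$depth["mean"], archetype$depth["sd"], 0, 45),
    topography = rtruncnorm(1L, archetype$topography["mean"],
                            archetype$topography["sd"], 1, 5),
    complexity = rtruncnorm(1L, archetype$complexity["mean"],
                            archetype$complexity["sd"], 1, 5),
    sub, overlay)
  names(prof) <- c("depth", "topography", "complexity", names(sub),
                   names(overlay))
  prof
}

profile_attribute <- function(prof, attribute) {
  comps <- composite_attributes()
  if (attribute %in% names(prof)) return(unname(prof[attribute]))
  if (attribute %in% names(comps)) return(sum(prof[comps[[attribute]]]))
  stop("unknown archetype attribute: ", attribute, call. = FALSE)
}

#' Generate labeled synthetic stations
#'
#' Draws stations from habitat archetypes: substrate compositions from a
#' Dirichlet simplex sampler scaled to 100, biotic overlays from truncated
#' normals (rescaled when the layers would exceed the observed area),
#' ordinal scores on a continuous \[1, 5\] scale, and depth. In `strict`
#' mode a station is redrawn until its habitat's archetypical attribute
#' reaches the guaranteed minimum (default 15%). The generating label is
#' stored in the `habitat` column, and identical seeds give identical
#' output.
#'
#' @param n stations per habitat: a single count or a named vector (names
#'   matching the archetypes).
#' @param archetypes named list of archetypes, see [default_archetypes()].
#' @param strict logical; enforce the archetype minimum by redrawing?
#' @param seed integer seed; fully determines the output.
#' @param max_redraws redraw budget per station in strict mode before the
#'   archetype is declared infeasible.
#' @return Station data frame in the schema of [read_stations()], with the
#'   generating habitat in `habitat`.
#' @export
generate_stations <- function(n = 200L, archetypes = default_archetypes(),
                              strict = TRUE, seed = NULL,
                              max_redraws = 1000L) {
  stopifnot(length(archetypes) >= 1L)
  if (is.null(names(archetypes))) {
    names(archetypes) <- vapply(archetypes, `[[`, character(1L), "habitat")
  }
  if (length(n) == 1L && is.null(names(n))) {
    n <- stats::setNames(rep(as.integer(n), length(archetypes)),
                         names(archetypes))
  }
  if (any(n < 0L)) stop("station counts must be >= 0", call. = FALSE)
  for (a in archetypes) {
    if (a$archetype_min > 100) {
      stop("archetype ", a$habitat, ": guaranteed minimum ", a$archetype_min,
           " is infeasible for a percent cover", call. = FALSE)
    }
  }
  with_seed(seed, {
    rows <- list()
    for (h in names(archetypes)) {
      a <- archetypes[[h]]
      nh <- if (h %in% names(n)) as.integer(n[[h]]) else 0L
      if (nh == 0L) next
      for (i in seq_len(nh)) {
        prof <- draw_profile(a)
        if (strict) {
          tries <- 0L
          while (profile_attribute(prof, a$archetype_attribute) < a$archetype_min) {
            tries <- tries + 1L
            if (tries > max_redraws) {
              stop("archetype ", a$habitat, " cannot reach ", a$archetype_min,
                   "% on ", a$archetype_attribute,
                   "; its parameters are infeasible in strict mode",
                   call. = FALSE)
            }
            prof <- draw_profile(a)
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          station_id = sprintf("SYN-%s-%04d", gsub("[^A-Za-z]", "", h), i),
          site = "synthetic", zone = "coastal",
          depth_m = prof[["depth"]],
          topography = prof[["topography"]], complexity = prof[["complexity"]],
          sand_pc = prof[["sand"]], debris_pc = prof[["debris"]],
          boulder_pc = prof[["boulder"]], rock_pc = prof[["rock"]],
          slab_pc = prof[["slab"]],
          live_coral_pc = prof[["live_coral"]],
          dead_coral_pc = prof[["dead_coral"]],
          erect_algae_pc = prof[["erect_algae"]],
          algal_turf_pc = prof[["algal_turf"]],
          seagrass_pc = prof[["seagrass"]],
          habitat = h, stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else empty_station_frame()
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic fish counts for labeled stations
#'
#' Per-family presence at a station is Bernoulli with the occurrence
#' probability of the station's habitat archetype; a present family
#' contributes two species whose per-rotation counts are Poisson with the
#' family's abundance scale split between species (three rotations per
#' station, with at least one individual guaranteed for a present family).
#'
#' @param stations labeled station data frame (`habitat` set for every row).
#' @param archetypes named list of archetypes, see [default_archetypes()].
#' @param seed integer seed.
#' @return Long-form fish count data frame: `station_id`, `species`,
#'   `family`, `rotation`, `count`.
#' @export
generate_fish <- function(stations, archetypes = default_archetypes(),
                          seed = NULL) {
  if (!"habitat" %in% names(stations) || anyNA(stations$habitat)) {
    stop("all stations must be labeled to generate fish counts", call. = FALSE)
  }
  with_seed(seed, {
    chunks <- vector("list", nrow(stations))
    for (r in seq_len(nrow(stations))) {
      h <- stations$habitat[r]
      a <- archetypes[[h]]
      if (is.null(a)) stop("no archetype for habitat ", h, call. = FALSE)
      fam <- a$fish
      present <- stats::runif(nrow(fam)) < fam$prob
      if (!any(present)) next
      sub <- fam[present, , drop = FALSE]
      per <- lapply(seq_len(nrow(sub)), function(i) {
        counts <- stats::rpois(6L, sub$scale[i] / 2)   # 2 species x 3 rotations
        if (sum(counts) == 0L) counts[1L] <- 1L        # present => observed
        data.frame(
          station_id = stations$station_id[r],
          species = rep(paste0(sub$family[i], c(" sp1", " sp2")), each = 3L),
          family = sub$family[i],
          rotation = rep(1:3, 2L),
          count = counts, stringsAsFactors = FALSE)
      })
      chunks[[r]] <- do.call(rbind, per)
    }
    out <- do.call(rbind, chunks) %||%
      data.frame(station_id = character(), species = character(),
                 family = character(), rotation = integer(),
                 count = integer())
    rownames(out) <- NULL
    out
  })
}
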