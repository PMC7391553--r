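# Shared fixtures, built in code.

# One station row in the canonical CSV schema; covers default to a pure-sand
# substrate so overrides stay physically consistent.
make_station <- function(id = "S1", habitat = NA_character_, depth = 10,
                         topography = 1.5, complexity = 1.5,
                         sand = 100, debris = 0, boulder = 0, rock = 0,
                         slab = 0, live_coral = 0, dead_coral = 0,
                         erect_algae = 0, algal_turf = 0, seagrass = 0,
                         site = "test", zone = "coastal") {
  data.frame(station_id = id, site = site, zone = zone, depth_m = depth,
             topography = topography, complexity = complexity,
             sand_pc = sand, debris_pc = debris, boulder_pc = boulder,
             rock_pc = rock, slab_pc = slab, live_coral_pc = live_coral,
             dead_coral_pc = dead_coral, erect_algae_pc = erect_algae,
             algal_turf_pc = algal_turf, seagrass_pc = seagrass,
             habitat = habitat, stringsAsFactors = FALSE)
}

# Six-frame annotation table with identical frames, overridable per column.
make_frames <- function(...) {
  prof <- list(depth = 10, topography = 1.5, complexity = 1.5, sand = 100,
               debris = 0, boulder = 0, rock = 0, slab = 0, live_coral = 0,
               dead_coral = 0, erect_algae = 0, algal_turf = 0, seagrass = 0)
  over <- list(...)
  out <- as.data.frame(lapply(prof, rep, 6L))
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

# Random small mining instance for oracle-equivalence checks.
random_instance <- function(n_max = 200L, m_max = 14L) {
  n <- sample(10:n_max, 1L)
  m <- sample(4:m_max, 1L)
  attrs <- paste0("a", sample.int(max(2L, m %/% 2L), m, replace = TRUE))
  M <- matrix(stats::runif(n * m) < stats::runif(1L, .2, .8), n, m)
  atoms <- data.frame(id = sprintf("c%02d_%s", seq_len(m), attrs),
                      attribute = attrs, stringsAsFactors = FALSE)
  labs <- sample(habitat_levels()[seq_len(sample(2:4, 1L))], n, replace = TRUE)
  new_transactions(M, atoms, labs)
}

# The 26 expert-rule antecedents in canonical grammar rendering, grouped as
# printed (soft-bottom table then hard-substrate table).
expert_antecedents <- c(
  MA1 = "algae > 80 AND algal_turf < 20",
  MA2 = "60 <= algae < 80 AND algal_turf <= 20 AND dead_coral < 5",
  MA3 = "40 <= algae < 60 AND algal_turf < 20 AND hard_coral <= 20",
  MA4 = "20 <= algae < 40 AND algal_turf < 5 AND seagrass < 40 AND hard_coral < 5",
  SG1 = "seagrass >= 80",
  SG2 = "60 <= seagrass < 80",
  SG3 = "40 <= seagrass < 60 AND algae < 40",
  SG4 = "20 <= seagrass < 40 AND algae < 40 AND depth >= 10",
  SA1 = "sand >= 80 AND seagrass < 20 AND algae < 20",
  SA2 = "sand >= 80 AND seagrass < 20 AND algae >= 20 AND algal_turf > 5",
  SA3 = "60 <= sand < 80 AND seagrass < 5 AND erect_algae < 20",
  SA4 = "40 <= sand < 60 AND 5 <= live_coral < 40 AND complexity < 2 AND hard_substrate < 40",
  SA5 = "40 <= sand < 60 AND 5 <= live_coral < 40 AND 2 <= complexity < 3 AND hard_substrate < 40",
  LC1 = "live_coral >= 60",
  LC2 = "40 <= live_coral < 60 AND hard_coral >= 60",
  LC3 = "40 <= live_coral < 60 AND hard_coral < 60",
  LC4 = "20 <= live_coral < 40 AND hard_coral >= 60",
  LC5 = "20 <= live_coral < 40 AND hard_coral < 60 AND hard_substrate < 40 AND complexity > 2 AND topography > 2",
  LC6 = "15 <= live_coral < 20 AND dead_coral >= 20 AND algal_turf >= 5",
  D1 = "debris >= 60",
  D2 = "40 <= debris < 60 AND boulder >= 1",
  D3 = "40 <= debris < 60 AND boulder < 1 AND sand < 40",
  D4 = "40 <= debris < 60 AND boulder < 1 AND sand >= 40 AND complexity > 1.5",
  D5 = "20 <= debris < 40 AND sand < 60 AND slab_boulder_rock >= 20",
  D6 = "20 <= debris < 40 AND sand < 60 AND 5 < slab_boulder_rock < 20 AND complexity > 2",
  D7 = "5 <= debris < 20 AND slab_boulder_rock >= 20 AND sand < 60 AND hard_coral < 40")

render_antecedent <- function(rule) {
  sub(" => .*$", "", sub("^[^:]+: ", "", render_rule(rule)))
}

# A station in the unclassifiable sand 20-40% band: degraded hard bottom
# with low live coral but hard coral reaching 40, which blocks D7.
unclassifiable_station <- function() {
  make_station("gap", sand = 30, debris = 10, boulder = 10, rock = 10,
               slab = 40, live_coral = 10, dead_coral = 30, complexity = 1.8,
               topography = 1.5, depth = 12)
}
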