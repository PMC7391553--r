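# Typology construction, consolidation, projection, characterization.
# Problem sizes follow the synthetic study conditions (200 stations per
# habitat, strict archetypes, low overlap).

stations_typo <- generate_stations(n = 200, seed = 301)

test_that("clustering recovers the generating habitats (ARI >= 0.9)", {
  mod <- habitat_typology(stations_typo, seed = 302)
  expect_gte(mclust::adjustedRandIndex(mod$habitat, stations_typo$habitat), 0.9)
  # archetype naming matched the generating labels for every cluster
  expect_setequal(unname(mod$cluster_habitat), habitat_levels())
  # determinism: same input and seed twice
  mod2 <- habitat_typology(stations_typo, seed = 302)
  expect_identical(mod$habitat, mod2$habitat)
  expect_identical(mod$cluster, mod2$cluster)
})

test_that("five extreme archetype stations form five correctly named clusters", {
  st <- rbind(
    make_station("sg", depth = 6, sand = 94, slab = 2, debris = 2,
                 boulder = 1, rock = 1, seagrass = 90, algal_turf = 1),
    make_station("ma", depth = 9, sand = 93, slab = 3, debris = 2,
                 boulder = 1, rock = 1, erect_algae = 85, algal_turf = 2),
    make_station("sa", depth = 15, sand = 99, debris = 1, live_coral = 1,
                 algal_turf = 2),
    make_station("de", sand = 3, debris = 90, boulder = 4, rock = 2, slab = 1,
                 dead_coral = 2, algal_turf = 3),
    make_station("lc", sand = 3, rock = 60, slab = 30, boulder = 4, debris = 3,
                 live_coral = 88, dead_coral = 4, complexity = 4,
                 topography = 3.5))
  mod <- habitat_typology(st, n_clusters = 5, seed = 1)
  expect_equal(length(unique(mod$cluster)), 5L)
  expect_equal(mod$habitat,
               c("Seagrass", "Macroalgae", "Sandy", "Debris", "Live Coral"))
})

test_that("consolidation reassigns planted low-archetype stations to Debris", {
  set.seed(303)
  planted <- generate_stations(n = c(Debris = 20), seed = 304)
  moved <- pmax(planted$debris_pc - 10, 0)            # push debris below 15
  planted$slab_pc <- planted$slab_pc + moved
  planted$debris_pc <- planted$debris_pc - moved
  planted$debris_pc <- pmin(planted$debris_pc, 12)
  planted$slab_pc <- 100 - planted$debris_pc - planted$sand_pc -
    planted$boulder_pc - planted$rock_pc
  planted$station_id <- paste0("PL-", seq_len(20))
  all_st <- rbind(stations_typo, planted)

  mod <- habitat_typology(all_st, seed = 305)
  cons <- consolidate(mod, threshold = 15, ntree = 500)
  expect_true(cons$consolidated)
  expect_true(all(cons$oob >= 0 & cons$oob <= 1))
  planted_idx <- which(all_st$station_id %in% planted$station_id)
  reassigned <- cons$reassigned[planted_idx]
  expect_gte(sum(reassigned), 15)                     # most were set aside
  expect_gte(mean(cons$habitat[planted_idx] == "Debris"), 0.8)

  # idempotence: a second pass changes nothing
  cons2 <- consolidate(cons, threshold = 15, ntree = 500)
  expect_identical(cons2$habitat, cons$habitat)
  expect_identical(cons2$reassigned, cons$reassigned)

  # station count conserved, single label each
  expect_equal(length(cons$habitat), nrow(all_st))
  expect_false(anyNA(cons$habitat))
})

test_that("threshold 0 never reassigns", {
  sub <- stations_typo[seq(1, nrow(stations_typo), by = 5), ]
  mod <- habitat_typology(sub, seed = 306)
  cons <- consolidate(mod, threshold = 0, ntree = 200)
  expect_false(any(cons$reassigned))
  expect_identical(cons$habitat, mod$habitat)
})

test_that("projection reproduces training labels and generalizes", {
  mod <- consolidate(habitat_typology(stations_typo, seed = 307), ntree = 500)
  resub <- predict(mod, stations_typo)
  expect_gte(mean(resub$habitat == mod$habitat), 0.95)
  # a station identical to a training station gets the same label
  one <- stations_typo[17, , drop = FALSE]
  expect_equal(predict(mod, one)$habitat, resub$habitat[17])
  # vote shares sum to 1
  votes <- predict(mod, stations_typo[1:10, ], type = "votes")
  expect_equal(unname(rowSums(votes)), rep(1, 10))
  # holdout accuracy on fresh strict-mode stations
  hold <- generate_stations(n = 100, seed = 308)
  pr <- predict(mod, hold)
  expect_gte(mean(pr$habitat == hold$habitat), 0.9)
  # unconsolidated models refuse to project
  expect_error(predict(habitat_typology(stations_typo, seed = 1),
                       stations_typo), "consolidate")
  # schema error on missing attributes
  expect_error(predict(mod, stations_typo[, -which(names(stations_typo) ==
                                                     "sand_pc")]),
               "sand_pc")
})

test_that("characterization finds planted effects and respects tiers", {
  ch <- characterize(stations_typo)
  sg <- ch[ch$habitat == "Seagrass" & ch$attribute == "seagrass", ]
  expect_equal(sg$direction, "higher")
  expect_equal(sg$significance, "highly significant")
  expect_gt(sg$cluster_mean, sg$global_mean)
  # an attribute is never both higher and lower within a habitat
  expect_false(any(duplicated(ch[, c("habitat", "attribute")])))
  # attributes sorted by decreasing significance within habitat
  for (h in unique(ch$habitat)) {
    p <- ch$p_adj[ch$habitat == h]
    expect_true(!is.unsorted(p, na.rm = TRUE))
  }
})

test_that("a constant attribute lands in neither list", {
  st <- stations_typo[1:100, ]
  st$depth_m <- 12
  ch <- characterize(st)
  expect_true(all(ch$significance[ch$attribute == "depth"] == "ns"))
})

test_that("permuted labels produce about the nominal significance rate", {
  st <- stations_typo[stations_typo$habitat %in%
                        c("Sandy", "Debris", "Seagrass"), ]
  st <- st[seq(1, nrow(st), by = 4), ]     # thin for speed
  set.seed(309)
  flagged <- replicate(20, {
    st$habitat <- sample(st$habitat)
    ch <- characterize(st)
    mean(ch$significance != "ns")
  })
  # Holm controls the familywise rate within each habitat at 5%
  expect_lte(mean(flagged), 0.1)
})
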