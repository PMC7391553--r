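test_that("the packaged expert ruleset has the printed structure", {
  rs <- expert_rules()
  habs <- vapply(rs$rules, `[[`, character(1), "habitat")
  expect_length(rs$rules, 26L)
  expect_equal(sum(habs == "Macroalgae"), 4L)
  expect_equal(sum(habs == "Seagrass"), 4L)
  expect_equal(sum(habs == "Sandy"), 5L)
  expect_equal(sum(habs == "Live Coral"), 6L)
  expect_equal(sum(habs == "Debris"), 7L)
})

test_that("the packaged conditions match the printed rules verbatim", {
  rs <- expert_rules()
  got <- vapply(rs$rules, render_antecedent, character(1))
  expect_equal(got[names(expert_antecedents)], expert_antecedents)
})

test_that("rulesets round-trip through the grammar", {
  rs <- expert_rules()
  back <- parse_ruleset(render_ruleset(rs))
  expect_equal(render_ruleset(back), render_ruleset(rs))
  expect_equal(names(back$rules), names(rs$rules))
  for (id in names(rs$rules)) {
    expect_equal(back$rules[[id]]$conditions, rs$rules[[id]]$conditions)
    expect_equal(back$rules[[id]]$conf, rs$rules[[id]]$conf)
    expect_equal(back$rules[[id]]$confusion, rs$rules[[id]]$confusion)
  }
})

test_that("the grammar reports malformed input precisely", {
  expect_error(parse_ruleset("R1: seagrass >>= 80 => Seagrass"), "line 1")
  expect_error(parse_ruleset("R1: rugosity >= 80 => Seagrass"),
               "unknown attribute")
  expect_error(parse_ruleset("R1: seagrass >= 80 => Atlantis"),
               "unknown habitat")
  expect_error(
    parse_ruleset(c("A: sand >= 80 => Sandy", "A: sand >= 90 => Sandy")),
    "duplicate")
  expect_warning(rs <- parse_ruleset(character()), "no rules")
  expect_length(rs$rules, 0L)
})

test_that("prediction fires the printed rules on archetypal stations", {
  rs <- expert_rules()
  # dense seagrass bed
  p <- predict_habitat(make_station("sg", seagrass = 85), rs)
  expect_equal(p$habitat, "Seagrass")
  expect_equal(p$rule_id, "SG1")
  expect_equal(p$confidence, 100)
  # healthy coral cover
  lc <- make_station("lc", sand = 5, rock = 60, slab = 30, boulder = 3,
                     debris = 2, live_coral = 65, complexity = 3.5,
                     topography = 3)
  p2 <- predict_habitat(lc, rs)
  expect_equal(p2$habitat, "Live Coral")
  expect_equal(p2$rule_id, "LC1")
  expect_equal(p2$confidence, 100)
  # the sand 20-40% band the ruleset deliberately leaves out
  p3 <- predict_habitat(unclassifiable_station(), rs)
  expect_equal(p3$habitat, "UNCLASSIFIED")
  expect_equal(p3$n_fired, 0L)
  expect_false(p3$conflict)
})

test_that("multi-rule fires are flagged and resolved by stored confidence", {
  rs <- expert_rules()
  # seagrass overlay on a debris bottom fires SG1 and D1 together
  both <- make_station("mix", sand = 30, debris = 70, seagrass = 85)
  p <- predict_habitat(both, rs)
  expect_true(p$conflict)
  expect_equal(p$n_fired, 2L)
  expect_setequal(strsplit(p$rule_id, ",")[[1]], c("SG1", "D1"))
  p_none <- predict_habitat(both, rs, priority = "none")
  expect_true(is.na(p_none$habitat))
})

test_that("assessment matches a station-by-station replay of predict", {
  rs <- expert_rules()
  st <- generate_stations(n = 60, seed = 71)
  ass <- assess_ruleset(st, rs)
  pred <- predict_habitat(st, rs)
  for (h in setdiff(ass$habitat, "Overall")) {
    in_h <- st$habitat == h
    expect_equal(ass$pct_classified[ass$habitat == h],
                 100 * mean(pred$n_fired[in_h] > 0))
    cl <- in_h & pred$n_fired > 0
    expect_equal(ass$overall_confidence[ass$habitat == h],
                 100 * mean(pred$habitat[cl] == h))
  }
  ov <- ass[ass$habitat == "Overall", ]
  expect_equal(ov$pct_classified, 100 * mean(pred$n_fired > 0))
})

test_that("assessment boundary cases: perfect rules and silent rules", {
  perfect <- parse_ruleset(c("S: seagrass >= 50 => Seagrass",
                             "D: debris >= 50 => Debris"))
  st <- rbind(make_station("a", seagrass = 80, habitat = "Seagrass"),
              make_station("b", sand = 20, debris = 80, habitat = "Debris"))
  ass <- suppressMessages(assess_ruleset(st, perfect))
  expect_true(all(ass$pct_classified == 100))
  expect_true(all(ass$overall_confidence == 100))

  silent <- parse_ruleset("M: algae > 90 => Macroalgae")
  ass0 <- suppressMessages(assess_ruleset(st, silent))
  expect_true(all(ass0$pct_classified == 0))
  expect_true(all(is.na(ass0$overall_confidence)))

  # habitats absent from the data are omitted with a note
  expect_message(assess_ruleset(st, perfect), "absent")
  expect_setequal(ass$habitat, c("Seagrass", "Debris", "Overall"))
})

test_that("exclusivity decisions are self-consistent", {
  rs <- expert_rules()
  # a rule paired with itself is satisfiable
  one <- new_ruleset(rs$rules["SG1"], name = "one")
  ex1 <- check_exclusivity(one)
  expect_equal(as.data.frame(ex1)$status, "SATISFIABLE")
  # dense algae and dense seagrass cannot share the observed area
  pair <- new_ruleset(rs$rules[c("MA1", "SG1")], name = "pair")
  ex2 <- as.data.frame(check_exclusivity(pair, include_self = FALSE))
  expect_equal(ex2$status[ex2$rule1 == "MA1" & ex2$rule2 == "SG1"],
               "EXCLUSIVE")
  # dropping the biotic-layer constraint makes the pair satisfiable
  ex3 <- as.data.frame(check_exclusivity(
    pair, constraints = default_cover_constraints(biotic_max = NULL),
    include_self = FALSE))
  expect_equal(ex3$status[ex3$rule1 == "MA1" & ex3$rule2 == "SG1"],
               "SATISFIABLE")

  # every witness re-fires both rules through predict()
  set.seed(81)
  sub <- new_ruleset(rs$rules[c("MA3", "SG3", "SA3", "SA5", "LC5", "D6", "D7")],
                     name = "sub")
  ex <- as.data.frame(check_exclusivity(sub))
  expect_false(any(ex$status == "INCONCLUSIVE"))
  for (i in which(ex$status == "SATISFIABLE")) {
    w <- ex$witness[[i]]
    fired <- predict_habitat(w, sub)
    ids <- strsplit(fired$rule_id, ",")[[1]]
    expect_true(all(c(ex$rule1[i], ex$rule2[i]) %in% ids))
  }
})

test_that("within-habitat expert rules are mutually exclusive", {
  rs <- expert_rules()
  habs <- vapply(rs$rules, `[[`, character(1), "habitat")
  set.seed(82)
  for (h in c("Seagrass", "Macroalgae")) {
    sub <- new_ruleset(rs$rules[habs == h], name = h)
    ex <- as.data.frame(check_exclusivity(sub, include_self = FALSE))
    expect_true(all(ex$status == "EXCLUSIVE"),
                info = paste("overlap within", h))
  }
})
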