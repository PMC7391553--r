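test_that("discretization maps stations to the grid conditions they satisfy", {
  st <- rbind(make_station("hi-sg", sand = 15, debris = 85, seagrass = 85,
                           habitat = "Seagrass"),
              make_station("zero", habitat = "Sandy"))
  tr <- discretize(st)
  expect_true("seagrass >= 80" %in% satisfied_conditions(tr, "hi-sg"))
  # an all-zero biotic profile satisfies only "<" conditions for those covers
  zero <- satisfied_conditions(tr, "zero")
  sg_conds <- grep("seagrass", zero, value = TRUE)
  expect_true(all(grepl("^seagrass <", sg_conds)))
  expect_true("seagrass < 1" %in% sg_conds)

  # a station fulfilling SA1 carries all of SA1's antecedent atoms
  sa1 <- make_station("sa1", sand = 90, debris = 10, habitat = "Sandy")
  tr2 <- discretize(sa1)
  conds <- satisfied_conditions(tr2, "sa1")
  expect_true(all(c("sand >= 80", "seagrass < 20", "algae < 20") %in% conds))

  expect_error(discretize(st, grid = list()), "empty")
  st$habitat[1] <- NA
  expect_error(discretize(st), "labeled")
})

test_that("a dominant single condition yields the expected top rule", {
  # one condition matched by 5 transactions, all labeled Sandy
  M <- matrix(c(rep(TRUE, 5), rep(FALSE, 5)), ncol = 1)
  atoms <- data.frame(id = "a1", attribute = "x")
  labs <- c(rep("Sandy", 5), rep("Debris", 5))
  tr <- new_transactions(M, atoms, labs)
  top <- mine_topk(tr, k = 1, min_conf = 80)
  expect_equal(nrow(top), 1L)
  expect_equal(top$support, 5)
  expect_equal(top$confidence, 100)
  expect_equal(top$consequent, "Sandy")
})

test_that("brute force enumerates the antecedent lattice", {
  # 1 transaction, 2 atoms on distinct attributes, max 2 conditions:
  # 3 antecedents (2 singletons + 1 pair), all confidence 100
  tr <- new_transactions(matrix(TRUE, 1, 2),
                         data.frame(id = c("a", "b"),
                                    attribute = c("x", "y")),
                         "Sandy")
  bf <- brute_force_rules(tr, min_conf = 50, max_len = 2)
  expect_equal(nrow(bf), 3L)
  expect_true(all(bf$confidence == 100))
  # max_len 1 keeps only singletons
  expect_equal(nrow(brute_force_rules(tr, min_conf = 50, max_len = 1)), 2L)
  # guard refuses large instances with a size hint
  big <- new_transactions(matrix(TRUE, 2, 25),
                          data.frame(id = paste0("a", 1:25),
                                     attribute = paste0("x", 1:25)),
                          c("Sandy", "Sandy"))
  expect_error(brute_force_rules(big), "guard")
})

test_that("min_conf = 100 with a counterexample everywhere returns nothing", {
  # every atom matches one Sandy and one Debris transaction
  M <- matrix(TRUE, 2, 2)
  tr <- new_transactions(M, data.frame(id = c("a", "b"),
                                       attribute = c("x", "y")),
                         c("Sandy", "Debris"))
  expect_equal(nrow(mine_topk(tr, k = 10, min_conf = 100)), 0L)
  expect_equal(nrow(brute_force_rules(tr, min_conf = 100)), 0L)
})

test_that("k beyond the number of valid rules returns them all", {
  set.seed(41)
  tr <- random_instance(n_max = 60, m_max = 8)
  bf <- brute_force_rules(tr, min_conf = 70)
  mk <- mine_topk(tr, k = 1e6, min_conf = 70)
  expect_equal(nrow(mk), nrow(bf))
})

test_that("the miner equals the brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:25) {
    tr <- random_instance()
    mc <- runif(1, 40, 95)
    bf <- brute_force_rules(tr, min_conf = mc)
    mk <- mine_topk(tr, k = Inf, min_conf = mc)
    expect_equal(as.data.frame(mk)[, 1:6], as.data.frame(bf)[, 1:6],
                 ignore_attr = TRUE)
  }
})

test_that("support is anti-monotone and consistent with confidence", {
  set.seed(43)
  tr <- random_instance()
  rules <- brute_force_rules(tr, min_conf = 10, max_len = 3)
  # confidence = support / antecedent-support exactly
  expect_equal(rules$confidence,
               100 * rules$support / rules$antecedent_support)
  expect_true(all(rules$support <= rules$antecedent_support))
  # adding a condition never increases support
  M <- tr$matches
  for (r in 1:50) {
    ii <- sample(ncol(M), 2)
    a1 <- sum(M[, ii[1]])
    a12 <- sum(M[, ii[1]] & M[, ii[2]])
    expect_lte(a12, a1)
  }
})

test_that("mining constraints are validated", {
  tr <- random_instance()
  expect_error(mine_topk(tr, k = 0), "positive")
  expect_error(mine_topk(tr, min_conf = 0), "min_conf")
  expect_error(mine_topk(tr, min_conf = 101), "min_conf")
})

test_that("per-class mining recovers rules for minority habitats", {
  # one rare class whose rules would fall outside a small global top-k
  M <- cbind(c(rep(TRUE, 40), rep(FALSE, 3)),
             c(rep(FALSE, 40), rep(TRUE, 3)))
  tr <- new_transactions(M, data.frame(id = c("common", "rare"),
                                       attribute = c("x", "y")),
                         c(rep("Sandy", 40), rep("Macroalgae", 3)))
  glob <- mine_topk(tr, k = 1, min_conf = 80)
  expect_false("Macroalgae" %in% glob$consequent)
  per <- mine_topk(tr, k = 1, min_conf = 80, per_class = TRUE)
  expect_true("Macroalgae" %in% per$consequent)
})

test_that("evaluate_rule computes support, confidence and confusion", {
  rs <- expert_rules()
  # 10 antecedent matches, 9 of the consequent habitat
  st <- do.call(rbind, lapply(1:10, function(i) {
    make_station(paste0("s", i), sand = 10, debris = 90, seagrass = 85,
                 habitat = if (i <= 9) "Seagrass" else "Debris")
  }))
  ev <- evaluate_rule(rs$rules$SG1, st)
  expect_equal(ev$conf, 90)
  expect_equal(ev$n, 9)
  expect_equal(ev$antecedent_n, 10)
  expect_equal(unname(ev$confusion[["Debris"]]), 10)
  expect_equal(ev$conf + sum(ev$confusion), 100)

  # antecedent matched by none -> not evaluable
  ev0 <- evaluate_rule(rs$rules$SG1, make_station("x", habitat = "Sandy"))
  expect_false(ev0$evaluable)
  expect_true(is.na(ev0$conf))

  # SG1 at 100% when no non-Seagrass station reaches seagrass >= 80
  st2 <- generate_stations(n = 50, seed = 91)
  stopifnot(!any(st2$seagrass_pc >= 80 & st2$habitat != "Seagrass"))
  ev2 <- evaluate_rule(rs$rules$SG1, st2)
  if (ev2$evaluable) expect_equal(ev2$conf, 100)
})

test_that("mined rules honor the antecedent length cap", {
  st <- generate_stations(n = 30, seed = 92)
  tr <- discretize(st)
  rules <- mine_topk(tr, k = 200, min_conf = 90, max_len = 3)
  expect_true(all(rules$n_conditions <= 3))
  expect_true(all(rules$confidence >= 90))
  # rules convert to the grammar and round-trip through it
  rs <- as_ruleset(utils::head(rules, 5), tr)
  back <- parse_ruleset(render_ruleset(rs))
  expect_equal(length(back$rules), 5L)
  expect_equal(render_ruleset(back), render_ruleset(rs))
})
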