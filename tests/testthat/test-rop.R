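test_that("ROPs divide monthly item counts by monthly totals", {
  ep <- rbind(make_episodes(rep("seed", 3), "ground", months = 1L),
              make_episodes("invertebrate", "tree", months = 1L),
              make_episodes("unidentified", "tree", months = 1L))
  rop <- compute_rop(tally_episodes(ep))
  expect_equal(unname(rop$values["Jan", c("seed", "invertebrate",
                                          "unidentified")]),
               c(0.6, 0.2, 0.2))
  expect_equal(rop$support[1], 5L)
  expect_false(rop$defined[2])
  expect_true(all(is.na(rop$values["Feb", ])))

  # single-item month
  solo <- compute_rop(tally_episodes(make_episodes(rep("seed", 5), "ground",
                                                   months = 3L)))
  expect_equal(unname(solo$values["Mar", "seed"]), 1)
})

test_that("identified-only ROPs renormalize over identified items", {
  ep <- rbind(make_episodes(rep("seed", 3), "ground", months = 1L),
              make_episodes("invertebrate", "tree", months = 1L),
              make_episodes("unidentified", "tree", months = 1L))
  ct <- tally_episodes(ep)
  rid <- rop_identified_only(ct)
  expect_equal(unname(rid$values["Jan", c("seed", "invertebrate")]),
               c(0.75, 0.25))
  expect_false("unidentified" %in% colnames(rid$values))

  # all episodes unidentified in a month -> undefined row
  allu <- tally_episodes(make_episodes("unidentified", "ground", months = 4L))
  expect_false(rop_identified_only(allu)$defined[4])

  # agreement with compute_rop when nothing is unidentified
  ep2 <- make_episodes(c("seed", "seed", "flower"), "ground", months = 6L)
  ct2 <- tally_episodes(ep2)
  expect_equal(rop_identified_only(ct2)$values[6, ],
               compute_rop(ct2)$values[6, colnames(rid$values)])
})

test_that("defined composition rows always sum to one", {
  set.seed(7)
  sch <- diet_schema()
  ep <- make_episodes(sample(sch$items, 200, replace = TRUE),
                      sample(sch$locations, 200, replace = TRUE),
                      months = sample(1:12, 200, replace = TRUE))
  ct <- tally_episodes(ep)
  for (tab in list(compute_rop(ct), rop_identified_only(ct),
                   location_profile(ct))) {
    sums <- rowSums(tab$values[tab$defined, , drop = FALSE])
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  # pooling invariance: reassigning years never changes ROPs
  ep2 <- ep
  ep2$year <- sample(1990:2006, nrow(ep), replace = TRUE)
  expect_identical(compute_rop(tally_episodes(ep2))$values,
                   compute_rop(ct)$values)
})

test_that("location profiles aggregate over items", {
  ep <- rbind(make_episodes(c("seed", "invertebrate"), "ground", months = 5L),
              make_episodes(c("seed", "unidentified"), "tree", months = 5L))
  lp <- location_profile(tally_episodes(ep))
  expect_equal(unname(lp$values["May", c("ground", "tree")]), c(0.5, 0.5))
  expect_false(lp$defined[1])
})

test_that("chi-square statistic matches the 2x2 closed form", {
  # fixed example and random positive-margin tables
  tab <- matrix(c(40L, 10L, 10L, 40L), 2, byrow = TRUE)
  expect_equal(chisq_2x2_closed_form(tab), 36)
  set.seed(11)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20) + 1L, 2, 2)
    got <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
    expect_equal(unname(got), chisq_2x2_closed_form(tab), tolerance = 1e-12)
  }
})

test_that("seasonal animal test builds the right table and one-sided p", {
  # 40 animal / 10 plant in breeding months, reversed in wintering
  ep <- rbind(
    make_episodes(rep("invertebrate", 40), "tree", months = 5L),
    make_episodes(rep("seed", 10), "ground", months = 6L),
    make_episodes(rep("invertebrate", 10), "tree", months = 11L),
    make_episodes(rep("seed", 40), "ground", months = 12L),
    make_episodes(rep("unidentified", 7), "ground", months = 1L)) # ignored
  st <- seasonal_animal_test(tally_episodes(ep))
  expect_equal(unname(st$table), matrix(c(40L, 10L, 10L, 40L), 2))
  expect_equal(st$statistic, 36)
  expect_true(st$direction_ok)
  expect_equal(st$p_one_sided,
               suppressWarnings(chisq.test(st$table,
                                           correct = FALSE))$p.value / 2)

  # no association: statistic 0, one-sided p = 0.5
  ep_flat <- rbind(
    make_episodes(rep("invertebrate", 20), "tree", months = 5L),
    make_episodes(rep("seed", 20), "ground", months = 6L),
    make_episodes(rep("invertebrate", 20), "tree", months = 11L),
    make_episodes(rep("seed", 20), "ground", months = 12L))
  st_flat <- seasonal_animal_test(tally_episodes(ep_flat))
  expect_equal(st_flat$statistic, 0)
  expect_equal(st_flat$p_one_sided, 0.5)

  # a season without identified episodes is flagged undefined
  st_un <- seasonal_animal_test(tally_episodes(
    make_episodes(rep("seed", 10), "ground", months = 1L)))
  expect_false(st_un$defined)
  expect_true(is.na(st_un$p_one_sided))
})

test_that("seasonal ground test uses wintering > breeding direction", {
  ep <- rbind(
    make_episodes(rep("seed", 10), "ground", months = 5L),
    make_episodes(rep("seed", 40), "tree", months = 6L),
    make_episodes(rep("seed", 40), "ground", months = 11L),
    make_episodes(rep("seed", 10), "tree", months = 12L))
  st <- seasonal_ground_test(tally_episodes(ep))
  expect_equal(st$statistic, 36)
  expect_true(st$direction_ok)
  expect_lt(st$p_one_sided, 0.01)

  # all-ground species: degenerate zero margin
  st_deg <- seasonal_ground_test(tally_episodes(
    make_episodes(rep("seed", 20), "ground", months = c(5L, 11L))))
  expect_false(st_deg$defined)
})

test_that("species summary reproduces totals and unidentified proportions", {
  ep <- rbind(make_episodes(c(rep("seed", 7), rep("unidentified", 3)),
                            "ground", months = 1L, species = "A"),
              make_episodes(c("seed", "unidentified"), "tree", months = 2L,
                            species = "B"))
  s <- species_summary(ep)
  expect_equal(s$species, c("A", "B"))   # ordered by total
  expect_equal(s$total, c(10L, 2L))
  expect_equal(s$identified, c(7L, 1L))
  expect_equal(s$prop_unidentified, c(0.3, 0.5))
  expect_equal(s$Jan, c(10L, 0L))
})
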