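seed <- parse_sequence("GlcA-pNA-N3")

test_that("eligibility encodes the enzyme specificity rules", {
  iv <- get_fixture("IV")$oligo

  # C5-epimerase acts only on a GlcA between two N-sulfoglucosamines:
  # on intermediate IV that is exactly the middle GlcA (residue C)
  expect_identical(eligible_sites(iv, "C5-epi"), "C")
  expect_identical(eligible_sites(iv, "C5-epi+2-OST"), "C")

  # ...but not before N-sulfation: the GlcNTFA backbone has no site
  backbone <- parse_sequence(
    "GlcA(1-4)GlcNTFA(1-4)GlcA(1-4)GlcNTFA(1-4)GlcA-pNA-N3")
  expect_identical(eligible_sites(backbone, "C5-epi"), character(0))
  expect_identical(eligible_sites(backbone, "deTFA+NST"), c("B", "D"))

  # 3-OST-1 needs GlcA on the non-reducing side: residue C, not E
  pre14 <- apply_action(apply_action(apply_action(
    get_fixture("VI")$oligo, "pmHS2+GlcNTFA"), "deTFA+NST"), "6-OST")
  expect_identical(eligible_sites(pre14, "3-OST-1"), "C")

  # with several GlcA-flanked sites, IdoA2S on the reducing side wins
  pre28 <- apply_action(apply_action(apply_action(apply_action(
    get_fixture("VI")$oligo, "pmHS2+GlcNTFA"), "pmHS2+GlcA"),
    "deTFA+NST"), "6-OST")
  expect_identical(eligible_sites(pre28, "3-OST-1"), "D")

  # elongation only extends the non-reducing end with the correct ring
  expect_identical(eligible_sites(seed, "pmHS2+GlcA"), character(0))
  expect_identical(eligible_sites(seed, "pmHS2+GlcNTFA"), "A")

  # 6-OST takes every GlcNS/GlcNAc lacking a 6-O-sulfo, not GlcNTFA
  mixed <- parse_sequence(
    "GlcA(1-4)GlcNAc(1-4)GlcA(1-4)GlcNS6S(1-4)GlcA(1-4)GlcNTFA(1-4)GlcA-pNA-N3")
  expect_identical(eligible_sites(mixed, "6-OST"), "B")
})

test_that("GlcNS3S6S counts as N-sulfo for the epimerase flanking rule", {
  cmp14 <- get_fixture("14")$oligo  # B = GlcA between GlcNS6S and GlcNS3S6S
  expect_identical(eligible_sites(cmp14, "C5-epi"), "B")
})

test_that("applying actions reproduces the documented transformations", {
  iv <- get_fixture("IV")$oligo

  expect_identical(format_sequence(apply_action(iv, "C5-epi+2-OST", "C")),
                   format_sequence(get_fixture("VI")$oligo))
  expect_identical(format_sequence(apply_action(iv, "C5-epi")),
                   format_sequence(get_fixture("V")$oligo))

  # 2-OST on GlcA: one site gives 65, both sites give 66
  expect_identical(format_sequence(apply_action(iv, "2-OST-on-GlcA", "C")),
                   format_sequence(get_fixture("65")$oligo))
  expect_identical(
    format_sequence(apply_action(iv, "2-OST-on-GlcA", c("A", "C"))),
    format_sequence(get_fixture("66")$oligo))
  # the aglycone-bearing terminal GlcA is off-limits by default
  expect_error(apply_action(iv, "2-OST-on-GlcA", "E"), "ineligible")
  expect_identical(
    eligible_sites(iv, "2-OST-on-GlcA",
                   planner_control(allow_terminal_2ost = TRUE)),
    c("C", "A", "E"))

  expect_error(apply_action(iv, "3-OST-1"), "not applicable")
  expect_error(apply_action(seed, "pmHS2+GlcA"), "not applicable")

  # every action output is itself a valid chain
  out <- apply_action(iv, "6-OST")
  expect_s3_class(out, "hs_oligo")
  expect_identical(out$tokens[c(2, 4)], c("GlcNS6S", "GlcNS6S"))
})

test_that("planned routes match the documented step sequences", {
  iv <- get_fixture("IV")$oligo
  rt <- plan_route(seed, iv)
  expect_true(rt$feasible)
  expect_identical(rt$steps$action,
                   c("pmHS2+GlcNTFA", "pmHS2+GlcA", "pmHS2+GlcNTFA",
                     "pmHS2+GlcA", "deTFA+NST"))
  expect_identical(rt$steps$donor[1], "UDP-GlcNTFA")

  rt2 <- plan_route(iv, get_fixture("VI")$oligo)
  expect_identical(rt2$steps$action, "C5-epi+2-OST")

  rt3 <- plan_route(get_fixture("VI")$oligo, get_fixture("14")$oligo)
  expect_identical(rt3$steps$action,
                   c("pmHS2+GlcNTFA", "deTFA+NST", "6-OST", "3-OST-1"))

  # determinism: identical inputs, identical routes
  rt3b <- plan_route(get_fixture("VI")$oligo, get_fixture("14")$oligo)
  expect_identical(rt3$steps, rt3b$steps)
})

test_that("planner routes replay cleanly and end at their targets", {
  for (nm in c("III", "IV", "V", "VI", "65", "66")) {
    target <- get_fixture(nm)$oligo
    rt <- plan_route(seed, target)
    expect_true(rt$feasible, info = nm)
    v <- validate_route(rt)
    expect_true(v$valid, info = nm)
    expect_identical(rt$steps$product[nrow(rt$steps)],
                     format_sequence(target), info = nm)
  }
  # the larger compounds, staged through intermediate VI
  vi <- get_fixture("VI")$oligo
  for (nm in c("14", "28", "46")) {
    rt <- plan_route(vi, get_fixture(nm)$oligo)
    expect_true(rt$feasible, info = nm)
    expect_true(validate_route(rt)$valid, info = nm)
  }
})

test_that("a tampered route fails validation with a diagnostic", {
  rt <- plan_route(seed, get_fixture("IV")$oligo)
  bad <- rt
  bad$steps$action[5] <- "6-OST"   # TFA backbone: 6-OST inapplicable
  v <- validate_route(bad)
  expect_false(v$valid)
  expect_identical(v$first_failure$step, 5L)
})

test_that("3-OST-1 before 6-OST is rejected by default, allowed by flag", {
  vi6 <- apply_action(apply_action(get_fixture("VI")$oligo,
                                   "pmHS2+GlcNTFA"), "deTFA+NST")
  # default rule: the acceptor must already carry 6-O-sulfo
  expect_identical(eligible_sites(vi6, "3-OST-1"), character(0))
  relaxed <- planner_control(require_6s_for_3ost = FALSE)
  expect_identical(eligible_sites(vi6, "3-OST-1", relaxed), "C")
})

test_that("unmakeable targets yield an infeasibility report", {
  target <- parse_sequence(
    "GlcA(1-4)GlcNAc(1-4)IdoA(1-4)GlcNAc(1-4)GlcA-pNA-N3")
  rt <- plan_route(seed, target, planner_control(max_steps = 8))
  expect_false(rt$feasible)
  expect_match(rt$reason, "no route within")
})

test_that("enumeration is deterministic and anchored at the seed", {
  expect_identical(enumerate_library(seed, 0), format_sequence(seed))
  lib3a <- enumerate_library(seed, 3)
  lib3b <- enumerate_library(seed, 3)
  expect_identical(lib3a, lib3b)
  expect_true(format_sequence(seed) %in% lib3a)
  expect_true(format_sequence(get_fixture("III")$oligo) %in% lib3a)
  # every enumerated sequence is a valid chain
  for (s in lib3a) expect_s3_class(parse_sequence(s), "hs_oligo")
})

test_that("IdoA2S and GlcA2S are locked against epimerization", {
  # no action may revert IdoA2S or epimerize GlcA2S, anywhere
  states <- list(get_fixture("VI")$oligo, get_fixture("66")$oligo,
                 get_fixture("14")$oligo)
  for (o in states) {
    expect_identical(eligible_sites(o, "C5-epi-rev"), character(0))
    locked2s <- which(o$tokens %in% c("IdoA2S", "GlcA2S"))
    modif <- setdiff(enzyme_actions()$name,
                     c("pmHS2+GlcNAc", "pmHS2+GlcNTFA", "pmHS2+GlcA"))
    for (a in modif) {
      elig <- eligible_sites(o, a)
      idx <- match(elig, residue_labels(o))
      expect_length(intersect(idx, locked2s), 0L)
    }
  }
})
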