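test_that("sequence grammar parses the worked compound strings", {
  s14 <- "GlcNS6S(1-4)GlcA(1-4)GlcNS3S6S(1-4)IdoA2S(1-4)GlcNS6S(1-4)GlcA-pNA-N3"
  o <- parse_sequence(s14)
  expect_length(o, 6L)
  expect_identical(o$aglycone, "pNA-N3")
  expect_identical(residue_labels(o), LETTERS[1:6])
  expect_identical(format_sequence(o), s14)

  seed <- parse_sequence("GlcA-pNA-N3")
  expect_length(seed, 1L)
  expect_identical(seed$tokens, "GlcA")

  # arrow spelling variant
  expect_identical(format_sequence(parse_sequence("GlcA(1->4)GlcNS-pNP")),
                   "GlcA(1-4)GlcNS-pNP")
})

test_that("invalid sequences are rejected with informative errors", {
  expect_error(parse_sequence("GlcNS(1-4)GlcNS-pNA-N3"), "alternation")
  expect_error(parse_sequence("GlcA(1-4)GlcA-pNA-N3"), "alternation")
  expect_error(parse_sequence("GlcQ-pNA-N3"), "unknown residue")
  expect_error(parse_sequence("GlcA6S-pNA-N3"), "unknown residue")
  # 3-O-sulfo demands N-sulfation: GlcNAc3S does not exist in this chemistry
  expect_error(parse_sequence("GlcNAc3S6S(1-4)GlcA-pNA-N3"), "N-sulfated")
  expect_error(hs_residue("gluco-uronic", o_sulfo = 6), "within \\{2\\}")
  expect_error(hs_residue("glucosamine", "sulfo", 2), "within \\{3, 6\\}")
})

test_that("anomeric configuration is derived from ring type", {
  expect_identical(parse_residue("GlcA")$anomeric_config, "beta")
  expect_identical(parse_residue("GlcA2S")$anomeric_config, "beta")
  expect_identical(parse_residue("IdoA2S")$anomeric_config, "alpha")
  expect_identical(parse_residue("GlcNS3S6S")$anomeric_config, "alpha")
})

test_that("parse/format round-trips over fixtures and random sequences", {
  for (o in all_fixture_oligos())
    expect_identical(parse_sequence(format_sequence(o)), o)
  for (i in 1:250) {
    o <- random_sequence(length = 1L + (i %% 9L), rng_seed = i,
                         first_ring = if (i %% 3L) "uronic" else "glucosamine",
                         aglycone = c("pNA-N3", "pNP", "free")[1L + i %% 3L])
    expect_identical(parse_sequence(format_sequence(o)), o)
  }
})

test_that("AT pentasaccharide motif is found exactly where expected", {
  hit14 <- find_at_motif(get_fixture("14")$oligo)
  expect_identical(hit14$start_label, "A")
  expect_identical(hit14$end_label, "E")

  expect_identical(find_at_motif(get_fixture("28")$oligo)$start_label, "B")
  expect_identical(find_at_motif(get_fixture("46")$oligo)$start_label, "C")

  # the bare pattern matches itself, once
  pat <- parse_sequence("GlcNS6S(1-4)GlcA(1-4)GlcNS3S6S(1-4)IdoA2S(1-4)GlcNS6S")
  expect_identical(nrow(find_at_motif(pat)), 1L)

  # no 3-O-sulfo residue anywhere in the intermediates: no hits
  for (nm in c("I", "II", "III", "IV", "V", "VI", "VII"))
    expect_identical(nrow(find_at_motif(get_fixture(nm)$oligo)), 0L)
})

test_that("sulfation statistics match hand counts and conserve totals", {
  s14 <- sulfation_stats(get_fixture("14")$oligo)
  expect_identical(s14$total_sulfo, 8L)
  expect_identical(c(s14$n_sulfo, s14$o2_sulfo, s14$o3_sulfo, s14$o6_sulfo),
                   c(3L, 1L, 1L, 3L))
  expect_equal(s14$sulfo_per_disaccharide, 8 / 3, tolerance = 1e-12)
  expect_equal(s14$pct_idoA_of_uronic, 100 / 3, tolerance = 1e-12)

  siv <- sulfation_stats(get_fixture("IV")$oligo)
  expect_identical(siv$total_sulfo, 2L)
  expect_identical(siv$n_sulfo, 2L)
  expect_identical(siv$pct_idoA_of_uronic, 0)

  backbone <- sulfation_stats(parse_sequence("GlcA(1-4)GlcNAc(1-4)GlcA-pNA-N3"))
  expect_identical(backbone$total_sulfo, 0L)

  for (o in all_fixture_oligos()) {
    s <- sulfation_stats(o)
    expect_identical(s$n_sulfo + s$o2_sulfo + s$o3_sulfo + s$o6_sulfo,
                     s$total_sulfo)
  }
})

test_that("fixture registry returns printed vs reconstructed structures", {
  f14 <- get_fixture("14")
  expect_identical(f14$flag, "printed")
  expect_identical(
    format_sequence(f14$oligo),
    "GlcNS6S(1-4)GlcA(1-4)GlcNS3S6S(1-4)IdoA2S(1-4)GlcNS6S(1-4)GlcA-pNA-N3")

  fvi <- get_fixture("VI")
  expect_identical(fvi$flag, "printed")
  expect_identical(format_sequence(fvi$oligo),
                   "GlcA(1-4)GlcNS(1-4)IdoA2S(1-4)GlcNS(1-4)GlcA-pNA-N3")

  fi <- get_fixture("I")
  expect_identical(fi$flag, "reconstructed")
  expect_identical(sum(fi$oligo$tokens == "GlcNAc"), 2L)
  expect_length(fi$oligo, 5L)

  expect_error(get_fixture("999"), "unknown compound")

  # every fixture terminates in an aglycone-bearing GlcA
  for (o in all_fixture_oligos()) {
    expect_identical(o$tokens[length(o)], "GlcA")
    expect_identical(o$aglycone, "pNA-N3")
  }
})

test_that("sequence files read back with comments stripped", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# two compounds", "GlcA-pNA-N3", "",
               "GlcA(1-4)GlcNS-pNP  # inline note"), path)
  seqs <- read_sequences(path)
  expect_length(seqs, 2L)
  expect_identical(format_sequence(seqs[[2]]), "GlcA(1-4)GlcNS-pNP")
})
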