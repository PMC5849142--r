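test_that("compound 14 predictions reproduce the characterized shifts", {
  sh <- predict_shifts(get_fixture("14")$oligo)
  get <- function(lab, col) sh[[col]][sh$label == lab]

  # GlcNS3S6S with IdoA2S reducing-side neighbor: downfield ~5.43 ppm
  expect_equal(get("C", "delta_h"), 5.43, tolerance = 1e-12)
  # IdoA2S: 5.18/99.0, flagged broad (conformer exchange)
  expect_equal(get("D", "delta_h"), 5.18, tolerance = 1e-12)
  expect_equal(get("D", "delta_c"), 99.0, tolerance = 1e-12)
  expect_identical(get("D", "note"), "broad")
  # reducing-end GlcA deshielded by the aromatic aglycone
  expect_equal(get("F", "delta_h"), 5.07, tolerance = 1e-12)
  # GlcA whose reducing-side glucosamine carries 6-O-sulfo
  expect_equal(get("B", "delta_h"), 4.54, tolerance = 1e-12)
  # GlcNS6S in GlcA context
  expect_equal(get("A", "delta_h"), 5.52, tolerance = 1e-12)
  expect_equal(get("E", "delta_h"), 5.52, tolerance = 1e-12)
  # the three glucosamine anomeric signals sit in the 5.4-5.6 window
  gl <- sh$delta_h[sh$label %in% c("A", "C", "E")]
  expect_true(all(gl >= 5.4 & gl <= 5.6))
})

test_that("predicted 4.54 for residue B is consistent with the observed 4.56", {
  sh <- predict_shifts(get_fixture("14")$oligo)
  expect_lt(abs(sh$delta_h[sh$label == "B"] - 4.56), 0.05)
})

test_that("context resolution uses only the reducing-side neighbor", {
  # same residue class, different reducing-side context
  in_glca <- predict_shifts(parse_sequence("GlcNS6S(1-4)GlcA-pNA-N3"))
  in_idoa <- predict_shifts(
    parse_sequence("GlcNS6S(1-4)IdoA2S(1-4)GlcNS6S(1-4)GlcA-pNA-N3"))
  expect_equal(in_glca$delta_h[1], 5.52, tolerance = 1e-12)
  expect_equal(in_idoa$delta_h[1], 5.33, tolerance = 1e-12)

  # changing the NON-reducing neighbor leaves the prediction unchanged
  a <- predict_shifts(parse_sequence("GlcA(1-4)GlcNS(1-4)GlcA-pNA-N3"))
  b <- predict_shifts(parse_sequence("IdoA2S(1-4)GlcNS(1-4)GlcA-pNA-N3"))
  expect_identical(a$delta_h[a$label == "B"], b$delta_h[b$label == "B"])
})

test_that("the model separates GlcNS from GlcNS6S only in IdoA context", {
  tab <- shift_table()
  g <- function(res, ctx) tab$delta_h[tab$residue == res & tab$context == ctx]
  expect_identical(g("GlcNS", "GlcA-neighbor"), g("GlcNS6S", "GlcA-neighbor"))
  expect_gte(abs(g("GlcNS", "IdoA-neighbor") - g("GlcNS6S", "IdoA-neighbor")),
             0.05)
  expect_equal(g("GlcNS", "IdoA-neighbor"), 5.24, tolerance = 1e-12)
  expect_equal(g("GlcNS6S", "IdoA-neighbor"), 5.33, tolerance = 1e-12)
})

test_that("unrepresented residue/context combinations refuse, not guess", {
  # GlcNAc before an iduronate has no model entry
  expect_error(
    predict_shifts(parse_sequence("GlcNAc(1-4)IdoA(1-4)GlcNAc(1-4)GlcA-pNA-N3")),
    "no model entry.*GlcNAc")
  # GlcNS3S6S in GlcA context is not present in the library
  expect_error(
    predict_shifts(parse_sequence("GlcNS3S6S(1-4)GlcA-pNA-N3")),
    "no model entry")
  # partial mode returns NA with the unresolved note instead
  sh <- predict_shifts(parse_sequence("GlcNS3S6S(1-4)GlcA-pNA-N3"),
                       partial = TRUE)
  expect_true(is.na(sh$delta_h[1]))
  expect_identical(sh$note[1], "unresolved")
  expect_equal(sh$delta_h[2], 5.07, tolerance = 1e-12)
})

test_that("the model resolves every residue of every fixture", {
  for (nm in fixture_names()) {
    sh <- predict_shifts(get_fixture(nm)$oligo)
    expect_false(any(is.na(sh$delta_h)), info = nm)
    expect_false(any(sh$note == "unresolved"), info = nm)
  }
})

test_that("missing 13C values stay absent", {
  sh <- predict_shifts(get_fixture("14")$oligo)
  expect_true(is.na(sh$delta_c[sh$label == "B"]))  # GlcA | 6S-neighbor
  expect_true(is.na(sh$delta_c[sh$label == "F"]))  # aglycone context
})

test_that("J-coupling classes partition residues by anomeric configuration", {
  expect_identical(j_class("GlcNS6S")$j_hz, 4)
  expect_identical(j_class("IdoA2S")$class, "alpha")
  expect_identical(j_class("GlcA")$j_hz, 8)

  sh <- predict_shifts(get_fixture("14")$oligo)
  expect_identical(sh$j_hz[match(c("A", "C", "E"), sh$label)], rep(4, 3))
  expect_identical(sh$j_hz[match(c("B", "F"), sh$label)], rep(8, 2))

  for (o in all_fixture_oligos()) {
    sh <- predict_shifts(o)
    rings <- vapply(residues(o), `[[`, "", "anomeric_config")
    expect_identical(sh$j_class, rings)
  }
})

test_that("anomeric signal count equals chain length", {
  expect_identical(count_anomeric_signals(get_fixture("14")$oligo), 6L)
  expect_identical(count_anomeric_signals(get_fixture("seed")$oligo), 1L)
  expect_identical(count_anomeric_signals(get_fixture("VII")$oligo), 7L)
})
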