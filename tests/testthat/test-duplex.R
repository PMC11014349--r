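test_that("facing-position arithmetic reproduces the blunt-duplex coordinate map", {
  expect_equal(facing_position(17, 23, 23), 7L)
  expect_equal(facing_position(10, 23, 23), 14L)
  expect_equal(facing_position(23, 23, 23), 1L)
  # guide-coordinate mismatch set of the native duplex maps onto the
  # passenger-coordinate set
  expect_equal(sort(facing_position(c(1, 4, 10, 20, 22, 23), 23, 23)),
               c(1L, 2L, 4L, 14L, 20L, 23L))
  expect_error(facing_position(0, 23, 23), class = "mirmimic_index_error")
  expect_error(facing_position(24, 23, 23), class = "mirmimic_index_error")
  # out-of-range facing index is NA, not an error
  expect_true(is.na(facing_position(3, 23, 16)))
})

test_that("facing_position is an involution on blunt equal-length duplexes", {
  for (len in c(5L, 22L, 23L)) {
    g <- seq_len(len)
    expect_equal(facing_position(facing_position(g, len, len), len, len), g)
  }
})

test_that("derive_passenger produces the reverse complement with spec edits", {
  g <- make_strand("UAAU")
  expect_equal(strand_sequence(derive_passenger(g)), "AUUA")

  guide <- make_strand(MIR200C_GUIDE)
  # default substitution copies the facing guide base: U-U at guide 17 / passenger 7
  p <- derive_passenger(guide, mismatch_spec(7))
  expect_equal(substr(strand_sequence(p), 7, 7), "U")
  expect_equal(guide$residues$base[17], "U")

  # asymmetric truncation keeps the passenger complementary to guide 8..23
  p16 <- derive_passenger(guide, length = 16)
  expect_equal(p16$facing, 23:8)
  comp <- vapply(23:8, function(gp) {
    c(A = "U", U = "A", G = "C", C = "G")[[guide$residues$base[gp]]]
  }, character(1))
  expect_equal(strand_sequence(p16), paste(comp, collapse = ""))

  # deletions remove the slot and shift downstream residues
  pdel <- derive_passenger(guide, mismatch_spec(7, "DELETION", NA))
  expect_equal(strand_length(pdel), 22L)
  expect_false(17 %in% pdel$facing)

  expect_error(derive_passenger(guide, mismatch_spec(20), length = 16),
               class = "mirmimic_spec_error")
})

test_that("mismatch_spec validates uniqueness and deletion overrides", {
  expect_error(mismatch_spec(c(3, 3)), class = "mirmimic_spec_error")
  expect_error(mismatch_spec(3, "DELETION", "U"), class = "mirmimic_spec_error")
  expect_equal(nrow(mismatch_spec()), 0L)
})

test_that("pairing maps classify fully complementary, native and asymmetric duplexes", {
  guide <- make_strand(MIR200C_GUIDE)
  # fully complementary 23+23
  d_full <- assemble_duplex(guide, derive_passenger(guide))
  cs <- count_pairing_states(d_full)
  expect_equal(cs$n[cs$state == "PAIRED"], 23L)
  expect_equal(sum(cs$n), 23L)

  # native duplex: mismatches at guide 1, 4, 10, 20, 22, 23 and a deletion
  # facing guide 17
  spec <- mismatch_spec(c(1, 2, 4, 14, 20, 23), "SUBSTITUTION",
                        c(NA, "U", "G", NA, NA, NA))
  spec <- rbind(spec, tibble::tibble(position = 7L, kind = "DELETION", base = NA))
  d_nat <- assemble_duplex(guide, derive_passenger(guide, spec))
  mm <- d_nat$pairing$guide_pos[d_nat$pairing$state == "MISMATCH"]
  expect_equal(sort(mm), c(1L, 4L, 10L, 20L, 22L, 23L))
  expect_equal(d_nat$pairing$state[17], "DELETION")
  cs <- count_pairing_states(d_nat)
  expect_equal(cs$n[cs$state == "MISMATCH"], 6L)
  expect_equal(cs$n[cs$state == "DELETION"], 1L)

  # 16-nt passenger, blunt at the guide 3' side: guide 1..7 unpaired
  d_asym <- assemble_duplex(guide, derive_passenger(guide, length = 16), "ASYMMETRIC")
  unp <- d_asym$pairing$guide_pos[d_asym$pairing$state == "UNPAIRED"]
  expect_equal(unp, 1:7)
})

test_that("G:U wobbles are classified as mismatches, not pairs", {
  g <- make_strand("GGGG")
  p <- make_strand("UUUU")  # G facing U at every position
  d <- assemble_duplex(g, p)
  expect_equal(unique(d$pairing$state), "MISMATCH")
})

test_that("architecture constraints are enforced at assembly", {
  guide <- make_strand(MIR200C_GUIDE)
  p <- derive_passenger(guide)
  expect_error(assemble_duplex(guide, p, "NICKED"),
               class = "mirmimic_architecture_error")
  expect_error(assemble_duplex(guide, list(p, p), "BLUNT_SYMMETRIC"),
               class = "mirmimic_architecture_error")
  expect_error(assemble_duplex(guide, p, "HAIRPIN"),
               class = "mirmimic_architecture_error")
})

test_that("nicked duplexes keep the facing map injective across segments", {
  reg <- load_registry()
  d <- apply_template(get_template(reg, "M22"))
  expect_equal(length(d$passenger_segments), 2L)
  faced <- d$pairing[!is.na(d$pairing$segment), c("segment", "passenger_pos")]
  expect_false(anyDuplicated(faced) > 0)
  expect_equal(sum(count_pairing_states(d)$n), 23L)
})

test_that("overhang residues are reported as unpaired passenger residues", {
  reg <- load_registry()
  d <- apply_template(get_template(reg, "M8"))
  extra <- unpaired_passenger_residues(d)
  expect_equal(nrow(extra), 2L)
  expect_equal(extra$base, c("U", "U"))
  # guide positions are unaffected by the overhang
  expect_equal(sum(count_pairing_states(d)$n), 23L)
})

test_that("perfect-complement passengers never produce mismatches", {
  set.seed(7)
  for (i in 1:25) {
    g <- make_strand(random_rna(sample(8:30, 1)))
    d <- assemble_duplex(g, derive_passenger(g))
    expect_equal(sum(d$pairing$state == "MISMATCH"), 0L)
    expect_equal(sum(count_pairing_states(d)$n), strand_length(g))
  }
})
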