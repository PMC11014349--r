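reg <- load_registry()

test_that("the built-in registry has the expected shape", {
  td <- tidy(reg)
  expect_equal(sum(grepl("^M[0-9]+$", td$id)), 38L)  # M1 plus 37 modified designs
  expect_equal(sum(td$shortlisted), 8L)
  expect_setequal(td$id[td$shortlisted],
                  c("M1", "M12", "M14", "M23", "M24", "M25", "M30", "M37"))
  expect_true(all(paste0("MA", 1:3) %in% td$id))
  expect_true(all(paste0("MB", 1:3) %in% td$id))
  # unmodified references carry empty rule lists
  for (id in c("M1", "MA1", "MB1")) {
    t <- get_template(reg, id)
    expect_length(t$guide_rules, 0)
    expect_length(t$passenger_rules, 0)
  }
})

test_that("registry loading rejects duplicate ids and unknown rule tags", {
  doc <- jsonlite::read_json(system.file("extdata", "mimic_templates.json",
                                         package = "mirmimic"))
  doc$templates <- c(doc$templates[1:2], doc$templates[2])
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, auto_unbox = TRUE)
  expect_error(load_registry(bad), "Duplicate", class = "mirmimic_registry_error")

  doc2 <- jsonlite::read_json(system.file("extdata", "mimic_templates.json",
                                          package = "mirmimic"))
  doc2$templates[[2]]$guide_rules[[1]]$tag <- "LNA"
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc2, bad2, auto_unbox = TRUE)
  expect_error(load_registry(bad2), "unknown rule tag",
               class = "mirmimic_registry_error")

  expect_error(get_template(reg, "M99"), class = "mirmimic_registry_error")
})

test_that("M1 applies to an unmodified, unphosphorylated duplex", {
  d <- apply_template(get_template(reg, "M1"))
  cm <- count_modifications(d)
  expect_equal(sum(cm$n[cm$category == "sugar" & cm$value == "RIBO"]), 46L)
  expect_equal(sum(cm$n[cm$value == "PS"]), 0L)
  expect_equal(sum(cm$n[cm$value == "five_prime_phosphate"]), 0L)
})

test_that("M23 places fluoro on exactly the guide pyrimidines", {
  d <- apply_template(get_template(reg, "M23"),
                      guide_seq = "UAAUACUGCCGGGUAAUGAUGGA")
  gres <- d$guide$residues
  expect_equal(sum(gres$sugar == "FLU"), 9L)  # pyrimidine count of the guide
  expect_setequal(gres$position[gres$sugar == "FLU"],
                  gres$position[gres$base %in% c("C", "U")])
  pres <- d$passenger_segments[[1]]$residues
  expect_setequal(pres$position[pres$sugar == "OME"],
                  pres$position[pres$base %in% c("C", "U")])
})

test_that("M6 carries six PS linkages in total", {
  cm <- count_modifications(apply_template(get_template(reg, "M6")))
  expect_equal(sum(cm$n[cm$value == "PS"]), 6L)
})

test_that("M5 differs from M2 only by the guide 5'-phosphate", {
  d2 <- apply_template(get_template(reg, "M2"))
  d5 <- apply_template(get_template(reg, "M5"))
  expect_false(d2$guide$five_prime_phosphate)
  expect_true(d5$guide$five_prime_phosphate)
  expect_equal(d5$guide$residues, d2$guide$residues)
  expect_equal(d5$passenger_segments[[1]]$residues, d2$passenger_segments[[1]]$residues)
})

test_that("every registry template applies cleanly to its native miRNA", {
  for (id in names(reg$templates)) {
    d <- apply_template(get_template(reg, id))
    expect_s3_class(d, "mimic_duplex")
    expect_equal(sum(count_pairing_states(d)$n), strand_length(d$guide))
    cm <- count_modifications(d)
    for (nm in unique(cm$strand)) {
      len <- if (nm == "guide") strand_length(d$guide)
             else strand_length(d$passenger_segments[[as.integer(sub("passenger", "", nm))]])
      expect_equal(sum(cm$n[cm$strand == nm & cm$category == "sugar"]), len)
    }
  }
})

test_that("apply_template is deterministic and idempotent at the rule level", {
  t23 <- get_template(reg, "M23")
  d1 <- apply_template(t23)
  d2 <- apply_template(t23)
  expect_equal(d1, d2)
  # re-applying to the duplex's own sequences reproduces identical chemistry
  d3 <- apply_template(t23, guide_seq = strand_sequence(d1$guide))
  expect_equal(d3$guide$residues, d1$guide$residues)
  expect_equal(d3$passenger_segments[[1]]$residues, d1$passenger_segments[[1]]$residues)
})

test_that("pyrimidine and purine base-class rules partition strand positions", {
  for (id in c("M23", "M26", "M29")) {
    d <- apply_template(get_template(reg, id))
    res <- d$guide$residues
    pyr <- res$base %in% c("C", "U", "T")
    pur <- res$base %in% c("A", "G")
    expect_equal(sum(pyr) + sum(pur), nrow(res))
    expect_equal(sum(pyr & pur), 0L)
  }
})

test_that("modification census orders M14 above M23, matching the stability rank", {
  n_mod <- function(id) {
    cm <- count_modifications(apply_template(get_template(reg, id)))
    sum(cm$n[cm$category == "sugar" & cm$value != "RIBO"]) + sum(cm$n[cm$value == "PS"])
  }
  expect_gt(n_mod("M14"), n_mod("M23"))
  expect_gt(n_mod("M23"), n_mod("M1"))
})

test_that("translation re-evaluates rules on the new sequence", {
  t20 <- get_template(reg, "M20")
  d <- apply_template(t20)
  expect_equal(strand_length(d$passenger_segments[[1]]), 16L)

  # fully complementary default warns loudly
  expect_warning(
    d155 <- translate_template(get_template(reg, "M14"),
                               "UUAAUGCUAAUCGUGAUAGGGGU", mirna_name = "miR-155"),
    class = "mirmimic_translation_warning"
  )
  expect_equal(d155$mimic_id, "M14@miR-155")
  expect_equal(strand_length(d155$guide), 23L)

  # base-class rules re-select on the 22-nt miR-34a guide
  d34 <- translate_template(get_template(reg, "M23"), "UGGCAGUGUCUUAGCUGGUUGU",
                            new_mismatch_spec = mismatch_spec(), mirna_name = "miR-34a")
  gres <- d34$guide$residues
  expect_setequal(gres$position[gres$sugar == "FLU"],
                  gres$position[gres$base %in% c("C", "U")])
})

test_that("translate_template on the native guide reproduces apply_template", {
  for (id in c("M14", "M23", "M20")) {
    t <- get_template(reg, id)
    a <- apply_template(t)
    b <- translate_template(t, t$guide, new_mismatch_spec = t$mismatch_spec)
    expect_equal(b$guide$residues, a$guide$residues)
    expect_equal(lapply(b$passenger_segments, function(s) s$residues),
                 lapply(a$passenger_segments, function(s) s$residues))
    expect_equal(b$pairing$state, a$pairing$state)
  }
})

test_that("registry MA/MB entries realise the translated designs", {
  for (id in c("MA2", "MA3", "MB2", "MB3")) {
    d <- apply_template(get_template(reg, id))
    expect_s3_class(d, "mimic_duplex")
  }
  dMB2 <- apply_template(get_template(reg, "MB2"))
  expect_equal(strand_length(dMB2$guide), 22L)
})

test_that("rules referencing positions beyond the strand raise rule errors", {
  t14 <- get_template(reg, "M14")
  t14$mismatch_spec <- mismatch_spec()  # isolate the positional-rule check
  expect_error(apply_template(t14, guide_seq = "UAAUACUGCC"),
               class = "mirmimic_rule_error")
  # the mismatch spec itself is checked first on short guides
  expect_error(apply_template(get_template(reg, "M14"), guide_seq = "UAAUACUGCC"),
               class = "mirmimic_spec_error")
  # translation clamps out-of-range positional entries with a warning
  expect_warning(
    translate_template(t14, "UAAUACUGCCGGG", new_mismatch_spec = mismatch_spec()),
    "dropping")
})
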