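test_that("ddct_ratio implements the comparative Ct identities", {
  expect_equal(ddct_ratio(20, 20, 20, 20), 1.0)
  expect_equal(ddct_ratio(22, 20, 20, 20), 0.25)
  expect_equal(ddct_ratio(19, 20, 20, 20), 2.0)
  # normalization identity for arbitrary Ct pairs
  for (a in c(15, 22.3, 30)) for (b in c(18, 25.7)) {
    expect_equal(ddct_ratio(a, b, a, b), 1.0)
  }
  # +1 cycle on the treated target halves the ratio exactly
  expect_equal(ddct_ratio(21, 20, 20, 20), ddct_ratio(20, 20, 20, 20) / 2)
  expect_error(ddct_ratio(Inf, 20, 20, 20), class = "mirmimic_value_error")
  expect_error(ddct_ratio(-1, 20, 20, 20), class = "mirmimic_value_error")
})

test_that("summarize_knockdown recovers planted ratios exactly at zero noise", {
  truth <- tibble::tibble(
    gene = rep(c("ZEB1", "ZEB2"), each = 2),
    condition = rep(c("mimic_a", "mimic_b"), 2),
    ratio = c(0.4, 0.25, 0.7, 1.5)
  )
  fx <- gen_ct_table(truth, noise_sd = 0, n_reps = 3, seed = 3)
  fc <- summarize_knockdown(fx$ct, ref_gene = "HPRT1", control_condition = "control")
  joined <- dplyr::inner_join(fc, truth, by = c("gene", "condition"))
  expect_equal(joined$ratio_mean, joined$ratio, tolerance = 1e-12)
  expect_true(all(joined$n == 3L))
  # control baseline is 1 by construction
  ctrl <- fc[fc$condition == "control", ]
  expect_equal(ctrl$ratio_mean, rep(1, nrow(ctrl)), tolerance = 1e-12)
})

test_that("identical treatment and control Ct values give ratio 1", {
  ct <- tidyr::expand_grid(condition = c("control", "treated"), replicate = 1:3,
                           gene = c("ZEB1", "HPRT1"))
  ct$ct <- ifelse(ct$gene == "HPRT1", 20, 24)
  ct$sample <- paste(ct$condition, ct$replicate)
  fc <- summarize_knockdown(ct, "HPRT1", "control")
  expect_equal(fc$ratio_mean, rep(1, nrow(fc)))
})

test_that("technical replicates are averaged at the Ct level", {
  ct <- tibble::tibble(
    condition = rep(c("control", "treated"), each = 4),
    replicate = 1L,
    gene = rep(c("ZEB1", "ZEB1", "HPRT1", "HPRT1"), 2),
    # treated target technical duplicate 23/25 averages to 24 = +2 cycles
    ct = c(22, 22, 20, 20, 23, 25, 20, 20)
  )
  fc <- summarize_knockdown(ct, "HPRT1", "control")
  expect_equal(fc$ratio_mean[fc$condition == "treated"], 0.25)
})

test_that("missing reference or control records raise pairing errors", {
  ct <- tibble::tibble(condition = "treated", replicate = 1L, gene = "ZEB1", ct = 20)
  expect_error(summarize_knockdown(ct, "HPRT1", "control"),
               class = "mirmimic_pairing_error")
  ct2 <- tibble::tibble(
    condition = rep(c("control", "treated"), each = 2),
    replicate = 1L,
    gene = c("ZEB1", "HPRT1", "ZEB1", "ZEB2"),  # treated lacks its HPRT1 record
    ct = 20
  )
  expect_error(summarize_knockdown(ct2, "HPRT1", "control"),
               class = "mirmimic_pairing_error", regexp = "treated")
})

test_that("filter_degs applies inclusive l2fc and strict FDR boundaries", {
  degs <- tibble::tibble(
    gene = c("a", "b", "c"),
    log2fc = c(-2.0, -1.0, 2.0),
    fdr = c(0.01, 0.01, 0.2)
  )
  expect_equal(filter_degs(degs, direction = "BOTH")$gene, "a")
  expect_equal(nrow(filter_degs(tibble::tibble(gene = character(),
                                               log2fc = numeric(),
                                               fdr = numeric()))), 0L)
  boundary <- tibble::tibble(gene = "x", log2fc = -1.3, fdr = 0.049)
  expect_equal(nrow(filter_degs(boundary, direction = "DOWN")), 1L)
  at_fdr <- tibble::tibble(gene = "x", log2fc = -1.3, fdr = 0.05)
  expect_equal(nrow(filter_degs(at_fdr, direction = "DOWN")), 0L)
  expect_equal(filter_degs(degs, direction = "UP")$gene, character(0))
  expect_error(filter_degs(tibble::tibble(gene = "x", log2fc = 1, fdr = 2)),
               class = "mirmimic_value_error")
})

test_that("luciferase percent activity is anchored at the control baseline", {
  tbl <- tibble::tibble(
    well = c("A1", "A2", "B1"),
    group = c("NEG_CONTROL", "NEG_CONTROL", "TREATED"),
    fluc = c(100, 50, 80),
    rluc = c(200, 100, 160)  # every well has ratio 2 = the control mean
  )
  out <- luciferase_percent(tbl)
  expect_equal(out$percent_activity, c(100, 100, 100))

  tbl2 <- tibble::tibble(well = c("A1", "A2", "B1"),
                         group = c("NEG_CONTROL", "NEG_CONTROL", "TREATED"),
                         fluc = 1, rluc = c(2, 2, 1))
  expect_equal(luciferase_percent(tbl2)$percent_activity[3], 50)

  # control wells average to 100 exactly, whatever their spread
  tbl3 <- tibble::tibble(well = letters[1:4], group = "NEG_CONTROL",
                         fluc = 1, rluc = c(1, 2, 3, 6))
  expect_equal(mean(luciferase_percent(tbl3)$percent_activity), 100)

  expect_error(luciferase_percent(tibble::tibble(well = "a", group = "TREATED",
                                                 fluc = 1, rluc = 1)),
               class = "mirmimic_configuration_error")
  expect_error(luciferase_percent(tibble::tibble(well = "a", group = "NEG_CONTROL",
                                                 fluc = 0, rluc = 1)),
               class = "mirmimic_value_error")
})
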