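test_that("RPKM formula, scale invariance and error contract", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(0, 2000, 5e6), 0)
  expect_equal(compute_rpkm(2 * 7, 1500, 2 * 3e6),
               compute_rpkm(7, 1500, 3e6))
  expect_error(compute_rpkm(5, 0, 1e6), "length_bp")
  expect_error(compute_rpkm(5, 1000, 0), "mapped_total")
})

test_that("counts-mode matrices convert to RPKM and round-trip via TSV", {
  counts <- matrix(c(10, 20, 0, 5), 2, 2,
                   dimnames = list(c("gA", "gB"), c("s1", "s2")))
  em <- expression_matrix(counts, mode = "counts",
                          lengths = c(gA = 1000, gB = 2000),
                          totals = c(s1 = 1e6, s2 = 2e6))
  rp <- to_rpkm(em)
  expect_equal(unname(rp$values["gA", ]), c(10, 0))
  expect_equal(unname(rp$values["gB", ]), c(10, 1.25))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "expr.tsv")
  write_expression(em, f)
  back <- read_expression(f)
  expect_identical(back$mode, "counts")
  expect_equal(back$values, em$values)
  expect_equal(back$lengths, em$lengths)
  expect_equal(back$totals, em$totals)
  # RPKM mode: a 0 entry survives exactly
  f2 <- file.path(dir, "rpkm.tsv")
  write_expression(rp, f2)
  back2 <- read_expression(f2)
  expect_identical(back2$mode, "rpkm")
  expect_equal(back2$values, rp$values)
})

test_that("expressed filter is strict at 1 RPKM", {
  values <- rbind(barely = c(0.03, 1.33), at_one = c(1.0, 1.0),
                  zero = c(0, 0), high = c(5, 2))
  colnames(values) <- c("s1", "s2")
  em <- expression_matrix(values, mode = "rpkm")
  kept <- expressed_filter(em)
  expect_setequal(rownames(kept$values), c("barely", "high"))
})

test_that("log2 fold change is antisymmetric and guards zero means", {
  expect_equal(log2_fold_change(0.03, 1.33), -log2_fold_change(1.33, 0.03))
  expect_equal(log2_fold_change(2, 2), 0)
  expect_equal(round(log2_fold_change(0.03, 1.33), 2), -5.47)
  expect_equal(round(log2_fold_change(2.11, 11.27), 2), -2.42)
  expect_error(log2_fold_change(0, 1), "undefined")
})

test_that("DE classification is inclusive at the boundary and swap-symmetric", {
  lf <- c(1.0, 0.99, -0.99, -1.0, 0, 2.5, NA)
  cls <- classify_de(lf)
  expect_identical(as.character(cls),
                   c("up", "ns", "ns", "down", "ns", "up", NA))
  expect_identical(as.character(classify_de(-lf)),
                   c("down", "ns", "ns", "up", "ns", "down", NA))
})

test_that("de_table flags undefined ratios instead of producing infinities", {
  values <- rbind(ok = c(4, 4, 2, 2), dead_lc = c(3, 3, 0, 0))
  colnames(values) <- c("MC1", "MC2", "LC1", "LC2")
  em <- expression_matrix(values, mode = "rpkm")
  g <- stats::setNames(factor(c("MC", "MC", "LC", "LC")), colnames(values))
  de <- de_table(em, g, numerator = "MC", denominator = "LC")
  expect_equal(de["ok", "log2fc"], 1)
  expect_false(de["dead_lc", "ratio_defined"])
  expect_true(is.na(de["dead_lc", "log2fc"]))
  expect_true(is.na(de["dead_lc", "class"]))
})

test_that("the lectin reference panel reproduces its published screen", {
  panel <- reference_panel("lectin")
  expect_identical(nrow(panel), 35L)
  rp <- reference_panel_matrix("lectin")
  # every member of the published panel clears the expression filter
  expect_identical(nrow(expressed_filter(rp$em)$values), 35L)
  de <- de_table(rp$em, rp$groups, numerator = "MC", denominator = "LC")
  expect_identical(sum(de$class == "up"), 3L)
  expect_identical(sum(de$class == "down"), 10L)
  # the boundary gene with ratio exactly 2 counts as upregulated
  expect_identical(as.character(de["LOC102189655", "class"]), "up")
  high <- high_expression_report(de, floor = 100,
                                 exclude = "LOC102180339")
  expect_identical(length(high), 6L)
  expect_setequal(high, c("LOC102184901", "LOC102180072", "CLEC3B",
                          "LGALS3", "LGALSL", "LGALS1"))
})

test_that("family subsetting partitions the panel", {
  rp <- reference_panel_matrix("lectin")
  fams <- unique(rp$em$annotations$family)
  subsets <- lapply(fams, function(f) rownames(subset_family(rp$em, f)$values))
  expect_setequal(unlist(subsets), rownames(rp$em$values))
  expect_identical(sum(lengths(subsets)), 35L)
  gal <- subset_family(rp$em, "galectin")
  expect_true(all(gal$annotations$family == "galectin"))
  empty <- subset_family(rp$em, genes = character(0))
  expect_identical(nrow(empty$values), 0L)
  expect_error(subset_family(rp$em, "pentraxin"), "unknown family")
  expect_error(subset_family(rp$em, genes = "NOPE"), "unknown gene")
})

test_that("high-expression census honors floor and exclusion edge cases", {
  rp <- reference_panel_matrix("lectin")
  de <- de_table(rp$em, rp$groups, numerator = "MC", denominator = "LC")
  expect_identical(length(high_expression_report(de, floor = 0)), 35L)
  expect_identical(length(high_expression_report(de, floor = 1e6)), 0L)
})
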