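test_that("generation is bit-identical for identical config and seed", {
  cfg <- small_config(dispersion = 0.01)
  a <- generate_otu_counts(cfg)
  b <- generate_otu_counts(cfg)
  expect_identical(a, b)
  ea <- generate_expression(cfg)
  eb <- generate_expression(cfg)
  expect_identical(ea$em$values, eb$em$values)
  # and the written fixture files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_fixtures(a, ea$em, ea$truth, d1)
  f2 <- write_fixtures(b, eb$em, eb$truth, d2)
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]))
  # a different seed changes the data
  other <- generate_otu_counts(small_config(dispersion = 0.01,
                                            rng_seed = 12L))
  expect_false(identical(a$counts, other$counts))
})

test_that("counts are non-negative integers and taxonomy is complete", {
  cfg <- small_config(dispersion = 0.02)
  x <- generate_otu_counts(cfg)
  expect_true(all(x$counts >= 0))
  expect_true(all(x$counts == round(x$counts)))
  expect_false(any(is.na(x$taxonomy)))
  expect_identical(nrow(x$taxonomy), 40L)
  # phylum aggregation conserves totals (hierarchical consistency)
  agg <- aggregate_at_rank(x, "phylum")
  expect_equal(rowSums(agg$counts), rowSums(x$counts))
  expect_lte(ncol(agg$counts), cfg$n_phyla)
})

test_that("noiseless planted effects are realized exactly", {
  cfg <- small_config(dispersion = 0)
  gen <- generate_expression(cfg)
  g <- gen$groups
  mu <- gen$em$values
  for (nm in names(cfg$planted_log2fc)) {
    realized <- log2(mean(mu[nm, g == "MC"]) / mean(mu[nm, g == "LC"]))
    expect_equal(realized, unname(cfg$planted_log2fc[nm]), tolerance = 0.01)
  }
  # co-expression blocks are perfectly monotone at dispersion 0
  for (i in seq_along(cfg$coexpr_blocks)) {
    b <- cfg$coexpr_blocks[[i]]
    target <- if (b$sign == "+") 1 else -1
    for (m in b$members)
      expect_equal(spearman_rho(mu[b$hub, ], mu[m, ]), target)
  }
  # the DE classifier recovers exactly the recorded truth
  de <- de_table(expressed_filter(gen$em), g,
                 numerator = "MC", denominator = "LC")
  found <- rownames(de)[!is.na(de$class) & de$class != "ns"]
  expect_setequal(found, names(gen$truth$de_genes))
})

test_that("planted effects stay within tolerance at the default dispersion", {
  cfg <- small_config(dispersion = 0.01)
  gen <- generate_expression(cfg)
  g <- gen$groups
  v <- gen$em$values
  for (nm in names(cfg$planted_log2fc)) {
    realized <- log2(mean(v[nm, g == "MC"]) / mean(v[nm, g == "LC"]))
    expect_lt(abs(realized - cfg$planted_log2fc[nm]), 0.3)
  }
})

test_that("a null config with no structure keeps groups exchangeable", {
  # dispersion -> 0 with equal group means: ANOSIM R centers on 0 over
  # replicates (single 3+3 null draws scatter widely, E[R] = 0)
  Rs <- vapply(1:20, function(i) {
    cfg <- null_config(dispersion = 1e-4, rng_seed = 100L + i)
    x <- generate_otu_counts(cfg)
    keep <- filter_min_count(x)
    anosim(bray_curtis(to_relative(keep)), keep$groups)$R
  }, numeric(1))
  expect_lt(abs(mean(Rs)), 0.2)
  # exactly at dispersion 0 nothing varies: all dissimilarities tie, R = 0
  x0 <- generate_otu_counts(null_config(dispersion = 0))
  k0 <- filter_min_count(x0)
  expect_equal(anosim(bray_curtis(to_relative(k0)), k0$groups)$R, 0)
})

test_that("configuration errors are caught at construction", {
  expect_error(synthetic_config(n_per_group = 1), "n_per_group")
  expect_error(synthetic_config(dispersion = -1), "dispersion")
  expect_error(synthetic_config(base_abundance = list(meanlog = 1)),
               "distribution")
  expect_error(synthetic_config(n_genes = 20, n_expressed = 12,
                                planted_log2fc = c(g015 = 2)),
               "without expressed baseline")
  expect_error(synthetic_config(
    n_genes = 20, n_expressed = 13,
    gene_otu_couplings = data.frame(gene = "g001", otu = "nope",
                                    direction = "+")),
    "unknown OTU")
  cfg <- small_config()
  expect_error(synthetic_config(
    n_otus = 40, n_phyla = 3, n_genera = 8, n_genes = 20, n_expressed = 12,
    planted_log2fc = stats::setNames(2, "g001"),
    gene_otu_couplings = data.frame(gene = "g001", otu = "otu0001",
                                    direction = "+"),
    otu_group_log2fc = stats::setNames(1, "otu0001")),
    "cannot carry both")
})

test_that("expression fixtures round-trip in both modes", {
  cfg <- small_config(dispersion = 0.01)
  for (mode in c("rpkm", "counts")) {
    gen <- generate_expression(cfg, mode = mode)
    dir <- withr::local_tempdir()
    f <- file.path(dir, "expr.tsv")
    write_expression(gen$em, f)
    back <- read_expression(f)
    expect_identical(back$mode, mode)
    expect_equal(back$values, gen$em$values)
  }
})

test_that("the truth record serializes to JSON and back", {
  gen <- generate_expression(small_config())
  dir <- withr::local_tempdir()
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(truth_as_list(gen$truth), f,
                       auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_setequal(names(back$de_genes), names(gen$truth$de_genes))
  expect_identical(back$coupled_pairs$otu, gen$truth$coupled_pairs$otu)
})
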