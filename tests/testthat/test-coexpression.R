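test_that("a planted noiseless block yields full hub degree at the thresholds", {
  cfg <- small_config(dispersion = 0)
  gen <- generate_expression(cfg)
  em <- expressed_filter(gen$em)
  net <- build_network(em, seeds = names(cfg$planted_log2fc))
  for (hub in names(gen$truth$block_membership)) {
    members <- gen$truth$block_membership[[hub]]
    expect_gte(unname(net$degree[hub]), length(members))
    expect_true(all(members %in% first_neighbors(net, hub)[[1]]))
  }
  # the negative block's edges carry a "-" sign
  neg_hub <- names(gen$truth$block_signs)[gen$truth$block_signs == "-"]
  e <- net$edges
  neg_edges <- e[(e$gene_a == neg_hub &
                    e$gene_b %in% gen$truth$block_membership[[neg_hub]]) |
                 (e$gene_b == neg_hub &
                    e$gene_a %in% gen$truth$block_membership[[neg_hub]]), ]
  expect_true(all(neg_edges$sign == "-"))
  expect_true(all(abs(net$edges$rho) > 0.8 & net$edges$p < 0.05))
})

test_that("an unreachable rho threshold empties the network", {
  cfg <- small_config(dispersion = 0)
  em <- expressed_filter(generate_expression(cfg)$em)
  net <- build_network(em, rho_min = 1.01)
  expect_identical(nrow(net$edges), 0L)
  expect_error(build_network(expression_matrix(
    matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
    mode = "rpkm")), "3 samples")
})

test_that("null false-edge rate per pair matches the exact-p tail", {
  # independent tie-free genes at n = 6: two-sided exact p < 0.05 iff
  # |rho| >= 0.8857, which 24/720 permutations attain
  set.seed(9)
  n_genes <- 150
  values <- matrix(stats::rlnorm(n_genes * 6), n_genes, 6,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   paste0("s", 1:6)))
  net <- build_network(expression_matrix(values, mode = "rpkm"))
  n_pairs <- choose(n_genes, 2)
  rate <- 24 / 720
  se <- sqrt(rate * (1 - rate) / n_pairs)
  expect_lt(abs(nrow(net$edges) / n_pairs - rate), 3 * se)
})

test_that("a single-pair null config rarely produces an edge", {
  # per-pair false-edge probability is exactly 1/30, so >= 95% of
  # replicates of a 2-gene null panel stay empty in expectation
  hits <- 0L
  for (i in 1:20) {
    values <- matrix(stats::rlnorm(12), 2, 6,
                     dimnames = list(c("a", "b"), paste0("s", 1:6)))
    set.seed(100 + i)
    values[] <- stats::rlnorm(12)
    net <- build_network(expression_matrix(values, mode = "rpkm"))
    hits <- hits + (nrow(net$edges) > 0)
  }
  expect_lte(hits, 2L)
})

test_that("neighbor sets are symmetric and empty for isolated seeds", {
  cfg <- small_config(dispersion = 0)
  em <- expressed_filter(generate_expression(cfg)$em)
  net <- build_network(em, seeds = names(cfg$planted_log2fc))
  nb_all <- first_neighbors(net, net$genes)
  for (a in net$genes) for (b in nb_all[[a]])
    expect_true(a %in% nb_all[[b]])
  expect_error(first_neighbors(net, "not_a_gene"), "unknown seed")
})

test_that("differential neighbors keep only DE genes with their edge sign", {
  cfg <- small_config(dispersion = 0)
  gen <- generate_expression(cfg)
  em <- expressed_filter(gen$em)
  de <- de_table(em, gen$groups, numerator = "MC", denominator = "LC")
  net <- build_network(em, seeds = names(cfg$planted_log2fc))
  tab <- differential_neighbors(net, names(cfg$planted_log2fc), de)
  expect_true(all(tab$neighbor_class %in% c("up", "down")))
  # planted members are DE by construction and coupled to their hub
  hub <- names(gen$truth$block_membership)[1]
  members <- gen$truth$block_membership[[hub]]
  got <- tab[tab$seed == hub, ]
  expect_true(all(members %in% got$neighbor))
  expect_true(all(got$sign[match(members, got$neighbor)] == "+"))
  # an empty seed set gives an empty table
  empty <- differential_neighbors(net, character(0), de)
  expect_identical(nrow(empty), 0L)
})

test_that("pathway aggregation matches hand grouping and keeps unmapped genes", {
  tab <- data.frame(seed = c("s1", "s1", "s2", "s2", "s2", "s1"),
                    neighbor = c("gA", "gB", "gB", "gC", "gD", "gE"),
                    rho = 1, sign = "+",
                    neighbor_class = "up", stringsAsFactors = FALSE)
  map <- data.frame(gene = c("gA", "gB", "gB", "gC"),
                    pathway = c("P1", "P1", "P2", "P2"),
                    stringsAsFactors = FALSE)
  agg <- aggregate_by_pathway(tab, map)
  expect_setequal(agg$pathway, c("P1", "P2", "unmapped"))
  expect_identical(agg$genes[agg$pathway == "P1"], "gA,gB")
  expect_identical(agg$genes[agg$pathway == "P2"], "gB,gC")  # multi-membership
  expect_identical(agg$genes[agg$pathway == "unmapped"], "gD,gE")
  # gB sits in P2 and neighbors both seeds, so P2 collects s1 and s2
  expect_identical(agg$seeds[agg$pathway == "P2"], "s1,s2")
  # empty map: everything unmapped
  agg0 <- aggregate_by_pathway(tab, map[0, ])
  expect_identical(agg0$pathway, "unmapped")
  expect_identical(agg0$n_genes, 5L)
})

test_that("network exports are readable (edges TSV and GraphML)", {
  cfg <- small_config(dispersion = 0)
  em <- expressed_filter(generate_expression(cfg)$em)
  net <- build_network(em)
  dir <- withr::local_tempdir()
  write_edges(net, file.path(dir, "edges.tsv"))
  back <- utils::read.delim(file.path(dir, "edges.tsv"))
  expect_identical(nrow(back), nrow(net$edges))
  write_graphml(net, file.path(dir, "net.graphml"))
  g <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), length(net$genes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
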