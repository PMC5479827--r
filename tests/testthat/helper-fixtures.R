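# Small in-code fixtures shared across test files.

# a compact synthetic configuration: 40 OTUs over 3 phyla / 8 genera,
# 20-gene panel with 12 expressed, 4 planted DE genes, one block, 3
# coupling pairs
small_config <- function(dispersion = 0, rng_seed = 11L, ...) {
  genes <- sprintf("g%03d", 1:20)
  otus <- sprintf("otu%04d", 1:40)
  synthetic_config(
    n_otus = 40, n_phyla = 3, n_genera = 8,
    n_genes = 20, n_expressed = 12,
    planted_log2fc = stats::setNames(c(1.2, -1.5, -2.5, 2.0), genes[1:4]),
    coexpr_blocks = list(list(hub = genes[2], members = genes[5:7],
                              sign = "+"),
                         list(hub = genes[3], members = genes[8:9],
                              sign = "-")),
    gene_otu_couplings = data.frame(
      gene = rep(genes[c(1, 2, 4)], each = 2),
      otu = otus[35:40],
      direction = rep(c("+", "-"), 3),
      stringsAsFactors = FALSE),
    otu_group_log2fc = stats::setNames(rep(c(1, -1, -1), 2), otus[1:6]),
    dispersion = dispersion, rng_seed = rng_seed, ...)
}

# a config with no planted structure at all (null communities)
null_config <- function(n_otus = 30, n_genes = 6, dispersion = 0.01,
                        rng_seed = 7L) {
  synthetic_config(
    n_otus = n_otus, n_phyla = 3, n_genera = 6,
    n_genes = n_genes, n_expressed = n_genes,
    planted_log2fc = stats::setNames(numeric(0), character(0)),
    coexpr_blocks = list(),
    gene_otu_couplings = data.frame(gene = character(0), otu = character(0),
                                    direction = character(0)),
    otu_group_log2fc = stats::setNames(numeric(0), character(0)),
    dispersion = dispersion, rng_seed = rng_seed)
}

# tiny hand-built OTU table: 4 samples x 5 OTUs, 2 phyla, one OTU
# unclassified at genus
toy_otu_table <- function() {
  counts <- matrix(c(10, 0, 3, 5, 2,
                     8, 1, 4, 5, 0,
                     0, 6, 2, 7, 9,
                     1, 7, 0, 6, 8),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("MC1", "MC2", "LC1", "LC2"),
                                   paste0("otu", 1:5)))
  taxonomy <- data.frame(
    kingdom = "Bacteria",
    phylum = c("p01", "p01", "p02", "p02", "p02"),
    class = c("c01", "c01", "c02", "c02", "c02"),
    order = c("o01", "o01", "o02", "o02", "o02"),
    family = c("f01", "f01", "f02", "f02", "f03"),
    genus = c("g01", "g01", "g02", "g02", UNCLASSIFIED),
    row.names = paste0("otu", 1:5), stringsAsFactors = FALSE)
  groups <- stats::setNames(factor(c("MC", "MC", "LC", "LC"),
                                   levels = c("MC", "LC")),
                            rownames(counts))
  otu_table(counts, taxonomy, groups)
}

# Monte Carlo rarefaction oracle: repeated subsampling without replacement
mc_rarefaction <- function(counts, m, n_draws) {
  pool <- rep(seq_along(counts), counts)
  draws <- vapply(seq_len(n_draws), function(i)
    length(unique(sample(pool, m))), numeric(1))
  c(mean = mean(draws), se = stats::sd(draws) / sqrt(n_draws))
}
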