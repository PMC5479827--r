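#' Configuration for the paired synthetic dataset
#'
#' Describes a paired OTU-count + gene-expression dataset with the
#' statistical structure the integration analysis assumes: a two-group
#' design of 3 vs 3 samples, ~647 OTUs over 14 phyla and 73 genera, a
#' 100-gene lectin-like panel of which 35 clear the expression filter,
#' planted differential expression at `|log2FC| >= 1`, co-expression
#' blocks around hub (seed) genes, and monotone gene-OTU couplings.
#'
#' Sample-level variation is built in deterministically: each gene gets a
#' permuted geometric ladder of per-sample multipliers (step 1.5),
#' renormalized to mean one within each group, so that (a) realized group
#' means equal the planted effects exactly in the noiseless limit and (b)
#' per-sample values are tie-free, which the exact permutation p-values
#' require. `dispersion = 0` switches off all count sampling (the fully
#' deterministic noiseless limit); positive values draw negative-binomial
#' counts with `size = 1/dispersion` around the expected values.
#'
#' @param n_per_group samples per group (>= 2; default 3).
#' @param n_otus number of OTUs (default 647).
#' @param n_phyla,n_genera taxonomy breadth (defaults 14 / 73).
#' @param n_genes size of the gene panel (default 100).
#' @param n_expressed genes whose baseline clears the 1-RPKM filter
#'   (default 35).
#' @param planted_log2fc named numeric vector of planted log2(MC/LC)
#'   effects on expressed genes; default: 3 up-, 10 down-regulated,
#'   mirroring a lectin screen. Magnitudes must be realizable
#'   (`|effect| >= 0`); an effect on a zero-baseline (non-panel) gene is a
#'   configuration error at generation time.
#' @param coexpr_blocks list of `list(hub=, members=, sign=)` planted
#'   co-expression blocks; default: 5 hubs among the DE genes with 4
#'   members each, one negative block on the strongest down-regulated hub.
#' @param gene_otu_couplings data.frame (`gene`, `otu`, `direction`) of
#'   planted monotone couplings; default: 62 OTUs coupled to the DE genes
#'   round-robin with alternating direction (so ~90% of OTUs are
#'   uncoupled, the removal regime the integration stage expects).
#' @param otu_group_log2fc named numeric vector of planted between-group
#'   abundance effects on (uncoupled) OTUs; default: 60 OTUs at +/-1.5.
#' @param dispersion negative-binomial dispersion shared by both tables
#'   (default 0.01, i.e. ~10% coefficient of variation on well-observed
#'   features, keeping planted monotone relations near-monotone at n = 6;
#'   0 = noiseless deterministic limit).
#' @param base_abundance log-normal parameters (`meanlog`, `sdlog`) for
#'   uncoupled OTU baseline abundances (default meanlog 3.5, sdlog 1.3).
#' @param mapped_total mapped reads per sample for the counts-mode
#'   expression table (default 2e7).
#' @param rng_seed integer seed; everything is deterministic given it.
#' @return An object of class `"synthetic_config"` (a validated list).
#' @export
synthetic_config <- function(n_per_group = 3, n_otus = 647, n_phyla = 14,
                             n_genera = 73, n_genes = 100, n_expressed = 35,
                             planted_log2fc = NULL, coexpr_blocks = NULL,
                             gene_otu_couplings = NULL,
                             otu_group_log2fc = NULL,
                             dispersion = 0.01,
                             base_abundance = list(meanlog = 3.5, sdlog = 1.3),
                             mapped_total = 2e7, rng_seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (n_expressed > n_genes) stop("n_expressed cannot exceed n_genes")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (!all(c("meanlog", "sdlog") %in% names(base_abundance)) ||
      base_abundance$sdlog < 0)
    stop("invalid base_abundance distribution parameters")
  genes <- sprintf("g%03d", seq_len(n_genes))
  otus <- sprintf("otu%04d", seq_len(n_otus))

  if (is.null(planted_log2fc)) {
    n_de <- min(13L, n_expressed)
    effects <- c(1.0, 1.2, 1.5,
                 -1.0, -1.05, -1.1, -1.2, -1.3, -1.5, -1.8, -2.4, -3.0,
                 -5.5)[seq_len(n_de)]
    planted_log2fc <- stats::setNames(effects, genes[seq_len(n_de)])
  }
  bad <- setdiff(names(planted_log2fc), genes[seq_len(n_expressed)])
  if (length(bad))
    stop("planted effect on gene(s) without expressed baseline: ",
         paste(bad, collapse = ", "))

  de_genes <- names(planted_log2fc)
  if (is.null(coexpr_blocks)) {
    n_hubs <- min(5L, length(de_genes))
    if (n_hubs == 0L) {
      coexpr_blocks <- list()
    } else {
      pool <- setdiff(genes[seq_len(n_expressed)], de_genes)
      # attach the negative block to the strongest down-regulated hub, so
      # member genes' realized opposite-sign effect clears |log2FC| >= 1
      hubs <- de_genes[seq_len(n_hubs)]
      neg_hub <- de_genes[which.min(planted_log2fc)]
      if (!neg_hub %in% hubs) hubs[n_hubs] <- neg_hub
      coexpr_blocks <- lapply(seq_along(hubs), function(i) {
        take <- pool[seq_len(min(4L, length(pool)))]
        pool <<- setdiff(pool, take)
        list(hub = hubs[i],
             members = take,
             sign = if (hubs[i] == neg_hub) "-" else "+")
      })
      coexpr_blocks <- Filter(function(b) length(b$members) > 0, coexpr_blocks)
    }
  }
  for (b in coexpr_blocks) {
    if (!b$hub %in% genes) stop("unknown hub gene: ", b$hub)
    if (!all(b$members %in% genes)) stop("unknown block member gene(s)")
    if (!b$sign %in% c("+", "-")) stop("block sign must be '+' or '-'")
  }

  if (is.null(gene_otu_couplings) && length(de_genes) == 0L)
    gene_otu_couplings <- data.frame(gene = character(0), otu = character(0),
                                     direction = character(0))
  if (is.null(gene_otu_couplings)) {
    # couplings come in compensating +/- pairs on the same gene, so the
    # coupled block's expected per-sample sum is constant and planted
    # structure cannot leak into every OTU through the compositional
    # (relative-abundance) denominator
    n_pairs <- min(31L, n_otus %/% 2L)
    coupled_otus <- otus[seq.int(n_otus - 2L * n_pairs + 1L,
                                 length.out = 2L * n_pairs)]
    gene_otu_couplings <- data.frame(
      gene = rep(rep_len(de_genes, n_pairs), each = 2L),
      otu = coupled_otus,
      direction = rep_len(c("+", "-"), 2L * n_pairs),
      stringsAsFactors = FALSE)
  }
  if (nrow(gene_otu_couplings)) {
    if (!all(gene_otu_couplings$gene %in% genes))
      stop("coupling references unknown gene(s)")
    if (!all(gene_otu_couplings$otu %in% otus))
      stop("coupling references unknown OTU(s)")
    if (anyDuplicated(gene_otu_couplings$otu))
      stop("each OTU may be coupled to at most one gene")
  }

  if (is.null(otu_group_log2fc)) {
    # +1/-1/-1 triplets on a shared baseline: one doubled OTU gains what
    # two halved OTUs lose, so planted group effects cancel in the
    # per-sample totals (the triplet sharing is enforced at generation)
    free <- setdiff(otus, gene_otu_couplings$otu)
    n_eff <- 3L * (min(60L, length(free)) %/% 3L)
    otu_group_log2fc <- stats::setNames(
      rep_len(c(1, -1, -1), n_eff), free[seq_len(n_eff)])
  }
  if (length(intersect(names(otu_group_log2fc), gene_otu_couplings$otu)))
    stop("an OTU cannot carry both a group effect and a coupling")

  structure(list(n_per_group = n_per_group, n_otus = n_otus,
                 n_phyla = n_phyla, n_genera = n_genera,
                 n_genes = n_genes, n_expressed = n_expressed,
                 genes = genes, otus = otus,
                 planted_log2fc = planted_log2fc,
                 coexpr_blocks = coexpr_blocks,
                 gene_otu_couplings = gene_otu_couplings,
                 otu_group_log2fc = otu_group_log2fc,
                 dispersion = dispersion,
                 base_abundance = base_abundance,
                 mapped_total = mapped_total,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

sample_ids <- function(config) {
  c(paste0("MC", seq_len(config$n_per_group)),
    paste0("LC", seq_len(config$n_per_group)))
}

sample_groups <- function(config) {
  ids <- sample_ids(config)
  stats::setNames(factor(rep(c("MC", "LC"), each = config$n_per_group),
                         levels = c("MC", "LC")), ids)
}

## Deterministic expected RPKM profile per gene (shared by both generators:
## OTU couplings are rank-transplants of these gene profiles).
expected_expression <- function(config) {
  with_seed(config$rng_seed + 1L, {
    n <- 2L * config$n_per_group
    grp <- sample_groups(config)
    genes <- config$genes
    base <- numeric(config$n_genes)
    expressed <- seq_len(config$n_expressed)
    base[expressed] <- 2 * 10^stats::runif(config$n_expressed, 0, 2.4)
    if (config$n_expressed < config$n_genes)
      base[-expressed] <- stats::runif(config$n_genes - config$n_expressed,
                                       0.02, 0.4)
    ladder <- 1.5^(0:(n - 1))
    mu <- matrix(0, config$n_genes, n, dimnames = list(genes, names(grp)))
    fc <- stats::setNames(rep(0, config$n_genes), genes)
    fc[names(config$planted_log2fc)] <- config$planted_log2fc
    member_of <- list()
    for (b in config$coexpr_blocks)
      for (m in b$members) member_of[[m]] <- b
    for (i in seq_len(config$n_genes)) {
      g <- genes[i]
      if (!is.null(member_of[[g]])) next       # filled from the hub below
      m <- sample(ladder)
      for (lv in levels(grp)) m[grp == lv] <- m[grp == lv] / mean(m[grp == lv])
      mu[i, ] <- base[i] * 2^(fc[g] * (grp == "MC")) * m
    }
    for (b in config$coexpr_blocks) {
      hub <- mu[b$hub, ]
      for (g in b$members) {
        i <- match(g, genes)
        mu[i, ] <- if (b$sign == "+") base[i] * hub / base[match(b$hub, genes)]
        else base[i] * base[match(b$hub, genes)] / hub
      }
    }
    lengths <- stats::setNames(round(stats::runif(config$n_genes, 500, 5000)),
                               genes)
    list(mu = mu, base = base, lengths = lengths, groups = grp)
  })
}

#' Generate the synthetic gene expression matrix plus ground truth
#'
#' Expected profiles are deterministic given the seed; with
#' `dispersion > 0`, read counts are drawn negative-binomially around the
#' expected counts and converted back to RPKM. The returned truth records
#' planted and realized effects, block membership, coupled pairs and the
#' expressed panel, and suffices to score recovery of every downstream
#' stage.
#'
#' @param config a [synthetic_config()].
#' @param mode return an `"rpkm"` (default) or `"counts"` mode matrix.
#' @return list with `em` (an [expression_matrix]), `groups` (named
#'   factor), `truth` (class `"synthetic_truth"`).
#' @export
generate_expression <- function(config, mode = c("rpkm", "counts")) {
  stopifnot(inherits(config, "synthetic_config"))
  mode <- match.arg(mode)
  exp_prof <- expected_expression(config)
  mu <- exp_prof$mu
  grp <- exp_prof$groups
  lengths <- exp_prof$lengths
  expected_counts <- mu * (lengths / 1000) * (config$mapped_total / 1e6)
  counts <- if (config$dispersion == 0) round(expected_counts) else
    with_seed(config$rng_seed + 2L, {
      k <- matrix(stats::rnbinom(length(expected_counts),
                                 mu = expected_counts,
                                 size = 1 / config$dispersion),
                  nrow(expected_counts), ncol(expected_counts))
      dimnames(k) <- dimnames(expected_counts)
      k
    })
  ann <- data.frame(symbol = config$genes,
                    description = "synthetic panel gene",
                    family = "synthetic",
                    row.names = config$genes, stringsAsFactors = FALSE)
  em <- if (mode == "counts") {
    expression_matrix(counts, mode = "counts", lengths = lengths,
                      totals = stats::setNames(rep(config$mapped_total,
                                                   ncol(counts)),
                                               colnames(counts)),
                      annotations = ann)
  } else if (config$dispersion == 0) {
    # noiseless limit: exact expected RPKM, free of count rounding
    expression_matrix(mu, mode = "rpkm", annotations = ann)
  } else {
    expression_matrix(sweep(counts / (lengths / 1000), 2L,
                            config$mapped_total / 1e6, "/"),
                      mode = "rpkm", annotations = ann)
  }

  realized <- data.frame(
    gene = config$genes,
    mean_mc = rowMeans(mu[, grp == "MC", drop = FALSE]),
    mean_lc = rowMeans(mu[, grp == "LC", drop = FALSE]),
    stringsAsFactors = FALSE)
  realized$log2fc <- log2(realized$mean_mc / realized$mean_lc)
  de_truth <- realized$gene[abs(realized$log2fc) >= 1 - 1e-9]
  truth <- structure(list(
    de_genes = stats::setNames(realized$log2fc[match(de_truth, realized$gene)],
                               de_truth),
    planted_log2fc = config$planted_log2fc,
    block_membership = stats::setNames(
      lapply(config$coexpr_blocks, function(b) b$members),
      vapply(config$coexpr_blocks, function(b) b$hub, "")),
    block_signs = stats::setNames(
      vapply(config$coexpr_blocks, function(b) b$sign, ""),
      vapply(config$coexpr_blocks, function(b) b$hub, "")),
    coupled_pairs = config$gene_otu_couplings,
    otu_group_log2fc = config$otu_group_log2fc,
    expressed_genes = config$genes[seq_len(config$n_expressed)],
    realized_group_means = realized),
    class = "synthetic_truth")
  list(em = em, groups = grp, truth = truth)
}

## Balanced random taxonomy over sentinel-safe labels p01.., g01..
generate_taxonomy <- function(config) {
  n_otus <- config$n_otus
  phyla <- sprintf("p%02d", seq_len(config$n_phyla))
  genera <- sprintf("g%02d", seq_len(config$n_genera))
  phylum_of_genus <- sort(rep_len(seq_len(config$n_phyla), config$n_genera))
  families <- sprintf("f%02d", ceiling(seq_len(config$n_genera) / 2))
  orders <- sprintf("o%02d", ceiling(seq_len(config$n_genera) / 4))
  classes <- sprintf("c%02d", ceiling(seq_len(config$n_genera) / 8))
  genus_of_otu <- sample(rep_len(seq_len(config$n_genera), n_otus))
  unclassified <- stats::runif(n_otus) < 0.1
  tax <- data.frame(
    kingdom = "Bacteria",
    phylum = phyla[phylum_of_genus[genus_of_otu]],
    class = classes[genus_of_otu],
    order = orders[genus_of_otu],
    family = families[genus_of_otu],
    genus = ifelse(unclassified, UNCLASSIFIED, genera[genus_of_otu]),
    row.names = config$otus, stringsAsFactors = FALSE)
  tax
}

#' Generate the synthetic OTU count table
#'
#' Uncoupled OTUs draw a log-normal baseline abundance, optionally split by
#' a planted between-group log2 effect; coupled OTUs take a geometric
#' abundance ladder (base 100-300, step 1.6) reordered so their expected
#' abundance is a monotone function of the coupled gene's expected
#' expression ("rank transplanting"), increasing or decreasing with the
#' planted direction. Counts are negative-binomial around the expected
#' abundances, or exactly their rounded values at `dispersion = 0` (in
#' which case uncoupled, effect-free OTUs are constant across samples:
#' the noiseless limit carries no unplanted variation by design).
#'
#' @param config a [synthetic_config()].
#' @return An [otu_table]; deterministic given `config$rng_seed`.
#' @export
generate_otu_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  exp_prof <- expected_expression(config)
  grp <- exp_prof$groups
  n <- length(grp)
  with_seed(config$rng_seed, {
    taxonomy <- generate_taxonomy(config)
    lambda <- matrix(0, n, config$n_otus,
                     dimnames = list(names(grp), config$otus))
    base <- stats::rlnorm(config$n_otus,
                          meanlog = config$base_abundance$meanlog,
                          sdlog = config$base_abundance$sdlog)
    for (j in seq_len(config$n_otus)) lambda[, j] <- base[j]
    eff <- config$otu_group_log2fc
    if (length(eff)) {
      # share one baseline within each +1/-1/-1 triplet so the planted
      # group effects cancel in the expected per-sample totals
      if (length(eff) %% 3L == 0L &&
          all(matrix(eff, nrow = 3L)[1, ] == 1) &&
          all(matrix(eff, nrow = 3L)[-1, ] == -1)) {
        trip <- rep(seq_len(length(eff) / 3L), each = 3L)
        shared <- base[match(names(eff), config$otus)][!duplicated(trip)][trip]
        for (i in seq_along(eff)) lambda[, names(eff)[i]] <- shared[i]
      }
      for (o in names(eff))
        lambda[, o] <- lambda[, o] * 2^(eff[[o]] * (grp == "MC"))
    }
    cp <- config$gene_otu_couplings
    counts <- if (config$dispersion == 0) round(lambda) else lambda
    if (nrow(cp)) {
      # compensating +/- pairs: one abundance base per pair within a gene;
      # the "-" member is the pair total minus the "+" ladder (integer-
      # exact at dispersion 0), so the coupled block's per-sample sum is
      # constant and planted structure cannot leak into other OTUs'
      # relative abundances through the denominator
      ladder_base <- stats::runif(nrow(cp), 100, 300)
      for (g in unique(cp$gene)) {
        pos <- which(cp$gene == g & cp$direction == "+")
        neg <- which(cp$gene == g & cp$direction == "-")
        np <- min(length(pos), length(neg))
        if (np) ladder_base[neg[seq_len(np)]] <- ladder_base[pos[seq_len(np)]]
      }
      C <- 1.6^(n - 1) + 1
      for (k in seq_len(nrow(cp))) {
        gene_mu <- exp_prof$mu[cp$gene[k], ]
        rk <- rank(gene_mu, ties.method = "first")
        up <- ladder_base[k] * 1.6^(rk - 1)
        lam_k <- if (cp$direction[k] == "-") {
          if (config$dispersion == 0) round(ladder_base[k] * C) - round(up)
          else ladder_base[k] * C - up
        } else up
        lambda[, cp$otu[k]] <- lam_k
        counts[, cp$otu[k]] <- if (config$dispersion == 0) {
          if (cp$direction[k] == "-") lam_k else round(lam_k)
        } else lam_k
      }
    }
    counts <- if (config$dispersion == 0) counts else {
      k <- matrix(stats::rnbinom(length(lambda), mu = lambda,
                                 size = 1 / config$dispersion),
                  nrow(lambda), ncol(lambda))
      dimnames(k) <- dimnames(lambda)
      k
    }
    otu_table(counts, taxonomy, grp)
  })
}

#' Write the synthetic fixture bundle to a directory
#'
#' Emits the round-trippable external formats: `otu_table.tsv` (QIIME
#' classic style), `sample_metadata.tsv`, `expression.tsv` (RPKM or counts
#' + lengths) and `truth.json`.
#'
#' @param otu an [otu_table].
#' @param expression an [expression_matrix].
#' @param truth a `"synthetic_truth"` (optional).
#' @param dir output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
write_fixtures <- function(otu, expression, truth = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(otu_table = file.path(dir, "otu_table.tsv"),
             metadata = file.path(dir, "sample_metadata.tsv"),
             expression = file.path(dir, "expression.tsv"))
  write_otu_table(otu, files[["otu_table"]])
  write_sample_metadata(otu$groups, files[["metadata"]])
  write_expression(expression, files[["expression"]])
  if (!is.null(truth)) {
    files[["truth"]] <- file.path(dir, "truth.json")
    jsonlite::write_json(truth_as_list(truth), files[["truth"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(files)
}

#' JSON-friendly form of a synthetic truth record
#'
#' Named numeric/character vectors become named lists so their names
#' survive serialization as JSON object keys.
#' @param truth a `"synthetic_truth"`.
#' @return a plain list, suitable for [jsonlite::write_json()].
#' @export
truth_as_list <- function(truth) {
  out <- unclass(truth)
  for (nm in c("de_genes", "planted_log2fc", "otu_group_log2fc",
               "block_signs"))
    out[[nm]] <- as.list(out[[nm]])
  out
}
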