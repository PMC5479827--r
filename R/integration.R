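#' Correlation screen of OTUs against seed-gene expression
#'
#' Reduces the microbial feature space before ordination: an OTU is
#' retained only if its per-sample relative abundance has a Spearman
#' correlation of magnitude at least `rho_min` with the expression of at
#' least one seed gene, at a permutation p-value of at most `p_max`
#' (the removal rule states the complement: everything with weaker or
#' non-significant correlation to all seeds goes). Inclusive boundaries on
#' retention mirror the strict wording of the removal rule. The sidedness,
#' tie fallback and exact-p machinery are shared with [build_network()].
#'
#' @param profile a `"taxon_profile"` at OTU level ([to_relative()]).
#' @param em an RPKM-mode [expression_matrix] containing the seed genes,
#'   with the same samples as `profile` (any order).
#' @param seeds seed gene ids (typically the DE lectins).
#' @param rho_min inclusive absolute-rho bound (default 0.6).
#' @param p_max inclusive p bound (default 0.05).
#' @param signed_rho if `TRUE`, only positive rho counts toward retention.
#' @param alternative sidedness of the permutation p.
#' @param n_mc,rng_seed Monte Carlo fallback settings for tied pairs.
#' @return list with `retained` (OTU ids), `removed` (OTU ids),
#'   `removal_fraction`, and `correlations`: data.frame of the best
#'   (largest `|rho|`, then smallest p) seed per OTU with columns
#'   `otu`, `gene`, `rho`, `p`, `passed`.
#' @export
otu_gene_scc_filter <- function(profile, em, seeds, rho_min = 0.6,
                                p_max = 0.05, signed_rho = FALSE,
                                alternative = "two.sided",
                                n_mc = 1e5, rng_seed = 1L) {
  stopifnot(inherits(profile, "taxon_profile"),
            inherits(em, "expression_matrix"))
  if (length(seeds) == 0) stop("no seed genes")
  missing <- setdiff(seeds, rownames(em$values))
  if (length(missing))
    stop("seed gene(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  samples <- rownames(profile$abund)
  if (!setequal(samples, colnames(em$values)))
    stop("sample sets differ between tables: only in profile {",
         paste(setdiff(samples, colnames(em$values)), collapse = ", "),
         "}, only in expression {",
         paste(setdiff(colnames(em$values), samples), collapse = ", "), "}")
  expr <- em$values[seeds, samples, drop = FALSE]
  abund <- profile$abund
  n <- length(samples)

  constant_seed <- apply(expr, 1L, function(v) length(unique(v)) == 1L)
  if (any(constant_seed)) {
    warning("seed gene(s) with constant expression skipped: ",
            paste(seeds[constant_seed], collapse = ", "))
    expr <- expr[!constant_seed, , drop = FALSE]
    if (nrow(expr) == 0) stop("all seed genes constant")
  }
  constant_otu <- apply(abund, 2L, function(v) length(unique(v)) == 1L)
  if (any(constant_otu))
    warning(sum(constant_otu),
            " OTU(s) with constant abundance: correlation undefined, removed")

  rho_mat <- suppressWarnings(
    stats::cor(abund, t(expr), method = "spearman"))  # OTUs x seeds
  pfun <- spearman_p_fun(n, alternative)
  seed_tied <- apply(expr, 1L, anyDuplicated) > 0
  otu_tied <- apply(abund, 2L, anyDuplicated) > 0

  otus <- colnames(abund)
  best <- data.frame(otu = otus, gene = NA_character_, rho = NA_real_,
                     p = NA_real_, passed = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(otus)) {
    if (constant_otu[i]) next
    rho <- rho_mat[i, ]
    ord <- order(-abs(rho))
    p <- rep(NA_real_, length(rho))
    for (j in ord) {
      if (!seed_tied[j] && !otu_tied[i]) {
        p[j] <- pfun(rho[j])
      } else {
        p[j] <- spearman_test(abund[, i], expr[j, ],
                              alternative = alternative,
                              n_mc = n_mc, rng_seed = rng_seed)$p
      }
      effective <- if (signed_rho) rho[j] else abs(rho[j])
      if (effective >= rho_min && p[j] <= p_max) break  # found a qualifying seed
    }
    eff <- if (signed_rho) rho else abs(rho)
    qualifying <- which(!is.na(p) & eff >= rho_min & p <= p_max)
    pick <- if (length(qualifying))
      qualifying[order(-eff[qualifying], p[qualifying])][1]
    else ord[1]
    best$gene[i] <- rownames(expr)[pick]
    best$rho[i] <- rho[pick]
    best$p[i] <- p[pick]
    best$passed[i] <- length(qualifying) > 0
  }
  retained <- otus[best$passed]
  list(retained = retained,
       removed = setdiff(otus, retained),
       removal_fraction = 1 - length(retained) / length(otus),
       correlations = best)
}

#' Full integration stage: correlation screen, CCA, genus centroids
#'
#' Composes [otu_gene_scc_filter()] on the OTU relative-abundance profile,
#' [cca_fit()] of the retained OTUs' relative abundances constrained by the
#' seed genes' RPKM, and [genus_centroids()]. The community fed to the CCA
#' is the relative abundance of the retained OTUs; expression constraints
#' are untransformed RPKM by default (a log2 option exists). With few
#' samples and many seeds, constraints beyond the sample rank are dropped
#' with a warning.
#'
#' @param profile OTU-level `"taxon_profile"`.
#' @param em RPKM-mode [expression_matrix].
#' @param seeds seed gene ids.
#' @param rho_min,p_max,signed_rho,alternative,n_mc,rng_seed passed to
#'   [otu_gene_scc_filter()].
#' @param log_constraints if `TRUE`, use `log2(RPKM + 1)` constraints.
#' @param weighted_centroids passed to [genus_centroids()].
#' @return list with `filter` (the screen result), `cca` (a
#'   [cca_fit()] result or `NULL`), `centroids`, `status`
#'   (`"ok"` or `"empty"`), `n_total`, `n_retained`, `removal_fraction`.
#' @export
run_integration <- function(profile, em, seeds, rho_min = 0.6, p_max = 0.05,
                            signed_rho = FALSE, alternative = "two.sided",
                            n_mc = 1e5, rng_seed = 1L,
                            log_constraints = FALSE,
                            weighted_centroids = FALSE) {
  screen <- otu_gene_scc_filter(profile, em, seeds, rho_min = rho_min,
                                p_max = p_max, signed_rho = signed_rho,
                                alternative = alternative, n_mc = n_mc,
                                rng_seed = rng_seed)
  if (length(screen$retained) == 0) {
    return(list(filter = screen, cca = NULL, centroids = NULL,
                status = "empty",
                n_total = ncol(profile$abund), n_retained = 0L,
                removal_fraction = screen$removal_fraction))
  }
  samples <- rownames(profile$abund)
  community <- profile$abund[, screen$retained, drop = FALSE]
  X <- t(em$values[seeds, samples, drop = FALSE])
  if (log_constraints) X <- log2(X + 1)
  fit <- cca_fit(community, X)
  centroids <- if (!is.null(profile$taxonomy))
    genus_centroids(fit, profile$taxonomy[screen$retained, , drop = FALSE],
                    weighted = weighted_centroids)
  list(filter = screen, cca = fit, centroids = centroids, status = "ok",
       n_total = ncol(profile$abund),
       n_retained = length(screen$retained),
       removal_fraction = screen$removal_fraction)
}
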