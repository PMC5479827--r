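#' Shannon diversity index (natural log)
#'
#' `H = -sum(p * log(p))` in nats over a vector of fractions; zero entries
#' contribute nothing. `H` is 0 for a single-taxon community and `log(S)`
#' for a uniform community of `S` taxa.
#'
#' @param fractions non-negative fractions summing to 1 (a profile row).
#' @return Shannon H in nats.
#' @export
shannon <- function(fractions) {
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1")
  p <- fractions[fractions > 0]
  -sum(p * log(p))
}

#' Shannon diversity per sample, community-wide or within one clade
#'
#' @param profile a [to_relative()] profile.
#' @param clade optional taxon label at `clade_rank`; if given, diversity is
#'   computed over the OTUs of that clade only (renormalized within it).
#' @param clade_rank rank at which `clade` is interpreted (default
#'   `"phylum"`).
#' @return named numeric vector of per-sample H (nats).
#' @export
shannon_per_sample <- function(profile, clade = NULL, clade_rank = "phylum") {
  stopifnot(inherits(profile, "taxon_profile"))
  mat <- profile$abund
  if (!is.null(clade)) {
    if (is.null(profile$taxonomy)) stop("profile carries no taxonomy")
    sel <- profile$taxonomy[[clade_rank]] == clade
    if (!any(sel)) stop("no taxa in clade ", clade)
    mat <- mat[, sel, drop = FALSE]
    mat <- mat / rowSums(mat)
  }
  apply(mat, 1L, shannon)
}

#' Analytic rarefaction: expected richness in a subsample
#'
#' Expected number of distinct OTUs in a uniform random subsample of `m`
#' reads drawn without replacement from one sample:
#' `E[S_m] = sum_i (1 - choose(N - N_i, m) / choose(N, m))`
#' (hypergeometric expectation, computed on the log-choose scale). The
#' curve is exact and deterministic; Monte Carlo subsampling is only ever
#' needed as an independent check.
#'
#' @param counts integer OTU counts of one sample.
#' @param depths subsample sizes `m`, each between 1 and `sum(counts)`.
#' @return numeric vector `E[S_m]`, one entry per depth.
#' @export
rarefaction_curve <- function(counts, depths) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  N <- sum(counts)
  if (any(depths < 1) || any(depths > N))
    stop("each depth must lie in [1, ", N, "]")
  if (any(depths != round(depths))) stop("depths must be integers")
  ni <- counts[counts > 0]
  vapply(depths, function(m) {
    # log P(OTU i entirely missed) = lchoose(N - ni, m) - lchoose(N, m)
    lmiss <- lchoose(N - ni, m) - lchoose(N, m)
    lmiss[N - ni < m] <- -Inf
    sum(1 - exp(lmiss))
  }, numeric(1))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a,b) = 1 - 2 * sum(min(p_a, p_b)) / sum(p_a + p_b)`; 0 for identical
#' samples, 1 for disjoint supports.
#'
#' @param profile a `"taxon_profile"` (or any samples x taxa matrix of
#'   non-negative values).
#' @return a symmetric `dist`-convertible matrix, zero diagonal, in `[0,1]`.
#' @export
bray_curtis <- function(profile) {
  mat <- if (inherits(profile, "taxon_profile")) profile$abund else
    as.matrix(profile)
  d <- as.matrix(vegan::vegdist(mat, method = "bray"))
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a dissimilarity
#' matrix: with midranks of all pairwise dissimilarities,
#' `R = (mean rank between groups - mean rank within groups) / (M/2)`,
#' `M = n(n-1)/2`. `R` is near 0 when between- and within-group
#' dissimilarities are exchangeable and 1 when every between-group
#' dissimilarity exceeds every within-group one. The p-value is the upper
#' tail of `R` over relabelings of the samples: exhaustive over all distinct
#' label assignments when there are at most `max_exhaustive` of them,
#' otherwise seeded Monte Carlo.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param groups two-level factor over the samples, each level with >= 2
#'   samples.
#' @param n_permutations Monte Carlo draws when enumeration is infeasible.
#' @param rng_seed seed for the Monte Carlo path.
#' @param max_exhaustive enumeration budget (default 10000 assignments).
#' @return list with `R`, `p` (inclusive upper-tail), `p_exclusive`
#'   (strict upper-tail, for randomized-PIT calibration of the discrete
#'   null), `n_permutations` (assignments actually evaluated),
#'   `exhaustive` flag.
#' @export
anosim <- function(d, groups, n_permutations = 9999, rng_seed = NULL,
                   max_exhaustive = 10000) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
    stop("d must be a square symmetric dissimilarity matrix")
  groups <- factor(as.character(groups))
  if (length(groups) != nrow(d)) stop("groups length must match d")
  tab <- table(groups)
  if (length(tab) != 2) stop("ANOSIM here expects exactly 2 groups")
  if (any(tab < 2)) stop("each group needs >= 2 samples, got a group of 1")

  n <- nrow(d)
  M <- n * (n - 1) / 2
  lower <- lower.tri(d)
  rk <- matrix(0, n, n)
  rk[lower] <- rank(d[lower])          # midranks
  rk <- rk + t(rk)

  stat <- function(g) {
    between <- outer(g, g, "!=") & lower.tri(d)
    within <- outer(g, g, "==") & lower.tri(d)
    (mean(rk[between]) - mean(rk[within])) / (M / 2)
  }
  R_obs <- stat(groups)

  n1 <- tab[[1]]
  n_assign <- choose(n, n1)
  if (n_assign <= max_exhaustive) {
    combs <- utils::combn(n, n1)
    Rs <- apply(combs, 2L, function(idx) {
      g <- rep(levels(groups)[2], n)
      g[idx] <- levels(groups)[1]
      stat(factor(g))
    })
    list(R = R_obs, p = mean(Rs >= R_obs - 1e-12),
         p_exclusive = mean(Rs > R_obs + 1e-12),
         n_permutations = as.integer(n_assign), exhaustive = TRUE)
  } else {
    Rs <- with_seed(rng_seed, vapply(seq_len(n_permutations), function(i)
      stat(sample(groups)), numeric(1)))
    list(R = R_obs,
         p = (1 + sum(Rs >= R_obs - 1e-12)) / (n_permutations + 1),
         p_exclusive = sum(Rs > R_obs + 1e-12) / (n_permutations + 1),
         n_permutations = as.integer(n_permutations), exhaustive = FALSE)
  }
}

#' Run a function under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so seeded
#' internals never perturb the caller's RNG stream. A `NULL` seed runs the
#' code as-is.
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}
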