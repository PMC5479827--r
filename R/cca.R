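#' Constrained correspondence analysis (CCA)
#'
#' Canonical correspondence analysis of a non-negative community table
#' `Y` (samples x species) with ordination axes constrained to linear
#' combinations of external variables `X` (samples x constraints), here
#' typically seed-gene RPKM. The algorithm is the classical weighted
#' chi-square formulation:
#'
#' 1. `P = Y / grand total`; row weights `r = rowSums(P)`, column weights
#'    `c = colSums(P)`.
#' 2. chi-square standardized matrix
#'    `Q_ij = (P_ij - r_i c_j) / sqrt(r_i c_j)`; the total inertia is
#'    `sum(Q^2)` (the chi-square statistic of `Y` over its grand total).
#' 3. constraints are centered with weights `r` and scaled by `sqrt(r)`;
#'    `Q` is projected onto their column space by weighted least squares
#'    (QR with pivoting; collinear columns are dropped right-to-left with
#'    a warning naming them).
#' 4. the SVD of the fitted matrix gives the constrained eigenvalues
#'    (squared singular values) and scores; the SVD of the residual gives
#'    the unconstrained axes. Constrained + unconstrained eigenvalues sum
#'    to the total inertia.
#'
#' Scores follow the species-conditional convention ("scaling 2") by
#' default: species in principal coordinates (`V D / sqrt(c)`), sites in
#' standard coordinates, with both linear-combination (LC, fitted) and
#' weighted-average (WA) site scores returned. The number of constrained
#' axes is at most `min(rank(X), n_samples - 1, n_species - 1)`.
#'
#' @param community numeric samples x species matrix, non-negative, with
#'   positive row and column sums.
#' @param constraints numeric samples x q matrix or data.frame.
#' @param scaling `2` (species-conditional, default) or `1`
#'   (site-conditional).
#' @return An object of class `"cca_result"`: list with `eigenvalues`
#'   (constrained, named `CCA1..`), `unconstrained_eigenvalues` (`CA1..`),
#'   `total_inertia`, `species_scores`, `site_scores_lc`, `site_scores_wa`,
#'   `biplot_scores` (weighted correlations of constraints with the LC
#'   axes), `row_weights`, `col_weights`, `dropped_constraints`, `scaling`.
#' @export
cca_fit <- function(community, constraints, scaling = 2) {
  Y <- as.matrix(community)
  if (any(Y < 0)) stop("community matrix must be non-negative")
  if (is.null(rownames(Y))) rownames(Y) <- paste0("site", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sp", seq_len(ncol(Y)))
  zr <- rownames(Y)[rowSums(Y) == 0]
  zc <- colnames(Y)[colSums(Y) == 0]
  if (length(zr)) stop("zero-sum sample row(s): ", paste(zr, collapse = ", "))
  if (length(zc)) stop("zero-sum species column(s): ", paste(zc, collapse = ", "))
  X <- as.matrix(as.data.frame(constraints))
  if (!is.numeric(X)) stop("constraints must be numeric")
  if (nrow(X) != nrow(Y)) stop("constraints must have one row per sample")
  if (is.null(colnames(X))) colnames(X) <- paste0("con", seq_len(ncol(X)))

  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P)
  cw <- colSums(P)
  E <- outer(r, cw)
  Q <- (P - E) / sqrt(E)
  total_inertia <- sum(Q^2)

  # weighted centering and row standardization of the constraints
  Xc <- sweep(X, 2L, colSums(X * r), "-")
  Xw <- Xc * sqrt(r)
  qrX <- qr(Xw)
  rank_x <- qrX$rank
  dropped <- character(0)
  if (rank_x < ncol(Xw)) {
    dropped <- colnames(X)[qrX$pivot[(rank_x + 1):ncol(Xw)]]
    warning("dropping collinear constraint(s): ",
            paste(dropped, collapse = ", "))
  }
  if (rank_x == 0) stop("constraints have no variance after weighted centering")

  Qfit <- qr.fitted(qrX, Q)
  Qres <- Q - Qfit

  k_max <- min(rank_x, nrow(Y) - 1L, ncol(Y) - 1L)
  sv <- svd(Qfit)
  keep <- which(sv$d > 1e-10 * max(sv$d, 1))
  keep <- keep[seq_len(min(length(keep), k_max))]
  lambda <- sv$d[keep]^2
  names(lambda) <- if (length(keep)) paste0("CCA", seq_along(keep))

  svr <- svd(Qres)
  k_res <- min(nrow(Y) - 1L, ncol(Y) - 1L)
  keep_r <- which(svr$d > 1e-10 * max(svr$d, 1))
  keep_r <- keep_r[seq_len(min(length(keep_r), k_res))]
  lambda_res <- svr$d[keep_r]^2
  names(lambda_res) <- if (length(keep_r)) paste0("CA", seq_along(keep_r))

  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]

  # standard coordinates
  phi <- U / sqrt(r)                     # sites (LC), standard
  psi <- V / sqrt(cw)                    # species, standard
  if (scaling == 2) {
    species <- sweep(psi, 2L, d, "*")    # species principal
    sites_lc <- phi
  } else {
    species <- psi
    sites_lc <- sweep(phi, 2L, d, "*")
  }
  # WA site scores: weighted averages of species principal coordinates
  wa <- (P / r) %*% sweep(psi, 2L, d, "*")
  if (scaling == 1) wa <- sweep(wa, 2L, d, "/")
  dimnames(species) <- list(colnames(Y), names(lambda))
  dimnames(sites_lc) <- list(rownames(Y), names(lambda))
  dimnames(wa) <- list(rownames(Y), names(lambda))

  # biplot scores: weighted correlation of constraints with LC axes
  biplot <- matrix(NA_real_, ncol(X), length(keep),
                   dimnames = list(colnames(X), names(lambda)))
  used <- setdiff(colnames(X), dropped)
  for (j in used) {
    xj <- Xc[, j]
    for (k in seq_along(keep)) {
      uk <- phi[, k]
      biplot[j, k] <- sum(r * xj * uk) /
        sqrt(sum(r * xj^2) * sum(r * uk^2))
    }
  }

  structure(list(eigenvalues = lambda,
                 unconstrained_eigenvalues = lambda_res,
                 total_inertia = total_inertia,
                 species_scores = species,
                 site_scores_lc = sites_lc,
                 site_scores_wa = wa,
                 biplot_scores = biplot,
                 row_weights = r, col_weights = cw,
                 dropped_constraints = dropped,
                 scaling = scaling),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("cca_result\n")
  cat(sprintf("total inertia: %.6f\n", x$total_inertia))
  cat(sprintf("constrained: %.6f (%d axes) | unconstrained: %.6f (%d axes)\n",
              sum(x$eigenvalues), length(x$eigenvalues),
              sum(x$unconstrained_eigenvalues),
              length(x$unconstrained_eigenvalues)))
  print(round(x$eigenvalues, 6))
  invisible(x)
}

#' Genus centroids on the ordination
#'
#' Places each genus at the centroid of its OTUs' species scores: the
#' unweighted arithmetic mean by default, or an abundance-weighted mean
#' (column weights of the CCA) behind a flag. A genus with no retained OTU
#' is absent from the output; the UNCLASSIFIED sentinel forms its own bin.
#'
#' @param cca a [cca_fit()] result.
#' @param taxonomy genus labels per OTU: either a named character vector or
#'   a data.frame with a `genus` column keyed by OTU id.
#' @param weighted if `TRUE`, weight each OTU by its community column mass.
#' @return matrix genus x axes.
#' @export
genus_centroids <- function(cca, taxonomy, weighted = FALSE) {
  stopifnot(inherits(cca, "cca_result"))
  if (is.data.frame(taxonomy)) {
    genus <- stats::setNames(taxonomy$genus, rownames(taxonomy))
  } else genus <- taxonomy
  otus <- rownames(cca$species_scores)
  missing <- setdiff(otus, names(genus))
  if (length(missing))
    stop("no genus label for OTU(s): ", paste(missing, collapse = ", "))
  genus <- genus[otus]
  w <- if (weighted) cca$col_weights[otus] else
    stats::setNames(rep(1, length(otus)), otus)
  out <- do.call(rbind, lapply(split(seq_along(otus), genus), function(idx) {
    colSums(cca$species_scores[idx, , drop = FALSE] * w[idx]) / sum(w[idx])
  }))
  out
}
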