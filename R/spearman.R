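#' Spearman rank correlation coefficient
#'
#' Pearson correlation of midranks (tie-aware). Undefined when either
#' vector is constant; callers exclude such genes with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA` (with a warning) for a constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

## Environment caching the exact permutation null of rho per n (tie-free).
.spearman_cache <- new.env(parent = emptyenv())

#' All permutations of 1..n (internal, n <= 8)
#' @keywords internal
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, p + (p >= k))))
}

#' Exact permutation null distribution of Spearman's rho
#'
#' Enumerates all `n!` rank permutations (tie-free case) and returns the
#' corresponding rho values `1 - 6*sum(d^2) / (n(n^2-1))`. At `n = 6` the
#' distribution lives on the grid `k/720` of probabilities and the smallest
#' attainable two-sided p-value is `2/720`.
#'
#' @param n number of paired observations, `3 <= n <= 8`.
#' @return numeric vector of length `n!` (cached across calls).
#' @export
spearman_null <- function(n) {
  if (n < 3 || n > 8) stop("exact enumeration supported for 3 <= n <= 8")
  key <- as.character(n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  perm <- all_permutations(n)
  d2 <- rowSums((perm - matrix(seq_len(n), nrow(perm), n, byrow = TRUE))^2)
  rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  .spearman_cache[[key]] <- rho
  rho
}

#' Exact (or t-approximate) p-value for Spearman's rho
#'
#' Exact mode (tie-free ranks, `n <= 8`): the proportion of the `n!` rank
#' permutations whose statistic is as or more extreme than `rho`
#' (two-sided: `|rho*| >= |rho|`). For `n > 8` the usual t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` is used instead and a notice is
#' emitted, since full enumeration is no longer practical.
#'
#' @param rho observed correlation(s).
#' @param n number of paired observations.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return p-value(s) in `(0, 1]`.
#' @export
spearman_exact_p <- function(rho, n,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n > 8) {
    message("n = ", n, " > 8: falling back to the t approximation")
    return(spearman_t_p(rho, n, alternative))
  }
  null <- spearman_null(n)
  eps <- 1e-9
  vapply(rho, function(r) switch(alternative,
    two.sided = mean(abs(null) >= abs(r) - eps),
    greater = mean(null >= r - eps),
    less = mean(null <= r + eps)), numeric(1))
}

#' t approximation to the Spearman p-value
#' @keywords internal
spearman_t_p <- function(rho, n, alternative = "two.sided") {
  rho <- pmin(pmax(rho, -1), 1)
  t_stat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  upper <- stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
  switch(alternative,
         two.sided = pmin(1, 2 * pmin(upper, 1 - upper)),
         greater = upper,
         less = 1 - upper)
}

#' Fast vectorized two-sided exact p lookup (tie-free, internal)
#'
#' Precomputes the sorted `|rho*|` null once and answers
#' `P(|rho*| >= |rho|)` by binary search; used by the all-pairs network and
#' OTU-gene screens.
#' @keywords internal
spearman_p_fun <- function(n, alternative = "two.sided") {
  if (n > 8) return(function(r) spearman_t_p(r, n, alternative))
  null <- spearman_null(n)
  L <- length(null)
  if (alternative == "two.sided") {
    sorted <- sort(abs(null))
    function(r) (L - findInterval(abs(r) - 1e-9, sorted)) / L
  } else if (alternative == "greater") {
    sorted <- sort(null)
    function(r) (L - findInterval(r - 1e-9, sorted)) / L
  } else {
    sorted <- sort(null)
    function(r) findInterval(r + 1e-9, sorted) / L
  }
}

#' Exact permutation p in the presence of ties (n <= 8, internal)
#'
#' The tabulated tie-free null does not apply to tied data, but the
#' permutation test itself stays exact: enumerate all `n!` relabelings of
#' one vector's midranks against the other's and count statistics as or
#' more extreme than the observed tie-corrected rho.
#' @keywords internal
spearman_exact_p_ties <- function(x, y, rho, alternative = "two.sided") {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  perm <- all_permutations(n)
  rxc <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
  ryc <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
  sims <- as.vector(matrix(ryc[perm], nrow(perm), n) %*% rxc)
  eps <- 1e-9
  switch(alternative,
         two.sided = mean(abs(sims) >= abs(rho) - eps),
         greater = mean(sims >= rho - eps),
         less = mean(sims <= rho + eps))
}

#' Spearman correlation test for one pair of vectors
#'
#' Computes rho and its permutation p-value. For `n <= 8` the p-value is
#' exact by enumeration of all `n!` relabelings: against the tabulated
#' tie-free null for tie-free inputs, or against the enumerated
#' distribution of the observed midranks when ties are present (still
#' exact; ties merely change the attainable statistic values). For
#' `n > 8`, tie-free inputs use the t approximation and tied inputs a
#' seeded Monte Carlo permutation p.
#'
#' @param x,y numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param n_mc Monte Carlo permutations for the large-n tie fallback.
#' @param rng_seed seed for that fallback.
#' @return list with `rho`, `p`, `method`.
#' @export
spearman_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                          n_mc = 1e5, rng_seed = 1L) {
  alternative <- match.arg(alternative)
  rho <- spearman_rho(x, y)
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_, method = "undefined"))
  n <- length(x)
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (!has_ties && n <= 8) {
    list(rho = rho, p = spearman_exact_p(rho, n, alternative),
         method = "exact")
  } else if (has_ties && n <= 8) {
    list(rho = rho, p = spearman_exact_p_ties(x, y, rho, alternative),
         method = "exact-ties")
  } else if (has_ties) {
    rx <- rank(x)
    p <- with_seed(rng_seed, {
      sims <- vapply(seq_len(n_mc), function(i)
        stats::cor(rx, sample(y), method = "spearman"), numeric(1))
      extreme <- switch(alternative,
                        two.sided = abs(sims) >= abs(rho) - 1e-9,
                        greater = sims >= rho - 1e-9,
                        less = sims <= rho + 1e-9)
      (1 + sum(extreme)) / (n_mc + 1)
    })
    list(rho = rho, p = p, method = "monte-carlo")
  } else {
    list(rho = rho, p = spearman_t_p(rho, n, alternative), method = "t")
  }
}
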