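random_community <- function(n, m, seed) {
  set.seed(seed)
  Y <- matrix(stats::rpois(n * m, lambda = stats::rgamma(n * m, 2, 0.1)),
              n, m, dimnames = list(paste0("s", 1:n), paste0("sp", 1:m)))
  Y[rowSums(Y) == 0, 1] <- 1
  Y[1, colSums(Y) == 0] <- 1
  Y
}

test_that("inertia decomposes exactly into constrained plus residual axes", {
  for (seed in 1:20) {
    Y <- random_community(6, 15, seed)
    X <- matrix(stats::rnorm(6 * 2), 6, 2)
    fit <- cca_fit(Y, X)
    expect_equal(sum(fit$eigenvalues) + sum(fit$unconstrained_eigenvalues),
                 fit$total_inertia, tolerance = 1e-8)
    expect_true(all(diff(fit$eigenvalues) < 1e-12))
    expect_true(all(fit$eigenvalues >= 0))
    # total inertia is the chi-square statistic over the grand total
    chi <- suppressWarnings(stats::chisq.test(Y)$statistic)
    expect_equal(fit$total_inertia, unname(chi) / sum(Y), tolerance = 1e-8)
  }
})

test_that("eigenvalues match vegan on random problems", {
  for (seed in 1:10) {
    Y <- random_community(7, 12, seed + 100)
    X <- matrix(stats::rnorm(7 * 3), 7, 3,
                dimnames = list(rownames(Y), paste0("x", 1:3)))
    fit <- cca_fit(Y, X)
    ref <- vegan::cca(Y ~ ., data = as.data.frame(X))
    expect_equal(unname(fit$eigenvalues), unname(ref$CCA$eig),
                 tolerance = 1e-8)
    expect_equal(unname(fit$unconstrained_eigenvalues), unname(ref$CA$eig),
                 tolerance = 1e-8)
    expect_equal(fit$total_inertia, ref$tot.chi, tolerance = 1e-8)
    # species scores span the same axes (proportional up to sign)
    sp <- vegan::scores(ref, display = "species", scaling = 2,
                        choices = seq_along(fit$eigenvalues))
    for (k in seq_along(fit$eigenvalues)) {
      r <- abs(stats::cor(fit$species_scores[, k], sp[, k]))
      expect_gt(r, 1 - 1e-6)
    }
  }
})

test_that("saturated constraints reduce CCA to plain CA", {
  Y <- random_community(6, 10, 42)
  # a full indicator basis of the samples spans the whole centered space
  X <- stats::model.matrix(~ 0 + f, data.frame(f = factor(1:6)))
  fit <- suppressWarnings(cca_fit(Y, X))
  ca <- vegan::cca(Y)
  expect_equal(unname(fit$eigenvalues), unname(ca$CA$eig), tolerance = 1e-8)
  expect_length(fit$unconstrained_eigenvalues, 0)
})

test_that("a single constraint yields exactly one constrained axis", {
  Y <- random_community(6, 10, 43)
  fit <- cca_fit(Y, matrix(c(1, 0, 1, 0, 1, 0), 6, 1))
  expect_length(fit$eigenvalues, 1)
  expect_equal(sum(fit$eigenvalues) + sum(fit$unconstrained_eigenvalues),
               fit$total_inertia, tolerance = 1e-10)
})

test_that("constrained inertia grows with nested constraint sets", {
  Y <- random_community(8, 12, 44)
  set.seed(44)
  X <- matrix(stats::rnorm(8 * 4), 8, 4)
  prev <- 0
  for (q in 1:4) {
    fit <- cca_fit(Y, X[, 1:q, drop = FALSE])
    expect_gte(sum(fit$eigenvalues), prev - 1e-10)
    prev <- sum(fit$eigenvalues)
  }
})

test_that("small-instance oracle: one binary constraint on a 3x3 table", {
  # worked example solved independently step by step (weighted chi-square
  # standardization, rank-1 weighted projection, SVD), then frozen
  Y <- matrix(c(4, 1, 1,
                1, 4, 1,
                1, 1, 4), 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("sp", 1:3)))
  x <- matrix(c(1, 0, 0), 3, 1)
  oracle <- local({
    P <- Y / sum(Y); r <- rowSums(P); cw <- colSums(P)
    Q <- (P - outer(r, cw)) / sqrt(outer(r, cw))
    xc <- x - sum(x * r)
    xw <- xc * sqrt(r)
    proj <- xw %*% (t(xw) / sum(xw^2))
    sum((proj %*% Q)^2)
  })
  fit <- cca_fit(Y, x)
  expect_length(fit$eigenvalues, 1)
  expect_equal(unname(fit$eigenvalues), oracle, tolerance = 1e-12)
  ref <- vegan::cca(Y ~ x)
  expect_equal(unname(fit$eigenvalues), unname(ref$CCA$eig),
               tolerance = 1e-10)
})

test_that("WA site scores are weighted averages of species scores per axis", {
  Y <- random_community(6, 9, 45)
  X <- matrix(stats::rnorm(12), 6, 2)
  fit <- cca_fit(Y, X)
  P <- Y / sum(Y)
  r <- rowSums(P)
  for (k in seq_along(fit$eigenvalues)) {
    wa_manual <- (P / r) %*% fit$species_scores[, k]
    expect_equal(unname(fit$site_scores_wa[, k]), unname(c(wa_manual)),
                 tolerance = 1e-10)
  }
  # under saturated constraints (pure CA) the WA scores collapse onto the
  # LC scores axis by axis; in a genuine CCA they differ by the residual
  sat <- suppressWarnings(
    cca_fit(Y, stats::model.matrix(~ 0 + f, data.frame(f = factor(1:6)))))
  for (k in seq_along(sat$eigenvalues)) {
    r_cor <- abs(stats::cor(sat$site_scores_wa[, k], sat$site_scores_lc[, k]))
    expect_gt(r_cor, 1 - 1e-8)
  }
})

test_that("degenerate inputs fail with named errors; collinearity is dropped", {
  Y <- random_community(5, 8, 46)
  Y[, 3] <- 0
  expect_error(cca_fit(Y, matrix(stats::rnorm(5), 5, 1)), "sp3")
  Y <- random_community(5, 8, 46)
  X <- cbind(a = stats::rnorm(5), b = 0)
  X <- cbind(X, c = X[, "a"] * 2)
  expect_warning(fit <- cca_fit(Y, X), "collinear")
  expect_true(all(c("b", "c") %in% fit$dropped_constraints) ||
                "c" %in% fit$dropped_constraints)
  expect_length(fit$eigenvalues, 1)
})

test_that("genus centroids average their OTUs' coordinates", {
  scores <- matrix(c(1, 0, -1, 0, 3, 4), 3, 2, byrow = TRUE,
                   dimnames = list(c("o1", "o2", "o3"), c("CCA1", "CCA2")))
  fake <- structure(list(species_scores = scores,
                         col_weights = c(o1 = 0.2, o2 = 0.6, o3 = 0.2)),
                    class = "cca_result")
  genus <- c(o1 = "gA", o2 = "gA", o3 = "gB")
  cent <- genus_centroids(fake, genus)
  expect_equal(unname(cent["gA", ]), c(0, 0))       # midpoint of (1,0),(-1,0)
  expect_equal(unname(cent["gB", ]), c(3, 4))       # single-OTU genus
  w <- genus_centroids(fake, genus, weighted = TRUE)
  expect_equal(unname(w["gA", ]), c((0.2 * 1 + 0.6 * -1) / 0.8, 0))
  expect_error(genus_centroids(fake, genus[1:2]), "no genus label")
})
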