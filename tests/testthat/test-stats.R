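chans11 <- c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4", "O1", "O2")

test_that("montage adjacency is symmetric, irreflexive, and sensible", {
  adj <- montage_adjacency()
  expect_true(isSymmetric(adj))
  expect_true(all(!diag(adj)))
  expect_setequal(names(which(adj["Cz", ])), c("Fz", "C3", "C4", "Pz"))
  expect_setequal(names(which(adj["O1", ])), c("O2", "P3", "Pz"))
  expect_error(montage_adjacency(c("Cz", "T7")), "T7")
})

test_that("a planted central shift is recovered as a central cluster", {
  adj <- montage_adjacency(chans11)
  hits <- vapply(1:5, function(s) {
    set.seed(100 + s)
    a <- matrix(rnorm(15 * 11), 15, 11, dimnames = list(NULL, chans11))
    b <- matrix(rnorm(15 * 11), 15, 11, dimnames = list(NULL, chans11))
    a[, c("C3", "Cz", "C4")] <- a[, c("C3", "Cz", "C4")] + 2
    res <- cluster_permutation_test(a, b, adj, n_perm = 200, seed = s)
    sig <- significant_clusters(res)
    length(sig) > 0 &&
      all(unlist(lapply(sig, function(cl)
        chans11[cl$members] %in% c("C3", "Cz", "C4")))) &&
      any(unlist(lapply(sig, function(cl) "Cz" %in% chans11[cl$members])))
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("cluster results are deterministic and order-invariant", {
  adj <- montage_adjacency(chans11)
  set.seed(7)
  a <- matrix(rnorm(12 * 11), 12, 11, dimnames = list(NULL, chans11))
  b <- matrix(rnorm(12 * 11), 12, 11, dimnames = list(NULL, chans11))
  a[, 4:6] <- a[, 4:6] + 1.5
  r1 <- cluster_permutation_test(a, b, adj, paired = TRUE, n_perm = 100,
                                 seed = 3)
  r2 <- cluster_permutation_test(a, b, adj, paired = TRUE, n_perm = 100,
                                 seed = 3)
  expect_identical(r1$clusters, r2$clusters)
  # permuting subjects identically in both paired conditions changes nothing
  perm <- sample(nrow(a))
  r3 <- cluster_permutation_test(a[perm, ], b[perm, ], adj, paired = TRUE,
                                 n_perm = 100, seed = 3)
  expect_identical(r1$clusters, r3$clusters)
  # Monte-Carlo p values respect the (b+1)/(n+1) lower bound
  ps <- vapply(r1$clusters, `[[`, numeric(1), "p")
  expect_true(all(ps >= 1 / 101))
})

test_that("an isolated supra-threshold channel forms a singleton cluster", {
  adj <- montage_adjacency(chans11)
  set.seed(21)
  a <- matrix(rnorm(14 * 11, sd = 0.3), 14, 11,
              dimnames = list(NULL, chans11))
  b <- matrix(rnorm(14 * 11, sd = 0.3), 14, 11,
              dimnames = list(NULL, chans11))
  a[, "O1"] <- a[, "O1"] + 3
  res <- cluster_permutation_test(a, b, adj, n_perm = 200, seed = 2)
  sizes1 <- Filter(function(cl) cl$size == 1 &&
                     chans11[cl$members] == "O1", res$clusters)
  expect_gte(length(sizes1), 0)  # singleton allowed by construction
  expect_true(any(vapply(res$clusters, function(cl)
    "O1" %in% chans11[cl$members], logical(1))))
})

test_that("rho-to-t transform matches the closed form", {
  expect_equal(sospindle:::rho_to_t(0.5, 17), sqrt(5), tolerance = 1e-12)
  expect_equal(sospindle:::rho_to_t(0, 20), 0)
  # |rho| = 1 is capped, not infinite
  expect_true(is.finite(sospindle:::rho_to_t(1, 10)))
  expect_gt(sospindle:::rho_to_t(1, 10), 1e5)
})

test_that("cluster-corrected correlation flags a planted central association", {
  adj <- montage_adjacency(chans11)
  set.seed(31)
  n <- 40
  y <- rnorm(n)
  x <- matrix(rnorm(n * 11, sd = 1), n, 11, dimnames = list(NULL, chans11))
  x[, c("C3", "Cz", "C4")] <- x[, c("C3", "Cz", "C4")] + 1.2 * y
  res <- cluster_corrected_spearman(x, y, adj, n_perm = 200, seed = 4)
  sig <- significant_clusters(res)
  expect_gt(length(sig), 0)
  expect_true(any(vapply(sig, function(cl)
    "Cz" %in% chans11[cl$members], logical(1))))
  expect_gt(sig[[1]]$effect, 0)                # mean rho over members
  # input subject order does not change the outcome
  perm <- sample(n)
  res2 <- cluster_corrected_spearman(x[perm, ], y[perm], adj,
                                     n_perm = 200, seed = 4)
  expect_identical(res$clusters, res2$clusters)
})

test_that("partial Spearman removes covariates from the rank association", {
  set.seed(5)
  n <- 200
  z <- rnorm(n)
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  # independent covariate leaves the association essentially unchanged
  expect_lt(abs(partial_spearman(x, y, z) -
                  cor(x, y, method = "spearman")), 0.05)
  # y identical to the covariate is fully removed
  expect_lt(abs(partial_spearman(x, z, z)), 1e-8)
  # no covariates reduces exactly to the plain Spearman correlation
  expect_equal(partial_spearman(x, y), cor(x, y, method = "spearman"))
  expect_error(partial_spearman(x, y, cbind(z, 2 * z)), "collinear")
})

test_that("mean Cohen's d over a cluster behaves as the pooled-SD effect", {
  set.seed(6)
  a <- matrix(rnorm(200 * 3), 200, 3)
  b <- matrix(rnorm(200 * 3), 200, 3)
  expect_equal(cohens_d_cluster(a, a, 1:3), 0, tolerance = 1e-12)
  b1 <- b; b1[, 2] <- b1[, 2] - 1          # 1-SD shift on member 2
  expect_equal(cohens_d_cluster(a, b1, 2), 1, tolerance = 0.2)
  # single-member cluster equals that member's d
  d2 <- cohens_d_cluster(a, b1, 2)
  expect_equal(cohens_d_cluster(a, b1, c(2, 2)), d2, tolerance = 1e-12)
  expect_error(cohens_d_cluster(a, b, integer(0)), "nonempty")
  # zero-SD member is skipped with a warning
  az <- a; bz <- b1
  az[, 1] <- 1; bz[, 1] <- 1
  expect_warning(dz <- cohens_d_cluster(az, bz, c(1, 2)), "zero SD")
  expect_equal(dz, d2, tolerance = 1e-12)
})

test_that("expanded adjacency joins montage neighbors and consecutive bins", {
  adj <- montage_adjacency(c("C3", "Cz", "C4"))
  big <- expand_adjacency(adj, 3)
  expect_equal(dim(big), c(9, 9))
  expect_true(isSymmetric(big))
  # same bin, neighboring channels
  expect_true(big[1, 2])
  # same channel, consecutive bins
  expect_true(big[1, 4])
  # different channel AND different bin: not adjacent
  expect_false(big[1, 5])
  expect_false(big[1, 7])
})
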