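test_that("Euclidean distances match the textbook definition", {
  m <- matrix(c(0, 0, 3, 4), 2, 2, dimnames = list(c("f1", "f2"),
                                                   c("s1", "s2")))
  d <- euclidean_distances(m)
  expect_equal(d["s1", "s2"], 5)
  expect_true(all(diag(d) == 0))
  set.seed(41)
  r <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("f", 1:5),
                                               paste0("s", 1:4)))
  d2 <- euclidean_distances(r)
  for (i in 1:4) {
    for (j in 1:4) {
      expect_equal(d2[i, j], sqrt(sum((r[, i] - r[, j])^2)))
    }
  }
  expect_error(euclidean_distances(r[, 1, drop = FALSE]), "2 samples")
})

test_that("PCoA recovers a planar configuration exactly", {
  set.seed(42)
  pts <- matrix(rnorm(20), ncol = 2,
                dimnames = list(paste0("s", 1:10), NULL))
  d <- as.matrix(dist(pts))
  pc <- suppressWarnings(pcoa(d))
  rec <- as.matrix(dist(pc$points[, 1:2]))
  expect_lt(max(abs(rec - d)), 1e-8)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$eig[pc$eig > 0]) <= 1e-12))  # sorted axes
  td <- tidy(pc)
  expect_equal(td$sample_id, rownames(pts))
  expect_s3_class(autoplot(pc, groups = rep(1:2, 5)), "ggplot")
})

test_that("PERMANOVA equals the brute-force partitioning oracle", {
  set.seed(43)
  m <- matrix(rnorm(24), 4, 6, dimnames = list(paste0("f", 1:4),
                                               paste0("s", 1:6)))
  d <- euclidean_distances(m)
  g <- rep(c("a", "b", "c"), each = 2)
  fit <- permanova(d, g, n_perm = 99, seed = 1)
  bf <- oracle_permanova(d, g)
  expect_equal(fit$pseudo_F, bf$F, tolerance = 1e-12)
  expect_equal(fit$R2, bf$R2, tolerance = 1e-12)
  # R2 + SS_within/SS_total = 1 by construction
  expect_equal(fit$R2 + (1 - fit$R2), 1)
  expect_gte(fit$p, 1 / (99 + 1))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n_samples, 6L)
})

test_that("separated clusters attain the minimum p at 9999 permutations", {
  set.seed(44)
  x <- cbind(matrix(rnorm(80), 20), matrix(rnorm(100) + 50, 20),
             matrix(rnorm(100) + 100, 20))
  dimnames(x) <- list(paste0("f", 1:20), paste0("s", 1:14))
  g <- rep(c("40", "60", "80"), c(4, 5, 5))
  fit <- permanova(euclidean_distances(x), g, n_perm = 9999, seed = 2)
  expect_equal(fit$p, 1e-4)
  # pseudo-F invariant to sample reordering
  ord <- sample(14)
  fit2 <- permanova(euclidean_distances(x[, ord]), g[ord],
                    n_perm = 99, seed = 3)
  expect_equal(fit2$pseudo_F, fit$pseudo_F, tolerance = 1e-12)
  expect_equal(fit2$R2, fit$R2, tolerance = 1e-12)
})

test_that("PERMANOVA rejects degenerate groupings", {
  d <- euclidean_distances(matrix(rnorm(12), 3, 4,
                                  dimnames = list(paste0("f", 1:3),
                                                  paste0("s", 1:4))))
  expect_error(permanova(d, rep("a", 4)), "2 groups")
  expect_error(permanova(d, c("a", "a", "a", "b")), "2 samples")
})

test_that("type-I error is calibrated on exchangeable data", {
  set.seed(45)
  g <- rep(c("40", "60", "80"), c(4, 5, 5))
  rej <- 0
  for (i in 1:500) {
    y <- matrix(rnorm(10 * 14), 10,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:14)))
    p <- permanova(euclidean_distances(y), g, n_perm = 199)$p
    rej <- rej + (p <= 0.05)
  }
  expect_gte(rej / 500, 0.03)
  expect_lte(rej / 500, 0.07)
})

test_that("PERMANOVA agrees with the reference implementation", {
  set.seed(46)
  m <- matrix(rnorm(10 * 12), 10, dimnames = list(paste0("f", 1:10),
                                                  paste0("s", 1:12)))
  g <- rep(c("a", "b", "c"), each = 4)
  d <- euclidean_distances(m)
  ours <- permanova(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("pairwise tests cover all pairs with BH adjustment", {
  set.seed(47)
  x <- cbind(matrix(rnorm(40), 10), matrix(rnorm(40) + 20, 10),
             matrix(rnorm(40) + 40, 10))
  dimnames(x) <- list(paste0("f", 1:10), paste0("s", 1:12))
  g <- rep(c("40", "60", "80"), each = 4)
  pw <- pairwise_permanova(euclidean_distances(x), g, n_perm = 199,
                           seed = 1)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$padj >= pw$p))
  expect_true(all(pw$padj < 0.05))  # separated groups
  # null groups: adjusted p not systematically significant
  y <- matrix(rnorm(120), 10, dimnames = dimnames(x))
  pw0 <- pairwise_permanova(euclidean_distances(y), g, n_perm = 199,
                            seed = 2)
  expect_gt(mean(pw0$padj), 0.1)
})

test_that("bootstrap power is calibrated, monotone and saturates", {
  set.seed(48)
  g <- rep(c("40", "60", "80"), c(4, 5, 5))
  y <- matrix(rnorm(20 * 14), 20, dimnames = list(paste0("f", 1:20),
                                                  paste0("s", 1:14)))
  p0 <- permanova_power(y, g, designs = list(c(3, 3, 3)), alpha = 0.05,
                        n_matrices = 100, n_perm = 199, seed = 1)
  expect_lte(p0$median_power, 0.15)  # near alpha under the null
  x <- y
  x[, 1:4] <- x[, 1:4] + 0.55
  x[, 5:9] <- x[, 5:9] + 1.1
  pw <- permanova_power(x, g,
                        designs = list(c(3, 3, 3), c(4, 4, 4),
                                       c(5, 5, 5)),
                        alpha = 0.05, n_matrices = 150, n_perm = 199,
                        seed = 2)
  expect_true(all(diff(pw$median_power) >= -0.05))  # nondecreasing
  xx <- y
  xx[, 1:4] <- xx[, 1:4] + 30
  xx[, 5:9] <- xx[, 5:9] + 60
  p1 <- permanova_power(xx, g, designs = list(c(5, 5, 5)), alpha = 0.05,
                        n_matrices = 50, n_perm = 199, seed = 3)
  expect_equal(p1$power, 1)
  expect_error(permanova_power(y, g, designs = list(c(0, 3, 3))),
               "size 0")
  expect_s3_class(autoplot(p0), "ggplot")
})
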