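test_that("Shannon diversity matches closed forms and coarsening", {
  m <- rbind(u = c(10, 10, 10, 10), s = c(40, 0, 0, 0))
  colnames(m) <- paste0("t", 1:4)
  h <- shannon(count_table(m))
  expect_equal(unname(h["u"]), log(4), tolerance = 1e-12)
  expect_equal(unname(h["s"]), 0, tolerance = 1e-12)
  ct <- toy_count_table(seed = 8)
  merged <- ct$counts
  merged[, 1] <- merged[, 1] + merged[, 2]
  merged <- merged[, -2]
  expect_true(all(shannon(count_table(merged)) <= shannon(ct) + 1e-12))
})

test_that("Bray-Curtis matches the formula, its oracle, and its bounds", {
  m <- rbind(a = c(2, 1, 0), b = c(1, 1, 1), c = c(2, 1, 0))
  colnames(m) <- paste0("t", 1:3)
  D <- bray_curtis(count_table(m))
  expect_equal(D["a", "b"], 1 / 3, tolerance = 1e-12)
  expect_equal(D["a", "c"], 0, tolerance = 1e-12)
  disjoint <- rbind(x = c(5, 5, 0, 0), y = c(0, 0, 7, 3))
  colnames(disjoint) <- paste0("t", 1:4)
  expect_equal(bray_curtis(count_table(disjoint))["x", "y"], 1, tolerance = 1e-12)

  ct <- toy_count_table(n_samples = 5, n_taxa = 8, seed = 14)
  D <- bray_curtis(ct)
  expect_equal(D, t(D))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(D[i, j], oracle_bray(ct$counts[i, ], ct$counts[j, ]),
                 tolerance = 1e-12)
})

test_that("PCoA embeds Euclidean configurations exactly", {
  pts <- cbind(c(0, 1, 2, 3.5))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  suppressWarnings(pc <- pcoa(D, k = 2))
  d1 <- as.matrix(dist(pc$coordinates[, 1]))
  expect_equal(unname(d1), unname(D), tolerance = 1e-9)
  # coordinates are centered (double-centering property)
  expect_equal(unname(colSums(pc$coordinates)), rep(0, ncol(pc$coordinates)),
               tolerance = 1e-9)
  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  suppressWarnings(pz <- pcoa(zero, k = 2))
  expect_true(all(abs(pz$coordinates) < 1e-12))
})

test_that("PERMANOVA pseudo-F equals the direct-sum oracle", {
  set.seed(3)
  X <- matrix(rpois(6 * 5, 20), 6, 5,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:5)))
  D <- bray_curtis(count_table(X))
  g <- rep(c("a", "b"), each = 3)
  pm <- suppressMessages(permanova(D, g, n_perm = 999, seed = 1))
  expect_equal(pm$pseudo_F, oracle_pseudo_F(D, g), tolerance = 1e-12)
  expect_error(permanova(D, rep("a", 6)), "2 groups")
})

test_that("separated clouds reach the permutation floor, pairwise Bonferroni applied", {
  set.seed(5)
  Y <- rbind(matrix(rnorm(30, 0, 1), 10, 3), matrix(rnorm(30, 10, 1), 10, 3),
             matrix(rnorm(30, 20, 1), 10, 3))
  D <- as.matrix(dist(Y)); D <- D / max(D)
  dimnames(D) <- list(paste0("s", 1:30), paste0("s", 1:30))
  g <- rep(c("a", "b", "c"), each = 10)
  pm <- permanova(D, g, n_perm = 999, seed = 2, pairwise = TRUE)
  expect_equal(pm$p, 0.001)
  expect_equal(pm$pairwise$p_bonferroni, pmin(1, pm$pairwise$p * 3))
  expect_equal(nrow(pm$pairwise), 3)
})

test_that("Levins niche breadth matches closed forms", {
  even <- matrix(5, 20, 3, dimnames = list(paste0("s", 1:20), paste0("t", 1:3)))
  expect_equal(unname(niche_breadth(count_table(even))), rep(20, 3),
               tolerance = 1e-12)
  m <- rbind(s1 = c(10, 5), s2 = c(0, 5), s3 = c(0, 5))
  colnames(m) <- c("solo", "spread")
  nb <- niche_breadth(count_table(m))
  expect_equal(unname(nb["solo"]), 1, tolerance = 1e-12)
  # P = (0.5, 0.5, 0) -> B = 2 for a taxon split over two of three samples
  m2 <- rbind(s1 = c(4, 6), s2 = c(4, 6), s3 = c(0, 10))
  colnames(m2) <- c("pair", "rest")
  expect_equal(unname(niche_breadth(count_table(m2))["pair"]), 2,
               tolerance = 1e-12)
  for (tx in colnames(m2))
    expect_equal(unname(niche_breadth(count_table(m2))[tx]),
                 oracle_levins(rel_abund(count_table(m2))[, tx]),
                 tolerance = 1e-12)
})

test_that("NST stays in the unit interval and is reproducible", {
  ct <- toy_count_table(n_samples = 8, n_taxa = 12, seed = 20, depth = 300)
  res <- nst(ct, R = 30, seed = 1)
  expect_gte(res$all$NST, 0)
  expect_lte(res$all$NST, 1)
  res2 <- nst(ct, R = 30, seed = 1)
  expect_identical(res$all$NST, res2$all$NST)
  expect_warning(nst(ct, groups = c(rep("a", 6), "b", "b"), R = 30, seed = 1),
                 "fewer than")
})
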