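test_that("core-taxon filter applies a strict read threshold", {
  m <- cbind(keep = c(600, 600), edge = c(500, 500), drop = c(10, 10))
  m <- cbind(m, matrix(800, 2, 9, dimnames = list(NULL, paste0("f", 1:9))))
  rownames(m) <- c("s1", "s2")
  ct <- count_table(m)
  filtered <- core_taxa_filter(ct, min_reads = 1000)
  expect_true("keep" %in% taxon_ids(filtered))
  expect_false("edge" %in% taxon_ids(filtered))  # total exactly 1000 excluded
  expect_false("drop" %in% taxon_ids(filtered))
  expect_identical(taxon_ids(core_taxa_filter(ct, min_reads = 0)), taxon_ids(ct))
  expect_error(core_taxa_filter(ct, min_reads = 1e7), "too few")
})

test_that("SparCC output satisfies the correlation-matrix contract", {
  cnt <- make_planted_counts(51, n = 60, D = 15, r = 0)
  rho <- sparcc(count_table(cnt))
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 15))
  expect_true(all(abs(rho) <= 1, na.rm = TRUE))
  expect_error(sparcc(count_table(cnt[1:5, ])), ">= 20 samples")
})

test_that("SparCC recovers a planted basis correlation", {
  cnt <- make_planted_counts(11, r = 0.8)
  rho <- sparcc(count_table(cnt))
  expect_lt(abs(rho[1, 2] - 0.8), 0.15)
})

test_that("independent taxa yield near-zero correlations", {
  cnt <- make_planted_counts(12, r = 0)
  rho <- sparcc(count_table(cnt))
  off <- abs(rho[upper.tri(rho)])
  expect_lte(max(off), 0.3)
})

test_that("permutation p-values are bounded and flag the planted pair", {
  cnt <- make_planted_counts(13, n = 100, D = 15, r = 0.9)
  ct <- count_table(cnt)
  rho <- sparcc(ct)
  p <- edge_significance(ct, rho, n_iter = 99, seed = 1)
  off <- p[upper.tri(p)]
  expect_true(all(off >= 1 / 100 & off <= 1, na.rm = TRUE))
  expect_equal(p[1, 2], 1 / 100)  # minimum attainable
  expect_warning(edge_significance(ct, rho, n_iter = 50, seed = 1),
                 "resolution")
})

test_that("edge retention matches hand enumeration on a toy", {
  rho <- matrix(c(1, 0.5, -0.45, 0.5, 1, 0.2, -0.45, 0.2, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- matrix(0.01, 3, 3, dimnames = dimnames(rho))
  p["a", "c"] <- p["c", "a"] <- 0.2  # significant rho, failing p
  net <- build_network(rho, p)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$from, net$edges$to), c("a", "b"))
  expect_equal(net$stats$n_positive, 1)
  expect_equal(net$stats$n_negative, 0)
  none <- build_network(rho * 0.5, p)
  expect_equal(nrow(none$edges), 0)
})

test_that("attack robustness reproduces hand-enumerated curves", {
  nodes <- data.frame(node = letters[1:10])
  e <- t(combn(letters[1:10], 2))
  k10 <- microbial_network(nodes, data.frame(from = e[, 1], to = e[, 2],
                                             rho = 0.5, p = 0.01))
  rc <- attack_robustness(k10)
  expect_equal(rc$auc, 0.5, tolerance = 1e-15)
  expect_equal(rc$lcc_frac, seq(1, 0, by = -0.1))

  star <- microbial_network(
    data.frame(node = c("hub", paste0("l", 1:10))),
    data.frame(from = "hub", to = paste0("l", 1:10), rho = 0.5, p = 0.01))
  expect_lt(attack_robustness(star)$auc, 0.2)
})

test_that("robustness equals the flood-fill oracle on random graphs", {
  for (s in 1:50) {
    net <- random_toy_network(600 + s, n_nodes = sample(4:15, 1))
    rc <- attack_robustness(net)
    expect_equal(rc$auc, oracle_robustness_auc(net, rc$order),
                 tolerance = 1e-12)
  }
})

test_that("removing an edge never increases AUC under a fixed order", {
  for (s in 1:15) {
    net <- random_toy_network(700 + s, n_nodes = 10, p_edge = 0.4)
    if (nrow(net$edges) < 2) next
    rc <- attack_robustness(net)
    drop <- sample(nrow(net$edges), 1)
    thinner <- microbial_network(net$nodes, net$edges[-drop, , drop = FALSE])
    rc2 <- attack_robustness(thinner, order = rc$order)
    expect_lte(rc2$auc, rc$auc + 1e-12)
  }
})

test_that("neighbor-shift scores match their Jaccard definition", {
  nA <- microbial_network(data.frame(node = c("v", "a", "b", "c", "d")),
                          data.frame(from = "v", to = c("a", "b", "c"),
                                     rho = 0.5, p = 0.01))
  nB <- microbial_network(data.frame(node = c("v", "a", "b", "c", "d")),
                          data.frame(from = "v", to = c("b", "c", "d"),
                                     rho = 0.5, p = 0.01))
  ns <- neighbor_shift(nA, nB)
  expect_equal(ns$nesh[ns$node == "v"], 0.5)  # {a,b,c} vs {b,c,d}
  expect_equal(ns$nesh[ns$node == "a"], 1)    # {v} vs empty
  same <- neighbor_shift(nA, nA)
  expect_true(all(same$nesh == 0))
  expect_false(any(same$driver))
  lonely <- microbial_network(data.frame(node = "z"))
  expect_warning(out <- neighbor_shift(nA, lonely), "no common")
  expect_equal(nrow(out), 0)
})

test_that("cross-site networks keep site tags and recover a planted link", {
  set.seed(77)
  n_subj <- 40
  latent <- rnorm(n_subj)
  mk_site <- function(tagseed, planted_col) {
    base <- matrix(rlnorm(n_subj * 12, 2, 0.4), n_subj, 12)
    base[, planted_col] <- exp(0.8 * latent + rnorm(n_subj, 0, 0.2) + 2)
    cnt <- t(apply(base, 1, function(x) rmultinom(1, 3000, x / sum(x))))
    dimnames(cnt) <- list(sprintf("sub%02d_%d", 1:n_subj, tagseed),
                          sprintf("g%02d", 1:12))
    count_table(cnt, data.frame(sample_id = rownames(cnt),
                                subject_id = sprintf("sub%02d", 1:n_subj),
                                site = c("saliva", "BAL")[tagseed]))
  }
  sal <- mk_site(1, 3); bal <- mk_site(2, 7)
  res <- cross_site_network(sal, bal, n_iter = 99, seed = 1,
                            rho_threshold = 0.3)
  expect_true(all(grepl("^(saliva|BAL):", res$network$nodes$node)))
  planted <- res$network$edges
  hit <- (planted$from == "saliva:g03" & planted$to == "BAL:g07") |
    (planted$from == "BAL:g07" & planted$to == "saliva:g03")
  expect_true(any(hit))
  # unpaired subjects are dropped with a warning
  sal_extra <- subset_count_table(sal, samples = 1:30)
  expect_warning(
    expect_error(cross_site_network(subset_count_table(sal, samples = 1:19),
                                    bal, n_iter = 99),
                 ">= 20 subjects"),
    "without both sites")
  expect_warning(res2 <- cross_site_network(sal_extra, bal, n_iter = 99,
                                            seed = 1, rho_threshold = 0.3),
                 "without both sites")
  expect_equal(nrow(res2$network$nodes), 24)
})
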