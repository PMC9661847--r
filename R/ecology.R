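#' Shannon alpha diversity
#'
#' `H = -sum p log p` over nonzero proportions, natural log.
#'
#' @param ct a `count_table`, or a samples x taxa matrix.
#' @return Named numeric vector, one value per sample.
#' @export
shannon <- function(ct) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (any(rowSums(m) <= 0)) stop("zero-total sample(s)")
  vegan::diversity(m, index = "shannon")
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computed on per-sample relative abundances (not rarefied counts);
#' `BC(a,b) = 1 - 2 sum min(a_t, b_t) / (sum a_t + sum b_t)`.
#'
#' @param ct a `count_table` (>= 2 samples), or a matrix already holding
#'   relative abundances when `relative = FALSE` conversion is skipped.
#' @param relative convert rows to relative abundances first.
#' @return Symmetric matrix of dissimilarities in `[0, 1]`, zero diagonal,
#'   with sample identifiers as dimnames.
#' @export
bray_curtis <- function(ct, relative = TRUE) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (nrow(m) < 2) stop("need >= 2 samples")
  if (relative) m <- m / rowSums(m)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the double-centered squared-distance matrix;
#' coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues. Negative eigenvalues are dropped and their absolute mass
#' fraction reported.
#'
#' @param D distance matrix (`dist` or symmetric matrix).
#' @param k number of axes requested.
#' @return List: `coordinates` (samples x axes), `eigenvalues` (all),
#'   `negative_mass` (fraction of total absolute eigenvalue mass dropped).
#' @export
pcoa <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  sc <- cmdscale(as.dist(D), k = min(k, n - 1), eig = TRUE)
  eig <- sc$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalues; truncating to ", n_pos, " axes")
    k <- n_pos
  }
  coords <- sc$points[, seq_len(min(k, ncol(sc$points))), drop = FALSE]
  if (ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  neg_mass <- sum(abs(eig[eig < 0])) / max(sum(abs(eig)), .Machine$double.eps)
  list(coordinates = coords, eigenvalues = eig, negative_mass = neg_mass)
}

#' PERMANOVA on a distance matrix
#'
#' Anderson's pseudo-F from the distance partition, with a permutation
#' p-value `(1 + #{F_perm >= F_obs}) / (n_perm + 1)`. Sample labels are
#' permuted freely (no strata). Pairwise mode tests every group pair and
#' applies Bonferroni correction.
#'
#' @param D distance matrix; `groups` factor of group labels (>= 2 groups
#'   with >= 2 members); `n_perm` permutations (>= 99).
#' @param groups group labels aligned with the rows of `D`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param pairwise also test all group pairs with Bonferroni correction.
#' @return List: `pseudo_F`, `p`, `R2`, `df`, and `pairwise` table when
#'   requested.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = 1, pairwise = FALSE) {
  D <- as.matrix(D)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 members")
  if (n_perm < 99) stop("n_perm must be >= 99")
  run_one <- function(Dm, g, op) {
    with_op_seed(seed, op, {
      fit <- vegan::adonis2(as.dist(Dm) ~ g, permutations = n_perm)
      list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1], R2 = fit$R2[1],
           df = fit$Df[1:2])
    })
  }
  out <- run_one(D, groups, "permanova")
  if (pairwise) {
    lv <- levels(droplevels(groups))
    pairs <- utils::combn(lv, 2)
    n_pairs <- ncol(pairs)
    pw <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                     pseudo_F = NA_real_, p = NA_real_, p_bonferroni = NA_real_)
    for (j in seq_len(n_pairs)) {
      sel <- groups %in% pairs[, j]
      r <- run_one(D[sel, sel], droplevels(groups[sel]),
                   paste0("permanova/", paste(pairs[, j], collapse = "-")))
      pw$pseudo_F[j] <- r$pseudo_F
      pw$p[j] <- r$p
    }
    pw$p_bonferroni <- pmin(1, pw$p * n_pairs)
    out$pairwise <- pw
  }
  out
}

#' Levins niche breadth per taxon
#'
#' `B_j = 1 / sum_i P_ij^2` where `P_ij` is taxon j's relative abundance in
#' sample i divided by its cohort-wide total (so `sum_i P_ij = 1`); ranges
#' from 1 (one sample) to N (spread evenly over all N samples). Taxa absent
#' from every sample are excluded with a note.
#'
#' @param ct a `count_table` or samples x taxa matrix.
#' @return Named numeric vector of niche breadths over present taxa.
#' @export
niche_breadth <- function(ct) {
  m <- if (inherits(ct, "count_table")) rel_abund(ct)
  else {
    m0 <- as.matrix(ct)
    m0 / rowSums(m0)
  }
  tot <- colSums(m)
  absent <- tot == 0
  if (any(absent)) {
    message("excluding ", sum(absent), " taxa absent from all samples")
    m <- m[, !absent, drop = FALSE]
    tot <- tot[!absent]
  }
  P <- sweep(m, 2, tot, "/")
  1 / colSums(P^2)
}

# one null community matrix: per-sample richness preserved; taxa drawn with
# probability proportional to occupancy; abundances proportional to the
# cohort mean relative abundance of the drawn taxa
nst_null_matrix <- function(rel, richness, occupancy, mean_ab) {
  T_ <- ncol(rel)
  null <- matrix(0, nrow(rel), T_, dimnames = dimnames(rel))
  for (i in seq_len(nrow(rel))) {
    r_i <- min(richness[i], sum(occupancy > 0))
    sel <- sample.int(T_, r_i, prob = occupancy)
    ab <- mean_ab[sel]
    if (sum(ab) == 0) ab <- rep(1, r_i)
    null[i, sel] <- ab / sum(ab)
  }
  null
}

#' Normalized stochasticity ratio (NST)
#'
#' Quantifies the proportion of stochastic (random) processes in community
#' assembly per group. Null communities preserve each sample's richness,
#' draw taxa with probability proportional to cohort occupancy, and assign
#' abundances proportional to the cohort mean relative abundance. For each
#' sample pair, the observed Bray-Curtis similarity `C = 1 - D` is compared
#' with the null expectation `E` over `R` randomizations and scored
#' `1 - |C - E| / max(E, 1 - E)` (1 when the observation matches the null
#' expectation exactly, 0 at the maximal possible deviation); NST is the
#' group mean, clamped to `[0, 1]`.
#'
#' @param ct a `count_table`.
#' @param groups group labels aligned with samples (single group by
#'   default); groups with fewer than `min_n` samples are skipped with a
#'   warning.
#' @param R number of randomizations (>= 30; default 100).
#' @param seed integer seed.
#' @param min_n minimum group size.
#' @return Named list per group, each of class `nst_result`: `NST`,
#'   `pair_values`, `obs_dissim`, `null_expectation`, `R`.
#' @export
nst <- function(ct, groups = NULL, R = 100, seed = 1, min_n = 4) {
  stopifnot(R >= 30)
  m <- rel_abund(ct)
  if (is.null(groups)) groups <- rep("all", nrow(m))
  groups <- as.character(groups)
  out <- list()
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) < min_n) {
      warning("group '", g, "' has fewer than ", min_n, " samples; skipped")
      next
    }
    rel <- m[rows, , drop = FALSE]
    occupancy <- colMeans(rel > 0)
    mean_ab <- colMeans(rel)
    richness <- rowSums(rel > 0)
    obs <- as.matrix(vegan::vegdist(rel, method = "bray"))
    null_sum <- matrix(0, length(rows), length(rows))
    with_op_seed(seed, paste0("nst/", g), {
      for (r in seq_len(R)) {
        nm <- nst_null_matrix(rel, richness, occupancy, mean_ab)
        null_sum <- null_sum + as.matrix(vegan::vegdist(nm, method = "bray"))
      }
    })
    null_mean <- null_sum / R
    iu <- upper.tri(obs)
    C <- 1 - obs[iu]
    E <- 1 - null_mean[iu]
    pair_vals <- 1 - abs(C - E) / pmax(E, 1 - E)
    out[[g]] <- structure(list(NST = min(max(mean(pair_vals), 0), 1),
                               pair_values = pair_vals,
                               obs_dissim = obs, null_expectation = null_mean,
                               R = R),
                          class = "nst_result")
  }
  out
}

#' @export
print.nst_result <- function(x, ...) {
  cat(sprintf("<nst_result> NST = %.3f over %d pairs (R = %d)\n",
              x$NST, length(x$pair_values), x$R))
  invisible(x)
}
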