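#' Core-taxon filter
#'
#' Keeps taxa whose cohort-wide total read count strictly exceeds
#' `min_reads` (default 1000), the core-taxon criterion applied before
#' network construction.
#'
#' @param ct a `count_table`.
#' @param min_reads threshold (strict inequality).
#' @return Filtered `count_table`; errors when fewer than 10 taxa survive
#'   (compositional correlation estimates become unreliable).
#' @export
core_taxa_filter <- function(ct, min_reads = 1000) {
  keep <- colSums(ct$counts) > min_reads
  if (sum(keep) < 10)
    stop("only ", sum(keep), " taxa exceed ", min_reads,
         " reads; too few for network inference")
  subset_count_table(ct, taxa = which(keep))
}

# solve the sparse-approximation linear system for basis variances given the
# variation matrix and a set of excluded pairs (logical matrix)
sparcc_basis <- function(Tm, excluded) {
  D <- nrow(Tm)
  keep <- !excluded
  diag(keep) <- FALSE
  A <- matrix(0, D, D)
  A[keep] <- 1
  diag(A) <- rowSums(keep)
  t_i <- rowSums(Tm * keep)
  omega <- tryCatch(solve(A, t_i) / 1, error = function(e) rep(NA_real_, D))
  omega
}

sparcc_rho <- function(Tm, omega) {
  D <- length(omega)
  s <- sqrt(pmax(omega, 0))
  denom <- 2 * outer(s, s)
  rho <- (outer(omega, rep(1, D)) + outer(rep(1, D), omega) - Tm) / denom
  rho[!is.finite(rho)] <- NA
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

#' SparCC compositional correlations
#'
#' Estimates basis correlations between taxa from compositional count data:
#' pseudocount-1 fractions, log-ratio variation matrix
#' `T_ij = Var(log(x_i/x_j))`, basis variances from the sparse-approximation
#' linear system solved in closed form, and
#' `rho_ij = (w_i + w_j - T_ij) / (2 sqrt(w_i w_j))` clamped to `[-1, 1]`.
#' The single strongest pair with `|rho|` above `exclusion_threshold` is
#' excluded from the system and the solution recomputed, up to
#' `n_exclusion_iter` rounds. Fraction estimation is deterministic
#' (pseudocount, not Dirichlet draws); uncertainty comes from the
#' permutation layer ([edge_significance()]).
#'
#' @param ct a `count_table` (>= 10 taxa, >= 20 samples).
#' @param n_exclusion_iter maximum strongly-correlated-pair exclusions.
#' @param exclusion_threshold `|rho|` above which a pair may be excluded.
#' @return Symmetric correlation matrix with unit diagonal; taxa whose
#'   basis variance turns non-positive are dropped to `NA` with a warning.
#' @export
sparcc <- function(ct, n_exclusion_iter = 10, exclusion_threshold = 0.1) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (ncol(m) < 10) stop("need >= 10 taxa")
  if (nrow(m) < 20) stop("need >= 20 samples")
  fr <- (m + 1) / rowSums(m + 1)
  lf <- log(fr)
  V <- cov(lf)
  d <- diag(V)
  Tm <- outer(d, rep(1, ncol(m))) + outer(rep(1, ncol(m)), d) - 2 * V

  D <- ncol(Tm)
  excluded <- matrix(FALSE, D, D)
  omega <- sparcc_basis(Tm, excluded)
  rho <- sparcc_rho(Tm, omega)
  for (it in seq_len(n_exclusion_iter)) {
    cand <- abs(rho)
    diag(cand) <- 0
    cand[excluded] <- 0
    mx <- max(cand, na.rm = TRUE)
    if (!is.finite(mx) || mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    excluded[ij[1], ij[2]] <- excluded[ij[2], ij[1]] <- TRUE
    omega <- sparcc_basis(Tm, excluded)
    rho <- sparcc_rho(Tm, omega)
  }
  bad <- which(!is.finite(omega) | omega <= 0)
  if (length(bad) > 0) {
    warning("non-positive basis variance for ", length(bad),
            " taxa; their correlations set to NA")
    rho[bad, ] <- NA
    rho[, bad] <- NA
    diag(rho) <- 1
  }
  dimnames(rho) <- list(colnames(m), colnames(m))
  rho
}

#' Permutation significance of SparCC correlations
#'
#' Null correlation distributions from datasets in which each taxon's
#' counts are independently shuffled across samples (the standard
#' compositional null); two-sided pseudo p-value
#' `(1 + #{|rho_null| >= |rho_obs|}) / (n_iter + 1)` per taxon pair. A
#' resampling-with-replacement (`"bootstrap"`) null is available for
#' comparison.
#'
#' @param ct the same `count_table` passed to [sparcc()].
#' @param rho_obs observed correlation matrix from [sparcc()].
#' @param n_iter null iterations (default 1000; < 99 triggers a resolution
#'   warning).
#' @param seed integer seed.
#' @param method `"permutation"` or `"bootstrap"`.
#' @param ... passed to [sparcc()].
#' @return Symmetric matrix of p-values in `[1/(n_iter+1), 1]`.
#' @export
edge_significance <- function(ct, rho_obs, n_iter = 1000, seed = 1,
                              method = c("permutation", "bootstrap"), ...) {
  method <- match.arg(method)
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (n_iter < 99) warning("n_iter < 99 gives poor p-value resolution")
  n <- nrow(m)
  exceed <- matrix(0, ncol(m), ncol(m))
  obs <- abs(rho_obs)
  with_op_seed(seed, "edge_significance", {
    for (it in seq_len(n_iter)) {
      perm <- apply(m, 2, function(col) {
        if (method == "permutation") col[sample.int(n)]
        else col[sample.int(n, n, replace = TRUE)]
      })
      rownames(perm) <- rownames(m)
      rho_null <- suppressWarnings(sparcc(perm, ...))
      exceed <- exceed + (abs(rho_null) >= obs & !is.na(rho_null) & !is.na(obs))
    }
  })
  p <- (1 + exceed) / (n_iter + 1)
  p[is.na(rho_obs)] <- NA
  diag(p) <- NA
  dimnames(p) <- dimnames(rho_obs)
  p
}

#' Build a thresholded co-occurrence network
#'
#' Retains taxon pairs with `|rho| >= rho_threshold` and `p < p_threshold`.
#'
#' @param rho,p matching symmetric matrices from [sparcc()] and
#'   [edge_significance()].
#' @param rho_threshold,p_threshold edge-retention thresholds.
#' @param node_annotations optional `data.frame` with a `node` column plus
#'   annotations (e.g. `mean_abund`, `site`, `phylum`).
#' @return A `microbial_network` (possibly with zero edges).
#' @export
build_network <- function(rho, p, rho_threshold = 0.4, p_threshold = 0.05,
                          node_annotations = NULL) {
  stopifnot(all(dim(rho) == dim(p)))
  taxa <- colnames(rho)
  nodes <- if (is.null(node_annotations)) data.frame(node = taxa,
                                                     stringsAsFactors = FALSE)
  else node_annotations
  iu <- which(upper.tri(rho), arr.ind = TRUE)
  ok <- !is.na(rho[iu]) & !is.na(p[iu]) &
    abs(rho[iu]) >= rho_threshold & p[iu] < p_threshold
  edges <- data.frame(from = taxa[iu[ok, 1]], to = taxa[iu[ok, 2]],
                      rho = rho[iu][ok], p = p[iu][ok],
                      stringsAsFactors = FALSE)
  microbial_network(nodes, edges)
}

#' Attack robustness of a network
#'
#' Removes nodes one at a time in descending initial-degree order (ties
#' broken by higher mean abundance when annotated, then lexicographic
#' name), recording after each removal the largest-connected-component size
#' as a fraction of the initial node count; the area under the curve of LCC
#' fraction versus fraction removed (trapezoid rule) summarizes robustness —
#' larger is more robust.
#'
#' @param net a `microbial_network` with >= 2 nodes.
#' @param order optional explicit removal order (character vector over all
#'   nodes), e.g. to compare two networks under one fixed attack sequence.
#' @return List of class `robustness_curve`: `removed_frac`, `lcc_frac`
#'   (starting at zero removals), `auc`, `order` (removal order).
#' @export
attack_robustness <- function(net, order = NULL) {
  n <- nrow(net$nodes)
  if (n < 2) stop("need >= 2 nodes")
  ab <- if ("mean_abund" %in% names(net$nodes)) net$nodes$mean_abund else rep(0, n)
  ord <- if (!is.null(order)) {
    stopifnot(setequal(order, net$nodes$node))
    order
  } else net$nodes$node[base::order(-net$nodes$degree, -ab, net$nodes$node)]
  g <- as_igraph(net)
  lcc <- numeric(n + 1)
  lcc[1] <- max(igraph::components(g)$csize)
  for (k in seq_len(n)) {
    g <- igraph::delete_vertices(g, ord[k])
    lcc[k + 1] <- if (igraph::vcount(g) == 0) 0 else max(igraph::components(g)$csize)
  }
  x <- (0:n) / n
  y <- lcc / n
  auc <- sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  structure(list(removed_frac = x, lcc_frac = y, auc = auc, order = ord),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat(sprintf("<robustness_curve> %d removals, AUC = %.4f\n",
              length(x$order), x$auc))
  invisible(x)
}

#' Neighbor-shift (NESH) driver scores between two networks
#'
#' For every node common to networks A and B, the neighbor-shift score is
#' the Jaccard dissimilarity of its neighborhoods,
#' `1 - |N_A ∩ N_B| / |N_A ∪ N_B|` (0 when both neighborhoods are empty).
#' Nodes whose score falls in the top quartile among common nodes and whose
#' degree increased in B are flagged as drivers of the between-network
#' difference. This is a simplified re-implementation of the neighbor-shift
#' idea behind driver-taxon screening.
#'
#' @param net_a,net_b `microbial_network`s sharing >= 1 node.
#' @return `data.frame`: `node`, `degree_a`, `degree_b`, `nesh`, `driver`.
#' @export
neighbor_shift <- function(net_a, net_b) {
  common <- intersect(net_a$nodes$node, net_b$nodes$node)
  if (length(common) == 0) {
    warning("no common nodes")
    return(data.frame(node = character(), degree_a = numeric(),
                      degree_b = numeric(), nesh = numeric(),
                      driver = logical()))
  }
  ga <- as_igraph(net_a); gb <- as_igraph(net_b)
  nb <- function(g, v) {
    nh <- igraph::neighbors(g, v)$name
    nh
  }
  res <- data.frame(node = common, degree_a = NA_real_, degree_b = NA_real_,
                    nesh = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(common)) {
    na_ <- nb(ga, common[i]); nb_ <- nb(gb, common[i])
    res$degree_a[i] <- length(na_); res$degree_b[i] <- length(nb_)
    u <- union(na_, nb_)
    res$nesh[i] <- if (length(u) == 0) 0 else 1 - length(intersect(na_, nb_)) / length(u)
  }
  q3 <- quantile(res$nesh, 0.75)
  res$driver <- res$nesh >= q3 & res$nesh > 0 & res$degree_b > res$degree_a
  res[order(-res$nesh), ]
}

#' Cross-site (saliva-lung) interaction network
#'
#' Concatenates, per subject, the site-tagged taxon abundances of both
#' sites into one feature vector, then applies SparCC, permutation
#' significance and thresholding. Reports per-node total and cross-site
#' edge counts (the edge-count ranking used to identify taxa bridging the
#' oral space and the lungs).
#'
#' @param site_a,site_b `count_table`s of the two sites with `subject_id`
#'   metadata (>= 20 subjects with both sites; unpaired subjects are
#'   dropped with a warning).
#' @param tag_a,tag_b site tags prefixed to taxon names.
#' @param rho_threshold,p_threshold,n_iter,seed network thresholds and
#'   significance settings.
#' @param min_reads core-taxon filter applied per site before tagging.
#' @return List of class `cross_site_network`: `network`
#'   (a `microbial_network` with site-tagged nodes), `node_summary`
#'   (`node`, `site`, `total_edges`, `cross_site_edges`, ranked by total).
#' @export
cross_site_network <- function(site_a, site_b, tag_a = "saliva", tag_b = "BAL",
                               rho_threshold = 0.4, p_threshold = 0.05,
                               n_iter = 1000, seed = 1, min_reads = 0) {
  ma <- site_a$metadata; mb <- site_b$metadata
  if (is.null(ma) || is.null(mb)) stop("both tables need subject_id metadata")
  common <- intersect(ma$subject_id, mb$subject_id)
  dropped <- length(setdiff(union(ma$subject_id, mb$subject_id), common))
  if (dropped > 0) warning("dropping ", dropped, " subject(s) without both sites")
  if (length(common) < 20) stop("need >= 20 subjects with both sites")
  if (min_reads > 0) {
    site_a <- core_taxa_filter(site_a, min_reads)
    site_b <- core_taxa_filter(site_b, min_reads)
  }
  ra <- site_a$counts[match(common, ma$subject_id), , drop = FALSE]
  rb <- site_b$counts[match(common, mb$subject_id), , drop = FALSE]
  colnames(ra) <- paste(tag_a, colnames(ra), sep = ":")
  colnames(rb) <- paste(tag_b, colnames(rb), sep = ":")
  combined <- cbind(ra, rb)
  rownames(combined) <- common
  ct <- count_table(combined)
  rho <- sparcc(ct)
  p <- edge_significance(ct, rho, n_iter = n_iter, seed = seed)
  nodes <- data.frame(node = colnames(combined),
                      site = rep(c(tag_a, tag_b), c(ncol(ra), ncol(rb))),
                      mean_abund = colMeans(combined / rowSums(combined)),
                      stringsAsFactors = FALSE)
  net <- build_network(rho, p, rho_threshold, p_threshold, nodes)
  site_of_node <- setNames(nodes$site, nodes$node)
  cross <- site_of_node[net$edges$from] != site_of_node[net$edges$to]
  cnt_total <- table(factor(c(net$edges$from, net$edges$to), levels = nodes$node))
  cnt_cross <- table(factor(c(net$edges$from[cross], net$edges$to[cross]),
                            levels = nodes$node))
  node_summary <- data.frame(node = nodes$node, site = nodes$site,
                             total_edges = as.integer(cnt_total),
                             cross_site_edges = as.integer(cnt_cross),
                             stringsAsFactors = FALSE)
  node_summary <- node_summary[order(-node_summary$total_edges), ]
  structure(list(network = net, node_summary = node_summary),
            class = "cross_site_network")
}
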