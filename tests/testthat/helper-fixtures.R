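# Fixtures are generated in code; oracles here are small, independent
# re-implementations used to cross-check the package's numerics.

toy_count_table <- function(n_samples = 5, n_taxa = 8, seed = 1, depth = 100) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, depth / n_taxa), n_samples, n_taxa,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("t%02d", seq_len(n_taxa))))
  m[1, 1] <- m[1, 1] + 1  # guard against an all-zero row
  count_table(m)
}

# site-like mixture fixture: three named sources with private dominant
# blocks plus a shared tail, and a sink drawn from a known mixture with a
# block of novel taxa feeding the unknown component
mixture_fixture <- function(seed, mix = c(A = 0.6, B = 0.3, C = 0),
                            unknown = 0.1, depth = 2000, source_depth = 20000) {
  set.seed(seed)
  n_taxa <- 150; n_novel <- 30
  taxa <- sprintf("t%03d", seq_len(n_taxa + n_novel))
  prof <- function(at) {
    x <- rlnorm(length(at), 0, 2)
    v <- setNames(numeric(length(taxa)), taxa)
    v[at] <- x / sum(x)
    v
  }
  blocks <- list(A = c(1:30, 91:150), B = c(31:60, 91:150), C = c(61:90, 91:150))
  profs <- lapply(blocks, prof)
  novel <- prof(n_taxa + seq_len(n_novel))
  mix_prof <- Reduce(`+`, Map(`*`, profs, mix)) + unknown * novel
  sink <- setNames(as.vector(rmultinom(1, depth, mix_prof)), taxa)
  sources <- lapply(profs, function(p)
    setNames(as.vector(rmultinom(1, source_depth, p)), taxa))
  list(sink = sink, sources = sources,
       truth = c(mix, unknown = unknown))
}

# exact posterior source proportions of the Gibbs model by exhaustive
# enumeration over all assignment vectors (feasible for <= 8 reads)
enumerate_apportionment <- function(sink, sources, params = st_params()) {
  taxa <- names(sink)
  S_named <- length(sources)
  Tn <- length(taxa)
  phi <- t(sapply(sources, function(m)
    (m + params$alpha1) / (sum(m) + params$alpha1 * Tn)))
  reads <- rep(seq_len(Tn), sink)
  n <- length(reads); S <- S_named + 1
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  logw <- apply(grid, 1, function(z) {
    lw <- 0
    for (r in seq_len(n)) if (z[r] <= S_named) lw <- lw + log(phi[z[r], reads[r]])
    cu <- tabulate(reads[z == S], nbins = Tn)
    lw <- lw + lgamma(params$alpha2 * Tn) - lgamma(params$alpha2 * Tn + sum(cu)) +
      sum(lgamma(params$alpha2 + cu) - lgamma(params$alpha2))
    ns <- tabulate(z, nbins = S)
    lw + sum(lgamma(params$beta + ns) - lgamma(params$beta))
  })
  w <- exp(logw - max(logw)); w <- w / sum(w)
  setNames(sapply(seq_len(S), function(s) sum(w * rowMeans(grid == s))),
           c(names(sources), "unknown"))
}

# two-component Dirichlet-multinomial mixture with disjoint dominant taxa
dm_mixture_fixture <- function(seed, n_per = 30, depth = 2000, conc = 50) {
  set.seed(seed)
  n_taxa <- 40
  base1 <- c(rep(5, 10), rep(0.2, 30)); base1 <- base1 / sum(base1) * conc
  base2 <- c(rep(0.2, 30), rep(5, 10)); base2 <- base2 / sum(base2) * conc
  z <- rep(1:2, each = n_per)
  counts <- t(sapply(z, function(k) {
    a <- if (k == 1) base1 else base2
    p <- rgamma(n_taxa, a); p <- p / sum(p)
    rmultinom(1, depth, p)
  }))
  dimnames(counts) <- list(sprintf("s%02d", seq_along(z)),
                           sprintf("t%02d", seq_len(n_taxa)))
  list(counts = counts, z = z)
}

# compositional counts with one planted basis-correlated taxon pair (1, 2)
make_planted_counts <- function(seed, n = 500, D = 50, r = 0.8, depth = 5000) {
  set.seed(seed)
  mu <- rnorm(D, 0, 1); sds <- runif(D, 0.5, 1.5)
  W <- matrix(rnorm(n * D), n, D)
  W[, 2] <- r * W[, 1] + sqrt(1 - r^2) * W[, 2]
  A <- exp(sweep(sweep(W, 2, sds, "*"), 2, mu, "+"))
  fr <- A / rowSums(A)
  cnt <- t(apply(fr, 1, function(p) rmultinom(1, depth, p)))
  dimnames(cnt) <- list(sprintf("s%03d", 1:n), sprintf("t%02d", 1:D))
  cnt
}

# independent one-liner oracles
oracle_shannon <- function(x) {p <- x[x > 0] / sum(x); -sum(p * log(p))}
oracle_bray <- function(a, b) {
  pa <- a / sum(a); pb <- b / sum(b)
  1 - 2 * sum(pmin(pa, pb)) / (sum(pa) + sum(pb))
}
oracle_levins <- function(col_across_samples) {
  P <- col_across_samples / sum(col_across_samples)
  1 / sum(P^2)
}
oracle_pseudo_F <- function(D, g) {
  n <- nrow(D); a <- length(unique(g))
  sst <- sum(D[upper.tri(D)]^2) / n
  ssw <- 0
  for (lv in unique(g)) {
    i <- which(g == lv)
    ssw <- ssw + sum(D[i, i][upper.tri(D[i, i])]^2) / length(i)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# brute-force largest connected component via flood fill on an edge list
oracle_lcc <- function(nodes, edges) {
  if (length(nodes) == 0) return(0L)
  comp <- setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$from[k]; b <- edges$to[k]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  max(table(comp))
}

oracle_robustness_auc <- function(net, ord) {
  nodes <- net$nodes$node
  n <- length(nodes)
  y <- numeric(n + 1)
  edges <- net$edges
  y[1] <- oracle_lcc(nodes, edges) / n
  for (k in seq_len(n)) {
    nodes <- setdiff(nodes, ord[k])
    edges <- edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
    y[k + 1] <- oracle_lcc(nodes, edges) / n
  }
  x <- (0:n) / n
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_toy_network <- function(seed, n_nodes = 10, p_edge = 0.3) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      rho = runif(sum(keep), 0.4, 0.9) *
                        sample(c(-1, 1), sum(keep), TRUE),
                      p = 0.01, stringsAsFactors = FALSE)
  microbial_network(data.frame(node = nodes, stringsAsFactors = FALSE), edges)
}
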