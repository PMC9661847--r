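#' @title Synthetic multi-site cohort with known ground truth
#' @description Generates saliva / oropharynx / nasal source communities and
#'   per-subject lung (BAL) communities assembled by neutral sampling from a
#'   subject-specific mixture of the sources, with two latent subject groups
#'   (HI / LO) that differ in saliva mixing weight and migration rate. Every
#'   downstream stage (neutral fits, source apportionment, pneumotyping,
#'   ecology, networks) can be exercised against this known truth.
#' @name synthetic_cohort
NULL

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

lognormal_profile <- function(n, sdlog = 1.5) {
  x <- rlnorm(n, meanlog = 0, sdlog = sdlog)
  x / sum(x)
}

#' Simulate the three upper-respiratory source communities
#'
#' Saliva and oropharynx share a log-normal abundance spectrum over an
#' "oral" taxon block (a fraction `overlap` of oral taxa have identical
#' underlying abundances in the two sites; the rest are redrawn), while the
#' nasal profile occupies a disjoint taxon block, emulating the observed
#' site specificity of nasal communities. One sample per subject per site is
#' drawn multinomially at the configured depth.
#'
#' @param n_taxa total taxa (>= 50, to honor the disjoint nasal block).
#' @param n_subjects number of subjects (one sample per site each).
#' @param overlap fraction in `[0, 1]` of oral-block taxa whose underlying
#'   abundance is shared between saliva and oropharynx; `overlap = 1` makes
#'   the two profiles identical.
#' @param depth reads per source sample.
#' @param nasal_frac fraction of taxa reserved for the nasal-specific block.
#' @param sdlog log-normal spectrum shape parameter.
#' @param seed integer seed.
#' @return List with `table` (a `count_table` of the source samples, with
#'   metadata) and `profiles` (site x taxon relative-abundance matrix).
#' @export
simulate_sources <- function(n_taxa = 150, n_subjects = 60, overlap = 0.7,
                             depth = 10000, nasal_frac = 0.3, sdlog = 1.5,
                             seed = 1) {
  if (n_taxa < 50) stop("n_taxa must be >= 50 to honor disjoint taxon blocks")
  stopifnot(overlap >= 0, overlap <= 1)
  with_op_seed(seed, "simulate_sources", {
    n_nasal <- floor(n_taxa * nasal_frac)
    n_oral <- n_taxa - n_nasal
    if (n_nasal < 10 || n_oral < 10) stop("taxon blocks too small; adjust nasal_frac")
    taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
    oral_idx <- seq_len(n_oral)
    nasal_idx <- n_oral + seq_len(n_nasal)

    base <- lognormal_profile(n_oral, sdlog)
    saliva <- numeric(n_taxa)
    saliva[oral_idx] <- base
    oro_raw <- base
    n_shared <- round(overlap * n_oral)
    if (n_shared < n_oral) {
      redraw <- sample(n_oral, n_oral - n_shared)
      # fresh spectrum entries on the same scale as the shared block
      oro_raw[redraw] <- rlnorm(length(redraw), meanlog = log(mean(base)), sdlog = sdlog)
    }
    oroph <- numeric(n_taxa)
    oroph[oral_idx] <- oro_raw / sum(oro_raw)
    nasal <- numeric(n_taxa)
    nasal[nasal_idx] <- lognormal_profile(n_nasal, sdlog)

    profiles <- rbind(saliva = saliva, oropharynx = oroph, nasal = nasal)
    colnames(profiles) <- taxa

    subjects <- sprintf("subj_%03d", seq_len(n_subjects))
    sites <- rownames(profiles)
    counts <- matrix(0, n_subjects * length(sites), n_taxa,
                     dimnames = list(NULL, taxa))
    meta <- data.frame(sample_id = character(n_subjects * length(sites)),
                       subject_id = "", site = "", stringsAsFactors = FALSE)
    r <- 0
    for (s in sites) {
      draws <- t(rmultinom(n_subjects, depth, profiles[s, ]))
      for (i in seq_len(n_subjects)) {
        r <- r + 1
        counts[r, ] <- draws[i, ]
        meta$sample_id[r] <- paste(subjects[i], s, sep = "_")
        meta$subject_id[r] <- subjects[i]
        meta$site[r] <- s
      }
    }
    rownames(counts) <- meta$sample_id
    list(table = count_table(counts, meta), profiles = profiles)
  })
}

#' Assemble the cohort ground truth
#'
#' Assigns each subject a latent group (HI = high oral input, LO = low) and a
#' mixing-weight vector over the source sites: the saliva weight is drawn
#' from a group-specific Beta distribution (bimodal across the cohort), the
#' remainder is split between oropharynx and nasal input, and each group
#' carries its own migration rate m (the HI group's exceeding the LO
#' group's, with magnitudes on the order of fitted lung-community values).
#'
#' @param profiles site x taxon profile matrix from [simulate_sources()].
#' @param n_subjects number of subjects.
#' @param prob_hi probability a subject belongs to the HI group.
#' @param beta_hi,beta_lo `c(shape1, shape2)` of the saliva-weight Beta law
#'   per group.
#' @param m_hi,m_lo group migration (diffusion) rates, `m_hi > m_lo`.
#' @param N_T neutral community size (reads per neutral draw); defaults to
#'   `depth`.
#' @param depth reads per BAL sample.
#' @param unknown_weight weight given to an "unknown" environmental source
#'   with its own log-normal profile (0 disables it).
#' @param seed integer seed.
#' @return Object of class `cohort_truth`: `source_profiles`, `subjects`
#'   (per-subject group, weights, m), `m_g`, `N_T`, `depth`.
#' @export
cohort_truth <- function(profiles, n_subjects = 60, prob_hi = 0.7,
                         beta_hi = c(8, 2), beta_lo = c(2, 8),
                         m_hi = 0.04, m_lo = 0.012,
                         N_T = NULL, depth = 10000,
                         unknown_weight = 0, seed = 1) {
  stopifnot(m_hi > 0, m_lo > 0, depth >= 100)
  if (is.null(N_T)) N_T <- depth
  if (N_T < 100) stop("N_T must be >= 100")
  with_op_seed(seed, "cohort_truth", {
    if (unknown_weight > 0) {
      unknown <- lognormal_profile(ncol(profiles))
      profiles <- rbind(profiles, unknown = unknown)
    }
    subjects <- sprintf("subj_%03d", seq_len(n_subjects))
    group <- ifelse(runif(n_subjects) < prob_hi, "HI", "LO")
    w_sal <- ifelse(group == "HI",
                    rbeta(n_subjects, beta_hi[1], beta_hi[2]),
                    rbeta(n_subjects, beta_lo[1], beta_lo[2]))
    w_sal <- w_sal * (1 - unknown_weight)
    rest <- 1 - unknown_weight - w_sal
    split <- rbeta(n_subjects, 4, 4)
    subj <- data.frame(subject_id = subjects, group = group,
                       w_saliva = w_sal,
                       w_oropharynx = rest * split,
                       w_nasal = rest * (1 - split),
                       w_unknown = unknown_weight,
                       m = ifelse(group == "HI", m_hi, m_lo),
                       stringsAsFactors = FALSE)
    structure(list(source_profiles = profiles, subjects = subj,
                   m_g = c(HI = m_hi, LO = m_lo), N_T = N_T, depth = depth),
              class = "cohort_truth")
  })
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d subjects (%d HI / %d LO), %d taxa, N_T=%g, depth=%g\n",
              nrow(x$subjects), sum(x$subjects$group == "HI"),
              sum(x$subjects$group == "LO"), ncol(x$source_profiles),
              x$N_T, x$depth))
  invisible(x)
}

#' Simulate lung (BAL) communities under neutral multi-source assembly
#'
#' For each subject, the regional species pool is the weight-mixed source
#' profile `q = sum_s w_s p^(s)`; the local lung composition is drawn from
#' `Dirichlet(N_T * m_g * q)` — the stationary abundance distribution whose
#' occurrence frequencies follow the beta-CDF neutral prediction, making
#' downstream parameter recovery a true inverse problem — and reads from
#' `Multinomial(depth, composition)`.
#'
#' @param truth a `cohort_truth`.
#' @param seed integer seed.
#' @return A `count_table` of BAL samples (one per subject) with metadata
#'   carrying the latent `group` label.
#' @export
simulate_lung_cohort <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "cohort_truth"))
  with_op_seed(seed, "simulate_lung_cohort", {
    p <- truth$source_profiles
    subj <- truth$subjects
    wcols <- paste0("w_", rownames(p))
    missing <- setdiff(wcols, names(subj))
    if (length(missing) > 0) stop("truth lacks weights for sources: ",
                                  paste(missing, collapse = ", "))
    W <- as.matrix(subj[, wcols, drop = FALSE])
    q <- W %*% p  # subjects x taxa regional pools
    if (any(is.na(q))) stop("regional pool contains NaN; taxa mismatch between sources")
    counts <- matrix(0, nrow(subj), ncol(p),
                     dimnames = list(paste0(subj$subject_id, "_BAL"), colnames(p)))
    for (i in seq_len(nrow(subj))) {
      alpha <- truth$N_T * subj$m[i] * q[i, ]
      pos <- alpha > 0
      comp <- numeric(ncol(p))
      comp[pos] <- rgamma(sum(pos), shape = alpha[pos])
      comp <- comp / sum(comp)
      counts[i, ] <- rmultinom(1, truth$depth, comp)
    }
    meta <- data.frame(sample_id = rownames(counts), subject_id = subj$subject_id,
                       site = "BAL", group = subj$group, stringsAsFactors = FALSE)
    count_table(counts, meta)
  })
}

#' Simulate a complete multi-site cohort
#'
#' Convenience wrapper: [simulate_sources()] + [cohort_truth()] +
#' [simulate_lung_cohort()], merged into one `count_table` spanning saliva,
#' oropharynx, nasal and BAL samples with shared subject identifiers.
#'
#' @param n_subjects,n_taxa,overlap,depth,seed see the component functions.
#' @param ... further arguments passed to [cohort_truth()].
#' @return List with `counts` (all sites, one `count_table`), `truth`.
#' @export
simulate_cohort <- function(n_subjects = 60, n_taxa = 150, overlap = 0.7,
                            depth = 10000, seed = 1, ...) {
  src <- simulate_sources(n_taxa = n_taxa, n_subjects = n_subjects,
                          overlap = overlap, depth = depth, seed = seed)
  truth <- cohort_truth(src$profiles, n_subjects = n_subjects, depth = depth,
                        seed = seed, ...)
  bal <- simulate_lung_cohort(truth, seed = seed)
  grp <- setNames(truth$subjects$group, truth$subjects$subject_id)
  meta_src <- src$table$metadata
  meta_src$group <- unname(grp[meta_src$subject_id])
  counts <- rbind(src$table$counts, bal$counts)
  meta <- rbind(meta_src, bal$metadata)
  list(counts = count_table(counts, meta), truth = truth)
}

#' Simulate single-source neutral sink communities
#'
#' Minimal generator for neutral-model parameter recovery: sinks assembled
#' from one source profile with a known migration rate, via the same
#' Dirichlet-multinomial mechanism as [simulate_lung_cohort()].
#'
#' @param profile source relative-abundance vector (summing to 1), or an
#'   integer `n_taxa` to draw a log-normal profile.
#' @param m migration rate; `N_T` community size; `n_sinks` number of sink
#'   samples; `depth` reads per sink (defaults to `N_T`).
#' @param N_T community size (reads per neutral draw).
#' @param n_sinks number of sink samples.
#' @param depth reads per sink sample.
#' @param seed integer seed.
#' @return List with `source` and `sinks` `count_table`s and the true `m`.
#' @export
simulate_neutral_sinks <- function(profile, m, N_T = 1000, n_sinks = 200,
                                   depth = N_T, seed = 1) {
  with_op_seed(seed, "simulate_neutral_sinks", {
    if (length(profile) == 1 && profile > 1)
      profile <- lognormal_profile(as.integer(profile))
    n_taxa <- length(profile)
    taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
    src_counts <- t(rmultinom(20, depth, profile))
    dimnames(src_counts) <- list(sprintf("src_%02d", 1:20), taxa)
    sinks <- matrix(0, n_sinks, n_taxa,
                    dimnames = list(sprintf("sink_%03d", seq_len(n_sinks)), taxa))
    alpha <- N_T * m * profile
    for (i in seq_len(n_sinks)) {
      comp <- numeric(n_taxa)
      pos <- alpha > 0
      comp[pos] <- rgamma(sum(pos), shape = alpha[pos])
      comp <- comp / sum(comp)
      sinks[i, ] <- rmultinom(1, depth, comp)
    }
    list(source = count_table(src_counts),
         sinks = count_table(sinks, drop_empty = TRUE),
         m = m, N_T = N_T, profile = setNames(profile, taxa))
  })
}
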