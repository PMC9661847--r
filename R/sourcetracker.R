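#' Default source-apportionment parameters
#'
#' Mirror the reference Gibbs source-tracking implementation's documented
#' defaults.
#'
#' @return Named list: `alpha1` (named-source pseudocount), `alpha2`
#'   (unknown-source pseudocount), `beta` (source-proportion Dirichlet
#'   prior), `burnin` sweeps, `restarts`, `draws` retained per restart,
#'   `thin` sweeps between draws, `rarefaction_depth`.
#' @export
st_params <- function() {
  list(alpha1 = 0.001, alpha2 = 0.1, beta = 10,
       burnin = 100, restarts = 10, draws = 1, thin = 10,
       rarefaction_depth = 1000)
}

rarefy_counts <- function(x, depth) {
  tot <- sum(x)
  if (tot <= depth) {
    if (tot < depth) warning("sample total ", tot, " below rarefaction depth ",
                             depth, "; used as-is")
    return(x)
  }
  reads <- rep(seq_along(x), x)
  keep <- sample(reads, depth)
  tab <- tabulate(keep, nbins = length(x))
  names(tab) <- names(x)
  tab
}

#' Apportion a sink community over named sources plus an unknown source
#'
#' Collapsed Gibbs sampling over per-read source assignments: named sources
#' contribute fixed taxon likelihoods from their count profiles (pseudocount
#' `alpha1`), the unknown source's taxon distribution is built from the sink
#' reads currently assigned to it (pseudocount `alpha2`), and the mixing
#' proportions carry a symmetric Dirichlet(`beta`) prior. Posterior means
#' are averaged over retained draws across independent restarts.
#'
#' @param sink named count vector over taxa (a single sink sample).
#' @param sources named list of count vectors (one per source site), or a
#'   matrix with sources in rows; taxa are aligned by name to the union
#'   universe.
#' @param params list as from [st_params()]; missing entries take defaults.
#' @param include_unknown include the unknown source component.
#' @param seed integer seed (restart seeds are derived from it).
#' @param sink_id identifier stored in the result.
#' @return Object of class `mixture_estimate`: `proportions` (posterior
#'   means over sources + `"unknown"`, summing to 1), `draws` (one row per
#'   retained draw), `ST` (the saliva entry when present).
#' @export
apportion <- function(sink, sources, params = list(), include_unknown = TRUE,
                      seed = 1, sink_id = "sink") {
  p <- utils::modifyList(st_params(), params)
  if (is.matrix(sources)) {
    sources <- setNames(lapply(seq_len(nrow(sources)), function(i) sources[i, ]),
                        rownames(sources))
  }
  stopifnot(is.list(sources), !is.null(names(sources)))
  taxa <- names(sink)
  for (s in sources) taxa <- union(taxa, names(s))
  align <- function(x) {
    v <- setNames(numeric(length(taxa)), taxa)
    v[names(x)] <- x
    v
  }
  sink <- align(sink)
  src_mat <- do.call(rbind, lapply(sources, align))

  src_names <- c(names(sources), if (include_unknown) "unknown")
  if (length(src_names) == 1) {
    # single named source, no unknown: trivially all attributed
    prop <- setNames(1, src_names)
    return(structure(list(sink_id = sink_id, proportions = prop,
                          draws = matrix(1, 1, 1, dimnames = list(NULL, src_names)),
                          ST = if ("saliva" %in% src_names) 1 else NA_real_),
                     class = "mixture_estimate"))
  }

  draws_all <- with_op_seed(seed, paste0("sourcetrack/", sink_id), {
    x <- rarefy_counts(sink, p$rarefaction_depth)
    if (sum(x) == 0) stop("sink '", sink_id, "' empty after rarefaction")
    read_taxa <- rep.int(seq_along(x) - 1L, x)
    out <- vector("list", p$restarts)
    for (r in seq_len(p$restarts)) {
      out[[r]] <- gibbs_sourcetrack_cpp(read_taxa, src_mat, include_unknown,
                                        p$alpha1, p$alpha2, p$beta,
                                        p$burnin, p$draws, p$thin)
    }
    do.call(rbind, out)
  })
  colnames(draws_all) <- src_names
  prop <- colMeans(draws_all)
  prop <- prop / sum(prop)
  structure(list(sink_id = sink_id, proportions = prop, draws = draws_all,
                 ST = if ("saliva" %in% names(prop)) unname(prop["saliva"]) else NA_real_),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("<mixture_estimate> %s: %s\n", x$sink_id,
              paste(sprintf("%s=%.3f", names(x$proportions), x$proportions),
                    collapse = ", ")))
  invisible(x)
}

#' Source-contribution (ST) values across a cohort of sinks
#'
#' Runs [apportion()] for every sink subject against its sources and
#' collects the posterior contribution of the designated oral source
#' (saliva) — the ST value whose bimodal cohort distribution defines the
#' pneumotypes. Sources are subject-paired when the pairing exists,
#' otherwise pooled per site across the cohort.
#'
#' @param sinks `count_table` of sink (BAL) samples with `subject_id`
#'   metadata.
#' @param sources `count_table` of source samples with `subject_id` and
#'   `site` metadata.
#' @param oral_site source site whose contribution is reported as ST.
#' @param mode `"paired"` (per-subject sources; subjects lacking a source
#'   sample at some site fall back to that site's pooled counts),
#'   `"pooled"` (cohort-pooled sources for all subjects), or `"auto"`
#'   (paired when any pairs exist).
#' @param params,include_unknown,seed passed to [apportion()].
#' @return `data.frame` with one row per sink subject: per-source posterior
#'   proportions, `unknown`, and `ST`.
#' @export
cohort_st <- function(sinks, sources, oral_site = "saliva",
                      mode = c("auto", "paired", "pooled"),
                      params = list(), include_unknown = TRUE, seed = 1) {
  mode <- match.arg(mode)
  smeta <- sources$metadata
  if (is.null(smeta) || !all(c("subject_id", "site") %in% names(smeta)))
    stop("sources need subject_id and site metadata")
  sites <- sort(unique(smeta$site))
  if (!oral_site %in% sites) stop("no source samples for designated oral site '",
                                  oral_site, "'")
  pooled <- lapply(setNames(sites, sites), function(s) {
    colSums(sources$counts[smeta$site == s, , drop = FALSE])
  })
  have_pairs <- any(sinks$metadata$subject_id %in% smeta$subject_id)
  if (mode == "auto") mode <- if (have_pairs) "paired" else "pooled"
  if (mode == "paired" && !have_pairs) stop("no subject-paired sources available")

  res <- vector("list", nrow(sinks$counts))
  for (i in seq_len(nrow(sinks$counts))) {
    subj <- sinks$metadata$subject_id[i]
    src <- pooled
    if (mode == "paired") {
      for (s in sites) {
        j <- which(smeta$subject_id == subj & smeta$site == s)
        if (length(j) == 1) src[[s]] <- sources$counts[j, ]
      }
    }
    est <- apportion(sinks$counts[i, ], src, params = params,
                     include_unknown = include_unknown, seed = seed,
                     sink_id = rownames(sinks$counts)[i])
    row <- as.data.frame(as.list(est$proportions))
    row$subject_id <- subj
    row$sample_id <- rownames(sinks$counts)[i]
    res[[i]] <- row
  }
  out <- do.call(rbind, res)
  out$ST <- out[[oral_site]]
  out[, c("sample_id", "subject_id", setdiff(names(out),
                                             c("sample_id", "subject_id", "ST")), "ST")]
}
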