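#' Predicted occurrence frequency under the Sloan neutral model
#'
#' A taxon with mean relative abundance `p` in the source pool is predicted
#' to occur (exceed the detection limit `d`) in local communities with
#' frequency `1 - pbeta(d, N_T*m*p, N_T*m*(1-p))`: the stationary abundance
#' distribution under neutral drift plus immigration is Beta with total
#' concentration `N_T*m`.
#'
#' @param p source relative abundance(s), strictly inside `(0, 1)`.
#' @param m migration (diffusion) coefficient, `> 0`.
#' @param N_T community size (reads per neutral draw), `> 0`.
#' @param d detection limit in `(0, 1)`, conventionally `1 / N_T`.
#' @return Predicted occurrence frequencies in `[0, 1]`, monotone in `p`
#'   and, for `p > d`, in `m`.
#' @export
predict_occurrence <- function(p, m, N_T, d = 1 / N_T) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  stopifnot(m > 0, N_T > 0, d > 0, d < 1)
  1 - pbeta(d, N_T * m * p, N_T * m * (1 - p))
}

#' Wilson score interval for a binomial proportion
#'
#' Used as the 95% neutrality band around predicted occurrence frequencies.
#'
#' @param phat observed proportion(s) in `[0, 1]`.
#' @param n number of trials (sink samples), `>= 1`.
#' @param z normal quantile (1.96 for a 95% interval).
#' @return Matrix with columns `lo`, `hi`, clamped to `[0, 1]`.
#' @export
wilson_interval <- function(phat, n, z = 1.96) {
  if (any(n < 1)) stop("n must be >= 1")
  stopifnot(all(phat >= 0 & phat <= 1))
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  cbind(lo = pmax(0, center - half), hi = pmin(1, center + half))
}

neutral_sse <- function(m, p, F_obs, N_T, d) {
  sum((F_obs - predict_occurrence(p, m, N_T, d))^2)
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration rate `m` by bounded nonlinear least squares on
#' observed versus predicted occurrence frequencies, from five log-spaced
#' starts across `m` in `[1e-6, 10]` (the SSE surface is unimodal in practice
#' but flat for tiny `m`). `N_T` is taken as the mean sink read depth, with
#' detection limit `d = 1/N_T`. Each taxon gets a 95% Wilson score band
#' around its predicted frequency (with `n` = number of sink samples) and a
#' neutrality partition: `neutral` when the observed frequency falls inside
#' the band, `above`/`below` otherwise.
#'
#' Because occurrence is scored as a nonzero read count among `N_T` reads,
#' the detection event "count >= 1" has probability 1/2 at abundance
#' `x = log(2)/N_T` (from `(1-x)^N_T = 1/2`), not at `1/N_T`; evaluating
#' the beta CDF at this median detection threshold (`detection = "median"`,
#' the default) removes a systematic upward bias in the fitted `m` that the
#' classic `d = 1/N_T` convention (`detection = "classic"`) carries when
#' occurrence comes from sampled zero counts.
#'
#' @param detection detection-limit convention: `"median"` for
#'   `d = log(2)/N_T`, `"classic"` for `d = 1/N_T`.
#' @param source a `count_table` of source samples, or a named relative-
#'   abundance profile vector over taxa.
#' @param sinks a `count_table` of sink samples (>= 10).
#' @param m_bounds search interval for `m`.
#' @param n_starts number of log-spaced multi-starts.
#' @return Object of class `neutral_fit`: `m`, `R2`, `N_T`, `d`, `n_sinks`
#'   and per-taxon data frame `taxa` (`p`, `F_obs`, `F_hat`, `ci_lo`,
#'   `ci_hi`, `partition`).
#' @export
fit_neutral <- function(source, sinks, m_bounds = c(1e-6, 10), n_starts = 5,
                        detection = c("median", "classic")) {
  detection <- match.arg(detection)
  stopifnot(inherits(sinks, "count_table"))
  if (nrow(sinks$counts) < 10) stop("need >= 10 sink samples")
  prof <- if (inherits(source, "count_table")) mean_profile(source) else source
  if (is.null(names(prof))) stop("source profile must be named by taxon")
  shared <- intersect(names(prof), taxon_ids(sinks))
  p <- prof[shared]
  keep <- p > 0 & p < 1
  p <- p[keep]
  if (length(p) < 20) stop("need >= 20 shared taxa with source abundance in (0,1); have ",
                           length(p))
  n_sinks <- nrow(sinks$counts)
  F_obs <- colMeans(sinks$counts[, names(p), drop = FALSE] > 0)
  N_T <- mean(rowSums(sinks$counts))
  d <- if (detection == "median") log(2) / N_T else 1 / N_T

  starts <- exp(seq(log(m_bounds[1] * 10), log(m_bounds[2] / 10),
                    length.out = n_starts))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      nlminb(log(s), function(lm) neutral_sse(exp(lm), p, F_obs, N_T, d),
             lower = log(m_bounds[1]), upper = log(m_bounds[2])),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) stop("neutral model fit failed at all starts")
  m_hat <- exp(best$par)
  F_hat <- predict_occurrence(p, m_hat, N_T, d)
  sse <- best$objective
  sst <- sum((F_obs - mean(F_obs))^2)
  r2 <- 1 - sse / sst
  band <- wilson_interval(F_hat, n_sinks)
  # guard against float loss at the band boundary (lo <= F_hat <= hi holds
  # analytically for the Wilson interval evaluated at its own phat)
  band[, "lo"] <- pmin(band[, "lo"], F_hat)
  band[, "hi"] <- pmax(band[, "hi"], F_hat)
  partition <- ifelse(F_obs > band[, "hi"], "above",
                      ifelse(F_obs < band[, "lo"], "below", "neutral"))
  taxa <- data.frame(taxon = names(p), p = unname(p), F_obs = unname(F_obs),
                     F_hat = unname(F_hat), ci_lo = unname(band[, "lo"]),
                     ci_hi = unname(band[, "hi"]), partition = unname(partition),
                     stringsAsFactors = FALSE)
  structure(list(m = m_hat, R2 = r2, N_T = N_T, d = d, detection = detection,
                 n_sinks = n_sinks, sse = sse, taxa = taxa),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("<neutral_fit> m = %.4g, R2 = %.4f, N_T = %.0f, %d taxa, %d sinks\n",
              x$m, x$R2, x$N_T, nrow(x$taxa), x$n_sinks))
  cat("  partition:", paste(sprintf("%s=%d", names(table(x$taxa$partition)),
                                    table(x$taxa$partition)), collapse = ", "), "\n")
  invisible(x)
}

#' Fit the multiple-source neutral model with per-site attribution
#'
#' Pools the source sites into one regional community (mean relative
#' abundance over the concatenated source samples, sites implicitly weighted
#' by sample count), fits the neutral model against the pool, attributes
#' each sink taxon to the site where its mean relative abundance is maximal
#' (ties broken by higher prevalence, then lexicographic site name), and
#' cross-tabulates attributed taxa by site and by lung occurrence-frequency
#' quartile group (boundary taxa go to the more extreme group).
#'
#' @param sources named list of `count_table`s, one per source site.
#' @param sinks a `count_table` of sink (BAL) samples.
#' @param ... passed to [fit_neutral()].
#' @return List of class `multi_source_fit`: `fit` (a `neutral_fit` against
#'   the pooled source), `attribution` (per-taxon site and frequency group),
#'   `contribution` (site x frequency-group count table over attributed
#'   taxa).
#' @export
fit_multi_source <- function(sources, sinks, ...) {
  stopifnot(is.list(sources), length(sources) >= 1, !is.null(names(sources)))
  taxa_universe <- taxon_ids(sinks)
  for (ct in sources) taxa_universe <- union(taxa_universe, taxon_ids(ct))

  # site-level mean profiles and prevalences on the shared universe
  site_profile <- sapply(sources, function(ct) {
    v <- setNames(numeric(length(taxa_universe)), taxa_universe)
    v[taxon_ids(ct)] <- mean_profile(ct)
    v
  })
  site_prev <- sapply(sources, function(ct) {
    v <- setNames(numeric(length(taxa_universe)), taxa_universe)
    v[taxon_ids(ct)] <- colMeans(ct$counts > 0)
    v
  })

  # pooled profile over concatenated samples
  all_rel <- do.call(rbind, lapply(sources, function(ct) {
    m <- matrix(0, nrow(ct$counts), length(taxa_universe),
                dimnames = list(rownames(ct$counts), taxa_universe))
    m[, taxon_ids(ct)] <- rel_abund(ct)
    m
  }))
  pooled <- colMeans(all_rel)

  fit <- fit_neutral(pooled, sinks, ...)

  present <- taxon_ids(sinks)[colSums(sinks$counts > 0) > 0]
  F_lung <- colMeans(sinks$counts[, present, drop = FALSE] > 0)

  site_names <- sort(colnames(site_profile))
  attribute_one <- function(tx) {
    ab <- setNames(site_profile[tx, ], colnames(site_profile))
    if (all(ab == 0)) return("unattributed")
    cand <- names(ab)[ab == max(ab)]
    if (length(cand) > 1) {
      pv <- setNames(site_prev[tx, ], colnames(site_prev))[cand]
      cand <- cand[pv == max(pv)]
      cand <- sort(cand)  # lexicographic tie-break
    }
    cand[1]
  }
  site_attr <- vapply(present, attribute_one, character(1))
  if (any(site_attr == "unattributed"))
    message(sum(site_attr == "unattributed"),
            " sink taxa absent from all sources left unattributed")

  q <- quantile(F_lung, c(0.25, 0.75))
  freq_group <- ifelse(F_lung <= q[1], "lower-quartile",
                       ifelse(F_lung >= q[2], "upper-quartile", "interquartile"))
  attribution <- data.frame(taxon = present, site = unname(site_attr),
                            F_lung = unname(F_lung),
                            freq_group = unname(freq_group),
                            stringsAsFactors = FALSE)
  attributed <- attribution[attribution$site != "unattributed", ]
  contribution <- table(site = factor(attributed$site, levels = site_names),
                        group = factor(attributed$freq_group,
                                       levels = c("lower-quartile",
                                                  "interquartile",
                                                  "upper-quartile")))
  structure(list(fit = fit, attribution = attribution,
                 contribution = contribution),
            class = "multi_source_fit")
}

#' @export
print.multi_source_fit <- function(x, ...) {
  print(x$fit)
  print(x$contribution)
  invisible(x)
}
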