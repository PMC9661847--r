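#' @title Dirichlet multinomial mixture (DMM) community typing
#' @description Finite mixture of Dirichlet-multinomial components fitted by
#'   EM, with the number of components selected by a Laplace-approximated
#'   negative log model evidence (BIC available as an alternative), as used
#'   for unsupervised community typing of the BAL samples.
#' @name dmm
NULL

# per-sample DM log-likelihood for one component (multinomial coefficient
# dropped; constant across components and across k)
dm_loglik_rows <- function(counts, alpha) {
  A <- sum(alpha)
  n_i <- rowSums(counts)
  lgamma(A) - lgamma(A + n_i) +
    rowSums(lgamma(sweep(counts, 2, alpha, "+"))) - sum(lgamma(alpha))
}

# Minka fixed-point update of alpha for one component, responsibilities w
dm_alpha_update <- function(counts, w, alpha, n_inner = 25, tol = 1e-8) {
  n_i <- rowSums(counts)
  for (it in seq_len(n_inner)) {
    A <- sum(alpha)
    num <- colSums(w * (digamma(sweep(counts, 2, alpha, "+")) -
                          rep(digamma(alpha), each = nrow(counts))))
    den <- sum(w * (digamma(A + n_i) - digamma(A)))
    alpha_new <- pmax(alpha * num / den, 1e-10)
    if (max(abs(alpha_new - alpha)) < tol * max(alpha)) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  alpha
}

dmm_em_once <- function(counts, k, max_iter = 100, tol = 1e-6) {
  n <- nrow(counts); T_ <- ncol(counts)
  props <- counts / rowSums(counts)
  # k-means on sqrt proportions for a spread-out initialization
  assign0 <- if (k == 1) rep(1, n) else {
    km <- tryCatch(stats::kmeans(sqrt(props), centers = k, nstart = 3),
                   error = function(e) NULL)
    if (is.null(km)) sample(rep_len(seq_len(k), n)) else km$cluster
  }
  alpha <- matrix(0, k, T_)
  for (j in seq_len(k)) {
    pm <- colMeans(props[assign0 == j, , drop = FALSE])
    alpha[j, ] <- pmax(pm, 1e-6) * 20
  }
  pi_k <- tabulate(assign0, k) / n

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  r <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    lmat <- sapply(seq_len(k), function(j) dm_loglik_rows(counts, alpha[j, ]))
    lmat <- matrix(lmat, n, k)
    lw <- sweep(lmat, 2, log(pmax(pi_k, 1e-300)), "+")
    mx <- apply(lw, 1, max)
    ll <- sum(mx + log(rowSums(exp(lw - mx))))
    ll_trace <- c(ll_trace, ll)
    r <- exp(lw - mx)
    r <- r / rowSums(r)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi_k <- colMeans(r)
    empty <- which(pi_k * n < 1e-6)
    if (length(empty) > 0) {
      warning("pruning ", length(empty), " empty DMM component(s)")
      keep <- setdiff(seq_len(k), empty)
      alpha <- alpha[keep, , drop = FALSE]
      r <- r[, keep, drop = FALSE]
      r <- r / rowSums(r)
      pi_k <- colMeans(r)
      k <- length(keep)
      ll_old <- -Inf
      next
    }
    for (j in seq_len(k))
      alpha[j, ] <- dm_alpha_update(counts, r[, j], alpha[j, ])
  }
  if (!converged) warning("DMM EM reached the iteration cap; best-so-far returned")
  list(k = k, pi = pi_k, alpha = alpha, resp = r, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, converged = converged)
}

# Laplace-approximated negative log evidence; the Hessian of the weighted
# per-component DM negative log-likelihood in alpha has diagonal-plus-
# rank-one structure, so its log-determinant is closed-form. A weak
# exponential prior (rate eta) on every Dirichlet parameter supplies the
# prior mass of the evidence, as in the reference implementations of the
# method; without it the approximation under-penalizes near-duplicate
# components whose flat likelihood directions carry almost no curvature.
dmm_laplace <- function(counts, fit, eta = 0.1) {
  n_i <- rowSums(counts)
  logdet <- 0
  for (j in seq_len(fit$k)) {
    alpha <- fit$alpha[j, ]
    w <- fit$resp[, j]
    A <- sum(alpha)
    c_k <- sum(w * (trigamma(A) - trigamma(A + n_i)))           # > 0
    a <- colSums(w * (rep(trigamma(alpha), each = nrow(counts)) -
                        trigamma(sweep(counts, 2, alpha, "+")))) # > 0
    a <- pmax(a, 1e-12)
    corr <- 1 - c_k * sum(1 / a)
    logdet <- logdet + sum(log(a)) + log(max(abs(corr), 1e-12))
  }
  p <- fit$k * ncol(counts) + (fit$k - 1)
  log_prior <- sum(log(eta) - eta * fit$alpha)
  -(fit$loglik + log_prior) - 0.5 * p * log(2 * pi) + 0.5 * logdet
}

#' Fit a Dirichlet multinomial mixture and select the number of components
#'
#' EM over component responsibilities with Dirichlet-multinomial component
#' likelihoods; the M-step updates each component's Dirichlet parameters by
#' fixed-point iteration. Each candidate `k` is fitted from several random
#' restarts (best likelihood kept) and the selected `k` minimizes the
#' model-selection score.
#'
#' @param counts a `count_table` or samples x taxa count matrix.
#' @param k_range candidate component counts (within 1..6).
#' @param seed integer seed.
#' @param restarts random restarts per `k`.
#' @param criterion `"laplace"` (Laplace-approximated negative log
#'   evidence) or `"bic"`.
#' @param ... passed to the EM routine (`max_iter`, `tol`).
#' @return Object of class `dmm_fit`: selected `k`, `pi`, `alpha`,
#'   `responsibilities`, hard `assignments`, per-sample `loglik_trace`, and
#'   the per-`k` model-selection `scores`.
#' @export
fit_dmm <- function(counts, k_range = 1:3, seed = 1, restarts = 3,
                    criterion = c("laplace", "bic"), ...) {
  criterion <- match.arg(criterion)
  if (inherits(counts, "count_table")) counts <- counts$counts
  counts <- as.matrix(counts)
  stopifnot(all(k_range >= 1), all(k_range <= 6))
  if (nrow(counts) < 2 * max(k_range))
    stop("need >= 2 samples per candidate component")
  fits <- list()
  scores <- setNames(numeric(length(k_range)), paste0("k", k_range))
  with_op_seed(seed, "dmm", {
    for (idx in seq_along(k_range)) {
      k <- k_range[idx]
      best <- NULL
      for (r in seq_len(restarts)) {
        f <- suppressWarnings(dmm_em_once(counts, k, ...))
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
      scores[idx] <- if (criterion == "laplace") dmm_laplace(counts, best)
      else -best$loglik + 0.5 * (best$k * ncol(counts) + best$k - 1) * log(nrow(counts))
      fits[[idx]] <- best
    }
  })
  sel <- which.min(scores)
  best <- fits[[sel]]
  structure(list(k = best$k, pi = best$pi, alpha = best$alpha,
                 responsibilities = best$resp,
                 assignments = apply(best$resp, 1, which.max),
                 loglik = best$loglik, loglik_trace = best$loglik_trace,
                 converged = best$converged,
                 scores = scores, criterion = criterion,
                 k_range = k_range),
            class = "dmm_fit")
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat(sprintf("<dmm_fit> k = %d selected by %s; scores: %s\n", x$k, x$criterion,
              paste(sprintf("%s=%.1f", names(x$scores), x$scores), collapse = ", ")))
  invisible(x)
}
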