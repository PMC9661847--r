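#' Locate the trough of a bimodal source-contribution distribution
#'
#' Gaussian kernel density (Silverman's bandwidth rule) of the ST values on
#' a fixed grid over `[0, 1]`; modes are local maxima whose height reaches
#' at least `mode_floor` of the global maximum (ignoring ripple); the
#' cutoff is the density minimum strictly between the two highest modes.
#'
#' @param st_values numeric vector of ST values in `[0, 1]` (>= 20 values).
#' @param bw bandwidth rule or value, passed to [stats::density()].
#' @param grid_size number of grid points.
#' @param mode_floor minimum mode height as a fraction of the global
#'   maximum.
#' @return List of class `density_trough`: `cutoff`, `modes` (x positions,
#'   highest first), `density` (data frame of the grid).
#' @export
density_trough <- function(st_values, bw = "nrd0", grid_size = 512,
                           mode_floor = 0.05) {
  st_values <- st_values[!is.na(st_values)]
  if (length(st_values) < 20) stop("need >= 20 ST values")
  if (any(st_values < 0 | st_values > 1)) stop("ST values must lie in [0, 1]")
  dens <- tryCatch(density(st_values, bw = bw, n = grid_size, from = 0, to = 1),
                   error = function(e) stop("unimodal distribution: ",
                                            conditionMessage(e)))
  x <- dens$x; y <- dens$y
  n <- length(y)
  is_max <- c(y[1] > y[2], y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n],
              y[n] > y[n - 1])
  modes_i <- which(is_max & y >= mode_floor * max(y))
  if (length(modes_i) < 2)
    stop("unimodal distribution: fewer than 2 qualifying modes; ",
         "supply a manual cutoff")
  top2 <- modes_i[order(y[modes_i], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- (lo + 1):(hi - 1)
  cutoff <- x[between[which.min(y[between])]]
  structure(list(cutoff = cutoff,
                 modes = x[modes_i[order(y[modes_i], decreasing = TRUE)]],
                 density = data.frame(x = x, y = y)),
            class = "density_trough")
}

#' @export
print.density_trough <- function(x, ...) {
  cat(sprintf("<density_trough> cutoff = %.3f; modes at %s\n", x$cutoff,
              paste(sprintf("%.3f", x$modes), collapse = ", ")))
  invisible(x)
}

#' Assign pneumotypes from ST values and a cutoff
#'
#' High-oral-input type (HOIT) when `ST >= cutoff` (the boundary is closed
#' on the high side), low-oral-input type (LOIT) otherwise.
#'
#' @param st_values numeric vector (names are preserved).
#' @param cutoff trough cutoff in `(0, 1)` (0 and 1 allowed as forced
#'   limits).
#' @return Character vector of `"HOIT"` / `"LOIT"` labels.
#' @export
assign_pneumotypes <- function(st_values, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1)
  setNames(ifelse(st_values >= cutoff, "HOIT", "LOIT"), names(st_values))
}

#' Concordance between two binary partitions
#'
#' 2x2 contingency table and two-sided Fisher exact test (hypergeometric
#' enumeration), used to quantify agreement between KDE-trough pneumotype
#' labels and DMM community-type assignments.
#'
#' @param labels_a,labels_b equal-length vectors over the same subjects,
#'   each with exactly <= 2 distinct values (2 for a meaningful test).
#' @return List: `table` (2x2), `fisher_p`, `agreement` (fraction on the
#'   majority-aligned diagonal).
#' @export
concordance <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  if (length(unique(labels_a)) > 2 || length(unique(labels_b)) > 2)
    stop("partitions must be binary")
  tab <- table(a = labels_a, b = labels_b)
  p <- fisher.test(tab)$p.value
  # agreement up to label permutation
  agree <- if (all(dim(tab) == c(2, 2))) {
    max(sum(diag(tab)), tab[1, 2] + tab[2, 1]) / sum(tab)
  } else 1
  list(table = tab, fisher_p = p, agreement = agree)
}

#' Call pneumotypes for a cohort
#'
#' End-to-end typing: KDE trough on the cohort's ST values, HOIT/LOIT
#' labels, and (optionally) concordance with DMM assignments.
#'
#' @param st `data.frame` from [cohort_st()] (columns `subject_id`, `ST`).
#' @param dmm optional `dmm_fit` on the same subjects (in the same order)
#'   for cross-method concordance.
#' @param cutoff optional manual cutoff overriding the KDE trough.
#' @return List of class `pneumotype_result`: `trough`, `cutoff`, `labels`
#'   (named by subject), and when `dmm` is given `dmm_assignments` and
#'   `concordance`.
#' @export
call_pneumotypes <- function(st, dmm = NULL, cutoff = NULL) {
  stv <- setNames(st$ST, st$subject_id)
  trough <- if (is.null(cutoff)) density_trough(stv) else NULL
  if (is.null(cutoff)) cutoff <- trough$cutoff
  labels <- assign_pneumotypes(stv, cutoff)
  out <- list(trough = trough, cutoff = cutoff, labels = labels)
  if (!is.null(dmm)) {
    out$dmm_assignments <- setNames(dmm$assignments, st$subject_id)
    out$concordance <- concordance(labels, out$dmm_assignments)
  }
  structure(out, class = "pneumotype_result")
}

#' @export
print.pneumotype_result <- function(x, ...) {
  cat(sprintf("<pneumotype_result> cutoff = %.3f; %d HOIT / %d LOIT\n",
              x$cutoff, sum(x$labels == "HOIT"), sum(x$labels == "LOIT")))
  if (!is.null(x$concordance))
    cat(sprintf("  DMM concordance: %.1f%% agreement, Fisher p = %.3g\n",
                100 * x$concordance$agreement, x$concordance$fisher_p))
  invisible(x)
}
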