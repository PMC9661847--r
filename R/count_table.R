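#' Construct a CountTable
#'
#' The universal exchange object of the pipeline: a samples x taxa matrix of
#' non-negative integer read counts plus optional per-sample metadata
#' (subject, body site, group label). Relative abundances are always derived
#' on demand ([rel_abund()]), never stored.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   row and column names. Values must be non-negative integers.
#' @param metadata optional `data.frame` with columns `sample_id`,
#'   `subject_id`, `site` (one of saliva, oropharynx, nasal, BAL) and
#'   optionally `group`. Rows are matched to `counts` by `sample_id`.
#' @param drop_empty drop samples whose row total is zero (with a warning)
#'   instead of erroring.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, metadata = NULL, drop_empty = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at sample '%s', taxon '%s': %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 counts[bad[1, , drop = FALSE]]))
  }
  storage.mode(counts) <- "double"
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    if (!drop_empty) stop("samples with zero total counts: ",
                          paste(rownames(counts)[tot == 0], collapse = ", "))
    warning("dropping ", sum(tot == 0), " sample(s) with zero total counts: ",
            paste(rownames(counts)[tot == 0], collapse = ", "))
    counts <- counts[tot > 0, , drop = FALSE]
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata)) stop("metadata needs a sample_id column")
    if (anyDuplicated(metadata$sample_id)) stop("duplicate sample_id in metadata")
    missing <- setdiff(rownames(counts), metadata$sample_id)
    if (length(missing) > 0)
      stop("samples absent from metadata: ", paste(missing, collapse = ", "))
    metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(counts = counts, metadata = metadata), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d taxa, total %s reads\n",
              nrow(x$counts), ncol(x$counts), format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$metadata) && "site" %in% names(x$metadata)) {
    tab <- table(x$metadata$site)
    cat("  sites:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Sample identifiers of a CountTable
#' @param ct a `count_table`.
#' @return character vector.
#' @export
sample_ids <- function(ct) rownames(ct$counts)

#' Taxon identifiers of a CountTable
#' @param ct a `count_table`.
#' @return character vector.
#' @export
taxon_ids <- function(ct) colnames(ct$counts)

#' Relative-abundance view of a CountTable
#'
#' @param ct a `count_table`.
#' @return Matrix of the same shape as `ct$counts`; every row sums to 1.
#' @export
rel_abund <- function(ct) {
  m <- ct$counts / rowSums(ct$counts)
  m
}

#' Subset a CountTable by samples and/or taxa
#'
#' @param ct a `count_table`.
#' @param samples,taxa character or logical/integer index vectors; `NULL`
#'   keeps all. Samples whose totals become zero after taxon subsetting are
#'   dropped with a warning.
#' @return A `count_table`.
#' @export
subset_count_table <- function(ct, samples = NULL, taxa = NULL) {
  counts <- ct$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(taxa)) counts <- counts[, taxa, drop = FALSE]
  meta <- ct$metadata
  if (!is.null(meta)) meta <- meta[meta$sample_id %in% rownames(counts), , drop = FALSE]
  count_table(counts, meta)
}

#' Body-site lookup for samples
#' @param ct a `count_table` with metadata.
#' @return Named character vector, sample_id -> site.
#' @export
site_of <- function(ct) {
  if (is.null(ct$metadata) || !"site" %in% names(ct$metadata))
    stop("count_table has no site metadata")
  setNames(as.character(ct$metadata$site), ct$metadata$sample_id)
}

#' Read a count table from TSV
#'
#' @param path TSV file with a header row; first column holds identifiers.
#' @param orientation `"samples-in-rows"` (canonical) or `"taxa-in-rows"`
#'   (transposed on read).
#' @param metadata optional metadata `data.frame` or path to a metadata TSV
#'   (columns `sample_id`, `subject_id`, `site`, optional `group`).
#' @return A `count_table` in the canonical samples-in-rows orientation;
#'   zero-total samples are dropped with a warning.
#' @export
read_count_table <- function(path, orientation = c("samples-in-rows", "taxa-in-rows"),
                             metadata = NULL) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric cell in %s at row '%s', column '%s'", path,
                 ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]]))
  }
  rownames(m) <- ids
  if (orientation == "taxa-in-rows") m <- t(m)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  count_table(m, metadata)
}

#' Write a count table to TSV
#'
#' @param ct a `count_table`; `path` output TSV. Written samples-in-rows with
#'   an identifier column named `sample_id`.
#' @param path output file path.
#' @export
write_count_table <- function(ct, path) {
  df <- data.frame(sample_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `site`, optional
#'   `group`.
#' @return A `data.frame`; errors on duplicate (subject, site) pairs.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "site")
  if (!all(req %in% names(df)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  key <- paste(df$subject_id, df$site)
  if (anyDuplicated(key))
    stop("more than one sample for subject/site pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df
}

#' Write sample metadata to TSV
#' @param metadata a metadata `data.frame`; `path` output TSV.
#' @param path output file path.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool samples of a CountTable into one source profile
#'
#' Mean of per-sample relative abundances (robust to depth imbalance), not
#' the pooled-count ratio.
#'
#' @param ct a `count_table`.
#' @return Named numeric vector over taxa, summing to 1.
#' @export
mean_profile <- function(ct) {
  colMeans(rel_abund(ct))
}
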