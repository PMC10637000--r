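#' Filter genes from a raw count table
#'
#' Keeps genes reaching at least `min_count` raw counts in at least one
#' sample, and removes experimentally perturbed genes (e.g., an
#' overexpressed transgene) whose expression change is attributable to the
#' perturbation itself rather than to cis-regulation.
#'
#' @param counts Tibble with a `gene_id` column followed by one numeric
#'   column per sample.
#' @param min_count Minimum raw count required in at least one sample,
#'   default 10.
#' @param perturbed Character vector of gene ids to drop regardless of
#'   counts.
#' @return The filtered count tibble, original gene order preserved.
#' @export
filter_genes <- function(counts, min_count = 10, perturbed = NULL) {
  mat <- count_matrix(counts)
  keep <- apply(mat, 1, max) >= min_count
  if (!is.null(perturbed)) keep <- keep & !(counts$gene_id %in% perturbed)
  if (!any(keep)) {
    te_abort("no genes pass the count filter", "te_validation_error")
  }
  counts[keep, , drop = FALSE]
}

# gene_id-first tibble -> numeric matrix with gene_id rownames
count_matrix <- function(counts) {
  if (!"gene_id" %in% names(counts)) {
    te_abort("count table needs a gene_id column", "te_validation_error")
  }
  mat <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(mat) <- counts$gene_id
  storage.mode(mat) <- "double"
  mat
}

#' Normalize raw counts to log2 TPM with a per-column pseudocount
#'
#' For each sample column, a pseudocount equal to the 5th percentile (linear
#' interpolation between order statistics) of the column's non-zero raw
#' counts is added to every entry. Counts are then divided by the gene
#' length, scaled to transcripts per million, and log2-transformed.
#'
#' @inheritParams filter_genes
#' @param lengths Gene lengths in bp: a tibble with `gene_id` and `length`
#'   (e.g. [gene_lengths()]) or a named numeric vector.
#' @param pseudocount_percentile Percentile of non-zero counts used as the
#'   per-column pseudocount, default 5.
#' @return A tibble (`gene_id` + samples) of log2 TPM values, with attribute
#'   `centering_state = "raw"`.
#' @export
normalize_log_tpm <- function(counts, lengths, pseudocount_percentile = 5) {
  mat <- count_matrix(counts)
  if (is.data.frame(lengths)) {
    len <- lengths$length[match(rownames(mat), lengths$gene_id)]
  } else {
    len <- unname(lengths[rownames(mat)])
  }
  if (anyNA(len)) {
    bad <- rownames(mat)[which(is.na(len))[1]]
    te_abort(sprintf("no gene length for gene '%s'", bad), "te_validation_error")
  }
  if (any(len <= 0)) {
    te_abort("gene lengths must be positive", "te_validation_error")
  }
  out <- mat
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    nz <- col[col > 0]
    if (length(nz) == 0) {
      te_abort(sprintf("sample '%s' has all-zero counts; pseudocount undefined",
                       colnames(mat)[j]), "te_validation_error")
    }
    pseudo <- stats::quantile(nz, pseudocount_percentile / 100, names = FALSE)
    rate <- (col + pseudo) / len
    out[, j] <- log2(rate / sum(rate) * 1e6)
  }
  res <- tibble::as_tibble(out)
  res <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(mat)), res)
  attr(res, "centering_state") <- "raw"
  res
}

#' Doubly center a log-expression matrix
#'
#' Subtracts each column (sample) mean, then each row (gene) mean. Column
#' centering removes sample-specific offsets (library scaling, batch);
#' row centering removes gene-specific basal expression. The result has all
#' row and column means equal to zero.
#'
#' @param expr Tibble (`gene_id` + samples) as produced by
#'   [normalize_log_tpm()].
#' @return The centered tibble, attribute `centering_state =
#'   "doubly_centered"`.
#' @export
double_center <- function(expr) {
  mat <- count_matrix(expr)
  if (ncol(mat) == 1) {
    warn("single-sample matrix: column centering yields all zeros")
  }
  mat <- sweep(mat, 2, colMeans(mat))
  mat <- sweep(mat, 1, rowMeans(mat))
  res <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(mat)),
                          tibble::as_tibble(mat))
  attr(res, "centering_state") <- "doubly_centered"
  res
}

#' Raw counts to stacked deltas in one call
#'
#' Convenience composition of the expression-side pipeline: the pseudocount
#' normalization is computed on the full count table (whose non-expressed
#' fraction keeps the per-column 5th percentile of non-zero counts at a few
#' reads), genes failing the count filter or listed as perturbed are then
#' dropped, and the doubly centered log2 TPM matrix is differenced per
#' sample pair.
#'
#' @inheritParams filter_genes
#' @inheritParams normalize_log_tpm
#' @param pairs Pair design tibble, see [build_delta()].
#' @return A stacked delta tibble, see [build_delta()].
#' @export
prepare_delta <- function(counts, lengths, pairs, min_count = 10,
                          perturbed = NULL) {
  keep <- filter_genes(counts, min_count = min_count, perturbed = perturbed)
  E <- normalize_log_tpm(counts, lengths)
  E <- E[match(keep$gene_id, E$gene_id), , drop = FALSE]
  build_delta(double_center(E), pairs)
}

#' Build the stacked delta-expression response
#'
#' For each (treatment, control) sample pair, computes the per-gene
#' difference of the doubly centered log expression; the per-pair vectors
#' are concatenated in design order, so replicate pairs expand the response
#' row-wise (the susceptibility matrix is expanded to match at fit time via
#' `gene_id`).
#'
#' @param expr Doubly centered expression tibble ([double_center()]).
#' @param pairs Tibble with columns `treatment` and `control`, one row per
#'   sample pair; a sample may appear in several pairs.
#' @return A tibble with columns `gene_id`, `pair` (label, design order),
#'   `delta`.
#' @export
build_delta <- function(expr, pairs) {
  mat <- count_matrix(expr)
  missing <- setdiff(unique(c(pairs$treatment, pairs$control)), colnames(mat))
  if (length(missing) > 0) {
    te_abort(sprintf("pair design references unknown sample '%s'", missing[1]),
             "te_validation_error")
  }
  purrr::pmap_dfr(
    list(pairs$treatment, pairs$control, seq_len(nrow(pairs))),
    function(t, c, i) {
      tibble::tibble(
        gene_id = rownames(mat),
        pair = paste0(i, ":", t, "-", c),
        delta = unname(mat[, t] - mat[, c])
      )
    }
  )
}
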