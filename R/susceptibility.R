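#' Gaussian distance kernel for cis-regulatory weighting
#'
#' Converts the distance between a TE integrant center and the closest
#' promoter center into a regulatory weight `exp(-d^2 / (2 L^2))`, where the
#' bandwidth `L` is the standard deviation of the kernel in base pairs. The
#' weight is 1 at distance 0 and strictly decreasing in `d`; at `d = 2L` it
#' equals `exp(-2)`, about 0.135.
#'
#' @param d Non-negative distance(s) in bp.
#' @param L Positive bandwidth in bp.
#' @return Weight(s) in `(0, 1]`.
#' @export
#' @examples
#' kernel_weight(250000, 250000) # ~0.61
#' kernel_weight(750000, 250000) # ~0.01
kernel_weight <- function(d, L) {
  if (length(L) != 1 || is.na(L) || L <= 0) {
    te_abort("bandwidth L must be a single positive number", "te_validation_error")
  }
  if (any(d < 0, na.rm = TRUE)) {
    te_abort("distances must be non-negative", "te_validation_error")
  }
  exp(-d^2 / (2 * L^2))
}

new_susceptibility_matrix <- function(values, mode, bandwidth = NULL,
                                      flank = NULL, tad_restricted = FALSE) {
  structure(
    list(values = values, mode = mode, bandwidth = bandwidth, flank = flank,
         tad_restricted = tad_restricted),
    class = "susceptibility_matrix"
  )
}

#' @export
print.susceptibility_matrix <- function(x, ...) {
  geom <- if (x$mode == "hard") sprintf("flank %g bp", x$flank)
          else sprintf("L = %g bp", x$bandwidth)
  cat(sprintf("<susceptibility_matrix> %d genes x %d subfamilies, %s mode (%s%s)\n",
              nrow(x$values), ncol(x$values), x$mode, geom,
              if (isTRUE(x$tad_restricted)) ", TAD-restricted" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @rdname assemble_susceptibility
#' @param x A `susceptibility_matrix`.
#' @param ... Unused.
tidy.susceptibility_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    subfamily = rep(colnames(x$values), each = nrow(x$values)),
    susceptibility = as.vector(x$values)
  )
}

# TAD id per position: index of the disjoint half-open interval containing it,
# NA when in no TAD.
tad_index <- function(pos, tads_chrom) {
  if (nrow(tads_chrom) == 0) return(rep(NA_integer_, length(pos)))
  ord <- order(tads_chrom$start)
  starts <- tads_chrom$start[ord]
  ends <- tads_chrom$end[ord]
  idx <- findInterval(pos, starts)
  inside <- idx >= 1 & pos < ends[pmax(idx, 1)]
  out <- rep(NA_integer_, length(pos))
  out[inside] <- ord[idx[inside]]
  out
}

# (gene_id, te row index) pairs where the TE overlaps the gene's promoters or
# exon union; these integrants are excluded from that gene's susceptibilities.
excluded_pairs <- function(gm, tes) {
  excl <- dplyr::bind_rows(gm$promoters, gm$exons)
  if (nrow(excl) == 0 || nrow(tes) == 0) {
    return(tibble::tibble(gene_id = character(), te = integer()))
  }
  te_gr <- GenomicRanges::GRanges(tes$chrom,
                                  IRanges::IRanges(tes$start + 1, tes$end))
  ex_gr <- GenomicRanges::GRanges(excl$chrom,
                                  IRanges::IRanges(excl$start + 1, excl$end))
  hits <- GenomicRanges::findOverlaps(te_gr, ex_gr, ignore.strand = TRUE)
  tibble::tibble(
    gene_id = excl$gene_id[S4Vectors::subjectHits(hits)],
    te = S4Vectors::queryHits(hits)
  ) %>% dplyr::distinct()
}

#' Assemble the gene-by-subfamily regulatory susceptibility matrix
#'
#' In `"hard"` mode the entry for gene `p` and subfamily `m` is the number of
#' merged integrants of `m` overlapping (by at least 1 bp) any cis-regulatory
#' window of `p`. In `"weighted"` mode it is the sum, over all retained
#' integrants of `m` on the gene's chromosome, of
#' [kernel_weight()] applied to the distance between the integrant center and
#' the closest promoter center. In both modes, integrants overlapping the
#' gene's promoters or exon union are excluded for that gene (but may still
#' count for other genes). With `tads`, a weight is zeroed whenever the TE
#' center and the closest promoter center fall in different TADs, or either
#' falls in none.
#'
#' @param gm A `gene_models` object ([build_gene_models()]).
#' @param tes A merged TE tibble ([merge_te_fragments()]).
#' @param mode `"hard"` or `"weighted"`.
#' @param flank Window flank (bp) used in hard mode; defaults to the flank
#'   the gene models were built with.
#' @param bandwidth Gaussian bandwidth `L` (bp), required in weighted mode.
#' @param tads Optional tibble of disjoint TAD intervals
#'   (`chrom`, `start`, `end`); weighted mode only.
#' @return A `susceptibility_matrix`: genes in the gene-model order as rows,
#'   subfamilies sorted by label as columns. All-zero rows are retained.
#' @export
assemble_susceptibility <- function(gm, tes, mode = c("hard", "weighted"),
                                    flank = NULL, bandwidth = NULL,
                                    tads = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(gm, "gene_models"))
  validate_te_table(tes)
  gene_ids <- gm$genes$gene_id
  if (anyDuplicated(gene_ids)) {
    te_abort("duplicate gene_ids in gene models", "te_validation_error")
  }
  subfams <- sort(unique(tes$subfamily))
  values <- matrix(0, nrow = length(gene_ids), ncol = length(subfams),
                   dimnames = list(gene_ids, subfams))

  if (mode == "hard") {
    if (is.null(flank)) flank <- attr(gm, "flank")
    windows <- if (identical(flank, attr(gm, "flank"))) {
      gm$windows
    } else {
      merge_intervals_grouped(
        dplyr::mutate(gm$promoters, start = pmax(0, .data$start - flank),
                      end = .data$end + flank)) %>%
        dplyr::left_join(gm$genes[, c("gene_id", "chrom")], by = "gene_id")
    }
    if (nrow(tes) > 0 && nrow(windows) > 0) {
      te_gr <- GenomicRanges::GRanges(tes$chrom,
                                      IRanges::IRanges(tes$start + 1, tes$end))
      win_gr <- GenomicRanges::GRanges(windows$chrom,
                                       IRanges::IRanges(windows$start + 1,
                                                        windows$end))
      hits <- GenomicRanges::findOverlaps(te_gr, win_gr, ignore.strand = TRUE)
      pairs <- tibble::tibble(
        gene_id = windows$gene_id[S4Vectors::subjectHits(hits)],
        te = S4Vectors::queryHits(hits)
      ) %>% dplyr::distinct()
      pairs <- dplyr::anti_join(pairs, excluded_pairs(gm, tes),
                                by = c("gene_id", "te"))
      if (nrow(pairs) > 0) {
        counts <- pairs %>%
          dplyr::mutate(subfamily = tes$subfamily[.data$te]) %>%
          dplyr::count(.data$gene_id, .data$subfamily)
        values[cbind(match(counts$gene_id, gene_ids),
                     match(counts$subfamily, subfams))] <- counts$n
      }
    }
    return(new_susceptibility_matrix(values, "hard", flank = flank))
  }

  # weighted mode
  if (is.null(bandwidth)) {
    te_abort("weighted mode needs a bandwidth", "te_validation_error")
  }
  excl <- excluded_pairs(gm, tes)
  te_center <- interval_center(tes$start, tes$end)
  prom <- gm$promoters
  prom$center <- interval_center(prom$start, prom$end)
  use_tads <- !is.null(tads)
  for (chr in unique(gm$genes$chrom)) {
    te_idx <- which(tes$chrom == chr)
    if (length(te_idx) == 0) next
    tc <- te_center[te_idx]
    tads_chr <- if (use_tads) tads[tads$chrom == chr, , drop = FALSE] else NULL
    te_tad <- if (use_tads) tad_index(tc, tads_chr) else NULL
    genes_chr <- gm$genes$gene_id[gm$genes$chrom == chr]
    prom_chr <- prom[prom$chrom == chr, , drop = FALSE]
    prom_by_gene <- split(prom_chr$center, prom_chr$gene_id)
    for (gid in genes_chr) {
      pc <- prom_by_gene[[gid]]
      if (is.null(pc)) next
      dmat <- abs(outer(tc, pc, "-"))
      nearest <- max.col(-dmat, ties.method = "first")
      d <- dmat[cbind(seq_along(tc), nearest)]
      w <- kernel_weight(d, bandwidth)
      if (use_tads) {
        prom_tad <- tad_index(pc, tads_chr)[nearest]
        w[is.na(te_tad) | is.na(prom_tad) | te_tad != prom_tad] <- 0
      }
      dropped <- excl$te[excl$gene_id == gid]
      if (length(dropped) > 0) w[te_idx %in% dropped] <- 0
      if (any(w > 0)) {
        sums <- tapply(w, tes$subfamily[te_idx], sum)
        sums <- sums[sums > 0]
        values[gid, names(sums)] <- values[gid, names(sums)] + sums
      }
    }
  }
  new_susceptibility_matrix(values, "weighted", bandwidth = bandwidth,
                            tad_restricted = use_tads)
}

#' Drop weakly represented TE subfamilies
#'
#' Removes subfamily columns whose total susceptibility over all genes is
#' strictly below `min_total` (default 150): their activity cannot be
#' estimated reliably from too few putatively regulated genes.
#'
#' @param N A `susceptibility_matrix`.
#' @param min_total Strict column-sum threshold, default 150.
#' @return The filtered `susceptibility_matrix`.
#' @export
filter_subfamilies <- function(N, min_total = 150) {
  stopifnot(inherits(N, "susceptibility_matrix"))
  sums <- colSums(N$values)
  keep <- sums >= min_total
  if (!any(keep)) {
    te_abort("all subfamilies fall below min_total; model would be empty",
             "te_validation_error")
  }
  dropped <- names(sums)[!keep]
  if (length(dropped) > 0) {
    message(sprintf("filter_subfamilies: dropping %d subfamil%s (%s)",
                    length(dropped), if (length(dropped) == 1) "y" else "ies",
                    paste(utils::head(dropped, 10), collapse = ", ")))
  }
  N$values <- N$values[, keep, drop = FALSE]
  N
}

#' Split TE subfamilies into functional and non-functional fractions
#'
#' Integrants overlapping (>= 1 bp) any interval in `functional_ranges`
#' (e.g., differential TF-binding or chromatin-accessibility peaks) form the
#' "functional" fraction of their subfamily; the rest form the
#' "non-functional" fraction. Each fraction becomes its own column, so
#' functional + non-functional susceptibilities sum exactly to the unsplit
#' column. Subfamilies absent from the filtered unsplit matrix `reference`
#' stay absent. If either fraction of a subfamily has a column sum below
#' `min_fraction_total` (default 100), both fractions are collapsed back to
#' the unsplit reference column — unless the subfamily is listed in
#' `protected`, in which case it always remains split.
#'
#' @inheritParams assemble_susceptibility
#' @param functional_ranges Tibble of functional intervals
#'   (`chrom`, `start`, `end`).
#' @param reference The filtered unsplit `susceptibility_matrix` built from
#'   the same gene models and TEs (see [filter_subfamilies()]).
#' @param protected Character vector of subfamily labels exempt from the
#'   collapse rule.
#' @param min_fraction_total Strict collapse threshold on fraction column
#'   sums, default 100.
#' @return A `susceptibility_matrix` whose columns are fraction columns
#'   (`"<subfamily>:functional"`, `"<subfamily>:non_functional"`) or unsplit
#'   subfamily columns, sorted by label.
#' @export
split_functional <- function(gm, tes, functional_ranges, reference,
                             protected = character(),
                             min_fraction_total = 100, tads = NULL) {
  stopifnot(inherits(reference, "susceptibility_matrix"))
  if (is.null(functional_ranges) || nrow(functional_ranges) == 0) {
    te_abort("functional_ranges must contain at least one interval",
             "te_validation_error")
  }
  validate_te_table(tes)
  te_gr <- GenomicRanges::GRanges(tes$chrom,
                                  IRanges::IRanges(tes$start + 1, tes$end))
  f_gr <- GenomicRanges::GRanges(functional_ranges$chrom,
                                 IRanges::IRanges(functional_ranges$start + 1,
                                                  functional_ranges$end))
  is_functional <- GenomicRanges::countOverlaps(te_gr, f_gr,
                                                ignore.strand = TRUE) > 0
  keep_subfams <- colnames(reference$values)
  tes_kept <- tes[tes$subfamily %in% keep_subfams, , drop = FALSE]
  is_functional <- is_functional[tes$subfamily %in% keep_subfams]
  tes_kept$parent <- tes_kept$subfamily
  tes_kept$subfamily <- paste0(tes_kept$parent,
                               ifelse(is_functional, ":functional",
                                      ":non_functional"))
  split_N <- assemble_susceptibility(
    gm, tes_kept, mode = reference$mode, flank = reference$flank,
    bandwidth = reference$bandwidth, tads = tads
  )
  vals <- split_N$values
  # guarantee both fraction columns per retained subfamily
  want <- c(paste0(keep_subfams, ":functional"),
            paste0(keep_subfams, ":non_functional"))
  absent <- setdiff(want, colnames(vals))
  if (length(absent) > 0) {
    zeros <- matrix(0, nrow = nrow(vals), ncol = length(absent),
                    dimnames = list(rownames(vals), absent))
    vals <- cbind(vals, zeros)
  }
  out_cols <- list()
  for (sf in keep_subfams) {
    f_col <- paste0(sf, ":functional")
    n_col <- paste0(sf, ":non_functional")
    collapse <- !(sf %in% protected) &&
      (sum(vals[, f_col]) < min_fraction_total ||
       sum(vals[, n_col]) < min_fraction_total)
    if (collapse) {
      out_cols[[sf]] <- reference$values[, sf]
    } else {
      out_cols[[f_col]] <- vals[, f_col]
      out_cols[[n_col]] <- vals[, n_col]
    }
  }
  out <- do.call(cbind, out_cols[sort(names(out_cols))])
  rownames(out) <- rownames(vals)
  new_susceptibility_matrix(out, reference$mode,
                            bandwidth = reference$bandwidth,
                            flank = reference$flank,
                            tad_restricted = !is.null(tads))
}
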