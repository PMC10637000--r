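#' Gene models: promoters, exon unions and cis-regulatory windows
#'
#' A `gene_models` object bundles, per protein-coding gene: its strand-aware
#' transcription start sites (TSS), promoter regions (TSS clusters spaced
#' < `cluster_gap`, padded by `pad` bp on each side), the disjoint union of
#' its exons across transcripts, and (for hard-threshold susceptibility) the
#' cis-regulatory windows obtained by extending promoters by `flank` bp.
#'
#' @param transcripts Tibble with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open), one row per transcript.
#' @param exons Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   one row per exon (any transcript of the gene).
#' @param cluster_gap,pad Promoter construction parameters, see
#'   [build_promoters()].
#' @param flank Window flank in bp, see [build_windows()].
#' @return An object of class `gene_models`: a list of tibbles `genes`
#'   (`gene_id`, `chrom`, `strand`), `tss` (`gene_id`, `pos`), `promoters`,
#'   `exons`, `windows` (each `gene_id`, `chrom`, `start`, `end`).
#' @export
build_gene_models <- function(transcripts, exons, cluster_gap = 1000,
                              pad = 500, flank = 50000) {
  needed <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(needed %in% names(transcripts))) {
    te_abort("transcripts table needs gene_id, chrom, strand, start, end",
             "te_validation_error")
  }
  transcripts <- tibble::as_tibble(transcripts)
  unknown <- !transcripts$strand %in% c("+", "-")
  if (any(unknown)) {
    warn(sprintf("%d transcript(s) with unknown strand treated as '+'",
                 sum(unknown)))
    transcripts$strand[unknown] <- "+"
  }
  transcripts$tss <- ifelse(transcripts$strand == "-",
                            transcripts$end, transcripts$start)

  genes <- transcripts %>%
    dplyr::distinct(.data$gene_id, .data$chrom, .data$strand)
  if (anyDuplicated(genes$gene_id)) {
    te_abort("gene(s) mapped to several chromosomes or strands",
             "te_validation_error")
  }

  tss_tbl <- transcripts %>%
    dplyr::distinct(.data$gene_id, pos = .data$tss)

  # single-linkage TSS clusters per gene (vectorized across all genes)
  tt <- dplyr::arrange(tss_tbl, .data$gene_id, .data$pos)
  new_cluster <- c(TRUE, tt$gene_id[-1] != tt$gene_id[-nrow(tt)] |
                     diff(tt$pos) >= cluster_gap)
  cl <- cumsum(new_cluster)
  clusters <- tibble::tibble(gene_id = tt$gene_id, pos = tt$pos, cl = cl) %>%
    dplyr::group_by(.data$cl) %>%
    dplyr::summarise(gene_id = .data$gene_id[1],
                     start = pmax(0, min(.data$pos) - pad),
                     end = max(.data$pos) + pad, .groups = "drop") %>%
    dplyr::select(-"cl")
  promoters <- merge_intervals_grouped(clusters)
  windows <- merge_intervals_grouped(
    dplyr::mutate(promoters, start = pmax(0, .data$start - flank),
                  end = .data$end + flank))

  exons <- tibble::as_tibble(exons)
  no_exons <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exons) > 0) {
    warn(sprintf("%d gene(s) without exon records; exon union is empty for them",
                 length(no_exons)))
  }
  exon_union <- merge_intervals_grouped(
    exons[, c("gene_id", "start", "end")])

  add_chrom <- function(df) {
    dplyr::left_join(df, genes[, c("gene_id", "chrom")], by = "gene_id") %>%
      dplyr::select("gene_id", "chrom", "start", "end")
  }
  out <- structure(
    list(
      genes = genes,
      tss = tss_tbl,
      promoters = add_chrom(promoters),
      exons = add_chrom(exon_union),
      windows = add_chrom(windows)
    ),
    cluster_gap = cluster_gap, pad = pad, flank = flank,
    class = "gene_models"
  )
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf(
    "<gene_models> %d genes, %d promoter region(s), %d window(s) (pad %g bp, flank %g bp)\n",
    nrow(x$genes), nrow(x$promoters), nrow(x$windows),
    attr(x, "pad"), attr(x, "flank")))
  invisible(x)
}

#' Exon-union gene lengths
#'
#' Total length (bp) of the disjoint exon union of each gene; used as the
#' gene length in TPM normalization.
#'
#' @param gm A `gene_models` object.
#' @return Tibble with `gene_id` and `length`.
#' @export
gene_lengths <- function(gm) {
  stopifnot(inherits(gm, "gene_models"))
  gm$exons %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(length = sum(.data$end - .data$start), .groups = "drop")
}

#' Read gene models from a GTF file
#'
#' Transcript records give strand-aware TSS (interval start for `+`, end for
#' `-`); exon records are unioned per gene. When the GTF carries a gene
#' biotype attribute, genes lacking the `protein_coding` biotype are dropped;
#' otherwise all genes are kept with a warning. Genes with no transcript
#' record are skipped with a warning.
#'
#' @param path Path to a GTF file.
#' @inheritParams build_gene_models
#' @return A `gene_models` object.
#' @export
read_gene_models_gtf <- function(path, cluster_gap = 1000, pad = 500,
                                 flank = 50000) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!"type" %in% names(meta) || !"gene_id" %in% names(meta)) {
    te_abort("GTF lacks type or gene_id attributes", "te_parse_error")
  }
  biotype_col <- intersect(c("gene_biotype", "gene_type"), names(meta))[1]
  if (!is.na(biotype_col)) {
    keep <- is.na(meta[[biotype_col]]) | meta[[biotype_col]] == "protein_coding"
    dropped <- unique(meta$gene_id[!keep])
    if (length(dropped) > 0) {
      message(sprintf("dropping %d non-protein-coding gene(s)", length(dropped)))
    }
    gr <- gr[keep & !(meta$gene_id %in% dropped)]
    meta <- S4Vectors::mcols(gr)
  } else {
    warn("GTF carries no gene biotype; keeping all genes")
  }
  as_tbl <- function(g) {
    tibble::tibble(
      gene_id = S4Vectors::mcols(g)$gene_id,
      chrom = as.character(GenomicRanges::seqnames(g)),
      strand = as.character(GenomicRanges::strand(g)),
      start = GenomicRanges::start(g) - 1,
      end = as.numeric(GenomicRanges::end(g))
    )
  }
  tx <- as_tbl(gr[meta$type == "transcript"])
  ex <- as_tbl(gr[meta$type == "exon"])
  gene_ids <- unique(S4Vectors::mcols(gr)$gene_id[S4Vectors::mcols(gr)$type == "gene"])
  no_tx <- setdiff(gene_ids, tx$gene_id)
  if (length(no_tx) > 0) {
    warn(sprintf("skipping %d gene(s) with no transcript record", length(no_tx)))
  }
  if (nrow(tx) == 0) {
    te_abort("GTF contains no transcript records", "te_parse_error")
  }
  build_gene_models(tx, ex[, c("gene_id", "chrom", "start", "end")],
                    cluster_gap = cluster_gap, pad = pad, flank = flank)
}

#' Read gene models from a flat TSV table
#'
#' One row per gene with comma-separated TSS positions and exon intervals, a
#' light-weight alternative to GTF for fixtures and simple annotations.
#' Expected columns: `gene_id`, `chrom`, `strand`, `tss` (comma-separated
#' 0-based positions), `exon_starts`, `exon_ends` (comma-separated,
#' positionally matched).
#'
#' @param path Path to the TSV file.
#' @inheritParams build_gene_models
#' @return A `gene_models` object.
#' @export
read_gene_models_tsv <- function(path, cluster_gap = 1000, pad = 500,
                                 flank = 50000) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  gene_models_from_table(df, cluster_gap = cluster_gap, pad = pad, flank = flank)
}

#' @rdname read_gene_models_tsv
#' @param df A data frame in the flat TSV layout described above.
#' @export
gene_models_from_table <- function(df, cluster_gap = 1000, pad = 500,
                                   flank = 50000) {
  needed <- c("gene_id", "chrom", "strand", "tss", "exon_starts", "exon_ends")
  if (!all(needed %in% names(df))) {
    te_abort(paste("flat gene table needs columns:", paste(needed, collapse = ", ")),
             "te_validation_error")
  }
  split_num <- function(x) lapply(strsplit(as.character(x), ","), as.numeric)
  tss_list <- split_num(df$tss)
  ex_start <- split_num(df$exon_starts)
  ex_end <- split_num(df$exon_ends)
  tx <- tibble::tibble(
    gene_id = rep(df$gene_id, lengths(tss_list)),
    chrom = rep(df$chrom, lengths(tss_list)),
    strand = rep(df$strand, lengths(tss_list)),
    pos = unlist(tss_list)
  )
  # encode each TSS as a 1-bp transcript whose strand-aware start is pos
  tx$start <- ifelse(tx$strand == "-", tx$pos - 1, tx$pos)
  tx$end <- ifelse(tx$strand == "-", tx$pos, tx$pos + 1)
  exons <- tibble::tibble(
    gene_id = rep(df$gene_id, lengths(ex_start)),
    chrom = rep(df$chrom, lengths(ex_start)),
    start = unlist(ex_start),
    end = unlist(ex_end)
  )
  build_gene_models(tx[, c("gene_id", "chrom", "strand", "start", "end")],
                    exons[, c("gene_id", "chrom", "start", "end")],
                    cluster_gap = cluster_gap, pad = pad, flank = flank)
}
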