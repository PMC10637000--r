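#' Genomic interval conventions
#'
#' All coordinates in this package are 0-based, half-open `[start, end)`,
#' the BED convention. GTF and RepeatMasker inputs are converted on read.
#' The center of an interval is `floor((start + end) / 2)`.
#'
#' @param start,end Numeric vectors of interval bounds.
#' @return `interval_center()` returns an integer-valued numeric vector.
#' @export
interval_center <- function(start, end) {
  floor((start + end) / 2)
}

# Union of possibly overlapping/abutting intervals on one sequence.
# Input/output: tibble with start/end (0-based half-open), sorted by start.
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  df <- dplyr::arrange(df, .data$start, .data$end)
  start <- df$start
  end <- cummax(df$end)
  # new block whenever the start exceeds the running max end (abutting merges)
  new_block <- c(TRUE, start[-1] > end[-nrow(df)])
  grp <- cumsum(new_block)
  tibble::tibble(
    start = tapply(df$start, grp, min)[unique(grp)] |> as.numeric(),
    end = tapply(df$end, grp, max)[unique(grp)] |> as.numeric()
  )
}

# Vectorized per-group interval union: df has group, start, end columns.
# Overlapping or abutting intervals within a group are merged.
merge_intervals_grouped <- function(df, group = "gene_id") {
  if (nrow(df) == 0) return(df)
  ord <- order(df[[group]], df$start, df$end)
  g <- df[[group]][ord]
  start <- df$start[ord]
  end <- df$end[ord]
  run_end <- stats::ave(end, g, FUN = cummax)
  prev_end <- c(-Inf, run_end[-length(run_end)])
  new_block <- c(TRUE, g[-1] != g[-length(g)]) | start > prev_end
  blk <- cumsum(new_block)
  out <- data.frame(g = g, start = start, end = end, blk = blk)
  res <- out %>%
    dplyr::group_by(.data$blk) %>%
    dplyr::summarise(gene_id = .data$g[1], start = min(.data$start),
                     end = max(.data$end), .groups = "drop") %>%
    dplyr::select(-"blk")
  names(res)[1] <- group
  tibble::as_tibble(res)
}

validate_te_table <- function(tes) {
  needed <- c("chrom", "start", "end", "strand", "subfamily")
  missing <- setdiff(needed, names(tes))
  if (length(missing) > 0) {
    te_abort(paste0("TE table lacks column(s): ", paste(missing, collapse = ", ")),
             "te_validation_error")
  }
  if (any(tes$end <= tes$start)) {
    bad <- which(tes$end <= tes$start)[1]
    te_abort(sprintf("TE interval %d has end <= start (%s:%s-%s)", bad,
                     tes$chrom[bad], tes$start[bad], tes$end[bad]),
             "te_validation_error")
  }
  if (any(!nzchar(tes$subfamily) | is.na(tes$subfamily))) {
    te_abort("TE records with empty subfamily label", "te_validation_error")
  }
  invisible(tes)
}

#' Read TE integrants from a BED6 file
#'
#' The name column (4th) carries the subfamily label, optionally suffixed with
#' an instance label as `"subfamily|instance"`. Coordinates are kept verbatim
#' (BED is already 0-based half-open).
#'
#' @param path Path to a BED6 file (tab- or space-separated).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `subfamily`, `instance_id`.
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tSVA_D\t0\t+", bed)
#' read_te_bed(bed)
read_te_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          strand = character(), subfamily = character(),
                          instance_id = character()))
  }
  fields <- strsplit(lines, "[ \t]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 6)) {
    bad <- which(n_fields < 6)[1]
    te_abort(sprintf("malformed BED6 record at line %d: %d field(s)", bad, n_fields[bad]),
             "te_parse_error")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    te_abort(sprintf("non-numeric coordinates at line %d", bad), "te_parse_error")
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    te_abort(sprintf("end <= start at line %d", bad), "te_validation_error")
  }
  name_parts <- strsplit(m[, 4], "|", fixed = TRUE)
  subfam <- vapply(name_parts, `[`, character(1), 1)
  instance <- vapply(name_parts, function(x) {
    if (length(x) > 1) paste(x[-1], collapse = "|") else NA_character_
  }, character(1))
  instance <- ifelse(is.na(instance),
                     paste0(subfam, "|", m[, 1], ":", m[, 2], "-", m[, 3]),
                     instance)
  strand <- m[, 6]
  strand[!strand %in% c("+", "-")] <- "*"
  out <- tibble::tibble(chrom = m[, 1], start = start, end = end,
                        strand = strand, subfamily = subfam,
                        instance_id = instance)
  validate_te_table(out)
  out
}

#' Read TE integrants from a RepeatMasker .out file
#'
#' Standard RepeatMasker layout: 3 header lines then whitespace-separated
#' records with 1-based inclusive coordinates. Coordinates are converted to
#' 0-based half-open (`begin - 1`, `end`); strand `"C"` (complement) becomes
#' `"-"`. The repeat name column is taken as the subfamily.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A tibble as returned by [read_te_bed()].
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    te_abort("RepeatMasker .out file lacks the 3 header lines", "te_parse_error")
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          strand = character(), subfamily = character(),
                          instance_id = character()))
  }
  fields <- strsplit(trimws(body), "[ \t]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 10)) {
    bad <- which(n_fields < 10)[1]
    te_abort(sprintf("truncated RepeatMasker record at line %d", bad + 3L),
             "te_parse_error")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:10))
  begin <- suppressWarnings(as.numeric(m[, 6]))
  end <- suppressWarnings(as.numeric(m[, 7]))
  if (anyNA(begin) || anyNA(end)) {
    bad <- which(is.na(begin) | is.na(end))[1]
    te_abort(sprintf("unparsable coordinates at line %d", bad + 3L), "te_parse_error")
  }
  strand <- ifelse(m[, 9] == "C", "-", ifelse(m[, 9] == "+", "+", "*"))
  out <- tibble::tibble(
    chrom = m[, 5], start = begin - 1, end = end, strand = strand,
    subfamily = m[, 10],
    instance_id = paste0(m[, 10], "|", m[, 5], ":", begin - 1, "-", end)
  )
  validate_te_table(out)
  out
}

#' Merge fragmented TE integrants
#'
#' RepeatMasker-style annotations often split a single degenerated integrant
#' into multiple fragments, inflating per-gene counts. Within each
#' (chromosome, strand, subfamily) group, fragments separated by a genomic
#' gap of strictly less than `max_gap` bases are chained into one integrant
#' spanning the merged extent. The operation is idempotent and
#' order-invariant.
#'
#' @param tes A TE tibble (see [read_te_bed()]).
#' @param max_gap Strict upper bound (bp) on the gap `next_start - prev_end`
#'   for merging. Default 100.
#' @return A TE tibble sorted by (chrom, start); `instance_id` is regenerated
#'   for merged records.
#' @export
merge_te_fragments <- function(tes, max_gap = 100) {
  validate_te_table(tes)
  if (nrow(tes) == 0) return(tes)
  gr <- GenomicRanges::GRanges(
    seqnames = tes$chrom,
    ranges = IRanges::IRanges(start = tes$start + 1, end = tes$end),
    strand = tes$strand
  )
  by_subfam <- S4Vectors::split(gr, tes$subfamily)
  merged <- GenomicRanges::reduce(by_subfam, min.gapwidth = max_gap,
                                  ignore.strand = FALSE)
  flat <- unlist(merged, use.names = TRUE)
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1,
    end = as.numeric(GenomicRanges::end(flat)),
    strand = as.character(GenomicRanges::strand(flat)),
    subfamily = names(flat)
  )
  out$instance_id <- paste0(out$subfamily, "|", out$chrom, ":", out$start, "-",
                            out$end, "(", out$strand, ")")
  dplyr::arrange(out, .data$chrom, .data$start, .data$end, .data$subfamily)
}

#' Build promoter regions from transcription start sites
#'
#' TSS on one chromosome are chained by single linkage into clusters of
#' consecutive sites spaced by strictly less than `cluster_gap` bp; each
#' cluster becomes the interval `[min_tss - pad, max_tss + pad)`, clipped at
#' 0. Padded clusters that overlap or abut are stored as their disjoint
#' union.
#'
#' @param tss Numeric vector of TSS positions (0-based) on one chromosome.
#' @param cluster_gap Strict single-linkage spacing threshold (bp), default
#'   1000.
#' @param pad Symmetric extension (bp) applied to each cluster, default 500.
#' @return A tibble with disjoint `start`/`end` columns, sorted by start.
#' @export
build_promoters <- function(tss, cluster_gap = 1000, pad = 500) {
  if (length(tss) == 0 || all(is.na(tss))) {
    te_abort("build_promoters() needs at least one TSS", "te_validation_error")
  }
  tss <- sort(unique(tss[!is.na(tss)]))
  grp <- cumsum(c(TRUE, diff(tss) >= cluster_gap))
  clusters <- tibble::tibble(
    start = pmax(0, tapply(tss, grp, min) - pad) |> as.numeric(),
    end = (tapply(tss, grp, max) + pad) |> as.numeric()
  )
  merge_intervals(clusters)
}

#' Extend promoter regions into cis-regulatory windows
#'
#' Each promoter interval is extended by `flank` bp on both sides, clipped at
#' the chromosome origin; overlapping or abutting extensions are unioned into
#' disjoint intervals.
#'
#' @param promoters Tibble with `start`/`end` columns (one chromosome).
#' @param flank Extension (bp) on each side, default 50000.
#' @return A tibble of disjoint `start`/`end` windows.
#' @export
build_windows <- function(promoters, flank = 50000) {
  if (nrow(promoters) == 0) {
    te_abort("build_windows() needs at least one promoter", "te_validation_error")
  }
  ext <- tibble::tibble(start = pmax(0, promoters$start - flank),
                        end = promoters$end + flank)
  merge_intervals(ext)
}
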