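#' Parameters for the synthetic genome / expression generator
#'
#' The defaults define the standard synthetic study: one 50-Mb chromosome
#' carrying 500 genes and 20 TE subfamilies of 200 integrants each, three
#' subfamilies with true activity differences of -0.15, +0.1 and +0.2 log2
#' units per integrant, Gaussian expression noise of 0.5 log2 units and two
#' treatment/control sample pairs. Susceptibilities are generated with a
#' Gaussian bandwidth of 100 kb.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length (bp).
#' @param n_genes Total number of genes.
#' @param n_subfamilies Number of TE subfamilies.
#' @param integrants_per_subfamily Integrants simulated per subfamily.
#' @param fragmentation_rate Probability that an integrant is emitted as two
#'   fragments separated by a gap of less than 100 bp (exercises fragment
#'   merging).
#' @param true_activities Named numeric vector of per-subfamily activity
#'   differences (log2 units per integrant); unnamed subfamilies are null.
#' @param active_fraction Optional fraction in `(0, 1]` of each active
#'   subfamily's integrants that truly carry the activity (for
#'   functional-split experiments); `NULL` means all integrants are active.
#' @param baseline_log2_tpm Mean/sd of the per-gene basal log2 TPM level.
#' @param silent_fraction Fraction of genes drawn from a trace-expression
#'   "silent" block. These genes pin the per-column pseudocount (the 5th
#'   percentile of non-zero counts) at a few reads — as the large
#'   non-expressed gene fraction does in real count tables — and fall below
#'   the count filter, so they never enter the model.
#' @param silent_log2_tpm Mean/sd of the silent block's log2 TPM level.
#' @param sample_offset_sd Sd of the per-sample log2 offset `d_s`.
#' @param noise_sd Sd of the i.i.d. Gaussian expression noise (log2 units).
#' @param generating_mode `"weighted"` or `"hard"` susceptibility geometry
#'   used to generate expression.
#' @param generating_L Gaussian bandwidth (bp) when generating in weighted
#'   mode.
#' @param generating_flank Window flank (bp) when generating in hard mode.
#' @param n_pairs Number of treatment/control pairs.
#' @param target_median_count Median raw count the library scaling aims for.
#' @param libsize_factor_range Range of per-sample library size factors
#'   (sizes differ by up to 2x by default, exercising the sample-offset
#'   centering).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   parameter set.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_chroms = 1,
                       chrom_length = 5e7,
                       n_genes = 500,
                       n_subfamilies = 20,
                       integrants_per_subfamily = 200,
                       fragmentation_rate = 0.1,
                       true_activities = c(subfam_01 = -0.15,
                                           subfam_02 = 0.1,
                                           subfam_03 = 0.2),
                       active_fraction = NULL,
                       baseline_log2_tpm = c(mean = 9, sd = 0.7),
                       silent_fraction = 0.1,
                       silent_log2_tpm = c(mean = 1.5, sd = 0.4),
                       sample_offset_sd = 0.2,
                       noise_sd = 0.5,
                       generating_mode = c("weighted", "hard"),
                       generating_L = 1e5,
                       generating_flank = 5e4,
                       n_pairs = 2,
                       target_median_count = 500,
                       libsize_factor_range = c(1, 2),
                       seed = 1) {
  generating_mode <- match.arg(generating_mode)
  stopifnot(noise_sd >= 0, fragmentation_rate >= 0, fragmentation_rate <= 1,
            silent_fraction >= 0, silent_fraction <= 1, n_pairs >= 1)
  if (!is.null(active_fraction)) {
    stopifnot(active_fraction > 0, active_fraction <= 1)
  }
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a toy genome annotation
#'
#' Places genes with 1-3 TSS each (some spaced under 1 kb to exercise
#' promoter clustering), per-gene exon intervals, and uniformly placed TE
#' integrants. A fraction of integrants is emitted as two fragments with a
#' gap under 100 bp, recorded against their parent so fragment merging can
#' be validated.
#'
#' @param params A [sim_params()] object.
#' @return A list with `genes_flat` (flat gene-model table, see
#'   [gene_models_from_table()]), `tes` (possibly fragmented TE tibble),
#'   `te_parents` (one row per parent integrant, with `n_fragments`), and
#'   `params`.
#' @export
simulate_annotation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, {
    chroms <- paste0("chr", seq_len(params$n_chroms))
    gene_chrom <- rep_len(chroms, params$n_genes)
    per_chrom <- table(factor(gene_chrom, levels = chroms))

    genes <- purrr::map_dfr(chroms, function(ch) {
      n <- per_chrom[[ch]]
      if (n == 0) return(NULL)
      spacing <- params$chrom_length / n
      anchors <- round((seq_len(n) - 0.5) * spacing +
                         stats::runif(n, -0.2, 0.2) * spacing)
      anchors <- pmin(pmax(anchors, 10000), params$chrom_length - 50000)
      tibble::tibble(chrom = ch, anchor = anchors)
    })
    genes$gene_id <- sprintf("gene_%03d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)

    ann <- purrr::pmap_dfr(genes, function(chrom, anchor, gene_id, strand) {
      n_tss <- sample(1:3, 1)
      # mix sub-1kb and super-1kb spacings
      offsets <- cumsum(c(0, sample(c(200, 700, 1500, 2500), n_tss - 1,
                                    replace = TRUE)))
      tss <- anchor + offsets
      n_ex <- sample(3:8, 1)
      ex_w <- sample(100:300, n_ex, replace = TRUE)
      ex_gap <- sample(500:2000, n_ex, replace = TRUE)
      ex_start <- anchor + cumsum(ex_gap) + cumsum(c(0, ex_w[-n_ex]))
      ex_end <- ex_start + ex_w
      if (strand == "-") {
        # mirror the layout so the gene body runs leftwards of the anchor
        new_start <- anchor - (ex_end - anchor)
        ex_end <- anchor - (ex_start - anchor)
        ex_start <- new_start
        tss <- anchor - offsets
      }
      tibble::tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        tss = paste(sort(tss), collapse = ","),
        exon_starts = paste(sort(ex_start), collapse = ","),
        exon_ends = paste(sort(ex_end), collapse = ",")
      )
    })

    subfams <- sprintf("subfam_%02d", seq_len(params$n_subfamilies))
    parents <- purrr::map_dfr(subfams, function(sf) {
      n <- params$integrants_per_subfamily
      chrom <- sample(chroms, n, replace = TRUE)
      w <- sample(300:3000, n, replace = TRUE)
      start <- round(stats::runif(n, 0, params$chrom_length - max(w) - 200))
      tibble::tibble(
        chrom = chrom, start = start, end = start + w,
        strand = sample(c("+", "-"), n, replace = TRUE),
        subfamily = sf,
        instance_id = sprintf("%s|parent_%03d", sf, seq_len(n)),
        fragmented = stats::runif(n) < params$fragmentation_rate
      )
    })

    tes <- purrr::pmap_dfr(parents, function(chrom, start, end, strand,
                                             subfamily, instance_id,
                                             fragmented) {
      if (!fragmented || end - start < 400) {
        tibble::tibble(chrom = chrom, start = start, end = end, strand = strand,
                       subfamily = subfamily, instance_id = instance_id)
      } else {
        cut <- round(stats::runif(1, start + 100, end - 200))
        gap <- sample(10:99, 1)
        tibble::tibble(
          chrom = chrom, start = c(start, cut + gap), end = c(cut, end),
          strand = strand, subfamily = subfamily,
          instance_id = paste0(instance_id, c("/frag1", "/frag2"))
        )
      }
    })
    parents$n_fragments <- ifelse(parents$fragmented & parents$end - parents$start >= 400,
                                  2L, 1L)

    list(genes_flat = ann, tes = tes,
         te_parents = parents[, c("chrom", "start", "end", "strand",
                                  "subfamily", "instance_id", "n_fragments")],
         params = params)
  })
}

#' Precompute the generating geometry of a simulated annotation
#'
#' Builds, once, the gene models, merged TEs and generating susceptibility
#' matrix of a simulated annotation, so repeated count draws over the same
#' annotation ([simulate_counts()]) do not recompute them.
#'
#' @param ann Output of [simulate_annotation()].
#' @param params A [sim_params()] object (usually `ann$params`).
#' @return A list with `gene_models`, `tes_merged`, `N`, `N_effect`,
#'   `functional_ranges`, `gene_lengths`.
#' @export
sim_geometry <- function(ann, params = ann$params) {
  gm <- gene_models_from_table(ann$genes_flat, flank = params$generating_flank)
  tes_merged <- merge_te_fragments(ann$tes)
  build_N <- function(t) {
    if (params$generating_mode == "weighted") {
      assemble_susceptibility(gm, t, mode = "weighted",
                              bandwidth = params$generating_L)
    } else {
      assemble_susceptibility(gm, t, mode = "hard",
                              flank = params$generating_flank)
    }
  }
  N <- build_N(tes_merged)
  functional_ranges <- NULL
  N_effect <- N
  if (!is.null(params$active_fraction)) {
    active_sf <- names(params$true_activities)
    pick <- with_local_seed(params$seed + 777L, {
      idx <- which(tes_merged$subfamily %in% active_sf)
      split(idx, tes_merged$subfamily[idx]) |>
        lapply(function(i) sample(i, max(1, round(params$active_fraction * length(i)))))
    })
    active_idx <- sort(unlist(pick, use.names = FALSE))
    functional_ranges <- tes_merged[active_idx,
                                    c("chrom", "start", "end"), drop = FALSE]
    keep <- !(tes_merged$subfamily %in% active_sf) |
      (seq_len(nrow(tes_merged)) %in% active_idx)
    N_effect <- build_N(tes_merged[keep, , drop = FALSE])
  }
  list(gene_models = gm, tes_merged = tes_merged, N = N, N_effect = N_effect,
       functional_ranges = functional_ranges, gene_lengths = gene_lengths(gm))
}

#' Simulate a paired treatment/control count table with known activities
#'
#' Builds the true susceptibility matrix from the simulated annotation with
#' the generating geometry, draws log2 expression
#' `E = c_p + d_s + sum_m N_pm A_ms + noise` where treatment samples carry
#' the true activity differences, and converts expression to integer counts
#' at the library scale. The silent gene block keeps the forward pseudocount
#' (5th percentile of non-zero counts) at a few reads, so normalizing the
#' counts recovers the generated expression of retained genes to within
#' rounding.
#'
#' @param ann Output of [simulate_annotation()].
#' @param params A [sim_params()] object (usually `ann$params`).
#' @param geometry Optional precomputed [sim_geometry()] result, reused
#'   across repeated count draws.
#' @param seed Seed for the expression noise draw; defaults to
#'   `params$seed + 1` so repeated count draws over one annotation can vary
#'   by passing different values.
#' @return A list: `counts` (tibble `gene_id` + samples), `pairs`
#'   (tibble `treatment`, `control`), `gene_lengths`, `gene_models`,
#'   `tes_merged`, and `truth` — a list carrying `activities`
#'   (tibble `subfamily`, `true_delta_a`), `N` (the generating
#'   `susceptibility_matrix`), `expected_delta` (per-gene expected
#'   treatment-control difference), and `functional_ranges` (intervals of
#'   the truly active integrants when `active_fraction` is set).
#' @export
simulate_counts <- function(ann, params = ann$params, seed = params$seed + 1,
                            geometry = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(geometry)) geometry <- sim_geometry(ann, params)
  gm <- geometry$gene_models
  tes_merged <- geometry$tes_merged
  N <- geometry$N
  N_effect <- geometry$N_effect
  functional_ranges <- geometry$functional_ranges
  subfams <- colnames(N$values)
  delta_a <- stats::setNames(rep(0, length(subfams)), subfams)
  known <- intersect(names(params$true_activities), subfams)
  delta_a[known] <- params$true_activities[known]

  lens <- geometry$gene_lengths
  gene_ids <- rownames(N$values)
  len <- lens$length[match(gene_ids, lens$gene_id)]
  P <- length(gene_ids)
  samples <- c(paste0("treat_", seq_len(params$n_pairs)),
               paste0("ctrl_", seq_len(params$n_pairs)))
  is_treat <- rep(c(TRUE, FALSE), each = params$n_pairs)

  eff_vals <- N_effect$values[, intersect(subfams, colnames(N_effect$values)),
                              drop = FALSE]
  expected_delta <- drop(eff_vals %*% delta_a[colnames(eff_vals)])

  sim <- with_local_seed(seed, {
    n_silent <- round(params$silent_fraction * P)
    silent <- sample(P, n_silent)
    c_p <- stats::rnorm(P, params$baseline_log2_tpm[["mean"]],
                        params$baseline_log2_tpm[["sd"]])
    c_p[silent] <- stats::rnorm(n_silent, params$silent_log2_tpm[["mean"]],
                                params$silent_log2_tpm[["sd"]])
    d_s <- stats::rnorm(length(samples), 0, params$sample_offset_sd)
    size_f <- stats::runif(length(samples), params$libsize_factor_range[1],
                           params$libsize_factor_range[2])
    E <- matrix(c_p, P, length(samples)) +
      matrix(d_s, P, length(samples), byrow = TRUE) +
      outer(expected_delta, as.numeric(is_treat)) +
      matrix(stats::rnorm(P * length(samples), 0, params$noise_sd),
             P, length(samples))
    dimnames(E) <- list(gene_ids, samples)
    list(E = E, size_f = size_f)
  })

  counts <- matrix(0, P, length(samples), dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    x <- 2^sim$E[, j] * len
    x <- x / stats::median(x) * params$target_median_count * sim$size_f[j]
    counts[, j] <- round(x)
  }

  list(
    counts = dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                              tibble::as_tibble(counts)),
    pairs = tibble::tibble(treatment = paste0("treat_", seq_len(params$n_pairs)),
                           control = paste0("ctrl_", seq_len(params$n_pairs))),
    gene_lengths = lens,
    gene_models = gm,
    tes_merged = tes_merged,
    truth = list(
      activities = tibble::tibble(subfamily = subfams,
                                  true_delta_a = unname(delta_a)),
      N = N,
      expected_delta = tibble::tibble(gene_id = gene_ids,
                                      expected = expected_delta),
      functional_ranges = functional_ranges
    ),
    params = params
  )
}

#' Write a simulated dataset in the formats the pipeline reads
#'
#' Emits BED6 TEs, the flat gene-model TSV, the counts TSV, the pair-design
#' TSV and the truth table into a directory.
#'
#' @param sim Output of [simulate_counts()].
#' @param ann Output of [simulate_annotation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim_data <- function(sim, ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tes = file.path(dir, "tes.bed"),
    genes = file.path(dir, "genes.tsv"),
    counts = file.path(dir, "counts.tsv"),
    pairs = file.path(dir, "pairs.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  bed <- ann$tes
  readr::write_tsv(
    tibble::tibble(chrom = bed$chrom, start = bed$start, end = bed$end,
                   name = bed$instance_id, score = 0, strand = bed$strand),
    paths["tes"], col_names = FALSE)
  readr::write_tsv(ann$genes_flat, paths["genes"])
  readr::write_tsv(sim$counts, paths["counts"])
  readr::write_tsv(sim$pairs, paths["pairs"])
  readr::write_tsv(sim$truth$activities, paths["truth"])
  invisible(paths)
}
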