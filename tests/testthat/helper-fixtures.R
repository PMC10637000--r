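# Shared fixtures and independent brute-force oracles.

# -- tiny deterministic gene/TE fixtures ------------------------------------

# A single-gene model on one chromosome with explicit promoters and exons.
tiny_gene_table <- function(gene_id = "gA", chrom = "chr1", strand = "+",
                            tss = 100000, exon_starts = 101000,
                            exon_ends = 101500) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tss = paste(tss, collapse = ","),
    exon_starts = paste(exon_starts, collapse = ","),
    exon_ends = paste(exon_ends, collapse = ",")
  )
}

tiny_te <- function(chrom, start, end, subfamily, strand = "+",
                    instance_id = NULL) {
  tibble::tibble(
    chrom = chrom, start = start, end = end, strand = strand,
    subfamily = subfamily,
    instance_id = instance_id %||%
      paste0(subfamily, "|", chrom, ":", start, "-", end)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small fixture for oracle-equivalence tests.
random_fixture <- function(seed, n_genes = 10, n_tes = 80, n_subfam = 5,
                           chrom_length = 2e6, n_chroms = 2) {
  withr::with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chroms))
    genes <- purrr::map_dfr(seq_len(n_genes), function(i) {
      anchor <- sample(5e4:(chrom_length - 1e5), 1)
      n_tss <- sample(1:3, 1)
      tss <- anchor + cumsum(c(0, sample(c(300, 800, 1200, 3000), n_tss - 1,
                                         replace = TRUE)))
      ex_start <- anchor + sort(sample(1000:20000, 3))
      tiny_gene_table(sprintf("g%02d", i), sample(chroms, 1),
                      sample(c("+", "-"), 1), tss,
                      ex_start, ex_start + sample(100:400, 3, replace = TRUE))
    })
    tes <- purrr::map_dfr(seq_len(n_tes), function(i) {
      s <- sample(0:(chrom_length - 5000), 1)
      tiny_te(sample(chroms, 1), s, s + sample(200:3000, 1),
              sprintf("sf%02d", sample(n_subfam, 1)),
              sample(c("+", "-"), 1))
    })
    list(genes = gene_models_from_table(genes), tes = merge_te_fragments(tes))
  })
}

# -- brute-force oracles -----------------------------------------------------

# Literal per-(gene, TE) loop over exclusion, window/distance and kernel
# rules; independent of the package's vectorized implementation.
oracle_susceptibility <- function(gm, tes, mode, flank = NULL, L = NULL,
                                  tads = NULL) {
  gene_ids <- gm$genes$gene_id
  subfams <- sort(unique(tes$subfamily))
  M <- matrix(0, length(gene_ids), length(subfams),
              dimnames = list(gene_ids, subfams))
  overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  in_tad <- function(pos, tads_c) {
    for (i in seq_len(nrow(tads_c))) {
      if (pos >= tads_c$start[i] && pos < tads_c$end[i]) return(i)
    }
    NA_integer_
  }
  for (g in gene_ids) {
    chrom <- gm$genes$chrom[gm$genes$gene_id == g]
    proms <- gm$promoters[gm$promoters$gene_id == g, ]
    exons <- gm$exons[gm$exons$gene_id == g, ]
    if (mode == "hard") {
      wins <- gm$promoters[gm$promoters$gene_id == g, ]
      wins <- data.frame(start = pmax(0, wins$start - flank),
                         end = wins$end + flank)
    }
    tads_c <- if (!is.null(tads)) tads[tads$chrom == chrom, ] else NULL
    for (k in seq_len(nrow(tes))) {
      if (tes$chrom[k] != chrom) next
      excluded <- FALSE
      for (i in seq_len(nrow(proms))) {
        if (overlaps(tes$start[k], tes$end[k], proms$start[i], proms$end[i]))
          excluded <- TRUE
      }
      for (i in seq_len(nrow(exons))) {
        if (overlaps(tes$start[k], tes$end[k], exons$start[i], exons$end[i]))
          excluded <- TRUE
      }
      if (excluded) next
      sf <- tes$subfamily[k]
      if (mode == "hard") {
        hit <- FALSE
        for (i in seq_len(nrow(wins))) {
          if (overlaps(tes$start[k], tes$end[k], wins$start[i], wins$end[i]))
            hit <- TRUE
        }
        if (hit) M[g, sf] <- M[g, sf] + 1
      } else {
        tc <- floor((tes$start[k] + tes$end[k]) / 2)
        pcs <- floor((proms$start + proms$end) / 2)
        d <- min(abs(tc - pcs))
        nearest <- pcs[which.min(abs(tc - pcs))]
        w <- exp(-d^2 / (2 * L^2))
        if (!is.null(tads_c)) {
          t1 <- in_tad(tc, tads_c); t2 <- in_tad(nearest, tads_c)
          if (is.na(t1) || is.na(t2) || t1 != t2) w <- 0
        }
        M[g, sf] <- M[g, sf] + w
      }
    }
  }
  M
}

# Normal-equations least squares with classical inference.
oracle_ols <- function(X, y) {
  Xi <- cbind(1, X)
  XtX <- t(Xi) %*% Xi
  beta <- solve(XtX, t(Xi) %*% y)
  r <- y - Xi %*% beta
  df <- length(y) - ncol(Xi)
  s2 <- sum(r^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  rss <- sum(r^2)
  f <- ((tss - rss) / ncol(X)) / (rss / df)
  list(beta = drop(beta), se = drop(se), t = drop(tval), p = drop(pval),
       f = f, f_p = pf(f, ncol(X), df, lower.tail = FALSE),
       adj_r2 = 1 - (rss / df) / (tss / (length(y) - 1)))
}

# Manual step-up BH: adj_(i) = min_{j >= i} p_(j) * m / j, input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- pmin(1, p[ord] * m / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Exhaustive enumeration of the hypergeometric upper tail P(X >= k):
# draws of size n from U balls of which K are special.
oracle_hypergeom_tail <- function(k, U, K, n) {
  draws <- utils::combn(U, n)
  special <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% special))
  mean(hits >= k)
}

# All-pairs AUC.
oracle_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# -- shared standard simulation (built once per test run) --------------------

std_sim_env <- new.env()

standard_sim <- function() {
  if (is.null(std_sim_env$geom)) {
    p <- sim_params(seed = 20240917)
    ann <- simulate_annotation(p)
    std_sim_env$params <- p
    std_sim_env$ann <- ann
    std_sim_env$geom <- sim_geometry(ann, p)
  }
  list(params = std_sim_env$params, ann = std_sim_env$ann,
       geom = std_sim_env$geom)
}

# Full expression pipeline: counts -> delta, on a simulate_counts() result.
pipeline_delta <- function(sim) {
  prepare_delta(sim$counts, sim$gene_lengths, sim$pairs)
}
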