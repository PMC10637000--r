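test_that("kernel weight matches its closed form and published values", {
  expect_equal(kernel_weight(0, 1000), 1.0)
  expect_equal(kernel_weight(250000, 250000), exp(-0.5))
  # printed two-decimal values for L = 250 kb
  expect_equal(round(kernel_weight(250000, 250000), 2), 0.61)
  expect_equal(round(kernel_weight(750000, 250000), 2), 0.01)
  # weight at two bandwidths exceeds the 0.13 counting threshold
  expect_gt(kernel_weight(2 * 5e4, 5e4), 0.13)
  expect_equal(kernel_weight(2 * 12345, 12345), exp(-2))
  # strictly decreasing
  d <- seq(0, 1e6, length.out = 50)
  expect_true(all(diff(kernel_weight(d, 2.5e5)) < 0))
  expect_error(kernel_weight(100, 0), class = "te_validation_error")
  expect_error(kernel_weight(-1, 100), class = "te_validation_error")
})

test_that("hard-mode counting honors windows and per-gene exclusion", {
  # gene at 100 kb: promoter [99.5, 100.5] kb, exon [101, 101.5] kb,
  # window = promoter +/- 50 kb
  gm <- gene_models_from_table(tiny_gene_table())
  tes <- dplyr::bind_rows(
    tiny_te("chr1", 120000, 120500, "sfA"),   # inside window, clean
    tiny_te("chr1", 101499, 101600, "sfB"),   # overlaps exon by 1 bp
    tiny_te("chr1", 150500, 150900, "sfC"),   # 1 bp outside window [49.5,150.5]kb
    tiny_te("chr1", 150499, 150900, "sfD"),   # overlaps window by 1 bp
    tiny_te("chr1", 99000, 99600, "sfE")      # overlaps promoter
  )
  N <- assemble_susceptibility(gm, tes, mode = "hard", flank = 50000)
  expect_equal(unname(N$values["gA", c("sfA", "sfB", "sfC", "sfD", "sfE")]),
               c(1, 0, 0, 1, 0))
  expect_true(all(N$values == floor(N$values)))
})

test_that("a TE excluded for one gene can still count for another", {
  genes <- dplyr::bind_rows(
    tiny_gene_table("gA", tss = 100000, exon_starts = 101000, exon_ends = 101500),
    tiny_gene_table("gB", tss = 130000, exon_starts = 131000, exon_ends = 131500)
  )
  gm <- gene_models_from_table(genes)
  te <- tiny_te("chr1", 101200, 101400, "sfX") # inside gA's exon, inside gB's window
  N <- assemble_susceptibility(gm, te, mode = "hard", flank = 50000)
  expect_equal(unname(N$values[, "sfX"]), c(0, 1))
})

test_that("weighted mode evaluates the kernel at promoter-center distance", {
  gm <- gene_models_from_table(tiny_gene_table())
  L <- 20000
  # promoter [99500,100500) has center 100000; TE centered at 100000 + L
  te <- tiny_te("chr1", 119800, 120200, "sfA")
  N <- assemble_susceptibility(gm, te, mode = "weighted", bandwidth = L)
  expect_equal(unname(N$values["gA", "sfA"]), exp(-0.5), tolerance = 1e-12)

  # TE overlapping the promoter contributes 0 even at distance ~0
  te0 <- tiny_te("chr1", 99800, 100200, "sfB")
  N0 <- assemble_susceptibility(gm, te0, mode = "weighted", bandwidth = L)
  expect_equal(unname(N0$values["gA", "sfB"]), 0)
})

test_that("TAD restriction zeroes cross-domain and orphan weights", {
  gm <- gene_models_from_table(tiny_gene_table())
  te <- tiny_te("chr1", 119800, 120200, "sfA") # center 120000
  # same TAD
  tads1 <- tibble::tibble(chrom = "chr1", start = 90000, end = 130000)
  # promoter and TE in different TADs
  tads2 <- tibble::tibble(chrom = "chr1", start = c(90000, 110000),
                          end = c(110000, 130000))
  # TE in no TAD
  tads3 <- tibble::tibble(chrom = "chr1", start = 90000, end = 110000)
  w <- function(tads) assemble_susceptibility(
    gm, te, mode = "weighted", bandwidth = 2e4, tads = tads)$values["gA", "sfA"]
  expect_equal(unname(w(tads1)), exp(-0.5), tolerance = 1e-12)
  expect_equal(unname(w(tads2)), 0)
  expect_equal(unname(w(tads3)), 0)
})

test_that("assembly matches the brute-force oracle on random fixtures", {
  for (seed in c(11, 22, 33)) {
    fx <- random_fixture(seed)
    Nh <- assemble_susceptibility(fx$genes, fx$tes, mode = "hard", flank = 5e4)
    expect_equal(Nh$values,
                 oracle_susceptibility(fx$genes, fx$tes, "hard", flank = 5e4))
    Nw <- assemble_susceptibility(fx$genes, fx$tes, mode = "weighted",
                                  bandwidth = 7e4)
    expect_equal(Nw$values,
                 oracle_susceptibility(fx$genes, fx$tes, "weighted", L = 7e4),
                 tolerance = 1e-12)
    tads <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 3),
                           start = rep(c(0, 7e5, 14e5), 2),
                           end = rep(c(6e5, 13e5, 2e6), 2))
    Nt <- assemble_susceptibility(fx$genes, fx$tes, mode = "weighted",
                                  bandwidth = 7e4, tads = tads)
    expect_equal(Nt$values,
                 oracle_susceptibility(fx$genes, fx$tes, "weighted", L = 7e4,
                                       tads = tads),
                 tolerance = 1e-12)
    # TAD restriction never increases an entry
    expect_true(all(Nt$values <= Nw$values + 1e-12))
  }
})

test_that("weighted mode approaches hard counts when TEs hug promoters", {
  # one gene per chromosome so the same-chromosome rule matches window logic
  genes <- dplyr::bind_rows(
    tiny_gene_table("g1", "chr1"), tiny_gene_table("g2", "chr2"))
  gm <- gene_models_from_table(genes)
  tes <- dplyr::bind_rows(
    tiny_te("chr1", 102000, 102400, "sfA"),
    tiny_te("chr1", 97000, 97500, "sfA"),
    tiny_te("chr2", 103000, 103500, "sfB")
  )
  L <- 1e8 # distances of a few kb are << 0.01 L
  Nw <- assemble_susceptibility(gm, tes, mode = "weighted", bandwidth = L)
  Nh <- assemble_susceptibility(gm, tes, mode = "hard", flank = 5e4)
  expect_equal(Nw$values, Nh$values, tolerance = 1e-4)
})

test_that("weighted entries grow with L and respect the count bound", {
  fx <- random_fixture(44)
  Ls <- c(1e4, 5e4, 2e5, 1e6)
  mats <- lapply(Ls, function(L) {
    assemble_susceptibility(fx$genes, fx$tes, mode = "weighted",
                            bandwidth = L)$values
  })
  for (i in seq_len(length(Ls) - 1)) {
    expect_true(all(mats[[i + 1]] >= mats[[i]] - 1e-12))
  }
  # never exceeds same-chromosome retained integrant counts
  per_chrom <- table(fx$tes$chrom, fx$tes$subfamily)
  for (g in rownames(mats[[4]])) {
    chrom <- fx$genes$genes$chrom[fx$genes$genes$gene_id == g]
    cap <- per_chrom[chrom, colnames(mats[[4]])]
    expect_true(all(mats[[4]][g, ] <= as.numeric(cap) + 1e-9))
  }
})

test_that("subfamily filtering applies a strict threshold", {
  vals <- cbind(a = c(100, 49.9), b = c(100, 50), c = c(1, 1))
  rownames(vals) <- c("g1", "g2")
  N <- teactivity:::new_susceptibility_matrix(vals, "weighted", bandwidth = 1e5)
  kept <- suppressMessages(filter_subfamilies(N, min_total = 150))
  expect_equal(colnames(kept$values), "b")
  expect_equal(colnames(filter_subfamilies(N, min_total = 0)$values),
               c("a", "b", "c"))
  expect_error(filter_subfamilies(N, min_total = 1000),
               class = "te_validation_error")
})

test_that("functional splitting conserves susceptibilities and collapses", {
  fx <- random_fixture(55, n_genes = 8, n_tes = 120, n_subfam = 4)
  ref_h <- assemble_susceptibility(fx$genes, fx$tes, mode = "hard", flank = 5e4)
  ref_w <- assemble_susceptibility(fx$genes, fx$tes, mode = "weighted",
                                   bandwidth = 1e5)
  fr <- fx$tes[seq(1, nrow(fx$tes), by = 2), c("chrom", "start", "end")]
  for (ref in list(ref_h, ref_w)) {
    sp <- split_functional(fx$genes, fx$tes, fr, ref,
                           protected = colnames(ref$values),
                           min_fraction_total = 0)
    for (sf in colnames(ref$values)) {
      both <- sp$values[, paste0(sf, c(":functional", ":non_functional"))]
      expect_equal(unname(rowSums(both)), unname(ref$values[, sf]),
                   tolerance = 1e-9)
    }
  }
  # collapse rule: without protection, fractions under the threshold fold back
  sp2 <- split_functional(fx$genes, fx$tes, fr, ref_h,
                          min_fraction_total = 1e6)
  expect_identical(colnames(sp2$values), colnames(ref_h$values))
  expect_equal(sp2$values, ref_h$values[, colnames(sp2$values)])
  # protection overrides the collapse
  prot <- colnames(ref_h$values)[1]
  sp3 <- split_functional(fx$genes, fx$tes, fr, ref_h, protected = prot,
                          min_fraction_total = 1e6)
  expect_true(all(paste0(prot, c(":functional", ":non_functional")) %in%
                    colnames(sp3$values)))
  expect_error(split_functional(fx$genes, fx$tes, fr[0, ], ref_h),
               class = "te_validation_error")
})

test_that("subfamilies filtered from the reference stay absent after splitting", {
  fx <- random_fixture(66, n_genes = 6, n_tes = 60, n_subfam = 3)
  Nh <- assemble_susceptibility(fx$genes, fx$tes, mode = "hard", flank = 5e4)
  sums <- sort(colSums(Nh$values), decreasing = TRUE)
  ref <- suppressMessages(filter_subfamilies(Nh, min_total = sums[1]))
  fr <- fx$tes[1:10, c("chrom", "start", "end")]
  sp <- split_functional(fx$genes, fx$tes, fr, ref, min_fraction_total = 0)
  dropped <- setdiff(colnames(Nh$values), colnames(ref$values))
  expect_gt(length(dropped), 0)
  expect_false(any(sub(":(non_)?functional$", "", colnames(sp$values)) %in%
                     dropped))
})
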