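test_that("read_te_bed maps BED6 records and validates coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tSVA_D\t0\t+",
               "chr2\t50\t800\tLTR5_Hs|inst7\t0\t-"), bed)
  tes <- read_te_bed(bed)
  expect_equal(tes$chrom, c("chr1", "chr2"))
  expect_equal(tes$start, c(100, 50))
  expect_equal(tes$end, c(200, 800))
  expect_equal(tes$strand, c("+", "-"))
  expect_equal(tes$subfamily, c("SVA_D", "LTR5_Hs"))
  expect_equal(tes$instance_id[2], "inst7")

  writeLines(character(0), bed)
  expect_equal(nrow(read_te_bed(bed)), 0)

  writeLines("chr1\t200\t100\tSVA_D\t0\t+", bed)
  expect_error(read_te_bed(bed), class = "te_validation_error")

  writeLines(c("chr1\t100\t200\tSVA_D\t0\t+", "chr1\t100"), bed)
  expect_error(read_te_bed(bed), "line 2", class = "te_parse_error")
})

test_that("read_repeatmasker_out converts coordinates and strand", {
  out <- withr::local_tempfile(fileext = ".out")
  hdr <- c("   SW  perc perc perc  query     position in query",
           "score  div. del. ins.  sequence  begin  end",
           "")
  writeLines(c(hdr,
    "  463  1.3  0.6  1.7  chrN  101  200  (500)  +  LTR7  LTR/ERV1  1  100  (0)  1",
    "  463  1.3  0.6  1.7  chrN  301  400  (300)  C  SVA_D  Retroposon/SVA  1  100  (0)  2"),
    out)
  tes <- read_repeatmasker_out(out)
  expect_equal(tes$start, c(100, 300))
  expect_equal(tes$end, c(200, 400))
  expect_equal(tes$strand, c("+", "-"))
  expect_equal(tes$subfamily, c("LTR7", "SVA_D"))

  writeLines(c(hdr, "  463  1.3  0.6"), out)
  expect_error(read_repeatmasker_out(out), class = "te_parse_error")
})

test_that("merge_te_fragments applies the strict sub-100 bp gap rule", {
  # gap 99 -> merge
  tes <- dplyr::bind_rows(tiny_te("chr1", 100, 200, "SVA_D"),
                          tiny_te("chr1", 299, 400, "SVA_D"))
  m <- merge_te_fragments(tes)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100, 400))

  # gap exactly 100 -> no merge ("less than 100 bp" is strict)
  tes <- dplyr::bind_rows(tiny_te("chr1", 100, 200, "SVA_D"),
                          tiny_te("chr1", 300, 400, "SVA_D"))
  expect_equal(nrow(merge_te_fragments(tes)), 2)

  # different strands never merge
  tes <- dplyr::bind_rows(tiny_te("chr1", 100, 200, "SVA_D", "+"),
                          tiny_te("chr1", 250, 400, "SVA_D", "-"))
  expect_equal(nrow(merge_te_fragments(tes)), 2)

  # different subfamilies never merge
  tes <- dplyr::bind_rows(tiny_te("chr1", 100, 200, "SVA_D"),
                          tiny_te("chr1", 250, 400, "SVA_C"))
  expect_equal(nrow(merge_te_fragments(tes)), 2)
})

test_that("merging is idempotent, order-invariant and coverage-preserving", {
  for (seed in 1:5) {
    tes <- withr::with_seed(seed, {
      n <- 60
      s <- sample(0:20000, n, replace = TRUE)
      tiny_te(sample(c("chr1", "chr2"), n, replace = TRUE),
              s, s + sample(50:500, n, replace = TRUE),
              sample(c("A", "B"), n, replace = TRUE),
              sample(c("+", "-"), n, replace = TRUE),
              instance_id = as.character(seq_len(n)))
    })
    m1 <- merge_te_fragments(tes)
    expect_identical(merge_te_fragments(m1), m1)
    shuffled <- tes[withr::with_seed(seed + 99, sample(nrow(tes))), ]
    expect_identical(merge_te_fragments(shuffled), m1)
    expect_lte(nrow(m1), nrow(tes))
    cover <- function(df) {
      df |>
        dplyr::group_by(subfamily) |>
        dplyr::group_map(~ sum(merge_intervals_by_chrom(.x))) |>
        unlist()
    }
    merge_intervals_by_chrom <- function(df) {
      vapply(split(df, paste(df$chrom, df$strand)), function(g) {
        m <- teactivity:::merge_intervals(g[, c("start", "end")])
        sum(m$end - m$start)
      }, numeric(1))
    }
    expect_true(all(cover(m1) >= cover(tes)))
  }
})

test_that("build_promoters clusters TSS by strict single linkage and pads", {
  expect_equal(as.data.frame(build_promoters(10000)),
               data.frame(start = 9500, end = 10500))
  # 999 bp spacing: one cluster
  expect_equal(as.data.frame(build_promoters(c(10000, 10999))),
               data.frame(start = 9500, end = 11499))
  # 1000 bp spacing: two clusters whose padded intervals abut; stored as union
  expect_equal(as.data.frame(build_promoters(c(10000, 11000))),
               data.frame(start = 9500, end = 11500))
  # clipped at the origin
  expect_equal(build_promoters(100)$start, 0)
  expect_error(build_promoters(numeric(0)), class = "te_validation_error")
})

test_that("promoters contain their TSS and windows contain promoters", {
  for (seed in 1:5) {
    tss <- withr::with_seed(seed, sort(sample(0:50000, 12)))
    proms <- build_promoters(tss)
    inside <- vapply(tss, function(t) any(t >= proms$start & t < proms$end),
                     logical(1))
    expect_true(all(inside))
    wins <- build_windows(proms, flank = 5000)
    contained <- vapply(seq_len(nrow(proms)), function(i) {
      any(wins$start <= proms$start[i] & wins$end >= proms$end[i])
    }, logical(1))
    expect_true(all(contained))
    # disjoint union
    expect_true(all(diff(as.vector(t(as.matrix(wins)))) > 0) || nrow(wins) == 1)
  }
})

test_that("build_windows clips, unions and honors flank 0", {
  p <- tibble::tibble(start = 9500, end = 10500)
  expect_equal(as.data.frame(build_windows(p, 50000)),
               data.frame(start = 0, end = 60500))
  p2 <- tibble::tibble(start = c(100000, 120000), end = c(101000, 121000))
  expect_equal(as.data.frame(build_windows(p2, 50000)),
               data.frame(start = 50000, end = 171000))
  expect_equal(as.data.frame(build_windows(p2, 0)), as.data.frame(p2))
})

test_that("gene models use strand-aware TSS and exon unions", {
  tx <- tibble::tibble(gene_id = "gM", chrom = "chr1", strand = "-",
                       start = 1000, end = 5000)
  ex <- tibble::tibble(gene_id = "gM", chrom = "chr1",
                       start = c(1000, 1050), end = c(1100, 1150))
  gm <- build_gene_models(tx, ex)
  expect_equal(gm$tss$pos, 5000)
  expect_equal(as.data.frame(gm$exons[, c("start", "end")]),
               data.frame(start = 1000, end = 1150))

  # two transcripts 300 bp apart share one promoter
  tx2 <- tibble::tibble(gene_id = "gP", chrom = "chr1", strand = "+",
                        start = c(2000, 2300), end = c(9000, 9000))
  gm2 <- suppressWarnings(build_gene_models(tx2, ex[0, ]))
  expect_equal(nrow(gm2$promoters), 1)
  expect_true(gm2$promoters$start <= 1500 && gm2$promoters$end >= 2800)

  # unknown strand treated as + with a warning
  tx3 <- tibble::tibble(gene_id = "gU", chrom = "chr1", strand = ".",
                        start = 100, end = 900)
  expect_warning(
    expect_warning(gm3 <- build_gene_models(tx3, ex[0, ]), "strand"),
    "exon")
  expect_equal(gm3$tss$pos, 100)
})

test_that("GTF and flat-table gene models agree", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  lines <- c(
    paste0("chr1\tsrc\tgene\t1001\t9000\t.\t+\t.\t",
           "gene_id \"gX\"; gene_biotype \"protein_coding\";"),
    paste0("chr1\tsrc\ttranscript\t1001\t9000\t.\t+\t.\t",
           "gene_id \"gX\"; transcript_id \"tX1\";"),
    paste0("chr1\tsrc\texon\t1001\t1200\t.\t+\t.\t",
           "gene_id \"gX\"; transcript_id \"tX1\";"),
    paste0("chr1\tsrc\texon\t2001\t2400\t.\t+\t.\t",
           "gene_id \"gX\"; transcript_id \"tX1\";"),
    paste0("chr1\tsrc\tgene\t20001\t30000\t.\t-\t.\t",
           "gene_id \"gY\"; gene_biotype \"lincRNA\";"),
    paste0("chr1\tsrc\ttranscript\t20001\t30000\t.\t-\t.\t",
           "gene_id \"gY\"; transcript_id \"tY1\";")
  )
  writeLines(lines, gtf)
  gm <- suppressMessages(read_gene_models_gtf(gtf))
  # non-protein-coding gY dropped
  expect_equal(gm$genes$gene_id, "gX")
  flat <- gene_models_from_table(
    tiny_gene_table("gX", "chr1", "+", tss = 1000,
                    exon_starts = c(1000, 2000), exon_ends = c(1200, 2400)))
  expect_equal(gm$tss$pos, flat$tss$pos)
  expect_equal(as.data.frame(gm$promoters), as.data.frame(flat$promoters))
  expect_equal(as.data.frame(gm$exons), as.data.frame(flat$exons))
  expect_equal(as.data.frame(gm$windows), as.data.frame(flat$windows))
})
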