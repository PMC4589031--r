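test_that("load_cgis parses, merges overlapping/adjacent islands, and validates", {
  one <- load_cgis("chr1 100 300")
  expect_equal(one[, c("chrom", "start", "end")],
               data.frame(chrom = "chr1", start = 100L, end = 300L))

  merged <- load_cgis(c("chr1 100 300", "chr1 250 400"))
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(100L, 400L))
  oracle <- oracle_merge_intervals(c(100, 250), c(300, 400), 1000)
  expect_equal(merged[, c("start", "end")], oracle, ignore_attr = TRUE)

  # book-ended intervals merge too; cross-chromosome ones do not
  expect_equal(nrow(load_cgis(c("chr1 100 200", "chr1 200 300"))), 1L)
  expect_equal(nrow(load_cgis(c("chr1 100 200", "chr2 100 200"))), 2L)

  expect_equal(nrow(load_cgis(character())), 0L)
  expect_error(load_cgis("chr1 100"), "line 1")
  expect_error(load_cgis("chr1 300 100"), "invalid interval")
})

test_that("load_cgis merging agrees with per-base union oracle on random inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(1:10, 1)
    s <- sample(0:900, n)
    e <- s + sample(10:100, n, replace = TRUE)
    got <- load_cgis(paste("chrZ", s, e))
    oracle <- oracle_merge_intervals(s, e, 1100)
    expect_equal(got[, c("start", "end")], oracle, ignore_attr = TRUE)
  }
})

refflat_line <- function(gene = "GNA", tx = "NM_1", chrom = "chr1",
                         strand = "+", txs = 1000, txe = 5000,
                         cdss = 1200, cdse = 4800, starts = c(1000, 4000),
                         ends = c(1500, 5000)) {
  paste(gene, tx, chrom, strand, txs, txe, cdss, cdse, length(starts),
        paste0(paste(starts, collapse = ","), ","),
        paste0(paste(ends, collapse = ","), ","), sep = "\t")
}

test_that("load_gene_models parses refFlat and validates structure", {
  g <- load_gene_models(refflat_line())
  expect_equal(nrow(g), 1L)
  expect_equal(g$exon_starts[[1]], c(1000L, 4000L))
  expect_equal(g$exon_ends[[1]], c(1500L, 5000L))

  # exonCount mismatch
  bad <- paste("G", "N", "chr1", "+", 0, 100, 0, 100, 3, "0,50,", "40,100,",
               sep = "\t")
  expect_error(load_gene_models(bad), "exonCount")

  expect_error(load_gene_models(refflat_line(strand = "*")), "strand")

  # minus strand: exons stay in ascending genomic order
  m <- load_gene_models(refflat_line(strand = "-",
                                     starts = c(4000, 1000),
                                     ends = c(5000, 1500)))
  expect_equal(m$strand, "-")
  expect_equal(m$exon_starts[[1]], c(1000L, 4000L))
})

test_that("isoforms collapse to the union of exons", {
  two <- c(refflat_line(tx = "NM_1", starts = c(1000, 4000), ends = c(1500, 5000)),
           refflat_line(tx = "NM_2", txs = 900, txe = 5000, cdss = 1100,
                        starts = c(900, 1400, 4000), ends = c(1600, 2000, 5000)))
  cg <- collapse_gene_models(load_gene_models(two))
  expect_equal(nrow(cg), 1L)
  expect_equal(cg$tx_start, 900L)
  expect_equal(cg$exon_starts[[1]], c(900L, 4000L))
  expect_equal(cg$exon_ends[[1]], c(2000L, 5000L))
  expect_equal(cg$cds_start, 1100L)
})

test_that("cgi_status uses half-open >= 1 bp overlap", {
  cgis <- load_cgis("chr1 100 300")
  expect_equal(cgi_status(data.frame(chrom = "chr1", start = 200, end = 400), cgis),
               "CGI")
  # book-ended bin shares no base under half-open semantics
  expect_equal(cgi_status(data.frame(chrom = "chr1", start = 300, end = 500), cgis),
               "NON_CGI")
  expect_equal(cgi_status(data.frame(chrom = "chr9", start = 100, end = 300), cgis),
               "NON_CGI")
})

test_that("classify_bin_region assigns the documented categories", {
  # + strand gene, exons [1000,1500) [2500,3000) [4000,5000), cds 1200-4800
  g <- collapse_gene_models(load_gene_models(
    refflat_line(starts = c(1000, 2500, 4000), ends = c(1500, 3000, 5000))))
  bin <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  r <- function(b) classify_bin_region(b, g, promoter_span = 2000)

  expect_equal(r(bin(4200, 4400))$region, "THREE_PRIME")   # inside last exon
  expect_equal(r(bin(1000, 1200))$region, "FIVE_PRIME")    # first exon
  expect_equal(r(bin(1600, 1800))$region, "GENE_BODY")     # internal intron
  expect_equal(r(bin(2600, 2800))$region, "GENE_BODY")     # internal exon
  expect_equal(r(bin(200, 400))$region, "FIVE_PRIME")      # promoter upstream
  expect_equal(r(bin(15000, 15200))$region, "INTERGENIC")  # 10 kb away
  expect_true(is.na(r(bin(15000, 15200))$gene))
  # promoter_span = 0 disables the upstream extension
  expect_equal(classify_bin_region(bin(200, 400), g, promoter_span = 0)$region,
               "INTERGENIC")

  # - strand gene: genomically rightmost exon is the first exon
  gm <- collapse_gene_models(load_gene_models(
    refflat_line(strand = "-", starts = c(1000, 2500, 4000),
                 ends = c(1500, 3000, 5000))))
  expect_equal(classify_bin_region(bin(4200, 4400), gm, 2000)$region, "FIVE_PRIME")
  expect_equal(classify_bin_region(bin(1000, 1200), gm, 2000)$region, "THREE_PRIME")
  expect_equal(classify_bin_region(bin(5100, 5300), gm, 2000)$region, "FIVE_PRIME")
})

test_that("category assignment is a partition over (bin, gene) pairs", {
  for (seed in 1:10) {
    toy <- random_toy_genome(seed)
    got <- classify_bin_region(toy$bins, toy$genes, 1000)
    expect_false(any(duplicated(got[, c("bin", "gene")])))
    expect_setequal(unique(got$bin), seq_len(nrow(toy$bins)))
  }
})

test_that("classification is invariant under coordinate mirror + strand flip", {
  for (seed in 1:8) {
    toy <- random_toy_genome(seed)
    L <- toy$genome_len
    g <- toy$genes
    gm <- g
    gm$strand <- ifelse(g$strand == "+", "-", "+")
    gm$tx_start <- L - g$tx_end
    gm$tx_end <- L - g$tx_start
    coding <- g$cds_start < g$cds_end
    gm$cds_start <- ifelse(coding, L - g$cds_end, gm$tx_start)
    gm$cds_end <- ifelse(coding, L - g$cds_start, gm$tx_start)
    gm$exon_starts <- lapply(seq_len(nrow(g)), function(i) rev(L - g$exon_ends[[i]]))
    gm$exon_ends <- lapply(seq_len(nrow(g)), function(i) rev(L - g$exon_starts[[i]]))
    bins_m <- data.frame(chrom = toy$bins$chrom, start = L - toy$bins$end,
                         end = L - toy$bins$start)
    a <- classify_bin_region(toy$bins, g, 500)
    b <- classify_bin_region(bins_m, gm, 500)
    merged <- merge(a, b, by = c("bin", "gene"))
    expect_equal(nrow(merged), nrow(a))
    expect_equal(merged$region.x, merged$region.y)
  }
})
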