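# A reduced genome keeps the generator tests quick; the full-size default
# is exercised by the acceptance suite.
small_config <- function(seed = 1, ...) {
  synth_config(seed = seed, n_chroms = 1L, chrom_length = 4e5, n_genes = 20L,
               n_cgis = 40L,
               planted_dmrs = data.frame(
                 kind = c("cgi_3prime", "noncgi_shore"),
                 direction = c("GAIN", "LOSS"), delta = 30,
                 contrast = "maturation", n = c(5L, 5L),
                 stringsAsFactors = FALSE),
               ...)
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 5)
  a1 <- generate_annotation(cfg); a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  t1 <- plant_truth(cfg, a1); t2 <- plant_truth(cfg, a2)
  expect_identical(t1, t2)
  g1 <- generate_counts(cfg, a1, t1); g2 <- generate_counts(cfg, a2, t2)
  expect_identical(g1$counts, g2$counts)
  expect_identical(generate_expression(cfg, t1), generate_expression(cfg, t2))
  p1 <- generate_panel(cfg); p2 <- generate_panel(cfg)
  expect_identical(p1$cnv$values, p2$cnv$values)

  # file outputs byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_annotation(a1, file.path(d1, "c.bed"), file.path(d1, "g.refflat"))
  write_annotation(a2, file.path(d2, "c.bed"), file.path(d2, "g.refflat"))
  expect_identical(readLines(file.path(d1, "g.refflat")),
                   readLines(file.path(d2, "g.refflat")))
})

test_that("annotation emission honours the format contracts", {
  cfg <- small_config(seed = 2)
  ann <- generate_annotation(cfg)
  d <- withr::local_tempdir()
  write_annotation(ann, file.path(d, "cgi.bed"), file.path(d, "genes.refflat"))
  cgis <- load_cgis(file.path(d, "cgi.bed"))
  expect_gt(nrow(cgis), 0)
  genes <- load_gene_models(file.path(d, "genes.refflat"))
  expect_equal(nrow(genes), 20L)
  expect_true(all(vapply(seq_len(nrow(genes)), function(i)
    length(genes$exon_starts[[i]]) >= 3, TRUE)))

  # no islands at all: genes still emitted
  none <- generate_annotation(synth_config(seed = 2, n_chroms = 1L,
                                           chrom_length = 4e5, n_genes = 20L,
                                           n_cgis = 0L))
  expect_equal(nrow(none$cgis), 0L)
  expect_equal(nrow(none$genes), 20L)
})

test_that("planted truth bins carry their intended CGI status and region", {
  for (seed in 1:3) {
    cfg <- small_config(seed = seed)
    ann <- generate_annotation(cfg)
    truth <- plant_truth(cfg, ann)
    cg <- load_cgis(with(ann$cgis, paste(chrom, start, end)))
    st <- cgi_status(truth, cg)
    expect_equal(st, ifelse(truth$kind == "noncgi_shore", "NON_CGI", "CGI"))
    cls <- classify_bin_region(truth, collapse_gene_models(ann$genes))
    m <- merge(data.frame(bin = seq_len(nrow(truth)), gene = truth$gene,
                          kind = truth$kind),
               cls, by = c("bin", "gene"))
    three <- m[m$kind == "cgi_3prime", ]
    expect_equal(three$region, rep("THREE_PRIME", nrow(three)))
  }
})

test_that("observed levels converge to truth at extreme coverage", {
  cfg <- small_config(seed = 8, coverage_mean = 1e4, dispersion = 0)
  ann <- generate_annotation(cfg)
  truth <- plant_truth(cfg, ann)
  gen <- generate_counts(cfg, ann, truth)
  prof <- meth_profile(bin_methylation(gen$counts[["ISC_P21"]]), "ISC_P21")
  obs <- prof$bins[match(truth$key, prof$bins$key), "level"]
  expect_true(all(abs(obs - truth$level_b) <= 1))
})

test_that("a null genome yields almost no DMRs at the 15-point threshold", {
  cfg <- synth_config(seed = 13, n_chroms = 1L, chrom_length = 4e5,
                      n_genes = 20L, n_cgis = 40L,
                      planted_dmrs = data.frame(kind = character(),
                                                direction = character(),
                                                delta = numeric(),
                                                contrast = character(),
                                                n = integer()))
  ann <- generate_annotation(cfg)
  truth <- plant_truth(cfg, ann)
  expect_equal(nrow(truth), 0L)
  gen <- generate_counts(cfg, ann, truth)
  pa <- meth_profile(bin_methylation(gen$counts[["ISC_P0"]]), "a")
  pb <- meth_profile(bin_methylation(gen$counts[["ISC_P21"]]), "b")
  d <- call_dmrs(pa, pb)
  n_tested <- length(intersect(pa$bins$key[pa$bins$passes_filter],
                               pb$bins$key[pb$bins$passes_filter]))
  expect_gt(n_tested, 1000)
  expect_lt(nrow(d) / n_tested, 0.01)
})

test_that("planted maturation DMRs surface end to end with their direction", {
  cfg <- small_config(seed = 4)
  ann <- generate_annotation(cfg)
  truth <- plant_truth(cfg, ann)
  gen <- generate_counts(cfg, ann, truth)
  pa <- meth_profile(bin_methylation(gen$counts[["ISC_P0"]]), "ISC_P0")
  pb <- meth_profile(bin_methylation(gen$counts[["ISC_P21"]]), "ISC_P21")
  d <- call_dmrs(pa, pb, contrast = "mDMR")
  gains <- truth[truth$direction == "GAIN", ]
  hit <- d[match(gains$key, d$key), ]
  expect_true(all(!is.na(hit$direction) & hit$direction == "GAIN"))
})

test_that("expression coupling is recovered exactly in the noise-free limit", {
  cfg <- small_config(seed = 6, expr_noise_sd = 0, expr_meth_noise_sd = 0)
  ann <- generate_annotation(cfg)
  truth <- plant_truth(cfg, ann)
  expr <- generate_expression(cfg, truth)
  one <- expr[expr$coupled & expr$gene == expr$gene[expr$coupled][1], ]
  fit <- suppressWarnings(age_adjusted_regression(one))  # perfect fit
  expect_equal(fit$coefficient, cfg$expression_coupling, tolerance = 1e-10)

  neg <- small_config(seed = 6, expr_noise_sd = 0, expr_meth_noise_sd = 0,
                      expression_coupling = -0.05)
  expr_n <- generate_expression(neg, plant_truth(neg, generate_annotation(neg)))
  one_n <- expr_n[expr_n$coupled & expr_n$gene == expr_n$gene[expr_n$coupled][1], ]
  fit_n <- suppressWarnings(age_adjusted_regression(one_n))
  expect_equal(fit_n$coefficient, -0.05, tolerance = 1e-10)
  expect_equal(fit_n$direction, "negative")
})

test_that("panel construction plants the germ-free deficit where intended", {
  cfg <- small_config(seed = 10)
  pan <- generate_panel(cfg)
  cnv <- pan$cnv; gf <- pan$gf
  last_age <- utils::tail(cfg$panel_ages, 1)
  sel <- cnv$age == last_age
  gain <- pan$truth$type == "developmental_gain"
  gap <- rowMeans(cnv$values[gain, sel]) - rowMeans(gf$values[gain, sel])
  # CNV-minus-GF difference at the last age approximates the planted deficit
  expect_equal(unname(gap), pan$truth$deficit[gain], tolerance = 0.2)
  rep_rows <- pan$truth$type == "repeat_element"
  rep_gap <- rowMeans(cnv$values[rep_rows, sel]) - rowMeans(gf$values[rep_rows, sel])
  expect_true(all(abs(rep_gap) < 5))
  loss <- pan$truth$type == "developmental_loss"
  loss_gap <- rowMeans(cnv$values[loss, sel]) - rowMeans(gf$values[loss, sel])
  expect_true(all(abs(loss_gap) < 10))
})
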