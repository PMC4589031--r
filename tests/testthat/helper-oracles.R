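# Brute-force oracles and fixture builders. Every oracle takes a deliberately
# naive route (per-base painting, explicit enumeration) independent of the
# package's interval-arithmetic implementations.

# Interval union by per-base marking on a small genome.
oracle_merge_intervals <- function(starts, ends, genome_len) {
  covered <- rep(FALSE, genome_len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(covered)
  stop_at <- cumsum(r$lengths)
  start_at <- c(0L, stop_at[-length(stop_at)])
  data.frame(start = start_at[r$values], end = stop_at[r$values])
}

# CGI status of bins by per-base marking.
oracle_cgi_status <- function(bins, cgis, genome_len) {
  covered <- rep(FALSE, genome_len)
  for (i in seq_len(nrow(cgis))) covered[(cgis$start[i] + 1):cgis$end[i]] <- TRUE
  vapply(seq_len(nrow(bins)), function(i) {
    if (any(covered[(bins$start[i] + 1):bins$end[i]])) "CGI" else "NON_CGI"
  }, "")
}

# Bin quantification by per-position accumulation.
oracle_bin_methylation <- function(sites, bin_size, min_cpgs = 2, min_calls = 10) {
  sites <- sites[sites$meth + sites$unmeth >= 1, , drop = FALSE]
  out <- list()
  for (chrom in unique(sites$chrom)) {
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    for (b in unique(s$pos %/% bin_size)) {
      inbin <- s[s$pos %/% bin_size == b, , drop = FALSE]
      meth <- sum(inbin$meth)
      tot <- sum(inbin$meth + inbin$unmeth)
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = b * bin_size, n_cpgs = nrow(inbin),
        meth_calls = meth, total_calls = tot, level = 100 * meth / tot,
        passes_filter = nrow(inbin) >= min_cpgs && tot >= min_calls)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Region classification by per-base category painting, straight from the
# definitions: THREE' = last exon or exonic 3' UTR; FIVE' = promoter span,
# first exon, or exonic 5' UTR; BODY = anywhere in the transcript span;
# bin category = highest precedence among its bases, per gene.
oracle_classify_region <- function(bins, genes, promoter_span, genome_len) {
  res <- list()
  for (g in seq_len(nrow(genes))) {
    ex_s <- genes$exon_starts[[g]]
    ex_e <- genes$exon_ends[[g]]
    n_ex <- length(ex_s)
    strand <- genes$strand[g]
    coding <- genes$cds_start[g] < genes$cds_end[g]
    pos <- 0:(genome_len - 1)
    exonic <- rep(FALSE, genome_len)
    for (i in seq_len(n_ex)) exonic <- exonic | (pos >= ex_s[i] & pos < ex_e[i])
    if (strand == "+") {
      first_ex <- pos >= ex_s[1] & pos < ex_e[1]
      last_ex <- pos >= ex_s[n_ex] & pos < ex_e[n_ex]
      prom <- pos >= genes$tx_start[g] - promoter_span & pos < genes$tx_start[g]
      utr5 <- coding & exonic & pos < genes$cds_start[g]
      utr3 <- coding & exonic & pos >= genes$cds_end[g]
    } else {
      first_ex <- pos >= ex_s[n_ex] & pos < ex_e[n_ex]
      last_ex <- pos >= ex_s[1] & pos < ex_e[1]
      prom <- pos >= genes$tx_end[g] & pos < genes$tx_end[g] + promoter_span
      utr5 <- coding & exonic & pos >= genes$cds_end[g]
      utr3 <- coding & exonic & pos < genes$cds_start[g]
    }
    three <- last_ex | utr3
    five <- first_ex | prom | utr5
    body <- pos >= genes$tx_start[g] & pos < genes$tx_end[g]
    for (b in seq_len(nrow(bins))) {
      span <- (bins$start[b] + 1):bins$end[b]
      region <- if (any(three[span])) "THREE_PRIME"
        else if (any(five[span])) "FIVE_PRIME"
        else if (any(body[span])) "GENE_BODY"
        else NA_character_
      if (!is.na(region)) {
        res[[length(res) + 1]] <- data.frame(
          bin = b, gene = genes$gene[g], region = region,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(bin = integer(), gene = character(), region = character())
  inter <- setdiff(seq_len(nrow(bins)), unique(hits$bin))
  out <- rbind(hits,
               if (length(inter) > 0)
                 data.frame(bin = inter, gene = NA_character_,
                            region = "INTERGENIC", stringsAsFactors = FALSE))
  out <- out[order(out$bin, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Two-sided Fisher p by explicit enumeration of all 2x2 tables with the
# observed margins, probabilities from log-binomial coefficients.
oracle_fisher_p <- function(k, K, n, N) {
  supp <- max(0, n + K - N):min(K, n)
  logp <- lchoose(K, supp) + lchoose(N - K, n - supp) - lchoose(N, n)
  p_tab <- exp(logp)
  obs <- p_tab[match(k, supp)]
  sum(p_tab[p_tab <= obs * (1 + 1e-07)])
}

# Random toy genome for oracle-equivalence checks: <= 10 kb, a few genes
# with valid exon structure, a few CGIs, random CpG counts.
random_toy_genome <- function(seed, genome_len = 10000L) {
  set.seed(seed)
  n_genes <- sample(1:3, 1)
  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    tx_start <- sample(0:(genome_len - 3000), 1)
    tx_len <- sample(1500:min(6000, genome_len - tx_start), 1)
    tx_end <- tx_start + tx_len
    n_ex <- sample(1:4, 1)
    cuts <- sort(sample(seq(tx_start, tx_end - 1, by = 50),
                        max(2, 2 * n_ex), replace = FALSE))
    ex_s <- cuts[seq(1, by = 2, length.out = n_ex)]
    ex_e <- cuts[seq(2, by = 2, length.out = n_ex)]
    ex_s[1] <- tx_start
    ex_e[n_ex] <- tx_end
    coding <- stats::runif(1) < 0.8
    if (coding && n_ex >= 1) {
      cds_start <- ex_s[1] + sample.int(max(1, ex_e[1] - ex_s[1] - 1), 1)
      cds_end <- ex_e[n_ex] - sample.int(max(1, ex_e[n_ex] - ex_s[n_ex] - 1), 1)
      if (cds_end <= cds_start) { cds_start <- tx_start; cds_end <- tx_start }
    } else {
      cds_start <- tx_start
      cds_end <- tx_start
    }
    genes[[g]] <- data.frame(gene = paste0("T", g), chrom = "chrT",
                             strand = sample(c("+", "-"), 1),
                             tx_start = tx_start, tx_end = tx_end,
                             cds_start = cds_start, cds_end = cds_end,
                             stringsAsFactors = FALSE)
    genes[[g]]$exon_starts <- list(ex_s)
    genes[[g]]$exon_ends <- list(ex_e)
  }
  genes <- do.call(rbind, genes)
  n_cgi <- sample(0:4, 1)
  cgi_start <- sort(sample(seq(0, genome_len - 600, by = 100), n_cgi))
  cgis <- data.frame(chrom = rep("chrT", n_cgi), start = cgi_start,
                     end = cgi_start + sample(200:600, max(n_cgi, 1))[seq_len(n_cgi)],
                     stringsAsFactors = FALSE)
  n_cpg <- sample(50:150, 1)
  pos <- sort(sample(0:(genome_len - 1), n_cpg))
  sites <- data.frame(chrom = "chrT", pos = pos,
                      meth = stats::rpois(n_cpg, 6),
                      unmeth = stats::rpois(n_cpg, 3),
                      stringsAsFactors = FALSE)
  bin_starts <- seq(0, genome_len - 200, by = 200)
  bins <- data.frame(chrom = "chrT", start = bin_starts,
                     end = bin_starts + 200, stringsAsFactors = FALSE)
  list(genome_len = genome_len, genes = genes, cgis = cgis, sites = sites,
       bins = bins)
}

# Minimal bin table / profile builders for DMR and proportion tests.
make_bins <- function(levels, total_calls = 100, chrom = "chr1",
                      passes = TRUE, bin_size = 200L) {
  n <- length(levels)
  start <- (seq_len(n) - 1L) * bin_size
  meth <- round(levels * total_calls / 100)
  data.frame(chrom = chrom, start = start, end = start + bin_size,
             key = paste0(chrom, ":", start), n_cpgs = 5L,
             meth_calls = meth, total_calls = rep(total_calls, n),
             level = levels, passes_filter = rep_len(passes, n),
             stringsAsFactors = FALSE)
}

make_profile <- function(levels, id = "S", ...) {
  meth_profile(make_bins(levels, ...), sample_id = id)
}
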