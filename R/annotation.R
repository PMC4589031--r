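# Genome annotation: CpG islands, gene models, and bin classification.

#' Load CpG islands from BED text
#'
#' Reads BED3+ lines (0-based, half-open), merges overlapping or book-ended
#' islands on the same chromosome, and returns them sorted by
#' (chrom, start). CGIs are consumed as a fixed interval list; the package
#' does no de novo island detection.
#'
#' @param x Path to a BED file, or a character vector of BED lines.
#' @return A data.frame with columns `chrom`, `start`, `end`, `id`, sorted by
#'   (chrom, start); intervals on one chromosome are disjoint after merging.
#' @export
load_cgis <- function(x) {
  lines <- .read_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      id = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3L)
  if (length(bad) > 0L) {
    .stopf("malformed BED line %d: expected at least 3 fields, got %d",
           bad[1L], n_fields[bad[1L]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) .stopf("malformed BED line %d: non-numeric coordinates", bad[1L])
  bad <- which(start < 0L | start >= end)
  if (length(bad) > 0L) {
    .stopf("invalid interval on BED line %d: start=%d end=%d", bad[1L],
           start[bad[1L]], end[bad[1L]])
  }
  gr <- .as_granges(data.frame(chrom = chrom, start = start, end = end))
  merged <- .from_granges(GenomicRanges::reduce(gr))
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  merged$id <- sprintf("CGI_%05d", seq_len(nrow(merged)))
  rownames(merged) <- NULL
  merged
}

#' Load gene models from refFlat text
#'
#' Parses the UCSC 11-column refFlat format (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds;
#' coordinates 0-based half-open). Exons are stored in ascending genomic
#' order regardless of strand.
#'
#' @param x Path to a refFlat file, or a character vector of refFlat lines.
#' @return A data.frame with one row per transcript: `gene`, `tx_name`,
#'   `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, and
#'   list columns `exon_starts`, `exon_ends`.
#' @export
load_gene_models <- function(x) {
  lines <- .read_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^#", lines)]
  empty <- data.frame(gene = character(), tx_name = character(),
                      chrom = character(), strand = character(),
                      tx_start = integer(), tx_end = integer(),
                      cds_start = integer(), cds_end = integer(),
                      stringsAsFactors = FALSE)
  empty$exon_starts <- list()
  empty$exon_ends <- list()
  if (length(lines) == 0L) return(empty)

  fields <- strsplit(lines, "\t")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 11L)
  if (length(bad) > 0L) {
    .stopf("malformed refFlat line %d: expected 11 tab-separated fields, got %d",
           bad[1L], n_fields[bad[1L]])
  }
  parse_csv_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1L]])
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    strand <- f[4L]
    if (!strand %in% c("+", "-")) {
      .stopf("refFlat line %d: unknown strand symbol '%s'", i, strand)
    }
    exon_count <- as.integer(f[9L])
    starts <- parse_csv_ints(f[10L])
    ends <- parse_csv_ints(f[11L])
    if (length(starts) != exon_count || length(ends) != exon_count) {
      .stopf("refFlat line %d: exonCount=%d but %d starts / %d ends",
             i, exon_count, length(starts), length(ends))
    }
    ord <- order(starts)
    starts <- starts[ord]
    ends <- ends[ord]
    tx_start <- as.integer(f[5L])
    tx_end <- as.integer(f[6L])
    if (any(ends <= starts) || starts[1L] < tx_start || ends[exon_count] > tx_end) {
      .stopf("refFlat line %d: exons inconsistent with transcript bounds", i)
    }
    out[[i]] <- list(gene = f[1L], tx_name = f[2L], chrom = f[3L],
                     strand = strand, tx_start = tx_start, tx_end = tx_end,
                     cds_start = as.integer(f[7L]), cds_end = as.integer(f[8L]),
                     exon_starts = starts, exon_ends = ends)
  }
  res <- data.frame(
    gene = vapply(out, `[[`, "", "gene"),
    tx_name = vapply(out, `[[`, "", "tx_name"),
    chrom = vapply(out, `[[`, "", "chrom"),
    strand = vapply(out, `[[`, "", "strand"),
    tx_start = vapply(out, `[[`, 0L, "tx_start"),
    tx_end = vapply(out, `[[`, 0L, "tx_end"),
    cds_start = vapply(out, `[[`, 0L, "cds_start"),
    cds_end = vapply(out, `[[`, 0L, "cds_end"),
    stringsAsFactors = FALSE
  )
  res$exon_starts <- lapply(out, `[[`, "exon_starts")
  res$exon_ends <- lapply(out, `[[`, "exon_ends")
  res
}

#' Collapse transcript isoforms to one model per gene
#'
#' Isoforms sharing a gene symbol on one chromosome and strand are merged by
#' the union of their exons; transcript bounds become the union span and the
#' coding region the union of coding spans. First/last exons used for region
#' classification are computed on this collapsed model in transcription
#' orientation.
#'
#' @param models Output of [load_gene_models()].
#' @return A data.frame with one row per gene, same columns as the input
#'   minus `tx_name`.
#' @export
collapse_gene_models <- function(models) {
  if (nrow(models) == 0L) {
    models$tx_name <- NULL
    return(models)
  }
  key <- paste(models$gene, models$chrom, models$strand, sep = "\r")
  groups <- split(seq_len(nrow(models)), key)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    starts <- unlist(models$exon_starts[idx])
    ends <- unlist(models$exon_ends[idx])
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      "x", IRanges::IRanges(starts + 1L, ends)))
    ex_start <- GenomicRanges::start(gr) - 1L
    ex_end <- GenomicRanges::end(gr)
    coding <- models$cds_start[idx] < models$cds_end[idx]
    row <- data.frame(
      gene = models$gene[idx[1L]],
      chrom = models$chrom[idx[1L]],
      strand = models$strand[idx[1L]],
      tx_start = min(models$tx_start[idx]),
      tx_end = max(models$tx_end[idx]),
      cds_start = if (any(coding)) min(models$cds_start[idx][coding]) else min(models$tx_start[idx]),
      cds_end = if (any(coding)) max(models$cds_end[idx][coding]) else min(models$tx_start[idx]),
      stringsAsFactors = FALSE
    )
    row$exon_starts <- list(ex_start)
    row$exon_ends <- list(ex_end)
    out[[g]] <- row
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$tx_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Per-gene genomic footprints of the three gene-region categories.
# Returns a data.frame (chrom, start, end, gene, region, precedence) where
# precedence 1 = THREE_PRIME, 2 = FIVE_PRIME, 3 = GENE_BODY. The GENE_BODY
# footprint is the whole transcript span; precedence resolves overlaps.
.region_footprints <- function(genes, promoter_span) {
  .assert(promoter_span >= 0, "promoter_span must be >= 0")
  if (nrow(genes) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      gene = character(), region = character(),
                      precedence = integer(), stringsAsFactors = FALSE))
  }
  pieces <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ex_s <- genes$exon_starts[[i]]
    ex_e <- genes$exon_ends[[i]]
    n_ex <- length(ex_s)
    strand <- genes$strand[i]
    coding <- genes$cds_start[i] < genes$cds_end[i]

    # Transcription orientation: on '-' the genomically rightmost exon is
    # the first exon and the 3' UTR sits at low coordinates.
    if (strand == "+") {
      first_ex <- c(ex_s[1L], ex_e[1L])
      last_ex <- c(ex_s[n_ex], ex_e[n_ex])
      prom <- c(max(0L, genes$tx_start[i] - promoter_span), genes$tx_start[i])
      utr5 <- if (coding) c(genes$tx_start[i], genes$cds_start[i]) else NULL
      utr3 <- if (coding) c(genes$cds_end[i], genes$tx_end[i]) else NULL
    } else {
      first_ex <- c(ex_s[n_ex], ex_e[n_ex])
      last_ex <- c(ex_s[1L], ex_e[1L])
      prom <- c(genes$tx_end[i], genes$tx_end[i] + promoter_span)
      utr5 <- if (coding) c(genes$cds_end[i], genes$tx_end[i]) else NULL
      utr3 <- if (coding) c(genes$tx_start[i], genes$cds_start[i]) else NULL
    }
    # UTR footprints are restricted to exonic bases.
    clip_to_exons <- function(iv) {
      if (is.null(iv) || iv[2L] <= iv[1L]) return(NULL)
      s <- pmax(ex_s, iv[1L])
      e <- pmin(ex_e, iv[2L])
      keep <- e > s
      if (!any(keep)) return(NULL)
      cbind(s[keep], e[keep])
    }
    three <- rbind(matrix(last_ex, ncol = 2L), clip_to_exons(utr3))
    five <- rbind(matrix(first_ex, ncol = 2L),
                  if (prom[2L] > prom[1L]) matrix(prom, ncol = 2L) else NULL,
                  clip_to_exons(utr5))
    body <- matrix(c(genes$tx_start[i], genes$tx_end[i]), ncol = 2L)
    piece <- function(mat, region, precedence) {
      if (is.null(mat) || nrow(mat) == 0L) return(NULL)
      data.frame(chrom = genes$chrom[i], start = mat[, 1L], end = mat[, 2L],
                 gene = genes$gene[i], region = region,
                 precedence = precedence, stringsAsFactors = FALSE)
    }
    pieces[[i]] <- rbind(piece(three, "THREE_PRIME", 1L),
                         piece(five, "FIVE_PRIME", 2L),
                         piece(body, "GENE_BODY", 3L))
  }
  do.call(rbind, pieces)
}

#' CGI status of genomic bins
#'
#' A bin is CGI-associated iff it overlaps any CpG island by at least one
#' base under half-open coordinates.
#'
#' @param bins A data.frame with columns `chrom`, `start`, `end`.
#' @param cgis Output of [load_cgis()] (merged, sorted).
#' @return Character vector, one of `"CGI"`/`"NON_CGI"` per bin.
#' @export
cgi_status <- function(bins, cgis) {
  if (nrow(bins) == 0L) return(character())
  if (nrow(cgis) == 0L) return(rep("NON_CGI", nrow(bins)))
  # disjoint seqlevels (a bin on a CGI-free chromosome) are a valid query
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_granges(bins), .as_granges(cgis)))
  status <- rep("NON_CGI", nrow(bins))
  status[unique(S4Vectors::queryHits(hits))] <- "CGI"
  status
}

#' Classify genomic bins by gene-region category
#'
#' Assigns each bin, for every gene it overlaps (gene span extended upstream
#' by `promoter_span`), exactly one category:
#' \describe{
#'   \item{THREE_PRIME}{last exon or 3' UTR (transcription orientation)}
#'   \item{FIVE_PRIME}{promoter extension, first exon, or 5' UTR}
#'   \item{GENE_BODY}{remaining introns and internal exons}
#'   \item{INTERGENIC}{bins overlapping no gene (gene recorded as NA)}
#' }
#' A bin straddling sub-regions of one gene takes the highest-precedence
#' category THREE_PRIME > FIVE_PRIME > GENE_BODY, so 3'-end assignments are
#' never diluted by the body. A bin overlapping several genes receives one
#' assignment per gene.
#'
#' @param bins A data.frame with columns `chrom`, `start`, `end`.
#' @param genes Collapsed gene models from [collapse_gene_models()] (raw
#'   [load_gene_models()] output is collapsed on the fly).
#' @param promoter_span Bases upstream of the TSS included in FIVE_PRIME
#'   (default 2000; 0 disables the upstream extension).
#' @return A data.frame with columns `bin` (row index into `bins`), `key`,
#'   `gene` (NA for intergenic), `region`.
#' @export
classify_bin_region <- function(bins, genes, promoter_span = 2000L) {
  if (!is.null(genes$tx_name)) genes <- collapse_gene_models(genes)
  empty <- data.frame(bin = integer(), key = character(), gene = character(),
                      region = character(), stringsAsFactors = FALSE)
  if (nrow(bins) == 0L) return(empty)
  fp <- .region_footprints(genes, as.integer(promoter_span))
  keys <- .bin_key(bins$chrom, bins$start)
  if (nrow(fp) > 0L) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(.as_granges(bins), .as_granges(fp)))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
  } else {
    q <- integer()
    s <- integer()
  }
  if (length(q) > 0L) {
    hit_df <- data.frame(bin = q, gene = fp$gene[s], region = fp$region[s],
                         precedence = fp$precedence[s], stringsAsFactors = FALSE)
    # one row per (bin, gene): the highest-precedence region wins
    ord <- order(hit_df$bin, hit_df$gene, hit_df$precedence)
    hit_df <- hit_df[ord, , drop = FALSE]
    keep <- !duplicated(hit_df[, c("bin", "gene")])
    hit_df <- hit_df[keep, , drop = FALSE]
    assigned <- unique(hit_df$bin)
  } else {
    hit_df <- NULL
    assigned <- integer()
  }
  inter <- setdiff(seq_len(nrow(bins)), assigned)
  res <- rbind(
    if (!is.null(hit_df))
      data.frame(bin = hit_df$bin, key = keys[hit_df$bin], gene = hit_df$gene,
                 region = hit_df$region, stringsAsFactors = FALSE),
    if (length(inter) > 0L)
      data.frame(bin = inter, key = keys[inter], gene = NA_character_,
                 region = "INTERGENIC", stringsAsFactors = FALSE)
  )
  res <- res[order(res$bin, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}
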