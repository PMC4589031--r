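# DMR calling between two binned profiles and eight-group classification.

#' Call differentially methylated bins between two profiles
#'
#' Compares bins passing the coverage filter in BOTH profiles and emits a
#' DMR for every bin whose methylation level differs by strictly more than
#' `threshold` percentage points. The orientation is a -> b (e.g. P0 -> P21
#' for a maturation contrast, ISC -> differentiated for a differentiation
#' contrast): `delta = level_b - level_a`, direction GAIN iff delta > 0.
#' No per-bin statistical test is attached: calling is the deterministic
#' threshold rule appropriate for pooled-sample methylomes.
#'
#' @param profile_a,profile_b [meth_profile()] objects binned with the same
#'   bin size.
#' @param threshold Minimum absolute difference in percentage points,
#'   exceeded strictly (default 15).
#' @param contrast `"mDMR"` (maturation, across ages) or `"dDMR"`
#'   (differentiation, across cell states).
#' @param merge_adjacent Merge runs of adjacent same-direction DMR bins
#'   into single regions (default FALSE: bin-level counting).
#' @return A data.frame of class `dmr_set` with columns `key`, `chrom`,
#'   `start`, `end`, `level_a`, `level_b`, `delta`, `direction`, and
#'   attributes `contrast` and `threshold`.
#' @export
call_dmrs <- function(profile_a, profile_b, threshold = 15,
                      contrast = c("mDMR", "dDMR"), merge_adjacent = FALSE) {
  contrast <- match.arg(contrast)
  .assert(threshold >= 0, "threshold must be >= 0")
  a <- profile_a$bins[profile_a$bins$passes_filter, , drop = FALSE]
  b <- profile_b$bins[profile_b$bins$passes_filter, , drop = FALSE]
  size_a <- unique(a$end - a$start)
  size_b <- unique(b$end - b$start)
  if (length(size_a) == 1L && length(size_b) == 1L && size_a != size_b) {
    .stopf("profiles binned at different bin sizes (%d vs %d)", size_a, size_b)
  }
  m <- merge(a[, c("key", "chrom", "start", "end", "level")],
             b[, c("key", "level")], by = "key",
             suffixes = c("_a", "_b"))
  m$delta <- m$level_b - m$level_a
  m <- m[abs(m$delta) > threshold, , drop = FALSE]
  m$direction <- ifelse(m$delta > 0, "GAIN", "LOSS")
  m <- m[order(m$chrom, m$start), , drop = FALSE]
  rownames(m) <- NULL

  if (merge_adjacent && nrow(m) > 1L) {
    bin_size <- m$end[1L] - m$start[1L]
    new_run <- c(TRUE, !(m$chrom[-1L] == m$chrom[-nrow(m)] &
                           m$start[-1L] == m$end[-nrow(m)] &
                           m$direction[-1L] == m$direction[-nrow(m)]))
    run <- cumsum(new_run)
    m <- do.call(rbind, lapply(split(m, run), function(g) {
      data.frame(key = g$key[1L], chrom = g$chrom[1L], start = min(g$start),
                 end = max(g$end), level_a = mean(g$level_a),
                 level_b = mean(g$level_b), delta = mean(g$delta),
                 direction = g$direction[1L], stringsAsFactors = FALSE)
    }))
    rownames(m) <- NULL
  }
  structure(m, class = c("dmr_set", "data.frame"),
            contrast = contrast, threshold = threshold)
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("<dmr_set> %s, |delta| > %s: %d DMRs (%d gain, %d loss)\n",
              attr(x, "contrast"), format(attr(x, "threshold")), nrow(x),
              sum(x$direction == "GAIN"), sum(x$direction == "LOSS")))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Annotate DMRs with CGI status and gene-region assignments
#'
#' Adds CGI status per bin and expands each DMR into one row per
#' overlapping gene with its region category (multi-gene assignment: a bin
#' overlapping several genes contributes to each). Bins overlapping no gene
#' are kept with `gene = NA`, `region = "INTERGENIC"`.
#'
#' @param dmrs A `dmr_set` from [call_dmrs()].
#' @param cgis Output of [load_cgis()].
#' @param genes Gene models ([load_gene_models()] or collapsed).
#' @param promoter_span Passed to [classify_bin_region()].
#' @return A data.frame of class `dmr_annotated`: the `dmr_set` columns
#'   plus `cgi`, `gene`, `region`, one row per (bin, gene) assignment.
#' @export
annotate_dmrs <- function(dmrs, cgis, genes, promoter_span = 2000L) {
  df <- as.data.frame(dmrs)
  if (nrow(df) == 0L) {
    df$cgi <- character()
    df$gene <- character()
    df$region <- character()
    return(structure(df, class = c("dmr_annotated", "data.frame"),
                     contrast = attr(dmrs, "contrast"),
                     threshold = attr(dmrs, "threshold")))
  }
  df$cgi <- cgi_status(df, cgis)
  assign <- classify_bin_region(df, genes, promoter_span)
  out <- df[assign$bin, , drop = FALSE]
  out$gene <- assign$gene
  out$region <- assign$region
  rownames(out) <- NULL
  structure(out, class = c("dmr_annotated", "data.frame"),
            contrast = attr(dmrs, "contrast"),
            threshold = attr(dmrs, "threshold"))
}

.eight_groups <- data.frame(
  direction = c("GAIN", "GAIN", "LOSS", "LOSS", "GAIN", "GAIN", "LOSS", "LOSS"),
  cgi = c("CGI", "CGI", "CGI", "CGI", "NON_CGI", "NON_CGI", "NON_CGI", "NON_CGI"),
  cell = c("five_prime", "body_or_3prime", "five_prime", "body_or_3prime",
           "five_prime", "body_or_3prime", "five_prime", "body_or_3prime"),
  group = c("gain at 5' CGI", "gain at gene body or 3' CGI",
            "loss at 5' CGI", "loss at gene body or 3' CGI",
            "gain at 5' non-CGI", "gain at gene body or 3' non-CGI",
            "loss at 5' non-CGI", "loss at gene body or 3' non-CGI"),
  stringsAsFactors = FALSE
)

.group_cell <- function(region) {
  ifelse(region == "FIVE_PRIME", "five_prime", "body_or_3prime")
}

#' Classify gene-associated DMRs into the eight groups
#'
#' Gene-associated DMR assignments are partitioned by direction
#' (gain/loss) x CGI status x gene-region cell, where FIVE_PRIME forms the
#' "5'" cell and GENE_BODY and THREE_PRIME pool into the "gene body or 3'"
#' cell. Intergenic assignments contribute to no group.
#'
#' @param dmrs A `dmr_annotated` data.frame from [annotate_dmrs()].
#' @return A data.frame with the eight groups in canonical order and a
#'   `count` column; counts partition the gene-associated assignments.
#' @export
classify_eight_groups <- function(dmrs) {
  needed <- c("direction", "cgi", "region")
  missing_cols <- setdiff(needed, names(dmrs))
  .assert(length(missing_cols) == 0L, "DMRs missing annotation columns: %s",
          paste(missing_cols, collapse = ", "))
  .assert(!anyNA(dmrs$cgi) && !anyNA(dmrs$region) && !anyNA(dmrs$direction),
          "DMR annotation contains missing values")
  d <- dmrs[dmrs$region != "INTERGENIC", , drop = FALSE]
  out <- .eight_groups
  if (nrow(d) == 0L) {
    out$count <- 0L
    return(out)
  }
  cell <- .group_cell(d$region)
  lbl <- paste(d$direction, d$cgi, cell, sep = "\r")
  ref <- paste(out$direction, out$cgi, out$cell, sep = "\r")
  out$count <- as.integer(table(factor(lbl, levels = ref)))
  out
}

#' Gene lists per DMR group
#'
#' Deduplicated gene sets for each of the eight groups; a gene with DMRs in
#' two groups appears in both.
#'
#' @param dmrs A `dmr_annotated` data.frame.
#' @return Named list of character vectors, one per group (canonical order).
#' @export
dmr_gene_lists <- function(dmrs) {
  out <- stats::setNames(vector("list", nrow(.eight_groups)), .eight_groups$group)
  for (i in seq_along(out)) out[[i]] <- character()
  d <- dmrs[!is.na(dmrs$gene) & dmrs$region != "INTERGENIC", , drop = FALSE]
  if (nrow(d) > 0L) {
    lbl <- paste(d$direction, d$cgi, .group_cell(d$region), sep = "\r")
    ref <- paste(.eight_groups$direction, .eight_groups$cgi,
                 .eight_groups$cell, sep = "\r")
    sets <- split(d$gene, factor(lbl, levels = ref))
    for (i in seq_along(out)) out[[i]] <- sort(unique(sets[[i]]))
  }
  out
}

#' Percentage overlap between two gene lists
#'
#' Reports the shared gene count, the size of the first list, and the
#' integer percentage floor(100 * |A intersect B| / |A|) -- the convention
#' behind statements like "7 % (41/517)".
#'
#' @param list_a,list_b Character vectors of gene names; `list_a` is the
#'   denominator and must be non-empty.
#' @return A list with `shared`, `n_a`, `percent`.
#' @export
overlap_percentage <- function(list_a, list_b) {
  a <- unique(list_a)
  .assert(length(a) > 0L, "list_a is empty; overlap percentage undefined")
  shared <- length(intersect(a, unique(list_b)))
  list(shared = shared, n_a = length(a),
       percent = as.integer(floor(100 * shared / length(a))))
}

#' Write annotated DMRs as a BED6+ track
#'
#' One record per (bin, gene) assignment; name = eight-group label (or
#' "intergenic"), score = |delta| capped at 1000, strand = ".".
#'
#' @param dmrs A `dmr_annotated` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  d <- as.data.frame(dmrs)
  name <- rep("intergenic", nrow(d))
  gene_assoc <- d$region != "INTERGENIC"
  if (any(gene_assoc)) {
    lbl <- paste(d$direction[gene_assoc], d$cgi[gene_assoc],
                 .group_cell(d$region[gene_assoc]), sep = "\r")
    ref <- paste(.eight_groups$direction, .eight_groups$cgi,
                 .eight_groups$cell, sep = "\r")
    name[gene_assoc] <- gsub(" ", "_", .eight_groups$group[match(lbl, ref)])
  }
  bed <- data.frame(chrom = d$chrom, start = d$start, end = d$end,
                    name = name, score = pmin(1000, round(abs(d$delta), 1)),
                    strand = ".", stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
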