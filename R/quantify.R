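# Per-CpG count parsing and 200-bp bin methylation quantification.

#' Read per-CpG bisulfite call counts
#'
#' Parses either the Bismark coverage dialect (chrom, start, end, percent,
#' count_methylated, count_unmethylated; 1-based, start == end) or the
#' bedGraph+2 dialect (same columns, 0-based half-open, end == start + 1).
#' The dialect is auto-detected from the start/end relationship. Since CpG
#' methylation is symmetric, calls landing on the G of the reverse strand
#' (position + 1) are by default folded into the forward-strand C record.
#'
#' @param x Path to a coverage file (gzip transparent), or a character
#'   vector of lines.
#' @param merge_strands Fold reverse-strand records at pos+1 into the
#'   forward-strand CpG record (default TRUE). Use FALSE for inputs already
#'   strand-merged.
#' @return A data.frame with columns `chrom`, `pos` (0-based coordinate of
#'   the forward-strand C), `meth`, `unmeth`, sorted by (chrom, pos).
#' @export
read_cpg_counts <- function(x, merge_strands = TRUE) {
  lines <- .read_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "numeric", "integer", "integer"),
                          col.names = c("chrom", "start", "end", "pct",
                                        "meth", "unmeth"))
  if (any(df$meth < 0L) || any(df$unmeth < 0L)) {
    .stopf("negative call counts in coverage input")
  }
  one_based <- all(df$start == df$end)
  pos <- if (one_based) df$start - 1L else df$start
  out <- data.frame(chrom = df$chrom, pos = pos,
                    meth = df$meth, unmeth = df$unmeth,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]

  if (merge_strands && nrow(out) > 1L) {
    # within a run of records at consecutive positions, odd offsets are
    # G-strand records of the CpG starting one base earlier
    consec <- c(FALSE, out$chrom[-1L] == out$chrom[-nrow(out)] &
                         out$pos[-1L] == out$pos[-nrow(out)] + 1L)
    run_id <- cumsum(!consec)
    offset <- stats::ave(seq_len(nrow(out)), run_id, FUN = seq_along) - 1L
    is_g <- offset %% 2L == 1L
    if (any(is_g)) {
      out$pos[is_g] <- out$pos[is_g] - 1L
      agg <- rowsum(cbind(meth = out$meth, unmeth = out$unmeth),
                    group = paste0(out$chrom, "\r", out$pos), reorder = FALSE)
      first <- !duplicated(paste0(out$chrom, "\r", out$pos))
      out <- data.frame(chrom = out$chrom[first], pos = out$pos[first],
                        meth = unname(agg[, "meth"]),
                        unmeth = unname(agg[, "unmeth"]),
                        stringsAsFactors = FALSE)
      out <- out[order(out$chrom, out$pos), , drop = FALSE]
    }
  }
  dup <- duplicated(paste0(out$chrom, "\r", out$pos))
  if (any(dup)) {
    warning(sprintf("%d duplicate CpG positions after merge; counts summed",
                    sum(dup)), call. = FALSE)
    agg <- rowsum(cbind(meth = out$meth, unmeth = out$unmeth),
                  group = paste0(out$chrom, "\r", out$pos), reorder = FALSE)
    first <- !dup
    out <- data.frame(chrom = out$chrom[first], pos = out$pos[first],
                      meth = unname(agg[, "meth"]),
                      unmeth = unname(agg[, "unmeth"]),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Aggregate CpG counts into fixed genomic bins
#'
#' Tiles each chromosome with fixed-phase bins of `bin_size` bases anchored
#' at coordinate 0; a CpG at position p belongs to bin floor(p / bin_size).
#' The bin methylation level is the percentage of methylated calls among
#' all calls in the bin. A bin passes the analysis filter iff it contains
#' at least `min_cpgs` covered CpG sites and at least `min_calls` total
#' calls. Bins containing no covered CpG are omitted (absence of data is
#' not hypomethylation).
#'
#' @param sites Output of [read_cpg_counts()].
#' @param bin_size Bin width in bases (default 200, near-nucleosomal).
#' @param min_cpgs Minimum covered CpG sites per bin (default 2).
#' @param min_calls Minimum total calls per bin (default 10).
#' @return A data.frame with columns `chrom`, `start`, `end`, `key`,
#'   `n_cpgs`, `meth_calls`, `total_calls`, `level`, `passes_filter`.
#' @export
bin_methylation <- function(sites, bin_size = 200L, min_cpgs = 2L,
                            min_calls = 10L) {
  .assert(bin_size > 0, "bin_size must be positive")
  covered <- sites$meth + sites$unmeth >= 1L
  sites <- sites[covered, , drop = FALSE]
  if (nrow(sites) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      key = character(), n_cpgs = integer(),
                      meth_calls = integer(), total_calls = integer(),
                      level = numeric(), passes_filter = logical(),
                      stringsAsFactors = FALSE))
  }
  bin_start <- (sites$pos %/% bin_size) * bin_size
  grp <- paste0(sites$chrom, "\r", bin_start)
  agg <- rowsum(cbind(n_cpgs = 1L, meth_calls = sites$meth,
                      total_calls = sites$meth + sites$unmeth),
                group = grp, reorder = FALSE)
  first <- !duplicated(grp)
  out <- data.frame(chrom = sites$chrom[first], start = bin_start[first],
                    stringsAsFactors = FALSE)
  out$end <- out$start + bin_size
  out$key <- .bin_key(out$chrom, out$start)
  out$n_cpgs <- unname(agg[, "n_cpgs"])
  out$meth_calls <- unname(agg[, "meth_calls"])
  out$total_calls <- unname(agg[, "total_calls"])
  out$level <- 100 * out$meth_calls / out$total_calls
  out$passes_filter <- out$n_cpgs >= min_cpgs & out$total_calls >= min_calls
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a per-sample methylation profile
#'
#' Bundles a binned methylation table with sample metadata. The bin table
#' is keyed by (chrom, start); duplicate keys are rejected.
#'
#' @param bins Output of [bin_methylation()].
#' @param sample_id Sample identifier.
#' @param age Age label (e.g. "P0", "P21").
#' @param cell_type Cell-type label (e.g. "ISC", "diff").
#' @return An object of class `meth_profile`.
#' @export
meth_profile <- function(bins, sample_id, age = NA_character_,
                         cell_type = NA_character_) {
  .assert(!anyDuplicated(bins$key), "duplicate bin keys in profile")
  structure(list(sample_id = sample_id, age = age, cell_type = cell_type,
                 bins = bins),
            class = "meth_profile")
}

#' @export
print.meth_profile <- function(x, ...) {
  cat(sprintf("<meth_profile> sample=%s age=%s cell_type=%s\n",
              x$sample_id, x$age, x$cell_type))
  cat(sprintf("  %d bins covered, %d passing the >=%s-CpG/>=%s-call filter\n",
              nrow(x$bins), sum(x$bins$passes_filter), "2", "10"))
  invisible(x)
}

#' Global methylation level of a profile
#'
#' Site mode pools calls over all passing bins (percentage of methylated
#' calls genome-wide); bin mode takes the unweighted mean of passing bin
#' levels. Site mode is the default, matching a per-CpG-call global
#' average; bin mode matches analyses that use the bin as the unit.
#'
#' @param profile A [meth_profile()].
#' @param mode `"site"` (call-weighted) or `"bin"` (unweighted over bins).
#' @return Percent methylation in \[0, 100\].
#' @export
global_methylation <- function(profile, mode = c("site", "bin")) {
  mode <- match.arg(mode)
  b <- profile$bins[profile$bins$passes_filter, , drop = FALSE]
  .assert(nrow(b) > 0L, "no bins pass the filter; global methylation undefined")
  if (mode == "site") {
    100 * sum(b$meth_calls) / sum(b$total_calls)
  } else {
    mean(b$level)
  }
}

#' Mean methylation of a bin category
#'
#' The methylation level of a gene or CGI category is the unweighted mean
#' of the levels of its associated passing bins.
#'
#' @param profile A [meth_profile()].
#' @param members Character vector of bin keys ("chrom:start").
#' @return A list with `mean` (percent) and `n` (contributing bins).
#' @export
category_mean <- function(profile, members) {
  .assert(length(members) > 0L, "empty member set")
  b <- profile$bins
  sel <- b$passes_filter & b$key %in% members
  .assert(any(sel), "no passing bins among members; category mean undefined")
  list(mean = mean(b$level[sel]), n = sum(sel))
}

#' Write a bin methylation table
#'
#' Tab-separated with columns chrom, start, end, n_cpgs, meth_calls,
#' total_calls, level, passes_filter.
#'
#' @param bins Output of [bin_methylation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bin_table <- function(bins, path) {
  utils::write.table(
    bins[, c("chrom", "start", "end", "n_cpgs", "meth_calls", "total_calls",
             "level", "passes_filter")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
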