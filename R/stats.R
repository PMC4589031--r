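# Statistical layer: bin-unit proportion test, Fisher gene-set enrichment,
# t tests, age-adjusted regression, BH FDR, hierarchical clustering.

#' Global methylation difference test with bins as units
#'
#' Tests whether one profile is globally more methylated than the other,
#' with the 200-bp bin as the unit of observation. The default "sign"
#' variant scores each mutually passing bin as a Bernoulli trial (success =
#' level_a > level_b, exact ties dropped) and tests p = 0.5: exact binomial
#' for up to 1000 informative bins, normal approximation with continuity
#' correction beyond. The "pooled" variant instead runs a two-proportion
#' test on methylated-call totals pooled over mutually passing bins.
#'
#' @param profile_a,profile_b [meth_profile()] objects.
#' @param variant `"sign"` (default) or `"pooled"`.
#' @return A list with `statistic` (proportion of informative bins higher
#'   in a, or pooled proportions), `p_value`, `n_bins`, `n_ties`, `method`.
#' @export
global_proportion_test <- function(profile_a, profile_b,
                                   variant = c("sign", "pooled")) {
  variant <- match.arg(variant)
  a <- profile_a$bins[profile_a$bins$passes_filter, , drop = FALSE]
  b <- profile_b$bins[profile_b$bins$passes_filter, , drop = FALSE]
  m <- merge(a[, c("key", "meth_calls", "total_calls", "level")],
             b[, c("key", "meth_calls", "total_calls", "level")],
             by = "key", suffixes = c("_a", "_b"))
  .assert(nrow(m) >= 30L, "fewer than 30 mutually passing bins (%d)", nrow(m))
  if (variant == "sign") {
    wins_a <- sum(m$level_a > m$level_b)
    wins_b <- sum(m$level_b > m$level_a)
    ties <- nrow(m) - wins_a - wins_b
    n <- wins_a + wins_b
    .assert(n >= 2L, "fewer than 2 informative (untied) bins")
    if (n <= 1000L) {
      p <- stats::binom.test(wins_a, n, p = 0.5)$p.value
      method <- "exact binomial sign test on per-bin direction"
    } else {
      z <- (abs(wins_a - n / 2) - 0.5) / sqrt(n / 4)
      p <- 2 * stats::pnorm(-z)
      method <- "normal-approximation sign test with continuity correction"
    }
    list(statistic = wins_a / n, p_value = p, n_bins = n, n_ties = ties,
         method = method)
  } else {
    ht <- stats::prop.test(c(sum(m$meth_calls_a), sum(m$meth_calls_b)),
                           c(sum(m$total_calls_a), sum(m$total_calls_b)))
    list(statistic = unname(ht$estimate), p_value = ht$p.value,
         n_bins = nrow(m), n_ties = 0L,
         method = "two-proportion test on pooled calls over mutual bins")
  }
}

# Two-sided Fisher p for one 2x2 table with margins (K, N-K) x (n, N-n),
# observed in-term DMR count k: sum of hypergeometric probabilities of all
# tables at most as likely as the observed one (minimum-likelihood rule).
.fisher_two_sided <- function(k, K, n, N) {
  supp <- max(0L, n + K - N):min(K, n)
  d <- stats::dhyper(supp, K, N - K, n)
  obs <- d[match(k, supp)]
  # relative tolerance guards against ties broken by floating-point noise;
  # the sum can exceed 1 by rounding when the observed table is the mode
  min(1, sum(d[d <= obs * (1 + 1e-07)]))
}

#' Gene-set enrichment by Fisher's exact test with Bonferroni correction
#'
#' For each term, tests the 2x2 table (in term / not in term) x (DMR gene /
#' other universe gene) with a two-sided Fisher exact test (minimum-
#' likelihood rule); p values are Bonferroni-adjusted over the number of
#' terms actually tested. Gene sets and DMR genes are restricted to the
#' universe before testing.
#'
#' @param dmr_genes Character vector of DMR-associated genes.
#' @param gene_sets Named list of character vectors (term -> genes), e.g.
#'   from [read_gmt()].
#' @param universe Character vector: all genes eligible for testing.
#' @return A data.frame of class `enrichment_result`, sorted by p, with
#'   columns `term`, `k` (DMR genes in term), `K` (term size), `n` (DMR
#'   genes in universe), `N` (universe size), `odds_ratio`, `p`, `p_bonf`.
#' @export
fisher_enrichment <- function(dmr_genes, gene_sets, universe) {
  universe <- unique(universe)
  .assert(length(universe) > 0L, "empty gene universe")
  dmr <- intersect(unique(dmr_genes), universe)
  N <- length(universe)
  n <- length(dmr)
  terms <- names(gene_sets)
  rows <- vector("list", length(gene_sets))
  for (i in seq_along(gene_sets)) {
    term_genes <- intersect(unique(gene_sets[[i]]), universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, dmr))
    p <- .fisher_two_sided(k, K, n, N)
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    rows[[i]] <- data.frame(term = terms[i], k = k, K = K, n = n, N = N,
                            odds_ratio = or, p = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$p_bonf <- pmin(1, res$p * nrow(res))
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}

#' Two-sample Student t test
#'
#' Two-tailed pooled-variance t test (classic Student), the convention for
#' candidate-gene group comparisons; Welch's unequal-variance form is
#' available by flag.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @param var_equal Pooled variance (TRUE, default) or Welch (FALSE).
#' @return A list with `t`, `df`, `p_value`.
#' @export
two_sample_ttest <- function(x, y, var_equal = TRUE) {
  .assert(length(x) >= 2L && length(y) >= 2L,
          "each group needs at least 2 values")
  pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  .assert(pooled_var > 0, "degenerate (zero) variance; t test undefined")
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Age-adjusted methylation-expression regression
#'
#' Ordinary least squares of expression on methylation with age (days) as a
#' covariate: expression ~ methylation + age. Returns the methylation
#' partial coefficient, its two-sided p value, and the direction of the
#' association. Age may optionally enter as log(age + 1).
#'
#' @param series A data.frame with columns `age` (days, >= 0),
#'   `methylation` (percent), `expression` (relative units); at least 4
#'   observations.
#' @param log_age Use log(age + 1) instead of age (default FALSE).
#' @return A list with `coefficient`, `se`, `p_value`, `direction`
#'   ("positive"/"negative"), `n`.
#' @export
age_adjusted_regression <- function(series, log_age = FALSE) {
  needed <- c("age", "methylation", "expression")
  .assert(all(needed %in% names(series)), "series needs columns %s",
          paste(needed, collapse = ", "))
  .assert(nrow(series) >= 4L, "need at least 4 observations, got %d",
          nrow(series))
  .assert(all(series$age >= 0), "ages must be non-negative")
  age <- if (log_age) log(series$age + 1) else series$age
  X <- cbind(1, series$methylation, age)
  .assert(qr(X)$rank == 3L,
          "degenerate design: methylation collinear with age/intercept")
  .assert(kappa(scale(X[, -1L], center = TRUE, scale = TRUE)) < 1e8,
          "degenerate design: condition number guard tripped")
  fit <- stats::lm(expression ~ methylation + age_v,
                   data = data.frame(expression = series$expression,
                                     methylation = series$methylation,
                                     age_v = age))
  sm <- summary(fit)$coefficients
  list(coefficient = sm["methylation", "Estimate"],
       se = sm["methylation", "Std. Error"],
       p_value = sm["methylation", "Pr(>|t|)"],
       direction = if (sm["methylation", "Estimate"] >= 0) "positive" else "negative",
       n = nrow(series))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' input order is preserved in the output.
#'
#' @param pvalues Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  .assert(all(!is.na(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
          "p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Read gene sets in GMT format
#'
#' Each line: term, description, then one gene per tab-separated field.
#'
#' @param x Path to a GMT file, or a character vector of lines.
#' @return Named list of character vectors (term -> genes).
#' @export
read_gmt <- function(x) {
  lines <- .read_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t")
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    .stopf("malformed GMT line %d: need term, description, >=1 gene", bad[1L])
  }
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1L))
}

#' Construct a CpG-panel methylation matrix
#'
#' A rectangular CpG-site x sample matrix of percent methylation with per-
#' sample age and condition labels, the substrate for developmental-panel
#' clustering and condition comparison.
#'
#' @param values Numeric matrix (rows = CpG sites, columns = samples),
#'   values in \[0, 100\], no missing entries.
#' @param age Character vector of per-sample age labels.
#' @param condition Character vector of per-sample condition labels.
#' @return An object of class `sample_panel`.
#' @export
sample_panel <- function(values, age, condition) {
  values <- as.matrix(values)
  .assert(!anyNA(values), "panel contains missing values")
  .assert(ncol(values) == length(age) && ncol(values) == length(condition),
          "age/condition labels must match the number of samples")
  .assert(all(values >= 0 & values <= 100), "panel values must be percent in [0, 100]")
  structure(list(values = values, age = as.character(age),
                 condition = as.character(condition)),
            class = "sample_panel")
}

#' @export
print.sample_panel <- function(x, ...) {
  cat(sprintf("<sample_panel> %d CpG sites x %d samples; ages: %s; conditions: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$age), collapse = ", "),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Read a CpG panel from TSV
#'
#' Expects a header row `site<TAB>sample ids...`, a second row
#' `meta<TAB>age|condition...`, then one row per CpG site.
#'
#' @param x Path to a panel TSV, or a character vector of lines.
#' @return A [sample_panel()].
#' @export
read_panel <- function(x) {
  lines <- .read_lines(x)
  lines <- lines[nzchar(lines)]
  .assert(length(lines) >= 3L, "panel needs two header rows and >= 1 site row")
  hdr <- strsplit(lines[1L], "\t")[[1L]]
  meta <- strsplit(lines[2L], "\t")[[1L]]
  .assert(length(meta) == length(hdr), "panel header rows have unequal width")
  parts <- strsplit(meta[-1L], "|", fixed = TRUE)
  .assert(all(lengths(parts) == 2L),
          "second header row must hold age|condition per sample")
  body <- strsplit(lines[-(1:2)], "\t")
  .assert(all(lengths(body) == length(hdr)), "ragged panel rows")
  vals <- t(vapply(body, function(f) as.numeric(f[-1L]),
                   numeric(length(hdr) - 1L)))
  rownames(vals) <- vapply(body, `[[`, "", 1L)
  colnames(vals) <- hdr[-1L]
  sample_panel(vals, age = vapply(parts, `[[`, "", 1L),
               condition = vapply(parts, `[[`, "", 2L))
}

#' Write a CpG panel as TSV
#'
#' Inverse of [read_panel()].
#'
#' @param panel A [sample_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  hdr <- paste(c("site", colnames(panel$values)), collapse = "\t")
  meta <- paste(c("meta", paste(panel$age, panel$condition, sep = "|")),
                collapse = "\t")
  body <- vapply(seq_len(nrow(panel$values)), function(i) {
    paste(c(rownames(panel$values)[i],
            format(panel$values[i, ], trim = TRUE)), collapse = "\t")
  }, "")
  writeLines(c(hdr, meta, body), path)
  invisible(path)
}

#' Unsupervised hierarchical clustering of a CpG panel
#'
#' Agglomerative clustering with Euclidean distance and average linkage by
#' default (both configurable), over samples or over CpG sites. Leaf order
#' is deterministic: ties in merge height are resolved by original input
#' index (the behaviour of [stats::hclust()]).
#'
#' @param panel A [sample_panel()] or a numeric matrix (rows = sites).
#' @param axis Cluster `"samples"` (columns) or `"sites"` (rows).
#' @param distance Distance measure for [stats::dist()] (default
#'   "euclidean").
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   "average").
#' @param standardize Z-score each CpG site row before distances (default
#'   FALSE: raw percent scale).
#' @return A list with `tree` (an `hclust`), `order` (leaf labels in
#'   dendrogram order), and the clustering metadata.
#' @export
hierarchical_cluster <- function(panel, axis = c("samples", "sites"),
                                 distance = "euclidean", linkage = "average",
                                 standardize = FALSE) {
  axis <- match.arg(axis)
  mat <- if (inherits(panel, "sample_panel")) panel$values else as.matrix(panel)
  if (standardize) {
    sds <- apply(mat, 1L, stats::sd)
    sds[sds == 0] <- 1  # constant rows contribute zero signal, not NaN
    mat <- (mat - rowMeans(mat)) / sds
  }
  items <- if (axis == "samples") t(mat) else mat
  .assert(nrow(items) >= 2L, "need >= 2 items on the clustered axis")
  if (is.null(rownames(items))) rownames(items) <- seq_len(nrow(items))
  d <- stats::dist(items, method = distance)
  tree <- stats::hclust(d, method = linkage)
  list(tree = tree, order = rownames(items)[tree$order], axis = axis,
       distance = distance, linkage = linkage, standardize = standardize)
}

#' Cut a panel clustering into k groups
#'
#' Thin wrapper over [stats::cutree()] returning cluster ids in input item
#' order.
#'
#' @param clustering Output of [hierarchical_cluster()].
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(clustering, k) {
  stats::cutree(clustering$tree, k = k)
}
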