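# Orchestration: configuration-driven end-to-end runs with a JSON report.

#' Build a validated pipeline run configuration
#'
#' Collects input paths, sample metadata and analysis parameters for
#' [run_dmr_analysis()] / [run_panel_analysis()]. All referenced paths must
#' exist at validation time.
#'
#' @param samples data.frame with columns `file` (coverage file),
#'   `sample_id`, `age`, `age_day` (numeric, orders the ages), `cell_type`.
#'   Required for the DMR analysis.
#' @param cgi_bed Path to the CGI BED file.
#' @param refflat Path to the refFlat gene-model table.
#' @param gmt Optional path to a GMT gene-set file (enrichment is skipped
#'   without it).
#' @param expression Optional path to an expression TSV with header columns
#'   gene, age, methylation, expression.
#' @param panel Optional path to a CpG-panel TSV ([read_panel()] format).
#' @param out_dir Output directory (created if absent).
#' @param bin_size,min_cpgs,min_calls Bin quantification parameters.
#' @param dmr_threshold DMR calling threshold (percentage points).
#' @param promoter_span FIVE_PRIME upstream extension (bases).
#' @param proportion_variant Variant for [global_proportion_test()].
#' @param clust_distance,clust_linkage Panel clustering parameters.
#' @param fdr_alpha Significance level on BH-adjusted p values.
#' @param seed Integer seed recorded in provenance.
#' @return A list of class `run_config`.
#' @export
run_config <- function(samples = NULL, cgi_bed = NULL, refflat = NULL,
                       gmt = NULL, expression = NULL, panel = NULL,
                       out_dir = tempfile("methbin_run_"),
                       bin_size = 200L, min_cpgs = 2L, min_calls = 10L,
                       dmr_threshold = 15, promoter_span = 2000L,
                       proportion_variant = "sign",
                       clust_distance = "euclidean",
                       clust_linkage = "average",
                       fdr_alpha = 0.05, seed = 1L) {
  for (p in c(cgi_bed, refflat, gmt, expression, panel)) {
    .assert(file.exists(p), "input path does not exist: %s", p)
  }
  if (!is.null(samples)) {
    needed <- c("file", "sample_id", "age", "age_day", "cell_type")
    .assert(all(needed %in% names(samples)),
            "samples needs columns %s", paste(needed, collapse = ", "))
    for (p in samples$file) .assert(file.exists(p), "coverage file missing: %s", p)
  }
  .assert(bin_size > 0 && min_cpgs >= 1 && min_calls >= 0 &&
            dmr_threshold >= 0 && promoter_span >= 0 && fdr_alpha > 0,
          "parameter out of documented range")
  structure(list(samples = samples, cgi_bed = cgi_bed, refflat = refflat,
                 gmt = gmt, expression = expression, panel = panel,
                 out_dir = out_dir, bin_size = as.integer(bin_size),
                 min_cpgs = as.integer(min_cpgs),
                 min_calls = as.integer(min_calls),
                 dmr_threshold = dmr_threshold,
                 promoter_span = as.integer(promoter_span),
                 proportion_variant = proportion_variant,
                 clust_distance = clust_distance,
                 clust_linkage = clust_linkage,
                 fdr_alpha = fdr_alpha, seed = as.integer(seed)),
            class = "run_config")
}

.provenance <- function(config) {
  pars <- config[setdiff(names(config),
                         c("samples", "cgi_bed", "refflat", "gmt",
                           "expression", "panel", "out_dir"))]
  list(parameters = pars, seed = config$seed,
       version = tryCatch(as.character(utils::packageVersion("methbin")),
                          error = function(e) "dev"))
}

# Enumerate the (a, b) profile pairs implied by the sample metadata:
# maturation within each cell type (earliest vs latest age), and
# differentiation within each age (first vs second cell type by appearance).
.plan_contrasts <- function(samples) {
  plan <- list()
  for (ct in unique(samples$cell_type)) {
    s <- samples[samples$cell_type == ct, , drop = FALSE]
    if (length(unique(s$age_day)) >= 2L) {
      a <- s$sample_id[which.min(s$age_day)]
      b <- s$sample_id[which.max(s$age_day)]
      plan[[paste0("mDMR_", ct)]] <- list(contrast = "mDMR", a = a, b = b,
                                          label = paste0(ct, ": ", s$age[which.min(s$age_day)],
                                                         " -> ", s$age[which.max(s$age_day)]))
    }
  }
  cts <- unique(samples$cell_type)
  if (length(cts) >= 2L) {
    for (ag in unique(samples$age)) {
      s <- samples[samples$age == ag, , drop = FALSE]
      if (all(cts[1:2] %in% s$cell_type)) {
        a <- s$sample_id[match(cts[1L], s$cell_type)]
        b <- s$sample_id[match(cts[2L], s$cell_type)]
        plan[[paste0("dDMR_", ag)]] <- list(contrast = "dDMR", a = a, b = b,
                                            label = paste0(ag, ": ", cts[1L],
                                                           " -> ", cts[2L]))
      }
    }
  }
  plan
}

#' Run the bin-based DMR analysis end to end
#'
#' Quantifies every sample into filtered 200-bp bins, forms maturation
#' (earliest vs latest age per cell type) and differentiation (between the
#' two cell types per age) contrasts, calls and annotates DMRs, tabulates
#' the eight CGI/region/direction groups, runs the bin-unit global
#' proportion test per maturation pair, gene-set enrichment when a GMT file
#' is supplied, and methylation-expression regression when an expression
#' table is supplied. All intermediate tables are written under
#' `config$out_dir`, along with `report.json`.
#'
#' @param config A [run_config()] with `samples`, `cgi_bed`, `refflat`.
#' @return The run report (list of class `run_report`), invisibly also
#'   written as JSON.
#' @export
run_dmr_analysis <- function(config) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  .assert(!is.null(config$samples), "DMR analysis needs sample metadata")
  plan <- .plan_contrasts(config$samples)
  .assert(length(plan) > 0L,
          "no contrast satisfiable from sample metadata (need two ages or two cell types)")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cgis <- load_cgis(config$cgi_bed)
  genes <- collapse_gene_models(load_gene_models(config$refflat))

  profiles <- list()
  global <- list()
  for (i in seq_len(nrow(config$samples))) {
    meta <- config$samples[i, ]
    sites <- read_cpg_counts(meta$file)
    bins <- bin_methylation(sites, config$bin_size, config$min_cpgs,
                            config$min_calls)
    prof <- meth_profile(bins, meta$sample_id, meta$age, meta$cell_type)
    profiles[[meta$sample_id]] <- prof
    write_bin_table(bins, file.path(config$out_dir,
                                    paste0(meta$sample_id, "_bins.tsv")))
    global[[meta$sample_id]] <- list(
      site_mode = global_methylation(prof, "site"),
      bin_mode = global_methylation(prof, "bin"),
      n_passing_bins = sum(bins$passes_filter))
    message(sprintf("[quantify] %s: %d bins covered, %d passing",
                    meta$sample_id, nrow(bins), sum(bins$passes_filter)))
  }

  contrasts <- list()
  proportion_tests <- list()
  all_dmr_genes <- list(mDMR = character(), dDMR = character())
  for (nm in names(plan)) {
    pl <- plan[[nm]]
    dmrs <- call_dmrs(profiles[[pl$a]], profiles[[pl$b]],
                      threshold = config$dmr_threshold, contrast = pl$contrast)
    ann <- annotate_dmrs(dmrs, cgis, genes, config$promoter_span)
    groups <- classify_eight_groups(ann)
    gl <- dmr_gene_lists(ann)
    write_dmr_bed(ann, file.path(config$out_dir, paste0(nm, "_dmrs.bed")))
    utils::write.table(groups[, c("group", "count")],
                       file.path(config$out_dir, paste0(nm, "_groups.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    contrasts[[nm]] <- list(contrast = pl$contrast, label = pl$label,
                            n_dmrs = nrow(dmrs),
                            n_gain = sum(dmrs$direction == "GAIN"),
                            n_loss = sum(dmrs$direction == "LOSS"),
                            eight_groups = groups,
                            gene_lists = gl)
    all_dmr_genes[[pl$contrast]] <- union(all_dmr_genes[[pl$contrast]],
                                          unlist(gl, use.names = FALSE))
    message(sprintf("[dmr] %s (%s): %d DMRs (%d gain / %d loss)", nm,
                    pl$label, nrow(dmrs), sum(dmrs$direction == "GAIN"),
                    sum(dmrs$direction == "LOSS")))
    if (pl$contrast == "mDMR") {
      proportion_tests[[nm]] <- global_proportion_test(
        profiles[[pl$a]], profiles[[pl$b]], config$proportion_variant)
    }
  }

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    universe <- unique(genes$gene)
    enrichment <- lapply(all_dmr_genes, function(g) {
      if (length(g) == 0L) return(NULL)
      res <- fisher_enrichment(g, sets, universe)
      as.data.frame(res)
    })
    for (ctr in names(enrichment)) {
      if (!is.null(enrichment[[ctr]])) {
        utils::write.table(enrichment[[ctr]],
                           file.path(config$out_dir,
                                     paste0("enrichment_", ctr, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  } else {
    message("[enrich] no GMT supplied; enrichment skipped")
  }

  regression <- NULL
  if (!is.null(config$expression)) {
    expr <- utils::read.table(config$expression, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    fits <- lapply(split(expr, expr$gene), function(s) {
      fit <- age_adjusted_regression(s)
      data.frame(gene = s$gene[1L], coefficient = fit$coefficient,
                 se = fit$se, p_value = fit$p_value,
                 direction = fit$direction, n = fit$n,
                 stringsAsFactors = FALSE)
    })
    regression <- do.call(rbind, fits)
    regression$p_bh <- bh_fdr(regression$p_value)
    regression <- regression[order(regression$p_value), , drop = FALSE]
    rownames(regression) <- NULL
    utils::write.table(regression,
                       file.path(config$out_dir, "regression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- structure(list(global_methylation = global,
                           contrasts = contrasts,
                           proportion_tests = proportion_tests,
                           enrichment = enrichment,
                           regression = regression,
                           provenance = .provenance(config)),
                      class = "run_report")
  .write_report(report, file.path(config$out_dir, "report.json"))
  report
}

#' Run the developmental-panel analysis
#'
#' Clusters the reference condition's samples and CpG sites (unsupervised,
#' Euclidean/average by default), applies the reference row and age order
#' to the comparison condition, and tests each CpG site between conditions
#' (two-tailed Student t over samples from post-baseline ages, BH FDR).
#' With a single condition the comparison section is skipped with a
#' warning.
#'
#' @param config A [run_config()] with `panel` set.
#' @param reference_condition Condition whose clustering defines the
#'   ordering (default: condition of the panel's first sample).
#' @return The run report (list of class `run_report`).
#' @export
run_panel_analysis <- function(config, reference_condition = NULL) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  .assert(!is.null(config$panel), "panel analysis needs a panel path")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- read_panel(config$panel)
  conds <- unique(panel$condition)
  ref_cond <- reference_condition %||% conds[1L]
  .assert(ref_cond %in% conds, "reference condition '%s' not in panel", ref_cond)

  subpanel <- function(cond) {
    keep <- panel$condition == cond
    sample_panel(panel$values[, keep, drop = FALSE], panel$age[keep],
                 panel$condition[keep])
  }
  ref <- subpanel(ref_cond)
  sample_clust <- hierarchical_cluster(ref, axis = "samples",
                                       distance = config$clust_distance,
                                       linkage = config$clust_linkage)
  site_clust <- hierarchical_cluster(ref, axis = "sites",
                                     distance = config$clust_distance,
                                     linkage = config$clust_linkage)
  age_order <- unique(ref$age[match(sample_clust$order, colnames(ref$values))])

  comparison <- NULL
  if (length(conds) >= 2L) {
    other_cond <- setdiff(conds, ref_cond)[1L]
    other <- subpanel(other_cond)
    .assert(identical(rownames(ref$values), rownames(other$values)),
            "panel conditions disagree on CpG sites")
    shared_ages <- intersect(unique(ref$age), unique(other$age))
    baseline_age <- shared_ages[order(.age_rank(shared_ages))][1L]
    post <- setdiff(shared_ages, baseline_age)
    use_ages <- if (length(post) > 0L) post else shared_ages
    x_idx <- ref$age %in% use_ages
    y_idx <- other$age %in% use_ages
    tests <- lapply(seq_len(nrow(ref$values)), function(i) {
      ht <- tryCatch(two_sample_ttest(ref$values[i, x_idx],
                                      other$values[i, y_idx]),
                     error = function(e) list(t = NA_real_, p_value = NA_real_))
      data.frame(site = rownames(ref$values)[i], t = ht$t,
                 mean_ref = mean(ref$values[i, x_idx]),
                 mean_other = mean(other$values[i, y_idx]),
                 p_value = ht$p_value, stringsAsFactors = FALSE)
    })
    cmp <- do.call(rbind, tests)
    ok <- !is.na(cmp$p_value)
    cmp$p_bh <- NA_real_
    cmp$p_bh[ok] <- bh_fdr(cmp$p_value[ok])
    cmp$significant <- !is.na(cmp$p_bh) & cmp$p_bh < config$fdr_alpha
    utils::write.table(cmp, file.path(config$out_dir, "panel_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comparison <- list(reference = ref_cond, other = other_cond,
                       ages_compared = use_ages, table = cmp)
  } else {
    warning("single condition in panel; comparison section skipped",
            call. = FALSE)
  }

  report <- structure(list(reference_condition = ref_cond,
                           sample_order = sample_clust$order,
                           site_order = site_clust$order,
                           age_order = age_order,
                           comparison = comparison,
                           provenance = .provenance(config)),
                      class = "run_report")
  .write_report(report, file.path(config$out_dir, "panel_report.json"))
  report
}

# Chronological rank of age labels like E18.5 / P0 / P21 / P100: the number
# in the label, with embryonic (E-prefixed) ages ordered before postnatal.
# Falls back to the given order when a label carries no number.
.age_rank <- function(labels) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]+", "", labels)))
  if (anyNA(num)) return(seq_along(labels))
  ifelse(grepl("^[Ee]", labels), num - 1e6, num)
}

.write_report <- function(report, path) {
  jsonlite::write_json(
    report, path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  if (!is.null(x$contrasts)) {
    cat("<run_report> DMR analysis\n")
    for (nm in names(x$global_methylation)) {
      cat(sprintf("  global methylation %-10s %.1f %% (site mode)\n", nm,
                  x$global_methylation[[nm]]$site_mode))
    }
    for (nm in names(x$contrasts)) {
      ctr <- x$contrasts[[nm]]
      cat(sprintf("  %-12s %4d DMRs (%d gain / %d loss)\n", nm,
                  ctr$n_dmrs, ctr$n_gain, ctr$n_loss))
    }
  } else {
    cat("<run_report> panel analysis\n")
    cat(sprintf("  age order: %s\n", paste(x$age_order, collapse = " < ")))
    if (!is.null(x$comparison)) {
      cat(sprintf("  %d/%d sites differ between %s and %s at FDR\n",
                  sum(x$comparison$table$significant, na.rm = TRUE),
                  nrow(x$comparison$table), x$comparison$reference,
                  x$comparison$other))
    }
  }
  invisible(x)
}
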