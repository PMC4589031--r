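# Synthetic-data generator: miniature CGI-structured genomes, beta-binomial
# per-CpG bisulfite counts with planted DMRs, methylation-coupled expression,
# and developmental CpG panels, each with ground truth.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale miniature methylome: 2 chromosomes x 2 Mb,
#' 200 genes, ~300 CpG islands, 20x mean coverage, CGI baseline 10 %
#' methylation versus 75 % elsewhere, and planted DMRs of |delta| = 30
#' percentage points whose composition mirrors the developmental signature
#' under study (CGI maturation gains concentrated at gene bodies and 3'
#' ends, non-CGI maturation losses at CGI shores, and a smaller
#' differentiation axis).
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_chroms,chrom_length Number and length (bases) of chromosomes.
#' @param n_genes Total genes, split evenly across chromosomes.
#' @param n_cgis Target CpG-island count (gene-anchored islands plus
#'   intergenic extras).
#' @param cpg_spacing Mean bases between CpGs outside CGIs.
#' @param cgi_cpg_spacing Mean bases between CpGs inside CGIs.
#' @param coverage_mean Expected calls per CpG (Poisson).
#' @param dispersion Beta-binomial overdispersion of per-CpG methylation in
#'   \[0, 1); 0 recovers pure binomial sampling.
#' @param baseline_noncgi,baseline_cgi Background percent methylation of the
#'   two compartments.
#' @param planted_dmrs data.frame(kind, direction, delta, contrast, n) of
#'   DMRs to plant; kinds: `cgi_5prime`, `cgi_body`, `cgi_3prime`,
#'   `noncgi_shore`; contrasts: `maturation`, `differentiation`.
#' @param ages Named numeric vector mapping age labels to days for the
#'   methylome samples (first element is the pre-change age).
#' @param expression_coupling Slope linking true 3' CGI methylation
#'   (percent) to expression of coupled genes.
#' @param expr_ages Named numeric vector of ages (days) for the
#'   expression/methylation time series.
#' @param expr_replicates Biological replicates per expression time point.
#' @param expr_noise_sd SD of Gaussian expression noise.
#' @param expr_meth_noise_sd SD (percent) of methylation measurement noise
#'   in the expression time series; 0 gives exact levels.
#' @param panel_ages Age labels for the CpG panel.
#' @param panel_samples_per_age Samples per age and condition in the panel.
#' @param panel_noise_sd Within-age SD (percent) of panel values.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_chroms = 2L,
                         chrom_length = 2e6,
                         n_genes = 200L,
                         n_cgis = 300L,
                         cpg_spacing = 20,
                         cgi_cpg_spacing = 8,
                         coverage_mean = 20,
                         dispersion = 0.01,
                         baseline_noncgi = 75,
                         baseline_cgi = 10,
                         planted_dmrs = NULL,
                         ages = c(P0 = 1, P21 = 22),
                         expression_coupling = 0.02,
                         expr_ages = c(E18.5 = 0, P0 = 1, P21 = 22,
                                       P100 = 101, P300 = 301),
                         expr_replicates = 3L,
                         expr_noise_sd = 0.05,
                         expr_meth_noise_sd = 2,
                         panel_ages = c("P0", "P21", "P100"),
                         panel_samples_per_age = 3L,
                         panel_noise_sd = 2) {
  if (is.null(planted_dmrs)) {
    planted_dmrs <- data.frame(
      kind = c("cgi_3prime", "cgi_body", "cgi_5prime", "cgi_5prime",
               "noncgi_shore", "noncgi_shore", "noncgi_shore", "cgi_3prime"),
      direction = c("GAIN", "GAIN", "GAIN", "LOSS",
                    "LOSS", "GAIN", "LOSS", "GAIN"),
      delta = 30,
      contrast = c("maturation", "maturation", "maturation", "maturation",
                   "maturation", "maturation", "differentiation",
                   "differentiation"),
      n = c(30L, 20L, 8L, 5L, 40L, 10L, 10L, 5L),
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              n_cgis = as.integer(n_cgis), cpg_spacing = cpg_spacing,
              cgi_cpg_spacing = cgi_cpg_spacing,
              coverage_mean = coverage_mean, dispersion = dispersion,
              baseline_noncgi = baseline_noncgi, baseline_cgi = baseline_cgi,
              planted_dmrs = planted_dmrs, ages = ages,
              expression_coupling = expression_coupling,
              expr_ages = expr_ages,
              expr_replicates = as.integer(expr_replicates),
              expr_noise_sd = expr_noise_sd,
              expr_meth_noise_sd = expr_meth_noise_sd,
              panel_ages = panel_ages,
              panel_samples_per_age = as.integer(panel_samples_per_age),
              panel_noise_sd = panel_noise_sd)
  .assert(cfg$chrom_length > 0 && cfg$coverage_mean >= 1,
          "chrom_length must be positive and coverage_mean >= 1")
  .assert(cfg$dispersion >= 0 && cfg$dispersion < 1,
          "dispersion must lie in [0, 1)")
  .assert(all(cfg$planted_dmrs$delta > 0 & cfg$planted_dmrs$delta < 100),
          "planted deltas must lie in (0, 100)")
  .assert(length(cfg$ages) >= 2L, "need at least two ages")
  structure(cfg, class = "synth_config")
}

#' Generate a miniature genome annotation
#'
#' Places non-overlapping multi-exon genes in regular slots along each
#' chromosome and attaches CpG islands preferentially to gene 5' and 3'
#' ends (plus some gene-body and intergenic islands), so that every planted
#' DMR kind has candidate locations. Deterministic given the config seed.
#'
#' @param config A [synth_config()].
#' @return A list with `genes` (a [load_gene_models()]-shaped data.frame)
#'   and `cgis` (data.frame chrom/start/end/id/role/gene; `role` records
#'   the anchoring: five_prime / three_prime / body / extra).
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  gpc <- config$n_genes %/% config$n_chroms
  slot <- floor(config$chrom_length / max(gpc, 1L))
  .assert(slot >= 20000L,
          "infeasible packing: %d genes per %g-base chromosome", gpc,
          config$chrom_length)
  genes <- vector("list", config$n_genes)
  cgis <- list()
  gi <- 0L
  for (ch in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ch)
    for (s in seq_len(gpc)) {
      gi <- gi + 1L
      slot_start <- (s - 1L) * slot
      len <- round(stats::runif(1, 6000, 12000))
      tx_start <- as.integer(slot_start + 4000 +
                               round(stats::runif(1, 0, slot - len - 8000)))
      tx_end <- as.integer(tx_start + len)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(3:7, 1L)
      ex_len <- round(stats::runif(n_ex, 250, 500))
      gap_total <- len - sum(ex_len)
      w <- stats::runif(n_ex - 1L, 0.5, 1.5)
      gaps <- floor(gap_total * w / sum(w))
      ex_s <- tx_start + cumsum(c(0L, ex_len[-n_ex] + gaps))
      ex_e <- ex_s + ex_len
      ex_e[n_ex] <- min(ex_e[n_ex], tx_end)
      cds_start <- as.integer(ex_s[1L] + ex_len[1L] %/% 2L)
      cds_end <- as.integer(ex_e[n_ex] - ex_len[n_ex] %/% 2L)
      name <- sprintf("G%04d", gi)
      genes[[gi]] <- list(gene = name, tx_name = paste0(name, ".1"),
                          chrom = chrom, strand = strand,
                          tx_start = tx_start, tx_end = tx_end,
                          cds_start = cds_start, cds_end = cds_end,
                          exon_starts = as.integer(ex_s),
                          exon_ends = as.integer(ex_e))
      # transcription-oriented anchors
      tss <- if (strand == "+") tx_start else tx_end
      last_mid <- if (strand == "+") (ex_s[n_ex] + ex_e[n_ex]) %/% 2L
                  else (ex_s[1L] + ex_e[1L]) %/% 2L
      cgi_len <- function() round(min(1500, max(400, stats::rnorm(1, 800, 150))))
      if (config$n_cgis > 0L && stats::runif(1) < 0.45) {
        L <- cgi_len()
        st <- if (strand == "+") tss - round(L * 0.4) else tss - round(L * 0.6)
        cgis[[length(cgis) + 1L]] <- data.frame(
          chrom = chrom, start = max(0L, as.integer(st)),
          end = as.integer(st + L), role = "five_prime", gene = name,
          stringsAsFactors = FALSE)
      }
      if (config$n_cgis > 0L && stats::runif(1) < 0.45) {
        L <- cgi_len()
        st <- as.integer(last_mid - L %/% 2L)
        cgis[[length(cgis) + 1L]] <- data.frame(
          chrom = chrom, start = max(0L, st), end = st + L,
          role = "three_prime", gene = name, stringsAsFactors = FALSE)
      }
      if (config$n_cgis > 0L && n_ex >= 3L && stats::runif(1) < 0.3) {
        mid_ex <- sample(2:(n_ex - 1L), 1L)
        mid <- (ex_s[mid_ex] + ex_e[mid_ex]) %/% 2L
        L <- cgi_len()
        st <- as.integer(mid - L %/% 2L)
        # keep the body island clear of the UTR footprints
        st <- max(st, cds_start + 10L)
        en <- min(st + L, cds_end - 10L)
        if (en - st >= 300L) {
          cgis[[length(cgis) + 1L]] <- data.frame(
            chrom = chrom, start = st, end = en, role = "body", gene = name,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  cgi_df <- if (length(cgis) > 0L) do.call(rbind, cgis) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               role = character(), gene = character(), stringsAsFactors = FALSE)
  extra <- config$n_cgis - nrow(cgi_df)
  if (extra > 0L) {
    ch <- sample(config$n_chroms, extra, replace = TRUE)
    st <- as.integer(round(stats::runif(extra, 0, config$chrom_length - 2000)))
    cgi_df <- rbind(cgi_df, data.frame(
      chrom = paste0("chr", ch), start = st,
      end = st + as.integer(round(stats::runif(extra, 400, 1200))),
      role = "extra", gene = NA_character_, stringsAsFactors = FALSE))
  }
  cgi_df <- cgi_df[order(cgi_df$chrom, cgi_df$start), , drop = FALSE]
  cgi_df$id <- sprintf("CGI_%05d", seq_len(nrow(cgi_df)))
  rownames(cgi_df) <- NULL

  gene_df <- data.frame(
    gene = vapply(genes, `[[`, "", "gene"),
    tx_name = vapply(genes, `[[`, "", "tx_name"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    tx_start = vapply(genes, `[[`, 0L, "tx_start"),
    tx_end = vapply(genes, `[[`, 0L, "tx_end"),
    cds_start = vapply(genes, `[[`, 0L, "cds_start"),
    cds_end = vapply(genes, `[[`, 0L, "cds_end"),
    stringsAsFactors = FALSE
  )
  gene_df$exon_starts <- lapply(genes, `[[`, "exon_starts")
  gene_df$exon_ends <- lapply(genes, `[[`, "exon_ends")
  list(genes = gene_df, cgis = cgi_df)
}

# Aligned 200-bp bin anchored to [s, e): the bin containing the midpoint,
# or with contain = TRUE the centermost aligned bin lying fully inside
# [s, e) (NA if none fits). Containment matters where a bin leaking past
# the feature edge would change its region class (e.g. gene-body islands
# next to the 5' UTR).
.anchor_bin <- function(s, e, bin_size = 200L, contain = FALSE) {
  if (e <= s) return(NA_integer_)
  if (!contain) return(as.integer(((s + e) %/% 2L) %/% bin_size) * bin_size)
  lo <- as.integer(ceiling(s / bin_size) * bin_size)
  hi <- as.integer((e %/% bin_size) * bin_size - bin_size)
  if (hi < lo) return(NA_integer_)
  cand <- seq(lo, hi, by = bin_size)
  cand[which.min(abs(cand + bin_size / 2 - (s + e) / 2))]
}

#' Plant ground-truth DMRs into an annotation
#'
#' Chooses one 200-bp bin per planted DMR inside a feature matching its
#' kind (a gene's 5' CGI, body CGI, 3' CGI, or the non-CGI shore flanking a
#' gene-end CGI) and records the true pre/post methylation pair. Baselines
#' are shifted into \[2, 98\] when a full +/- delta step would leave the
#' percent scale, so every planted DMR has the exact configured |delta|.
#'
#' @param config A [synth_config()].
#' @param annotation Output of [generate_annotation()].
#' @return A data.frame (the truth set): chrom, start, end, key, kind,
#'   direction, delta, contrast, gene, level_a, level_b.
#' @export
plant_truth <- function(config, annotation) {
  set.seed(config$seed + 1L)
  cg <- annotation$cgis
  gn <- annotation$genes
  used <- character()
  rows <- list()
  feature_bin <- function(kind) {
    # candidate (bin_start, chrom, gene) choices for one planted kind
    if (kind == "noncgi_shore") {
      src <- cg[cg$role %in% c("five_prime", "three_prime"), , drop = FALSE]
      bin <- (src$end %/% 200L + 1L) * 200L  # first aligned bin beyond the island
      out <- data.frame(chrom = src$chrom, start = bin, gene = src$gene,
                        stringsAsFactors = FALSE)
    } else {
      role <- c(cgi_5prime = "five_prime", cgi_body = "body",
                cgi_3prime = "three_prime")[[kind]]
      src <- cg[cg$role == role, , drop = FALSE]
      idx <- match(src$gene, gn$gene)
      anchor <- integer(nrow(src))
      for (i in seq_len(nrow(src))) {
        g <- idx[i]
        ex_s <- gn$exon_starts[[g]]
        ex_e <- gn$exon_ends[[g]]
        n_ex <- length(ex_s)
        target <- switch(role,
          five_prime = if (gn$strand[g] == "+") c(ex_s[1L], ex_e[1L])
                       else c(ex_s[n_ex], ex_e[n_ex]),
          three_prime = if (gn$strand[g] == "+") c(ex_s[n_ex], ex_e[n_ex])
                        else c(ex_s[1L], ex_e[1L]),
          # internal territory: inside the coding span and clear of the
          # first and last exons (which belong to the 5'/3' footprints)
          body = c(max(gn$cds_start[g], ex_e[1L]),
                   min(gn$cds_end[g], ex_s[n_ex])))
        anchor[i] <- .anchor_bin(max(src$start[i], target[1L]),
                                 min(src$end[i], target[2L]),
                                 contain = (role == "body"))
      }
      out <- data.frame(chrom = src$chrom, start = anchor, gene = src$gene,
                        stringsAsFactors = FALSE)
      out <- out[!is.na(out$start), , drop = FALSE]
    }
    # for shores: reject bins that still touch any island
    if (kind == "noncgi_shore" && nrow(out) > 0L) {
      st <- cgi_status(data.frame(chrom = out$chrom, start = out$start,
                                  end = out$start + 200L), cg)
      out <- out[st == "NON_CGI", , drop = FALSE]
    }
    out
  }
  spec <- config$planted_dmrs
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      key = character(), kind = character(),
                      direction = character(), delta = numeric(),
                      contrast = character(), gene = character(),
                      level_a = numeric(), level_b = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(spec) == 0L) return(empty)
  for (i in seq_len(nrow(spec))) {
    cand <- feature_bin(spec$kind[i])
    cand$key <- .bin_key(cand$chrom, cand$start)
    cand <- cand[!cand$key %in% used & !duplicated(cand$key), , drop = FALSE]
    .assert(nrow(cand) >= spec$n[i],
            "cannot plant %d '%s' DMRs: only %d candidate bins",
            spec$n[i], spec$kind[i], nrow(cand))
    pick <- cand[sample(nrow(cand), spec$n[i]), , drop = FALSE]
    used <- c(used, pick$key)
    base <- if (spec$kind[i] == "noncgi_shore") config$baseline_noncgi
            else config$baseline_cgi
    delta <- spec$delta[i]
    if (spec$direction[i] == "GAIN") {
      level_a <- if (base + delta > 98) 98 - delta else base
      level_b <- level_a + delta
    } else {
      level_a <- if (base - delta < 2) 2 + delta else base
      level_b <- level_a - delta
    }
    rows[[i]] <- data.frame(chrom = pick$chrom, start = pick$start,
                            end = pick$start + 200L, key = pick$key,
                            kind = spec$kind[i], direction = spec$direction[i],
                            delta = delta, contrast = spec$contrast[i],
                            gene = pick$gene, level_a = level_a,
                            level_b = level_b, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  truth
}

# CpG positions along each chromosome: dense inside islands, sparse outside.
.generate_cpg_positions <- function(config, cgis) {
  pos_list <- list()
  for (ch in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ch)
    n_exp <- ceiling(config$chrom_length / config$cpg_spacing * 1.3)
    gaps <- stats::rexp(n_exp, 1 / config$cpg_spacing) + 2
    p <- cumsum(gaps)
    p <- p[p < config$chrom_length]
    cc <- cgis[cgis$chrom == chrom, , drop = FALSE]
    in_cgi <- rep(FALSE, length(p))
    extra <- list()
    for (i in seq_len(nrow(cc))) {
      in_cgi <- in_cgi | (p >= cc$start[i] & p < cc$end[i])
      L <- cc$end[i] - cc$start[i]
      k <- ceiling(L / config$cgi_cpg_spacing * 1.3)
      g <- stats::rexp(k, 1 / config$cgi_cpg_spacing) + 2
      q <- cc$start[i] + cumsum(g)
      extra[[i]] <- q[q < cc$end[i]]
    }
    # islands keep only their dense process
    p <- c(p[!in_cgi], unlist(extra))
    p <- sort(unique(as.integer(round(p))))
    pos_list[[ch]] <- data.frame(chrom = chrom, pos = p,
                                 stringsAsFactors = FALSE)
  }
  do.call(rbind, pos_list)
}

#' Generate per-sample bisulfite coverage counts
#'
#' Draws per-CpG call counts for each sample: depth ~ Poisson(coverage
#' mean); methylated calls ~ beta-binomial around the CpG's true level. The
#' true level is the compartment baseline (CGI low, non-CGI high), replaced
#' inside planted DMR bins by the truth pair: maturation DMRs switch from
#' `level_a` to `level_b` after the first age in both cell types;
#' differentiation DMRs hold `level_a` in ISC and `level_b` in
#' differentiated samples at every age.
#'
#' @param config A [synth_config()].
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [plant_truth()].
#' @param out_dir If non-NULL, Bismark-coverage files (1-based,
#'   `<sample>.cov`) are written there.
#' @return A list with `samples` (metadata data.frame: sample_id, age,
#'   age_day, cell_type), `counts` (named list of [read_cpg_counts()]-shaped
#'   data.frames), `cpgs` (site positions), and `files` (paths or NULL).
#' @export
generate_counts <- function(config, annotation, truth, out_dir = NULL) {
  set.seed(config$seed + 2L)
  .assert(all(truth$key %in% .bin_key(truth$chrom, truth$start)),
          "truth keys inconsistent")
  cpgs <- .generate_cpg_positions(config, annotation$cgis)
  compart <- cgi_status(data.frame(chrom = cpgs$chrom, start = cpgs$pos,
                                   end = cpgs$pos + 1L), annotation$cgis)
  base_level <- ifelse(compart == "CGI", config$baseline_cgi,
                       config$baseline_noncgi)
  bin_key <- .bin_key(cpgs$chrom, (cpgs$pos %/% 200L) * 200L)
  t_idx <- match(bin_key, truth$key)

  ages <- config$ages
  samples <- expand.grid(cell_type = c("ISC", "diff"),
                         age = names(ages), stringsAsFactors = FALSE)
  samples$age_day <- ages[samples$age]
  samples$sample_id <- paste(samples$cell_type, samples$age, sep = "_")
  samples <- samples[, c("sample_id", "age", "age_day", "cell_type")]

  first_age <- names(ages)[1L]
  counts <- list()
  files <- if (is.null(out_dir)) NULL else character(0)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (s in seq_len(nrow(samples))) {
    level <- base_level
    hit <- !is.na(t_idx)
    if (any(hit)) {
      ti <- t_idx[hit]
      is_mat <- truth$contrast[ti] == "maturation"
      post <- samples$age[s] != first_age
      is_diff_sample <- samples$cell_type[s] == "diff"
      lv_mat <- if (post) truth$level_b[ti] else truth$level_a[ti]
      lv_diff <- if (is_diff_sample) truth$level_b[ti] else truth$level_a[ti]
      level[hit] <- ifelse(is_mat, lv_mat, lv_diff)
    }
    p <- pmin(pmax(level / 100, 0.001), 0.999)
    depth <- stats::rpois(nrow(cpgs), config$coverage_mean)
    if (config$dispersion > 0) {
      d <- config$dispersion
      p_draw <- stats::rbeta(nrow(cpgs), p * (1 - d) / d, (1 - p) * (1 - d) / d)
    } else {
      p_draw <- p
    }
    meth <- stats::rbinom(nrow(cpgs), depth, p_draw)
    keep <- depth > 0L
    df <- data.frame(chrom = cpgs$chrom[keep], pos = cpgs$pos[keep],
                     meth = meth[keep], unmeth = depth[keep] - meth[keep],
                     stringsAsFactors = FALSE)
    counts[[samples$sample_id[s]]] <- df
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, paste0(samples$sample_id[s], ".cov"))
      cov <- data.frame(chrom = df$chrom, start = df$pos + 1L,
                        end = df$pos + 1L,
                        pct = round(100 * df$meth / (df$meth + df$unmeth), 6),
                        meth = df$meth, unmeth = df$unmeth)
      utils::write.table(cov, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, path)
    }
  }
  list(samples = samples, counts = counts, cpgs = cpgs, files = files)
}

#' Generate a methylation-coupled expression time series
#'
#' Genes carrying a planted 3' CGI maturation gain are "coupled": their
#' expression follows intercept + coupling x true 3' CGI methylation + age
#' trend + Gaussian noise. An equal number of uncoupled control genes get
#' the same age trend but methylation-independent expression. Values are
#' expressed relative to a constant simulated reference gene.
#'
#' @param config A [synth_config()].
#' @param truth Output of [plant_truth()].
#' @return A data.frame: gene, coupled, age_label, age (days), replicate,
#'   methylation (percent, with measurement noise), expression.
#' @export
generate_expression <- function(config, truth) {
  set.seed(config$seed + 3L)
  .assert(is.finite(config$expression_coupling), "coupling must be finite")
  gain3 <- truth[truth$kind == "cgi_3prime" & truth$direction == "GAIN" &
                   truth$contrast == "maturation", , drop = FALSE]
  coupled_genes <- unique(gain3$gene)
  other <- setdiff(unique(truth$gene), coupled_genes)
  control_genes <- utils::head(other, length(coupled_genes))
  ramp_day <- config$ages[[length(config$ages)]]
  age_slope <- 0.001
  rows <- list()
  emit <- function(gene, coupled, level_a, level_b) {
    for (a in seq_along(config$expr_ages)) {
      day <- config$expr_ages[[a]]
      true_meth <- level_a + (level_b - level_a) * min(1, max(0, day / ramp_day))
      for (r in seq_len(config$expr_replicates)) {
        meth_obs <- min(100, max(0, true_meth +
                                   stats::rnorm(1, 0, config$expr_meth_noise_sd)))
        mu <- 1 + age_slope * day +
          if (coupled) config$expression_coupling * true_meth else 0
        rows[[length(rows) + 1L]] <<- data.frame(
          gene = gene, coupled = coupled,
          age_label = names(config$expr_ages)[a], age = day, replicate = r,
          methylation = meth_obs,
          expression = mu + stats::rnorm(1, 0, config$expr_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  for (g in coupled_genes) {
    t <- gain3[gain3$gene == g, , drop = FALSE][1L, ]
    emit(g, TRUE, t$level_a, t$level_b)
  }
  for (g in control_genes) {
    t <- truth[truth$gene == g, , drop = FALSE][1L, ]
    emit(g, FALSE, t$level_a, t$level_b)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate gene sets with a planted enrichment signal
#'
#' Builds GMT-style gene sets over the synthetic gene universe: one term
#' per planted-DMR kind/direction group (the signal terms) plus random
#' decoy terms drawn uniformly from the universe.
#'
#' @param config A [synth_config()].
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [plant_truth()].
#' @param n_decoys Number of decoy terms (default 20).
#' @param decoy_size Genes per decoy term (default 15).
#' @return Named list of character vectors (term -> genes).
#' @export
generate_gene_sets <- function(config, annotation, truth, n_decoys = 20L,
                               decoy_size = 15L) {
  set.seed(config$seed + 4L)
  universe <- annotation$genes$gene
  grp <- paste(truth$kind, tolower(truth$direction), sep = "_")
  sets <- lapply(split(truth$gene, grp), function(g) sort(unique(g)))
  names(sets) <- paste0("planted_", names(sets))
  for (i in seq_len(n_decoys)) {
    sets[[sprintf("decoy_%02d", i)]] <- sort(sample(universe, decoy_size))
  }
  sets
}

#' Generate developmental CpG panels for two microbiome conditions
#'
#' Emulates a candidate-gene methylation panel measured across development:
#' rows are CpG sites of three archetypes -- `developmental_gain` (low at
#' the first age, stepping up afterwards; in the germ-free condition the
#' post-natal gain fails to occur), `developmental_loss` (high, stepping
#' down; identical in both conditions), and `repeat_element` (two rows of
#' constant high methylation mimicking generic repeats, identical in both
#' conditions). Within-age noise is far smaller than between-age steps.
#'
#' @param config A [synth_config()].
#' @param n_gain,n_loss Numbers of gain/loss rows (defaults 40 / 30).
#' @return A list with `cnv` and `gf` ([sample_panel()] objects sharing row
#'   names) and `truth` (data.frame: site, type, deficit -- the configured
#'   CNV-minus-GF difference at post-gain ages).
#' @export
generate_panel <- function(config, n_gain = 40L, n_loss = 30L) {
  set.seed(config$seed + 5L)
  ages <- config$panel_ages
  .assert(length(ages) >= 2L && config$panel_samples_per_age >= 2L,
          "panel needs >= 2 ages and >= 2 samples per age")
  k <- config$panel_samples_per_age
  n_rep <- 2L
  site <- c(sprintf("gain%02d_cg%d", rep(seq_len(n_gain)), 1L),
            sprintf("loss%02d_cg%d", rep(seq_len(n_loss)), 1L),
            "Line1_cg1", "IAP_cg1")
  type <- c(rep("developmental_gain", n_gain),
            rep("developmental_loss", n_loss),
            rep("repeat_element", n_rep))
  n_sites <- length(site)
  # per-site age trajectories (percent)
  base_gain <- stats::runif(n_gain, 5, 15)
  step_gain <- stats::runif(n_gain, 20, 35)
  base_loss <- stats::runif(n_loss, 65, 85)
  step_loss <- stats::runif(n_loss, 20, 35)
  traj <- function(condition) {
    m <- matrix(0, n_sites, length(ages))
    for (a in seq_along(ages)) {
      frac <- (a - 1) / (length(ages) - 1)  # 0 at first age, 1 at last
      gain_here <- if (condition == "GF") 0 else frac
      m[seq_len(n_gain), a] <- base_gain + step_gain * gain_here
      m[n_gain + seq_len(n_loss), a] <- base_loss - step_loss * frac
      m[n_gain + n_loss + seq_len(n_rep), a] <- 85
    }
    m
  }
  build <- function(condition) {
    mu <- traj(condition)
    cols <- length(ages) * k
    vals <- matrix(0, n_sites, cols)
    age_lab <- character(cols)
    cn <- character(cols)
    j <- 0L
    for (a in seq_along(ages)) {
      for (r in seq_len(k)) {
        j <- j + 1L
        vals[, j] <- pmin(100, pmax(0, mu[, a] +
                            stats::rnorm(n_sites, 0, config$panel_noise_sd)))
        age_lab[j] <- ages[a]
        cn[j] <- paste(condition, ages[a], r, sep = "_")
      }
    }
    rownames(vals) <- site
    colnames(vals) <- cn
    sample_panel(vals, age = age_lab, condition = rep(condition, cols))
  }
  cnv <- build("CNV")
  gf <- build("GF")
  deficit <- c(step_gain, rep(0, n_loss), rep(0, n_rep))
  list(cnv = cnv, gf = gf,
       truth = data.frame(site = site, type = type, deficit = deficit,
                          stringsAsFactors = FALSE))
}

#' Write annotation files for a synthetic genome
#'
#' Emits the CGI BED (3 columns + id) and the 11-column refFlat table.
#'
#' @param annotation Output of [generate_annotation()].
#' @param cgi_path,refflat_path Output file paths.
#' @return Invisibly, c(cgi_path, refflat_path).
#' @export
write_annotation <- function(annotation, cgi_path, refflat_path) {
  cg <- annotation$cgis
  utils::write.table(cg[, c("chrom", "start", "end", "id")], cgi_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  gn <- annotation$genes
  lines <- vapply(seq_len(nrow(gn)), function(i) {
    paste(gn$gene[i], gn$tx_name[i], gn$chrom[i], gn$strand[i],
          gn$tx_start[i], gn$tx_end[i], gn$cds_start[i], gn$cds_end[i],
          length(gn$exon_starts[[i]]),
          paste0(paste(gn$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(gn$exon_ends[[i]], collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, refflat_path)
  invisible(c(cgi_path, refflat_path))
}

#' Write a GMT gene-set file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(tm) {
    paste(c(tm, "synthetic", gene_sets[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
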