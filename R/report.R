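# Locus-level tallies, discovery comparisons, enrichment statistics, and
# end-to-end pipeline orchestration on a synthetic study.

#' Define genome-wide significant GWAS loci
#'
#' With LD-block definitions, each block containing at least one SNP with
#' `p < p_max` becomes a locus (lead = smallest p). Without blocks,
#' significant SNPs are distance-clumped: SNPs within `clump_distance` of
#' each other merge into one locus whose bounds span its member SNPs.
#'
#' @param gwas GWAS summary data.frame (snp_id, chrom, pos, z).
#' @param blocks Optional LD-block data.frame (chrom, start, end; 1-based
#'   inclusive, e.g. from [read_bed()]).
#' @param p_max Genome-wide significance threshold (default 5e-8, strict).
#' @param clump_distance Clumping distance in bp (default 1 Mb).
#' @return data.frame: locus_id, chrom, start, end, lead_snp, lead_p.
#' @export
define_gwas_loci <- function(gwas, blocks = NULL, p_max = 5e-8,
                             clump_distance = 1e6) {
  p <- 2 * stats::pnorm(-abs(gwas$z))
  sig <- gwas[p < p_max, , drop = FALSE]
  sig$p <- p[p < p_max]
  if (!nrow(sig)) {
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      lead_snp = character(0), lead_p = numeric(0)))
  }
  if (!is.null(blocks)) {
    rows <- lapply(seq_len(nrow(blocks)), function(i) {
      b <- blocks[i, ]
      inb <- sig[sig$chrom == b$chrom & sig$pos >= b$start & sig$pos <= b$end, ]
      if (!nrow(inb)) return(NULL)
      lead <- inb[which.min(inb$p), ]
      data.frame(chrom = b$chrom, start = b$start, end = b$end,
                 lead_snp = lead$snp_id, lead_p = lead$p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    out <- NULL
    for (ch in unique(sig$chrom)) {
      s <- sig[sig$chrom == ch, ]
      s <- s[order(s$pos), ]
      grp <- cumsum(c(TRUE, diff(s$pos) > clump_distance))
      for (g in unique(grp)) {
        cl <- s[grp == g, ]
        lead <- cl[which.min(cl$p), ]
        out <- rbind(out, data.frame(chrom = ch, start = min(cl$pos),
                                     end = max(cl$pos), lead_snp = lead$snp_id,
                                     lead_p = lead$p, stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(locus_id = sprintf("gwas_locus%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tag GWAS loci with significant TWAS/isoTWAS features
#'
#' A locus is tagged by a method iff at least one of that method's
#' significant features has a gene body within `window` of the locus
#' bounds. Features falling outside every locus are counted separately.
#'
#' @param loci Output of [define_gwas_loci()].
#' @param features data.frame of significant features with columns
#'   feature_id, level (`"gene"`/`"isoform"`), chrom, gene_start, gene_end.
#' @param window Assignment window in bp (default 1 Mb).
#' @return List: `loci` (with twas_tagged / isotwas_tagged / both flags),
#'   `counts` (n_loci, twas, isotwas, both, either),
#'   `features_outside_loci` per level.
#' @export
tag_loci <- function(loci, features, window = 1e6) {
  tag_one <- function(lv) {
    f <- features[features$level == lv, , drop = FALSE]
    vapply(seq_len(nrow(loci)), function(i) {
      l <- loci[i, ]
      any(f$chrom == l$chrom & f$gene_end >= l$start - window &
            f$gene_start <= l$end + window)
    }, logical(1))
  }
  loci$twas_tagged <- if (nrow(loci)) tag_one("gene") else logical(0)
  loci$isotwas_tagged <- if (nrow(loci)) tag_one("isoform") else logical(0)
  loci$both <- loci$twas_tagged & loci$isotwas_tagged
  inside <- function(lv) {
    f <- features[features$level == lv, , drop = FALSE]
    if (!nrow(f)) return(0L)
    hit <- vapply(seq_len(nrow(f)), function(j) {
      any(loci$chrom == f$chrom[j] & f$gene_end[j] >= loci$start - window &
            f$gene_start[j] <= loci$end + window)
    }, logical(1))
    sum(!hit)
  }
  list(
    loci = loci,
    counts = c(n_loci = nrow(loci), twas = sum(loci$twas_tagged),
               isotwas = sum(loci$isotwas_tagged), both = sum(loci$both),
               either = sum(loci$twas_tagged | loci$isotwas_tagged)),
    features_outside_loci = c(gene = inside("gene"), isoform = inside("isoform"))
  )
}

#' Two-proportion enrichment test
#'
#' 2x2 chi-square test that proportion k1/n1 differs from k2/n2, with the
#' enrichment ratio `(k1/n1) / (k2/n2)`. Falls back to Fisher's exact test
#' when any expected cell is below 5 (logged via a message).
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @param correct Continuity correction for the chi-square test (default
#'   TRUE).
#' @return List: chi2_stat, p_two_sided, ratio, method.
#' @export
proportion_enrichment_test <- function(k1, n1, k2, n2, correct = TRUE) {
  stopifnot(k1 <= n1, k2 <= n2, n1 > 0, n2 > 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ratio <- (k1 / n1) / (k2 / n2)
  if (any(expected < 5)) {
    message("expected cell below 5; using Fisher's exact test")
    ft <- stats::fisher.test(tab)
    return(list(chi2_stat = NA_real_, p_two_sided = ft$p.value, ratio = ratio,
                method = "fisher"))
  }
  ct <- stats::chisq.test(tab, correct = correct)
  list(chi2_stat = unname(ct$statistic), p_two_sided = ct$p.value,
       ratio = ratio, method = "chisq")
}

#' Default configuration for the synthetic end-to-end study
#'
#' @param ... Overrides of the named defaults.
#' @return Config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_ref = 400,            # reference/training panel size
    n_snps = 400,
    maf_range = c(0.05, 0.5),
    rho = 0.6,
    block_size = 10,
    snp_spacing = 50000,    # 20 Mb span: loci are well separated
    n_genes = 8,
    n_isoforms = 2,
    n_causal = 2,
    h2_cis = 0.35,
    resid_cor = 0.25,
    n_mediated_genes = 3,    # genes whose isoforms carry opposing trait effects
    alpha_magnitude = 0.22,
    n_gwas = 5e4,
    n_covariates = 4,
    k_folds = 10,
    alpha_level = 0.05,
    perm_B = 1000,
    max_causal_features = 1,
    seed = 1
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full synthetic study end-to-end
#'
#' Simulates a reference panel and transcriptome, trains gene and isoform
#' models, simulates GWAS summary statistics under an opposing-isoform
#' mediated architecture, runs burden tests with the two-stage adjustment
#' and permutation filter, fine-maps significant isoform loci, maps cis
#' QTLs and colocalizes mediated genes, fits the mediated-heritability
#' regression, and tallies locus tagging. Deterministic given
#' `config$seed`.
#'
#' @param config A [pipeline_config()] list.
#' @param out_dir Optional directory; when supplied, TSV/JSON outputs and a
#'   run manifest are written there.
#' @return List with components `panel`, `annotation`, `truth`, `models`,
#'   `assoc` (gene + isoform tables), `finemap`, `qtl`, `coloc`,
#'   `mediation`, `loci`, `tags`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  map <- snp_map(cfg$n_snps, spacing = cfg$snp_spacing)
  panel <- stage("simulate", {
    p <- simulate_genotypes(cfg$n_ref, map, maf_range = cfg$maf_range,
                            rho = cfg$rho, block_size = cfg$block_size,
                            seed = cfg$seed)
    filter_variants(p, maf_min = 0.01, hwe_p_min = 1e-6)
  })
  span <- cfg$n_snps * cfg$snp_spacing
  gene_gap <- max(2.2e6, (span - 1e6) / cfg$n_genes - 4e4)
  ann <- simulate_annotation(cfg$n_genes, cfg$n_isoforms,
                             first_start = 3e5, gene_length = 4e4,
                             gene_gap = gene_gap, seed = cfg$seed + 1)
  if (max(ann$genes$gene_end) > span + 1e5) {
    stop("config error: genes extend beyond the simulated SNP span")
  }
  # Opposing-isoform architecture for the first n_mediated_genes genes.
  med_genes <- ann$genes$gene_id[seq_len(min(cfg$n_mediated_genes, cfg$n_genes))]
  tx <- ann$transcripts
  alpha <- stats::setNames(rep(0, nrow(tx)), tx$transcript_id)
  for (g in med_genes) {
    ids <- tx$transcript_id[tx$gene_id == g]
    sgn <- rep(c(1, -1), length.out = length(ids))
    alpha[ids] <- sgn * cfg$alpha_magnitude
  }
  sim <- stage("simulate", simulate_isoform_expression(
    panel, ann, n_causal = cfg$n_causal, h2_cis = cfg$h2_cis,
    resid_cor = cfg$resid_cor, alpha = alpha,
    n_covariates = cfg$n_covariates, seed = cfg$seed + 2))
  V <- ld_matrix(panel)
  gwas <- stage("gwas", simulate_gwas_summary(V, sim$truth, cfg$n_gwas,
                                              mode = "analytic",
                                              seed = cfg$seed + 3))
  gwas_h <- harmonize_gwas(gwas, panel$snp_map)

  iso_r <- residualize_expression(sim$isoform, sim$isoform$covariates)
  gene_r <- residualize_expression(sim$gene, sim$gene$covariates)

  models <- stage("train", {
    out <- list()
    for (g in seq_len(nrow(ann$genes))) {
      gi <- ann$genes[g, ]
      cis <- cis_snps(panel$snp_map, gi$chrom, gi$gene_start, gi$gene_end, 1e6)
      Xc <- panel$dosages[, cis, drop = FALSE]
      t_ids <- tx$transcript_id[tx$gene_id == gi$gene_id]
      out <- c(out,
               train_feature_model(Xc, iso_r$values[, t_ids, drop = FALSE],
                                   level = "isoform", k_folds = cfg$k_folds,
                                   seed = cfg$seed + 10 + g),
               train_feature_model(Xc, gene_r$values[, gi$gene_id],
                                   feature_ids = gi$gene_id, level = "gene",
                                   families = "enet", k_folds = cfg$k_folds,
                                   seed = cfg$seed + 10 + g))
    }
    select_models(model_db(out))
  })
  kept <- retained_models(models)
  by_level <- split(kept, vapply(kept, `[[`, character(1), "level"))

  assoc_tab <- stage("associate", {
    mk_tab <- function(ms) {
      rows <- lapply(ms, function(m) {
        gid <- if (m$level == "isoform") tx$gene_id[tx$transcript_id == m$feature_id]
               else m$feature_id
        tryCatch(burden_test(m, gwas_h, V, gene_id = gid),
                 error = function(e) NULL)
      })
      do.call(rbind, rows)
    }
    iso_tab <- mk_tab(by_level$isoform)
    gene_tab <- mk_tab(by_level$gene)
    list(isoform = if (!is.null(iso_tab)) two_stage_adjust(iso_tab, cfg$alpha_level),
         gene = if (!is.null(gene_tab)) two_stage_adjust(gene_tab, cfg$alpha_level))
  })

  add_perm <- function(tab) {
    if (is.null(tab)) return(tab)
    tab$p_perm <- NA_real_
    sig <- which(tab$significant)
    mods <- stats::setNames(kept, vapply(kept, `[[`, character(1), "feature_id"))
    for (i in sig) {
      tab$p_perm[i] <- permutation_test(mods[[tab$feature_id[i]]], gwas_h, V,
                                        B = cfg$perm_B, seed = cfg$seed + 20 + i)
    }
    tab$significant <- tab$significant & !is.na(tab$p_perm) &
      tab$p_perm < cfg$alpha_level
    tab
  }
  assoc_tab$isoform <- stage("permute", add_perm(assoc_tab$isoform))
  assoc_tab$gene <- stage("permute", add_perm(assoc_tab$gene))

  mods_by_id <- stats::setNames(kept, vapply(kept, `[[`, character(1), "feature_id"))
  sig_iso <- assoc_tab$isoform[assoc_tab$isoform$significant %in% TRUE, ,
                               drop = FALSE]
  fm <- stage("finemap", {
    if (!is.null(sig_iso) && nrow(sig_iso)) {
      finemap_loci(sig_iso, mods_by_id, V, ann,
                   max_causal = cfg$max_causal_features)
    } else NULL
  })

  qtl <- stage("qtl", map_cis_qtl(panel, iso_r, ann,
                                  covariates = sim$isoform$covariates))
  coloc <- stage("coloc", {
    rows <- lapply(unique(sig_iso$feature_id), function(fid) {
      q <- qtl[qtl$feature_id == fid, , drop = FALSE]
      if (nrow(q) < 2) return(NULL)
      tryCatch(colocalize_feature(gwas_h, q, V), error = function(e) NULL)
    })
    do.call(rbind, rows)
  })

  med <- stage("mediate", {
    eff <- sim$truth$eqtl_effects
    es <- compute_expression_scores(eff, V)
    ls <- compute_ld_scores(V)
    tryCatch(mesc_fit(gwas_h, es, ls, n_gwas = cfg$n_gwas, n_blocks = 10),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "mediation_estimate"))
  })

  loci <- stage("report", define_gwas_loci(gwas_h))
  sig_features <- rbind(
    if (!is.null(sig_iso) && nrow(sig_iso)) {
      ix <- match(sig_iso$gene_id, ann$genes$gene_id)
      data.frame(feature_id = sig_iso$feature_id, level = "isoform",
                 chrom = ann$genes$chrom[ix],
                 gene_start = ann$genes$gene_start[ix],
                 gene_end = ann$genes$gene_end[ix], stringsAsFactors = FALSE)
    },
    {
      sg <- assoc_tab$gene[assoc_tab$gene$significant %in% TRUE, , drop = FALSE]
      if (!is.null(sg) && nrow(sg)) {
        ix <- match(sg$gene_id, ann$genes$gene_id)
        data.frame(feature_id = sg$feature_id, level = "gene",
                   chrom = ann$genes$chrom[ix],
                   gene_start = ann$genes$gene_start[ix],
                   gene_end = ann$genes$gene_end[ix], stringsAsFactors = FALSE)
      }
    })
  if (is.null(sig_features)) {
    sig_features <- data.frame(feature_id = character(0), level = character(0),
                               chrom = character(0), gene_start = integer(0),
                               gene_end = integer(0))
  }
  tags <- stage("report", tag_loci(loci, sig_features))

  manifest <- list(
    package_version = as.character(utils::packageVersion("twasiso")),
    seed = cfg$seed, config = cfg,
    n_models_retained = sum(models$summary$retained),
    timestamp = NA_character_ # deliberately fixed so manifests are comparable
  )
  result <- list(panel = panel, annotation = ann, truth = sim$truth,
                 models = models, gwas = gwas_h, assoc = assoc_tab,
                 finemap = fm, qtl = qtl, coloc = coloc, mediation = med,
                 loci = loci, tags = tags, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) if (!is.null(x))
      data.table::fwrite(x, file.path(out_dir, f), sep = "\t")
    wt(assoc_tab$isoform, "assoc_isoform.tsv")
    wt(assoc_tab$gene, "assoc_gene.tsv")
    wt(fm, "finemap.tsv")
    wt(qtl, "qtl.tsv")
    wt(coloc, "coloc.tsv")
    wt(tags$loci, "loci.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (!inherits(med, "character") && is.null(med$error)) {
      jsonlite::write_json(med[c("h2_total", "h2_med", "ratio", "se_ratio",
                                 "wald_p")],
                           file.path(out_dir, "mediation.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  result
}
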