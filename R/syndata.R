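# Synthetic study generator: block-LD genotypes, heritable isoform expression
# aggregated to genes, and GWAS summary statistics under a mediated
# architecture. Every stochastic function takes an explicit seed.

#' Build a SNP map
#'
#' A SNP map is a data.frame with one row per variant: `snp_id`, `chrom`,
#' `pos` (1-based), `allele_ref`, `allele_alt`. Positions must be strictly
#' increasing within a chromosome and ids unique.
#'
#' @param n_snps Number of SNPs.
#' @param chrom Chromosome label.
#' @param start Position of the first SNP (bp).
#' @param spacing Distance between adjacent SNPs (bp).
#' @return A `snp_map` data.frame.
#' @export
snp_map <- function(n_snps, chrom = "1", start = 1e5, spacing = 5e3) {
  stopifnot(n_snps >= 1, spacing >= 1)
  # Unambiguous allele pair by default so strand filtering keeps everything.
  map <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    chrom = as.character(chrom),
    pos = as.integer(start + (seq_len(n_snps) - 1L) * spacing),
    allele_ref = "A",
    allele_alt = "G",
    stringsAsFactors = FALSE
  )
  validate_snp_map(map)
}

#' @rdname snp_map
#' @param map A data.frame with the SNP-map columns.
#' @export
validate_snp_map <- function(map) {
  need <- c("snp_id", "chrom", "pos", "allele_ref", "allele_alt")
  stopifnot(all(need %in% names(map)))
  if (anyDuplicated(map$snp_id)) stop("snp_ids must be unique")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  class(map) <- c("snp_map", "data.frame")
  map
}

#' Simulate a genotype reference panel with block LD
#'
#' Dosages are unphased allele counts in {0,1,2}, formed by summing two
#' haplotypes. Each haplotype is drawn from a latent Gaussian first-order
#' Markov chain within LD blocks (independence across blocks), thresholded
#' at the allele-frequency quantile. The latent adjacent correlation is set
#' to `sin(pi * rho / 2)` so that the realized allele-level adjacent
#' correlation matches `rho` at MAF 0.5 (tetrachoric inversion); at lower
#' MAF the realized correlation is somewhat attenuated, as in real panels.
#'
#' @param n Number of individuals (>= 2).
#' @param map A [snp_map()].
#' @param maf_range Interval in (0, 0.5] from which per-SNP alternate-allele
#'   frequencies are drawn uniformly.
#' @param rho Within-block adjacent-SNP LD (correlation), in [0, 1).
#' @param block_size SNPs per LD block.
#' @param seed Integer seed.
#' @return A `genotype_panel`: list with `dosages` (n x m matrix, columns
#'   named by snp_id), `snp_map`, `maf` (empirical minor-allele frequency),
#'   and a `recipe` attribute recording the generator settings.
#' @export
simulate_genotypes <- function(n, map, maf_range = c(0.05, 0.5),
                               rho = 0.6, block_size = 20L, seed = 1L) {
  stopifnot(n >= 2, length(maf_range) == 2)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie in (0, 0.5]")
  }
  if (rho >= 1) stop("rho >= 1 implies a non-positive-definite LD structure")
  if (rho < 0) stop("rho must be nonnegative")
  map <- validate_snp_map(map)
  m <- nrow(map)
  set.seed(seed)
  f <- stats::runif(m, maf_range[1], maf_range[2]) # alt-allele frequency
  thr <- stats::qnorm(f)
  rho_lat <- sin(pi * rho / 2)
  block <- rep(seq_len(ceiling(m / block_size)), each = block_size)[seq_len(m)]
  # Blocks never span chromosomes.
  block <- paste(map$chrom, block)
  draw_hap <- function() {
    Z <- matrix(stats::rnorm(n * m), n, m)
    new_block <- c(TRUE, block[-1] != block[-m])
    for (j in seq_len(m)[-1]) {
      if (!new_block[j]) {
        Z[, j] <- rho_lat * Z[, j - 1] + sqrt(1 - rho_lat^2) * Z[, j]
      }
    }
    sweep(Z, 2, thr, `<`) + 0
  }
  dosages <- draw_hap() + draw_hap()
  colnames(dosages) <- map$snp_id
  rownames(dosages) <- sprintf("ind%05d", seq_len(n))
  panel <- structure(
    list(dosages = dosages, snp_map = map,
         maf = pmin(colMeans(dosages) / 2, 1 - colMeans(dosages) / 2)),
    class = "genotype_panel",
    recipe = list(maf_range = maf_range, rho = rho,
                  block_size = block_size, seed = seed)
  )
  panel
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs\n")
  invisible(x)
}

#' LD (correlation) matrix of a genotype panel
#'
#' @param panel A `genotype_panel` or a numeric dosage matrix with column
#'   names.
#' @param snp_ids Optional subset of SNPs.
#' @return Symmetric correlation matrix with unit diagonal, dimnames set to
#'   snp ids.
#' @export
ld_matrix <- function(panel, snp_ids = NULL) {
  X <- if (inherits(panel, "genotype_panel")) panel$dosages else panel
  if (!is.null(snp_ids)) X <- X[, snp_ids, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("monomorphic SNP(s) in LD computation: ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  V <- stats::cor(X)
  # Enforce exact symmetry/unit diagonal against floating-point drift.
  V <- (V + t(V)) / 2
  diag(V) <- 1
  V
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the minor-allele count, the two-sided
#' p-value is the total probability of heterozygote counts no more likely
#' than the observed one under the HWE sampling distribution.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return Exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_minor <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab) # rarer-allele count
  # Heterozygote count shares the parity of the minor-allele count.
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # Unnormalized log probabilities of each possible het count, conditional
  # on allele counts: P(h) ∝ n! / (naa! nab! nbb!) * 2^h
  log_p <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2          # minor homozygotes
    b <- n - a - h                  # major homozygotes
    h * log(2) - lfactorial(a) - lfactorial(b) - lfactorial(h)
  }, numeric(1))
  p <- exp(log_p - max(log_p))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele count")
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Filter panel variants on MAF, HWE, and external frequency
#'
#' Mirrors reference-panel quality control: drop SNPs with minor-allele
#' frequency below `maf_min`, exact-test HWE p-value below `hwe_p_min`, or
#' (when an external frequency lookup is supplied) external MAF below
#' `external_maf_min`.
#'
#' @param panel A `genotype_panel` with integer dosages.
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param hwe_p_min Minimum exact HWE p-value (default 1e-5).
#' @param external_maf Optional named vector of external-panel MAFs.
#' @param external_maf_min Threshold applied to `external_maf` (default 0.01).
#' @return Filtered `genotype_panel`; the per-SNP pass/fail table is
#'   attached as attribute `"filter_report"`.
#' @export
filter_variants <- function(panel, maf_min = 0.05, hwe_p_min = 1e-5,
                            external_maf = NULL, external_maf_min = 0.01) {
  stopifnot(inherits(panel, "genotype_panel"))
  stopifnot(maf_min > 0, maf_min < 0.5, hwe_p_min > 0, hwe_p_min < 0.5)
  G <- round(panel$dosages)
  counts <- apply(G, 2, function(g) c(sum(g == 0), sum(g == 1), sum(g == 2)))
  hwe_p <- apply(counts, 2, function(ct) hwe_exact_test(ct[1], ct[2], ct[3]))
  maf <- panel$maf
  report <- data.frame(
    snp_id = panel$snp_map$snp_id,
    maf = maf,
    hwe_p = hwe_p,
    pass_maf = maf >= maf_min,
    pass_hwe = hwe_p >= hwe_p_min,
    stringsAsFactors = FALSE
  )
  if (!is.null(external_maf)) {
    ext <- external_maf[report$snp_id]
    report$external_maf <- unname(ext)
    report$pass_external <- !is.na(ext) & ext >= external_maf_min
  } else {
    report$pass_external <- TRUE
  }
  report$pass <- report$pass_maf & report$pass_hwe & report$pass_external
  if (!any(report$pass)) stop("variant filtering removed every SNP")
  keep <- which(report$pass)
  out <- structure(
    list(dosages = panel$dosages[, keep, drop = FALSE],
         snp_map = validate_snp_map(panel$snp_map[keep, , drop = FALSE]),
         maf = panel$maf[keep]),
    class = "genotype_panel",
    recipe = attr(panel, "recipe")
  )
  attr(out, "filter_report") <- report
  out
}

#' Build a synthetic transcriptome annotation
#'
#' Lays out `n_genes` genes along one chromosome with a configurable number
#' of transcript isoforms per gene. TSS is the gene start for plus-strand
#' genes and the gene end for minus-strand genes; per-transcript TSSs are
#' jittered within the gene body.
#'
#' @param n_genes Number of genes.
#' @param n_isoforms Isoforms per gene (scalar or length-`n_genes` vector).
#' @param chrom Chromosome label.
#' @param first_start Start of the first gene body (bp).
#' @param gene_length Length of each gene body (bp).
#' @param gene_gap Gap between consecutive gene bodies (bp).
#' @param seed Integer seed (for strand and TSS jitter).
#' @return A `tx_annotation`: list with `genes` and `transcripts`
#'   data.frames.
#' @export
simulate_annotation <- function(n_genes, n_isoforms = 3L, chrom = "1",
                                first_start = 5e5, gene_length = 5e4,
                                gene_gap = 2e5, seed = 1L) {
  stopifnot(n_genes >= 1, all(n_isoforms >= 1))
  n_iso <- rep_len(n_isoforms, n_genes)
  set.seed(seed)
  start <- first_start + (seq_len(n_genes) - 1) * (gene_length + gene_gap)
  end <- start + gene_length - 1
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("GENE%04d", seq_len(n_genes)),
    chrom = as.character(chrom),
    strand = strand,
    gene_start = as.integer(start),
    gene_end = as.integer(end),
    tss = as.integer(ifelse(strand == "+", start, end)),
    stringsAsFactors = FALSE
  )
  tx <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    k <- n_iso[g]
    jitter <- c(0L, sample.int(gene_length - 1L, k - 1L, replace = TRUE))
    tss <- if (strand[g] == "+") start[g] + jitter else end[g] - jitter
    data.frame(
      transcript_id = sprintf("%s.T%02d", genes$gene_id[g], seq_len(k)),
      gene_id = genes$gene_id[g],
      chrom = genes$chrom[g],
      strand = strand[g],
      tss = as.integer(tss),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(genes = genes, transcripts = tx), class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat("tx_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts\n")
  invisible(x)
}

#' Cis-window SNP ids for a feature
#'
#' @param map A [snp_map()].
#' @param chrom Chromosome of the feature.
#' @param start,end Feature interval (1-based inclusive); for a TSS-centred
#'   window pass `start = end = tss`.
#' @param window Flank size in bp (default 1 Mb each side).
#' @return Character vector of snp ids inside `[start - window, end + window]`.
#' @export
cis_snps <- function(map, chrom, start, end = start, window = 1e6) {
  sel <- map$chrom == as.character(chrom) &
    map$pos >= start - window & map$pos <= end + window
  map$snp_id[sel]
}

#' Simulate heritable isoform expression and its gene-level aggregate
#'
#' Each isoform k of a gene is `y_k = X beta_k + eps_k` with causal SNPs
#' drawn from the gene's 1 Mb cis window, effects rescaled so the genetic
#' variance fraction equals `h2_cis`, and residuals correlated across a
#' gene's isoforms. Gene expression is the row-sum of its isoform columns
#' (the normalized-scale stand-in for counts-level aggregation, which
#' preserves cancellation between opposing isoforms). Trait architecture
#' (isoform effects `alpha`, optional direct SNP effects) is recorded in
#' the returned ground truth for downstream GWAS simulation.
#'
#' @param panel A `genotype_panel`.
#' @param annotation A `tx_annotation`.
#' @param n_causal Causal SNPs per isoform.
#' @param h2_cis Cis-heritability per isoform (scalar or per-transcript
#'   named vector).
#' @param resid_cor Residual correlation between a gene's isoforms.
#' @param alpha Isoform-on-trait effects: scalar, or named vector keyed by
#'   transcript_id (unnamed entries 0).
#' @param n_direct_snps,h2_direct Number of SNPs with direct (non-mediated)
#'   trait effects and their total variance contribution.
#' @param n_covariates Number of generic covariates to emit (standard
#'   normal; no loading on expression unless `covariate_sd > 0`).
#' @param covariate_sd Standard deviation of covariate loadings on
#'   expression (default 0: expression is emitted residual-ready).
#' @param seed Integer seed.
#' @return List with `isoform` and `gene` expression sets (each a list of
#'   `values`, `feature_ids`, `level`, `covariates`) and `truth`, a
#'   `sim_truth` holding per-isoform standardized effect vectors, cis
#'   heritabilities, `alpha`, direct SNP effects, the standardized joint
#'   SNP-trait effect `b`, `h2_trait`, and `h2_med_true`.
#' @export
simulate_isoform_expression <- function(panel, annotation, n_causal = 2L,
                                        h2_cis = 0.3, resid_cor = 0.3,
                                        alpha = 0, n_direct_snps = 0L,
                                        h2_direct = 0, n_covariates = 5L,
                                        covariate_sd = 0, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(annotation, "tx_annotation"))
  stopifnot(all(h2_cis >= 0), all(h2_cis <= 1), abs(resid_cor) < 1)
  map <- panel$snp_map
  X <- .standardize(panel$dosages)
  n <- nrow(X)
  m <- ncol(X)
  tx <- annotation$transcripts
  genes <- annotation$genes
  set.seed(seed)

  h2 <- if (!is.null(names(h2_cis))) {
    out <- rep(h2_cis[1], nrow(tx)); names(out) <- tx$transcript_id
    out[names(h2_cis)[names(h2_cis) %in% tx$transcript_id]] <-
      h2_cis[names(h2_cis) %in% tx$transcript_id]
    out
  } else stats::setNames(rep_len(h2_cis, nrow(tx)), tx$transcript_id)
  a <- stats::setNames(rep(0, nrow(tx)), tx$transcript_id)
  if (!is.null(names(alpha))) {
    a[names(alpha)[names(alpha) %in% tx$transcript_id]] <-
      alpha[names(alpha) %in% tx$transcript_id]
  } else a[] <- rep_len(alpha, nrow(tx))

  iso_vals <- matrix(0, n, nrow(tx), dimnames = list(rownames(panel$dosages),
                                                     tx$transcript_id))
  beta_list <- vector("list", nrow(tx))
  names(beta_list) <- tx$transcript_id
  eps_all <- matrix(0, n, nrow(tx))

  for (g in seq_len(nrow(genes))) {
    gi <- genes[g, ]
    k_idx <- which(tx$gene_id == gi$gene_id)
    cis <- cis_snps(map, gi$chrom, gi$gene_start, gi$gene_end, 1e6)
    if (length(cis) < n_causal) {
      stop("gene ", gi$gene_id, ": requested ", n_causal,
           " causal SNPs but only ", length(cis), " cis-SNPs available")
    }
    K <- length(k_idx)
    # Exchangeable residual correlation across the gene's isoforms.
    R <- matrix(resid_cor, K, K); diag(R) <- 1
    E <- matrix(stats::rnorm(n * K), n, K) %*% chol(R)
    for (j in seq_len(K)) {
      t_id <- tx$transcript_id[k_idx[j]]
      h2_k <- h2[t_id]
      beta <- stats::setNames(numeric(m), colnames(X))
      if (h2_k > 0) {
        causal <- sample(cis, n_causal)
        beta[causal] <- stats::rnorm(n_causal)
        gcomp <- X %*% beta
        v <- stats::var(as.vector(gcomp))
        beta <- beta * sqrt(h2_k / v)
        gcomp <- gcomp * sqrt(h2_k / v)
      } else gcomp <- numeric(n)
      eps <- E[, j]
      eps <- eps / stats::sd(eps) * sqrt(max(1 - h2_k, 0))
      iso_vals[, k_idx[j]] <- as.vector(gcomp) + eps
      eps_all[, k_idx[j]] <- eps
      beta_list[[t_id]] <- beta[beta != 0]
    }
  }

  gene_vals <- vapply(genes$gene_id, function(gid) {
    rowSums(iso_vals[, tx$transcript_id[tx$gene_id == gid], drop = FALSE])
  }, numeric(n))

  covars <- matrix(stats::rnorm(n * n_covariates), n, n_covariates,
                   dimnames = list(rownames(panel$dosages),
                                   paste0("COV", seq_len(max(n_covariates, 0)))))
  if (covariate_sd > 0 && n_covariates > 0) {
    iso_vals <- iso_vals + covars %*%
      matrix(stats::rnorm(n_covariates * ncol(iso_vals), sd = covariate_sd),
             n_covariates, ncol(iso_vals))
    gene_vals <- vapply(genes$gene_id, function(gid) {
      rowSums(iso_vals[, tx$transcript_id[tx$gene_id == gid], drop = FALSE])
    }, numeric(n))
  }

  # --- ground-truth trait architecture on the standardized-genotype scale
  b_full <- stats::setNames(numeric(m), colnames(X))
  b_med <- b_full
  for (t_id in names(beta_list)) {
    bk <- beta_list[[t_id]]
    if (length(bk)) b_med[names(bk)] <- b_med[names(bk)] + a[t_id] * bk
  }
  delta <- stats::setNames(numeric(m), colnames(X))
  if (n_direct_snps > 0 && h2_direct > 0) {
    dsnp <- sample(colnames(X), n_direct_snps)
    delta[dsnp] <- stats::rnorm(n_direct_snps)
  }
  V <- ld_matrix(panel)
  if (any(delta != 0)) {
    vd <- as.numeric(t(delta) %*% V %*% delta)
    delta <- delta * sqrt(h2_direct / vd)
  }
  b_full <- b_med + delta
  var_gen <- as.numeric(t(b_full) %*% V %*% b_full)
  # Residual trait noise: alpha' Sigma_eps alpha plus environment so that the
  # total trait variance is 1 whenever the genetic share permits.
  var_aeps <- stats::var(as.vector(eps_all %*% a))
  sigma0_sq <- max(1 - var_gen - var_aeps, 0.01)
  var_trait <- var_gen + var_aeps + sigma0_sq
  truth <- structure(list(
    eqtl_effects = beta_list,
    h2_cis = h2,
    alpha = a,
    direct_snp_effects = delta / sqrt(var_trait),
    b = b_full / sqrt(var_trait),
    b_mediated = b_med / sqrt(var_trait),
    h2_trait = var_gen / var_trait,
    h2_med_true = as.numeric(t(b_med) %*% V %*% b_med) / var_trait,
    var_trait = var_trait,
    sigma0_sq = sigma0_sq,
    annotation = annotation,
    recipe = attr(panel, "recipe"),
    snp_map = map,
    seed = seed
  ), class = "sim_truth")

  iso_set <- structure(list(values = iso_vals, feature_ids = tx$transcript_id,
                            level = "isoform", covariates = covars),
                       class = "expression_set")
  gene_set <- structure(list(values = gene_vals, feature_ids = genes$gene_id,
                             level = "gene", covariates = covars),
                        class = "expression_set")
  list(isoform = iso_set, gene = gene_set, truth = truth)
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set (", x$level, "): ", nrow(x$values), " individuals x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' Simulate GWAS summary statistics from a trait architecture
#'
#' In `"analytic"` mode marginal z-scores are drawn from their asymptotic
#' distribution `z ~ MVN(sqrt(n) V b, V)` given the LD matrix `V` and the
#' standardized joint SNP effect `b` recorded in the ground truth. In
#' `"individual"` mode a fresh cohort of genotypes is generated from the
#' panel recipe, phenotypes are built from the truth (mediated isoform
#' effects plus direct effects plus noise), and per-SNP marginal z-scores
#' are computed by regression; the two modes agree in distribution.
#'
#' @param V LD correlation matrix on the truth's SNPs (analytic mode).
#' @param truth A `sim_truth`.
#' @param n_gwas GWAS sample size.
#' @param mode `"analytic"` or `"individual"`.
#' @param seed Integer seed.
#' @return A GWAS summary data.frame: snp_id, chrom, pos, a_ref, a_alt,
#'   beta, se, z, n.
#' @export
simulate_gwas_summary <- function(V, truth, n_gwas,
                                  mode = c("analytic", "individual"),
                                  seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "sim_truth"), n_gwas > 0)
  map <- truth$snp_map
  b <- truth$b
  set.seed(seed)
  if (mode == "analytic") {
    if (!.is_square_corr(V)) stop("V must be a correlation matrix")
    stopifnot(nrow(V) == length(b))
    L <- .chol_psd(V, ridge = 1e-6)
    z <- as.vector(sqrt(n_gwas) * V %*% b + t(L) %*% stats::rnorm(length(b)))
  } else {
    rec <- truth$recipe
    if (is.null(rec)) stop("truth carries no genotype recipe for individual mode")
    cohort <- simulate_genotypes(n_gwas, map, maf_range = rec$maf_range,
                                 rho = rec$rho, block_size = rec$block_size,
                                 seed = seed + 1L)
    Xg <- .standardize(cohort$dosages)
    ann <- truth$annotation
    y <- numeric(n_gwas)
    for (t_id in names(truth$eqtl_effects)) {
      bk <- truth$eqtl_effects[[t_id]]
      a_k <- truth$alpha[t_id]
      if (a_k == 0) next
      gk <- if (length(bk)) as.vector(Xg[, names(bk), drop = FALSE] %*% bk) else 0
      ek <- stats::rnorm(n_gwas, sd = sqrt(max(1 - truth$h2_cis[t_id], 0)))
      y <- y + a_k * (gk + ek)
    }
    # direct effects are stored pre-normalized; undo to the raw scale
    d <- truth$direct_snp_effects * sqrt(truth$var_trait)
    if (any(d != 0)) y <- y + as.vector(Xg[, names(d), drop = FALSE] %*% d)
    y <- y + stats::rnorm(n_gwas, sd = sqrt(truth$sigma0_sq))
    y <- as.vector(scale(y))
    r <- as.vector(crossprod(Xg, y)) / (n_gwas - 1)
    r <- pmin(pmax(r, -0.999), 0.999)
    z <- r * sqrt(n_gwas - 2) / sqrt(1 - r^2)
  }
  data.frame(
    snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
    a_ref = map$allele_ref, a_alt = map$allele_alt,
    beta = z / sqrt(n_gwas), se = 1 / sqrt(n_gwas), z = z,
    n = as.integer(n_gwas), stringsAsFactors = FALSE
  )
}
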