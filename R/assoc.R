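# Weighted burden association of genetically predicted expression with GWAS
# summary statistics, the two-stage (gene screen -> within-gene FWER)
# multiple-testing framework, permutation filtering, and the mean-chi^2
# effective-sample-size comparison.

#' Harmonize GWAS summary statistics to a reference SNP map
#'
#' Matches SNPs by id, flips the sign of z/beta where the GWAS alternate
#' allele equals the panel reference allele (and vice versa), drops SNPs
#' with incompatible alleles, and (by default) drops strand-ambiguous A/T
#' and C/G SNPs.
#'
#' @param gwas GWAS summary data.frame (snp_id, a_ref, a_alt, z, ...).
#' @param map A [snp_map()].
#' @param drop_ambiguous Drop A/T and C/G SNPs (default TRUE).
#' @return The harmonized GWAS rows, in map order, with flips applied.
#' @export
harmonize_gwas <- function(gwas, map, drop_ambiguous = TRUE) {
  idx <- match(map$snp_id, gwas$snp_id)
  g <- gwas[idx[!is.na(idx)], , drop = FALSE]
  m <- map[!is.na(idx), , drop = FALSE]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  same <- g$a_ref == m$allele_ref & g$a_alt == m$allele_alt
  flipped <- g$a_ref == m$allele_alt & g$a_alt == m$allele_ref
  ambiguous <- g$a_alt == comp[g$a_ref]
  keep <- (same | flipped) & !(drop_ambiguous & ambiguous)
  g <- g[keep, , drop = FALSE]
  sgn <- ifelse(flipped[keep], -1, 1)
  g$z <- g$z * sgn
  if ("beta" %in% names(g)) g$beta <- g$beta * sgn
  g[c("a_ref", "a_alt")] <- m[keep, c("allele_ref", "allele_alt")]
  rownames(g) <- NULL
  g
}

#' Weighted burden test of a predicted-expression model against GWAS
#'
#' The association z-score of a feature with SNP weights `w` is
#' `z_assoc = w'z / sqrt(w'Vw)` over the SNPs shared between the model and
#' the GWAS, with `V` the reference LD. Invariant to positive rescaling of
#' the weights.
#'
#' @param model A `weight_model`.
#' @param gwas Harmonized GWAS summary data.frame (snp_id, z).
#' @param V LD correlation matrix with dimnames covering the shared SNPs.
#' @param gene_id Optional gene id to carry through (isoform records).
#' @return One-row data.frame: feature_id, gene_id, level, z_assoc, p_raw,
#'   chisq, n_snps.
#' @export
burden_test <- function(model, gwas, V, gene_id = NA_character_) {
  stopifnot(inherits(model, "weight_model"))
  w_all <- model$weights
  shared <- intersect(names(w_all), gwas$snp_id)
  shared <- intersect(shared, colnames(V))
  if (!length(shared)) stop("no SNP overlap between model ", model$feature_id,
                            " and the GWAS/LD reference")
  w <- w_all[shared]
  z <- gwas$z[match(shared, gwas$snp_id)]
  Vs <- V[shared, shared, drop = FALSE]
  quad <- as.numeric(t(w) %*% Vs %*% w)
  if (quad <= 1e-12) stop("degenerate model for ", model$feature_id,
                          ": w'Vw <= 1e-12")
  z_assoc <- sum(w * z) / sqrt(quad)
  data.frame(
    feature_id = model$feature_id, gene_id = gene_id, level = model$level,
    z_assoc = z_assoc, p_raw = 2 * stats::pnorm(-abs(z_assoc)),
    chisq = z_assoc^2, n_snps = length(shared), stringsAsFactors = FALSE
  )
}

#' Cauchy combination (ACAT) of p-values
#'
#' Combines dependent p-values through the tangent transform: the test
#' statistic `T = sum(w_i tan((0.5 - p_i) pi))` is treated as standard
#' Cauchy, so the combined p is `0.5 - atan(T)/pi`. Exact for a single
#' input, robust to arbitrary dependence for small p.
#'
#' @param p Vector of p-values in (0, 1); values at 0/1 are clamped to
#'   machine-safe bounds.
#' @param weights Optional nonnegative weights (default equal).
#' @return Combined p-value.
#' @export
acat_combine <- function(p, weights = NULL) {
  if (!length(p)) stop("acat_combine needs at least one p-value")
  if (any(is.na(p))) stop("NA p-values")
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  if (is.null(weights)) weights <- rep(1 / length(p), length(p))
  stopifnot(length(weights) == length(p), all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  t_stat <- sum(weights * tan((0.5 - p) * pi))
  p_out <- 0.5 - atan(t_stat) / pi
  min(max(p_out, 1e-300), 1)
}

#' Two-stage multiple-testing adjustment for isoform associations
#'
#' Stage 1 screens genes: each gene's isoform p-values are combined by the
#' Cauchy combination and Benjamini-Hochberg adjusted across genes. Stage 2
#' controls the family-wise error within each gene by Bonferroni across its
#' isoforms. A feature is transcriptome-wide significant iff both adjusted
#' values fall below `alpha`. Gene-level (TWAS) records, which carry one
#' test per gene, pass through stage 1 only (their within-gene adjustment
#' is the identity).
#'
#' @param records Association data.frame with columns feature_id, gene_id,
#'   level, p_raw.
#' @param alpha Significance level for both stages (default 0.05).
#' @return `records` augmented with p_gene_screen, p_fdr, p_fwer_within,
#'   and logical `significant`.
#' @export
two_stage_adjust <- function(records, alpha = 0.05) {
  stopifnot(all(c("feature_id", "gene_id", "p_raw") %in% names(records)))
  if (!"level" %in% names(records)) records$level <- "isoform"
  g <- factor(records$gene_id)
  k <- tabulate(g)
  # Equal-weight Cauchy combination per gene, vectorized (same clamping as
  # acat_combine).
  p <- pmin(pmax(records$p_raw, 1e-300), 1 - 1e-16)
  t_mean <- as.vector(rowsum(tan((0.5 - p) * pi), g)) / k
  screen <- pmin(pmax(0.5 - atan(t_mean) / pi, 1e-300), 1)
  fdr <- stats::p.adjust(screen, method = "BH")
  gi <- as.integer(g)
  records$p_gene_screen <- screen[gi]
  records$p_fdr <- fdr[gi]
  records$p_fwer_within <- pmin(1, records$p_raw * k[gi])
  records$significant <- records$p_fdr < alpha & records$p_fwer_within < alpha
  records
}

#' Permutation filter for a burden association
#'
#' Re-assigns the model's weight values to SNP positions uniformly at
#' random (holding the GWAS z and LD fixed), recomputes the burden z each
#' time, and reports `p_perm = (1 + #{|z_perm| >= |z_obs|}) / (B + 1)`.
#' Intended for features already passing the two-stage adjustment. With
#' fewer than 3 SNPs all m! arrangements are enumerated instead.
#'
#' @param model A `weight_model`.
#' @param gwas Harmonized GWAS summary data.frame.
#' @param V LD matrix.
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Permutation p-value.
#' @export
permutation_test <- function(model, gwas, V, B = 10000L, seed = 1L) {
  stopifnot(inherits(model, "weight_model"))
  if (B < 100) warning("B < 100 gives a coarse permutation p-value")
  shared <- intersect(intersect(names(model$weights), gwas$snp_id), colnames(V))
  w <- model$weights[shared]
  z <- gwas$z[match(shared, gwas$snp_id)]
  Vs <- V[shared, shared, drop = FALSE]
  m <- length(w)
  if (m == 0) stop("no shared SNPs")
  quad0 <- as.numeric(t(w) %*% Vs %*% w)
  if (quad0 <= 1e-12) stop("degenerate model: w'Vw <= 1e-12")
  z_obs <- sum(w * z) / sqrt(quad0)
  set.seed(seed)
  if (m < 3) {
    perms <- if (m == 1) matrix(1, 1, 1) else rbind(c(1, 2), c(2, 1))
  } else {
    perms <- t(vapply(seq_len(B), function(b) sample.int(m), integer(m)))
  }
  P <- apply(perms, 1, function(ix) w[ix]) # m x B matrix of permuted weights
  if (is.null(dim(P))) P <- matrix(P, nrow = m)
  num <- as.vector(crossprod(P, z))
  quad <- colSums(P * (Vs %*% P))
  z_perm <- num / sqrt(pmax(quad, 1e-300))
  (1 + sum(abs(z_perm) >= abs(z_obs) - 1e-12)) / (nrow(perms) + 1)
}

#' Percent increase in effective sample size from paired chi-square tests
#'
#' Because the mean of a noncentral chi-square statistic grows linearly in
#' the GWAS sample size, `(mean(chi2) - 1)` is proportional to effective
#' sample size; the comparison statistic is
#' `100 * ((mean(chi2_iso) - 1) / (mean(chi2_twas) - 1) - 1)`,
#' computed over gene pairs passing the chi^2 > 1 filter, with a
#' leave-one-gene-out jackknife standard error and Wald 95% CI.
#'
#' @param chisq_iso,chisq_twas Paired per-gene chi-square statistics (the
#'   isoform arm takes each gene's best isoform statistic upstream).
#' @param filter `"union"` keeps pairs where either arm exceeds 1 (default);
#'   `"each"` filters the two arms separately.
#' @return List with `pct_increase`, `se_jackknife`, `ci95`,
#'   `n_features_used`.
#' @export
effective_sample_increase <- function(chisq_iso, chisq_twas,
                                      filter = c("union", "each")) {
  filter <- match.arg(filter)
  stopifnot(length(chisq_iso) == length(chisq_twas))
  if (filter == "union") {
    keep <- chisq_iso > 1 | chisq_twas > 1
    iso <- chisq_iso[keep]
    twas <- chisq_twas[keep]
    est <- function(ix) {
      d <- mean(twas[ix]) - 1
      if (d <= 0) return(NA_real_)
      100 * ((mean(iso[ix]) - 1) / d - 1)
    }
    n <- length(iso)
  } else {
    iso <- chisq_iso
    twas <- chisq_twas
    ki <- chisq_iso > 1
    kt <- chisq_twas > 1
    est <- function(ix) {
      d <- mean(twas[ix][kt[ix]]) - 1
      if (!is.finite(d) || d <= 0) return(NA_real_)
      100 * ((mean(iso[ix][ki[ix]]) - 1) / d - 1)
    }
    n <- length(iso)
  }
  if (n < 2) stop("need at least 2 gene pairs after filtering")
  pct <- est(seq_len(n))
  if (is.na(pct)) stop("denominator mean chi-square <= 1; percent increase undefined")
  loo <- vapply(seq_len(n), function(i) est(setdiff(seq_len(n), i)), numeric(1))
  loo <- loo[is.finite(loo)]
  se <- sqrt((length(loo) - 1) / length(loo) * sum((loo - mean(loo))^2))
  list(pct_increase = pct, se_jackknife = se,
       ci95 = c(pct - 1.96 * se, pct + 1.96 * se),
       n_features_used = n)
}
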