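# Expression-mediated SNP-heritability estimation: LD scores, expression
# scores built from sparse cis eQTL effect estimates, and the mediated
# expression-score regression of GWAS chi-square statistics with block
# jackknife standard errors.

#' Per-SNP LD scores
#'
#' `ld_score_j = sum_i r^2_ij` over the window covered by `V` (the self
#' r^2 = 1 term included).
#'
#' @param V LD correlation matrix.
#' @return Named vector of LD scores.
#' @export
compute_ld_scores <- function(V) {
  stopifnot(.is_square_corr(V))
  out <- colSums(V^2)
  names(out) <- colnames(V)
  out
}

#' Per-SNP expression scores
#'
#' LD-smeared squared cis effects:
#' `expr_score_j = sum_features sum_i r^2_ij beta_i(feature)^2`, with
#' effects on the standardized-genotype scale (e.g. LASSO estimates of cis
#' eQTL effects). The total cis expression heritability
#' `sum_f beta_f' V beta_f` is attached as attribute `"total_h2_cis"` for
#' use by [mesc_fit()].
#'
#' @param eqtl_effects List (one element per feature) of named sparse
#'   effect vectors.
#' @param V LD correlation matrix whose dimnames cover the effect SNPs.
#' @return Named vector of expression scores with attribute
#'   `"total_h2_cis"`.
#' @export
compute_expression_scores <- function(eqtl_effects, V) {
  stopifnot(.is_square_corr(V))
  ids <- colnames(V)
  b2 <- stats::setNames(numeric(length(ids)), ids)
  total_h2 <- 0
  for (bk in eqtl_effects) {
    if (!length(bk)) next
    if (!all(names(bk) %in% ids)) stop("effect SNP(s) missing from V")
    b2[names(bk)] <- b2[names(bk)] + bk^2
    Vb <- V[names(bk), names(bk), drop = FALSE]
    total_h2 <- total_h2 + as.numeric(t(bk) %*% Vb %*% bk)
  }
  out <- as.vector(V^2 %*% b2)
  names(out) <- ids
  attr(out, "total_h2_cis") <- total_h2
  out
}

#' Estimate per-feature cis eQTL effects by LASSO
#'
#' Sparse standardized-scale effect vectors for expression-score
#' construction, one LASSO fit per feature on its cis SNPs.
#'
#' @param panel A `genotype_panel`.
#' @param expr An `expression_set` (residualized).
#' @param annotation A `tx_annotation`.
#' @param window Cis window around the gene body (default 1 Mb).
#' @param seed Integer seed (cross-validated penalty).
#' @return Named list of sparse effect vectors keyed by feature id.
#' @export
lasso_eqtl_effects <- function(panel, expr, annotation, window = 1e6,
                               seed = 1L) {
  Xs <- .standardize(panel$dosages)
  map <- panel$snp_map
  tx <- annotation$transcripts
  genes <- annotation$genes
  set.seed(seed)
  out <- lapply(expr$feature_ids, function(fid) {
    gid <- if (expr$level == "isoform") tx$gene_id[tx$transcript_id == fid] else fid
    g <- genes[genes$gene_id == gid, ]
    cis <- cis_snps(map, g$chrom, g$gene_start, g$gene_end, window)
    y <- expr$values[, fid]
    if (length(cis) < 2 || stats::sd(y) == 0) return(numeric(0))
    cv <- glmnet::cv.glmnet(Xs[, cis, drop = FALSE], y, alpha = 1, nfolds = 5,
                            standardize = FALSE)
    b <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    names(b) <- cis
    b[b != 0]
  })
  names(out) <- expr$feature_ids
  out
}

#' Mediated expression-score regression
#'
#' Regresses per-SNP GWAS chi-square statistics on the scaled expression
#' and LD scores with an intercept:
#' `E[chi2_j] = 1 + n * sigma_a^2 * expr_score_j + n * sigma_d^2 * ld_score_j`.
#' The mediated heritability is `sigma_a^2 * total_h2_cis` (slope times the
#' total cis expression heritability of the feature set), the non-mediated
#' component `sigma_d^2 * M`, and the reported ratio is
#' `h2_med / (h2_med + h2_nonmed)`. Fitting is two-step weighted least
#' squares with heteroskedasticity weights `1 / (2 * fitted^2)`
#' (approximating the chi-square variance, as in LD-score-family
#' regressions). Standard errors come from a delete-one block jackknife
#' over contiguous SNP blocks; the Wald p tests ratio = 0.
#'
#' @param gwas GWAS summary data.frame (snp_id, z, n) or named z vector.
#' @param expr_scores Output of [compute_expression_scores()].
#' @param ld_scores Output of [compute_ld_scores()].
#' @param n_gwas GWAS sample size (defaults to `gwas$n[1]`).
#' @param total_h2_cis Total cis expression heritability; defaults to the
#'   attribute on `expr_scores`.
#' @param n_blocks Jackknife blocks (default 20).
#' @return A `mediation_estimate`: list with h2_total, h2_med, h2_nonmed,
#'   ratio, se_ratio, wald_p, n_snps, flagged.
#' @export
mesc_fit <- function(gwas, expr_scores, ld_scores, n_gwas = NULL,
                     total_h2_cis = NULL, n_blocks = 20L) {
  if (is.data.frame(gwas)) {
    if (is.null(n_gwas)) n_gwas <- gwas$n[1]
    z <- stats::setNames(gwas$z, gwas$snp_id)
  } else z <- gwas
  if (is.null(n_gwas)) stop("n_gwas required")
  ids <- intersect(names(z), names(expr_scores))
  ids <- intersect(ids, names(ld_scores))
  if (length(ids) < 200) stop("need >= 200 SNPs aligned across inputs")
  if (is.null(total_h2_cis)) total_h2_cis <- attr(expr_scores, "total_h2_cis")
  if (is.null(total_h2_cis)) stop("total_h2_cis required")
  chi2 <- z[ids]^2
  M <- length(ids)
  X <- cbind(expr = n_gwas * expr_scores[ids], ld = n_gwas * ld_scores[ids])

  fit_once <- function(keep) {
    Xk <- X[keep, , drop = FALSE]
    yk <- chi2[keep]
    b0 <- stats::lm.fit(cbind(1, Xk), yk)$coefficients
    fitted <- pmax(cbind(1, Xk) %*% b0, 0.5)
    w <- 1 / (2 * fitted^2)
    b <- stats::lm.wfit(cbind(1, Xk), yk, as.vector(w))$coefficients
    h2_med <- b[2] * total_h2_cis
    h2_non <- b[3] * M
    c(h2_med = unname(h2_med), h2_non = unname(h2_non))
  }

  full <- fit_once(seq_len(M))
  h2_med <- full["h2_med"]
  h2_total <- full["h2_med"] + full["h2_non"]
  flagged <- h2_total <= 0
  ratio <- if (flagged) NA_real_ else unname(h2_med / h2_total)

  blocks <- split(seq_len(M), cut(seq_len(M), n_blocks, labels = FALSE))
  theta <- vapply(blocks, function(bl) {
    est <- fit_once(setdiff(seq_len(M), bl))
    tot <- est["h2_med"] + est["h2_non"]
    if (tot <= 0) NA_real_ else unname(est["h2_med"] / tot)
  }, numeric(1))
  theta <- theta[is.finite(theta)]
  B <- length(theta)
  se_ratio <- if (B >= 2) sqrt((B - 1) / B * sum((theta - mean(theta))^2)) else NA_real_
  wald_p <- if (is.na(ratio) || is.na(se_ratio) || se_ratio == 0) NA_real_
            else 2 * stats::pnorm(-abs(ratio / se_ratio))
  structure(list(h2_total = unname(h2_total), h2_med = unname(h2_med),
                 h2_nonmed = unname(full["h2_non"]), ratio = ratio,
                 se_ratio = se_ratio, wald_p = wald_p, n_snps = M,
                 n_blocks_used = B, flagged = flagged),
            class = "mediation_estimate")
}

#' @export
print.mediation_estimate <- function(x, ...) {
  cat("mediation_estimate: h2 =", formatC(x$h2_total, digits = 3),
      " h2_med =", formatC(x$h2_med, digits = 3),
      " ratio =", formatC(x$ratio, digits = 3),
      "+/-", formatC(x$se_ratio, digits = 3),
      " (Wald p =", formatC(x$wald_p, digits = 3), ")\n")
  invisible(x)
}

#' Average expression scores across tissue replicates
#'
#' Simple element-wise mean of per-tissue expression-score vectors (the
#' in-scope reduction of multi-tissue meta-analysis); total cis
#' heritabilities are averaged likewise.
#'
#' @param score_list List of expression-score vectors on a common SNP set.
#' @return Averaged score vector with averaged `"total_h2_cis"`.
#' @export
meta_expression_scores <- function(score_list) {
  stopifnot(length(score_list) >= 1)
  ids <- names(score_list[[1]])
  mat <- vapply(score_list, function(s) s[ids], numeric(length(ids)))
  out <- rowMeans(mat)
  names(out) <- ids
  attr(out, "total_h2_cis") <-
    mean(vapply(score_list, function(s) attr(s, "total_h2_cis"), numeric(1)))
  out
}
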