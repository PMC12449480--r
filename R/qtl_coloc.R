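# cis-QTL mapping by ordinary least squares and eCAVIAR-style
# colocalization posterior probabilities between GWAS and QTL signals.

#' Map cis quantitative trait loci by ordinary least squares
#'
#' For each feature, every SNP within `window` of its transcription start
#' site is tested marginally: expression is regressed on allelic dosage
#' (0/1/2) jointly with the covariates; the reported effect, Wald standard
#' error, and two-sided p-value are for the dosage term. Computed via
#' covariate projection, which is numerically identical to the joint fit
#' (Frisch-Waugh), with residual degrees of freedom `n - c - 2`.
#'
#' @param panel A `genotype_panel`.
#' @param expr An `expression_set` (isoform or gene level).
#' @param annotation A `tx_annotation`.
#' @param covariates Covariate matrix; defaults to the expression set's.
#' @param window Cis window around the TSS (default 1 Mb each side).
#' @return data.frame: feature_id, snp_id, beta, se, p_wald.
#' @export
map_cis_qtl <- function(panel, expr, annotation, covariates = NULL,
                        window = 1e6) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(expr, "expression_set"))
  if (is.null(covariates)) covariates <- expr$covariates
  map <- panel$snp_map
  n <- nrow(panel$dosages)
  C <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    C <- C[, qrC$pivot[seq_len(qrC$rank)], drop = FALSE]
    qrC <- qr(C)
  }
  df_resid <- n - ncol(C) - 1
  proj <- function(M) M - C %*% qr.coef(qrC, M)

  feats <- if (expr$level == "isoform") {
    annotation$transcripts[, c("transcript_id", "chrom", "tss")]
  } else {
    data.frame(transcript_id = annotation$genes$gene_id,
               chrom = annotation$genes$chrom, tss = annotation$genes$tss,
               stringsAsFactors = FALSE)
  }
  feats <- feats[feats$transcript_id %in% expr$feature_ids, , drop = FALSE]
  mono <- apply(panel$dosages, 2, stats::sd) == 0
  if (any(mono)) message("skipping ", sum(mono), " monomorphic SNP(s)")

  out <- lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    cis <- cis_snps(map, f$chrom, f$tss, f$tss, window)
    cis <- cis[!mono[cis]]
    if (!length(cis)) return(NULL)
    Xr <- proj(panel$dosages[, cis, drop = FALSE])
    yr <- as.vector(proj(expr$values[, f$transcript_id, drop = FALSE]))
    ssx <- colSums(Xr^2)
    beta <- as.vector(crossprod(Xr, yr)) / ssx
    rss <- sum(yr^2) - beta^2 * ssx
    se <- sqrt(pmax(rss, 0) / df_resid / ssx)
    tval <- beta / se
    data.frame(feature_id = f$transcript_id, snp_id = cis, beta = beta,
               se = se, p_wald = 2 * stats::pt(-abs(tval), df_resid),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-SNP posterior probability of causality at a locus
#'
#' eCAVIAR-style per-trait fine-mapping: enumerate causal SNP
#' configurations up to `max_causal` under `z ~ MVN(0, V)` (null) against
#' `MVN(0, V + prior_var V_c V_c')` (causal set c), with an independent
#' Bernoulli(1/m) prior, and return each SNP's marginal inclusion
#' posterior. Near-duplicate SNPs (|r| > 0.99) are greedily pruned before
#' enumeration (keeping the larger |z|); pruned SNPs inherit the posterior
#' of their retained proxy.
#'
#' @param z Per-SNP z-scores, named by snp_id.
#' @param V LD correlation matrix.
#' @param max_causal Configuration size cap (default 2).
#' @param prior_p Per-SNP prior (default 1/m).
#' @param prior_var Prior variance of a causal SNP's z-score (default
#'   5.2^2, the conventional non-centrality scale).
#' @param max_snps Enumeration guard on locus size (default 100).
#' @return Named per-SNP posterior vector; attribute `"null_posterior"`.
#' @export
snp_causal_posterior <- function(z, V, max_causal = 2L, prior_p = NULL,
                                 prior_var = 5.2^2, max_snps = 100L) {
  m <- length(z)
  stopifnot(nrow(V) == m, ncol(V) == m)
  if (is.null(names(z))) names(z) <- colnames(V)
  ids <- names(z)
  # Greedy pruning of near-duplicate SNPs.
  keep <- integer(0)
  proxy <- stats::setNames(integer(m), ids)
  for (j in order(-abs(z))) {
    if (!length(keep) || all(abs(V[j, keep]) <= 0.99)) {
      keep <- c(keep, j)
      proxy[j] <- j
    } else {
      proxy[j] <- keep[which(abs(V[j, keep]) > 0.99)[1]]
    }
  }
  keep <- sort(keep)
  if (length(keep) > max_snps) {
    stop("locus has ", length(keep), " SNPs after pruning; enumeration capped at ",
         max_snps)
  }
  Vk <- V[keep, keep, drop = FALSE]
  ridge <- 0
  if (inherits(tryCatch(chol(Vk), error = function(e) e), "error")) {
    ridge <- 1e-4
    Vk <- Vk + diag(ridge, length(keep))
  }
  pp <- if (is.null(prior_p)) 1 / length(keep) else prior_p
  res <- .enumerate_posterior(z[keep], Vk, pp, prior_var,
                              min(max_causal, length(keep)))
  post_keep <- stats::setNames(res$pip, ids[keep])
  out <- post_keep[ids[proxy]]
  names(out) <- ids
  structure(out, null_posterior = res$null_posterior, ridge = ridge)
}

#' Colocalization posterior probability
#'
#' `clpp = sum_j gwas_posterior_j * qtl_posterior_j`: the posterior that
#' one SNP is causal for both the trait and the expression feature, summed
#' over SNPs. Both posteriors must be on the identical SNP list.
#'
#' @param gwas_posterior,qtl_posterior Named per-SNP causal posteriors.
#' @return CLPP in [0, 1].
#' @export
clpp_score <- function(gwas_posterior, qtl_posterior) {
  if (length(gwas_posterior) != length(qtl_posterior)) {
    stop("posteriors must cover identical SNP lists")
  }
  if (!is.null(names(gwas_posterior)) && !is.null(names(qtl_posterior)) &&
      !identical(names(gwas_posterior), names(qtl_posterior))) {
    stop("posteriors must cover identical SNP lists (intersect upstream)")
  }
  min(sum(as.numeric(gwas_posterior) * as.numeric(qtl_posterior)), 1)
}

#' Call a colocalized feature
#'
#' A feature colocalizes with a GWAS locus iff a SNP has (1) a strong GWAS
#' effect (P below `gwas_p_max`), (2) a strong QTL effect (P below
#' `qtl_p_max`), and (3) the CLPP exceeds `clpp_min`. All three conditions
#' are strict.
#'
#' @param gwas_min_p Minimum GWAS p-value at the locus.
#' @param qtl_min_p Minimum QTL p-value for the feature.
#' @param clpp Colocalization posterior probability.
#' @param gwas_p_max,qtl_p_max,clpp_min Thresholds (defaults 5e-8, 1e-6,
#'   0.01).
#' @return Logical.
#' @export
coloc_call <- function(gwas_min_p, qtl_min_p, clpp,
                       gwas_p_max = 5e-8, qtl_p_max = 1e-6, clpp_min = 0.01) {
  gwas_min_p < gwas_p_max & qtl_min_p < qtl_p_max & clpp > clpp_min
}

#' Colocalize one feature's QTL signal with the GWAS at a locus
#'
#' @param gwas Harmonized GWAS summary rows at the locus.
#' @param qtl QTL records for one feature (from [map_cis_qtl()]).
#' @param V LD matrix on the shared SNPs.
#' @inheritParams snp_causal_posterior
#' @inheritParams coloc_call
#' @return One-row data.frame: feature_id, clpp, gwas_min_p, qtl_min_p,
#'   colocalized.
#' @export
colocalize_feature <- function(gwas, qtl, V, max_causal = 2L,
                               prior_var = 5.2^2, gwas_p_max = 5e-8,
                               qtl_p_max = 1e-6, clpp_min = 0.01) {
  shared <- Reduce(intersect, list(gwas$snp_id, qtl$snp_id, colnames(V)))
  if (length(shared) < 1) stop("no shared SNPs between GWAS and QTL records")
  Vs <- V[shared, shared, drop = FALSE]
  zg <- stats::setNames(gwas$z[match(shared, gwas$snp_id)], shared)
  qq <- qtl[match(shared, qtl$snp_id), ]
  zq <- stats::setNames(qq$beta / qq$se, shared)
  pg <- snp_causal_posterior(zg, Vs, max_causal = max_causal,
                             prior_var = prior_var)
  pq <- snp_causal_posterior(zq, Vs, max_causal = max_causal,
                             prior_var = prior_var)
  clpp <- clpp_score(pg, pq)
  gwas_min_p <- min(2 * stats::pnorm(-abs(zg)))
  qtl_min_p <- min(qq$p_wald)
  data.frame(feature_id = qtl$feature_id[1], clpp = clpp,
             gwas_min_p = gwas_min_p, qtl_min_p = qtl_min_p,
             colocalized = coloc_call(gwas_min_p, qtl_min_p, clpp,
                                      gwas_p_max, qtl_p_max, clpp_min),
             stringsAsFactors = FALSE)
}
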