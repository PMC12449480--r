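# Bayesian fine-mapping of correlated TWAS/isoTWAS association statistics:
# induced feature correlations, posterior inclusion probabilities by
# configuration enumeration, and 90% credible sets.

#' Correlation of genetically predicted expression induced by LD
#'
#' For features a, b with weight vectors embedded on the union SNP set,
#' `omega_ab = w_a' V w_b / sqrt(w_a' V w_a * w_b' V w_b)`. Degenerate
#' features (quadratic form <= 1e-12) are excluded with a warning.
#'
#' @param models List of `weight_model` objects.
#' @param V LD correlation matrix with dimnames covering all model SNPs.
#' @return A `feature_correlation`: list with `feature_ids` and `omega`.
#' @export
induced_correlation <- function(models, V) {
  ids <- vapply(models, `[[`, character(1), "feature_id")
  snps <- sort(unique(unlist(lapply(models, function(m) names(m$weights)))))
  snps <- intersect(snps, colnames(V))
  if (!length(snps)) stop("no model SNPs found in the LD matrix")
  W <- matrix(0, length(snps), length(models), dimnames = list(snps, ids))
  for (j in seq_along(models)) {
    w <- models[[j]]$weights
    w <- w[names(w) %in% snps]
    W[names(w), j] <- w
  }
  S <- t(W) %*% V[snps, snps] %*% W
  d <- diag(S)
  ok <- d > 1e-12
  if (!all(ok)) {
    warning("excluding degenerate feature(s): ", paste(ids[!ok], collapse = ", "))
    S <- S[ok, ok, drop = FALSE]
    d <- d[ok]
    ids <- ids[ok]
  }
  omega <- S / sqrt(outer(d, d))
  omega <- (omega + t(omega)) / 2
  diag(omega) <- 1
  structure(list(feature_ids = ids, omega = omega),
            class = "feature_correlation")
}

#' Group significant features into overlapping loci
#'
#' Single-linkage clustering along each chromosome: two features join the
#' same locus when their gene bodies lie within `window` of each other
#' (chains propagate membership).
#'
#' @param records Association data.frame with feature_id, gene_id (and
#'   optionally level).
#' @param annotation A `tx_annotation` supplying gene-body coordinates.
#' @param window Linking distance in bp (default 1 Mb).
#' @return `records` with a `locus_id` column added.
#' @export
group_overlapping <- function(records, annotation, window = 1e6) {
  g <- annotation$genes
  ix <- match(records$gene_id, g$gene_id)
  if (anyNA(ix)) stop("unknown gene_id(s): ",
                      paste(unique(records$gene_id[is.na(ix)]), collapse = ", "))
  records$chrom <- g$chrom[ix]
  records$gene_start <- g$gene_start[ix]
  records$gene_end <- g$gene_end[ix]
  records$locus_id <- NA_character_
  locus_n <- 0L
  for (ch in unique(records$chrom)) {
    sel <- which(records$chrom == ch)
    sel <- sel[order(records$gene_start[sel])]
    cur_end <- -Inf
    for (i in sel) {
      if (records$gene_start[i] > cur_end + window) {
        locus_n <- locus_n + 1L
        cur_end <- records$gene_end[i]
      } else {
        cur_end <- max(cur_end, records$gene_end[i])
      }
      records$locus_id[i] <- sprintf("locus%03d", locus_n)
    }
  }
  records
}

#' @noRd
.config_log_bf <- function(z, R, idx, prior_var) {
  # log Bayes factor of causal configuration idx against the null, under
  # z ~ MVN(0, R) (null) vs MVN(0, R + prior_var * R[,idx] R[idx,]) (causal).
  if (!length(idx)) return(0)
  Rc <- R[, idx, drop = FALSE]
  S1 <- R + prior_var * Rc %*% t(Rc)
  .log_dmvnorm0(z, S1) - .log_dmvnorm0(z, R)
}

#' @noRd
.enumerate_posterior <- function(z, R, prior_p, prior_var, max_causal) {
  # Shared engine for feature- and SNP-level fine-mapping: enumerate causal
  # configurations up to size max_causal (plus the null), weight by the
  # independent-Bernoulli prior and MVN Bayes factor, return marginal
  # inclusion posteriors and the null posterior.
  k <- length(z)
  prior_p <- rep_len(prior_p, k)
  configs <- list(integer(0))
  for (s in seq_len(max_causal)) {
    configs <- c(configs,
                 if (s == 1) as.list(seq_len(k))
                 else unlist(apply(utils::combn(k, s), 2, list), recursive = FALSE))
  }
  log_prior <- vapply(configs, function(ix) {
    inc <- rep(FALSE, k)
    inc[ix] <- TRUE
    sum(log(ifelse(inc, prior_p, 1 - prior_p)))
  }, numeric(1))
  log_bf <- vapply(configs, function(ix) .config_log_bf(z, R, ix, prior_var),
                   numeric(1))
  lp <- log_prior + log_bf
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  pip <- vapply(seq_len(k), function(a) {
    sum(post[vapply(configs, function(ix) a %in% ix, logical(1))])
  }, numeric(1))
  list(pip = pip, null_posterior = post[1], configs = configs, posterior = post)
}

#' Posterior inclusion probabilities for a locus's features
#'
#' Enumerates causal feature configurations up to `max_causal` (including
#' the empty configuration) under a spike-and-slab model: given a causal
#' set c, the association z-scores are multivariate normal with covariance
#' `omega + prior_var * omega[,c] omega[c,]`. Configuration posteriors use
#' an independent Bernoulli(`prior_p`) prior; the per-feature PIP is the
#' posterior mass of configurations containing it.
#'
#' @param z Association z-scores, named by feature id (or a
#'   `feature_correlation`-aligned vector).
#' @param omega A `feature_correlation` or plain correlation matrix.
#' @param prior_p Per-feature prior causal probability (default the
#'   non-informative 1/k).
#' @param prior_var Prior variance of a causal feature's association
#'   z-score (default 40, a conventional scale for burden-statistic
#'   fine-mapping).
#' @param max_causal Maximum causal features per configuration (default 1;
#'   enumeration supported up to `min(k, 3)` unless overridden).
#' @return A `finemap_result`: data.frame feature_id, pip (sorted as
#'   input), with attributes `null_posterior` and `ridge`.
#' @export
compute_pips <- function(z, omega, prior_p = NULL, prior_var = 40,
                         max_causal = 1L) {
  R <- if (inherits(omega, "feature_correlation")) omega$omega else omega
  ids <- if (inherits(omega, "feature_correlation")) omega$feature_ids
         else if (!is.null(colnames(R))) colnames(R)
         else names(z)
  k <- length(z)
  stopifnot(nrow(R) == k)
  if (k > 30) stop("exhaustive enumeration guarded at k <= 30 features")
  if (is.null(ids)) ids <- paste0("feature", seq_len(k))
  if (is.null(prior_p)) prior_p <- 1 / k
  max_causal <- min(max_causal, k)
  ridge_used <- 0
  if (inherits(tryCatch(chol(R), error = function(e) e), "error")) {
    ridge_used <- 1e-4
    R <- R + diag(ridge_used, k)
  }
  res <- .enumerate_posterior(as.numeric(z), R, prior_p, prior_var, max_causal)
  out <- data.frame(feature_id = ids, pip = res$pip, stringsAsFactors = FALSE)
  structure(out, class = c("finemap_result", "data.frame"),
            null_posterior = res$null_posterior, ridge = ridge_used,
            level = NA_real_)
}

#' 90% credible set of features
#'
#' Features are sorted by PIP (ties broken by feature id); the credible set
#' is the smallest prefix whose cumulative PIP, normalized by the non-null
#' posterior mass, reaches `level`. If the total mass cannot reach `level`
#' every feature is returned and the result is flagged.
#'
#' @param result A `finemap_result` from [compute_pips()].
#' @param level Coverage level (default 0.90).
#' @return Character vector of feature ids; attribute `"complete"` is FALSE
#'   when the mass was insufficient.
#' @export
credible_set <- function(result, level = 0.90) {
  stopifnot(inherits(result, "finemap_result"))
  ord <- order(-result$pip, result$feature_id)
  pip <- result$pip[ord]
  null_mass <- attr(result, "null_posterior")
  denom <- if (!is.null(null_mass)) max(sum(pip), 1 - null_mass) else sum(pip)
  # Raw posterior mass too small to certify the level: return everything.
  if (denom <= 0 || sum(pip) < level - 1e-12) {
    out <- result$feature_id[ord]
    attr(out, "complete") <- FALSE
    return(out)
  }
  cum <- cumsum(pip) / denom
  n_take <- which(cum >= level - 1e-12)[1]
  out <- result$feature_id[ord][seq_len(n_take)]
  attr(out, "complete") <- TRUE
  out
}

#' Fine-map every locus in an association table
#'
#' Convenience wrapper: groups significant records into loci, builds the
#' induced correlation per locus from the retained models, computes PIPs
#' and the 90% credible set.
#'
#' @param records Significant association records (with gene_id).
#' @param models Named list of `weight_model`s keyed by feature_id.
#' @param V LD matrix.
#' @param annotation A `tx_annotation`.
#' @inheritParams compute_pips
#' @param level Credible-set coverage.
#' @return data.frame: locus_id, feature_id, pip, in_credible_set, level.
#' @export
finemap_loci <- function(records, models, V, annotation, prior_var = 40,
                         max_causal = 1L, level = 0.90) {
  grouped <- group_overlapping(records, annotation)
  out <- lapply(split(grouped, grouped$locus_id), function(loc) {
    ms <- models[loc$feature_id]
    om <- induced_correlation(ms, V)
    keep <- match(om$feature_ids, loc$feature_id)
    fr <- compute_pips(loc$z_assoc[keep], om, max_causal = max_causal,
                       prior_var = prior_var)
    cs <- credible_set(fr, level)
    data.frame(locus_id = loc$locus_id[1], feature_id = fr$feature_id,
               pip = fr$pip, in_credible_set = fr$feature_id %in% cs,
               level = level, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
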