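# Shared fixture builders: all synthetic, constructed in code at test time.

# Block-diagonal AR(1) LD matrix with named SNPs.
make_block_V <- function(m, block_size = 10, rho = 0.5) {
  bs <- block_size
  blk <- outer(seq_len(bs), seq_len(bs), function(i, j) rho^abs(i - j))
  V <- matrix(0, m, m)
  for (s in seq(1, m, bs)) {
    e <- min(s + bs - 1, m)
    V[s:e, s:e] <- blk[seq_len(e - s + 1), seq_len(e - s + 1)]
  }
  dimnames(V) <- list(paste0("s", seq_len(m)), paste0("s", seq_len(m)))
  V
}

# Draw z ~ MVN(sqrt(n) V b, V) using per-block Cholesky (V block-diagonal).
draw_block_z <- function(V, b, n_gwas, block_size = 10) {
  m <- nrow(V)
  mu <- sqrt(n_gwas) * as.vector(V %*% b)
  eps <- numeric(m)
  for (s in seq(1, m, block_size)) {
    e <- min(s + block_size - 1, m)
    L <- chol(V[s:e, s:e])
    eps[s:e] <- as.vector(t(L) %*% rnorm(e - s + 1))
  }
  stats::setNames(mu + eps, colnames(V))
}

# Hand-built genotype panel from an explicit dosage matrix.
make_panel <- function(dosages, chrom = "1", start = 1e5, spacing = 5e3) {
  m <- ncol(dosages)
  map <- snp_map(m, chrom = chrom, start = start, spacing = spacing)
  colnames(dosages) <- map$snp_id
  rownames(dosages) <- sprintf("ind%03d", seq_len(nrow(dosages)))
  structure(list(dosages = dosages, snp_map = map,
                 maf = pmin(colMeans(dosages) / 2, 1 - colMeans(dosages) / 2)),
            class = "genotype_panel")
}

# Minimal weight_model constructor for tests.
make_model <- function(feature_id, weights, level = "isoform", cv_r2 = 0.5) {
  structure(list(feature_id = feature_id, level = level,
                 snp_ids = names(weights), weights = weights, cv_r2 = cv_r2,
                 family = "enet", n_train = 100L, fold_seed = 1L),
            class = "weight_model")
}

# Independent brute-force posterior over all causal configurations of sizes
# 0..max_causal: same Bayesian model as the package, written as a literal
# loop over subsets for oracle comparisons.
brute_force_posterior <- function(z, R, prior_p, prior_var, max_causal) {
  k <- length(z)
  ldmvn <- function(x, S) {
    # direct log-density via solve/determinant (different route than chol
    # backsolve used in the package)
    -0.5 * k * log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
      0.5 * as.numeric(t(x) %*% solve(S) %*% x)
  }
  subsets <- list(integer(0))
  for (s in seq_len(max_causal)) {
    subsets <- c(subsets, combn(k, s, simplify = FALSE))
  }
  wts <- sapply(subsets, function(ix) {
    inc <- seq_len(k) %in% ix
    lp <- sum(log(ifelse(inc, prior_p, 1 - prior_p)))
    S <- R
    if (length(ix)) {
      Rc <- R[, ix, drop = FALSE]
      S <- R + prior_var * Rc %*% t(Rc)
    }
    lp + ldmvn(z, S)
  })
  post <- exp(wts - max(wts))
  post <- post / sum(post)
  pip <- sapply(seq_len(k), function(a) {
    sum(post[sapply(subsets, function(ix) a %in% ix)])
  })
  list(pip = pip, null = post[1])
}
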