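# Synthetic-data generator: genotypes, variant QC, expression, GWAS.

test_that("dosages are allele counts with the requested frequency", {
  map <- snp_map(10, spacing = 6000)
  p <- simulate_genotypes(200, map, maf_range = c(0.5, 0.5), rho = 0,
                          seed = 11)
  expect_true(all(p$dosages %in% 0:2))
  # Binomial(2, 0.5): mean 1, SE sqrt(0.5/200) per SNP
  expect_true(all(abs(colMeans(p$dosages) - 1) < 3 * sqrt(0.5 / 200)))
})

test_that("rho = 0 gives near-independent SNPs", {
  p <- simulate_genotypes(500, snp_map(30, spacing = 6000),
                          maf_range = c(0.1, 0.5), rho = 0, seed = 12)
  V <- ld_matrix(p)
  off <- abs(V[upper.tri(V)])
  expect_lt(mean(off), 0.1)
})

test_that("within-block adjacent LD tracks the requested rho", {
  p <- simulate_genotypes(2000, snp_map(60, spacing = 6000),
                          maf_range = c(0.3, 0.5), rho = 0.9,
                          block_size = 20, seed = 13)
  V <- ld_matrix(p)
  adj <- diag(V[-1, -ncol(V)])
  adj <- adj[-c(20, 40)] # block boundaries are independent
  expect_gte(mean(adj), 0.8)
  expect_lte(mean(adj), 0.95)
})

test_that("impossible LD and bad frequency ranges are rejected", {
  map <- snp_map(10)
  expect_error(simulate_genotypes(100, map, rho = 1), "positive-definite")
  expect_error(simulate_genotypes(100, map, maf_range = c(0, 0.5)))
  expect_error(simulate_genotypes(100, map, maf_range = c(0.1, 0.6)))
})

test_that("empirical LD converges to the generator's block structure", {
  map <- snp_map(40, spacing = 6000)
  args <- list(map = map, maf_range = c(0.3, 0.5), rho = 0.7, block_size = 10)
  ref <- ld_matrix(do.call(simulate_genotypes, c(list(n = 40000, seed = 99), args)))
  d <- sapply(c(200, 2000, 20000), function(n) {
    V <- ld_matrix(do.call(simulate_genotypes, c(list(n = n, seed = n), args)))
    norm(V - ref, "F")
  })
  expect_true(all(diff(d) < 0))
})

test_that("exact HWE test matches an independent enumeration oracle", {
  # Oracle: closed-form conditional probability with the explicit
  # normalization constant choose(2n, n_minor).
  hwe_oracle <- function(naa, nab, nbb) {
    n <- naa + nab + nbb
    nm <- min(2 * naa + nab, 2 * nbb + nab)
    hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
    pr <- sapply(hets, function(h) {
      a <- (nm - h) / 2
      b <- n - a - h
      exp(lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(h) +
            h * log(2) + lfactorial(nm) + lfactorial(2 * n - nm) -
            lfactorial(2 * n))
    })
    expect_equal(sum(pr), 1, tolerance = 1e-9) # sanity on the oracle itself
    obs <- pr[match(nab, hets)]
    sum(pr[pr <= obs + 1e-12])
  }
  cases <- list(c(25, 50, 25), c(0, 100, 0), c(60, 30, 10), c(5, 40, 55),
                c(90, 9, 1))
  for (ct in cases) {
    expect_equal(hwe_exact_test(ct[1], ct[2], ct[3]),
                 hwe_oracle(ct[1], ct[2], ct[3]), tolerance = 1e-9)
  }
  expect_equal(hwe_exact_test(25, 50, 25), 1)
})

test_that("variant filters remove low-MAF and HWE-violating SNPs", {
  # 100 individuals; col1: MAF 0.04, HWE-consistent; col2: perfect
  # proportions; col3: all heterozygous (gross HWE violation).
  d1 <- c(rep(1, 8), rep(0, 92))
  d2 <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  d3 <- rep(1, 100)
  p <- make_panel(cbind(d1, d2, d3))
  f <- filter_variants(p, maf_min = 0.05, hwe_p_min = 1e-5)
  rep_ <- attr(f, "filter_report")
  expect_false(rep_$pass[1]) # MAF 0.04 < 5%
  expect_true(rep_$pass[2])  # exact HWE P = 1 at perfect proportions
  expect_false(rep_$pass[3]) # all-het wildly out of HWE
  expect_equal(colnames(f$dosages), p$snp_map$snp_id[2])

  ext <- setNames(c(0.2, 0.005, 0.2), p$snp_map$snp_id)
  expect_error(
    filter_variants(p, maf_min = 0.05, hwe_p_min = 1e-5, external_maf = ext),
    "every SNP"
  )
})

test_that("isoform expression carries its target cis-heritability", {
  map <- snp_map(30, spacing = 6000)
  p <- simulate_genotypes(5000, map, maf_range = c(0.2, 0.5), rho = 0.4,
                          seed = 21)
  ann <- simulate_annotation(1, 2, first_start = 1.5e5, gene_length = 4e4,
                             seed = 22)
  sim <- simulate_isoform_expression(p, ann, n_causal = 2, h2_cis = 0.3,
                                     seed = 23)
  X <- scale(p$dosages)
  for (t_id in ann$transcripts$transcript_id) {
    bk <- sim$truth$eqtl_effects[[t_id]]
    g <- as.vector(X[, names(bk), drop = FALSE] %*% bk)
    ratio <- var(g) / var(sim$isoform$values[, t_id])
    expect_gte(ratio, 0.25)
    expect_lte(ratio, 0.35)
  }
})

test_that("degenerate heritability settings behave as constructed", {
  map <- snp_map(20, spacing = 6000)
  p <- simulate_genotypes(300, map, seed = 31)
  ann <- simulate_annotation(1, 2, first_start = 1.5e5, gene_length = 4e4,
                             seed = 32)
  sim0 <- simulate_isoform_expression(p, ann, h2_cis = 0, seed = 33)
  expect_true(all(lengths(sim0$truth$eqtl_effects) == 0))
  v <- apply(sim0$isoform$values, 2, var)
  expect_true(all(abs(v - 1) < 0.1)) # pure noise at unit variance

  sim1 <- simulate_isoform_expression(p, ann, h2_cis = 1, seed = 34)
  X <- scale(p$dosages)
  for (t_id in ann$transcripts$transcript_id) {
    bk <- sim1$truth$eqtl_effects[[t_id]]
    g <- as.vector(X[, names(bk), drop = FALSE] %*% bk)
    expect_lt(max(abs(g - sim1$isoform$values[, t_id])), 1e-10)
  }
})

test_that("gene expression is exactly the sum of its isoforms", {
  p <- simulate_genotypes(200, snp_map(20, spacing = 6000), seed = 41)
  ann <- simulate_annotation(2, 3, first_start = 1.5e5, gene_length = 3e4,
                             gene_gap = 1e5, seed = 42)
  sim <- simulate_isoform_expression(p, ann, seed = 43)
  for (g in ann$genes$gene_id) {
    t_ids <- ann$transcripts$transcript_id[ann$transcripts$gene_id == g]
    expect_equal(sim$gene$values[, g],
                 rowSums(sim$isoform$values[, t_ids, drop = FALSE]))
  }
  expect_error(
    simulate_isoform_expression(p, ann, n_causal = 100, seed = 44),
    "causal SNPs"
  )
})

test_that("recorded mediated heritability matches its empirical value", {
  map <- snp_map(30, spacing = 6000)
  p <- simulate_genotypes(20000, map, maf_range = c(0.2, 0.5), rho = 0.4,
                          seed = 51)
  ann <- simulate_annotation(1, 2, first_start = 1.5e5, gene_length = 4e4,
                             seed = 52)
  alpha <- setNames(c(0.4, -0.25), ann$transcripts$transcript_id)
  sim <- simulate_isoform_expression(p, ann, h2_cis = 0.4, alpha = alpha,
                                     n_direct_snps = 3, h2_direct = 0.05,
                                     seed = 53)
  tr <- sim$truth
  X <- scale(p$dosages)
  # rebuild the trait empirically on the raw scale:
  # trait = sum_k alpha_k y_k + X delta + e0
  delta_raw <- tr$direct_snp_effects * sqrt(tr$var_trait)
  set.seed(54)
  trait <- as.vector(sim$isoform$values %*% tr$alpha) +
    as.vector(X %*% delta_raw) +
    rnorm(nrow(X), sd = sqrt(tr$sigma0_sq))
  b_med_raw <- tr$b_mediated * sqrt(tr$var_trait)
  y_med <- as.vector(X %*% b_med_raw)
  expect_equal(var(y_med) / var(trait), tr$h2_med_true, tolerance = 0.5) # rel
  expect_lt(abs(var(y_med) / var(trait) - tr$h2_med_true), 0.03)
})

test_that("null GWAS z-scores are central chi-square", {
  map <- snp_map(250, spacing = 6000)
  p <- simulate_genotypes(300, map, maf_range = c(0.2, 0.5), rho = 0,
                          seed = 61)
  ann <- simulate_annotation(1, 2, first_start = 6e5, gene_length = 4e4,
                             seed = 62)
  sim <- simulate_isoform_expression(p, ann, h2_cis = 0.3, alpha = 0,
                                     seed = 63)
  V <- diag(250)
  dimnames(V) <- list(map$snp_id, map$snp_id)
  chi2 <- unlist(lapply(1:4, function(s) {
    simulate_gwas_summary(V, sim$truth, 5e4, seed = 70 + s)$z^2
  }))
  expect_lt(abs(mean(chi2) - 1), 3 * sqrt(2 / length(chi2)))
})

test_that("a single causal SNP shifts only its own z-score", {
  map <- snp_map(20, spacing = 6000)
  p <- simulate_genotypes(300, map, maf_range = c(0.3, 0.5), rho = 0,
                          seed = 71)
  ann <- simulate_annotation(1, 1, first_start = 1.5e5, gene_length = 3e4,
                             seed = 72)
  sim <- simulate_isoform_expression(p, ann, n_causal = 1, h2_cis = 0.2,
                                     alpha = 0.5, seed = 73)
  b <- sim$truth$b
  j <- which(b != 0)
  expect_length(j, 1)
  V <- diag(20)
  dimnames(V) <- list(map$snp_id, map$snp_id)
  n_gwas <- 1e4
  Z <- sapply(1:200, function(s) {
    simulate_gwas_summary(V, sim$truth, n_gwas, seed = 100 + s)$z
  })
  zbar <- rowMeans(Z)
  expect_equal(zbar[j], sqrt(n_gwas) * b[j], tolerance = 3 / sqrt(200),
               ignore_attr = TRUE)
  expect_lt(max(abs(zbar[-j])), 4 / sqrt(200))
})

test_that("analytic and individual-level GWAS modes agree in distribution", {
  map <- snp_map(30, spacing = 6000)
  p <- simulate_genotypes(1000, map, maf_range = c(0.2, 0.5), rho = 0.5,
                          block_size = 10, seed = 81)
  ann <- simulate_annotation(1, 2, first_start = 1.5e5, gene_length = 4e4,
                             seed = 82)
  alpha <- setNames(c(0.4, 0.3), ann$transcripts$transcript_id)
  sim <- simulate_isoform_expression(p, ann, h2_cis = 0.4, alpha = alpha,
                                     seed = 83)
  V <- ld_matrix(p)
  n_gwas <- 2000
  za <- rowMeans(sapply(1:60, function(s) {
    simulate_gwas_summary(V, sim$truth, n_gwas, mode = "analytic",
                          seed = 200 + s)$z
  }))
  zi <- rowMeans(sapply(1:60, function(s) {
    simulate_gwas_summary(V, sim$truth, n_gwas, mode = "individual",
                          seed = 400 + s)$z
  }))
  # both estimate sqrt(n) V b; each mean has SE ~ 1/sqrt(60)
  expect_lt(max(abs(za - zi)), 5 / sqrt(60) + 0.15 * max(abs(za)))
  expect_gt(cor(za, zi), 0.98)
})
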