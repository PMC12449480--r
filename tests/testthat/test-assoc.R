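# Weighted burden test, ACAT, two-stage adjustment, permutation filter,
# effective sample size.

make_gwas <- function(z, map) {
  data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
             a_ref = map$allele_ref, a_alt = map$allele_alt,
             beta = z / 100, se = 1 / 100, z = z, n = 10000L,
             stringsAsFactors = FALSE)
}

test_that("burden test reduces to the single-SNP z and the closed form", {
  map <- snp_map(3)
  V <- diag(3)
  dimnames(V) <- list(map$snp_id, map$snp_id)
  g <- make_gwas(c(2, 2, -1.3), map)
  # indicator weight picks out that SNP's z
  m1 <- make_model("f1", setNames(1, map$snp_id[3]))
  expect_equal(burden_test(m1, g, V)$z_assoc, -1.3)
  # V = I, w = (1,1), z = (2,2): z = 4/sqrt(2)
  m2 <- make_model("f2", setNames(c(1, 1), map$snp_id[1:2]))
  r <- burden_test(m2, g, V)
  expect_equal(r$z_assoc, 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(r$chisq, r$z_assoc^2, tolerance = 1e-12)
  expect_equal(r$p_raw, 2 * pnorm(-4 / sqrt(2)))
})

test_that("burden z is invariant to positive weight rescaling", {
  set.seed(1)
  map <- snp_map(8)
  p <- simulate_genotypes(300, map, maf_range = c(0.2, 0.5), rho = 0.5,
                          seed = 2)
  V <- ld_matrix(p)
  g <- make_gwas(rnorm(8), map)
  w <- setNames(rnorm(5), map$snp_id[2:6])
  z1 <- burden_test(make_model("a", w), g, V)$z_assoc
  z2 <- burden_test(make_model("a", w * 37.5), g, V)$z_assoc
  expect_lt(abs(z1 - z2), 1e-10)
})

test_that("degenerate weights raise an error", {
  map <- snp_map(2)
  V <- diag(2)
  dimnames(V) <- list(map$snp_id, map$snp_id)
  g <- make_gwas(c(1, 1), map)
  expect_error(burden_test(make_model("f", setNames(c(0, 0), map$snp_id)),
                           g, V), "degenerate")
})

test_that("summary-based burden z matches individual-level regression", {
  # Planted mediated effects: the summary statistic w'z/sqrt(w'Vw) should
  # track the z-score of regressing predicted expression on the phenotype
  # in the GWAS cohort itself.
  set.seed(3)
  n_gwas <- 20000
  m <- 60
  map <- snp_map(m, spacing = 6000)
  cohort <- simulate_genotypes(n_gwas, map, maf_range = c(0.2, 0.5),
                               rho = 0.5, block_size = 10, seed = 4)
  Xs <- scale(cohort$dosages)
  V <- ld_matrix(cohort)
  n_feat <- 60
  ws <- lapply(1:n_feat, function(i) {
    w <- setNames(numeric(m), map$snp_id)
    w[sample(map$snp_id, 3)] <- rnorm(3)
    w[w != 0]
  })
  alpha <- rnorm(n_feat, sd = 0.04)
  y <- rnorm(n_gwas)
  for (i in 1:n_feat) {
    y <- y + alpha[i] * as.vector(Xs[, names(ws[[i]]), drop = FALSE] %*% ws[[i]])
  }
  y <- as.vector(scale(y))
  r <- as.vector(crossprod(Xs, y)) / (n_gwas - 1)
  zg <- r * sqrt(n_gwas - 2) / sqrt(1 - r^2)
  gwas <- make_gwas(zg, map)
  z_sum <- sapply(1:n_feat, function(i) {
    burden_test(make_model(paste0("f", i), ws[[i]]), gwas, V)$z_assoc
  })
  z_ind <- sapply(1:n_feat, function(i) {
    pred <- as.vector(Xs[, names(ws[[i]]), drop = FALSE] %*% ws[[i]])
    ct <- cor.test(pred, y)
    sign(ct$estimate) * sqrt(ct$statistic^2)
  })
  expect_gt(cor(z_sum, z_ind), 0.99)
})

test_that("ACAT matches direct Cauchy-CDF evaluation", {
  acat_oracle <- function(p, w = rep(1 / length(p), length(p))) {
    pcauchy(sum(w * tan((0.5 - p) * pi)), lower.tail = FALSE)
  }
  expect_equal(acat_combine(0.05), 0.05, tolerance = 1e-12)
  expect_equal(acat_combine(c(0.05, 0.05, 0.05)), 0.05, tolerance = 1e-12)
  expect_equal(acat_combine(c(0.01, 0.5)), acat_oracle(c(0.01, 0.5)),
               tolerance = 1e-10)
  expect_equal(acat_combine(c(0.01, 0.5)), 0.0199803, tolerance = 1e-5)
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    expect_equal(acat_combine(p), acat_oracle(p), tolerance = 1e-10)
  }
  expect_error(acat_combine(numeric(0)), "at least one")
})

test_that("two-stage adjustment flags strong signals and applies Bonferroni", {
  set.seed(6)
  n_genes <- 1000
  recs <- data.frame(
    feature_id = paste0("t", 1:n_genes), gene_id = paste0("g", 1:n_genes),
    level = "isoform", p_raw = runif(n_genes), stringsAsFactors = FALSE
  )
  recs$p_raw[1] <- 1e-10
  out <- two_stage_adjust(recs)
  expect_true(out$significant[1])
  expect_lte(mean(out$significant[-1]), 0.01)

  two <- two_stage_adjust(data.frame(
    feature_id = c("a", "b"), gene_id = "g", level = "isoform",
    p_raw = c(1e-6, 0.9), stringsAsFactors = FALSE))
  expect_equal(two$p_fwer_within, c(2e-6, 1.0))
  expect_equal(two$p_gene_screen[1], acat_combine(c(1e-6, 0.9)))
})

test_that("permutation p-value is 1 for null or exchange-invariant weights", {
  map <- snp_map(6)
  V <- diag(6)
  dimnames(V) <- list(map$snp_id, map$snp_id)
  # z chosen orthogonal to w: z_obs = 0
  g <- make_gwas(c(1, -1, 0, 0, 0, 0), map)
  m0 <- make_model("f", setNames(c(1, 1), map$snp_id[1:2]))
  expect_equal(permutation_test(m0, g, V, B = 200, seed = 1), 1.0)
  # all weights equal: every permutation identical
  g2 <- make_gwas(c(3, 1, 2, 0.5, -1, 2), map)
  m1 <- make_model("f", setNames(rep(0.7, 6), map$snp_id))
  expect_equal(permutation_test(m1, g2, V, B = 200, seed = 2), 1.0)
})

test_that("few-SNP models fall back to exact enumeration", {
  map <- snp_map(2)
  V <- diag(2)
  dimnames(V) <- list(map$snp_id, map$snp_id)
  g <- make_gwas(c(4, 0), map)
  m <- make_model("f", setNames(c(1, 0.1), map$snp_id))
  # 2 arrangements; observed is the more extreme: p = (1 + 1)/(2 + 1)
  expect_warning(p <- permutation_test(m, g, V, B = 50, seed = 3), "coarse")
  expect_equal(p, 2 / 3)
})

test_that("permutation and raw p-values are rank-concordant under the null", {
  set.seed(7)
  map <- snp_map(8)
  V <- diag(8)
  dimnames(V) <- list(map$snp_id, map$snp_id)
  res <- t(replicate(200, {
    g <- make_gwas(rnorm(8), map)
    m <- make_model("f", setNames(rnorm(8), map$snp_id))
    c(p_raw = burden_test(m, g, V)$p_raw,
      p_perm = permutation_test(m, g, V, B = 300, seed = sample.int(1e6, 1)))
  }))
  expect_gt(cor(res[, "p_raw"], res[, "p_perm"], method = "spearman"), 0.9)
})

test_that("effective sample size estimator has its closed form and CI shape", {
  expect_equal(effective_sample_increase(c(2, 3, 4), c(2, 3, 4))$pct_increase, 0)
  r <- effective_sample_increase(c(3, 3, 3, 3), c(2, 2, 2, 2))
  expect_equal(r$pct_increase, 100)
  expect_equal(r$ci95, r$pct_increase + c(-1.96, 1.96) * r$se_jackknife)
  # a pair with chi2 <= 1 in both arms is dropped by the union filter
  r2 <- effective_sample_increase(c(3, 3, 0.5), c(2, 2, 0.9))
  expect_equal(r2$n_features_used, 2)
  expect_equal(r2$pct_increase, 100)
  expect_error(effective_sample_increase(c(1.2, 1.1), c(0.4, 0.5)),
               "undefined")
})

test_that("allele harmonization flips and drops correctly", {
  map <- snp_map(5)
  map$allele_alt[3] <- "T"          # SNP3 is strand-ambiguous A/T
  g <- make_gwas(c(1, 2, 3, 4, 5), map)
  g$a_ref <- c("A", "G", "A", "A", "C")  # SNP2 swapped vs map (A/G),
  g$a_alt <- c("G", "A", "T", "G", "T")  # SNP5 allele-incompatible
  out <- harmonize_gwas(g, map)
  expect_equal(out$snp_id, map$snp_id[c(1, 2, 4)])
  expect_equal(out$z, c(1, -2, 4))
  out2 <- harmonize_gwas(g, map, drop_ambiguous = FALSE)
  expect_equal(out2$snp_id, map$snp_id[1:4])
})
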