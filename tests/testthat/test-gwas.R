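test_that("scan thresholds follow the Bonferroni and suggestive rules", {
  th <- gwas_thresholds(6635)
  expect_equal(unname(th), c(0.05 / 6635, 1 / 6635))
  expect_equal(unname(gwas_thresholds(1)), c(0.05, 1))
  for (n in c(10, 500, 6635)) {
    th <- gwas_thresholds(n)
    expect_lt(th[["genome_wide"]], th[["suggestive"]])
  }
})

test_that("under iid covariance the scan reduces to ordinary least squares", {
  # permanent-environment + residual with one record per individual
  # makes V proportional to the identity
  cfg <- sim_config(n_sires = 12, dams_per_sire = 2, offspring_per_dam = 2,
                    n_snps = 60, harvest_age_range = c(3L, 3L), seed = 71)
  sim <- simulate_horn_study(cfg, traits = "length")
  phen <- sim$phenotypes[sim$phenotypes$age == 2, ]
  qc <- qc_genotypes(sim$genotypes)
  grm <- stabilize_grm(compute_grm(qc$genotypes))
  fit <- animal_model(phen, grm, trait = "length", random = "pe")
  scan <- gwas_scan(fit, qc$genotypes, genomic_control = FALSE)
  g <- qc$genotypes
  ii <- match(phen$id, g$ids)
  for (j in sample(ncol(g$calls), 8)) {
    ols <- coef(lm(phen$value ~ g$calls[ii, j]))[2]
    row <- scan$results[scan$results$snp == g$map$snp[j], ]
    expect_equal(row$beta, unname(ols), tolerance = 1e-8)
  }
})

test_that("scan effects match dense GLS on a six-observation fixture", {
  d <- data.frame(id = rep(c("a", "b", "c"), each = 2),
                  birth_year = rep(2000L, 6),
                  meas_year = rep(c(2002L, 2003L), 3),
                  age = rep(c(2L, 3L), 3),
                  trait = "length",
                  value = c(101.3, 118.2, 96.5, 119.8, 104.9, 125.7))
  K <- matrix(c(1, 0.5, 0.25, 0.5, 1, 0.25, 0.25, 0.25, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  grm <- structure(list(K = K, ids = c("a", "b", "c"), n_loci = 100L),
                   class = "grm")
  calls <- rbind(a = c(0L, 2L, 1L), b = c(1L, 1L, 0L), c = c(2L, 0L, 1L))
  g <- genotype_matrix(calls, data.frame(chrom = c(1, 1, 2),
                                         snp = c("s1", "s2", "s3"),
                                         pos = c(10L, 20L, 10L)))
  fit <- animal_model(d, grm, trait = "length",
                      random = c("additive", "pe"),
                      control = reml_control(max_iter = 50))
  scan <- gwas_scan(fit, g, genomic_control = FALSE)
  V <- dense_V(fit)
  ii <- match(d$id, g$ids)
  for (j in 1:3) {
    Xa <- cbind(fit$design$X, snp = g$calls[ii, j])
    oracle <- dense_gls_last(d$value, Xa, V)
    row <- scan$results[scan$results$snp == g$map$snp[j], ]
    expect_equal(row$beta, unname(oracle[["beta"]]), tolerance = 1e-10)
    expect_equal(row$se, unname(oracle[["se"]]), tolerance = 1e-10)
    expect_equal(row$wald, unname((oracle[["beta"]] / oracle[["se"]])^2),
                 tolerance = 1e-8)
  }
})

test_that("genomic lambda behaves as a regression slope", {
  m <- 500
  expected <- qchisq((1:m - 0.5) / m, df = 1)
  gl <- genomic_lambda(expected)
  expect_equal(gl$lambda, 1, tolerance = 1e-12)
  gl2 <- genomic_lambda(2 * expected)
  expect_equal(gl2$lambda, 2, tolerance = 1e-12)
  expect_equal(gl2$lambda_median, 2, tolerance = 1e-4)
  expect_error(genomic_lambda(rep(1, 5)), "at least 10")
})

test_that("a null scan is calibrated and ignoring relatedness inflates it", {
  st <- small_study()
  fit <- small_fit()
  scan <- gwas_scan(fit, st$qc$genotypes, genomic_control = FALSE)
  p <- scan$results$p
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(frac - 0.05), 5 * se)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.001)
  # same data scanned with V = sigma^2 I: related repeated measures
  # inflate the statistics
  fit_iid <- fit
  fit_iid$theta[] <- c(0, 0, 0, 0, sum(fit$theta))
  scan_iid <- gwas_scan(fit_iid, st$qc$genotypes, genomic_control = FALSE)
  expect_gt(scan_iid$lambda, scan$lambda)
  expect_gt(scan_iid$lambda, 1.1)
})

test_that("monomorphic and missing-call loci are handled per locus", {
  st <- small_study()
  fit <- small_fit()
  g <- st$qc$genotypes
  calls <- g$calls
  calls[, 1] <- 1L                       # monomorphic in everyone
  calls[3:6, 2] <- NA                    # partial missingness
  g2 <- genotype_matrix(calls, g$map, ids = g$ids)
  scan <- gwas_scan(fit, g2, genomic_control = FALSE)
  expect_equal(scan$n_monomorphic, 1)
  r1 <- scan$results[scan$results$snp == g$map$snp[1], ]
  expect_true(is.na(r1$beta) && is.na(r1$p))
  # missing-call locus: oracle drops those observations
  keep <- !(fit$design$ids %in% g$ids[3:6])
  V <- dense_V(fit)[keep, keep]
  ii <- match(fit$design$ids, g2$ids)
  Xa <- cbind(fit$design$X[keep, ], snp = g2$calls[ii, 2][keep])
  oracle <- dense_gls_last(fit$design$y[keep], Xa, V)
  r2 <- scan$results[scan$results$snp == g$map$snp[2], ]
  expect_equal(r2$beta, unname(oracle[["beta"]]), tolerance = 1e-8)
  expect_equal(r2$se, unname(oracle[["se"]]), tolerance = 1e-8)
})

test_that("scan output is ordered and consistent with its tables", {
  st <- small_study()
  fit <- small_fit()
  scan <- gwas_scan(fit, st$qc$genotypes)
  res <- scan$results
  ord <- order(hornherit:::chrom_order(res$chrom), res$pos)
  expect_equal(ord, seq_len(nrow(res)))
  tabs <- manhattan_qq_tables(scan)
  expect_equal(nrow(tabs$qq), sum(is.finite(res$p)))
  expect_equal(max(tabs$manhattan$neglog10p, na.rm = TRUE),
               -log10(min(res$p, na.rm = TRUE)))
  expect_true(all(diff(tabs$manhattan$cum_pos) > 0))
  # processing order must not matter: permute loci, results identical
  perm <- sample(ncol(st$qc$genotypes$calls))
  gp <- hornherit:::subset_genotypes(st$qc$genotypes, loci = perm)
  scan_perm <- gwas_scan(fit, gp)
  expect_equal(scan_perm$results, scan$results)
  expect_equal(scan_perm$lambda, scan$lambda)
})

test_that("a spiked causal SNP is detected above the suggestive threshold", {
  cfg0 <- small_config(seed = 91)
  sim0 <- simulate_horn_study(cfg0, traits = "length")
  maf <- minor_allele_freq(sim0$genotypes)
  locus <- which.min(abs(maf - 0.3))
  beta <- causal_effect_for_share(sim0$genotypes, locus, 0.3,
                                  cfg0$total_phenotypic_variance[["length"]])
  cfg <- small_config(seed = 91,
                      causal_snps = data.frame(locus = locus, effect = beta))
  sim <- simulate_horn_study(cfg, traits = "length")
  qc <- qc_genotypes(sim$genotypes)
  grm <- stabilize_grm(compute_grm(qc$genotypes))
  fit <- animal_model(sim$phenotypes, grm, trait = "length")
  scan <- gwas_scan(fit, qc$genotypes)
  snp_name <- sim0$genotypes$map$snp[locus]
  top <- scan$results[which.min(scan$results$p), ]
  expect_equal(top$snp, snp_name)
  expect_lt(top$p, scan$thresholds[["suggestive"]])
})

test_that("scan summaries and writers expose thresholds and hits", {
  st <- small_study()
  fit <- small_fit()
  scan <- gwas_scan(fit, st$qc$genotypes)
  summ <- summary(scan)
  expect_s3_class(summ, "summary.gwas_scan")
  prefix <- withr::local_tempfile()
  write_gwas(scan, prefix)
  res <- read.delim(paste0(prefix, ".tsv"))
  expect_equal(nrow(res), scan$n_snps)
  meta <- read.delim(paste0(prefix, ".summary.tsv"))
  expect_equal(meta$lambda, scan$lambda)
})
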