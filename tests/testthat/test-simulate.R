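test_that("founder genotypes follow the requested allele-frequency model", {
  # degenerate frequency range pins the pooled allele frequency at 0.5
  g <- simulate_founder_genotypes(200, 300, maf_range = c(0.5, 0.5), seed = 2)
  pooled <- mean(g$calls) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 200 * 300))
  expect_lt(abs(pooled - 0.5), 3 * se)

  g2 <- simulate_founder_genotypes(100, 500, maf_range = c(0.01, 0.5), seed = 1)
  expect_false(anyNA(g2$calls))
  expect_true(all(g2$calls %in% 0:2))
  p <- allele_freq(g2)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(sort(unique(g2$map$chrom)), 1:26)
  expect_true(all(g2$map$pos >= 1))

  expect_identical(simulate_founder_genotypes(30, 50, seed = 7),
                   simulate_founder_genotypes(30, 50, seed = 7))
  expect_error(simulate_founder_genotypes(10, 10, maf_range = c(0, 0.6)),
               "maf_range")
})

test_that("gene drop obeys Mendelian transmission", {
  # homozygous x homozygous -> offspring certainty
  ped <- sib_pedigree(1)
  L <- 50L
  founder <- genotype_matrix(
    matrix(0L, 2, L), snp_map(L)[seq_len(L), ], ids = c("S01", "D01"))
  off <- gene_drop(ped, founder, seed = 5)
  expect_true(all(off$calls[c("O001", "O002"), ] == 0L))

  # heterozygous x heterozygous -> 1:2:1 across many independent loci
  L <- 10000L
  founder <- genotype_matrix(
    matrix(1L, 2, L), snp_map(L), ids = c("S01", "D01"))
  off <- gene_drop(sib_pedigree(1, sibs = 1L), founder, seed = 8)
  counts <- tabulate(off$calls["O001", ] + 1L, nbins = 3)
  expect_gt(chisq.test(counts, p = c(1, 2, 1) / 4)$p.value, 0.001)
})

test_that("gene drop requires both parents known", {
  ped <- sib_pedigree(1)
  ped$dam[3] <- NA
  founder <- genotype_matrix(matrix(1L, 2, 10), snp_map(10),
                             ids = c("S01", "D01"))
  expect_error(gene_drop(ped, founder, seed = 1), "one known parent")
})

test_that("gene-dropped full sibs show relationship 1/2 in the GRM", {
  n_pairs <- 30L
  ped <- sib_pedigree(n_pairs)
  founder <- simulate_founder_genotypes(2L * n_pairs, 2000L,
                                        maf_range = c(0.1, 0.5), seed = 21,
                                        ids = ped$id[seq_len(2L * n_pairs)])
  dropped <- gene_drop(ped, founder, seed = 22)
  keep <- which(ped$phenotyped)
  g <- subset_all <- hornherit:::subset_genotypes(dropped, ind = keep)
  maf <- minor_allele_freq(g)
  g <- hornherit:::subset_genotypes(g, loci = which(maf > 0.05))
  K <- compute_grm(g)$K
  sib_entries <- K[cbind(seq(1, 2 * n_pairs, 2), seq(2, 2 * n_pairs, 2))]
  expect_lt(abs(mean(sib_entries) - 0.5), 0.05)
})

test_that("simulated phenotypes reduce to the growth curve without noise", {
  cfg <- sim_config(n_sires = 4, dams_per_sire = 2, offspring_per_dam = 1,
                    n_snps = 50, seed = 9,
                    total_phenotypic_variance = c(length = 1e-12,
                                                  circumference = 1e-12,
                                                  volume = 1e-12))
  sim <- simulate_horn_study(cfg, traits = "length")
  gp <- cfg$growth_params$length
  mu <- gp[["L_inf"]] * (1 - exp(-gp[["k"]] * sim$phenotypes$age))
  expect_lt(max(abs(sim$phenotypes$value - mu)), 1e-4)
})

test_that("phenotype generation matches its variance-component targets", {
  # realized decomposition of the stored true effect draws at the default
  # 180-ram design stays within Monte-Carlo error of the generating values
  cfg <- sim_config(seed = 31)
  sim <- simulate_horn_study(cfg, traits = "length")
  truth <- attr(sim$phenotypes, "truth")$length
  d <- sim$phenotypes
  ii <- match(d$id, truth$ids)
  real <- c(
    va = var(truth$breeding_values[ii]),
    vpe = var(truth$permanent_env[ii]),
    vyb = var(truth$birth_year_effects[as.character(d$birth_year)]),
    vym = var(truth$meas_year_effects[as.character(d$meas_year)]),
    vr = var(truth$residuals)
  )
  real_prop <- real / sum(real)
  target <- cfg$variance_proportions$length[names(real_prop)]
  # breeding values dominate the Monte-Carlo error at n = 180
  expect_lt(max(abs(real_prop - target)), 0.06)
  expect_equal(truth$h2, 0.33)
})

test_that("a large causal SNP effect is recovered by naive regression", {
  cfg0 <- sim_config(n_sires = 25, dams_per_sire = 3, offspring_per_dam = 3,
                     n_snps = 200, seed = 13)
  sim0 <- simulate_horn_study(cfg0, traits = "length")
  locus <- which.max(minor_allele_freq(sim0$genotypes))
  beta <- 30 * sqrt(cfg0$total_phenotypic_variance[["length"]])
  cfg <- sim_config(n_sires = 25, dams_per_sire = 3, offspring_per_dam = 3,
                    n_snps = 200, seed = 13,
                    causal_snps = data.frame(locus = locus, effect = beta))
  sim <- simulate_horn_study(cfg, traits = "length")
  d <- sim$phenotypes
  x <- sim$genotypes$calls[match(d$id, sim$genotypes$ids), locus]
  slope <- coef(lm(d$value ~ x + factor(d$age)))[["x"]]
  expect_lt(abs(slope - beta) / beta, 0.05)
})

test_that("phenotype simulation rejects ungenotyped individuals", {
  cfg <- small_config()
  ped <- half_sib_pedigree(cfg)
  g <- simulate_founder_genotypes(3, 20, seed = 1,
                                  ids = ped$id[is.na(ped$sire)][1:3])
  expect_error(simulate_phenotypes(cfg, ped, g), "lack genotypes")
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- small_config(seed = 17)
  s1 <- simulate_horn_study(cfg, traits = "length")
  s2 <- simulate_horn_study(cfg, traits = "length")
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$phenotypes, s2$phenotypes)
})

test_that("simulated breeding values have the pedigree covariance", {
  # across replicates, cov of full-sib breeding values -> 0.5 * sigma2_a
  cfg <- sim_config(n_sires = 40, dams_per_sire = 1, offspring_per_dam = 2,
                    n_snps = 10, seed = 1)
  ped <- half_sib_pedigree(cfg)
  g <- simulate_founder_genotypes(length(ped$id[is.na(ped$sire)]), 10,
                                  seed = 1, ids = ped$id[is.na(ped$sire)])
  gall <- gene_drop(ped, g, seed = 2)
  va <- cfg$variance_proportions$length[["va"]] *
    cfg$total_phenotypic_variance[["length"]]
  covs <- sapply(1:40, function(r) {
    ph <- simulate_phenotypes(cfg, ped, gall, seed = 1000 + r,
                              traits = "length")
    bv <- attr(ph, "truth")$length$breeding_values
    n <- length(bv)
    mean(bv[seq(1, n, 2)] * bv[seq(2, n, 2)])
  })
  mc_se <- sd(covs) / sqrt(length(covs))
  expect_lt(abs(mean(covs) - 0.5 * va), 3 * mc_se)
})

test_that("rendered horn records invert back to the phenotype table", {
  # low-noise configuration keeps cumulative lengths monotone
  cfg <- sim_config(n_sires = 6, dams_per_sire = 2, offspring_per_dam = 2,
                    n_snps = 40, seed = 23,
                    total_phenotypic_variance = c(length = 25,
                                                  circumference = 9,
                                                  volume = 100))
  sim <- simulate_horn_study(cfg, traits = c("length", "circumference"))
  recs <- render_horn_records(sim$phenotypes, seed = 3)
  rebuilt <- reconstruct_phenotypes(recs, qc = FALSE)$phenotypes
  for (tr in c("length", "circumference")) {
    a <- sim$phenotypes[sim$phenotypes$trait == tr, ]
    b <- rebuilt[rebuilt$trait == tr, ]
    m <- merge(a, b, by = c("id", "age"))
    expect_equal(nrow(m), nrow(a))
    expect_lt(max(abs(m$value.x - m$value.y)), 1e-9)
  }
})

test_that("implausible-growth injection is flagged at the expected rate", {
  cfg <- sim_config(n_sires = 50, dams_per_sire = 2, offspring_per_dam = 2,
                    n_snps = 20, seed = 3,
                    total_phenotypic_variance = c(length = 25,
                                                  circumference = 9,
                                                  volume = 100))
  sim <- simulate_horn_study(cfg, traits = c("length", "circumference"))
  recs <- render_horn_records(sim$phenotypes, seed = 3,
                              implausible_fraction = 0.1)
  n <- length(recs)
  res <- apply_growth_qc(recs)
  expected <- 0.1 * n
  se <- sqrt(n * 0.1 * 0.9)
  expect_lt(abs(length(res$excluded) - expected), 3 * se + 1)
})
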