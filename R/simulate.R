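# Simulation of a harvest-record quantitative-genetics study ------------
#
# Generates a two-generation half-sib pedigree, founder genotypes,
# gene-dropped offspring genotypes, and annuli-structured repeated horn
# measurements under a known five-component variance decomposition, so
# that relatedness estimation, REML and the association scan can all be
# validated against ground truth.

# Published variance decomposition used as the default generating truth.
# Proportions of Vp for each trait: additive (va), permanent environment
# (vpe), year of measurement (vym), birth-year cohort (vyb), residual (vr).
# The volume row is renormalized (its printed proportions sum to 1.03).
horn_variance_defaults <- function() {
  vol <- c(va = 0.36, vpe = 0.31, vym = 0.01, vyb = 0.01, vr = 0.34)
  list(
    length        = c(va = 0.33, vpe = 0.35, vym = 0.02, vyb = 0.01, vr = 0.29),
    circumference = c(va = 0.36, vpe = 0.29, vym = 0.06, vyb = 0.01, vr = 0.28),
    volume        = vol / sum(vol)
  )
}

# Total phenotypic variances (age-adjusted) and growth-curve parameters.
# Lengths/circumferences in mm, volume in cm^3.
horn_scale_defaults <- function() {
  list(
    total_phenotypic_variance = c(length = 2926, circumference = 542,
                                  volume = 796253),
    growth_params = list(
      length        = c(L_inf = 720,  k = 0.16),
      circumference = c(L_inf = 300,  k = 0.55),
      volume        = c(L_inf = 9000, k = 0.15)
    )
  )
}

#' Configuration for a simulated horn-size study
#'
#' Bundles every tunable of the synthetic-data generator: the half-sib
#' mating design, marker panel, measurement-year structure, and the
#' per-trait variance decomposition used as generating truth. Defaults
#' emulate the harvested Dall's sheep study design: ~180 genotyped rams
#' at 6,635 unlinked autosomal SNPs with repeated annuli-derived
#' measurements (mean ~8.5 usable records per ram at ages 2 and up).
#'
#' @param n_sires,dams_per_sire,offspring_per_dam half-sib design counts;
#'   the default 30 x 3 x 2 yields 180 phenotyped offspring.
#' @param n_extra_founders additional unrelated phenotyped rams (default 0).
#' @param n_snps number of biallelic autosomal SNPs.
#' @param maf_range founder allele-frequency range, within (0, 0.5].
#' @param birth_year_range calendar-year range offspring cohorts are drawn
#'   from (uniform).
#' @param harvest_age_range integer range of ages at harvest (uniform);
#'   each ram contributes one record per year of life from age 2 to
#'   harvest, so records per ram = harvest age - 1.
#' @param variance_proportions named list, trait -> named vector
#'   `c(va, vpe, vym, vyb, vr)` summing to 1.
#' @param total_phenotypic_variance named vector of Vp per trait, in
#'   squared trait units.
#' @param growth_params named list, trait -> `c(L_inf, k)` of the
#'   von Bertalanffy age mean `L_inf * (1 - exp(-k * age))`.
#' @param causal_snps optional data frame with columns `locus` (column
#'   index into the marker panel) and `effect` (trait units per alternate
#'   allele copy), applied to every simulated trait.
#' @param seed master seed; all stages derive their streams from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sires = 30L, dams_per_sire = 3L,
                       offspring_per_dam = 2L, n_extra_founders = 0L,
                       n_snps = 6635L, maf_range = c(0.01, 0.5),
                       birth_year_range = c(2002L, 2009L),
                       harvest_age_range = c(6L, 13L),
                       variance_proportions = horn_variance_defaults(),
                       total_phenotypic_variance =
                         horn_scale_defaults()$total_phenotypic_variance,
                       growth_params = horn_scale_defaults()$growth_params,
                       causal_snps = NULL,
                       seed = 1L) {
  counts <- c(n_sires = n_sires, dams_per_sire = dams_per_sire,
              offspring_per_dam = offspring_per_dam,
              n_extra_founders = n_extra_founders)
  stop_if(any(counts < 0), "design counts must be >= 0")
  stop_if(n_snps < 1, "n_snps must be >= 1")
  check_maf_range(maf_range)
  stop_if(harvest_age_range[1] < 2 || diff(harvest_age_range) < 0,
          "harvest_age_range must be an increasing range with minimum >= 2")
  for (tr in names(variance_proportions)) {
    vp <- variance_proportions[[tr]]
    stop_if(!all(c("va", "vpe", "vym", "vyb", "vr") %in% names(vp)),
            "variance_proportions[['%s']] must name va, vpe, vym, vyb, vr", tr)
    stop_if(any(vp < 0) || any(vp > 1),
            "variance proportions for '%s' must be in [0, 1]", tr)
    stop_if(abs(sum(vp) - 1) > 1e-12,
            "variance proportions for '%s' must sum to 1 (got %.15f)",
            tr, sum(vp))
  }
  stop_if(!all(names(variance_proportions) %in%
                 names(total_phenotypic_variance)),
          "total_phenotypic_variance must cover every trait")
  if (!is.null(causal_snps)) {
    causal_snps <- as.data.frame(causal_snps)
    stop_if(!all(c("locus", "effect") %in% names(causal_snps)),
            "causal_snps needs columns locus, effect")
    stop_if(any(causal_snps$locus < 1 | causal_snps$locus > n_snps),
            "causal locus index out of range")
  }
  structure(list(
    n_sires = as.integer(n_sires),
    dams_per_sire = as.integer(dams_per_sire),
    offspring_per_dam = as.integer(offspring_per_dam),
    n_extra_founders = as.integer(n_extra_founders),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    birth_year_range = as.integer(birth_year_range),
    harvest_age_range = as.integer(harvest_age_range),
    mean_records_per_individual = mean(harvest_age_range) - 1,
    variance_proportions = variance_proportions,
    total_phenotypic_variance = total_phenotypic_variance,
    growth_params = growth_params,
    causal_snps = causal_snps,
    seed = as.integer(seed)
  ), class = "sim_config")
}

check_maf_range <- function(maf_range) {
  stop_if(length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
            maf_range[1] <= 0 || maf_range[2] > 0.5,
          "maf_range must be within (0, 0.5] with low <= high, got (%s)",
          paste(format(maf_range), collapse = ", "))
  invisible(maf_range)
}

#' @export
print.sim_config <- function(x, ...) {
  n_off <- x$n_sires * x$dams_per_sire * x$offspring_per_dam
  cat("sim_config:\n")
  cat(sprintf("  design: %d sires x %d dams x %d offspring (+%d unrelated) = %d phenotyped rams\n",
              x$n_sires, x$dams_per_sire, x$offspring_per_dam,
              x$n_extra_founders, n_off + x$n_extra_founders))
  cat(sprintf("  markers: %d SNPs, founder MAF in (%.3g, %.3g)\n",
              x$n_snps, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  records: ages 2..harvest, harvest age %d..%d (mean %.1f records/ram)\n",
              x$harvest_age_range[1], x$harvest_age_range[2],
              x$mean_records_per_individual))
  cat(sprintf("  traits: %s\n",
              paste(names(x$variance_proportions), collapse = ", ")))
  invisible(x)
}

# Pedigree ---------------------------------------------------------------

#' Build the default two-generation half-sib pedigree
#'
#' Sires are each mated to `dams_per_sire` unrelated dams, each dam
#' producing `offspring_per_dam` full-sib offspring; optional extra
#' unrelated founders join the phenotyped cohort. The resulting mix of
#' full sibs (relatedness 1/2), half sibs (1/4) and unrelated pairs gives
#' the relatedness contrast required to separate additive-genetic from
#' permanent-environment variance.
#'
#' @param config a [sim_config()].
#' @return Data frame with columns `id`, `sire`, `dam` (`NA` for
#'   founders), `birth_year`, and `phenotyped` (logical).
#' @export
half_sib_pedigree <- function(config) {
  set.seed(derive_seed(config$seed, "harvest"))
  ns <- config$n_sires; nd <- config$dams_per_sire
  no <- config$offspring_per_dam; nx <- config$n_extra_founders
  sires <- sprintf("S%03d", seq_len(ns))
  dams  <- sprintf("D%03d", seq_len(ns * nd))
  extras <- if (nx > 0) sprintf("U%03d", seq_len(nx)) else character()
  founder_year <- config$birth_year_range[1] - 4L
  off_id <- off_sire <- off_dam <- character(0)
  if (ns * nd * no > 0) {
    dam_sire <- rep(sires, each = nd)
    off_sire <- rep(dam_sire, each = no)
    off_dam  <- rep(dams, each = no)
    off_id   <- sprintf("I%03d", seq_along(off_sire))
  }
  by_range <- config$birth_year_range
  off_by <- sample_range(by_range[1], by_range[2], length(off_id))
  extra_by <- sample_range(by_range[1], by_range[2], length(extras))
  ped <- data.frame(
    id = c(sires, dams, extras, off_id),
    sire = c(rep(NA_character_, ns + ns * nd + nx), off_sire),
    dam = c(rep(NA_character_, ns + ns * nd + nx), off_dam),
    birth_year = c(rep(founder_year, ns + ns * nd), extra_by, off_by),
    phenotyped = c(rep(FALSE, ns + ns * nd), rep(TRUE, nx),
                   rep(TRUE, length(off_id))),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  stop_if(!all(c("id", "sire", "dam", "birth_year") %in% names(ped)),
          "pedigree needs columns id, sire, dam, birth_year")
  stop_if(anyDuplicated(ped$id) > 0, "duplicate pedigree ids")
  one_parent <- xor(is.na(ped$sire), is.na(ped$dam))
  stop_if(any(one_parent),
          "individuals with exactly one known parent: %s",
          paste(ped$id[one_parent], collapse = ", "))
  known <- !is.na(ped$sire)
  miss <- setdiff(c(ped$sire[known], ped$dam[known]), ped$id)
  stop_if(length(miss) > 0, "parent ids absent from pedigree: %s",
          paste(miss, collapse = ", "))
  idx <- match(ped$id, ped$id)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  bad_year <- known & (ped$birth_year <= ped$birth_year[si] |
                         ped$birth_year <= ped$birth_year[di])
  stop_if(any(bad_year, na.rm = TRUE),
          "offspring born no later than a parent: %s",
          paste(ped$id[which(bad_year)], collapse = ", "))
  # acyclicity follows from the strict birth-year ordering checked above
  invisible(ped)
}

#' Pedigree numerator relationship matrix
#'
#' Wright's additive relationship matrix by the tabular method, used as
#' the exact covariance structure for simulated breeding values and as
#' the expectation the marker-based GRM must recover.
#'
#' @param ped pedigree data frame (see [half_sib_pedigree()]).
#' @return Symmetric matrix with one row/column per pedigree id.
#' @export
pedigree_nrm <- function(ped) {
  validate_pedigree(ped)
  ord <- order(ped$birth_year, match(ped$id, ped$id))
  ped <- ped[ord, , drop = FALSE]
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s)) {
      A[i, i] <- 1
    } else {
      A[i, i] <- 1 + 0.5 * A[s, d]
      prev <- seq_len(i - 1L)
      A[i, prev] <- A[prev, i] <- 0.5 * (A[prev, s] + A[prev, d])
    }
  }
  A
}

# Genotype simulation ----------------------------------------------------

#' Simulate founder genotypes
#'
#' Draws per-locus allele frequencies uniformly from `maf_range` and
#' founder genotypes as independent binomial(2, p) alternate-allele
#' counts (Hardy-Weinberg, linkage equilibrium). Loci are assigned
#' chromosome/position metadata spanning 26 autosomes.
#'
#' @param n_founders number of founder individuals.
#' @param n_snps number of loci.
#' @param maf_range allele-frequency range, within (0, 0.5].
#' @param seed RNG seed.
#' @param ids optional founder ids (default `F001`...).
#' @return A [genotype_matrix()] with no missing calls; the per-locus
#'   generating frequencies are attached as attribute `"founder_freq"`.
#' @export
simulate_founder_genotypes <- function(n_founders, n_snps,
                                       maf_range = c(0.01, 0.5),
                                       seed = 1L, ids = NULL) {
  stop_if(n_founders < 1, "n_founders must be >= 1")
  check_maf_range(maf_range)
  set.seed(seed)
  p <- runif(n_snps, maf_range[1], maf_range[2])
  calls <- matrix(rbinom(n_founders * n_snps, 2L, rep(p, each = n_founders)),
                  nrow = n_founders, ncol = n_snps)
  if (is.null(ids)) ids <- sprintf("F%03d", seq_len(n_founders))
  g <- genotype_matrix(calls, snp_map(n_snps), ids = ids)
  attr(g, "founder_freq") <- p
  g
}

# Evenly spread loci over 26 autosomes with 1-based positions.
snp_map <- function(n_snps) {
  chrom <- rep(seq_len(26L), length.out = n_snps)
  chrom <- sort(chrom)
  pos <- integer(n_snps)
  for (cc in unique(chrom)) {
    k <- sum(chrom == cc)
    pos[chrom == cc] <- seq(50000L, by = 150000L, length.out = k)
  }
  data.frame(chrom = chrom,
             snp = sprintf("snp%05d", seq_len(n_snps)),
             pos = pos)
}

#' Gene-drop genotypes through a pedigree
#'
#' Each offspring receives one allele from each parent, sampled
#' independently per locus (unlinked loci, no mutation). Founders keep
#' their simulated genotypes.
#'
#' @param ped pedigree data frame; founders must all be present in
#'   `founder_genotypes`.
#' @param founder_genotypes a [genotype_matrix()] of pedigree founders.
#' @param seed RNG seed.
#' @return A [genotype_matrix()] covering every pedigree individual, in
#'   pedigree order.
#' @export
gene_drop <- function(ped, founder_genotypes, seed = 1L) {
  validate_pedigree(ped)
  founders <- ped$id[is.na(ped$sire)]
  miss <- setdiff(founders, founder_genotypes$ids)
  stop_if(length(miss) > 0, "founders missing from founder_genotypes: %s",
          paste(miss, collapse = ", "))
  set.seed(seed)
  ord <- order(ped$birth_year, seq_len(nrow(ped)))
  ped_o <- ped[ord, , drop = FALSE]
  L <- ncol(founder_genotypes$calls)
  calls <- matrix(NA_integer_, nrow(ped_o), L,
                  dimnames = list(ped_o$id, NULL))
  fidx <- match(founders, founder_genotypes$ids)
  calls[founders, ] <- founder_genotypes$calls[fidx, , drop = FALSE]
  for (i in seq_len(nrow(ped_o))) {
    if (is.na(ped_o$sire[i])) next
    gs <- calls[ped_o$sire[i], ]
    gd <- calls[ped_o$dam[i], ]
    calls[i, ] <- rbinom(L, 1L, gs / 2) + rbinom(L, 1L, gd / 2)
  }
  # restore original pedigree order
  calls <- calls[ped$id, , drop = FALSE]
  genotype_matrix(calls, founder_genotypes$map, ids = ped$id)
}

# Phenotype simulation ---------------------------------------------------

#' Simulate annuli-structured repeated horn measurements
#'
#' Generates, for every phenotyped pedigree individual, one record per
#' year of life from age 2 to its age at harvest, under the
#' repeated-measures animal model
#' \deqn{y_{iat} = \mu(a) + g_i + a_i + pe_i + b_{birth(i)} + m_t + e_{iat}}
#' where \eqn{\mu(a)} is a von Bertalanffy age mean, \eqn{g_i} the causal
#' SNP contribution (zero unless `causal_snps` is set), \eqn{a_i} a
#' breeding value drawn with covariance \eqn{\sigma^2_a A} from the
#' pedigree numerator relationship matrix, \eqn{pe_i} a permanent
#' environment deviate, \eqn{b} and \eqn{m} independent birth-year and
#' measurement-year effects, and \eqn{e} the residual. Component
#' variances are `variance_proportions[trait] * total_phenotypic_variance[trait]`.
#'
#' @param config a [sim_config()].
#' @param ped pedigree data frame.
#' @param genotypes [genotype_matrix()] covering all phenotyped ids
#'   (required when `causal_snps` is set, and checked regardless).
#' @param seed RNG seed (default: derived from `config$seed`).
#' @param traits traits to simulate (default: all in the config).
#' @return A long-format data frame (`id`, `birth_year`, `meas_year`,
#'   `age`, `trait`, `value`) with one row per individual-year-trait.
#'   Ground truth (breeding values, permanent-environment and year
#'   effects, causal contributions, generating variances) is attached as
#'   attribute `"truth"`, a per-trait list.
#' @export
simulate_phenotypes <- function(config, ped, genotypes,
                                seed = derive_seed(config$seed, "phenotypes"),
                                traits = names(config$variance_proportions)) {
  pheno_ids <- ped$id[ped$phenotyped %||% rep(TRUE, nrow(ped))]
  miss <- setdiff(pheno_ids, genotypes$ids)
  stop_if(length(miss) > 0, "phenotyped individuals lack genotypes: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  set.seed(seed)
  n <- length(pheno_ids)
  ages_at_harvest <- sample_range(config$harvest_age_range[1],
                                  config$harvest_age_range[2], n)
  birth <- ped$birth_year[match(pheno_ids, ped$id)]
  rec_id <- rep(pheno_ids, times = ages_at_harvest - 1L)
  rec_age <- unlist(lapply(ages_at_harvest, function(a) seq(2L, a)),
                    use.names = FALSE)
  rec_birth <- rep(birth, times = ages_at_harvest - 1L)
  rec_year <- rec_birth + rec_age
  A <- pedigree_nrm(ped)
  La <- chol(A[pheno_ids, pheno_ids])   # upper triangular, t(La) %*% La = A
  ii <- match(rec_id, pheno_ids)
  yb_levels <- sort(unique(rec_birth))
  ym_levels <- sort(unique(rec_year))
  gcaus <- rep(0, n)
  if (!is.null(config$causal_snps)) {
    x <- genotypes$calls[pheno_ids, config$causal_snps$locus, drop = FALSE]
    gcaus <- as.numeric(x %*% config$causal_snps$effect)
  }
  out <- vector("list", length(traits))
  truth <- vector("list", length(traits))
  names(truth) <- traits
  for (t_i in seq_along(traits)) {
    tr <- traits[t_i]
    props <- config$variance_proportions[[tr]]
    vp_tot <- config$total_phenotypic_variance[[tr]]
    vc <- props * vp_tot
    gp <- config$growth_params[[tr]]
    mu <- gp[["L_inf"]] * (1 - exp(-gp[["k"]] * rec_age))
    a_ind <- as.numeric(crossprod(La, rnorm(n))) * sqrt(vc[["va"]])
    pe_ind <- rnorm(n, 0, sqrt(vc[["vpe"]]))
    b_yb <- rnorm(length(yb_levels), 0, sqrt(vc[["vyb"]]))
    m_ym <- rnorm(length(ym_levels), 0, sqrt(vc[["vym"]]))
    e <- rnorm(length(rec_id), 0, sqrt(vc[["vr"]]))
    value <- mu + gcaus[ii] + a_ind[ii] + pe_ind[ii] +
      b_yb[match(rec_birth, yb_levels)] + m_ym[match(rec_year, ym_levels)] + e
    out[[t_i]] <- data.frame(id = rec_id, birth_year = rec_birth,
                             meas_year = rec_year, age = rec_age,
                             trait = tr, value = value,
                             stringsAsFactors = FALSE)
    truth[[tr]] <- list(
      ids = pheno_ids,
      breeding_values = a_ind, permanent_env = pe_ind,
      birth_year_effects = stats::setNames(b_yb, yb_levels),
      meas_year_effects = stats::setNames(m_ym, ym_levels),
      causal_contribution = gcaus, residuals = e,
      variance_components = vc, h2 = unname(props[["va"]])
    )
  }
  phenos <- do.call(rbind, out)
  rownames(phenos) <- NULL
  attr(phenos, "truth") <- truth
  phenos
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [half_sib_pedigree()],
#' [simulate_founder_genotypes()], [gene_drop()] and
#' [simulate_phenotypes()], with per-stage seeds derived from the
#' config's master seed.
#'
#' @param config a [sim_config()].
#' @param traits traits to simulate.
#' @return List with `pedigree`, `genotypes` (phenotyped individuals
#'   only), `all_genotypes` (every pedigree member), and `phenotypes`
#'   (with the `"truth"` attribute).
#' @export
simulate_horn_study <- function(config,
                                traits = names(config$variance_proportions)) {
  ped <- half_sib_pedigree(config)
  founders <- ped$id[is.na(ped$sire)]
  fg <- simulate_founder_genotypes(length(founders), config$n_snps,
                                   config$maf_range,
                                   seed = derive_seed(config$seed, "founders"),
                                   ids = founders)
  gall <- gene_drop(ped, fg, seed = derive_seed(config$seed, "gene_drop"))
  phen_idx <- which(ped$phenotyped)
  gphen <- subset_genotypes(gall, ind = match(ped$id[phen_idx], gall$ids))
  phenos <- simulate_phenotypes(config, ped, gall, traits = traits)
  list(pedigree = ped, genotypes = gphen, all_genotypes = gall,
       phenotypes = phenos, config = config)
}

#' Per-allele effect giving a target variance share
#'
#' Computes the additive effect size beta such that a locus with sample
#' allele frequency p explains `share` of the phenotypic variance:
#' `2 p (1-p) beta^2 = share * vp`.
#'
#' @param g [genotype_matrix()] containing the locus.
#' @param locus column index of the locus.
#' @param share fraction of `vp` the locus should explain.
#' @param vp total phenotypic variance in squared trait units.
#' @return Effect size in trait units per alternate-allele copy.
#' @export
causal_effect_for_share <- function(g, locus, share, vp) {
  p <- allele_freq(g)[locus]
  stop_if(is.na(p) || p <= 0 || p >= 1, "locus %d is monomorphic", locus)
  sqrt(share * vp / (2 * p * (1 - p)))
}

# Rendering phenotypes back to raw annuli records ------------------------

#' Render phenotypes as raw horn records
#'
#' Inverse of [reconstruct_yearly_measures()]: converts an individual's
#' cumulative post-QC horn lengths (ages 2..harvest) and per-annulus base
#' circumferences into the raw harvest-record form, adding a synthetic
#' year-1 lamb-tip segment and first-annulus circumference (which the QC
#' rules later discard). Optionally injects implausibly large year-1
#' growth into a fraction of records to exercise the growth filters.
#'
#' @param phenos long phenotype table with traits `length` and
#'   `circumference` (e.g. from [simulate_phenotypes()]); cumulative
#'   lengths must be non-decreasing in age within an individual.
#' @param seed RNG seed for the synthetic lamb-tip draws.
#' @param implausible_fraction fraction of records whose year-1 segment
#'   is inflated past the 160 mm plausibility bound.
#' @return List of [horn_record()] objects, one per individual.
#' @export
render_horn_records <- function(phenos, seed = 1L,
                                implausible_fraction = 0) {
  check_fraction(implausible_fraction, "implausible_fraction")
  set.seed(seed)
  len <- phenos[phenos$trait == "length", , drop = FALSE]
  circ <- phenos[phenos$trait == "circumference", , drop = FALSE]
  stop_if(nrow(len) == 0 || nrow(circ) == 0,
          "phenotypes must contain 'length' and 'circumference' traits")
  ids <- unique(len$id)
  flag <- runif(length(ids)) < implausible_fraction
  recs <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    li <- len[len$id == ids[k], , drop = FALSE]
    ci <- circ[circ$id == ids[k], , drop = FALSE]
    li <- li[order(li$age), , drop = FALSE]
    ci <- ci[order(ci$age), , drop = FALSE]
    stop_if(!identical(li$age, ci$age),
            "length/circumference ages disagree for %s", ids[k])
    stop_if(is.unsorted(li$value, strictly = FALSE),
            "non-monotone cumulative lengths for %s", ids[k])
    tip <- if (flag[k]) runif(1, 170, 300) else runif(1, 90, 150)
    segs <- c(tip, li$value[1], diff(li$value))
    circs <- c(0.8 * ci$value[1], ci$value)
    recs[[k]] <- horn_record(id = ids[k],
                             harvest_year = max(li$meas_year),
                             age_at_harvest = max(li$age),
                             segments = segs,
                             base_circumferences = circs)
  }
  recs
}

# Text-format writers ----------------------------------------------------

#' Write a long phenotype table as TSV
#'
#' Columns `id`, `birth_year`, `meas_year`, `age`, `trait`, `value`,
#' one header line.
#'
#' @param phenos phenotype data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenos, path) {
  utils::write.table(phenos, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long phenotype table from TSV
#'
#' @param path file written by [write_phenotypes()].
#' @return Phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write simulation ground truth as TSV files
#'
#' One file per trait holding per-individual true breeding values,
#' permanent-environment deviates and causal contributions, plus a
#' components file with the generating variance components.
#'
#' @param phenos phenotype table carrying the `"truth"` attribute.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_truth <- function(phenos, dir) {
  truth <- attr(phenos, "truth")
  stop_if(is.null(truth), "phenotypes carry no truth attribute")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp <- do.call(rbind, lapply(names(truth), function(tr) {
    vc <- truth[[tr]]$variance_components
    data.frame(trait = tr, component = names(vc), variance = as.numeric(vc))
  }))
  utils::write.table(comp, file.path(dir, "true_components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tr in names(truth)) {
    tt <- truth[[tr]]
    df <- data.frame(id = tt$ids, breeding_value = tt$breeding_values,
                     permanent_env = tt$permanent_env,
                     causal = tt$causal_contribution)
    utils::write.table(df, file.path(dir, sprintf("true_effects_%s.tsv", tr)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
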