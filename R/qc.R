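# Marker and individual quality control ---------------------------------

#' Remove individuals with low genotyping call rate
#'
#' @param g a [genotype_matrix()].
#' @param min_call_rate minimum fraction of non-missing calls (default
#'   0.9, the standard chip-QC threshold).
#' @return List with `genotypes` (filtered) and `report` (data frame
#'   with the removal count).
#' @export
filter_individuals <- function(g, min_call_rate = 0.9) {
  check_fraction(min_call_rate, "min_call_rate")
  cr <- rowMeans(!is.na(g$calls))
  keep <- cr >= min_call_rate
  out <- if (all(keep)) g else subset_genotypes(g, ind = which(keep))
  report <- data.frame(stage = "individual_call_rate", axis = "individual",
                       removed = sum(!keep),
                       threshold = min_call_rate,
                       stringsAsFactors = FALSE)
  list(genotypes = out, report = report,
       removed_ids = g$ids[!keep])
}

#' Remove low-quality loci
#'
#' Applies, in order: locus call rate, x-linked drop (chromosome label
#' `"X"`/`"x"`), then minor allele frequency computed over non-missing
#' calls of the surviving individuals. The order matters and is recorded
#' in the report: MAF depends on which individuals survive upstream
#' filtering, so this filter should run after [filter_individuals()].
#'
#' @param g a [genotype_matrix()].
#' @param min_call_rate minimum locus call rate (default 0.9).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param drop_x drop x-linked loci (default `TRUE`).
#' @return List with `genotypes` and `report` (one row per stage in
#'   application order).
#' @export
filter_loci <- function(g, min_call_rate = 0.9, min_maf = 0.01,
                        drop_x = TRUE) {
  check_fraction(min_call_rate, "min_call_rate")
  check_fraction(min_maf, "min_maf")
  cr <- colMeans(!is.na(g$calls))
  keep <- cr >= min_call_rate
  n_cr <- sum(!keep)
  g <- subset_genotypes(g, loci = which(keep))
  n_x <- 0L
  if (drop_x) {
    is_x <- toupper(as.character(g$map$chrom)) == "X"
    n_x <- sum(is_x)
    if (n_x > 0) g <- subset_genotypes(g, loci = which(!is_x))
  }
  maf <- minor_allele_freq(g)
  keep_maf <- !is.na(maf) & maf >= min_maf
  n_maf <- sum(!keep_maf)
  if (n_maf > 0) g <- subset_genotypes(g, loci = which(keep_maf))
  report <- data.frame(
    stage = c("locus_call_rate", "x_linked", "maf"),
    axis = "locus",
    removed = c(n_cr, n_x, n_maf),
    threshold = c(min_call_rate, NA, min_maf),
    stringsAsFactors = FALSE
  )
  list(genotypes = g, report = report)
}

#' Exact Hardy-Weinberg test p-value
#'
#' Exact test on the conditional distribution of the heterozygote count
#' given the minor-allele count (Levene/Haldane distribution): the
#' p-value is the total probability of all heterozygote counts no more
#' probable than the observed one (no mid-p correction).
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote,
#'   heterozygote, minor homozygote; orientation is irrelevant).
#' @return Two-sided exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(NA_real_)
  n_minor <- 2 * min(n_aa, n_bb) + n_ab
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # log conditional probability of each possible heterozygote count
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) + lgamma(n + 1) -
      (lgamma(h + 1) + lgamma(hom_min + 1) + lgamma(hom_maj + 1)) -
      (lgamma(2 * n + 1) - lgamma(n_minor + 1) - lgamma(2 * n - n_minor + 1))
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Chi-square Hardy-Weinberg test p-value
#'
#' One-degree-of-freedom goodness-of-fit alternative to the exact test.
#'
#' @inheritParams hwe_exact_p
#' @return P-value.
#' @export
hwe_chisq_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(NA_real_)
  p <- (2 * n_aa + n_ab) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(e == 0)) return(1)
  x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Flag loci out of Hardy-Weinberg equilibrium
#'
#' Loci with an HWE test p-value below `alpha` are flagged but never
#' removed: loci under selection, hence potentially associated with the
#' trait, are expected to deviate from HWE.
#'
#' @param g a [genotype_matrix()] (post-filtering).
#' @param alpha significance level (default 0.001).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return Data frame of flagged loci (`snp`, `chrom`, `pos`, `p_hwe`);
#'   the full p-value vector is attached as attribute `"p_hwe"`. The
#'   genotype matrix is never modified.
#' @export
hwe_flag <- function(g, alpha = 0.001, method = c("exact", "chisq")) {
  method <- match.arg(method)
  check_fraction(alpha, "alpha")
  test <- if (method == "exact") hwe_exact_p else hwe_chisq_p
  pvals <- apply(g$calls, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      warning("locus with zero non-missing calls skipped")
      return(NA_real_)
    }
    test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  })
  flagged <- which(!is.na(pvals) & pvals < alpha)
  out <- data.frame(snp = g$map$snp[flagged], chrom = g$map$chrom[flagged],
                    pos = g$map$pos[flagged], p_hwe = pvals[flagged],
                    stringsAsFactors = FALSE)
  attr(out, "p_hwe") <- pvals
  out
}

#' Full genotype quality-control pipeline
#'
#' Applies, in order: individual call rate, locus call rate, x-linked
#' drop, minor allele frequency; then flags (never removes) HWE
#' deviations. A reserved `cluster_quality` stage (GC-score filtering,
#' which requires raw chip intensities) is carried in the report with
#' zero removals so real-data accounting can mirror full chip-QC
#' pipelines.
#'
#' @param g a [genotype_matrix()].
#' @param ind_call_rate,locus_call_rate,min_maf,drop_x,hwe_alpha filter
#'   settings (defaults 0.9 / 0.9 / 0.01 / `TRUE` / 0.001).
#' @return Object of class `qc_result`: list with `genotypes`, `report`
#'   (per-stage counts plus surviving dimensions), `hwe_flagged`, and
#'   `removed_ids`.
#' @export
qc_genotypes <- function(g, ind_call_rate = 0.9, locus_call_rate = 0.9,
                         min_maf = 0.01, drop_x = TRUE, hwe_alpha = 0.001) {
  n0 <- nrow(g$calls); l0 <- ncol(g$calls)
  fi <- filter_individuals(g, ind_call_rate)
  fl <- filter_loci(fi$genotypes, locus_call_rate, min_maf, drop_x)
  hw <- hwe_flag(fl$genotypes, hwe_alpha)
  report <- rbind(
    data.frame(stage = "cluster_quality", axis = "locus", removed = 0L,
               threshold = NA_real_, stringsAsFactors = FALSE),
    fi$report, fl$report
  )
  res <- structure(list(
    genotypes = fl$genotypes,
    report = report,
    hwe_flagged = hw,
    removed_ids = fi$removed_ids,
    input_dim = c(individuals = n0, loci = l0),
    output_dim = c(individuals = nrow(fl$genotypes$calls),
                   loci = ncol(fl$genotypes$calls))
  ), class = "qc_result")
  check_qc_accounting(res)
  res
}

check_qc_accounting <- function(res) {
  rem_ind <- sum(res$report$removed[res$report$axis == "individual"])
  rem_loc <- sum(res$report$removed[res$report$axis == "locus"])
  stop_if(res$input_dim[["individuals"]] - rem_ind !=
            res$output_dim[["individuals"]],
          "QC accounting mismatch on individuals")
  stop_if(res$input_dim[["loci"]] - rem_loc != res$output_dim[["loci"]],
          "QC accounting mismatch on loci")
  invisible(res)
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("genotype QC: %d x %d -> %d x %d (individuals x loci)\n",
              x$input_dim[1], x$input_dim[2],
              x$output_dim[1], x$output_dim[2]))
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-22s removed %6d (%s)\n", x$report$stage[i],
                x$report$removed[i], x$report$axis[i]))
  }
  cat(sprintf("  HWE-flagged (kept): %d loci\n", nrow(x$hwe_flagged)))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param res a `qc_result` from [qc_genotypes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(res, path) {
  utils::write.table(res$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
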