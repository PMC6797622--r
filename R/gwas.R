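# Covariance-aware single-SNP association scan --------------------------
#
# Two-step strategy: the null repeated-measures animal model is fitted
# once, and each SNP is then tested by generalized least squares with
# the phenotypic covariance V fixed at the null-model estimate. The
# individual's allele count is expanded over its repeated records. V is
# factorized once (Woodbury) and reused across all loci.

#' Significance thresholds for a genome-wide scan
#'
#' Genome-wide (Bonferroni, `0.05 / nSNPs`) and suggestive (one expected
#' false positive per genome scan, `1 / nSNPs`) p-value thresholds.
#'
#' @param n_snps number of markers tested.
#' @return Named vector `c(genome_wide, suggestive)`.
#' @examples
#' gwas_thresholds(6635)
#' @export
gwas_thresholds <- function(n_snps) {
  stop_if(n_snps < 1, "n_snps must be >= 1")
  c(genome_wide = 0.05 / n_snps, suggestive = 1 / n_snps)
}

#' Genomic inflation factor
#'
#' Converts the scan's Wald statistics (1-df chi-square) to lambda, the
#' slope of the zero-intercept regression of the sorted observed
#' statistics on the expected chi-square(1) order statistics. A
#' well-calibrated scan has lambda close to 1; lambda > 1 signals
#' unmodeled structure (e.g. relatedness). The median-ratio lambda
#' (median observed / 0.4549) is reported alongside as a diagnostic.
#'
#' @param statistics numeric vector of 1-df chi-square statistics (a
#'   `gwas_scan` object is also accepted; its uncorrected statistics are
#'   used).
#' @return Named list with `lambda`, `se` (regression standard error),
#'   `lambda_median`, and `n` (testable loci).
#' @export
genomic_lambda <- function(statistics) {
  if (inherits(statistics, "gwas_scan")) {
    statistics <- statistics$results$wald_raw
  }
  obs <- sort(statistics[is.finite(statistics)])
  m <- length(obs)
  stop_if(m < 10, "need at least 10 testable loci to estimate lambda (got %d)", m)
  expd <- stats::qchisq((seq_len(m) - 0.5) / m, df = 1)
  lambda <- sum(obs * expd) / sum(expd^2)
  resid <- obs - lambda * expd
  se <- sqrt(sum(resid^2) / (m - 1) / sum(expd^2))
  list(lambda = lambda, se = se,
       lambda_median = stats::median(obs) / stats::qchisq(0.5, df = 1),
       n = m)
}

#' Genome-wide association scan with the null-model covariance
#'
#' For each locus, the observation-level genotype covariate (the
#' individual's alternate-allele count repeated over its records) is
#' appended to the fixed effects of the null animal model and its effect
#' estimated by generalized least squares with V fixed at the null REML
#' estimate; significance is a Wald test against chi-square(1). Loci
#' monomorphic among the phenotyped individuals are emitted with missing
#' statistics. Observations with a missing call are dropped for that
#' locus only. When `genomic_control = TRUE` the Wald statistics are
#' divided by the inflation factor lambda before p-values and threshold
#' comparisons.
#'
#' @param fit a converged `animal_model` (the null model).
#' @param genotypes [genotype_matrix()] covering the fitted individuals.
#' @param genomic_control apply genomic control (default `TRUE`).
#' @return Object of class `gwas_scan`: `results` (one row per locus:
#'   `snp`, `chrom`, `pos`, `maf`, `beta`, `se`, `wald_raw`, `wald`,
#'   `p`), `n_snps`, `n_monomorphic`, `lambda`, `lambda_se`,
#'   `lambda_median`, `thresholds`, `genomic_control`, `trait`.
#' @export
gwas_scan <- function(fit, genotypes, genomic_control = TRUE) {
  stopifnot(inherits(fit, "animal_model"))
  stop_if(fit$degenerate, "null model is degenerate")
  des <- fit$design
  miss <- setdiff(des$ind_levels, genotypes$ids)
  stop_if(length(miss) > 0, "fitted individuals lack genotypes: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  y <- des$y; X <- des$X
  n <- length(y)
  blocks <- lapply(des$terms, term_factor)
  st <- reml_eval(y, X, blocks, fit$theta)
  Ainv <- chol2inv(st$cX)
  XtViy <- crossprod(X, vops_solve(st$vs, y))
  bX <- drop(Ainv %*% XtViy)
  ii <- match(des$ids, genotypes$ids)
  calls <- genotypes$calls[ii, , drop = FALSE]          # obs x loci
  L <- ncol(calls)
  # sample MAF among phenotyped individuals (each counted once)
  ind_calls <- genotypes$calls[match(des$ind_levels, genotypes$ids), ,
                               drop = FALSE]
  p_ind <- colMeans(ind_calls, na.rm = TRUE) / 2
  maf <- pmin(p_ind, 1 - p_ind)
  call_var <- colMeans(ind_calls^2, na.rm = TRUE) -
    colMeans(ind_calls, na.rm = TRUE)^2
  mono <- !is.finite(maf) | !is.finite(call_var) | call_var < 1e-12
  has_na <- colSums(is.na(calls)) > 0L
  beta <- se <- rep(NA_real_, L)
  easy <- which(!mono & !has_na)
  if (length(easy) > 0) {
    Gm <- calls[, easy, drop = FALSE]
    storage.mode(Gm) <- "double"
    ViG <- vops_solve(st$vs, Gm)
    b_gg <- colSums(Gm * ViG)
    Cx <- crossprod(X, ViG)                              # p x L
    d <- crossprod(Gm, vops_solve(st$vs, y))             # L x 1
    AiC <- Ainv %*% Cx
    denom <- b_gg - colSums(Cx * AiC)
    num <- drop(d) - drop(crossprod(Cx, Ainv %*% XtViy))
    ok <- denom > 1e-10
    beta[easy[ok]] <- num[ok] / denom[ok]
    se[easy[ok]] <- sqrt(1 / denom[ok])
  }
  # loci with missing calls: per-locus GLS on the observed subset
  for (l in which(!mono & has_na)) {
    keep <- !is.na(calls[, l])
    if (length(unique(calls[keep, l])) < 2) next
    blocks_s <- lapply(blocks, function(B) B[keep, , drop = FALSE])
    st_s <- tryCatch(
      reml_eval(y[keep], X[keep, , drop = FALSE], blocks_s, fit$theta),
      error = function(e) NULL)
    if (is.null(st_s)) next
    res <- gls_snp(st_s, X[keep, , drop = FALSE], y[keep],
                   as.numeric(calls[keep, l]))
    beta[l] <- res[1]; se[l] <- res[2]
  }
  wald_raw <- (beta / se)^2
  if (sum(is.finite(wald_raw)) >= 10) {
    gl <- genomic_lambda(wald_raw)
  } else {
    if (genomic_control) {
      warning("fewer than 10 testable loci: lambda not estimated, ",
              "genomic control skipped")
      genomic_control <- FALSE
    }
    gl <- list(lambda = NA_real_, se = NA_real_, lambda_median = NA_real_)
  }
  wald <- if (genomic_control) wald_raw / gl$lambda else wald_raw
  pvals <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  results <- data.frame(
    snp = genotypes$map$snp, chrom = genotypes$map$chrom,
    pos = genotypes$map$pos, maf = maf,
    beta = beta, se = se, wald_raw = wald_raw, wald = wald, p = pvals,
    stringsAsFactors = FALSE
  )
  ord <- order(chrom_order(results$chrom), results$pos)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, n_snps = L,
                 n_monomorphic = sum(mono),
                 lambda = gl$lambda, lambda_se = gl$se,
                 lambda_median = gl$lambda_median,
                 thresholds = gwas_thresholds(L),
                 genomic_control = genomic_control,
                 trait = fit$trait),
            class = "gwas_scan")
}

# single-SNP GLS given a reml_eval state on the matching observations
gls_snp <- function(st, X, y, x) {
  Vix <- vops_solve(st$vs, x)
  Ainv <- chol2inv(st$cX)
  cx <- crossprod(X, Vix)
  denom <- sum(x * Vix) - drop(crossprod(cx, Ainv %*% cx))
  if (denom <= 1e-10) return(c(NA_real_, NA_real_))
  XtViy <- crossprod(X, vops_solve(st$vs, y))
  num <- sum(x * vops_solve(st$vs, y)) - drop(crossprod(cx, Ainv %*% XtViy))
  c(num / denom, sqrt(1 / denom))
}

chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(as.character(chrom)))
  num[is.na(num)] <- 1000 + as.integer(factor(as.character(chrom)[is.na(num)]))
  num
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("gwas_scan, trait '%s': %d loci (%d monomorphic skipped)\n",
              x$trait, x$n_snps, x$n_monomorphic))
  cat(sprintf("  lambda = %.3f (SE %.3f), median-ratio lambda = %.3f%s\n",
              x$lambda, x$lambda_se, x$lambda_median,
              if (x$genomic_control) "; genomic control applied" else ""))
  cat(sprintf("  thresholds: genome-wide p < %.3g, suggestive p < %.3g\n",
              x$thresholds[["genome_wide"]], x$thresholds[["suggestive"]]))
  top <- x$results[order(x$results$p), ][1, ]
  cat(sprintf("  top locus: %s (chr %s) p = %.3g\n",
              top$snp, top$chrom, top$p))
  invisible(x)
}

#' @export
summary.gwas_scan <- function(object, ...) {
  hits_gw <- object$results[!is.na(object$results$p) &
                              object$results$p < object$thresholds[["genome_wide"]], ]
  hits_sg <- object$results[!is.na(object$results$p) &
                              object$results$p < object$thresholds[["suggestive"]], ]
  out <- list(scan = object, genome_wide = hits_gw, suggestive = hits_sg)
  class(out) <- "summary.gwas_scan"
  out
}

#' @export
print.summary.gwas_scan <- function(x, ...) {
  print(x$scan)
  cat(sprintf("\n%d genome-wide, %d suggestive associations\n",
              nrow(x$genome_wide), nrow(x$suggestive)))
  if (nrow(x$suggestive) > 0) {
    print(x$suggestive[, c("snp", "chrom", "pos", "maf", "beta", "se", "p")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Plot-ready Manhattan and Q-Q tables
#'
#' The Manhattan table carries a cumulative genome coordinate, -log10 p,
#' and a chromosome parity band; the Q-Q table pairs expected and
#' observed -log10 p for every testable locus. Threshold lines are
#' included as an attribute-free list element.
#'
#' @param scan a `gwas_scan`.
#' @return List with `manhattan`, `qq` (data frames) and `thresholds`.
#' @export
manhattan_qq_tables <- function(scan) {
  res <- scan$results  # already sorted by (chromosome, position)
  chroms <- unique(res$chrom)
  offs <- stats::setNames(numeric(length(chroms)), as.character(chroms))
  run <- 0
  for (cc in chroms) {
    offs[as.character(cc)] <- run
    run <- run + max(res$pos[res$chrom == cc]) + 1
  }
  man <- data.frame(
    snp = res$snp, chrom = res$chrom, pos = res$pos,
    cum_pos = res$pos + offs[as.character(res$chrom)],
    neglog10p = -log10(res$p),
    band = match(res$chrom, chroms) %% 2L,
    stringsAsFactors = FALSE
  )
  obs <- sort(res$p[is.finite(res$p)])
  m <- length(obs)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(obs))
  list(manhattan = man, qq = qq,
       thresholds = -log10(scan$thresholds))
}

#' @export
plot.gwas_scan <- function(x, which = c("manhattan", "qq"), ...) {
  which <- match.arg(which)
  tabs <- manhattan_qq_tables(x)
  if (which == "manhattan") {
    man <- tabs$manhattan
    graphics::plot(man$cum_pos, man$neglog10p,
                   col = c("grey40", "steelblue")[man$band + 1L],
                   pch = 16, cex = 0.5, xlab = "genome position",
                   ylab = expression(-log[10](p)),
                   main = sprintf("GWAS: %s", x$trait), ...)
    graphics::abline(h = tabs$thresholds[["genome_wide"]], col = "black")
    graphics::abline(h = tabs$thresholds[["suggestive"]], col = "red")
  } else {
    qq <- tabs$qq
    graphics::plot(qq$expected, qq$observed, pch = 16, cex = 0.5,
                   xlab = expression(expected - log[10](p)),
                   ylab = expression(observed - log[10](p)),
                   main = sprintf("Q-Q: %s (lambda = %.3f)", x$trait,
                                  x$lambda), ...)
    graphics::abline(0, 1)
    graphics::abline(0, x$lambda, col = "red")
  }
  invisible(x)
}

#' Write scan results as TSV
#'
#' Per-locus results plus a `<prefix>.summary.tsv` with lambda and the
#' significance thresholds.
#'
#' @param scan a `gwas_scan`.
#' @param prefix output prefix.
#' @return `prefix`, invisibly.
#' @export
write_gwas <- function(scan, prefix) {
  utils::write.table(scan$results, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- data.frame(trait = scan$trait, n_snps = scan$n_snps,
                     n_monomorphic = scan$n_monomorphic,
                     lambda = scan$lambda, lambda_se = scan$lambda_se,
                     lambda_median = scan$lambda_median,
                     genome_wide = scan$thresholds[["genome_wide"]],
                     suggestive = scan$thresholds[["suggestive"]],
                     genomic_control = scan$genomic_control)
  utils::write.table(summ, paste0(prefix, ".summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
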