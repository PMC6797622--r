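# Genomic relationship matrix -------------------------------------------

#' Compute the genomic relationship matrix
#'
#' Allele-sharing relatedness weighted by allele frequencies: entry
#' (i, j) is
#' \deqn{\frac{1}{L_{ij}} \sum_k \frac{(x_{ik} - 2p_k)(x_{jk} - 2p_k)}
#'   {2 p_k (1 - p_k)}}
#' with x the alternate-allele count, p the sample allele frequency, and
#' the sum over loci where both calls are non-missing (pairwise-complete,
#' `L_ij` = that count). The diagonal uses the same formula. This
#' centered-and-standardized estimator has expectation equal to the
#' pedigree numerator relationship matrix under random mating. A raw
#' identity-by-state variant (`method = "ibs"`, mean proportion of shared
#' alleles) is provided for sensitivity checks.
#'
#' @param g a [genotype_matrix()], post-QC; every locus must be
#'   polymorphic.
#' @param method `"vanraden"` (default) or `"ibs"`.
#' @param freqs optional per-locus alternate-allele frequencies to
#'   center and scale with; defaults to the sample frequencies, which is
#'   appropriate for a single-population analysis (and gives
#'   off-diagonals an expected offset of about `-1/(n-1)`).
#' @return Object of class `grm`: list with `K` (symmetric matrix),
#'   `ids`, `n_loci`, `n_loci_pair` (pairwise-complete locus counts),
#'   `freqs`, `method`.
#' @export
compute_grm <- function(g, method = c("vanraden", "ibs"), freqs = NULL) {
  method <- match.arg(method)
  p <- freqs %||% allele_freq(g)
  stop_if(length(p) != ncol(g$calls),
          "freqs must have one entry per locus")
  stop_if(any(is.na(p) | p <= 0 | p >= 1),
          "monomorphic or all-missing loci present (%d); filter them first",
          sum(is.na(p) | p <= 0 | p >= 1))
  X <- g$calls
  obs <- !is.na(X)
  npair <- tcrossprod(obs * 1)
  if (method == "vanraden") {
    S <- sweep(X, 2, 2 * p)
    S <- sweep(S, 2, sqrt(2 * p * (1 - p)), "/")
    S[!obs] <- 0
    K <- tcrossprod(S) / npair
  } else {
    I0 <- (X == 0L) & obs; I1 <- (X == 1L) & obs; I2 <- (X == 2L) & obs
    storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
    absdiff <- 2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0)) +
      tcrossprod(I1, I0 + I2) + tcrossprod(I0 + I2, I1)
    K <- 1 - absdiff / (2 * npair)
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- list(g$ids, g$ids)
  structure(list(K = K, ids = g$ids, n_loci = ncol(X),
                 n_loci_pair = npair, freqs = p, method = method,
                 bent = FALSE),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$K)
  off <- x$K[upper.tri(x$K)]
  cat(sprintf("grm (%s): %d individuals, %d loci\n", x$method, n, x$n_loci))
  cat(sprintf("  diagonal: mean %.3f; off-diagonal: mean %.4f, range [%.3f, %.3f]\n",
              mean(diag(x$K)), mean(off), min(off), max(off)))
  if (isTRUE(x$bent)) cat("  (diagonal ridge applied for positive definiteness)\n")
  invisible(x)
}

#' Make a GRM usable as a covariance matrix
#'
#' If the smallest eigenvalue is below `1e-8`, adds a diagonal ridge
#' (doubling until positive definiteness is reached) so the matrix can
#' serve as the additive-genetic covariance in REML. Off-diagonals are
#' never changed; whether bending occurred is recorded.
#'
#' @param grm a `grm` from [compute_grm()].
#' @param ridge initial ridge (default 1e-6).
#' @return The (possibly bent) `grm`.
#' @export
stabilize_grm <- function(grm, ridge = 1e-6) {
  ev <- min(eigen(grm$K, symmetric = TRUE, only.values = TRUE)$values)
  r <- ridge
  while (ev < 1e-8) {
    grm$K <- grm$K + diag(r, nrow(grm$K))
    grm$bent <- TRUE
    ev <- min(eigen(grm$K, symmetric = TRUE, only.values = TRUE)$values)
    r <- r * 2
  }
  grm
}

#' Write a GRM to text files
#'
#' Writes (a) a square TSV with a header row of ids and (b) a
#' GCTA-style lower-triangle file (`id1 id2 n_loci value`, one row per
#' ordered pair with `id1` index >= `id2` index).
#'
#' @param grm a `grm`.
#' @param prefix output prefix (`.grm.tsv` and `.grm.txt` appended).
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  sq <- as.data.frame(grm$K)
  utils::write.table(cbind(id = grm$ids, sq), paste0(prefix, ".grm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n <- length(grm$ids)
  lower <- which(lower.tri(grm$K, diag = TRUE), arr.ind = TRUE)
  tri <- data.frame(id1 = grm$ids[lower[, 1]], id2 = grm$ids[lower[, 2]],
                    n_loci = grm$n_loci_pair[lower],
                    value = grm$K[lower])
  utils::write.table(tri, paste0(prefix, ".grm.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
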