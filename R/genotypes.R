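# Genotype container ----------------------------------------------------

#' Construct a genotype matrix object
#'
#' Container for biallelic SNP calls coded as alternate-allele counts
#' (0, 1, 2 or `NA` for missing), together with locus metadata. This is
#' the unit on which quality control and genomic-relationship construction
#' operate.
#'
#' @param calls integer matrix, individuals in rows, loci in columns;
#'   entries in `{0, 1, 2, NA}`. Row names (if any) are taken as
#'   individual ids unless `ids` is given.
#' @param map data frame with columns `chrom` (chromosome label),
#'   `snp` (locus id, unique), `pos` (1-based bp position).
#' @param ids character vector of individual ids.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `map` and `ids`. Per-locus sample allele frequencies are
#'   available through [allele_freq()].
#' @seealso [read_plink()], [compute_grm()], [qc_genotypes()]
#' @export
genotype_matrix <- function(calls, map, ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stop_if(is.null(ids), "individual ids are required")
  ids <- as.character(ids)
  stop_if(length(ids) != nrow(calls),
          "length of ids (%d) does not match rows of calls (%d)",
          length(ids), nrow(calls))
  stop_if(anyDuplicated(ids) > 0L, "duplicate individual ids")
  map <- as.data.frame(map)
  stop_if(!all(c("chrom", "snp", "pos") %in% names(map)),
          "map must have columns chrom, snp, pos")
  stop_if(nrow(map) != ncol(calls),
          "map has %d loci but calls has %d columns", nrow(map), ncol(calls))
  stop_if(anyDuplicated(map$snp) > 0L, "duplicate snp ids in map")
  stop_if(any(map$pos < 1, na.rm = TRUE), "bp positions must be >= 1")
  bad <- calls[!is.na(calls)]
  stop_if(any(bad < 0L | bad > 2L), "calls must be in {0, 1, 2, NA}")
  dimnames(calls) <- list(ids, as.character(map$snp))
  structure(list(calls = calls, map = map, ids = ids),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci\n",
              nrow(x$calls), ncol(x$calls)))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$map$chrom)[seq_len(min(8, length(unique(x$map$chrom))))],
                    collapse = ", ")))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Sample allele frequencies
#'
#' Per-locus alternate-allele frequency computed over non-missing calls.
#'
#' @param g a [genotype_matrix()].
#' @return Numeric vector, one frequency per locus (`NaN` where all calls
#'   are missing).
#' @export
allele_freq <- function(g) {
  colMeans(g$calls, na.rm = TRUE) / 2
}

#' Minor allele frequencies
#'
#' @param g a [genotype_matrix()].
#' @return `pmin(p, 1 - p)` of the sample alternate-allele frequency.
#' @export
minor_allele_freq <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}

# subset individuals/loci, keeping metadata aligned
subset_genotypes <- function(g, ind = NULL, loci = NULL) {
  calls <- g$calls
  ids <- g$ids
  map <- g$map
  if (!is.null(ind)) {
    calls <- calls[ind, , drop = FALSE]
    ids <- ids[ind]
  }
  if (!is.null(loci)) {
    calls <- calls[, loci, drop = FALSE]
    map <- map[loci, , drop = FALSE]
    rownames(map) <- NULL
  }
  genotype_matrix(calls, map, ids)
}
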