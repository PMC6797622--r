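# PLINK text (PED/MAP) input/output -------------------------------------

#' Read genotypes from PLINK text files
#'
#' Parses whitespace-delimited PED/MAP pairs. Alleles are letters (`A` =
#' reference, `B` = alternate by default) with `0` for missing; a call is
#' missing when either allele is `0`. MAP columns are chromosome, snp id,
#' genetic distance (ignored) and 1-based bp position.
#'
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` are read.
#' @param alt_allele letter counted as the alternate allele.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix, alt_allele = "B") {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  stop_if(!file.exists(ped_path), "missing PED file: %s", ped_path)
  stop_if(!file.exists(map_path), "missing MAP file: %s", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE,
                               stringsAsFactors = FALSE,
                               col.names = c("chrom", "snp", "cm", "pos"))
  L <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  calls <- matrix(NA_integer_, n, L)
  ids <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    stop_if(length(tok) != 2L * L + 6L,
            "PED line %d: expected %d fields (2 x %d loci + 6), found %d",
            i, 2L * L + 6L, L, length(tok))
    ids[i] <- tok[2]
    a1 <- tok[seq(7L, by = 2L, length.out = L)]
    a2 <- tok[seq(8L, by = 2L, length.out = L)]
    g <- (a1 == alt_allele) + (a2 == alt_allele)
    g[a1 == "0" | a2 == "0"] <- NA_integer_
    calls[i, ] <- g
  }
  genotype_matrix(calls, map_raw[, c("chrom", "snp", "pos")], ids = ids)
}

#' Write genotypes as PLINK text files
#'
#' Inverse of [read_plink()]: alleles written as `A`/`B` letters with
#' missing calls as `0 0`; family id equals individual id, parents and
#' phenotype set to 0, sex to 1 (the study design samples rams).
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix (`.ped` and `.map` are appended).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  map <- data.frame(g$map$chrom, g$map$snp, 0L, g$map$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(g$calls); L <- ncol(g$calls)
  first <- c("A", "A", "B", "0")  # indexed by call + 1, NA -> "0"
  second <- c("A", "B", "B", "0")
  idx <- g$calls + 1L
  idx[is.na(idx)] <- 4L
  a1 <- matrix(first[idx], n, L)
  a2 <- matrix(second[idx], n, L)
  geno_cols <- matrix(character(0), n, 0)
  inter <- matrix("", n, 2L * L)
  inter[, seq(1L, by = 2L, length.out = L)] <- a1
  inter[, seq(2L, by = 2L, length.out = L)] <- a2
  body <- apply(inter, 1L, paste, collapse = " ")
  lines <- paste(g$ids, g$ids, 0L, 0L, 1L, 0L, body)
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}
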