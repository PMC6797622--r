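# Raw annuli records and their reconstruction into yearly traits --------

#' A raw harvest horn record
#'
#' One harvested ram's per-annulus measurements: ordered annual segment
#' lengths from lamb tip (year 1) to horn base, the base circumference at
#' each annulus, and harvest metadata. The annuli count gives the age at
#' harvest.
#'
#' @param id individual identifier.
#' @param harvest_year calendar year of harvest.
#' @param age_at_harvest age in years; must equal `length(segments)`.
#' @param segments annual segment lengths in mm, tip first.
#' @param base_circumferences per-annulus base circumferences in mm,
#'   aligned with `segments` (annulus j's circumference is measured at
#'   the base of year-j growth).
#' @return An object of class `horn_record`.
#' @export
horn_record <- function(id, harvest_year, age_at_harvest, segments,
                        base_circumferences) {
  segments <- as.numeric(segments)
  base_circumferences <- as.numeric(base_circumferences)
  stop_if(length(segments) != age_at_harvest,
          "record %s: %d segments but age_at_harvest = %d",
          id, length(segments), age_at_harvest)
  stop_if(length(base_circumferences) != length(segments),
          "record %s: %d segments but %d circumferences",
          id, length(segments), length(base_circumferences))
  stop_if(any(segments < 0) || any(base_circumferences < 0),
          "record %s: negative measurements", id)
  structure(list(id = as.character(id),
                 harvest_year = as.integer(harvest_year),
                 age_at_harvest = as.integer(age_at_harvest),
                 segments = segments,
                 base_circumferences = base_circumferences),
            class = "horn_record")
}

#' @export
print.horn_record <- function(x, ...) {
  cat(sprintf("horn_record %s: harvested %d at age %d\n",
              x$id, x$harvest_year, x$age_at_harvest))
  cat("  segments (mm):", paste(format(x$segments), collapse = " "), "\n")
  cat("  base circumferences (mm):",
      paste(format(x$base_circumferences), collapse = " "), "\n")
  invisible(x)
}

#' Volume of a conical frustum
#'
#' `V = (1/3) pi H (r1^2 + r1 r2 + r2^2)`, the standard approximation of
#' one year's horn growth segment as a truncated cone. Symmetric in
#' `r1`, `r2`; linear in `H`. Vectorized.
#'
#' @param r1,r2 base radii at either end of the segment (mm).
#' @param H segment length (mm).
#' @return Volume in mm^3.
#' @examples
#' frustum_volume(10, 10, 30)  # cylinder limit: 3000 * pi
#' frustum_volume(10, 0, 30)   # cone limit: 1000 * pi
#' @export
frustum_volume <- function(r1, r2, H) {
  stop_if(any(r1 < 0) || any(r2 < 0) || any(H < 0),
          "frustum dimensions must be >= 0")
  (1 / 3) * pi * H * (r1^2 + r1 * r2 + r2^2)
}

#' Growth-plausibility quality control
#'
#' A missed first annulus merges year-1 and year-2 growth into one
#' implausibly large increment and shifts all later ages. Records are
#' excluded when year-1 growth exceeds `year1_max` (160 mm) or when the
#' sum of year-1 and year-2 growth exceeds `year12_max` (420 mm). The
#' disjunctive reading (either condition excludes) is the default; set
#' `rule = "both"` to require both.
#'
#' @param records list of [horn_record()] objects.
#' @param year1_max year-1 growth bound in mm.
#' @param year12_max bound on year-1 plus year-2 growth in mm.
#' @param rule `"either"` (default) or `"both"`.
#' @return List with `kept` and `excluded` (lists of records) and
#'   `report`, a data frame of per-rule exclusion counts (a record
#'   failing both rules is counted under both, `n_excluded` counts it
#'   once).
#' @export
apply_growth_qc <- function(records, year1_max = 160, year12_max = 420,
                            rule = c("either", "both")) {
  rule <- match.arg(rule)
  if (length(records) == 0) {
    return(list(kept = list(), excluded = list(),
                report = growth_qc_report(0L, 0L, 0L, 0L, rule)))
  }
  y1 <- vapply(records, function(r) r$segments[1], numeric(1))
  y2 <- vapply(records, function(r) {
    if (length(r$segments) >= 2) r$segments[2] else 0
  }, numeric(1))
  fail1 <- y1 > year1_max
  fail2 <- (y1 + y2) > year12_max
  out <- if (rule == "either") fail1 | fail2 else fail1 & fail2
  list(kept = records[!out], excluded = records[out],
       report = growth_qc_report(length(records), sum(fail1), sum(fail2),
                                 sum(out), rule))
}

growth_qc_report <- function(n_in, n_year1, n_sum, n_excluded, rule) {
  data.frame(stage = c("input", "year1_rule", "year12_sum_rule", "excluded",
                       "kept"),
             count = c(n_in, n_year1, n_sum, n_excluded, n_in - n_excluded),
             rule = rule, stringsAsFactors = FALSE)
}

#' Reconstruct yearly trait measures from a horn record
#'
#' Applies the standard lamb-tip corrections: year-1 measures are
#' dropped, year-1 growth is subtracted from all cumulative lengths, and
#' no frustum volume is computed for the lamb tip. For ages
#' `j = 2..age_at_harvest` this yields cumulative length
#' `sum(segments[2..j])`, circumference `base_circumferences[j]`, and
#' volume `sum_{i=2..j} frustum_volume(r_i, r_{i-1}, segments[i])` with
#' `r_i = base_circumferences[i] / (2 pi)`; the first-annulus
#' circumference serves only as a frustum boundary and is never emitted
#' as a trait value. Volumes are reported in cm^3.
#'
#' @param record a [horn_record()]; should have passed
#'   [apply_growth_qc()].
#' @param birth_year optional; defaults to
#'   `harvest_year - age_at_harvest`.
#' @return Long-format data frame (`id`, `birth_year`, `meas_year`,
#'   `age`, `trait`, `value`); empty for age-1-only records.
#' @export
reconstruct_yearly_measures <- function(record,
                                        birth_year = record$harvest_year -
                                          record$age_at_harvest) {
  stopifnot(inherits(record, "horn_record"))
  T_ <- record$age_at_harvest
  empty <- data.frame(id = character(), birth_year = integer(),
                      meas_year = integer(), age = integer(),
                      trait = character(), value = numeric(),
                      stringsAsFactors = FALSE)
  if (T_ < 2) return(empty)
  ages <- seq(2L, T_)
  segs <- record$segments
  circ <- record$base_circumferences
  lengths <- cumsum(segs[ages])                 # year-1 growth excluded
  r <- circ / (2 * pi)
  frusta <- frustum_volume(r[ages], r[ages - 1L], segs[ages])
  volumes <- cumsum(frusta) / 1000              # mm^3 -> cm^3
  out <- rbind(
    data.frame(id = record$id, birth_year = birth_year,
               meas_year = birth_year + ages, age = ages,
               trait = "length", value = lengths,
               stringsAsFactors = FALSE),
    data.frame(id = record$id, birth_year = birth_year,
               meas_year = birth_year + ages, age = ages,
               trait = "circumference", value = circ[ages],
               stringsAsFactors = FALSE),
    data.frame(id = record$id, birth_year = birth_year,
               meas_year = birth_year + ages, age = ages,
               trait = "volume", value = volumes,
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Reconstruct a phenotype table from many records
#'
#' Runs [apply_growth_qc()] then [reconstruct_yearly_measures()] on the
#' surviving records and stacks the results.
#'
#' @inheritParams apply_growth_qc
#' @param qc apply the growth filters first (default `TRUE`).
#' @return List with `phenotypes` (long data frame), `qc` (the QC
#'   result, `NULL` when `qc = FALSE`).
#' @export
reconstruct_phenotypes <- function(records, qc = TRUE,
                                   year1_max = 160, year12_max = 420,
                                   rule = c("either", "both")) {
  qc_res <- NULL
  if (qc) {
    qc_res <- apply_growth_qc(records, year1_max, year12_max,
                              rule = match.arg(rule))
    records <- qc_res$kept
  }
  phen <- do.call(rbind, lapply(records, reconstruct_yearly_measures))
  if (is.null(phen)) {
    phen <- reconstruct_yearly_measures(
      horn_record("x", 2000L, 1L, 0, 0))  # empty template
  }
  rownames(phen) <- NULL
  list(phenotypes = phen, qc = qc_res)
}

# Raw-record TSV I/O -----------------------------------------------------

#' Read raw horn records from TSV
#'
#' Expected columns: `id`, `harvest_year`, `age`, `segments`
#' (comma-separated mm), `circumferences` (comma-separated mm).
#'
#' @param path TSV file.
#' @return List of [horn_record()] objects.
#' @examples
#' path <- system.file("extdata", "synthetic_horn_records.tsv",
#'                     package = "hornherit")
#' recs <- read_horn_records(path)
#' apply_growth_qc(recs)$report
#' @export
read_horn_records <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    horn_record(df$id[i], df$harvest_year[i], df$age[i],
                as.numeric(strsplit(df$segments[i], ",")[[1]]),
                as.numeric(strsplit(df$circumferences[i], ",")[[1]]))
  })
}

#' Write raw horn records to TSV
#'
#' @param records list of [horn_record()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_horn_records <- function(records, path) {
  df <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    harvest_year = vapply(records, `[[`, integer(1), "harvest_year"),
    age = vapply(records, `[[`, integer(1), "age_at_harvest"),
    segments = vapply(records, function(r)
      paste(format(r$segments, trim = TRUE, digits = 15), collapse = ","),
      character(1)),
    circumferences = vapply(records, function(r)
      paste(format(r$base_circumferences, trim = TRUE, digits = 15),
            collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
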