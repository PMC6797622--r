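# End-to-end pipeline orchestration -------------------------------------

#' Pipeline run configuration
#'
#' Validates and normalizes the configuration driving [run_pipeline()].
#' Accepts a YAML file path or a named list. Fields: `genotypes` (PLINK
#' prefix), exactly one of `horn_records` (raw TSV) or `phenotypes`
#' (long TSV), `out_dir`, `traits`, QC thresholds (`ind_call_rate`,
#' `locus_call_rate`, `min_maf`, `drop_x`, `hwe_alpha`, `year1_max`,
#' `year12_max`, `qc_rule`), `grm_method` (`"vanraden"` or `"ibs"`),
#' `genomic_control`, and `seed`.
#'
#' @param config named list or path to a YAML file.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    stop_if(!file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stop_if(!is.list(config), "config must be a list or a YAML file path")
  defaults <- list(
    genotypes = NULL, horn_records = NULL, phenotypes = NULL,
    out_dir = "hornherit_run", traits = c("length", "circumference", "volume"),
    ind_call_rate = 0.9, locus_call_rate = 0.9, min_maf = 0.01,
    drop_x = TRUE, hwe_alpha = 0.001,
    year1_max = 160, year12_max = 420, qc_rule = "either",
    grm_method = "vanraden", genomic_control = TRUE, gwas = TRUE,
    seed = 1L
  )
  unknown <- setdiff(names(config), names(defaults))
  stop_if(length(unknown) > 0, "unknown config fields: %s",
          paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  stop_if(is.null(cfg$genotypes), "config field 'genotypes' is required")
  stop_if(!file.exists(paste0(cfg$genotypes, ".ped")),
          "genotype PED file not found: %s.ped", cfg$genotypes)
  stop_if(is.null(cfg$horn_records) && is.null(cfg$phenotypes),
          "one of 'horn_records' or 'phenotypes' is required")
  src <- cfg$horn_records %||% cfg$phenotypes
  stop_if(!file.exists(src), "phenotype input not found: %s", src)
  for (f in c("ind_call_rate", "locus_call_rate", "min_maf", "hwe_alpha")) {
    check_fraction(cfg[[f]], f)
  }
  stop_if(!cfg$grm_method %in% c("vanraden", "ibs"),
          "grm_method must be 'vanraden' or 'ibs'")
  stop_if(!cfg$qc_rule %in% c("either", "both"),
          "qc_rule must be 'either' or 'both'")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes horn-record QC and reconstruction (when raw records are the
#' input), genotype QC, GRM construction, per-trait REML animal-model
#' fits, and (optionally) per-trait association scans. All stage outputs
#' are written as TSV under `out_dir`, along with a per-stage accounting
#' log and a machine-readable JSON run manifest (package version, seed,
#' config hash).
#'
#' @param config a [run_config()] (or anything it accepts).
#' @return Invisibly, a list with `qc`, `grm`, `fits`, `scans`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", "hornherit", sprintf(fmt, ...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  # phenotypes -----------------------------------------------------------
  horn_qc <- NULL
  phenos <- stage("phenotypes", {
    if (!is.null(cfg$horn_records)) {
      recs <- read_horn_records(cfg$horn_records)
      rec_res <- reconstruct_phenotypes(recs, qc = TRUE,
                                        year1_max = cfg$year1_max,
                                        year12_max = cfg$year12_max,
                                        rule = cfg$qc_rule)
      horn_qc <- rec_res$qc
      utils::write.table(rec_res$qc$report,
                         file.path(cfg$out_dir, "horn_qc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logf("horn QC: %d records in, %d kept", length(recs),
           length(rec_res$qc$kept))
      write_phenotypes(rec_res$phenotypes,
                       file.path(cfg$out_dir, "phenotypes.tsv"))
      rec_res$phenotypes
    } else {
      read_phenotypes(cfg$phenotypes)
    }
  })
  # genotype QC ----------------------------------------------------------
  qc <- stage("genotype_qc", {
    g <- read_plink(cfg$genotypes)
    logf("genotypes: %d individuals x %d loci", nrow(g$calls), ncol(g$calls))
    res <- qc_genotypes(g, cfg$ind_call_rate, cfg$locus_call_rate,
                        cfg$min_maf, cfg$drop_x, cfg$hwe_alpha)
    write_qc_report(res, file.path(cfg$out_dir, "genotype_qc.tsv"))
    logf("genotype QC: %d x %d surviving; %d HWE-flagged (kept)",
         res$output_dim[1], res$output_dim[2], nrow(res$hwe_flagged))
    res
  })
  # GRM ------------------------------------------------------------------
  grm <- stage("grm", {
    gr <- stabilize_grm(compute_grm(qc$genotypes, method = cfg$grm_method))
    write_grm(gr, file.path(cfg$out_dir, "relatedness"))
    logf("GRM (%s): %d individuals, %d loci%s", gr$method,
         length(gr$ids), gr$n_loci,
         if (gr$bent) " (bent to positive definite)" else "")
    gr
  })
  # restrict phenotypes to QC-passed genotyped individuals
  phenos <- phenos[phenos$id %in% grm$ids, , drop = FALSE]
  traits <- intersect(cfg$traits, unique(phenos$trait))
  stop_if(length(traits) == 0, "no requested trait present in phenotypes")
  # REML + GWAS per trait -------------------------------------------------
  fits <- list(); scans <- list()
  for (tr in traits) {
    fits[[tr]] <- stage(paste0("reml_", tr),
                        animal_model(phenos, grm, trait = tr))
    logf("REML %s: h2 = %.3f (SE %.3f), logLik %.2f", tr,
         fits[[tr]]$h2, fits[[tr]]$h2_se, fits[[tr]]$loglik)
    if (isTRUE(cfg$gwas)) {
      scans[[tr]] <- stage(paste0("gwas_", tr),
                           gwas_scan(fits[[tr]], qc$genotypes,
                                     genomic_control = cfg$genomic_control))
      write_gwas(scans[[tr]], file.path(cfg$out_dir, paste0("gwas_", tr)))
      logf("GWAS %s: lambda = %.3f, min p = %.3g", tr, scans[[tr]]$lambda,
           min(scans[[tr]]$results$p, na.rm = TRUE))
    }
  }
  write_variance_components(fits,
                            file.path(cfg$out_dir, "variance_components.tsv"))
  manifest <- list(
    package = "hornherit",
    version = as.character(utils::packageVersion("hornherit")),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    traits = traits,
    n_individuals = length(grm$ids),
    n_loci = grm$n_loci
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(qc = qc, grm = grm, fits = fits, scans = scans,
                 horn_qc = horn_qc, manifest = manifest))
}

config_hash <- function(cfg) {
  dat <- paste(utils::capture.output(utils::str(unclass(cfg))),
               collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(dat, tf)
  unname(tools::md5sum(tf))
}

#' Simulate a study and write its inputs to disk
#'
#' Runs the synthetic-data generator and writes PLINK PED/MAP, the long
#' phenotype TSV, raw horn-record TSV (rendered from the length and
#' circumference traits where monotone), and ground-truth TSVs — a
#' complete input set for [run_pipeline()].
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param render write raw horn records (requires monotone simulated
#'   lengths; default `FALSE`).
#' @return Invisibly, the simulated study list.
#' @export
simulate_to_files <- function(config, out_dir, render = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_horn_study(config)
  write_plink(sim$genotypes, file.path(out_dir, "genotypes"))
  write_phenotypes(sim$phenotypes, file.path(out_dir, "phenotypes.tsv"))
  write_truth(sim$phenotypes, file.path(out_dir, "truth"))
  if (render) {
    recs <- render_horn_records(sim$phenotypes,
                                seed = derive_seed(config$seed, "records"))
    write_horn_records(recs, file.path(out_dir, "horn_records.tsv"))
  }
  invisible(sim)
}
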