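# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small but non-trivial study: 16 sires x 2 x 2 = 64 phenotyped rams.
small_config <- function(seed = 11L, ...) {
  sim_config(n_sires = 16L, dams_per_sire = 2L, offspring_per_dam = 2L,
             n_snps = 800L, seed = seed, ...)
}

small_study <- function() {
  cached("small_study", {
    sim <- simulate_horn_study(small_config(), traits = "length")
    qc <- qc_genotypes(sim$genotypes)
    grm <- stabilize_grm(compute_grm(qc$genotypes))
    list(sim = sim, qc = qc, grm = grm)
  })
}

small_fit <- function() {
  cached("small_fit", {
    st <- small_study()
    animal_model(st$sim$phenotypes, st$grm, trait = "length")
  })
}

# A tiny deterministic genotype fixture with known QC failures:
# 3 x-linked loci, 4 low-MAF loci (one heterozygote in 60 individuals
# gives MAF 1/120 < 0.01), and room to engineer low-call individuals.
toy_genotypes <- function(n_ind = 60L, n_ok = 12L) {
  set.seed(99)
  n_x <- 3L; n_rare <- 4L
  L <- n_ok + n_x + n_rare
  calls <- matrix(rbinom(n_ind * L, 2L, 0.4), n_ind, L)
  # rare loci: exactly one heterozygote carrier -> MAF = 1/(2 n_ind)
  for (j in n_ok + n_x + seq_len(n_rare)) {
    calls[, j] <- 0L
    calls[1L + (j %% n_ind), j] <- 1L
  }
  map <- data.frame(
    chrom = c(rep(1L, n_ok), rep("X", n_x), rep(2L, n_rare)),
    snp = sprintf("t%02d", seq_len(L)),
    pos = seq_len(L) * 1000L
  )
  genotype_matrix(calls, map, ids = sprintf("ind%02d", seq_len(n_ind)))
}
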