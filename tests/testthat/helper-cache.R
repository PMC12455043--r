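# Shared expensive fixtures, computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Default synthetic dataset (generator defaults, seed 1).
default_sim <- function() {
  if (!exists("sim", envir = .fixture_cache)) {
    assign("sim", simulate_dataset(sim_config(seed = 1L)),
           envir = .fixture_cache)
  }
  get("sim", envir = .fixture_cache)
}

# SNP-track scan of the default dataset.
default_snp_scan <- function() {
  if (!exists("scan", envir = .fixture_cache)) {
    assign("scan",
           suppressMessages(snp_scan(default_sim()$panels,
                                     default_sim()$layout, load_config())),
           envir = .fixture_cache)
  }
  get("scan", envir = .fixture_cache)
}

# Small fast dataset for structural tests.
small_sim <- function() {
  if (!exists("small", envir = .fixture_cache)) {
    cfg <- sim_config(seed = 11L,
                      chrom_lengths = c(chr1 = 4e5, chr2 = 3e5),
                      sv_count = 200L, str_count = 300L, n_sweeps = 2L,
                      sweep_length = 5e4)
    assign("small", simulate_dataset(cfg), envir = .fixture_cache)
  }
  get("small", envir = .fixture_cache)
}

# Fraction of planted sweeps overlapped by supported regions, and the
# fraction of supported regions wholly outside any planted sweep.
sweep_recovery <- function(regions, sweeps) {
  hit <- vapply(seq_len(nrow(sweeps)), function(i) {
    any(regions$chrom == sweeps$chrom[i] &
          regions$start < sweeps$end[i] & regions$end > sweeps$start[i])
  }, logical(1))
  false_region <- vapply(seq_len(nrow(regions)), function(i) {
    !any(sweeps$chrom == regions$chrom[i] &
           sweeps$start < regions$end[i] & sweeps$end > regions$start[i])
  }, logical(1))
  list(hit_fraction = mean(hit),
       false_fraction = if (nrow(regions) > 0) mean(false_region) else 0)
}
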