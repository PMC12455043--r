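# The synthetic-data generator: frequency model, haplotype mosaics with
# planted sweeps, marker loci, annotation, reproducibility.

test_that("Balding-Nichols frequencies have the right moments", {
  set.seed(1)
  # F -> 0 limit: frequencies collapse onto the ancestral value
  f <- balding_nichols_freqs(rep(0.4, 1000), F = 1e-6, n_pops = 1)
  expect_gte(mean(abs(f - 0.4) < 0.01), 0.99)
  # mean and variance at p = 0.5, F = 0.02
  f <- balding_nichols_freqs(rep(0.5, 10000), F = 0.02, n_pops = 1)
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.5), 3 * se)
  expect_lt(abs(var(f) - 0.02 * 0.25) / (0.02 * 0.25), 0.2)
  # determinism
  set.seed(99); d1 <- balding_nichols_freqs(runif(50, 0.1, 0.9), 0.05)
  set.seed(99); d2 <- balding_nichols_freqs(runif(50, 0.1, 0.9), 0.05)
  expect_identical(d1, d2)
  expect_error(balding_nichols_freqs(0.5, F = 0), "strictly inside")
  expect_error(balding_nichols_freqs(0.5, F = 1), "strictly inside")
})

test_that("sweeps force haplotype homozygosity; rho = 0 gives pure founders", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 2e5),
                    n_diploid = 8L, n_sweeps = 1L, sweep_length = 5e4,
                    f_sweep = 1.0)
  set.seed(5)
  sweeps <- data.frame(chrom = "chr1", start = 50000, end = 100000)
  panels <- mosaic_panel_with_sweep(cfg, "chr1", sweeps)
  in_rg <- panels$B$pos >= 50000 & panels$B$pos < 100000
  hap_in <- panels$B$hap[, in_rg, drop = FALSE]
  expect_true(all(apply(hap_in, 2, function(x) length(unique(x)) == 1)))
  # f_sweep = 1: EHH = 1 across the swept region
  core <- which(in_rg)[1]
  cv <- ehh_curve(panels$B, core, allele = "der", side = "right",
                  cutoff = 0)
  if (is.null(cv)) cv <- ehh_curve(panels$B, core, allele = "anc",
                                   side = "right", cutoff = 0)
  n_in <- sum(panels$B$pos >= panels$B$pos[core] & in_rg)
  expect_true(all(cv$ehh[seq_len(n_in)] == 1))

  # rho = 0: every haplotype equals one founder everywhere
  cfg0 <- sim_config(seed = 6, chrom_lengths = c(chr1 = 1e5),
                     n_diploid = 6L, rho = 0, n_sweeps = 1L,
                     sweep_length = 1e4, f_sweep = 0.0001)
  set.seed(6)
  p0 <- mosaic_panel_with_sweep(cfg0, "chr1", NULL)
  founders_A <- attr(p0, "founders")[[1]]
  for (h in seq_len(nrow(p0$A$hap))) {
    match_one <- any(apply(founders_A, 1, function(f) {
      all(f == p0$A$hap[h, ])
    }))
    expect_true(match_one)
  }

  expect_error(mosaic_panel_with_sweep(
    cfg, "chr1", data.frame(chrom = "chr1", start = 0, end = 3e5)),
    "outside chromosome")
})

test_that("swept windows lose diversity relative to the genome background", {
  sim <- default_sim()
  win <- make_windows(sim$layout)
  stats <- window_stats_scan(sim$panels, win)
  genome_median <- median(stats$pi_B, na.rm = TRUE)
  sw <- sim$truth$sweeps
  lowered <- vapply(seq_len(nrow(sw)), function(i) {
    in_sw <- stats$chrom == sw$chrom[i] & stats$start >= sw$start[i] &
      stats$end <= sw$end[i]
    if (!any(in_sw)) in_sw <- stats$chrom == sw$chrom[i] &
        stats$start < sw$end[i] & stats$end > sw$start[i]
    mean(stats$pi_B[in_sw], na.rm = TRUE) < genome_median
  }, logical(1))
  expect_gte(sum(lowered), 9)
})

test_that("marker loci carry the planted differentiation structure", {
  cfg <- sim_config(seed = 8, sv_count = 500L, str_count = 1000L)
  set.seed(8)
  loci <- simulate_marker_loci(cfg)
  expect_equal(length(loci$svs$id), 500)
  expect_equal(length(loci$strs$id), 1000)
  expect_true(all(loci$strs$period %in% 1:6))
  expect_true(all(loci$svs$length > 0))
  expect_true(all(loci$svs$end >= loci$svs$start))

  # a strongly divergent SV yields high Weir-Cockerham FST
  pA <- rbinom(40, 1, 0.95); pB <- rbinom(40, 1, 0.05)
  dos <- list(pA[1:20] + pA[21:40], pB[1:20] + pB[21:40])
  expect_gt(wc_fst_site(dos), 0.5)
  div <- which(loci$sv_truth$divergent)
  th <- vapply(div, function(j) {
    dA <- loci$svs$a1[1:20, j] + loci$svs$a2[1:20, j]
    dB <- loci$svs$a1[21:40, j] + loci$svs$a2[21:40, j]
    wc_fst_site(list(dA, dB))
  }, numeric(1))
  expect_gt(median(th), 0.3)

  # neutral STRs: parametric Jost's D computed from the simulated (true)
  # population frequency vectors is small for at least 95% of loci
  neut <- which(!loci$str_truth$divergent)
  tr <- loci$str_truth
  d <- vapply(neut, function(j) {
    dA <- polyscan:::.str_allele_dist(tr$mu_A[j], cfg$str_sd)
    dB <- polyscan:::.str_allele_dist(tr$mu_B[j], cfg$str_sd)
    lv <- sort(union(dA$counts, dB$counts))
    fa <- dA$prob[match(lv, dA$counts)]; fa[is.na(fa)] <- 0
    fb <- dB$prob[match(lv, dB$counts)]; fb[is.na(fb)] <- 0
    Hs <- ((1 - sum(fa^2)) + (1 - sum(fb^2))) / 2
    Ht <- 1 - sum(((fa + fb) / 2)^2)
    (Ht - Hs) / (1 - Hs) * 2
  }, numeric(1))
  expect_gte(mean(d < 0.1), 0.95)
  expect_error(simulate_marker_loci(sim_config(sv_div_frac = 1.5)),
               "divergent fraction")
})

test_that("generated annotation is frame-consistent with ~16 kb spacing", {
  sim <- small_sim()
  cds_len <- tapply(sim$genes$cds$end - sim$genes$cds$start,
                    sim$genes$cds$gene_id, sum)
  expect_true(all(cds_len %% 3 == 0))
  # every spliced CDS is a clean ORF: starts ATG, ends with a stop, no
  # internal stops
  for (g in sim$genes$index$id[1:10]) {
    seg <- gene_cds(sim$genes, g)
    chars <- lapply(seq_len(nrow(seg)), function(s) {
      x <- Biostrings::subseq(sim$ref[[seg$chrom[s]]], seg$start[s] + 1,
                              seg$end[s])
      if (seg$strand[s] == "-") x <- Biostrings::reverseComplement(x)
      as.character(x)
    })
    orf <- paste(unlist(chars), collapse = "")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  # intergenic gaps: mean/2 within 15% of 8 kb on the default-scale run
  sim_big <- default_sim()
  idx <- sim_big$genes$index
  gaps <- unlist(lapply(split(idx, idx$chrom), function(g) {
    g <- g[order(g$start), ]
    g$start[-1] - g$end[-nrow(g)]
  }))
  expect_lt(abs(mean(gaps) / 2 - 8000) / 8000, 0.15)
  # genes overlapping planted sweeps are recorded in the truth
  swg <- sim_big$truth$sweep_genes
  sw <- sim_big$truth$sweeps
  for (g in swg[1:5]) {
    gi <- idx[idx$id == g, ]
    expect_true(any(sw$chrom == gi$chrom & sw$start < gi$end &
                      sw$end > gi$start))
  }
})

test_that("datasets are byte-identical across runs with the same seed", {
  cfg <- sim_config(seed = 19, chrom_lengths = c(chr1 = 1.5e5),
                    n_diploid = 6L, sv_count = 50L, str_count = 60L,
                    n_sweeps = 1L, sweep_length = 3e4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # truth ids resolve against the emitted files
  pm <- read_popmap(file.path(d1, "popmap.tsv"))
  svs <- load_genotypes(file.path(d1, "svs.vcf"), "sv", pm)
  strs <- load_genotypes(file.path(d1, "strs.vcf"), "str", pm)
  truth <- read.table(file.path(d1, "truth_loci.tsv"), header = TRUE,
                      sep = "\t")
  expect_true(all(truth$id[truth$type == "sv"] %in% svs$id))
  expect_true(all(truth$id[truth$type == "str"] %in% strs$id))
  ann <- load_annotation(file.path(d1, "genes.gff3"),
                         file.path(d1, "ref.fa"))
  expect_true(all(readLines(file.path(d1, "truth_genes.txt")) %in%
                    ann$genes$index$id))
})

test_that("stronger background F raises genome-wide Hudson FST", {
  meds <- vapply(c(0.01, 0.05, 0.2), function(Fb) {
    cfg <- sim_config(seed = 23, chrom_lengths = c(chr1 = 3e5),
                      F_background = Fb, n_sweeps = 1L,
                      sweep_length = 3e4)
    set.seed(23)
    p <- mosaic_panel_with_sweep(cfg, "chr1", NULL)
    w <- make_windows(genome_layout("chr1", 3e5))
    s <- window_stats_scan(list(chr1 = p), w)
    median(s$fst_hudson, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
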