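# I/O boundary: configuration, VCF/GFF parsing, coordinate conventions,
# deterministic table writing.

test_that("configuration defaults, overrides and validation", {
  cfg <- load_config(NULL)
  expect_equal(cfg$window_size, 50000)
  expect_equal(cfg$window_step, 25000)
  expect_equal(cfg$q_threshold, 0.05)
  expect_equal(cfg$proximity_bp, 8000)
  expect_equal(cfg$n_permutations, 1000)
  expect_equal(cfg$str_maf_min, 0.1)

  empty <- withr::local_tempfile(fileext = ".cfg")
  writeLines(character(0), empty)
  expect_equal(load_config(empty), cfg)

  good <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("window_size = 50000", "window_step = 25000"), good)
  expect_equal(load_config(good)$window_step, 25000)

  bad_step <- withr::local_tempfile(fileext = ".cfg")
  writeLines("window_step = 0", bad_step)
  expect_error(load_config(bad_step), "window_step")

  too_big <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("window_size = 1000", "window_step = 5000"), too_big)
  expect_error(load_config(too_big), "window_step")

  unknown <- withr::local_tempfile(fileext = ".cfg")
  writeLines("wnidow_size = 1", unknown)
  expect_error(load_config(unknown), "unknown config key")
})

test_that("phased SNP VCF parses to a haplotype panel with 0-based sites", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gts <- rbind(c("0|1", "0|0", "1|1"),
               c("0|0", "0|1", "1|0"),
               c("1|1", "0|0", "0|1"),
               c("0|0", "0|0", "0|0"),
               c("0|1", "1|1", "0|0"))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=1000>",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1", "s2", "s3"),
                     collapse = "\t"),
               vapply(1:5, function(i) {
                 paste(c("chr1", i * 100, ".", "A", "G", ".", "PASS",
                         "AA=A", "GT", gts[i, ]), collapse = "\t")
               }, character(1))), vcf)
  pm <- population_map(c("s1", "s2", "s3", "s4"),
                       c("popA", "popA", "popB", "popB"))
  panels <- load_genotypes(vcf, "snp", pm)
  p <- panels$chr1
  expect_equal(nrow(p$hap), 6)          # 2 haplotypes x 3 samples
  expect_equal(length(p$pos), 5)
  expect_equal(p$pos, c(99, 199, 299, 399, 499))  # 1-based -> 0-based
  expect_equal(p$hap[1:2, 1], c(0L, 1L))          # s1 "0|1" at site 1
  expect_true(all(p$anc_is_ref))
})

test_that("unphased genotypes abort naming the site", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1", "s2"),
                     collapse = "\t"),
               paste(c("chr1", 42, ".", "A", "G", ".", "PASS", ".",
                       "GT", "0/1", "0|0"), collapse = "\t")), vcf)
  pm <- population_map(c("s1", "s2", "x1", "x2"),
                       c("popA", "popA", "popB", "popB"))
  expect_error(load_genotypes(vcf, "snp", pm), "chr1:42")
})

test_that("SV records convert coordinates and reject unknown SVTYPE", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1", "s2"),
                     collapse = "\t"),
               paste(c("chr1", 100, "del1", "N", "<DEL>", ".", "PASS",
                       "SVTYPE=DEL;END=600;SVLEN=501", "GT", "0/1",
                       "1/1"), collapse = "\t"),
               paste(c("chr1", 700, "odd1", "N", "<BND>", ".", "PASS",
                       "SVTYPE=BND;END=701", "GT", "0/0", "./."),
                     collapse = "\t")), vcf)
  pm <- population_map(c("s1", "s2", "x1", "x2"),
                       c("popA", "popA", "popB", "popB"))
  expect_warning(svs <- load_genotypes(vcf, "sv", pm), "SVTYPE")
  expect_equal(length(svs$id), 1)       # BND rejected
  expect_equal(svs$start, 99)           # POS=100 -> 0-based 99
  expect_equal(svs$end, 600)
  expect_equal(svs$length, 501)
  expect_equal(svs$a1[, 1], c(0L, 1L))
})

test_that("STR alleles become repeat counts via the repeat unit", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1", "s2"),
                     collapse = "\t"),
               paste(c("chr1", 50, "strA", strrep("AT", 10),
                       strrep("AT", 12), ".", "PASS", "RU=AT;PERIOD=2",
                       "GT", "0/1", "1/1"), collapse = "\t"),
               paste(c("chr1", 90, "strBad", "ATATA", "ATAT", ".",
                       "PASS", "RU=AT;PERIOD=2", "GT", "0/0", "0/1"),
                     collapse = "\t")), vcf)
  pm <- population_map(c("s1", "s2", "x1", "x2"),
                       c("popA", "popA", "popB", "popB"))
  expect_warning(strs <- load_genotypes(vcf, "str", pm), "repeat unit")
  expect_equal(length(strs$id), 1)      # 5 bp allele is not 2n
  expect_equal(strs$period, 2L)
  expect_equal(sort(unique(c(strs$a1, strs$a2))), c(10, 12))
})

test_that("samples missing from the popmap are excluded with a warning", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1", "s2", "zz"),
                     collapse = "\t"),
               paste(c("chr1", 10, ".", "A", "G", ".", "PASS", ".",
                       "GT", "0|1", "0|0", "1|1"), collapse = "\t")), vcf)
  pm <- population_map(c("s1", "s2", "p1", "p2"),
                       c("popA", "popA", "popB", "popB"))
  expect_warning(panels <- load_genotypes(vcf, "snp", pm), "zz")
  expect_equal(nrow(panels$chr1$hap), 4)
})

test_that("GFF3 gene models convert coordinates and keep the longest mRNA", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", strrep("ACGT", 750)), fa)
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tID=g1",
               "chr1\tsrc\tmRNA\t1001\t1500\t.\t-\t.\tID=g1.t1;Parent=g1",
               "chr1\tsrc\tmRNA\t1001\t2000\t.\t-\t.\tID=g1.t2;Parent=g1",
               "chr1\tsrc\tCDS\t1001\t1099\t.\t-\t0\tID=c1;Parent=g1.t2",
               "chr1\tsrc\tCDS\t1201\t1302\t.\t-\t0\tID=c2;Parent=g1.t2",
               "chr1\tsrc\tCDS\t1001\t1050\t.\t-\t0\tID=c3;Parent=g1.t1"),
             gff)
  ann <- load_annotation(gff, fa)
  expect_equal(ann$genes$index$start, 1000)   # 1-based -> 0-based
  expect_equal(ann$genes$index$end, 2000)
  expect_equal(ann$genes$index$strand, "-")
  expect_equal(nrow(ann$genes$cds), 2)        # longest mRNA retained
  expect_equal(sort(ann$genes$cds$start), c(1000, 1200))
})

test_that("annotation referencing a missing contig aborts", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrX", strrep("ACGT", 100)), fa)
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1"), gff)
  expect_error(load_annotation(gff, fa), "missing from FASTA")
})

test_that("table writing is deterministic, sorted, and round-trips exactly", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  stats <- data.frame(chrom = c("chr2", "chr1"), start = c(0, 25000),
                      end = c(50000, 75000),
                      pi_A = c(1 / 3, 0.00123456789012345),
                      dxy = c(pi, exp(1)) * 1e-3)
  regions <- list(
    supported = data.frame(chrom = c("chr2", "chr1", "chr1"),
                           start = c(0, 50000, 0), end = c(75000, 99000,
                                                           25000),
                           support = c(3L, 2L, 2L)),
    all = data.frame(chrom = "chr1", start = 0, end = 25000,
                     support = 1L))
  res <- list(window_stats = stats, regions = regions, seed = 1)
  p1 <- write_tables(res, d1)
  p2 <- write_tables(res, d2)
  expect_identical(readLines(p1[["window_stats"]]),
                   readLines(p2[["window_stats"]]))
  back <- read.table(p1[["window_stats"]], header = TRUE, sep = "\t")
  expect_identical(back$pi_A, stats$pi_A)     # full precision round trip
  expect_identical(back$dxy, stats$dxy)
  bed <- read.table(p1[["regions"]], sep = "\t")
  expect_equal(bed$V1, c("chr1", "chr1", "chr2"))  # sorted
  expect_equal(bed$V2, c(0, 50000, 0))

  empty <- list(window_stats = stats[0, ],
                regions = list(supported = regions$supported[0, ],
                               all = regions$all[0, ]))
  pe <- write_tables(empty, withr::local_tempdir())
  expect_equal(length(readLines(pe[["window_stats"]])), 1)  # header only
  expect_equal(length(readLines(pe[["regions"]])), 0)
})

test_that("VCF coordinate conversion is self-inverse on random positions", {
  set.seed(42)
  pos0 <- sort(sample.int(1e6, 2000)) - 1        # internal 0-based
  vcf_pos <- pos0 + 1                            # to VCF
  expect_identical(vcf_pos - 1, pos0)            # and back
  # through the writers/readers
  sim <- small_sim()
  d <- withr::local_tempdir()
  write_dataset(sim, d)
  pm <- read_popmap(file.path(d, "popmap.tsv"))
  panels <- load_genotypes(file.path(d, "snps.vcf"), "snp", pm)
  expect_identical(panels$chr1$pos, sim$panels$chr1$A$pos)
  svs <- load_genotypes(file.path(d, "svs.vcf"), "sv", pm)
  expect_setequal(svs$start, sim$svs$start)
})
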