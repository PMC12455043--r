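# Gene proximity, permutation enrichment, fixed differences, coding
# effects, STR-CDS density, candidate cross-referencing, summaries, PCA.

test_that("gene proximity honours the half-open 8 kb boundary", {
  idx <- data.frame(id = "g1", chrom = "c", start = 10000, end = 20000,
                    strand = "+")
  cds <- data.frame(gene_id = "g1", chrom = "c", start = 10000,
                    end = 20000, strand = "+", phase = 0L)
  genes <- gene_annotation(idx, cds)
  pt <- function(x) data.frame(chrom = "c", start = x, end = x + 1,
                               id = "f")
  expect_equal(nrow(gene_proximity(pt(27999), genes)), 1)
  expect_equal(nrow(gene_proximity(pt(28000), genes)), 0)
  expect_equal(nrow(gene_proximity(pt(2000), genes)), 1)
  expect_equal(nrow(gene_proximity(pt(1999), genes)), 0)
  # window overlapping the gene body: distance 0
  w <- data.frame(chrom = "c", start = 0, end = 50000, id = "w")
  h <- gene_proximity(w, genes)
  expect_equal(h$distance, 0)
  expect_equal(h$relation, "overlaps_gene")
  # reported distances never exceed the threshold
  h2 <- gene_proximity(pt(27999), genes)
  expect_lte(h2$distance, 8000)
})

test_that("proximity at distance 0 equals brute-force interval overlap", {
  set.seed(43)
  idx <- data.frame(id = sprintf("g%03d", 1:100), chrom = "c",
                    start = st <- sort(sample.int(9e5, 100)),
                    end = st + sample(100:5000, 100, TRUE),
                    strand = "+")
  cds <- data.frame(gene_id = idx$id, chrom = "c", start = idx$start,
                    end = idx$end, strand = "+", phase = 0L)
  genes <- gene_annotation(idx, cds)
  feats <- data.frame(chrom = "c",
                      start = fs <- sample.int(9e5, 1000),
                      end = fs + sample(1:2000, 1000, TRUE),
                      id = sprintf("f%04d", 1:1000))
  hits <- gene_proximity(feats, genes, distance = 0)
  brute <- 0L
  for (i in seq_len(nrow(feats))) for (j in seq_len(nrow(idx))) {
    if (feats$start[i] < idx$end[j] && feats$end[i] > idx$start[j]) {
      brute <- brute + 1L
    }
  }
  expect_equal(nrow(hits), brute)
})

test_that("variant-type exclusivity is plain set algebra", {
  sets <- list(SNP = c("a", "b"), SV = c("b", "c"), STR = c("c"))
  ex <- gene_set_exclusivity(sets)
  expect_equal(ex$n_unique_genes, 3)
  expect_equal(ex$n_single_type, 1)      # only "a"
  expect_equal(ex$n_multi_type, 2)       # "b", "c"
  expect_equal(ex$table$methods[ex$table$gene == "b"], "SNP, SV")
})

test_that("permutation enrichment handles the degenerate extremes", {
  toy <- toy_annotation()
  feats <- data.frame(chrom = "chrT", start = c(100, 300, 600),
                      end = c(120, 320, 620))
  # genes + 8 kb margin cover the whole 1 kb toy genome: saturation
  pr <- permutation_enrichment(feats, toy$genes, toy$layout,
                               n_perm = 100, distance = 8000, seed = 1)
  expect_equal(pr$observed, 3)
  expect_true(all(pr$null_counts == 3))
  expect_equal(pr$p, 1)
  expect_gte(pr$p, 1 / 101)
  expect_error(permutation_enrichment(
    data.frame(chrom = "chrT", start = 0, end = 5000), toy$genes,
    toy$layout), "longer than its chromosome")
  # observed above every null count -> p = 2/(n_perm + 1)
  lay <- genome_layout("c", 1e6)
  idx <- data.frame(id = "g1", chrom = "c", start = 0, end = 100,
                    strand = "+")
  cds <- data.frame(gene_id = "g1", chrom = "c", start = 0, end = 100,
                    strand = "+", phase = 0L)
  genes1 <- gene_annotation(idx, cds)
  feats1 <- data.frame(chrom = "c", start = rep(0, 5), end = rep(10, 5))
  pr1 <- permutation_enrichment(feats1, genes1, lay, n_perm = 1000,
                                distance = 0, seed = 2)
  expect_equal(pr1$observed, 5)
  expect_equal(pr1$p, 2 / 1001)
})

test_that("fixed differences require complete, opposite homozygosity", {
  pm <- population_map(c("A1", "A2", "B1", "B2"),
                       c("popA", "popA", "popB", "popB"))
  mk <- function(a1, a2) genotype_matrix("c", c(10, 20, 30), a1, a2,
                                         c("A1", "A2", "B1", "B2"),
                                         ref = c("A", "C", "G"),
                                         alt = c("T", "G", "A"))
  # site 1 fixed (A ref / B alt), site 2 has a het, site 3 has a missing
  a1 <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, NA), c(1, 1, 1))
  a2 <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 1), c(1, 1, 1))
  fx <- fixed_differences(mk(a1, a2), pm)
  expect_equal(fx$pos, 10)
  expect_equal(fx$alt_fixed_in, "popB")
  # mirror orientation is reported with the flag swapped
  gm2 <- genotype_matrix("c", 10, 1 - a1[, 1, drop = FALSE],
                         1 - a2[, 1, drop = FALSE],
                         c("A1", "A2", "B1", "B2"))
  fx2 <- fixed_differences(gm2, pm)
  expect_equal(fx2$alt_fixed_in, "popA")
})

test_that("coding effects classify synonymous/missense/nonsense by strand", {
  toy <- toy_annotation()
  # gene1 (+): codons ATG AAA GGA | CTG TAA
  # GGA -> GGG third-position change is synonymous (G at pos 108)
  r <- classify_coding_effect("chrT", 108, "A", "G", toy$genes, toy$ref)
  expect_equal(r$context, "CDS")
  expect_equal(r$effect, "synonymous")
  expect_equal(r$codon_ref, "GGA")
  expect_equal(r$codon_alt, "GGG")
  # AAA -> GAA (K -> E) missense at pos 103
  r <- classify_coding_effect("chrT", 103, "A", "G", toy$genes, toy$ref)
  expect_equal(r$effect, "missense")
  # CTG -> TAG would need two changes; make a nonsense via AAA -> TAA
  r <- classify_coding_effect("chrT", 103, "A", "T", toy$genes, toy$ref)
  expect_equal(r$effect, "nonsense")
  # minus-strand gene2: transcript ATG GGA TCT TGG TAG built by hand.
  # Genomic [500,509) = AGATCCCAT (rc of ATGGGATCT). Genomic 505 (C) is
  # the first base of transcript codon GGA; genomic C->T is transcript
  # G->A: GGA -> AGA (G -> R), missense.
  r <- classify_coding_effect("chrT", 505, "C", "T", toy$genes, toy$ref)
  expect_equal(r$context, "CDS")
  expect_equal(r$codon_ref, "GGA")
  expect_equal(r$effect, "missense")
  # genomic 500 (A) is the third base of transcript codon TCT (serine);
  # genomic A->G is transcript T->C: TCT -> TCC, still serine.
  r <- classify_coding_effect("chrT", 500, "A", "G", toy$genes, toy$ref)
  expect_equal(r$codon_ref, "TCT")
  expect_equal(r$effect, "synonymous")
  # intron and intergenic contexts
  r <- classify_coding_effect("chrT", 150, "A", "G", toy$genes, toy$ref)
  expect_equal(r$context, "intron")
  expect_equal(r$effect, "non_coding")
  r <- classify_coding_effect("chrT", 700, "A", "G", toy$genes, toy$ref)
  expect_equal(r$context, "intergenic")
  # reference mismatch aborts naming the site
  expect_error(classify_coding_effect("chrT", 108, "C", "G", toy$genes,
                                      toy$ref), "chrT:109")
  # inconsistent phase flags the site unclassifiable
  bad <- toy$genes
  bad$cds$phase[2] <- 2L
  expect_warning(r <- classify_coding_effect("chrT", 201, "T", "C", bad,
                                             toy$ref), "phase")
  expect_true(is.na(r$effect))
})

test_that("STR-CDS densities integrate to one and peak where planted", {
  toy <- toy_annotation()
  set.seed(47)
  n <- 60
  strs <- str_set("chrT", c(rep(100, 30), sample(0:990, 30)),
                  rep(2L, n), sprintf("s%02d", 1:n),
                  matrix(10L, 2, n), matrix(12L, 2, n),
                  c("A1", "B1"), motif = rep("AT", n))
  d <- str_cds_density(strs, toy$genes, range = 2000)
  dists <- attr(d, "distances")
  for (k in unique(paste(d$period, d$anchor))) {
    dd <- d[paste(d$period, d$anchor) == k, ]
    # exact mass of the Gaussian-kernel mixture over the returned grid
    raw <- if (dd$anchor[1] == "cds_start") dists$d_start else
      dists$d_end
    raw <- raw[dists$period == dd$period[1] & !is.na(raw) &
                 abs(raw) <= 2000]
    mass <- mean(pnorm((max(dd$x) - raw) / dd$bw[1]) -
                   pnorm((min(dd$x) - raw) / dd$bw[1]))
    expect_equal(mass, 1, tolerance = 1e-6)
    # and the trapezoid integral of the curve agrees closely
    integral <- sum(diff(dd$x) * (head(dd$density, -1) +
                                    tail(dd$density, -1)) / 2)
    expect_equal(integral, 1, tolerance = 1e-3)
  }
  # half the STRs sit exactly on the gene1 CDS start: density peaks at 0
  ds <- d[d$anchor == "cds_start", ]
  expect_lt(abs(ds$x[which.max(ds$density)]), 100)
  expect_error(str_cds_density(subset_loci(strs, 1), toy$genes), "2 STRs")
})

test_that("candidate cross-referencing joins case-insensitively", {
  sets <- list(SNP = c("Alpha"), SV = c("CSMD3"), STR = c("csmd3", "Beta"))
  cands <- candidate_genes(c("CSMD3", "ALPHA", "gamma"))
  x <- crossref_candidates(sets, cands)
  expect_setequal(x$matched$gene, c("Alpha", "CSMD3", "csmd3"))
  expect_equal(x$matched$methods[x$matched$gene == "CSMD3"], "SV")
  expect_true("Beta" %in% x$full$gene)
  expect_false("Beta" %in% x$matched$gene)
  empty <- crossref_candidates(sets, candidate_genes(character(0)))
  expect_equal(nrow(empty$matched), 0)
})

test_that("summary comparisons match direct formula computation", {
  set.seed(53)
  n <- 20
  stats <- data.frame(pi_A = runif(n), dxy = runif(n),
                      fst_hudson = runif(n))
  stats$pi_B <- 2 * stats$pi_A          # perfect correlation
  out <- rep(c(TRUE, FALSE), c(6, n - 6))
  s <- summary_compare(stats, out)
  r_ab <- s$pearson[s$pearson$scope == "genome" & s$pearson$x == "pi_A", ]
  expect_equal(r_ab$r, 1, tolerance = 1e-12)
  # direct Pearson + t-test oracle for fst vs dxy
  x <- stats$fst_hudson; y <- stats$dxy
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p_manual <- 2 * pt(-abs(tstat), n - 2)
  row <- s$pearson[s$pearson$scope == "genome" &
                     s$pearson$x == "fst_hudson" & s$pearson$y == "dxy", ]
  expect_equal(row$r, r, tolerance = 1e-9)
  expect_equal(row$p, p_manual, tolerance = 1e-9)
  # Wilcoxon W from first principles (midranks)
  rk <- rank(c(stats$fst_hudson[out], stats$fst_hudson[!out]))
  W_manual <- sum(rk[seq_len(sum(out))]) - sum(out) * (sum(out) + 1) / 2
  wrow <- s$wilcoxon[s$wilcoxon$statistic == "fst_hudson", ]
  expect_equal(wrow$W, W_manual)
  # identical groups: p near 1
  stats2 <- stats
  stats2$fst_hudson <- rep(c(1, 2, 3, 4, 5), 4)
  s2 <- summary_compare(stats2, rep(c(TRUE, FALSE), 10))
  expect_gt(s2$wilcoxon$p[s2$wilcoxon$statistic == "fst_hudson"], 0.9)
})

test_that("genotype PCA separates structured populations", {
  set.seed(59)
  dos <- rbind(matrix(rbinom(5 * 40, 2, 0.9), 5),
               matrix(rbinom(5 * 40, 2, 0.1), 5))
  rownames(dos) <- sprintf("s%02d", 1:10)
  pc <- genotype_pca(dos)
  g1 <- pc$coords[1:5, 1]; g2 <- pc$coords[6:10, 1]
  expect_true(max(g1) < min(g2) || min(g1) > max(g2))
  expect_lte(sum(pc$explained), 1 + 1e-9)
  expect_error(genotype_pca(matrix(1, 5, 3)), "zero-variance")
})
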