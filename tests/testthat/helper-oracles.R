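# Independent oracles (brute force / literal formula transcriptions) and
# small fixture builders. The oracles deliberately avoid the package's own
# code paths: pairwise enumeration instead of frequency algebra, explicit
# loops instead of vectorised rank tricks.

# Random phased panel pair on a shared site grid.
random_panel_pair <- function(n_hap = 8, n_sites = 50, L = 10000,
                              chrom = "chrT") {
  pos <- sort(sample.int(L, n_sites)) - 1
  mk <- function() {
    p <- runif(n_sites, 0.05, 0.95)
    hap <- matrix(rbinom(n_hap * n_sites, 1, rep(p, each = n_hap)), n_hap)
    haplotype_panel(chrom, pos, hap,
                    sprintf("s%02d", seq_len(n_hap / 2)))
  }
  list(A = mk(), B = mk())
}

# Brute-force pi (mean pairwise Hamming distance over all haplotype pairs)
# and dxy (over all cross-population pairs), per accessible site.
oracle_pi <- function(panel, start, end, acc) {
  in_win <- panel$pos >= start & panel$pos < end
  h <- panel$hap[, in_win, drop = FALSE]
  n <- nrow(h)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(h[i, ] != h[j, ]); np <- np + 1
  }
  tot / np / acc
}

oracle_dxy <- function(panelA, panelB, start, end, acc) {
  in_win <- panelA$pos >= start & panelA$pos < end
  hA <- panelA$hap[, in_win, drop = FALSE]
  hB <- panelB$hap[, in_win, drop = FALSE]
  tot <- 0; np <- 0
  for (i in seq_len(nrow(hA))) for (j in seq_len(nrow(hB))) {
    tot <- tot + sum(hA[i, ] != hB[j, ]); np <- np + 1
  }
  tot / np / acc
}

# Line-by-line transcription of the Weir & Cockerham (1984) single-locus
# variance components for two alleles and r populations of diploids.
oracle_wc84 <- function(dosage_by_pop) {
  dos <- lapply(dosage_by_pop, function(d) d[!is.na(d)])
  r <- length(dos)
  n <- sapply(dos, length)
  p <- sapply(dos, function(d) sum(d) / (2 * length(d)))
  h <- sapply(dos, function(d) sum(d == 1) / length(d))
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# Transcription of the Nei-Chesson-corrected Jost's D estimator for two
# populations from raw allele vectors.
oracle_jost <- function(allelesA, allelesB) {
  allelesA <- allelesA[!is.na(allelesA)]
  allelesB <- allelesB[!is.na(allelesB)]
  lv <- sort(unique(c(allelesA, allelesB)))
  fa <- sapply(lv, function(a) mean(allelesA == a))
  fb <- sapply(lv, function(a) mean(allelesB == a))
  Hs <- ((1 - sum(fa^2)) + (1 - sum(fb^2))) / 2
  Ht <- 1 - sum(((fa + fb) / 2)^2)
  nA <- length(allelesA) / 2; nB <- length(allelesB) / 2
  n_harm <- 2 / (1 / nA + 1 / nB)
  Hs_hat <- (2 * n_harm) / (2 * n_harm - 1) * Hs
  Ht_hat <- Ht + Hs_hat / (2 * n_harm * 2)
  (Ht_hat - Hs_hat) / (1 - Hs_hat) * 2 / (2 - 1)
}

# Min-over-suffix BH q-values, explicit loop.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in n:1) {
    v <- p[o[i]] * n / i
    q_sorted[i] <- if (i == n) min(1, v) else min(q_sorted[i + 1], v, 1)
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# EHH by explicit haplotype-pair enumeration: probability that two distinct
# carriers are identical at every site between core and j (inclusive).
oracle_ehh <- function(hap, carriers, core, j) {
  rng <- min(core, j):max(core, j)
  n <- length(carriers)
  hom <- 0; np <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    np <- np + 1
    if (all(hap[carriers[a], rng] == hap[carriers[b], rng])) hom <- hom + 1
  }
  hom / np
}

# Tajima's D from pairwise enumeration plus the published coefficients.
oracle_tajima <- function(hap) {
  n <- nrow(hap)
  S <- sum(apply(hap, 2, function(x) length(unique(x)) > 1))
  if (S == 0) return(NA_real_)
  k <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + sum(hap[i, ] != hap[j, ]); np <- np + 1
  }
  k <- k / np
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Tiny two-gene annotation + reference used by the annotation tests.
toy_annotation <- function() {
  # gene1 (+): CDS [100,109) + [200,206): ATGAAAGGA | CTGTAA
  # gene2 (-): CDS [402,408) + [500,509): transcript = rc([500,509)) +
  #   rc([402,408)) = ATGGGATCT | TGGTAG
  L <- 1000
  seqc <- rep("A", L)
  put <- function(s, str) {
    seqc[(s + 1):(s + nchar(str))] <<- strsplit(str, "")[[1]]
  }
  put(100, "ATGAAAGGA"); put(200, "CTGTAA")
  put(500, "AGATCCCAT"); put(402, "CTACCA")
  ref <- Biostrings::DNAStringSet(paste(seqc, collapse = ""))
  names(ref) <- "chrT"
  idx <- data.frame(id = c("gene1", "gene2"), chrom = "chrT",
                    start = c(100, 402), end = c(206, 509),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = c("gene1", "gene1", "gene2", "gene2"),
                    chrom = "chrT", start = c(100, 200, 402, 500),
                    end = c(109, 206, 408, 509),
                    strand = c("+", "+", "-", "-"),
                    phase = c(0L, 0L, 0L, 0L), stringsAsFactors = FALSE)
  list(genes = gene_annotation(idx, cds), ref = ref,
       layout = genome_layout("chrT", L))
}
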