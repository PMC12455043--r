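# Synthetic two-population dataset with planted divergent loci.
#
# The generator does not aim at coalescent realism: it creates exactly the
# statistical structure the scans consume. Allele-frequency differentiation
# follows the Balding-Nichols model at a background F; haplotypes are
# founder mosaics (switch rate rho per bp) so that linkage decays over
# physical distance; planted sweep regions replace population-B haplotypes
# by a designated founder with probability f_sweep, creating low diversity,
# elevated differentiation and long-range haplotype homozygosity there.

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: two chromosomes of 5 Mb,
#' 20 diploids per population, weak background differentiation (F = 0.02),
#' ancestral per-site diversity 0.0035 with population B scaled to 0.94 of
#' it (target window-median diversities of about 0.0035 and 0.0033 and
#' dXY near 0.0035), ten planted 100 kb sweep regions in population B at
#' sweep-haplotype frequency 0.8, 2,000 SV and 5,000 STR loci of which 2%
#' are divergent, and a gene annotation with mean intergenic gap 16 kb.
#'
#' @param seed integer RNG seed.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param n_diploid diploids per population (>= 6).
#' @param F_background Balding--Nichols differentiation parameter in (0,1).
#' @param theta_anc ancestral per-site diversity (heterozygosity per bp).
#' @param diversity_scaling length-2 vector: per-population diversity
#'   scaling (population A, population B).
#' @param n_founders founder haplotypes per population.
#' @param rho per-bp founder-switch (copying) probability.
#' @param n_sweeps,sweep_length,f_sweep planted sweep regions: count,
#'   length in bp, and sweep-haplotype frequency in population B.
#' @param sv_count,sv_div_frac,sv_dp_min SV loci: count, divergent
#'   fraction, minimum divergent allele-frequency difference.
#' @param str_count,str_div_frac,str_shift_min STR loci: count, divergent
#'   fraction, minimum divergent mean repeat-count shift (units).
#' @param str_sd,str_jitter_sd repeat-count s.d. within a population and
#'   the neutral between-population jitter of mean repeat counts.
#' @param intergenic_mean mean intergenic gap in bp (exponential law).
#' @param include_hybrid also emit a third, admixed population (excluded
#'   from scans).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_diploid = 20L,
                       F_background = 0.02,
                       theta_anc = 0.0035,
                       diversity_scaling = c(A = 1.0, B = 0.94),
                       n_founders = 30L,
                       rho = 1e-6,
                       n_sweeps = 10L,
                       sweep_length = 1e5,
                       f_sweep = 0.8,
                       sv_count = 2000L,
                       sv_div_frac = 0.02,
                       sv_dp_min = 0.6,
                       str_count = 5000L,
                       str_div_frac = 0.02,
                       str_shift_min = 2,
                       str_sd = 1.5,
                       str_jitter_sd = 0.2,
                       intergenic_mean = 16000,
                       include_hybrid = FALSE) {
  if (n_diploid < 6) stop("at least 6 diploids per population")
  if (F_background <= 0 || F_background >= 1) stop("F must be in (0, 1)")
  if (f_sweep <= 0 || f_sweep > 1) stop("f_sweep must be in (0, 1]")
  if (sv_div_frac > 1 || str_div_frac > 1) stop("divergent fraction > 1")
  if (n_founders < 2) stop("founder panel size must be >= 2")
  if (n_sweeps * sweep_length > sum(chrom_lengths)) {
    stop("sweep regions do not fit in the genome")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Balding--Nichols per-population allele frequencies
#'
#' Each population's frequency is an independent draw from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so that E = p and Var = F p (1 - p).
#'
#' @param p_anc ancestral allele frequency vector, strictly inside (0, 1).
#' @param F differentiation parameter, strictly inside (0, 1).
#' @param n_pops number of populations.
#' @return matrix (length(p_anc) x n_pops) of frequencies.
#' @export
balding_nichols_freqs <- function(p_anc, F, n_pops = 2) {
  if (F <= 0 || F >= 1) stop("F must lie strictly inside (0, 1)")
  if (any(p_anc <= 0 | p_anc >= 1)) stop("p_anc must be inside (0, 1)")
  scale <- (1 - F) / F
  vapply(seq_len(n_pops), function(k) {
    rbeta(length(p_anc), p_anc * scale, (1 - p_anc) * scale)
  }, numeric(length(p_anc)))
}

# Expected per-site heterozygosity of 2p(1-p) under p ~ U(a, b).
.uniform_e2pq <- function(a = 0.05, b = 0.95) {
  2 * (0.5 - (a^2 + a * b + b^2) / 3)
}

# One population's mixture frequencies: Balding-Nichols with probability
# `scaling`, else fixed (1 with probability p_anc). Multiplies expected
# heterozygosity by `scaling` while leaving the mean frequency at p_anc.
.scaled_pop_freqs <- function(p_anc, F, scaling) {
  p <- balding_nichols_freqs(p_anc, F, n_pops = 1)[, 1]
  if (scaling < 1) {
    fix <- runif(length(p)) > scaling
    p[fix] <- rbinom(sum(fix), 1, p_anc[fix])
  }
  p
}

# Mosaic haplotypes copied from a founder panel, switch rate rho per bp.
.mosaic_haplotypes <- function(founders, pos, L, n_hap, rho) {
  n_f <- nrow(founders)
  hap <- matrix(0L, n_hap, ncol(founders))
  for (h in seq_len(n_hap)) {
    k <- rpois(1, rho * L)
    bp <- sort(runif(k, 0, L))
    fid <- sample.int(n_f, k + 1, replace = TRUE)
    seg <- findInterval(pos, bp) + 1L
    hap[h, ] <- founders[cbind(fid[seg], seq_along(pos))]
  }
  hap
}

#' Mosaic haplotype panels with planted sweeps for one chromosome
#'
#' Sites are placed by a Poisson process whose density is calibrated so the
#' expected per-bp heterozygosity of population A equals
#' `theta_anc * scaling_A` (accounting for the (1 - F) Balding--Nichols
#' shrinkage and the 1 - 1/n_founders identity from mosaic copying).
#' Founder haplotypes are drawn site-wise from the population frequencies;
#' sample haplotypes are founder mosaics. Inside each sweep region, each
#' population-B haplotype is replaced by the designated sweep founder with
#' probability `f_sweep`.
#'
#' @param config a [sim_config()].
#' @param chrom chromosome name (must be in `config$chrom_lengths`).
#' @param sweeps data frame of sweep regions on this chromosome
#'   (`start`, `end`), or `NULL`.
#' @return list with [haplotype_panel()]s `A` and `B`, plus `ref`/`alt`
#'   placeholders filled by the dataset writer.
#' @export
mosaic_panel_with_sweep <- function(config, chrom, sweeps = NULL) {
  L <- config$chrom_lengths[[chrom]]
  if (!is.null(sweeps) && nrow(sweeps) > 0 &&
      any(sweeps$start < 0 | sweeps$end > L)) {
    stop("sweep region outside chromosome ", chrom)
  }
  e_het <- (1 - config$F_background) * (1 - 1 / config$n_founders) *
    .uniform_e2pq() * config$diversity_scaling[[1]]
  lambda <- config$theta_anc / e_het
  n_sites <- rpois(1, lambda * L)
  pos <- sort(sample.int(L, n_sites)) - 1
  p_anc <- runif(n_sites, 0.05, 0.95)
  n_hap <- 2L * config$n_diploid
  panels <- list()
  founder_pool <- list()
  for (k in 1:2) {
    p_pop <- .scaled_pop_freqs(p_anc, config$F_background,
                               config$diversity_scaling[[k]])
    founders <- matrix(rbinom(config$n_founders * n_sites, 1,
                              rep(p_pop, each = config$n_founders)),
                       nrow = config$n_founders)
    founder_pool[[k]] <- founders
    hap <- .mosaic_haplotypes(founders, pos, L, n_hap, config$rho)
    if (k == 2 && !is.null(sweeps) && nrow(sweeps) > 0) {
      for (s in seq_len(nrow(sweeps))) {
        in_rg <- pos >= sweeps$start[s] & pos < sweeps$end[s]
        if (!any(in_rg)) next
        sweep_founder <- founders[sample.int(config$n_founders, 1), in_rg]
        swept <- runif(n_hap) < config$f_sweep
        hap[swept, in_rg] <- rep(sweep_founder, each = sum(swept))
      }
    }
    tag <- c("A", "B")[k]
    samples <- sprintf("%s%02d", tag, seq_len(config$n_diploid))
    panels[[tag]] <- haplotype_panel(chrom, pos, hap, samples)
  }
  if (isTRUE(config$include_hybrid)) {
    # admixed analog: mosaics over the pooled founder panels of A and B
    founders_h <- rbind(founder_pool[[1]], founder_pool[[2]])
    hap <- .mosaic_haplotypes(founders_h, pos, L, n_hap, config$rho)
    samples <- sprintf("H%02d", seq_len(config$n_diploid))
    panels$H <- haplotype_panel(chrom, pos, hap, samples)
  }
  attr(panels, "founders") <- founder_pool
  panels
}

# Discretised-Gaussian STR allele distribution over repeat counts.
.str_allele_dist <- function(mu, sd) {
  lo <- max(2, floor(mu - 4 * sd))
  hi <- ceiling(mu + 4 * sd)
  counts <- lo:hi
  w <- dnorm(counts, mu, sd)
  list(counts = counts, prob = w / sum(w))
}

#' Simulate SV and STR marker loci
#'
#' SV positions are uniform over the genome, types DEL-dominant
#' (0.7/0.1/0.1/0.1 for DEL/INS/DUP/INV), lengths log-uniform between 50 bp
#' and 100 kb. Neutral loci are genotyped from Balding--Nichols frequencies
#' at the background F; divergent loci get population frequencies differing
#' by at least `sv_dp_min`. STR allele distributions are discretised
#' Gaussians over repeat counts; divergent STRs shift the population mean
#' by at least `str_shift_min` units. Genotypes are two independent draws
#' per diploid.
#'
#' @param config a [sim_config()].
#' @return list with `svs` ([sv_set()]), `strs` ([str_set()]),
#'   `sv_truth` and `str_truth` data frames.
#' @export
simulate_marker_loci <- function(config) {
  layout <- genome_layout(names(config$chrom_lengths),
                          unname(config$chrom_lengths))
  samples <- c(sprintf("A%02d", seq_len(config$n_diploid)),
               sprintf("B%02d", seq_len(config$n_diploid)))
  if (isTRUE(config$include_hybrid)) {
    samples <- c(samples, sprintf("H%02d", seq_len(config$n_diploid)))
  }
  n <- length(samples)

  ## ---- SVs ----
  m <- config$sv_count
  chrom_i <- sample.int(nrow(layout), m, replace = TRUE,
                        prob = layout$length)
  svlen <- round(exp(runif(m, log(50), log(1e5))))
  svtype <- sample(c("DEL", "INS", "DUP", "INV"), m, replace = TRUE,
                   prob = c(0.7, 0.1, 0.1, 0.1))
  span <- ifelse(svtype == "INS", 1, svlen)
  start <- floor(runif(m) * (layout$length[chrom_i] - span - 1))
  n_div <- round(m * config$sv_div_frac)
  divergent <- sample.int(m, n_div)
  pA <- pB <- numeric(m)
  neutral <- setdiff(seq_len(m), divergent)
  p_anc <- runif(length(neutral), 0.05, 0.95)
  bn <- balding_nichols_freqs(p_anc, config$F_background, 2)
  pA[neutral] <- bn[, 1]; pB[neutral] <- bn[, 2]
  dp <- runif(n_div, config$sv_dp_min, 0.9)
  lo <- runif(n_div, 0.05, 0.95 - dp)
  hi_is_A <- runif(n_div) < 0.5
  pA[divergent] <- ifelse(hi_is_A, lo + dp, lo)
  pB[divergent] <- ifelse(hi_is_A, lo, lo + dp)
  p_by_sample <- rbind(matrix(rep(pA, each = config$n_diploid),
                              config$n_diploid),
                       matrix(rep(pB, each = config$n_diploid),
                              config$n_diploid))
  if (isTRUE(config$include_hybrid)) {
    p_by_sample <- rbind(p_by_sample,
                         matrix(rep((pA + pB) / 2,
                                    each = config$n_diploid),
                                config$n_diploid))
  }
  a1 <- matrix(rbinom(n * m, 1, p_by_sample), n)
  a2 <- matrix(rbinom(n * m, 1, p_by_sample), n)
  ids <- sprintf("sv%04d", seq_len(m))
  svs <- sv_set(layout$chrom[chrom_i], start,
                start + span, svtype, svlen, ids, a1, a2, samples)
  sv_truth <- data.frame(id = ids, divergent = seq_len(m) %in% divergent,
                         p_A = pA, p_B = pB, stringsAsFactors = FALSE)

  ## ---- STRs ----
  m <- config$str_count
  chrom_i <- sample.int(nrow(layout), m, replace = TRUE,
                        prob = layout$length)
  pos <- floor(runif(m) * (layout$length[chrom_i] - 100))
  period <- sample(1:6, m, replace = TRUE,
                   prob = c(0.35, 0.30, 0.15, 0.08, 0.07, 0.05))
  motif <- vapply(period, function(p) {
    paste(sample(c("A", "C", "G", "T"), p, replace = TRUE), collapse = "")
  }, character(1))
  n_div <- round(m * config$str_div_frac)
  divergent <- sample.int(m, n_div)
  mu0 <- runif(m, 8, 20)
  shift <- numeric(m)
  shift[divergent] <- sample(c(-1, 1), n_div, replace = TRUE) *
    runif(n_div, config$str_shift_min, config$str_shift_min + 2)
  muA <- mu0 + rnorm(m, 0, config$str_jitter_sd)
  muB <- mu0 + rnorm(m, 0, config$str_jitter_sd) + shift
  a1 <- a2 <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    dA <- .str_allele_dist(muA[j], config$str_sd)
    dB <- .str_allele_dist(muB[j], config$str_sd)
    nd <- config$n_diploid
    a1[1:nd, j] <- sample(dA$counts, nd, TRUE, dA$prob)
    a2[1:nd, j] <- sample(dA$counts, nd, TRUE, dA$prob)
    a1[nd + (1:nd), j] <- sample(dB$counts, nd, TRUE, dB$prob)
    a2[nd + (1:nd), j] <- sample(dB$counts, nd, TRUE, dB$prob)
    if (isTRUE(config$include_hybrid)) {
      dH <- .str_allele_dist((muA[j] + muB[j]) / 2, config$str_sd)
      a1[2 * nd + (1:nd), j] <- sample(dH$counts, nd, TRUE, dH$prob)
      a2[2 * nd + (1:nd), j] <- sample(dH$counts, nd, TRUE, dH$prob)
    }
  }
  ids <- sprintf("str%04d", seq_len(m))
  strs <- str_set(layout$chrom[chrom_i], pos, period, ids, a1, a2,
                  samples, motif = motif)
  str_truth <- data.frame(id = ids, divergent = seq_len(m) %in% divergent,
                          mu_A = muA, mu_B = muB,
                          stringsAsFactors = FALSE)
  list(svs = svs, strs = strs, sv_truth = sv_truth, str_truth = str_truth)
}

# Non-overlapping sweep regions, proportional to chromosome lengths.
.place_sweeps <- function(config) {
  layout <- genome_layout(names(config$chrom_lengths),
                          unname(config$chrom_lengths))
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  tries <- 0
  while (nrow(placed) < config$n_sweeps) {
    tries <- tries + 1
    if (tries > 10000) stop("could not place non-overlapping sweep regions")
    ci <- sample.int(nrow(layout), 1, prob = layout$length)
    L <- layout$length[ci]
    if (L <= config$sweep_length) next
    st <- floor(runif(1) * (L - config$sweep_length))
    cand <- data.frame(chrom = layout$chrom[ci], start = st,
                       end = st + config$sweep_length)
    same <- placed[placed$chrom == cand$chrom, , drop = FALSE]
    if (nrow(same) == 0 ||
        all(cand$end <= same$start | cand$start >= same$end)) {
      placed <- rbind(placed, cand)
    }
  }
  placed[order(placed$chrom, placed$start), , drop = FALSE]
}

#' Generate the full synthetic dataset
#'
#' Orchestrates annotation + reference generation, the mosaic haplotype
#' panels with planted sweeps, and the SV/STR marker loci; everything is
#' reproducible from `config$seed`. When `out_dir` is given, writes
#' `snps.vcf`, `svs.vcf`, `strs.vcf`, `genes.gff3`, `ref.fa`,
#' `popmap.tsv`, `truth_regions.bed` and `truth_loci.tsv` there.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `layout`, `panels` (per chromosome: `A`, `B`),
#'   `popmap`, `svs`, `strs`, `genes`, `ref` (DNAStringSet), `truth`
#'   (list: `sweeps`, `sv`, `str`, `sweep_genes`), and `files` (paths, when
#'   written).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  layout <- genome_layout(names(config$chrom_lengths),
                          unname(config$chrom_lengths))
  ann <- generate_annotation(config)
  sweeps <- .place_sweeps(config)
  panels <- list()
  for (chrom in layout$chrom) {
    sw <- sweeps[sweeps$chrom == chrom, , drop = FALSE]
    panels[[chrom]] <- mosaic_panel_with_sweep(config, chrom, sw)
  }
  loci <- simulate_marker_loci(config)
  cycle <- c(A = "C", C = "G", G = "T", T = "A")
  for (chrom in layout$chrom) {
    chars <- strsplit(as.character(ann$ref[[chrom]]), "")[[1]]
    refb <- chars[panels[[chrom]][[1]]$pos + 1]
    altb <- unname(cycle[refb])
    for (k in names(panels[[chrom]])) {
      panels[[chrom]][[k]]$ref <- refb
      panels[[chrom]][[k]]$alt <- altb
    }
  }
  samples <- c(sprintf("A%02d", seq_len(config$n_diploid)),
               sprintf("B%02d", seq_len(config$n_diploid)))
  labels <- rep(c("popA", "popB"), each = config$n_diploid)
  if (isTRUE(config$include_hybrid)) {
    samples <- c(samples, sprintf("H%02d", seq_len(config$n_diploid)))
    labels <- c(labels, rep("popH", config$n_diploid))
  }
  popmap <- population_map(samples, labels, scan_pops = c("popA", "popB"))
  gene_idx <- ann$genes$index
  sweep_genes <- character(0)
  for (i in seq_len(nrow(sweeps))) {
    hit <- gene_idx$chrom == sweeps$chrom[i] &
      gene_idx$start < sweeps$end[i] & gene_idx$end > sweeps$start[i]
    sweep_genes <- union(sweep_genes, gene_idx$id[hit])
  }
  truth <- list(sweeps = sweeps, sv = loci$sv_truth, str = loci$str_truth,
                sweep_genes = sweep_genes)
  out <- list(layout = layout, panels = panels, popmap = popmap,
              svs = loci$svs, strs = loci$strs, genes = ann$genes,
              ref = ann$ref, truth = truth, config = config)
  if (!is.null(out_dir)) out$files <- write_dataset(out, out_dir)
  out
}
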