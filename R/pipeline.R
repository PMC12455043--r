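# End-to-end orchestration of the three scan tracks.

#' SNP-track scan: windows, haplotype statistics, DCMS, regions
#'
#' Computes the five window statistics over the sliding-window grid
#' (diversity/divergence/FST/Tajima's D from the panels; window means of
#' |iHS| and |xpEHH| from the haplotype scans), combines them into the
#' DCMS, assigns robust-normal significance with BH q-values, and merges
#' significant windows into supported outlier regions.
#'
#' @param panels named list per chromosome with [haplotype_panel()]s `A`
#'   and `B` on shared site grids.
#' @param layout a [genome_layout()].
#' @param config a configuration list from [load_config()].
#' @return list with `windows` (full statistic + DCMS table), `regions`
#'   (list `supported`/`all`), `ihs`, `xpehh` (per-site tables).
#' @export
snp_scan <- function(panels, layout, config = load_config()) {
  windows <- make_windows(layout, config$window_size, config$window_step)
  stats <- window_stats_scan(panels, windows,
                             tajima_population = config$tajima_population,
                             min_accessible = config$min_accessible)
  ihs_pop <- if (config$tajima_population == "B") "B" else "A"
  ihs <- ihs_scan(lapply(panels, `[[`, ihs_pop),
                  maf_min = config$snp_maf_min, bins = config$ihs_bins,
                  cutoff = config$ehh_cutoff,
                  gap_limit = config$ehh_gap_limit,
                  max_extend = config$ehh_max_extend)
  xp <- xpehh_scan(lapply(panels, `[[`, "A"), lapply(panels, `[[`, "B"),
                   cutoff = config$ehh_cutoff,
                   gap_limit = config$ehh_gap_limit,
                   max_extend = config$ehh_max_extend)
  stats$mean_abs_ihs <- window_mean_abs(ihs, windows, "ihs")
  stats$mean_abs_xpehh <- window_mean_abs(xp, windows, "xpehh")
  stats <- dcms_table(stats)
  regions <- merge_outlier_regions(stats, stats$q_dcms,
                                   q_max = config$q_threshold,
                                   min_support = config$min_support)
  list(windows = stats, regions = regions, ihs = ihs, xpehh = xp)
}

#' Full three-track divergence scan
#'
#' Runs the SNP window/DCMS track, the per-SV Weir--Cockerham FST track and
#' the per-STR Jost's D track, then annotates outliers against the gene
#' models (proximity + permutation enrichment) and summarises.
#'
#' @param sim a dataset as returned by [simulate_dataset()] (or an
#'   equivalently shaped list built from loaded files).
#' @param config a configuration list from [load_config()].
#' @return list with `snp`, `sv`, `str` scan results, `gene_hits` (per
#'   track), `exclusivity`, `permutation`, `summary`, `fixed_sites`
#'   (fixed homozygous SNP differences with coding effects), `pca`
#'   (per-track genotype PCAs) and `str_density` (STR-to-CDS densities).
#' @export
divergence_scan <- function(sim, config = load_config()) {
  snp <- snp_scan(sim$panels, sim$layout, config)
  sv <- sv_scan(sim$svs, sim$popmap, q_max = config$q_threshold,
                max_missing = config$sv_max_missing)
  str <- str_scan(sim$strs, sim$popmap, maf_min = config$str_maf_min,
                  q_max = config$q_threshold)
  reg <- snp$regions$supported
  feats <- list(
    SNP = if (nrow(reg) > 0)
      data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
                 id = sprintf("region%03d", seq_len(nrow(reg))))
    else NULL,
    SV = with(sv[sv$outlier, ], if (length(id) > 0)
      data.frame(chrom = chrom, start = start, end = start + 1, id = id)
      else NULL),
    STR = with(str[str$outlier, ], if (length(id) > 0)
      data.frame(chrom = chrom, start = pos, end = pos + 1, id = id)
      else NULL))
  gene_hits <- lapply(feats, function(f) {
    if (is.null(f)) return(NULL)
    gene_proximity(f, sim$genes, distance = config$proximity_bp)
  })
  gene_sets <- lapply(gene_hits, function(h) {
    if (is.null(h)) character(0) else unique(h$gene_id)
  })
  excl <- gene_set_exclusivity(gene_sets)
  perm <- lapply(feats[!vapply(feats, is.null, logical(1))], function(f) {
    permutation_enrichment(f, sim$genes, sim$layout,
                           n_perm = config$n_permutations,
                           distance = config$proximity_bp,
                           seed = config$seed)
  })
  outlier <- !is.na(snp$windows$q_dcms) &
    snp$windows$q_dcms < config$q_threshold
  summary <- summary_compare(snp$windows, outlier)
  fixed <- .scan_fixed_sites(sim, config)
  pca <- .scan_pcas(sim)
  density <- if (!is.null(sim$genes) && length(sim$strs$id) >= 2)
    str_cds_density(sim$strs, sim$genes) else NULL
  list(snp = snp, sv = sv, str = str, gene_hits = gene_hits,
       exclusivity = excl, permutation = perm, summary = summary,
       fixed_sites = fixed, pca = pca, str_density = density)
}

# Fixed homozygous SNP differences from the haplotype panels, with coding
# effects when annotation + reference are available.
.scan_fixed_sites <- function(sim, config) {
  out <- list()
  for (chrom in names(sim$panels)) {
    pp <- sim$panels[[chrom]]
    hapAB <- rbind(pp$A$hap, pp$B$hap)
    odd <- seq(1, nrow(hapAB), 2)
    gm <- genotype_matrix(chrom, pp$A$pos, hapAB[odd, , drop = FALSE],
                          hapAB[odd + 1, , drop = FALSE],
                          c(pp$A$sample, pp$B$sample),
                          ref = pp$A$ref, alt = pp$A$alt)
    fx <- fixed_differences(gm, sim$popmap)
    if (nrow(fx) == 0) next
    fx$context <- fx$effect <- fx$gene_id <- NA_character_
    if (!is.null(sim$genes) && !is.null(sim$ref) && !anyNA(fx$ref)) {
      for (i in seq_len(nrow(fx))) {
        cl <- classify_coding_effect(chrom, fx$pos[i], fx$ref[i],
                                     fx$alt[i], sim$genes, sim$ref)
        fx$context[i] <- cl$context
        fx$effect[i] <- cl$effect
        fx$gene_id[i] <- cl$gene_id
      }
    }
    out[[chrom]] <- fx
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Genotype PCAs per variant class, restricted to the scan samples.
.scan_pcas <- function(sim, max_snp_sites = 2000L) {
  pcas <- list()
  dos <- do.call(cbind, lapply(sim$panels, function(pp) {
    hapAB <- rbind(pp$A$hap, pp$B$hap)
    odd <- seq(1, nrow(hapAB), 2)
    hapAB[odd, , drop = FALSE] + hapAB[odd + 1, , drop = FALSE]
  }))
  rownames(dos) <- c(sim$panels[[1]]$A$sample, sim$panels[[1]]$B$sample)
  if (ncol(dos) > max_snp_sites) {
    dos <- dos[, round(seq(1, ncol(dos), length.out = max_snp_sites))]
  }
  pcas$SNP <- genotype_pca(dos)
  scan_samples <- unlist(lapply(sim$popmap$scan_pops, pop_samples,
                                popmap = sim$popmap))
  if (!is.null(sim$svs)) {
    pcas$SV <- genotype_pca(subset_samples(sim$svs, scan_samples))
  }
  if (!is.null(sim$strs)) {
    pcas$STR <- genotype_pca(subset_samples(sim$strs, scan_samples))
  }
  pcas
}

#' Assemble a dataset from files
#'
#' Loads the on-disk representation (VCFs, GFF3, FASTA, popmap TSV) into
#' the in-memory shape consumed by [divergence_scan()]: per-chromosome
#' haplotype panels split by scan population, marker-locus sets, gene
#' models and layout.
#'
#' @param snps,svs,strs VCF paths (any may be `NULL` to skip that track).
#' @param gff,fasta annotation and reference paths.
#' @param popmap popmap TSV path or a [population_map()].
#' @param scan_pops optional pair of scan population labels.
#' @return a list shaped like the output of [simulate_dataset()].
#' @export
load_dataset <- function(snps = NULL, svs = NULL, strs = NULL,
                         gff = NULL, fasta = NULL, popmap = NULL,
                         scan_pops = NULL) {
  pm <- if (inherits(popmap, "population_map")) popmap else
    read_popmap(popmap, scan_pops = scan_pops)
  out <- list(popmap = pm)
  if (!is.null(gff) && !is.null(fasta)) {
    ann <- load_annotation(gff, fasta)
    out$genes <- ann$genes
    out$ref <- ann$ref
    out$layout <- genome_layout(names(ann$ref),
                                Biostrings::width(ann$ref))
  }
  if (!is.null(snps)) {
    full <- load_genotypes(snps, "snp", pm)
    out$panels <- lapply(full, function(p) {
      list(A = panel_subset(p, pm, pm$scan_pops[1]),
           B = panel_subset(p, pm, pm$scan_pops[2]))
    })
    if (is.null(out$layout)) {
      lens <- vapply(full, function(p) max(p$pos) + 1, numeric(1))
      out$layout <- genome_layout(names(full), lens)
    }
  }
  if (!is.null(svs)) out$svs <- load_genotypes(svs, "sv", pm)
  if (!is.null(strs)) out$strs <- load_genotypes(strs, "str", pm)
  out
}
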