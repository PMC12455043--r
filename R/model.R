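# Shared data model. All internal coordinates are 0-based half-open;
# VCF/GFF3 1-based coordinates are converted at the I/O boundary.

#' Genome layout
#'
#' Ordered chromosome names and lengths. All module coordinates are
#' validated against this layout.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @return A `genome_layout` object (data frame with columns `chrom`,
#'   `length`).
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != base::length(length)) stop("chrom/length size mismatch")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Population map
#'
#' Assigns each sample to exactly one population label. Scans are run on two
#' populations; samples carrying any other label (e.g. a hybrid population)
#' are excluded from scans but may be present in the VCFs.
#'
#' @param sample character vector of sample ids.
#' @param population character vector of population labels.
#' @param scan_pops the two labels used for scanning (default: the first two
#'   distinct labels in order of appearance).
#' @return A `population_map` object.
#' @export
population_map <- function(sample, population, scan_pops = NULL) {
  sample <- as.character(sample)
  population <- as.character(population)
  if (length(sample) != length(population)) stop("sample/population mismatch")
  if (anyDuplicated(sample)) stop("duplicate sample ids in population map")
  if (is.null(scan_pops)) scan_pops <- unique(population)[1:2]
  if (length(scan_pops) != 2 || anyNA(scan_pops)) {
    stop("exactly two scan populations are required")
  }
  n_by_pop <- table(population)[scan_pops]
  if (any(is.na(n_by_pop)) || any(n_by_pop < 2)) {
    stop("each scan population needs at least 2 samples")
  }
  structure(list(sample = sample, population = population,
                 scan_pops = as.character(scan_pops)),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat("population_map:", length(x$sample), "samples;",
      "scan populations:", paste(x$scan_pops, collapse = " vs "), "\n")
  print(table(x$population))
  invisible(x)
}

#' Samples belonging to one population
#' @param popmap a [population_map()].
#' @param pop population label.
#' @return character vector of sample ids.
#' @export
pop_samples <- function(popmap, pop) {
  popmap$sample[popmap$population == pop]
}

#' Phased haplotype panel
#'
#' Complete (no missing alleles) phased biallelic panel: a 0/1 matrix of
#' haplotypes (rows) by sites (columns), with per-site positions and the
#' ancestral-allele designation. Two haplotype rows per diploid sample.
#'
#' @param chrom single chromosome name.
#' @param pos integer vector of 0-based site positions, strictly increasing.
#' @param hap integer/logical matrix in {0,1}, `2 * n_samples` rows.
#' @param sample character vector of sample ids (each owns two consecutive
#'   rows of `hap`).
#' @param anc_is_ref logical per site: TRUE when the reference (0) allele is
#'   ancestral.
#' @param ref,alt optional reference/alternate allele bases per site.
#' @return A `haplotype_panel` object.
#' @export
haplotype_panel <- function(chrom, pos, hap, sample,
                            anc_is_ref = rep(TRUE, length(pos)),
                            ref = NULL, alt = NULL) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (anyNA(hap)) stop("haplotype panel must be complete (no missing alleles)")
  if (!all(hap %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  if (ncol(hap) != length(pos)) stop("hap columns must match positions")
  if (nrow(hap) != 2L * length(sample)) {
    stop("expected two haplotypes per diploid sample")
  }
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("site positions must be strictly increasing")
  }
  structure(list(chrom = as.character(chrom)[1], pos = as.numeric(pos),
                 hap = hap, sample = as.character(sample),
                 anc_is_ref = as.logical(anc_is_ref), ref = ref,
                 alt = alt),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$hap), "haplotypes x", length(x$pos),
      "sites on", x$chrom, "\n")
  invisible(x)
}

#' Number of haplotypes in a panel
#' @param panel a [haplotype_panel()].
#' @return integer haplotype count.
#' @export
n_haplotypes <- function(panel) nrow(panel$hap)

#' Restrict a haplotype panel to one population
#' @param panel a [haplotype_panel()].
#' @param popmap a [population_map()].
#' @param pop population label.
#' @return a [haplotype_panel()] containing only that population's samples.
#' @export
panel_subset <- function(panel, popmap, pop) {
  keep <- panel$sample %in% pop_samples(popmap, pop)
  if (!any(keep)) stop("no samples of population '", pop, "' in panel")
  rows <- rep(which(keep) * 2L, each = 2L) - c(1L, 0L)
  haplotype_panel(panel$chrom, panel$pos, panel$hap[rows, , drop = FALSE],
                  panel$sample[keep], panel$anc_is_ref,
                  ref = panel$ref, alt = panel$alt)
}

#' Diploid genotype matrix (missing allowed)
#'
#' Per-site pairs of allele indices; used for fixed-difference detection and
#' per-site Weir--Cockerham FST. Stored as two aligned allele matrices.
#'
#' @param chrom chromosome name.
#' @param pos 0-based positions, sorted.
#' @param a1,a2 integer matrices (sample x site) of allele indices, `NA` for
#'   missing.
#' @param sample sample ids.
#' @param ref,alt optional reference/alternate allele strings per site.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(chrom, pos, a1, a2, sample,
                            ref = NULL, alt = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2))) stop("allele matrices differ in shape")
  if (ncol(a1) != length(pos)) stop("columns must match positions")
  if (nrow(a1) != length(sample)) stop("rows must match samples")
  if (is.unsorted(pos)) stop("positions must be sorted")
  structure(list(chrom = as.character(chrom)[1], pos = as.numeric(pos),
                 a1 = a1, a2 = a2, sample = as.character(sample),
                 ref = ref, alt = alt),
            class = "genotype_matrix")
}

#' Structural-variant records
#'
#' @param chrom,start,end vectors (0-based half-open span).
#' @param svtype one of DEL/INS/DUP/INV per record.
#' @param length SV length in bp (> 0).
#' @param id record ids.
#' @param a1,a2 allele matrices (sample x record), `NA` missing.
#' @param sample sample ids.
#' @return A `sv_set` object.
#' @export
sv_set <- function(chrom, start, end, svtype, length, id, a1, a2, sample) {
  chrom <- rep(as.character(chrom), length.out = base::length(id))
  svtype <- rep(as.character(svtype), length.out = base::length(id))
  bad <- !svtype %in% c("DEL", "INS", "DUP", "INV")
  if (any(bad)) stop("unknown SVTYPE: ", paste(unique(svtype[bad]), collapse = ","))
  if (any(end < start)) stop("SV end must be >= start")
  if (any(length <= 0)) stop("SV length must be positive")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), svtype = svtype,
                 length = as.numeric(length), id = as.character(id),
                 a1 = a1, a2 = a2, sample = as.character(sample)),
            class = "sv_set")
}

#' @export
print.sv_set <- function(x, ...) {
  cat("sv_set:", length(x$id), "SVs x", length(x$sample), "samples\n")
  print(table(x$svtype))
  invisible(x)
}

#' Short-tandem-repeat records
#'
#' Alleles are integer repeat counts of a 1--6 bp motif.
#'
#' @param chrom,pos locus coordinates (0-based positions).
#' @param period repeat-unit length per locus, in 1..6.
#' @param id locus ids.
#' @param a1,a2 repeat-count matrices (sample x locus), `NA` missing.
#' @param sample sample ids.
#' @param motif optional repeat-unit sequences.
#' @return A `str_set` object.
#' @export
str_set <- function(chrom, pos, period, id, a1, a2, sample, motif = NULL) {
  chrom <- rep(as.character(chrom), length.out = length(id))
  period <- rep(as.integer(period), length.out = length(id))
  if (any(period < 1 | period > 6)) stop("STR period must be in 1..6")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  structure(list(chrom = chrom, pos = as.numeric(pos),
                 period = period, id = as.character(id),
                 a1 = a1, a2 = a2, sample = as.character(sample),
                 motif = motif),
            class = "str_set")
}

#' @export
print.str_set <- function(x, ...) {
  cat("str_set:", length(x$id), "STRs x", length(x$sample), "samples\n")
  invisible(x)
}

#' Subset loci of an sv_set / str_set
#' @param x an `sv_set` or `str_set`.
#' @param i locus index or logical vector.
#' @return object of the same class restricted to the selected loci.
#' @export
subset_loci <- function(x, i) {
  if (inherits(x, "sv_set")) {
    sv_set(x$chrom[i], x$start[i], x$end[i], x$svtype[i], x$length[i],
           x$id[i], x$a1[, i, drop = FALSE], x$a2[, i, drop = FALSE],
           x$sample)
  } else if (inherits(x, "str_set")) {
    str_set(x$chrom[i], x$pos[i], x$period[i], x$id[i],
            x$a1[, i, drop = FALSE], x$a2[, i, drop = FALSE], x$sample,
            motif = if (!is.null(x$motif)) x$motif[i] else NULL)
  } else stop("unsupported class")
}

#' Subset samples of an sv_set / str_set
#' @param x an `sv_set` or `str_set`.
#' @param samples character vector of sample ids to keep.
#' @return same class, restricted to those samples.
#' @export
subset_samples <- function(x, samples) {
  keep <- x$sample %in% samples
  if (!any(keep)) stop("no matching samples")
  x$a1 <- x$a1[keep, , drop = FALSE]
  x$a2 <- x$a2[keep, , drop = FALSE]
  x$sample <- x$sample[keep]
  x
}

#' Candidate gene list
#' @param symbols character vector of gene symbols (case-insensitively
#'   unique; duplicates after case folding are collapsed).
#' @return a `candidate_genes` object.
#' @export
candidate_genes <- function(symbols) {
  symbols <- as.character(symbols)
  symbols <- symbols[!duplicated(toupper(symbols))]
  structure(list(symbols = symbols), class = "candidate_genes")
}
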