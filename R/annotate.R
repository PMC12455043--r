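# Outlier-to-gene annotation, permutation enrichment, fixed differences and
# coding-effect classification, STR-to-CDS density, and summary statistics.

#' Gene proximity of outlier features
#'
#' A feature hits a gene when its interval overlaps the gene span extended
#' by `distance` bp on both sides by at least 1 bp (half-open arithmetic).
#' Point features are 1 bp intervals. The reported distance is 0 for
#' overlaps of the gene body, otherwise the gap to the gene span.
#'
#' @param features data frame with `chrom`, `start`, `end` and `id`
#'   (points: `end = start + 1`).
#' @param genes a [gene_annotation()].
#' @param distance proximity threshold in bp (default 8000).
#' @return data frame of hits: `feature_id`, `gene_id`, `distance`,
#'   `relation` ("overlaps_gene" or "within_distance").
#' @export
gene_proximity <- function(features, genes, distance = 8000) {
  idx <- genes$index
  hits <- list()
  for (chrom in unique(features$chrom)) {
    fi <- which(features$chrom == chrom)
    gi <- which(idx$chrom == chrom)
    if (length(gi) == 0) next
    fr <- IRanges::IRanges(start = features$start[fi] + 1,
                           end = features$end[fi])
    gr <- IRanges::IRanges(start = pmax(0, idx$start[gi] - distance) + 1,
                           end = idx$end[gi] + distance)
    ov <- IRanges::findOverlaps(fr, gr)
    if (length(ov) == 0) next
    f <- fi[S4Vectors::queryHits(ov)]
    g <- gi[S4Vectors::subjectHits(ov)]
    gap <- pmax(0, idx$start[g] - features$end[f],
                features$start[f] - idx$end[g])
    hits[[chrom]] <- data.frame(
      feature_id = features$id[f], gene_id = idx$id[g], distance = gap,
      relation = ifelse(gap == 0, "overlaps_gene", "within_distance"),
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0) {
    return(data.frame(feature_id = character(0), gene_id = character(0),
                      distance = numeric(0), relation = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(hits, make.row.names = FALSE))
}

#' Variant-type exclusivity of outlier genes
#'
#' Set algebra over per-variant-type outlier gene sets: for each gene, the
#' supporting variant types, and the counts of genes found by exactly one
#' type versus shared between types.
#'
#' @param gene_sets named list of character vectors (e.g. `SNP`, `SV`,
#'   `STR`) of outlier gene ids.
#' @return list with `table` (gene, methods), `n_unique_genes`,
#'   `n_single_type`, `n_multi_type`.
#' @export
gene_set_exclusivity <- function(gene_sets) {
  all_genes <- sort(unique(unlist(gene_sets)))
  methods <- vapply(all_genes, function(g) {
    paste(names(gene_sets)[vapply(gene_sets, function(s) g %in% s,
                                  logical(1))], collapse = ", ")
  }, character(1))
  n_types <- vapply(all_genes, function(g) {
    sum(vapply(gene_sets, function(s) g %in% s, logical(1)))
  }, numeric(1))
  list(table = data.frame(gene = all_genes, methods = methods,
                          stringsAsFactors = FALSE),
       n_unique_genes = length(all_genes),
       n_single_type = sum(n_types == 1),
       n_multi_type = sum(n_types > 1))
}

# Disjoint, sorted, distance-expanded gene intervals per chromosome.
.expanded_gene_intervals <- function(genes, distance) {
  out <- list()
  for (chrom in unique(genes$index$chrom)) {
    gi <- genes$index[genes$index$chrom == chrom, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(0, gi$start - distance) + 1, end = gi$end + distance))
    out[[chrom]] <- data.frame(start = IRanges::start(ir) - 1,
                               end = IRanges::end(ir))
  }
  out
}

# Do [s, s+len) intervals overlap any of the disjoint sorted intervals?
.stab_overlap <- function(s, len, istart, iend) {
  idx <- findInterval(s, istart)
  left <- idx >= 1 & iend[pmax(idx, 1)] > s
  right <- idx < length(istart) & istart[pmin(idx + 1, length(istart))] <
    s + len
  left | right
}

#' Permutation test of gene-proximity enrichment
#'
#' Each permutation re-places every feature uniformly at random on its own
#' chromosome (length preserved, start clipped so the feature fits); the
#' statistic is the number of features within `distance` of at least one
#' gene. The two-sided empirical p-value uses the add-one correction and
#' is capped at 1.
#'
#' @param features data frame with `chrom`, `start`, `end`.
#' @param genes a [gene_annotation()].
#' @param layout a [genome_layout()].
#' @param n_perm number of permutations (default 1000).
#' @param distance proximity threshold in bp (default 8000).
#' @param seed RNG seed for the permutations.
#' @return list with `observed`, `null_counts`, `p`, `seed`.
#' @export
permutation_enrichment <- function(features, genes, layout,
                                   n_perm = 1000, distance = 8000,
                                   seed = 1L) {
  if (nrow(features) == 0) stop("no features to permute")
  chrom_len <- stats::setNames(layout$length, layout$chrom)
  len <- features$end - features$start
  if (any(len > chrom_len[features$chrom])) {
    stop("feature longer than its chromosome")
  }
  iv <- .expanded_gene_intervals(genes, distance)
  hit_one <- function(starts) {
    hit <- logical(length(starts))
    for (chrom in unique(features$chrom)) {
      fi <- features$chrom == chrom
      itab <- iv[[chrom]]
      if (is.null(itab) || nrow(itab) == 0) next
      hit[fi] <- .stab_overlap(starts[fi], len[fi], itab$start, itab$end)
    }
    sum(hit)
  }
  observed <- hit_one(features$start)
  set.seed(seed)
  max_start <- chrom_len[features$chrom] - len
  null_counts <- vapply(seq_len(n_perm), function(i) {
    hit_one(floor(runif(nrow(features)) * (max_start + 1)))
  }, numeric(1))
  p_hi <- (sum(null_counts >= observed) + 1) / (n_perm + 1)
  p_lo <- (sum(null_counts <= observed) + 1) / (n_perm + 1)
  list(observed = observed, null_counts = null_counts,
       p = min(1, 2 * min(p_hi, p_lo)), seed = seed)
}

#' Fixed homozygous differences between the scan populations
#'
#' A site is reported iff every individual of one population is homozygous
#' for the reference allele and every individual of the other population is
#' homozygous for the alternate allele, with no missing genotype in either
#' population.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @return data frame: `chrom`, `pos`, `ref`, `alt`,
#'   `alt_fixed_in` (which scan population carries the alternate).
#' @export
fixed_differences <- function(gm, popmap) {
  popA <- gm$sample %in% pop_samples(popmap, popmap$scan_pops[1])
  popB <- gm$sample %in% pop_samples(popmap, popmap$scan_pops[2])
  dos <- gm$a1 + gm$a2
  complete <- colSums(is.na(dos[popA | popB, , drop = FALSE])) == 0
  sumA <- colSums(dos[popA, , drop = FALSE])
  sumB <- colSums(dos[popB, , drop = FALSE])
  nA <- sum(popA); nB <- sum(popB)
  a_ref_b_alt <- complete & sumA == 0 & sumB == 2 * nB
  a_alt_b_ref <- complete & sumA == 2 * nA & sumB == 0
  sel <- which(a_ref_b_alt | a_alt_b_ref)
  data.frame(chrom = gm$chrom, pos = gm$pos[sel],
             ref = if (!is.null(gm$ref)) gm$ref[sel] else NA_character_,
             alt = if (!is.null(gm$alt)) gm$alt[sel] else NA_character_,
             alt_fixed_in = ifelse(a_ref_b_alt[sel], popmap$scan_pops[2],
                                   popmap$scan_pops[1]),
             stringsAsFactors = FALSE)
}

#' Classify the coding effect of a single-nucleotide substitution
#'
#' Context precedence is CDS > intron > intergenic. For CDS sites the codon
#' is assembled from the spliced CDS in transcript orientation (reverse
#' complemented on the minus strand) using the recorded phases; the
#' alternate allele is substituted and the amino acids compared
#' (synonymous / missense / nonsense). A reference-allele mismatch aborts;
#' an inconsistent CDS phase flags the site unclassifiable.
#'
#' @param chrom,pos site (0-based position).
#' @param ref_allele,alt_allele single bases (plus-strand, as in the VCF).
#' @param genes a [gene_annotation()].
#' @param ref `DNAStringSet` reference.
#' @return list with `context` ("CDS", "intron", "intergenic"), `effect`
#'   ("synonymous", "missense", "nonsense", "non_coding", or `NA` when
#'   unclassifiable), `gene_id` (or `NA`), `codon_ref`, `codon_alt`.
#' @export
classify_coding_effect <- function(chrom, pos, ref_allele, alt_allele,
                                   genes, ref) {
  base_at <- function(p) {
    as.character(Biostrings::subseq(ref[[chrom]], p + 1, p + 1))
  }
  if (base_at(pos) != ref_allele) {
    stop("reference mismatch at ", chrom, ":", pos + 1, " (VCF ",
         ref_allele, ", FASTA ", base_at(pos), ")")
  }
  cds_hit <- genes$cds[genes$cds$chrom == chrom & genes$cds$start <= pos &
                         genes$cds$end > pos, , drop = FALSE]
  if (nrow(cds_hit) == 0) {
    gene_hit <- genes$index[genes$index$chrom == chrom &
                              genes$index$start <= pos &
                              genes$index$end > pos, , drop = FALSE]
    if (nrow(gene_hit) > 0) {
      return(list(context = "intron", effect = "non_coding",
                  gene_id = gene_hit$id[1], codon_ref = NA, codon_alt = NA))
    }
    return(list(context = "intergenic", effect = "non_coding",
                gene_id = NA_character_, codon_ref = NA, codon_alt = NA))
  }
  gid <- cds_hit$gene_id[1]
  seg <- gene_cds(genes, gid)  # transcript order
  strand <- seg$strand[1]
  # spliced CDS genomic coordinates in transcript order
  tx_pos <- unlist(lapply(seq_len(nrow(seg)), function(s) {
    p <- seg$start[s]:(seg$end[s] - 1)
    if (strand == "-") rev(p) else p
  }))
  widths <- seg$end - seg$start
  cum_before <- cumsum(c(0, widths))[seq_len(nrow(seg))]
  p0 <- seg$phase[1]
  expected <- (3 - ((cum_before - p0) %% 3)) %% 3
  expected[1] <- p0
  if (!all(seg$phase == expected)) {
    warning("inconsistent CDS phase in ", gid, "; site unclassifiable")
    return(list(context = "CDS", effect = NA_character_, gene_id = gid,
                codon_ref = NA, codon_alt = NA))
  }
  t <- which(tx_pos == pos) - 1L
  if (length(t) == 0 || t < p0) {
    return(list(context = "CDS", effect = NA_character_, gene_id = gid,
                codon_ref = NA, codon_alt = NA))
  }
  off <- (t - p0) %% 3
  codon_t <- (t - off):(t - off + 2)
  if (max(codon_t) >= length(tx_pos)) {
    return(list(context = "CDS", effect = NA_character_, gene_id = gid,
                codon_ref = NA, codon_alt = NA))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  read_base <- function(gp) {
    b <- base_at(gp)
    if (strand == "-") unname(comp[b]) else b
  }
  codon_ref <- vapply(tx_pos[codon_t + 1L], read_base, character(1))
  codon_alt <- codon_ref
  alt_tx <- if (strand == "-") unname(comp[alt_allele]) else alt_allele
  codon_alt[off + 1L] <- alt_tx
  aa <- function(cdn) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(paste(cdn, collapse = "")),
      no.init.codon = TRUE))
  }
  aa_ref <- aa(codon_ref); aa_alt <- aa(codon_alt)
  effect <- if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "missense"
  list(context = "CDS", effect = effect, gene_id = gid,
       codon_ref = paste(codon_ref, collapse = ""),
       codon_alt = paste(codon_alt, collapse = ""))
}

#' STR density around CDS starts and ends
#'
#' Orientation-aware signed distance from each STR to the nearest CDS start
#' and, separately, the nearest CDS end (start/end in transcript
#' orientation; positive = downstream in transcript direction). Gaussian
#' kernel densities are estimated per repeat period from distances within
#' `range` bp, with Silverman's rule when no bandwidth is supplied.
#'
#' @param strs an [str_set()].
#' @param genes a [gene_annotation()].
#' @param bandwidth kernel bandwidth in bp, or `NULL` for Silverman.
#' @param range half-width of the distance window (default 50 kb).
#' @return data frame: `period`, `anchor` ("cds_start"/"cds_end"), `x`,
#'   `density`; attribute `distances` holds the raw signed distances.
#' @export
str_cds_density <- function(strs, genes, bandwidth = NULL, range = 50000) {
  if (length(strs$id) < 2) stop("need at least 2 STRs")
  if (nrow(genes$cds) == 0) stop("no genes in the annotation")
  cds <- genes$cds
  cds$tx_start <- ifelse(cds$strand == "+", cds$start, cds$end - 1)
  cds$tx_end <- ifelse(cds$strand == "+", cds$end - 1, cds$start)
  sign_of <- ifelse(cds$strand == "+", 1, -1)
  dist_to <- function(anchor_pos, sign_vec, chrom, pos) {
    ai <- which(cds$chrom == chrom)
    if (length(ai) == 0) return(NA_real_)
    d <- (pos - anchor_pos[ai]) * sign_vec[ai]
    d[which.min(abs(d))]
  }
  n <- length(strs$id)
  d_start <- d_end <- numeric(n)
  for (i in seq_len(n)) {
    d_start[i] <- dist_to(cds$tx_start, sign_of, strs$chrom[i], strs$pos[i])
    d_end[i] <- dist_to(cds$tx_end, sign_of, strs$chrom[i], strs$pos[i])
  }
  dists <- data.frame(period = strs$period, d_start = d_start,
                      d_end = d_end)
  rows <- list()
  for (per in sort(unique(strs$period))) {
    for (anchor in c("cds_start", "cds_end")) {
      d <- if (anchor == "cds_start") d_start else d_end
      d <- d[strs$period == per]
      d <- d[!is.na(d) & abs(d) <= range]
      if (length(d) < 2) next
      # wide cut + fine grid so the returned curve carries the full
      # kernel mass (trapezoid-integrates to 1 within 1e-6)
      dn <- if (is.null(bandwidth)) density(d, n = 4096, cut = 6) else
        density(d, bw = bandwidth, n = 4096, cut = 6)
      rows[[paste(per, anchor)]] <-
        data.frame(period = per, anchor = anchor, x = dn$x,
                   density = dn$y, bw = dn$bw, n_loci = length(d),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no STR-CDS distances within range")
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "distances") <- dists
  out
}

#' Cross-reference outlier genes against a candidate list
#'
#' Case-insensitive join of outlier genes to the curated candidate-gene
#' symbols, recording which variant types support each gene.
#'
#' @param gene_sets named list of per-variant-type outlier gene symbol
#'   vectors (e.g. `SNP`, `SV`, `STR`).
#' @param candidates a [candidate_genes()] object.
#' @return list with `matched` (genes on the candidate list) and `full`
#'   (all outlier genes), both with a `methods` column.
#' @export
crossref_candidates <- function(gene_sets, candidates) {
  excl <- gene_set_exclusivity(gene_sets)
  full <- excl$table
  full$in_candidates <- toupper(full$gene) %in%
    toupper(candidates$symbols)
  list(matched = full[full$in_candidates, c("gene", "methods"),
                      drop = FALSE],
       full = full)
}

#' Pearson / Wilcoxon summary comparisons of window statistics
#'
#' Pearson correlations (two-sided t-test, n - 2 df) for the pairs
#' (pi_A, pi_B), (dxy, mean pi), (fst, dxy) and (fst, mean pi), genome-wide
#' and within outlier windows; Wilcoxon rank-sum tests (normal
#' approximation with continuity correction) comparing fst, dxy and per
#' -population pi between outlier and non-outlier windows.
#'
#' @param stats window statistics table (columns `pi_A`, `pi_B`, `dxy`,
#'   `fst_hudson`).
#' @param outlier logical vector over windows.
#' @return list with `pearson` and `wilcoxon` data frames.
#' @export
summary_compare <- function(stats, outlier) {
  stats$mean_pi <- (stats$pi_A + stats$pi_B) / 2
  pairs <- list(c("pi_A", "pi_B"), c("dxy", "mean_pi"),
                c("fst_hudson", "dxy"), c("fst_hudson", "mean_pi"))
  rows <- list()
  for (scope in c("genome", "outlier")) {
    sel <- if (scope == "genome") rep(TRUE, nrow(stats)) else outlier
    for (pr in pairs) {
      x <- stats[[pr[1]]][sel]; y <- stats[[pr[2]]][sel]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        warning("constant or short vector for ", pr[1], " vs ", pr[2],
                " (", scope, "); correlation nulled")
        rows[[paste(scope, pr[1], pr[2])]] <-
          data.frame(scope = scope, x = pr[1], y = pr[2], r = NA_real_,
                     p = NA_real_, n = sum(ok))
        next
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      rows[[paste(scope, pr[1], pr[2])]] <-
        data.frame(scope = scope, x = pr[1], y = pr[2],
                   r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }
  }
  pearson <- do.call(rbind, c(rows, make.row.names = FALSE))
  wrows <- list()
  for (cl in c("fst_hudson", "dxy", "pi_A", "pi_B")) {
    x <- stats[[cl]][outlier]; y <- stats[[cl]][!outlier]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 3 || length(y) < 3) next
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                       correct = TRUE))
    wrows[[cl]] <- data.frame(statistic = cl, W = unname(wt$statistic),
                              p = wt$p.value,
                              median_outlier = median(x),
                              median_background = median(y))
  }
  list(pearson = pearson,
       wilcoxon = do.call(rbind, c(wrows, make.row.names = FALSE)))
}

#' Genotype PCA
#'
#' Allele-dosage PCA: per-locus mean centring, with biallelic loci scaled
#' by \eqn{\sqrt{p(1-p)}}; missing dosages are imputed at the locus mean;
#' zero-variance loci are dropped. Coordinates come from the singular value
#' decomposition, with explained-variance fractions.
#'
#' @param x a [genotype_matrix()], [sv_set()], [str_set()], or a numeric
#'   dosage matrix (samples x loci).
#' @param n_components number of components to return (default 2).
#' @return list with `coords` (samples x components), `explained`
#'   (variance fractions), `samples`.
#' @export
genotype_pca <- function(x, n_components = 2) {
  if (inherits(x, c("genotype_matrix", "sv_set", "str_set"))) {
    dos <- x$a1 + x$a2
    samples <- x$sample
  } else {
    dos <- as.matrix(x)
    samples <- rownames(dos)
  }
  if (nrow(dos) < 3 || ncol(dos) < 2) stop("need >=3 samples and >=2 loci")
  mu <- colMeans(dos, na.rm = TRUE)
  for (j in which(colSums(is.na(dos)) > 0)) dos[is.na(dos[, j]), j] <- mu[j]
  v <- apply(dos, 2, var)
  keep <- v > 0
  if (!any(keep)) stop("zero-variance genotype matrix")
  dos <- dos[, keep, drop = FALSE]
  mu <- mu[keep]
  biallelic <- all(dos %in% 0:2)
  sc <- if (biallelic) {
    p <- mu / 2
    sqrt(pmax(p * (1 - p), 1e-12))
  } else {
    rep(1, ncol(dos))
  }
  z <- sweep(sweep(dos, 2, mu), 2, sc, `/`)
  sv <- svd(z)
  k <- min(n_components, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  rownames(coords) <- samples
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, explained = sv$d^2 / sum(sv$d^2),
       samples = samples)
}
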