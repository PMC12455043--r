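# On-disk formats. VCF (4.2) and GFF3 are 1-based inclusive on disk and
# converted to 0-based half-open at this boundary; BED is already 0-based
# half-open. Parsing goes through vcfR / rtracklayer / Biostrings; the
# writers emit plain text deterministically (same input -> identical bytes).

# ---------------------------------------------------------------- readers

#' Load genotypes from a VCF
#'
#' Dispatches on `mode`:
#' \describe{
#'   \item{snp}{phased biallelic SNPs -> named list of [haplotype_panel()]s,
#'     one per chromosome. Multi-allelic sites are excluded (count
#'     reported); an unphased genotype aborts with the offending site. The
#'     `AA` INFO key, when present, sets the ancestral designation
#'     (default: reference is ancestral).}
#'   \item{sv}{SVTYPE/END/SVLEN records -> an [sv_set()]. Records with an
#'     unknown SVTYPE are dropped with a warning.}
#'   \item{str}{repeat-unit annotated records -> an [str_set()]. Repeat
#'     counts are allele length divided by the RU length; records whose
#'     allele lengths are not exact multiples of the unit are dropped with
#'     a warning.}
#' }
#' Samples absent from the population map are excluded with a warning.
#'
#' @param path VCF file.
#' @param mode "snp", "sv" or "str".
#' @param popmap a [population_map()].
#' @return see above.
#' @export
load_genotypes <- function(path, mode = c("snp", "sv", "str"), popmap) {
  mode <- match.arg(mode)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt[, -1, drop = FALSE]
  vcf_samples <- colnames(gt)
  extra <- setdiff(vcf_samples, popmap$sample)
  if (length(extra) > 0) {
    warning(length(extra), " VCF samples absent from population map ",
            "excluded: ", paste(head(extra, 5), collapse = ","))
  }
  keep_s <- vcf_samples %in% popmap$sample
  gt <- gt[, keep_s, drop = FALSE]
  fix <- v@fix
  switch(mode,
         snp = .parse_snp(fix, gt),
         sv = .parse_sv(fix, gt),
         str = .parse_str(fix, gt))
}

.info_field <- function(info, key) {
  m <- regexec(paste0("(^|;)", key, "=([^;]*)"), info)
  res <- regmatches(info, m)
  vapply(res, function(r) if (length(r) >= 3) r[3] else NA_character_,
         character(1))
}

.parse_snp <- function(fix, gt) {
  gt_only <- matrix(sub(":.*$", "", gt), nrow(gt),
                    dimnames = dimnames(gt))
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  if (any(!biallelic)) {
    message(sum(!biallelic), " multi-allelic or non-SNP sites excluded")
  }
  fix <- fix[biallelic, , drop = FALSE]
  gt_only <- gt_only[biallelic, , drop = FALSE]
  unphased <- !grepl("|", gt_only, fixed = TRUE)
  if (any(unphased)) {
    i <- which(rowSums(matrix(unphased, nrow(gt_only))) > 0)[1]
    stop("unphased genotype at ", fix[i, "CHROM"], ":", fix[i, "POS"])
  }
  a1 <- substr(gt_only, 1, 1); a2 <- substr(gt_only, 3, 3)
  if (any(a1 %in% c(".", "") | a2 %in% c(".", ""))) {
    stop("missing alleles are not allowed in a phased haplotype panel")
  }
  aa <- .info_field(fix[, "INFO"], "AA")
  anc_is_ref <- is.na(aa) | aa == fix[, "REF"]
  samples <- colnames(gt)
  panels <- list()
  for (chrom in unique(fix[, "CHROM"])) {
    ci <- fix[, "CHROM"] == chrom
    pos <- as.numeric(fix[ci, "POS"]) - 1
    ord <- order(pos)
    idx <- which(ci)[ord]
    hap <- matrix(0L, 2 * length(samples), length(idx))
    hap[seq(1, nrow(hap), 2), ] <- t(matrix(as.integer(a1[idx, ]),
                                            length(idx)))
    hap[seq(2, nrow(hap), 2), ] <- t(matrix(as.integer(a2[idx, ]),
                                            length(idx)))
    panels[[chrom]] <- haplotype_panel(chrom, pos[ord], hap, samples,
                                       anc_is_ref[idx],
                                       ref = unname(fix[idx, "REF"]),
                                       alt = unname(fix[idx, "ALT"]))
  }
  panels
}

.geno_split <- function(gt_only) {
  sp <- strsplit(as.vector(gt_only), "[/|]")
  a1 <- vapply(sp, function(x) x[1], character(1))
  a2 <- vapply(sp, function(x) if (length(x) > 1) x[2] else NA_character_,
               character(1))
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  list(a1 = matrix(as.integer(a1), nrow(gt_only)),
       a2 = matrix(as.integer(a2), nrow(gt_only)))
}

.parse_sv <- function(fix, gt) {
  info <- fix[, "INFO"]
  svtype <- .info_field(info, "SVTYPE")
  known <- svtype %in% c("DEL", "INS", "DUP", "INV")
  if (any(!known)) {
    warning(sum(!known), " SV records with unknown SVTYPE rejected: ",
            paste(unique(svtype[!known]), collapse = ","))
  }
  fix <- fix[known, , drop = FALSE]; gt <- gt[known, , drop = FALSE]
  info <- info[known]; svtype <- svtype[known]
  pos1 <- as.numeric(fix[, "POS"])
  end <- suppressWarnings(as.numeric(.info_field(info, "END")))
  svlen <- suppressWarnings(abs(as.numeric(.info_field(info, "SVLEN"))))
  start <- pos1 - 1
  end[is.na(end)] <- start[is.na(end)] + 1
  svlen[is.na(svlen)] <- (end - start)[is.na(svlen)]
  g <- .geno_split(matrix(sub(":.*$", "", gt), nrow(gt)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("sv_anon%05d",
                                          which(is.na(ids) | ids == "."))
  sv_set(fix[, "CHROM"], start, end, svtype, svlen, ids,
         t(g$a1), t(g$a2), colnames(gt))
}

.parse_str <- function(fix, gt) {
  info <- fix[, "INFO"]
  ru <- .info_field(info, "RU")
  period <- nchar(ru)
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_rec <- nrow(fix)
  counts_list <- vector("list", n_rec)
  ok <- rep(TRUE, n_rec)
  for (i in seq_len(n_rec)) {
    lens <- c(nchar(fix[i, "REF"]), nchar(alt_list[[i]]))
    if (is.na(period[i]) || period[i] < 1 || period[i] > 6 ||
        any(lens %% period[i] != 0)) {
      ok[i] <- FALSE
      next
    }
    counts_list[[i]] <- lens %/% period[i]
  }
  if (any(!ok)) {
    warning(sum(!ok), " STR records dropped (allele length not a ",
            "multiple of the repeat unit, or invalid RU)")
  }
  gt_ok <- gt[ok, , drop = FALSE]
  g <- .geno_split(matrix(sub(":.*$", "", gt_ok), nrow(gt_ok)))
  fix <- fix[ok, , drop = FALSE]
  counts_list <- counts_list[ok]
  rc1 <- g$a1; rc2 <- g$a2
  for (i in seq_len(nrow(fix))) {
    rc1[i, ] <- counts_list[[i]][g$a1[i, ] + 1L]
    rc2[i, ] <- counts_list[[i]][g$a2[i, ] + 1L]
  }
  str_set(fix[, "CHROM"], as.numeric(fix[, "POS"]) - 1,
          nchar(.info_field(fix[, "INFO"], "RU")), fix[, "ID"],
          t(rc1), t(rc2), colnames(gt),
          motif = .info_field(fix[, "INFO"], "RU"))
}

#' Load a gene annotation (GFF3) and reference (FASTA)
#'
#' Builds one gene model per gene (keeping the longest mRNA when several),
#' converting 1-based inclusive GFF intervals to 0-based half-open. A CDS
#' with an absent phase is assumed in-frame (phase 0) with a warning; a
#' gene on a contig missing from the FASTA aborts.
#'
#' @param gff_path GFF3 file with gene/mRNA/CDS features.
#' @param fasta_path FASTA file of the reference contigs.
#' @return list with `genes` (a [gene_annotation()]) and `ref`
#'   (`DNAStringSet`).
#' @export
load_annotation <- function(gff_path, fasta_path) {
  gr <- rtracklayer::import(gff_path)
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  df <- as.data.frame(gr)
  miss <- setdiff(unique(as.character(df$seqnames)), names(ref))
  if (length(miss) > 0) {
    stop("GFF contig missing from FASTA: ", paste(miss, collapse = ","))
  }
  genes_df <- df[df$type == "gene", , drop = FALSE]
  mrna_df <- df[df$type == "mRNA", , drop = FALSE]
  cds_df <- df[df$type == "CDS", , drop = FALSE]
  # longest mRNA per gene
  if (nrow(mrna_df) > 0) {
    mrna_df$parent <- vapply(mrna_df$Parent, function(p) p[1], character(1))
    mrna_df <- mrna_df[order(-mrna_df$width), , drop = FALSE]
    mrna_df <- mrna_df[!duplicated(mrna_df$parent), , drop = FALSE]
    keep_tx <- mrna_df$ID
    cds_df$parent <- vapply(cds_df$Parent, function(p) p[1], character(1))
    cds_df <- cds_df[cds_df$parent %in% keep_tx, , drop = FALSE]
    tx2gene <- stats::setNames(mrna_df$parent, mrna_df$ID)
    cds_df$gene_id <- tx2gene[cds_df$parent]
  } else {
    cds_df$gene_id <- vapply(cds_df$Parent, function(p) p[1], character(1))
  }
  phase <- suppressWarnings(as.integer(as.character(cds_df$phase)))
  if (anyNA(phase)) {
    warning(sum(is.na(phase)), " CDS segments without phase assumed 0")
    phase[is.na(phase)] <- 0L
  }
  index <- data.frame(id = genes_df$ID,
                      chrom = as.character(genes_df$seqnames),
                      start = genes_df$start - 1, end = genes_df$end,
                      strand = as.character(genes_df$strand),
                      stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = cds_df$gene_id,
                    chrom = as.character(cds_df$seqnames),
                    start = cds_df$start - 1, end = cds_df$end,
                    strand = as.character(cds_df$strand),
                    phase = phase, stringsAsFactors = FALSE)
  list(genes = gene_annotation(index, cds), ref = ref)
}

#' Read a population map TSV (columns: sample, population)
#' @param path TSV file.
#' @param scan_pops optional pair of scan population labels.
#' @return a [population_map()].
#' @export
read_popmap <- function(path, scan_pops = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  population_map(df$sample, df$population, scan_pops = scan_pops)
}

#' Read a candidate gene list (TSV with a `symbol` column, or one symbol
#' per line)
#' @param path TSV file.
#' @return a [candidate_genes()] object.
#' @export
read_candidate_genes <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\\bsymbol\\b", first)) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    candidate_genes(df$symbol)
  } else {
    candidate_genes(readLines(path, warn = FALSE))
  }
}

# ---------------------------------------------------------------- writers

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%d", as.integer(round(pmin(pmax(x, -2e9), 2e9)))),
                sprintf("%.17g", x)))
}

.write_tsv <- function(df, path) {
  out <- df
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- .fmt_num(out[[cl]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

.write_bed <- function(df, path) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  keep <- intersect(c("chrom", "start", "end", "name", "support"),
                    names(df))
  writeLines(do.call(paste, c(unname(df[keep]), sep = "\t")), path)
  invisible(path)
}

#' Write scan outputs to a directory
#'
#' Emits the window/DCMS tables (TSV), outlier regions (BED, 0-based
#' half-open, sorted by chromosome then start), per-locus outlier tables
#' and a run log (configuration, seed, package version). Output is
#' deterministic: identical inputs give byte-identical files. Empty
#' results yield header-only files.
#'
#' @param results named list; recognised elements: `window_stats`, `dcms`,
#'   `regions` (list with `supported`, `all`), `sv`, `str`, `config`,
#'   `seed`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (!is.null(results$window_stats)) {
    paths["window_stats"] <- .write_tsv(results$window_stats,
                                        file.path(out_dir,
                                                  "window_stats.tsv"))
  }
  if (!is.null(results$dcms)) {
    paths["dcms"] <- .write_tsv(results$dcms,
                                file.path(out_dir, "dcms.tsv"))
  }
  if (!is.null(results$regions)) {
    paths["regions"] <- .write_bed(results$regions$supported,
                                   file.path(out_dir,
                                             "outlier_regions.bed"))
    paths["regions_all"] <- .write_bed(results$regions$all,
                                       file.path(out_dir,
                                                 "outlier_regions_all.bed"))
  }
  if (!is.null(results$sv)) {
    paths["sv"] <- .write_tsv(results$sv,
                              file.path(out_dir, "sv_outliers.tsv"))
  }
  if (!is.null(results$str)) {
    paths["str"] <- .write_tsv(results$str,
                               file.path(out_dir, "str_outliers.tsv"))
  }
  if (!is.null(results$gene_hits)) {
    gh <- results$gene_hits
    gh <- gh[!vapply(gh, is.null, logical(1))]
    tab <- do.call(rbind, c(Map(function(nm, h) cbind(track = nm, h),
                                names(gh), gh), make.row.names = FALSE))
    paths["gene_hits"] <- .write_tsv(tab,
                                     file.path(out_dir, "gene_hits.tsv"))
  }
  if (!is.null(results$fixed_sites)) {
    paths["fixed_sites"] <- .write_tsv(results$fixed_sites,
                                       file.path(out_dir,
                                                 "fixed_sites.tsv"))
  }
  if (!is.null(results$permutation)) {
    jsonlite::write_json(results$permutation,
                         file.path(out_dir, "permutation.json"),
                         auto_unbox = TRUE, digits = NA)
    paths["permutation"] <- file.path(out_dir, "permutation.json")
  }
  if (!is.null(results$str_density)) {
    paths["str_density"] <- .write_tsv(results$str_density,
                                       file.path(out_dir,
                                                 "str_cds_density.tsv"))
  }
  if (!is.null(results$summary)) {
    jsonlite::write_json(results$summary,
                         file.path(out_dir, "summary_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    paths["summary"] <- file.path(out_dir, "summary_stats.json")
  }
  if (!is.null(results$pca)) {
    tab <- do.call(rbind, c(Map(function(nm, p) {
      data.frame(track = nm, sample = p$samples,
                 PC1 = p$coords[, 1],
                 PC2 = if (ncol(p$coords) > 1) p$coords[, 2] else NA_real_,
                 stringsAsFactors = FALSE)
    }, names(results$pca), results$pca), make.row.names = FALSE))
    paths["pca"] <- .write_tsv(tab, file.path(out_dir, "pca.tsv"))
  }
  log_lines <- c(
    paste0("polyscan ", as.character(utils::packageVersion("polyscan"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("seed\t", if (!is.null(results$seed)) results$seed else "NA"))
  if (!is.null(results$config)) {
    cfg <- results$config
    log_lines <- c(log_lines,
                   paste0(names(cfg), "\t",
                          vapply(cfg, function(x) paste(x, collapse = ","),
                                 character(1))))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths["log"] <- file.path(out_dir, "run_log.txt")
  paths
}

.write_vcf_header <- function(con, layout, samples, extra = character(0)) {
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                       as.integer(layout$length)),
               extra,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
}

#' Write a phased SNP VCF from haplotype panels
#'
#' The reference (0) allele is the reference-genome base; the alternate is
#' the next base in A>C>G>T cyclic order. The `AA` INFO key records the
#' ancestral allele (the reference, by construction).
#'
#' @param panels named list per chromosome of lists of
#'   [haplotype_panel()]s (entries `A`, `B`, optionally `H`) sharing a site
#'   grid per chromosome.
#' @param ref `DNAStringSet` reference.
#' @param layout a [genome_layout()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(panels, ref, layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  first <- panels[[1]]
  samples <- unlist(lapply(first[names(first) != "pos"],
                           function(p) p$sample), use.names = FALSE)
  .write_vcf_header(con, layout, samples,
                    c("##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"))
  cycle <- c(A = "C", C = "G", G = "T", T = "A")
  for (chrom in names(panels)) {
    pp <- panels[[chrom]]
    pos <- pp[[1]]$pos
    if (!is.null(pp[[1]]$ref)) {
      refb <- pp[[1]]$ref
      altb <- pp[[1]]$alt
    } else {
      chars <- strsplit(as.character(ref[[chrom]]), "")[[1]]
      refb <- chars[pos + 1]
      altb <- unname(cycle[refb])
    }
    hap <- do.call(rbind, lapply(pp, function(p) p$hap))
    n_s <- length(samples)
    gt <- matrix("", length(pos), n_s)
    for (i in seq_len(n_s)) {
      gt[, i] <- paste0(hap[2 * i - 1, ], "|", hap[2 * i, ])
    }
    lines <- paste(chrom, pos + 1,
                   sprintf("%s_%d", chrom, pos + 1), refb, altb, ".",
                   "PASS", paste0("AA=", refb), "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write an SV VCF (symbolic alleles, SVTYPE/END/SVLEN INFO keys)
#' @param svs an [sv_set()].
#' @param layout a [genome_layout()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_vcf_header(con, layout, svs$sample,
                    c("##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
                      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
                      "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"))
  ord <- order(svs$chrom, svs$start)
  gtc <- matrix(paste0(ifelse(is.na(svs$a1), ".", svs$a1), "/",
                       ifelse(is.na(svs$a2), ".", svs$a2)),
                nrow(svs$a1))
  lines <- paste(svs$chrom[ord], as.integer(svs$start[ord] + 1),
                 svs$id[ord], "N", paste0("<", svs$svtype[ord], ">"),
                 ".", "PASS",
                 sprintf("SVTYPE=%s;END=%d;SVLEN=%d", svs$svtype[ord],
                         as.integer(svs$end[ord]),
                         as.integer(svs$length[ord])),
                 "GT",
                 apply(gtc[, ord, drop = FALSE], 2, paste,
                       collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write an STR VCF (sequence alleles; RU INFO key gives the repeat unit)
#' @param strs an [str_set()].
#' @param layout a [genome_layout()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_str_vcf <- function(strs, layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_vcf_header(con, layout, strs$sample,
                    c("##INFO=<ID=RU,Number=1,Type=String,Description=\"Repeat unit\">",
                      "##INFO=<ID=PERIOD,Number=1,Type=Integer,Description=\"Repeat unit length\">",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"))
  ord <- order(strs$chrom, strs$pos)
  lines <- character(length(ord))
  for (k in seq_along(ord)) {
    j <- ord[k]
    alleles <- sort(unique(c(strs$a1[, j], strs$a2[, j])))
    alleles <- alleles[!is.na(alleles)]
    seqs <- vapply(alleles, function(r) {
      paste(rep(strs$motif[j], r), collapse = "")
    }, character(1))
    idx1 <- match(strs$a1[, j], alleles) - 1L
    idx2 <- match(strs$a2[, j], alleles) - 1L
    gt <- paste0(ifelse(is.na(idx1), ".", idx1), "/",
                 ifelse(is.na(idx2), ".", idx2))
    alt <- if (length(seqs) > 1) paste(seqs[-1], collapse = ",") else "."
    lines[k] <- paste(strs$chrom[j], as.integer(strs$pos[j] + 1),
                      strs$id[j], seqs[1], alt, ".", "PASS",
                      sprintf("RU=%s;PERIOD=%d", strs$motif[j],
                              strs$period[j]),
                      "GT", paste(gt, collapse = "\t"), sep = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write a gene annotation as GFF3 (gene/mRNA/CDS)
#' @param genes a [gene_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  idx <- genes$index[order(genes$index$chrom, genes$index$start), ,
                     drop = FALSE]
  for (i in seq_len(nrow(idx))) {
    g <- idx[i, ]
    writeLines(paste(g$chrom, "polyscan", "gene", g$start + 1, g$end,
                     ".", g$strand, ".", paste0("ID=", g$id), sep = "\t"),
               con)
    tid <- paste0(g$id, ".t1")
    writeLines(paste(g$chrom, "polyscan", "mRNA", g$start + 1, g$end,
                     ".", g$strand, ".",
                     paste0("ID=", tid, ";Parent=", g$id), sep = "\t"),
               con)
    seg <- genes$cds[genes$cds$gene_id == g$id, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    for (s in seq_len(nrow(seg))) {
      writeLines(paste(seg$chrom[s], "polyscan", "CDS", seg$start[s] + 1,
                       seg$end[s], ".", seg$strand[s], seg$phase[s],
                       paste0("ID=", tid, ".cds", s, ";Parent=", tid),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write the complete synthetic dataset
#' @param sim result of [simulate_dataset()].
#' @param out_dir output directory.
#' @return named character vector of file paths.
#' @export
write_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(snps = file.path(out_dir, "snps.vcf"),
         svs = file.path(out_dir, "svs.vcf"),
         strs = file.path(out_dir, "strs.vcf"),
         gff = file.path(out_dir, "genes.gff3"),
         fasta = file.path(out_dir, "ref.fa"),
         popmap = file.path(out_dir, "popmap.tsv"),
         truth_regions = file.path(out_dir, "truth_regions.bed"),
         truth_loci = file.path(out_dir, "truth_loci.tsv"))
  write_snp_vcf(sim$panels, sim$ref, sim$layout, f["snps"])
  write_sv_vcf(sim$svs, sim$layout, f["svs"])
  write_str_vcf(sim$strs, sim$layout, f["strs"])
  write_gff3(sim$genes, f["gff"])
  Biostrings::writeXStringSet(sim$ref, f["fasta"], width = 80)
  .write_tsv(data.frame(sample = sim$popmap$sample,
                        population = sim$popmap$population),
             f["popmap"])
  .write_bed(sim$truth$sweeps, f["truth_regions"])
  sv_t <- cbind(type = "sv", sim$truth$sv)
  names(sv_t)[names(sv_t) %in% c("p_A", "p_B")] <- c("value_A", "value_B")
  str_t <- cbind(type = "str", sim$truth$str)
  names(str_t)[names(str_t) %in% c("mu_A", "mu_B")] <-
    c("value_A", "value_B")
  .write_tsv(rbind(sv_t, str_t), f["truth_loci"])
  writeLines(sort(sim$truth$sweep_genes),
             file.path(out_dir, "truth_genes.txt"))
  f
}
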