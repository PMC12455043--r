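# Gene models: flat index + CDS tables (0-based half-open internally).

#' Gene annotation container
#'
#' @param index data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (one row per gene, 0-based half-open spans).
#' @param cds data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `phase` (one row per CDS segment).
#' @return a `gene_annotation` object.
#' @export
gene_annotation <- function(index, cds) {
  stopifnot(all(c("id", "chrom", "start", "end", "strand") %in%
                  names(index)),
            all(c("gene_id", "chrom", "start", "end", "strand", "phase")
                %in% names(cds)))
  if (anyDuplicated(index$id)) stop("gene ids must be unique")
  bad <- !cds$gene_id %in% index$id
  if (any(bad)) stop("CDS referencing unknown gene: ",
                     paste(unique(cds$gene_id[bad]), collapse = ","))
  for (g in unique(cds$gene_id)) {
    seg <- cds[cds$gene_id == g, , drop = FALSE]
    gi <- index[index$id == g, ]
    if (any(seg$start < gi$start | seg$end > gi$end)) {
      stop("CDS outside gene span for ", g)
    }
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)])) {
      stop("overlapping CDS segments within gene ", g)
    }
  }
  structure(list(index = index, cds = cds), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$index), "genes,", nrow(x$cds),
      "CDS segments on", length(unique(x$index$chrom)), "chromosomes\n")
  invisible(x)
}

#' CDS segments of one gene, in transcript order
#' @param genes a [gene_annotation()].
#' @param id gene id.
#' @return data frame of CDS segments ordered 5' to 3' on the transcript.
#' @export
gene_cds <- function(genes, id) {
  seg <- genes$cds[genes$cds$gene_id == id, , drop = FALSE]
  seg[order(seg$start, decreasing = seg$strand[1] == "-"), , drop = FALSE]
}

.SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Generate a synthetic gene annotation and reference sequence
#'
#' Genes are placed left-to-right per chromosome with intergenic gaps drawn
#' from an exponential law (mean `config$intergenic_mean`). Each gene has
#' 2--8 CDS segments separated by introns; the concatenated CDS is a valid
#' open reading frame (ATG start, internal sense codons, terminal stop),
#' written into the random reference sequence on the gene's strand with
#' consistent GFF phases.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (a [gene_annotation()]) and `ref` (a
#'   `Biostrings::DNAStringSet`).
#' @export
generate_annotation <- function(config) {
  bases <- c("A", "C", "G", "T")
  idx_rows <- list(); cds_rows <- list(); seqs <- list()
  gene_n <- 0L
  for (chrom in names(config$chrom_lengths)) {
    L <- as.integer(config$chrom_lengths[[chrom]])
    seq_chars <- sample(bases, L, replace = TRUE)
    cursor <- 0
    repeat {
      gap <- rexp(1, 1 / config$intergenic_mean)
      g_start <- round(cursor + gap)
      n_seg <- sample(2:8, 1)
      n_codons <- sample(max(60L, 10L * n_seg + 2L):600, 1)
      total_nt <- 3L * n_codons
      # split the CDS into n_seg parts of >= 30 bp each
      extra <- total_nt - 30L * n_seg
      w <- runif(n_seg)
      parts <- floor(extra * w / sum(w))
      parts[1] <- parts[1] + extra - sum(parts)
      seg_nt <- 30L + as.integer(parts)
      introns <- sample(200:3000, n_seg - 1, replace = TRUE)
      g_end <- g_start + sum(seg_nt) + sum(introns)
      if (g_end > L - 2000) break
      strand <- sample(c("+", "-"), 1)
      codons <- c("ATG",
                  sample(.SENSE_CODONS, n_codons - 2, replace = TRUE),
                  sample(c("TAA", "TAG", "TGA"), 1))
      cds_seq <- paste(codons, collapse = "")
      genomic_seq <- if (strand == "+") cds_seq else .revcomp(cds_seq)
      # genomic-order segment intervals
      seg_start <- g_start + cumsum(c(0, seg_nt[-n_seg] +
                                        introns))
      seg_end <- seg_start + seg_nt
      # write CDS nucleotides into the chromosome
      nt <- strsplit(genomic_seq, "")[[1]]
      off <- 0L
      for (s in seq_len(n_seg)) {
        seq_chars[(seg_start[s] + 1):seg_end[s]] <-
          nt[(off + 1):(off + seg_nt[s])]
        off <- off + seg_nt[s]
      }
      # phases follow transcript order
      tr_order <- if (strand == "+") seq_len(n_seg) else rev(seq_len(n_seg))
      cum_before <- cumsum(c(0L, seg_nt[tr_order]))[seq_len(n_seg)]
      phase_tr <- (3L - cum_before %% 3L) %% 3L
      phase <- integer(n_seg)
      phase[tr_order] <- phase_tr
      gene_n <- gene_n + 1L
      gid <- sprintf("gene%04d", gene_n)
      idx_rows[[gid]] <- data.frame(id = gid, chrom = chrom,
                                    start = g_start, end = g_end,
                                    strand = strand,
                                    stringsAsFactors = FALSE)
      cds_rows[[gid]] <- data.frame(gene_id = gid, chrom = chrom,
                                    start = seg_start, end = seg_end,
                                    strand = strand, phase = phase,
                                    stringsAsFactors = FALSE)
      cursor <- g_end
    }
    seqs[[chrom]] <- paste(seq_chars, collapse = "")
  }
  if (length(idx_rows) == 0) stop("insufficient space to place genes")
  genes <- gene_annotation(do.call(rbind, c(idx_rows,
                                            make.row.names = FALSE)),
                           do.call(rbind, c(cds_rows,
                                            make.row.names = FALSE)))
  ref <- Biostrings::DNAStringSet(unlist(seqs))
  names(ref) <- names(seqs)
  list(genes = genes, ref = ref)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
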