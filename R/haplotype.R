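# EHH-based long-range haplotype statistics. Physical distance (bp) stands
# in for genetic distance; cores whose decay curve crosses an inter-site gap
# larger than the gap limit are discarded, mirroring the usual gap guards.

.anc_allele <- function(panel) ifelse(panel$anc_is_ref, 0L, 1L)

#' EHH decay curve from a core site
#'
#' EHH at a site s is the probability that two distinct carrier haplotypes
#' are identical at every site from the core to s. The curve starts at 1 at
#' the core and is non-increasing; computation stops when it drops below
#' `cutoff`, at the chromosome end, or at an inter-site gap larger than
#' `gap_limit`.
#'
#' @param panel a [haplotype_panel()].
#' @param core site index (1-based column of the panel).
#' @param allele which carrier class: "anc" or "der".
#' @param side "left" or "right".
#' @param cutoff decay cutoff (default 0.05).
#' @param gap_limit maximum tolerated inter-site gap in bp.
#' @param max_extend maximum physical extension from the core in bp
#'   (default 300 kb); the curve is truncated there.
#' @return list with `pos`, `ehh`, `gap_hit`; `NULL` if the allele class has
#'   fewer than 2 carriers.
#' @export
ehh_curve <- function(panel, core, allele = c("der", "anc"),
                      side = c("right", "left"), cutoff = 0.05,
                      gap_limit = 200000, max_extend = 300000) {
  allele <- match.arg(allele)
  side <- match.arg(side)
  anc <- .anc_allele(panel)[core]
  want <- if (allele == "anc") anc else 1L - anc
  carriers <- which(panel$hap[, core] == want) - 1L
  if (length(carriers) < 2) return(NULL)
  .ehh_curve_cpp(panel$hap, panel$pos, core - 1L, carriers,
                 if (side == "right") 1L else -1L, cutoff, gap_limit,
                 max_extend, FALSE)
}

#' Integrated EHH from a pair of decay curves
#'
#' Trapezoid area under the left and right EHH curves against physical
#' position, truncated at the cutoff crossing with linear interpolation to
#' the cutoff. Curves that never reach the cutoff are integrated to their
#' last point.
#'
#' @param left,right curves as returned by [ehh_curve()] (either may be
#'   `NULL` or empty, contributing 0).
#' @param cutoff decay cutoff used when the curves were computed.
#' @return iHH in bp.
#' @export
integrated_ehh <- function(left, right, cutoff = 0.05) {
  one_side <- function(cv) {
    if (is.null(cv) || length(cv$pos) < 2) return(0)
    xs <- cv$pos; es <- cv$ehh
    area <- 0
    for (k in 2:length(xs)) {
      dx <- abs(xs[k] - xs[k - 1])
      if (es[k] < cutoff) {
        e0 <- es[k - 1]
        if (e0 <= cutoff) break
        frac <- (e0 - cutoff) / (e0 - es[k])
        area <- area + 0.5 * (e0 + cutoff) * dx * frac
        break
      }
      area <- area + 0.5 * (es[k] + es[k - 1]) * dx
    }
    area
  }
  one_side(left) + one_side(right)
}

# Unstandardised per-site iHH table for one chromosome panel.
.ihs_table <- function(panel, maf_min = 0.05, cutoff = 0.05,
                       gap_limit = 200000, max_extend = 300000) {
  p_alt <- colMeans(panel$hap)
  daf <- ifelse(panel$anc_is_ref, p_alt, 1 - p_alt)
  cores <- which(daf >= maf_min & daf <= 1 - maf_min)
  if (length(cores) == 0) {
    return(data.frame(chrom = character(0), pos = numeric(0),
                      daf = numeric(0), ihh_a = numeric(0),
                      ihh_d = numeric(0), ihs_unstd = numeric(0)))
  }
  ihh <- .ihh_pair_scan_cpp(panel$hap, panel$pos, .anc_allele(panel),
                            cores - 1L, cutoff, gap_limit, max_extend)
  unstd <- ifelse(is.na(ihh[, 1]) | is.na(ihh[, 2]) |
                    ihh[, 1] <= 0 | ihh[, 2] <= 0,
                  NA_real_, log(ihh[, 1] / ihh[, 2]))
  data.frame(chrom = panel$chrom, pos = panel$pos[cores], daf = daf[cores],
             ihh_a = ihh[, 1], ihh_d = ihh[, 2], ihs_unstd = unstd,
             stringsAsFactors = FALSE)
}

# Frequency-bin standardisation of unstandardised iHS values.
.ihs_standardise <- function(tab, bins = 20) {
  tab$bin <- pmin(bins, floor(tab$daf * bins) + 1L)
  tab$ihs <- NA_real_
  starved <- 0L
  for (b in unique(tab$bin)) {
    i <- which(tab$bin == b & is.finite(tab$ihs_unstd))
    if (length(i) < 2 || sd(tab$ihs_unstd[i]) == 0) {
      starved <- starved + 1L
      next
    }
    tab$ihs[i] <- (tab$ihs_unstd[i] - mean(tab$ihs_unstd[i])) /
      sd(tab$ihs_unstd[i])
  }
  if (starved > 0) {
    warning(starved, " frequency bins had <2 usable sites; scores nulled")
  }
  tab
}

#' iHS scan over one or several chromosome panels
#'
#' For each core site with derived-allele frequency inside
#' `[maf_min, 1 - maf_min]`, computes the integrated EHH of the ancestral
#' and derived carrier classes and their log-ratio
#' \eqn{\ln(iHH_A / iHH_D)}, then standardises within equal-width
#' derived-allele-frequency bins (mean 0, s.d. 1 per bin). Multi-chromosome
#' input is standardised jointly.
#'
#' @param panels a [haplotype_panel()] or list of them (one per chromosome).
#' @param maf_min derived-frequency bound for core sites (default 0.05).
#' @param bins number of equal-width frequency bins (default 20).
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param gap_limit maximum tolerated inter-site gap in bp (default 200 kb).
#' @param max_extend maximum physical EHH extension from the core in bp
#'   (default 300 kb).
#' @return data frame: `chrom`, `pos`, `daf`, `ihh_a`, `ihh_d`,
#'   `ihs_unstd`, `bin`, `ihs`.
#' @export
ihs_scan <- function(panels, maf_min = 0.05, bins = 20, cutoff = 0.05,
                     gap_limit = 200000, max_extend = 300000) {
  if (inherits(panels, "haplotype_panel")) panels <- list(panels)
  tab <- do.call(rbind, lapply(panels, .ihs_table, maf_min = maf_min,
                               cutoff = cutoff, gap_limit = gap_limit,
                               max_extend = max_extend))
  .ihs_standardise(tab, bins = bins)
}

# Unstandardised xpEHH table for one chromosome pair.
.xpehh_table <- function(panelA, panelB, cutoff = 0.05,
                         gap_limit = 200000, max_extend = 300000) {
  if (!identical(panelA$pos, panelB$pos)) {
    stop("panels must share the same site grid")
  }
  cores <- seq_along(panelA$pos)
  ihhA <- .ihh_pooled_scan_cpp(panelA$hap, panelA$pos, cores - 1L,
                               cutoff, gap_limit, max_extend)
  ihhB <- .ihh_pooled_scan_cpp(panelB$hap, panelB$pos, cores - 1L,
                               cutoff, gap_limit, max_extend)
  unstd <- ifelse(is.na(ihhA) | is.na(ihhB) | ihhA <= 0 | ihhB <= 0,
                  NA_real_, log(ihhA / ihhB))
  data.frame(chrom = panelA$chrom, pos = panelA$pos, ihh_A = ihhA,
             ihh_B = ihhB, xpehh_unstd = unstd, stringsAsFactors = FALSE)
}

#' Cross-population EHH scan
#'
#' Per core site, the log-ratio of pooled (both-allele) integrated EHH
#' between the two populations, \eqn{\ln(iHH_A / iHH_B)}, standardised by
#' the genome-wide mean and standard deviation. Negative scores mean longer
#' haplotype homozygosity in population B.
#'
#' @param panelsA,panelsB [haplotype_panel()]s or lists of them (same
#'   chromosomes in the same order), sharing site grids per chromosome.
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param gap_limit maximum tolerated inter-site gap in bp (default 200 kb).
#' @param max_extend maximum physical EHH extension from the core in bp
#'   (default 300 kb).
#' @return data frame: `chrom`, `pos`, `ihh_A`, `ihh_B`, `xpehh_unstd`,
#'   `xpehh`.
#' @export
xpehh_scan <- function(panelsA, panelsB, cutoff = 0.05,
                       gap_limit = 200000, max_extend = 300000) {
  if (inherits(panelsA, "haplotype_panel")) {
    panelsA <- list(panelsA); panelsB <- list(panelsB)
  }
  tab <- do.call(rbind, Map(function(a, b) {
    .xpehh_table(a, b, cutoff = cutoff, gap_limit = gap_limit,
                 max_extend = max_extend)
  }, panelsA, panelsB))
  ok <- is.finite(tab$xpehh_unstd)
  if (sum(ok) < 2 || sd(tab$xpehh_unstd[ok]) == 0) {
    stop("degenerate xpEHH distribution: cannot standardise")
  }
  tab$xpehh <- NA_real_
  tab$xpehh[ok] <- (tab$xpehh_unstd[ok] - mean(tab$xpehh_unstd[ok])) /
    sd(tab$xpehh_unstd[ok])
  tab
}

#' Window means of absolute haplotype scores
#'
#' Arithmetic mean of |score| over scored sites per window; `NA` for
#' windows without scored sites.
#'
#' @param scores data frame with `chrom`, `pos` and the score column.
#' @param windows window grid from [make_windows()].
#' @param column score column name (e.g. "ihs" or "xpehh").
#' @return numeric vector aligned with `windows` rows.
#' @export
window_mean_abs <- function(scores, windows, column) {
  out <- rep(NA_real_, nrow(windows))
  for (chrom in unique(windows$chrom)) {
    wi <- which(windows$chrom == chrom)
    sc <- scores[scores$chrom == chrom & is.finite(scores[[column]]), ,
                 drop = FALSE]
    if (nrow(sc) == 0) next
    ord <- order(sc$pos)
    pos <- sc$pos[ord]; val <- abs(sc[[column]][ord])
    tot <- .window_sums(val, pos, windows$start[wi], windows$end[wi])
    cnt <- .window_counts(pos, windows$start[wi], windows$end[wi])
    out[wi] <- ifelse(cnt > 0, tot / cnt, NA_real_)
  }
  out
}
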