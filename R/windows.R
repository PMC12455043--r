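# Sliding-window diversity and differentiation on phased haplotype panels.
# Denominators are accessible-site counts (monomorphic sites included), so
# pi and dXY are per-bp quantities comparable across windows.

#' Build a sliding-window grid
#'
#' Windows start at 0 and advance by `step`, truncating at the chromosome
#' end. A trailing partial window is emitted only when it is strictly longer
#' than the step; a chromosome shorter than one full window yields a single
#' window covering it.
#'
#' @param layout a [genome_layout()].
#' @param size window width in bp (default 50 kb).
#' @param step slide in bp (default 25 kb).
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `window_id`.
#' @export
make_windows <- function(layout, size = 50000, step = 25000) {
  if (step <= 0 || size <= 0) stop("window size and step must be positive")
  if (step > size) stop("window step must not exceed window size")
  out <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    starts <- seq(0, max(0, L - 1), by = step)
    ends <- pmin(starts + size, L)
    keep <- starts == 0 | (ends - starts) > step
    data.frame(chrom = layout$chrom[i], start = starts[keep],
               end = ends[keep], stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, out)
  win$window_id <- sprintf("%s:%d-%d", win$chrom, win$start, win$end)
  win
}

# Sum a per-site vector over [start, end) windows given sorted positions.
.window_sums <- function(values, pos, starts, ends) {
  cs <- c(0, cumsum(values))
  lo <- findInterval(starts - 0.5, pos) + 1L
  hi <- findInterval(ends - 0.5, pos)
  cs[hi + 1L] - cs[lo]
}

.window_counts <- function(pos, starts, ends, flag = NULL) {
  v <- if (is.null(flag)) rep(1, length(pos)) else as.numeric(flag)
  .window_sums(v, pos, starts, ends)
}

# Per-site summaries shared by the window statistics.
.site_summary <- function(panelA, panelB) {
  if (!identical(panelA$pos, panelB$pos)) {
    stop("panels must share the same site grid")
  }
  nA <- nrow(panelA$hap); nB <- nrow(panelB$hap)
  pA <- colMeans(panelA$hap); pB <- colMeans(panelB$hap)
  list(pos = panelA$pos, pA = pA, pB = pB, nA = nA, nB = nB,
       hetA = 2 * pA * (1 - pA) * nA / (nA - 1),
       hetB = 2 * pB * (1 - pB) * nB / (nB - 1),
       dxy = pA * (1 - pB) + pB * (1 - pA))
}

#' Per-window diversity and divergence
#'
#' Computes, for one window, nucleotide diversity per population
#' (\eqn{\pi = \sum 2\hat p(1-\hat p)\, n/(n-1) / n_{acc}}), absolute
#' divergence (\eqn{d_{XY} = \sum [p_A(1-p_B)+p_B(1-p_A)] / n_{acc}}) and
#' Hudson-style window FST (\eqn{1 - \bar\pi_{within}/d_{XY}}, `NA` when
#' \eqn{d_{XY} = 0}).
#'
#' @param panelA,panelB [haplotype_panel()]s on a shared site grid.
#' @param start,end window span, 0-based half-open.
#' @param n_accessible accessible-site denominator; defaults to the window
#'   span `end - start`.
#' @return list with `pi_A`, `pi_B`, `dxy`, `fst_hudson`, `n_variant`.
#' @export
window_diversity <- function(panelA, panelB, start, end,
                             n_accessible = end - start) {
  if (n_accessible <= 0) {
    return(list(pi_A = NA_real_, pi_B = NA_real_, dxy = NA_real_,
                fst_hudson = NA_real_, n_variant = 0L))
  }
  s <- .site_summary(panelA, panelB)
  in_win <- s$pos >= start & s$pos < end
  pi_A <- sum(s$hetA[in_win]) / n_accessible
  pi_B <- sum(s$hetB[in_win]) / n_accessible
  dxy <- sum(s$dxy[in_win]) / n_accessible
  fst <- if (dxy > 0) 1 - mean(c(pi_A, pi_B)) / dxy else NA_real_
  poly <- in_win & ((s$pA > 0 & s$pA < 1) | (s$pB > 0 & s$pB < 1) |
                      (s$pA != s$pB))
  list(pi_A = pi_A, pi_B = pi_B, dxy = dxy, fst_hudson = fst,
       n_variant = sum(poly))
}

#' Tajima's D coefficients
#'
#' Standard constants of Tajima's variance formula for `n` haplotypes.
#'
#' @param n haplotype count (>= 4).
#' @return named list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_coefficients <- function(n) {
  if (n < 4) stop("Tajima's D requires at least 4 haplotypes")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D in a window
#'
#' \eqn{D = (\hat\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} with \eqn{\hat\pi}
#' the mean number of pairwise differences among haplotypes in the window.
#' Returns `NA` when there are no segregating sites.
#'
#' @param panel a [haplotype_panel()].
#' @param start,end window span, 0-based half-open.
#' @return Tajima's D (scalar), `NA` if S = 0.
#' @export
tajimas_d <- function(panel, start, end) {
  n <- nrow(panel$hap)
  co <- tajima_coefficients(n)
  in_win <- panel$pos >= start & panel$pos < end
  cnt <- colSums(panel$hap[, in_win, drop = FALSE])
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  k_hat <- sum(cnt[seg] * (n - cnt[seg])) / choose(n, 2)
  (k_hat - S / co$a1) / sqrt(co$e1 * S + co$e2 * S * (S - 1))
}

#' Weir--Cockerham FST at a single locus
#'
#' Weir & Cockerham's (1984) \eqn{\theta} from the variance components
#' a (among populations), b (among individuals within populations) and
#' c (within individuals), for a biallelic locus in two or more populations
#' of diploids. May be negative; `NA` when a + b + c = 0 or when no
#' population has a genotyped individual.
#'
#' @param dosage_by_pop list (one element per population) of alt-allele
#'   dosage vectors (0, 1, 2; `NA` = missing) over individuals.
#' @return `theta` (scalar).
#' @export
wc_fst_site <- function(dosage_by_pop) {
  dosage_by_pop <- lapply(dosage_by_pop, function(d) d[!is.na(d)])
  n_i <- vapply(dosage_by_pop, length, numeric(1))
  if (any(n_i == 0)) return(NA_real_)
  r <- length(dosage_by_pop)
  if (r < 2) stop("at least two populations are required")
  p_i <- vapply(dosage_by_pop, function(d) mean(d) / 2, numeric(1))
  h_i <- vapply(dosage_by_pop, function(d) mean(d == 1), numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc <= 0) return(NA_real_)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  if (denom == 0) return(NA_real_)
  a / denom
}

#' Genome-wide window scan of the SNP statistics
#'
#' Runs [window_diversity()] and [tajimas_d()] over a window grid for a set
#' of per-chromosome panel pairs, vectorised with cumulative sums. Windows
#' whose accessible fraction falls below `min_accessible` are nulled.
#'
#' @param panels named list: for each chromosome, `list(A = panel, B =
#'   panel)` on a shared site grid.
#' @param windows window grid from [make_windows()].
#' @param accessible optional BED-like data frame (`chrom`, `start`, `end`)
#'   of accessible intervals; default: everything accessible.
#' @param tajima_population which population's panel feeds Tajima's D
#'   ("A" or "B", default "B").
#' @param min_accessible minimum accessible fraction per window (default
#'   0.1) below which statistics are `NA`.
#' @return `windows` with columns `n_accessible`, `n_variant`, `pi_A`,
#'   `pi_B`, `dxy`, `fst_hudson`, `tajima_d` appended.
#' @export
window_stats_scan <- function(panels, windows, accessible = NULL,
                              tajima_population = "B",
                              min_accessible = 0.1) {
  windows$n_accessible <- windows$end - windows$start
  if (!is.null(accessible)) {
    windows$n_accessible <- .accessible_overlap(windows, accessible)
  }
  cols <- c("n_variant", "pi_A", "pi_B", "dxy", "fst_hudson", "tajima_d")
  for (cl in cols) windows[[cl]] <- NA_real_
  for (chrom in unique(windows$chrom)) {
    wi <- which(windows$chrom == chrom)
    pp <- panels[[chrom]]
    if (is.null(pp)) next
    s <- .site_summary(pp$A, pp$B)
    st <- windows$start[wi]; en <- windows$end[wi]
    acc <- windows$n_accessible[wi]
    piA <- .window_sums(s$hetA, s$pos, st, en) / acc
    piB <- .window_sums(s$hetB, s$pos, st, en) / acc
    dxy <- .window_sums(s$dxy, s$pos, st, en) / acc
    poly <- (s$pA > 0 & s$pA < 1) | (s$pB > 0 & s$pB < 1) | (s$pA != s$pB)
    nvar <- .window_counts(s$pos, st, en, poly)
    fst <- ifelse(dxy > 0, 1 - (piA + piB) / 2 / dxy, NA_real_)
    tp <- if (tajima_population == "B") pp$B else pp$A
    n <- nrow(tp$hap)
    co <- tajima_coefficients(n)
    cntT <- colMeans(tp$hap) * n
    segT <- cntT > 0 & cntT < n
    Sw <- .window_counts(tp$pos, st, en, segT)
    kw <- .window_sums(ifelse(segT, cntT * (n - cntT), 0), tp$pos, st, en) /
      choose(n, 2)
    taj <- ifelse(Sw > 0,
                  (kw - Sw / co$a1) / sqrt(co$e1 * Sw + co$e2 * Sw * (Sw - 1)),
                  NA_real_)
    windows$pi_A[wi] <- piA; windows$pi_B[wi] <- piB
    windows$dxy[wi] <- dxy; windows$fst_hudson[wi] <- fst
    windows$tajima_d[wi] <- taj; windows$n_variant[wi] <- nvar
  }
  low <- windows$n_accessible < min_accessible * (windows$end - windows$start)
  if (any(low)) {
    windows[low, cols] <- NA_real_
    message(sum(low), " windows nulled for low accessible fraction")
  }
  windows
}

.accessible_overlap <- function(windows, accessible) {
  vapply(seq_len(nrow(windows)), function(i) {
    m <- accessible[accessible$chrom == windows$chrom[i], , drop = FALSE]
    if (nrow(m) == 0) return(0)
    sum(pmax(0, pmin(m$end, windows$end[i]) - pmax(m$start, windows$start[i])))
  }, numeric(1))
}
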