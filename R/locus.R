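# Per-locus differentiation scans. Both tracks share the same outlier
# machinery: the per-locus statistic is fitted to a normal distribution by
# maximum likelihood, upper-tail p-values are BH-adjusted, and loci at
# q < 0.05 are flagged. The normal null mirrors the fitdistr/q-value lineage
# and is deliberately literal: a skewness/kurtosis diagnostic is reported
# instead of substituting a different null for these bounded statistics.

#' STR call-rate and MAF prefilter
#'
#' Keeps loci genotyped in every sample whose minor allele frequency
#' exceeds `maf_min`. For multi-allelic loci the MAF is one minus the
#' frequency of the most common allele.
#'
#' @param strs an [str_set()].
#' @param maf_min minimum minor allele frequency (default 0.1, exclusive).
#' @return filtered [str_set()] with attribute `kept` (logical over input
#'   loci).
#' @export
str_prefilter <- function(strs, maf_min = 0.1) {
  n_loci <- length(strs$id)
  keep <- logical(n_loci)
  for (j in seq_len(n_loci)) {
    al <- c(strs$a1[, j], strs$a2[, j])
    if (anyNA(al)) next
    tab <- table(al)
    maf <- 1 - max(tab) / sum(tab)
    keep[j] <- maf > maf_min && length(tab) >= 2
  }
  out <- subset_loci(strs, keep)
  attr(out, "kept") <- keep
  out
}

#' Jost's D at a single multi-allelic locus
#'
#' Differentiation in terms of effective allele numbers (Jost 2008), with
#' Nei--Chesson small-sample corrections: \eqn{H_S} is the mean
#' within-population expected heterozygosity, \eqn{H_T} the total expected
#' heterozygosity at the unweighted mean frequencies,
#' \eqn{\hat H_S = \frac{2\tilde n}{2\tilde n - 1} H_S},
#' \eqn{\hat H_T = H_T + \frac{\hat H_S}{2\tilde n k}} and
#' \eqn{D = \frac{\hat H_T - \hat H_S}{1 - \hat H_S}\cdot\frac{k}{k-1}},
#' with \eqn{\tilde n} the harmonic mean of the per-population diploid
#' sample sizes and k the number of populations. The uncorrected
#' (parametric) variant replaces the estimators by \eqn{H_S, H_T}.
#'
#' @param alleles_by_pop list (per population) of allele vectors (2 entries
#'   per genotyped diploid; `NA` dropped).
#' @return list with `Hs`, `Ht`, `Hs_est`, `Ht_est`, `n_harmonic`, `k`,
#'   `D` (bias-corrected) and `D_param`; `D` is `NA` when
#'   \eqn{\hat H_S = 1}.
#' @export
josts_d <- function(alleles_by_pop) {
  alleles_by_pop <- lapply(alleles_by_pop, function(a) a[!is.na(a)])
  k <- length(alleles_by_pop)
  if (k < 2) stop("at least two populations are required")
  n_dip <- vapply(alleles_by_pop, length, numeric(1)) / 2
  if (any(n_dip < 1)) stop("each population needs a genotyped diploid")
  all_alleles <- sort(unique(unlist(alleles_by_pop)))
  freq <- vapply(alleles_by_pop, function(a) {
    as.numeric(table(factor(a, levels = all_alleles)) / length(a))
  }, numeric(length(all_alleles)))
  Hs <- mean(1 - colSums(freq^2))
  pbar <- rowMeans(freq)
  Ht <- 1 - sum(pbar^2)
  n_harm <- k / sum(1 / n_dip)
  Hs_est <- (2 * n_harm / (2 * n_harm - 1)) * Hs
  Ht_est <- Ht + Hs_est / (2 * n_harm * k)
  D <- if (Hs_est >= 1) NA_real_ else
    ((Ht_est - Hs_est) / (1 - Hs_est)) * k / (k - 1)
  D_param <- if (Hs >= 1) NA_real_ else ((Ht - Hs) / (1 - Hs)) * k / (k - 1)
  list(Hs = Hs, Ht = Ht, Hs_est = Hs_est, Ht_est = Ht_est,
       n_harmonic = n_harm, k = k, D = D, D_param = D_param)
}

#' Normal-fit outlier scan over per-locus statistics
#'
#' Fits Normal(mu, sigma) by maximum likelihood (sample mean, ML standard
#' deviation), converts each value to an upper-tail probability, adjusts by
#' BH, and flags loci with q below `q_max`. A skewness/excess-kurtosis
#' diagnostic of the input distribution is reported via `message()` since a
#' normal null on a bounded statistic can misbehave for heavy tails.
#'
#' @param values per-locus statistic (`NA` allowed; >= 30 non-null values
#'   required).
#' @param q_max outlier threshold on q (default 0.05).
#' @param two_tailed use two-tailed p-values (default FALSE: only high
#'   differentiation is an outlier).
#' @return data frame with `value`, `p`, `q`, `outlier` aligned with the
#'   input; attributes `mu` and `sigma`.
#' @export
normal_fit_outlier_scan <- function(values, q_max = 0.05,
                                    two_tailed = FALSE) {
  ok <- is.finite(values)
  if (sum(ok) < 30) stop("need at least 30 loci for the normal fit")
  x <- values[ok]
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("degenerate statistic distribution (zero variance)")
  z <- (x - mu) / sigma
  skw <- mean(z^3); kur <- mean(z^4) - 3
  message(sprintf("normal fit: mu=%.4g sigma=%.4g skewness=%.2f kurtosis=%.2f",
                  mu, sigma, skw, kur))
  p <- rep(NA_real_, length(values))
  p[ok] <- if (two_tailed) 2 * pnorm(abs(z), lower.tail = FALSE) else
    pnorm(z, lower.tail = FALSE)
  q <- bh_qvalues(p)
  data.frame(value = values, p = p, q = q,
             outlier = !is.na(q) & q < q_max) |>
    structure(mu = mu, sigma = sigma)
}

# Alt-allele dosage matrix (sample x locus) from paired allele matrices.
.dosage <- function(x) {
  d <- x$a1 + x$a2
  d[is.na(x$a1) | is.na(x$a2)] <- NA
  d
}

#' SV outlier scan
#'
#' Weir--Cockerham \eqn{\theta} per biallelic SV between the two scan
#' populations, fed through [normal_fit_outlier_scan()]. SVs with more than
#' `max_missing` missing genotypes are excluded. Fixed differences (one
#' population entirely homozygous reference, the other entirely homozygous
#' alternate, no missing calls) are reported separately.
#'
#' @param svs an [sv_set()].
#' @param popmap a [population_map()]; scans use its two scan populations.
#' @param q_max outlier threshold (default 0.05).
#' @param max_missing per-locus missing-genotype ceiling (default 0.2).
#' @return data frame with locus metadata plus `value` (theta), `p`, `q`,
#'   `outlier`, `fixed_difference`; excluded loci keep `NA` statistics.
#' @export
sv_scan <- function(svs, popmap, q_max = 0.05, max_missing = 0.2) {
  svs <- subset_samples(svs, unlist(lapply(popmap$scan_pops, pop_samples,
                                           popmap = popmap)))
  dos <- .dosage(svs)
  popA <- svs$sample %in% pop_samples(popmap, popmap$scan_pops[1])
  popB <- svs$sample %in% pop_samples(popmap, popmap$scan_pops[2])
  n_loci <- length(svs$id)
  theta <- rep(NA_real_, n_loci)
  fixed <- logical(n_loci)
  miss_frac <- colMeans(is.na(dos))
  for (j in seq_len(n_loci)) {
    if (miss_frac[j] > max_missing) next
    dA <- dos[popA, j]; dB <- dos[popB, j]
    theta[j] <- wc_fst_site(list(dA, dB))
    fixed[j] <- !anyNA(c(dA, dB)) &&
      ((all(dA == 0) && all(dB == 2)) || (all(dA == 2) && all(dB == 0)))
  }
  if (any(miss_frac > max_missing)) {
    message(sum(miss_frac > max_missing),
            " SVs excluded for missingness > ", max_missing)
  }
  scan <- normal_fit_outlier_scan(theta, q_max = q_max)
  out <- data.frame(id = svs$id, chrom = svs$chrom, start = svs$start,
                    end = svs$end, svtype = svs$svtype,
                    length = svs$length, value = scan$value, p = scan$p,
                    q = scan$q, outlier = scan$outlier,
                    fixed_difference = fixed, stringsAsFactors = FALSE)
  structure(out, mu = attr(scan, "mu"), sigma = attr(scan, "sigma"))
}

#' STR outlier scan
#'
#' Applies [str_prefilter()], computes bias-corrected Jost's D per
#' remaining locus between the two scan populations, and calls outliers via
#' [normal_fit_outlier_scan()].
#'
#' @param strs an [str_set()].
#' @param popmap a [population_map()].
#' @param maf_min prefilter MAF threshold (default 0.1).
#' @param q_max outlier threshold (default 0.05).
#' @return data frame with locus metadata plus `value` (Jost's D), `p`,
#'   `q`, `outlier`; attribute `kept` maps back to the input loci.
#' @export
str_scan <- function(strs, popmap, maf_min = 0.1, q_max = 0.05) {
  strs <- subset_samples(strs, unlist(lapply(popmap$scan_pops, pop_samples,
                                             popmap = popmap)))
  filt <- str_prefilter(strs, maf_min = maf_min)
  popA <- filt$sample %in% pop_samples(popmap, popmap$scan_pops[1])
  popB <- filt$sample %in% pop_samples(popmap, popmap$scan_pops[2])
  n_loci <- length(filt$id)
  if (n_loci == 0) stop("no STRs survive the prefilter")
  d <- vapply(seq_len(n_loci), function(j) {
    josts_d(list(c(filt$a1[popA, j], filt$a2[popA, j]),
                 c(filt$a1[popB, j], filt$a2[popB, j])))$D
  }, numeric(1))
  scan <- normal_fit_outlier_scan(d, q_max = q_max)
  out <- data.frame(id = filt$id, chrom = filt$chrom, pos = filt$pos,
                    period = filt$period, value = scan$value, p = scan$p,
                    q = scan$q, outlier = scan$outlier,
                    stringsAsFactors = FALSE)
  structure(out, kept = attr(filt, "kept"), mu = attr(scan, "mu"),
            sigma = attr(scan, "sigma"))
}
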