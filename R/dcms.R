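# Decorrelated composite of multiple signals (DCMS): per-statistic empirical
# p-values are combined as a weighted sum of log((1-p)/p), with weights that
# damp the contribution of mutually correlated statistics. Significance comes
# from a robust-normal model of the composite, FDR from BH q-values, and
# significant windows are merged into supported outlier regions.

#' Rank-based empirical p-values
#'
#' One-tailed empirical probability p = r/(n+1), where r is the number of
#' non-null values as or more extreme than the value in the configured tail.
#' `NA` values are excluded from the ranking and returned as `NA`.
#'
#' @param values numeric vector of per-window statistic values.
#' @param tail "upper" (large values extreme) or "lower".
#' @return numeric vector of p-values in (0, 1), same length as `values`.
#' @export
empirical_pvalues <- function(values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("need at least 2 non-null values")
  x <- values[ok]
  if (length(unique(x)) == 1) {
    warning("all values identical; empirical p-values set to 0.5")
    p <- rep(NA_real_, length(values)); p[ok] <- 0.5
    return(p)
  }
  n <- length(x)
  # tie-aware count of values as-or-more extreme in the tail
  r <- if (tail == "upper") {
    n - rank(x, ties.method = "min") + 1
  } else {
    rank(x, ties.method = "max")
  }
  p <- rep(NA_real_, length(values))
  p[ok] <- r / (n + 1)
  p
}

#' DCMS scores from a p-value matrix
#'
#' \eqn{DCMS_j = \sum_i w_i \ln((1-p_{ij})/p_{ij})} with weights
#' \eqn{w_i = 1/\sum_k |r_{ik}|}, where r is the Pearson correlation matrix
#' of the p-value columns over complete windows. Windows with some (not all)
#' missing statistics are scored on the available statistics with the total
#' weight renormalised; fully missing windows get `NA`.
#'
#' @param p matrix (windows x statistics) of p-values in (0, 1); `NA`
#'   allowed.
#' @return list with `dcms` (per-window score), `weights`, `correlation`,
#'   and `n_partial` (count of partially-scored windows).
#' @export
dcms_scores <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) < 1) stop("at least one statistic is required")
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    stop("p-values must lie strictly inside (0, 1)")
  }
  complete <- complete.cases(p)
  if (ncol(p) == 1) {
    r <- matrix(1, 1, 1)
  } else {
    if (sum(complete) < 3) stop("too few complete windows for correlation")
    r <- suppressWarnings(cor(p[complete, , drop = FALSE]))
    const <- apply(p[complete, , drop = FALSE], 2, function(x) sd(x) == 0)
    if (any(const) || anyNA(r)) {
      warning("constant statistic column; its correlations set to 0")
      r[is.na(r)] <- 0
      diag(r) <- 1
    }
  }
  w <- 1 / rowSums(abs(r))
  terms <- log((1 - p) / p)
  wterm <- sweep(terms, 2, w, `*`)
  avail <- !is.na(p)
  w_avail <- avail %*% w
  total_w <- sum(w)
  dcms <- ifelse(w_avail > 0,
                 rowSums(wterm, na.rm = TRUE) * total_w / w_avail,
                 NA_real_)
  n_partial <- sum(w_avail > 0 & w_avail < total_w)
  if (n_partial > 0) {
    message(n_partial, " windows scored on a renormalised statistic subset")
  }
  list(dcms = as.numeric(dcms), weights = w, correlation = r,
       n_partial = n_partial)
}

#' Robust-normal upper-tail p-values for DCMS scores
#'
#' Location is the Huber M-estimate (tuning constant 1.345) of an
#' intercept-only model; scale is 1.4826 times the median absolute
#' deviation. p-values are upper-tail normal probabilities of the
#' standardised scores.
#'
#' @param dcms numeric vector of DCMS scores (`NA` allowed; >= 30 non-null
#'   values required).
#' @return list with `p` (aligned with input), `location`, `scale`.
#' @export
robust_tail_pvalues <- function(dcms) {
  ok <- is.finite(dcms)
  if (sum(ok) < 30) stop("need at least 30 windows for the robust fit")
  x <- dcms[ok]
  s <- mad(x)
  if (s == 0) stop("degenerate score distribution (MAD = 0)")
  fit <- MASS::huber(x, k = 1.345)
  p <- rep(NA_real_, length(dcms))
  p[ok] <- pnorm(x, mean = fit$mu, sd = fit$s, lower.tail = FALSE)
  list(p = p, location = fit$mu, scale = fit$s)
}

#' Benjamini--Hochberg q-values
#'
#' Step-up FDR adjustment \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j},
#' clipped at 1, mapped back to input order. `NA`s are passed through.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Merge significant windows into outlier regions
#'
#' Windows with q below `q_max` are merged when overlapping or directly
#' adjacent; each region's support is the number of member windows. Regions
#' below `min_support` are excluded from the supported set but retained in
#' the full listing.
#'
#' @param windows window grid (columns `chrom`, `start`, `end`,
#'   `window_id`).
#' @param q q-values aligned with `windows` rows.
#' @param q_max significance threshold (default 0.05).
#' @param min_support minimum member-window count (default 2).
#' @return list with data frames `supported` and `all` (columns `chrom`,
#'   `start`, `end`, `support`, `members`).
#' @export
merge_outlier_regions <- function(windows, q, q_max = 0.05,
                                  min_support = 2) {
  sig <- which(!is.na(q) & q < q_max)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), support = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (length(sig) == 0) return(list(supported = empty, all = empty))
  w <- windows[sig, , drop = FALSE]
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  regions <- list()
  cur <- w[1, ]
  members <- cur$window_id
  for (i in seq_len(nrow(w))[-1]) {
    if (w$chrom[i] == cur$chrom && w$start[i] <= cur$end) {
      cur$end <- max(cur$end, w$end[i])
      members <- c(members, w$window_id[i])
    } else {
      regions[[length(regions) + 1]] <-
        data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
                   support = length(members),
                   members = paste(members, collapse = ","),
                   stringsAsFactors = FALSE)
      cur <- w[i, ]
      members <- cur$window_id
    }
  }
  regions[[length(regions) + 1]] <-
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               support = length(members),
               members = paste(members, collapse = ","),
               stringsAsFactors = FALSE)
  all_regions <- do.call(rbind, regions)
  list(supported = all_regions[all_regions$support >= min_support, ,
                               drop = FALSE],
       all = all_regions)
}

#' Full DCMS table from window statistics
#'
#' Convenience wrapper: builds per-statistic empirical p-values with the
#' selection-oriented tails (pi lower, Tajima's D lower, FST upper,
#' mean |iHS| upper, mean |xpEHH| upper), computes DCMS scores, the
#' robust-normal p-values and BH q-values.
#'
#' @param stats window statistics table from the pipeline, with columns
#'   `pi_B` (scan population's diversity), `tajima_d`, `fst_hudson`,
#'   `mean_abs_ihs`, `mean_abs_xpehh`.
#' @param tails named character vector overriding the default tails.
#' @return `stats` with columns `dcms`, `p_dcms`, `q_dcms` appended, plus
#'   attributes `weights` and `correlation`.
#' @export
dcms_table <- function(stats, tails = NULL) {
  default_tails <- c(pi_B = "lower", tajima_d = "lower",
                     fst_hudson = "upper", mean_abs_ihs = "upper",
                     mean_abs_xpehh = "upper")
  if (!is.null(tails)) default_tails[names(tails)] <- tails
  use <- intersect(names(default_tails), names(stats))
  if (length(use) == 0) stop("no statistic columns found")
  p <- vapply(use, function(cl) {
    empirical_pvalues(stats[[cl]], tail = default_tails[[cl]])
  }, numeric(nrow(stats)))
  sc <- dcms_scores(p)
  rp <- robust_tail_pvalues(sc$dcms)
  stats$dcms <- sc$dcms
  stats$p_dcms <- rp$p
  stats$q_dcms <- bh_qvalues(rp$p)
  attr(stats, "weights") <- sc$weights
  attr(stats, "correlation") <- sc$correlation
  stats
}
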