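# Statistics over detected structures: Spearman correlation with two-sided
# significance, OLS fits with 95% confidence bands, sign discordance of
# fold-change pairs, rank-sum group comparison, Benjamini-Hochberg
# adjustment, the Tau tissue-specificity index, and scale-adjusted /
# anchored signal metaprofiles.

#' Spearman rank correlation with two-sided p value
#'
#' rho is computed from average ranks. The p value is exact (permutation
#' distribution) for n <= 10 without ties and uses the t approximation
#' otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite.
#' @return list: rho, p, n. A constant vector yields `rho = NA` with a
#'   warning.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_cor: lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("spearman_cor: need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("spearman_cor: constant input, rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    p <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(1, p), n = n)
}

#' Ordinary least-squares fit with 95% confidence band
#'
#' @param x,y numeric vectors, n >= 3; `x` must be non-constant.
#' @param conf confidence level of the pointwise mean-response band.
#' @return list: slope, intercept, model (the `lm` fit), band (data.table
#'   x, fit, lwr, upr at sorted unique x).
#' @export
linear_fit <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("linear_fit: lengths differ")
  if (length(x) < 3) stop("linear_fit: need at least 3 points")
  if (sd(x) == 0) stop("linear_fit: constant x")
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  xs <- sort(unique(x))
  pr <- predict(fit, newdata = data.frame(x = xs), interval = "confidence",
                level = conf)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       model = fit,
       band = data.table(x = xs, fit = pr[, "fit"], lwr = pr[, "lwr"],
                         upr = pr[, "upr"]))
}

#' Fraction of fold-change pairs with discordant signs
#'
#' The fraction of pairs where the two log2 fold changes have strictly
#' opposite signs; pairs containing a zero count as concordant.
#'
#' @param a,b numeric vectors of log2 fold changes (equal length, n >= 1).
#' @return fraction in `[0, 1]`.
#' @export
sign_discordance <- function(a, b) {
  if (length(a) != length(b)) stop("sign_discordance: lengths differ")
  if (length(a) == 0) stop("sign_discordance: empty input")
  mean(a * b < 0)
}

#' Rank-sum comparison of two groups
#'
#' Mann-Whitney U with normal approximation and tie correction
#' (two-sided).
#'
#' @param values_a,values_b numeric vectors, both non-empty.
#' @return list: statistic (U for the first group), p, n_a, n_b.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("compare_groups: empty group")
  wt <- suppressWarnings(wilcox.test(values_a, values_b, exact = FALSE,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_a = length(values_a), n_b = length(values_b))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement.
#'
#' @param pvalues numeric vector of p values in `[0, 1]`.
#' @return adjusted q values (same order as input).
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("bh_adjust: p values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Tau tissue-specificity index
#'
#' `tau = sum_i (1 - x_i / max(x)) / (n - 1)`: 0 for uniform expression
#' across tissues, 1 for single-tissue expression.
#'
#' @param x non-negative expression values across n >= 2 tissues.
#' @return tau in `[0, 1]`; `NA` with a warning when `max(x) == 0`.
#' @export
tau_index <- function(x) {
  if (length(x) < 2) stop("tau_index: need at least 2 tissues")
  if (any(!is.finite(x)) || any(x < 0)) stop("tau_index: values must be finite and non-negative")
  mx <- max(x)
  if (mx == 0) {
    warning("tau_index: all-zero expression, tau undefined")
    return(NA_real_)
  }
  sum(1 - x / mx) / (length(x) - 1)
}

# Per-base signal vector over [start, end) for a region, 5'->3' orientation
# (reversed for minus-strand regions).
.region_values <- function(track, ch, start, end, str) {
  len <- end - start
  v <- numeric(len)
  if (is(track, "coverage_track")) {
    runs <- track$runs[chrom == ch & strand == str]
    if (nrow(runs)) {
      for (i in seq_len(nrow(runs))) {
        lo <- max(runs$start[i], start); hi <- min(runs$end[i], end)
        if (hi > lo) v[(lo - start + 1):(hi - start)] <- v[(lo - start + 1):(hi - start)] + runs$depth[i]
      }
    }
  } else if (is(track, "end_track")) {
    cnt <- track$counts[chrom == ch & strand == str & pos >= start & pos < end]
    if (nrow(cnt)) v[cnt$pos - start + 1] <- cnt$count
  } else stop("metaprofile: unsupported track")
  if (str == "-") rev(v) else v
}

#' Signal metaprofile over regions
#'
#' `scaled` mode rescales every region to `n_bins` equal fractions (so
#' anchors align across loci of different lengths); `anchored` mode uses a
#' fixed window of `flank` bp on both sides of each region's 5' anchor.
#' Minus-strand regions are reversed so bin 1 is always the 5' anchor;
#' regions shorter than the bin count contribute by fractional overlap.
#'
#' @param regions data.frame with chrom, start, end, strand.
#' @param track [coverage_track()] or [end_track()].
#' @param n_bins number of bins (>= 1).
#' @param mode `"scaled"` or `"anchored"`.
#' @param flank half-window in bp for anchored mode.
#' @return numeric vector of per-bin signal, averaged across regions with
#'   equal weight per region.
#' @export
metaprofile <- function(regions, track, n_bins = 100L,
                        mode = c("scaled", "anchored"), flank = 1000L) {
  mode <- match.arg(mode)
  regions <- as.data.table(regions)
  if (nrow(regions) == 0) stop("metaprofile: no regions")
  if (n_bins < 1) stop("metaprofile: n_bins must be >= 1")
  prof <- matrix(0, nrow(regions), n_bins)
  for (i in seq_len(nrow(regions))) {
    if (mode == "scaled") {
      s <- regions$start[i]; e <- regions$end[i]
    } else {
      anchor <- if (regions$strand[i] == "+") regions$start[i] else regions$end[i] - 1L
      s <- anchor - flank; e <- anchor + flank + 1L
    }
    v <- .region_values(track, regions$chrom[i], s, e, regions$strand[i])
    prof[i, ] <- .bin_mean(v, n_bins)
  }
  colMeans(prof)
}

# Mean of v within n equal fractional bins (length(v) need not be a
# multiple of n; bases are split across bins by fractional overlap).
.bin_mean <- function(v, n) {
  L <- length(v)
  out <- numeric(n)
  w <- L / n
  for (j in seq_len(n)) {
    lo <- (j - 1) * w; hi <- j * w
    b0 <- floor(lo); b1 <- ceiling(hi) - 1
    tot <- 0
    for (b in b0:b1) {
      if (b < 0 || b >= L) next
      frac <- min(hi, b + 1) - max(lo, b)
      if (frac > 0) tot <- tot + v[b + 1] * frac
    }
    out[j] <- tot / w
  }
  out
}

#' Correlation report for fold-change pairs, optionally by group
#'
#' Computes for each group (or overall): n, Spearman rho and two-sided p,
#' OLS slope and intercept, and the sign-discordance fraction.
#'
#' @param lfc_a,lfc_b numeric vectors of log2 fold changes.
#' @param groups optional factor/vector of group labels.
#' @return data.table, one row per group plus an `all` row.
#' @export
correlation_report <- function(lfc_a, lfc_b, groups = NULL) {
  one <- function(a, b, label) {
    sp <- tryCatch(spearman_cor(a, b),
                   warning = function(w) list(rho = NA_real_, p = NA_real_, n = length(a)),
                   error = function(e) list(rho = NA_real_, p = NA_real_, n = length(a)))
    lf <- tryCatch(linear_fit(a, b), error = function(e) NULL)
    data.table(group = label, n = length(a), rho = sp$rho, p = sp$p,
               slope = if (is.null(lf)) NA_real_ else lf$slope,
               intercept = if (is.null(lf)) NA_real_ else lf$intercept,
               sign_discordance = sign_discordance(a, b))
  }
  out <- list(one(lfc_a, lfc_b, "all"))
  if (!is.null(groups)) {
    for (g in levels(factor(groups))) {
      sel <- groups == g
      if (sum(sel) >= 3) out[[length(out) + 1]] <- one(lfc_a[sel], lfc_b[sel], g)
    }
  }
  rbindlist(out)
}
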