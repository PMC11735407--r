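# Per-sample end-tag counting in features, median-of-ratios normalization
# and pseudocounted log2 fold changes between conditions. This is a
# deliberately simple differential layer: the downstream co-regulation
# analyses consume log2FC values only, so no per-feature dispersion model
# or Wald testing is attempted.

#' Count end-tags in features for one sample
#'
#' Counts tags whose position lies within `[start, end)` on the feature
#' strand. Features overlapping on the same strand are counted
#' independently (no double-count correction).
#'
#' @param track an [end_track()].
#' @param features data.frame with columns chrom, start, end, strand (and
#'   optionally feature_id).
#' @return numeric vector of counts, one per feature row.
#' @export
count_in_features <- function(track, features) {
  ft <- as.data.table(features)[, .(chrom = as.character(chrom),
                                    start = as.integer(start), end = as.integer(end),
                                    strand = as.character(strand))]
  ft[, fid := .I]
  n <- nrow(ft)
  if (n == 0) return(numeric(0))
  cnt <- track$counts
  if (nrow(cnt) == 0) return(numeric(n))
  x <- cnt[, .(chrom, strand, start = pos, end = pos + 1L, count)]
  setkey(ft, chrom, strand, start, end)
  setkey(x, NULL)
  ov <- foverlaps(x, ft, by.x = c("chrom", "strand", "start", "end"),
                  type = "within", nomatch = NULL)
  res <- numeric(n)
  if (nrow(ov)) {
    agg <- ov[, .(count = sum(as.numeric(count))), by = fid]
    res[agg$fid] <- agg$count
  }
  res
}

#' Build a count matrix over features and samples
#'
#' @param tracks named list of [end_track()] objects (one per sample).
#' @param features data.frame with chrom, start, end, strand and
#'   feature_id columns.
#' @param samples data.frame with sample_id, condition (and optionally
#'   replicate); `sample_id` must match `names(tracks)`.
#' @return object of class `count_matrix`: list with `counts`
#'   (features x samples matrix), `features`, `samples`, `size_factors`
#'   (filled by [size_factors()], initially NULL).
#' @export
count_matrix <- function(tracks, features, samples) {
  features <- as.data.table(features)
  samples <- as.data.table(samples)
  if (!all(samples$sample_id %in% names(tracks)))
    stop("count_matrix: missing tracks for some samples")
  m <- vapply(samples$sample_id,
              function(s) count_in_features(tracks[[s]], features),
              numeric(nrow(features)))
  m <- matrix(m, nrow = nrow(features), ncol = nrow(samples),
              dimnames = list(features$feature_id, samples$sample_id))
  structure(list(counts = m, features = features, samples = samples,
                 size_factors = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (with
#' all-positive rows) of the ratio of the count to the feature's geometric
#' mean across samples. When no feature row is positive in every sample,
#' falls back to total-count scaling (normalized to geometric mean 1) with
#' a warning.
#'
#' @param x a `count_matrix` or a numeric count matrix (features x samples).
#' @return numeric vector of per-sample size factors.
#' @export
size_factors <- function(x) {
  m <- if (is(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(m) == 1) return(setNames(1, colnames(m)))
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    warning("size_factors: no feature positive in all samples; using total-count scaling")
    tot <- colSums(m)
    sf <- tot / exp(mean(log(tot)))
    return(sf)
  }
  mp <- m[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(mp)))
  apply(mp, 2, function(col) median(col / geo))
}

#' Pseudocounted log2 fold changes between two conditions
#'
#' Counts are normalized by the size factors; the fold change is
#' `log2((mean normalized treated + eps) / (mean normalized control + eps))`
#' and `base_mean` is the mean normalized count across all samples.
#'
#' @param cm a `count_matrix`.
#' @param treated,control condition labels in `cm$samples$condition`.
#' @param pseudocount eps added to both normalized means.
#' @param sf optional precomputed size factors (defaults to
#'   [size_factors()]).
#' @return data.table: feature_id, base_mean, log2fc.
#' @export
log2fc <- function(cm, treated = "treated", control = "control",
                   pseudocount = 1, sf = NULL) {
  stopifnot(is(cm, "count_matrix"))
  cond <- cm$samples$condition
  if (!treated %in% cond) stop("log2fc: condition not present: ", treated)
  if (!control %in% cond) stop("log2fc: condition not present: ", control)
  if (is.null(sf)) sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2, sf, `/`)
  mt <- rowMeans(norm[, cond == treated, drop = FALSE])
  mc <- rowMeans(norm[, cond == control, drop = FALSE])
  data.table(feature_id = as.character(cm$features$feature_id),
             base_mean = rowMeans(norm),
             log2fc = log2((mt + pseudocount) / (mc + pseudocount)))
}

#' Rank-based tertile labels
#'
#' Splits values into three equal-count groups by rank; ties are assigned
#' to the lower group (so an all-equal vector is entirely "low").
#'
#' @param values numeric vector, length at least 3.
#' @return factor with ordered levels low < medium < high.
#' @export
tertiles <- function(values) {
  n <- length(values)
  if (n < 3) stop("tertiles: need at least 3 values")
  r <- rank(values, ties.method = "min")
  g <- pmin(floor(3 * (r - 1) / n), 2)
  factor(c("low", "medium", "high")[g + 1],
         levels = c("low", "medium", "high"), ordered = TRUE)
}
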