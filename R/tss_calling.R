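# Strand-specific peak calling on end-count tracks, peak merging, and
# summit (CTSS/QTTS) localisation by local maxima. The seed/extend rule is
# a reproducible, parameter-exposed caller: a position seeds a peak when its
# pooled count passes both a fixed count floor and a Poisson upper-tail test
# against the genome-wide background rate; peaks extend over contiguous
# signal tolerating short internal zero gaps.

#' Peak-calling parameters
#'
#' @param min_seed_count minimum pooled tag count for a seed position (tags).
#' @param max_internal_gap bp of zero signal tolerated inside a peak.
#' @param merge_gap peaks closer than this (bp, inclusive) are merged.
#' @param background_alpha Poisson upper-tail probability bound for seeds;
#'   the rate is the genome-wide mean pooled count per bp.
#' @return list of class `peak_params`.
#' @export
peak_params <- function(min_seed_count = 5L, max_internal_gap = 10L,
                        merge_gap = 50L, background_alpha = 1e-3) {
  stopifnot(min_seed_count >= 0, max_internal_gap >= 0, merge_gap >= 0,
            background_alpha > 0, background_alpha <= 1)
  structure(list(min_seed_count = as.integer(min_seed_count),
                 max_internal_gap = as.integer(max_internal_gap),
                 merge_gap = as.integer(merge_gap),
                 background_alpha = background_alpha),
            class = "peak_params")
}

# Pool a list of end_track objects (same strand and signal kind) into one
# sparse counts table.
.pool_end_tracks <- function(tracks) {
  if (length(tracks) == 0) stop("call_end_peaks: empty track set")
  if (is(tracks, "end_track")) tracks <- list(tracks)
  kinds <- unique(vapply(tracks, function(t) t$signal_kind, character(1)))
  if (length(kinds) != 1) stop("call_end_peaks: mixed signal kinds")
  pooled <- rbindlist(lapply(tracks, function(t) t$counts))
  if (nrow(pooled)) pooled <- pooled[, .(count = sum(count)), by = .(chrom, strand, pos)]
  setkey(pooled, chrom, strand, pos)
  pooled
}

#' Call end-count peaks on one strand
#'
#' Tracks are pooled across samples; any position whose pooled count is at
#' least `min_seed_count` and whose Poisson upper-tail probability under the
#' genome-wide mean rate is at most `background_alpha` seeds a peak. Peaks
#' extend over runs of nonzero signal allowing internal zero gaps of at most
#' `max_internal_gap` bp. Output peaks are sorted and disjoint.
#'
#' @param tracks an `end_track` or list of `end_track`s (same signal kind);
#'   all counts must lie on a single strand.
#' @param params [peak_params()].
#' @param genome_size total genome length in bp used for the background
#'   rate; defaults to the span covered by the pooled track
#'   (`sum over chroms of (max position + 1)`).
#' @return data.table of peaks: chrom, start, end, strand, pooled_count,
#'   summit_pos, summit_count. Class `peaks`.
#' @export
call_end_peaks <- function(tracks, params = peak_params(), genome_size = NULL) {
  pooled <- .pool_end_tracks(tracks)
  if (nrow(pooled) == 0) return(.empty_peaks())
  if (length(unique(pooled$strand)) > 1) stop("call_end_peaks: mixed strands in input")
  if (is.null(genome_size))
    genome_size <- sum(pooled[, .(len = max(pos) + 1), by = chrom]$len)
  lambda <- sum(as.numeric(pooled$count)) / genome_size
  setkey(pooled, chrom, strand, pos)  # sorted within each group
  res <- pooled[, .self_call_islands(pos, count, params, lambda),
                by = .(chrom, strand)]
  if (nrow(res) == 0) return(.empty_peaks())
  setcolorder(res, c("chrom", "start", "end", "strand", "pooled_count",
                     "summit_pos", "summit_count"))
  setorder(res, chrom, start)
  res[]
}

.empty_peaks <- function() {
  data.table(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), pooled_count = numeric(0),
             summit_pos = integer(0), summit_count = numeric(0))
}

# Islands of nonzero positions with inter-position zero gaps <= max gap;
# keep islands containing a seed. pos must be sorted.
.self_call_islands <- function(pos, count, params, lambda) {
  gapped <- c(TRUE, diff(pos) - 1L > params$max_internal_gap)
  island <- cumsum(gapped)
  seed <- count >= params$min_seed_count &
    ppois(count - 1, lambda, lower.tail = FALSE) <= params$background_alpha
  keep <- unique(island[seed])
  if (length(keep) == 0)
    return(list(start = integer(0), end = integer(0), pooled_count = numeric(0),
                summit_pos = integer(0), summit_count = numeric(0)))
  idx <- island %in% keep
  pos <- pos[idx]; count <- count[idx]; island <- island[idx]
  dt <- data.table(pos = pos, count = count, island = island)
  out <- dt[, {
    m <- which.max(count)  # first maximum = leftmost tie-break
    list(start = pos[1], end = pos[.N] + 1L,
         pooled_count = sum(as.numeric(count)),
         summit_pos = pos[m], summit_count = as.numeric(count[m]))
  }, by = island][, island := NULL]
  as.list(out)
}

#' Merge nearby peaks
#'
#' Any two peaks on the same strand whose gap (`next start - previous end`)
#' is at most `merge_gap` bp are unioned, transitively. Pooled counts are
#' summed and summits recomputed from the pooled track.
#'
#' @param peaks a `peaks` table (sorted by chrom, start; single strand).
#' @param pooled pooled counts table (`chrom`, `strand`, `pos`, `count`) or
#'   the tracks the peaks were called from; used to recompute summits.
#' @param merge_gap bp, inclusive.
#' @return merged `peaks` table.
#' @export
merge_peaks <- function(peaks, pooled, merge_gap = 50L) {
  if (nrow(peaks) == 0) return(peaks)
  if (length(unique(peaks$strand)) > 1) stop("merge_peaks: mixed strands")
  if (!identical(order(peaks$chrom, peaks$start), seq_len(nrow(peaks))))
    stop("merge_peaks: peaks must be sorted by (chrom, start)")
  if (!is.data.frame(pooled)) pooled <- .pool_end_tracks(pooled)
  pk <- as.data.table(peaks)[, .(chrom, start, end, strand)]
  pk[, grp := cumsum(c(TRUE, start[-1] - end[-.N] > merge_gap)), by = chrom]
  merged <- pk[, .(start = min(start), end = max(end), strand = strand[1]),
               by = .(chrom, grp)][, grp := NULL]
  merged[, mid := .I]
  pp <- as.data.table(pooled)[count > 0, .(chrom, strand, start = pos, end = pos + 1L,
                                           pos = pos, count = count)]
  setkey(merged, chrom, strand, start, end)
  setkey(pp, NULL)
  ov <- foverlaps(pp, merged, by.x = c("chrom", "strand", "start", "end"),
                  type = "within", nomatch = NULL)
  setorder(ov, mid, pos)
  out <- ov[, .(chrom = chrom[1], start = start[1], end = end[1], strand = strand[1],
                pooled_count = sum(as.numeric(count)),
                summit_pos = pos[which.max(count)],
                summit_count = as.numeric(max(count))),
            by = mid][, mid := NULL]
  if (nrow(out) != nrow(merged)) stop("merge_peaks: merged peak with no signal")
  setcolorder(out, c("chrom", "start", "end", "strand", "pooled_count",
                     "summit_pos", "summit_count"))
  setorder(out, chrom, start)
  out[]
}

#' Locate the summit of a peak
#'
#' The summit is the position of maximum pooled end-count within the peak
#' interval; ties resolve to the smallest genomic coordinate.
#'
#' @param peak one-row peak (list or data.frame row with chrom, start, end,
#'   strand).
#' @param pooled pooled counts table (chrom, strand, pos, count).
#' @return list: chrom, pos, strand, pooled_count (count at the summit).
#' @export
locate_summit <- function(peak, pooled) {
  sub <- pooled[chrom == peak$chrom & strand == peak$strand &
                pos >= peak$start & pos < peak$end & count > 0][order(pos)]
  if (nrow(sub) == 0) stop("locate_summit: peak contains no signal")
  m <- which.max(sub$count)
  list(chrom = peak$chrom, pos = sub$pos[m], strand = peak$strand,
       pooled_count = as.numeric(sub$count[m]))
}

#' Call CTSS/QTTS site summits on one strand
#'
#' Convenience wrapper: pool tracks, call peaks, merge within `merge_gap`,
#' and report per-peak summits as site calls.
#'
#' @param tracks `end_track` or list thereof (single strand, same signal).
#' @param params [peak_params()].
#' @param genome_size see [call_end_peaks()].
#' @return data.table of site calls: chrom, pos, strand, kind (`"CTSS"` for
#'   five_prime input, `"QTTS"` for three_prime), pooled_count (summit
#'   count), peak_start, peak_end, peak_count. Sorted by (chrom, pos).
#' @export
call_sites <- function(tracks, params = peak_params(), genome_size = NULL) {
  if (is(tracks, "end_track")) tracks <- list(tracks)
  kind <- switch(tracks[[1]]$signal_kind, five_prime = "CTSS", three_prime = "QTTS")
  pooled <- .pool_end_tracks(tracks)
  pk <- call_end_peaks(tracks, params, genome_size)
  pk <- merge_peaks(pk, pooled, params$merge_gap)
  sites <- pk[, .(chrom, pos = summit_pos, strand, kind = kind,
                  pooled_count = summit_count, peak_start = start,
                  peak_end = end, peak_count = pooled_count)]
  setorder(sites, chrom, pos)
  sites[]
}
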