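# Annotation of downstream antisense RNAs (daRNAs). Starting from a daTSS
# with no annotated gene start, the transcript body is extended in the
# direction of transcription by consecutive coverage windows; extension
# stops at the first window failing the coverage threshold or at the first
# annotated same-strand TSS supported by a CAGE peak. 3' ends come from
# QTTS calls inside the body; transcripts are ranked by QTTS expression.

#' daRNA annotation parameters
#'
#' @param window_len sliding-window length in bp.
#' @param coverage_threshold required RNA-seq coverage within a window, in
#'   reads. With `mode = "mean"` (default) a window passes when its mean
#'   per-base coverage is at least the threshold; with `mode = "sum"` when
#'   its summed coverage is.
#' @param step window advance in bp (defaults to non-overlapping windows).
#' @param mode `"mean"` or `"sum"` (see `coverage_threshold`).
#' @return list of class `darna_params`.
#' @export
darna_params <- function(window_len = 100L, coverage_threshold = 10,
                         step = window_len, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(window_len >= 1, coverage_threshold >= 0, step >= 1)
  structure(list(window_len = as.integer(window_len),
                 coverage_threshold = coverage_threshold,
                 step = as.integer(step), mode = mode),
            class = "darna_params")
}

# Per-(chrom,strand) prefix-sum index over coverage runs for O(log n)
# window sums.
.coverage_index <- function(cov) {
  runs <- if (is(cov, "coverage_track")) cov$runs else as.data.table(cov)
  split(runs, by = c("chrom", "strand"), drop = TRUE)
}

# Sum of per-base coverage over [from, to) given one chrom/strand run table
# (sorted, disjoint).
.window_sum <- function(runs, from, to) {
  if (is.null(runs) || nrow(runs) == 0 || to <= from) return(0)
  i1 <- findInterval(from, runs$start)
  i2 <- findInterval(to - 1L, runs$start)
  if (i2 == 0) return(0)
  i1 <- max(i1, 1L)
  s <- 0
  for (i in i1:i2) {
    lo <- max(runs$start[i], from); hi <- min(runs$end[i], to)
    if (hi > lo) s <- s + runs$depth[i] * (hi - lo)
  }
  s
}

# Annotated same-strand TSSs that are CAGE-supported (inside a CAGE peak on
# the same strand). Returns data.table(chrom, pos, strand).
.cage_supported_tss <- function(annotation, cage_peaks) {
  ann <- annotated_tss(annotation)
  if (nrow(ann) == 0) return(ann[, .(chrom, pos, strand)])
  pk <- as.data.table(cage_peaks)
  if (nrow(pk) == 0)
    return(data.table(chrom = character(0), pos = integer(0), strand = character(0)))
  pcols <- if ("peak_start" %in% names(pk)) c("peak_start", "peak_end") else c("start", "end")
  pk <- pk[, .(chrom, strand, start = get(pcols[1]), end = get(pcols[2]))]
  setkey(pk, chrom, strand, start, end)
  q <- ann[, .(chrom, strand, start = pos, end = pos + 1L, pos)]
  setkey(q, NULL)
  ov <- foverlaps(q, pk, by.x = c("chrom", "strand", "start", "end"),
                  type = "any", nomatch = NULL)
  unique(ov[, .(chrom, pos, strand)])
}

#' Extend a daRNA transcript body
#'
#' Starting at the daTSS, consecutive windows advance in the direction of
#' transcription while they pass the coverage threshold. Within each step
#' the termination check precedes the coverage check: an annotated
#' same-strand TSS supported by a CAGE peak truncates the body at that TSS
#' even under continuous coverage.
#'
#' @param da_pos,da_strand,chrom daTSS summit (0-based) and strand.
#' @param coverage a [coverage_track()] (or runs table) on the daTSS strand
#'   (antisense RNA-seq coverage, typically pooled across samples).
#' @param annotation `transcript_annotation`; a daTSS coinciding with an
#'   annotated gene start yields no body (`NULL`, "not a daRNA").
#' @param cage_peaks CAGE peak or site-call table used for the termination
#'   rule (needs chrom, strand and peak interval columns).
#' @param params [darna_params()].
#' @return list `(start, end)` of the covered interval (0-based half-open,
#'   contains `da_pos`; minimal 1-bp interval when the first window fails),
#'   or `NULL` when the daTSS sits on an annotated gene start.
#' @export
extend_body <- function(da_pos, da_strand, chrom, coverage, annotation,
                        cage_peaks, params = darna_params()) {
  stopifnot(da_strand %in% c("+", "-"))
  ch <- chrom
  ann <- annotated_tss(annotation)
  if (nrow(ann[chrom == ch & strand == da_strand & pos == da_pos]) > 0)
    return(NULL)
  sup <- .cage_supported_tss(annotation, cage_peaks)
  sup <- sup[chrom == ch & strand == da_strand]
  idx <- .coverage_index(coverage)
  runs <- idx[[paste(ch, da_strand, sep = ".")]]
  .extend_body_impl(da_pos, da_strand, runs, sup$pos, params)
}

# Core window walk; sup_pos are CAGE-supported annotated same-strand TSS
# positions on the chromosome.
.extend_body_impl <- function(da_pos, da_strand, runs, sup_pos, params) {
  w <- params$window_len; step <- params$step
  need <- if (params$mode == "mean") params$coverage_threshold * w else params$coverage_threshold
  lo <- da_pos; hi <- da_pos + 1L   # current body [lo, hi)
  k <- 0L
  repeat {
    if (da_strand == "+") {
      ws <- da_pos + k * step; we <- ws + w
    } else {
      we <- da_pos - k * step + 1L; ws <- we - w
    }
    # termination rule first: annotated CAGE-supported TSS inside the window
    t_in <- sup_pos[sup_pos >= ws & sup_pos < we & sup_pos != da_pos]
    if (da_strand == "+") t_in <- t_in[t_in > da_pos] else t_in <- t_in[t_in < da_pos]
    if (length(t_in)) {
      if (da_strand == "+") {
        return(list(start = lo, end = as.integer(min(t_in))))      # body ends at the TSS
      } else {
        return(list(start = as.integer(max(t_in)) + 1L, end = hi))
      }
    }
    if (.window_sum(runs, ws, we) < need) break
    if (da_strand == "+") hi <- we else lo <- max(0L, ws)
    k <- k + 1L
    if (k > 1e6L) stop("extend_body: runaway extension")
  }
  list(start = lo, end = hi)
}

#' Assign daRNA transcripts from QTTSs within a body
#'
#' One transcript per QTTS inside the body, ranked by descending QTTS
#' pooled count (da1, da2, ...; count ties break toward the longer
#' transcript). Without any QTTS a single transcript ending at the body
#' end is returned with `qtts_pos = NA`.
#'
#' @param body list/row with `start`, `end` (0-based half-open).
#' @param da_pos,da_strand daTSS summit and strand.
#' @param qtts QTTS site calls on the daTSS strand (chrom, pos,
#'   pooled_count); only sites inside the body are used.
#' @return data.table: rank, tx_start, tx_end, length, qtts_pos,
#'   qtts_count, dominant (rank 1).
#' @export
assign_transcripts <- function(body, da_pos, da_strand, qtts) {
  qt <- as.data.table(qtts)
  if (nrow(qt)) qt <- qt[pos >= body$start & pos < body$end]
  if (nrow(qt) == 0) {
    if (da_strand == "+") {
      tx <- data.table(tx_start = as.integer(da_pos), tx_end = as.integer(body$end))
    } else {
      tx <- data.table(tx_start = as.integer(body$start), tx_end = as.integer(da_pos) + 1L)
    }
    return(tx[, .(rank = 1L, tx_start, tx_end, length = tx_end - tx_start,
                  qtts_pos = NA_integer_, qtts_count = NA_real_, dominant = TRUE)])
  }
  if (da_strand == "+") {
    qt[, `:=`(tx_start = as.integer(da_pos), tx_end = pos + 1L)]
  } else {
    qt[, `:=`(tx_start = as.integer(pos), tx_end = as.integer(da_pos) + 1L)]
  }
  qt[, length := tx_end - tx_start]
  setorder(qt, -pooled_count, -length)
  qt[, rank := .I]
  qt[, .(rank, tx_start, tx_end, length, qtts_pos = pos,
         qtts_count = as.numeric(pooled_count), dominant = rank == 1L)]
}

#' Select the dominant daRNA at a locus
#'
#' The dominant transcript carries the strongest QTTS signal; ties break by
#' daTSS expression (column `da_count` when present), then by length.
#'
#' @param darnas data.table of transcripts at one locus with columns
#'   `qtts_count`, `length` and optionally `da_count`.
#' @return the row index of the dominant transcript.
#' @export
select_dominant <- function(darnas) {
  d <- as.data.table(darnas)
  if (nrow(d) == 0) stop("select_dominant: empty input")
  qc <- d$qtts_count; qc[is.na(qc)] <- -Inf
  dc <- if ("da_count" %in% names(d)) d$da_count else rep(0, nrow(d))
  ord <- order(-qc, -dc, -d$length)
  ord[1]
}

#' Does a daRNA body traverse the host TSS?
#'
#' TRUE when the body covers the host TSS position (half-open interval,
#' i.e. a body ending exactly at the host TSS does not traverse it).
#'
#' @param body list/row with `start`, `end`.
#' @param da_strand daRNA strand.
#' @param host_pos,host_strand host TSS summit and strand (must be the
#'   opposite strand).
#' @return logical.
#' @export
host_traversal <- function(body, da_strand, host_pos, host_strand) {
  if (da_strand == host_strand)
    stop("host_traversal: daRNA and host TSS must be on opposite strands")
  host_pos >= body$start && host_pos < body$end
}

#' Annotate daRNAs for a set of convergent pairs
#'
#' For each pair whose daTSS has no annotated gene start, extends the
#' transcript body from antisense RNA-seq coverage, assigns 3' ends from
#' QTTS calls, ranks transcripts, flags the dominant one and computes host
#' TSS traversal.
#'
#' @param pairs extended-pair table ([detect_extended()]) or labeled
#'   quadruples (TSS2 as host, TSS3 as daTSS).
#' @param coverage [coverage_track()] with antisense RNA-seq coverage
#'   (typically pooled across samples).
#' @param qtts QTTS site calls (both strands).
#' @param annotation `transcript_annotation`.
#' @param cage_peaks CAGE site-call/peak table for the termination rule.
#' @param params [darna_params()].
#' @return data.table, one row per daRNA transcript: locus id, host gene,
#'   daTSS, body, rank, length, dominant, qtts columns,
#'   traverses_host_tss.
#' @export
annotate_darnas <- function(pairs, coverage, qtts, annotation, cage_peaks,
                            params = darna_params()) {
  pr <- as.data.table(pairs)
  if (nrow(pr) == 0) return(.empty_darnas())
  if ("tss2_pos" %in% names(pr)) {
    pr <- pr[, .(chrom, host_pos = tss2_pos, host_strand = tss2_strand,
                 host_count = tss2_count, da_pos = tss3_pos,
                 da_strand = tss3_strand, da_count = tss3_count,
                 host_gene_id)]
  }
  ann <- annotated_tss(annotation)
  sup <- .cage_supported_tss(annotation, cage_peaks)
  idx <- .coverage_index(coverage)
  qt <- as.data.table(qtts)
  out <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    ch <- pr$chrom[i]; dp <- pr$da_pos[i]; ds <- pr$da_strand[i]
    if (nrow(ann[chrom == ch & strand == ds & pos == dp]) > 0) next  # not a daRNA
    runs <- idx[[paste(ch, ds, sep = ".")]]
    sp <- sup[chrom == ch & strand == ds]$pos
    body <- .extend_body_impl(dp, ds, runs, sp, params)
    qsub <- qt[chrom == ch & strand == ds]
    # The coverage walk quantizes the 3' boundary to the window grid; a
    # QTTS within one window beyond the edge marks the true terminus at
    # the coverage margin, so snap the body to include it.
    if (nrow(qsub)) {
      if (ds == "+") {
        cand <- qsub[pos >= body$end & pos < body$end + params$window_len]
        if (nrow(cand)) body$end <- max(cand$pos) + 1L
      } else {
        cand <- qsub[pos < body$start & pos >= body$start - params$window_len]
        if (nrow(cand)) body$start <- min(cand$pos)
      }
    }
    tx <- assign_transcripts(body, dp, ds, qsub)
    tx[, `:=`(locus_id = i, chrom = ch, host_gene_id = pr$host_gene_id[i],
              host_pos = pr$host_pos[i], host_strand = pr$host_strand[i],
              da_pos = dp, da_strand = ds, da_count = pr$da_count[i],
              body_start = body$start, body_end = body$end)]
    tx[, name := sprintf("%s-da%d", host_gene_id, rank)]
    tx[, traverses_host_tss := host_pos >= tx_start & host_pos < tx_end]
    out[[i]] <- tx
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(.empty_darnas())
  res <- rbindlist(out)
  setcolorder(res, c("locus_id", "chrom", "host_gene_id", "host_pos", "host_strand",
                     "da_pos", "da_strand", "da_count", "body_start", "body_end",
                     "rank", "name", "tx_start", "tx_end", "length",
                     "qtts_pos", "qtts_count", "dominant", "traverses_host_tss"))
  res[]
}

.empty_darnas <- function() {
  data.table(locus_id = integer(0), chrom = character(0), host_gene_id = character(0),
             host_pos = integer(0), host_strand = character(0), da_pos = integer(0),
             da_strand = character(0), da_count = numeric(0), body_start = integer(0),
             body_end = integer(0), rank = integer(0), name = character(0),
             tx_start = integer(0), tx_end = integer(0), length = integer(0),
             qtts_pos = integer(0), qtts_count = numeric(0), dominant = logical(0),
             traverses_host_tss = logical(0))
}
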