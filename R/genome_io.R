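#' @import data.table
#' @importFrom stats cor cor.test lm median na.omit ppois predict quantile
#'   rbinom rgeom rnbinom rnorm rpois runif setNames wilcox.test p.adjust
#'   complete.cases sd
#' @importFrom utils head tail packageVersion
#' @importFrom methods is
NULL

# Internal coordinate convention: 0-based, half-open [start, end), BED-style.
# GTF is converted at the read/write boundary (1-based, closed).

.valid_strands <- c("+", "-")

#' Construct a stranded end-count track
#'
#' An end track stores per-base counts of read 5' or 3' ends for one sample,
#' as a sparse table. Positions are 0-based.
#'
#' @param counts data.frame/data.table with columns `chrom`, `pos`, `strand`,
#'   `count` (non-negative integers).
#' @param sample_id sample identifier.
#' @param signal_kind `"five_prime"` or `"three_prime"`.
#' @return An object of class `end_track`: a list with elements `counts`
#'   (keyed data.table), `sample_id`, `signal_kind` and `library_size`.
#' @export
end_track <- function(counts, sample_id = "sample", signal_kind = c("five_prime", "three_prime")) {
  signal_kind <- match.arg(signal_kind)
  counts <- as.data.table(counts)[, .(chrom = as.character(chrom),
                                      pos = as.integer(pos),
                                      strand = as.character(strand),
                                      count = as.integer(count))]
  if (nrow(counts)) {
    if (any(counts$count < 0)) stop("end_track: negative counts")
    if (any(counts$pos < 0)) stop("end_track: negative positions")
    if (!all(counts$strand %in% .valid_strands)) stop("end_track: strand must be '+' or '-'")
    counts <- counts[count > 0]
    counts <- counts[, .(count = sum(count)), by = .(chrom, strand, pos)]
  }
  setkey(counts, chrom, strand, pos)
  structure(list(counts = counts, sample_id = sample_id, signal_kind = signal_kind,
                 library_size = sum(as.numeric(counts$count))),
            class = "end_track")
}

#' Construct a run-length coverage track
#'
#' @param runs data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `depth`; intervals 0-based half-open. Overlapping runs on the same
#'   chrom/strand are summed and merged into a canonical disjoint set.
#' @param sample_id sample identifier.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(runs, sample_id = "sample") {
  runs <- as.data.table(runs)[, .(chrom = as.character(chrom),
                                  start = as.integer(start), end = as.integer(end),
                                  strand = as.character(strand),
                                  depth = as.numeric(depth))]
  if (nrow(runs)) {
    if (any(runs$depth < 0)) stop("coverage_track: negative depth")
    if (any(runs$start >= runs$end)) stop("coverage_track: start must be < end")
    if (!all(runs$strand %in% .valid_strands)) stop("coverage_track: strand must be '+' or '-'")
    runs <- .flatten_runs(runs)
  }
  setkey(runs, chrom, strand, start)
  structure(list(runs = runs, sample_id = sample_id), class = "coverage_track")
}

# Sum overlapping runs into disjoint sorted runs per chrom/strand.
.flatten_runs <- function(runs) {
  runs[depth > 0,
       {
         bnd <- sort(unique(c(start, end)))
         if (length(bnd) < 2) {
           list(start = integer(0), end = integer(0), depth = numeric(0))
         } else {
           s <- bnd[-length(bnd)]; e <- bnd[-1]
           d <- vapply(seq_along(s), function(i) sum(depth[start <= s[i] & end >= e[i]]), numeric(1))
           keep <- d > 0
           # merge adjacent runs with equal depth
           s <- s[keep]; e <- e[keep]; d <- d[keep]
           if (length(s) > 1) {
             grp <- cumsum(c(TRUE, !(s[-1] == e[-length(e)] & d[-1] == d[-length(d)])))
             list(start = as.integer(tapply(s, grp, min)),
                  end = as.integer(tapply(e, grp, max)),
                  depth = as.numeric(tapply(d, grp, function(z) z[1])))
           } else list(start = s, end = e, depth = d)
         }
       },
       by = .(chrom, strand)][, .(chrom, start, end, strand, depth)]
}

#' @export
print.end_track <- function(x, ...) {
  cat(sprintf("<end_track> sample=%s kind=%s positions=%d library_size=%.0f\n",
              x$sample_id, x$signal_kind, nrow(x$counts), x$library_size))
  invisible(x)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> sample=%s runs=%d\n", x$sample_id, nrow(x$runs)))
  invisible(x)
}

#' Read a strand-specific bedGraph file
#'
#' bedGraph files are 0-based half-open and carry no strand column; the
#' strand is supplied by the caller (the pipeline uses a
#' `{sample}.{signal}.{strand}.bedgraph` naming convention). Validation
#' reports the 1-based file line of the first offending record.
#'
#' @param path file path.
#' @param strand `"+"` or `"-"`.
#' @param signal_kind `"five_prime"`, `"three_prime"` or `"coverage"`.
#' @param sample_id sample identifier attached to the returned track.
#' @return An [end_track()] (per-base counts) for end signals, or a
#'   [coverage_track()] for `signal_kind = "coverage"`.
#' @export
read_bedgraph <- function(path, strand, signal_kind = c("five_prime", "three_prime", "coverage"),
                          sample_id = sub("\\..*$", "", basename(path))) {
  signal_kind <- match.arg(signal_kind)
  if (!strand %in% .valid_strands) stop("read_bedgraph: strand must be '+' or '-'")
  if (!file.exists(path)) stop("read_bedgraph: file not found: ", path)
  first <- readLines(path, n = 1L)
  skip <- length(first) == 1L && (startsWith(first, "track") || startsWith(first, "#"))
  dt <- tryCatch(
    fread(path, header = FALSE, skip = as.integer(skip), sep = "\t",
          colClasses = list(character = 1), fill = TRUE),
    error = function(e) stop("read_bedgraph: cannot parse ", path, ": ", conditionMessage(e))
  )
  offset <- as.integer(skip)  # data row i is file line i + offset
  if (nrow(dt) == 0) {
    empty <- data.table(chrom = character(0), pos = integer(0),
                        strand = character(0), count = integer(0))
    if (signal_kind == "coverage")
      return(coverage_track(data.table(chrom = character(0), start = integer(0),
                                       end = integer(0), strand = character(0),
                                       depth = numeric(0)), sample_id))
    return(end_track(empty, sample_id, signal_kind))
  }
  if (ncol(dt) != 4)
    stop(sprintf("read_bedgraph: %s line %d: expected 4 columns, found %d",
                 path, 1L + offset, ncol(dt)))
  setnames(dt, c("chrom", "start", "end", "value"))
  bad <- which(is.na(suppressWarnings(as.numeric(dt$start))) |
               is.na(suppressWarnings(as.numeric(dt$end))) |
               is.na(suppressWarnings(as.numeric(dt$value))))
  if (length(bad))
    stop(sprintf("read_bedgraph: %s line %d: non-numeric field", path, bad[1] + offset))
  dt[, `:=`(start = as.integer(start), end = as.integer(end), value = as.numeric(value))]
  bad <- which(dt$start >= dt$end)
  if (length(bad))
    stop(sprintf("read_bedgraph: %s line %d: start >= end", path, bad[1] + offset))
  bad <- which(dt$start < 0)
  if (length(bad))
    stop(sprintf("read_bedgraph: %s line %d: negative coordinate", path, bad[1] + offset))
  bad <- which(dt$value < 0)
  if (length(bad))
    stop(sprintf("read_bedgraph: %s line %d: negative value", path, bad[1] + offset))
  if (signal_kind == "coverage") {
    sel_strand <- strand
    return(coverage_track(dt[, .(chrom, start, end, strand = sel_strand, depth = value)],
                          sample_id))
  }
  # expand runs to per-base sparse counts (end signals are near point-source)
  run <- dt[value > 0]
  reps <- run$end - run$start
  cnt <- data.table(chrom = rep(run$chrom, reps),
                    pos = sequence(reps) - 1L + rep(run$start, reps),
                    strand = strand,
                    count = rep(as.integer(run$value), reps))
  end_track(cnt, sample_id, signal_kind)
}

#' Write a track to bedGraph
#'
#' Writes the selected strand as a canonical, sorted bedGraph (0-based,
#' half-open); adjacent per-base records with equal value are collapsed
#' into runs.
#'
#' @param x an [end_track()] or [coverage_track()].
#' @param path output path.
#' @param strand strand to write.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, strand) {
  if (!strand %in% .valid_strands) stop("write_bedgraph: strand must be '+' or '-'")
  sel <- strand
  if (is(x, "end_track")) {
    dt <- x$counts[strand == sel, .(chrom, start = pos, end = pos + 1L, value = count)]
  } else if (is(x, "coverage_track")) {
    dt <- x$runs[strand == sel, .(chrom, start, end, value = depth)]
  } else stop("write_bedgraph: unsupported object")
  setorder(dt, chrom, start)
  if (nrow(dt) > 1) {  # collapse equal-valued adjacent records
    grp <- cumsum(c(TRUE, !(dt$chrom[-1] == dt$chrom[-nrow(dt)] &
                            dt$start[-1] == dt$end[-nrow(dt)] &
                            dt$value[-1] == dt$value[-nrow(dt)])))
    dt <- dt[, .(chrom = chrom[1], start = start[1], end = end[.N], value = value[1]),
             by = .(grp)][, grp := NULL]
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a transcript annotation (GTF or BED12)
#'
#' Parses via `rtracklayer` and converts to the package's 0-based half-open
#' convention. The annotated TSS of a `+` transcript is its `start`; of a
#' `-` transcript its `end - 1`. All distinct transcript TSSs are kept.
#'
#' @param path GTF (`.gtf`) or BED12 (`.bed`) file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed"`.
#' @return Object of class `transcript_annotation`: list with `records`
#'   (one row per transcript: gene_id, transcript_id, chrom, start, end,
#'   strand, biotype) and `tss` (keyed table of annotated TSS positions).
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_annotation: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gtf = "gtf", gff = "gtf", bed = "bed",
                     stop("read_annotation: unknown format for extension '.", ext, "'"))
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "transcript"]
    if (length(gr) == 0) stop("read_annotation: no transcript records in ", path)
    rec <- data.table(
      gene_id = as.character(gr$gene_id),
      transcript_id = as.character(gr$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # GTF 1-based closed -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype) else NA_character_
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0) stop("read_annotation: no records in ", path)
    nm <- if (!is.null(gr$name)) as.character(gr$name) else sprintf("tx%d", seq_along(gr))
    rec <- data.table(
      gene_id = nm, transcript_id = nm,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # import() is 1-based in R
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = NA_character_
    )
  }
  if (any(!rec$strand %in% .valid_strands))
    stop("read_annotation: records without strand in ", path)
  transcript_annotation(rec)
}

#' Build a transcript annotation from a records table
#'
#' @param records data.frame with columns gene_id, transcript_id, chrom,
#'   start, end, strand (0-based half-open) and optionally biotype.
#' @return `transcript_annotation` object.
#' @export
transcript_annotation <- function(records) {
  rec <- as.data.table(records)
  if (!"biotype" %in% names(rec)) rec[, biotype := NA_character_]
  rec <- rec[, .(gene_id = as.character(gene_id), transcript_id = as.character(transcript_id),
                 chrom = as.character(chrom), start = as.integer(start), end = as.integer(end),
                 strand = as.character(strand), biotype = as.character(biotype))]
  if (nrow(rec)) {
    if (any(rec$start >= rec$end)) stop("transcript_annotation: start must be < end")
    if (!all(rec$strand %in% .valid_strands)) stop("transcript_annotation: invalid strand")
  }
  tss <- rec[, .(chrom, pos = ifelse(strand == "+", start, end - 1L), strand,
                 gene_id, transcript_id)]
  setkey(tss, chrom, strand, pos)
  structure(list(records = rec, tss = tss), class = "transcript_annotation")
}

#' Annotated TSS positions
#'
#' @param annotation a `transcript_annotation`.
#' @return data.table of distinct annotated TSSs (chrom, pos, strand,
#'   gene_id, transcript_id), sorted.
#' @export
annotated_tss <- function(annotation) {
  stopifnot(is(annotation, "transcript_annotation"))
  annotation$tss
}

#' @export
print.transcript_annotation <- function(x, ...) {
  cat(sprintf("<transcript_annotation> transcripts=%d genes=%d\n",
              nrow(x$records), length(unique(x$records$gene_id))))
  invisible(x)
}

#' Write a BED6 file
#'
#' @param x data.frame with columns chrom, start, end, name, score, strand
#'   (0-based half-open).
#' @param path output path.
#' @return `path` invisibly. Rows are written sorted by (chrom, start, strand).
#' @export
write_bed6 <- function(x, path) {
  dt <- as.data.table(x)[, .(chrom, start = as.integer(start), end = as.integer(end),
                             name, score, strand)]
  setorder(dt, chrom, start, strand)
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a TSV with header
#'
#' @param x data.frame.
#' @param path output path.
#' @param sort_by optional character vector of columns for deterministic order.
#' @return `path` invisibly.
#' @export
write_tsv <- function(x, path, sort_by = NULL) {
  dt <- as.data.table(x)
  if (!is.null(sort_by) && nrow(dt)) setorderv(dt, sort_by)
  fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read a TSV with header
#' @param path file path.
#' @return data.table.
#' @export
read_tsv <- function(path) fread(path, sep = "\t", header = TRUE)

#' Write gene/transcript records as minimal GTF
#'
#' Emits `gene` and `transcript` features (1-based, closed coordinates) via
#' rtracklayer, sorted by (chrom, start).
#'
#' @param records data.frame with columns gene_id, transcript_id, chrom,
#'   start, end, strand (0-based half-open), optional biotype.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_gtf <- function(records, path) {
  rec <- as.data.table(records)
  if (nrow(rec) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  setorder(rec, chrom, start, gene_id)
  gene <- rec[, .(start = min(start), end = max(end), strand = strand[1],
                  biotype = if ("biotype" %in% names(rec)) biotype[1] else NA_character_),
              by = .(chrom, gene_id)]
  mk <- function(dt, type, tx_id) {
    GenomicRanges::GRanges(dt$chrom,
                           IRanges::IRanges(dt$start + 1L, dt$end),
                           strand = dt$strand, type = type,
                           gene_id = dt$gene_id, transcript_id = tx_id,
                           gene_biotype = if ("biotype" %in% names(dt)) dt$biotype else NA_character_)
  }
  gr <- c(mk(gene, "gene", NA_character_), mk(rec, "transcript", rec$transcript_id))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
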