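# Detection of convergent promoters from CTSS site calls.
#
# Core set: divergent TSS pairs (a minus-strand CTSS followed by a
# plus-strand CTSS within 400 bp) are themselves paired within 2,500 bp to
# form quadruples of four TSSs; the most expressed TSS becomes TSS2 (host),
# its divergent partner TSS1, the convergent counterpart TSS3 and TSS3's
# partner TSS4. Quadruples are kept only when an annotated TSS on TSS2's
# strand falls inside TSS2's peak.
#
# Extended set: plus-strand CTSSs are paired directly with downstream
# minus-strand CTSSs within 2,500 bp; pairs are kept when at least one
# member's peak overlaps an annotated same-strand TSS, which defines the
# host; expression breaks ties.

#' Detection parameters
#'
#' @param divergent_window maximum distance (bp, inclusive) for divergent
#'   (-TSS then +TSS) pairing.
#' @param convergent_window maximum distance (bp, inclusive) for convergent
#'   pairing / quadruple assembly.
#' @param min_gap minimum convergent distance in bp; the default of 1
#'   forbids degenerate zero-distance pairs.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(divergent_window = 400L, convergent_window = 2500L,
                             min_gap = 1L) {
  stopifnot(divergent_window >= 0, convergent_window >= 0, min_gap >= 0)
  structure(list(divergent_window = as.integer(divergent_window),
                 convergent_window = as.integer(convergent_window),
                 min_gap = as.integer(min_gap)),
            class = "detection_params")
}

.check_sorted_sites <- function(sites, what) {
  if (nrow(sites) && !identical(order(sites$chrom, sites$pos), seq_len(nrow(sites))))
    stop(what, ": site calls must be sorted by (chrom, pos)")
}

# Mutual-nearest one-to-one pairing of upstream-strand sites with
# downstream-strand sites: for every row u of `up` the nearest d of `down`
# with d$pos >= u$pos at distance <= window, kept when the relation is
# mutual. Returns index pairs (iu, id) plus distance.
.mutual_nearest <- function(up, down, window) {
  out <- vector("list", 0L)
  for (ch in intersect(unique(up$chrom), unique(down$chrom))) {
    u <- which(up$chrom == ch); d <- which(down$chrom == ch)
    upos <- up$pos[u]; dpos <- down$pos[d]
    # nearest downstream d for each u: first dpos >= upos
    j <- findInterval(upos - 1L, dpos) + 1L          # index into dpos
    # nearest upstream u for each d: last upos <= dpos
    i <- findInterval(dpos, upos)                    # index into upos
    ok <- which(j <= length(dpos))
    for (k in ok) {
      jj <- j[k]
      if (i[jj] == k && dpos[jj] - upos[k] <= window) {
        out[[length(out) + 1L]] <- c(u[k], d[jj], dpos[jj] - upos[k])
      }
    }
  }
  if (length(out) == 0)
    return(data.table(iu = integer(0), id = integer(0), distance = integer(0)))
  m <- do.call(rbind, out)
  data.table(iu = m[, 1], id = m[, 2], distance = m[, 3])
}

#' Pair divergent CTSSs
#'
#' Mutual-nearest one-to-one pairing of each minus-strand CTSS with a
#' downstream plus-strand CTSS at distance `plus - minus` of at most
#' `divergent_window` (inclusive). No CTSS joins two pairs.
#'
#' @param sites_minus,sites_plus site-call tables as returned by
#'   [call_sites()], sorted by (chrom, pos).
#' @param params [detection_params()].
#' @return data.table of pairs, one row per divergent pair, with
#'   `minus_*`/`plus_*` columns (pos, pooled_count, peak_start, peak_end)
#'   plus chrom and distance; sorted by (chrom, minus_pos).
#' @export
pair_divergent <- function(sites_minus, sites_plus, params = detection_params()) {
  sites_minus <- as.data.table(sites_minus)
  sites_plus <- as.data.table(sites_plus)
  .check_sorted_sites(sites_minus, "pair_divergent")
  .check_sorted_sites(sites_plus, "pair_divergent")
  if (nrow(sites_minus) && any(sites_minus$strand != "-"))
    stop("pair_divergent: sites_minus must be '-' strand")
  if (nrow(sites_plus) && any(sites_plus$strand != "+"))
    stop("pair_divergent: sites_plus must be '+' strand")
  mn <- .mutual_nearest(sites_minus, sites_plus, params$divergent_window)
  pairs <- data.table(
    chrom = sites_minus$chrom[mn$iu],
    minus_pos = sites_minus$pos[mn$iu],
    minus_count = sites_minus$pooled_count[mn$iu],
    minus_peak_start = sites_minus$peak_start[mn$iu],
    minus_peak_end = sites_minus$peak_end[mn$iu],
    plus_pos = sites_plus$pos[mn$id],
    plus_count = sites_plus$pooled_count[mn$id],
    plus_peak_start = sites_plus$peak_start[mn$id],
    plus_peak_end = sites_plus$peak_end[mn$id],
    distance = mn$distance
  )
  setorder(pairs, chrom, minus_pos)
  pairs[]
}

#' Assemble candidate quadruples from divergent pairs
#'
#' Consecutive divergent pairs A (upstream) and B (downstream) on the same
#' chromosome are joined when the gap between the inner convergent TSSs,
#' `B.minus_pos - A.plus_pos`, lies in `[min_gap, convergent_window]`
#' (with `min_gap >= 1` this means strictly positive). Each divergent pair
#' joins at most one quadruple on each side.
#'
#' @param pairs output of [pair_divergent()], sorted by (chrom, minus_pos).
#' @param params [detection_params()].
#' @return data.table of unlabeled quadruples: `a_*` columns for the
#'   upstream pair, `b_*` for the downstream pair, and `gap` between the
#'   inner TSSs (`b_minus_pos - a_plus_pos`).
#' @export
assemble_quadruples <- function(pairs, params = detection_params()) {
  pairs <- as.data.table(pairs)
  if (nrow(pairs) && !identical(order(pairs$chrom, pairs$minus_pos), seq_len(nrow(pairs))))
    stop("assemble_quadruples: pairs must be sorted by (chrom, minus_pos)")
  if (nrow(pairs) < 2) return(.empty_quads())
  a <- pairs[-nrow(pairs)]
  b <- pairs[-1]
  gap <- b$minus_pos - a$plus_pos
  keep <- a$chrom == b$chrom & gap >= max(1L, params$min_gap) &
    gap <= params$convergent_window
  if (!any(keep)) return(.empty_quads())
  a <- a[keep]; b <- b[keep]
  quads <- data.table(chrom = a$chrom)
  for (col in setdiff(names(pairs), c("chrom", "distance"))) {
    set(quads, j = paste0("a_", col), value = a[[col]])
    set(quads, j = paste0("b_", col), value = b[[col]])
  }
  set(quads, j = "gap", value = b$minus_pos - a$plus_pos)
  quads[]
}

.empty_quads <- function() {
  cols <- c("minus_pos", "minus_count", "minus_peak_start", "minus_peak_end",
            "plus_pos", "plus_count", "plus_peak_start", "plus_peak_end")
  out <- data.table(chrom = character(0))
  for (col in cols) {
    set(out, j = paste0("a_", col), value = numeric(0))
    set(out, j = paste0("b_", col), value = numeric(0))
  }
  set(out, j = "gap", value = integer(0))
  out
}

# Annotated same-strand TSSs falling inside [peak_start, peak_end); returns
# for each query row the gene_id of the annotated TSS nearest to the summit
# (NA when none).
.peak_annotation_hit <- function(chrom, strand, peak_start, peak_end, summit, ann_tss) {
  n <- length(chrom)
  hit <- rep(NA_character_, n)
  if (n == 0 || nrow(ann_tss) == 0) return(hit)
  q <- data.table(chrom = chrom, strand = strand, start = as.integer(peak_start),
                  end = as.integer(peak_end), summit = as.integer(summit), qid = seq_len(n))
  a <- ann_tss[, .(chrom, strand, start = pos, end = pos + 1L, gene_id)]
  setkey(a, chrom, strand, start, end)
  setkey(q, NULL)
  ov <- foverlaps(q, a, by.x = c("chrom", "strand", "start", "end"),
                  type = "any", nomatch = NULL)
  if (nrow(ov) == 0) return(hit)
  ov[, d := abs(start - summit)]
  setorder(ov, qid, d)
  best <- ov[, .SD[1], by = qid]
  hit[best$qid] <- best$gene_id
  hit
}

#' Label quadruples and filter by annotation
#'
#' The most expressed of the four TSSs becomes TSS2; its divergent partner
#' TSS1; the convergent counterpart TSS3; and TSS3's divergent partner
#' TSS4. Labels mirror by strand symmetry when the dominant TSS is the
#' minus-strand member of the downstream pair. Expression ties resolve
#' toward the TSS overlapping an annotated TSS, then leftmost. A quadruple
#' is retained only when an annotated TSS on TSS2's strand falls within
#' TSS2's peak interval; candidates whose most expressed TSS is an outer
#' TSS cannot take the convergent orientation and are rejected.
#'
#' @param quads output of [assemble_quadruples()].
#' @param annotation a `transcript_annotation`.
#' @return data.table of labeled quadruples: chrom, `tss1_pos` ...
#'   `tss4_pos`, `tss*_strand`, `tss*_count`, `tss2_peak_start/end`,
#'   `tss3_peak_start/end`, orientation (`plus_host`/`minus_host`),
#'   host_gene_id, distance_2_3.
#' @export
label_quadruples <- function(quads, annotation) {
  quads <- as.data.table(quads)
  ann <- annotated_tss(annotation)
  n <- nrow(quads)
  if (n == 0) return(.empty_labeled())
  # candidate matrix: columns aM, aP, bM, bP
  pos <- cbind(quads$a_minus_pos, quads$a_plus_pos, quads$b_minus_pos, quads$b_plus_pos)
  cnt <- cbind(quads$a_minus_count, quads$a_plus_count, quads$b_minus_count, quads$b_plus_count)
  str <- c("-", "+", "-", "+")
  pstart <- cbind(quads$a_minus_peak_start, quads$a_plus_peak_start,
                  quads$b_minus_peak_start, quads$b_plus_peak_start)
  pend <- cbind(quads$a_minus_peak_end, quads$a_plus_peak_end,
                quads$b_minus_peak_end, quads$b_plus_peak_end)
  ann_hit <- matrix(NA_character_, n, 4)
  for (k in 1:4) {
    ann_hit[, k] <- .peak_annotation_hit(quads$chrom, rep(str[k], n),
                                         pstart[, k], pend[, k], pos[, k], ann)
  }
  dominant <- integer(n)
  for (i in seq_len(n)) {
    mx <- max(cnt[i, ])
    tied <- which(cnt[i, ] == mx)
    if (length(tied) > 1) {
      with_ann <- tied[!is.na(ann_hit[i, tied])]
      if (length(with_ann) >= 1) tied <- with_ann
      tied <- tied[order(pos[i, tied])]
    }
    dominant[i] <- tied[1]
  }
  # orientation: dominant must be an inner TSS (aP = 2 or bM = 3)
  ok <- dominant %in% c(2L, 3L)
  res <- vector("list", n)
  for (i in which(ok)) {
    if (dominant[i] == 2L) {          # plus_host: TSS1=aM TSS2=aP TSS3=bM TSS4=bP
      lab <- c(1L, 2L, 3L, 4L); idx <- c(1L, 2L, 3L, 4L); orient <- "plus_host"
    } else {                          # minus_host: TSS1=bP TSS2=bM TSS3=aP TSS4=aM
      lab <- c(1L, 2L, 3L, 4L); idx <- c(4L, 3L, 2L, 1L); orient <- "minus_host"
    }
    host_gene <- ann_hit[i, if (orient == "plus_host") 2L else 3L]
    if (is.na(host_gene)) next   # annotation filter: no annotated TSS in TSS2 peak
    tssidx <- idx                # tssidx[k] = candidate column of TSSk
    res[[i]] <- data.table(
      chrom = quads$chrom[i],
      tss1_pos = pos[i, tssidx[1]], tss1_strand = str[tssidx[1]], tss1_count = cnt[i, tssidx[1]],
      tss2_pos = pos[i, tssidx[2]], tss2_strand = str[tssidx[2]], tss2_count = cnt[i, tssidx[2]],
      tss3_pos = pos[i, tssidx[3]], tss3_strand = str[tssidx[3]], tss3_count = cnt[i, tssidx[3]],
      tss4_pos = pos[i, tssidx[4]], tss4_strand = str[tssidx[4]], tss4_count = cnt[i, tssidx[4]],
      tss2_peak_start = pstart[i, tssidx[2]], tss2_peak_end = pend[i, tssidx[2]],
      tss3_peak_start = pstart[i, tssidx[3]], tss3_peak_end = pend[i, tssidx[3]],
      orientation = orient, host_gene_id = host_gene,
      distance_2_3 = abs(pos[i, tssidx[3]] - pos[i, tssidx[2]])
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(.empty_labeled())
  out <- rbindlist(res)
  setorder(out, chrom, tss2_pos)
  out[]
}

.empty_labeled <- function() {
  out <- data.table(chrom = character(0))
  for (k in 1:4) {
    set(out, j = sprintf("tss%d_pos", k), value = integer(0))
    set(out, j = sprintf("tss%d_strand", k), value = character(0))
    set(out, j = sprintf("tss%d_count", k), value = numeric(0))
  }
  for (col in c("tss2_peak_start", "tss2_peak_end", "tss3_peak_start",
                "tss3_peak_end"))
    set(out, j = col, value = integer(0))
  set(out, j = "orientation", value = character(0))
  set(out, j = "host_gene_id", value = character(0))
  set(out, j = "distance_2_3", value = integer(0))
  out
}

#' Detect the core set of convergent promoter quadruples
#'
#' Runs [pair_divergent()], [assemble_quadruples()] and
#' [label_quadruples()].
#'
#' @param sites_minus,sites_plus CTSS site calls per strand (sorted).
#' @param annotation `transcript_annotation`.
#' @param params [detection_params()].
#' @return labeled quadruple table (see [label_quadruples()]).
#' @export
detect_core <- function(sites_minus, sites_plus, annotation,
                        params = detection_params()) {
  pairs <- pair_divergent(sites_minus, sites_plus, params)
  quads <- assemble_quadruples(pairs, params)
  label_quadruples(quads, annotation)
}

#' Detect the extended set of convergent promoter pairs
#'
#' Mutual-nearest pairing of each plus-strand CTSS with a downstream
#' minus-strand CTSS at distance in `[min_gap, convergent_window]`. A pair
#' is kept when at least one member's peak overlaps an annotated TSS on its
#' own strand; the overlapping member is the host. When both overlap, the
#' more expressed member is the host (tie: leftmost).
#'
#' @param sites_plus,sites_minus CTSS site calls per strand (sorted).
#' @param annotation `transcript_annotation`.
#' @param params [detection_params()].
#' @return data.table of convergent pairs: chrom, host_pos, host_strand,
#'   host_count, da_pos, da_strand, da_count, da_peak_start, da_peak_end,
#'   host_peak_start, host_peak_end, host_gene_id, distance.
#' @export
detect_extended <- function(sites_plus, sites_minus, annotation,
                            params = detection_params()) {
  sites_plus <- as.data.table(sites_plus)
  sites_minus <- as.data.table(sites_minus)
  .check_sorted_sites(sites_plus, "detect_extended")
  .check_sorted_sites(sites_minus, "detect_extended")
  ann <- annotated_tss(annotation)
  mn <- .mutual_nearest(sites_plus, sites_minus, params$convergent_window)
  mn <- mn[distance >= max(1L, params$min_gap)]
  if (nrow(mn) == 0) return(.empty_extended())
  p <- sites_plus[mn$iu]; m <- sites_minus[mn$id]
  hit_p <- .peak_annotation_hit(p$chrom, p$strand, p$peak_start, p$peak_end, p$pos, ann)
  hit_m <- .peak_annotation_hit(m$chrom, m$strand, m$peak_start, m$peak_end, m$pos, ann)
  keep <- !is.na(hit_p) | !is.na(hit_m)
  if (!any(keep)) return(.empty_extended())
  p <- p[keep]; m <- m[keep]
  hit_p <- hit_p[keep]; hit_m <- hit_m[keep]; dist <- mn$distance[keep]
  # host selection
  host_is_plus <- ifelse(!is.na(hit_p) & is.na(hit_m), TRUE,
                  ifelse(is.na(hit_p) & !is.na(hit_m), FALSE,
                         p$pooled_count > m$pooled_count |
                           (p$pooled_count == m$pooled_count & p$pos <= m$pos)))
  pick <- function(pl, mi) ifelse(host_is_plus, pl, mi)
  out <- data.table(
    chrom = p$chrom,
    host_pos = as.integer(pick(p$pos, m$pos)),
    host_strand = ifelse(host_is_plus, "+", "-"),
    host_count = pick(p$pooled_count, m$pooled_count),
    host_peak_start = as.integer(pick(p$peak_start, m$peak_start)),
    host_peak_end = as.integer(pick(p$peak_end, m$peak_end)),
    da_pos = as.integer(pick(m$pos, p$pos)),
    da_strand = ifelse(host_is_plus, "-", "+"),
    da_count = pick(m$pooled_count, p$pooled_count),
    da_peak_start = as.integer(pick(m$peak_start, p$peak_start)),
    da_peak_end = as.integer(pick(m$peak_end, p$peak_end)),
    host_gene_id = ifelse(host_is_plus, hit_p, hit_m),
    distance = as.integer(dist)
  )
  setorder(out, chrom, host_pos)
  out[]
}

.empty_extended <- function() {
  data.table(chrom = character(0), host_pos = integer(0), host_strand = character(0),
             host_count = numeric(0), host_peak_start = integer(0),
             host_peak_end = integer(0), da_pos = integer(0), da_strand = character(0),
             da_count = numeric(0), da_peak_start = integer(0), da_peak_end = integer(0),
             host_gene_id = character(0), distance = integer(0))
}

#' Summit-to-summit TSS2-TSS3 distances
#'
#' @param quads labeled quadruple table.
#' @return integer vector of `|TSS3 - TSS2|` distances.
#' @export
quadruple_distance <- function(quads) {
  abs(as.integer(quads$tss3_pos) - as.integer(quads$tss2_pos))
}

#' Overlap two sets of convergent constellations
#'
#' Two constellations are shared when their TSS2-TSS3 spans intersect on
#' the same host strand and chromosome.
#'
#' @param set_a,set_b labeled quadruple tables (or extended-pair tables
#'   with host/da columns).
#' @return list with logical vectors `shared_a`, `shared_b` and the
#'   fractions `frac_a`, `frac_b` of each set shared with the other.
#' @export
overlap_sets <- function(set_a, set_b) {
  span <- function(s) {
    s <- as.data.table(s)
    if (nrow(s) == 0)
      return(data.table(chrom = character(0), start = integer(0), end = integer(0),
                        host_strand = character(0)))
    if ("tss2_pos" %in% names(s)) {
      data.table(chrom = s$chrom,
                 start = pmin(s$tss2_pos, s$tss3_pos),
                 end = pmax(s$tss2_pos, s$tss3_pos) + 1L,
                 host_strand = s$tss2_strand)
    } else {
      data.table(chrom = s$chrom,
                 start = pmin(s$host_pos, s$da_pos),
                 end = pmax(s$host_pos, s$da_pos) + 1L,
                 host_strand = s$host_strand)
    }
  }
  a <- span(set_a); b <- span(set_b)
  a[, ida := .I]; b[, idb := .I]
  shared_a <- rep(FALSE, nrow(a)); shared_b <- rep(FALSE, nrow(b))
  if (nrow(a) && nrow(b)) {
    setkey(b, chrom, host_strand, start, end)
    ov <- foverlaps(a, b, by.x = c("chrom", "host_strand", "start", "end"),
                    type = "any", nomatch = NULL)
    shared_a[unique(ov$ida)] <- TRUE
    shared_b[unique(ov$idb)] <- TRUE
  }
  list(shared_a = shared_a, shared_b = shared_b,
       frac_a = if (length(shared_a)) mean(shared_a) else NA_real_,
       frac_b = if (length(shared_b)) mean(shared_b) else NA_real_)
}
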