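# Recovery metrics against a planted truth set: how well detection and
# daRNA annotation reconstruct the simulated architecture.

#' Quadruple recovery against planted truth
#'
#' A detected quadruple matches a planted one when both inner TSS summits
#' lie within `tol` bp of the planted inner pair (as an unordered pair);
#' the TSS2 label is correct when the match also holds with the labels in
#' their planted orientation.
#'
#' @param truth `truth_set` from [plant_loci()].
#' @param core labeled quadruple table from [detect_core()].
#' @param tol matching tolerance in bp (defaults to the generator's
#'   jitter cap).
#' @return list: n_planted, n_detected, recall, precision,
#'   label_accuracy.
#' @export
evaluate_quadruple_recovery <- function(truth, core, tol = 10L) {
  q <- truth$tss[architecture == "quadruple" & label %in% c("TSS2", "TSS3")]
  planted <- dcast(q, locus_id + chrom ~ label, value.var = "pos")
  n_planted <- nrow(planted)
  n_detected <- nrow(core)
  if (n_planted == 0 || n_detected == 0)
    return(list(n_planted = n_planted, n_detected = n_detected,
                recall = if (n_planted) 0 else NA_real_,
                precision = if (n_detected) 0 else NA_real_,
                label_accuracy = NA_real_))
  det_matched <- logical(n_detected)
  det_labeled <- logical(n_detected)
  planted_matched <- logical(n_planted)
  for (i in seq_len(n_detected)) {
    same <- planted$chrom == core$chrom[i]
    ordered <- same & abs(planted$TSS2 - core$tss2_pos[i]) <= tol &
      abs(planted$TSS3 - core$tss3_pos[i]) <= tol
    swapped <- same & abs(planted$TSS3 - core$tss2_pos[i]) <= tol &
      abs(planted$TSS2 - core$tss3_pos[i]) <= tol
    hit <- which(ordered | swapped)
    if (length(hit)) {
      det_matched[i] <- TRUE
      det_labeled[i] <- any(ordered)
      planted_matched[hit] <- TRUE
    }
  }
  list(n_planted = n_planted, n_detected = n_detected,
       recall = mean(planted_matched),
       precision = mean(det_matched),
       label_accuracy = if (any(det_matched))
         mean(det_labeled[det_matched]) else NA_real_)
}

#' daRNA recovery against planted truth
#'
#' Joins dominant daRNAs to the planted loci by host gene and scores the
#' inferred 3' boundary (the strand-aware far end of the transcript)
#' against the planted daRNA end, and whether the dominant transcript
#' carries the planted (strongest) QTTS.
#'
#' @param truth `truth_set`.
#' @param darnas output of [annotate_darnas()].
#' @param boundary_tol bp tolerance for the 3' boundary (defaults to one
#'   coverage window).
#' @param qtts_tol bp tolerance for matching the dominant QTTS to the
#'   planted terminus.
#' @return list: n, boundary_within_tol (fraction), dominant_qtts_match
#'   (fraction), median_dominant_length, traversal_fraction.
#' @export
evaluate_darna_recovery <- function(truth, darnas, boundary_tol = 100L,
                                    qtts_tol = 10L) {
  dom <- as.data.table(darnas)[dominant == TRUE]
  planted <- truth$loci[architecture == "quadruple" & !is.na(darna_end),
                        .(host_gene_id, darna_end)]
  m <- merge(dom, planted, by = "host_gene_id")
  if (nrow(m) == 0)
    return(list(n = 0L, boundary_within_tol = NA_real_,
                dominant_qtts_match = NA_real_,
                median_dominant_length = NA_real_,
                traversal_fraction = NA_real_))
  bound <- ifelse(m$da_strand == "+", m$tx_end - 1L, m$tx_start)
  list(n = nrow(m),
       boundary_within_tol = mean(abs(bound - m$darna_end) <= boundary_tol),
       dominant_qtts_match = mean(!is.na(m$qtts_pos) &
                                  abs(m$qtts_pos - m$darna_end) <= qtts_tol),
       median_dominant_length = as.numeric(median(m$length)),
       traversal_fraction = mean(m$traverses_host_tss))
}
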