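# Synthetic data generator: plants convergent promoter quadruples,
# divergent-only promoters and isolated TSSs on a toy genome, draws
# correlated treatment effects for the inner convergent TSS pair, and
# simulates strand-specific 5'-end, 3'-end and RNA-seq coverage tracks
# with negative-binomial replicate noise plus Poisson background.
#
# Quadruples follow the layout TSS1(-) < TSS2(+) < TSS3(-) < TSS4(+):
# TSS1/TSS2 are a divergent pair (uaRNA / host RNA), TSS3/TSS4 the
# downstream divergent pair (daRNA / dsRNA), TSS2 transcribing toward
# TSS3. The host RNA (TSS2) and the daRNA (TSS3) get RNA-seq bodies and
# 3'-end signal; the unstable uaRNA/dsRNA classes get 5'-end signal only.

#' Simulation configuration
#'
#' @param chrom_sizes named integer vector of chromosome lengths; `NULL`
#'   auto-sizes a single chromosome to fit all loci.
#' @param n_quadruples,n_divergent_only,n_isolated numbers of planted
#'   architectures.
#' @param gap_range (min, max) bp for the TSS2-TSS3 distance; minimum 2.
#' @param divergent_gap_range (min, max) bp for divergent TSS1-TSS2 and
#'   TSS3-TSS4 distances.
#' @param baseline_mean_range (min, max) expected 5'-end tags per TSS per
#'   replicate; baselines are drawn log-uniformly.
#' @param dispersion negative-binomial dispersion
#'   (`variance = mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param effect_rho target correlation of the TSS2/TSS3 treatment log2FC
#'   effects, in `[0, 1]`.
#' @param effect_sd standard deviation of the planted log2FC effects.
#' @param n_replicates replicates per condition (conditions are `control`
#'   and `treated`).
#' @param background_rate expected background tags per bp per strand per
#'   sample on the end-count tracks.
#' @param coverage_depth expected RNA-seq per-base coverage over a
#'   transcript body per sample.
#' @param dominant_margin factor by which the TSS2 baseline exceeds the
#'   strongest other TSS of its quadruple.
#' @param jitter_cap,jitter_p positional jitter of end tags: offset
#'   magnitudes are geometric(`jitter_p`) capped at `jitter_cap` bp with a
#'   random sign, so the planted position is the unique mode.
#' @param min_spacing minimum bp between the bounding boxes of planted
#'   loci (prevents cross-locus pairings under the 2,500 bp window).
#' @param darna_len_range,host_len_range,ua_len_range,ds_len_range
#'   (min, max) bp transcript body lengths per RNA class.
#' @param seed integer seed; all generator randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = NULL,
                       n_quadruples = 50L, n_divergent_only = 20L, n_isolated = 20L,
                       gap_range = c(2L, 2300L),
                       divergent_gap_range = c(60L, 300L),
                       baseline_mean_range = c(20, 200),
                       dispersion = 0.05,
                       effect_rho = 0.6, effect_sd = 1,
                       n_replicates = 3L,
                       background_rate = 0.01,
                       coverage_depth = 15,
                       dominant_margin = 2,
                       jitter_cap = 10L, jitter_p = 0.5,
                       min_spacing = 5000L,
                       darna_len_range = c(2000L, 12000L),
                       host_len_range = c(3000L, 8000L),
                       ua_len_range = c(300L, 1500L),
                       ds_len_range = c(1000L, 3000L),
                       seed = 1L) {
  stopifnot(n_quadruples >= 0, n_divergent_only >= 0, n_isolated >= 0,
            effect_rho >= 0, effect_rho <= 1, dispersion >= 0,
            gap_range[1] >= 2, gap_range[1] <= gap_range[2],
            baseline_mean_range[1] > 0, n_replicates >= 1,
            background_rate >= 0, coverage_depth >= 0, dominant_margin >= 1,
            min_spacing >= 0, effect_sd >= 0)
  cfg <- list(chrom_sizes = chrom_sizes,
              n_quadruples = as.integer(n_quadruples),
              n_divergent_only = as.integer(n_divergent_only),
              n_isolated = as.integer(n_isolated),
              gap_range = as.integer(gap_range),
              divergent_gap_range = as.integer(divergent_gap_range),
              baseline_mean_range = as.numeric(baseline_mean_range),
              dispersion = dispersion, effect_rho = effect_rho,
              effect_sd = effect_sd, n_replicates = as.integer(n_replicates),
              background_rate = background_rate, coverage_depth = coverage_depth,
              dominant_margin = dominant_margin,
              jitter_cap = as.integer(jitter_cap), jitter_p = jitter_p,
              min_spacing = as.integer(min_spacing),
              darna_len_range = as.integer(darna_len_range),
              host_len_range = as.integer(host_len_range),
              ua_len_range = as.integer(ua_len_range),
              ds_len_range = as.integer(ds_len_range),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Run expr with a private RNG stream; restores the caller's RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.runifint <- function(n, lo, hi) as.integer(floor(runif(n, lo, hi + 1)))
.loguniform <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Plant promoter architectures
#'
#' Places `n_quadruples + n_divergent_only + n_isolated` loci with at
#' least `min_spacing` bp between locus bounding boxes, draws baselines
#' and correlated treatment effects, and records the planted truth.
#' Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return object of class `truth_set`: list with `tss` (one row per
#'   planted TSS: locus_id, architecture, label, chrom, pos, strand,
#'   baseline, log2fc, body_start, body_end, tts_pos, has_body,
#'   gene_id), `loci` (locus summaries incl. darna_end), `chrom_sizes`
#'   and the config.
#' @export
plant_loci <- function(config) {
  stopifnot(is(config, "sim_config"))
  .with_seed(config$seed, .plant_loci_impl(config))
}

.plant_loci_impl <- function(cfg) {
  n_total <- cfg$n_quadruples + cfg$n_divergent_only + cfg$n_isolated
  arch <- rep(c("quadruple", "divergent_only", "isolated"),
              c(cfg$n_quadruples, cfg$n_divergent_only, cfg$n_isolated))
  if (n_total == 0) {
    return(structure(list(tss = .empty_truth_tss(), loci = .empty_truth_loci(),
                          chrom_sizes = cfg$chrom_sizes %||% c(chrS1 = 10000L),
                          config = cfg),
                     class = "truth_set"))
  }
  # correlated treatment effects for quadruples (TSS2, TSS3)
  eff23 <- .bvn_effects(cfg$n_quadruples, cfg$effect_rho, cfg$effect_sd)
  # per-locus geometry and anchored (TSS2-relative) layout
  loci <- vector("list", n_total)
  tss <- vector("list", n_total)
  qi <- 0L
  for (i in seq_len(n_total)) {
    a <- arch[i]
    if (a == "quadruple") {
      qi <- qi + 1L
      g12 <- .runifint(1, cfg$divergent_gap_range[1], cfg$divergent_gap_range[2])
      g23 <- .runifint(1, cfg$gap_range[1], cfg$gap_range[2])
      g34 <- .runifint(1, cfg$divergent_gap_range[1], cfg$divergent_gap_range[2])
      len_ua <- .runifint(1, cfg$ua_len_range[1], cfg$ua_len_range[2])
      len_host <- .runifint(1, cfg$host_len_range[1], cfg$host_len_range[2])
      len_da <- .runifint(1, cfg$darna_len_range[1], cfg$darna_len_range[2])
      len_ds <- .runifint(1, cfg$ds_len_range[1], cfg$ds_len_range[2])
      base_other <- .loguniform(3, cfg$baseline_mean_range[1], cfg$baseline_mean_range[2])
      base2 <- cfg$dominant_margin * max(base_other) * runif(1, 1.0, 1.5)
      lfc2 <- eff23[qi, 1]; lfc3 <- eff23[qi, 2]
      # positions relative to TSS2 = 0
      rel <- c(tss1 = -g12, tss2 = 0L, tss3 = g23, tss4 = g23 + g34)
      t <- data.table(
        label = c("TSS1", "TSS2", "TSS3", "TSS4"),
        rel_pos = as.integer(rel),
        strand = c("-", "+", "-", "+"),
        baseline = c(base_other[1], base2, base_other[2], base_other[3]),
        log2fc = c(lfc2, lfc2, lfc3, lfc3),   # outer TSSs copy their divergent partner
        body_len = c(len_ua, len_host, len_da, len_ds),
        has_body = c(FALSE, TRUE, TRUE, FALSE)
      )
      t[, `:=`(rel_body_start = ifelse(strand == "+", rel_pos, rel_pos - body_len + 1L),
               rel_body_end = ifelse(strand == "+", rel_pos + body_len, rel_pos + 1L))]
    } else if (a == "divergent_only") {
      g12 <- .runifint(1, cfg$divergent_gap_range[1], cfg$divergent_gap_range[2])
      len_ua <- .runifint(1, cfg$ua_len_range[1], cfg$ua_len_range[2])
      len_host <- .runifint(1, cfg$host_len_range[1], cfg$host_len_range[2])
      base <- .loguniform(2, cfg$baseline_mean_range[1], cfg$baseline_mean_range[2])
      lfc <- rnorm(1, 0, cfg$effect_sd)
      t <- data.table(
        label = c("uTSS", "TSS"),
        rel_pos = c(-g12, 0L), strand = c("-", "+"),
        baseline = c(base[1], max(base)), log2fc = c(lfc, lfc),
        body_len = c(len_ua, len_host), has_body = c(FALSE, TRUE)
      )
      t[, `:=`(rel_body_start = ifelse(strand == "+", rel_pos, rel_pos - body_len + 1L),
               rel_body_end = ifelse(strand == "+", rel_pos + body_len, rel_pos + 1L))]
    } else {
      len_host <- .runifint(1, cfg$host_len_range[1], cfg$host_len_range[2])
      str <- sample(c("+", "-"), 1)
      base <- .loguniform(1, cfg$baseline_mean_range[1], cfg$baseline_mean_range[2])
      lfc <- rnorm(1, 0, cfg$effect_sd)
      t <- data.table(label = "TSS", rel_pos = 0L, strand = str,
                      baseline = base, log2fc = lfc,
                      body_len = len_host, has_body = TRUE)
      t[, `:=`(rel_body_start = ifelse(strand == "+", rel_pos, rel_pos - body_len + 1L),
               rel_body_end = ifelse(strand == "+", rel_pos + body_len, rel_pos + 1L))]
    }
    t[, locus_id := i]
    t[, architecture := a]
    tss[[i]] <- t
  }
  tss <- rbindlist(tss)
  # bounding boxes relative to the locus anchor
  bounds <- tss[, .(lo = min(c(rel_pos, rel_body_start)),
                    hi = max(c(rel_pos + 1L, rel_body_end))), by = locus_id]
  widths <- bounds$hi - bounds$lo
  # sequential placement with min_spacing between boxes
  total_needed <- sum(widths) + (n_total + 1) * cfg$min_spacing
  if (is.null(cfg$chrom_sizes)) {
    chrom_sizes <- c(chrS1 = as.integer(total_needed))
  } else {
    chrom_sizes <- cfg$chrom_sizes
    if (sum(as.numeric(chrom_sizes)) < total_needed)
      stop("plant_loci: chromosomes too small to place all loci with the required spacing")
  }
  anchors <- integer(n_total); chroms <- character(n_total)
  ci <- 1L
  cursor <- cfg$min_spacing
  for (i in seq_len(n_total)) {
    while (cursor + widths[i] + cfg$min_spacing > chrom_sizes[ci]) {
      ci <- ci + 1L
      if (ci > length(chrom_sizes))
        stop("plant_loci: chromosomes too small to place all loci with the required spacing")
      cursor <- cfg$min_spacing
    }
    anchors[i] <- as.integer(cursor - bounds$lo[i])
    chroms[i] <- names(chrom_sizes)[ci]
    cursor <- cursor + widths[i] + cfg$min_spacing
  }
  tss[, chrom := chroms[locus_id]]
  tss[, anchor := anchors[locus_id]]
  tss[, pos := as.integer(anchor + rel_pos)]
  tss[, body_start := as.integer(anchor + rel_body_start)]
  tss[, body_end := as.integer(anchor + rel_body_end)]
  tss[, tts_pos := ifelse(strand == "+", body_end - 1L, body_start)]
  tss[, gene_id := ifelse(
    (architecture == "quadruple" & label == "TSS2") |
      (architecture != "quadruple" & label == "TSS"),
    sprintf("SIMG%04d", locus_id), NA_character_)]
  tss <- tss[, .(locus_id, architecture, label, chrom, pos, strand, baseline,
                 log2fc, body_start, body_end, tts_pos, has_body, gene_id)]
  loci <- tss[, .(architecture = architecture[1], chrom = chrom[1],
                  start = min(pos), end = max(pos) + 1L,
                  host_gene_id = na.omit(gene_id)[1],
                  darna_end = if (architecture[1] == "quadruple")
                    body_start[label == "TSS3"] else NA_integer_,
                  gap_2_3 = if (architecture[1] == "quadruple")
                    pos[label == "TSS3"] - pos[label == "TSS2"] else NA_integer_),
              by = locus_id]
  structure(list(tss = tss, loci = loci, chrom_sizes = chrom_sizes, config = cfg),
            class = "truth_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_truth_tss <- function() {
  data.table(locus_id = integer(0), architecture = character(0), label = character(0),
             chrom = character(0), pos = integer(0), strand = character(0),
             baseline = numeric(0), log2fc = numeric(0), body_start = integer(0),
             body_end = integer(0), tts_pos = integer(0), has_body = logical(0),
             gene_id = character(0))
}

.empty_truth_loci <- function() {
  data.table(locus_id = integer(0), architecture = character(0), chrom = character(0),
             start = integer(0), end = integer(0), host_gene_id = character(0),
             darna_end = integer(0), gap_2_3 = integer(0))
}

# Bivariate normal effects with correlation rho and sd s.
.bvn_effects <- function(n, rho, s) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(s * z1, s * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> loci=%d (quadruple=%d divergent_only=%d isolated=%d)\n",
              nrow(x$loci), sum(x$loci$architecture == "quadruple"),
              sum(x$loci$architecture == "divergent_only"),
              sum(x$loci$architecture == "isolated")))
  invisible(x)
}

# NB draw with variance mu + disp*mu^2 (Poisson when disp == 0).
.rcounts <- function(n, mu, disp) {
  if (length(mu) < n) mu <- rep(mu, length.out = n)
  if (disp == 0) return(rpois(n, mu))
  rnbinom(n, size = 1 / disp, mu = mu)
}

#' Simulate strand-specific signal tracks
#'
#' For every sample (condition x replicate), 5'-end tags pile at each
#' planted TSS with total NB(mu = baseline * 2^(log2fc * treated),
#' dispersion) spread over geometric positional jitter; 3'-end tags pile
#' the same way at the planted transcript 3' ends of host and daRNA
#' bodies; RNA-seq coverage spans each such body at NB-drawn constant
#' depth; background tags are Poisson per bp on the end tracks.
#' Deterministic given the config seed.
#'
#' @param truth a `truth_set` from [plant_loci()].
#' @param config the [sim_config()] (defaults to the one in `truth`).
#' @return object of class `sim_tracks`: list with `samples` (sample
#'   sheet), long-format `five_prime`, `three_prime` (sample_id, chrom,
#'   pos, strand, count) and `coverage` (sample_id, chrom, start, end,
#'   strand, depth) tables, and `chrom_sizes`.
#' @export
simulate_tracks <- function(truth, config = truth$config) {
  stopifnot(is(truth, "truth_set"))
  if (any(truth$tss$baseline < 0)) stop("simulate_tracks: negative baseline means")
  .with_seed(config$seed + 1L, .simulate_tracks_impl(truth, config))
}

.simulate_tracks_impl <- function(truth, cfg) {
  samples <- data.table(
    sample_id = c(sprintf("control_rep%d", seq_len(cfg$n_replicates)),
                  sprintf("treated_rep%d", seq_len(cfg$n_replicates))),
    condition = rep(c("control", "treated"), each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), 2)
  )
  tssdt <- truth$tss
  chrom_sizes <- truth$chrom_sizes
  genome <- sum(as.numeric(chrom_sizes))
  five <- list(); three <- list(); cov <- list()
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    treated <- samples$condition[si] == "treated"
    if (nrow(tssdt)) {
      mu <- tssdt$baseline * 2^(tssdt$log2fc * treated)
      tot5 <- .rcounts(nrow(tssdt), mu, cfg$dispersion)
      five[[length(five) + 1]] <-
        .jitter_tags(tssdt$chrom, tssdt$pos, tssdt$strand, tot5,
                     cfg$jitter_p, cfg$jitter_cap, chrom_sizes)[, sample_id := sid]
      bodies <- tssdt[has_body == TRUE]
      if (nrow(bodies)) {
        mu_b <- bodies$baseline * 2^(bodies$log2fc * treated)
        tot3 <- .rcounts(nrow(bodies), mu_b, cfg$dispersion)
        three[[length(three) + 1]] <-
          .jitter_tags(bodies$chrom, bodies$tts_pos, bodies$strand, tot3,
                       cfg$jitter_p, cfg$jitter_cap, chrom_sizes)[, sample_id := sid]
        depth <- .rcounts(nrow(bodies), cfg$coverage_depth * 2^(bodies$log2fc * treated),
                          cfg$dispersion)
        cov[[length(cov) + 1]] <- data.table(
          sample_id = sid, chrom = bodies$chrom, start = bodies$body_start,
          end = bodies$body_end, strand = bodies$strand, depth = as.numeric(depth)
        )[depth > 0]
      }
    }
    if (cfg$background_rate > 0) {
      for (sig in c("five", "three")) {
        bg <- .background_tags(chrom_sizes, cfg$background_rate)
        if (nrow(bg)) {
          bg[, sample_id := sid]
          if (sig == "five") five[[length(five) + 1]] <- bg
          else three[[length(three) + 1]] <- bg
        }
      }
    }
  }
  bind <- function(lst) {
    if (length(lst) == 0)
      return(data.table(sample_id = character(0), chrom = character(0),
                        pos = integer(0), strand = character(0), count = integer(0)))
    out <- rbindlist(lst, use.names = TRUE)
    out <- out[, .(count = sum(count)), by = .(sample_id, chrom, strand, pos)]
    setorder(out, sample_id, chrom, strand, pos)
    out[, .(sample_id, chrom, pos, strand, count)]
  }
  covdt <- if (length(cov)) rbindlist(cov) else
    data.table(sample_id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), depth = numeric(0))
  setorder(covdt, sample_id, chrom, strand, start)
  structure(list(samples = samples, five_prime = bind(five), three_prime = bind(three),
                 coverage = covdt, chrom_sizes = chrom_sizes, config = cfg),
            class = "sim_tracks")
}

# Spread per-site totals over geometric positional jitter.
.jitter_tags <- function(chrom, pos, strand, totals, p, cap, chrom_sizes) {
  totals <- as.integer(totals)
  keep <- totals > 0
  if (!any(keep))
    return(data.table(chrom = character(0), pos = integer(0),
                      strand = character(0), count = integer(0)))
  chrom <- rep(chrom[keep], totals[keep])
  anchor <- rep(pos[keep], totals[keep])
  strand <- rep(strand[keep], totals[keep])
  n <- length(anchor)
  off <- pmin(rgeom(n, p), cap) * sample(c(-1L, 1L), n, replace = TRUE)
  at <- anchor + off
  lim <- chrom_sizes[chrom]
  at <- pmax(0L, pmin(as.integer(lim) - 1L, at))
  dt <- data.table(chrom = chrom, pos = as.integer(at), strand = strand)
  dt[, .(count = .N), by = .(chrom, pos, strand)][, .(chrom, pos, strand, count)]
}

# Poisson background: total tags ~ Pois(rate * length) per chrom/strand,
# positions uniform.
.background_tags <- function(chrom_sizes, rate) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    len <- as.numeric(chrom_sizes[[ch]])
    for (s in c("+", "-")) {
      n <- rpois(1, rate * len)
      if (n > 0) {
        at <- .runifint(n, 0, len - 1)
        out[[length(out) + 1]] <- data.table(chrom = ch, pos = at, strand = s)
      }
    }
  }
  if (length(out) == 0)
    return(data.table(chrom = character(0), pos = integer(0),
                      strand = character(0), count = integer(0)))
  dt <- rbindlist(out)
  dt[, .(count = .N), by = .(chrom, pos, strand)][, .(chrom, pos, strand, count)]
}

#' @export
print.sim_tracks <- function(x, ...) {
  cat(sprintf("<sim_tracks> samples=%d five_prime=%d three_prime=%d coverage_runs=%d\n",
              nrow(x$samples), nrow(x$five_prime), nrow(x$three_prime),
              nrow(x$coverage)))
  invisible(x)
}

#' Extract one sample's track from simulated data
#'
#' @param sim a `sim_tracks` object.
#' @param sample_id sample to extract.
#' @param signal `"five_prime"`, `"three_prime"` or `"coverage"`.
#' @return [end_track()] or [coverage_track()].
#' @export
get_track <- function(sim, sample_id, signal = c("five_prime", "three_prime", "coverage")) {
  signal <- match.arg(signal)
  sid <- sample_id
  if (!sid %in% sim$samples$sample_id) stop("get_track: unknown sample ", sid)
  if (signal == "coverage") {
    coverage_track(sim$coverage[sample_id == sid, .(chrom, start, end, strand, depth)], sid)
  } else {
    end_track(sim[[signal]][sample_id == sid, .(chrom, pos, strand, count)],
              sid, signal)
  }
}

#' Pool simulated coverage across samples
#'
#' Total (summed) per-base depth across all samples, as obtained from
#' merged libraries; the daRNA coverage threshold is applied to this
#' pooled signal.
#'
#' @param sim `sim_tracks`.
#' @return [coverage_track()] with per-base total depth across samples.
#' @export
pooled_coverage <- function(sim) {
  coverage_track(sim$coverage[, .(chrom, start, end, strand, depth)], "pooled")
}

#' Write the planted truth to files
#'
#' Writes `truth_tss.bed` (BED6, name = label, score = baseline),
#' `truth_table.tsv` (all planted TSS attributes incl. log2FCs and body
#' ends) and `annotation.gtf` (host genes; annotated TSS at TSS2 for
#' quadruples, at the single TSS otherwise).
#'
#' @param truth `truth_set`.
#' @param outdir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
write_truth <- function(truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tss <- truth$tss
  bed <- tss[, .(chrom, start = pos, end = pos + 1L,
                 name = sprintf("L%d_%s", locus_id, label),
                 score = round(baseline, 3), strand)]
  f_bed <- file.path(outdir, "truth_tss.bed")
  write_bed6(bed, f_bed)
  f_tsv <- file.path(outdir, "truth_table.tsv")
  write_tsv(tss, f_tsv, sort_by = c("chrom", "pos", "strand"))
  ann <- .truth_annotation_records(truth)
  f_gtf <- file.path(outdir, "annotation.gtf")
  write_gtf(ann, f_gtf)
  invisible(list(bed = f_bed, tsv = f_tsv, gtf = f_gtf))
}

# Host-gene annotation records (the daRNA/uaRNA/dsRNA classes stay
# unannotated, as for novel antisense transcripts).
.truth_annotation_records <- function(truth) {
  g <- truth$tss[!is.na(gene_id)]
  if (nrow(g) == 0)
    return(data.table(gene_id = character(0), transcript_id = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), biotype = character(0)))
  g[, .(gene_id, transcript_id = paste0(gene_id, ".1"), chrom,
        start = body_start, end = body_end, strand, biotype = "protein_coding")]
}

#' Truth annotation as an in-memory object
#'
#' @param truth `truth_set`.
#' @return `transcript_annotation` of the planted host genes.
#' @export
truth_annotation <- function(truth) {
  transcript_annotation(.truth_annotation_records(truth))
}

#' Write simulated tracks as bedGraph files plus a sample sheet
#'
#' One file per sample, signal and strand, named
#' `{sample}.{signal}.{strand}.bedgraph` (strand encoded as `plus` /
#' `minus`), plus `samples.tsv`.
#'
#' @param sim `sim_tracks`.
#' @param outdir output directory.
#' @return data.table manifest of written files, invisibly.
#' @export
write_tracks <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (sid in sim$samples$sample_id) {
    for (sig in c("five_prime", "three_prime", "coverage")) {
      tr <- get_track(sim, sid, sig)
      for (s in c("+", "-")) {
        f <- file.path(outdir, sprintf("%s.%s.%s.bedgraph", sid, sig,
                                       ifelse(s == "+", "plus", "minus")))
        write_bedgraph(tr, f, s)
        manifest[[length(manifest) + 1]] <-
          data.table(sample_id = sid, signal = sig, strand = s, path = f)
      }
    }
  }
  write_tsv(sim$samples, file.path(outdir, "samples.tsv"))
  invisible(rbindlist(manifest))
}
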