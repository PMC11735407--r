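# Pipeline orchestration: stages call-tss -> detect-core/extended ->
# annotate-darna -> quantify -> correlate, driven by a validated config,
# with deterministic outputs and a machine-readable JSON manifest.

.pipeline_config_keys <- c(
  "input_dir", "annotation", "sample_sheet", "outdir", "seed",
  "peak_params", "detection_params", "darna_params",
  "treated", "control", "pseudocount", "log_level"
)

#' Build a pipeline configuration
#'
#' @param input_dir directory with `{sample}.{signal}.{strand}.bedgraph`
#'   track files (as written by [write_tracks()]).
#' @param annotation path to a GTF/BED12 transcript annotation.
#' @param sample_sheet path to a TSV with sample_id, condition columns;
#'   defaults to `samples.tsv` inside `input_dir`.
#' @param outdir output directory.
#' @param seed integer seed recorded in the manifest (the pipeline stages
#'   are deterministic; the seed is reserved for stochastic extensions).
#' @param peak_params,detection_params,darna_params component parameter
#'   objects.
#' @param treated,control condition labels for the fold-change contrast.
#' @param pseudocount pseudocount for [log2fc()].
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, annotation,
                            sample_sheet = file.path(input_dir, "samples.tsv"),
                            outdir = "cocoprom_out", seed = 1L,
                            peak_params = cocoprom::peak_params(),
                            detection_params = cocoprom::detection_params(),
                            darna_params = cocoprom::darna_params(),
                            treated = "treated", control = "control",
                            pseudocount = 1, log_level = "info") {
  cfg <- list(input_dir = input_dir, annotation = annotation,
              sample_sheet = sample_sheet, outdir = outdir, seed = as.integer(seed),
              peak_params = peak_params, detection_params = detection_params,
              darna_params = darna_params, treated = treated, control = control,
              pseudocount = pseudocount, log_level = log_level)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are errors (fail loud); nested parameter blocks map onto
#' [peak_params()], [detection_params()] and [darna_params()].
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("read_pipeline_config: file not found: ", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), .pipeline_config_keys)
  if (length(unknown))
    stop("read_pipeline_config: unknown config keys: ", paste(unknown, collapse = ", "))
  args <- y
  for (blk in c("peak_params", "detection_params", "darna_params")) {
    if (!is.null(y[[blk]])) args[[blk]] <- do.call(blk, y[[blk]])
  }
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration
#'
#' Checks that referenced inputs exist; fails naming the offending path.
#'
#' @param config `pipeline_config`.
#' @return `config`, invisibly.
#' @export
validate_pipeline_config <- function(config) {
  for (f in c(config$input_dir, config$annotation, config$sample_sheet)) {
    if (!file.exists(f))
      stop("pipeline config: missing input: ", f)
  }
  invisible(config)
}

.log <- function(cfg, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[cfg$log_level %||% "info"]] >= lv[[level]])
    message(sprintf("[cocoprom] %s", paste0(...)))
}

# Stable hash of the parameter set (md5 of its canonical JSON).
.strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_classes) else x
}

.params_hash <- function(cfg) {
  plain <- .strip_classes(cfg)
  js <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

# Read all per-strand track files for the samples into end_track /
# coverage_track objects.
.read_sample_tracks <- function(cfg, samples, signal) {
  out <- list()
  for (sid in samples$sample_id) {
    parts <- list()
    for (s in c("+", "-")) {
      f <- file.path(cfg$input_dir,
                     sprintf("%s.%s.%s.bedgraph", sid, signal,
                             ifelse(s == "+", "plus", "minus")))
      if (!file.exists(f)) stop("run_pipeline: missing input: ", f)
      parts[[s]] <- read_bedgraph(f, s, if (signal == "coverage") "coverage" else signal,
                                  sample_id = sid)
    }
    if (signal == "coverage") {
      out[[sid]] <- coverage_track(rbind(parts[["+"]]$runs, parts[["-"]]$runs), sid)
    } else {
      out[[sid]] <- end_track(rbind(parts[["+"]]$counts, parts[["-"]]$counts), sid, signal)
    }
  }
  out
}

# Single-strand subset of an end_track.
.strand_track <- function(tr, s) {
  end_track(tr$counts[strand == s], tr$sample_id, tr$signal_kind)
}

#' Run the full convergent-promoter pipeline
#'
#' Executes call-tss (5' CTSS and 3' QTTS site calling), detect-core,
#' detect-extended, annotate-darna, quantify and correlate, writing one
#' TSV per stage plus a JSON run manifest with a parameter hash. Outputs
#' are pure functions of (inputs, parameters, seed); rerunning with an
#' identical config reproduces byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly; also written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  samples <- read_tsv(cfg$sample_sheet)
  annotation <- read_annotation(cfg$annotation)
  manifest <- list(package = "cocoprom",
                   version = as.character(packageVersion("cocoprom")),
                   seed = cfg$seed, params_hash = .params_hash(cfg),
                   stages = list())
  t5 <- .read_sample_tracks(cfg, samples, "five_prime")
  t3 <- .read_sample_tracks(cfg, samples, "three_prime")
  cov <- .read_sample_tracks(cfg, samples, "coverage")

  # stage: call-tss
  .log(cfg, "info", "stage call-tss")
  ctss <- rbind(call_sites(lapply(t5, .strand_track, "+"), cfg$peak_params),
                call_sites(lapply(t5, .strand_track, "-"), cfg$peak_params))
  setorder(ctss, chrom, pos)
  qtts <- rbind(call_sites(lapply(t3, .strand_track, "+"), cfg$peak_params),
                call_sites(lapply(t3, .strand_track, "-"), cfg$peak_params))
  setorder(qtts, chrom, pos)
  f_ctss <- file.path(cfg$outdir, "ctss.tsv"); write_tsv(ctss, f_ctss)
  f_qtts <- file.path(cfg$outdir, "qtts.tsv"); write_tsv(qtts, f_qtts)
  manifest$stages$call_tss <- list(outputs = c(f_ctss, f_qtts),
                                   n_ctss = nrow(ctss), n_qtts = nrow(qtts))

  # stage: detect-core
  .log(cfg, "info", "stage detect-core")
  core <- detect_core(ctss[strand == "-"], ctss[strand == "+"], annotation,
                      cfg$detection_params)
  f_core <- file.path(cfg$outdir, "core_quadruples.tsv")
  write_tsv(core, f_core, sort_by = c("chrom", "tss2_pos"))
  manifest$stages$detect_core <- list(outputs = f_core, n = nrow(core))

  # stage: detect-extended
  .log(cfg, "info", "stage detect-extended")
  extended <- detect_extended(ctss[strand == "+"], ctss[strand == "-"], annotation,
                              cfg$detection_params)
  f_ext <- file.path(cfg$outdir, "extended_pairs.tsv")
  write_tsv(extended, f_ext, sort_by = c("chrom", "host_pos"))
  manifest$stages$detect_extended <- list(outputs = f_ext, n = nrow(extended))

  # stage: annotate-darna (total coverage pooled across samples)
  .log(cfg, "info", "stage annotate-darna")
  pooled_cov <- coverage_track(rbindlist(lapply(cov, function(x) x$runs)), "pooled")
  darnas <- annotate_darnas(core, pooled_cov, qtts, annotation, ctss,
                            cfg$darna_params)
  f_darna <- file.path(cfg$outdir, "darnas.tsv")
  write_tsv(darnas, f_darna, sort_by = c("chrom", "da_pos", "rank"))
  f_darna_gtf <- file.path(cfg$outdir, "darnas.gtf")
  if (nrow(darnas)) {
    write_gtf(darnas[, .(gene_id = paste0(host_gene_id, "_daRNA"),
                         transcript_id = name, chrom, start = tx_start,
                         end = tx_end, strand = da_strand, biotype = "daRNA")],
              f_darna_gtf)
  } else writeLines(character(0), f_darna_gtf)
  manifest$stages$annotate_darna <- list(outputs = c(f_darna, f_darna_gtf),
                                         n = nrow(darnas))

  # stage: quantify (per-sample 5'-end counts in CTSS peaks)
  .log(cfg, "info", "stage quantify")
  features <- unique(ctss[, .(chrom, start = peak_start, end = peak_end, strand)])
  features[, feature_id := sprintf("%s:%d-%d:%s", chrom, start, end, strand)]
  cm <- count_matrix(t5, features, samples)
  diff <- log2fc(cm, cfg$treated, cfg$control, cfg$pseudocount)
  f_counts <- file.path(cfg$outdir, "counts.tsv")
  write_tsv(data.table(feature_id = features$feature_id, cm$counts), f_counts)
  f_diff <- file.path(cfg$outdir, "log2fc.tsv")
  write_tsv(diff, f_diff, sort_by = "feature_id")
  manifest$stages$quantify <- list(outputs = c(f_counts, f_diff),
                                   n_features = nrow(features))

  # stage: correlate (TSS2 vs TSS3 log2FC, grouped by expression and distance)
  .log(cfg, "info", "stage correlate")
  fid <- function(chrom, s, e, strand) sprintf("%s:%d-%d:%s", chrom, s, e, strand)
  lfc <- setNames(diff$log2fc, diff$feature_id)
  bm <- setNames(diff$base_mean, diff$feature_id)
  report <- data.table()
  pairs_lfc <- data.table()
  if (nrow(core)) {
    id2 <- fid(core$chrom, core$tss2_peak_start, core$tss2_peak_end, core$tss2_strand)
    id3 <- fid(core$chrom, core$tss3_peak_start, core$tss3_peak_end, core$tss3_strand)
    pairs_lfc <- data.table(host_gene_id = core$host_gene_id,
                            chrom = core$chrom,
                            tss2_pos = core$tss2_pos, tss3_pos = core$tss3_pos,
                            distance_2_3 = core$distance_2_3,
                            tss2_log2fc = lfc[id2], tss3_log2fc = lfc[id3],
                            tss2_base_mean = bm[id2])
    pairs_lfc <- pairs_lfc[is.finite(tss2_log2fc) & is.finite(tss3_log2fc)]
    if (nrow(pairs_lfc) >= 3) {
      grp_expr <- if (nrow(pairs_lfc) >= 9)
        paste0("expression_", tertiles(pairs_lfc$tss2_base_mean)) else NULL
      grp_dist <- if (nrow(pairs_lfc) >= 9)
        paste0("distance_", tertiles(pairs_lfc$distance_2_3)) else NULL
      report <- rbind(
        correlation_report(pairs_lfc$tss2_log2fc, pairs_lfc$tss3_log2fc, grp_expr),
        if (!is.null(grp_dist))
          correlation_report(pairs_lfc$tss2_log2fc, pairs_lfc$tss3_log2fc,
                             grp_dist)[group != "all"]
      )
    }
  }
  f_pairs <- file.path(cfg$outdir, "tss_pair_log2fc.tsv")
  write_tsv(pairs_lfc, f_pairs, sort_by = if (nrow(pairs_lfc)) c("chrom", "tss2_pos") else NULL)
  f_report <- file.path(cfg$outdir, "correlation_report.tsv")
  write_tsv(report, f_report)
  manifest$stages$correlate <- list(outputs = c(f_pairs, f_report),
                                    n_pairs = nrow(pairs_lfc))

  f_manifest <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .log(cfg, "info", "done; manifest at ", f_manifest)
  invisible(manifest)
}

#' Simulate a dataset to disk
#'
#' Convenience wrapper: [plant_loci()], [simulate_tracks()],
#' [write_truth()] and [write_tracks()] into one directory, ready for
#' [run_pipeline()].
#'
#' @param config [sim_config()].
#' @param outdir output directory.
#' @return list with the truth set and the written file manifest,
#'   invisibly.
#' @export
simulate_dataset <- function(config, outdir) {
  truth <- plant_loci(config)
  sim <- simulate_tracks(truth, config)
  files <- write_truth(truth, outdir)
  tracks <- write_tracks(sim, outdir)
  invisible(list(truth = truth, sim = sim, truth_files = files, track_files = tracks))
}

#' Run detection and co-regulation analysis on simulated tracks in memory
#'
#' Convenience path used for validation studies: performs CTSS/QTTS site
#' calling, core and extended detection, daRNA annotation, peak-level
#' quantification and the TSS2/TSS3 fold-change correlation directly on a
#' [simulate_tracks()] object, without touching the file system.
#'
#' @param truth `truth_set` (supplies the host-gene annotation).
#' @param sim `sim_tracks`.
#' @param peak_params,detection_params,darna_params stage parameters.
#' @param treated,control condition labels.
#' @return list: ctss, qtts, core, extended, darnas, diff (feature
#'   log2fc), pairs_lfc (per-quadruple TSS2/TSS3 log2FCs), report
#'   (correlation summary).
#' @export
run_sim_analysis <- function(truth, sim,
                             peak_params = cocoprom::peak_params(),
                             detection_params = cocoprom::detection_params(),
                             darna_params = cocoprom::darna_params(),
                             treated = "treated", control = "control") {
  annotation <- truth_annotation(truth)
  samples <- sim$samples
  t5 <- lapply(samples$sample_id, function(s) get_track(sim, s, "five_prime"))
  names(t5) <- samples$sample_id
  t3 <- lapply(samples$sample_id, function(s) get_track(sim, s, "three_prime"))
  genome <- sum(as.numeric(sim$chrom_sizes))
  ctss <- rbind(call_sites(lapply(t5, .strand_track, "+"), peak_params, genome),
                call_sites(lapply(t5, .strand_track, "-"), peak_params, genome))
  setorder(ctss, chrom, pos)
  qtts <- rbind(call_sites(lapply(t3, .strand_track, "+"), peak_params, genome),
                call_sites(lapply(t3, .strand_track, "-"), peak_params, genome))
  setorder(qtts, chrom, pos)
  core <- detect_core(ctss[strand == "-"], ctss[strand == "+"], annotation,
                      detection_params)
  extended <- detect_extended(ctss[strand == "+"], ctss[strand == "-"], annotation,
                              detection_params)
  darnas <- annotate_darnas(core, pooled_coverage(sim), qtts, annotation, ctss,
                            darna_params)
  features <- unique(ctss[, .(chrom, start = peak_start, end = peak_end, strand)])
  features[, feature_id := sprintf("%s:%d-%d:%s", chrom, start, end, strand)]
  cm <- count_matrix(t5, features, samples)
  diff <- log2fc(cm, treated, control)
  lfc <- setNames(diff$log2fc, diff$feature_id)
  bm <- setNames(diff$base_mean, diff$feature_id)
  pairs_lfc <- data.table()
  report <- data.table()
  if (nrow(core)) {
    fid <- function(chrom, s, e, strand) sprintf("%s:%d-%d:%s", chrom, s, e, strand)
    id2 <- fid(core$chrom, core$tss2_peak_start, core$tss2_peak_end, core$tss2_strand)
    id3 <- fid(core$chrom, core$tss3_peak_start, core$tss3_peak_end, core$tss3_strand)
    pairs_lfc <- data.table(host_gene_id = core$host_gene_id, chrom = core$chrom,
                            tss2_pos = core$tss2_pos, tss3_pos = core$tss3_pos,
                            distance_2_3 = core$distance_2_3,
                            tss2_log2fc = lfc[id2], tss3_log2fc = lfc[id3],
                            tss2_base_mean = bm[id2])
    pairs_lfc <- pairs_lfc[is.finite(tss2_log2fc) & is.finite(tss3_log2fc)]
    if (nrow(pairs_lfc) >= 3)
      report <- correlation_report(pairs_lfc$tss2_log2fc, pairs_lfc$tss3_log2fc)
  }
  list(ctss = ctss, qtts = qtts, core = core, extended = extended,
       darnas = darnas, diff = diff, pairs_lfc = pairs_lfc, report = report)
}
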