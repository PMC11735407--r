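test_that("divergent pairing honors the 400 bp window boundary", {
  minus <- mk_sites(1000L, "-")
  plus_in <- mk_sites(1400L, "+")
  plus_out <- mk_sites(1401L, "+")
  p1 <- pair_divergent(minus, plus_in)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$distance, 400L)
  expect_equal(nrow(pair_divergent(minus, plus_out)), 0)
  # wrong strands and unsorted input are rejected
  expect_error(pair_divergent(plus_in, minus), "strand")
  unsorted <- rbind(mk_sites(500L, "-"), mk_sites(100L, "-"))
  expect_error(pair_divergent(unsorted, plus_in), "sorted")
})

test_that("divergent pairing equals the exhaustive mutual-nearest oracle", {
  set.seed(7)
  for (rep in 1:200) {
    nm <- sample(1:20, 1); np <- sample(1:20, 1)
    mpos <- sort(sample(0:3000, nm))
    ppos <- sort(sample(0:3000, np))
    pairs <- pair_divergent(mk_sites(mpos, "-"), mk_sites(ppos, "+"),
                            detection_params(divergent_window = 400))
    om <- oracle_mutual_pairs(mpos, ppos, 400)
    expect_equal(nrow(pairs), nrow(om))
    if (nrow(om)) {
      expect_equal(pairs$minus_pos, as.integer(om[, 1]))
      expect_equal(pairs$plus_pos, as.integer(om[, 2]))
    }
    # one-to-one: no site in two pairs
    expect_false(any(duplicated(pairs$minus_pos)))
    expect_false(any(duplicated(pairs$plus_pos)))
  }
})

test_that("quadruple assembly honors the 2,500 bp join boundary", {
  mk_pairs <- function(...) {
    pos <- list(...)
    rbindlist(lapply(pos, function(p)
      data.table::data.table(chrom = "chr1", minus_pos = p[1], minus_count = 10,
                             minus_peak_start = p[1] - 5L, minus_peak_end = p[1] + 6L,
                             plus_pos = p[2], plus_count = 10,
                             plus_peak_start = p[2] - 5L, plus_peak_end = p[2] + 6L,
                             distance = p[2] - p[1])))
  }
  q <- assemble_quadruples(mk_pairs(c(900L, 1000L), c(1500L, 1600L)))
  expect_equal(nrow(q), 1)
  expect_equal(q$gap, 500L)
  expect_equal(q$a_plus_pos, 1000L)
  expect_equal(q$b_minus_pos, 1500L)
  # gap of exactly 2,500 joins; 2,501 does not
  expect_equal(nrow(assemble_quadruples(mk_pairs(c(900L, 1000L), c(3500L, 3600L)))), 1)
  expect_equal(nrow(assemble_quadruples(mk_pairs(c(900L, 1000L), c(3501L, 3600L)))), 0)
  # zero gap is degenerate and rejected
  expect_equal(nrow(assemble_quadruples(mk_pairs(c(900L, 1000L), c(1000L, 1100L)))), 0)
})

test_that("quadruple assembly equals the pair-of-pairs enumeration oracle", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    # disjoint divergent pairs along the chromosome
    minus <- integer(n); plus <- integer(n); cur <- 0L
    for (i in seq_len(n)) {
      minus[i] <- cur + sample(1:3000, 1)
      plus[i] <- minus[i] + sample(0:400, 1)
      cur <- plus[i]
    }
    pairs <- data.table::data.table(
      chrom = "chr1", minus_pos = minus, minus_count = 10,
      minus_peak_start = minus - 5L, minus_peak_end = minus + 6L,
      plus_pos = plus, plus_count = 10,
      plus_peak_start = plus - 5L, plus_peak_end = plus + 6L,
      distance = plus - minus)
    q <- assemble_quadruples(pairs)
    om <- oracle_assemble(minus, plus, 2500)
    expect_equal(nrow(q), nrow(om))
    if (nrow(om)) {
      expect_equal(q$a_plus_pos, as.integer(om[, 1]))
      expect_equal(q$b_minus_pos, as.integer(om[, 2]))
      expect_equal(q$gap, as.integer(om[, 3]))
    }
  }
})

# A raw quadruple candidate: divergent pairs A = (900-, 1000+) and
# B = (1500-, 1600+), with per-TSS counts settable for label tests.
mk_quad <- function(counts = c(aM = 10, aP = 100, bM = 40, bP = 5)) {
  data.table::data.table(
    chrom = "chr1",
    a_minus_pos = 900L, b_minus_pos = 1500L,
    a_minus_count = counts[["aM"]], b_minus_count = counts[["bM"]],
    a_minus_peak_start = 895L, b_minus_peak_start = 1495L,
    a_minus_peak_end = 906L, b_minus_peak_end = 1506L,
    a_plus_pos = 1000L, b_plus_pos = 1600L,
    a_plus_count = counts[["aP"]], b_plus_count = counts[["bP"]],
    a_plus_peak_start = 995L, b_plus_peak_start = 1595L,
    a_plus_peak_end = 1006L, b_plus_peak_end = 1606L,
    gap = 500L)
}

test_that("the most expressed inner TSS becomes TSS2 with labels per orientation", {
  # dominant a_plus (+, upstream pair): plus_host layout TSS1- TSS2+ TSS3- TSS4+
  ann <- mk_ann("chr1", 1000L, 4000L, "+", "HOSTP")
  lab <- label_quadruples(mk_quad(), ann)
  expect_equal(nrow(lab), 1)
  expect_equal(lab$orientation, "plus_host")
  expect_equal(unlist(lab[, .(tss1_pos, tss2_pos, tss3_pos, tss4_pos)]),
               c(tss1_pos = 900L, tss2_pos = 1000L, tss3_pos = 1500L, tss4_pos = 1600L))
  expect_equal(unlist(lab[, .(tss1_strand, tss2_strand, tss3_strand, tss4_strand)]),
               c(tss1_strand = "-", tss2_strand = "+", tss3_strand = "-",
                 tss4_strand = "+"))
  expect_equal(lab$host_gene_id, "HOSTP")
  expect_equal(lab$distance_2_3, 500L)

  # dominant b_minus (-, downstream pair): labels mirror by strand symmetry
  annm <- mk_ann("chr1", 500L, 1501L, "-", "HOSTM")
  labm <- label_quadruples(mk_quad(c(aM = 10, aP = 40, bM = 100, bP = 5)), annm)
  expect_equal(labm$orientation, "minus_host")
  expect_equal(unlist(labm[, .(tss1_pos, tss2_pos, tss3_pos, tss4_pos)]),
               c(tss1_pos = 1600L, tss2_pos = 1500L, tss3_pos = 1000L, tss4_pos = 900L))
  expect_equal(labm$tss2_strand, "-")
  expect_equal(labm$host_gene_id, "HOSTM")
  expect_equal(labm$distance_2_3, 500L)
})

test_that("quadruples without annotation support or inner dominance are rejected", {
  # no annotated TSS inside the dominant peak
  far_ann <- mk_ann("chr1", 9000L, 9500L, "+")
  expect_equal(nrow(label_quadruples(mk_quad(), far_ann)), 0)
  # annotated TSS on the wrong strand
  wrong <- mk_ann("chr1", 500L, 1001L, "-")
  expect_equal(nrow(label_quadruples(mk_quad(), wrong)), 0)
  # dominant TSS is an outer TSS: no convergent orientation exists
  ann <- mk_ann("chr1", 1000L, 4000L, "+")
  expect_equal(nrow(label_quadruples(
    mk_quad(c(aM = 100, aP = 10, bM = 40, bP = 5)), ann)), 0)
})

test_that("expression ties resolve toward annotation support, then leftmost", {
  ann <- mk_ann("chr1", 500L, 1501L, "-", "G3")  # annotated TSS at 1500 on -
  lab <- label_quadruples(mk_quad(c(aM = 10, aP = 100, bM = 100, bP = 5)), ann)
  # tie between a_plus and b_minus: only b_minus overlaps annotation
  expect_equal(lab$orientation, "minus_host")
  expect_equal(lab$tss2_pos, 1500L)
  # with no annotation distinction the leftmost of the tied TSSs wins, and
  # host annotation must then support it
  ann2 <- mk_ann(c("chr1", "chr1"), c(1000L, 500L), c(4000L, 1501L),
                 c("+", "-"), c("GP", "GM"))
  lab2 <- label_quadruples(mk_quad(c(aM = 10, aP = 100, bM = 100, bP = 5)), ann2)
  expect_equal(lab2$orientation, "plus_host")
  expect_equal(lab2$tss2_pos, 1000L)
})

test_that("detection is invariant under mirroring the genome", {
  set.seed(23)
  L <- 100000L
  for (rep in 1:20) {
    nm <- sample(5:15, 1); np <- sample(5:15, 1)
    mpos <- sort(sample(0:(L - 1), nm))
    ppos <- sort(sample(0:(L - 1), np))
    cnt <- sample(100:10000, nm + np)  # distinct so labeling has no ties
    cm <- cnt[seq_len(nm)]; cp <- cnt[nm + seq_len(np)]
    ann_pos <- sort(sample(0:(L - 1), 5))
    ann <- mk_ann("chr1", ann_pos, ann_pos + 100L, "+")
    fwd <- detect_core(mk_sites(mpos, "-", cm), mk_sites(ppos, "+", cp), ann)
    # mirror: x -> L-1-x, strands flip; peaks [s,e) -> [L-e, L-s)
    ann_mir <- mk_ann("chr1", L - (ann_pos + 100L), L - ann_pos, "-")
    rev_ <- detect_core(mk_sites(L - 1L - ppos, "-", cp),
                        mk_sites(L - 1L - mpos, "+", cm), ann_mir)
    expect_equal(nrow(rev_), nrow(fwd))
    if (nrow(fwd)) {
      expect_setequal(L - 1L - rev_$tss2_pos, fwd$tss2_pos)
      expect_setequal(L - 1L - rev_$tss3_pos, fwd$tss3_pos)
      expect_equal(sort(rev_$distance_2_3), sort(fwd$distance_2_3))
    }
  }
})

test_that("extended pairing applies the stated host selection rules", {
  params <- detection_params()
  # only + annotated: + is host
  ann_p <- mk_ann("chr1", 500L, 2000L, "+", "GP")
  e1 <- detect_extended(mk_sites(500L, "+", count = 10),
                        mk_sites(900L, "-", count = 50), ann_p, params)
  expect_equal(nrow(e1), 1)
  expect_equal(e1$host_strand, "+")
  expect_equal(e1$host_pos, 500L)
  expect_equal(e1$da_pos, 900L)
  expect_equal(e1$distance, 400L)
  expect_equal(e1$host_gene_id, "GP")
  # both annotated, - more expressed: - is host
  ann_b <- mk_ann(c("chr1", "chr1"), c(500L, 300L), c(2000L, 901L),
                  c("+", "-"), c("GP", "GM"))
  e2 <- detect_extended(mk_sites(500L, "+", count = 10),
                        mk_sites(900L, "-", count = 50), ann_b, params)
  expect_equal(e2$host_strand, "-")
  expect_equal(e2$host_gene_id, "GM")
  # neither annotated: pair dropped
  e3 <- detect_extended(mk_sites(500L, "+"), mk_sites(900L, "-"),
                        mk_ann("chr1", 9000L, 9100L, "+"), params)
  expect_equal(nrow(e3), 0)
  # beyond the window: no pair
  e4 <- detect_extended(mk_sites(500L, "+"), mk_sites(3001L, "-"), ann_p, params)
  expect_equal(nrow(e4), 0)
})

test_that("extended pairing equals the exhaustive oracle before filtering", {
  set.seed(29)
  for (rep in 1:200) {
    np <- sample(1:15, 1); nm <- sample(1:15, 1)
    ppos <- sort(sample(0:20000, np))
    mpos <- sort(sample(0:20000, nm))
    # annotate every summit on both strands so no candidate is dropped by
    # the filter (1 bp transcripts put the TSS exactly at the summit)
    allpos <- sort(unique(c(ppos, mpos)))
    ann <- mk_ann(rep("chr1", 2 * length(allpos)),
                  rep(allpos, 2), rep(allpos + 1L, 2),
                  rep(c("+", "-"), each = length(allpos)))
    ex <- detect_extended(mk_sites(ppos, "+"), mk_sites(mpos, "-"), ann)
    om <- oracle_mutual_pairs(ppos, mpos, 2500)
    om <- om[om[, 2] - om[, 1] >= 1, , drop = FALSE]
    expect_equal(nrow(ex), nrow(om))
    if (nrow(om)) {
      got <- ex[, .(p = pmin(host_pos, da_pos), m = pmax(host_pos, da_pos))][order(p)]
      expect_equal(got$p, as.integer(om[, 1]))
      expect_equal(got$m, as.integer(om[, 2]))
    }
  }
})

test_that("distances and set overlap behave as defined", {
  ann <- mk_ann("chr1", 1000L, 4000L, "+")
  lab <- label_quadruples(mk_quad(), ann)
  expect_equal(quadruple_distance(lab), 500L)
  # the field-typical example: summits at 1,000(+) and 1,413(-)
  q413 <- data.table::copy(lab)[, `:=`(tss3_pos = 1413L)]
  expect_equal(quadruple_distance(q413), 413L)
  ov <- overlap_sets(lab, lab)
  expect_equal(ov$frac_a, 1)
  expect_equal(ov$frac_b, 1)
  other <- data.table::copy(lab)[, chrom := "chr2"]
  ov2 <- overlap_sets(lab, other)
  expect_equal(ov2$frac_a, 0)
})

test_that("the core set projects into the extended set on synthetic data", {
  cfg <- sim_config(n_quadruples = 20, n_divergent_only = 5, n_isolated = 5,
                    seed = 41)
  truth <- plant_loci(cfg)
  sim <- simulate_tracks(truth, cfg)
  res <- run_sim_analysis(truth, sim)
  expect_gt(nrow(res$core), 0)
  expect_gte(nrow(res$extended), nrow(res$core))
  core_pairs <- res$core[, .(chrom, host = tss2_pos, da = tss3_pos)]
  ext_pairs <- res$extended[, .(chrom, host = host_pos, da = da_pos)]
  found <- merge(core_pairs, ext_pairs, by = c("chrom", "host", "da"))
  expect_equal(nrow(found), nrow(core_pairs))
})
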