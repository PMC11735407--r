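no_ann <- mk_ann()

test_that("a uniformly covered body extends to the last passing window", {
  # plus-strand walk: coverage 15x over [1000, 2000), zero beyond
  cov <- mk_cov(1000L, 2000L, 15, strand = "+")
  body <- extend_body(1000L, "+", "chr1", cov, no_ann, mk_sites(integer(0), character(0)))
  expect_equal(body$start, 1000L)
  expect_equal(body$end, 2000L)
  # minus-strand walk mirrors
  covm <- mk_cov(1000L, 2000L, 15, strand = "-")
  bodym <- extend_body(1999L, "-", "chr1", covm, no_ann, mk_sites(integer(0), character(0)))
  expect_equal(bodym$start, 1000L)
  expect_equal(bodym$end, 2000L)
})

test_that("an annotated CAGE-supported TSS truncates even continuous coverage", {
  cov <- mk_cov(1000L, 4000L, 15, strand = "+")
  ann <- mk_ann("chr1", 1600L, 3000L, "+", "DOWNSTREAM")
  cage <- mk_sites(1600L, "+")
  body <- extend_body(1000L, "+", "chr1", cov, ann, cage)
  expect_equal(body$end, 1600L)
  # without CAGE support at the annotated TSS the walk continues
  body2 <- extend_body(1000L, "+", "chr1", cov, ann, mk_sites(integer(0), character(0)))
  expect_equal(body2$end, 4000L)
})

test_that("sub-threshold coverage yields a minimal body and an annotated daTSS none", {
  cov <- mk_cov(1000L, 3000L, 9, strand = "+")
  body <- extend_body(1000L, "+", "chr1", cov, no_ann, mk_sites(integer(0), character(0)))
  expect_equal(body$end - body$start, 1L)
  # daTSS on an annotated gene start: not a daRNA
  ann <- mk_ann("chr1", 1000L, 2000L, "+", "KNOWN")
  expect_null(extend_body(1000L, "+", "chr1", cov, ann, mk_sites(integer(0), character(0))))
})

test_that("body extension equals a dense per-base window-scan oracle", {
  set.seed(19)
  params <- darna_params()
  for (rep in 1:200) {
    L <- 3000L
    da <- sample(500:2500, 1)
    strand <- sample(c("+", "-"), 1)
    # random run-length coverage
    n_runs <- sample(1:6, 1)
    st <- sort(sample(0:(L - 50), n_runs))
    en <- pmin(st + sample(50:1200, n_runs, replace = TRUE), L)
    dp <- sample(c(5, 9, 12, 15, 30), n_runs, replace = TRUE)
    dense <- numeric(L)
    for (i in seq_len(n_runs)) dense[(st[i] + 1):en[i]] <- dense[(st[i] + 1):en[i]] + dp[i]
    sup <- sort(sample(setdiff(0:(L - 1), da), 3))
    cov <- coverage_track(data.table::data.table(chrom = "chr1", start = st, end = en,
                                                 strand = strand, depth = dp))
    ann <- mk_ann(rep("chr1", 3), sup, sup + 1L, rep(strand, 3))
    cage <- mk_sites(sup, rep(strand, 3))
    body <- extend_body(da, strand, "chr1", cov, ann, cage, params)
    om <- oracle_extend(da, strand, dense, sup, params$window_len,
                        params$coverage_threshold)
    expect_equal(c(body$start, body$end), as.integer(om))
  }
})

test_that("raising the coverage threshold never lengthens a body", {
  set.seed(37)
  for (rep in 1:50) {
    st <- sort(sample(0:2000, 3))
    en <- st + sample(100:900, 3, replace = TRUE)
    dp <- sample(5:30, 3, replace = TRUE)
    cov <- coverage_track(data.table::data.table(chrom = "chr1", start = st, end = en,
                                                 strand = "+", depth = dp))
    da <- st[1]
    lens <- vapply(c(5, 10, 20), function(th) {
      b <- extend_body(da, "+", "chr1", cov, no_ann,
                       mk_sites(integer(0), character(0)),
                       darna_params(coverage_threshold = th))
      b$end - b$start
    }, numeric(1))
    expect_true(all(diff(lens) <= 0))
  }
})

test_that("transcripts are ranked by QTTS expression with documented ties", {
  body <- list(start = 0L, end = 1000L)
  qt <- data.table::data.table(chrom = "chr1", pos = c(800L, 400L), strand = "+",
                               pooled_count = c(100, 20))
  tx <- assign_transcripts(body, 0L, "+", qt)
  expect_equal(tx$rank, c(1L, 2L))
  expect_equal(tx$qtts_pos, c(800L, 400L))
  expect_true(tx$dominant[1] && !tx$dominant[2])
  expect_equal(tx$length, c(801L, 401L))
  # equal counts: tie broken toward the longer transcript
  qt2 <- data.table::data.table(chrom = "chr1", pos = c(400L, 800L), strand = "+",
                                pooled_count = c(50, 50))
  tx2 <- assign_transcripts(body, 0L, "+", qt2)
  expect_equal(tx2$qtts_pos[1], 800L)
  # no QTTS inside the body: fallback transcript ending at the body end
  tx3 <- assign_transcripts(body, 0L, "+", qt[0])
  expect_equal(nrow(tx3), 1)
  expect_true(is.na(tx3$qtts_pos))
  expect_equal(tx3$tx_end, 1000L)
  expect_equal(tx3$rank, 1L)
  # minus-strand lengths measured daTSS -> 3' end
  txm <- assign_transcripts(list(start = 0L, end = 1000L), 999L, "-",
                            data.table::data.table(chrom = "chr1", pos = 100L,
                                                   strand = "-", pooled_count = 5))
  expect_equal(txm$length, 900L)
})

test_that("dominant selection matches an argmax oracle", {
  expect_equal(select_dominant(data.table::data.table(qtts_count = 10, length = 5)), 1)
  d <- data.table::data.table(qtts_count = c(20, 100), length = c(10, 5))
  expect_equal(select_dominant(d), 2)
  expect_error(select_dominant(d[0]), "empty")
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(1:8, 1)
    d <- data.table::data.table(qtts_count = sample(1:50, n, replace = TRUE),
                                da_count = sample(1:50, n, replace = TRUE),
                                length = sample(1:5000, n))
    got <- select_dominant(d)
    best <- which(d$qtts_count == max(d$qtts_count))
    if (length(best) > 1) best <- best[d$da_count[best] == max(d$da_count[best])]
    if (length(best) > 1) best <- best[which.max(d$length[best])]
    expect_equal(got, best[1])
  }
})

test_that("host traversal uses half-open body containment", {
  # minus-strand daRNA from 1,400 with body [400, 1500) passes host at 500
  expect_true(host_traversal(list(start = 400L, end = 1500L), "-", 500L, "+"))
  # plus-strand bodies: end 600 and 501 cover host 500; end 500 does not
  expect_true(host_traversal(list(start = 100L, end = 600L), "+", 500L, "-"))
  expect_true(host_traversal(list(start = 100L, end = 501L), "+", 500L, "-"))
  expect_false(host_traversal(list(start = 100L, end = 500L), "+", 500L, "-"))
  expect_error(host_traversal(list(start = 100L, end = 600L), "+", 500L, "+"),
               "opposite")
  set.seed(9)
  for (rep in 1:200) {
    s <- sample(0:1000, 1); e <- s + sample(1:1000, 1)
    h <- sample(0:2000, 1)
    expect_equal(host_traversal(list(start = s, end = e), "-", h, "+"),
                 h >= s && h < e)
  }
})

test_that("planted daRNA bodies and dominant 3' ends are recovered end-to-end", {
  cfg <- sim_config(n_quadruples = 30, n_divergent_only = 0, n_isolated = 0,
                    background_rate = 0, seed = 47)
  truth <- plant_loci(cfg)
  sim <- simulate_tracks(truth, cfg)
  res <- run_sim_analysis(truth, sim)
  dom <- res$darnas[dominant == TRUE]
  expect_equal(nrow(dom), nrow(res$core))
  m <- merge(dom, truth$loci[architecture == "quadruple",
                             .(host_gene_id, darna_end)], by = "host_gene_id")
  # inferred 3' boundary within one window of the planted end
  expect_true(all(abs(m$body_start - m$darna_end) <= 100))
  # dominant transcripts carry the planted strongest QTTS
  expect_true(all(!is.na(m$qtts_pos)))
  expect_true(all(abs(m$qtts_pos - m$darna_end) <= cfg$jitter_cap))
  # traversal calls agree with the planted geometry (a daRNA traverses
  # its host TSS exactly when the planted body reaches past it); cases
  # with the boundary within one window of the host TSS are left out
  t2 <- truth$tss[label == "TSS2", .(host_gene_id = gene_id, tss2_pos = pos)]
  m2 <- merge(m, t2, by = "host_gene_id")
  clearcut <- abs(m2$darna_end - m2$tss2_pos) > 150
  expect_true(all(m2$traverses_host_tss[clearcut] ==
                  (m2$darna_end <= m2$tss2_pos)[clearcut]))
})
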