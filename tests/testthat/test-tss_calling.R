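test_that("an all-zero track yields no peaks", {
  tr <- end_track(data.table::data.table(chrom = character(0), pos = integer(0),
                                         strand = character(0), count = integer(0)))
  expect_equal(nrow(call_end_peaks(tr)), 0)
  expect_error(call_end_peaks(list()), "empty track set")
})

test_that("a single spike becomes exactly one peak containing it", {
  tr <- mk_track(5000L, 50L)
  pk <- call_end_peaks(tr, genome_size = 10000)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start <= 5000 && pk$end > 5000)
  expect_equal(pk$summit_pos, 5000L)
  expect_equal(pk$pooled_count, 50)
})

test_that("mixed-strand input is rejected", {
  bad <- end_track(data.table::data.table(chrom = "chr1", pos = c(1L, 2L),
                                          strand = c("+", "-"), count = c(5L, 5L)))
  expect_error(call_end_peaks(bad), "mixed strands")
})

test_that("seed/extend calling matches an exhaustive position scan", {
  params <- peak_params(min_seed_count = 3)
  set.seed(42)
  for (rep in 1:200) {
    len <- 2000L
    bg_n <- rpois(1, 0.1 * len)
    pos <- sample(0:(len - 1), bg_n, replace = TRUE)
    spikes <- sample(0:(len - 1), 3)
    pos <- c(pos, rep(spikes, each = 30))
    dt <- data.table::data.table(pos = pos)[, .(count = .N), by = pos]
    tr <- mk_track(dt$pos, dt$count)
    pk <- call_end_peaks(tr, params, genome_size = len)
    orc <- oracle_call_peaks(dt$pos, dt$count, len, params$min_seed_count,
                             params$max_internal_gap, params$background_alpha)
    expect_equal(nrow(pk), length(orc))
    if (length(orc)) {
      om <- do.call(rbind, lapply(orc, function(o) c(o$start, o$end, o$total, o$summit)))
      expect_equal(pk$start, as.integer(om[, 1]))
      expect_equal(pk$end, as.integer(om[, 2]))
      expect_equal(pk$pooled_count, om[, 3])
      expect_equal(pk$summit_pos, as.integer(om[, 4]))
    }
    # every planted spike is recovered
    expect_true(all(vapply(spikes, function(s) any(pk$start <= s & pk$end > s),
                           logical(1))))
  }
})

test_that("peaks merge at a gap of exactly 50 bp but not 51", {
  pooled <- data.table::data.table(chrom = "chr1", strand = "+",
                                   pos = c(150L, 280L), count = c(10L, 8L))
  pk50 <- data.table::data.table(chrom = "chr1", start = c(100L, 250L),
                                 end = c(200L, 300L), strand = "+",
                                 pooled_count = c(10, 8),
                                 summit_pos = c(150L, 280L), summit_count = c(10, 8))
  m <- merge_peaks(pk50, pooled, 50L)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 300L)
  expect_equal(m$pooled_count, 18)
  expect_equal(m$summit_pos, 150L)

  pk51 <- data.table::copy(pk50)[2, start := 251L]
  pooled51 <- data.table::copy(pooled)[2, pos := 281L]
  m2 <- merge_peaks(pk51, pooled51, 50L)
  expect_equal(nrow(m2), 2)
})

test_that("merging equals the transitive union-find closure and is idempotent", {
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    # sorted, non-overlapping peaks with random gaps straddling the 50 bp rule
    starts <- integer(n); ends <- integer(n); cur <- 0L
    for (i in seq_len(n)) {
      starts[i] <- cur + sample(0:120, 1)
      ends[i] <- starts[i] + sample(10:80, 1)
      cur <- ends[i]
    }
    summits <- starts + sample(0:9, n, replace = TRUE)
    pooled <- data.table::data.table(chrom = "chr1", strand = "+",
                                     pos = summits, count = sample(5:50, n, replace = TRUE))
    pk <- data.table::data.table(chrom = "chr1", start = starts, end = ends,
                                 strand = "+", pooled_count = pooled$count,
                                 summit_pos = summits, summit_count = pooled$count)
    m <- merge_peaks(pk, pooled, 50L)
    om <- oracle_merge(starts, ends, 50L)
    expect_equal(m$start, as.integer(om[, 1]))
    expect_equal(m$end, as.integer(om[, 2]))
    # idempotence
    m2 <- merge_peaks(m, pooled, 50L)
    expect_equal(m2, m)
    # disjoint and sorted
    expect_true(all(diff(m$start) > 0))
    expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  }
})

test_that("unsorted peaks are rejected by merge", {
  pooled <- data.table::data.table(chrom = "chr1", strand = "+",
                                   pos = c(10L, 500L), count = c(9L, 9L))
  pk <- data.table::data.table(chrom = "chr1", start = c(400L, 5L), end = c(520L, 20L),
                               strand = "+", pooled_count = c(9, 9),
                               summit_pos = c(500L, 10L), summit_count = c(9, 9))
  expect_error(merge_peaks(pk, pooled, 50L), "sorted")
})

test_that("summits are the leftmost pooled-count maximum", {
  pooled <- data.table::data.table(chrom = "chr1", strand = "+",
                                   pos = c(103L, 105L, 107L), count = c(4L, 9L, 2L))
  s <- locate_summit(list(chrom = "chr1", start = 100L, end = 110L, strand = "+"), pooled)
  expect_equal(s$pos, 105L)
  expect_equal(s$pooled_count, 9)
  tie <- data.table::data.table(chrom = "chr1", strand = "+",
                                pos = c(103L, 107L), count = c(7L, 7L))
  expect_equal(locate_summit(list(chrom = "chr1", start = 100L, end = 110L,
                                  strand = "+"), tie)$pos, 103L)
  empty <- tie[0]
  expect_error(locate_summit(list(chrom = "chr1", start = 100L, end = 110L,
                                  strand = "+"), empty), "no signal")
  # randomized argmax oracle
  set.seed(3)
  for (rep in 1:200) {
    n <- sample(1:20, 1)
    pos <- sort(sample(0:99, n))
    cnt <- sample(1:30, n, replace = TRUE)
    pooled <- data.table::data.table(chrom = "chr1", strand = "+", pos = pos, count = cnt)
    s <- locate_summit(list(chrom = "chr1", start = 0L, end = 100L, strand = "+"), pooled)
    expect_equal(s$pos, pos[which.max(cnt)])
  }
})

test_that("noise-free simulations are recalled perfectly with summits on target", {
  cfg <- sim_config(n_quadruples = 10, n_divergent_only = 5, n_isolated = 5,
                    background_rate = 0, seed = 31)
  truth <- plant_loci(cfg)
  sim <- simulate_tracks(truth, cfg)
  tr <- lapply(sim$samples$sample_id, function(s) get_track(sim, s, "five_prime"))
  genome <- sum(as.numeric(sim$chrom_sizes))
  for (s in c("+", "-")) {
    sites <- call_sites(lapply(tr, function(x)
      end_track(x$counts[strand == s], x$sample_id, x$signal_kind)),
      genome_size = genome)
    planted <- truth$tss[strand == s]$pos
    # 100% recall with summits within the jitter cap of the planted TSS
    hit <- vapply(planted, function(p) min(abs(sites$pos - p)), numeric(1))
    expect_true(all(hit <= cfg$jitter_cap))
    expect_equal(nrow(sites), length(planted))
  }
})

test_that("pure-background false peak count stays near its Poisson expectation", {
  cfg <- sim_config(n_quadruples = 0, n_divergent_only = 0, n_isolated = 1,
                    chrom_sizes = c(bg = 200000L), background_rate = 0.05,
                    baseline_mean_range = c(1e-9, 1e-9), n_replicates = 2, seed = 12)
  truth <- plant_loci(cfg)
  sim <- simulate_tracks(truth, cfg)
  tr <- lapply(sim$samples$sample_id, function(s) get_track(sim, s, "five_prime"))
  params <- peak_params()
  sites <- call_sites(lapply(tr, function(x)
    end_track(x$counts[strand == "+"], x$sample_id, x$signal_kind)),
    params, genome_size = 200000)
  # expected false peaks <= alpha * genome length, checked at 10x slack
  expect_lte(nrow(sites), 10 * params$background_alpha * 200000)
})
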