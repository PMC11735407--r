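# Independent brute-force oracles used across the unit and acceptance
# suites. Each oracle is a direct, exhaustive implementation of the
# operation's definition, deliberately sharing no code with the package
# internals it checks.

library(data.table)

# Quick end_track from vectors.
mk_track <- function(pos, count, strand = "+", chrom = "chr1",
                     sample_id = "s1", signal = "five_prime") {
  end_track(data.table(chrom = chrom, pos = pos, strand = strand, count = count),
            sample_id, signal)
}

# Quick coverage_track from run vectors.
mk_cov <- function(start, end, depth, strand = "-", chrom = "chr1") {
  coverage_track(data.table(chrom = chrom, start = start, end = end,
                            strand = strand, depth = depth))
}

# Minimal annotation with one transcript per row of (chrom, start, end, strand).
mk_ann <- function(chrom = character(0), start = integer(0), end = integer(0),
                   strand = character(0), gene_id = NULL) {
  n <- length(start)
  if (is.null(gene_id)) gene_id <- if (n) sprintf("G%d", seq_len(n)) else character(0)
  transcript_annotation(data.table(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
    chrom = rep_len(chrom, n), start = start, end = end,
    strand = rep_len(strand, n)))
}

# Site-call table from raw vectors (peak = summit +- pad).
mk_sites <- function(pos, strand, count = 100, chrom = "chr1", pad = 5L) {
  dt <- data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
                   kind = "CTSS", pooled_count = as.numeric(count),
                   peak_start = as.integer(pos) - pad, peak_end = as.integer(pos) + pad + 1L,
                   peak_count = as.numeric(count))
  setorder(dt, chrom, pos)
  dt
}

# --- oracle: peak calling by exhaustive position scan ------------------
# Dense scan over [0, len): seed positions, then greedy island growth.
oracle_call_peaks <- function(pos, count, len, min_seed, max_gap, alpha) {
  dense <- integer(len)
  dense[pos + 1L] <- count
  lambda <- sum(count) / len
  seeds <- which(dense >= min_seed &
                 ppois(dense - 1, lambda, lower.tail = FALSE) <= alpha) - 1L
  nz <- which(dense > 0) - 1L
  if (length(seeds) == 0 || length(nz) == 0) return(list())
  # islands: maximal runs of nonzero positions with gaps <= max_gap
  brk <- c(0L, which(diff(nz) - 1L > max_gap), length(nz))
  out <- list()
  for (i in seq_len(length(brk) - 1)) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    island <- nz[idx]
    if (any(island %in% seeds)) {
      cnt <- dense[island + 1L]
      out[[length(out) + 1]] <- list(start = min(island), end = max(island) + 1L,
                                     total = sum(cnt),
                                     summit = island[which.max(cnt)])
    }
  }
  out
}

# --- oracle: transitive peak merging by union-find over all pairs ------
oracle_merge <- function(starts, ends, gap) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      g <- max(starts[j] - ends[i], starts[i] - ends[j])
      if (g <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  grp <- split(seq_len(n), root)
  res <- lapply(grp, function(ix) c(min(starts[ix]), max(ends[ix])))
  m <- do.call(rbind, res)
  m[order(m[, 1]), , drop = FALSE]
}

# --- oracle: mutual-nearest divergent/convergent pairing ---------------
# All ordered (upstream u, downstream d) pairs with d >= u and d - u <=
# window; keep (u, d) when d is u's nearest eligible downstream partner
# and u is d's nearest eligible upstream partner.
oracle_mutual_pairs <- function(upos, dpos, window) {
  pairs <- list()
  for (k in seq_along(upos)) {
    cand <- dpos[dpos >= upos[k]]
    if (length(cand) == 0) next
    d <- min(cand)
    back <- upos[upos <= d]
    u_star <- max(back)
    if (u_star == upos[k] && d - upos[k] <= window)
      pairs[[length(pairs) + 1]] <- c(upos[k], d)
  }
  if (length(pairs) == 0) return(matrix(numeric(0), 0, 2))
  do.call(rbind, pairs)
}

# --- oracle: quadruple assembly over all pair-of-pairs -----------------
# A (upstream) joined to B when no other pair lies between them and the
# inner gap is in [1, window].
oracle_assemble <- function(minus_pos, plus_pos, window) {
  n <- length(minus_pos)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (minus_pos[j] <= minus_pos[i]) next
    between <- any(minus_pos > minus_pos[i] & minus_pos < minus_pos[j])
    if (between) next
    gap <- minus_pos[j] - plus_pos[i]
    if (gap >= 1 && gap <= window)
      out[[length(out) + 1]] <- c(a_plus = plus_pos[i], b_minus = minus_pos[j], gap = gap)
  }
  if (length(out) == 0) return(matrix(numeric(0), 0, 3))
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

# --- oracle: daRNA body extension by dense per-base window scan --------
# Dense coverage vector cov (index 1 = position 0); returns the body
# interval per the window walk definition (termination before coverage).
oracle_extend <- function(da_pos, da_strand, cov, sup_pos, window, thresh_mean) {
  L <- length(cov)
  lo <- da_pos; hi <- da_pos + 1L
  k <- 0L
  repeat {
    if (da_strand == "+") { ws <- da_pos + k * window; we <- ws + window }
    else { we <- da_pos - k * window + 1L; ws <- we - window }
    t_in <- sup_pos[sup_pos >= ws & sup_pos < we]
    t_in <- if (da_strand == "+") t_in[t_in > da_pos] else t_in[t_in < da_pos]
    if (length(t_in)) {
      if (da_strand == "+") return(c(lo, min(t_in)))
      return(c(max(t_in) + 1L, hi))
    }
    idx <- (ws:(we - 1L))
    vals <- ifelse(idx >= 0 & idx < L, cov[pmax(idx, 0) + 1L], 0)
    vals[idx < 0 | idx >= L] <- 0
    if (mean(vals) < thresh_mean) break
    if (da_strand == "+") hi <- we else lo <- max(0L, ws)
    k <- k + 1L
  }
  c(lo, hi)
}

# --- oracle: median-of-ratios size factors by the direct formula -------
oracle_size_factors <- function(m) {
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  ok <- apply(m, 1, function(r) all(r > 0))
  apply(m, 2, function(col) median(col[ok] / geo[ok]))
}

# --- oracle: Spearman rho by the rank formula (no ties) ----------------
oracle_spearman_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# --- oracle: BH step-up by hand ----------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# --- oracle: metaprofile by direct per-base averaging ------------------
oracle_metaprofile <- function(mat_values, n_bins) {
  # mat_values: list of per-base 5'->3' numeric vectors, one per region
  prof <- sapply(mat_values, function(v) {
    L <- length(v)
    sapply(seq_len(n_bins), function(j) {
      lo <- (j - 1) * L / n_bins; hi <- j * L / n_bins
      s <- 0
      for (b in 0:(L - 1)) {
        frac <- min(hi, b + 1) - max(lo, b)
        if (frac > 0) s <- s + v[b + 1] * frac
      }
      s / (L / n_bins)
    })
  })
  rowMeans(matrix(prof, nrow = n_bins))
}

# --- oracle: Mann-Whitney U by pair counting ---------------------------
oracle_u_stat <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}
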