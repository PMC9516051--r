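# Fixture builders and brute-force reference implementations. The oracles
# are deliberately naive (per-base enumeration, direct combinatorics) and
# share no code with the package internals.

make_map <- function(chrom, pos, context, meth, total,
                     strand = rep("+", length(pos)), sample_id = "s") {
  dinuc <- ifelse(context == "CG", "CG", ifelse(context == "CHG", "CA", "CT"))
  dt <- data.table::data.table(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    context = context, dinuc = dinuc,
    meth_reads = as.integer(meth), total_reads = as.integer(total)
  )
  data.table::setattr(dt, "sample_id", sample_id)
  dt
}

make_pairs <- function(chrom, pos, meth_a, total_a, meth_b, total_b,
                       context = "CG") {
  dt <- data.table::data.table(
    chrom = chrom, pos = as.integer(pos),
    meth_a = meth_a, total_a = total_a,
    meth_b = meth_b, total_b = total_b
  )
  data.table::setattr(dt, "context", context)
  dt
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_start = 2000,
                           max_width = 60) {
  start <- sample.int(max_start, n, replace = TRUE)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE)
  )
}

# set of integer base positions (0-based) covered by a region table
bf_bases <- function(regions) {
  if (nrow(regions) == 0) return(character())
  unlist(lapply(seq_len(nrow(regions)), function(i) {
    if (regions$end[i] <= regions$start[i]) return(character())
    paste(regions$chrom[i], seq(regions$start[i], regions$end[i] - 1))
  }))
}

# covered bases of one query under the union of elements
bf_overlap_bp <- function(query, elements) {
  qb <- bf_bases(query)
  length(intersect(qb, unique(bf_bases(elements))))
}

bf_merge <- function(regions, max_gap, min_len) {
  out <- NULL
  for (ch in sort(unique(regions$chrom))) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start, r$end), , drop = FALSE]
    cur_s <- r$start[1]; cur_e <- r$end[1]
    for (i in seq_len(nrow(r))[-1]) {
      if (r$start[i] - cur_e <= max_gap) {
        cur_e <- max(cur_e, r$end[i])
      } else {
        out <- rbind(out, data.frame(chrom = ch, start = cur_s, end = cur_e))
        cur_s <- r$start[i]; cur_e <- r$end[i]
      }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cur_s, end = cur_e))
  }
  out <- out[out$end - out$start >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# gap distance between two 0-based half-open intervals on one chromosome
bf_gap <- function(s1, e1, s2, e2) max(0, s2 - e1, s1 - e2)

bf_nearest <- function(queries, targets) {
  vapply(seq_len(nrow(queries)), function(i) {
    t <- targets[targets$chrom == queries$chrom[i], , drop = FALSE]
    if (nrow(t) == 0) return(NA_real_)
    min(vapply(seq_len(nrow(t)), function(j)
      bf_gap(queries$start[i], queries$end[i], t$start[j], t$end[j]),
      numeric(1)))
  }, numeric(1))
}

bf_fisher <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 - (n - c1)):min(r1, c1)
  probs <- choose(r1, support) * choose(n - r1, c1 - support) / choose(n, c1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

bf_binom <- function(k, n, p0) {
  probs <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - (0:n))
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
}

# Yates chi-square evaluated cell-by-cell (independent of the margin
# shortcut used in the implementation)
bf_chi2_yates <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum(pmax(0, abs(m - e) - 0.5)^2 / e)
}

bf_motif_positions <- function(seq, motif) {
  codes <- strsplit(Biostrings::IUPAC_CODE_MAP[
    strsplit(toupper(motif), "")[[1]]], "")
  s <- strsplit(seq, "")[[1]]
  k <- length(codes)
  which(vapply(seq_len(nchar(seq) - k + 1), function(i) {
    all(mapply(function(ch, opts) ch %in% opts, s[i:(i + k - 1)], codes))
  }, logical(1)))
}

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    genome = c(chr1 = 2e5, chr2 = 2e5, scaffold_282 = 2e4),
    n_genes = 20L, n_helitrons = 30L, n_gypsies = 5L, gypsy_length = 4000L,
    n_tandem = 4L, n_trna = 10L, n_mirna = 8L, n_5s = 3L, n_nor = 1L,
    n_dmrs = 25L, n_scaffold_dmrs = 2L, n_chh_islands = 10L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

region_key <- function(x) paste(x$chrom, x$start, x$end)
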