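test_that("interval merge-and-filter matches examples and a brute-force merge", {
  x <- data.frame(chrom = "chr1", start = c(0, 140), end = c(100, 240))
  out <- merge_and_filter_intervals(x, max_gap = 50, min_len = 100)
  expect_equal(out, data.frame(chrom = "chr1", start = 0, end = 240))
  # gap of exactly max_gap merges; one more does not
  y <- data.frame(chrom = "chr1", start = c(0, 150), end = c(100, 240))
  expect_equal(nrow(merge_and_filter_intervals(y, 50, 0)), 1L)
  expect_equal(nrow(merge_and_filter_intervals(y, 49, 0)), 2L)
  # short survivor removed
  expect_equal(nrow(merge_and_filter_intervals(
    data.frame(chrom = "chr1", start = 0, end = 80), 50, 100)), 0L)
  expect_error(merge_and_filter_intervals(x, -1, 100), "non-negative")

  set.seed(101)
  for (i in 1:200) {
    r <- random_regions(sample(2:15, 1))
    gap <- sample(0:60, 1); ml <- sample(c(0, 30, 80), 1)
    got <- merge_and_filter_intervals(r, gap, ml)
    want <- bf_merge(r, gap, ml)
    expect_equal(got[order(got$chrom, got$start), ],
                 want[order(want$chrom, want$start), ],
                 ignore_attr = TRUE)
  }
})

test_that("overlap_select applies fractional-overlap semantics", {
  q <- data.frame(chrom = "chr1", start = 0, end = 200)
  el <- data.frame(chrom = "chr1", start = 100, end = 300)
  expect_equal(nrow(overlap_select(q, el, 0.5)), 1L)       # 100/200
  el99 <- data.frame(chrom = "chr1", start = 101, end = 300)
  expect_equal(nrow(overlap_select(q, el99, 0.5)), 0L)     # 99/200
  # multiple small overlaps accumulate against the element union
  el2 <- data.frame(chrom = "chr1", start = c(0, 150), end = c(60, 200))
  expect_equal(nrow(overlap_select(q, el2, 0.5)), 1L)      # 60 + 50 = 110
  expect_error(overlap_select(q, el, 0), "min_frac")

  set.seed(102)
  for (i in 1:300) {
    qs <- random_regions(sample(1:12, 1))
    es <- random_regions(sample(1:10, 1))
    frac <- sample(c(0.001, 0.25, 0.5, 0.9, 1), 1)
    kept <- overlap_select(qs, es, frac)
    drop <- overlap_select(qs, es, frac, invert = TRUE)
    # invert partitions the query set
    expect_equal(nrow(kept) + nrow(drop), nrow(qs))
    want <- vapply(seq_len(nrow(qs)), function(j)
      bf_overlap_bp(qs[j, ], es) >= frac * (qs$end[j] - qs$start[j]),
      logical(1))
    expect_equal(unname(which(want)), as.integer(rownames(kept)))
  }
})

test_that("element enrichment is a ratio of overlap proportions", {
  regs <- data.frame(chrom = "chr1", start = 1000 * (0:99),
                     end = 1000 * (0:99) + 200)
  # any set against itself as control gives exactly 1
  el <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(20000, 90000))
  expect_equal(as.numeric(element_enrichment(regs, regs, el)), 1)

  # 10/100 queries vs 5/500 controls overlapping -> 10.0
  mk <- function(n, n_hit, off) {
    s <- off + 1000 * (0:(n - 1))
    data.frame(chrom = "chr1", start = s, end = s + 200,
               hit = seq_len(n) <= n_hit)
  }
  q <- mk(100, 10, 0); ctl <- mk(500, 5, 2e5)
  elements <- rbind(q[q$hit, 1:3], ctl[ctl$hit, 1:3])
  fold <- element_enrichment(q[1:3], ctl[1:3], elements)
  expect_equal(as.numeric(fold), 10)
  expect_equal(attr(fold, "prop_query"), 0.1)
  expect_warning(
    element_enrichment(q[1:3],
                       data.frame(chrom = "chr2", start = 0, end = 200),
                       elements),
    "undefined")
})

test_that("end-anchored profiles are oriented and control-normalized", {
  anchors <- data.frame(chrom = "chr1", pos = c(10000, 50000),
                        strand = c("+", "-"))
  regs <- data.frame(chrom = "chr1", start = c(9000, 9500),
                     end = c(9200, 9700))
  prof <- end_anchored_enrichment(regs, regs, anchors, window = 3000)
  expect_equal(prof$enrichment[prof$n_control > 0],
               rep(1, sum(prof$n_control > 0)))
  expect_true(all(is.na(prof$enrichment[prof$n_control == 0])))

  # a region 500 bp upstream of a plus-strand anchor peaks at offset -500
  up <- data.frame(chrom = "chr1", start = 9500, end = 9550)
  ctl <- data.frame(chrom = "chr1", start = seq(7000, 13000, 100),
                    end = seq(7000, 13000, 100) + 50)
  p <- end_anchored_enrichment(up, ctl, anchors[1, ], window = 3000)
  expect_equal(p$offset[which.max(p$n_query)], -500)
  # mirrored for the minus-strand anchor: upstream means larger coordinate
  dn <- data.frame(chrom = "chr1", start = 50450, end = 50500)
  p2 <- end_anchored_enrichment(dn, ctl, anchors[2, ], window = 3000)
  expect_equal(p2$offset[which.max(p2$n_query)], -500)
})

test_that("distance_to_nearest reports gap distances with brute-force parity", {
  q <- data.frame(chrom = "chr1", start = c(5000, 100), end = c(5200, 300))
  t1 <- data.frame(chrom = "chr1", start = c(3800, 150), end = c(4000, 160))
  d <- distance_to_nearest(q, t1)
  expect_equal(d[1], 1000)   # [5000,5200) vs target ending at 4000
  expect_equal(d[2], 0)      # overlap
  # no target on the chromosome -> NA
  expect_true(is.na(distance_to_nearest(
    data.frame(chrom = "chr9", start = 0, end = 10), t1)))

  set.seed(103)
  for (i in 1:200) {
    qs <- random_regions(sample(1:10, 1))
    ts <- random_regions(sample(1:10, 1))
    expect_equal(distance_to_nearest(qs, ts), bf_nearest(qs, ts))
  }
  # symmetric under coordinate mirroring
  L <- 5000
  qs <- random_regions(8, max_start = 4000, max_width = 50)
  ts <- random_regions(8, max_start = 4000, max_width = 50)
  mirror <- function(x) data.frame(chrom = x$chrom, start = L - x$end,
                                   end = L - x$start)
  expect_equal(distance_to_nearest(qs, ts),
               distance_to_nearest(mirror(qs), mirror(ts)))
})

test_that("flank profiles average count-weighted methylation per offset bin", {
  # uniform 50% methylation -> flat profile at 0.5 wherever sites exist
  set.seed(104)
  pos <- sort(sample(1:40000, 4000))
  map <- make_map("chr1", pos, rep("CG", 4000), rep(1L, 4000),
                  rep(2L, 4000))
  regs <- data.frame(chrom = "chr1", start = c(10000, 20000),
                     end = c(10200, 20200))
  prof <- flank_profile(regs, map, "CG", flank = 3000, bin = 100)
  expect_equal(nrow(prof), 62L)   # 30 + 2 + 30 bins
  expect_true(all(abs(prof$level[prof$n > 0] - 0.5) < 1e-12))

  # demethylated core gives a V shape with missing (not zero) empty bins
  core <- pos > 10000 & pos <= 10200   # 1-based sites inside [10000, 10200)
  map2 <- data.table::copy(map)
  map2$meth_reads[core] <- 0L
  # remove all coverage upstream of 8 kb to create empty bins
  map2 <- map2[map2$pos >= 8000 & map2$pos <= 14000, ]
  prof2 <- flank_profile(regs[1, ], map2, "CG", flank = 3000, bin = 100)
  centre <- prof2$level[prof2$offset %in% c(0, 100)]
  expect_true(all(centre < 0.01))
  expect_true(all(prof2$level[prof2$offset < -2200] %in% NA_real_) ||
                all(is.na(prof2$level[prof2$offset < -2200])))
  flanks <- prof2$level[prof2$offset > 300 & !is.na(prof2$level)]
  expect_true(all(flanks > 0.4))
  # coverage below min_cov is excluded
  prof3 <- flank_profile(regs[1, ], map, "CG", min_cov = 3)
  expect_true(all(is.na(prof3$level)))
})

test_that("GC content excludes ambiguous bases", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_equal(gc_content(c("GG", "AATT"), per_sequence = TRUE),
               c(1, 0))
  expect_equal(gc_content(c("GG", "AATT")), 2 / 6)
  expect_warning(gc_content("NNN"), "undefined")
})

test_that("IUPAC motif scanning matches a brute-force sliding window", {
  expect_equal(iupac_motif_scan("TTACCATATA", "TTWCCATATW",
                                both_strands = FALSE)$start, 1L)
  expect_equal(nrow(iupac_motif_scan("TTGCCATATA", "TTWCCATATW")), 0L)
  expect_error(iupac_motif_scan("ACGT", "QQ"), "IUPAC")

  # reverse-complement hits are reported on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTACCATATA")))
  hits <- iupac_motif_scan(paste0("GG", rc, "GG"), "TTWCCATATW")
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 3L)

  set.seed(105)
  seqs <- simulate_sequences(3, 10000, gc = 0.45, seed = 9)
  for (motif in c("TTWCCATATW", "CCAWAAATGG", "WWCC")) {
    got <- iupac_motif_scan(seqs, motif, both_strands = FALSE)
    for (i in 1:3) {
      expect_equal(got$start[got$seq == i], bf_motif_positions(seqs[i], motif))
    }
  }
})
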