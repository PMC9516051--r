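test_that("bin_sites uses a 0-anchored grid and hand-checked aggregates", {
  # 1-based position 200 belongs to [0,200); 201 to [200,400)
  tab <- make_pairs("chr1", c(200, 201), c(1, 2), c(2, 4), c(0, 1), c(2, 4))
  bins <- bin_sites(tab, 200)
  expect_equal(bins$start, c(0L, 200L))
  expect_equal(bins$end, c(200L, 400L))

  expect_equal(nrow(bin_sites(make_pairs(character(), integer(),
                                         integer(), integer(),
                                         integer(), integer()), 200)), 0L)

  # 12 sites across 3 bins, hand aggregation
  pos <- c(10, 50, 150, 210, 220, 230, 240, 410, 420, 430, 440, 450)
  tab <- make_pairs("chr1", pos,
                    meth_a = rep(1, 12), total_a = rep(2, 12),
                    meth_b = rep(3, 12), total_b = rep(4, 12))
  bins <- bin_sites(tab, 200)
  expect_equal(bins$n_sites, c(3L, 4L, 5L))
  expect_equal(bins$sum_meth_a, c(3, 4, 5))
  expect_equal(bins$sum_total_b, c(12, 16, 20))
  expect_equal(bins$level_a, rep(0.5, 3))
  expect_equal(bins$mean_cov_b, rep(4, 3))
})

test_that("eligibility requires 5 sites at 3x mean coverage per context in both samples", {
  # exactly at threshold: 5 CGs and 5 CHGs totalling 15 reads each
  at <- function(ctx) make_pairs("chr1", seq(10, 50, 10),
                                 meth_a = rep(1, 5), total_a = rep(3, 5),
                                 meth_b = rep(1, 5), total_b = rep(3, 5),
                                 context = ctx)
  elig <- eligible_bins(bin_sites(at("CG")), bin_sites(at("CHG")))
  expect_equal(nrow(elig), 1L)
  expect_equal(elig$label, "eligible")

  # 4 sites of coverage 100 fail the site-count requirement
  four <- make_pairs("chr1", seq(10, 40, 10), rep(10, 4), rep(100, 4),
                     rep(10, 4), rep(100, 4), context = "CG")
  expect_equal(nrow(eligible_bins(bin_sites(four), bin_sites(at("CHG")))), 0L)

  # coverage below 3 in one sample fails
  low <- make_pairs("chr1", seq(10, 50, 10), rep(1, 5), rep(3, 5),
                    rep(1, 5), rep(2, 5), context = "CG")
  expect_equal(nrow(eligible_bins(bin_sites(low), bin_sites(at("CHG")))), 0L)

  # random bins match an independent per-bin predicate
  set.seed(11)
  pos <- sort(sample(1:20000, 600))
  rnd <- function(ctx) make_pairs("chr1", pos,
                                  rbinom(600, 4, 0.5), rpois(600, 4),
                                  rbinom(600, 4, 0.5), rpois(600, 4),
                                  context = ctx)
  rnd_cg <- rnd("CG"); rnd_chg <- rnd("CHG")
  rnd_cg$meth_a <- pmin(rnd_cg$meth_a, rnd_cg$total_a)
  rnd_cg$meth_b <- pmin(rnd_cg$meth_b, rnd_cg$total_b)
  rnd_chg$meth_a <- pmin(rnd_chg$meth_a, rnd_chg$total_a)
  rnd_chg$meth_b <- pmin(rnd_chg$meth_b, rnd_chg$total_b)
  elig <- eligible_bins(bin_sites(rnd_cg), bin_sites(rnd_chg))
  brute <- function(df, s) {
    b <- (df$pos - 1) %/% 200
    ok <- logical(0)
    for (bb in sort(unique(b))) {
      i <- b == bb
      ok[as.character(bb)] <-
        sum(i) >= 5 && mean(df$total_a[i]) >= 3 && mean(df$total_b[i]) >= 3
    }
    as.integer(names(ok)[ok]) * 200
  }
  expect_setequal(elig$start,
                  intersect(brute(rnd_cg), brute(rnd_chg)))
})

test_that("DMR thresholds are strict, with the zero-denominator fold rule", {
  mk <- function(va, vb) {
    b <- make_pairs("chr1", seq(10, 50, 10),
                    meth_a = round(va * 20) * rep(1, 5), total_a = rep(20, 5),
                    meth_b = round(vb * 20) * rep(1, 5), total_b = rep(20, 5))
    bin_sites(b)
  }
  p <- dmr_params()
  # v1=0.10, v2=0.35: 3.5-fold and +0.25 -> hyper
  expect_equal(nrow(call_context_dmrs(mk(0.10, 0.35), p)$hyper), 1L)
  # v1=0.40, v2=0.25: fold 1.6 < 2 -> neither
  r <- call_context_dmrs(mk(0.40, 0.25), p)
  expect_equal(nrow(r$hyper) + nrow(r$hypo), 0L)
  # v1=0, v2=0.25: zero-denominator rule -> hyper
  expect_equal(nrow(call_context_dmrs(mk(0, 0.25), p)$hyper), 1L)
  # an absolute difference of exactly 0.20 is not "greater than 20%"
  r <- call_context_dmrs(mk(0.05, 0.25), p)
  expect_equal(nrow(r$hyper), 0L)
  # hypo is the mirror image
  expect_equal(nrow(call_context_dmrs(mk(0.35, 0.10), p)$hypo), 1L)
})

test_that("context combination intersects grid bins and discards scaffolds", {
  mkbins <- function(chrom, starts) {
    dt <- data.table::data.table(chrom = chrom, start = starts,
                                 end = starts + 200,
                                 level_a = 0.8, level_b = 0.05)
    data.table::setattr(dt, "bin_size", 200L)
    dt
  }
  cg <- mkbins(c("chr1", "chr1", "scaffold_282"), c(0, 200, 400))
  chg <- mkbins(c("chr1", "scaffold_282"), c(200, 400))
  out <- combine_contexts(cg, chg, "hypo")
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 200)
  expect_equal(out$label, "hypoDMR")
  # without a chromosome restriction the scaffold bin is kept
  out2 <- combine_contexts(cg, chg, "hypo", chromosomes = NULL)
  expect_equal(nrow(out2), 2L)
})

test_that("swapping samples maps hypoDMRs onto hyperDMRs exactly", {
  set.seed(21)
  n <- 3000
  pos <- sort(sample(1:200000, n))
  mkctx <- function(ctx) {
    ta <- rpois(n, 8) + 1L
    tb <- rpois(n, 8) + 1L
    make_pairs("chr1", pos, rbinom(n, ta, runif(n)), ta,
               rbinom(n, tb, runif(n)), tb, context = ctx)
  }
  cg <- mkctx("CG"); chg <- mkctx("CHG")
  swap <- function(x) {
    y <- data.table::copy(x)
    data.table::setnames(y, c("meth_a", "total_a", "meth_b", "total_b"),
                         c("meth_b", "total_b", "meth_a", "total_a"))
    data.table::setattr(y, "context", attr(x, "context"))
    y
  }
  p <- dmr_params(chromosomes = "chr1")
  fwd <- call_dmrs(cg, chg, p)
  rev <- call_dmrs(swap(cg), swap(chg), p)
  expect_setequal(region_key(fwd$hypo), region_key(rev$hyper))
  expect_setequal(region_key(fwd$hyper), region_key(rev$hypo))
  expect_setequal(region_key(fwd$eligible), region_key(rev$eligible))
  # every DMR is an eligible region
  expect_true(all(region_key(fwd$hypo) %in% region_key(fwd$eligible)))
  expect_true(all(region_key(fwd$hyper) %in% region_key(fwd$eligible)))
  # raising min_abs_dif can only shrink the DMR set
  stricter <- call_dmrs(cg, chg, dmr_params(min_abs_dif = 0.4,
                                            chromosomes = "chr1"))
  expect_true(all(region_key(stricter$hypo) %in% region_key(fwd$hypo)))
  expect_true(all(region_key(stricter$hyper) %in% region_key(fwd$hyper)))
})

test_that("identical truth in noise-free mode yields zero DMRs", {
  cfg <- tiny_config(seed = 5)
  ann <- make_genome_annotation(cfg)
  sim <- simulate_methylomes(cfg, ann,
                             tissues = c("mdr1_endosperm", "embryo"),
                             deterministic = TRUE)
  a <- merge_replicates(sim$replicates$mdr1_endosperm)
  b <- merge_replicates(sim$replicates$embryo)   # same truth everywhere
  res <- call_dmrs(intersect_samples(a, b, "CG"),
                   intersect_samples(a, b, "CHG"),
                   dmr_params(chromosomes = c("chr1", "chr2")))
  expect_gt(nrow(res$eligible), 0)
  expect_equal(nrow(res$hypo), 0L)
  expect_equal(nrow(res$hyper), 0L)
})

test_that("methylated- and unmethylated-region callers use inclusive thresholds", {
  mkmap <- function(meth, total, ctx) {
    n <- length(meth)
    make_map("chr1", seq(10, 10 + (n - 1) * 10, 10),
             rep(ctx, n), meth, total)
  }
  # 5 CHH sites, 10 reads total, 2 methylated -> level 0.2, reported
  b <- bin_methylome(mkmap(c(2, 0, 0, 0, 0), rep(2, 5), "CHH"), "CHH")
  expect_equal(b$level, 0.2)
  expect_equal(nrow(find_methylated_regions(b)), 1L)
  expect_equal(find_methylated_regions(b)$label, "mCHH_region")
  # level just below 0.2 (19/100) is not reported
  b19 <- bin_methylome(mkmap(c(19, rep(0, 4)), rep(20, 5), "CHH"), "CHH")
  expect_equal(nrow(find_methylated_regions(b19)), 0L)

  # UMR: level 0 with 6 sites at coverage 3 reported; 4 sites not
  u6 <- bin_methylome(mkmap(rep(0, 6), rep(3, 6), "CHG"), "CHG")
  expect_equal(find_unmethylated_regions(u6)$label, "CHG_UMR")
  u4 <- bin_methylome(mkmap(rep(0, 4), rep(3, 4), "CHG"), "CHG")
  expect_equal(nrow(find_unmethylated_regions(u4)), 0L)

  # random bins equal brute-force evaluation
  set.seed(31)
  pos <- sort(sample(1:50000, 2000))
  tot <- rpois(2000, 3) + 1L
  map <- make_map("chr1", pos, rep("CHH", 2000), rbinom(2000, tot, 0.2), tot)
  bins <- bin_methylome(map, "CHH")
  got <- find_methylated_regions(bins)$start
  df <- as.data.frame(map)
  df$bin <- (df$pos - 1) %/% 200
  want <- c()
  for (bb in unique(df$bin)) {
    i <- df$bin == bb
    if (sum(i) >= 5 && mean(df$total_reads[i]) >= 2 &&
        sum(df$meth_reads[i]) / sum(df$total_reads[i]) >= 0.2)
      want <- c(want, bb * 200)
  }
  expect_setequal(got, want)
})

test_that("methylated control regions need both contexts >= 0.2 in one sample", {
  ctrl <- data.frame(
    chrom = "chr1", start = c(0, 200, 400), end = c(200, 400, 600),
    cg_a = c(0.9, 0.9, 0.1), cg_b = c(0.0, 0.9, 0.9),
    chg_a = c(0.8, 0.1, 0.1), chg_b = c(0.0, 0.1, 0.9)
  )
  out <- methylated_control_filter(ctrl)
  # row 1 qualifies via sample a; row 2 fails CHG in both; row 3 via sample b
  expect_equal(out$start, c(0, 400))
  expect_equal(out$label, rep("methylated_control", 2))

  set.seed(41)
  r <- data.frame(chrom = "chr1", start = 200 * (0:199),
                  end = 200 * (1:200),
                  cg_a = runif(200), cg_b = runif(200),
                  chg_a = runif(200), chg_b = runif(200))
  got <- methylated_control_filter(r)$start
  want <- r$start[(r$cg_a >= 0.2 & r$chg_a >= 0.2) |
                    (r$cg_b >= 0.2 & r$chg_b >= 0.2)]
  expect_setequal(got, want)
})
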