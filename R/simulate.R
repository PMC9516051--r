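# Synthetic-data generators with planted ground truth. Every input the
# pipeline consumes can be emulated at desk scale: genome annotations,
# replicated per-cytosine methylomes with planted DMRs, small-RNA
# libraries, allele-specific count tables, and bulked-segregant variant
# tables. All generators are deterministic for a fixed seed.

with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

#' Simulation configuration with desk-scale defaults
#'
#' Bundles every tunable parameter of the synthetic-data generators. The
#' defaults define the standard study conditions used throughout the test
#' suite: a 2 x 5 Mb chromosome genome plus a 0.5 Mb unplaced scaffold;
#' methylomes of 3 biological replicates per tissue at 10x coverage each
#' (30x merged); 300 planted hypoDMR bins demethylated from 0.80 to 0.05
#' in both mCG and mCHG in wild-type endosperm; siRNA libraries of 1e5
#' reads per replicate with a two-fold mutant emission multiplier at DMRs;
#' an imprinting panel of 1,000 genes at ~200 informative reads each with
#' 2:1 maternal dosage; and a marker-level BSA genome of 10 x 20 Mb with
#' a causal locus at chr4:17.5 Mb, 500 selected progeny and 30x pooled
#' depth.
#'
#' @param seed Default integer seed for all generators.
#' @param genome Named vector of sequence lengths (chromosomes plus
#'   scaffolds).
#' @param chromosomes Names of the real chromosomes (annotation and DMR
#'   finalization are restricted to these).
#' @param n_genes,gene_length Gene annotation plan.
#' @param n_helitrons,helitron_length,helitron_motif_frac Helitron family
#'   plan (fraction carrying a planted binding motif).
#' @param n_gypsies,gypsy_length,solo_ltr_frac LTR retrotransposon plan.
#' @param n_tandem,tandem_length Tandem-repeat array plan.
#' @param n_trna,n_mirna,n_5s,n_nor Structural-RNA (siRNA exclusion) loci.
#' @param site_density Cytosines per bp for each context.
#' @param baseline Per-compartment truth levels: list with `het` and `eu`
#'   named vectors over CG/CHG/CHH.
#' @param n_dmrs Planted hypoDMR bins on chromosomes.
#' @param n_scaffold_dmrs Additional planted bins on the scaffold (these
#'   must be discarded at DMR finalization).
#' @param dmr_levels Named vector `c(high=, low=)`: planted truth in the
#'   methylated tissues and in demethylated wild-type endosperm.
#' @param n_chh_islands Planted RdDM-like mCHH bins near genes.
#' @param chh_island_level mCHH truth inside those bins (endosperm).
#' @param coverage,n_replicates Per-replicate mean site coverage and
#'   replicate count.
#' @param conversion_error Apparent methylation added to unmethylated
#'   cytosines by incomplete conversion.
#' @param bin_size Analysis grid (bp).
#' @param sirna List: `total_reads` per replicate, `dmr_multiplier` for
#'   mutant emission at DMRs, `len_probs` over 20-25 nt, `lowmapq_frac`,
#'   `structural_frac` (reads from exclusion loci), `offsize_frac` (reads
#'   outside the 20-25 window), `n_background_loci`.
#' @param imprinting List: `n_genes`, `meg_frac`, `peg_frac`, `depth`
#'   (mean informative reads per gene), `p_biallelic` (2/3 dosage),
#'   `p_meg`, `p_peg`.
#' @param bsa List: `n_chrom`, `chrom_length`, `marker_spacing`,
#'   `causal_chrom`, `causal_pos`, `cm_per_mb`, `n_progeny`, `depth_mut`,
#'   `depth_w22`, `error`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    genome = c(chr1 = 5e6, chr2 = 5e6, scaffold_282 = 5e5),
    chromosomes = c("chr1", "chr2"),
    n_genes = 300L, gene_length = 2000L,
    n_helitrons = 400L, helitron_length = 1000L, helitron_motif_frac = 0.5,
    n_gypsies = 120L, gypsy_length = 8000L, solo_ltr_frac = 0.25,
    n_tandem = 30L, tandem_length = 4000L,
    n_trna = 80L, n_mirna = 60L, n_5s = 20L, n_nor = 5L,
    site_density = c(CG = 0.04, CHG = 0.04, CHH = 0.04),
    baseline = list(het = c(CG = 0.85, CHG = 0.70, CHH = 0.05),
                    eu = c(CG = 0.05, CHG = 0.02, CHH = 0.02)),
    n_dmrs = 300L, n_scaffold_dmrs = 10L,
    dmr_levels = c(high = 0.80, low = 0.05),
    n_chh_islands = 100L, chh_island_level = 0.4,
    coverage = 10, n_replicates = 3L, conversion_error = 0.005,
    bin_size = 200L,
    sirna = list(total_reads = 1e5, dmr_multiplier = 2,
                 len_probs = c(`20` = 0.04, `21` = 0.10, `22` = 0.08,
                               `23` = 0.06, `24` = 0.60, `25` = 0.12),
                 lowmapq_frac = 0.2, structural_frac = 0.05,
                 offsize_frac = 0.03, n_background_loci = 500L),
    imprinting = list(n_genes = 1000L, meg_frac = 0.05, peg_frac = 0.02,
                      depth = 200, p_biallelic = 2 / 3, p_meg = 0.97,
                      p_peg = 0.03),
    bsa = list(n_chrom = 10L, chrom_length = 2e7, marker_spacing = 5e4,
               causal_chrom = "chr4", causal_pos = 1.75e7, cm_per_mb = 5,
               n_progeny = 500L, depth_mut = 30, depth_w22 = 8,
               error = 0.005)) {
  cfg <- as.list(environment())
  stopifnot(all(genome > 0), all(chromosomes %in% names(genome)),
            all(unlist(site_density) > 0),
            all(unlist(baseline) >= 0), all(unlist(baseline) <= 1),
            dmr_levels["high"] <= 1, dmr_levels["low"] >= 0,
            conversion_error >= 0, conversion_error < 1,
            coverage > 0, n_replicates >= 1)
  structure(cfg, class = "sim_config")
}

# place n non-overlapping intervals of length len on the given chromosomes,
# avoiding `occupied` (a GRanges); returns BED-style df
place_intervals <- function(n, len, chrom_lengths, occupied = NULL,
                            max_tries = 50L) {
  if (n == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  chroms <- names(chrom_lengths)
  placed <- NULL
  todo <- n
  for (i in seq_len(max_tries)) {
    if (todo <= 0L) break
    ch <- sample(chroms, todo, replace = TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    start <- floor(runif(todo) * (chrom_lengths[ch] - len))
    cand <- data.frame(chrom = ch, start = start, end = start + len)
    gr <- regions_to_granges(cand)
    grs <- Filter(Negate(is.null), list(
      occupied,
      if (!is.null(placed) && nrow(placed)) regions_to_granges(placed)))
    busy <- if (length(grs)) Reduce(c, grs) else NULL
    bad <- rep(FALSE, todo)
    if (!is.null(busy) && length(busy)) {
      h <- harmonize_seqlevels(gr, busy)
      bad <- GenomicRanges::countOverlaps(h[[1]], h[[2]],
                                          ignore.strand = TRUE) > 0
    }
    # also reject overlaps within the candidate batch itself
    selfhit <- GenomicRanges::countOverlaps(gr, gr,
                                            ignore.strand = TRUE) > 1
    keep <- cand[!(bad | selfhit), , drop = FALSE]
    placed <- rbind(placed, keep)
    todo <- n - nrow(placed)
  }
  if (todo > 0L)
    stop("could not place ", n, " intervals of ", len,
         " bp: genome too full", call. = FALSE)
  rownames(placed) <- NULL
  placed[order(placed$chrom, placed$start), , drop = FALSE]
}

#' Generate a synthetic genome annotation set
#'
#' Places non-overlapping genes (with strand, TSS and polyA anchors), a
#' Helitron family with and without planted binding motifs, LTR
#' retrotransposons (Gypsy-like, a fraction flagged as solo LTRs), tandem
#' repeat arrays, and structural-RNA loci (tRNA, 5S, NOR, miRNA; the siRNA
#' exclusion set) on the configured chromosomes. Also derives the
#' euchromatin plan (gene bodies plus 1 kb flanks) used by the methylome
#' simulator.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return List of BED-style tables: `genes`, `transposons`,
#'   `tandem_repeats`, `exclusion_loci`, `euchromatin`.
#' @export
make_genome_annotation <- function(config = sim_config(),
                                   seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    lens <- config$genome[config$chromosomes]
    genes <- place_intervals(config$n_genes, config$gene_length, lens)
    if (nrow(genes)) {
      genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
      genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
      genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
      genes$polya <- ifelse(genes$strand == "+", genes$end, genes$start)
    } else {
      genes$strand <- character(); genes$gene_id <- character()
      genes$tss <- numeric(); genes$polya <- numeric()
    }
    occ <- if (nrow(genes)) regions_to_granges(genes) else NULL

    hel <- place_intervals(config$n_helitrons, config$helitron_length,
                           lens, occ)
    hel$element_class <- rep("DHH", nrow(hel))
    hel$family <- rep("DHH00002", nrow(hel))
    hel$solo_ltr <- rep(FALSE, nrow(hel))
    hel$has_motif <- runif(nrow(hel)) < config$helitron_motif_frac
    occ <- c(occ, regions_to_granges(hel))

    gyp <- place_intervals(config$n_gypsies, config$gypsy_length, lens, occ)
    gyp$element_class <- rep("RLG", nrow(gyp))
    gyp$family <- rep("RLG00001", nrow(gyp))
    gyp$solo_ltr <- runif(nrow(gyp)) < config$solo_ltr_frac
    gyp$has_motif <- rep(FALSE, nrow(gyp))
    occ <- c(occ, regions_to_granges(gyp))

    tes <- rbind(hel, gyp)
    tes$strand <- sample(c("+", "-"), nrow(tes), replace = TRUE)
    tes$te_id <- sprintf("te%04d", seq_len(nrow(tes)))

    tr_class <- sample(c("Knob180", "CentC", "TR-1"), config$n_tandem,
                       replace = TRUE)
    tandem <- place_intervals(config$n_tandem, config$tandem_length,
                              lens, occ)
    tandem$element_class <- tr_class
    occ <- c(occ, regions_to_granges(tandem))

    tag <- function(df, cls) {
      df$element_class <- rep(cls, nrow(df))
      df
    }
    excl <- rbind(
      tag(place_intervals(config$n_trna, 75L, lens, occ), "tRNA"),
      tag(place_intervals(config$n_mirna, 130L, lens, occ), "miRNA"),
      tag(place_intervals(config$n_5s, 120L, lens, occ), "5S"),
      tag(place_intervals(config$n_nor, 2000L, lens, occ), "NOR")
    )
    excl <- excl[order(excl$chrom, excl$start), , drop = FALSE]
    rownames(excl) <- NULL

    eu <- genes[, c("chrom", "start", "end")]
    eu$start <- pmax(eu$start - 1000L, 0)
    eu$end <- eu$end + 1000L
    eu <- merge_and_filter_intervals(eu, max_gap = 0L, min_len = 0L)

    list(genes = genes, transposons = tes, tandem_repeats = tandem,
         exclusion_loci = excl, euchromatin = eu)
  })
}

# sample planted DMR bins on the analysis grid: ~50% inside Helitrons,
# ~30% in gene-proximal heterochromatin (1-2 kb from a gene), rest in
# distal heterochromatin; none may fall in euchromatin
sample_dmr_bins <- function(config, annotation) {
  bs <- config$bin_size
  lens <- config$genome[config$chromosomes]
  grid_bin <- function(chrom, pos) {
    start <- (pmax(pos, 0) %/% bs) * bs
    data.frame(chrom = chrom, start = start, end = start + bs)
  }
  n <- config$n_dmrs
  hel <- annotation$transposons[
    nrow(annotation$transposons) > 0 &
      annotation$transposons$family == "DHH00002", , drop = FALSE]
  n_hel <- if (nrow(hel)) round(0.5 * n) else 0L
  n_gene <- if (nrow(annotation$genes)) round(0.3 * n) else 0L
  n_rand <- n - n_hel - n_gene
  b1 <- if (n_hel > 0) {
    pick_hel <- hel[sample.int(nrow(hel), n_hel,
                               replace = n_hel > nrow(hel)), ]
    grid_bin(pick_hel$chrom,
             pick_hel$start +
               floor(runif(n_hel) *
                       pmax(pick_hel$end - pick_hel$start - bs, 1)))
  } else NULL
  b2 <- if (n_gene > 0) {
    g <- annotation$genes[sample.int(nrow(annotation$genes), n_gene,
                                     replace = n_gene > nrow(annotation$genes)), ]
    side <- sample(c(-1, 1), n_gene, replace = TRUE)
    off <- 1000 + floor(runif(n_gene) * 1000)   # 1-2 kb beyond the flank
    pos <- ifelse(side > 0, g$end + off, g$start - off - bs)
    grid_bin(g$chrom, pos)
  } else NULL
  ch <- sample(names(lens), n_rand, replace = TRUE,
               prob = lens / sum(lens))
  b3 <- grid_bin(ch, floor(runif(n_rand) * (lens[ch] - bs)))
  bins <- unique(rbind(b1, b2, b3))
  bins <- bins[bins$start >= 0 &
                 bins$end <= config$genome[bins$chrom], , drop = FALSE]
  drop <- region_overlap_fraction(bins, annotation$euchromatin) > 0
  bins <- bins[!drop, , drop = FALSE]
  # top up bins lost to deduplication or the euchromatin exclusion
  tries <- 0L
  while (nrow(bins) < n && tries < 20L) {
    tries <- tries + 1L
    need <- n - nrow(bins)
    ch <- sample(names(lens), need, replace = TRUE, prob = lens / sum(lens))
    extra <- grid_bin(ch, floor(runif(need) * (lens[ch] - bs)))
    extra <- extra[region_overlap_fraction(extra, annotation$euchromatin) == 0, ,
                   drop = FALSE]
    bins <- unique(rbind(bins, extra))
  }
  # scaffold bins, planted to exercise the finalization filter
  scaf <- setdiff(names(config$genome), config$chromosomes)
  if (length(scaf) && config$n_scaffold_dmrs > 0) {
    sc <- sample(scaf, config$n_scaffold_dmrs, replace = TRUE)
    sb <- grid_bin(sc, floor(runif(config$n_scaffold_dmrs) *
                               (config$genome[sc] - bs)))
    bins <- unique(rbind(bins, sb))
  }
  rownames(bins) <- NULL
  bins[order(bins$chrom, bins$start), , drop = FALSE]
}

#' Simulate replicated per-cytosine methylomes with planted DMRs
#'
#' Generates cytosine sites at the configured densities, assigns each a
#' true methylation level from its compartment (heterochromatin vs the
#' euchromatin plan) and context, plants hypoDMR bins whose mCG and mCHG
#' truth is `dmr_levels["high"]` in the methylated tissues (mdr1 mutant
#' endosperm, embryo) and `dmr_levels["low"]` in wild-type endosperm, and
#' plants RdDM-like mCHH islands near genes in the endosperm tissues.
#' Observed counts per replicate are Binomial(coverage, truth adjusted by
#' the conversion error) with Poisson site coverage; `deterministic = TRUE`
#' replaces both noise sources (fixed coverage, rounded counts), the
#' infinite-coverage limit used for noise-free invariants.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [make_genome_annotation()].
#' @param tissues Subset of `c("mdr1_endosperm", "wt_endosperm", "embryo")`.
#' @param seed Integer seed.
#' @param deterministic Disable sampling noise and conversion error.
#' @return List with `replicates` (per tissue, a list of methylome maps)
#'   and `truth` (`dmrs`: planted bins with an `on_scaffold` flag;
#'   `chh_islands`).
#' @export
simulate_methylomes <- function(config = sim_config(),
                                annotation = make_genome_annotation(config),
                                tissues = c("mdr1_endosperm",
                                            "wt_endosperm", "embryo"),
                                seed = config$seed,
                                deterministic = FALSE) {
  tissues <- match.arg(tissues, several.ok = TRUE)
  with_seed(seed + 1L, {
    lens <- config$genome
    # site scaffold, shared by all samples (positions are genomic)
    sites <- data.table::rbindlist(lapply(names(lens), function(ch) {
      data.table::rbindlist(lapply(names(config$site_density), function(ctx) {
        n <- round(lens[[ch]] * config$site_density[[ctx]])
        data.table::data.table(
          chrom = ch,
          pos = sort(sample.int(lens[[ch]], n)),
          context = ctx
        )
      }))
    }))
    sites <- unique(sites, by = c("chrom", "pos"))
    sites[, strand := sample(c("+", "-"), .N, replace = TRUE)]
    sites[, dinuc := data.table::fcase(context == "CG", "CG",
                                       context == "CHG", "CA",
                                       default = "CT")]
    # compartments
    sites[, eu := FALSE]
    eugr <- regions_to_granges(annotation$euchromatin)
    sgr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos, sites$pos))
    sites[S4Vectors::queryHits(GenomicRanges::findOverlaps(sgr, eugr)),
          eu := TRUE]
    base <- function(compartment_eu, ctx) {
      b <- ifelse(compartment_eu, config$baseline$eu[ctx],
                  config$baseline$het[ctx])
      unname(b)
    }
    sites[, truth_ref := base(eu, context)]   # mutant endosperm / embryo
    sites[, truth_wt := truth_ref]            # wild-type endosperm

    dmrs <- sample_dmr_bins(config, annotation)
    dmrs$on_scaffold <- !dmrs$chrom %in% config$chromosomes
    dgr <- regions_to_granges(dmrs)
    in_dmr <- S4Vectors::queryHits(GenomicRanges::findOverlaps(sgr, dgr))
    hi <- config$dmr_levels[["high"]]
    lo <- config$dmr_levels[["low"]]
    sites[in_dmr, `:=`(
      truth_ref = data.table::fifelse(context %in% c("CG", "CHG"), hi,
                                      truth_ref),
      truth_wt = data.table::fifelse(context %in% c("CG", "CHG"), lo,
                                     truth_wt)
    )]
    # RdDM-like mCHH islands near genes (endosperm tissues only)
    gene_flanks <- annotation$genes[, c("chrom", "start", "end")]
    gene_flanks$start <- pmax(gene_flanks$start - 500L, 0)
    gene_flanks$end <- gene_flanks$start + 200L
    n_isl <- min(config$n_chh_islands, nrow(gene_flanks))
    isl <- gene_flanks[sample.int(nrow(gene_flanks), n_isl), , drop = FALSE]
    igr <- regions_to_granges(isl)
    in_isl <- S4Vectors::queryHits(GenomicRanges::findOverlaps(sgr, igr))
    sites[, chh_endo := FALSE]
    sites[in_isl, chh_endo := context == "CHH"]

    truth_for <- function(tissue) {
      tr <- if (tissue == "wt_endosperm") sites$truth_wt else sites$truth_ref
      if (tissue %in% c("wt_endosperm", "mdr1_endosperm"))
        tr <- ifelse(sites$chh_endo, config$chh_island_level, tr)
      tr
    }
    make_rep <- function(tissue, rep_i) {
      tr <- truth_for(tissue)
      if (deterministic) {
        cov <- rep(round(config$coverage), nrow(sites))
        meth <- round(tr * cov)
      } else {
        cov <- rpois(nrow(sites), config$coverage)
        p <- tr + (1 - tr) * config$conversion_error
        meth <- rbinom(nrow(sites), cov, p)
      }
      keep <- cov > 0
      new_methylome_map(
        data.table::data.table(
          chrom = sites$chrom[keep], pos = sites$pos[keep],
          strand = sites$strand[keep], context = sites$context[keep],
          dinuc = sites$dinuc[keep],
          meth_reads = as.integer(meth[keep]),
          total_reads = as.integer(cov[keep])
        ),
        sample_id = paste0(tissue, "_rep", rep_i)
      )
    }
    reps <- lapply(tissues, function(ti)
      lapply(seq_len(config$n_replicates), function(i) make_rep(ti, i)))
    names(reps) <- tissues
    list(replicates = reps,
         truth = list(dmrs = dmrs, chh_islands = isl))
  })
}

#' Simulate small-RNA sequencing libraries
#'
#' Draws reads per replicate for wild-type and mdr1 mutant endosperm from a
#' locus model: planted DMR bins (mutant emission multiplied by
#' `dmr_multiplier`), background siRNA loci near genes, and structural-RNA
#' loci (a `structural_frac` share, later removed by classification).
#' Lengths follow the configured 20-25 nt mix dominated by 24 nt, with an
#' `offsize_frac` share outside the window; a `lowmapq_frac` share is
#' tagged multi-mapped (MAPQ < 20).
#'
#' @param config A [sim_config()].
#' @param annotation Output of [make_genome_annotation()].
#' @param dmrs BED-style table of planted DMR bins (chromosome bins of the
#'   methylome truth, typically).
#' @param seed Integer seed.
#' @return data.frame of reads: `chrom`, `start`, `end`, `length`, `mapq`,
#'   `library_id`, `replicate_id`.
#' @export
simulate_sirna_libraries <- function(config = sim_config(), annotation,
                                     dmrs, seed = config$seed) {
  with_seed(seed + 2L, {
    sc <- config$sirna
    bg <- annotation$genes[, c("chrom", "start", "end")]
    bg$end <- pmin(bg$start + 400L, bg$end)
    n_bg <- min(sc$n_background_loci, nrow(bg))
    bg <- bg[sample.int(nrow(bg), n_bg), , drop = FALSE]
    loci <- rbind(
      cbind(dmrs[, c("chrom", "start", "end")], kind = "dmr"),
      cbind(bg, kind = "background"),
      cbind(annotation$exclusion_loci[, c("chrom", "start", "end")],
            kind = "structural")
    )
    lens_nt <- as.integer(names(sc$len_probs))
    draw_library <- function(tissue, rep_i) {
      w <- ifelse(loci$kind == "dmr",
                  if (tissue == "mdr1_endosperm") sc$dmr_multiplier else 1,
                  1)
      # structural loci get the weight that yields the configured share
      w_str <- sum(w[loci$kind != "structural"]) * sc$structural_frac /
        (1 - sc$structural_frac) / sum(loci$kind == "structural")
      w[loci$kind == "structural"] <- w_str
      n <- sc$total_reads
      li <- sample.int(nrow(loci), n, replace = TRUE, prob = w)
      len <- sample(lens_nt, n, replace = TRUE, prob = sc$len_probs)
      off <- runif(n) < sc$offsize_frac
      len[off] <- sample(c(18L, 19L, 26L, 28L), sum(off), replace = TRUE)
      lo <- loci$start[li]
      hi <- pmax(loci$end[li] - len, lo + 1L)
      start <- lo + floor(runif(n) * (hi - lo))
      mapq <- ifelse(runif(n) < sc$lowmapq_frac,
                     sample(0:10, n, replace = TRUE), 42L)
      data.frame(
        chrom = loci$chrom[li], start = start, end = start + len,
        length = len, mapq = mapq,
        library_id = tissue, replicate_id = paste0(tissue, "_rep", rep_i),
        stringsAsFactors = FALSE
      )
    }
    out <- lapply(c("wt_endosperm", "mdr1_endosperm"), function(ti)
      lapply(seq_len(config$n_replicates), function(i)
        draw_library(ti, i)))
    do.call(rbind, unlist(out, recursive = FALSE))
  })
}

#' Simulate allele-specific read counts for imprinting analysis
#'
#' Genes are assigned a truth category (`biallelic`, `MEG`, `PEG`) at the
#' configured fractions; per gene, informative read depth is Poisson around
#' `depth`, split across the two reciprocal cross directions, and maternal
#' reads are Binomial with maternal probability 2/3 (biallelic genome
#' dosage), `p_meg` or `p_peg`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `counts` (feature_id, direction, maternal, paternal) and
#'   `truth` (feature_id, truth_category).
#' @export
simulate_allele_counts <- function(config = sim_config(),
                                   seed = config$seed) {
  with_seed(seed + 3L, {
    ip <- config$imprinting
    n <- ip$n_genes
    n_meg <- round(ip$meg_frac * n)
    n_peg <- round(ip$peg_frac * n)
    cat_t <- sample(c(rep("MEG", n_meg), rep("PEG", n_peg),
                      rep("biallelic", n - n_meg - n_peg)))
    p <- c(biallelic = ip$p_biallelic, MEG = ip$p_meg, PEG = ip$p_peg)[cat_t]
    depth <- rpois(n, ip$depth)
    d1 <- rbinom(n, depth, 0.5)
    d2 <- depth - d1
    m1 <- rbinom(n, d1, p)
    m2 <- rbinom(n, d2, p)
    id <- sprintf("gene%04d", seq_len(n))
    counts <- rbind(
      data.frame(feature_id = id, direction = "AxB", maternal = m1,
                 paternal = d1 - m1),
      data.frame(feature_id = id, direction = "BxA", maternal = m2,
                 paternal = d2 - m2)
    )
    list(counts = counts[order(counts$feature_id), ],
         truth = data.frame(feature_id = id, truth_category = cat_t))
  })
}

# Phred-scaled genotype likelihoods for a pooled sample treated as a
# diploid call: simple binomial model over alt reads with error `e`;
# normalized so the best genotype has PL 0. Internally consistent with
# depths -- the BSA filters treat these fields as opaque thresholds.
genotype_pl <- function(alt, depth, e = 0.005) {
  l_homref <- alt * log10(e) + (depth - alt) * log10(1 - e)
  l_het <- depth * log10(0.5)
  l_homalt <- (depth - alt) * log10(e) + alt * log10(1 - e)
  ll <- cbind(l_homref, l_het, l_homalt)
  pl <- round(-10 * (ll - apply(ll, 1, max)))
  gq <- apply(pl, 1, function(x) sort(x)[2])
  list(pl_homref = pl[, 1], pl_het = pl[, 2], pl_homalt = pl[, 3],
       gq = pmin(gq, 99))
}

#' Simulate a bulked-segregant variant table
#'
#' Models the mapping cross: a mother heterozygous for the causal mutation
#' (and for stock-specific markers genome-wide, in coupling with it) is
#' crossed to a homozygous mutant father; mutant homozygotes are selected.
#' At a marker with recombination fraction `r` from the causal locus
#' (Haldane map at `cm_per_mb`; 1/2 on other chromosomes), the maternal
#' gamete carries the alternative (stock) allele with probability `1 - r`
#' and the paternal always does, so the expected pooled alternative allele
#' frequency is `1 - r/2`: 0.75 genome-wide, approaching 1 at the causal
#' locus. Pooled read counts are binomial at Poisson depth with sequencing
#' error; the wild-type reference bulk carries the reference allele.
#' Genotype-quality and likelihood fields are synthesized with a binomial
#' model consistent with the depths.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Variant table (one marker per `marker_spacing` bp) with columns
#'   `chrom`, `pos`, `ref`, `alt`, `expected_af`, per-bulk depth/frequency/
#'   quality/likelihood fields, and attributes `causal` (list with `chrom`,
#'   `pos`) and `chrom_lengths`.
#' @export
simulate_bsa <- function(config = sim_config(), seed = config$seed) {
  with_seed(seed + 4L, {
    b <- config$bsa
    chroms <- paste0("chr", seq_len(b$n_chrom))
    mk <- data.table::rbindlist(lapply(chroms, function(ch) {
      data.table::data.table(
        chrom = ch,
        pos = seq(b$marker_spacing, b$chrom_length, by = b$marker_spacing)
      )
    }))
    d_cM <- ifelse(mk$chrom == b$causal_chrom,
                   abs(mk$pos - b$causal_pos) / 1e6 * b$cm_per_mb, Inf)
    r <- ifelse(is.finite(d_cM), haldane(d_cM), 0.5)
    n <- b$n_progeny
    mat_alt <- rbinom(nrow(mk), n, 1 - r)       # maternal gametes with alt
    true_af <- (n + mat_alt) / (2 * n)          # paternal allele always alt
    e <- b$error
    dp_mut <- rpois(nrow(mk), b$depth_mut)
    alt_mut <- rbinom(nrow(mk), dp_mut, true_af * (1 - e) + (1 - true_af) * e)
    dp_w22 <- rpois(nrow(mk), b$depth_w22)
    alt_w22 <- rbinom(nrow(mk), dp_w22, e)
    plm <- genotype_pl(alt_mut, dp_mut, e)
    plw <- genotype_pl(alt_w22, dp_w22, e)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nrow(mk), replace = TRUE)
    alt <- vapply(ref, function(x) sample(setdiff(bases, x), 1), "")
    out <- data.frame(
      chrom = mk$chrom, pos = mk$pos, ref = ref, alt = alt,
      expected_af = 1 - r / 2,
      dp_w22 = dp_w22,
      af_w22 = ifelse(dp_w22 > 0, alt_w22 / dp_w22, NA_real_),
      gq_w22 = plw$gq,
      dp_mut = dp_mut,
      af_mut = ifelse(dp_mut > 0, alt_mut / dp_mut, NA_real_),
      gq_mut = plm$gq,
      pl_homref_mut = plm$pl_homref,
      pl_het_mut = plm$pl_het,
      pl_homalt_mut = plm$pl_homalt,
      stringsAsFactors = FALSE
    )
    attr(out, "causal") <- list(chrom = b$causal_chrom, pos = b$causal_pos)
    attr(out, "chrom_lengths") <-
      stats::setNames(rep(b$chrom_length, b$n_chrom), chroms)
    out
  })
}

#' Generate random DNA sequences, optionally embedding a motif
#'
#' Bases are drawn i.i.d. at the given GC content; when `embed_motif` is an
#' IUPAC consensus, one concrete instance (ambiguity codes resolved
#' uniformly) is written at a random position of each sequence. Used to
#' emulate element sequences for GC-content and motif-matching analyses.
#'
#' @param n Number of sequences.
#' @param length Sequence length (bp).
#' @param gc GC fraction.
#' @param embed_motif Optional IUPAC consensus to plant.
#' @param seed Optional integer seed.
#' @return Character vector of sequences.
#' @export
simulate_sequences <- function(n, length, gc = 0.47, embed_motif = NULL,
                               seed = NULL) {
  run <- function() {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(names(p), length, replace = TRUE, prob = p),
            collapse = ""), "")
    if (!is.null(embed_motif)) {
      mlen <- nchar(embed_motif)
      stopifnot(mlen <= length)
      for (i in seq_len(n)) {
        inst <- vapply(strsplit(toupper(embed_motif), "")[[1]], function(code) {
          opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
          sample(opts, 1)
        }, "")
        at <- sample.int(length - mlen + 1L, 1)
        substr(seqs[i], at, at + mlen - 1L) <- paste(inst, collapse = "")
      }
    }
    seqs
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
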