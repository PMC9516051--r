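# 200-bp grid region callers: eligibility, hypo/hyper DMRs requiring
# concordant mCG+mCHG differences, mCHH regions, CHG unmethylated regions
# (the euchromatin proxy), and methylated control regions.

#' Parameters for dual-context DMR calling
#'
#' Defaults reproduce the threshold set used for endosperm DMR discovery:
#' non-overlapping 200-bp bins, at least 5 informative cytosines per context
#' with a mean coverage of at least 3 in both samples (eligibility), and a
#' DMR requires, in both CG and CHG contexts independently, a greater than
#' two-fold relative change together with an absolute difference greater
#' than 0.20.
#'
#' @param bin_size Bin width in bp (grid anchored at coordinate 0).
#' @param min_cov Minimum mean read depth over a bin's informative sites,
#'   per context and per sample, for eligibility.
#' @param min_sites Minimum informative cytosines per context per sample.
#' @param min_abs_dif Minimum absolute methylation difference (strict `>`).
#' @param fold Minimum fold change (strict `>`).
#' @param chromosomes Allowed sequence names for finalized DMRs; bins on
#'   other sequences (scaffolds) are discarded at the context-combination
#'   step. `NULL` keeps all.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(bin_size = 200L, min_cov = 3, min_sites = 5L,
                       min_abs_dif = 0.20, fold = 2,
                       chromosomes = paste0("chr", 1:10)) {
  stopifnot(bin_size > 0, min_cov > 0, min_sites > 0, min_abs_dif > 0,
            fold > 1)
  structure(list(bin_size = as.integer(bin_size), min_cov = min_cov,
                 min_sites = as.integer(min_sites),
                 min_abs_dif = min_abs_dif, fold = fold,
                 chromosomes = chromosomes),
            class = "dmr_params")
}

#' Aggregate a paired site table onto a fixed bin grid
#'
#' Bins are laid on a grid anchored at coordinate 0 of each chromosome; a
#' site at 1-based position `p` falls in bin `floor((p - 1) / bin_size)`,
#' so positions 1..200 fall in \[0, 200). Bin methylation levels are
#' count-weighted (sum of methylated reads over sum of total reads), not
#' means of per-site fractions.
#'
#' @param table A paired site table from [intersect_samples()].
#' @param bin_size Bin width in bp.
#' @return A `data.table` of non-empty bins with columns `chrom`, `start`,
#'   `end`, `n_sites`, read-count sums, `level_a`, `level_b`, `mean_cov_a`,
#'   `mean_cov_b`; attributes `context` and `bin_size`.
#' @export
bin_sites <- function(table, bin_size = 200L) {
  stopifnot(bin_size > 0)
  dt <- data.table::as.data.table(table)
  need <- c("chrom", "pos", "meth_a", "total_a", "meth_b", "total_b")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("paired site table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bin_size <- as.integer(bin_size)
  bins <- dt[, .(
    n_sites = .N,
    sum_meth_a = sum(meth_a), sum_total_a = sum(total_a),
    sum_meth_b = sum(meth_b), sum_total_b = sum(total_b)
  ), by = .(chrom, start = ((pos - 1L) %/% bin_size) * bin_size)]
  bins[, `:=`(
    end = start + bin_size,
    level_a = sum_meth_a / sum_total_a,
    level_b = sum_meth_b / sum_total_b,
    mean_cov_a = sum_total_a / n_sites,
    mean_cov_b = sum_total_b / n_sites
  )]
  data.table::setcolorder(bins, c("chrom", "start", "end"))
  data.table::setorder(bins, chrom, start)
  data.table::setattr(bins, "context", attr(table, "context"))
  data.table::setattr(bins, "bin_size", bin_size)
  bins[]
}

#' Aggregate a single methylome map onto a fixed bin grid
#'
#' Single-sample analogue of [bin_sites()], used by the mCHH-region and
#' CHG-UMR callers. Only sites of the requested context with coverage are
#' aggregated.
#'
#' @param map A methylome map.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param bin_size Bin width in bp.
#' @return A `data.table` of non-empty bins with `n_sites`, count sums,
#'   `level` and `mean_cov`.
#' @export
bin_methylome <- function(map, context = c("CG", "CHG", "CHH"),
                          bin_size = 200L) {
  context <- match.arg(context)
  ctx <- context
  bin_size <- as.integer(bin_size)
  dt <- data.table::as.data.table(map)[context == ctx & total_reads > 0]
  bins <- dt[, .(
    n_sites = .N, sum_meth = sum(meth_reads), sum_total = sum(total_reads)
  ), by = .(chrom, start = ((pos - 1L) %/% bin_size) * bin_size)]
  bins[, `:=`(end = start + bin_size, level = sum_meth / sum_total,
              mean_cov = sum_total / n_sites)]
  data.table::setcolorder(bins, c("chrom", "start", "end"))
  data.table::setorder(bins, chrom, start)
  data.table::setattr(bins, "context", ctx)
  data.table::setattr(bins, "bin_size", bin_size)
  bins[]
}

check_same_grid <- function(cg_bins, chg_bins) {
  ba <- attr(cg_bins, "bin_size")
  bb <- attr(chg_bins, "bin_size")
  if (!is.null(ba) && !is.null(bb) && ba != bb)
    stop("mismatched bin grids: ", ba, " vs ", bb, " bp", call. = FALSE)
  invisible(TRUE)
}

#' Identify bins eligible for differential methylation analysis
#'
#' A bin is eligible if and only if, in both samples, it has at least
#' `min_sites` informative CGs with mean coverage at least `min_cov`, and
#' likewise for CHGs. The eligible set is the control-region denominator for
#' all enrichment statistics: these bins share the mappability and
#' informative-cytosine biases of the DMRs.
#'
#' @param cg_bins,chg_bins Binned paired site tables from [bin_sites()] for
#'   the CG and CHG contexts, on the same grid.
#' @param params A [dmr_params()] object.
#' @return A `data.table` of eligible bins with per-context levels
#'   `cg_a`, `cg_b`, `chg_a`, `chg_b` and `label = "eligible"`.
#' @export
eligible_bins <- function(cg_bins, chg_bins, params = dmr_params()) {
  check_same_grid(cg_bins, chg_bins)
  ok <- function(b) {
    b$n_sites >= params$min_sites &
      b$mean_cov_a >= params$min_cov & b$mean_cov_b >= params$min_cov
  }
  cg <- data.table::as.data.table(cg_bins)[ok(cg_bins),
    .(chrom, start, end, cg_a = level_a, cg_b = level_b)]
  chg <- data.table::as.data.table(chg_bins)[ok(chg_bins),
    .(chrom, start, end, chg_a = level_a, chg_b = level_b)]
  out <- merge(cg, chg, by = c("chrom", "start", "end"), sort = TRUE)
  out[, label := "eligible"]
  data.table::setattr(out, "bin_size", attr(cg_bins, "bin_size"))
  out[]
}

# strict fold-change test with the zero-denominator rule: when the
# denominator level is 0 the fold condition holds iff the numerator is > 0
fold_exceeds <- function(num, den, fold) {
  data.table::fifelse(den > 0, num > fold * den, num > 0)
}

#' Call single-context hypo- and hyperDMR bins
#'
#' With `v1 = level_a` and `v2 = level_b`: a bin is hyper iff
#' `v2 > fold * v1` and `v2 - v1 > min_abs_dif`; hypo iff the opposite
#' (`v1 > fold * v2` and `v1 - v2 > min_abs_dif`). Inequalities are strict.
#' Bins should already be restricted to the eligible set.
#'
#' @param bins A binned paired site table (one context).
#' @param params A [dmr_params()] object.
#' @return `list(hypo = , hyper = )` of bin subsets.
#' @export
call_context_dmrs <- function(bins, params = dmr_params()) {
  dt <- data.table::as.data.table(bins)
  hyper <- fold_exceeds(dt$level_b, dt$level_a, params$fold) &
    (dt$level_b - dt$level_a > params$min_abs_dif)
  hypo <- fold_exceeds(dt$level_a, dt$level_b, params$fold) &
    (dt$level_a - dt$level_b > params$min_abs_dif)
  out <- list(hypo = dt[hypo], hyper = dt[hyper])
  for (nm in names(out)) {
    data.table::setattr(out[[nm]], "context", attr(bins, "context"))
    data.table::setattr(out[[nm]], "bin_size", attr(bins, "bin_size"))
  }
  out
}

#' Intersect CG and CHG DMR sets and drop scaffold bins
#'
#' A finalized DMR is a grid bin called in the same direction in both the CG
#' and CHG contexts (same-grid-bin identity, equivalent to any-overlap
#' intersection on a shared grid). Bins on sequences outside `chromosomes`
#' (unplaced scaffolds) are discarded.
#'
#' @param cg,chg Single-context DMR bin tables of the same direction.
#' @param direction `"hypo"` or `"hyper"` (recorded in the `label` column).
#' @param chromosomes Allowed sequence names; `NULL` keeps all.
#' @return A `data.table` of DMR bins with per-context levels and a `label`.
#' @export
combine_contexts <- function(cg, chg, direction = c("hypo", "hyper"),
                             chromosomes = paste0("chr", 1:10)) {
  direction <- match.arg(direction)
  check_same_grid(cg, chg)
  cgd <- data.table::as.data.table(cg)[,
    .(chrom, start, end, cg_a = level_a, cg_b = level_b)]
  chgd <- data.table::as.data.table(chg)[,
    .(chrom, start, end, chg_a = level_a, chg_b = level_b)]
  out <- merge(cgd, chgd, by = c("chrom", "start", "end"), sort = TRUE)
  if (!is.null(chromosomes)) out <- out[chrom %in% chromosomes]
  out[, label := paste0(direction, "DMR")]
  out[]
}

#' Call dual-context DMRs and eligible control regions from paired tables
#'
#' Convenience wrapper running the full caller: bin both contexts, derive
#' the eligible set, call per-context DMRs on the eligible bins, intersect
#' contexts per direction and drop scaffold bins. HypoDMRs are bins where
#' methylation is lower in sample b than in sample a.
#'
#' @param pairs_cg,pairs_chg Paired site tables from [intersect_samples()]
#'   for the CG and CHG contexts of the same sample pair.
#' @param params A [dmr_params()] object.
#' @return `list(eligible = , hypo = , hyper = )`. The eligible set keeps
#'   scaffold bins (controls are defined genome-wide); the DMR sets do not.
#' @export
call_dmrs <- function(pairs_cg, pairs_chg, params = dmr_params()) {
  cg_bins <- bin_sites(pairs_cg, params$bin_size)
  chg_bins <- bin_sites(pairs_chg, params$bin_size)
  elig <- eligible_bins(cg_bins, chg_bins, params)
  key <- c("chrom", "start", "end")
  cg_e <- cg_bins[elig[, key, with = FALSE], on = key, nomatch = NULL]
  chg_e <- chg_bins[elig[, key, with = FALSE], on = key, nomatch = NULL]
  data.table::setattr(cg_e, "bin_size", params$bin_size)
  data.table::setattr(chg_e, "bin_size", params$bin_size)
  cg_d <- call_context_dmrs(cg_e, params)
  chg_d <- call_context_dmrs(chg_e, params)
  list(
    eligible = elig,
    hypo = combine_contexts(cg_d$hypo, chg_d$hypo, "hypo",
                            params$chromosomes),
    hyper = combine_contexts(cg_d$hyper, chg_d$hyper, "hyper",
                             params$chromosomes)
  )
}

#' Call methylated regions from single-sample bins
#'
#' Reports bins with at least `min_sites` informative cytosines, mean
#' coverage at least `min_cov`, and methylation level at least `min_level`
#' (inclusive comparisons). With the defaults and CHH-context bins this is
#' the mCHH-region caller (RdDM signature).
#'
#' @param bins Single-sample bins from [bin_methylome()].
#' @param min_sites,min_cov,min_level Thresholds.
#' @return The qualifying bin subset with `label = "mCHH_region"` when the
#'   bins are CHH-context, otherwise `"methylated_region"`.
#' @export
find_methylated_regions <- function(bins, min_sites = 5L, min_cov = 2,
                                    min_level = 0.2) {
  dt <- data.table::as.data.table(bins)
  out <- dt[n_sites >= min_sites & mean_cov >= min_cov & level >= min_level]
  ctx <- attr(bins, "context")
  out[, label := if (identical(ctx, "CHH")) "mCHH_region"
      else "methylated_region"]
  out[]
}

#' Call unmethylated regions from single-sample bins
#'
#' Reports bins with at least `min_sites` informative cytosines, mean
#' coverage at least `min_cov`, and methylation level at most `max_level`
#' (inclusive). Applied to CHG-context embryo bins this yields the
#' euchromatin proxy track: euchromatin is stably depleted of mCHG across
#' maize development.
#'
#' @param bins Single-sample bins from [bin_methylome()].
#' @param min_sites,min_cov,max_level Thresholds.
#' @return The qualifying bin subset with `label = "CHG_UMR"` when the bins
#'   are CHG-context, otherwise `"unmethylated_region"`.
#' @export
find_unmethylated_regions <- function(bins, min_sites = 5L, min_cov = 2,
                                      max_level = 0.2) {
  dt <- data.table::as.data.table(bins)
  out <- dt[n_sites >= min_sites & mean_cov >= min_cov & level <= max_level]
  ctx <- attr(bins, "context")
  out[, label := if (identical(ctx, "CHG")) "CHG_UMR"
      else "unmethylated_region"]
  out[]
}

#' Restrict control regions to those with methylation potential
#'
#' Keeps an eligible control region iff both its mCG and mCHG levels are at
#' least `min_level` in at least one of the two samples. Regions that are
#' unmethylated in both samples cannot, by definition, be demethylated, so
#' this set is the denominator for enrichment relative to regions with the
#' potential to be methylated.
#'
#' @param controls Eligible regions from [eligible_bins()] (columns `cg_a`,
#'   `cg_b`, `chg_a`, `chg_b`).
#' @param min_level Threshold (inclusive).
#' @return The qualifying subset with `label = "methylated_control"`.
#' @export
methylated_control_filter <- function(controls, min_level = 0.2) {
  dt <- data.table::as.data.table(controls)
  out <- dt[(cg_a >= min_level & chg_a >= min_level) |
              (cg_b >= min_level & chg_b >= min_level)]
  out[, label := "methylated_control"]
  out[]
}
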