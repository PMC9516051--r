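# Bulked-segregant analysis: variant-table filters, windowed alternative
# allele-frequency and density scans, and candidate-region detection.
#
# Variant tables are VCF exports with one row per site and per-bulk columns:
# af_* (alternative allele frequency), dp_* (depth), gq_* (genotype
# quality), pl_homref_* / pl_het_* / pl_homalt_* (normalized Phred-scaled
# likelihoods, minimum 0). Bulk suffixes are `w22` (wild-type reference
# bulk) and `mut` (selected mutant bulks combined).

bsa_drop_incomplete <- function(tab, cols) {
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  complete <- stats::complete.cases(tab[, cols, drop = FALSE])
  n_skipped <- sum(!complete)
  if (n_skipped > 0)
    message(n_skipped, " record(s) skipped for missing fields")
  structure(tab[complete, , drop = FALSE], n_skipped = n_skipped)
}

#' Filter BSA variants for causal linkage (likelihood-based method)
#'
#' Keeps records with: alternative allele frequency of zero in the
#' wild-type bulk with depth 2 to 15; depth 5 to 50 in the combined mutant
#' bulks; and, in the mutant bulks, a normalized Phred-scaled likelihood of
#' at least 400 for homozygous reference and exactly 0 for homozygous
#' alternative. Depth bounds are inclusive. This selects near-homozygous
#' alternative alleles genome-wide; the causal region stands out by its
#' frequency near 1.
#'
#' @param table Variant table (see file-level format notes). Records with
#'   missing fields are skipped with a logged count.
#' @return The qualifying subset, with an `n_skipped` attribute.
#' @export
filter_variants_method1 <- function(table) {
  cols <- c("af_w22", "dp_w22", "dp_mut", "pl_homref_mut", "pl_homalt_mut")
  tab <- bsa_drop_incomplete(table, cols)
  keep <- tab$af_w22 == 0 &
    tab$dp_w22 >= 2 & tab$dp_w22 <= 15 &
    tab$dp_mut >= 5 & tab$dp_mut <= 50 &
    tab$pl_homref_mut >= 400 & tab$pl_homalt_mut == 0
  structure(tab[keep, , drop = FALSE], n_skipped = attr(tab, "n_skipped"))
}

#' Filter BSA variants for causal linkage (genotype-quality method)
#'
#' Keeps records with genotype quality at least 20 in both bulks, wild-type
#' bulk depth 5 to 14, combined mutant-bulk depth 6 to 49, and mutant-bulk
#' alternative allele frequency strictly above 0.75 (the cross's background
#' expectation). Depth bounds are inclusive; the frequency bound is strict.
#'
#' @inheritParams filter_variants_method1
#' @return The qualifying subset, with an `n_skipped` attribute.
#' @export
filter_variants_method2 <- function(table) {
  cols <- c("gq_w22", "gq_mut", "dp_w22", "dp_mut", "af_mut")
  tab <- bsa_drop_incomplete(table, cols)
  keep <- tab$gq_w22 >= 20 & tab$gq_mut >= 20 &
    tab$dp_w22 >= 5 & tab$dp_w22 <= 14 &
    tab$dp_mut >= 6 & tab$dp_mut <= 49 &
    tab$af_mut > 0.75
  structure(tab[keep, , drop = FALSE], n_skipped = attr(tab, "n_skipped"))
}

#' Windowed variant-frequency and density scan
#'
#' Sliding windows of `window` bp advanced by `step` bp along each
#' chromosome. Per window: variant count, density per Mb, and the
#' unweighted mean of the chosen per-variant value (by default the
#' mutant-bulk alternative allele frequency); a depth-weighted mean is
#' available via `weight_col`.
#'
#' @param variants Variant table with `chrom` and `pos` (1-based).
#' @param window,step Window and step size in bp (`window >= step > 0`).
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   absent each chromosome extends to its last variant.
#' @param value_col Column averaged per window.
#' @param weight_col Optional column of weights (e.g. `"dp_mut"`) for a
#'   weighted mean.
#' @return data.frame with `chrom`, `start`, `end`, `n_variants`,
#'   `mean_af` (`NA` for empty windows) and `density_per_mb`.
#' @export
window_scan <- function(variants, window = 1e6, step = 2e5,
                        chrom_lengths = NULL, value_col = "af_mut",
                        weight_col = NULL) {
  if (!(window >= step && step > 0))
    stop("need window >= step > 0", call. = FALSE)
  dt <- data.table::as.data.table(variants)
  stopifnot(all(c("chrom", "pos") %in% names(dt)))
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths)
            else sort(unique(dt$chrom))
  res <- lapply(chroms, function(ch) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]]
           else max(dt[chrom == ch, pos], 0)
    if (len < window) return(NULL)
    starts <- seq(0, len - window, by = step)
    sub <- dt[chrom == ch]
    val <- sub[[value_col]]
    wt <- if (!is.null(weight_col)) sub[[weight_col]] else rep(1, nrow(sub))
    # assign each variant to the window indices covering it
    out <- data.table::data.table(start = starts, n_variants = 0L,
                                  sum_v = 0, sum_w = 0)
    if (nrow(sub)) {
      p0 <- sub$pos - 1                      # 0-based
      last <- pmin(p0 %/% step, length(starts) - 1)
      first <- pmax(floor((p0 - window) / step) + 1, 0)
      reps <- pmax(last - first + 1, 0)
      vidx <- rep(seq_len(nrow(sub)), reps)
      widx <- unlist(mapply(function(f, l) if (l >= f) seq(f, l) else integer(),
                            first, last, SIMPLIFY = FALSE)) + 1
      agg <- data.table::data.table(
        w = widx, v = val[vidx], wt = wt[vidx]
      )[, .(n = .N, sv = sum(wt * v, na.rm = TRUE),
            sw = sum(wt[!is.na(v)])), by = w]
      out$n_variants[agg$w] <- agg$n
      out$sum_v[agg$w] <- agg$sv
      out$sum_w[agg$w] <- agg$sw
    }
    data.table::data.table(
      chrom = ch, start = out$start, end = out$start + window,
      n_variants = out$n_variants,
      mean_af = ifelse(out$sum_w > 0, out$sum_v / out$sum_w, NA_real_),
      density_per_mb = out$n_variants / (window / 1e6)
    )
  })
  as.data.frame(data.table::rbindlist(res))
}

#' Detect the candidate causal region from window statistics
#'
#' Finds, per chromosome, maximal runs of consecutive windows whose mean
#' frequency exceeds `background + margin`, keeps runs of at least
#' `min_windows` windows, and returns the longest; ties are broken by
#' higher pooled frequency, then by leftmost coordinate. The pooled
#' frequency is computed over `variants` falling in the run's span when a
#' variant table is supplied, otherwise as the variant-count-weighted mean
#' of the window means.
#'
#' @param stats Output of [window_scan()].
#' @param background Expected genome-wide frequency from the cross design
#'   (0.75 for a het-mother by homozygous-mutant-father design with
#'   selection of mutant homozygotes).
#' @param margin Required excess over background (default 0.15).
#' @param min_windows Minimum consecutive qualifying windows.
#' @param variants Optional variant table for the pooled frequency.
#' @param value_col Frequency column in `variants`.
#' @return One-row data.frame `chrom`, `start`, `end`, `n_windows`,
#'   `pooled_af`; zero rows (with a message) when no run qualifies.
#' @export
candidate_region <- function(stats, background = 0.75, margin = 0.15,
                             min_windows = 3L, variants = NULL,
                             value_col = "af_mut") {
  dt <- data.table::as.data.table(stats)
  data.table::setorder(dt, chrom, start)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      pooled_af = numeric())
  runs <- dt[, {
    flag <- !is.na(mean_af) & mean_af > background + margin
    r <- rle(flag)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    ok <- r$values & r$lengths >= min_windows
    if (any(ok)) {
      .(start = start[starts_i[ok]], end = end[ends_i[ok]],
        n_windows = r$lengths[ok],
        win_af = vapply(which(ok), function(i) {
          idx <- starts_i[i]:ends_i[i]
          sum(mean_af[idx] * n_variants[idx]) / sum(n_variants[idx])
        }, numeric(1)))
    } else NULL
  }, by = chrom]
  if (nrow(runs) == 0L) {
    message("no run of ", min_windows, " windows above ",
            background + margin, " found")
    return(empty)
  }
  runs[, pooled_af := win_af]
  if (!is.null(variants)) {
    v <- data.table::as.data.table(variants)
    runs[, pooled_af := mapply(function(ch, s, e) {
      x <- v[chrom == ch & pos > s & pos <= e][[value_col]]
      mean(x, na.rm = TRUE)
    }, chrom, start, end)]
  }
  data.table::setorder(runs, -n_windows, -pooled_af, chrom, start)
  as.data.frame(runs[1L, .(chrom, start, end, n_windows, pooled_af)])
}
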