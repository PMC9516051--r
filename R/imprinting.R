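# Imprinting classification from allele-specific read counts, DMR-distance
# contingency summaries, and expression-category assignment from an RPM
# matrix.

#' Classify imprinting status from maternal/paternal read counts
#'
#' The maternal ratio is maternal / (maternal + paternal) reads at
#' allele-informative positions. Because endosperm inherits two maternal
#' genome copies and one paternal, the biallelic expectation is 2/3 (0.67).
#' A feature is a MEG when its ratio exceeds `meg_threshold` (default 0.9),
#' a PEG below `peg_threshold` (default 0.1), biallelic otherwise, and
#' uncallable when fewer than `min_informative` reads are available. Counts
#' are summed across cross directions and replicates before the ratio is
#' taken; per-direction ratios are attached for diagnostics when a
#' `direction` column is present.
#'
#' @param counts data.frame with columns `feature_id`, `maternal`,
#'   `paternal` and optionally `direction`.
#' @param min_informative Minimum total informative reads to call a
#'   feature (default 10).
#' @param meg_threshold,peg_threshold Maternal-ratio thresholds (strict).
#' @return data.frame with `feature_id`, summed counts, `maternal_ratio`
#'   and `category` in `{MEG, PEG, biallelic, uncallable}`; per-direction
#'   ratios in the `by_direction` attribute when applicable.
#' @export
call_imprinting <- function(counts, min_informative = 10L,
                            meg_threshold = 0.9, peg_threshold = 0.1) {
  stopifnot(min_informative >= 1)
  dt <- data.table::as.data.table(counts)
  miss <- setdiff(c("feature_id", "maternal", "paternal"), names(dt))
  if (length(miss))
    stop("counts is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(dt$maternal < 0) || any(dt$paternal < 0))
    stop("negative read counts", call. = FALSE)
  by_dir <- NULL
  if ("direction" %in% names(dt)) {
    by_dir <- dt[, .(maternal = sum(maternal), paternal = sum(paternal)),
                 by = .(feature_id, direction)]
    by_dir[, maternal_ratio := data.table::fifelse(
      maternal + paternal > 0, maternal / (maternal + paternal), NA_real_)]
  }
  tot <- dt[, .(maternal = sum(maternal), paternal = sum(paternal)),
            by = feature_id]
  tot[, total := maternal + paternal]
  tot[, maternal_ratio := data.table::fifelse(total > 0, maternal / total,
                                              NA_real_)]
  tot[, category := data.table::fcase(
    total < min_informative, "uncallable",
    maternal_ratio > meg_threshold, "MEG",
    maternal_ratio < peg_threshold, "PEG",
    default = "biallelic"
  )]
  out <- as.data.frame(tot)
  if (!is.null(by_dir)) attr(out, "by_direction") <- as.data.frame(by_dir)
  out
}

#' Cross-tabulate imprinting categories by distance to the nearest DMR
#'
#' Each feature is placed in a distance bin: `overlap` when it overlaps a
#' DMR by at least `min_overlap` bp, `within` when the gap to the nearest
#' DMR is at most `near` bp, `beyond` otherwise (including chromosomes with
#' no DMR at all). The summary reports, per imprinting category, the count
#' and proportion of features in each bin; category comparisons can then be
#' tested with [chi2_yates()] or [fisher_exact_2x2()].
#'
#' @param calls Output of [call_imprinting()].
#' @param features BED-style table with a `feature_id` column locating each
#'   called feature.
#' @param dmrs BED-style DMR table.
#' @param min_overlap Minimum overlap (bp) for the `overlap` bin.
#' @param near Maximum gap (bp) for the `within` bin (default 2 kb).
#' @return data.frame with `category`, `distance_bin`, `n` and `prop`
#'   (proportion within the category); the per-feature bin assignment is
#'   attached as the `features` attribute.
#' @export
category_dmr_overlap <- function(calls, features, dmrs,
                                 min_overlap = 100L, near = 2000L) {
  validate_regions(features)
  if (!"feature_id" %in% names(features))
    stop("features needs a feature_id column", call. = FALSE)
  feat <- merge(
    data.table::as.data.table(features),
    data.table::as.data.table(calls)[, .(feature_id, category)],
    by = "feature_id"
  )
  fdf <- as.data.frame(feat)
  if (nrow(dmrs) == 0L) {
    ov_bp <- rep(0, nrow(fdf))
    dist <- rep(NA_real_, nrow(fdf))
  } else {
    ov_bp <- region_overlap_fraction(fdf, dmrs) * (fdf$end - fdf$start)
    dist <- distance_to_nearest(fdf, dmrs)
  }
  fdf$distance_bin <- ifelse(
    ov_bp >= min_overlap, "overlap",
    ifelse(!is.na(dist) & dist <= near, "within", "beyond"))
  dt <- data.table::as.data.table(fdf)
  grid <- data.table::CJ(category = unique(dt$category),
                         distance_bin = c("overlap", "within", "beyond"))
  tab <- dt[, .(n = .N), by = .(category, distance_bin)][
    grid, on = c("category", "distance_bin")]
  tab[is.na(n), n := 0L]
  tab[, prop := n / sum(n), by = category]
  out <- as.data.frame(tab)
  attr(out, "features") <- fdf
  out
}

#' Assign expression categories from an RPM matrix
#'
#' Categories follow a fixed precedence. A gene is `constitutive_off` when
#' it has RPM above `on_rpm` in fewer than `min_on_total` of all libraries.
#' Among the remaining genes, `endosperm_on` requires RPM above `on_rpm` in
#' at least `min_on_endosperm` endosperm libraries, and `endosperm_off`
#' requires RPM below `off_rpm` in at least `min_off_endosperm` endosperm
#' libraries; everything else is `unclassified`. The count defaults match a
#' 225-library atlas with 21 endosperm libraries (fewer than 3 of 225; at
#' least 18 of 21; at least 20 of 21).
#'
#' @param rpm Numeric gene-by-library matrix with column names.
#' @param endosperm_libs Column names or indices of the endosperm
#'   libraries.
#' @param on_rpm,off_rpm RPM cutoffs for "expressed" (strict `>`) and
#'   "silent" (strict `<`).
#' @param min_on_total,min_on_endosperm,min_off_endosperm Library-count
#'   thresholds.
#' @return Character vector of categories, one per gene (row), named by
#'   rownames of `rpm`.
#' @export
classify_expression <- function(rpm, endosperm_libs, on_rpm = 1,
                                off_rpm = 0.5, min_on_total = 3L,
                                min_on_endosperm = 18L,
                                min_off_endosperm = 20L) {
  rpm <- as.matrix(rpm)
  endo <- rpm[, endosperm_libs, drop = FALSE]
  n_on_total <- rowSums(rpm > on_rpm)
  n_on_endo <- rowSums(endo > on_rpm)
  n_off_endo <- rowSums(endo < off_rpm)
  out <- rep("unclassified", nrow(rpm))
  out[n_on_endo >= min_on_endosperm] <- "endosperm_on"
  out[n_off_endo >= min_off_endosperm] <- "endosperm_off"
  out[n_on_total < min_on_total] <- "constitutive_off"
  names(out) <- rownames(rpm)
  out
}
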