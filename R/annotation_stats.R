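# Characterization of region sets against genomic annotations: interval
# merge/length-filter, fractional-overlap selection, control-normalized
# enrichment, end-anchored and flanking profiles, distances to euchromatin,
# GC content, degenerate-consensus motif matching.

#' Merge nearby intervals and drop short survivors
#'
#' Intervals that overlap or are separated by at most `max_gap` bp are
#' unioned; merged intervals shorter than `min_len` bp are removed. This is
#' the merge-and-length-filter rule used to build tandem-repeat and
#' structural-RNA locus annotations from raw alignments.
#'
#' @param intervals BED-style region table.
#' @param max_gap Maximum gap (bp) between intervals to merge.
#' @param min_len Minimum merged length (bp) to keep.
#' @return A BED-style region table of merged intervals, sorted.
#' @export
merge_and_filter_intervals <- function(intervals, max_gap = 50L,
                                       min_len = 100L) {
  if (max_gap < 0 || min_len < 0)
    stop("max_gap and min_len must be non-negative", call. = FALSE)
  gr <- GenomicRanges::reduce(regions_to_granges(intervals),
                              min.gapwidth = max_gap + 1L,
                              ignore.strand = TRUE)
  gr <- gr[IRanges::width(gr) >= min_len]
  out <- granges_to_regions(GenomicRanges::sort(gr))
  out$strand <- NULL
  out
}

#' Select (or drop) queries by fractional overlap with an element set
#'
#' Keeps each query region that overlaps at least `min_frac` of its own
#' length with the union of `elements` (multiple small overlaps accumulate);
#' with `invert = TRUE` keeps the complement. Mirrors interval selection
#' with `-u -f F` / `-v -f F` semantics.
#'
#' @param queries,elements BED-style region tables.
#' @param min_frac Required overlap as a fraction of the query length,
#'   in (0, 1]; the comparison is inclusive (`>=`).
#' @param invert Drop instead of keep qualifying queries.
#' @return The selected subset of `queries`, original order and columns.
#' @export
overlap_select <- function(queries, elements, min_frac = 0.5,
                           invert = FALSE) {
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1)
    stop("min_frac must be in (0, 1]", call. = FALSE)
  frac <- region_overlap_fraction(queries, elements)
  keep <- frac >= min_frac
  if (invert) keep <- !keep
  queries[keep, , drop = FALSE]
}

#' Control-normalized element overlap enrichment
#'
#' Enrichment is the proportion of query regions that overlap an element by
#' at least `min_frac` of their length, divided by the proportion of control
#' regions that do. Controls should share the mappability biases of the
#' queries (the eligible-region framework).
#'
#' @param dmrs,controls,elements BED-style region tables.
#' @param min_frac Overlap fraction threshold (default half the region).
#' @return The enrichment fold as a numeric scalar with attributes
#'   `prop_query` and `prop_control`; `NA` (with a warning) when the control
#'   proportion is zero, in which case the enrichment is undefined.
#' @export
element_enrichment <- function(dmrs, controls, elements, min_frac = 0.5) {
  if (nrow(controls) == 0L) stop("controls must be non-empty", call. = FALSE)
  p_q <- nrow(overlap_select(dmrs, elements, min_frac)) / nrow(dmrs)
  p_c <- nrow(overlap_select(controls, elements, min_frac)) / nrow(controls)
  if (p_c == 0) {
    warning("zero control proportion: enrichment undefined")
    fold <- NA_real_
  } else {
    fold <- p_q / p_c
  }
  structure(fold, prop_query = p_q, prop_control = p_c)
}

# expand anchors into per-offset 100-bp genomic bins, in transcript
# orientation (minus-strand anchors mirrored); returns counts per offset
count_anchor_bins <- function(regions, anchors, offsets, bin) {
  n_a <- nrow(anchors)
  n_o <- length(offsets)
  plus <- anchors$strand != "-"
  # genomic start of the bin at transcript offset `off` for each anchor
  starts <- matrix(NA_real_, n_a, n_o)
  for (j in seq_len(n_o)) {
    off <- offsets[j]
    starts[plus, j] <- anchors$pos[plus] + off
    starts[!plus, j] <- anchors$pos[!plus] - off - bin
  }
  bins <- data.frame(
    chrom = rep(anchors$chrom, times = n_o),
    start = as.vector(starts),
    offset_idx = rep(seq_len(n_o), each = n_a)
  )
  bins$end <- bins$start + bin
  bins <- bins[bins$start >= 0, , drop = FALSE]
  h <- harmonize_seqlevels(regions_to_granges(bins),
                           regions_to_granges(regions))
  cnt <- GenomicRanges::countOverlaps(h[[1]], h[[2]], ignore.strand = TRUE)
  out <- integer(n_o)
  agg <- tapply(cnt, bins$offset_idx, sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' End-anchored enrichment profile of a region set
#'
#' For each 100-bp offset bin relative to strand-annotated anchor points
#' (TSS, polyA, or transposon ends), counts query regions overlapping the
#' bin and divides by the count for control regions. Minus-strand anchors
#' are mirrored so offsets are in transcript orientation; a region is
#' counted once per anchor-bin it touches. Callers excluding solo-LTR
#' retrotransposon ends should filter the anchor table first.
#'
#' @param dmrs,controls BED-style region tables.
#' @param anchors data.frame with columns `chrom`, `pos` (0-based anchor
#'   coordinate) and `strand`.
#' @param window Half-width of the profile in bp.
#' @param bin Offset bin width in bp.
#' @return data.frame with `offset` (bin start, transcript orientation),
#'   `n_query`, `n_control`, and `enrichment` (`NA` where the control count
#'   is zero: a missing value, never imputed).
#' @export
end_anchored_enrichment <- function(dmrs, controls, anchors,
                                    window = 3000L, bin = 100L) {
  stopifnot(window > 0, bin > 0, all(c("chrom", "pos", "strand") %in%
                                       names(anchors)))
  offsets <- seq(-window, window - bin, by = bin)
  n_q <- count_anchor_bins(dmrs, anchors, offsets, bin)
  n_c <- count_anchor_bins(controls, anchors, offsets, bin)
  data.frame(
    offset = offsets,
    n_query = n_q,
    n_control = n_c,
    enrichment = ifelse(n_c > 0, n_q / n_c, NA_real_)
  )
}

#' Gap distance from each query to the nearest target region
#'
#' Distance is the number of bases strictly between a query and its nearest
#' target on the same chromosome (0 for overlapping or bookended regions).
#' Queries on chromosomes without any target get `NA`.
#'
#' @param queries,targets BED-style region tables.
#' @return Numeric vector of distances, one per query row.
#' @export
distance_to_nearest <- function(queries, targets) {
  qgr <- regions_to_granges(queries)
  tgr <- regions_to_granges(targets)
  out <- rep(NA_real_, nrow(queries))
  if (nrow(targets) == 0L) return(out)
  h <- harmonize_seqlevels(qgr, tgr)
  hits <- GenomicRanges::distanceToNearest(h[[1]], h[[2]],
                                           ignore.strand = TRUE)
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Methylation profile in and around a set of regions
#'
#' Computes count-weighted methylation in 100-bp offset bins spanning each
#' region and `flank` bp on either side, using sites of one context with
#' coverage at least `min_cov`. Each region contributes its own
#' count-weighted level per bin; the profile is the mean across regions
#' with data in that bin. Bins where no region has a covered site are
#' reported as missing (`NA`), never zero. All regions must share one width
#' (the 200-bp grid), so the region interior occupies the central bins.
#'
#' @param regions BED-style region table (uniform width).
#' @param map A methylome map (one sample).
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param flank Flank width in bp on each side.
#' @param bin Offset bin width in bp.
#' @param min_cov Minimum per-site read coverage (default 1).
#' @return data.frame with `offset` (bp relative to region start; negative
#'   upstream), `level` and `n` (regions contributing).
#' @export
flank_profile <- function(regions, map, context = c("CG", "CHG", "CHH"),
                          flank = 3000L, bin = 100L, min_cov = 1) {
  context <- match.arg(context)
  validate_regions(regions)
  w <- unique(regions$end - regions$start)
  if (length(w) != 1L)
    stop("flank_profile requires regions of uniform width", call. = FALSE)
  ctx <- context
  sites <- data.table::as.data.table(map)[context == ctx &
                                            total_reads >= min_cov,
    .(chrom, pos, meth_reads, total_reads)]
  offsets <- seq(-flank, w + flank - bin, by = bin)
  empty <- data.frame(offset = offsets, level = NA_real_, n = 0L)
  if (nrow(sites) == 0L || nrow(regions) == 0L) return(empty)
  reg <- data.table::as.data.table(regions[, c("chrom", "start", "end")])
  reg[, region_id := .I]
  reg[, `:=`(win_start = start + 1L - flank, win_end = end + flank)]
  sites[, `:=`(pos_start = pos, pos_end = pos)]
  data.table::setkey(reg, chrom, win_start, win_end)
  ov <- data.table::foverlaps(sites, reg,
                              by.x = c("chrom", "pos_start", "pos_end"),
                              type = "within", nomatch = NULL)
  if (nrow(ov) == 0L) return(empty)
  ov[, bin_idx := ((pos - 1L - start) + flank) %/% bin + 1L]
  per_region <- ov[, .(level = sum(meth_reads) / sum(total_reads)),
                   by = .(region_id, bin_idx)]
  prof <- per_region[, .(level = mean(level), n = .N), by = bin_idx]
  out <- empty
  out$level[prof$bin_idx] <- prof$level
  out$n[prof$bin_idx] <- prof$n
  out
}

#' GC content of a set of sequences
#'
#' (G + C) / (A + C + G + T); `N` and other ambiguity codes are excluded
#' from the denominator.
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet].
#' @param per_sequence Return one fraction per sequence instead of the
#'   pooled fraction over the whole set.
#' @return Numeric scalar (or vector); `NA` with a warning when no
#'   unambiguous bases are present.
#' @export
gc_content <- function(sequences, per_sequence = FALSE) {
  seqs <- if (inherits(sequences, "DNAStringSet")) sequences
          else Biostrings::DNAStringSet(sequences)
  gc <- Biostrings::letterFrequency(seqs, "GC")[, 1]
  acgt <- Biostrings::letterFrequency(seqs, "ACGT")[, 1]
  if (per_sequence) {
    out <- ifelse(acgt > 0, gc / acgt, NA_real_)
    if (anyNA(out)) warning("sequence(s) with no unambiguous bases")
    return(unname(out))
  }
  if (sum(acgt) == 0) {
    warning("no unambiguous bases: GC content undefined")
    return(NA_real_)
  }
  sum(gc) / sum(acgt)
}

#' Scan sequences for exact matches to an IUPAC consensus motif
#'
#' Every position where the expanded degenerate pattern matches exactly is
#' reported, on the forward and (optionally) reverse-complement strand.
#' Exact consensus matching replaces score-based motif scanning; the motifs
#' of interest (e.g. `TTWCCATATW`, `CCAWAAATGG`) carry no ambiguity beyond
#' W, so a p-value model adds nothing.
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet].
#' @param motif IUPAC consensus string.
#' @param both_strands Also scan the reverse complement of the motif.
#' @return data.frame with `seq` (index into `sequences`), `start`, `end`
#'   (1-based, on the forward strand of the subject) and `strand`.
#' @export
iupac_motif_scan <- function(sequences, motif, both_strands = TRUE) {
  ok <- strsplit(toupper(motif), "")[[1]] %in%
    names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok))
    stop("invalid IUPAC code(s) in motif: ", motif, call. = FALSE)
  seqs <- if (inherits(sequences, "DNAStringSet")) sequences
          else Biostrings::DNAStringSet(sequences)
  scan1 <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, seqs, fixed = "subject")
    idx <- rep(seq_along(m), S4Vectors::elementNROWS(m))
    ir <- unlist(m)
    if (length(ir) == 0L)
      return(data.frame(seq = integer(), start = integer(),
                        end = integer(), strand = character()))
    data.frame(seq = idx, start = IRanges::start(ir), end = IRanges::end(ir),
               strand = strand)
  }
  hits <- scan1(motif, "+")
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    hits <- rbind(hits, scan1(rc, "-"))
  }
  hits[order(hits$seq, hits$start, hits$strand), , drop = FALSE]
}
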