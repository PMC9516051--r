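# Small-RNA read classification, subsampling, length distributions, and
# siRNA-producing region calls.

validate_reads <- function(reads) {
  validate_regions(reads, "read table")
  miss <- setdiff(c("length", "mapq"), names(reads))
  if (length(miss))
    stop("read table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(reads$end - reads$start != reads$length)
  if (length(bad))
    stop("read footprint width != read length at row ", bad[1],
         call. = FALSE)
  invisible(reads)
}

#' Classify aligned small-RNA reads as siRNAs
#'
#' Keeps reads of length `min_len` to `max_len` nt that do not overlap at
#' least `excl_frac` of their length with the union of structural-RNA loci
#' (tRNA, 5S rRNA, NOR rRNA, miRNA). The remaining reads are called siRNA
#' reads. Exclusion is fractional: a 24-nt read overlapping a miRNA locus by
#' 21 bp (87.5%) survives a 0.9 threshold.
#'
#' @param reads BED-style read table with `length` and `mapq` columns; each
#'   row is one alignment record.
#' @param exclusion_loci BED-style table of structural-RNA loci.
#' @param min_len,max_len Inclusive length window in nt.
#' @param excl_frac Overlap fraction at or above which a read is removed.
#' @return The siRNA subset of `reads`.
#' @export
classify_sirnas <- function(reads, exclusion_loci, min_len = 20L,
                            max_len = 25L, excl_frac = 0.9) {
  validate_reads(reads)
  keep_len <- reads$length >= min_len & reads$length <= max_len
  sized <- reads[keep_len, , drop = FALSE]
  if (nrow(sized) == 0L) return(sized)
  frac <- region_overlap_fraction(sized, exclusion_loci)
  sized[frac < excl_frac, , drop = FALSE]
}

#' Subsample a read table without replacement
#'
#' Uniform sample of `n` reads, reproducible for a fixed seed. Used to put
#' libraries of different depth on a common footing before comparing
#' siRNA-region counts.
#'
#' @param reads Read table.
#' @param n Target read count; must not exceed the library size.
#' @param seed Optional integer seed (set locally for the draw).
#' @return A read table with `n` rows.
#' @export
subsample_reads <- function(reads, n, seed = NULL) {
  if (n > nrow(reads))
    stop("cannot subsample ", n, " reads from a library of ", nrow(reads),
         " (short by ", n - nrow(reads), ")", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  reads[sample.int(nrow(reads), n), , drop = FALSE]
}

#' siRNA length distribution with replicate error bars
#'
#' Per-length proportions within each replicate, summarized as the mean
#' across replicates with the standard error of the mean (`sd / sqrt(r)`).
#'
#' @param reads Read table with a `replicate_id` column (all reads are
#'   treated as one replicate when absent).
#' @param lengths Lengths to tabulate (others are ignored).
#' @return data.frame with `length`, `mean_prop`, `sem` (`NA` for a single
#'   replicate) and `n_replicates`.
#' @export
length_distribution <- function(reads, lengths = 20:25) {
  dt <- data.table::as.data.table(reads)
  if (!"replicate_id" %in% names(dt)) dt[, replicate_id := "rep1"]
  dt <- dt[length %in% lengths]
  per <- dt[, .(n = .N), by = .(replicate_id, length)]
  per[, prop := n / sum(n), by = replicate_id]
  grid <- data.table::CJ(replicate_id = unique(dt$replicate_id),
                         length = lengths)
  per <- per[grid, on = c("replicate_id", "length")]
  per[is.na(prop), prop := 0]
  out <- per[, .(
    mean_prop = mean(prop),
    sem = if (.N > 1L) stats::sd(prop) / sqrt(.N) else NA_real_,
    n_replicates = .N
  ), by = length]
  data.table::setorder(out, length)
  as.data.frame(out)
}

#' Assign siRNA reads to a region set by fractional overlap
#'
#' Keeps reads overlapping at least `frac` of their length with the union
#' of `regions`. With `unique_only = TRUE` only uniquely mappable reads
#' (MAPQ at least `min_mapq`) are considered, reproducing the
#' unique-mappers analysis; the default counts every alignment record where
#' it is placed, so multi-mappers contribute at each reported location.
#'
#' @param reads Read table.
#' @param regions BED-style region table (e.g. DMRs).
#' @param frac Overlap fraction threshold (inclusive).
#' @param unique_only Restrict to reads with `mapq >= min_mapq` first.
#' @param min_mapq MAPQ cutoff defining unique mappability.
#' @return The qualifying subset of `reads`.
#' @export
assign_reads_to_regions <- function(reads, regions, frac = 0.9,
                                    unique_only = FALSE, min_mapq = 20L) {
  validate_reads(reads)
  if (unique_only) reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  if (nrow(reads) == 0L) return(reads)
  fr <- region_overlap_fraction(reads, regions)
  reads[fr >= frac, , drop = FALSE]
}

#' Call siRNA-producing regions by spanned bases
#'
#' For each region, `spanned_bp` is the number of its bases covered by the
#' union of read footprints (duplicated reads change nothing); a region is
#' an siRNA region when at least `min_span` bp are spanned.
#'
#' @param regions BED-style region table.
#' @param reads Read table (already classified and, if desired, subsampled).
#' @param min_span Minimum spanned bases (inclusive).
#' @return `regions` with added `spanned_bp` and `has_sirna` columns.
#' @export
call_sirna_regions <- function(regions, reads, min_span = 50L) {
  validate_regions(regions)
  out <- regions
  if (nrow(reads) == 0L) {
    out$spanned_bp <- 0L
    out$has_sirna <- FALSE
    return(out)
  }
  h <- harmonize_seqlevels(
    regions_to_granges(regions),
    GenomicRanges::reduce(regions_to_granges(reads), ignore.strand = TRUE))
  rgr <- h[[1]]; cov <- h[[2]]
  hits <- GenomicRanges::findOverlaps(rgr, cov, ignore.strand = TRUE)
  spanned <- integer(nrow(regions))
  if (length(hits)) {
    ov <- IRanges::pintersect(rgr[S4Vectors::queryHits(hits)],
                              cov[S4Vectors::subjectHits(hits)],
                              ignore.strand = TRUE)
    w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    spanned[as.integer(names(w))] <- as.integer(w)
  }
  out$spanned_bp <- spanned
  out$has_sirna <- spanned >= min_span
  out
}
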