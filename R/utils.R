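#' @import data.table
#' @importFrom stats dbinom dhyper pchisq pt rbinom rpois runif sd var
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

# Region tables are BED-style throughout: 0-based half-open [start, end).
# Conversion to the 1-based closed coordinates of IRanges happens only here.

#' Convert a BED-style region table to a GRanges object
#'
#' Regions are 0-based half-open (`start`, `end`); the returned
#' [GenomicRanges::GRanges] is 1-based closed, as IRanges expects.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand` (`"."` is mapped to `"*"`).
#' @return A `GRanges` of the same length and order as `x`.
#' @export
regions_to_granges <- function(x) {
  validate_regions(x)
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else rep("*", nrow(x))
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Convert a GRanges object to a BED-style region table
#'
#' @param gr A `GRanges`.
#' @return data.frame with 0-based half-open `chrom`, `start`, `end`, `strand`.
#' @export
granges_to_regions <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

validate_regions <- function(x, what = deparse(substitute(x))) {
  if (!is.data.frame(x))
    stop(what, " must be a data.frame of regions", call. = FALSE)
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss))
    stop(what, " is missing region column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(x) && any(x$end < x$start))
    stop(what, " has regions with end < start", call. = FALSE)
  invisible(x)
}

# put two GRanges on the union of their sequence levels so pairwise
# operations do not warn about disjoint chromosome sets
harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

# fraction of each query's own length covered by the union of `elements`
region_overlap_fraction <- function(queries, elements) {
  qgr <- regions_to_granges(queries)
  if (nrow(elements) == 0L) return(rep(0, nrow(queries)))
  red <- GenomicRanges::reduce(regions_to_granges(elements), ignore.strand = TRUE)
  h <- harmonize_seqlevels(qgr, red)
  qgr <- h[[1]]; red <- h[[2]]
  hits <- GenomicRanges::findOverlaps(qgr, red, ignore.strand = TRUE)
  covered <- numeric(nrow(queries))
  if (length(hits)) {
    ov <- IRanges::pintersect(qgr[S4Vectors::queryHits(hits)],
                              red[S4Vectors::subjectHits(hits)],
                              ignore.strand = TRUE)
    w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(w))] <- as.numeric(w)
  }
  covered / (queries$end - queries$start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
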