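# Per-cytosine methylation call files (CGmap dialect) and site-level
# operations: read/write, replicate merging, per-context sample intersection.

CGMAP_CONTEXTS <- c("CG", "CHG", "CHH")

# a methylome map is a data.table of per-cytosine sites with an attached
# sample_id attribute; one row per (chrom, pos), strand-aware (no CpG collapsing)
new_methylome_map <- function(sites, sample_id) {
  dt <- data.table::as.data.table(sites)
  data.table::setcolorder(
    dt, c("chrom", "pos", "strand", "context", "dinuc",
          "meth_reads", "total_reads"))
  data.table::setorder(dt, chrom, pos)
  data.table::setattr(dt, "sample_id", sample_id)
  dt[]
}

validate_sites <- function(dt, where = "methylome map") {
  if (nrow(dt) == 0L) return(invisible(dt))
  bad <- which(dt$total_reads < dt$meth_reads)
  if (length(bad))
    stop(where, ": total_reads < meth_reads at row ", bad[1], call. = FALSE)
  if (any(dt$meth_reads < 0L) || any(dt$total_reads < 0L))
    stop(where, ": negative read counts", call. = FALSE)
  badc <- which(!dt$context %in% CGMAP_CONTEXTS)
  if (length(badc))
    stop(where, ": unknown context '", dt$context[badc[1]], "' at row ",
         badc[1], call. = FALSE)
  dup <- duplicated(dt, by = c("chrom", "pos"))
  if (any(dup)) {
    i <- which(dup)[1]
    stop(where, ": duplicate site at ", dt$chrom[i], ":", dt$pos[i],
         call. = FALSE)
  }
  invisible(dt)
}

#' Read a CGmap-format per-cytosine methylation call file
#'
#' CGmap files are 8-column tab-separated text, one line per covered cytosine:
#' chromosome, reference nucleotide (`C` on the plus strand, `G` on the
#' minus strand), 1-based position, context (`CG`/`CHG`/`CHH`), dinucleotide,
#' methylation level, methylated read count, total read count. The level
#' column is ignored and always recomputed from the counts, which are the
#' ground truth for count-weighted binning.
#'
#' @param path Path to a CGmap file (plain text, no header).
#' @param sample_id Label attached to the returned map; defaults to the
#'   file name without extension.
#' @return A methylome map: a `data.table` with columns `chrom`, `pos`,
#'   `strand`, `context`, `dinuc`, `meth_reads`, `total_reads`, one row per
#'   (chrom, pos), and a `sample_id` attribute.
#' @export
read_cgmap <- function(path, sample_id = sub("\\.[^.]*$", "", basename(path))) {
  dt <- data.table::fread(
    path, header = FALSE, sep = "\t",
    colClasses = list(character = c(1, 2, 4, 5), numeric = 6,
                      integer = c(3, 7, 8)),
    fill = FALSE
  )
  if (ncol(dt) != 8L)
    stop("malformed CGmap file (expected 8 tab-separated columns): ", path,
         call. = FALSE)
  data.table::setnames(dt, c("chrom", "nuc", "pos", "context", "dinuc",
                             "level", "meth_reads", "total_reads"))
  badnuc <- which(!dt$nuc %in% c("C", "G"))
  if (length(badnuc))
    stop("malformed CGmap line ", badnuc[1], ": nucleotide column must be C or G",
         call. = FALSE)
  dt[, strand := data.table::fifelse(nuc == "C", "+", "-")]
  dt[, c("nuc", "level") := NULL]
  validate_sites(dt, where = path)
  new_methylome_map(dt, sample_id)
}

#' Write a methylome map as a CGmap file
#'
#' Inverse of [read_cgmap()]: counts round-trip bit-exactly; the level column
#' is recomputed as `meth_reads / total_reads` (0 for uncovered sites).
#'
#' @param map A methylome map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(map, path) {
  dt <- data.table::as.data.table(map)
  out <- dt[, .(
    chrom,
    nuc = data.table::fifelse(strand == "+", "C", "G"),
    pos, context, dinuc,
    level = data.table::fifelse(total_reads > 0,
                                meth_reads / total_reads, 0),
    meth_reads, total_reads
  )]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Merge replicate methylome maps by summing read counts
#'
#' For every (chrom, pos) present in any input, methylated and total read
#' counts are summed across inputs; a site absent from a replicate simply
#' contributes zero coverage. Context and strand must agree across inputs at
#' a shared position.
#'
#' @param maps A list of methylome maps (or a single map).
#' @param sample_id Label for the merged map; defaults to the input labels
#'   joined with `+`.
#' @return A merged methylome map.
#' @export
merge_replicates <- function(maps, sample_id = NULL) {
  if (is.data.frame(maps)) maps <- list(maps)
  if (!length(maps)) stop("need at least one map", call. = FALSE)
  ids <- vapply(maps, function(m) attr(m, "sample_id") %||% "?", "")
  all <- data.table::rbindlist(lapply(maps, data.table::as.data.table))
  merged <- all[, .(
    strand = strand[1L], context = context[1L], dinuc = dinuc[1L],
    n_context = data.table::uniqueN(context),
    n_strand = data.table::uniqueN(strand),
    meth_reads = sum(meth_reads), total_reads = sum(total_reads)
  ), by = .(chrom, pos)]
  bad <- which(merged$n_context > 1L | merged$n_strand > 1L)
  if (length(bad)) {
    i <- bad[1]
    stop("conflicting context/strand at ", merged$chrom[i], ":",
         merged$pos[i], call. = FALSE)
  }
  merged[, c("n_context", "n_strand") := NULL]
  new_methylome_map(merged, sample_id %||% paste(ids, collapse = "+"))
}

#' Intersect two methylome maps in one sequence context
#'
#' Produces a paired site table restricted to positions of the given context
#' that have coverage (`total_reads > 0`) in both samples, sorted by
#' (chrom, pos). This is the per-context input to the 200-bp binning step.
#'
#' @param a,b Methylome maps from the same genome. `a` is the first
#'   (reference) sample and `b` the second sample of all downstream
#'   comparisons.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @return A `data.table` with columns `chrom`, `pos`, `meth_a`, `total_a`,
#'   `meth_b`, `total_b` and attributes `context`, `sample_a`, `sample_b`.
#' @export
intersect_samples <- function(a, b, context = c("CG", "CHG", "CHH")) {
  context <- match.arg(context)
  ctx <- context
  da <- data.table::as.data.table(a)[context == ctx & total_reads > 0,
    .(chrom, pos, meth_a = meth_reads, total_a = total_reads)]
  db <- data.table::as.data.table(b)[context == ctx & total_reads > 0,
    .(chrom, pos, meth_b = meth_reads, total_b = total_reads)]
  out <- merge(da, db, by = c("chrom", "pos"), sort = TRUE)
  data.table::setattr(out, "context", ctx)
  data.table::setattr(out, "sample_a", attr(a, "sample_id"))
  data.table::setattr(out, "sample_b", attr(b, "sample_id"))
  out[]
}
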