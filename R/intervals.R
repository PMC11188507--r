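# Genomic interval sets and exact length-based set algebra.
#
# All user-facing coordinates are 0-based, half-open (BED convention):
# an interval [start, end) covers bases start, start+1, ..., end-1 and has
# length end - start. Internally intervals are carried as GRanges (1-based,
# closed); the two helpers below are the only place the conversion happens.

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open). Extra columns are carried along as metadata columns.
#' @return A `GRanges` object (1-based, closed coordinates).
#' @export
df_to_gr <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  }
  gr
}

#' Convert GRanges back to a 0-based half-open interval table
#' @param gr A `GRanges` object.
#' @export
gr_to_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) df <- cbind(df, as.data.frame(mc, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

# Put two GRanges on a shared, sorted seqlevels universe so set operations
# never complain about non-matching sequence levels.
sync_seqlevels <- function(...) {
  grs <- list(...)
  sl <- sort(unique(unlist(lapply(grs, GenomeInfoDb::seqlevels))))
  lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- sl
    g
  })
}

#' Build a normalized interval set
#'
#' Validates raw intervals and normalizes them: sorted by (chrom, start),
#' with overlapping and abutting intervals on the same chromosome merged.
#' Normalization preserves per-base coverage, so the total length is
#' invariant under re-normalization.
#'
#' @param chrom Character vector of chromosome names, or a data.frame with
#'   columns `chrom`, `start`, `end` (then `start`/`end` are ignored).
#' @param start,end Numeric vectors of 0-based half-open coordinates.
#' @return A normalized `GRanges` object.
#' @examples
#' iv <- interval_set(c("chr1", "chr1"), c(0, 50), c(100, 150))
#' total_length(iv)  # 150
#' @export
interval_set <- function(chrom, start = NULL, end = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
  } else {
    df <- data.frame(chrom = chrom, start = start, end = end,
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop(sprintf(
      "malformed interval at record %d: %s:[%s,%s) (need 0 <= start < end)",
      bad[1], df$chrom[bad[1]], format(df$start[bad[1]]), format(df$end[bad[1]])
    ))
  }
  normalize_intervals(df_to_gr(df[, c("chrom", "start", "end")]))
}

#' Normalize a GRanges into a canonical interval set
#'
#' Sorts, merges overlapping and abutting ranges, and drops metadata.
#' Idempotent; the covered bases are unchanged.
#'
#' @param gr A `GRanges` object.
#' @return A normalized `GRanges`.
#' @export
normalize_intervals <- function(gr) {
  gr <- GenomicRanges::granges(gr)
  # drop seqlengths: interval sets are self-contained and coverage-derived
  # objects would otherwise carry clashing sequence metadata
  GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::Seqinfo(
    seqnames = GenomeInfoDb::seqlevels(gr))
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Total length of an interval set in bp
#' @param x A `GRanges` object.
#' @return Numeric length in bp (sum of widths).
#' @export
total_length <- function(x) {
  sum(as.numeric(GenomicRanges::width(x)))
}

#' Length of the intersection of two interval sets
#'
#' @param a,b Normalized `GRanges` objects.
#' @return Intersection length in bp; symmetric, bounded by the smaller
#'   total length.
#' @export
intersect_length <- function(a, b) {
  g <- sync_seqlevels(normalize_intervals(a), normalize_intervals(b))
  total_length(GenomicRanges::intersect(g[[1]], g[[2]]))
}

#' Length of the union of two interval sets
#' @param a,b Normalized `GRanges` objects.
#' @return Union length in bp.
#' @export
union_length <- function(a, b) {
  g <- sync_seqlevels(normalize_intervals(a), normalize_intervals(b))
  total_length(GenomicRanges::union(g[[1]], g[[2]]))
}

#' Jaccard index of two interval sets
#'
#' Intersection length divided by union length, the region-level
#' reproducibility measure used throughout the package. When both sets are
#' empty the index is undefined and `NA_real_` is returned (never 0).
#'
#' @param a,b `GRanges` objects.
#' @return Ratio in `[0, 1]`, or `NA_real_` when both sets are empty.
#' @examples
#' a <- interval_set("chr1", 0, 100)
#' b <- interval_set("chr1", 50, 150)
#' jaccard_index(a, b)  # 50 / 150
#' @export
jaccard_index <- function(a, b) {
  u <- union_length(a, b)
  if (u == 0) return(NA_real_)
  intersect_length(a, b) / u
}

#' Subtract a mask from an interval set
#'
#' Removes every base of `mask` from `x`; used to apply exclusion regions
#' (e.g. wholly lost chromosome arms and assembly gaps) before any scoring
#' or comparison.
#'
#' @param x,mask `GRanges` objects.
#' @return Normalized `GRanges` covering `x` minus `mask`.
#' @export
subtract_intervals <- function(x, mask) {
  g <- sync_seqlevels(normalize_intervals(x), normalize_intervals(mask))
  GenomicRanges::setdiff(g[[1]], g[[2]])
}

#' Restrict an interval set to an annotation track
#'
#' Keeps only the bases of `x` that fall inside `track` (e.g. RefSeq gene
#' or exon regions), for gene- and exon-level concordance.
#'
#' @param x,track `GRanges` objects.
#' @return Normalized `GRanges` equal to the intersection.
#' @export
restrict_to_annotation <- function(x, track) {
  g <- sync_seqlevels(normalize_intervals(x), normalize_intervals(track))
  GenomicRanges::intersect(g[[1]], g[[2]])
}

#' Partition several interval sets into disjoint supported pieces
#'
#' Splits the union of the input sets into a minimal collection of disjoint
#' intervals such that every piece is covered either fully or not at all by
#' each input set, and records which inputs cover each piece (the same
#' operation as BedTools `multiinter`, reimplemented on GRanges).
#'
#' @param sets Named list of normalized `GRanges` objects (>= 1).
#' @return List with elements `intervals` (a sorted disjoint `GRanges`) and
#'   `support` (logical matrix, pieces x input sets; no all-`FALSE` row).
#' @examples
#' p <- partition_support(list(A = interval_set("chr1", 0, 100),
#'                             B = interval_set("chr1", 50, 150)))
#' gr_to_df(p$intervals)
#' p$support
#' @export
partition_support <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, normalize_intervals)
  sl <- sort(unique(unlist(lapply(sets, GenomeInfoDb::seqlevels))))
  sets <- lapply(sets, function(g) {
    GenomeInfoDb::seqlevels(g) <- sl
    g
  })
  all_gr <- do.call(c, unname(sets))
  pieces <- GenomicRanges::disjoin(all_gr)
  pieces <- GenomicRanges::sort(pieces)
  support <- vapply(sets, function(s) IRanges::overlapsAny(pieces, s),
                    logical(length(pieces)))
  if (length(pieces) == 1L) support <- matrix(support, nrow = 1L,
                                              dimnames = list(NULL, names(sets)))
  if (length(pieces) == 0L) support <- matrix(logical(0), nrow = 0L,
                                              ncol = length(sets),
                                              dimnames = list(NULL, names(sets)))
  list(intervals = pieces, support = support)
}

#' Create an exclusion mask
#'
#' A labelled normalized interval set marking regions excluded from all
#' analyses (for the study genome: the p-arm of chr6, the q-arm of chr16,
#' chrX, and assembly gap regions, all of which defeat length-based CNV
#' accounting). The mask is a required input; an example fixture ships in
#' `inst/extdata/exclusion_mask_synthetic.bed`.
#'
#' @param regions A `GRanges` (normalized on construction).
#' @param label Free-text description.
#' @return A `GRanges` with attribute `label`.
#' @export
exclusion_mask <- function(regions, label = "exclusion") {
  m <- normalize_intervals(regions)
  attr(m, "label") <- label
  m
}

#' Harmonize chromosome naming
#'
#' Input dialects differ in whether chromosome names carry a `"chr"`
#' prefix; matching is exact-string, so this helper applies (or strips)
#' the prefix consistently.
#'
#' @param gr A `GRanges`.
#' @param prefix If `TRUE` ensure every seqlevel starts with `"chr"`;
#'   if `FALSE` strip the prefix.
#' @return The relabelled `GRanges`.
#' @export
harmonize_chr <- function(gr, prefix = TRUE) {
  sl <- GenomeInfoDb::seqlevels(gr)
  new <- if (prefix) ifelse(grepl("^chr", sl), sl, paste0("chr", sl)) else
    sub("^chr", "", sl)
  GenomeInfoDb::seqlevels(gr) <- as.character(new)
  gr
}

#' Read a BED3 file as a normalized interval set
#' @param path Path to a tab-separated BED file (0-based half-open).
#' @return Normalized `GRanges`.
#' @export
read_bed <- function(path) {
  normalize_intervals(rtracklayer::import(path, format = "BED"))
}

#' Write an interval set as BED3
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- gr_to_df(normalize_intervals(gr))
  utils::write.table(df[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
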