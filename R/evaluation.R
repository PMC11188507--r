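# Region-based evaluation: precision/recall/F1, pairwise Jaccard
# concordance matrices, length-weighted ploidy, and re-centering shifts.

#' Precision, recall, and F1 of a query call set against a benchmark
#'
#' All three are length ratios over genomic regions of the requested CNV
#' type: precision is the fraction of the query's affected length that
#' lies inside the benchmark's regions, recall is the fraction of the
#' benchmark's affected length recovered by the query, and F1 is their
#' harmonic mean. An empty query makes precision undefined (`NA`), an
#' empty benchmark makes recall undefined; undefined values propagate
#' rather than silently becoming 0, so a caller that fails to make any
#' call of a type is visible as such.
#'
#' @param query A `cnv_callset` (or anything [typed_regions()] accepts).
#' @param truth A `cnv_benchmark`, truth profile, or region source.
#' @param cnv_type CNV type to evaluate.
#' @param mask Optional exclusion `GRanges` applied to both sides.
#' @return List of class `eval_metrics`: `precision`, `recall`, `f1`,
#'   `query_length`, `truth_length`, `overlap_length`.
#' @export
precision_recall_f1 <- function(query, truth, cnv_type, mask = NULL) {
  q <- typed_regions(query, cnv_type)
  t <- typed_regions(truth, cnv_type)
  if (!is.null(mask)) {
    if (length(q)) q <- subtract_intervals(q, mask)
    if (length(t)) t <- subtract_intervals(t, mask)
  }
  ql <- total_length(q)
  tl <- total_length(t)
  ov <- intersect_length(q, t)
  p <- if (ql > 0) ov / ql else NA_real_
  r <- if (tl > 0) ov / tl else NA_real_
  f1 <- if (is.na(p) || is.na(r)) NA_real_ else
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  structure(list(precision = p, recall = r, f1 = f1,
                 query_length = ql, truth_length = tl, overlap_length = ov),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f (query %.2f Mb, truth %.2f Mb, overlap %.2f Mb)\n",
              x$precision, x$recall, x$f1,
              x$query_length / 1e6, x$truth_length / 1e6,
              x$overlap_length / 1e6))
  invisible(x)
}

#' Pairwise Jaccard concordance matrix across call sets
#'
#' Region-level Jaccard index between every pair of call sets for one CNV
#' type. At gene or exon level both sides are first restricted to the
#' annotation track.
#'
#' @param callsets List of `cnv_callset` objects (named, or names are
#'   derived from provenance).
#' @param cnv_type CNV type to compare.
#' @param level `"segment"`, `"gene"`, or `"exon"`.
#' @param annotation `GRanges` annotation track (required for gene/exon
#'   level).
#' @param mask Optional exclusion `GRanges`.
#' @return Symmetric numeric matrix with unit diagonal (`NA` where both
#'   members of a pair are empty).
#' @export
pairwise_jaccard <- function(callsets, cnv_type,
                             level = c("segment", "gene", "exon"),
                             annotation = NULL, mask = NULL) {
  level <- match.arg(level)
  if (level != "segment" && is.null(annotation)) {
    stop("annotation track required for ", level, "-level concordance")
  }
  if (is.null(names(callsets))) {
    names(callsets) <- vapply(callsets, callset_id, character(1))
  }
  regions <- lapply(callsets, function(cs) {
    r <- typed_regions(cs, cnv_type)
    if (!is.null(mask) && length(r)) r <- subtract_intervals(r, mask)
    if (level != "segment" && length(r)) r <- restrict_to_annotation(r, annotation)
    r
  })
  n <- length(regions)
  m <- matrix(NA_real_, n, n, dimnames = list(names(regions), names(regions)))
  for (i in seq_len(n)) {
    m[i, i] <- if (length(regions[[i]])) 1 else NA_real_
    if (i < n) for (j in seq(i + 1, n)) {
      v <- jaccard_index(regions[[i]], regions[[j]])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Length-weighted overall ploidy of a call set
#'
#' Each called segment contributes the product of its length and total
#' copy number; the sum over segments is divided by the total length
#' covered by called segments.
#'
#' @param x A `cnv_callset`, truth profile, or data.frame of calls with
#'   `start`, `end`, `total_cn`.
#' @return List of class `ploidy_estimate`: `ploidy`, `covered_length`.
#' @examples
#' calls <- cnv_calls("chr1", c(0, 100), c(100, 200), total_cn = c(2, 4))
#' estimate_ploidy(calls)$ploidy  # 3
#' @export
estimate_ploidy <- function(x) {
  calls <- if (is.data.frame(x)) x else if (!is.null(x$calls)) x$calls else
    x$segments
  stopifnot(all(c("start", "end", "total_cn") %in% names(calls)))
  calls <- calls[!is.na(calls$total_cn), , drop = FALSE]
  len <- calls$end - calls$start
  covered <- sum(as.numeric(len))
  if (covered <= 0) stop("zero covered length: ploidy undefined")
  structure(list(ploidy = sum(len * calls$total_cn) / covered,
                 covered_length = covered),
            class = "ploidy_estimate")
}

#' Log2 re-centering shift for a non-diploid genome
#'
#' Callers that place the copy-neutral level at the genome median coverage
#' mis-center on aneuploid genomes; shifting log-ratios by
#' `log2(2 / ploidy)` moves the neutral level back to zero. For the study
#' genome's ploidy of 2.85 the shift is `log2(2 / 2.85) = -0.51` (2 dp).
#'
#' @param ploidy Overall genome ploidy (> 0).
#' @return The log2 shift (0 at ploidy 2, negative above).
#' @export
recenter_shift <- function(ploidy) {
  if (any(ploidy <= 0)) stop("ploidy must be positive")
  log2(2 / ploidy)
}
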