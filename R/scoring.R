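# Consensus scoring: disjoint support intervals -> per-caller group scores
# -> converted scores -> total score -> confidence level, separately for
# GAIN, LOSS, and LOH.

CONFIDENCE_LEVELS <- c("NONE", "NEUTRAL", "WEAK", "MEDIUM", "STRONG")

confidence_factor <- function(x) {
  factor(x, levels = CONFIDENCE_LEVELS, ordered = TRUE)
}

#' Default replicate grouping scheme
#'
#' The 21 WGS replicates are divided into five groups per caller: three
#' three-replicate groups for the centers that sequenced in triplicate
#' (FD, IL, NV), one nine-replicate group (NS) whose supporting-replicate
#' count is divided by 3 so no single center dominates, and one group
#' pooling the three single-replicate centers (EA, LL, NC). Each group
#' therefore contributes 0 to 3 to a caller's cumulative score, which
#' ranges from 0 to 15.
#'
#' @return data.frame with columns `center`, `replicate`, `group`,
#'   `divisor` (21 rows).
#' @export
default_grouping <- function() {
  rows <- rbind(
    data.frame(center = "FD", replicate = as.character(1:3), group = 1L),
    data.frame(center = "IL", replicate = as.character(1:3), group = 2L),
    data.frame(center = "NV", replicate = as.character(1:3), group = 3L),
    data.frame(center = "NS", replicate = as.character(1:9), group = 4L),
    data.frame(center = c("EA", "LL", "NC"), replicate = "1", group = 5L)
  )
  rows$divisor <- ifelse(rows$group == 4L, 3, 1)
  rows
}

#' Read a grouping scheme from a TSV file
#' @param path Tab-separated file with header columns `center`,
#'   `replicate`, `group`, `divisor`.
#' @return Grouping data.frame.
#' @export
read_grouping <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("center", "replicate", "group", "divisor") %in% names(g)))
  if (any(g$divisor < 1)) stop("group divisors must be >= 1")
  g$replicate <- as.character(g$replicate)
  g
}

#' Cumulative group score for one caller
#'
#' Each group contributes its count of supporting replicates divided by the
#' group's divisor (an intermediate score of 0-3 under the default
#' scheme); the contributions are summed across the five groups, giving a
#' cumulative score in `[0, 15]`.
#'
#' @param supported Named logical vector, one element per replicate of the
#'   caller; names are `"<center>_<replicate>"`.
#' @param grouping Grouping scheme data.frame (see [default_grouping()]).
#' @return Cumulative group score (numeric scalar).
#' @examples
#' sup <- setNames(rep(FALSE, 21),
#'                 replicate_ids(default_grouping()))
#' sup[c("FD_1", "FD_2")] <- TRUE
#' caller_cumulative_score(sup)  # 2: two of three FD replicates agree
#' @export
caller_cumulative_score <- function(supported, grouping = default_grouping()) {
  ids <- names(supported)
  key <- paste(grouping$center, grouping$replicate, sep = "_")
  unknown <- setdiff(ids, key)
  if (length(unknown)) stop("replicate not in grouping scheme: ", unknown[1])
  idx <- match(ids, key)
  grp <- grouping$group[idx]
  div <- grouping$divisor[idx]
  contrib <- tapply(as.numeric(supported), grp, sum) /
    tapply(div, grp, function(d) d[1])
  sum(contrib)
}

#' Replicate identifiers of a grouping scheme
#' @param grouping Grouping data.frame.
#' @return Character vector `"<center>_<replicate>"`.
#' @export
replicate_ids <- function(grouping = default_grouping()) {
  paste(grouping$center, grouping$replicate, sep = "_")
}

#' Convert a cumulative group score to the 0-3 scale
#'
#' Piecewise-constant, monotone mapping: cumulative 10-15 converts to 3,
#' 7-9 to 2, 4-6 to 1, and 0-3 to 0. Fractional cumulative scores (the
#' nine-replicate group contributes thirds) fall into the same bins read
#' as `[0,3]`, `(3,6]`, `(6,9]`, `(9,15]`.
#'
#' @param score Numeric vector of cumulative scores in `[0, 15]`.
#' @return Integer vector over `{0, 1, 2, 3}`.
#' @export
convert_cumulative <- function(score) {
  eps <- 1e-9
  if (any(score < -eps | score > 15 + eps)) {
    stop("cumulative group score outside [0, 15]: ",
         score[score < -eps | score > 15 + eps][1])
  }
  out <- integer(length(score))
  out[score > 3 + eps] <- 1L
  out[score > 6 + eps] <- 2L
  out[score > 9 + eps] <- 3L
  out
}

#' Confidence level for gain/loss intervals from the six-caller total
#'
#' The total score is the sum of the six callers' converted scores
#' (0-18). Totals of 11-18 are strong evidence, 8-10 medium, 4-7 weak,
#' and 1-3 neutral. A total of 0 (possible only for degenerate masked
#' input) maps to `"NONE"`.
#'
#' @param total_score Numeric vector in `[0, 18]`.
#' @return Ordered factor over `NONE < NEUTRAL < WEAK < MEDIUM < STRONG`.
#' @export
assign_confidence_gain_loss <- function(total_score) {
  eps <- 1e-9
  if (any(total_score < -eps | total_score > 18 + eps)) {
    stop("gain/loss total score outside [0, 18]")
  }
  out <- rep("NONE", length(total_score))
  out[total_score > eps] <- "NEUTRAL"
  out[total_score > 3 + eps] <- "WEAK"
  out[total_score > 7 + eps] <- "MEDIUM"
  out[total_score > 10 + eps] <- "STRONG"
  confidence_factor(out)
}

#' Confidence level for LOH intervals from the five-caller total
#'
#' LOH is reported by five callers, so the total ranges over `[0, 15]`.
#' Totals strictly greater than 8 are strong evidence, 6-7 medium, 4-5
#' weak, and scores below 3 neutral. The stated scale leaves totals of
#' exactly 8 and exactly 3 unassigned; both gaps are closed downward
#' (8 is medium, 3 is neutral), preserving the strict "> 8" strong rule.
#'
#' @param total_score Numeric vector in `[0, 15]`.
#' @return Ordered factor over `NONE < NEUTRAL < WEAK < MEDIUM < STRONG`.
#' @export
assign_confidence_loh <- function(total_score) {
  eps <- 1e-9
  if (any(total_score < -eps | total_score > 15 + eps)) {
    stop("LOH total score outside [0, 15]")
  }
  out <- rep("NONE", length(total_score))
  out[total_score > eps] <- "NEUTRAL"
  out[total_score > 3 + eps] <- "WEAK"
  out[total_score > 5 + eps] <- "MEDIUM"
  out[total_score > 8 + eps] <- "STRONG"
  confidence_factor(out)
}

#' Build the disjoint support matrix for one CNV type
#'
#' Extracts each call set's regions of the requested type (after masking),
#' and partitions them into disjoint intervals annotated with which call
#' sets support each piece.
#'
#' @param ch A `cnv_cohort`.
#' @param cnv_type `"GAIN"`, `"LOSS"`, or `"LOH"`.
#' @param mask Optional exclusion `GRanges` subtracted from every call set.
#' @return As [partition_support()]: `intervals` plus a logical `support`
#'   matrix keyed by call-set id; empty when no call set carries the type.
#' @export
build_support_matrix <- function(ch, cnv_type, mask = NULL) {
  stopifnot(inherits(ch, "cnv_cohort"))
  ids <- names(ch$callsets)
  dfs <- lapply(ch$callsets, function(cs)
    cs$calls[cs$calls$cnv_type == cnv_type, c("chrom", "start", "end"),
             drop = FALSE])
  n_per <- vapply(dfs, nrow, integer(1))
  empty <- list(intervals = GenomicRanges::GRanges(),
                support = matrix(logical(0), 0, length(ids),
                                 dimnames = list(NULL, ids)))
  if (sum(n_per) == 0L) return(empty)
  # one flat GRanges for all call sets, reduced per set, keeps the S4
  # construction cost independent of the cohort size
  all_df <- do.call(rbind, dfs)
  gr <- df_to_gr(all_df)
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  set_idx <- rep(seq_along(ids), n_per)
  grl <- GenomicRanges::reduce(
    GenomicRanges::split(gr, factor(set_idx, levels = seq_along(ids))))
  flat <- unlist(grl, use.names = FALSE)
  flat_set <- rep(seq_along(ids), lengths(grl))
  pieces <- GenomicRanges::sort(GenomicRanges::disjoin(flat))
  hits <- GenomicRanges::findOverlaps(pieces, flat)
  support <- matrix(FALSE, nrow = length(pieces), ncol = length(ids),
                    dimnames = list(NULL, ids))
  support[cbind(S4Vectors::queryHits(hits),
                flat_set[S4Vectors::subjectHits(hits)])] <- TRUE
  if (!is.null(mask)) {
    # punching mask bases out of the disjoint pieces is equivalent to
    # masking every input set first (the mask is common to all sets)
    m <- normalize_intervals(mask)
    g <- sync_seqlevels(pieces, m)
    d <- GenomicRanges::disjoin(c(g[[1]], g[[2]]))
    keep <- d[IRanges::overlapsAny(d, g[[1]]) & !IRanges::overlapsAny(d, g[[2]])]
    ov <- GenomicRanges::findOverlaps(keep, g[[1]])
    pieces <- keep[S4Vectors::queryHits(ov)]
    support <- support[S4Vectors::subjectHits(ov), , drop = FALSE]
    if (!length(pieces)) return(empty)
  }
  list(intervals = pieces, support = support)
}

#' Score a cohort's call sets for one CNV type
#'
#' The full consensus scoring path: mask each call set's typed regions,
#' partition into disjoint intervals, compute each caller's cumulative
#' group score per interval, convert to the 0-3 scale, total across
#' callers, and assign a confidence level (six-caller scale for gain and
#' loss, five-caller scale for LOH). Callers that never report LOH are
#' dropped from LOH scoring with a warning.
#'
#' @param ch A `cnv_cohort`.
#' @param cnv_type `"GAIN"`, `"LOSS"`, or `"LOH"`.
#' @param mask Optional exclusion `GRanges`.
#' @return data.frame of class `scored_intervals`: `chrom`, `start`,
#'   `end`, `cnv_type`, one `score_<caller>` column per caller,
#'   `total_score`, `confidence` (ordered factor). Intervals are disjoint
#'   and sorted; every interval has at least one supporting call set.
#' @export
score_cohort <- function(ch, cnv_type, mask = NULL) {
  cnv_type <- match.arg(toupper(cnv_type), c("GAIN", "LOSS", "LOH"))
  callers <- cohort_callers(ch)
  if (cnv_type == "LOH") {
    has_loh <- vapply(callers, function(ca) {
      any(vapply(ch$callsets, function(cs)
        cs$caller == ca && any(cs$calls$cnv_type == "LOH"), logical(1)))
    }, logical(1))
    if (any(!has_loh)) {
      warning("caller(s) reporting no LOH dropped from the LOH scale: ",
              paste(callers[!has_loh], collapse = ", "))
      callers <- callers[has_loh]
    }
  }
  part <- build_support_matrix(ch, cnv_type, mask)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cnv_type = character(0))
  if (length(part$intervals) == 0L) {
    for (ca in callers) empty[[paste0("score_", ca)]] <- integer(0)
    empty$total_score <- numeric(0)
    empty$confidence <- confidence_factor(character(0))
    class(empty) <- c("scored_intervals", class(empty))
    return(empty)
  }
  cs_caller <- vapply(ch$callsets, `[[`, character(1), "caller")
  cs_rep <- vapply(ch$callsets, function(cs)
    replicate_id(cs$center, cs$replicate), character(1))
  conv <- matrix(0L, nrow = length(part$intervals), ncol = length(callers),
                 dimnames = list(NULL, callers))
  key <- replicate_ids(ch$grouping)
  for (ca in callers) {
    cols <- which(cs_caller == ca)
    sup <- part$support[, cols, drop = FALSE]
    # cumulative score is linear in replicate support: each supporting
    # replicate contributes 1 / (its group's divisor)
    w <- 1 / ch$grouping$divisor[match(cs_rep[cols], key)]
    if (anyNA(w)) stop("replicate not in grouping scheme: ",
                       cs_rep[cols][is.na(w)][1])
    cum <- as.numeric(sup %*% w)
    conv[, ca] <- convert_cumulative(cum)
  }
  total <- rowSums(conv)
  conf <- if (cnv_type == "LOH") assign_confidence_loh(total) else
    assign_confidence_gain_loss(total)
  out <- gr_to_df(part$intervals)
  out$cnv_type <- cnv_type
  for (ca in callers) out[[paste0("score_", ca)]] <- conv[, ca]
  out$total_score <- total
  out$confidence <- conf
  class(out) <- c("scored_intervals", class(out))
  out
}

#' Write a scored-interval table as TSV
#' @param scored `scored_intervals` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scored <- function(scored, path) {
  utils::write.table(scored, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
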