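# Orthogonal-technology validation, conflict resolution, breakpoint
# trimming, and benchmark assembly.

#' Create an orthogonal-technology call set
#'
#' @param calls data.frame from [cnv_calls()].
#' @param technology Technology identifier (e.g. an SNP-array platform or
#'   optical genome mapping).
#' @return Object of class `orthogonal_callset`.
#' @export
orthogonal_callset <- function(calls, technology) {
  stopifnot(is.data.frame(calls))
  structure(list(calls = calls, technology = as.character(technology)),
            class = "orthogonal_callset")
}

#' @export
print.orthogonal_callset <- function(x, ...) {
  cat(sprintf("<orthogonal_callset> %s: %d calls\n",
              x$technology, nrow(x$calls)))
  invisible(x)
}

# union of same-type regions across a list of orthogonal call sets
tech_union <- function(techs, cnv_type) {
  if (!length(techs)) return(GenomicRanges::GRanges())
  grs <- lapply(techs, typed_regions, cnv_type = cnv_type)
  normalize_intervals(do.call(c, unname(sync_seqlevels_list(grs))))
}

sync_seqlevels_list <- function(grs) {
  sl <- sort(unique(unlist(lapply(grs, GenomeInfoDb::seqlevels))))
  lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- sl
    g
  })
}

# regions covered by >= k of the given (already reduced) region sets
coverage_at_least <- function(grs, k) {
  grs <- sync_seqlevels_list(lapply(grs, normalize_intervals))
  all_gr <- do.call(c, unname(grs))
  if (!length(all_gr)) return(GenomicRanges::GRanges())
  cvg <- GenomicRanges::coverage(all_gr)
  hit <- methods::as(cvg >= k, "GRanges")
  normalize_intervals(hit[S4Vectors::mcols(hit)$score])
}

# punch `sub` out of `gr`, keeping each surviving piece's metadata columns.
# `gr` must be disjoint.
gr_subtract_keep_mcols <- function(gr, sub) {
  sub <- normalize_intervals(sub)
  if (!length(sub) || !length(gr)) return(gr)
  g <- sync_seqlevels(GenomicRanges::granges(gr), sub)
  d <- GenomicRanges::disjoin(c(g[[1]], g[[2]]))
  keep <- d[IRanges::overlapsAny(d, g[[1]]) & !IRanges::overlapsAny(d, g[[2]])]
  ov <- GenomicRanges::findOverlaps(keep, g[[1]])
  out <- keep[S4Vectors::queryHits(ov)]
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)[S4Vectors::subjectHits(ov), ,
                                                drop = FALSE]
  GenomicRanges::sort(out)
}

# keep only the bases of `gr` inside `region`, keeping metadata columns.
gr_intersect_keep_mcols <- function(gr, region) {
  region <- normalize_intervals(region)
  if (!length(gr)) return(gr)
  if (!length(region)) return(gr[0])
  g <- sync_seqlevels(GenomicRanges::granges(gr), region)
  d <- GenomicRanges::disjoin(c(g[[1]], g[[2]]))
  keep <- d[IRanges::overlapsAny(d, g[[1]]) & IRanges::overlapsAny(d, g[[2]])]
  ov <- GenomicRanges::findOverlaps(keep, g[[1]])
  out <- keep[S4Vectors::queryHits(ov)]
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)[S4Vectors::subjectHits(ov), ,
                                                drop = FALSE]
  GenomicRanges::sort(out)
}

scored_to_gr <- function(scored) {
  gr <- df_to_gr(scored[, c("chrom", "start", "end")])
  S4Vectors::mcols(gr)$confidence <- as.character(scored$confidence)
  gr
}

#' Length of an interval set validated by one technology
#'
#' Per-base accounting: the validated length is the intersection of the
#' intervals with the technology's same-type regions, so an interval can
#' be partially validated.
#'
#' @param intervals `GRanges` of consensus intervals of one type.
#' @param tech An `orthogonal_callset`.
#' @param cnv_type The CNV type being validated.
#' @return Validated length in bp.
#' @export
validated_length <- function(intervals, tech, cnv_type) {
  intersect_length(intervals, typed_regions(tech, cnv_type))
}

#' Percentage of a collapsed region length that is validated
#' @param validated,collapsed Lengths in the same units.
#' @return `100 * validated / collapsed` (0 when `collapsed` is 0).
#' @export
percent_validated <- function(validated, collapsed) {
  ifelse(collapsed > 0, 100 * validated / collapsed, 0)
}

#' Tabulate orthogonal validation per confidence level
#'
#' For each confidence level of a scored-interval table: the collapsed
#' region length, each technology's validated length, the length validated
#' by at least one technology (union of same-type technology regions), and
#' by at least two (union of pairwise intersections), with percentages of
#' the collapsed length. Lengths are reported in Mb.
#'
#' @param scored `scored_intervals` data.frame (one CNV type).
#' @param techs List of `orthogonal_callset` objects (>= 1).
#' @return data.frame with one row per confidence level present
#'   (strong through neutral), columns `cnv_type`, `confidence`,
#'   `collapsed_mb`, `<technology>_mb` per technology, `ge1_mb`, `ge1_pct`,
#'   `ge2_mb`, `ge2_pct`.
#' @export
validation_table <- function(scored, techs) {
  stopifnot(length(techs) >= 1L)
  cnv_type <- unique(scored$cnv_type)
  stopifnot(length(cnv_type) <= 1L)
  if (!nrow(scored)) cnv_type <- NA_character_
  tech_names <- vapply(techs, `[[`, character(1), "technology")
  tech_regions <- lapply(techs, typed_regions, cnv_type = cnv_type)
  ge1 <- tech_union(techs, cnv_type)
  ge2 <- coverage_at_least(tech_regions, 2L)
  levels_used <- c("STRONG", "MEDIUM", "WEAK", "NEUTRAL")
  rows <- lapply(levels_used, function(lv) {
    sub <- scored[as.character(scored$confidence) == lv, , drop = FALSE]
    gr <- if (nrow(sub)) df_to_gr(sub[, c("chrom", "start", "end")]) else
      GenomicRanges::GRanges()
    collapsed <- total_length(gr)
    per_tech <- vapply(tech_regions, function(tr)
      intersect_length(gr, tr), numeric(1))
    v1 <- intersect_length(gr, ge1)
    v2 <- intersect_length(gr, ge2)
    row <- data.frame(cnv_type = cnv_type, confidence = lv,
                      collapsed_mb = collapsed / 1e6,
                      stringsAsFactors = FALSE)
    for (i in seq_along(tech_names)) {
      row[[paste0(tech_names[i], "_mb")]] <- per_tech[i] / 1e6
    }
    row$ge1_mb <- v1 / 1e6
    row$ge1_pct <- percent_validated(v1, collapsed)
    row$ge2_mb <- v2 / 1e6
    row$ge2_pct <- percent_validated(v2, collapsed)
    row
  })
  do.call(rbind, rows)
}

#' Collapse replicate calls of one technology into a non-redundant set
#'
#' Single-linkage clustering of same-type calls: two calls link when their
#' positions (starts) lie within `proximity` of each other and their sizes
#' are similar (`min(len)/max(len) > similarity`); requiring both
#' breakpoints to agree would make the size criterion redundant and would
#' never merge calls of visibly different size. Each cluster is replaced by
#' one representative call with the median start, median end, and median
#' copy number. Idempotent.
#'
#' @param calls data.frame of CNV calls (from replicates of one
#'   technology).
#' @param proximity Maximum breakpoint distance in bp (default 10,000).
#' @param similarity Minimum size-similarity ratio (default 0.5,
#'   exclusive).
#' @return data.frame of representative calls.
#' @export
cluster_nonredundant <- function(calls, proximity = 1e4, similarity = 0.5) {
  if (!nrow(calls)) return(calls)
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  len <- calls$end - calls$start
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (calls$cnv_type[i] != calls$cnv_type[j]) next
      if (calls$chrom[i] != calls$chrom[j]) next
      if (abs(calls$start[i] - calls$start[j]) > proximity) next
      if (min(len[i], len[j]) / max(len[i], len[j]) <= similarity) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  reps <- lapply(split(seq_len(n), root), function(idx) {
    sub <- calls[idx, , drop = FALSE]
    data.frame(chrom = sub$chrom[1],
               start = round(stats::median(sub$start)),
               end = round(stats::median(sub$end)),
               total_cn = stats::median(sub$total_cn),
               minor_cn = stats::median(sub$minor_cn),
               loh = sub$loh[1],
               cnv_type = sub$cnv_type[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, reps)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve gain/loss conflicts against orthogonal evidence
#'
#' A consensus gain base that orthogonal technologies call a loss, with no
#' orthogonal gain support, is removed (and symmetrically for loss bases).
#' Where any technology supports the consensus type, the base is retained
#' even if another technology calls the opposite type. Removals are
#' per-base and logged.
#'
#' @param gain_gr,loss_gr Disjoint `GRanges` with a `confidence` metadata
#'   column (as produced inside [assemble_benchmark()]).
#' @param techs List of `orthogonal_callset` objects.
#' @return List with `gain`, `loss` (kept pieces, metadata preserved) and
#'   `removed` (data.frame log of removed pieces).
#' @export
resolve_conflicts <- function(gain_gr, loss_gr, techs) {
  tg <- tech_union(techs, "GAIN")
  tl <- tech_union(techs, "LOSS")
  kill_gain <- subtract_intervals(tl, tg)   # loss-only orthogonal evidence
  kill_loss <- subtract_intervals(tg, tl)   # gain-only orthogonal evidence
  removed_gain <- gr_intersect_keep_mcols(gain_gr, kill_gain)
  removed_loss <- gr_intersect_keep_mcols(loss_gr, kill_loss)
  log <- rbind(
    if (length(removed_gain)) cbind(gr_to_df(removed_gain),
                                    cnv_type = "GAIN",
                                    reason = "orthogonal_loss_only"),
    if (length(removed_loss)) cbind(gr_to_df(removed_loss),
                                    cnv_type = "LOSS",
                                    reason = "orthogonal_gain_only")
  )
  if (is.null(log)) {
    log <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), confidence = character(0),
                      cnv_type = character(0), reason = character(0))
  }
  list(gain = gr_subtract_keep_mcols(gain_gr, kill_gain),
       loss = gr_subtract_keep_mcols(loss_gr, kill_loss),
       removed = log)
}

#' Trim overlapping gain/loss breakpoints using orthogonal evidence
#'
#' Where a gain interval and a loss interval still overlap after conflict
#' resolution, the end supported by any same-type orthogonal call keeps
#' its coordinate and the unsupported end is trimmed back to abut it. If
#' both or neither end is supported, the overlap is split at its midpoint;
#' both tie-break cases are logged. No gain/loss overlap remains
#' afterwards.
#'
#' @param gain_gr,loss_gr Disjoint `GRanges` with metadata.
#' @param techs List of `orthogonal_callset` objects.
#' @return List with `gain`, `loss`, and `trim_log` (data.frame).
#' @export
trim_breakpoints <- function(gain_gr, loss_gr, techs) {
  tg <- tech_union(techs, "GAIN")
  tl <- tech_union(techs, "LOSS")
  gU <- normalize_intervals(gain_gr)
  lU <- normalize_intervals(loss_gr)
  g <- sync_seqlevels(gU, lU)
  ovs <- GenomicRanges::intersect(g[[1]], g[[2]])  # disjoint overlap regions
  cut_gain <- GenomicRanges::GRanges()
  cut_loss <- GenomicRanges::GRanges()
  log <- vector("list", length(ovs))
  for (i in seq_along(ovs)) {
    o <- ovs[i]
    gsup <- intersect_length(o, tg) > 0
    lsup <- intersect_length(o, tl) > 0
    if (gsup && !lsup) {
      cut_loss <- c(cut_loss, sync_seqlevels(cut_loss, o)[[2]])
      outcome <- "gain_end_retained"
    } else if (lsup && !gsup) {
      cut_gain <- c(cut_gain, sync_seqlevels(cut_gain, o)[[2]])
      outcome <- "loss_end_retained"
    } else {
      s0 <- GenomicRanges::start(o) - 1L
      e0 <- GenomicRanges::end(o)
      m <- (s0 + e0) %/% 2
      chrom <- as.character(GenomicRanges::seqnames(o))
      # the end adjacent to the gain body keeps its side of the midpoint
      gi <- g[[1]][S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(o, g[[1]]))[1]]
      li <- g[[2]][S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(o, g[[2]]))[1]]
      gain_left <- GenomicRanges::start(gi) <= GenomicRanges::start(li)
      gain_half <- interval_set(chrom, if (gain_left) m else s0,
                                if (gain_left) e0 else m)
      loss_half <- interval_set(chrom, if (gain_left) s0 else m,
                                if (gain_left) m else e0)
      cut_gain <- c(cut_gain, sync_seqlevels(cut_gain, gain_half)[[2]])
      cut_loss <- c(cut_loss, sync_seqlevels(cut_loss, loss_half)[[2]])
      outcome <- if (gsup) "tie_both_supported_midpoint" else
        "tie_neither_supported_midpoint"
    }
    log[[i]] <- cbind(gr_to_df(GenomicRanges::granges(o)),
                      outcome = outcome)
  }
  trim_log <- if (length(log)) do.call(rbind, log) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               outcome = character(0))
  list(gain = gr_subtract_keep_mcols(gain_gr, cut_gain),
       loss = gr_subtract_keep_mcols(loss_gr, cut_loss),
       trim_log = trim_log)
}

#' Assemble the high-confidence CNV benchmark set
#'
#' Keeps strong-evidence intervals unconditionally; keeps medium- and
#' weak-evidence intervals only where (per base) at least two orthogonal
#' technologies call the same type; drops neutral and unsupported
#' intervals. Gain/loss conflicts are then resolved against orthogonal
#' evidence and overlapping breakpoints trimmed, and each benchmark
#' interval is annotated with the median copy number over the cohort's
#' same-type overlapping calls and the list of supporting technologies.
#' With no technologies supplied, the benchmark degenerates to
#' strong-evidence intervals only.
#'
#' @param scored_list Named list of `scored_intervals` data.frames,
#'   names among `"GAIN"`, `"LOSS"`, `"LOH"`.
#' @param techs List of `orthogonal_callset` objects (may be empty).
#' @param ch Optional `cnv_cohort` used for the median copy number.
#' @return data.frame of class `cnv_benchmark` with columns `chrom`,
#'   `start`, `end`, `cnv_type`, `confidence`, `median_cn`,
#'   `tech_support`; attribute `"logs"` holds the removal and trim logs.
#' @export
assemble_benchmark <- function(scored_list, techs = list(), ch = NULL) {
  stopifnot(all(names(scored_list) %in% c("GAIN", "LOSS", "LOH")))
  kept <- lapply(names(scored_list), function(ty) {
    sc <- scored_list[[ty]]
    if (!nrow(sc)) {
      g0 <- GenomicRanges::GRanges()
      S4Vectors::mcols(g0)$confidence <- character(0)
      return(g0)
    }
    gr <- scored_to_gr(sc)
    conf <- S4Vectors::mcols(gr)$confidence
    strong <- gr[conf == "STRONG"]
    mw <- gr[conf %in% c("MEDIUM", "WEAK")]
    if (length(techs)) {
      ge2 <- coverage_at_least(lapply(techs, typed_regions, cnv_type = ty), 2L)
      mw <- gr_intersect_keep_mcols(mw, ge2)
    } else {
      mw <- mw[0]
    }
    GenomicRanges::sort(c(strong, mw))
  })
  names(kept) <- names(scored_list)
  logs <- list()
  if (length(techs) && !is.null(kept$GAIN) && !is.null(kept$LOSS)) {
    res <- resolve_conflicts(kept$GAIN, kept$LOSS, techs)
    logs$removed <- res$removed
    tr <- trim_breakpoints(res$gain, res$loss, techs)
    logs$trim <- tr$trim_log
    kept$GAIN <- tr$gain
    kept$LOSS <- tr$loss
  }
  # fuse abutting partition pieces that share a confidence level, so a
  # benchmark call is one contiguous region rather than scoring slivers
  kept <- lapply(kept, function(gr) {
    if (!length(gr)) return(gr)
    parts <- lapply(unique(S4Vectors::mcols(gr)$confidence), function(lv) {
      r <- GenomicRanges::reduce(gr[S4Vectors::mcols(gr)$confidence == lv])
      S4Vectors::mcols(r)$confidence <- lv
      r
    })
    GenomicRanges::sort(do.call(c, parts))
  })
  rows <- lapply(names(kept), function(ty) {
    gr <- kept[[ty]]
    if (!length(gr)) return(NULL)
    df <- gr_to_df(gr)
    df$cnv_type <- ty
    df$median_cn <- benchmark_median_cn(gr, ch, ty)
    if (length(techs)) {
      tech_names <- vapply(techs, `[[`, character(1), "technology")
      sup <- vapply(techs, function(te) {
        tr <- typed_regions(te, ty)
        g <- sync_seqlevels(gr, tr)
        IRanges::overlapsAny(g[[1]], g[[2]])
      }, logical(length(gr)))
      if (length(gr) == 1L) sup <- matrix(sup, nrow = 1L)
      df$tech_support <- apply(sup, 1L, function(s)
        paste(tech_names[s], collapse = ","))
    } else {
      df$tech_support <- ""
    }
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), confidence = character(0),
                      cnv_type = character(0), median_cn = numeric(0),
                      tech_support = character(0))
  }
  out <- out[order(out$chrom, out$start, out$cnv_type), , drop = FALSE]
  out <- out[, c("chrom", "start", "end", "cnv_type", "confidence",
                 "median_cn", "tech_support")]
  rownames(out) <- NULL
  attr(out, "logs") <- logs
  class(out) <- c("cnv_benchmark", class(out))
  out
}

benchmark_median_cn <- function(gr, ch, cnv_type) {
  if (is.null(ch)) return(rep(NA_real_, length(gr)))
  calls <- do.call(rbind, lapply(ch$callsets, function(cs)
    cs$calls[cs$calls$cnv_type == cnv_type,
             c("chrom", "start", "end", "total_cn"), drop = FALSE]))
  if (is.null(calls) || !nrow(calls)) return(rep(NA_real_, length(gr)))
  call_gr <- df_to_gr(calls)
  g <- sync_seqlevels(gr, call_gr)
  ov <- GenomicRanges::findOverlaps(g[[1]], g[[2]])
  out <- rep(NA_real_, length(gr))
  if (length(ov)) {
    med <- tapply(calls$total_cn[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), stats::median)
    out[as.integer(names(med))] <- as.numeric(med)
  }
  out
}

#' Write a benchmark table as TSV
#' @param benchmark A `cnv_benchmark` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(benchmark, path) {
  utils::write.table(benchmark, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
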