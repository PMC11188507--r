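# CNV call sets: copy-number classification, segment-table I/O, cohorts.

CNV_TYPES <- c("GAIN", "LOSS", "LOH", "NEUTRAL")

#' Classify a copy-number call as gain, loss, LOH, or neutral
#'
#' The cutoffs sit on the diploid copy number: total copy number above 2 is
#' a gain, below 2 a loss. At exactly 2 the call is LOH when the caller
#' flags loss of heterozygosity (or reports minor-allele copy number 0),
#' otherwise copy-neutral. Copy numbers may be fractional (several callers
#' emit non-integer estimates), so equality with 2 is tested with a small
#' tolerance.
#'
#' @param total_cn Numeric vector of total copy numbers (>= 0).
#' @param loh Optional logical vector: caller-reported LOH flag.
#' @param minor_cn Optional numeric vector of minor-allele copy numbers.
#' @param tol Equality tolerance around copy number 2 (default `1e-6`).
#' @return Character vector over `"GAIN"`, `"LOSS"`, `"LOH"`, `"NEUTRAL"`.
#' @examples
#' classify_call(c(3, 1, 2, 2), loh = c(NA, NA, TRUE, FALSE))
#' @export
classify_call <- function(total_cn, loh = NULL, minor_cn = NULL, tol = 1e-6) {
  if (any(is.na(total_cn))) stop("total_cn must not contain NA")
  if (any(total_cn < 0)) stop("negative copy number rejected: ",
                              min(total_cn))
  n <- length(total_cn)
  if (is.null(loh)) loh <- rep(NA, n)
  if (is.null(minor_cn)) minor_cn <- rep(NA_real_, n)
  loh <- rep_len(as.logical(loh), n)
  minor_cn <- rep_len(as.numeric(minor_cn), n)
  out <- rep("NEUTRAL", n)
  out[total_cn > 2 + tol] <- "GAIN"
  out[total_cn < 2 - tol] <- "LOSS"
  at2 <- abs(total_cn - 2) <= tol
  is_loh <- (!is.na(loh) & loh) |
    (is.na(loh) & !is.na(minor_cn) & abs(minor_cn) <= tol)
  out[at2 & is_loh] <- "LOH"
  out
}

#' Build a table of CNV calls
#'
#' @param chrom,start,end Segment coordinates (0-based half-open).
#' @param total_cn Total copy number per segment.
#' @param minor_cn Optional minor-allele copy number (must satisfy
#'   `0 <= minor_cn <= total_cn`).
#' @param loh Optional logical LOH flag.
#' @param cnv_type Optional type; derived via [classify_call()] when absent.
#' @return data.frame of calls with a consistent `cnv_type` column.
#' @export
cnv_calls <- function(chrom, start, end, total_cn,
                      minor_cn = NA_real_, loh = NA, cnv_type = NULL) {
  n <- length(start)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = start, end = end,
                   total_cn = rep_len(total_cn, n),
                   minor_cn = rep_len(as.numeric(minor_cn), n),
                   loh = rep_len(as.logical(loh), n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    bad <- which(!(df$start >= 0 & df$start < df$end))
    if (length(bad)) stop("malformed call at record ", bad[1],
                          ": start >= end")
    bad_cn <- which(!is.na(df$minor_cn) &
                      (df$minor_cn < 0 | df$minor_cn > df$total_cn))
    if (length(bad_cn)) stop("minor_cn outside [0, total_cn] at record ",
                             bad_cn[1])
  }
  if (is.null(cnv_type)) {
    df$cnv_type <- if (nrow(df)) {
      classify_call(df$total_cn, df$loh, df$minor_cn)
    } else character(0)
  } else {
    stopifnot(all(cnv_type %in% CNV_TYPES))
    df$cnv_type <- as.character(cnv_type)
  }
  df
}

#' Create a call set (one caller on one replicate)
#'
#' @param calls data.frame from [cnv_calls()].
#' @param caller,center,replicate Provenance identifiers.
#' @param platform One of `"WGS"`, `"WES"`, `"other"`.
#' @return Object of class `cnv_callset`.
#' @export
callset <- function(calls, caller, center, replicate, platform = "WGS") {
  stopifnot(is.data.frame(calls),
            all(c("chrom", "start", "end", "total_cn", "cnv_type")
                %in% names(calls)))
  structure(
    list(calls = calls, caller = as.character(caller),
         center = as.character(center), replicate = as.character(replicate),
         platform = match.arg(platform, c("WGS", "WES", "other"))),
    class = "cnv_callset"
  )
}

#' @export
print.cnv_callset <- function(x, ...) {
  cat(sprintf("<cnv_callset> %s / %s rep %s (%s): %d calls\n",
              x$caller, x$center, x$replicate, x$platform, nrow(x$calls)))
  tl <- vapply(c("GAIN", "LOSS", "LOH"), function(t)
    total_length(typed_regions(x, t)) / 1e6, numeric(1))
  cat(sprintf("  gain %.2f Mb, loss %.2f Mb, LOH %.2f Mb\n",
              tl[1], tl[2], tl[3]))
  invisible(x)
}

callset_id <- function(cs) paste(cs$caller, cs$center, cs$replicate, sep = "|")

replicate_id <- function(center, replicate) paste(center, replicate, sep = "_")

#' Extract the typed regions of a call set as a normalized interval set
#'
#' @param x A `cnv_callset`, orthogonal call set, truth profile, benchmark
#'   data.frame (with a `cnv_type` column), or plain `GRanges`.
#' @param cnv_type One of `"GAIN"`, `"LOSS"`, `"LOH"`, `"NEUTRAL"`.
#' @return Normalized `GRanges` of the regions carrying that type.
#' @export
typed_regions <- function(x, cnv_type) {
  cnv_type <- match.arg(toupper(cnv_type), CNV_TYPES)
  if (inherits(x, "GRanges")) return(normalize_intervals(x))
  calls <- if (is.data.frame(x)) x else x$calls
  if (is.null(calls) && !is.null(x$segments)) calls <- x$segments
  sel <- calls[calls$cnv_type == cnv_type, , drop = FALSE]
  if (!nrow(sel)) return(GenomicRanges::GRanges())
  normalize_intervals(df_to_gr(sel[, c("chrom", "start", "end")]))
}

# ---- segment-table dialect registry -----------------------------------

.dialects <- new.env(parent = emptyenv())

#' Register a segment-table dialect
#'
#' A dialect maps the package's call fields onto the column names of a
#' caller's converted segment table. Tables are tab-separated; lines
#' starting with `#` are comments. Two dialects are pre-registered:
#' `"standard"` (chrom, start, end, total_cn, minor_cn, loh; header) and
#' `"bedcn"` (four headerless BED-like columns chrom, start, end, total_cn).
#'
#' @param name Dialect name.
#' @param columns Named character vector mapping fields (`chrom`, `start`,
#'   `end`, `total_cn`, and optionally `minor_cn`, `loh`, `cnv_type`) to
#'   file column names (header dialects) or indices (headerless).
#' @param header Does the file carry a header line?
#' @return `name`, invisibly.
#' @export
register_dialect <- function(name, columns, header = TRUE) {
  stopifnot(all(c("chrom", "start", "end", "total_cn") %in% names(columns)))
  assign(name, list(columns = columns, header = header), envir = .dialects)
  invisible(name)
}

#' List registered segment dialects
#' @return Character vector of dialect names.
#' @export
list_dialects <- function() ls(.dialects)

get_dialect <- function(name) {
  if (!exists(name, envir = .dialects, inherits = FALSE)) {
    stop("unknown dialect '", name, "'; registered dialects: ",
         paste(list_dialects(), collapse = ", "))
  }
  get(name, envir = .dialects, inherits = FALSE)
}

register_builtin_dialects <- function() {
  register_dialect("standard", c(
    chrom = "chrom", start = "start", end = "end", total_cn = "total_cn",
    minor_cn = "minor_cn", loh = "loh"
  ), header = TRUE)
  register_dialect("bedcn", c(chrom = "1", start = "2", end = "3",
                              total_cn = "4"), header = FALSE)
}

#' Read a CNV segment table as a call set
#'
#' @param path Path to a tab-separated segment table.
#' @param dialect Registered dialect name (see [register_dialect()]).
#' @param caller,center,replicate,platform Provenance metadata.
#' @return A `cnv_callset`.
#' @export
read_segments <- function(path, dialect = "standard",
                          caller = "caller", center = "center",
                          replicate = "1", platform = "WGS") {
  d <- get_dialect(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = d$header, comment.char = "#",
                           stringsAsFactors = FALSE)
  pick <- function(field) {
    if (!field %in% names(d$columns)) return(NULL)
    key <- d$columns[[field]]
    if (is.na(key)) return(NULL)
    if (d$header) {
      if (!key %in% names(tab)) return(NULL)
      tab[[key]]
    } else {
      tab[[as.integer(key)]]
    }
  }
  chrom <- pick("chrom"); start <- pick("start"); end <- pick("end")
  cn <- pick("total_cn")
  if (is.null(chrom) || is.null(start) || is.null(end) || is.null(cn)) {
    stop("dialect '", dialect, "' columns missing from ", path)
  }
  n_header <- if (d$header) 1L else 0L
  bad <- which(!(is.finite(start) & is.finite(end) & start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("unparseable segment at %s line %d: start >= end or non-numeric",
                 path, bad[1] + n_header))
  }
  minor <- pick("minor_cn"); lohv <- pick("loh"); typev <- pick("cnv_type")
  calls <- cnv_calls(chrom, start, end, cn,
                     minor_cn = if (is.null(minor)) NA_real_ else minor,
                     loh = if (is.null(lohv)) NA else as.logical(lohv),
                     cnv_type = typev)
  callset(calls, caller, center, replicate, platform)
}

#' Write a call set's segments in the standard dialect
#' @param cs A `cnv_callset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(cs, path) {
  cols <- c("chrom", "start", "end", "total_cn", "minor_cn", "loh", "cnv_type")
  utils::write.table(cs$calls[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- cohorts -----------------------------------------------------------

#' Assemble call sets into a cohort
#'
#' @param callsets List of `cnv_callset` objects with unique
#'   (caller, center, replicate, platform) provenance.
#' @param grouping Replicate grouping scheme, see [default_grouping()].
#' @return Object of class `cnv_cohort`.
#' @export
cohort <- function(callsets, grouping = default_grouping()) {
  stopifnot(length(callsets) >= 1L,
            all(vapply(callsets, inherits, logical(1), "cnv_callset")))
  ids <- vapply(callsets, callset_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate call-set provenance: ",
                               ids[duplicated(ids)][1])
  reps <- unique(vapply(callsets, function(cs)
    replicate_id(cs$center, cs$replicate), character(1)))
  known <- replicate_id(grouping$center, grouping$replicate)
  missing <- setdiff(reps, known)
  if (length(missing)) stop("replicate not in grouping scheme: ", missing[1])
  names(callsets) <- ids
  structure(list(callsets = callsets, grouping = grouping),
            class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  callers <- unique(vapply(x$callsets, `[[`, character(1), "caller"))
  cat(sprintf("<cnv_cohort> %d call sets, %d callers, %d replicate slots\n",
              length(x$callsets), length(callers), nrow(x$grouping)))
  invisible(x)
}

cohort_callers <- function(ch) {
  unique(vapply(ch$callsets, `[[`, character(1), "caller"))
}
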