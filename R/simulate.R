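# Synthetic cohort generator: a hyper-diploid truth CNV landscape plus
# imperfect caller and orthogonal-technology call sets with controlled
# noise (dropouts, false calls, breakpoint jitter, global ploidy
# mis-centering).

#' Define a synthetic genome
#'
#' The default genome is three chromosomes of 30/20/10 Mb, small enough
#' that the full pipeline runs in seconds while still producing dozens of
#' CNV segments per replicate.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param mask Optional exclusion `GRanges` within chromosome bounds.
#' @return Object of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes = c(chr1 = 3e7, chr2 = 2e7, chr3 = 1e7),
                        mask = NULL) {
  stopifnot(!is.null(names(chromosomes)), all(chromosomes > 0))
  structure(list(chromosomes = chromosomes, mask = mask),
            class = "genome_spec")
}

# Deterministic 32-bit FNV-1a hash of the concatenated arguments, used to
# derive independent RNG streams so adding a caller or technology never
# perturbs existing streams.
stable_seed <- function(...) {
  s <- paste(unlist(list(...)), collapse = "|")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1)) + 1L
}

#' Caller noise model
#'
#' Parameters of one simulated caller: per-type detection sensitivity,
#' false-call rate, breakpoint jitter, minimum detectable segment length,
#' and a global ploidy mis-centering failure mode in which a whole
#' replicate's copy numbers shift by an integer offset (re-typing neutral
#' segments as gains or losses en masse, as observed for ploidy-confused
#' callers).
#'
#' @param sensitivity Named probabilities for `GAIN`, `LOSS`, `LOH`.
#' @param fp_rate Expected false segments per 100 Mb of genome.
#' @param breakpoint_jitter_sd SD (bp) of the rounded Gaussian breakpoint
#'   noise.
#' @param min_detectable_length Segments at or below this length are never
#'   emitted.
#' @param ploidy_shift_prob Per-replicate probability of the global
#'   copy-number shift.
#' @param ploidy_shift_delta Integer copy-number offset applied when the
#'   shift fires (nonzero when `ploidy_shift_prob > 0`).
#' @param seed Stream seed for this caller.
#' @return Object of class `caller_model`.
#' @export
caller_model <- function(sensitivity = c(GAIN = 0.95, LOSS = 0.95, LOH = 0.95),
                         fp_rate = 1, breakpoint_jitter_sd = 1e4,
                         min_detectable_length = 5e4,
                         ploidy_shift_prob = 0, ploidy_shift_delta = 2L,
                         seed = 1L) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(c("GAIN", "LOSS", "LOH") %in% names(sensitivity)),
            fp_rate >= 0, breakpoint_jitter_sd >= 0)
  if (ploidy_shift_prob > 0 && ploidy_shift_delta == 0) {
    stop("ploidy_shift_delta must be nonzero when ploidy_shift_prob > 0")
  }
  structure(list(sensitivity = sensitivity, fp_rate = fp_rate,
                 breakpoint_jitter_sd = breakpoint_jitter_sd,
                 min_detectable_length = min_detectable_length,
                 ploidy_shift_prob = ploidy_shift_prob,
                 ploidy_shift_delta = as.integer(ploidy_shift_delta),
                 seed = as.integer(seed)),
            class = "caller_model")
}

#' Orthogonal-technology noise model
#'
#' Like [caller_model()] but without the ploidy failure mode; stands in
#' for array / optical-mapping resolution limits.
#'
#' @inheritParams caller_model
#' @return Object of class `orthogonal_model`.
#' @export
orthogonal_model <- function(sensitivity = c(GAIN = 0.98, LOSS = 0.98,
                                             LOH = 0.98),
                             fp_rate = 0.5, breakpoint_jitter_sd = 2e3,
                             min_detectable_length = 5e4, seed = 1L) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1))
  structure(list(sensitivity = sensitivity, fp_rate = fp_rate,
                 breakpoint_jitter_sd = breakpoint_jitter_sd,
                 min_detectable_length = min_detectable_length,
                 seed = as.integer(seed)),
            class = "orthogonal_model")
}

#' Simulate a truth CNV landscape for a hyper-diploid genome
#'
#' Tiles every chromosome with segments (no gaps, no overlaps) and assigns
#' each a type and copy number: gains at CN 3-5, losses at CN 1, copy-
#' neutral LOH, and neutral diploid segments. The gain fraction is chosen
#' so the expected length-weighted ploidy equals `target_ploidy`
#' (default 2.85, the study genome's hyper-diploid level); type counts
#' are fixed and shuffled across segments, so the realized ploidy varies
#' only through segment-length dispersion and stays within about +-0.3 of
#' the target.
#'
#' @param spec A `genome_spec`.
#' @param target_ploidy Target length-weighted mean copy number.
#' @param mean_seg_len,min_seg_len Segment-length parameters in bp.
#' @param loss_frac,loh_frac Fractions of segments typed loss / LOH.
#' @param gain_cn_probs Named probabilities over gain copy numbers.
#' @param seed RNG seed (the profile is deterministic given the seed).
#' @return Object of class `truth_profile` with elements `spec`,
#'   `segments` (tiling call table), and `ploidy`.
#' @export
simulate_truth <- function(spec = genome_spec(), target_ploidy = 2.85,
                           mean_seg_len = 1.5e6, min_seg_len = 2e5,
                           loss_frac = 0.08, loh_frac = 0.22,
                           gain_cn_probs = c("3" = 0.5, "4" = 0.35,
                                             "5" = 0.15),
                           seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  if (min_seg_len * 3 > min(spec$chromosomes)) {
    stop("infeasible parameters: min_seg_len too large for the genome")
  }
  set.seed(seed)
  gain_mean_cn <- sum(as.numeric(names(gain_cn_probs)) * gain_cn_probs)
  gain_frac <- (target_ploidy - 2 + loss_frac) / (gain_mean_cn - 2)
  gain_frac <- max(0, min(1, gain_frac))
  neutral_frac <- 1 - gain_frac - loss_frac - loh_frac
  if (neutral_frac < 0) {
    stop("infeasible parameters: type fractions exceed 1")
  }
  segs <- lapply(names(spec$chromosomes), function(ch) {
    len <- spec$chromosomes[[ch]]
    n <- max(3L, round(len / mean_seg_len))
    w <- stats::rexp(n)
    lens <- floor(w / sum(w) * (len - n * min_seg_len)) + min_seg_len
    lens[n] <- lens[n] + (len - sum(lens))  # exact tiling
    ends <- cumsum(lens)
    data.frame(chrom = ch, start = c(0, ends[-n]), end = ends,
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  n <- nrow(segs)
  counts <- c(GAIN = round(gain_frac * n), LOSS = round(loss_frac * n),
              LOH = round(loh_frac * n))
  counts <- pmin(counts, n)
  n_neutral <- n - sum(counts)
  if (n_neutral < 0) {
    counts["GAIN"] <- counts["GAIN"] + n_neutral
    n_neutral <- 0
  }
  types <- sample(rep(c(names(counts), "NEUTRAL"),
                      times = c(counts, n_neutral)))
  # the shuffled assignment ignores segment lengths, so the realized
  # length-weighted ploidy can drift; greedily swap neutral <-> gain
  # assignments (smallest corrective step first) until it is on target
  types <- balance_ploidy(types, segs$end - segs$start, target_ploidy,
                          gain_mean_cn, tol = 0.1)
  cn <- rep(2, n)
  minor <- rep(1, n)
  is_gain <- types == "GAIN"
  cn[is_gain] <- as.numeric(sample(names(gain_cn_probs), sum(is_gain),
                                   replace = TRUE, prob = gain_cn_probs))
  cn[types == "LOSS"] <- 1
  minor[types == "LOSS"] <- 0
  minor[types == "LOH"] <- 0
  segments <- cnv_calls(segs$chrom, segs$start, segs$end, cn,
                        minor_cn = minor, loh = types == "LOH")
  stopifnot(identical(segments$cnv_type, types))
  structure(list(spec = spec, segments = segments,
                 ploidy = estimate_ploidy(segments)$ploidy,
                 seed = seed),
            class = "truth_profile")
}

#' @export
print.truth_profile <- function(x, ...) {
  cat(sprintf("<truth_profile> %d segments on %d chromosomes, ploidy %.3f\n",
              nrow(x$segments), length(x$spec$chromosomes), x$ploidy))
  invisible(x)
}

# Deterministic greedy correction of the type assignment so the expected
# length-weighted ploidy lands within `tol` of the target: swap NEUTRAL
# segments to GAIN (raising ploidy) or GAIN to NEUTRAL (lowering it),
# always taking the largest step that does not overshoot.
balance_ploidy <- function(types, lens, target, gain_mean_cn, tol = 0.1) {
  L <- sum(as.numeric(lens))
  expected_cn <- function(ty) switch(ty, GAIN = gain_mean_cn, LOSS = 1, 2)
  current <- sum(lens * vapply(types, expected_cn, numeric(1))) / L
  step <- lens * (gain_mean_cn - 2) / L
  for (i in seq_len(length(types) * 2L)) {
    dev <- target - current
    if (abs(dev) <= tol) break
    cand <- if (dev > 0) which(types == "NEUTRAL") else which(types == "GAIN")
    if (!length(cand)) break
    eff <- step[cand] * sign(dev)
    ok <- cand[abs(eff) <= abs(dev)]
    pick <- if (length(ok)) ok[which.max(step[ok])] else {
      sm <- cand[which.min(step[cand])]
      if (abs(step[sm]) >= 2 * abs(dev)) break  # would overshoot further out
      sm
    }
    types[pick] <- if (dev > 0) "GAIN" else "NEUTRAL"
    current <- current + step[pick] * sign(dev)
  }
  types
}

# shared emission channel for caller and orthogonal simulation.
# Random draws are made for every truth segment up front (emission,
# jitter), so lowering sensitivity only removes segments without
# re-randomizing the survivors — detection is monotone in sensitivity by
# construction.
emit_calls <- function(truth, sensitivity, jitter_sd, min_len, fp_rate,
                       shift = 0L, strict_min = FALSE) {
  segs <- truth$segments
  n <- nrow(segs)
  chrom_len <- truth$spec$chromosomes
  u_emit <- stats::runif(n)
  jit <- matrix(round(stats::rnorm(2 * n, 0, jitter_sd)), ncol = 2)
  if (shift != 0L) {
    segs$total_cn <- pmax(0, segs$total_cn + shift)
    segs$loh <- !is.na(segs$minor_cn) & segs$minor_cn == 0 &
      segs$total_cn == 2
    segs$cnv_type <- classify_call(segs$total_cn, segs$loh, segs$minor_cn)
  }
  len <- segs$end - segs$start
  sens <- rep(0, n)
  typed <- segs$cnv_type != "NEUTRAL"
  sens[typed] <- sensitivity[segs$cnv_type[typed]]
  long_enough <- if (strict_min) len >= min_len else len > min_len
  keep <- typed & long_enough & u_emit < sens
  out <- segs[keep, , drop = FALSE]
  if (nrow(out)) {
    cl <- chrom_len[out$chrom]
    out$start <- pmin(pmax(out$start + jit[keep, 1], 0), cl)
    out$end <- pmin(pmax(out$end + jit[keep, 2], 0), cl)
    out <- out[out$start < out$end, , drop = FALSE]
  }
  genome_len <- sum(chrom_len)
  n_fp <- stats::rpois(1, fp_rate * genome_len / 1e8)
  if (n_fp > 0) {
    fp_chrom <- sample(names(chrom_len), n_fp, replace = TRUE,
                       prob = chrom_len / genome_len)
    fp_len <- pmax(round(stats::rlnorm(n_fp, log(3e5), 0.6)), 1e3)
    fp_type <- sample(c("GAIN", "LOSS", "LOH"), n_fp, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
    fp_start <- floor(stats::runif(n_fp) *
                        pmax(chrom_len[fp_chrom] - fp_len, 1))
    fp_cn <- c(GAIN = 3, LOSS = 1, LOH = 2)[fp_type]
    fp_minor <- c(GAIN = 1, LOSS = 0, LOH = 0)[fp_type]
    fp <- cnv_calls(fp_chrom, fp_start,
                    pmin(fp_start + fp_len, chrom_len[fp_chrom]),
                    fp_cn, minor_cn = fp_minor, loh = fp_type == "LOH")
    out <- rbind(out[, names(fp), drop = FALSE], fp)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate one caller's call set on one replicate
#'
#' The noise channel: an optional global copy-number shift (the ploidy
#' mis-centering pathology) with subsequent re-typing, per-type dropout,
#' a minimum detectable length, rounded Gaussian breakpoint jitter clamped
#' to the chromosome (degenerate segments dropped), and Poisson false
#' segments. Neutral segments are never emitted. The RNG stream is derived
#' deterministically from (model seed, caller, center, replicate).
#'
#' @param truth A `truth_profile`.
#' @param model A `caller_model`.
#' @param caller,center,replicate Provenance identifiers.
#' @return A `cnv_callset`.
#' @export
simulate_callset <- function(truth, model, caller, center, replicate) {
  stopifnot(inherits(truth, "truth_profile"), inherits(model, "caller_model"))
  set.seed(stable_seed(model$seed, caller, center, replicate, "callset"))
  u_shift <- stats::runif(1)
  shift <- if (u_shift < model$ploidy_shift_prob) model$ploidy_shift_delta
  else 0L
  calls <- emit_calls(truth, model$sensitivity, model$breakpoint_jitter_sd,
                      model$min_detectable_length, model$fp_rate,
                      shift = shift)
  callset(calls, caller, center, replicate, platform = "WGS")
}

#' Simulate an orthogonal technology's call set
#'
#' Same channel as [simulate_callset()] minus the ploidy shift; segments
#' shorter than the minimum detectable length are never emitted.
#'
#' @param truth A `truth_profile`.
#' @param model An `orthogonal_model`.
#' @param technology Technology identifier.
#' @return An `orthogonal_callset`.
#' @export
simulate_orthogonal <- function(truth, model, technology) {
  stopifnot(inherits(truth, "truth_profile"),
            inherits(model, "orthogonal_model"))
  set.seed(stable_seed(model$seed, technology, "orthogonal"))
  calls <- emit_calls(truth, model$sensitivity, model$breakpoint_jitter_sd,
                      model$min_detectable_length, model$fp_rate,
                      strict_min = TRUE)
  orthogonal_callset(calls, technology)
}

#' Default caller noise models
#'
#' Six callers at 0.95 sensitivity for every type, one false call per
#' 100 Mb, 10 kb breakpoint jitter, and no ploidy failure. The first
#' caller has LOH sensitivity 0, mirroring a caller that does not report
#' LOH, so LOH consensus runs on five callers.
#'
#' @param seed Root seed shared by all models (streams are separated by
#'   caller name).
#' @param n_callers Number of callers (default 6).
#' @return Named list of `caller_model` objects.
#' @export
default_caller_models <- function(seed = 1L, n_callers = 6L) {
  models <- lapply(seq_len(n_callers), function(i) {
    sens <- c(GAIN = 0.95, LOSS = 0.95, LOH = if (i == 1L) 0 else 0.95)
    caller_model(sensitivity = sens, seed = seed)
  })
  names(models) <- sprintf("caller%d", seq_len(n_callers))
  models
}

#' Default orthogonal-technology models
#' @param seed Root seed.
#' @param n_tech Number of technologies (default 3).
#' @return Named list of `orthogonal_model` objects.
#' @export
default_orthogonal_models <- function(seed = 1L, n_tech = 3L) {
  models <- lapply(seq_len(n_tech), function(i) orthogonal_model(seed = seed))
  names(models) <- sprintf("tech%s", LETTERS[seq_len(n_tech)])
  models
}

#' Simulate a full cohort of caller-by-replicate call sets
#'
#' One call set per caller and replicate of the grouping scheme; under the
#' default scheme and six callers this yields 126 call sets. Deterministic
#' given the model seeds.
#'
#' @param truth A `truth_profile`.
#' @param models Named list of `caller_model` objects (names are caller
#'   ids).
#' @param grouping Grouping scheme data.frame.
#' @return A `cnv_cohort`.
#' @export
simulate_cohort <- function(truth, models = default_caller_models(),
                            grouping = default_grouping()) {
  callsets <- list()
  for (ca in names(models)) {
    for (i in seq_len(nrow(grouping))) {
      cs <- simulate_callset(truth, models[[ca]], ca,
                             grouping$center[i], grouping$replicate[i])
      callsets[[length(callsets) + 1L]] <- cs
    }
  }
  cohort(callsets, grouping)
}

#' Simulate the default orthogonal technologies
#' @param truth A `truth_profile`.
#' @param models Named list of `orthogonal_model` objects.
#' @return List of `orthogonal_callset` objects.
#' @export
simulate_orthogonal_set <- function(truth,
                                    models = default_orthogonal_models()) {
  lapply(names(models), function(te)
    simulate_orthogonal(truth, models[[te]], te))
}
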