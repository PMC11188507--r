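# Brute-force per-base membership oracle for interval algebra, independent
# of the package's GRanges-backed implementation. Coordinates live in a
# small space (3 chromosomes x 10 kb) so per-base logical vectors are cheap.

ORACLE_CHROMS <- c("chrA", "chrB", "chrC")
ORACLE_MAX <- 10000L

# 0-based half-open df -> list of per-base logical vectors (index b+1 = base b)
oracle_vec <- function(df) {
  v <- sapply(ORACLE_CHROMS, function(ch) logical(ORACLE_MAX),
              simplify = FALSE)
  for (i in seq_len(nrow(df))) {
    v[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  v
}

oracle_len <- function(v) sum(vapply(v, sum, numeric(1)))
oracle_and <- function(a, b) mapply(`&`, a, b, SIMPLIFY = FALSE)
oracle_or <- function(a, b) mapply(`|`, a, b, SIMPLIFY = FALSE)
oracle_diff <- function(a, b) mapply(function(x, y) x & !y, a, b,
                                     SIMPLIFY = FALSE)

# per-base coverage vector of a normalized GRanges, for comparison
gr_to_vec <- function(gr) oracle_vec(gr_to_df(gr))

rand_intervals <- function(n_max = 12L, allow_empty = TRUE) {
  n <- sample(if (allow_empty) 0:n_max else 1:n_max, 1)
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  chrom <- sample(ORACLE_CHROMS, n, replace = TRUE)
  start <- sample(0:(ORACLE_MAX - 2L), n, replace = TRUE)
  len <- sample(1:600, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = pmin(start + len, ORACLE_MAX), stringsAsFactors = FALSE)
}

rand_interval_set <- function(...) interval_set(rand_intervals(...))

# quick constructors for small call tables
calls_of <- function(chrom, start, end, cn, minor = NA_real_, loh = NA) {
  cnv_calls(chrom, start, end, cn, minor_cn = minor, loh = loh)
}

# a tiny grouping scheme for fast cohort tests: two centers, one with a
# divisor, mirroring the structure (not the size) of the default scheme
tiny_grouping <- function() {
  data.frame(
    center = c("X", "X", "Y", "Y", "Y"),
    replicate = c("1", "2", "1", "2", "3"),
    group = c(1L, 1L, 2L, 2L, 2L),
    divisor = c(1, 1, 3, 3, 3)
  )
}

# a grouping that can reach strong evidence with four callers: four
# triplicate centers, divisor 1, so a caller's cumulative score tops at 12
quad_grouping <- function() {
  data.frame(
    center = rep(c("P", "Q", "R", "S"), each = 3),
    replicate = rep(as.character(1:3), 4),
    group = rep(1:4, each = 3),
    divisor = 1
  )
}

# build a cohort from a list of per-callset GAIN call tables
gain_cohort <- function(tables, callers, grouping) {
  idx <- 0L
  callsets <- list()
  for (ca in callers) {
    for (i in seq_len(nrow(grouping))) {
      idx <- idx + 1L
      callsets[[idx]] <- callset(tables[[idx]], ca,
                                 grouping$center[i], grouping$replicate[i])
    }
  }
  cohort(callsets, grouping)
}
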