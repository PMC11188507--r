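test_that("group contributions follow the divisor scheme", {
  g <- default_grouping()
  expect_equal(nrow(g), 21L)
  expect_equal(sum(g$group == 4L), 9L)

  sup <- setNames(rep(FALSE, 21), replicate_ids(g))
  expect_equal(caller_cumulative_score(sup, g), 0)

  # two of three replicates in one center
  sup2 <- sup; sup2[c("FD_1", "FD_2")] <- TRUE
  expect_equal(caller_cumulative_score(sup2, g), 2)

  # full support across all groups: 3 + 3 + 3 + 9/3 + 3
  expect_equal(caller_cumulative_score(!sup, g), 15)

  # nine-replicate group is down-weighted by 3
  sup3 <- sup; sup3[paste0("NS_", 1:9)] <- TRUE
  expect_equal(caller_cumulative_score(sup3, g), 3)
  sup4 <- sup; sup4[paste0("NS_", 1:4)] <- TRUE
  expect_equal(caller_cumulative_score(sup4, g), 4 / 3)

  bad <- c(sup, ZZ_1 = FALSE)
  expect_error(caller_cumulative_score(bad, g), "ZZ_1")
})

test_that("cumulative-to-converted mapping reproduces every bin", {
  expect_equal(convert_cumulative(0:15),
               c(0, 0, 0, 0, 1, 1, 1, 2, 2, 2, 3, 3, 3, 3, 3, 3))
  # fractional scores fall in the same bins
  expect_equal(convert_cumulative(c(1 / 3, 3 + 1 / 3, 6 + 2 / 3, 9 + 1 / 3)),
               c(0, 1, 2, 3))
  expect_error(convert_cumulative(16), "\\[0, 15\\]")
  expect_error(convert_cumulative(-1), "\\[0, 15\\]")
})

test_that("gain/loss confidence scale reproduces every bin", {
  conf <- assign_confidence_gain_loss(0:18)
  expect_equal(as.character(conf),
               c("NONE", rep("NEUTRAL", 3), rep("WEAK", 4),
                 rep("MEDIUM", 3), rep("STRONG", 8)))
  expect_true(is.ordered(conf))
  expect_error(assign_confidence_gain_loss(19), "\\[0, 18\\]")
})

test_that("LOH confidence scale keeps strong strictly above 8", {
  conf <- assign_confidence_loh(0:15)
  expect_equal(as.character(conf),
               c("NONE", rep("NEUTRAL", 3), rep("WEAK", 2),
                 rep("MEDIUM", 3), rep("STRONG", 7)))
  # the stated gaps close downward: 8 -> MEDIUM, 3 -> NEUTRAL
  expect_equal(as.character(assign_confidence_loh(8)), "MEDIUM")
  expect_equal(as.character(assign_confidence_loh(3)), "NEUTRAL")
  expect_error(assign_confidence_loh(16), "\\[0, 15\\]")
})

test_that("scores and confidence are monotone in replicate support", {
  g <- default_grouping()
  ids <- replicate_ids(g)
  set.seed(21)
  for (i in 1:30) {
    sup <- setNames(runif(21) < 0.4, ids)
    cum <- caller_cumulative_score(sup, g)
    off <- which(!sup)
    if (!length(off)) next
    sup2 <- sup; sup2[sample(off, 1)] <- TRUE
    cum2 <- caller_cumulative_score(sup2, g)
    expect_gte(cum2, cum)
    expect_gte(convert_cumulative(cum2), convert_cumulative(cum))
  }
  # confidence is monotone along each scale
  expect_true(!is.unsorted(assign_confidence_gain_loss(0:18)))
  expect_true(!is.unsorted(assign_confidence_loh(0:15)))
})

test_that("cohort scoring composes partition, scores, and confidence", {
  g <- tiny_grouping()
  # two callers, 5 replicates each; all replicates call the same gain
  seg <- cnv_calls("chr1", 1000, 5000, 3)
  tables <- replicate(10, seg, simplify = FALSE)
  ch <- gain_cohort(tables, c("c1", "c2"), g)
  sc <- score_cohort(ch, "GAIN")
  expect_equal(nrow(sc), 1L)
  # per caller: group1 2/1 + group2 3/3 = 3 cumulative -> converted 0
  expect_equal(sc$score_c1, 0L)
  expect_equal(sc$total_score, 0)
  expect_equal(as.character(sc$confidence), "NONE")

  # a single supporting replicate converts to 0 (cumulative 1)
  one <- c(list(seg), replicate(9, seg[0, ], simplify = FALSE))
  ch1 <- gain_cohort(one, c("c1", "c2"), g)
  sc1 <- score_cohort(ch1, "GAIN")
  expect_equal(sc1$total_score, 0)
  expect_equal(as.character(sc1$confidence), "NONE")

  # requesting a type nobody called yields an empty table
  expect_equal(nrow(score_cohort(ch, "LOSS")), 0L)
})

test_that("full agreement across the default cohort scores strong", {
  g <- default_grouping()
  seg <- cnv_calls("chr1", 0, 1e6, 3)
  tables <- replicate(6 * 21, seg, simplify = FALSE)
  ch <- gain_cohort(tables, paste0("c", 1:6), g)
  sc <- score_cohort(ch, "GAIN")
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$total_score, 18)
  expect_equal(as.character(sc$confidence), "STRONG")
  for (ca in paste0("c", 1:6)) expect_equal(sc[[paste0("score_", ca)]], 3L)
})

test_that("scoring is invariant to call-set order and conserves the union", {
  g <- tiny_grouping()
  set.seed(33)
  tables <- replicate(10, {
    n <- sample(1:4, 1)
    s <- sort(sample(seq(0, 9000, by = 100), n))
    cnv_calls("chr1", s, s + sample(100:800, n, replace = TRUE), 3)
  }, simplify = FALSE)
  ch <- gain_cohort(tables, c("c1", "c2"), g)
  sc <- score_cohort(ch, "GAIN")

  perm <- sample(length(ch$callsets))
  ch2 <- cohort(ch$callsets[perm], g)
  sc2 <- score_cohort(ch2, "GAIN")
  expect_equal(sc[, c("chrom", "start", "end", "total_score")],
               sc2[, c("chrom", "start", "end", "total_score")])

  # conservation: scored union equals union of typed inputs
  inputs <- lapply(ch$callsets, typed_regions, cnv_type = "GAIN")
  u <- Reduce(function(a, b) normalize_intervals(c(a, b)), inputs)
  scored_u <- interval_set(sc[, c("chrom", "start", "end")])
  expect_equal(intersect_length(u, scored_u), total_length(u))
  expect_equal(total_length(scored_u), total_length(u))
})

test_that("cohort scores match a per-base brute-force recomputation", {
  g <- tiny_grouping()
  set.seed(44)
  for (trial in 1:5) {
    tables <- replicate(10, {
      n <- sample(0:3, 1)
      if (n == 0) return(cnv_calls(character(0), numeric(0), numeric(0),
                                   numeric(0)))
      s <- sort(sample(seq(0, 8000, by = 50), n))
      cnv_calls("chr1", s, s + sample(50:1500, n, replace = TRUE), 3)
    }, simplify = FALSE)
    ch <- gain_cohort(tables, c("c1", "c2"), g)
    sc <- score_cohort(ch, "GAIN")

    # brute force: per base b, each supporting replicate contributes
    # 1/divisor to its caller's cumulative score, then convert and total
    div <- g$divisor
    vecs <- lapply(tables, function(tb) {
      v <- logical(ORACLE_MAX)
      for (i in seq_len(nrow(tb))) v[(tb$start[i] + 1):tb$end[i]] <- TRUE
      v
    })
    base_total <- numeric(ORACLE_MAX)
    for (cidx in 0:1) {
      cum <- numeric(ORACLE_MAX)
      for (r in 1:5) cum <- cum + vecs[[cidx * 5 + r]] / div[r]
      base_total <- base_total + convert_cumulative(cum)
    }
    # expand the scored table to per-base totals
    sc_total <- numeric(ORACLE_MAX)
    for (i in seq_len(nrow(sc))) {
      sc_total[(sc$start[i] + 1):sc$end[i]] <- sc$total_score[i]
    }
    expect_identical(sc_total, base_total)
  }
})

test_that("LOH scoring drops callers that never report LOH", {
  g <- tiny_grouping()
  loh_seg <- cnv_calls("chr1", 0, 2000, 2, minor_cn = 0)
  gain_seg <- cnv_calls("chr1", 0, 2000, 3)
  tables <- c(replicate(5, loh_seg, simplify = FALSE),
              replicate(5, gain_seg, simplify = FALSE))
  ch <- gain_cohort(tables, c("withLOH", "noLOH"), g)
  expect_warning(sc <- score_cohort(ch, "LOH"), "noLOH")
  expect_false("score_noLOH" %in% names(sc))
  expect_true("score_withLOH" %in% names(sc))
})

test_that("masking removes excluded bases before scoring", {
  g <- tiny_grouping()
  seg <- cnv_calls("chr1", 0, 1000, 3)
  tables <- replicate(10, seg, simplify = FALSE)
  ch <- gain_cohort(tables, c("c1", "c2"), g)
  mask <- exclusion_mask(interval_set("chr1", 200, 300))
  sc <- score_cohort(ch, "GAIN", mask = mask)
  scored_u <- interval_set(sc[, c("chrom", "start", "end")])
  expect_equal(intersect_length(scored_u, mask), 0)
  expect_equal(total_length(scored_u), 900)
})
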