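# helpers to build scored tables and orthogonal call sets by hand
mk_scored <- function(chrom, start, end, type, conf) {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   cnv_type = type, total_score = NA_real_,
                   confidence = factor(conf,
                                       levels = c("NONE", "NEUTRAL", "WEAK",
                                                  "MEDIUM", "STRONG"),
                                       ordered = TRUE),
                   stringsAsFactors = FALSE)
  class(df) <- c("scored_intervals", class(df))
  df
}

mk_tech <- function(name, chrom, start, end, type) {
  cn <- c(GAIN = 3, LOSS = 1, LOH = 2)[type]
  minor <- c(GAIN = 1, LOSS = 0, LOH = 0)[type]
  orthogonal_callset(cnv_calls(chrom, start, end, cn, minor_cn = minor,
                               loh = type == "LOH"), name)
}

test_that("validated length is per-base, same-type intersection", {
  iv <- interval_set("chr1", 0, 100)
  tech <- mk_tech("t1", "chr1", 50, 150, "GAIN")
  expect_equal(validated_length(iv, tech, "GAIN"), 50)
  expect_equal(validated_length(iv, tech, "LOSS"), 0)
  full <- mk_tech("t2", "chr1", 0, 200, "GAIN")
  expect_equal(validated_length(iv, full, "GAIN"), 100)
})

test_that("validation table applies the >=1 and >=2 technology rules", {
  sc <- mk_scored("chr1", 0, 100, "GAIN", "STRONG")
  t1 <- mk_tech("t1", "chr1", 0, 100, "GAIN")
  t2 <- mk_tech("t2", "chr1", 0, 100, "GAIN")
  t3 <- mk_tech("t3", "chr1", 500, 600, "GAIN")
  vt <- validation_table(sc, list(t1, t2, t3))
  strong <- vt[vt$confidence == "STRONG", ]
  expect_equal(strong$collapsed_mb, 100 / 1e6)
  expect_equal(strong$ge1_mb, 100 / 1e6)
  expect_equal(strong$ge2_mb, 100 / 1e6)
  expect_equal(strong$ge1_pct, 100)
  expect_equal(strong$ge2_pct, 100)

  # exactly one technology: ge1 full, ge2 zero
  vt1 <- validation_table(sc, list(t1, t3))
  s1 <- vt1[vt1$confidence == "STRONG", ]
  expect_equal(s1$ge1_mb, 100 / 1e6)
  expect_equal(s1$ge2_mb, 0)

  # no support at all
  vt0 <- validation_table(sc, list(t3))
  s0 <- vt0[vt0$confidence == "STRONG", ]
  expect_equal(s0$ge1_mb, 0)
  expect_equal(s0$ge1_pct, 0)
})

test_that("validation table invariants hold on random inputs", {
  set.seed(55)
  for (i in 1:8) {
    df <- rand_intervals(8, allow_empty = FALSE)
    df <- gr_to_df(interval_set(df))
    conf <- sample(c("STRONG", "MEDIUM", "WEAK", "NEUTRAL"), nrow(df),
                   replace = TRUE)
    sc <- mk_scored(df$chrom, df$start, df$end, "GAIN", conf)
    techs <- lapply(1:3, function(k) {
      d <- rand_intervals(6, allow_empty = FALSE)
      mk_tech(paste0("t", k), d$chrom, d$start, d$end, "GAIN")
    })
    vt <- validation_table(sc, techs)
    expect_true(all(vt$ge2_mb <= vt$ge1_mb + 1e-12))
    expect_true(all(vt$ge1_mb <= vt$collapsed_mb + 1e-12))
    per_tech <- rowSums(vt[, grep("_mb$", names(vt))[2:4]])
    expect_true(all(vt$ge1_mb <= per_tech + 1e-12))
    expect_true(all(vt$ge1_pct <= 100 + 1e-9))
  }
})

test_that("replicate clustering merges by proximity and size similarity", {
  # starts 1 kb apart, sizes 100 kb vs 60 kb (similarity 0.6): merged
  a <- cnv_calls(c("chr1", "chr1"), c(0, 1000), c(100000, 61000), c(3, 3))
  m <- cluster_nonredundant(a)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 500)  # median of the two starts

  # sizes 100 kb vs 40 kb (similarity 0.4): not merged
  b <- cnv_calls(c("chr1", "chr1"), c(0, 1000), c(100000, 41000), c(3, 3))
  expect_equal(nrow(cluster_nonredundant(b)), 2L)

  # positions farther apart than the proximity threshold: not merged
  d <- cnv_calls(c("chr1", "chr1"), c(0, 20000), c(100000, 115000), c(3, 3))
  expect_equal(nrow(cluster_nonredundant(d)), 2L)

  # different types never merge
  e <- cnv_calls(c("chr1", "chr1"), c(0, 1000), c(100000, 101000), c(3, 1))
  expect_equal(nrow(cluster_nonredundant(e)), 2L)

  # singleton passes through
  one <- cnv_calls("chr1", 0, 5000, 3)
  expect_equal(cluster_nonredundant(one), one)
})

test_that("replicate clustering is idempotent", {
  set.seed(66)
  for (i in 1:5) {
    n <- sample(3:10, 1)
    s <- sample(seq(0, 5e6, by = 1e3), n)
    calls <- cnv_calls("chr1", s, s + sample(5e4:2e5, n, replace = TRUE),
                       sample(c(1, 3), n, replace = TRUE))
    once <- cluster_nonredundant(calls)
    twice <- cluster_nonredundant(once)
    expect_equal(twice, once)
  }
})

test_that("conflict resolution removes only unsupported opposite-type bases", {
  gain <- scored_gr <- df_to_gr(data.frame(chrom = "chr1", start = 0,
                                           end = 100))
  S4Vectors::mcols(gain)$confidence <- "STRONG"
  loss0 <- GenomicRanges::GRanges()
  S4Vectors::mcols(loss0)$confidence <- character(0)

  # covered only by an orthogonal loss: removed
  res <- resolve_conflicts(gain, loss0,
                           list(mk_tech("t1", "chr1", 0, 100, "LOSS")))
  expect_equal(length(res$gain), 0L)
  expect_equal(res$removed$reason, "orthogonal_loss_only")

  # gain support from one tech outweighs loss calls from another: retained
  res2 <- resolve_conflicts(gain, loss0,
                            list(mk_tech("t1", "chr1", 0, 100, "LOSS"),
                                 mk_tech("t2", "chr1", 0, 100, "GAIN")))
  expect_equal(total_length(res2$gain), 100)
  expect_equal(nrow(res2$removed), 0L)

  # no orthogonal coverage: retained (the rule fires only on evidence)
  res3 <- resolve_conflicts(gain, loss0, list(mk_tech("t1", "chr2", 0,
                                                      100, "LOSS")))
  expect_equal(total_length(res3$gain), 100)

  # conservation: removed + kept lengths equal the input length
  res4 <- resolve_conflicts(gain, loss0,
                            list(mk_tech("t1", "chr1", 40, 60, "LOSS")))
  removed_len <- sum(res4$removed$end - res4$removed$start)
  expect_equal(total_length(res4$gain) + removed_len, 100)
})

test_that("breakpoint trimming keeps the orthogonally supported end", {
  mk_conf_gr <- function(start, end) {
    g <- df_to_gr(data.frame(chrom = "chr1", start = start, end = end))
    S4Vectors::mcols(g)$confidence <- "STRONG"
    g
  }
  gain <- mk_conf_gr(0, 120)
  loss <- mk_conf_gr(100, 200)

  # gain end supported: gain keeps [0,120), loss trimmed to [120,200)
  tr <- trim_breakpoints(gain, loss,
                         list(mk_tech("t1", "chr1", 90, 125, "GAIN")))
  expect_equal(gr_to_df(tr$gain)[, c("start", "end")],
               data.frame(start = 0, end = 120))
  expect_equal(gr_to_df(tr$loss)[, c("start", "end")],
               data.frame(start = 120, end = 200))
  expect_equal(tr$trim_log$outcome, "gain_end_retained")

  # mirror: loss end supported
  tr2 <- trim_breakpoints(gain, loss,
                          list(mk_tech("t1", "chr1", 90, 125, "LOSS")))
  expect_equal(gr_to_df(tr2$gain)$end, 100)
  expect_equal(gr_to_df(tr2$loss)$start, 100)

  # neither supported: midpoint split at 110
  tr3 <- trim_breakpoints(gain, loss, list(mk_tech("t1", "chr2", 0, 10,
                                                   "GAIN")))
  expect_equal(gr_to_df(tr3$gain)$end, 110)
  expect_equal(gr_to_df(tr3$loss)$start, 110)
  expect_match(tr3$trim_log$outcome, "midpoint")

  # non-overlapping intervals unchanged
  tr4 <- trim_breakpoints(mk_conf_gr(0, 50), mk_conf_gr(100, 200), list())
  expect_equal(gr_to_df(tr4$gain)$end, 50)
  expect_equal(nrow(tr4$trim_log), 0L)

  # no gain/loss overlap remains in any case
  for (t in list(tr, tr2, tr3, tr4)) {
    expect_equal(intersect_length(t$gain, t$loss), 0)
  }
})

test_that("benchmark assembly applies the confidence and technology rules", {
  sc_gain <- mk_scored(rep("chr1", 3), c(0, 1000, 2000),
                       c(500, 1500, 2500), "GAIN",
                       c("STRONG", "MEDIUM", "NEUTRAL"))
  t_all <- function(nm) mk_tech(nm, "chr1", 0, 3000, "GAIN")
  # strong kept without any tech support
  b0 <- assemble_benchmark(list(GAIN = sc_gain),
                           techs = list(mk_tech("t1", "chr2", 0, 10,
                                                "GAIN")))
  expect_equal(b0$start, 0)
  expect_equal(b0$confidence, "STRONG")

  # medium kept only with >= 2 technologies
  b1 <- assemble_benchmark(list(GAIN = sc_gain), techs = list(t_all("t1")))
  expect_false(1000 %in% b1$start)
  b2 <- assemble_benchmark(list(GAIN = sc_gain),
                           techs = list(t_all("t1"), t_all("t2")))
  expect_true(1000 %in% b2$start)
  expect_equal(sort(b2$tech_support),
               sort(c("t1,t2", "t1,t2")))

  # neutral always dropped, even with full support
  b3 <- assemble_benchmark(list(GAIN = sc_gain),
                           techs = list(t_all("t1"), t_all("t2"),
                                        t_all("t3")))
  expect_false(2000 %in% b3$start)

  # no technologies: strong-only benchmark
  b4 <- assemble_benchmark(list(GAIN = sc_gain), techs = list())
  expect_equal(nrow(b4), 1L)
  expect_equal(b4$confidence, "STRONG")
})

test_that("assembled benchmark attaches the cohort median copy number", {
  g <- tiny_grouping()
  tables <- lapply(1:5, function(i) cnv_calls("chr1", 0, 1000, 2 + i))
  ch <- gain_cohort(tables, "c1", g)
  sc <- mk_scored("chr1", 0, 1000, "GAIN", "STRONG")
  b <- assemble_benchmark(list(GAIN = sc), techs = list(), ch = ch)
  expect_equal(b$median_cn, 5)  # median of 3,4,5,6,7
})

test_that("gain and loss regions are disjoint after assembly", {
  set.seed(77)
  truth <- simulate_truth(seed = 77)
  models <- default_caller_models(seed = 77, n_callers = 4)
  grouping <- quad_grouping()
  ch <- simulate_cohort(truth, models, grouping)
  techs <- simulate_orthogonal_set(truth, default_orthogonal_models(77, 2))
  scored <- list(GAIN = score_cohort(ch, "GAIN"),
                 LOSS = score_cohort(ch, "LOSS"))
  b <- assemble_benchmark(scored, techs, ch)
  expect_equal(intersect_length(typed_regions(b, "GAIN"),
                                typed_regions(b, "LOSS")), 0)
})
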