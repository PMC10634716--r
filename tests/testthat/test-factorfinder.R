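test_that("quadrant counting partitions reads by strand and side", {
  c0 <- 1000L
  pos <- c(c0 - 10L, c0 + 12L, c0 + 3L)
  strand <- c("+", "-", "+")
  expect_equal(quadrant_counts(pos, strand, c0, 100L),
               c(n1 = 1L, n2 = 1L, n3 = 0L, n4 = 1L))
  expect_equal(quadrant_counts(integer(0), character(0), c0, 100L),
               c(n1 = 0L, n2 = 0L, n3 = 0L, n4 = 0L))
  expect_error(quadrant_counts(pos, strand, c0, 0L), "w must be > 0")
  # reads exactly at the center are downstream (Q1/Q4)
  expect_equal(quadrant_counts(c(c0, c0), c("+", "-"), c0, 50L),
               c(n1 = 1L, n2 = 0L, n3 = 0L, n4 = 1L))
  # reads outside the window are ignored
  expect_equal(quadrant_counts(c(c0 - 101L, c0 + 101L), c("+", "-"),
                               c0, 100L),
               c(n1 = 0L, n2 = 0L, n3 = 0L, n4 = 0L))
})

test_that("statistic formula, sentinels, cap and symmetry", {
  expect_equal(ff_statistic(1, 10, 1, 8), 3)      # log2(8/1)
  expect_equal(ff_statistic(3, 3, 3, 3), 0)
  expect_equal(ff_statistic(0, 6, 0, 4), 5)       # capped at grid top
  expect_equal(ff_statistic(1, 0, 1, 8), -Inf)    # needs pile-up in BOTH
  expect_equal(ff_statistic(1, 8, 1, 0), -Inf)
  expect_equal(ff_statistic(0, 0, 0, 0), -Inf)
  # clipping of very large finite ratios
  expect_equal(ff_statistic(1, 100, 1, 100), 5)

  set.seed(12)
  for (i in 1:50) {
    n <- sample.int(30L, 4, TRUE) - 1L
    s0 <- ff_statistic(n[1], n[2], n[3], n[4])
    expect_identical(s0, ff_statistic(n[3], n[4], n[1], n[2]))  # n1<->n3, n2<->n4
    expect_identical(s0, ff_statistic(n[1], n[4], n[3], n[2]))  # n2<->n4
    expect_identical(s0, ff_statistic(n[3], n[2], n[1], n[4]))  # n1<->n3
  }
})

test_that("null table is reproducible, monotone, and sub-certain at 0", {
  t1 <- suppressWarnings(build_null_table(5L, 8L, reps = 2e4, seed = 9L))
  t2 <- suppressWarnings(build_null_table(5L, 8L, reps = 2e4, seed = 9L))
  expect_identical(t1$surv, t2$surv)
  # enrichment (stat >= 0) is never certain under the null
  expect_true(all(t1$surv[, 1] < 1))
  # survival non-increasing along the grid in every row
  for (r in seq_len(nrow(t1$surv))) {
    expect_true(all(diff(t1$surv[r, ]) <= 0))
  }
  expect_warning(build_null_table(5L, 5L, reps = 1e4, seed = 1L),
                 "reps < 1e5")
})

test_that("null table serialization round-trips", {
  tab <- tiny_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_null_table(tab, f)
  back <- read_null_table(f)
  expect_equal(back$n_min, tab$n_min)
  expect_equal(back$n_max, tab$n_max)
  expect_equal(back$reps, tab$reps)
  expect_equal(back$seed, tab$seed)
  expect_equal(max(abs(back$surv - tab$surv)), 0)
})

test_that("p-value lookup: row binning, sentinels, floor, monotonicity", {
  tab <- tiny_table()
  # N above n_max reuses the n_max row
  expect_equal(ff_pvalue(2, 600L, tab), ff_pvalue(2, tab$n_max, tab))
  # N below n_min is untestable
  expect_true(is.na(ff_pvalue(2, 4L, tab)))
  # (3,3,3,3): stat 0 -> the largest p the test can assign to enrichment
  s <- ff_statistic(3, 3, 3, 3)
  expect_equal(ff_pvalue(s, 12L, tab),
               unname(tab$surv[12L - tab$n_min + 1L, 1]))
  # negative statistic -> p = 1
  expect_equal(ff_pvalue(-0.5, 20L, tab), 1)
  expect_equal(ff_pvalue(-Inf, 20L, tab), 1)
  # floored at 1/reps
  expect_gte(ff_pvalue(5, 60L, tab), 1 / tab$reps)
  # for fixed N, p non-increasing in the statistic
  set.seed(2)
  for (N in c(10L, 40L)) {
    st <- sort(runif(50, 0, 5))
    p <- ff_pvalue(st, N, tab)
    expect_true(all(diff(p) <= 0))
  }
})

test_that("peak calling finds a planted footprint and nothing in noise", {
  tab <- tiny_table()
  cp <- caller_params(p_threshold = 1e-4)  # within tiny table resolution
  ct <- footprint_contacts(50000L, n = 25L)
  pk <- call_peaks(ct, tab, cp)
  expect_equal(nrow(pk), 1L)
  expect_lte(abs(pk$summit - 50000L), 20L)
  expect_true(pk$summit >= pk$start && pk$summit < pk$end)

  # no reads -> no peaks
  expect_equal(nrow(call_peaks(footloop:::empty_contacts(), tab, cp)), 0L)

  # uniform noise: no calls expected at this threshold on ~1e5 windows
  noise <- simulate_null_region(5e5, 1e5, seed = 31L)
  pk0 <- call_peaks(noise, tab, caller_params(p_threshold = 1e-5))
  expect_lte(nrow(pk0), 2L)
})

test_that("uniform reads give equal mean quadrant counts", {
  noise <- simulate_null_region(2e6, 4e5, seed = 17L)
  tab <- tiny_table()
  centers <- data.frame(chrom = "chrN",
                        center = seq(500L, 2e6 - 500L, by = 400L))
  win <- scan_windows(noise, tab, caller_params(), centers = centers)
  mn <- c(mean(win$n1), mean(win$n2), mean(win$n3), mean(win$n4))
  expect_true(all(abs(mn / mean(mn) - 1) < 0.02))
})

test_that("motif p/q assignment: nearest window, ties, 1 kb cutoff, BH", {
  motifs <- as_motifs(data.frame(
    chrom = "chr1", start = c(100L, 300L, 5000L),
    end = c(119L, 319L, 5019L), strand = "+"))
  win <- data.table::data.table(
    chrom = "chr1", center = c(109L, 309L, 312L),
    pvalue = c(0.01, 0.02, 0.03))
  mq <- assign_motif_qvalues(motifs, win)
  expect_equal(mq$pvalue, c(0.01, 0.02, 1))  # third motif: no window in 1 kb
  expect_equal(mq$qvalue, p.adjust(c(0.01, 0.02, 1), "BH"))

  # equidistant windows -> the smaller p wins
  m2 <- as_motifs(data.frame(chrom = "chr1", start = 191L, end = 210L,
                             strand = "+"))  # center 200
  w2 <- data.table::data.table(chrom = "chr1", center = c(150L, 250L),
                               pvalue = c(1e-3, 1e-6))
  expect_equal(assign_motif_qvalues(m2, w2)$pvalue, 1e-6)

  # BH closed form: {0.01, 0.02, 0.03} with m = 3 -> all 0.03
  m3 <- as_motifs(data.frame(chrom = "chr1",
                             start = c(100L, 200L, 300L),
                             end = c(119L, 219L, 319L), strand = "+"))
  w3 <- data.table::data.table(chrom = "chr1", center = c(109L, 209L, 309L),
                               pvalue = c(0.01, 0.02, 0.03))
  expect_equal(assign_motif_qvalues(m3, w3)$qvalue, rep(0.03, 3))
})

test_that("BH agrees with the step-up definition on random p-vectors", {
  set.seed(22)
  for (i in 1:100) {
    p <- runif(sample.int(40L, 1) + 1L)^sample(c(1, 2, 4), 1)
    expect_equal(p.adjust(p, "BH"), bh_manual(p))
  }
})

test_that("precision/recall bookkeeping matches the definitions", {
  truth <- data.frame(chrom = "chr1",
                      center = seq(1000L, 10000L, by = 1000L))
  # summits on 9 truths plus one stray
  pk <- data.table::data.table(chrom = "chr1",
                               summit = c(truth$center[1:9] + 3L, 500000L))
  pr <- evaluate_pr(pk, truth)
  expect_equal(pr$tp, 9L)
  expect_equal(pr$fp, 1L)
  expect_equal(pr$fn, 1L)
  expect_equal(pr$precision, 0.9)
  expect_equal(pr$recall, 0.9)

  pk2 <- data.table::data.table(chrom = "chr1", summit = truth$center)
  pr2 <- evaluate_pr(pk2, truth)
  expect_equal(c(pr2$precision, pr2$recall), c(1, 1))

  expect_error(evaluate_pr(pk, truth[0, ]), "empty truth")
  expect_error(evaluate_pr(pk, truth, truth), "overlap")
})
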