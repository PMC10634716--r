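test_that("P(s) curve: single-bin input, normalization, power-law slope", {
  ct <- make_contacts("c", rep(0L, 100L), "+", 50L,
                      "c", rep(50000L, 100L), "-", 50L)
  pc <- ps_curve(ct)
  expect_equal(sum(pc$count > 0), 1L)
  expect_true(pc$s_lo[pc$count > 0] <= 50000 &&
                pc$s_hi[pc$count > 0] > 50000)
  expect_equal(sum(pc$freq * (pc$s_hi - pc$s_lo)), 1)

  set.seed(5)
  s <- as.integer(r_powerlaw(2e5, 1e4, 1e6))
  ct2 <- make_contacts("c", rep(0L, length(s)), "+", 50L,
                       "c", s, "+", 50L)
  pc2 <- ps_curve(ct2, s_min = 1e4, s_max = 1e6)
  fit <- lm(log10(freq) ~ log10(s_mid), data = pc2[pc2$freq > 0, ])
  expect_lt(abs(unname(coef(fit)[2]) + 1), 0.05)

  trans <- make_contacts("a", 0L, "+", 50L, "b", 50000L, "+", 50L)
  expect_error(ps_curve(trans), "no cis contacts")
})

test_that("fully extruded fraction: formula, min-frag filter, duplication
           invariance", {
  # one '+' CBS with 100 TF fragments, 10 of them convergent
  cbs <- make_motif("chr1", 9991L, 10010L, "+")  # center 10000
  minus <- data.frame(chrom = "chr1", start = 60000L, end = 60019L,
                      strand = "-", score = 1)
  motifs <- rbind(data.frame(chrom = "chr1", start = 9991L, end = 10010L,
                             strand = "+", score = 1), minus)
  n <- 100L
  partner_pos <- c(rep(60009L, 10L), seq(150000L, by = 1000L,
                                         length.out = n - 10L))
  ct <- make_contacts("chr1", rep(9980L, n), "+", rep(45L, n),
                      "chr1", partner_pos, "+", rep(40L, n))
  est <- fully_extruded_fraction(ct, cbs, motifs)
  expect_equal(est$point, 5)          # 10/100 * 0.5 * 100
  expect_equal(est$n_fragments, 100L)
  expect_equal(est$n_convergent, 10L)

  # duplicating every contact leaves the ratio estimator unchanged
  est2 <- fully_extruded_fraction(rbind(ct, ct), cbs, motifs)
  expect_equal(est2$point, est$point)

  # a site below min_frags is dropped from the site-level range
  cbs2 <- as_motifs(rbind(
    data.frame(chrom = "chr1", start = 9991L, end = 10010L, strand = "+",
               score = 1),
    data.frame(chrom = "chr1", start = 999991L, end = 1000010L,
               strand = "+", score = 1)))
  ct49 <- make_contacts("chr1", rep(999980L, 49L), "+", rep(45L, 49L),
                        "chr1", seq(1150000L, by = 1000L, length.out = 49L),
                        "+", rep(40L, 49L))
  est3 <- fully_extruded_fraction(rbind(ct, ct49), cbs2, motifs)
  expect_equal(nrow(est3$per_cbs), 1L)

  # no qualifying '+' sites is an error
  expect_error(fully_extruded_fraction(ct, make_motif("chr1", 9991L,
                                                      10010L, "-"), motifs),
               "'\\+' strand")
})

test_that("region annotation matches a brute-force per-bp oracle", {
  # deterministic toy: 10 kb windows on a small segmented chromosome
  set.seed(30)
  seg_start <- seq(0L, 49000L, by = 1000L)
  seg <- data.frame(chrom = "chr1", start = seg_start,
                    end = seg_start + 1000L,
                    state = sample(paste0("E", 1:4), 50L, TRUE))
  cbs <- as_motifs(data.frame(chrom = "chr1",
                              start = c(4991L, 29991L),
                              end = c(5010L, 30010L),
                              strand = c("+", "-")))
  ann <- annotate_region(cbs, seg, window_size = 10000)
  for (i in 1:2) {
    w0 <- ann$regions$start[i]; w1 <- ann$regions$end[i]
    bp <- w0:(w1 - 1L)
    st <- rep(NA_character_, length(bp))
    for (j in seq_len(nrow(seg))) {
      inside <- bp >= seg$start[j] & bp < seg$end[j]
      st[inside] <- seg$state[j]
    }
    for (s in colnames(ann$fractions)) {
      expect_equal(unname(ann$fractions[i, s]),
                   sum(st == s, na.rm = TRUE) / length(bp))
    }
  }
  # '+' window extends right of the center, '-' window left
  expect_equal(ann$regions$start[1], cbs$center[1])
  expect_equal(ann$regions$end[2], cbs$center[2])

  # single-state segmentation -> fraction 1
  seg1 <- data.frame(chrom = "chr1", start = 0L, end = 100000L,
                     state = "E9")
  a1 <- annotate_region(cbs[1], seg1, window_size = 10000)
  expect_equal(unname(a1$fractions[1, "E9"]), 1)

  # two 500 bp peaks in the window -> 1000 covered bp; 3 pol2 peaks counted
  k27 <- data.frame(chrom = "chr1", start = c(6000L, 8000L),
                    end = c(6500L, 8500L))
  pol2 <- data.frame(chrom = "chr1", start = c(6000L, 8000L, 9000L),
                     end = c(6300L, 8300L, 9300L))
  a2 <- annotate_region(cbs[1], seg1, k27, pol2, window_size = 10000)
  expect_equal(a2$regions$k27ac_bp, 1000L)
  expect_equal(a2$regions$pol2_n, 3L)

  # windows past the chromosome end are truncated and flagged
  a3 <- annotate_region(cbs[1], seg1, window_size = 10000,
                        chrom_sizes = c(chr1 = 8000))
  expect_true(a3$regions$truncated[1])
  expect_equal(a3$regions$end[1], 8000L)
})

test_that("state grouping: manual quantiles, auto clustering, tie rule", {
  # manual map: region at 95% quiescent with cutoff below it is a member
  f <- matrix(0, 10, 2, dimnames = list(NULL, c("Sq", "Sa")))
  f[, "Sq"] <- c(0.95, seq(0.1, 0.9, length.out = 9))
  f[, "Sa"] <- 1 - f[, "Sq"]
  gs <- group_states(f, mapping = c(Sq = "quiescent", Sa = "active"))
  expect_true(gs$top_members[1, "quiescent"])
  expect_equal(sum(gs$top_members[, "quiescent"]), 2L)  # ceiling(0.2*10)

  # three blocks of perfectly correlated states recover the planted groups
  set.seed(41)
  n <- 60L
  fr <- matrix(runif(n * 9, 0, 0.02), n, 9,
               dimnames = list(NULL, paste0("S", 1:9)))
  grp <- rep(1:3, each = 20L)
  for (i in seq_len(n)) {
    fr[i, (grp[i] - 1L) * 3L + 1:3] <- runif(3, 0.2, 0.3)
  }
  auto <- group_states(fr)
  planted <- rep(1:3, each = 3)
  expect_equal(length(unique(auto$state_groups)), 3L)
  # states of the same planted block always co-cluster, and every region
  # is assigned the group its block's states define
  for (b in 1:3) {
    expect_equal(length(unique(auto$state_groups[planted == b])), 1L)
    expect_equal(length(unique(auto$region_group[grp == b])), 1L)
  }

  # identical regions: membership falls to the lowest indices
  same <- matrix(rep(c(0.5, 0.5), each = 10), 10, 2,
                 dimnames = list(NULL, c("A", "B")))
  g2 <- group_states(same, mapping = c(A = "x", B = "y"))
  expect_equal(which(g2$top_members[, "x"]), 1:2)

  expect_error(group_states(matrix(1, 5, 2,
                                   dimnames = list(NULL, c("A", "B")))),
               "at least 3")
})

test_that("loop size per stratum: point values and monotonicity", {
  cbs <- make_motif("chr1", 9991L, 10010L, "+")
  ct <- make_contacts("chr1", rep(9980L, 50L), "+", rep(45L, 50L),
                      "chr1", rep(9980L + 100000L, 50L), "+", NA_integer_)
  ls <- loop_size_by_stratum(ct, cbs, "only")
  expect_equal(ls$mean_log10, 5)
  expect_equal(ls$kb, 100)
  expect_equal(ls$n, 50L)

  # single fragment
  ls1 <- loop_size_by_stratum(ct[1], cbs, "solo")
  expect_equal(ls1$mean_log10, log10(interaction_length(ct[1])))

  # stochastically larger lengths give a larger estimate
  cbs2 <- as_motifs(data.frame(
    chrom = "chr1", start = c(9991L, 509991L), end = c(10010L, 510010L),
    strand = "+"))
  set.seed(6)
  sA <- as.integer(10^rnorm(200, 4.8, 0.2))
  sB <- as.integer(10^rnorm(200, 5.4, 0.2))
  ctA <- make_contacts("chr1", rep(9980L, 200L), "+", 45L,
                       "chr1", 9980L + sA, "+", NA_integer_)
  ctB <- make_contacts("chr1", rep(509980L, 200L), "+", 45L,
                       "chr1", 509980L + sB, "+", NA_integer_)
  ls2 <- loop_size_by_stratum(rbind(ctA, ctB), cbs2, c("A", "B"))
  expect_gt(ls2$mean_log10[ls2$stratum == "B"],
            ls2$mean_log10[ls2$stratum == "A"])

  # empty stratum omitted with a warning
  expect_warning(
    loop_size_by_stratum(ctA, cbs2, c("A", "B")), "omitted")
})

test_that("cohesin effect: exact two-site case and degenerate input", {
  # two sites; at each, TF fragments at 10^5 and nucleosome at 10^4.5
  cbs <- as_motifs(data.frame(
    chrom = "chr1", start = c(9991L, 509991L), end = c(10010L, 510010L),
    strand = "+"))
  one_site <- function(center) {
    tf <- make_contacts("chr1", rep(center - 20L, 10L), "+", 45L,
                        "chr1", center + 100000L + 0:9, "+", NA_integer_)
    nuc <- make_contacts("chr1", rep(center - 70L, 10L), "+", NA_integer_,
                         "chr1", center + as.integer(10^4.5) + 0:9, "+",
                         NA_integer_)
    rbind(tf, nuc)
  }
  ct <- rbind(one_site(10000L), one_site(510000L))
  ce <- cohesin_effect(ct, cbs)
  expect_equal(ce$effect, 0.5, tolerance = 0.01)
  expect_equal(nrow(ce$per_cbs), 2L)

  # TF fragments only -> no site has both classes
  tf_only <- make_contacts("chr1", rep(9980L, 10L), "+", 45L,
                           "chr1", 9980L + 100000L + 0:9, "+", NA_integer_)
  expect_error(cohesin_effect(tf_only, cbs), "both classes")
})

test_that("strand-dependent windows mirror under global strand flip", {
  sim <- tiny_sim()
  motifs <- sim$truth$motifs[1:30]
  flipped <- data.table::copy(motifs)
  flipped[, strand := ifelse(strand == "+", "-", "+")]
  seg <- sim$truth$segmentation
  a1 <- annotate_region(motifs, seg, window_size = 5e4)
  a2 <- annotate_region(flipped, seg, window_size = 5e4)
  plus <- motifs$strand == "+"
  # '+' windows become left-extending windows ending at the center
  expect_equal(a2$regions$end[plus], motifs$center[plus])
  expect_equal(a1$regions$start[plus], motifs$center[plus])
})
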