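test_that("metaplot counts per-offset fragment overlap, strand-oriented", {
  m <- make_motif("chrT", 991L, 1010L, "+")  # center 1000
  ct <- make_contacts("chrT", 980L, "+", 40L, "chrT", 90000L, "+",
                      NA_integer_)  # fragment [980, 1020)
  prof <- coverage_metaplot(ct, m, flank = 30L,
                            length_breaks = c(0, Inf))
  expect_equal(nrow(prof), 61L)
  on <- prof$offset >= -20L & prof$offset <= 19L
  expect_true(all(prof$coverage[on] == 1))
  expect_true(all(prof$coverage[!on] == 0))

  # same fragment at a '-' motif appears mirrored
  m2 <- make_motif("chrT", 991L, 1010L, "-")
  prof2 <- coverage_metaplot(ct, m2, flank = 30L,
                             length_breaks = c(0, Inf))
  expect_equal(prof2$coverage, rev(prof$coverage))

  # zero contacts -> all-zero profile
  prof0 <- coverage_metaplot(footloop:::empty_contacts(), m, flank = 10L)
  expect_true(all(prof0$coverage == 0))
})

test_that("metaplot mass equals total clipped overlap width", {
  sim <- tiny_sim()
  sub <- sim$contacts[1:2000]
  motifs <- sim$truth$motifs[1:40]
  flank <- 100L
  prof <- coverage_metaplot(sub, motifs, flank = flank,
                            length_breaks = c(0, Inf))
  # brute-force oracle: loop over fragments x motifs, sum overlap widths
  sides <- contact_sides(sub)
  total <- 0L
  for (k in seq_len(nrow(motifs))) {
    lo <- motifs$center[k] - flank
    hi <- motifs$center[k] + flank
    ov <- pmin(sides$frag_end - 1L, hi) - pmax(sides$frag_start, lo) + 1L
    total <- total + sum(pmax(ov, 0L))
  }
  expect_equal(sum(prof$coverage), total)
})

test_that("footprint difference: symmetry, degenerate flank, antisymmetry", {
  sym <- data.frame(offset = -50:50, coverage = dnorm(-50:50, 0, 20))
  expect_true(all(footprint_difference(sym)$diff == 0))

  expect_equal(nrow(footprint_difference(
    data.frame(offset = 0L, coverage = 5))), 0L)

  # flipping all motif strands exactly negates the difference profile
  sim <- tiny_sim()
  motifs <- sim$truth$motifs[1:50]
  flipped <- data.table::copy(motifs)
  flipped[, strand := ifelse(strand == "+", "-", "+")]
  p1 <- coverage_metaplot(sim$contacts, motifs, flank = 80L,
                          length_breaks = c(0, Inf))
  p2 <- coverage_metaplot(sim$contacts, flipped, flank = 80L,
                          length_breaks = c(0, Inf))
  d1 <- footprint_difference(p1)
  d2 <- footprint_difference(p2)
  expect_equal(d2$diff, -d1$diff)
})

test_that("long-fragment profile shows ~200 bp nucleosome phasing", {
  sim <- tiny_sim()
  prof <- coverage_metaplot(sim$contacts, sim$truth$motifs, flank = 500L)
  lng <- prof[prof$length_bin == "(120,Inf]", ]
  ac <- acf(lng$coverage, lag.max = 280L, plot = FALSE)$acf
  peak_lag <- which.max(ac[150:280]) + 148L
  expect_true(abs(peak_lag - 200L) <= 10L)
})

test_that("RAD21 stratification: quantiles, distance cutoff, ties", {
  n <- 100L
  motifs <- as_motifs(data.frame(
    chrom = "chr1", start = seq(10000L, by = 5000L, length.out = n),
    end = seq(10019L, by = 5000L, length.out = n), strand = "+"))
  peaks <- data.frame(chrom = "chr1", start = motifs$center - 50L,
                      end = motifs$center + 50L,
                      signal_value = as.numeric(1:n))
  st <- stratify_rad21(motifs, peaks)
  q75 <- quantile(1:n, 0.75)  # 75.25
  expect_equal(which(st == "HIGH"), which(1:n >= q75))
  expect_equal(which(st == "LOW"), which(1:n <= quantile(1:n, 0.25)))

  # peak 60 bp away from the motif center -> unassigned
  m1 <- make_motif("chr1", 991L, 1010L, "+")
  far <- data.frame(chrom = "chr1", start = 1061L, end = 1200L,
                    signal_value = 99)
  expect_equal(stratify_rad21(m1, far), "UNASSIGNED")

  # all signals equal: strict quantile rule leaves everything unassigned
  eq <- data.frame(chrom = "chr1", start = motifs$center - 50L,
                   end = motifs$center + 50L, signal_value = 7)
  expect_true(all(stratify_rad21(motifs, eq) == "UNASSIGNED"))
})

test_that("cohesin footprint appears only in the upstream/high stratum", {
  sim <- tiny_sim()
  st <- stratify_rad21(sim$truth$motifs, sim$truth$rad21_peaks)
  # strata recover the planted cohesin status where assigned
  coh <- sim$truth$motifs$cohesin
  expect_true(all(coh[st == "HIGH"]))
  expect_true(all(!coh[st == "LOW"]))

  fp <- cohesin_footprint(sim$contacts, sim$truth$motifs, st)
  d <- fp$difference
  up_high <- d[d$orientation == "UPSTREAM_FRAGMENT" & d$rad21 == "HIGH", ]
  lo <- d[d$rad21 == "LOW", ]
  # strong positive downstream excess in the planted stratum...
  expect_gt(mean(up_high$diff[up_high$offset <= 60]), 50)
  # ...and nothing comparable where no footprint was planted
  if (nrow(lo)) {
    expect_lt(abs(mean(lo$diff[lo$offset <= 60])),
              mean(up_high$diff[up_high$offset <= 60]) / 10)
  }

  # removing long-range contacts empties every stratum
  cis_short <- sim$contacts[abs(pos2 - pos1) < 5000L]
  fp0 <- cohesin_footprint(cis_short, sim$truth$motifs, st)
  expect_equal(nrow(fp0$coverage), 0L)
  expect_equal(length(fp0$empty_strata), 4L)
})
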