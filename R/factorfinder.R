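#' Peak caller parameters
#'
#' @param halfwidth Window half-width w in bp (default 100): short-fragment
#'   enrichment at bound CTCF motifs is confined to roughly +/-100 bp.
#' @param step Candidate-center step in bp (default 1 for full resolution).
#' @param min_reads Minimum windowed read count to test (default 5, the null
#'   table's smallest row).
#' @param p_threshold Significance threshold (default 1e-05).
#' @param merge_gap Retained windows closer than this are merged into one
#'   peak (default 30 bp, the summit-matching scale).
#' @return List of class `caller_params`.
#' @export
caller_params <- function(halfwidth = 100L, step = 1L, min_reads = 5L,
                          p_threshold = 1e-05, merge_gap = 30L) {
  stopifnot(halfwidth > 0L, step >= 1L, min_reads >= 1L,
            p_threshold > 0, p_threshold < 1, merge_gap >= 0L)
  structure(list(halfwidth = as.integer(halfwidth), step = as.integer(step),
                 min_reads = as.integer(min_reads),
                 p_threshold = p_threshold,
                 merge_gap = as.integer(merge_gap)),
            class = "caller_params")
}

#' Quadrant read counts around a candidate center
#'
#' Reads (5' ends of observed-ligation, i.e. short-fragment, sides) within
#' `center +/- w` are partitioned by strand and side:
#' Q2 = `+` strand upstream (`pos5 < center`), Q1 = `+` strand downstream
#' (`pos5 >= center`), Q3 = `-` strand upstream, Q4 = `-` strand downstream.
#' A read exactly at the center counts as downstream (Q1/Q4), a fixed
#' deterministic tie rule.
#'
#' @param pos5 Read 5' positions.
#' @param strand Read strands (`+`/`-`).
#' @param center Candidate center (single position).
#' @param w Window half-width (bp, > 0).
#' @return Named integer vector `c(n1, n2, n3, n4)`.
#' @export
quadrant_counts <- function(pos5, strand, center, w) {
  if (w <= 0) stop("window half-width w must be > 0")
  keep <- abs(pos5 - center) <= w
  pos5 <- pos5[keep]; strand <- strand[keep]
  up <- pos5 < center
  c(n1 = sum(strand == "+" & !up), n2 = sum(strand == "+" & up),
    n3 = sum(strand == "-" & up), n4 = sum(strand == "-" & !up))
}

#' The quadrant enrichment statistic
#'
#' `log2(min(n2, n4) / max(n1, n3))`. TF binding piles reads into *both* Q2
#' and Q4 while depleting Q1/Q3; taking min over the enriched quadrants and
#' max over the depleted ones requires pile-up on both flanks, so a
#' single-sided pile-up cannot score. If `min(n2, n4) == 0` the site is not
#' enriched and the statistic is `-Inf`; if `max(n1, n3) == 0` with a
#' positive numerator the statistic is capped at the grid top (5.0). All
#' values are clipped to at most 5.0.
#'
#' @param n1,n2,n3,n4 Quadrant counts (vectors, recycled).
#' @return Numeric vector of `log2` statistics in `[-Inf, 5]`.
#' @export
ff_statistic <- function(n1, n2, n3, n4) {
  num <- pmin(n2, n4)
  den <- pmax(n1, n3)
  stat <- ifelse(num == 0, -Inf,
                 ifelse(den == 0, 5, log2(num / den)))
  pmin(stat, 5)
}

FF_GRID <- seq(0, 5, by = 0.01)

# Snap statistics DOWN onto the grid (conservative p). Returns the 1-based
# grid index, or NA for stat < 0 (including -Inf).
ff_grid_index <- function(stat) {
  idx <- floor(stat * 100 + 1e-9) + 1L
  idx[stat < 0 | is.infinite(stat) & stat < 0] <- NA_integer_
  pmin(idx, length(FF_GRID))
}

#' Build the Monte-Carlo multinomial null table
#'
#' Under the null, each read falls in any of the four quadrants with equal
#' probability 1/4. For every total read count `N` in `n_min..n_max`, `reps`
#' multinomial samples are drawn and the empirical survival function of
#' `log2` statistic values is evaluated on the grid `0.00..5.00` (step
#' 0.01). Read counts above `n_max` reuse the `n_max` row at lookup time.
#'
#' @param n_min,n_max Read-count range of the table (defaults 5, 500).
#' @param reps Simulations per read count (default 1e6; at least 1e5
#'   recommended -- smaller values are recorded as `low_reps` in the table
#'   metadata).
#' @param seed RNG seed; two tables built with the same seed are identical.
#' @return Object of class `ff_null_table`: list with `grid`, `surv`
#'   (matrix, rows = read counts `n_min..n_max`, columns = grid points,
#'   entries = P(statistic >= grid value)), `n_min`, `n_max`, `reps`,
#'   `seed`, `low_reps`.
#' @export
build_null_table <- function(n_min = 5L, n_max = 500L, reps = 1e6,
                             seed = 1L) {
  stopifnot(n_min >= 1L, n_max >= n_min, reps >= 1)
  low_reps <- reps < 1e5
  if (low_reps) {
    warning("reps < 1e5: null tail estimates will be coarse ",
            "(recorded in table metadata)")
  }
  ns <- n_min:n_max
  surv <- matrix(0, nrow = length(ns), ncol = length(FF_GRID),
                 dimnames = list(N = ns, NULL))
  set.seed(seed)
  for (k in seq_along(ns)) {
    x <- rmultinom(reps, ns[k], rep(0.25, 4))
    stat <- ff_statistic(x[1, ], x[2, ], x[3, ], x[4, ])
    idx <- ff_grid_index(stat)
    counts <- tabulate(idx[!is.na(idx)], nbins = length(FF_GRID))
    # snapping down means: P(stat >= grid[g]) = P(snapped index >= g)
    surv[k, ] <- rev(cumsum(rev(counts))) / reps
  }
  structure(list(grid = FF_GRID, surv = surv, n_min = as.integer(n_min),
                 n_max = as.integer(n_max), reps = reps,
                 seed = as.integer(seed), low_reps = low_reps),
            class = "ff_null_table")
}

#' @export
print.ff_null_table <- function(x, ...) {
  cat("ff_null_table: N in", x$n_min, "..", x$n_max, ",", x$reps,
      "reps per N, seed", x$seed,
      if (x$low_reps) "(low reps)" else "", "\n")
  invisible(x)
}

#' Write / read a null table as annotated TSV
#'
#' Plain-text serialization with `#key: value` metadata lines so a table can
#' be rebuilt bit-for-bit or shipped between runs.
#'
#' @param table `ff_null_table`.
#' @param path Output path.
#' @return `path` (write) / `ff_null_table` (read).
#' @export
write_null_table <- function(table, path) {
  writeLines(sprintf("#%s: %s", c("n_min", "n_max", "reps", "seed"),
                     c(table$n_min, table$n_max,
                       format(table$reps, scientific = FALSE),
                       table$seed)), path)
  dt <- as.data.table(table$surv)
  setnames(dt, as.character(seq_along(table$grid)))
  dt <- cbind(N = table$n_min:table$n_max, dt)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_null_table
#' @export
read_null_table <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- as.list(setNames(
    sub("^#[a-z_]+: *", "", hdr),
    sub("^#([a-z_]+):.*", "\\1", hdr)))
  dt <- fread(path, sep = "\t", header = FALSE, skip = length(hdr))
  surv <- as.matrix(dt[, -1])
  dimnames(surv) <- list(N = dt[[1]], NULL)
  structure(list(grid = FF_GRID, surv = surv,
                 n_min = as.integer(meta$n_min),
                 n_max = as.integer(meta$n_max),
                 reps = as.numeric(meta$reps),
                 seed = as.integer(meta$seed),
                 low_reps = as.numeric(meta$reps) < 1e5),
            class = "ff_null_table")
}

#' P-values for observed quadrant statistics
#'
#' The observed `log2` statistic is snapped *down* to the grid
#' (conservative) and looked up in the survival row for `min(N, n_max)`;
#' read counts of 500+ behave like 500. Statistics below 0 (including the
#' `-Inf` not-enriched sentinel) give p = 1. P-values are floored at
#' `1/reps` to avoid zeros from a finite null. Read counts below `n_min`
#' are untestable and return `NA` (no-test sentinel).
#'
#' @param stat Observed `log2` statistic(s) from [ff_statistic()].
#' @param N Total read count(s).
#' @param table [build_null_table()] output.
#' @return Numeric vector of p-values in `(0, 1]`, `NA` where `N < n_min`.
#' @export
ff_pvalue <- function(stat, N, table) {
  stopifnot(inherits(table, "ff_null_table"))
  n <- pmax(length(stat), length(N))
  stat <- rep_len(stat, n); N <- rep_len(N, n)
  p <- rep(NA_real_, n)
  testable <- N >= table$n_min
  row <- pmin(N, table$n_max) - table$n_min + 1L
  gi <- ff_grid_index(stat)
  below <- testable & is.na(gi)
  p[below] <- 1
  ok <- testable & !is.na(gi)
  if (any(ok)) {
    p[ok] <- table$surv[cbind(row[ok], gi[ok])]
    p[ok] <- pmax(p[ok], 1 / table$reps)
  }
  p
}

# Observed-ligation read 5' ends usable for peak calling, per chromosome.
# Both sides of a contact contribute.
short_fragment_reads <- function(contacts) {
  dt <- as.data.table(contacts)
  reads <- rbindlist(list(
    dt[obs_lig1 == TRUE, .(chrom = chrom1, pos5 = pos1, strand = strand1)],
    dt[obs_lig2 == TRUE, .(chrom = chrom2, pos5 = pos2, strand = strand2)]
  ))
  setkey(reads, chrom, pos5)
  reads
}

# count of sorted positions `sp` falling in [lo, hi], vectorized over lo/hi
.count_in <- function(sp, lo, hi) {
  findInterval(hi, sp) - findInterval(lo - 1L, sp)
}

#' Evaluate sliding windows genome-wide
#'
#' Computes quadrant counts, the statistic and its p-value for candidate
#' window centers. By default candidates are every `step` bp position whose
#' windowed read count reaches `min_reads`; an explicit `centers` table
#' (columns `chrom`, `center`) overrides this.
#'
#' @param contacts Contacts table; only observed-ligation sides contribute
#'   reads.
#' @param table [build_null_table()] output.
#' @param params [caller_params()].
#' @param centers Optional `data.frame(chrom, center)` of explicit centers.
#' @return `data.table(chrom, center, n1, n2, n3, n4, N, stat, pvalue)`.
#' @export
scan_windows <- function(contacts, table, params = caller_params(),
                         centers = NULL) {
  reads <- short_fragment_reads(contacts)
  if (nrow(reads) == 0L) {
    return(data.table(chrom = character(), center = integer(),
                      n1 = integer(), n2 = integer(), n3 = integer(),
                      n4 = integer(), N = integer(), stat = numeric(),
                      pvalue = numeric()))
  }
  w <- params$halfwidth
  out <- vector("list", 0L)
  for (ch in unique(reads$chrom)) {
    r <- reads[chrom == ch]
    pos_all <- sort(r$pos5)
    pos_p <- sort(r[strand == "+", pos5])
    pos_m <- sort(r[strand == "-", pos5])
    if (is.null(centers)) {
      lo <- max(0L, pos_all[1] - w)
      hi <- pos_all[length(pos_all)] + w
      cand <- seq.int(lo, hi, by = params$step)
      keep <- .count_in(pos_all, cand - w, cand + w) >= params$min_reads
      cand <- cand[keep]
    } else {
      cand <- as.integer(centers$center[centers$chrom == ch])
    }
    if (length(cand) == 0L) next
    n2 <- .count_in(pos_p, cand - w, cand - 1L)
    n1 <- .count_in(pos_p, cand, cand + w)
    n3 <- .count_in(pos_m, cand - w, cand - 1L)
    n4 <- .count_in(pos_m, cand, cand + w)
    dt <- data.table(chrom = ch, center = cand, n1 = n1, n2 = n2, n3 = n3,
                     n4 = n4, N = n1 + n2 + n3 + n4)
    dt[, stat := ff_statistic(n1, n2, n3, n4)]
    dt[, pvalue := ff_pvalue(stat, N, table)]
    out[[length(out) + 1L]] <- dt
  }
  rbindlist(out)
}

#' Call TF binding-site peaks
#'
#' Windows significant at `p_threshold` are merged when their centers lie
#' within `merge_gap` bp; each merged run becomes one peak. The summit is
#' the middle window of the run of maximal-statistic windows: on a clean
#' footprint the statistic plateaus across the protected span, and the
#' plateau midpoint estimates the motif center.
#'
#' @inheritParams scan_windows
#' @return `data.table` of peaks: `chrom, start, end, summit, stat, N,
#'   pvalue, qvalue` (`qvalue` = BH across called peaks; `summit` in
#'   `[start, end)`).
#' @export
call_peaks <- function(contacts, table, params = caller_params()) {
  win <- scan_windows(contacts, table, params)
  sig <- win[!is.na(pvalue) & pvalue < params$p_threshold]
  if (nrow(sig) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), summit = integer(), stat = numeric(),
                      N = integer(), pvalue = numeric(), qvalue = numeric()))
  }
  setorder(sig, chrom, center)
  sig[, peak_id := cumsum(c(1L, (diff(center) > params$merge_gap) |
                                 (chrom[-1] != chrom[-.N])))]
  peaks <- sig[, {
    mx <- max(stat)
    cand <- center[stat == mx]
    smt <- cand[ceiling(length(cand) / 2)]
    i <- which(center == smt)[1]
    .(start = center[1], end = center[.N] + 1L, summit = smt,
      stat = mx, N = N[i], pvalue = pvalue[i])
  }, by = .(chrom, peak_id)]
  peaks[, peak_id := NULL]
  peaks[, qvalue := p.adjust(pvalue, method = "BH")]
  peaks[]
}

#' Assign per-motif p- and q-values from sliding windows
#'
#' Each motif receives the p-value of the window whose center is closest to
#' the motif center (ties resolved to the smaller p). Motifs with no tested
#' window within `max_gap` bp are assigned p = 1. Benjamini-Hochberg across
#' all motifs yields q-values.
#'
#' @param motifs Motif table ([as_motifs()]).
#' @param windows [scan_windows()] output.
#' @param max_gap Maximum motif-to-window distance (default 1000 bp).
#' @return `motifs` with added columns `pvalue`, `qvalue`.
#' @export
assign_motif_qvalues <- function(motifs, windows, max_gap = 1000L) {
  m <- as_motifs(motifs)
  p <- rep(1, nrow(m))
  win <- as.data.table(windows)[!is.na(pvalue)]
  for (ch in unique(m$chrom)) {
    mi <- which(m$chrom == ch)
    wch <- win[chrom == ch]
    if (nrow(wch) == 0L) next
    setorder(wch, center, pvalue)
    ctr <- wch$center
    j <- findInterval(m$center[mi], ctr)
    jlo <- pmax(j, 1L); jhi <- pmin(j + 1L, length(ctr))
    dlo <- abs(m$center[mi] - ctr[jlo])
    dhi <- abs(m$center[mi] - ctr[jhi])
    dbest <- pmin(dlo, dhi)
    # candidate windows at the best distance on either side; tie -> min p
    pbest <- ifelse(dlo < dhi, wch$pvalue[jlo],
                    ifelse(dhi < dlo, wch$pvalue[jhi],
                           pmin(wch$pvalue[jlo], wch$pvalue[jhi])))
    # a run of equal centers can hide equal-distance duplicates; centers are
    # unique by construction of scan_windows, so the two neighbours suffice
    pbest[dbest > max_gap] <- 1
    p[mi] <- pbest
  }
  m[, pvalue := p]
  m[, qvalue := p.adjust(p, method = "BH")]
  m[]
}

#' Precision and recall of called peaks against a planted truth
#'
#' A truth positive is detected (TP) when a significant summit lies within
#' `match_dist` bp of its center; significant summits matching no positive
#' are false positives; unmatched positives are false negatives.
#'
#' @param peaks [call_peaks()] output (already thresholded).
#' @param truth_pos `data.frame(chrom, center)` of true binding sites.
#' @param truth_neg Optional `data.frame(chrom, center)` of decoys; checked
#'   for disjointness with `truth_pos` only.
#' @param match_dist Matching distance in bp (default 20).
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
evaluate_pr <- function(peaks, truth_pos, truth_neg = NULL,
                        match_dist = 20L) {
  tp_tab <- as.data.table(truth_pos)
  if (nrow(tp_tab) == 0L) stop("empty truth-positive set: PR undefined")
  if (!is.null(truth_neg) && nrow(as.data.table(truth_neg))) {
    both <- merge(tp_tab, as.data.table(truth_neg),
                  by = c("chrom", "center"))
    if (nrow(both)) stop("truth positive and negative sets overlap")
  }
  pk <- as.data.table(peaks)
  matched_pos <- logical(nrow(tp_tab))
  matched_summit <- logical(nrow(pk))
  for (ch in unique(tp_tab$chrom)) {
    ti <- which(tp_tab$chrom == ch)
    si <- which(pk$chrom == ch)
    if (length(si) == 0L) next
    s <- sort(pk$summit[si])
    d <- .nearest_dist(tp_tab$center[ti], s)
    matched_pos[ti] <- d <= match_dist
    tt <- sort(tp_tab$center[ti])
    ds <- .nearest_dist(pk$summit[si], tt)
    matched_summit[si] <- ds <= match_dist
  }
  tp <- sum(matched_pos)
  fp <- sum(!matched_summit)
  fn <- sum(!matched_pos)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = tp / (tp + fn), tp = tp, fp = fp, fn = fn)
}

# distance from each query to its nearest value in sorted vector `sv`
.nearest_dist <- function(q, sv) {
  if (length(sv) == 0L) return(rep(Inf, length(q)))
  j <- findInterval(q, sv)
  jlo <- pmax(j, 1L); jhi <- pmin(j + 1L, length(sv))
  pmin(abs(q - sv[jlo]), abs(q - sv[jhi]))
}

#' Summit-to-truth-center distances
#'
#' For each summit within `max_dist` of a truth center, the absolute
#' distance to the nearest center. Used for resolution summaries (median
#' distance, fraction within 20 bp).
#'
#' @param peaks [call_peaks()] output.
#' @param truth `data.frame(chrom, center)`.
#' @param max_dist Association radius (default 150 bp).
#' @return Numeric vector of distances (one per associated summit).
#' @export
summit_distances <- function(peaks, truth, max_dist = 150L) {
  pk <- as.data.table(peaks)
  tr <- as.data.table(truth)
  out <- numeric(0)
  for (ch in unique(pk$chrom)) {
    s <- pk$summit[pk$chrom == ch]
    tt <- sort(tr$center[tr$chrom == ch])
    if (length(s) == 0L || length(tt) == 0L) next
    d <- .nearest_dist(s, tt)
    out <- c(out, d[d <= max_dist])
  }
  out
}
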