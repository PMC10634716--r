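#' Fragment coverage metaplot around motif centers
#'
#' Per-offset fragment-overlap counts in a `+/- flank` window around motif
#' centers, summed over motifs and oriented by motif strand (positive
#' offsets are downstream of the motif). Fragments are binned by length;
#' censored fragments enter the top (read-length-scale) bin using the
#' nominal length `read_length` -- they are known to be at least that long
#' -- but never enter TF-class analyses.
#'
#' @param contacts Contacts table.
#' @param motifs Motif table ([as_motifs()]).
#' @param flank Half-window in bp (default 500).
#' @param length_breaks Numeric cut points for fragment-length bins
#'   (default `c(0, 80, 120, Inf)` giving short / mid / long strata).
#' @param params [class_params()].
#' @param sides Optional pre-filtered [contact_sides()]-style table (used
#'   internally for stratified footprints); when given, `contacts` is
#'   ignored.
#' @return `data.table(offset, length_bin, coverage)` with `offset` in
#'   `-flank..flank`; one row per offset per occupied bin (empty bins give
#'   zero rows only if no fragment of that bin exists at all).
#' @export
coverage_metaplot <- function(contacts, motifs, flank = 500L,
                              length_breaks = c(0, 80, 120, Inf),
                              params = class_params(), sides = NULL) {
  m <- as_motifs(motifs)
  L <- 2L * flank + 1L
  empty <- data.table(offset = integer(), length_bin = character(),
                      coverage = numeric())
  if (nrow(m) == 0L) return(empty)
  if (is.null(sides)) sides <- contact_sides(contacts, params)
  if (nrow(sides) == 0L) {
    return(data.table(offset = seq.int(-flank, flank),
                      length_bin = "all", coverage = 0))
  }
  len_nom <- fifelse(is.na(sides$frag_len),
                     params$read_length, sides$frag_len)
  bins <- cut(len_nom, breaks = length_breaks, include.lowest = TRUE)
  win <- data.table(chrom = m$chrom, wstart = m$center - flank,
                    wend = m$center + flank, center = m$center,
                    strand = m$strand)
  setkey(win, chrom, wstart, wend)
  qq <- data.table(chrom = sides$chrom, xstart = sides$frag_start,
                   xend = sides$frag_end - 1L, bin = as.character(bins))
  hits <- foverlaps(qq, win, by.x = c("chrom", "xstart", "xend"),
                    type = "any", nomatch = NULL)
  out <- vector("list", 0L)
  for (b in sort(unique(qq$bin))) {
    h <- hits[bin == b]
    cov <- numeric(L)
    if (nrow(h)) {
      # clip fragment to window, express as strand-oriented offsets
      a <- pmax(h$xstart, h$wstart) - h$center
      z <- pmin(h$xend, h$wend) - h$center
      minus <- h$strand == "-"
      a2 <- fifelse(minus, -z, a)
      z2 <- fifelse(minus, -a, z)
      i1 <- a2 + flank + 1L
      i2 <- z2 + flank + 1L
      delta <- tabulate(i1, nbins = L + 1L) -
        tabulate(i2 + 1L, nbins = L + 1L)
      cov <- cumsum(delta)[seq_len(L)]
    }
    out[[length(out) + 1L]] <- data.table(offset = seq.int(-flank, flank),
                                          length_bin = b, coverage = cov)
  }
  rbindlist(out)
}

#' Downstream-minus-upstream coverage difference
#'
#' For a motif-strand-oriented coverage profile, `diff[k] = coverage[+k] -
#' coverage[-k]` for `k = 1..flank`. A protein footprint on the downstream
#' (N-terminal, cohesin-stabilizing) side of CTCF shows as positive values
#' at small positive offsets.
#'
#' @param profile `data.frame(offset, coverage)` covering `-flank..flank`
#'   (one stratum).
#' @return `data.table(offset, diff)` with `offset = 1..flank`; empty when
#'   `flank = 0`.
#' @export
footprint_difference <- function(profile) {
  p <- as.data.table(profile)
  flank <- max(p$offset)
  stopifnot(min(p$offset) == -flank)
  if (flank == 0L) return(data.table(offset = integer(), diff = numeric()))
  cov <- p$coverage[match(seq.int(-flank, flank), p$offset)]
  k <- seq_len(flank)
  data.table(offset = k, diff = cov[flank + 1L + k] - cov[flank + 1L - k])
}

#' Stratify motifs by adjacent RAD21 ChIP signal
#'
#' Each motif is matched to the nearest RAD21 peak whose interval lies
#' within `max_dist` bp of the motif center. Matched motifs are `HIGH` when
#' their peak signal reaches the top quantile of matched-peak signals and
#' `LOW` in the bottom quantile; ties straddling both cutoffs (e.g. all
#' signals equal) are `UNASSIGNED`, keeping the HIGH and LOW sets disjoint.
#' Motifs without a peak within `max_dist` are `UNASSIGNED`.
#'
#' @param motifs Motif table.
#' @param rad21_peaks Interval table with a `signal_value` column.
#' @param q Quantile for the high/low cut (default 0.25: top/bottom 25%).
#' @param max_dist Maximum motif-center-to-peak distance (default 50 bp).
#' @return Character vector (`HIGH`/`LOW`/`UNASSIGNED`), one per motif.
#' @export
stratify_rad21 <- function(motifs, rad21_peaks, q = 0.25, max_dist = 50L) {
  m <- as_motifs(motifs)
  pk <- as.data.table(rad21_peaks)
  stopifnot(!is.null(pk$signal_value))
  sig <- rep(NA_real_, nrow(m))
  for (ch in unique(m$chrom)) {
    mi <- which(m$chrom == ch)
    pch <- pk[chrom == ch]
    if (nrow(pch) == 0L) next
    gm <- GenomicRanges::GRanges(ch, IRanges::IRanges(m$center[mi] + 1L,
                                                      m$center[mi] + 1L))
    gp <- GenomicRanges::GRanges(ch, IRanges::IRanges(pch$start + 1L,
                                                      pch$end))
    hit <- GenomicRanges::distanceToNearest(gm, gp)
    qh <- S4Vectors::queryHits(hit)
    ok <- S4Vectors::mcols(hit)$distance <= max_dist
    sig[mi[qh[ok]]] <- pch$signal_value[S4Vectors::subjectHits(hit)[ok]]
  }
  level <- rep("UNASSIGNED", nrow(m))
  matched <- !is.na(sig)
  if (any(matched)) {
    qs <- quantile(sig[matched], c(q, 1 - q), names = FALSE)
    hi <- matched & sig >= qs[2]
    lo <- matched & sig <= qs[1]
    level[hi & !lo] <- "HIGH"
    level[lo & !hi] <- "LOW"
  }
  level
}

#' Cohesin occupancy footprint by orientation and RAD21 stratum
#'
#' Builds downstream-minus-upstream differenced coverage profiles over
#' `+/- flank` bp around motif centers, separately for each combination of
#' partner orientation (upstream/downstream fragment) and RAD21 level
#' (high/low). Only mid-size fragments (`midsize_range`, approximating
#' joint CTCF+cohesin protection) with long-range cis partners
#' (`> longrange_min`) contribute; this isolates the extrusion-associated
#' footprint.
#'
#' @param contacts Contacts table.
#' @param motifs Motif table.
#' @param strata Character vector from [stratify_rad21()], one per motif.
#' @param params [class_params()].
#' @param flank Half-window (default 80 bp).
#' @return List with `coverage` (`data.table(orientation, rad21, offset,
#'   coverage)`), `difference` (`data.table(orientation, rad21, offset,
#'   diff)`), and `empty_strata` (character vector of strata with zero
#'   fragments).
#' @export
cohesin_footprint <- function(contacts, motifs, strata,
                              params = class_params(), flank = 80L) {
  m <- as_motifs(motifs)
  stopifnot(length(strata) == nrow(m))
  fam <- fragments_at_motifs(contacts, m, params)
  fam <- fam[obs_lig == TRUE &
               !is.na(frag_len) &
               frag_len >= params$midsize_range[1] &
               frag_len <= params$midsize_range[2] &
               !is.na(int_len) & int_len > params$longrange_min &
               !is.na(orientation)]
  fam[, level := strata[motif_id]]
  combos <- CJ(orientation = c("UPSTREAM_FRAGMENT", "DOWNSTREAM_FRAGMENT"),
               rad21 = c("HIGH", "LOW"))
  cov_out <- vector("list", 0L)
  diff_out <- vector("list", 0L)
  empty <- character(0)
  for (i in seq_len(nrow(combos))) {
    ori <- combos$orientation[i]; lev <- combos$rad21[i]
    sub <- fam[orientation == ori & level == lev]
    tag <- paste(ori, lev, sep = ":")
    if (nrow(sub) == 0L) {
      empty <- c(empty, tag)
      next
    }
    midx <- sort(unique(sub$motif_id))
    prof <- coverage_metaplot(NULL, m[motif_id %in% midx], flank = flank,
                              length_breaks = c(0, Inf), params = params,
                              sides = sub)
    prof <- prof[, .(coverage = sum(coverage)), by = offset]
    dif <- footprint_difference(prof)
    cov_out[[length(cov_out) + 1L]] <-
      data.table(orientation = ori, rad21 = lev, prof)
    diff_out[[length(diff_out) + 1L]] <-
      data.table(orientation = ori, rad21 = lev, dif)
  }
  list(coverage = rbindlist(cov_out), difference = rbindlist(diff_out),
       empty_strata = empty)
}
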