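#' Contact probability P(s) curve
#'
#' Cis contact frequency as a function of genomic separation `s`, on
#' log-spaced distance bins, normalized so that the integral over the
#' covered range is 1 (`sum(freq * binwidth) == 1`).
#'
#' @param contacts Contacts table (cis contacts with separation in
#'   `[s_min, s_max)` are used).
#' @param bins_per_decade Number of log10 bins per decade (default 20).
#' @param s_min,s_max Distance range in bp (defaults 1e3, 1e7).
#' @return `data.table(s_lo, s_hi, s_mid, count, freq)`; empty bins have
#'   `freq = 0`.
#' @export
ps_curve <- function(contacts, bins_per_decade = 20L, s_min = 1e3,
                     s_max = 1e7) {
  s <- interaction_length(contacts)
  s <- s[!is.na(s) & s >= s_min & s < s_max]
  if (length(s) == 0L) stop("no cis contacts in [s_min, s_max)")
  breaks <- 10^seq(log10(s_min), log10(s_max), by = 1 / bins_per_decade)
  idx <- findInterval(s, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  width <- diff(breaks)
  data.table(s_lo = head(breaks, -1L), s_hi = breaks[-1],
             s_mid = sqrt(head(breaks, -1L) * breaks[-1]),
             count = counts,
             freq = counts / sum(counts) / width)
}

#' Extrusion estimator parameters
#'
#' @param occupancy TF occupancy correction factor: convergence estimates
#'   are conditional on the focal site being bound, so they are multiplied
#'   by the occupancy (~50%, default 0.5) to obtain the unconditional
#'   loop frequency.
#' @param min_frags Minimum upstream TF-protected fragments per site for a
#'   site-level estimate (default 50).
#' @param pad Extra bp of slack when testing partner-fragment overlap with
#'   a convergent motif (default 0).
#' @return List of class `extrusion_params`.
#' @export
extrusion_params <- function(occupancy = 0.5, min_frags = 50L, pad = 0L) {
  stopifnot(occupancy > 0, occupancy <= 1, min_frags >= 1L, pad >= 0L)
  structure(list(occupancy = occupancy, min_frags = as.integer(min_frags),
                 pad = as.integer(pad)), class = "extrusion_params")
}

#' Genome-wide frequency of the fully extruded CTCF-CTCF state
#'
#' Fragments considered are TF-protected, upstream-oriented, long-range
#' (`> longrange_min`) fragments overlapping a bound CTCF site. A fragment
#' is *convergent* when its interaction partner's fragment overlaps an
#' opposite-strand CTCF motif on the downstream side of the site (for a
#' `+` site: a `-` motif at higher coordinate) -- the configuration of a
#' fully extruded convergent loop. The observed convergent fraction is
#' conditional on CTCF occupancy at the anchor and is multiplied by the
#' occupancy factor (default 0.5).
#'
#' The point estimate pools all qualifying fragments genome-wide; the
#' reported range is the 1st/99th percentile of site-level estimates over
#' sites with at least `min_frags` fragments.
#'
#' @param contacts Contacts table.
#' @param bound_cbs Bound CTCF sites (motif table; typically motifs
#'   significant at p < 1e-05, or an accepted BED input).
#' @param motifs All CTCF motifs genome-wide (convergence targets are drawn
#'   from the opposite-strand subset).
#' @param cparams [class_params()].
#' @param params [extrusion_params()].
#' @return List of class `extruded_state_estimate`: `point`, `range_lo`,
#'   `range_hi` (all in %), `n_fragments`, `n_convergent`, `per_cbs`
#'   (`data.table(motif_id, n_frags, n_conv, pct)`), `occupancy`,
#'   `min_frags`.
#' @export
fully_extruded_fraction <- function(contacts, bound_cbs, motifs,
                                    cparams = class_params(),
                                    params = extrusion_params()) {
  cbs <- as_motifs(bound_cbs)
  # the estimator is defined at '+' anchors (downstream '-' convergent
  # partner); '-' sites in the input are ignored rather than mirrored, so a
  # loop is never counted once from each of its two anchors
  cbs <- cbs[strand == "+"]
  if (nrow(cbs) == 0L) stop("no '+' strand sites in bound_cbs")
  mm <- as_motifs(motifs)
  fam <- fragments_at_motifs(contacts, cbs, cparams)
  fam <- fam[class == "TF_PROTECTED" &
               orientation == "UPSTREAM_FRAGMENT" &
               !is.na(int_len) & int_len > cparams$longrange_min]
  if (nrow(fam) == 0L) stop("no qualifying upstream TF-protected fragments")
  fam[, convergent := .partner_convergent(.SD, mm, params$pad)]
  per_cbs <- fam[, .(n_frags = .N, n_conv = sum(convergent)),
                 by = motif_id]
  total <- nrow(fam)
  conv <- sum(fam$convergent)
  point <- 100 * conv / total * params$occupancy
  eligible <- per_cbs[n_frags >= params$min_frags]
  if (nrow(eligible) == 0L) {
    stop("no site has >= ", params$min_frags,
         " qualifying fragments; cannot compute site-level range")
  }
  eligible[, pct := 100 * n_conv / n_frags * params$occupancy]
  rng <- quantile(eligible$pct, c(0.01, 0.99), names = FALSE)
  structure(list(point = point, range_lo = rng[1], range_hi = rng[2],
                 n_fragments = total, n_convergent = conv,
                 per_cbs = eligible[], occupancy = params$occupancy,
                 min_frags = params$min_frags),
            class = "extruded_state_estimate")
}

# Does each fragment's partner overlap an opposite-strand motif downstream
# of the focal site (in focal-motif-strand orientation)?
.partner_convergent <- function(fam, motifs, pad = 0L) {
  out <- logical(nrow(fam))
  for (ch in unique(fam$chrom)) {
    fi <- which(fam$chrom == ch & fam$partner_chrom == ch)
    if (length(fi) == 0L) next
    for (st in c("+", "-")) {
      ii <- fi[fam$motif_strand[fi] == st]
      if (length(ii) == 0L) next
      targets <- motifs[motifs$chrom == ch &
                          motifs$strand == (if (st == "+") "-" else "+"), ]
      if (nrow(targets) == 0L) next
      gq <- IRanges::IRanges(fam$partner_start[ii] + 1L - pad,
                             fam$partner_end[ii] + pad)
      gt <- IRanges::IRanges(targets$start + 1L, targets$end)
      ov <- IRanges::findOverlaps(gq, gt)
      if (length(ov) == 0L) next
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      downstream <- if (st == "+") {
        targets$center[sh] > fam$motif_center[ii][qh]
      } else {
        targets$center[sh] < fam$motif_center[ii][qh]
      }
      hit_q <- unique(qh[downstream])
      out[ii[hit_q]] <- TRUE
    }
  }
  out
}

#' @export
print.extruded_state_estimate <- function(x, ...) {
  cat(sprintf(
    "fully extruded state: %.2f%% genome-wide (site-level 1st-99th pct: %.2f-%.2f%%)\n",
    x$point, x$range_lo, x$range_hi))
  cat(sprintf("  %d convergent / %d fragments; occupancy factor %.2f; %d sites with >= %d fragments\n",
              x$n_convergent, x$n_fragments, x$occupancy, nrow(x$per_cbs),
              x$min_frags))
  invisible(x)
}

#' Annotate the 1 Mb extrusion window downstream of each site
#'
#' The window extends `window_size` bp downstream of the site center in
#' motif-strand orientation (right of `+` sites, left of `-` sites),
#' truncated (and flagged) at chromosome ends. Chromatin-state fractions
#' are base-pair overlap fractions of the window; covariates are the number
#' of base pairs covered by H3K27ac peaks (union) and the count of RNAPII
#' peaks overlapping the window.
#'
#' @param cbs Site table ([as_motifs()]).
#' @param segmentation ChromHMM-style `data.frame(chrom, start, end,
#'   state)` (gaps allowed).
#' @param peaks_k27ac,peaks_pol2 Interval tables (may be `NULL`).
#' @param window_size Window length (default 1e6 bp).
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   right-end truncation.
#' @return List: `regions` (`data.table(motif_id, chrom, start, end,
#'   strand, truncated, k27ac_bp, pol2_n)`) and `fractions` (matrix, rows =
#'   sites, columns = states, entries in `[0,1]`, row sums `<= 1`).
#' @export
annotate_region <- function(cbs, segmentation, peaks_k27ac = NULL,
                            peaks_pol2 = NULL, window_size = 1e6,
                            chrom_sizes = NULL) {
  m <- as_motifs(cbs)
  seg <- as.data.table(segmentation)
  if (is.null(seg$state)) {
    if (!is.null(seg$name)) seg[, state := name] else
      stop("segmentation needs a 'state' (or 'name') column")
  }
  win <- data.table(
    motif_id = m$motif_id, chrom = m$chrom, strand = m$strand,
    start = fifelse(m$strand == "+", m$center,
                    m$center - as.integer(window_size)),
    end = fifelse(m$strand == "+", m$center + as.integer(window_size),
                  m$center)
  )
  win[, truncated := start < 0L]
  win[start < 0L, start := 0L]
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[win$chrom]
    over <- !is.na(lim) & win$end > lim
    win[over, `:=`(end = as.integer(lim[over]), truncated = TRUE)]
  }
  states <- sort(unique(seg$state))
  frac <- matrix(0, nrow = nrow(win), ncol = length(states),
                 dimnames = list(NULL, states))
  gw <- GenomicRanges::GRanges(win$chrom,
                               IRanges::IRanges(win$start + 1L, win$end))
  gs <- GenomicRanges::GRanges(seg$chrom,
                               IRanges::IRanges(seg$start + 1L, seg$end))
  ov <- GenomicRanges::findOverlaps(gw, gs)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gw)[qh], IRanges::ranges(gs)[sh]))
    dd <- data.table(row = qh, state = seg$state[sh], w = w)
    agg <- dd[, .(w = sum(w)), by = .(row, state)]
    frac[cbind(agg$row, match(agg$state, states))] <-
      agg$w / (win$end - win$start)[agg$row]
  }
  win[, k27ac_bp := 0L]
  if (!is.null(peaks_k27ac) && nrow(as.data.table(peaks_k27ac))) {
    pk <- as.data.table(peaks_k27ac)
    gp <- GenomicRanges::reduce(GenomicRanges::GRanges(
      pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end)))
    ov <- GenomicRanges::findOverlaps(gw, gp)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(gw)[qh], GenomicRanges::ranges(gp)[sh]))
      agg <- data.table(row = qh, w = w)[, .(w = sum(w)), by = row]
      win[agg$row, k27ac_bp := agg$w]
    }
  }
  win[, pol2_n := 0L]
  if (!is.null(peaks_pol2) && nrow(as.data.table(peaks_pol2))) {
    pk <- as.data.table(peaks_pol2)
    gp <- GenomicRanges::GRanges(pk$chrom,
                                 IRanges::IRanges(pk$start + 1L, pk$end))
    cnt <- GenomicRanges::countOverlaps(gw, gp)
    win[, pol2_n := as.integer(cnt)]
  }
  list(regions = win[], fractions = frac)
}

#' Group chromatin states and select top-membership regions
#'
#' In `auto` mode, states are clustered into `k` groups by Ward
#' agglomerative clustering (`ward.D2`) on the distance `1 - Pearson
#' correlation` between state-fraction vectors across regions; a manual
#' `mapping` (named vector `state -> group`) overrides clustering. Each
#' region's group fraction is the sum of its member-state fractions; a
#' region belongs to a group's analysis set when its group fraction ranks
#' in the top `top_frac` (ties broken toward the lowest region index; the
#' sets of different groups may overlap and each is analyzed
#' independently).
#'
#' @param fractions Region x state fraction matrix ([annotate_region()]).
#' @param mapping Optional named character vector mapping states to groups.
#' @param k Number of clusters for auto mode (default 3).
#' @param top_frac Membership fraction (default 0.2).
#' @return List: `state_groups` (named vector state -> group label),
#'   `group_fractions` (region x group matrix), `region_group` (argmax
#'   group per region), `top_members` (logical region x group matrix).
#' @export
group_states <- function(fractions, mapping = NULL, k = 3L,
                         top_frac = 0.2) {
  stopifnot(is.matrix(fractions))
  states <- colnames(fractions)
  if (is.null(mapping)) {
    if (length(states) < k) {
      stop("auto clustering needs at least ", k, " distinct states")
    }
    cc <- suppressWarnings(cor(fractions))
    cc[is.na(cc)] <- 0
    hc <- hclust(as.dist(1 - cc), method = "ward.D2")
    cl <- cutree(hc, k = k)
    # label each cluster by its most prevalent state
    labs <- vapply(seq_len(k), function(g) {
      member <- states[cl == g]
      member[which.max(colMeans(fractions[, member, drop = FALSE]))]
    }, character(1))
    mapping <- setNames(paste0("grp_", labs[cl]), states)
  } else {
    miss <- setdiff(states, names(mapping))
    if (length(miss)) {
      stop("mapping is missing states: ", paste(miss, collapse = ", "))
    }
    mapping <- mapping[states]
  }
  groups <- unique(unname(mapping))
  gf <- vapply(groups, function(g) {
    rowSums(fractions[, states[mapping == g], drop = FALSE])
  }, numeric(nrow(fractions)))
  if (is.null(dim(gf))) gf <- matrix(gf, nrow = 1,
                                     dimnames = list(NULL, groups))
  n_top <- max(1L, ceiling(top_frac * nrow(gf)))
  top <- matrix(FALSE, nrow(gf), ncol(gf), dimnames = dimnames(gf))
  for (g in seq_len(ncol(gf))) {
    ord <- order(-gf[, g], seq_len(nrow(gf)))
    top[ord[seq_len(n_top)], g] <- TRUE
  }
  list(state_groups = mapping, group_fractions = gf,
       region_group = groups[max.col(gf, ties.method = "first")],
       top_members = top)
}

#' Extruded loop size per stratum
#'
#' The extruded-loop-size estimand is the mean log10 cis interaction length
#' of long-range TF-protected upstream fragments overlapping bound sites,
#' computed per stratum, with the kb back-transform `10^mean / 1000`.
#'
#' @param contacts Contacts table.
#' @param cbs Bound site table.
#' @param strata Either a character/factor vector of stratum labels (one
#'   per site, `NA` = unstratified) or a logical site x stratum membership
#'   matrix (overlapping memberships allowed, e.g. top-20% chromatin
#'   groups).
#' @param cparams [class_params()].
#' @param upstream_only Restrict to upstream-oriented fragments (default
#'   `TRUE`).
#' @return `data.table(stratum, n, mean_log10, se, kb)`; empty strata are
#'   omitted and recorded in the `omitted` attribute.
#' @export
loop_size_by_stratum <- function(contacts, cbs, strata,
                                 cparams = class_params(),
                                 upstream_only = TRUE) {
  m <- as_motifs(cbs)
  fam <- fragments_at_motifs(contacts, m, cparams)
  fam <- fam[class == "TF_PROTECTED" & !is.na(int_len) &
               int_len > cparams$longrange_min]
  if (upstream_only) fam <- fam[orientation == "UPSTREAM_FRAGMENT"]
  if (is.matrix(strata)) {
    stopifnot(nrow(strata) == nrow(m))
    labels <- colnames(strata)
    res <- vector("list", 0L)
    omitted <- character(0)
    for (g in labels) {
      sub <- fam[motif_id %in% which(strata[, g])]
      if (nrow(sub) == 0L) { omitted <- c(omitted, g); next }
      lg <- log10(sub$int_len)
      res[[length(res) + 1L]] <- data.table(
        stratum = g, n = nrow(sub), mean_log10 = mean(lg),
        se = sd(lg) / sqrt(nrow(sub)), kb = 10^mean(lg) / 1000)
    }
    out <- rbindlist(res)
  } else {
    stopifnot(length(strata) == nrow(m))
    fam[, stratum := as.character(strata[motif_id])]
    fam <- fam[!is.na(stratum)]
    out <- fam[, {
      lg <- log10(int_len)
      .(n = .N, mean_log10 = mean(lg), se = sd(lg) / sqrt(.N),
        kb = 10^mean(lg) / 1000)
    }, by = stratum]
    omitted <- setdiff(unique(stats::na.omit(as.character(strata))),
                       out$stratum)
  }
  if (length(omitted)) {
    warning("strata with zero fragments omitted: ",
            paste(omitted, collapse = ", "))
  }
  setattr(out, "omitted", omitted)
  out[]
}

#' Per-site cohesin effect on interaction length
#'
#' For each site with both TF-protected and nucleosome-protected fragments,
#' the difference in mean log10 cis interaction length (TF minus
#' nucleosome) estimates the increase in loop reach attributable to
#' CTCF/cohesin occupancy, controlling for the site's background contact
#' geography. The overall effect is the precision-weighted mean of per-site
#' differences: weights `w_i = 1 / (1/n_TF + 1/n_nuc)` with a pooled
#' within-site variance, `SE = sqrt(sigma2_pool / sum(w))`.
#'
#' @param contacts Contacts table.
#' @param cbs Bound site table.
#' @param cparams [class_params()].
#' @return List: `effect` (delta mean log10), `se`, `sigma2_pool`,
#'   `per_cbs` (`data.table(motif_id, n_tf, n_nuc, d)`).
#' @export
cohesin_effect <- function(contacts, cbs, cparams = class_params()) {
  m <- as_motifs(cbs)
  fam <- fragments_at_motifs(contacts, m, cparams)
  fam <- fam[class %in% c("TF_PROTECTED", "NUCLEOSOME") & !is.na(int_len) &
               int_len > 0]
  per <- fam[, {
    lt <- log10(int_len[class == "TF_PROTECTED"])
    ln <- log10(int_len[class == "NUCLEOSOME"])
    .(n_tf = length(lt), n_nuc = length(ln),
      d = mean(lt) - mean(ln),
      ss = sum((lt - mean(lt))^2) + sum((ln - mean(ln))^2))
  }, by = motif_id][n_tf >= 1L & n_nuc >= 1L]
  if (nrow(per) == 0L) {
    stop("no site has fragments of both classes; effect undefined")
  }
  df <- sum(pmax(per$n_tf - 1L, 0L) + pmax(per$n_nuc - 1L, 0L))
  sigma2 <- if (df > 0) sum(per$ss) / df else NA_real_
  w <- 1 / (1 / per$n_tf + 1 / per$n_nuc)
  effect <- sum(w * per$d) / sum(w)
  se <- sqrt(sigma2 / sum(w))
  list(effect = effect, se = se, sigma2_pool = sigma2,
       per_cbs = per[, .(motif_id, n_tf, n_nuc, d)])
}
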