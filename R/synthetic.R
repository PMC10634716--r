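#' Synthetic MNase HiChIP generator configuration
#'
#' Defines the study conditions the generator emulates: a bimodal fragment
#' length distribution (~30-60 bp TF-protected around bound motifs, ~147 bp
#' nucleosomal elsewhere), strand-specific 5'-end bimodality at bound
#' motifs, ~200 bp nucleosome phasing, observed-ligation censoring at
#' `read_length - min_mappable`, a power-law cis contact background, an
#' extruded long-range contact component whose log10 scale depends on
#' regional chromatin group, a plantable convergent CTCF-CTCF capture
#' fraction, and a plantable cohesin footprint downstream of
#' cohesin-positive motifs.
#'
#' @param n_bound,n_decoy Numbers of bound motifs and nucleosome-occupied
#'   decoy motifs (defaults 1000 each).
#' @param motif_spacing Mean motif spacing in bp (default 5000).
#' @param motif_width Motif width (default 19 bp, odd so the center is the
#'   middle base).
#' @param plus_frac Fraction of `+` strand motifs (default 0.5).
#' @param chrom Chromosome name of the simulated genome.
#' @param margin Motif-free margin at each genome end (default 25 kb).
#' @param occupancy Per-fragment probability that the motif is TF-occupied
#'   (theta, default 0.8).
#' @param depth_tf Expected TF-protected fragments per bound motif
#'   (default 50); total fragment depth is `depth_tf / occupancy`.
#' @param ctcf_protect TF-protected span (default 40 bp; with cut jitter
#'   this yields 40-60 bp fragments).
#' @param cut_jitter Maximum extra bp of MNase nibbling per fragment edge
#'   (uniform 0..`cut_jitter`, default 10).
#' @param nuc_len,nuc_spacing,nuc_jitter,nuc_slots Nucleosome length
#'   (147 bp), phasing period (200 bp), placement jitter SD, and number of
#'   phased positions on each side of the motif (default 2).
#' @param decoy_depth Expected nucleosomal fragments per decoy motif.
#' @param background_rate Fraction of all fragments that are uniform
#'   background cut noise (default 0.10).
#' @param read_length,min_mappable Read length (150) and minimum alignable
#'   bases (25); fragments longer than their difference are censored.
#' @param p_upstream Probability a motif fragment's partner lies downstream
#'   of the motif (i.e. the fragment is the upstream partner; default 0.5).
#' @param cohesin_frac Fraction of bound motifs that are cohesin-positive
#'   (default 0.5).
#' @param cohesin_ext Extra protection (bp) added on the downstream side of
#'   upstream-oriented TF fragments at cohesin-positive motifs (default 40;
#'   extended fragments fall in the 80-120 bp mid-size band).
#' @param convergent_capture Probability that an upstream TF fragment at a
#'   bound motif is captured in a fully extruded loop, its partner placed on
#'   a convergent opposite-strand bound motif downstream (default 0.10).
#' @param s_lo,s_hi Truncation range of the `s^-1` power-law background
#'   contact-distance model (defaults 1e3, 2e6).
#' @param extruded_sd SD of log10 distance for the extruded component
#'   (default 0.25).
#' @param group_log10_len Named vector of mean log10 extruded interaction
#'   length per chromatin group (defaults: active 5.16, polycomb 5.28,
#'   quiescent 5.40, i.e. ~145 kb / ~190 kb / ~250 kb).
#' @param region_len Length of constant-chromatin-group genome blocks
#'   (default 1 Mb).
#' @param seg_len ChromHMM segment length (default 2000 bp).
#' @param state_purity Probability a segment's state is drawn from its
#'   block group's own states (default 0.7).
#' @param cohesin_delta Optional planted class effect: when set, nucleosome
#'   fragments draw partners log-normally with mean
#'   `group mean - cohesin_delta` instead of from the power law.
#' @param cbs_intercept_sd SD of per-motif random intercepts on log10
#'   distance (default 0).
#' @param k27ac_rate,pol2_rate Named vectors: expected peaks per Mb per
#'   chromatin group.
#' @param k27ac_width,pol2_width Peak widths (bp).
#' @param seed RNG seed; fixes the entire output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_bound = 1000L, n_decoy = 1000L,
                       motif_spacing = 5000L, motif_width = 19L,
                       plus_frac = 0.5, chrom = "chrS", margin = 25000L,
                       occupancy = 0.8, depth_tf = 50,
                       ctcf_protect = 40L, cut_jitter = 10L,
                       nuc_len = 147L, nuc_spacing = 200L, nuc_jitter = 10,
                       nuc_slots = 2L, decoy_depth = 30,
                       background_rate = 0.10,
                       read_length = 150L, min_mappable = 25L,
                       p_upstream = 0.5, cohesin_frac = 0.5,
                       cohesin_ext = 40L, convergent_capture = 0.10,
                       s_lo = 1e3, s_hi = 2e6, extruded_sd = 0.25,
                       group_log10_len = c(active = 5.16, polycomb = 5.28,
                                           quiescent = 5.40),
                       region_len = 1e6, seg_len = 2000L,
                       state_purity = 0.7, cohesin_delta = NULL,
                       cbs_intercept_sd = 0,
                       k27ac_rate = c(active = 80, polycomb = 25,
                                      quiescent = 5),
                       pol2_rate = c(active = 60, polycomb = 15,
                                     quiescent = 3),
                       k27ac_width = 500L, pol2_width = 300L,
                       seed = 1L) {
  probs <- c(plus_frac, occupancy, background_rate, p_upstream,
             cohesin_frac, convergent_capture, state_purity)
  if (any(probs < 0 | probs > 1)) {
    stop("all probability parameters must lie in [0, 1]")
  }
  stopifnot(n_bound >= 0, n_decoy >= 0, motif_spacing > 0, motif_width > 0,
            depth_tf >= 0, ctcf_protect > 0, cut_jitter >= 0, nuc_len > 0,
            nuc_spacing > 0, s_lo > 0, s_hi > s_lo, region_len > 0,
            seg_len > 0, read_length > min_mappable)
  stopifnot(identical(sort(names(group_log10_len)),
                      sort(names(k27ac_rate))),
            identical(sort(names(group_log10_len)),
                      sort(names(pol2_rate))))
  cfg <- as.list(environment())
  cfg$probs <- NULL
  n_motifs <- n_bound + n_decoy
  cfg$genome_length <- as.integer(2L * margin + n_motifs * motif_spacing)
  structure(cfg, class = "sim_config")
}

# truncated power-law s^-1 sampler (standard contact-decay null)
#' Sample contact distances from a truncated `s^-1` power law
#'
#' Inverse-CDF sampling of the standard contact-probability decay
#' `P(s) ~ s^-1` on `[s_lo, s_hi]`.
#'
#' @param n Number of draws.
#' @param s_lo,s_hi Range (bp).
#' @return Numeric vector of distances.
#' @export
r_powerlaw <- function(n, s_lo = 1e3, s_hi = 2e6) {
  s_lo * (s_hi / s_lo)^runif(n)
}

#' Simulate a synthetic MNase HiChIP dataset with planted truth
#'
#' Emits one proximity-ligation contact per fragment: the focal side is a
#' TF-protected, nucleosomal or background fragment; the partner side is
#' drawn from the contact model (extruded log-normal component for
#' TF-protected fragments at bound motifs, truncated `s^-1` power law
#' otherwise, and convergent capture onto opposite-strand bound motifs for
#' a planted fraction of upstream TF fragments). Fragments longer than
#' `read_length - min_mappable` are censored exactly as the analysis
#' modules expect. Deterministic given `config$seed`.
#'
#' @param config [sim_config()].
#' @return List with `contacts` (contacts `data.table`, one row per
#'   fragment, truth-aligned), and `truth`: `motifs` (all motifs with
#'   `bound`, `cohesin`, `group`, `lambda`), `bound_motifs`,
#'   `decoy_motifs`, `rad21_peaks`, `k27ac_peaks`, `pol2_peaks`,
#'   `segmentation`, `regions`, `state_groups`, `fragments` (per-contact
#'   truth: `motif_id`, `kind`, `true_len`, `upstream`, `convergent`) and
#'   `params` (the planted parameter values).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  L <- cf$genome_length
  groups <- names(cf$group_log10_len)
  censor_max <- cf$read_length - cf$min_mappable

  ## motifs -------------------------------------------------------------
  m <- cf$n_bound + cf$n_decoy
  base <- cf$margin + (seq_len(m) - 1L) * cf$motif_spacing
  center <- as.integer(base +
    round(runif(m, -cf$motif_spacing / 10, cf$motif_spacing / 10)))
  half <- cf$motif_width %/% 2L
  motifs <- data.table(
    chrom = cf$chrom,
    start = center - half, end = center - half + cf$motif_width,
    name = sprintf("motif_%04d", seq_len(m)),
    score = round(runif(m, 5, 20), 2),
    strand = fifelse(runif(m) < cf$plus_frac, "+", "-")
  )
  motifs <- as_motifs(motifs)
  bound <- seq_len(m) %in% sample.int(m, cf$n_bound)
  motifs[, bound := bound]
  cohesin <- bound & runif(m) < cf$cohesin_frac
  motifs[, cohesin := cohesin]

  ## chromatin-group blocks and annotation tracks -----------------------
  block_start <- seq(0, L - 1, by = cf$region_len)
  block_group <- sample(groups, length(block_start), replace = TRUE)
  regions <- data.table(chrom = cf$chrom, start = as.integer(block_start),
                        end = as.integer(pmin(block_start + cf$region_len,
                                              L)),
                        group = block_group)
  motif_block <- findInterval(motifs$center, block_start)
  motifs[, group := block_group[motif_block]]
  motifs[, lambda := cf$group_log10_len[group]]
  u <- rnorm(m, 0, cf$cbs_intercept_sd)

  n_states_per_group <- 5L
  state_groups <- setNames(
    rep(groups, each = n_states_per_group),
    paste0("E", seq_len(n_states_per_group * length(groups))))
  seg_start <- seq(0, L - 1, by = cf$seg_len)
  seg_block <- findInterval(seg_start, block_start)
  own <- runif(length(seg_start)) < cf$state_purity
  seg_state <- character(length(seg_start))
  for (g in groups) {
    own_states <- names(state_groups)[state_groups == g]
    other_states <- names(state_groups)[state_groups != g]
    sel <- seg_block %in% which(block_group == g)
    n_own <- sum(sel & own); n_oth <- sum(sel & !own)
    seg_state[sel & own] <- sample(own_states, n_own, replace = TRUE)
    seg_state[sel & !own] <- sample(other_states, n_oth, replace = TRUE)
  }
  segmentation <- data.table(chrom = cf$chrom,
                             start = as.integer(seg_start),
                             end = as.integer(pmin(seg_start + cf$seg_len,
                                                   L)),
                             state = seg_state)

  rad21 <- motifs[bound == TRUE,
                  .(chrom, start = center - 100L +
                      as.integer(round(runif(.N, -20, 20))))]
  rad21[, end := start + 200L]
  rad21[, signal_value := fifelse(cohesin[which(bound)],
                                  runif(.N, 75, 100), runif(.N, 1, 25))]

  peak_track <- function(rate, width) {
    nb <- rpois(nrow(regions), rate[regions$group] *
                  (regions$end - regions$start) / 1e6)
    pos <- unlist(Map(function(s, e, k) {
      if (k == 0) integer(0) else
        as.integer(floor(runif(k, s, max(s + 1, e - width))))
    }, regions$start, regions$end, nb))
    data.table(chrom = cf$chrom, start = pos, end = pos + as.integer(width))
  }
  k27ac <- peak_track(cf$k27ac_rate, cf$k27ac_width)
  pol2 <- peak_track(cf$pol2_rate, cf$pol2_width)

  ## focal fragments at motifs ------------------------------------------
  depth_total <- if (cf$occupancy > 0) cf$depth_tf / cf$occupancy else
    cf$depth_tf
  n_at <- fifelse(motifs$bound, rpois(m, depth_total),
                  rpois(m, cf$decoy_depth))
  mid <- rep(seq_len(m), n_at)
  nf <- length(mid)
  is_tf <- motifs$bound[mid] & runif(nf) < cf$occupancy

  fstart <- integer(nf); fend <- integer(nf)
  ctr <- motifs$center[mid]
  phalf <- cf$ctcf_protect %/% 2L
  # TF-protected fragments: protected span plus per-edge nibbling jitter
  tf <- which(is_tf)
  j1 <- sample.int(cf$cut_jitter + 1L, length(tf), replace = TRUE) - 1L
  j2 <- sample.int(cf$cut_jitter + 1L, length(tf), replace = TRUE) - 1L
  fstart[tf] <- ctr[tf] - phalf - j1
  fend[tf] <- ctr[tf] + phalf + j2
  # nucleosomal fragments: phased at multiples of nuc_spacing
  nuc <- which(!is_tf)
  slot <- sample(seq.int(-cf$nuc_slots, cf$nuc_slots), length(nuc),
                 replace = TRUE)
  nstart <- ctr[nuc] + slot * cf$nuc_spacing - cf$nuc_len %/% 2L +
    as.integer(round(rnorm(length(nuc), 0, cf$nuc_jitter)))
  fstart[nuc] <- nstart
  fend[nuc] <- nstart + cf$nuc_len

  ## partner placement ---------------------------------------------------
  # desired orientation: upstream fragment <=> partner downstream of motif
  want_up <- runif(nf) < cf$p_upstream
  d <- numeric(nf)
  lam <- motifs$lambda[mid] + u[mid]
  d[tf] <- 10^rnorm(length(tf), lam[tf], cf$extruded_sd)
  if (!is.null(cf$cohesin_delta)) {
    d[nuc] <- 10^rnorm(length(nuc), lam[nuc] - cf$cohesin_delta,
                       cf$extruded_sd)
  } else {
    d[nuc] <- r_powerlaw(length(nuc), cf$s_lo, cf$s_hi)
  }
  d <- pmax(round(d), 2L * cf$nuc_len)
  # distances that cannot be placed on either side of the anchor (possible
  # on short test genomes) are redrawn from the truncated power law, not
  # clamped: clamping would pile partners onto a single coordinate and
  # fabricate a read pile-up there
  avail <- pmax(ctr, L - 1 - ctr) - 2L * cf$nuc_len
  too_far <- d > avail
  if (any(too_far)) {
    u <- runif(sum(too_far))
    d[too_far] <- pmax(round(cf$s_lo * (avail[too_far] / cf$s_lo)^u),
                       2L * cf$nuc_len)
  }
  mstrand <- motifs$strand[mid]
  # genomic direction implied by desired orientation and motif strand
  right <- (want_up & mstrand == "+") | (!want_up & mstrand == "-")
  ppoint <- ctr + fifelse(right, 1, -1) * d
  flip <- ppoint < 0 | ppoint >= L
  ppoint[flip] <- ctr[flip] - fifelse(right[flip], 1, -1) * d[flip]
  ppoint <- pmin(pmax(ppoint, cf$nuc_len), L - 1 - cf$nuc_len)
  # actual orientation after edge flips
  p_downstream <- fifelse(mstrand == "+", ppoint >= ctr, ppoint <= ctr)
  upstream <- p_downstream

  ## convergent capture --------------------------------------------------
  # Captures are planted from the '+' anchor only; the reciprocal fragment
  # at the '-' anchor is emitted as the partner side. Planting from both
  # anchors independently would make every loop count twice when measured
  # at one anchor strand, inflating the convergent fraction above the
  # planted capture probability.
  convergent <- rep(FALSE, nf)
  cap_u <- runif(nf)
  cap <- which(is_tf & upstream & mstrand == "+" &
                 cap_u < cf$convergent_capture)
  if (length(cap)) {
    bplus <- motifs[bound == TRUE & strand == "+", sort(center)]
    bminus <- motifs[bound == TRUE & strand == "-", sort(center)]
    target <- rep(NA_real_, length(cap))
    for (k in seq_along(cap)) {
      i <- cap[k]
      cc <- ctr[i]
      # targets strictly beyond the long-range cutoff so captured contacts
      # survive the >10 kb analysis filter
      if (mstrand[i] == "+") {
        lo <- findInterval(cc + 12000, bminus) + 1L
        hi <- findInterval(cc + 1e6, bminus)
        if (hi >= lo) target[k] <- bminus[lo + (hi - lo + 1L) * runif(1) %/% 1]
      } else {
        hi <- findInterval(cc - 12000, bplus)
        lo <- findInterval(cc - 1e6, bplus) + 1L
        if (hi >= lo) target[k] <- bplus[lo + (hi - lo + 1L) * runif(1) %/% 1]
      }
    }
    ok <- !is.na(target)
    cap <- cap[ok]; target <- target[ok]
    ppoint[cap] <- target
    convergent[cap] <- TRUE
  }

  ## cohesin footprint: downstream extension of upstream TF fragments ----
  ext <- is_tf & upstream & motifs$cohesin[mid]
  fend[ext & mstrand == "+"] <- fend[ext & mstrand == "+"] + cf$cohesin_ext
  fstart[ext & mstrand == "-"] <- fstart[ext & mstrand == "-"] -
    cf$cohesin_ext

  ## background fragments ------------------------------------------------
  n_bg <- if (cf$background_rate > 0) {
    as.integer(round(nf * cf$background_rate / (1 - cf$background_rate)))
  } else 0L
  bg_len <- if (n_bg) sample(30:150, n_bg, replace = TRUE) else integer(0)
  bg_start <- if (n_bg) {
    as.integer(floor(runif(n_bg, 0, L - max(bg_len, 1))))
  } else integer(0)
  bg_d <- r_powerlaw(n_bg, cf$s_lo, cf$s_hi)
  bg_avail <- pmax(bg_start, L - 1 - bg_start) - 2 * cf$nuc_len
  bg_far <- bg_d > bg_avail
  if (any(bg_far)) {
    bg_d[bg_far] <- cf$s_lo * (bg_avail[bg_far] / cf$s_lo)^runif(sum(bg_far))
  }
  bg_right <- runif(n_bg) < 0.5
  bg_point <- bg_start + fifelse(bg_right, 1, -1) * round(bg_d)
  bg_flip <- bg_point < 0 | bg_point >= L
  bg_point[bg_flip] <- bg_start[bg_flip] -
    fifelse(bg_right[bg_flip], 1, -1) * round(bg_d[bg_flip])
  bg_point <- pmin(pmax(bg_point, cf$nuc_len), L - 1 - cf$nuc_len)

  ## assemble sides ------------------------------------------------------
  foc_start <- c(fstart, bg_start)
  foc_end <- c(fend, bg_start + bg_len)
  foc_len <- foc_end - foc_start
  foc_strand <- fifelse(runif(nf + n_bg) < 0.5, "+", "-")
  foc_pos5 <- fifelse(foc_strand == "+", foc_start, foc_end - 1L)
  foc_obs <- foc_len <= censor_max

  all_point <- c(ppoint, bg_point)
  ntot <- nf + n_bg
  # partner fragment: mostly censored nucleosome, some observed short
  p_obs_short <- runif(ntot) < 0.3 & !convergent_all(convergent, n_bg)
  p_len <- fifelse(p_obs_short,
                   sample(40:120, ntot, replace = TRUE), cf$nuc_len)
  # captured partners are TF-scale fragments on the target motif
  capi <- c(convergent, rep(FALSE, n_bg))
  if (any(capi)) {
    ncap <- sum(capi)
    p_len[capi] <- cf$ctcf_protect +
      sample.int(cf$cut_jitter + 1L, ncap, TRUE) - 1L +
      sample.int(cf$cut_jitter + 1L, ncap, TRUE) - 1L
  }
  p_start <- as.integer(round(all_point - p_len / 2))
  p_end <- as.integer(p_start + p_len)
  p_strand <- fifelse(runif(ntot) < 0.5, "+", "-")
  p_pos5 <- fifelse(p_strand == "+", p_start, p_end - 1L)
  p_obs <- p_len <= censor_max

  contacts <- data.table(
    chrom1 = cf$chrom, pos1 = as.integer(foc_pos5), strand1 = foc_strand,
    frag_len1 = fifelse(foc_obs, as.integer(foc_len), NA_integer_),
    obs_lig1 = foc_obs,
    chrom2 = cf$chrom, pos2 = as.integer(p_pos5), strand2 = p_strand,
    frag_len2 = fifelse(p_obs, as.integer(p_len), NA_integer_),
    obs_lig2 = p_obs
  )
  contacts <- order_contact_sides(contacts)

  frag_truth <- data.table(
    motif_id = c(mid, rep(NA_integer_, n_bg)),
    kind = c(fifelse(is_tf, "TF", "NUC"), rep("BG", n_bg)),
    true_len = as.integer(foc_len),
    partner_true_len = as.integer(p_len),
    upstream = c(upstream, rep(NA, n_bg)),
    convergent = c(convergent, rep(FALSE, n_bg)),
    extended = c(ext, rep(FALSE, n_bg))
  )

  truth <- list(
    motifs = motifs[],
    bound_motifs = motifs[bound == TRUE],
    decoy_motifs = motifs[bound == FALSE],
    rad21_peaks = rad21[],
    k27ac_peaks = k27ac, pol2_peaks = pol2,
    segmentation = segmentation, regions = regions,
    state_groups = state_groups,
    fragments = frag_truth,
    params = list(occupancy = cf$occupancy,
                  convergent_capture = cf$convergent_capture,
                  group_log10_len = cf$group_log10_len,
                  cohesin_delta = cf$cohesin_delta,
                  cohesin_frac = cf$cohesin_frac,
                  p_upstream = cf$p_upstream,
                  genome_length = L)
  )
  list(contacts = contacts, truth = truth, config = cf)
}

# helper: pad the focal convergent vector for background rows
convergent_all <- function(convergent, n_bg) {
  c(convergent, rep(FALSE, n_bg))
}

#' Simulate a structure-free null region
#'
#' Uniform read 5' positions with fair-coin strands and short observed
#' fragment lengths: the multinomial null's data-generating process. The
#' partner side is placed uniformly with censored length, so only the focal
#' reads enter window testing.
#'
#' @param length Region length in bp.
#' @param n_reads Number of reads (>= 0).
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @param read_length Read length (censoring bookkeeping only).
#' @return Contacts `data.table`.
#' @export
simulate_null_region <- function(length, n_reads, seed = 1L,
                                 chrom = "chrN", read_length = 150L) {
  stopifnot(n_reads >= 0, length > 0)
  set.seed(seed)
  if (n_reads == 0L) return(empty_contacts())
  pos <- as.integer(floor(runif(n_reads, 0, length)))
  strand <- fifelse(runif(n_reads) < 0.5, "+", "-")
  len <- sample(30:100, n_reads, replace = TRUE)
  ppos <- as.integer(floor(runif(n_reads, 0, length)))
  contacts <- data.table(
    chrom1 = chrom, pos1 = pos, strand1 = strand,
    frag_len1 = as.integer(len), obs_lig1 = TRUE,
    chrom2 = chrom, pos2 = ppos,
    strand2 = fifelse(runif(n_reads) < 0.5, "+", "-"),
    frag_len2 = NA_integer_, obs_lig2 = FALSE
  )
  order_contact_sides(contacts)
}
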