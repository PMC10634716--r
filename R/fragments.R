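#' Fragment classification parameters
#'
#' Centralizes the fragment-length and distance thresholds used throughout
#' the footprinting and extrusion analyses. Thresholds differ deliberately
#' between analyses (TF/nucleosome boundary at 115 bp, observed-ligation
#' proxy at 125 bp, cohesin mid-size band 80-120 bp) and are therefore kept
#' as separate parameters rather than unified.
#'
#' @param tf_max_len Fragments strictly shorter than this are TF-scale
#'   (default 115 bp).
#' @param min_edge_dist Minimum distance (bp) of both fragment edges from the
#'   motif center for a TF-protected call (default 15); removes confounding
#'   by MNase cut sites under the motif.
#' @param short_proxy_max Maximum length of an observed-ligation fragment
#'   (default 125 bp); the proxy for "short fragment".
#' @param midsize_range Length band (bp, inclusive) approximating joint
#'   CTCF+cohesin protection, default `c(80, 120)`.
#' @param longrange_min Minimum cis interaction length (bp) for "long-range"
#'   contacts (default 10000).
#' @param read_length Sequencing read length (default 150 bp).
#' @param min_mappable Minimum alignable bases; observed ligations require
#'   both sub-reads to map, so the observable fragment-length ceiling is
#'   `read_length - min_mappable` (default 25, giving 125 bp).
#' @return A list of class `class_params`.
#' @export
class_params <- function(tf_max_len = 115L, min_edge_dist = 15L,
                         short_proxy_max = 125L,
                         midsize_range = c(80L, 120L),
                         longrange_min = 10000L,
                         read_length = 150L, min_mappable = 25L) {
  stopifnot(tf_max_len < read_length,
            midsize_range[1] >= 1L, midsize_range[2] <= read_length,
            midsize_range[1] <= midsize_range[2],
            min_edge_dist >= 0L, longrange_min > 0L)
  structure(list(tf_max_len = as.integer(tf_max_len),
                 min_edge_dist = as.integer(min_edge_dist),
                 short_proxy_max = as.integer(short_proxy_max),
                 midsize_range = as.integer(midsize_range),
                 longrange_min = as.integer(longrange_min),
                 read_length = as.integer(read_length),
                 min_mappable = as.integer(min_mappable)),
            class = "class_params")
}

#' Reconstruct fragment intervals from read 5' ends
#'
#' For a `+` strand read the fragment is `[pos5, pos5 + len)`; for a `-`
#' strand read it is `[pos5 - len + 1, pos5 + 1)`. Censored lengths (`NA`)
#' yield `NA` intervals unless `nominal_censored = TRUE`, in which case the
#' censored fragment is assigned the nominal length `read_length` (it is
#' known to be at least read-length scale); used for coverage metaplots,
#' never for TF-class analyses.
#'
#' @param pos5 Integer vector of 0-based 5'-end positions.
#' @param strand Character vector of `+`/`-`.
#' @param frag_len Integer vector of fragment lengths, `NA` when censored.
#' @param read_length Read length (bp); observed lengths above
#'   `read_length` are invalid.
#' @param nominal_censored Substitute `read_length` for censored lengths.
#' @return `data.table` with columns `start`, `end` (0-based half-open;
#'   `NA` for censored fragments unless `nominal_censored`).
#' @export
fragment_interval <- function(pos5, strand, frag_len, read_length = 150L,
                              nominal_censored = FALSE) {
  stopifnot(length(pos5) == length(strand),
            length(pos5) == length(frag_len))
  known <- !is.na(frag_len)
  if (any(frag_len[known] > read_length)) {
    stop("observed fragment length exceeds read_length (", read_length, ")")
  }
  len <- frag_len
  if (nominal_censored) len[!known] <- read_length
  plus <- strand == "+"
  start <- fifelse(plus, pos5, pos5 - len + 1L)
  end <- fifelse(plus, pos5 + len, pos5 + 1L)
  miss <- is.na(len)  # censored and no nominal substitution: no interval
  start[miss] <- NA_integer_
  end[miss] <- NA_integer_
  data.table(start = as.integer(start), end = as.integer(end))
}

#' Classify fragments at a motif as TF-protected, nucleosomal, or excluded
#'
#' A fragment is `TF_PROTECTED` iff its length is known, shorter than
#' `tf_max_len`, and both edges lie at least `min_edge_dist` bp from the
#' motif center (the fragment brackets the center). Fragments with length
#' `>= tf_max_len`, or with censored length (necessarily long), are
#' `NUCLEOSOME`. Short fragments whose edge approaches the center are
#' `EXCLUDED` (a cut under the motif implies no TF was bound in that cell,
#' but such fragments are confounded for footprint analyses).
#'
#' The classification is total and deterministic: every (fragment, motif)
#' pair maps to exactly one label.
#'
#' @param frag_len Fragment lengths (`NA` = censored).
#' @param frag_start,frag_end Fragment interval (0-based half-open); may be
#'   `NA` for censored fragments.
#' @param center Motif center position(s), recycled.
#' @param params [class_params()].
#' @return Character vector in `{"TF_PROTECTED","NUCLEOSOME","EXCLUDED"}`.
#' @export
classify_fragments <- function(frag_len, frag_start, frag_end, center,
                               params = class_params()) {
  known <- !is.na(frag_len)
  nuc <- !known | frag_len >= params$tf_max_len
  # edge distances measured to the outermost covered bases
  start_d <- center - frag_start
  end_d <- (frag_end - 1L) - center
  tf <- known & frag_len < params$tf_max_len &
    !is.na(frag_start) &
    start_d >= params$min_edge_dist & end_d >= params$min_edge_dist
  fifelse(nuc, "NUCLEOSOME", fifelse(tf, "TF_PROTECTED", "EXCLUDED"))
}

#' Cis interaction length of contacts
#'
#' Distance between the two 5' positions of a contact. Defined from 5' ends
#' (not fragment midpoints) so it applies to censored sides too.
#' Trans-chromosomal contacts return `NA` and are excluded from all
#' length-based analyses.
#'
#' @param contacts Contacts table.
#' @return Numeric vector, `NA` for trans contacts.
#' @export
interaction_length <- function(contacts) {
  ifelse(contacts$chrom1 == contacts$chrom2,
         abs(contacts$pos2 - contacts$pos1), NA_real_)
}

#' Orientation of a motif-overlapping fragment relative to its partner
#'
#' A fragment overlapping a CTCF motif is the *upstream* member of its
#' contact when the interaction partner lies downstream of the motif in
#' motif-strand orientation (downstream is to the right of a `+` motif and
#' to the left of a `-` motif). Upstream fragments have looping contacts in
#' the direction expected for cohesin stabilized at CTCF's N terminus.
#'
#' @param partner_pos5 Partner 5' positions (0-based).
#' @param partner_start,partner_end Partner fragment interval (nominal
#'   length for censored partners); used to exclude partners that overlap
#'   the motif itself (ambiguous).
#' @param motif_start,motif_end,motif_center,motif_strand Motif coordinates,
#'   recycled.
#' @return Character vector `"UPSTREAM_FRAGMENT"`/`"DOWNSTREAM_FRAGMENT"`,
#'   `NA` for ambiguous (partner overlapping the motif).
#' @export
partner_orientation <- function(partner_pos5, partner_start, partner_end,
                                motif_start, motif_end, motif_center,
                                motif_strand) {
  overlaps <- partner_start < motif_end & partner_end > motif_start
  partner_downstream <- fifelse(motif_strand == "+",
                                partner_pos5 >= motif_center,
                                partner_pos5 <= motif_center)
  out <- fifelse(partner_downstream, "UPSTREAM_FRAGMENT",
                 "DOWNSTREAM_FRAGMENT")
  out[overlaps] <- NA_character_
  out
}

#' Long side-level view of a contacts table
#'
#' Melts contacts into one row per side, carrying the partner's coordinates.
#' Internal workhorse for motif-overlap analyses.
#'
#' @param contacts Contacts table.
#' @param params [class_params()] (for nominal censored lengths).
#' @return `data.table` with columns `contact_id, side, chrom, pos5, strand,
#'   frag_len, obs_lig, frag_start, frag_end` (nominal intervals for
#'   censored) plus partner columns `partner_chrom, partner_pos5,
#'   partner_len, partner_obs, partner_start, partner_end` and `int_len`
#'   (`NA` for trans).
#' @export
contact_sides <- function(contacts, params = class_params()) {
  dt <- as.data.table(contacts)
  n <- nrow(dt)
  il <- interaction_length(dt)
  one <- function(s, p) {
    out <- data.table(
      contact_id = seq_len(n), side = s,
      chrom = dt[[paste0("chrom", s)]],
      pos5 = dt[[paste0("pos", s)]],
      strand = dt[[paste0("strand", s)]],
      frag_len = dt[[paste0("frag_len", s)]],
      obs_lig = dt[[paste0("obs_lig", s)]],
      partner_chrom = dt[[paste0("chrom", p)]],
      partner_pos5 = dt[[paste0("pos", p)]],
      partner_len = dt[[paste0("frag_len", p)]],
      partner_obs = dt[[paste0("obs_lig", p)]],
      partner_strand = dt[[paste0("strand", p)]],
      int_len = il
    )
    fi <- fragment_interval(out$pos5, out$strand, out$frag_len,
                            params$read_length, nominal_censored = TRUE)
    out[, `:=`(frag_start = fi$start, frag_end = fi$end)]
    pi <- fragment_interval(out$partner_pos5, out$partner_strand,
                            out$partner_len, params$read_length,
                            nominal_censored = TRUE)
    out[, `:=`(partner_start = pi$start, partner_end = pi$end)]
    out
  }
  rbindlist(list(one(1L, 2L), one(2L, 1L)))
}

#' Fragments overlapping motifs, with class and orientation annotations
#'
#' Joins the side-level view of `contacts` to `motifs` by fragment-interval
#' overlap and annotates each (fragment, motif) pair with its fragment class
#' ([classify_fragments()]) and partner orientation
#' ([partner_orientation()]).
#'
#' @param contacts Contacts table.
#' @param motifs Motif table from [read_motifs()]/[as_motifs()].
#' @param params [class_params()].
#' @return `data.table`: one row per (side, motif) overlap with all
#'   [contact_sides()] columns plus `motif_id, motif_start, motif_end,
#'   motif_center, motif_strand, class, orientation`.
#' @export
fragments_at_motifs <- function(contacts, motifs, params = class_params()) {
  sides <- contact_sides(contacts, params)
  m <- as_motifs(motifs)
  mk <- data.table(chrom = m$chrom, xstart = m$start, xend = m$end,
                   motif_id = m$motif_id, motif_start = m$start,
                   motif_end = m$end, motif_center = m$center,
                   motif_strand = m$strand)
  setkey(mk, chrom, xstart, xend)
  qq <- copy(sides)[, `:=`(xstart = frag_start, xend = frag_end - 1L)]
  hits <- foverlaps(qq, mk, by.x = c("chrom", "xstart", "xend"),
                    type = "any", nomatch = NULL)
  hits[, c("xstart", "xend", "i.xstart", "i.xend") := NULL]
  if (nrow(hits) == 0L) {
    hits[, `:=`(class = character(), orientation = character())]
    return(hits[])
  }
  hits[, class := classify_fragments(frag_len, frag_start, frag_end,
                                     motif_center, params)]
  same_chrom <- hits$partner_chrom == hits$chrom
  ori <- partner_orientation(hits$partner_pos5, hits$partner_start,
                             hits$partner_end, hits$motif_start,
                             hits$motif_end, hits$motif_center,
                             hits$motif_strand)
  ori[!same_chrom] <- NA_character_
  hits[, orientation := ori]
  hits[]
}
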