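#' Read a BED-family interval file
#'
#' Reads BED3/BED6 or narrowPeak-like tab-separated files. Coordinates are
#' kept in BED-native 0-based half-open convention, which is also the
#' package-internal convention, so no shifting occurs.
#'
#' @param path Path to a tab-separated BED file. Lines starting with `#`,
#'   `track` or `browser` are skipped.
#' @param with_score If `TRUE`, require at least 5 columns and return the
#'   score column as numeric.
#' @return A `data.table` with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`, plus `signal_value`,
#'   `peak_p`, `peak_q`, `summit_offset` for narrowPeak (10-column) input.
#'   Rows are in file order.
#' @seealso [read_motifs()] for stranded motif input, [write_bed()].
#' @export
read_bed <- function(path, with_score = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- if (with_score) 5L else 3L
  bad <- which(nf < min_cols)
  if (length(bad)) {
    stop("malformed BED line ", lineno[bad[1]], " in ", path,
         ": expected >= ", min_cols, " tab-separated columns, got ",
         nf[bad[1]])
  }
  ncol_use <- min(nf)
  m <- matrix(unlist(lapply(fields, `[`, seq_len(ncol_use))),
              ncol = ncol_use, byrow = TRUE)
  out <- data.table(chrom = m[, 1],
                    start = suppressWarnings(as.integer(m[, 2])),
                    end   = suppressWarnings(as.integer(m[, 3])))
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1]
    stop("malformed BED line ", lineno[bad], " in ", path,
         ": non-numeric coordinates")
  }
  if (any(out$start >= out$end)) {
    bad <- which(out$start >= out$end)[1]
    stop("invalid interval at line ", lineno[bad], " in ", path,
         ": start >= end")
  }
  if (any(out$start < 0L)) {
    stop("invalid interval in ", path, ": negative start coordinate")
  }
  if (ncol_use >= 4L) out[, name := m[, 4]]
  if (ncol_use >= 5L) out[, score := suppressWarnings(as.numeric(m[, 5]))]
  if (ncol_use >= 6L) {
    st <- m[, 6]
    if (!all(st %in% c("+", "-", "."))) {
      stop("invalid strand value in ", path,
           ": must be one of '+', '-', '.'")
    }
    out[, strand := st]
  }
  if (ncol_use >= 10L) {
    out[, signal_value := suppressWarnings(as.numeric(m[, 7]))]
    out[, peak_p := suppressWarnings(as.numeric(m[, 8]))]
    out[, peak_q := suppressWarnings(as.numeric(m[, 9]))]
    out[, summit_offset := suppressWarnings(as.integer(m[, 10]))]
  } else if (ncol_use >= 7L) {
    out[, signal_value := suppressWarnings(as.numeric(m[, 7]))]
  }
  out[]
}

#' Read stranded CTCF motifs from BED6
#'
#' Motifs must carry a `+`/`-` strand. The motif center is defined as
#' `floor((start + end) / 2)`, deterministic for even-length motifs.
#'
#' @inheritParams read_bed
#' @return `data.table` with BED6 columns plus `center` and `motif_id`
#'   (1-based row index).
#' @export
read_motifs <- function(path) {
  m <- read_bed(path)
  if (is.null(m$strand)) stop("motif file ", path, " must be BED6 (strand)")
  if (any(m$strand == ".")) {
    stop("motif strand must be '+' or '-' for all records")
  }
  as_motifs(m)
}

#' Attach motif centers and ids to an interval table
#'
#' @param x `data.frame`/`data.table` with `chrom`, `start`, `end`, `strand`.
#' @return `data.table` with `center = floor((start+end)/2)` and `motif_id`.
#' @export
as_motifs <- function(x) {
  m <- as.data.table(x)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(m)))
  if (!all(m$strand %in% c("+", "-"))) {
    stop("motif strand must be '+' or '-'")
  }
  m[, center := as.integer(floor((start + end) / 2))]
  m[, motif_id := .I]
  m[]
}

#' Write intervals to a BED file
#'
#' Writes whichever of the BED6 columns are present (missing name/score/strand
#' filled with `.`/`0`/`.`). Coordinates written as-is (0-based half-open).
#'
#' @param x Interval table with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @param extra_cols Optional character vector of additional columns to append
#'   after the first six.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra_cols = NULL) {
  x <- as.data.table(x)
  out <- data.table(
    chrom = x$chrom,
    start = as.integer(x$start),
    end = as.integer(x$end),
    name = if (!is.null(x$name)) x$name else ".",
    score = if (!is.null(x$score)) x$score else 0,
    strand = if (!is.null(x$strand)) x$strand else "."
  )
  for (cc in extra_cols) out[[cc]] <- x[[cc]]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

PAIRS_HEADER <- "#columns: chrom1 pos1 strand1 chrom2 pos2 strand2 frag_len1 frag_len2"

#' Read contacts from the extended pairs dialect
#'
#' The dialect is a pairs-style text format with one proximity-ligation
#' contact per line and 8 tab-separated columns: `chrom1 pos1 strand1 chrom2
#' pos2 strand2 frag_len1 frag_len2`. Positions are 1-based on disk (pairs
#' ecosystem convention) and converted to 0-based in memory. A fragment
#' length of `-1` encodes a censored length (no observed ligation; the
#' pre-ligation fragment was longer than the mappable limit); in memory it
#' becomes `NA` with `obs_lig = FALSE`.
#'
#' @param path Path to the pairs file. The header line
#'   `r PAIRS_HEADER` is required.
#' @param read_length Sequencing read length in bp; observed fragment lengths
#'   must not exceed it.
#' @return A contacts `data.table` with columns `chrom1, pos1, strand1,
#'   frag_len1, obs_lig1, chrom2, pos2, strand2, frag_len2, obs_lig2`,
#'   positions 0-based, sides ordered by `(chrom, pos)`.
#' @seealso [write_contacts()]
#' @export
read_contacts <- function(path, read_length = 150L) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 50L)
  hdr <- grep("^#columns:", head_lines, value = TRUE)
  if (length(hdr) == 0L || gsub("\\s+", " ", trimws(hdr[1])) !=
        gsub("\\s+", " ", PAIRS_HEADER)) {
    stop("pairs file ", path, " is missing the required header line '",
         PAIRS_HEADER, "'")
  }
  n_skip <- match(FALSE, startsWith(head_lines, "#"), nomatch = 0L) - 1L
  if (n_skip < 0L) {  # every line is a header line
    if (length(head_lines) < 50L) return(empty_contacts())
    n_skip <- length(head_lines)
  }
  dt <- fread(path, sep = "\t", header = FALSE, skip = n_skip,
              colClasses = list(character = c(1, 3, 4, 6)))
  if (nrow(dt) > 0L && ncol(dt) != 8L) {
    stop("pairs file ", path, ": expected 8 columns, found ", ncol(dt))
  }
  if (nrow(dt) == 0L) return(empty_contacts())
  setnames(dt, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
                 "frag_len1", "frag_len2"))
  if (!all(dt$strand1 %in% c("+", "-")) || !all(dt$strand2 %in% c("+", "-"))) {
    stop("pairs file ", path, ": strand must be '+' or '-'")
  }
  if (any(dt$pos1 <= 0L) || any(dt$pos2 <= 0L)) {
    stop("pairs file ", path, ": positions must be >= 1 (1-based on disk)")
  }
  dt[, `:=`(pos1 = as.integer(pos1) - 1L, pos2 = as.integer(pos2) - 1L)]
  dt[, `:=`(frag_len1 = fifelse(frag_len1 < 0L, NA_integer_,
                                as.integer(frag_len1)),
            frag_len2 = fifelse(frag_len2 < 0L, NA_integer_,
                                as.integer(frag_len2)))]
  if (any(stats::na.omit(c(dt$frag_len1, dt$frag_len2)) < 1L)) {
    stop("pairs file ", path, ": known fragment lengths must be >= 1")
  }
  if (any(stats::na.omit(c(dt$frag_len1, dt$frag_len2)) > read_length)) {
    stop("pairs file ", path, ": observed fragment length exceeds ",
         "read_length (", read_length, ")")
  }
  dt[, `:=`(obs_lig1 = !is.na(frag_len1), obs_lig2 = !is.na(frag_len2))]
  order_contact_sides(dt)
}

empty_contacts <- function() {
  data.table(chrom1 = character(), pos1 = integer(), strand1 = character(),
             frag_len1 = integer(), obs_lig1 = logical(),
             chrom2 = character(), pos2 = integer(), strand2 = character(),
             frag_len2 = integer(), obs_lig2 = logical())
}

# Enforce the side-ordering invariant: side1 <= side2 by (chrom, pos5).
order_contact_sides <- function(dt) {
  swap <- (dt$chrom2 < dt$chrom1) |
    (dt$chrom2 == dt$chrom1 & dt$pos2 < dt$pos1)
  if (any(swap)) {
    s1 <- c("chrom1", "pos1", "strand1", "frag_len1", "obs_lig1")
    s2 <- c("chrom2", "pos2", "strand2", "frag_len2", "obs_lig2")
    tmp <- dt[swap, ..s1]
    for (k in seq_along(s1)) set(dt, which(swap), s1[k], dt[swap][[s2[k]]])
    for (k in seq_along(s2)) set(dt, which(swap), s2[k], tmp[[k]])
  }
  setcolorder(dt, c("chrom1", "pos1", "strand1", "frag_len1", "obs_lig1",
                    "chrom2", "pos2", "strand2", "frag_len2", "obs_lig2"))
  dt[]
}

#' Write contacts to the extended pairs dialect
#'
#' Inverse of [read_contacts()]: positions are shifted to 1-based, censored
#' fragment lengths written as `-1`, and the `#columns:` header emitted.
#'
#' @param contacts Contacts table as returned by [read_contacts()] or
#'   [simulate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  dt <- as.data.table(contacts)
  out <- data.table(
    chrom1 = dt$chrom1, pos1 = dt$pos1 + 1L, strand1 = dt$strand1,
    chrom2 = dt$chrom2, pos2 = dt$pos2 + 1L, strand2 = dt$strand2,
    frag_len1 = fifelse(is.na(dt$frag_len1), -1L, dt$frag_len1),
    frag_len2 = fifelse(is.na(dt$frag_len2), -1L, dt$frag_len2)
  )
  writeLines(PAIRS_HEADER, path)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         append = TRUE)
  invisible(path)
}
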