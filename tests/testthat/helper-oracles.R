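# Shared fixtures and independent oracles, built in code.

.cache <- new.env(parent = emptyenv())

# Small null table shared by module tests. p floor is 1/2e4 = 5e-5, so
# module-level peak calls use p_threshold = 1e-4.
tiny_table <- function() {
  if (is.null(.cache$tab)) {
    .cache$tab <- suppressWarnings(
      build_null_table(n_min = 5L, n_max = 60L, reps = 2e4, seed = 404L))
  }
  .cache$tab
}

# Small default-flavour simulated dataset shared by module tests.
tiny_sim <- function() {
  if (is.null(.cache$sim)) {
    .cache$sim <- simulate_dataset(
      sim_config(n_bound = 200L, n_decoy = 100L, seed = 308L))
  }
  .cache$sim
}

# Exact null survival at total read count N by enumeration of multinomial
# compositions weighted by dmultinom (equivalent to the 4^N equally likely
# quadrant assignments, exactly). Independent of build_null_table.
exact_null_survival <- function(N) {
  comp <- as.matrix(expand.grid(n1 = 0:N, n2 = 0:N, n3 = 0:N, n4 = 0:N))
  comp <- comp[rowSums(comp) == N, , drop = FALSE]
  pr <- apply(comp, 1, function(x) dmultinom(x, prob = rep(0.25, 4)))
  st <- ff_statistic(comp[, 1], comp[, 2], comp[, 3], comp[, 4])
  grid <- seq(0, 5, by = 0.01)
  idx <- floor(st * 100 + 1e-9) + 1L
  idx[st < 0] <- NA_integer_
  idx <- pmin(idx, length(grid))
  vapply(seq_along(grid),
         function(g) sum(pr[!is.na(idx) & idx >= g]), numeric(1))
}

# Direct step-up Benjamini-Hochberg, from the definition:
# q_(i) = min over j >= i of p_(j) * m / j.
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Build a contacts table from parallel side vectors (0-based positions).
make_contacts <- function(chrom1, pos1, strand1, len1,
                          chrom2, pos2, strand2, len2) {
  dt <- data.table::data.table(
    chrom1 = chrom1, pos1 = as.integer(pos1), strand1 = strand1,
    frag_len1 = as.integer(len1), obs_lig1 = !is.na(len1),
    chrom2 = chrom2, pos2 = as.integer(pos2), strand2 = strand2,
    frag_len2 = as.integer(len2), obs_lig2 = !is.na(len2))
  footloop:::order_contact_sides(dt)
}

# A one-row motif table.
make_motif <- function(chrom, start, end, strand, score = 10) {
  as_motifs(data.frame(chrom = chrom, start = start, end = end,
                       strand = strand, score = score))
}

# Contacts giving a clean TF footprint at a '+' motif: n '+' reads just
# upstream, n '-' reads just downstream, partners far away.
footprint_contacts <- function(center, n = 25L, chrom = "chrT",
                               partner_at = center + 50000L) {
  ppos <- rep(partner_at, 2L * n)
  make_contacts(
    chrom1 = chrom,
    pos1 = c(center - 20L - seq_len(n) %% 8L, center + 20L + seq_len(n) %% 8L),
    strand1 = rep(c("+", "-"), each = n),
    len1 = rep(45L, 2L * n),
    chrom2 = chrom, pos2 = ppos, strand2 = "+", len2 = NA_integer_)
}
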