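# Shared fixtures built in code.

# A small fully-simulated dataset used by several test files.
small_sim <- function(seed = 11, reads = 5000, format = "hits") {
  cfg <- sim_config(n_families = 4, n_taxa = 8, n_sites_per_region = 1,
                    reads_per_sample = reads, seed = seed)
  col <- generate_reference_collection(cfg)
  sc <- generate_community_scenario(cfg, col)
  sq <- simulate_sequencing(sc, col, format = format)
  list(cfg = cfg, col = col, sc = sc, sq = sq)
}

# One hit-table row in the extended tabular format.
hit_row <- function(qseqid, sseqid, subject_set, bitscore,
                    pident = 98, length = 80, evalue = 1e-20, qlen = 150) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = 0L, gapopen = 0L, qstart = 1L,
             qend = length, sstart = 1L, send = length,
             evalue = evalue, bitscore = bitscore, qlen = qlen,
             subject_set = subject_set, stringsAsFactors = FALSE)
}

# Restrict a scenario to its first n samples.
subset_scenario <- function(sc, n) {
  sc$samples <- sc$samples[seq_len(n), , drop = FALSE]
  sc$truth_matrix <- sc$truth_matrix[, seq_len(n), drop = FALSE]
  sc$truth <- sc$truth[sc$truth$sample_id %in% sc$samples$sample_id, ]
  sc
}

# Naive PERMANOVA pseudo-F computed with explicit loops over pairs
# (independent of the package's internals).
naive_permanova_f <- function(d, groups) {
  n <- length(groups)
  ss_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a < b) s <- s + d[idx[a], idx[b]]^2
      }
    }
    ss_w <- ss_w + s / length(idx)
  }
  g <- length(unique(groups))
  ((ss_tot - ss_w) / (g - 1)) / (ss_w / (n - g))
}
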