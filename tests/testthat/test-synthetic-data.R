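test_that("reference collection follows the stated construction rules", {
  cfg <- sim_config(n_families = 5, n_taxa = 10, seed = 1)
  col <- generate_reference_collection(cfg)

  expect_equal(nrow(col$taxa), 10)
  expect_equal(length(unique(col$taxa$family)), 5)
  expect_equal(nrow(col$standards), 3)
  expect_true(all(col$taxa$genome_length >= 1.3e6 &
                    col$taxa$genome_length <= 9e6))
  # one protein gene per kilobase, never below one, genes fit in the genome
  expect_equal(col$taxa$protein_gene_count,
               pmax(1L, as.integer(round(col$taxa$genome_length / 1000))))
  expect_true(all(col$taxa$genome_length >= col$taxa$protein_gene_count))
  expect_true(all(col$taxa$has_recA))
  expect_true(all(nchar(col$taxa$reference_bins) > 0))
  # standards carry molecule counts consistent with their mass
  expect_equal(col$standards$S_a,
               molecules_added(col$standards$mass_added_ng,
                               col$standards$genome_length))

  # determinism: identical config reproduces identical output
  expect_identical(col, generate_reference_collection(cfg))

  expect_error(sim_config(n_families = 5, n_taxa = 3), "n_taxa")
})

test_that("community scenario applies gradient and year effects as configured", {
  # null scenario: no gradient, no indicators -> all samples exchangeable
  cfg0 <- sim_config(n_families = 5, n_taxa = 10, gradient_log10_span = 0,
                     seed = 2)
  col <- generate_reference_collection(cfg0)
  sc0 <- generate_community_scenario(cfg0, col)
  expect_equal(nrow(sc0$samples), 2 * 5 * cfg0$n_sites_per_region)
  expect_true(all(sc0$truth_matrix >= 0) && all(is.finite(sc0$truth_matrix)))
  expect_identical(sc0$truth_matrix,
                   generate_community_scenario(cfg0, col)$truth_matrix)

  # an indicator multiplier of 1e-3 moves the year-1 median by ~3 decades
  cfg1 <- sim_config(n_families = 5, n_taxa = 10, n_sites_per_region = 5,
                     gradient_log10_span = 0,
                     elnino_indicator_families = c(fam02 = 1e-3), seed = 2)
  sc1 <- generate_community_scenario(cfg1, generate_reference_collection(cfg1))
  taxa <- generate_reference_collection(cfg1)$taxa
  tid <- taxa$taxon_id[taxa$family == "fam02"][1]
  y1 <- sc1$truth_matrix[tid, sc1$samples$year == 1]
  y2 <- sc1$truth_matrix[tid, sc1$samples$year == 2]
  # 25 sites/year, log-normal noise sd 0.3 log10: median ratio within ~0.5 dex
  expect_lt(abs(log10(median(y1) / median(y2)) - (-3)), 0.5)

  expect_error(
    generate_community_scenario(
      sim_config(n_families = 5, n_taxa = 10,
                 elnino_indicator_families = c(nope = 0.1), seed = 1),
      col),
    "unknown family")
})

test_that("sequencing conserves reads and matches multinomial expectations", {
  sim <- small_sim(seed = 5, reads = 2000, format = "counts")
  per_sample <- tapply(sim$sq$counts$reads, sim$sq$counts$sample_id, sum) +
    tapply(sim$sq$recovery$S_s, sim$sq$recovery$sample_id, sum)
  expect_true(all(per_sample == sim$cfg$reads_per_sample))

  # determinism
  sq2 <- simulate_sequencing(sim$sc, sim$col, format = "counts")
  expect_identical(sim$sq$counts, sq2$counts)
  expect_identical(sim$sq$recovery, sq2$recovery)

  # observed category counts sit within 5 SDs of N * p in >= 99% of cases,
  # checked across 100 independent seeds at small depth
  n_ok <- 0L; n_tot <- 0L
  for (seed in 1:100) {
    cfg <- sim_config(n_families = 3, n_taxa = 6, n_sites_per_region = 1,
                      reads_per_sample = 2000, seed = seed)
    col <- generate_reference_collection(cfg)
    sc <- subset_scenario(generate_community_scenario(cfg, col), 1)
    sq <- simulate_sequencing(sc, col, format = "counts")
    sid <- sc$samples$sample_id[1]
    w <- c(sc$truth_matrix[, sid] * cfg$volume_L * col$taxa$protein_gene_count,
           col$standards$S_a * col$standards$S_p)
    p <- w / sum(w)
    obs <- c(sq$counts$reads, sq$recovery$S_s)
    expectation <- cfg$reads_per_sample * p
    sd <- sqrt(cfg$reads_per_sample * p * (1 - p))
    z_ok <- abs(obs - expectation) <= 5 * pmax(sd, .Machine$double.eps)
    n_ok <- n_ok + sum(z_ok); n_tot <- n_tot + length(z_ok)
  }
  expect_gte(n_ok / n_tot, 0.99)

  # full misannotation: nothing survives the downstream bit filter
  cfg <- sim_config(n_families = 3, n_taxa = 6, n_sites_per_region = 1,
                    reads_per_sample = 1000, misannotation_rate = 1,
                    dual_hit_rate = 0, seed = 9)
  col <- generate_reference_collection(cfg)
  sc <- generate_community_scenario(cfg, col)
  sq <- simulate_sequencing(sc, col, format = "counts")
  expect_true(all(sq$counts$low_bit == sq$counts$reads))
  expect_true(all(sq$counts$recA == 0))
})

test_that("hits format agrees with the counts bookkeeping", {
  sim <- small_sim(seed = 13, reads = 4000, format = "hits")
  sid <- sim$sc$samples$sample_id[1]
  hits <- sim$sq$hits[[sid]]
  reads <- sim$sq$reads[[sid]]
  res <- process_sample_hits(hits, reads)

  # standard protein reads per standard match the drawn counts
  rec <- sim$sq$recovery[sim$sq$recovery$sample_id == sid, ]
  expect_equal(unname(res$S_s[rec$standard_id]), rec$S_s)

  # recA counts per taxon match
  cnt <- sim$sq$counts[sim$sq$counts$sample_id == sid, ]
  got <- setNames(rep(0, nrow(cnt)), cnt$taxon_id)
  got[res$recA_counts$taxon_id] <- res$recA_counts$recA
  expect_equal(unname(got), cnt$recA)

  # partition property: standard + community reads = all reads, disjoint
  std_ids <- unlist(res$partition$standard_reads, use.names = FALSE)
  expect_length(intersect(std_ids, res$partition$community_reads), 0)
  expect_setequal(c(std_ids, res$partition$community_reads), reads$read_id)
})

test_that("fixture sets round-trip through disk", {
  sim <- small_sim(seed = 21, reads = 500, format = "hits")
  dir <- withr::local_tempdir()
  manifest <- write_fixture_set(sim$sc, sim$sq, sim$col, file.path(dir, "fx"))
  expect_true(all(c("metadata.tsv", "truth.tsv", "manifest.tsv") %in%
                    c(manifest$file, "manifest.tsv")))
  back <- read_fixture_set(file.path(dir, "fx"))
  expect_equal(back$metadata, sim$sc$samples, ignore_attr = TRUE)
  expect_equal(back$truth, sim$sc$truth, ignore_attr = TRUE)
  sid <- sim$sc$samples$sample_id[1]
  expect_equal(back$hits[[sid]], sim$sq$hits[[sid]],
               ignore_attr = TRUE, tolerance = 1e-12)
  # manifest row counts are accurate
  expect_equal(manifest$rows[manifest$file == paste0("hits_", sid, ".tsv")],
               nrow(sim$sq$hits[[sid]]))
  # a fixture set missing its truth table is rejected
  file.remove(file.path(dir, "fx", "truth.tsv"))
  writeLines(character(0), file.path(dir, "fx", "truth.tsv"))
  man <- read.delim(file.path(dir, "fx", "manifest.tsv"))
  man <- man[man$file != "truth.tsv", ]
  write.table(man, file.path(dir, "fx", "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_fixture_set(file.path(dir, "fx")), "missing")
})
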