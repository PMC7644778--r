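test_that("top-hit selection keeps the best bit score with deterministic ties", {
  h <- rbind(hit_row("r1", "sX", "refseq_prot", 60),
             hit_row("r1", "sY", "refseq_prot", 80),
             hit_row("r1", "sZ", "refseq_prot", 75))
  expect_equal(select_top_hit(h)$sseqid, "sY")

  tie <- rbind(hit_row("r1", "B", "refseq_prot", 80),
               hit_row("r1", "A", "refseq_prot", 80))
  expect_equal(select_top_hit(tie)$sseqid, "A")

  low <- rbind(hit_row("r1", "s1", "refseq_prot", 49),
               hit_row("r1", "s2", "refseq_prot", 30))
  expect_null(select_top_hit(low))
  # the bit-50 pre-filter applies to the community search only
  low_nuc <- rbind(hit_row("r1", "s1", "standard_nuc", 49))
  expect_equal(select_top_hit(low_nuc)$bitscore, 49)
  expect_null(select_top_hit(h[0, ]))
})

test_that("standard reads require all four nucleotide-search cutoffs", {
  reads <- data.frame(read_id = paste0("r", 1:6), read_length = 150)
  h <- rbind(
    hit_row("r1", "std_A_genome", "standard_nuc", 120, pident = 97, length = 100,
            evalue = 1e-5),                          # passes everything
    hit_row("r2", "std_A_genome", "standard_nuc", 120, pident = 95, length = 100,
            evalue = 1e-5),                          # %ID not > 95
    hit_row("r3", "std_A_genome", "standard_nuc", 120, pident = 97, length = 60,
            evalue = 1e-5),                          # 40% of read aligned
    hit_row("r4", "std_A_genome", "standard_nuc", 50, pident = 97, length = 100,
            evalue = 1e-5),                          # bit not > 50
    hit_row("r5", "std_B_genome", "standard_nuc", 120, pident = 97, length = 100,
            evalue = 0.01)                           # e-value too high
  )
  part <- identify_standard_reads(h, reads)
  expect_equal(part$standard_reads, list(std_A = "r1"))
  expect_setequal(part$community_reads, c("r2", "r3", "r4", "r5", "r6"))

  expect_error(
    identify_standard_reads(h, data.frame(read_id = "r1", read_length = NA)),
    "read_length")
})

test_that("standard protein counting keeps hits at the bit-40 / %ID-95 boundary", {
  reads <- data.frame(read_id = paste0("r", 1:4), read_length = 150)
  nuc <- do.call(rbind, lapply(paste0("r", 1:4), function(r)
    hit_row(r, "std_A_genome", "standard_nuc", 120, pident = 97,
            length = 100, evalue = 1e-5)))
  part <- identify_standard_reads(nuc, reads)
  prot <- rbind(
    hit_row("r1", "std_A_p1", "standard_prot", 39, pident = 99),   # bit < 40
    hit_row("r2", "std_A_p1", "standard_prot", 45, pident = 96),   # counted
    hit_row("r3", "std_A_p1", "standard_prot", 100, pident = 94),  # %ID < 95
    hit_row("r4", "std_A_p1", "standard_prot", 40, pident = 95)    # boundary kept
  )
  expect_equal(count_standard_protein_reads(prot, part), c(std_A = 2))

  stray <- hit_row("r9", "std_A_p1", "standard_prot", 80)
  expect_error(count_standard_protein_reads(stray, part), "not in the standard")
})

test_that("viral override replaces the bacterial annotation only on higher bit", {
  b <- hit_row("r1", "bact", "refseq_prot", 60)
  v75 <- hit_row("r1", "vir", "viral_prot", 75)
  v60 <- hit_row("r1", "vir", "viral_prot", 60)
  expect_equal(viral_override(b, v75), "viral")
  expect_equal(viral_override(hit_row("r1", "bact", "refseq_prot", 80), v75),
               "bacterial")
  expect_equal(viral_override(b, v60), "bacterial")  # tie keeps original
  expect_equal(viral_override(NULL, v75), "viral")
  expect_equal(viral_override(NULL, NULL), "unannotated")
})

test_that("recA keyword membership matches the four phrases case-sensitively", {
  t <- data.frame(
    subject_id = c("a", "b", "c", "d", "e", "f"),
    title = c("protein RecA [Pelagibacter sp.]",
              "recombinase RecB",
              "DNA recombinase A, partial",
              "RecA protein, putative",
              "PROTEIN RECA",
              "recombinase RecA domain protein"))
  expect_setequal(recA_title_members(t), c("a", "c", "d", "f"))
  expect_true("e" %in% recA_title_members(t, ignore_case = TRUE))
})

test_that("recA counting requires bit > 50 and a confirming annotation", {
  titles <- data.frame(
    subject_id = c("tax1_recA", "tax1_flag", "tax2_recA"),
    title = c("protein RecA [tax1]", "flagellin [tax1]",
              "recombinase RecA [tax2]"))
  ann <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    label = c("bacterial", "bacterial", "bacterial", "viral"),
    subject_id = c("tax1_recA", "tax1_flag", "tax2_recA", "vir_1"),
    bitscore = c(120, 90, 80, 70), stringsAsFactors = FALSE)
  rh <- rbind(
    hit_row("r1", "tax1_recA", "recA_prot", 120),  # counted
    hit_row("r2", "tax1_recA", "recA_prot", 120),  # refseq says flagellin
    hit_row("r3", "tax2_recA", "recA_prot", 50),   # bit not > 50
    hit_row("r4", "tax2_recA", "recA_prot", 90)    # viral-overridden read
  )
  out <- count_recA(rh, ann, titles,
                    subject_taxon = function(id) sub("_.*$", "", id))
  expect_equal(out$taxon_id, "tax1")
  expect_equal(out$recA, 1)
  # r2 (flagellin) and r4 (viral-overridden) fail confirmation; r3 never
  # reaches it because its recA bit score is not above 50
  expect_equal(attr(out, "unconfirmed"), 2L)
})

test_that("filtering equals a naive row-by-row oracle on a simulated table", {
  cfg <- sim_config(n_families = 4, n_taxa = 8, n_sites_per_region = 1,
                    reads_per_sample = 800, total_cells_per_L = 1e8,
                    misannotation_rate = 0.05, dual_hit_rate = 0.05,
                    seed = 31)
  col <- generate_reference_collection(cfg)
  sc <- generate_community_scenario(cfg, col)
  sim <- list(sc = sc, sq = simulate_sequencing(sc, col, format = "hits"))
  sid <- sim$sc$samples$sample_id[2]
  hits <- sim$sq$hits[[sid]]
  reads <- sim$sq$reads[[sid]]
  res <- process_sample_hits(hits, reads)

  # naive oracle: evaluate each predicate per read with explicit loops
  th <- annotation_thresholds()
  oracle_std <- character(0)
  for (r in reads$read_id) {
    h <- hits[hits$qseqid == r & hits$subject_set == "standard_nuc", ]
    if (nrow(h) == 0) next
    h <- h[order(-h$bitscore, h$sseqid), ][1, ]
    rl <- reads$read_length[reads$read_id == r]
    if (h$evalue < th$evalue_max && h$pident > th$std_nuc_pident &&
        h$length > th$std_nuc_len_frac * rl && h$bitscore > th$std_nuc_bit) {
      oracle_std <- c(oracle_std, r)
    }
  }
  expect_gt(length(oracle_std), 0)
  expect_setequal(unlist(res$partition$standard_reads, use.names = FALSE),
                  oracle_std)

  oracle_viral <- 0L
  for (r in res$partition$community_reads) {
    hb <- hits[hits$qseqid == r & hits$subject_set == "refseq_prot" &
                 hits$bitscore >= th$refseq_bit, ]
    hv <- hits[hits$qseqid == r & hits$subject_set == "viral_prot" &
                 hits$bitscore >= th$refseq_bit, ]
    lab <- if (nrow(hb) == 0 && nrow(hv) == 0) "unannotated"
    else if (nrow(hb) == 0) "viral"
    else if (nrow(hv) == 0) "bacterial"
    else if (max(hv$bitscore) > max(hb$bitscore)) "viral" else "bacterial"
    expect_equal(res$annotations$label[res$annotations$read_id == r], lab)
    if (lab == "viral") oracle_viral <- oracle_viral + 1L
  }
  expect_equal(sum(res$annotations$label == "viral"), oracle_viral)
})

test_that("raising any threshold never increases retained reads", {
  sim <- small_sim(seed = 41, reads = 1500, format = "hits")
  sid <- sim$sc$samples$sample_id[1]
  hits <- sim$sq$hits[[sid]]
  reads <- sim$sq$reads[[sid]]

  n_std <- function(th) {
    p <- identify_standard_reads(hits, reads, thresholds = th)
    length(unlist(p$standard_reads))
  }
  n_annotated <- function(th) {
    p <- identify_standard_reads(hits, reads)
    a <- arbitrate_annotations(hits, p$community_reads, thresholds = th)
    sum(a$label != "unannotated")
  }
  base <- annotation_thresholds()
  for (knob in c("std_nuc_pident", "std_nuc_len_frac", "std_nuc_bit")) {
    prev <- Inf
    for (mult in c(0.5, 1, 1.5)) {
      th <- base; th[[knob]] <- base[[knob]] * mult
      cur <- n_std(th)
      expect_lte(cur, prev)
      prev <- cur
    }
  }
  prev <- Inf
  for (bit in c(30, 50, 80, 120)) {
    th <- base; th$refseq_bit <- bit
    cur <- n_annotated(th)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("viral-override fraction of dual-hit reads matches the simulated odds", {
  cfg <- sim_config(n_families = 4, n_taxa = 8, n_sites_per_region = 1,
                    reads_per_sample = 20000, dual_hit_rate = 0.2,
                    misannotation_rate = 0, seed = 51)
  col <- generate_reference_collection(cfg)
  sc <- subset_scenario(generate_community_scenario(cfg, col), 2)
  sq <- simulate_sequencing(sc, col, format = "hits")
  n_dual <- 0L; n_viral <- 0L
  for (sid in sc$samples$sample_id) {
    hits <- sq$hits[[sid]]
    reads <- sq$reads[[sid]]
    part <- identify_standard_reads(hits, reads)
    ann <- arbitrate_annotations(hits, part$community_reads)
    dual_ids <- unique(hits$qseqid[hits$subject_set == "viral_prot"])
    n_dual <- n_dual + length(dual_ids)
    n_viral <- n_viral +
      sum(ann$label[ann$read_id %in% dual_ids] == "viral")
  }
  # viral and bacterial bit scores are drawn iid, so P(viral wins) = 0.5
  p <- 0.5
  expect_lt(abs(n_viral / n_dual - p), 3 * sqrt(p * (1 - p) / n_dual))
})

test_that("hit tables round-trip through the tabular format", {
  sim <- small_sim(seed = 61, reads = 300, format = "hits")
  sid <- sim$sc$samples$sample_id[1]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(sim$sq$hits[[sid]], f)
  back <- read_hit_table(f)
  expect_equal(back, sim$sq$hits[[sid]], ignore_attr = TRUE,
               tolerance = 1e-10)
  bad <- sim$sq$hits[[sid]]
  bad$subject_set[1] <- "mystery"
  expect_error(validate_hit_table <- write_hit_table(bad, f), "subject_set")
})
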