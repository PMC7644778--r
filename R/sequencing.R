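#' Simulate spike-in calibrated metagenome sequencing
#'
#' Draws annotated reads for every sample of a scenario. Each sample's reads
#' are multinomial over (taxon, standard) categories where a taxon's weight is
#' `cells_per_L x volume_L x protein_gene_count` (its gene molecules in the
#' sample) and each standard's weight is `S_a x S_p` (gene molecules added).
#' Within a taxon's reads, recA reads are binomial with probability
#' `1/protein_gene_count`, enforcing single-copy semantics exactly. A
#' `misannotation_rate` fraction of community reads receives a bit score below
#' 50 and is lost to the downstream filters; a `dual_hit_rate` fraction also
#' receives a viral hit whose bit score is drawn independently from the same
#' distribution as the bacterial one, so the viral-override rule relabels half
#' of them in expectation.
#'
#' With `format = "counts"` the per-read bookkeeping is collapsed to exact
#' per-category counts (fast; used for large designs). With `format = "hits"`
#' full per-read hit tables are emitted in the extended tabular format of
#' [hit_tables], one per sample, ready for [identify_standard_reads()] and
#' friends. Both formats draw category counts from the same model.
#'
#' @param scenario A [generate_community_scenario()] result.
#' @param collection The matching [generate_reference_collection()] result.
#' @param format `"counts"` or `"hits"`.
#' @return A list of class `sim_sequencing`:
#'   \describe{
#'     \item{counts}{long data.frame per sample and taxon: `reads` (all reads
#'       drawn for the taxon), `low_bit` (misannotated, bit < 50), `dual`
#'       (reads that also carry a viral hit), `viral` (relabeled by the viral
#'       override), `recA` (recA reads that survive filtering and
#'       confirmation).}
#'     \item{recovery}{data.frame `sample_id`, `standard_id`, `S_s` (standard
#'       protein reads recovered).}
#'     \item{hits}{named list of per-sample hit tables (`format = "hits"`).}
#'     \item{reads}{named list of per-sample read-length tables
#'       (`read_id`, `read_length`; `format = "hits"`).}
#'   }
#' @export
simulate_sequencing <- function(scenario, collection,
                                format = c("counts", "hits")) {
  stopifnot(inherits(scenario, "community_scenario"),
            inherits(collection, "ref_collection"))
  format <- match.arg(format)
  config <- scenario$config
  taxa <- collection$taxa
  std <- collection$standards
  set.seed(config$seed + 2L)

  counts_list <- vector("list", nrow(scenario$samples))
  recovery_list <- vector("list", nrow(scenario$samples))
  hits_list <- list()
  reads_list <- list()

  for (j in seq_len(nrow(scenario$samples))) {
    sm <- scenario$samples[j, ]
    abund <- scenario$truth_matrix[, sm$sample_id]
    w_taxa <- abund * sm$volume_L * taxa$protein_gene_count
    w_std <- std$S_a * std$S_p
    w <- c(w_taxa, w_std)
    if (sum(w) <= 0) {
      stop("simulate_sequencing: zero total gene-molecule weight in sample ",
           sm$sample_id, call. = FALSE)
    }
    n <- as.vector(stats::rmultinom(1, config$reads_per_sample, w))
    n_taxa <- n[seq_len(nrow(taxa))]
    n_std <- n[nrow(taxa) + seq_len(nrow(std))]

    low_bit <- stats::rbinom(length(n_taxa), n_taxa, config$misannotation_rate)
    ok <- n_taxa - low_bit
    dual <- stats::rbinom(length(ok), ok, config$dual_hit_rate)
    viral <- stats::rbinom(length(dual), dual, 0.5)
    retained <- ok - viral
    recA <- stats::rbinom(length(retained), retained,
                          1 / taxa$protein_gene_count)

    counts_list[[j]] <- data.frame(
      sample_id = sm$sample_id, taxon_id = taxa$taxon_id,
      reads = n_taxa, low_bit = low_bit, dual = dual, viral = viral,
      recA = recA,
      stringsAsFactors = FALSE
    )
    recovery_list[[j]] <- data.frame(
      sample_id = sm$sample_id, standard_id = std$standard_id, S_s = n_std,
      stringsAsFactors = FALSE
    )

    if (format == "hits") {
      hl <- build_sample_hits(sm$sample_id, counts_list[[j]],
                              recovery_list[[j]], taxa, std)
      hits_list[[sm$sample_id]] <- hl$hits
      reads_list[[sm$sample_id]] <- hl$reads
    }
  }

  out <- list(counts = do.call(rbind, counts_list),
              recovery = do.call(rbind, recovery_list),
              config = config)
  if (format == "hits") {
    out$hits <- hits_list
    out$reads <- reads_list
  }
  class(out) <- "sim_sequencing"
  out
}

# Expand per-category counts into per-read hit-table rows for one sample.
# Standard reads pass the nucleotide and protein filters by construction;
# annotation noise is carried by the community reads (low_bit, viral flags).
build_sample_hits <- function(sample_id, counts, recovery, taxa, std) {
  n_comm <- sum(counts$reads)
  n_stdr <- sum(recovery$S_s)
  n_total <- n_comm + n_stdr
  read_id <- sprintf("%s_r%07d", sample_id, seq_len(n_total))
  qlen <- as.integer(round(stats::runif(n_total, 100, 290)))
  reads <- data.frame(read_id = read_id, read_length = qlen,
                      stringsAsFactors = FALSE)

  rows <- list()
  blast_row <- function(qseqid, sseqid, pident, length, evalue, bitscore,
                        qlen, subject_set) {
    data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
               length = length,
               mismatch = as.integer(round((1 - pident / 100) * length)),
               gapopen = 0L, qstart = 1L, qend = length,
               sstart = 1L, send = length,
               evalue = evalue, bitscore = bitscore, qlen = qlen,
               subject_set = subject_set, stringsAsFactors = FALSE)
  }

  # --- standard reads -------------------------------------------------
  i0 <- 0L
  for (k in seq_len(nrow(std))) {
    ns <- recovery$S_s[k]
    if (ns == 0) next
    idx <- i0 + seq_len(ns)
    ql <- qlen[idx]
    aln <- as.integer(ceiling(stats::runif(ns, 0.55, 0.95) * ql))
    rows[[length(rows) + 1L]] <- blast_row(
      read_id[idx], paste0(std$standard_id[k], "_genome"),
      pident = stats::runif(ns, 96, 99.9), length = aln,
      evalue = 10 ^ stats::runif(ns, -60, -20),
      bitscore = stats::runif(ns, 100, 280), qlen = ql,
      subject_set = "standard_nuc"
    )
    rows[[length(rows) + 1L]] <- blast_row(
      read_id[idx], sprintf("%s_p%04d", std$standard_id[k],
                            sample.int(std$S_p[k], ns, replace = TRUE)),
      pident = stats::runif(ns, 95, 100),
      length = as.integer(pmax(20, round(ql / 3 * 0.8))),
      evalue = 10 ^ stats::runif(ns, -40, -10),
      bitscore = stats::runif(ns, 40, 150), qlen = ql,
      subject_set = "standard_prot"
    )
    i0 <- i0 + ns
  }

  # --- community reads ------------------------------------------------
  for (t in seq_len(nrow(counts))) {
    nt <- counts$reads[t]
    if (nt == 0) next
    idx <- i0 + seq_len(nt)
    ql <- qlen[idx]
    tid <- counts$taxon_id[t]
    sp <- taxa$protein_gene_count[match(tid, taxa$taxon_id)]

    # read fates, consistent with the drawn per-category counts
    fate <- rep("ok", nt)
    fate[seq_len(counts$low_bit[t])] <- "low_bit"
    if (counts$viral[t] > 0) {
      fate[counts$low_bit[t] + seq_len(counts$viral[t])] <- "viral"
    }
    fate <- sample(fate)  # shuffle so fates are not positional
    # recA reads were drawn among retained reads; place them there
    is_recA <- rep(FALSE, nt)
    ret_idx <- which(fate == "ok")
    if (counts$recA[t] > 0) {
      is_recA[ret_idx[sample.int(length(ret_idx), counts$recA[t])]] <- TRUE
    }

    bact_bit <- ifelse(fate == "low_bit",
                       stats::runif(nt, 20, 49.5),
                       stats::runif(nt, 60, 200))
    gene_id <- ifelse(is_recA, paste0(tid, "_recA"),
                      sprintf("%s_g%04d", tid,
                              sample.int(max(sp - 1L, 1L), nt, replace = TRUE)))
    rows[[length(rows) + 1L]] <- blast_row(
      read_id[idx], gene_id,
      pident = stats::runif(nt, 70, 100),
      length = as.integer(pmax(20, round(ql / 3 * 0.8))),
      evalue = 10 ^ stats::runif(nt, -30, -5),
      bitscore = bact_bit, qlen = ql, subject_set = "refseq_prot"
    )

    # viral hits: every viral-override read gets one with a higher bit score;
    # an equal number of retained reads gets one with a lower bit score, so
    # dual-hit reads split between the two outcomes as drawn
    # dual-hit reads: the drawn winners (fate == "viral") plus dual - viral
    # reads whose bacterial annotation out-scores the viral hit
    n_vir <- counts$viral[t]
    loser_pool <- which(fate == "ok" & !is_recA)
    n_lose <- min(counts$dual[t] - n_vir, length(loser_pool))
    vir_sel <- c(which(fate == "viral"),
                 if (n_lose > 0) loser_pool[sample.int(length(loser_pool), n_lose)])
    if (length(vir_sel)) {
      wins <- fate[vir_sel] == "viral"
      vb <- numeric(length(vir_sel))
      vb[wins] <- bact_bit[vir_sel[wins]] + stats::runif(sum(wins), 1, 40)
      vb[!wins] <- pmax(25, bact_bit[vir_sel[!wins]] -
                          stats::runif(sum(!wins), 1, 40))
      rows[[length(rows) + 1L]] <- blast_row(
        read_id[idx][vir_sel],
        sprintf("vir_%05d", sample.int(99999, length(vir_sel), replace = TRUE)),
        pident = stats::runif(length(vir_sel), 60, 100),
        length = as.integer(pmax(20, round(ql[vir_sel] / 3 * 0.7))),
        evalue = 10 ^ stats::runif(length(vir_sel), -20, -4),
        bitscore = vb, qlen = ql[vir_sel], subject_set = "viral_prot"
      )
    }

    # recA-database hits for recA reads
    if (any(is_recA)) {
      ridx <- which(is_recA)
      rows[[length(rows) + 1L]] <- blast_row(
        read_id[idx][ridx], paste0(tid, "_recA"),
        pident = stats::runif(length(ridx), 80, 100),
        length = as.integer(pmax(20, round(ql[ridx] / 3 * 0.8))),
        evalue = 10 ^ stats::runif(length(ridx), -40, -10),
        bitscore = stats::runif(length(ridx), 60, 200),
        qlen = ql[ridx], subject_set = "recA_prot"
      )
    }
    i0 <- i0 + nt
  }

  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  list(hits = hits, reads = reads)
}

#' Protein titles for a synthetic reference collection
#'
#' Gene subject identifiers emitted by [simulate_sequencing()] follow
#' `<taxon>_recA` for the single-copy recombinase gene and `<taxon>_g<k>` for
#' all other genes; this helper builds the (id, title) table used by
#' [recA_title_members()] and [count_recA()] when confirming annotations.
#'
#' @param hits A hit table; titles are generated for its `refseq_prot` and
#'   `recA_prot` subject identifiers.
#' @return data.frame with `subject_id` and `title`.
#' @export
protein_titles <- function(hits) {
  ids <- unique(hits$sseqid[hits$subject_set %in% c("refseq_prot", "recA_prot")])
  taxon <- sub("_(recA|g[0-9]+)$", "", ids)
  title <- ifelse(grepl("_recA$", ids),
                  paste0("protein RecA [", taxon, "]"),
                  paste0("hypothetical protein [", taxon, "]"))
  data.frame(subject_id = ids, title = title, stringsAsFactors = FALSE)
}
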