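#' Annotation filtering thresholds
#'
#' All cutoffs used by the hit-arbitration stage, centralized in one place.
#' Strictness follows the filtering protocol literally: thresholds quoted with
#' a strict inequality are applied strictly, so a standard-read candidate at
#' exactly 95 percent identity fails (`> 95` required) while a standard
#' protein hit at exactly bit 40 or 95 percent identity is kept (hits are
#' removed only when `bit < 40` or `pident < 95`).
#'
#' @param evalue_max Maximum e-value for any considered hit (strict `<`).
#' @param std_nuc_pident Identity a standard nucleotide hit must exceed.
#' @param std_nuc_len_frac Fraction of the read length the alignment must
#'   exceed (nucleotide search).
#' @param std_nuc_bit Bit score a standard nucleotide hit must exceed.
#' @param std_prot_bit Standard protein hits below this bit score are removed.
#' @param std_prot_pident Standard protein hits below this identity are removed.
#' @param refseq_bit Community protein hits below this bit score are removed.
#' @param recA_bit Bit score a recA hit must exceed to be counted.
#' @return A named list of thresholds.
#' @export
annotation_thresholds <- function(evalue_max = 0.001,
                                  std_nuc_pident = 95,
                                  std_nuc_len_frac = 0.5,
                                  std_nuc_bit = 50,
                                  std_prot_bit = 40,
                                  std_prot_pident = 95,
                                  refseq_bit = 50,
                                  recA_bit = 50) {
  list(evalue_max = evalue_max, std_nuc_pident = std_nuc_pident,
       std_nuc_len_frac = std_nuc_len_frac, std_nuc_bit = std_nuc_bit,
       std_prot_bit = std_prot_bit, std_prot_pident = std_prot_pident,
       refseq_bit = refseq_bit, recA_bit = recA_bit)
}

#' Select the top hit among a read's hits in one subject set
#'
#' Deduplicates multi-hit reads to a single retained hit: the hit with the
#' maximal bit score, ties broken by lexicographically smallest subject
#' identifier, then first occurrence. For the `refseq_prot` set, hits with bit
#' score below 50 are removed before selection (so a read whose best hit is at
#' bit 49 ends up unannotated).
#'
#' @param hits_for_read Hit table rows sharing one `qseqid` and `subject_set`.
#' @param thresholds See [annotation_thresholds()].
#' @return A one-row hit table, or `NULL` if no hit survives.
#' @export
select_top_hit <- function(hits_for_read, thresholds = annotation_thresholds()) {
  if (is.null(hits_for_read) || nrow(hits_for_read) == 0) return(NULL)
  stopifnot(length(unique(hits_for_read$qseqid)) == 1,
            length(unique(hits_for_read$subject_set)) == 1)
  if (hits_for_read$subject_set[1] == "refseq_prot") {
    hits_for_read <- hits_for_read[hits_for_read$bitscore >= thresholds$refseq_bit, ,
                                   drop = FALSE]
    if (nrow(hits_for_read) == 0) return(NULL)
  }
  ord <- order(-hits_for_read$bitscore, hits_for_read$sseqid,
               seq_len(nrow(hits_for_read)))
  hits_for_read[ord[1], , drop = FALSE]
}

# Vectorized top-hit selection over a whole table, per (qseqid, subject_set).
top_hits <- function(hits, min_bit = NULL) {
  if (nrow(hits) == 0) return(hits)
  if (!is.null(min_bit)) {
    hits <- hits[hits$bitscore >= min_bit, , drop = FALSE]
    if (nrow(hits) == 0) return(hits)
  }
  key <- paste(hits$qseqid, hits$subject_set, sep = "\r")
  ord <- order(key, -hits$bitscore, hits$sseqid, seq_len(nrow(hits)))
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(key[ord]), , drop = FALSE]
}

#' Partition reads into internal-standard and community reads
#'
#' A read is an internal-standard read iff its best hit against the standard
#' genomes (nucleotide search) satisfies all four cutoffs: e-value below
#' 0.001, identity above 95 percent, alignment length above half the read
#' length, and bit score above 50. Standard reads are assigned to the standard
#' of their best hit and removed from all downstream annotation; every other
#' read is a community read.
#'
#' @param nuc_hits Hit table rows with `subject_set == "standard_nuc"`.
#' @param reads data.frame with `read_id` and `read_length` for every read in
#'   the sample (reads without a standard hit are community reads).
#' @param standard_of Function or named vector mapping a standard-genome
#'   subject identifier to its `standard_id`. Default strips a `_genome`
#'   suffix, matching the simulator's identifiers.
#' @param thresholds See [annotation_thresholds()].
#' @return A list of class `read_partition`: `standard_reads` (named list of
#'   read-identifier vectors, one per standard), `community_reads`, and
#'   `discarded` (data.frame `read_id`, `reason`; empty at this stage).
#' @export
identify_standard_reads <- function(nuc_hits, reads,
                                    standard_of = function(id) sub("_genome$", "", id),
                                    thresholds = annotation_thresholds()) {
  stopifnot(all(c("read_id", "read_length") %in% names(reads)))
  if (any(is.na(reads$read_length)) || any(reads$read_length <= 0)) {
    stop("identify_standard_reads: read_length missing or non-positive",
         call. = FALSE)
  }
  nuc_hits <- nuc_hits[nuc_hits$subject_set == "standard_nuc", , drop = FALSE]
  unknown <- setdiff(nuc_hits$qseqid, reads$read_id)
  if (length(unknown)) {
    stop("identify_standard_reads: hits for reads absent from the read table",
         call. = FALSE)
  }
  best <- top_hits(nuc_hits)
  rl <- reads$read_length[match(best$qseqid, reads$read_id)]
  pass <- best$evalue < thresholds$evalue_max &
    best$pident > thresholds$std_nuc_pident &
    best$length > thresholds$std_nuc_len_frac * rl &
    best$bitscore > thresholds$std_nuc_bit
  std_best <- best[pass, , drop = FALSE]
  sid <- if (is.function(standard_of)) standard_of(std_best$sseqid) else
    unname(standard_of[std_best$sseqid])
  standard_reads <- split(std_best$qseqid, sid)
  community <- setdiff(reads$read_id, std_best$qseqid)
  structure(list(standard_reads = standard_reads,
                 community_reads = community,
                 discarded = data.frame(read_id = character(0),
                                        reason = character(0),
                                        stringsAsFactors = FALSE)),
            class = "read_partition")
}

#' @export
print.read_partition <- function(x, ...) {
  ns <- vapply(x$standard_reads, length, integer(1))
  cat(sprintf("Read partition: %d standard read(s) [%s], %d community, %d discarded\n",
              sum(ns), paste(sprintf("%s: %d", names(ns), ns), collapse = ", "),
              length(x$community_reads), nrow(x$discarded)))
  invisible(x)
}

#' Count protein-encoding internal-standard reads (S_s)
#'
#' Standard reads are re-searched against the standard protein sequences;
#' hits with bit score below 40 or identity below 95 percent are removed
#' (kept on equality), after an e-value < 0.001 prefilter. The count of
#' surviving reads per standard is `S_s`, the numerator of the recovery ratio.
#'
#' @param prot_hits Hit table rows with `subject_set == "standard_prot"`,
#'   covering standard reads only.
#' @param partition A [identify_standard_reads()] result.
#' @param thresholds See [annotation_thresholds()].
#' @return Named numeric vector of `S_s` per standard (zeros included for
#'   standards present in the partition).
#' @export
count_standard_protein_reads <- function(prot_hits, partition,
                                         thresholds = annotation_thresholds()) {
  stopifnot(inherits(partition, "read_partition"))
  prot_hits <- prot_hits[prot_hits$subject_set == "standard_prot", , drop = FALSE]
  std_of_read <- rep(names(partition$standard_reads),
                     lengths(partition$standard_reads))
  names(std_of_read) <- unlist(partition$standard_reads, use.names = FALSE)
  if (!all(prot_hits$qseqid %in% names(std_of_read))) {
    stop("count_standard_protein_reads: protein hits for reads not in the standard partition",
         call. = FALSE)
  }
  prot_hits <- prot_hits[prot_hits$evalue < thresholds$evalue_max, , drop = FALSE]
  best <- top_hits(prot_hits)
  keep <- best$bitscore >= thresholds$std_prot_bit &
    best$pident >= thresholds$std_prot_pident
  counted <- std_of_read[best$qseqid[keep]]
  out <- stats::setNames(numeric(length(partition$standard_reads)),
                         names(partition$standard_reads))
  tb <- table(counted)
  out[names(tb)] <- as.numeric(tb)
  out
}

#' Arbitrate between a bacterial and a viral annotation for one read
#'
#' A retained bacterial annotation is replaced by the viral one iff the viral
#' hit has a strictly higher bit score; on ties the bacterial annotation is
#' kept. A read with only a viral hit is labeled viral; with neither hit it is
#' unannotated.
#'
#' @param bacterial_hit One-row hit table or `NULL`.
#' @param viral_hit One-row hit table or `NULL`.
#' @return One of `"bacterial"`, `"viral"`, `"unannotated"`.
#' @export
viral_override <- function(bacterial_hit, viral_hit) {
  has_b <- !is.null(bacterial_hit) && nrow(bacterial_hit) > 0
  has_v <- !is.null(viral_hit) && nrow(viral_hit) > 0
  if (!has_b && !has_v) return("unannotated")
  if (!has_b) return("viral")
  if (!has_v) return("bacterial")
  if (viral_hit$bitscore > bacterial_hit$bitscore) "viral" else "bacterial"
}

#' Final per-read community annotations after viral arbitration
#'
#' Applies top-hit selection with the bit-score cutoff to the bacterial
#' (`refseq_prot`) and viral (`viral_prot`) searches, then the
#' [viral_override()] rule read by read.
#'
#' @param hits Hit table containing `refseq_prot` and/or `viral_prot` rows for
#'   community reads.
#' @param read_ids Community read identifiers (reads without any surviving hit
#'   are reported unannotated).
#' @param thresholds See [annotation_thresholds()].
#' @return data.frame: `read_id`, `label` (bacterial/viral/unannotated),
#'   `subject_id`, `bitscore` (NA when unannotated).
#' @export
arbitrate_annotations <- function(hits, read_ids,
                                  thresholds = annotation_thresholds()) {
  bact <- top_hits(hits[hits$subject_set == "refseq_prot", , drop = FALSE],
                   min_bit = thresholds$refseq_bit)
  vir <- top_hits(hits[hits$subject_set == "viral_prot", , drop = FALSE],
                  min_bit = thresholds$refseq_bit)
  bb <- stats::setNames(bact$bitscore, bact$qseqid)
  vb <- stats::setNames(vir$bitscore, vir$qseqid)
  b <- unname(bb[read_ids]); v <- unname(vb[read_ids])
  label <- ifelse(is.na(b) & is.na(v), "unannotated",
                  ifelse(is.na(b), "viral",
                         ifelse(is.na(v), "bacterial",
                                ifelse(v > b, "viral", "bacterial"))))
  subject <- ifelse(label == "bacterial",
                    bact$sseqid[match(read_ids, bact$qseqid)],
                    ifelse(label == "viral",
                           vir$sseqid[match(read_ids, vir$qseqid)], NA))
  bit <- ifelse(label == "bacterial", b, ifelse(label == "viral", v, NA))
  data.frame(read_id = read_ids, label = label, subject_id = subject,
             bitscore = bit, stringsAsFactors = FALSE)
}
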