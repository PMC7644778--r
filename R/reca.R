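#' Select RecA proteins from reference titles
#'
#' Builds the membership of the single-copy-gene reference set by keyword:
#' a protein belongs iff its title contains any of the phrases
#' "recombinase RecA", "protein RecA", "recombinase A", or "RecA protein" as a
#' substring. Matching is case-sensitive by default (the phrases are quoted
#' verbatim from annotation practice); set `ignore_case = TRUE` for a
#' forgiving mode.
#'
#' @param titles data.frame with `subject_id` and `title`, or a named
#'   character vector of titles.
#' @param ignore_case Match case-insensitively.
#' @return Character vector of member `subject_id`s.
#' @export
#' @examples
#' t <- data.frame(subject_id = c("a", "b"),
#'                 title = c("protein RecA [Pelagibacter sp.]",
#'                           "recombinase RecB"))
#' recA_title_members(t)
recA_title_members <- function(titles, ignore_case = FALSE) {
  if (is.data.frame(titles)) {
    ids <- titles$subject_id
    txt <- titles$title
  } else {
    ids <- names(titles)
    txt <- unname(titles)
  }
  keywords <- c("recombinase RecA", "protein RecA", "recombinase A",
                "RecA protein")
  hit <- rep(FALSE, length(txt))
  for (kw in keywords) {
    hit <- hit | grepl(kw, txt, fixed = !ignore_case,
                       ignore.case = ignore_case)
  }
  ids[hit]
}

#' Count recA reads per taxon
#'
#' A community read counts as a recA gene for taxon T iff (i) its top hit
#' against the RecA reference set has bit score strictly above 50 and (ii) its
#' final community annotation (after the viral override) confirms a RecA
#' product, i.e. the annotation is bacterial and the annotated subject's title
#' matches the RecA keywords. The taxon is taken from the RecA search's
#' subject; when the two searches disagree on the taxon the RecA subject wins
#' and the conflict is tallied.
#'
#' @param recA_hits Hit table rows with `subject_set == "recA_prot"`.
#' @param annotations Per-read annotations from [arbitrate_annotations()].
#' @param titles Protein title table (`subject_id`, `title`) covering the
#'   annotated subjects, used for confirmation; see [recA_title_members()].
#' @param subject_taxon Function or named vector mapping a protein subject
#'   identifier to its taxon. Default strips the simulator's gene suffixes.
#' @param thresholds See [annotation_thresholds()].
#' @param ignore_case Passed to [recA_title_members()].
#' @return data.frame `taxon_id`, `recA` (read counts), with attributes
#'   `conflicts` (number of reads whose two searches named different taxa) and
#'   `unconfirmed` (reads whose RecA hit passed the bit cutoff but whose
#'   community annotation did not confirm a RecA product).
#' @export
count_recA <- function(recA_hits, annotations, titles,
                       subject_taxon = function(id) sub("_(recA|g[0-9]+)$", "", id),
                       thresholds = annotation_thresholds(),
                       ignore_case = FALSE) {
  map_taxon <- function(id) {
    if (is.function(subject_taxon)) subject_taxon(id) else
      unname(subject_taxon[id])
  }
  best <- top_hits(recA_hits[recA_hits$subject_set == "recA_prot", ,
                             drop = FALSE])
  best <- best[best$bitscore > thresholds$recA_bit, , drop = FALSE]
  if (nrow(best) == 0) {
    out <- data.frame(taxon_id = character(0), recA = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "conflicts") <- 0L
    attr(out, "unconfirmed") <- 0L
    return(out)
  }
  recA_ids <- recA_title_members(titles, ignore_case = ignore_case)
  ann <- annotations[match(best$qseqid, annotations$read_id), ]
  confirmed <- !is.na(ann$label) & ann$label == "bacterial" &
    ann$subject_id %in% recA_ids
  unconfirmed <- sum(!confirmed)
  best <- best[confirmed, , drop = FALSE]
  ann <- ann[confirmed, , drop = FALSE]
  taxon <- map_taxon(best$sseqid)
  conflicts <- sum(taxon != map_taxon(ann$subject_id), na.rm = TRUE)
  tb <- table(taxon)
  out <- data.frame(taxon_id = names(tb), recA = as.numeric(tb),
                    stringsAsFactors = FALSE)
  attr(out, "conflicts") <- conflicts
  attr(out, "unconfirmed") <- unconfirmed
  out
}

#' Run the whole filtering stage on one sample's hit tables
#'
#' Convenience wrapper chaining [identify_standard_reads()],
#' [count_standard_protein_reads()], [arbitrate_annotations()] and
#' [count_recA()] for one sample.
#'
#' @param hits Extended-format hit table for the sample (all subject sets).
#' @param reads data.frame `read_id`, `read_length` for every sequenced read.
#' @param titles Protein titles; defaults to [protein_titles()] of `hits`.
#' @param thresholds See [annotation_thresholds()].
#' @return List: `partition`, `S_s` (named vector), `annotations`,
#'   `recA_counts`.
#' @export
process_sample_hits <- function(hits, reads, titles = protein_titles(hits),
                                thresholds = annotation_thresholds()) {
  part <- identify_standard_reads(hits, reads, thresholds = thresholds)
  S_s <- count_standard_protein_reads(hits, part, thresholds = thresholds)
  comm <- hits[hits$qseqid %in% part$community_reads &
                 hits$subject_set %in% c("refseq_prot", "viral_prot"), ,
               drop = FALSE]
  ann <- arbitrate_annotations(comm, part$community_reads,
                               thresholds = thresholds)
  recA_tab <- count_recA(
    hits[hits$qseqid %in% part$community_reads &
           hits$subject_set == "recA_prot", , drop = FALSE],
    ann, titles, thresholds = thresholds)
  list(partition = part, S_s = S_s, annotations = ann,
       recA_counts = recA_tab)
}
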