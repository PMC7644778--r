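#' BLAST/DIAMOND tabular hit tables
#'
#' The pipeline consumes homology-search results in the standard 12-column
#' tabular format (`qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`) extended by two columns: `qlen` (query length)
#' and `subject_set` (which reference database was searched: `standard_nuc`,
#' `standard_prot`, `refseq_prot`, `viral_prot` or `recA_prot`). Files carry no
#' header line, as written by `blastn -outfmt 6` / `diamond blastx`.
#'
#' @name hit_tables
NULL

hit_table_columns <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore",
    "qlen", "subject_set")
}

subject_sets <- function() {
  c("standard_nuc", "standard_prot", "refseq_prot", "viral_prot", "recA_prot")
}

#' Read a tabular hit file
#'
#' @param path File in extended 12+2 column tabular format (no header).
#' @return data.frame with the columns of [hit_tables].
#' @export
read_hit_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = hit_table_columns(),
                          colClasses = c("character", "character",
                                         rep("numeric", 10),
                                         "integer", "character"),
                          quote = "", comment.char = "")
  validate_hit_table(df)
}

#' Write a tabular hit file
#'
#' @param hits Hit table data.frame.
#' @param path Output path; written tab-separated without header.
#' @export
write_hit_table <- function(hits, path) {
  hits <- validate_hit_table(hits)
  utils::write.table(hits[, hit_table_columns()], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_hit_table <- function(hits) {
  missing <- setdiff(hit_table_columns(), names(hits))
  if (length(missing)) {
    stop("hit table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(hits$subject_set), subject_sets())
  if (length(bad)) {
    stop("unknown subject_set value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(hits$bitscore)) || any(hits$bitscore < 0)) {
    stop("bit scores must be finite and >= 0", call. = FALSE)
  }
  hits
}
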