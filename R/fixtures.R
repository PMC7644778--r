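#' Write a simulated scenario to disk as a fixture set
#'
#' Emits everything a downstream analysis needs as plain-text files: one hit
#' table per sample (extended tabular format), per-sample read-length tables,
#' sample metadata, the ground-truth abundance table, the standards table, and
#' a `manifest.tsv` listing every file with its row count. The configuration is
#' recorded in `config.dcf`.
#'
#' @param scenario A [generate_community_scenario()] result.
#' @param sequencing A [simulate_sequencing()] result with `format = "hits"`.
#' @param collection The matching reference collection.
#' @param path Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_fixture_set <- function(scenario, sequencing, collection, path) {
  if (is.null(sequencing$hits)) {
    stop("write_fixture_set: sequencing must be simulated with format = \"hits\"",
         call. = FALSE)
  }
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    stop("write_fixture_set: cannot create directory ", path, call. = FALSE)
  }
  files <- character(0); rows <- integer(0)
  emit <- function(df, name) {
    utils::write.table(df, file.path(path, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, name); rows <<- c(rows, nrow(df))
  }
  emit(scenario$samples, "metadata.tsv")
  emit(scenario$truth, "truth.tsv")
  emit(collection$taxa, "taxa.tsv")
  emit(collection$standards, "standards.tsv")
  for (sid in names(sequencing$hits)) {
    hn <- paste0("hits_", sid, ".tsv")
    write_hit_table(sequencing$hits[[sid]], file.path(path, hn))
    files <- c(files, hn); rows <- c(rows, nrow(sequencing$hits[[sid]]))
    rn <- paste0("reads_", sid, ".tsv")
    emit(sequencing$reads[[sid]], rn)
  }
  cfg <- scenario$config
  dcf <- data.frame(field = names(cfg)[!vapply(cfg, is.null, logical(1))])
  dcf$value <- vapply(cfg[dcf$field], function(v)
    paste(format(v, digits = 15), collapse = ","), character(1))
  utils::write.table(dcf, file.path(path, "config.dcf"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- data.frame(file = files, rows = rows, stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(path, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a fixture set back from disk
#'
#' @param path Directory written by [write_fixture_set()].
#' @return A list with `metadata`, `truth`, `taxa`, `standards`, `hits`
#'   (named list), `reads` (named list), and `manifest`.
#' @export
read_fixture_set <- function(path) {
  manifest <- utils::read.delim(file.path(path, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  need <- c("metadata.tsv", "truth.tsv", "taxa.tsv", "standards.tsv")
  missing <- setdiff(need, manifest$file)
  if (length(missing)) {
    stop("fixture set at ", path, " is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rd <- function(name) utils::read.delim(file.path(path, name),
                                         stringsAsFactors = FALSE)
  out <- list(metadata = rd("metadata.tsv"), truth = rd("truth.tsv"),
              taxa = rd("taxa.tsv"), standards = rd("standards.tsv"),
              hits = list(), reads = list(), manifest = manifest)
  for (f in manifest$file[startsWith(manifest$file, "hits_")]) {
    sid <- sub("^hits_(.*)\\.tsv$", "\\1", f)
    out$hits[[sid]] <- read_hit_table(file.path(path, f))
  }
  for (f in manifest$file[startsWith(manifest$file, "reads_")]) {
    sid <- sub("^reads_(.*)\\.tsv$", "\\1", f)
    out$reads[[sid]] <- rd(f)
  }
  out
}
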