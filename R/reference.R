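#' Generate a synthetic reference collection
#'
#' Builds the taxon/family reference tables the rest of the pipeline consumes:
#' one row per community taxon with its family, genome length, protein-gene
#' count and reference-bin identifiers, plus three genomic spike-in standards
#' that are not part of the community. Genome lengths are drawn log-uniformly
#' between 1.3 and 9 Mbp; each genome carries one protein-coding gene per
#' kilobase (rounded, at least one) of which exactly one is the single-copy
#' recombinase gene recA.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `ref_collection` with elements
#'   \describe{
#'     \item{taxa}{data.frame: `taxon_id`, `family`, `genome_length`,
#'       `protein_gene_count`, `has_recA`, `reference_bins`
#'       (comma-separated bin identifiers).}
#'     \item{standards}{data.frame: `standard_id`, `genome_length`,
#'       `S_p` (protein genes), `mass_added_ng`, `S_a` (molecules added,
#'       from [molecules_added()]).}
#'     \item{seed}{the seed used.}
#'   }
#' @export
#' @examples
#' col <- generate_reference_collection(sim_config(n_families = 5, n_taxa = 10))
#' nrow(col$taxa)
generate_reference_collection <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  n <- config$n_taxa
  taxon_id <- sprintf("tax%03d", seq_len(n))
  family <- sprintf("fam%02d", rep_len(seq_len(config$n_families), n))
  genome_length <- round(10 ^ stats::runif(n, log10(1.3e6), log10(9e6)))
  protein_gene_count <- pmax(1L, as.integer(round(genome_length / 1000)))
  n_bins <- sample(1:3, n, replace = TRUE)
  reference_bins <- vapply(seq_len(n), function(i) {
    paste(sprintf("%s_bin%02d", taxon_id[i], seq_len(n_bins[i])),
          collapse = ",")
  }, character(1))

  taxa <- data.frame(
    taxon_id = taxon_id,
    family = family,
    genome_length = genome_length,
    protein_gene_count = protein_gene_count,
    has_recA = TRUE,
    reference_bins = reference_bins,
    stringsAsFactors = FALSE
  )

  # Three spike-in standards with genome sizes typical of the cultured,
  # non-marine genomes used as internal standards.
  standards <- data.frame(
    standard_id = c("std_A", "std_B", "std_C"),
    genome_length = c(2.1e6, 3.2e6, 6.1e6),
    stringsAsFactors = FALSE
  )
  standards$S_p <- pmax(1L, as.integer(round(standards$genome_length / 1000)))
  standards$mass_added_ng <- config$standard_mass_ng
  standards$S_a <- molecules_added(standards$mass_added_ng,
                                   standards$genome_length)

  structure(list(taxa = taxa, standards = standards, seed = config$seed),
            class = "ref_collection")
}

#' @export
print.ref_collection <- function(x, ...) {
  cat(sprintf("Reference collection: %d taxa / %d families, %d standards (seed %d)\n",
              nrow(x$taxa), length(unique(x$taxa$family)), nrow(x$standards),
              x$seed))
  invisible(x)
}

#' Taxon to family lookup from a reference collection
#' @param collection A `ref_collection`.
#' @return Named character vector mapping `taxon_id` to `family`.
#' @export
taxon_family_map <- function(collection) {
  stats::setNames(collection$taxa$family, collection$taxa$taxon_id)
}
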