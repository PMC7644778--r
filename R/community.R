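#' Bin taxon abundances at the family level
#'
#' Sums member-taxon values within each family, per sample. Taxa without a
#' family mapping are collected in an `"unclassified"` family and reported via
#' a message.
#'
#' @param taxon_abundances taxa x samples numeric matrix (rownames are taxon
#'   identifiers), e.g. from [abundance_matrix()].
#' @param mapping Named character vector `taxon_id -> family`, e.g. from
#'   [taxon_family_map()].
#' @return families x samples numeric matrix; column sums equal those of the
#'   input exactly.
#' @export
bin_by_family <- function(taxon_abundances, mapping) {
  fam <- unname(mapping[rownames(taxon_abundances)])
  unmapped <- is.na(fam)
  if (any(unmapped)) {
    message(sum(unmapped), " taxa without family mapping -> 'unclassified'")
    fam[unmapped] <- "unclassified"
  }
  rowsum(taxon_abundances, group = fam)
}

#' Abundance class of a volumetric abundance
#'
#' Four classes partition the non-negative axis: dominant (> 1e8 cells/L),
#' abundant (> 1e7), minor (> 1e6), rare (everything else, including the
#' boundary values themselves — thresholds are strict).
#'
#' @param value Cells per liter (>= 0; vectorized).
#' @param thresholds Named vector with `dominant`, `abundant`, `minor` lower
#'   bounds (strict).
#' @return factor with levels `dominant`, `abundant`, `minor`, `rare`.
#' @export
#' @examples
#' classify_abundance(c(2e8, 5e6, 1e6))
classify_abundance <- function(value,
                               thresholds = c(dominant = 1e8,
                                              abundant = 1e7,
                                              minor = 1e6)) {
  if (any(value < 0)) {
    stop("classify_abundance: abundances must be >= 0", call. = FALSE)
  }
  cls <- ifelse(value > thresholds["dominant"], "dominant",
                ifelse(value > thresholds["abundant"], "abundant",
                       ifelse(value > thresholds["minor"], "minor", "rare")))
  factor(cls, levels = c("dominant", "abundant", "minor", "rare"))
}

#' Relative abundances (percent of sample total)
#'
#' @param family_table families x samples matrix of non-negative values.
#' @return Matrix of percentages; each column sums to 100.
#' @export
relative_abundance <- function(family_table) {
  totals <- colSums(family_table)
  if (any(totals == 0)) {
    stop("relative_abundance: sample(s) with zero total: ",
         paste(colnames(family_table)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(family_table, 2, totals, "/") * 100
}

#' Top-n families by overall abundance
#'
#' Families are ranked by their total across samples; ties at the cut are
#' broken lexicographically. Also reports what fraction of the grand total the
#' selected families contain.
#'
#' @param family_table families x samples matrix.
#' @param n Number of families to keep (capped at the number available).
#' @return List: `families` (character), `coverage` (fraction of grand total).
#' @export
top_n_families <- function(family_table, n) {
  if (n < 1) stop("top_n_families: n must be >= 1", call. = FALSE)
  totals <- rowSums(family_table)
  ord <- order(-totals, rownames(family_table))
  n <- min(n, nrow(family_table))
  keep <- rownames(family_table)[ord[seq_len(n)]]
  list(families = keep, coverage = sum(totals[keep]) / sum(totals))
}

#' Rank-order reference-bin recruitment
#'
#' Per sample, reference bins are ranked 1 (highest read count) to B; ties
#' share the minimum rank of the tied block (competition ranking). Samples
#' that are entirely `NA` are returned as `NA` columns (no metagenome
#' acquired).
#'
#' @param read_counts bins x samples matrix of read counts (>= 0, or NA
#'   columns for missing samples).
#' @return bins x samples integer matrix of ranks.
#' @export
#' @examples
#' m <- cbind(s1 = c(50, 50, 20))
#' rank_recruitment(m)
rank_recruitment <- function(read_counts) {
  apply(read_counts, 2, function(x) {
    if (all(is.na(x))) return(rep(NA_integer_, length(x)))
    if (any(x < 0, na.rm = TRUE)) {
      stop("rank_recruitment: counts must be >= 0", call. = FALSE)
    }
    as.integer(rank(-x, ties.method = "min"))
  })
}
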