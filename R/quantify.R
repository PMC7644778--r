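#' Molecules of a genomic standard added from its mass
#'
#' Converts a dsDNA mass to genome molecule counts using the average molar
#' mass of a base pair (650 g/mol/bp) and the Avogadro constant. Both
#' constants are arguments so alternative conventions can be used.
#'
#' @param mass_ng Mass added, nanograms (> 0).
#' @param genome_length Genome length, base pairs (> 0).
#' @param bp_molar_mass Molar mass per base pair, g/mol/bp.
#' @param avogadro Avogadro constant, 1/mol.
#' @return Molecules added (`S_a`).
#' @export
#' @examples
#' molecules_added(4, 2e6)  # ~1.853e6 molecules
molecules_added <- function(mass_ng, genome_length,
                            bp_molar_mass = 650,
                            avogadro = 6.02214076e23) {
  if (any(mass_ng <= 0) || any(genome_length <= 0)) {
    stop("molecules_added: mass and genome length must be positive",
         call. = FALSE)
  }
  (mass_ng * 1e-9) / (genome_length * bp_molar_mass) * avogadro
}

#' Recovery ratio of an internal standard
#'
#' `S_r = S_s / S_p` converts protein-encoding standard reads into genome
#' copies recovered; `R = S_r / S_a` is the proportion of added standard
#' molecules that were sequenced — the sample's normalization constant.
#'
#' @param S_s Standard protein reads recovered (>= 0).
#' @param S_p Protein-encoding genes in the standard genome (>= 1).
#' @param S_a Molecules of standard genome added (> 0).
#' @return List with `S_r` and `R` (vectorized).
#' @export
#' @examples
#' recovery_ratio(4000, 2000, 2e6)  # S_r = 2, R = 1e-6
recovery_ratio <- function(S_s, S_p, S_a) {
  if (any(S_p < 1)) stop("recovery_ratio: S_p must be >= 1", call. = FALSE)
  if (any(S_a <= 0)) stop("recovery_ratio: S_a must be > 0", call. = FALSE)
  if (any(S_s < 0)) stop("recovery_ratio: S_s must be >= 0", call. = FALSE)
  S_r <- S_s / S_p
  list(S_r = S_r, R = S_r / S_a)
}

#' Volumetric abundance of a gene category
#'
#' Divides the read count of a gene category by the recovery ratio to obtain
#' molecules in the sample, then by the seawater volume filtered to obtain
#' genes per liter.
#'
#' @param G_s Reads of the gene category in the library (>= 0).
#' @param R Recovery ratio (> 0; 0 only allowed when `G_s` is 0).
#' @param V Seawater volume filtered, liters (> 0).
#' @return Genes per liter.
#' @export
#' @examples
#' gene_abundance(100, 1e-6, 2)  # 5e7 genes/L
gene_abundance <- function(G_s, R, V) {
  if (any(V <= 0)) stop("gene_abundance: V must be > 0", call. = FALSE)
  if (any(G_s < 0)) stop("gene_abundance: G_s must be >= 0", call. = FALSE)
  if (any(R < 0)) stop("gene_abundance: R must be >= 0", call. = FALSE)
  bad <- R == 0 & G_s > 0
  if (any(bad)) {
    stop("gene_abundance: zero recovery ratio with non-zero counts; abundance undefined",
         call. = FALSE)
  }
  if (any(R == 0)) {
    warning("gene_abundance: zero recovery ratio with zero counts; returning 0")
  }
  n <- max(length(G_s), length(R), length(V))
  G_s <- rep_len(G_s, n); R <- rep_len(R, n); V <- rep_len(V, n)
  out <- numeric(n)
  nz <- R > 0
  out[nz] <- (G_s[nz] / R[nz]) / V[nz]
  names(out) <- names(G_s)
  out
}

#' Total protein-encoding genes per liter
#'
#' The community-wide gene abundance: the total annotated read count divided
#' by the recovery ratio and volume.
#'
#' @inheritParams gene_abundance
#' @param total_reads Total annotated reads in the library.
#' @return Genes per liter.
#' @export
total_protein_genes <- function(total_reads, R, V) {
  gene_abundance(total_reads, R, V)
}

#' Genome equivalents (cells per liter) from single-copy gene counts
#'
#' Because recA occurs exactly once per genome, recA read counts divided by
#' the recovery ratio and volume estimate genomes — and hence cells — per
#' liter.
#'
#' @param recA_count recA reads annotated for the taxon (>= 0).
#' @inheritParams gene_abundance
#' @return Cells per liter.
#' @export
#' @examples
#' genome_equivalents(50, 1e-6, 1)  # 5e7 cells/L
genome_equivalents <- function(recA_count, R, V) {
  gene_abundance(recA_count, R, V)
}

#' Percent coefficient of variation across the three standards
#'
#' `%CV = sd / mean x 100` with the sample (n-1) standard deviation, the
#' per-sample summary of how consistently the standards were recovered.
#'
#' @param R_values Recovery ratios of the standards in one sample (length 3).
#' @return Percent CV.
#' @export
#' @examples
#' standards_cv(c(1, 2, 3))  # 50
standards_cv <- function(R_values) {
  if (length(R_values) != 3) {
    stop("standards_cv: exactly three per-standard values expected",
         call. = FALSE)
  }
  m <- mean(R_values)
  if (m == 0) stop("standards_cv: mean recovery is zero; %CV undefined",
                   call. = FALSE)
  stats::sd(R_values) / m * 100
}

#' 95 percent confidence interval from the three per-standard estimates
#'
#' A t-distribution interval (df = 2) around the mean of the three
#' per-standard abundance estimates, floored at zero.
#'
#' @param per_standard Three abundance estimates for one taxon and sample.
#' @param level Confidence level.
#' @return Named vector `c(low, high)`; `NA` with a warning when fewer than
#'   three estimates are supplied.
#' @export
abundance_ci <- function(per_standard, level = 0.95) {
  if (length(per_standard) < 3 || anyNA(per_standard)) {
    warning("abundance_ci: fewer than three per-standard estimates; CI undefined")
    return(c(low = NA_real_, high = NA_real_))
  }
  n <- length(per_standard)
  m <- mean(per_standard)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) *
    stats::sd(per_standard) / sqrt(n)
  c(low = max(0, m - half), high = m + half)
}

#' Detection limit of the sequencing library
#'
#' The volumetric abundance at which one read of a single-copy gene is
#' expected: `1 / (R x V)`. Below it, a taxon is more often missed than seen.
#' An alternative Poisson definition returns the abundance at which the
#' probability of observing at least one read reaches `p_detect`.
#'
#' @param R Recovery ratio (> 0).
#' @param V Volume filtered, liters (> 0).
#' @param method `"expected_one"` (default) or `"poisson"`.
#' @param p_detect Detection probability for `method = "poisson"`.
#' @return Cells per liter.
#' @export
#' @examples
#' detection_limit(1e-6, 2)  # 5e5 cells/L
detection_limit <- function(R, V, method = c("expected_one", "poisson"),
                            p_detect = 0.95) {
  method <- match.arg(method)
  if (any(R <= 0) || any(V <= 0)) {
    stop("detection_limit: R and V must be positive", call. = FALSE)
  }
  if (method == "expected_one") 1 / (R * V) else -log(1 - p_detect) / (R * V)
}

#' Volumetric abundance table from recA counts and standard recoveries
#'
#' The sample-level assembly of the whole quantification stage. Per sample,
#' each standard's recovery ratio is computed from its `S_s`, `S_p`, `S_a`;
#' the point estimate of every taxon's cells per liter uses the arithmetic
#' mean R of the three standards, while the per-standard estimates provide a
#' 95 percent confidence interval and the percent CV. Zero-count taxa are
#' reported as 0 cells per liter with the sample's detection limit attached,
#' never as missing.
#'
#' @param counts data.frame `sample_id`, `taxon_id`, `recA` (reads).
#' @param recovery data.frame `sample_id`, `standard_id`, `S_s`.
#' @param standards data.frame `standard_id`, `S_p`, `S_a`.
#' @param metadata data.frame `sample_id`, `volume_L` (extra columns kept).
#' @return Object of class `abundance_table`: a data.frame with one row per
#'   (taxon, sample): `cells_per_L`, `ci_low`, `ci_high`, `R_mean`,
#'   `cv_percent` (of the standard recoveries), `detection_limit`.
#'   The per-sample recovery summary is attached as attribute `recovery`.
#' @export
quantify_samples <- function(counts, recovery, standards, metadata) {
  stopifnot(all(c("sample_id", "taxon_id", "recA") %in% names(counts)),
            all(c("sample_id", "standard_id", "S_s") %in% names(recovery)),
            all(c("standard_id", "S_p", "S_a") %in% names(standards)),
            all(c("sample_id", "volume_L") %in% names(metadata)))
  recovery <- merge(recovery, standards[, c("standard_id", "S_p", "S_a")],
                    by = "standard_id", sort = FALSE)
  rr <- recovery_ratio(recovery$S_s, recovery$S_p, recovery$S_a)
  recovery$R <- rr$R

  samples <- unique(metadata$sample_id)
  taxa <- sort(unique(counts$taxon_id))
  rows <- vector("list", length(samples))
  rec_summary <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    sid <- samples[i]
    V <- metadata$volume_L[match(sid, metadata$sample_id)]
    Rs <- recovery$R[recovery$sample_id == sid]
    if (length(Rs) == 0 || all(Rs == 0)) {
      stop("quantify_samples: no standard recovery for sample ", sid,
           call. = FALSE)
    }
    R_mean <- mean(Rs)
    cv <- if (length(Rs) == 3) standards_cv(Rs) else NA_real_
    dl <- detection_limit(R_mean, V)
    cnt <- counts[counts$sample_id == sid, ]
    n_recA <- stats::setNames(rep(0, length(taxa)), taxa)
    n_recA[cnt$taxon_id] <- cnt$recA
    est <- genome_equivalents(n_recA, R_mean, V)
    if (length(Rs) == 3 && all(Rs > 0)) {
      per_std <- vapply(Rs, function(R) genome_equivalents(n_recA, R, V),
                        numeric(length(taxa)))
      ci <- t(apply(per_std, 1, abundance_ci))
    } else {
      if (any(Rs == 0)) {
        warning("quantify_samples: standard with zero recovery in sample ",
                sid, "; per-standard CIs unavailable")
      }
      ci <- matrix(NA_real_, length(taxa), 2)
    }
    rows[[i]] <- data.frame(
      taxon_id = taxa, sample_id = sid, recA = as.numeric(n_recA),
      cells_per_L = as.numeric(est),
      ci_low = ci[, 1], ci_high = ci[, 2],
      R_mean = R_mean, cv_percent = cv, detection_limit = dl,
      volume_L = V, stringsAsFactors = FALSE
    )
    rec_summary[[i]] <- data.frame(sample_id = sid, R_mean = R_mean,
                                   cv_percent = cv, detection_limit = dl,
                                   stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "recovery") <- do.call(rbind, rec_summary)
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d taxa x %d samples\n",
              length(unique(x$taxon_id)), length(unique(x$sample_id))))
  rec <- attr(x, "recovery")
  if (is.data.frame(rec)) {
    cat(sprintf("  mean R: %.3g; mean %%CV of standards: %.1f; mean detection limit: %.3g cells/L\n",
                mean(rec$R_mean), mean(rec$cv_percent, na.rm = TRUE),
                mean(rec$detection_limit)))
  }
  NextMethod()
}

#' Wide matrix view of an abundance table
#'
#' @param x An `abundance_table`.
#' @param value Column to spread (default `cells_per_L`).
#' @return taxa x samples numeric matrix.
#' @export
abundance_matrix <- function(x, value = "cells_per_L") {
  taxa <- sort(unique(x$taxon_id))
  samples <- unique(x$sample_id)
  m <- matrix(0, length(taxa), length(samples),
              dimnames = list(taxa, samples))
  m[cbind(match(x$taxon_id, taxa), match(x$sample_id, samples))] <- x[[value]]
  m
}
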