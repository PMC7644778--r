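#' Simulation configuration
#'
#' Bundles every tunable of the community/sequencing simulator into a single
#' validated object. The defaults describe a surface pelagic bacterioplankton
#' survey: an archipelago split into five regions sampled in two years, three
#' genomic standards spiked at 4 ng each, a west-to-east abundance gradient
#' spanning 1.5 orders of magnitude for designated families, and
#' order-of-magnitude year effects for designated indicator families.
#'
#' @param n_families Number of bacterial families in the community.
#' @param n_taxa Number of taxa (>= `n_families`); taxa are distributed round
#'   robin over families so every family has at least one member.
#' @param n_sites_per_region Sites simulated per region; the five regions are
#'   `west`, `north`, `central`, `caldera`, `east`, sampled in both years.
#' @param gradient_log10_span Log10 span of the multiplicative west-to-east
#'   abundance gradient applied to `gradient_families`.
#' @param gradient_families Family identifiers carrying the spatial gradient.
#'   `NULL` (default) selects the first family.
#' @param elnino_indicator_families Named numeric vector mapping family
#'   identifiers to the multiplier applied in year 1 only (e.g. `c(fam03 =
#'   0.1)` for a ten-fold El Nino drop). Empty by default.
#' @param reads_per_sample Sequencing depth per sample (annotated read level).
#' @param standard_mass_ng DNA mass of each genomic standard added per sample,
#'   in nanograms.
#' @param total_cells_per_L Target total community abundance (cells per liter)
#'   around which per-taxon baselines are drawn. Must stay within
#'   `total_bounds`.
#' @param total_bounds Admissible range for the realized total community
#'   abundance, cells per liter.
#' @param volume_L Seawater volume filtered per sample, liters.
#' @param noise_sd_log10 Per taxon-sample log-normal noise, in log10 units.
#' @param misannotation_rate Probability that a community read receives a low
#'   scoring annotation (bit score below 50) and is lost to the downstream
#'   filters.
#' @param dual_hit_rate Probability that a community read receives both a
#'   bacterial and a viral hit with independent bit scores.
#' @param seed Integer seed recorded in all simulator outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_families = 5, n_taxa = 10, seed = 1)
#' cfg$reads_per_sample
sim_config <- function(n_families = 30,
                       n_taxa = 60,
                       n_sites_per_region = 2,
                       gradient_log10_span = 1.5,
                       gradient_families = NULL,
                       elnino_indicator_families = numeric(0),
                       reads_per_sample = 1e5,
                       standard_mass_ng = 4,
                       total_cells_per_L = 1.5e9,
                       total_bounds = c(1e8, 1e10),
                       volume_L = 2,
                       noise_sd_log10 = 0.3,
                       misannotation_rate = 0.01,
                       dual_hit_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    n_taxa = as.integer(n_taxa),
    n_sites_per_region = as.integer(n_sites_per_region),
    gradient_log10_span = gradient_log10_span,
    gradient_families = gradient_families,
    elnino_indicator_families = elnino_indicator_families,
    reads_per_sample = as.integer(reads_per_sample),
    standard_mass_ng = standard_mass_ng,
    total_cells_per_L = total_cells_per_L,
    total_bounds = total_bounds,
    volume_L = volume_L,
    noise_sd_log10 = noise_sd_log10,
    misannotation_rate = misannotation_rate,
    dual_hit_rate = dual_hit_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_families < 1L || cfg$n_taxa < 1L || cfg$n_sites_per_region < 1L ||
      cfg$reads_per_sample < 1L) {
    stop("sim_config: counts must be >= 1", call. = FALSE)
  }
  if (cfg$n_taxa < cfg$n_families) {
    stop("sim_config: n_taxa must be >= n_families", call. = FALSE)
  }
  for (p in c("misannotation_rate", "dual_hit_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("sim_config: %s must lie in [0, 1]", p), call. = FALSE)
    }
  }
  if (cfg$standard_mass_ng <= 0 || cfg$volume_L <= 0 ||
      cfg$total_cells_per_L <= 0 || cfg$noise_sd_log10 < 0) {
    stop("sim_config: masses, volumes and scales must be positive",
         call. = FALSE)
  }
  if (cfg$total_cells_per_L < cfg$total_bounds[1] ||
      cfg$total_cells_per_L > cfg$total_bounds[2]) {
    stop("sim_config: total_cells_per_L outside total_bounds", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  community: %d taxa in %d families, %d site(s)/region x 5 regions x 2 years\n",
              x$n_taxa, x$n_families, x$n_sites_per_region))
  cat(sprintf("  depth: %s reads/sample; standards: 3 x %g ng; volume: %g L\n",
              format(x$reads_per_sample, big.mark = ","), x$standard_mass_ng,
              x$volume_L))
  cat(sprintf("  noise: sd %.2f log10; misannotation %.3f; dual hits %.3f; seed %d\n",
              x$noise_sd_log10, x$misannotation_rate, x$dual_hit_rate, x$seed))
  invisible(x)
}

#' Regions of the simulated archipelago, ordered west to east
#' @keywords internal
region_levels <- function() c("west", "north", "central", "caldera", "east")
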