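#' Simulation configuration for a multi-population strain collection
#'
#' Builds the parameter set for the Balding-Nichols genotype simulator and its
#' companion annotation and phenotype generators. The defaults emulate a
#' shiitake-style collection: three populations of 26/6/26 strains plus two
#' admixed "hybrid" strains, allele frequencies diverged to the
#' F_ST ~ 0.2-0.3 scale, substantial within-population inbreeding, and 13
#' group-structured agronomic traits.
#'
#' @param n_populations number of source populations.
#' @param strains_per_population integer vector of population sizes.
#' @param n_loci number of biallelic SNP loci to simulate.
#' @param scaffold_layout data frame with columns `scaffold` and `length`
#'   (bp); loci are placed uniformly, proportional to length.
#' @param ancestral_freq_range interval in (0, 1) for the ancestral allele
#'   frequency draw.
#' @param baseline_divergence per-population Balding-Nichols divergence c_j
#'   in (0, 1) for neutral loci (recycled to `n_populations`).
#' @param outlier_fraction proportion of loci flagged as divergence outliers.
#' @param outlier_divergence Balding-Nichols c for flagged loci; must exceed
#'   every baseline value.
#' @param inbreeding per-population within-population inbreeding F_IS in
#'   (-1, 1).
#' @param n_hybrids number of admixed strains drawing one allele from each of
#'   two parent populations.
#' @param hybrid_parents length-2 integer vector of parent population indices.
#' @param maf_floor minimum minor allele frequency across all strains; loci
#'   below it are redrawn (at most `max_redraws` attempts).
#' @param max_redraws redraw cap per locus before erroring.
#' @param n_genes number of non-overlapping gene models to place.
#' @param gene_length gene model length in bp.
#' @param missense_rate proportion of genic SNPs labelled missense (the rest
#'   are synonymous).
#' @param n_go_terms number of GO terms in the vocabulary.
#' @param n_enriched_terms number of terms preferentially attached to genes
#'   carrying group-specific missense SNPs (planted enrichment signal).
#' @param phenotype_effects numeric matrix of per-group trait shifts
#'   (populations x 13 traits); `NULL` uses the default pattern where every
#'   trait except NF and SL separates the groups.
#' @param phenotype_noise strain-level Gaussian noise SD.
#' @param phenotype_missing_rate missing-at-random rate in the phenotype
#'   table.
#' @param seed integer seed fixing all randomness end-to-end.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 3,
                       strains_per_population = c(26, 6, 26),
                       n_loci = 10000,
                       scaffold_layout = default_scaffolds(),
                       ancestral_freq_range = c(0.1, 0.9),
                       baseline_divergence = c(0.30, 0.30, 0.18),
                       outlier_fraction = 0.01,
                       outlier_divergence = 0.6,
                       inbreeding = c(0.40, 0.45, 0.20),
                       n_hybrids = 2,
                       hybrid_parents = c(1, 3),
                       maf_floor = 0.05,
                       max_redraws = 100,
                       n_genes = 400,
                       gene_length = 1500,
                       missense_rate = 0.3,
                       n_go_terms = 40,
                       n_enriched_terms = 2,
                       phenotype_effects = NULL,
                       phenotype_noise = 1,
                       phenotype_missing_rate = 0.02,
                       seed = 1) {
  strains_per_population <- as.integer(rep(strains_per_population,
                                           length.out = n_populations))
  baseline_divergence <- rep(baseline_divergence, length.out = n_populations)
  inbreeding <- rep(inbreeding, length.out = n_populations)
  scaffold_layout <- as_tibble(scaffold_layout)
  stopifnot(
    n_populations >= 1, all(strains_per_population >= 1),
    n_loci >= 1,
    all(c("scaffold", "length") %in% names(scaffold_layout)),
    all(scaffold_layout$length >= 1),
    length(ancestral_freq_range) == 2,
    ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
    ancestral_freq_range[1] <= ancestral_freq_range[2],
    all(baseline_divergence > 0), all(baseline_divergence < 1),
    outlier_fraction >= 0, outlier_fraction < 1,
    outlier_divergence > 0, outlier_divergence < 1,
    all(inbreeding > -1), all(inbreeding < 1),
    n_hybrids >= 0, maf_floor >= 0, maf_floor < 0.5,
    seed == as.integer(seed)
  )
  if (outlier_fraction > 0 && outlier_divergence <= max(baseline_divergence)) {
    stop("outlier_divergence must exceed every baseline_divergence")
  }
  if (n_hybrids > 0) {
    stopifnot(length(hybrid_parents) == 2,
              all(hybrid_parents %in% seq_len(n_populations)))
  }
  if (is.null(phenotype_effects)) {
    phenotype_effects <- default_phenotype_effects(n_populations)
  }
  stopifnot(is.matrix(phenotype_effects),
            nrow(phenotype_effects) == n_populations,
            ncol(phenotype_effects) == length(trait_names()))
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_populations, " populations (",
      paste(x$strains_per_population, collapse = "/"), " strains) + ",
      x$n_hybrids, " hybrids; ", x$n_loci, " loci on ",
      nrow(x$scaffold_layout), " scaffolds; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

default_scaffolds <- function(n = 10, length = 5e5) {
  tibble(scaffold = sprintf("scaffold_%02d", seq_len(n)),
         length = as.integer(length))
}

#' The 13 agronomic trait names
#'
#' Growth, precocity, morphology and yield traits measured on each strain:
#' FP/FB (days to first primordium / first fruiting body), PD/PT/PW (pileus
#' diameter/thickness/weight), SL/SD/SW (stipe length/diameter/weight), NF
#' (fruiting bodies per bag), WF (single fruiting body weight), Y (yield per
#' bag), and the two mycelium growth rates DGR-myg and DGR-sd.
#'
#' @return Character vector of length 13.
#' @export
trait_names <- function() {
  c("FP", "FB", "PD", "PT", "PW", "SL", "SD", "SW", "NF", "WF", "Y",
    "DGR-myg", "DGR-sd")
}

default_phenotype_effects <- function(n_populations, delta = 1.5) {
  traits <- trait_names()
  eff <- matrix(0, nrow = n_populations, ncol = length(traits),
                dimnames = list(NULL, traits))
  # groups separate on every trait except NF and SL
  shifted <- setdiff(traits, c("NF", "SL"))
  base <- seq(-1, 1, length.out = n_populations) * delta
  for (tr in shifted) eff[, tr] <- base
  eff
}

# Deterministic per-stage seeds derived from the one global seed, so stages
# can be re-run independently without sharing RNG streams.
stage_seed <- function(seed, stage) {
  stages <- c(genotypes = 1L, annotation = 2L, phenotypes = 3L,
              scan = 4L, bootstrap = 5L)
  offset <- stages[[stage]]
  as.integer((as.numeric(seed) * 48271 + offset * 99991) %% 2147483647)
}
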