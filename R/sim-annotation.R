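#' Simulate snpEff-style SNP annotations and a gene-to-GO mapping
#'
#' Places non-overlapping gene models on the configured scaffolds, classifies
#' every simulated SNP as `missense_variant`, `synonymous_variant` (genic
#' SNPs, split by `missense_rate`) or `intergenic`, and assigns 1-5 GO terms
#' per gene. A configurable number of "enriched" terms is preferentially
#' attached to genes that carry group-specific missense SNPs, planting an
#' over-representation signal the enrichment stage can be tested against.
#'
#' @param config a [sim_config()].
#' @param sim the result of [simulate_genotypes()] (genotypes + truth).
#' @return A list with tibbles `annotation` (scaffold, pos, gene_id, effect),
#'   `genes` (gene_id, scaffold, start, end), `go_map` (gene_id, term) and
#'   the character vector `enriched_terms`.
#' @export
simulate_annotation <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "annotation"))
  lay <- config$scaffold_layout
  n_slots <- floor(lay$length / (2 * config$gene_length))
  if (config$n_genes > sum(n_slots)) {
    stop("cannot place ", config$n_genes, " non-overlapping genes on ",
         sum(lay$length), " bp of scaffold")
  }
  if (config$n_genes < 1) stop("need at least one gene")

  # allocate genes to scaffolds proportionally to available slots
  alloc <- floor(n_slots * config$n_genes / sum(n_slots))
  short <- config$n_genes - sum(alloc)
  if (short > 0) {
    extra <- order(n_slots - alloc, decreasing = TRUE)[seq_len(short)]
    alloc[extra] <- alloc[extra] + 1L
  }
  genes <- purrr::map2_dfr(seq_len(nrow(lay)), alloc, function(i, k) {
    if (k == 0) return(NULL)
    slots <- sort(sample.int(n_slots[i], k))
    start <- (slots - 1L) * 2L * config$gene_length + 1L
    tibble(scaffold = lay$scaffold[i], start = as.integer(start),
           end = as.integer(start + config$gene_length - 1L))
  })
  genes <- genes[order(genes$scaffold, genes$start), ]
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "scaffold", "start", "end")]

  loci <- sim$genotypes$loci
  gene_at <- map_loci_to_genes(loci, genes)
  genic <- !is.na(gene_at)
  effect <- rep("intergenic", nrow(loci))
  effect[genic] <- ifelse(runif(sum(genic)) < config$missense_rate,
                          "missense_variant", "synonymous_variant")
  annotation <- tibble(scaffold = loci$scaffold, pos = loci$pos,
                       gene_id = gene_at, effect = effect)

  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  n_enr <- min(config$n_enriched_terms, config$n_go_terms)
  enriched_terms <- terms[seq_len(n_enr)]
  common_terms <- if (n_enr > 0 && config$n_go_terms > n_enr) {
    terms[-seq_len(n_enr)]
  } else {
    terms
  }

  # genes carrying group-specific missense SNPs get the enriched terms
  spec <- tryCatch(
    group_specific_snps(sim$genotypes, sim$truth$groups),
    error = function(e) tibble(scaffold = character(), pos = integer())
  )
  spec_key <- paste(spec$scaffold, spec$pos)
  target_genes <- unique(stats::na.omit(
    annotation$gene_id[effect == "missense_variant" &
                         paste(annotation$scaffold, annotation$pos) %in% spec_key]
  ))
  go_map <- purrr::map_dfr(genes$gene_id, function(g) {
    k <- sample.int(5, 1)
    tm <- sample(common_terms, min(k, length(common_terms)))
    if (g %in% target_genes && runif(1) < 0.8 && n_enr > 0) {
      tm <- unique(c(sample(enriched_terms, 1), tm))[seq_len(k)]
      tm <- tm[!is.na(tm)]
    }
    tibble(gene_id = g, term = tm)
  })
  list(annotation = annotation, genes = genes, go_map = go_map,
       enriched_terms = enriched_terms)
}

map_loci_to_genes <- function(loci, genes) {
  out <- rep(NA_character_, nrow(loci))
  for (sc in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == sc, ]
    idx <- which(loci$scaffold == sc)
    if (length(idx) == 0) next
    # genes are non-overlapping and sorted: findInterval on starts
    hit <- findInterval(loci$pos[idx], g$start)
    ok <- hit >= 1 & hit <= nrow(g)
    inside <- ok
    inside[ok] <- loci$pos[idx][ok] <= g$end[hit[ok]]
    out[idx[inside]] <- g$gene_id[hit[inside]]
  }
  out
}

#' Simulate group-structured phenotypes
#'
#' Each trait value is a global mean plus the strain's group shift plus
#' Gaussian noise; hybrids receive the average of all group shifts. A
#' missing-at-random mask is applied at the configured rate.
#'
#' @param config a [sim_config()].
#' @param truth the `sim_truth` from [simulate_genotypes()].
#' @param global_mean baseline trait value.
#' @return A tibble with column `strain` followed by the 13 trait columns.
#' @export
simulate_phenotypes <- function(config, truth, global_mean = 10) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(stage_seed(config$seed, "phenotypes"))
  traits <- trait_names()
  eff <- config$phenotype_effects
  labels <- population_labels(config$n_populations)
  pop_idx <- match(truth$strains$population, labels)
  n <- nrow(truth$strains)
  vals <- matrix(global_mean, nrow = n, ncol = length(traits),
                 dimnames = list(truth$strains$strain, traits))
  for (i in seq_len(n)) {
    shift <- if (is.na(pop_idx[i])) colMeans(eff) else eff[pop_idx[i], ]
    vals[i, ] <- vals[i, ] + shift
  }
  vals <- vals + matrix(rnorm(n * length(traits), 0, config$phenotype_noise),
                        nrow = n)
  if (config$phenotype_missing_rate > 0) {
    mask <- matrix(runif(n * length(traits)) < config$phenotype_missing_rate,
                   nrow = n)
    vals[mask] <- NA_real_
  }
  dplyr::bind_cols(tibble(strain = truth$strains$strain),
                   as_tibble(as.data.frame(vals, check.names = FALSE)))
}
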