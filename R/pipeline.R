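#' Pipeline configuration
#'
#' Either a set of input file paths (VCF, group assignment, annotation, GO
#' map, phenotypes) or a simulation block — never both. Thresholds default
#' to the conventional strain-resequencing values: site QUAL 30, mean depth
#' 5, MAF 0.05, 1,000-bp thinning, 5-kb windows, top 5% windows, q < 0.05.
#'
#' @param inputs named list of paths: `vcf`, `groups`, and optionally
#'   `annotation`, `go_map`, `phenotypes`.
#' @param simulation a [sim_config()]; mutually exclusive with `inputs`.
#' @param min_qual,min_mean_depth,min_maf site filters.
#' @param thin_bp distance-thinning threshold (bp) for the structure stage.
#' @param window_size diversity/F_ST window size (bp).
#' @param top_fraction fraction of windows kept as divergence candidates.
#' @param q_threshold scan q-value cutoff.
#' @param prior_odds scan prior odds for the neutral model.
#' @param scan_mcmc named list overriding scan MCMC settings (`n_burn`,
#'   `n_keep`, `thin`, `n_pilot`).
#' @param seed integer seed for every stochastic stage.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, simulation = NULL,
                            min_qual = 30, min_mean_depth = 5,
                            min_maf = 0.05, thin_bp = 1000,
                            window_size = 5000, top_fraction = 0.05,
                            q_threshold = 0.05, prior_odds = 10,
                            scan_mcmc = list(), seed = 1,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(inputs) == is.null(simulation)) {
    stop("exactly one of 'inputs' or 'simulation' must be given")
  }
  if (!is.null(inputs)) {
    if (!all(c("vcf", "groups") %in% names(inputs))) {
      stop("inputs must name at least 'vcf' and 'groups' files")
    }
  } else {
    stopifnot(inherits(simulation, "sim_config"))
  }
  stopifnot(min_maf >= 0, min_maf < 0.5, window_size >= 1,
            top_fraction > 0, top_fraction <= 1,
            q_threshold > 0, q_threshold < 1, prior_odds > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulation` block holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    y$simulation <- do.call(sim_config, y$simulation)
  }
  do.call(pipeline_config, y)
}

#' Run the full population-genomic pipeline
#'
#' Stages run in order: simulate/read genotypes, filter, thin, windowed
#' diversity, strain heterozygosity, AMOVA, NJ tree, per-pair windowed
#' F_ST, Bayesian outlier scan, candidate assignment, enrichment, and
#' phenotype normalisation/clustering. Every declared output file is listed
#' in a manifest with md5 content hashes; the same config and seed
#' reproduce identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the stage results and the `manifest`
#'   tibble.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  say <- function(...) {
    if (config$log_level == "info") {
      message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0)), ...)
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()

  run_stage("input", {
    if (!is.null(config$simulation)) {
      say("simulating genotypes (seed ", config$simulation$seed, ")")
      sim <- simulate_genotypes(config$simulation)
      ann <- simulate_annotation(config$simulation, sim)
      phen <- simulate_phenotypes(config$simulation, sim$truth)
      res$records <- NULL
      res$raw <- sim$genotypes
      res$truth <- sim$truth
      res$groups <- sim$truth$groups
      res$annotation <- ann$annotation
      res$go_map <- ann$go_map
      res$phenotypes <- phen
    } else {
      say("reading ", config$inputs$vcf)
      res$records <- read_vcf(config$inputs$vcf)
      res$groups <- read_groups(config$inputs$groups)
      res$annotation <- if (!is.null(config$inputs$annotation)) {
        readr::read_tsv(config$inputs$annotation, show_col_types = FALSE)
      }
      res$go_map <- if (!is.null(config$inputs$go_map)) {
        readr::read_tsv(config$inputs$go_map, show_col_types = FALSE)
      }
      res$phenotypes <- if (!is.null(config$inputs$phenotypes)) {
        readr::read_csv(config$inputs$phenotypes, show_col_types = FALSE)
      }
    }
  })

  run_stage("filter", {
    gm <- if (!is.null(res$records)) {
      filter_variants(res$records, config$min_qual, config$min_mean_depth,
                      config$min_maf)
    } else {
      res$raw
    }
    say("filtered matrix: ", nrow(gm$loci), " loci x ",
        length(gm$strains), " strains")
    if (nrow(gm$loci) == 0) stop("no loci survive filtering")
    res$genotypes <- gm
  })

  run_stage("thin", {
    res$thinned <- thin_by_distance(res$genotypes, config$thin_bp)
    say("thinned to ", nrow(res$thinned$loci), " loci (>= ",
        config$thin_bp, " bp apart)")
  })

  run_stage("diversity", {
    res$windows <- windowed_diversity(res$genotypes, config$window_size)
    res$het <- strain_het(res$genotypes)
    readr::write_tsv(res$windows, file.path(out_dir, "windows_diversity.tsv"))
    readr::write_tsv(res$het, file.path(out_dir, "strain_het.tsv"))
  })

  run_stage("amova", {
    res$amova <- amova(res$thinned, res$groups)
    readr::write_tsv(tidy(res$amova), file.path(out_dir, "amova.tsv"))
  })

  run_stage("structure", {
    d <- genotype_distance(res$genotypes)
    res$tree <- neighbor_joining(d)
    dm <- as.data.frame(d)
    dm <- dplyr::bind_cols(tibble(strain = rownames(d)), dm)
    readr::write_tsv(dm, file.path(out_dir, "distance_matrix.tsv"))
    writeLines(ape::write.tree(res$tree), file.path(out_dir, "tree.nwk"))
  })

  run_stage("fst", {
    pops <- sort(setdiff(unique(res$groups$group), "outlier"))
    prs <- utils::combn(pops, 2, simplify = FALSE)
    sites_all <- wc_fst_sites(res$genotypes, res$groups)
    win_all <- wc_fst_windows(sites_all, config$window_size)
    res$fst_windows <- dplyr::bind_cols(tibble(pair = "all"), win_all)
    res$top_windows <- list()
    for (pr in prs) {
      nm <- paste(pr, collapse = "-")
      w <- wc_fst_windows(wc_fst_sites(res$genotypes, res$groups, pops = pr),
                          config$window_size)
      res$fst_windows <- dplyr::bind_rows(
        res$fst_windows, dplyr::bind_cols(tibble(pair = nm), w))
      res$top_windows[[nm]] <- top_fraction_windows(w, config$top_fraction)
    }
    readr::write_tsv(res$fst_windows, file.path(out_dir, "fst_windows.tsv"))
    say("mean window F_ST (all groups): ",
        round(mean(win_all$fst, na.rm = TRUE), 3))
  })

  run_stage("scan", {
    ac <- allele_counts(res$genotypes, res$groups)
    mc <- modifyList(list(n_burn = 5000, n_keep = 20000, thin = 10,
                          n_pilot = 2000, se_threshold = 0.1),
                     config$scan_mcmc)
    res$scan <- fst_outlier_scan(
      ac$alt, ac$tot, prior_odds = config$prior_odds,
      n_burn = mc$n_burn, n_keep = mc$n_keep, thin = mc$thin,
      n_pilot = mc$n_pilot, se_threshold = mc$se_threshold,
      seed = config$seed, loci = res$genotypes$loci)
    res$outliers <- call_outliers(res$scan, config$q_threshold)
    readr::write_tsv(tidy(res$scan), file.path(out_dir, "outlier_scan.tsv"))
    say(nrow(res$outliers), " outlier SNPs called")
  })

  run_stage("assignment", {
    res$assignment <- assign_candidate_divergence_snps(
      res$outliers[, c("scaffold", "pos")], res$top_windows)
    res$genes <- if (!is.null(res$annotation)) {
      candidate_genes(res$assignment, res$annotation)
    }
    readr::write_tsv(as_tibble(res$assignment),
                     file.path(out_dir, "candidate_assignment.tsv"))
  })

  run_stage("enrichment", {
    if (!is.null(res$annotation) && !is.null(res$go_map)) {
      spec <- group_specific_snps(res$genotypes, res$groups)
      sets <- missense_gene_sets(spec, res$annotation)
      bg <- unique(stats::na.omit(dplyr::left_join(
        res$genotypes$loci[, c("scaffold", "pos")], res$annotation,
        by = c("scaffold", "pos"))$gene_id))
      enr <- purrr::map_dfr(unique(sets$group), function(g) {
        genes <- sets$gene_id[sets$group == g]
        dplyr::bind_cols(tibble(group = g),
                         fisher_enrichment(genes, res$go_map, bg))
      })
      res$enrichment <- enr
    } else {
      res$enrichment <- tibble()
    }
    readr::write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  })

  run_stage("phenotypes", {
    if (!is.null(res$phenotypes)) {
      norm <- normalize_phenotypes(res$phenotypes)
      res$pheno_norm <- norm
      res$pheno_clust <- cluster_phenotypes(norm)
    } else {
      res$pheno_norm <- tibble(strain = character())
    }
    readr::write_tsv(res$pheno_norm,
                     file.path(out_dir, "phenotype_normalized.tsv"))
  })

  declared <- c("windows_diversity.tsv", "strain_het.tsv", "amova.tsv",
                "tree.nwk", "distance_matrix.tsv", "fst_windows.tsv",
                "outlier_scan.tsv", "candidate_assignment.tsv",
                "enrichment.tsv", "phenotype_normalized.tsv")
  manifest <- tibble(
    file = declared,
    md5 = unname(tools::md5sum(file.path(out_dir, declared))),
    bytes = file.size(file.path(out_dir, declared))
  )
  if (anyNA(manifest$md5)) stop("declared output missing from ", out_dir)
  manifest <- dplyr::bind_rows(
    manifest,
    tibble(file = "seed", md5 = as.character(config$seed), bytes = NA_real_)
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  res$manifest <- manifest
  say("pipeline complete: ", length(declared), " outputs in ", out_dir)
  invisible(res)
}

#' Write the pipeline summary report
#'
#' A single TSV of key-value summary rows mirroring the headline tables of
#' a strain-collection study: per-group SNP counts, diversity and Tajima's D
#' summaries, heterozygosity and inbreeding, mean window F_ST per pair, the
#' AMOVA rows, outlier and candidate counts, and the Venn tallies. All
#' values are copied from stage outputs — nothing is recomputed.
#'
#' @param run result of [run_pipeline()].
#' @param out_dir directory holding the pipeline outputs.
#' @param groups group assignment (defaults to the run's).
#' @return The report tibble, invisibly; written to `report.tsv`.
#' @export
write_report <- function(run, out_dir, groups = run$groups) {
  gm <- run$genotypes
  pops <- sort(setdiff(unique(groups$group), "outlier"))
  rows <- list(tibble(section = "snps", key = "total",
                      value = nrow(gm$loci)))
  for (g in pops) {
    rows <- c(rows, list(tibble(
      section = "snps", key = paste0("group_", g),
      value = group_snp_count(gm, groups, g))))
  }
  rows <- c(rows, list(
    tibble(section = "diversity", key = "mean_window_pi",
           value = mean(run$windows$pi)),
    tibble(section = "diversity", key = "mean_tajima_d",
           value = mean(run$windows$tajima_d, na.rm = TRUE)),
    tibble(section = "het", key = "mean_f", value = mean(run$het$f))
  ))
  fw <- run$fst_windows
  for (pr in unique(fw$pair)) {
    rows <- c(rows, list(tibble(
      section = "fst", key = paste0("mean_window_fst_", pr),
      value = mean(fw$fst[fw$pair == pr], na.rm = TRUE))))
  }
  am <- tidy(run$amova)
  rows <- c(rows, list(tibble(section = "amova",
                              key = paste0("pct_", c("among_pop",
                                                     "among_strain",
                                                     "within_strain",
                                                     "total")),
                              value = am$pct_var)))
  rows <- c(rows, list(tibble(section = "outliers", key = "n_called",
                              value = nrow(run$outliers))))
  vc <- venn_counts(run$assignment)
  rows <- c(rows, list(tibble(section = "venn",
                              key = paste(vc$kind, vc$set, sep = "_"),
                              value = as.numeric(vc$n))))
  report <- dplyr::bind_rows(rows)
  readr::write_tsv(report, file.path(out_dir, "report.tsv"))
  invisible(report)
}
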