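#' Simulate multi-population diploid genotypes under the Balding-Nichols model
#'
#' For each locus an ancestral allele frequency p is drawn uniformly from
#' `ancestral_freq_range`; each population's frequency is drawn from
#' `Beta(p (1-c)/c, (1-p)(1-c)/c)`, where the divergence parameter c is the
#' population's baseline value at neutral loci and `outlier_divergence` at the
#' flagged outlier loci — c is exactly the expected F_ST of that locus, which
#' is what every downstream estimator is tested against. Diploid genotypes are
#' drawn with inbreeding-adjusted Hardy-Weinberg probabilities, and hybrid
#' strains draw one allele from each of the two parent populations (giving
#' them the excess heterozygosity, F < 0, seen in admixed individuals). Loci
#' whose overall minor allele frequency falls below `maf_floor` are redrawn a
#' bounded number of times.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genotypes` (a [geno_mat()]) and `truth`, a
#'   `sim_truth` list of tibbles: `loci` (ancestral and per-population
#'   frequencies, outlier flags), `strains` (population of origin, hybrid
#'   flag) and `groups` (a ready-to-use group assignment with populations
#'   labelled by Roman numerals and hybrids labelled `"outlier"`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  P <- config$n_populations
  L <- config$n_loci
  sizes <- config$strains_per_population
  n_core <- sum(sizes)
  n_all <- n_core + config$n_hybrids

  loci <- place_loci(config)
  n_out <- round(config$outlier_fraction * L)
  is_outlier <- logical(L)
  if (n_out > 0) is_outlier[sample.int(L, n_out)] <- TRUE

  pop_of <- rep(seq_len(P), times = sizes)
  strains <- sprintf("S%03d", seq_len(n_all))
  labels <- population_labels(P)

  p_anc <- runif(L, config$ancestral_freq_range[1],
                 config$ancestral_freq_range[2])
  p_pop <- matrix(NA_real_, nrow = L, ncol = P)
  geno <- matrix(NA_integer_, nrow = n_all, ncol = L)

  draw_all <- function(idx) {
    # (re)draw per-pop freqs and genotypes for loci idx, in place
    nl <- length(idx)
    for (j in seq_len(P)) {
      cj <- ifelse(is_outlier[idx], config$outlier_divergence,
                   config$baseline_divergence[j])
      p_pop[idx, j] <<- rbeta(nl, p_anc[idx] * (1 - cj) / cj,
                              (1 - p_anc[idx]) * (1 - cj) / cj)
    }
    # guard against Beta draws collapsing to exactly 0/1 numerically
    p_pop[idx, ] <<- pmin(pmax(p_pop[idx, , drop = FALSE], 1e-9), 1 - 1e-9)
    for (s in seq_len(n_core)) {
      j <- pop_of[s]
      pj <- p_pop[idx, j]
      Fj <- config$inbreeding[j]
      pr2 <- pj^2 + Fj * pj * (1 - pj)
      pr1 <- 2 * pj * (1 - pj) * (1 - Fj)
      pr0 <- (1 - pj)^2 + Fj * pj * (1 - pj)
      pr2 <- pmax(pr2, 0); pr1 <- pmax(pr1, 0); pr0 <- pmax(pr0, 0)
      tot <- pr2 + pr1 + pr0
      u <- runif(length(idx)) * tot
      geno[s, idx] <<- ifelse(u < pr2, 2L, ifelse(u < pr2 + pr1, 1L, 0L))
    }
    if (config$n_hybrids > 0) {
      pa <- p_pop[idx, config$hybrid_parents[1]]
      pb <- p_pop[idx, config$hybrid_parents[2]]
      for (h in seq_len(config$n_hybrids)) {
        geno[n_core + h, idx] <<-
          rbinom(length(idx), 1L, pa) + rbinom(length(idx), 1L, pb)
      }
    }
    invisible(NULL)
  }

  draw_all(seq_len(L))

  if (config$maf_floor > 0) {
    for (attempt in seq_len(config$max_redraws)) {
      af <- colSums(geno) / (2 * n_all)
      fail <- which(pmin(af, 1 - af) < config$maf_floor)
      if (length(fail) == 0) break
      p_anc[fail] <- runif(length(fail), config$ancestral_freq_range[1],
                           config$ancestral_freq_range[2])
      draw_all(fail)
    }
    af <- colSums(geno) / (2 * n_all)
    fail <- which(pmin(af, 1 - af) < config$maf_floor)
    if (length(fail) > 0) {
      stop("MAF-floor redraw budget (", config$max_redraws,
           ") exhausted at locus index ", fail[1])
    }
  }

  rownames(geno) <- strains
  gm <- geno_mat(geno, loci)

  truth_loci <- dplyr::bind_cols(
    loci[, c("scaffold", "pos")],
    tibble(p_ancestral = p_anc, is_outlier = is_outlier),
    as_tibble(setNames(as.data.frame(p_pop), paste0("p_", labels)))
  )
  truth_strains <- tibble(
    strain = strains,
    population = c(labels[pop_of], rep(NA_character_, config$n_hybrids)),
    is_hybrid = c(rep(FALSE, n_core), rep(TRUE, config$n_hybrids))
  )
  groups <- tibble(
    strain = strains,
    group = c(labels[pop_of], rep("outlier", config$n_hybrids))
  )
  truth <- structure(list(loci = truth_loci, strains = truth_strains,
                          groups = groups),
                     class = "sim_truth")
  list(genotypes = gm, truth = truth)
}

population_labels <- function(P) {
  as.character(utils::as.roman(seq_len(P)))
}

place_loci <- function(config) {
  lay <- config$scaffold_layout
  scaf <- sample(lay$scaffold, config$n_loci, replace = TRUE,
                 prob = lay$length / sum(lay$length))
  len <- lay$length[match(scaf, lay$scaffold)]
  pos <- ceiling(runif(config$n_loci) * len)
  # unique positions within scaffold
  for (k in 1:50) {
    dup <- duplicated(paste(scaf, pos))
    if (!any(dup)) break
    pos[dup] <- ceiling(runif(sum(dup)) * len[dup])
  }
  if (anyDuplicated(paste(scaf, pos))) stop("could not place loci uniquely")
  ref_alt <- replicate(config$n_loci,
                       sample(c("A", "C", "G", "T"), 2, replace = FALSE))
  ord <- order(scaf, pos)
  tibble(scaffold = scaf, pos = as.integer(pos),
         ref = ref_alt[1, ], alt = ref_alt[2, ],
         qual = round(runif(config$n_loci, 40, 200), 1))[ord, ]
}
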