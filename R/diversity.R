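#' Per-site nucleotide diversity
#'
#' The proportion of differing pairs among the 2N called alleles at one
#' locus, i.e. the unbiased heterozygosity `2 p (1-p) * 2N / (2N - 1)`.
#'
#' @param dosage integer vector of alternate-allele dosages (0/1/2, `NA`
#'   allowed) for one locus.
#' @return Per-site diversity (0 when monomorphic; `NaN` with < 2 alleles).
#' @export
site_pi <- function(dosage) {
  n <- 2 * sum(!is.na(dosage))
  if (n < 2) return(NaN)
  p <- sum(dosage, na.rm = TRUE) / n
  2 * p * (1 - p) * n / (n - 1)
}

site_pi_all <- function(x) {
  n <- 2 * colSums(!is.na(x$geno))
  p <- colSums(x$geno, na.rm = TRUE) / n
  ifelse(n < 2, NaN, 2 * p * (1 - p) * n / (n - 1))
}

#' Windowed nucleotide diversity and Tajima's D
#'
#' Tiles each scaffold with non-overlapping windows starting at position 1
#' and reports, per window, the number of SNPs, per-bp nucleotide diversity
#' (sum of site diversities divided by the window size, the VCFtools
#' `--window-pi` convention) and Tajima's D computed from the window's
#' segregating-site count and diversity sum with n = 2N sampled alleles.
#' D is `NA` where a window holds no segregating site.
#'
#' @param x a [geno_mat()].
#' @param window_size window width in bp (default 5 kb).
#' @param scaffold_lengths optional named vector of scaffold lengths; by
#'   default windows extend to the last SNP of each scaffold.
#' @return A tibble with columns `scaffold`, `start`, `end`, `n_sites`,
#'   `pi`, `tajima_d`.
#' @export
windowed_diversity <- function(x, window_size = 5000,
                               scaffold_lengths = NULL) {
  stopifnot(inherits(x, "geno_mat"), window_size >= 1)
  n_alleles <- 2 * length(x$strains)
  if (n_alleles < 4) stop("Tajima's D needs at least 4 sampled alleles")
  sp <- site_pi_all(x)
  seg <- allele_freq(x) > 0 & allele_freq(x) < 1
  win_of <- (x$loci$pos - 1) %/% window_size
  scafs <- unique(x$loci$scaffold)
  purrr::map_dfr(scafs, function(sc) {
    idx <- which(x$loci$scaffold == sc)
    max_pos <- if (!is.null(scaffold_lengths) && sc %in% names(scaffold_lengths)) {
      scaffold_lengths[[sc]]
    } else {
      max(x$loci$pos[idx])
    }
    wins <- 0:((max_pos - 1) %/% window_size)
    pi_sum <- vapply(wins, function(w) {
      sum(sp[idx][win_of[idx] == w], na.rm = TRUE)
    }, numeric(1))
    s_cnt <- vapply(wins, function(w) {
      sum(seg[idx][win_of[idx] == w], na.rm = TRUE)
    }, numeric(1))
    n_sites <- vapply(wins, function(w) sum(win_of[idx] == w), integer(1))
    tibble(
      scaffold = sc,
      start = as.integer(wins * window_size + 1),
      end = as.integer((wins + 1) * window_size),
      n_sites = n_sites,
      pi = pi_sum / window_size,
      tajima_d = vapply(seq_along(wins), function(i) {
        tajima_d_stat(s_cnt[i], pi_sum[i], n_alleles)
      }, numeric(1))
    )
  })
}

#' @rdname windowed_diversity
#' @export
window_pi <- function(x, window_size = 5000, scaffold_lengths = NULL) {
  windowed_diversity(x, window_size, scaffold_lengths)
}

#' @rdname windowed_diversity
#' @export
window_tajima_d <- function(x, window_size = 5000, scaffold_lengths = NULL) {
  windowed_diversity(x, window_size, scaffold_lengths)
}

#' Tajima's D from summary quantities
#'
#' The 1989 statistic `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S-1))` with
#' the standard a1, a2, b1, b2, c1, c2, e1, e2 constants for `n` sampled
#' alleles.
#'
#' @param s number of segregating sites in the window.
#' @param pi_sum sum of per-site diversities over the window (not per-bp).
#' @param n number of sampled alleles (2N for diploids); must be >= 4.
#' @return D, or `NA` when `s` = 0.
#' @export
tajima_d_stat <- function(s, pi_sum, n) {
  if (n < 4) stop("Tajima's D requires n >= 4 sampled alleles")
  if (s == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

#' Per-strain heterozygosity and inbreeding coefficient
#'
#' Counts heterozygous (Ne) and homozygous (No) loci per strain and computes
#' the method-of-moments inbreeding coefficient
#' `F = (No - E[hom]) / (L - E[hom])`, where the expected homozygosity under
#' Hardy-Weinberg uses cohort allele frequencies with the unbiased
#' `2N/(2N-1)` correction (the VCFtools `--het` convention). Negative F
#' marks an excess of heterozygotes, the signature of admixed/hybrid
#' strains.
#'
#' @param x a [geno_mat()]; frequencies are pooled over all its strains, so
#'   pass a group subset to estimate F within that group.
#' @return A tibble with columns `strain`, `n_het`, `n_hom`, `exp_hom`, `f`.
#' @export
strain_het <- function(x) {
  stopifnot(inherits(x, "geno_mat"))
  het <- x$geno == 1L
  n_het <- rowSums(het, na.rm = TRUE)
  n_called <- rowSums(!is.na(x$geno))
  n_hom <- n_called - n_het
  exp_het_site <- site_pi_all(x)
  exp_hom <- sum(1 - exp_het_site, na.rm = TRUE)
  L <- nrow(x$loci)
  tibble(
    strain = x$strains,
    n_het = as.integer(unname(n_het)),
    n_hom = as.integer(unname(n_hom)),
    exp_hom = exp_hom,
    f = unname((n_hom - exp_hom) / (n_called - exp_hom))
  )
}

#' SNP class counts and ratios per group
#'
#' Joins the genotype matrix with a snpEff-style annotation table and
#' reports, for every group (loci detected in that group per the membership
#' rule) and for all strains combined, the counts of total, intragenic,
#' missense and synonymous SNPs plus the two headline ratios:
#' intragenic/total and missense/synonymous.
#'
#' @param x a [geno_mat()].
#' @param annotation tibble with columns `scaffold`, `pos`, `gene_id`,
#'   `effect` (values `missense_variant`, `synonymous_variant`,
#'   `intergenic`).
#' @param groups group assignment table.
#' @param rule group membership rule, see [group_membership()].
#' @return A tibble, one row per group plus `"all"`.
#' @export
snp_class_ratios <- function(x, annotation, groups,
                             rule = c("polymorphic", "alt_present")) {
  rule <- match.arg(rule)
  ann <- dplyr::left_join(x$loci[, c("scaffold", "pos")],
                          as_tibble(annotation),
                          by = c("scaffold", "pos"))
  genic <- !is.na(ann$gene_id)
  missense <- genic & ann$effect == "missense_variant"
  synonymous <- genic & ann$effect == "synonymous_variant"
  memb <- group_membership(x, groups, rule)
  sel <- cbind(memb, all = rep(TRUE, nrow(x$loci)))
  counts <- purrr::map_dfr(colnames(sel), function(g) {
    k <- sel[, g]
    tibble(group = g,
           n_total = sum(k),
           n_intragenic = sum(k & genic),
           n_missense = sum(k & missense),
           n_synonymous = sum(k & synonymous))
  })
  snp_class_ratio_table(counts)
}

#' Ratio arithmetic for SNP class count tables
#'
#' Computes the report ratios intragenic/total and missense/synonymous from
#' a table of class counts, rounded to 3 decimals; a zero denominator yields
#' `NA` with a warning.
#'
#' @param counts tibble with columns `group`, `n_total`, `n_intragenic`,
#'   `n_missense`, `n_synonymous`.
#' @return The input with `intragenic_ratio` and `missense_syn_ratio`
#'   columns appended.
#' @export
snp_class_ratio_table <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("group", "n_total", "n_intragenic", "n_missense", "n_synonymous")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$n_synonymous == 0) || any(counts$n_total == 0)) {
    warning("zero denominator in a class ratio; reporting NA")
  }
  dplyr::mutate(
    counts,
    intragenic_ratio = ifelse(.data$n_total > 0,
                              round(.data$n_intragenic / .data$n_total, 3),
                              NA_real_),
    missense_syn_ratio = ifelse(.data$n_synonymous > 0,
                                round(.data$n_missense / .data$n_synonymous, 3),
                                NA_real_)
  )
}
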