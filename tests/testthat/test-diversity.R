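test_that("site diversity matches pairwise allele enumeration", {
  expect_equal(site_pi(c(0L, 0L, 0L)), 0)                 # monomorphic
  expect_equal(site_pi(c(1L, 1L)), oracle_site_pi(c(1L, 1L)))   # 2/2 split
  expect_equal(site_pi(c(1L, 1L)), 2 / 3, tolerance = 1e-12)
  expect_equal(site_pi(c(1L, 0L)), oracle_site_pi(c(1L, 0L)))   # 1/3 split
  expect_equal(site_pi(c(1L, 0L)), 0.5, tolerance = 1e-12)
  # random dosage vectors vs enumeration
  set.seed(101)
  for (i in 1:60) {
    d <- sample(0:2, sample(3:12, 1), replace = TRUE)
    expect_equal(site_pi(d), oracle_site_pi(d), tolerance = 1e-9)
  }
})

test_that("window diversity follows the per-bp convention", {
  # one 2/2-split site in a 5-kb window
  gm <- tiny_geno(matrix(c(1L, 1L), nrow = 2, ncol = 1), pos = 100L)
  w <- window_pi(gm, 5000)
  expect_equal(w$pi, (2 / 3) / 5000, tolerance = 1e-12)
  # doubling the window size halves per-bp diversity
  w2 <- window_pi(gm, 10000)
  expect_equal(w2$pi, w$pi / 2, tolerance = 1e-12)
})

test_that("empty windows report zero diversity and undefined D", {
  gm <- tiny_geno(matrix(c(1L, 1L), nrow = 2, ncol = 1), pos = 7000L)
  w <- windowed_diversity(gm, 5000)
  expect_equal(nrow(w), 2)
  expect_equal(w$pi[1], 0)
  expect_true(is.na(w$tajima_d[1]))
  expect_equal(w$n_sites, c(0L, 1L))
})

test_that("Tajima's D matches the independently coded constants to 1e-9", {
  expect_true(is.na(tajima_d_stat(0, 0, 10)))
  expect_error(tajima_d_stat(5, 1, 3), "n >= 4")
  expect_equal(tajima_d_stat(16, 3.888, 10), oracle_tajima_d(16, 3.888, 10),
               tolerance = 1e-9)
  set.seed(202)
  for (i in 1:100) {
    n <- sample(4:80, 1)
    s <- sample(1:200, 1)
    pis <- runif(1, 0, s)
    expect_equal(tajima_d_stat(s, pis, n), oracle_tajima_d(s, pis, n),
                 tolerance = 1e-9)
  }
})

test_that("windows of singletons give negative D", {
  # every site: exactly one het strain among 10 -> all singletons
  geno <- matrix(0L, nrow = 10, ncol = 30)
  for (l in 1:30) geno[1 + (l %% 10), l] <- 1L
  gm <- tiny_geno(geno, pos = seq_len(30) * 100L)
  w <- windowed_diversity(gm, 5000)
  expect_lt(w$tajima_d[1], 0)
})

test_that("windowed statistics match a single-file oracle on random windows", {
  ss <- small_sim(seed = 51, n_loci = 600)
  gm <- ss$sim$genotypes
  w <- windowed_diversity(gm, 5000)
  n <- 2 * length(gm$strains)
  for (i in sample(nrow(w), min(100, nrow(w)))) {
    idx <- which(gm$loci$scaffold == w$scaffold[i] &
                   gm$loci$pos >= w$start[i] & gm$loci$pos <= w$end[i])
    pis <- vapply(idx, function(l) oracle_site_pi(gm$geno[, l]), 0)
    af <- colSums(gm$geno[, idx, drop = FALSE]) / n
    s <- sum(af > 0 & af < 1)
    expect_equal(w$pi[i], sum(pis) / 5000, tolerance = 1e-9)
    if (s > 0) {
      expect_equal(w$tajima_d[i], oracle_tajima_d(s, sum(pis), n),
                   tolerance = 1e-9)
    } else {
      expect_true(is.na(w$tajima_d[i]))
    }
  }
})

test_that("Tajima's D centres near zero on neutral-like spectra", {
  # build columns whose allele counts follow the standard neutral SFS
  # (P[i derived of n] proportional to 1/i), the regime D is centred for
  set.seed(77)
  n_strains <- 30
  n <- 2 * n_strains
  n_windows <- 220
  sites_per_window <- 25
  L <- n_windows * sites_per_window
  counts <- sample(1:(n - 1), L, replace = TRUE, prob = 1 / (1:(n - 1)))
  geno <- vapply(counts, function(k) {
    chrom <- sample(c(rep(1L, k), rep(0L, n - k)))
    chrom[seq(1, n, 2)] + chrom[seq(2, n, 2)]
  }, integer(n_strains))
  rownames(geno) <- sprintf("S%02d", seq_len(n_strains))
  pos <- as.integer(outer(seq_len(sites_per_window) * 150,
                          (seq_len(n_windows) - 1) * 5000, "+"))
  gm <- tiny_geno(geno, pos = sort(pos))
  w <- windowed_diversity(gm, 5000)
  w <- w[!is.na(w$tajima_d), ]
  expect_gt(nrow(w), 200)
  expect_lt(abs(mean(w$tajima_d)), 0.5)
})

test_that("strain heterozygosity edge cases and formula agree with the oracle", {
  # strain het at every locus -> F < 0
  geno <- rbind(S1 = rep(1L, 20), S2 = rep(0L, 20), S3 = rep(2L, 20),
                S4 = sample(0:2, 20, replace = TRUE))
  het <- strain_het(tiny_geno(geno))
  expect_lt(het$f[het$strain == "S1"], 0)
  expect_equal(het$n_het[1], 20L)
  expect_equal(het$n_het + het$n_hom, rep(20L, 4))
  # all-hom strains at p = 0.5: F = 1
  geno2 <- rbind(A = rep(0L, 10), B = rep(2L, 10))
  het2 <- strain_het(tiny_geno(geno2))
  expect_equal(het2$f, c(1, 1), tolerance = 1e-12)
  # random fixture vs direct formula
  set.seed(303)
  geno3 <- matrix(sample(0:2, 8 * 50, replace = TRUE), nrow = 8,
                  dimnames = list(sprintf("T%d", 1:8), NULL))
  gm3 <- tiny_geno(geno3)
  het3 <- strain_het(gm3)
  n <- 2 * 8
  p <- colSums(geno3) / n
  ehom <- sum(1 - 2 * p * (1 - p) * n / (n - 1))
  for (i in 1:8) {
    nhom <- sum(geno3[i, ] != 1)
    expect_equal(het3$f[i], (nhom - ehom) / (50 - ehom), tolerance = 1e-9)
  }
  expect_true(all(het3$f <= 1))
})

test_that("mean within-population F is near zero without inbreeding", {
  cfg <- sim_config(n_loci = 3000, strains_per_population = c(25, 25),
                    n_populations = 2, baseline_divergence = 0.2,
                    inbreeding = 0, n_hybrids = 0, outlier_fraction = 0,
                    seed = 55)
  sim <- simulate_genotypes(cfg)
  g1 <- subset_by_group(sim$genotypes, sim$truth$groups, "I",
                        loci_rule = "all")
  expect_lt(abs(mean(strain_het(g1)$f)), 0.05)
})

test_that("SNP class ratios reproduce known arithmetic and flag zero denominators", {
  counts <- tibble::tibble(
    group = c("all", "I"),
    n_total = c(230487, 88314),
    n_intragenic = c(177330, 66658),
    n_missense = c(41403, 17784),
    n_synonymous = c(99819, 35804))
  out <- snp_class_ratio_table(counts)
  expect_equal(out$missense_syn_ratio, c(0.415, 0.497))
  expect_equal(out$intragenic_ratio, c(0.769, 0.755))
  expect_warning(
    bad <- snp_class_ratio_table(
      tibble::tibble(group = "x", n_total = 10, n_intragenic = 2,
                     n_missense = 1, n_synonymous = 0)),
    "denominator")
  expect_true(is.na(bad$missense_syn_ratio))
})

test_that("per-group class ratios count only loci detected in the group", {
  ss <- small_sim(seed = 57, n_loci = 300)
  ann <- simulate_annotation(ss$cfg, ss$sim)
  out <- snp_class_ratios(ss$sim$genotypes, ann$annotation,
                          ss$sim$truth$groups)
  expect_setequal(out$group, c("I", "II", "III", "all"))
  all_row <- out[out$group == "all", ]
  expect_equal(all_row$n_total, 300L)
  expect_true(all(out$n_total[out$group != "all"] <= 300L))
  expect_true(all(out$n_intragenic <= out$n_total))
})
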