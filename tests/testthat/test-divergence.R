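test_that("equal allele and heterozygote counts across populations show no positive differentiation", {
  # both populations: 3 RR, 2 RA, 1 AA. The unbiased estimator subtracts
  # the expected sampling variance, so the point estimate is <= 0 here
  # (its expectation over resampling is 0), never positive.
  g1 <- c(0L, 0L, 0L, 1L, 1L, 2L)
  gm <- tiny_geno(matrix(c(g1, g1), ncol = 1,
                         dimnames = list(sprintf("S%02d", 1:12), NULL)))
  st <- wc_fst_sites(gm, two_pop_groups(6, 6))
  expect_lte(st$a, 0)
  expect_lte(st$theta, 0)
  expect_equal(st$a, unname(oracle_wc_abc(list(g1, g1))["a"]),
               tolerance = 1e-12)
})

test_that("W&C components match the published-formula oracle to 1e-9", {
  # hand fixture: pop1 4 RR + 1 RA, pop2 1 RR + 1 RA + 3 AA
  g <- c(0L, 0L, 0L, 0L, 1L, 0L, 1L, 2L, 2L, 2L)
  gm <- tiny_geno(matrix(g, ncol = 1,
                         dimnames = list(sprintf("S%02d", 1:10), NULL)))
  st <- wc_fst_sites(gm, two_pop_groups(5, 5))
  o <- oracle_wc_abc(list(g[1:5], g[6:10]))
  expect_equal(st$a, unname(o["a"]), tolerance = 1e-9)
  expect_equal(st$b, unname(o["b"]), tolerance = 1e-9)
  expect_equal(st$c, unname(o["c"]), tolerance = 1e-9)
  expect_equal(st$theta, unname(o["a"] / sum(o)), tolerance = 1e-9)

  # random fixtures, 2 and 3 populations
  set.seed(808)
  for (rep in 1:50) {
    P <- sample(2:3, 1)
    sizes <- sample(3:8, P, replace = TRUE)
    gl <- lapply(sizes, function(k) sample(0:2, k, replace = TRUE))
    geno <- matrix(unlist(gl), ncol = 1)
    rownames(geno) <- sprintf("S%02d", seq_len(sum(sizes)))
    groups <- tibble::tibble(
      strain = rownames(geno),
      group = rep(c("I", "II", "III")[seq_len(P)], times = sizes))
    st <- wc_fst_sites(tiny_geno(geno), groups)
    o <- oracle_wc_abc(gl)
    if (abs(sum(o)) > 1e-300) {
      expect_equal(st$theta, unname(o["a"] / sum(o)), tolerance = 1e-9)
    } else {
      expect_true(is.na(st$theta))
    }
  }
})

test_that("near-fixed frequency differences give strong differentiation", {
  # p = 0.95 vs 0.05 in two pops of 20 strains
  g1 <- c(rep(2L, 18), 1L, 1L)   # p_alt = 0.95
  g2 <- c(rep(0L, 18), 1L, 1L)   # p_alt = 0.05
  gm <- tiny_geno(matrix(c(g1, g2), ncol = 1,
                         dimnames = list(sprintf("S%02d", 1:40), NULL)))
  st <- wc_fst_sites(gm, two_pop_groups(20, 20))
  expect_gt(st$theta, 0.7)
})

test_that("monomorphic loci are flagged undefined", {
  gm <- tiny_geno(matrix(0L, nrow = 8, ncol = 2,
                         dimnames = list(sprintf("S%02d", 1:8), NULL)))
  st <- wc_fst_sites(gm, two_pop_groups(4, 4))
  expect_true(all(is.na(st$theta)))
})

test_that("window theta is the ratio of sums, not the mean of ratios", {
  sites <- tibble::tibble(
    scaffold = "sc1", pos = c(100L, 200L),
    a = c(1, 0), b = c(0, 0), c = c(1, 2),
    theta = c(0.5, 0))
  w <- wc_fst_windows(sites, 5000)
  expect_equal(w$fst, 1 / 4)          # (1+0) / (2+2)
  expect_equal(w$fst_num, 1)
  expect_equal(w$fst_den, 4)
  # single-site window equals the site theta
  w1 <- wc_fst_windows(sites[1, ], 5000)
  expect_equal(w1$fst, 0.5)
})

test_that("windows with no defined site are flagged", {
  sites <- tibble::tibble(scaffold = "sc1", pos = 10L,
                          a = NA_real_, b = NA_real_, c = NA_real_,
                          theta = NA_real_)
  w <- wc_fst_windows(sites, 5000)
  expect_true(is.na(w$fst))
})

test_that("window theta lies between the site theta extremes", {
  ss <- small_sim(seed = 81, n_loci = 500)
  sites <- wc_fst_sites(ss$sim$genotypes, ss$sim$truth$groups)
  w <- wc_fst_windows(sites, 5000)
  for (i in which(!is.na(w$fst) & w$n_sites > 1)) {
    idx <- sites$scaffold == w$scaffold[i] &
      sites$pos >= w$start[i] & sites$pos <= w$end[i] & !is.na(sites$theta) &
      (sites$a + sites$b + sites$c) > 0
    if (sum(idx) > 1) {
      expect_gte(w$fst[i], min(sites$theta[idx]) - 1e-12)
      expect_lte(w$fst[i], max(sites$theta[idx]) + 1e-12)
    }
  }
})

test_that("top-window selection is nearest-rank with tie inclusion", {
  set.seed(909)
  w <- tibble::tibble(scaffold = "sc1",
                      start = seq(1, by = 5000, length.out = 40),
                      end = seq(5000, by = 5000, length.out = 40),
                      n_sites = 1L, fst_num = 1, fst_den = 1,
                      fst = runif(40))
  top <- top_fraction_windows(w, 0.05)
  expect_equal(nrow(top), 2)           # ceiling(0.05 * 40)
  expect_equal(sort(top$fst, decreasing = TRUE),
               sort(w$fst, decreasing = TRUE)[1:2])
  # all-equal values are all kept by the tie rule
  w$fst <- 0.3
  expect_equal(nrow(top_fraction_windows(w, 0.05)), 40)
  # oracle: sort and slice honouring ties, random fractions
  for (rep in 1:20) {
    w$fst <- sample(round(runif(40, 0, 1), 1))   # forces ties
    fr <- runif(1, 0.03, 0.5)
    top <- top_fraction_windows(w, fr)
    k <- ceiling(fr * 40)
    cutoff <- sort(w$fst, decreasing = TRUE)[k]
    expect_setequal(top$start, w$start[w$fst >= cutoff])
  }
  # NA windows are not counted in the denominator
  w$fst[1:10] <- NA
  top <- top_fraction_windows(w, 0.1)
  expect_gte(nrow(top), ceiling(0.1 * 30))
})

test_that("pairwise-intersection assignment follows the two-pair rule", {
  pairs <- c("I-II", "I-III", "II-III")
  win <- function(sc, s) tibble::tibble(scaffold = sc, start = s,
                                        end = s + 4999, n_sites = 1L,
                                        fst_num = 1, fst_den = 1, fst = 0.9)
  tw <- list(
    "I-II" = win("sc1", c(1, 5001)),
    "I-III" = win("sc1", c(1, 10001)),
    "II-III" = win("sc1", 20001))
  snps <- tibble::tibble(scaffold = "sc1",
                         pos = c(100L, 5100L, 10100L, 20100L, 30000L))
  asg <- assign_candidate_divergence_snps(snps, tw)
  # SNP 1 is in I-II and I-III windows only -> Group I
  expect_equal(asg$groups[1], "I")
  # SNP 2 only in I-II -> none; SNP 3 only in I-III -> none
  expect_equal(asg$groups[2], "")
  expect_equal(asg$groups[3], "")
  # SNP 4 only in II-III -> none; SNP 5 nowhere
  expect_equal(asg$groups[4], "")
  expect_equal(asg$groups[5], "")
  # SNP in all three pairs' windows supports all three groups
  tw2 <- list("I-II" = win("sc1", 1), "I-III" = win("sc1", 1),
              "II-III" = win("sc1", 1))
  asg2 <- assign_candidate_divergence_snps(snps[1, ], tw2)
  expect_equal(asg2$groups, "I,II,III")
})

test_that("assignment agrees with the eight-pattern enumeration oracle and is order-invariant", {
  set.seed(910)
  win1 <- tibble::tibble(scaffold = "sc1", start = 1, end = 5000,
                         n_sites = 1L, fst_num = 1, fst_den = 1, fst = 1)
  empty <- win1[0, ]
  for (rep in 1:40) {
    memb <- runif(3) < 0.5     # is the SNP in each pair's window set?
    tw <- list("I-II" = if (memb[1]) win1 else empty,
               "I-III" = if (memb[2]) win1 else empty,
               "II-III" = if (memb[3]) win1 else empty)
    snp <- tibble::tibble(scaffold = "sc1", pos = 100L)
    asg <- assign_candidate_divergence_snps(snp, tw)
    expect_equal(asg$groups, oracle_assign(memb[1], memb[2], memb[3]))
    # order of pairs must not matter
    perm <- sample(3)
    asg2 <- assign_candidate_divergence_snps(snp, tw[perm])
    expect_equal(asg2$groups, asg$groups)
  }
})

test_that("candidate genes deduplicate per group and skip intergenic SNPs", {
  ann <- tibble::tibble(
    scaffold = "sc1", pos = c(100L, 200L, 300L),
    gene_id = c("gene_A", "gene_A", NA), effect = "missense_variant")
  win <- tibble::tibble(scaffold = "sc1", start = 1, end = 5000,
                        n_sites = 1L, fst_num = 1, fst_den = 1, fst = 1)
  tw <- list("I-II" = win, "I-III" = win, "II-III" = win[0, ])
  snps <- tibble::tibble(scaffold = "sc1", pos = c(100L, 200L, 300L))
  asg <- assign_candidate_divergence_snps(snps, tw)
  cg <- candidate_genes(asg, ann)
  expect_equal(cg$gene_sets,
               tibble::tibble(group = "I", gene_id = "gene_A"))
  expect_equal(cg$sharing$n_groups, 1L)
})
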