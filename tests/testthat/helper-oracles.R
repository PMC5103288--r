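# Independent brute-force oracles. These deliberately avoid the package's
# code paths: pairwise enumeration, direct formula transcriptions and
# exhaustive scans, kept simple enough to verify by eye.

# per-site diversity by literal pairwise enumeration over alleles
oracle_site_pi <- function(dosage) {
  alleles <- unlist(lapply(dosage[!is.na(dosage)], function(g) {
    if (g == 0) c(0L, 0L) else if (g == 1) c(0L, 1L) else c(1L, 1L)
  }))
  n <- length(alleles)
  if (n < 2) return(NaN)
  diff_pairs <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) diff_pairs <- diff_pairs + (alleles[i] != alleles[j])
  }
  diff_pairs / choose(n, 2)
}

# Tajima (1989) constants transcribed independently
oracle_tajima_d <- function(s, pi_sum, n) {
  if (s == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

# Weir & Cockerham (1984) a/b/c for one biallelic locus, scalar arithmetic
oracle_wc_abc <- function(geno_by_pop) {
  r <- length(geno_by_pop)
  n_i <- vapply(geno_by_pop, length, 0)
  p_i <- vapply(geno_by_pop, function(g) sum(g) / (2 * length(g)), 0)
  h_i <- vapply(geno_by_pop, function(g) mean(g == 1), 0)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# nested allele-level ANOVA by explicit observation loops
oracle_amova_ss <- function(geno_by_pop) {
  alleles <- function(g) if (g == 1) c(0, 1) else c(g / 2, g / 2)
  obs <- list()
  for (k in seq_along(geno_by_pop)) {
    for (s in seq_along(geno_by_pop[[k]])) {
      obs[[length(obs) + 1]] <- list(pop = k, strain = paste(k, s),
                                     x = alleles(geno_by_pop[[k]][s]))
    }
  }
  allx <- unlist(lapply(obs, `[[`, "x"))
  gm <- mean(allx)
  ss_within <- sum(vapply(obs, function(o) sum((o$x - mean(o$x))^2), 0))
  ss_strain <- 0
  ss_pop <- 0
  for (k in seq_along(geno_by_pop)) {
    pk <- unlist(lapply(obs[vapply(obs, function(o) o$pop == k, TRUE)],
                        `[[`, "x"))
    pm <- mean(pk)
    ss_pop <- ss_pop + length(pk) * (pm - gm)^2
    for (o in obs) {
      if (o$pop == k) ss_strain <- ss_strain + 2 * (mean(o$x) - pm)^2
    }
  }
  c(pop = ss_pop, strain = ss_strain, within = ss_within)
}

# hypergeometric upper tail by direct summation
oracle_fisher_tail <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# record-by-record filter oracle
oracle_filter_keep <- function(rec, min_qual = 30, min_mean_depth = 5,
                               min_maf = 0.05) {
  if (grepl(",", rec$alt) || nchar(rec$ref) != 1 || nchar(rec$alt) != 1) {
    return(FALSE)
  }
  if (is.na(rec$qual) || rec$qual < min_qual) return(FALSE)
  dp <- rec$dp[!is.na(rec$dp)]
  if (length(dp) == 0 || mean(dp) < min_mean_depth) return(FALSE)
  if (any(is.na(rec$gt))) return(FALSE)
  af <- sum(rec$gt) / (2 * length(rec$gt))
  min(af, 1 - af) >= min_maf
}

# divergence assignment by brute force over membership patterns
oracle_assign <- function(in_12, in_13, in_23) {
  out <- character(0)
  if (in_12 && in_13) out <- c(out, "I")
  if (in_12 && in_23) out <- c(out, "II")
  if (in_13 && in_23) out <- c(out, "III")
  paste(out, collapse = ",")
}
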