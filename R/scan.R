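#' Bayesian F_ST outlier scan (multinomial-Dirichlet model)
#'
#' Scans biallelic allele counts for loci whose among-population
#' differentiation exceeds the genome-wide background, using the
#' multinomial-Dirichlet model: population allele frequencies follow a beta
#' distribution around the ancestral frequency with precision
#' `(1 - F_ST)/F_ST`, and locus-by-population F_ST is decomposed on the
#' logit scale into a locus selection effect (alpha) and a population effect
#' (beta). A reversible-jump MCMC toggles each locus effect in and out of
#' the model with prior odds `prior_odds` in favour of the neutral model;
#' birth proposals are tuned in a pilot phase. Posterior error probability
#' is 1 minus the posterior inclusion probability, and the q-value of a
#' locus is the mean PEP over loci at least as extreme.
#'
#' @param alt,tot integer matrices (loci x populations) of alternate-allele
#'   and total allele counts, e.g. from [allele_counts()].
#' @param prior_odds prior odds for the neutral (no selection) model.
#' @param n_burn,n_keep,thin MCMC burn-in, kept iterations, thinning.
#' @param n_pilot pilot iterations used to tune per-locus proposals.
#' @param sd_alpha prior SD of the locus effect alpha (mean 0).
#' @param mu_beta,sd_beta prior mean and SD of the population effect beta.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param se_threshold split-chain disagreement in inclusion probability
#'   above which a convergence warning is emitted.
#' @param loci optional tibble with columns `scaffold`, `pos` to label loci.
#' @return An object of class `fst_scan` whose `result` tibble has one row
#'   per locus: `alpha`, `prob` (posterior inclusion), `pep`, `qvalue` and
#'   the posterior mean per-locus `fst`.
#' @export
fst_outlier_scan <- function(alt, tot, prior_odds = 10,
                             n_burn = 5000, n_keep = 20000, thin = 10,
                             n_pilot = 2000,
                             sd_alpha = 2, mu_beta = -1, sd_beta = 2,
                             seed = NULL, se_threshold = 0.1,
                             loci = NULL) {
  alt <- as.matrix(alt); tot <- as.matrix(tot)
  stopifnot(all(dim(alt) == dim(tot)), ncol(alt) >= 2,
            all(alt >= 0), all(alt <= tot), all(tot >= 1))
  if (!is.null(seed)) set.seed(stage_seed(seed, "scan"))
  raw <- scan_mcmc_cpp(alt, tot, prior_odds, as.integer(n_burn),
                       as.integer(n_keep), as.integer(thin),
                       as.integer(n_pilot), sd_alpha, mu_beta, sd_beta,
                       0.05, 0.3, 0.05)
  pep <- 1 - raw$prob
  res <- tibble(
    locus = if (!is.null(rownames(alt))) rownames(alt)
            else sprintf("L%05d", seq_len(nrow(alt))),
    alpha = raw$alpha,
    prob = raw$prob,
    pep = pep,
    qvalue = qvalues_from_pep(pep),
    fst = raw$fst
  )
  if (!is.null(loci)) {
    loci <- as_tibble(loci)
    stopifnot(nrow(loci) == nrow(res))
    res <- dplyr::bind_cols(loci[, c("scaffold", "pos")], res)
  }
  split_disagreement <- max(abs(raw$prob_first_half - raw$prob_second_half),
                            na.rm = TRUE)
  if (is.finite(split_disagreement) && split_disagreement > se_threshold) {
    warning(sprintf(paste0("scan chain may not have converged: max ",
                           "split-half inclusion-probability disagreement ",
                           "%.3f > %.3f"), split_disagreement, se_threshold))
  }
  structure(list(result = res, beta = raw$beta,
                 n_samples = raw$n_samples,
                 split_disagreement = split_disagreement,
                 settings = list(prior_odds = prior_odds, n_burn = n_burn,
                                 n_keep = n_keep, thin = thin,
                                 n_pilot = n_pilot, sd_alpha = sd_alpha,
                                 mu_beta = mu_beta, sd_beta = sd_beta,
                                 seed = seed)),
            class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat("<fst_scan> ", nrow(x$result), " loci, ", length(x$beta),
      " populations, ", x$n_samples, " posterior samples\n",
      "  loci at q < 0.05: ", sum(x$result$qvalue < 0.05),
      "; split-half disagreement ", round(x$split_disagreement, 3),
      "\n", sep = "")
  invisible(x)
}

#' @rdname fst_outlier_scan
#' @param x an `fst_scan`.
#' @param ... unused.
#' @export
tidy.fst_scan <- function(x, ...) x$result

#' @rdname fst_outlier_scan
#' @export
glance.fst_scan <- function(x, ...) {
  tibble(n_loci = nrow(x$result),
         n_q05 = sum(x$result$qvalue < 0.05),
         mean_fst = mean(x$result$fst),
         split_disagreement = x$split_disagreement,
         n_samples = x$n_samples)
}

#' q-values from posterior error probabilities
#'
#' `q_i` is the mean PEP over all loci with PEP at most `PEP_i` — the
#' Bayesian false-discovery-rate estimate for the list that calls locus i
#' and everything more confident than it.
#'
#' @param pep numeric vector of posterior error probabilities in [0, 1].
#' @return q-values, same length and order as `pep`.
#' @export
qvalues_from_pep <- function(pep) {
  stopifnot(all(pep >= 0 & pep <= 1))
  ord <- order(pep)
  cm <- cumsum(pep[ord]) / seq_along(pep)
  # ties share the q of the last tied position
  last_at <- vapply(pep, function(v) sum(pep <= v), integer(1))
  q <- cm[last_at]
  q
}

#' Call outlier loci from a scan
#'
#' A locus is an outlier when its q-value is below `q_threshold` and its
#' posterior locus F_ST exceeds the mean F_ST across all scanned loci.
#'
#' @param scan an `fst_scan` (or its tidy `result` tibble).
#' @param q_threshold q-value cutoff.
#' @param require_fst_above_mean also require per-locus F_ST above the
#'   scan-wide mean.
#' @return The rows of the scan result that are called outliers.
#' @export
call_outliers <- function(scan, q_threshold = 0.05,
                          require_fst_above_mean = TRUE) {
  res <- if (inherits(scan, "fst_scan")) scan$result else as_tibble(scan)
  keep <- res$qvalue < q_threshold
  if (require_fst_above_mean) keep <- keep & res$fst > mean(res$fst)
  res[keep, , drop = FALSE]
}
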