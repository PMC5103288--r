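#' Weir-Cockerham F_ST variance components per site
#'
#' The Weir & Cockerham (1984) variance-component estimator on diploid
#' genotypes: per locus the among-population (a), among-individual (b) and
#' within-individual (c) components, with observed heterozygote frequencies
#' feeding b and c, and `theta = a / (a + b + c)`. Strains labelled
#' `"outlier"` are excluded; pass `pops` to restrict to one pairwise
#' comparison.
#'
#' @param x a [geno_mat()].
#' @param groups group assignment table.
#' @param pops optional character vector of population labels to include
#'   (default: all non-outlier groups).
#' @return A tibble with columns `scaffold`, `pos`, `a`, `b`, `c`, `theta`
#'   (`theta` is `NA` where the denominator is zero, e.g. monomorphic loci).
#' @export
wc_fst_sites <- function(x, groups, pops = NULL) {
  stopifnot(inherits(x, "geno_mat"))
  groups <- validate_groups(groups, x$strains)
  groups <- groups[groups$group != "outlier", ]
  if (!is.null(pops)) groups <- groups[groups$group %in% pops, ]
  labels <- sort(unique(groups$group))
  r <- length(labels)
  if (r < 2) stop("Weir-Cockerham F_ST needs at least 2 populations")

  n_i <- sapply(labels, function(g) {
    s <- groups$strain[groups$group == g]
    colSums(!is.na(x$geno[s, , drop = FALSE]))
  })                                              # loci x pops called sizes
  p_i <- sapply(labels, function(g) {
    s <- groups$strain[groups$group == g]
    colSums(x$geno[s, , drop = FALSE], na.rm = TRUE)
  }) / (2 * n_i)
  h_i <- sapply(labels, function(g) {
    s <- groups$strain[groups$group == g]
    colSums(x$geno[s, , drop = FALSE] == 1L, na.rm = TRUE)
  }) / n_i

  L <- nrow(x$loci)
  n_i <- matrix(n_i, nrow = L); p_i <- matrix(p_i, nrow = L)
  h_i <- matrix(h_i, nrow = L)
  nbar <- rowSums(n_i) / r
  nc <- (r * nbar - rowSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_i * p_i) / (r * nbar)
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / (r * nbar)

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  den <- a + b + cc
  tibble(scaffold = x$loci$scaffold, pos = x$loci$pos,
         a = a, b = b, c = cc,
         theta = ifelse(abs(den) < 1e-300 | den == 0, NA_real_, a / den))
}

#' Windowed Weir-Cockerham F_ST by ratio of sums
#'
#' Aggregates per-site variance components into non-overlapping windows with
#' the Weir-Cockerham weighted ("ratio of sums") convention used by
#' VCFtools: `theta_window = sum(a) / sum(a + b + c)` over the window's
#' sites. Windows without any site carrying defined components get `NA`.
#'
#' @param sites output of [wc_fst_sites()].
#' @param window_size window width in bp.
#' @return A tibble with `scaffold`, `start`, `end`, `n_sites`, `fst_num`,
#'   `fst_den`, `fst`.
#' @export
wc_fst_windows <- function(sites, window_size = 5000) {
  sites <- as_tibble(sites)
  ok <- !is.na(sites$a + sites$b + sites$c)
  sites |>
    dplyr::mutate(win = (.data$pos - 1) %/% window_size, defined = ok) |>
    dplyr::group_by(.data$scaffold, .data$win) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      fst_num = sum(.data$a[.data$defined]),
      fst_den = sum((.data$a + .data$b + .data$c)[.data$defined]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      start = as.integer(.data$win * window_size + 1),
      end = as.integer((.data$win + 1) * window_size),
      fst = ifelse(.data$fst_den > 0, .data$fst_num / .data$fst_den, NA_real_)
    ) |>
    dplyr::select("scaffold", "start", "end", "n_sites",
                  "fst_num", "fst_den", "fst") |>
    dplyr::arrange(.data$scaffold, .data$start)
}

#' Top-fraction F_ST windows (nearest-rank with tie inclusion)
#'
#' Keeps the `ceiling(fraction * N_defined)` windows with the highest F_ST
#' among windows with a defined value; any window tied with the cutoff value
#' is also kept. Ordering is deterministic: F_ST descending, then scaffold,
#' then start.
#'
#' @param windows output of [wc_fst_windows()].
#' @param fraction fraction of defined windows to keep.
#' @return The selected rows of `windows`.
#' @export
top_fraction_windows <- function(windows, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  defined <- windows[!is.na(windows$fst), ]
  if (nrow(defined) == 0) return(defined)
  defined <- defined[order(-defined$fst, defined$scaffold, defined$start), ]
  k <- ceiling(fraction * nrow(defined))
  cutoff <- defined$fst[k]
  defined[defined$fst >= cutoff, ]
}
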