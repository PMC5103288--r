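#' Hierarchical analysis of molecular variance
#'
#' Partitions total genetic variance into three hierarchical levels — among
#' populations, among strains within populations, and within individual
#' strains — treating each diploid strain as two allele observations per
#' locus and summing squared allele-indicator deviations over loci. Variance
#' components come from the standard nested moment equations
#' `E[MS_within] = s2w`, `E[MS_strain] = s2w + 2 s2s`,
#' `E[MS_pop] = s2w + 2 s2s + n0 s2p` with
#' `n0 = (A - sum(Ak^2)/A)/(P - 1)` over the allele-observation counts Ak.
#' Strains labelled `"outlier"` are excluded.
#'
#' @param x a [geno_mat()] without missing calls.
#' @param groups group assignment table.
#' @return An object of class `amova_fit`; its `table` element mirrors the
#'   conventional AMOVA layout (df, SS, MS, variance component, percent of
#'   total).
#' @export
amova <- function(x, groups) {
  stopifnot(inherits(x, "geno_mat"))
  if (anyNA(x$geno)) stop("AMOVA requires complete genotypes")
  groups <- validate_groups(groups, x$strains)
  groups <- groups[groups$group != "outlier", ]
  pops <- sort(unique(groups$group))
  if (length(pops) < 2) stop("AMOVA needs at least 2 populations")
  sizes <- vapply(pops, function(g) sum(groups$group == g), integer(1))
  if (any(sizes == 0)) stop("empty population")
  g <- x$geno[groups$strain, , drop = FALSE]
  N <- nrow(g); P <- length(pops); L <- ncol(g)

  # per-locus means at each level (allele scale: strain mean = dosage/2)
  strain_mean <- g / 2
  pop_idx <- match(groups$group, pops)
  pop_sum <- rowsum(g, pop_idx)                    # P x L dosage sums
  pop_mean <- pop_sum / (2 * sizes)
  tot_mean <- colSums(g) / (2 * N)

  # within-strain SS: the two alleles of a het strain deviate by 0.5 each
  ss_within <- 0.5 * sum(g == 1L)
  ss_strain <- 2 * sum((strain_mean - pop_mean[pop_idx, , drop = FALSE])^2)
  ss_pop <- 2 * sum(sizes * (pop_mean -
                               matrix(tot_mean, nrow = P, ncol = L,
                                      byrow = TRUE))^2)
  amova_components_from_ss(c(ss_pop, ss_strain, ss_within),
                           df = c(P - 1L, N - P, N),
                           sizes = sizes)
}

#' AMOVA variance components from printed sums of squares
#'
#' The moment-equation back-end of [amova()], exposed so that a published
#' AMOVA table (SS, df, population sizes) can be re-solved directly for its
#' variance components and percentages.
#'
#' @param ss numeric length-3: SS among populations, among strains within
#'   populations, within individual strains.
#' @param df integer length-3 degrees of freedom for the same rows
#'   (`P - 1`, `N - P`, `N` for P populations and N strains).
#' @param sizes population sizes in strains (two allele-observations each).
#' @return An object of class `amova_fit`.
#' @export
amova_components_from_ss <- function(ss, df, sizes) {
  stopifnot(length(ss) == 3, length(df) == 3, all(df > 0), all(sizes > 0))
  ms <- ss / df
  Ak <- 2 * sizes
  A <- sum(Ak)
  P <- length(sizes)
  n0 <- (A - sum(Ak^2) / A) / (P - 1)
  s2w <- ms[3]
  s2s <- (ms[2] - s2w) / 2
  s2p <- (ms[1] - ms[2]) / n0
  vc <- c(s2p, s2s, s2w)
  if (any(vc < 0)) {
    warning("negative variance component estimated; reported as-is")
  }
  vc_all <- c(vc, sum(vc))
  pct_all <- 100 * vc_all / sum(vc)
  tab <- tibble(
    source = c("Among populations", "Among strains within populations",
               "Within individual strains", "Total"),
    df = c(df, sum(df)),
    ss = c(ss, sum(ss)),
    ms = c(ms, sum(ss) / sum(df)),
    vc = vc_all,
    pct_var = pct_all
  )
  structure(list(table = tab, n0 = n0, sizes = sizes), class = "amova_fit")
}

#' @export
print.amova_fit <- function(x, digits = 2, ...) {
  cat("Hierarchical AMOVA (n0 =", round(x$n0, 3), ")\n")
  tab <- x$table
  tab$ss <- round(tab$ss, digits); tab$ms <- round(tab$ms, digits)
  tab$vc <- round(tab$vc, digits); tab$pct_var <- round(tab$pct_var, digits)
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' @rdname amova
#' @param x an `amova_fit`.
#' @param ... unused.
#' @export
tidy.amova_fit <- function(x, ...) x$table

#' @rdname amova
#' @export
glance.amova_fit <- function(x, ...) {
  tab <- x$table
  tibble(
    n_populations = length(x$sizes),
    n_strains = sum(x$sizes),
    n0 = x$n0,
    phi_st = tab$vc[1] / tab$vc[4],
    pct_among_populations = tab$pct_var[1],
    pct_among_strains = tab$pct_var[2],
    pct_within_strains = tab$pct_var[3]
  )
}
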