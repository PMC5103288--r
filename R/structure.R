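#' Allele-sharing genotype distance
#'
#' `d(i, j) = (1/L) * sum_l |g_il - g_jl| / 2` over dosage genotypes:
#' 0 for identical strains, 1 for opposite homozygotes at every locus.
#'
#' @param x a [geno_mat()] without missing calls.
#' @return A symmetric numeric matrix with strain dimnames.
#' @export
genotype_distance <- function(x) {
  stopifnot(inherits(x, "geno_mat"))
  if (anyNA(x$geno)) stop("distance requires complete genotypes")
  L <- nrow(x$loci)
  if (L == 0) stop("no loci")
  d <- as.matrix(dist(x$geno / 2, method = "manhattan")) / L
  dimnames(d) <- list(x$strains, x$strains)
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via ape). Negative branch lengths, which NJ
#' can produce on non-additive matrices, are clamped to zero and counted in
#' the `clamped_edges` attribute.
#'
#' @param d symmetric distance matrix (or `dist`) over at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbour joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  tr <- ape::nj(d)
  n_neg <- sum(tr$edge.length < 0)
  if (n_neg > 0) tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_edges") <- n_neg
  tr
}

#' Root a tree on an outgroup's pendant edge
#'
#' @param tree a `phylo` tree.
#' @param taxon outgroup tip label (e.g. a distant species added to the
#'   distance matrix).
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, taxon) {
  stopifnot(inherits(tree, "phylo"))
  if (!taxon %in% tree$tip.label) {
    stop("outgroup '", taxon, "' is not a tip of the tree")
  }
  ape::root(tree, outgroup = taxon, resolve.root = TRUE)
}

#' Bootstrap support by locus resampling
#'
#' Resamples loci with replacement, rebuilds the NJ tree each time, and
#' reports for each internal node of the reference tree the fraction of
#' pseudoreplicates in which its clade is recovered.
#'
#' @param x a [geno_mat()].
#' @param n_boot number of pseudoreplicates.
#' @param seed integer seed.
#' @return The NJ tree of `x` with `node.label` set to support fractions.
#' @export
nj_bootstrap <- function(x, n_boot = 100, seed = 1) {
  set.seed(stage_seed(seed, "bootstrap"))
  ref <- neighbor_joining(genotype_distance(x))
  L <- nrow(x$loci)
  reps <- replicate(n_boot, {
    idx <- sample.int(L, L, replace = TRUE)
    neighbor_joining(genotype_distance(geno_subset(x, loci = idx)))
  }, simplify = FALSE)
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- counts / n_boot
  ref
}

#' The maximal monophyletic strain groups of a tree
#'
#' Checks whether each group's strains form a monophyletic clade of the tree
#' when rooted on an outgroup (or on the first hybrid-free bipartition).
#'
#' @param tree a `phylo` tree whose tips are strains.
#' @param groups group assignment table; `"outlier"` strains are ignored.
#' @return Named logical vector, one entry per group.
#' @export
group_monophyly <- function(tree, groups) {
  groups <- validate_groups(groups)
  groups <- groups[groups$group %in% setdiff(unique(groups$group), "outlier") &
                     groups$strain %in% tree$tip.label, ]
  pops <- sort(unique(groups$group))
  keep <- ape::keep.tip(tree, groups$strain)
  vapply(setNames(pops, pops), function(g) {
    ape::is.monophyletic(keep, groups$strain[groups$group == g])
  }, logical(1))
}
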