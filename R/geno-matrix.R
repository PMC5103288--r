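#' Genotype matrix container
#'
#' Strains-by-loci matrix of alternate-allele dosages (0, 1, 2; `NA` for a
#' missing call) together with per-locus metadata. Dikaryotic strains carry
#' two haploid nuclei per cell and are genotyped as diploids, so each strain
#' contributes two allele observations per locus.
#'
#' @param geno integer matrix, strains in rows, loci in columns; entries in
#'   `{0, 1, 2, NA}` counting copies of the alternate allele.
#' @param loci data frame with one row per locus and at least columns
#'   `scaffold`, `pos` (1-based bp), `ref`, `alt`; optional `qual` and
#'   `mean_dp` site-quality columns.
#' @param strains character vector of strain names; defaults to
#'   `rownames(geno)`.
#'
#' @return An object of class `geno_mat`.
#' @export
geno_mat <- function(geno, loci, strains = rownames(geno)) {
  geno <- as.matrix(geno)
  loci <- as_tibble(loci)
  stopifnot(ncol(geno) == nrow(loci))
  if (is.null(strains)) strains <- paste0("S", seq_len(nrow(geno)))
  stopifnot(length(strains) == nrow(geno), !anyDuplicated(strains))
  need <- c("scaffold", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(loci))
  if (length(missing_cols) > 0) {
    stop("loci table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  rownames(geno) <- strains
  colnames(geno) <- locus_id(loci)
  structure(list(geno = geno, loci = loci, strains = strains),
            class = "geno_mat")
}

locus_id <- function(loci) paste(loci$scaffold, loci$pos, sep = ":")

#' @export
print.geno_mat <- function(x, ...) {
  n_miss <- sum(is.na(x$geno))
  cat("<geno_mat> ", length(x$strains), " strains x ", nrow(x$loci),
      " loci (", length(unique(x$loci$scaffold)), " scaffolds",
      if (n_miss > 0) paste0(", ", n_miss, " missing calls"), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_mat <- function(x) dim(x$geno)

#' Number of loci in a genotype matrix
#' @param x a [geno_mat()].
#' @return integer count of loci.
#' @export
n_loci <- function(x) nrow(x$loci)

#' Convert a genotype matrix to a long tibble
#'
#' @param x a [geno_mat()].
#' @param ... unused.
#' @return A tibble with columns `strain`, `scaffold`, `pos`, `dosage`.
#' @export
as_tibble.geno_mat <- function(x, ...) {
  tibble(
    strain = rep(x$strains, times = nrow(x$loci)),
    scaffold = rep(x$loci$scaffold, each = length(x$strains)),
    pos = rep(x$loci$pos, each = length(x$strains)),
    dosage = as.vector(x$geno)
  )
}

#' Subset a genotype matrix by loci and/or strains
#'
#' @param x a [geno_mat()].
#' @param loci integer or logical index into loci.
#' @param strains character names, or integer/logical index into strains.
#' @return A `geno_mat` restricted to the selection.
#' @export
geno_subset <- function(x, loci = NULL, strains = NULL) {
  if (is.null(loci)) loci <- seq_len(nrow(x$loci))
  if (is.null(strains)) strains <- x$strains
  if (is.character(strains)) {
    missing_s <- setdiff(strains, x$strains)
    if (length(missing_s) > 0) {
      stop("unknown strain(s): ", paste(missing_s, collapse = ", "))
    }
  }
  geno_mat(x$geno[strains, loci, drop = FALSE],
           x$loci[loci, , drop = FALSE])
}

#' Alternate-allele frequencies across called genotypes
#'
#' Frequencies are computed over allele observations (two per called
#' genotype), the convention used by VCF-style frequency filters.
#'
#' @param x a [geno_mat()].
#' @return Numeric vector, one frequency per locus (`NaN` where no calls).
#' @export
allele_freq <- function(x) {
  colSums(x$geno, na.rm = TRUE) / (2 * colSums(!is.na(x$geno)))
}

#' Per-population allele counts at each locus
#'
#' @param x a [geno_mat()].
#' @param groups a group assignment (see [read_groups()]): data frame with
#'   columns `strain` and `group`.
#' @param drop_outliers drop strains labelled `"outlier"` before counting.
#' @return A list with integer matrices `alt` and `tot` (loci x populations)
#'   and the vector `pops` of population labels.
#' @export
allele_counts <- function(x, groups, drop_outliers = TRUE) {
  groups <- validate_groups(groups, x$strains)
  if (drop_outliers) groups <- groups[groups$group != "outlier", ]
  pops <- sort(unique(groups$group))
  alt <- sapply(pops, function(g) {
    s <- groups$strain[groups$group == g]
    colSums(x$geno[s, , drop = FALSE], na.rm = TRUE)
  })
  tot <- sapply(pops, function(g) {
    s <- groups$strain[groups$group == g]
    2L * colSums(!is.na(x$geno[s, , drop = FALSE]))
  })
  alt <- matrix(as.integer(alt), ncol = length(pops),
                dimnames = list(locus_id(x$loci), pops))
  tot <- matrix(as.integer(tot), ncol = length(pops),
                dimnames = list(locus_id(x$loci), pops))
  list(alt = alt, tot = tot, pops = pops)
}

validate_groups <- function(groups, strains = NULL) {
  groups <- as_tibble(groups)
  if (!all(c("strain", "group") %in% names(groups))) {
    stop("group assignment needs columns 'strain' and 'group'")
  }
  groups$strain <- as.character(groups$strain)
  groups$group <- as.character(groups$group)
  if (!is.null(strains)) {
    missing_s <- setdiff(strains, groups$strain)
    if (length(missing_s) > 0) {
      stop("strains without a group label: ", paste(missing_s, collapse = ", "))
    }
    groups <- groups[match(strains, groups$strain), ]
  }
  groups
}
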