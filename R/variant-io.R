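#' Read a VCF file into variant records
#'
#' Reads a VCFv4.x file (via vcfR) and returns the records in file order,
#' preserving missing genotypes and multiallelic sites — those are removed
#' later by [filter_variants()], not at read time. Genotypes are converted to
#' alternate-allele dosages; any non-diploid genotype call is an error since
#' dikaryotic strains are genotyped as diploids throughout.
#'
#' @param path VCF file path.
#' @return An object of class `vcf_records`: a list with `fixed` (tibble of
#'   scaffold, pos, ref, alt, qual), `gt` and `dp` (strains x loci matrices)
#'   and `strains`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  strains <- colnames(v@gt)[-1]
  if (is.null(strains)) strains <- character()
  if (n_rec == 0) {
    return(structure(list(
      fixed = tibble(scaffold = character(), pos = integer(),
                     ref = character(), alt = character(), qual = numeric()),
      gt = matrix(NA_integer_, nrow = length(strains), ncol = 0,
                  dimnames = list(strains, NULL)),
      dp = matrix(NA_integer_, nrow = length(strains), ncol = 0,
                  dimnames = list(strains, NULL)),
      strains = strains), class = "vcf_records"))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dp_raw)) {
    dp_raw <- matrix(NA_real_, nrow = n_rec, ncol = length(strains))
  }
  # dosage conversion; reject mixed/odd ploidy
  gt_chr <- gsub("\\|", "/", gt_raw)
  known <- is.na(gt_chr) | gt_chr %in% c("0/0", "0/1", "1/0", "1/1", "./.",
                                         ".", "0/2", "2/0", "1/2", "2/1",
                                         "2/2", "0/3", "3/0", "./1", "1/.",
                                         "./0", "0/.")
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop("unsupported genotype '", gt_raw[bad[1], bad[2]],
         "' at record ", bad[1], " (mixed ploidy?)")
  }
  dose_one <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", "./0", "0/.", "./1", "1/.")) {
      return(NA_integer_)
    }
    sum(as.integer(strsplit(g, "/", fixed = TRUE)[[1]]) > 0L)
  }
  lookup_keys <- unique(as.vector(gt_chr))
  lookup <- vapply(lookup_keys, dose_one, integer(1))
  gt <- matrix(lookup[match(as.vector(gt_chr), lookup_keys)],
               nrow = n_rec, ncol = length(strains))
  structure(list(
    fixed = tibble(scaffold = fix$CHROM,
                   pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   qual = suppressWarnings(as.numeric(fix$QUAL))),
    gt = t(gt) |> `dimnames<-`(list(strains, NULL)),
    dp = t(dp_raw) |> `dimnames<-`(list(strains, NULL)),
    strains = strains), class = "vcf_records")
}

#' @export
print.vcf_records <- function(x, ...) {
  cat("<vcf_records> ", nrow(x$fixed), " records, ", length(x$strains),
      " strains\n", sep = "")
  invisible(x)
}

#' Apply the site filters to raw variant records
#'
#' Retains exactly the records that pass all of: biallelic SNP (single-base
#' REF and ALT), site QUAL at or above `min_qual`, mean per-sample depth at
#' or above `min_mean_depth`, no missing genotype call, and allele-frequency
#' MAF at or above `min_maf` (computed over the 2N called alleles; the bound
#' is inclusive). Mean depth is averaged over samples with a reported DP.
#'
#' @param records a `vcf_records` from [read_vcf()].
#' @param min_qual minimum phred site quality.
#' @param min_mean_depth minimum mean per-sample depth.
#' @param min_maf minimum minor allele frequency (inclusive).
#' @param require_complete drop sites with any missing genotype.
#' @param biallelic_only drop multiallelic records and indels.
#' @return A [geno_mat()] of the surviving loci (with `qual` and `mean_dp`
#'   in the locus table). Zero survivors yields an empty matrix with a
#'   warning.
#' @export
filter_variants <- function(records, min_qual = 30, min_mean_depth = 5,
                            min_maf = 0.05, require_complete = TRUE,
                            biallelic_only = TRUE) {
  stopifnot(inherits(records, "vcf_records"))
  if (length(records$strains) < 1) stop("need at least one strain")
  fx <- records$fixed
  n <- nrow(fx)
  keep <- rep(TRUE, n)
  if (biallelic_only) {
    keep <- keep & !grepl(",", fx$alt, fixed = TRUE) &
      nchar(fx$ref) == 1 & nchar(fx$alt) == 1 &
      fx$ref %in% c("A", "C", "G", "T") & fx$alt %in% c("A", "C", "G", "T")
  }
  keep <- keep & !is.na(fx$qual) & fx$qual >= min_qual
  mean_dp <- colMeans(records$dp, na.rm = TRUE)
  mean_dp[is.nan(mean_dp)] <- NA_real_
  keep <- keep & !is.na(mean_dp) & mean_dp >= min_mean_depth
  n_called <- colSums(!is.na(records$gt))
  if (require_complete) keep <- keep & n_called == length(records$strains)
  af <- colSums(records$gt, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(af, 1 - af)
  keep <- keep & n_called > 0 & maf >= min_maf
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    warning("no variants survive filtering; returning an empty matrix")
  }
  loci <- dplyr::bind_cols(fx[keep, , drop = FALSE],
                           tibble(mean_dp = mean_dp[keep]))
  gm <- geno_mat(records$gt[, keep, drop = FALSE], loci,
                 strains = records$strains)
  ord <- order(gm$loci$scaffold, gm$loci$pos)
  geno_subset(gm, loci = ord)
}

#' Thin loci to a minimum pairwise distance within each scaffold
#'
#' Greedy left-to-right thinning, the conventional linkage-disequilibrium
#' pruning used before model-based structure analyses: the first locus of
#' each scaffold is kept, and each subsequent locus is kept iff it lies at
#' least `min_bp` beyond the last kept position.
#'
#' @param x a [geno_mat()] with loci sorted by (scaffold, pos).
#' @param min_bp minimum distance in bp between kept loci.
#' @return The thinned [geno_mat()].
#' @export
thin_by_distance <- function(x, min_bp = 1000) {
  stopifnot(inherits(x, "geno_mat"))
  loci <- x$loci
  if (nrow(loci) == 0 || min_bp <= 0) return(x)
  if (any(order(loci$scaffold, loci$pos) != seq_len(nrow(loci)))) {
    stop("loci must be sorted by (scaffold, pos) before thinning")
  }
  keep <- logical(nrow(loci))
  last_scaffold <- ""
  last_pos <- -Inf
  for (i in seq_len(nrow(loci))) {
    if (loci$scaffold[i] != last_scaffold ||
        loci$pos[i] - last_pos >= min_bp) {
      keep[i] <- TRUE
      last_scaffold <- loci$scaffold[i]
      last_pos <- loci$pos[i]
    }
  }
  geno_subset(x, loci = which(keep))
}

#' Which loci segregate within each group
#'
#' A locus is "detected" in a group when, among that group's strains, it is
#' polymorphic (both alleles observed — the default) or, under
#' `rule = "alt_present"`, when the alternate allele is observed at all.
#'
#' @param x a [geno_mat()].
#' @param groups group assignment table.
#' @param rule membership rule.
#' @param include_outliers also compute membership for the `"outlier"` label.
#' @return Logical matrix, loci x groups.
#' @export
group_membership <- function(x, groups,
                             rule = c("polymorphic", "alt_present"),
                             include_outliers = FALSE) {
  rule <- match.arg(rule)
  groups <- validate_groups(groups, x$strains)
  if (!include_outliers) groups <- groups[groups$group != "outlier", ]
  pops <- sort(unique(groups$group))
  memb <- sapply(pops, function(g) {
    s <- groups$strain[groups$group == g]
    sub <- x$geno[s, , drop = FALSE]
    alt <- colSums(sub, na.rm = TRUE)
    tot <- 2L * colSums(!is.na(sub))
    if (rule == "polymorphic") alt > 0L & alt < tot else alt > 0L
  })
  matrix(memb, ncol = length(pops),
         dimnames = list(locus_id(x$loci), pops))
}

#' Subset a genotype matrix to one group's strains and segregating loci
#'
#' @inheritParams group_membership
#' @param group group label to keep.
#' @param loci_rule `"detected"` keeps only loci detected in the group per
#'   `rule`; `"all"` keeps every locus.
#' @return A [geno_mat()] of the group's strains.
#' @export
subset_by_group <- function(x, groups, group,
                            rule = c("polymorphic", "alt_present"),
                            loci_rule = c("detected", "all")) {
  rule <- match.arg(rule)
  loci_rule <- match.arg(loci_rule)
  groups <- validate_groups(groups, x$strains)
  s <- groups$strain[groups$group == group]
  if (length(s) == 0) stop("no strains in group '", group, "'")
  keep <- if (loci_rule == "detected") {
    which(group_membership(x, groups, rule, include_outliers = TRUE)[, group])
  } else {
    seq_len(nrow(x$loci))
  }
  geno_subset(x, loci = keep, strains = s)
}

#' Count SNPs detected within a group
#'
#' @inheritParams subset_by_group
#' @return Integer count of loci detected in the group.
#' @export
group_snp_count <- function(x, groups, group,
                            rule = c("polymorphic", "alt_present")) {
  rule <- match.arg(rule)
  memb <- group_membership(x, groups, rule, include_outliers = TRUE)
  if (!group %in% colnames(memb)) stop("no strains in group '", group, "'")
  sum(memb[, group])
}
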