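#' Write a genotype matrix to a VCFv4.2 file
#'
#' Emits a minimal but valid VCFv4.2 file with `GT:DP` per sample. Genotypes
#' are written unphased (`0/0`, `0/1`, `1/1`, `./.`); QUAL is taken from the
#' locus table when present. The file round-trips losslessly through
#' [read_vcf()] + [filter_variants()].
#'
#' @param x a [geno_mat()].
#' @param path output file path.
#' @param depth per-sample read depth to record in `DP`; either a single
#'   value or a strains-by-loci matrix.
#' @param scaffold_lengths optional named vector of scaffold lengths for the
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, depth = 50L, scaffold_lengths = NULL) {
  stopifnot(inherits(x, "geno_mat"))
  scafs <- unique(x$loci$scaffold)
  contig <- if (is.null(scaffold_lengths)) {
    sprintf("##contig=<ID=%s>", scafs)
  } else {
    sprintf("##contig=<ID=%s,length=%d>", scafs,
            as.integer(scaffold_lengths[scafs]))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mycopop",
    contig,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$strains), collapse = "\t")
  )
  L <- nrow(x$loci)
  if (L == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (!is.matrix(depth)) {
    depth <- matrix(as.integer(depth), nrow = length(x$strains), ncol = L)
  }
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$geno + 1L],
                   nrow = length(x$strains))
  gt_str[is.na(x$geno)] <- "./."
  field <- matrix(paste0(gt_str, ":", depth), nrow = length(x$strains))
  qual <- if ("qual" %in% names(x$loci)) x$loci$qual else rep(60, L)
  body <- paste(
    x$loci$scaffold, x$loci$pos, ".", x$loci$ref, x$loci$alt,
    qual, "PASS", ".", "GT:DP",
    apply(field, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write simulator outputs as plain-text fixture tables
#'
#' Writes the VCF, the group-assignment TSV, the annotation TSV, the
#' gene-to-GO TSV, the phenotype CSV and the per-locus truth TSV into `dir`.
#'
#' @param sim result of [simulate_genotypes()].
#' @param annotation result of [simulate_annotation()].
#' @param phenotypes result of [simulate_phenotypes()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_sim_tables <- function(sim, annotation, phenotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    groups = file.path(dir, "groups.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    go_map = file.path(dir, "go_map.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    truth_loci = file.path(dir, "truth_loci.tsv")
  )
  write_vcf(sim$genotypes, paths["vcf"])
  readr::write_tsv(sim$truth$groups, paths["groups"])
  readr::write_tsv(annotation$annotation, paths["annotation"])
  readr::write_tsv(annotation$go_map, paths["go_map"])
  readr::write_csv(phenotypes, paths["phenotypes"])
  readr::write_tsv(sim$truth$loci, paths["truth_loci"])
  paths
}

#' Read a group-assignment table
#'
#' @param path TSV with columns `strain` and `group` (labels such as I, II,
#'   III and `outlier` for admixed strains excluded from between-group
#'   analyses).
#' @return A tibble with columns `strain`, `group`.
#' @export
read_groups <- function(path) {
  validate_groups(readr::read_tsv(path, show_col_types = FALSE))
}
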