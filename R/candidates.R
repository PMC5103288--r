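#' Assign outlier SNPs to the group divergences they support
#'
#' Implements the pairwise-intersection rule for candidate divergence loci:
#' each pairwise comparison (e.g. I-II) contributes the set of top-F_ST
#' windows from [top_fraction_windows()]; an outlier SNP supports the
#' divergence of group X iff it falls inside a top window of BOTH pairwise
#' comparisons involving X. A SNP inside all three pairs' windows supports
#' all three groups; a SNP inside at most one pair's windows supports none
#' but is still tallied per pair (the Venn view).
#'
#' @param outliers tibble of outlier SNPs with columns `scaffold`, `pos`
#'   (e.g. from [call_outliers()] on a scan labelled with loci).
#' @param top_windows named list of window tibbles, one per pair, with names
#'   like `"I-II"`, `"I-III"`, `"II-III"` (group labels joined by `-`).
#' @return An object of class `candidate_assignment`: a tibble with one row
#'   per outlier SNP, a logical `in_<pair>` column per pair, and `groups`
#'   (comma-separated labels of the supported groups, `""` for none).
#' @export
assign_candidate_divergence_snps <- function(outliers, top_windows) {
  outliers <- as_tibble(outliers)
  stopifnot(all(c("scaffold", "pos") %in% names(outliers)),
            length(top_windows) >= 1, !is.null(names(top_windows)))
  pairs <- names(top_windows)
  pair_groups <- strsplit(pairs, "-", fixed = TRUE)
  all_groups <- sort(unique(unlist(pair_groups)))

  memb <- matrix(FALSE, nrow = nrow(outliers), ncol = length(pairs),
                 dimnames = list(NULL, pairs))
  for (pr in pairs) memb[, pr] <- snp_in_windows(outliers, top_windows[[pr]])
  assigned <- vapply(seq_len(nrow(outliers)), function(i) {
    supp <- vapply(all_groups, function(g) {
      involving <- pairs[vapply(pair_groups, function(pg) g %in% pg,
                                logical(1))]
      length(involving) >= 2 && all(memb[i, involving])
    }, logical(1))
    paste(all_groups[supp], collapse = ",")
  }, character(1))

  out <- dplyr::bind_cols(
    outliers,
    as_tibble(setNames(as.data.frame(memb), paste0("in_", pairs))),
    tibble(groups = assigned)
  )
  structure(out, class = c("candidate_assignment", class(out)))
}

snp_in_windows <- function(snps, windows) {
  if (nrow(windows) == 0 || nrow(snps) == 0) {
    return(rep(FALSE, nrow(snps)))
  }
  vapply(seq_len(nrow(snps)), function(i) {
    any(windows$scaffold == snps$scaffold[i] &
          windows$start <= snps$pos[i] &
          windows$end >= snps$pos[i])
  }, logical(1))
}

#' Venn-style tally of outlier SNPs across pairwise top-window sets
#'
#' @param assignment a `candidate_assignment`.
#' @return A tibble with per-pair counts, per-group candidate counts, and
#'   the count of SNPs in all pairs' windows.
#' @export
venn_counts <- function(assignment) {
  pair_cols <- grep("^in_", names(assignment), value = TRUE)
  per_pair <- tibble(
    set = sub("^in_", "", pair_cols),
    kind = "pair_windows",
    n = vapply(pair_cols, function(cn) sum(assignment[[cn]]), integer(1))
  )
  groups <- setdiff(unique(unlist(strsplit(assignment$groups[
    assignment$groups != ""], ","))), "")
  per_group <- tibble(
    set = if (length(groups)) sort(groups) else character(),
    kind = "group_candidates",
    n = vapply(if (length(groups)) sort(groups) else character(),
               function(g) {
                 sum(vapply(strsplit(assignment$groups, ","),
                            function(v) g %in% v, logical(1)))
               }, integer(1))
  )
  all_pairs <- tibble(
    set = "all_pairs", kind = "intersection",
    n = sum(rowSums(as.matrix(assignment[, pair_cols])) == length(pair_cols))
  )
  dplyr::bind_rows(per_pair, per_group, all_pairs)
}

#' Candidate divergence genes per group
#'
#' Maps each assigned candidate SNP to its gene via the annotation table
#' (intergenic SNPs contribute nothing), deduplicates per group, and
#' reports how many groups share each gene.
#'
#' @param assignment a `candidate_assignment`.
#' @param annotation tibble with columns `scaffold`, `pos`, `gene_id`.
#' @return A list with `gene_sets` (tibble `group`, `gene_id`) and
#'   `sharing` (tibble `gene_id`, `n_groups`, `groups`).
#' @export
candidate_genes <- function(assignment, annotation) {
  ann <- as_tibble(annotation)[, c("scaffold", "pos", "gene_id")]
  joined <- dplyr::left_join(as_tibble(assignment), ann,
                             by = c("scaffold", "pos"))
  long <- joined |>
    dplyr::filter(.data$groups != "", !is.na(.data$gene_id)) |>
    tidyr::separate_rows("groups", sep = ",") |>
    dplyr::distinct(group = .data$groups, gene_id = .data$gene_id) |>
    dplyr::arrange(.data$group, .data$gene_id)
  sharing <- long |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_groups = dplyr::n(),
                     groups = paste(sort(.data$group), collapse = ","),
                     .groups = "drop")
  list(gene_sets = long, sharing = sharing)
}
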