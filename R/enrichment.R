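#' Group-specific SNPs
#'
#' A locus is specific to group X when it is detected (per the membership
#' rule, default polymorphic-within-group) in X and in no other non-outlier
#' group. Specific sets are pairwise disjoint by construction.
#'
#' @inheritParams group_membership
#' @return A tibble with columns `scaffold`, `pos`, `group`.
#' @export
group_specific_snps <- function(x, groups,
                                rule = c("polymorphic", "alt_present")) {
  rule <- match.arg(rule)
  memb <- group_membership(x, groups, rule)
  n_in <- rowSums(memb)
  specific <- which(n_in == 1L)
  if (length(specific) == 0) {
    return(tibble(scaffold = character(), pos = integer(),
                  group = character()))
  }
  grp <- colnames(memb)[apply(memb[specific, , drop = FALSE], 1, which.max)]
  tibble(scaffold = x$loci$scaffold[specific],
         pos = x$loci$pos[specific],
         group = grp)
}

#' Missense gene sets from group-specific SNPs
#'
#' Filters each group's specific SNP set to those annotated as missense and
#' maps them to genes, deduplicating genes while keeping the originating
#' SNP count.
#'
#' @param specific output of [group_specific_snps()].
#' @param annotation tibble with columns `scaffold`, `pos`, `gene_id`,
#'   `effect`.
#' @return A tibble with columns `group`, `gene_id`, `n_snps`.
#' @export
missense_gene_sets <- function(specific, annotation) {
  ann <- as_tibble(annotation)
  dplyr::inner_join(as_tibble(specific), ann, by = c("scaffold", "pos")) |>
    dplyr::filter(.data$effect == "missense_variant", !is.na(.data$gene_id)) |>
    dplyr::count(.data$group, .data$gene_id, name = "n_snps") |>
    dplyr::arrange(.data$group, .data$gene_id)
}

#' Fisher's exact over-representation test for GO terms
#'
#' One-sided hypergeometric tail test per term: with N background genes of
#' which K carry the term, and a study set of n genes of which k carry it,
#' `p = P[X >= k]`, `X ~ Hypergeom(N, K, n)`. Terms are reported with the
#' log2 odds of [log_odds()], significance stars at 0.05/0.01, and a
#' Benjamini-Hochberg adjusted column as an optional extra.
#'
#' @param gene_set character vector of study genes (must all be in
#'   `background`).
#' @param go_map tibble with columns `gene_id`, `term`.
#' @param background character vector of background genes (conventionally
#'   all genes carrying at least one analysed SNP).
#' @return A tibble with one row per term, sorted by p.
#' @export
fisher_enrichment <- function(gene_set, go_map, background) {
  gene_set <- unique(as.character(gene_set))
  background <- unique(as.character(background))
  missing_bg <- setdiff(gene_set, background)
  if (length(missing_bg) > 0) {
    stop("study genes absent from background: ",
         paste(head(missing_bg, 5), collapse = ", "))
  }
  go_map <- as_tibble(go_map)
  go_map <- go_map[go_map$gene_id %in% background, ]
  N <- length(background)
  n <- length(gene_set)
  terms <- sort(unique(go_map$term))
  rows <- purrr::map_dfr(terms, function(tm) {
    with_term <- unique(go_map$gene_id[go_map$term == tm])
    K <- length(with_term)
    k <- sum(gene_set %in% with_term)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = tm, k = k, n = n, K = K, N = N, p = p,
           log2_odds = log_odds(k, n, K, N))
  })
  rows$stars <- ifelse(rows$p < 0.01, "**", ifelse(rows$p < 0.05, "*", ""))
  rows$p_adj_bh <- stats::p.adjust(rows$p, method = "BH")
  rows[order(rows$p, rows$term), ]
}

#' Log2 odds of a term's frequency in a set versus the background
#'
#' `log2((k/n) / (K/N))`; `NA` (flagged by the caller) when `k` or `K` is
#' zero.
#'
#' @param k study genes carrying the term.
#' @param n study set size.
#' @param K background genes carrying the term.
#' @param N background size.
#' @return Numeric log2 odds.
#' @export
log_odds <- function(k, n, K, N) {
  ifelse(k == 0 | K == 0, NA_real_, log2((k / n) / (K / N)))
}
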