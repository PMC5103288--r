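#' Min-max normalisation of phenotype traits
#'
#' Rescales each trait to [0, 1] with
#' `(P - min_p) / (max_p - min_p)` over the non-missing entries of that
#' trait; missing values stay missing. A constant trait (max = min) is set
#' to all zeros with a warning.
#'
#' @param table tibble with a `strain` column followed by numeric trait
#'   columns (missing allowed).
#' @return The table with every trait column normalised.
#' @export
normalize_phenotypes <- function(table) {
  table <- as_tibble(table)
  stopifnot("strain" %in% names(table))
  traits <- setdiff(names(table), "strain")
  for (tr in traits) {
    v <- table[[tr]]
    if (all(is.na(v))) stop("trait '", tr, "' has no non-missing value")
    rng <- range(v, na.rm = TRUE)
    if (rng[1] == rng[2]) {
      warning("trait '", tr, "' is constant; normalised to 0")
      table[[tr]] <- ifelse(is.na(v), NA_real_, 0)
    } else {
      table[[tr]] <- (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  table
}

#' Complete-linkage clustering of strains and traits
#'
#' Agglomerative clustering with complete linkage on Euclidean distances,
#' applied to both the rows (strains) and the columns (traits) of the
#' normalised phenotype table — the standard two-way heatmap ordering.
#' Missing entries are imputed by the trait mean and flagged.
#'
#' @param table a normalised phenotype table (see [normalize_phenotypes()]).
#' @return An object of class `pheno_clust`: `strain_hclust` and
#'   `trait_hclust` (`hclust` objects), `matrix` (imputed values, original
#'   order), `ordered_matrix` (rows/cols in dendrogram order) and `imputed`
#'   (tibble of imputed cells).
#' @export
cluster_phenotypes <- function(table) {
  table <- as_tibble(table)
  stopifnot("strain" %in% names(table))
  m <- as.matrix(table[, setdiff(names(table), "strain")])
  rownames(m) <- table$strain
  imputed_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(imputed_idx) > 0) {
    trait_means <- colMeans(m, na.rm = TRUE)
    m[imputed_idx] <- trait_means[imputed_idx[, "col"]]
  }
  sh <- hclust(dist(m, method = "euclidean"), method = "complete")
  th <- hclust(dist(t(m), method = "euclidean"), method = "complete")
  structure(list(
    strain_hclust = sh,
    trait_hclust = th,
    matrix = m,
    ordered_matrix = m[sh$order, th$order, drop = FALSE],
    imputed = tibble(
      strain = rownames(m)[imputed_idx[, "row"]],
      trait = colnames(m)[imputed_idx[, "col"]]
    )
  ), class = "pheno_clust")
}

#' @export
print.pheno_clust <- function(x, ...) {
  cat("<pheno_clust> ", nrow(x$matrix), " strains x ", ncol(x$matrix),
      " traits; ", nrow(x$imputed), " imputed cells\n", sep = "")
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust` object (e.g. from [cluster_phenotypes()]).
#' @return A Newick string with the merge heights as branch lengths.
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Per-group trait means and SDs
#'
#' @param table phenotype table (raw or normalised) with a `strain` column.
#' @param groups group assignment table.
#' @return A tibble with one row per (group, trait): `n_obs`, `mean`, `sd`
#'   (`NA` with fewer than 2 observations).
#' @export
group_summary <- function(table, groups) {
  table <- as_tibble(table)
  groups <- validate_groups(groups)
  table |>
    dplyr::inner_join(groups, by = "strain") |>
    tidyr::pivot_longer(cols = -c("strain", "group"),
                        names_to = "trait", values_to = "value") |>
    dplyr::group_by(.data$group, .data$trait) |>
    dplyr::summarise(
      n_obs = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}
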