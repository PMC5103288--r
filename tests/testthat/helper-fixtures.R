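# Small in-code fixtures shared across test files.

tiny_geno <- function(geno, scaffold = "sc1", pos = NULL, qual = 100) {
  geno <- as.matrix(geno)
  L <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(L) * 10L
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("S%02d", seq_len(nrow(geno)))
  }
  geno_mat(geno, tibble::tibble(
    scaffold = rep(scaffold, length.out = L),
    pos = as.integer(pos),
    ref = rep("A", L), alt = rep("T", L),
    qual = rep(qual, length.out = L)
  ))
}

two_pop_groups <- function(n1, n2, prefix = "S") {
  tibble::tibble(
    strain = sprintf("%s%02d", prefix, seq_len(n1 + n2)),
    group = c(rep("I", n1), rep("II", n2))
  )
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  agree <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

small_sim <- function(seed = 42, n_loci = 400, ...) {
  args <- list(n_loci = n_loci,
               strains_per_population = c(8, 6, 8),
               scaffold_layout = tibble::tibble(
                 scaffold = c("sc1", "sc2"), length = c(60000, 40000)),
               n_genes = 30, n_go_terms = 10,
               seed = seed)
  args <- utils::modifyList(args, list(...))
  cfg <- do.call(sim_config, args)
  list(cfg = cfg, sim = simulate_genotypes(cfg))
}
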