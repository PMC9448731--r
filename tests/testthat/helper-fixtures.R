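# Shared toy fixtures and independent oracles, built in code.

# A 3-gene path A-B-C as a deduplicated interaction set.
toy_chain <- function() {
  merge_and_dedupe(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                              source = "toy"))
}

# Uniform annotations: every gene in the same single domain, every level
# identical, so all edge weights collapse to a constant.
uniform_localization <- function(genes, domain = "cytosol") {
  setNames(rep(list(domain), length(genes)), genes)
}

uniform_abundance <- function(genes, tissues, level = "medium") {
  matrix(level, nrow = length(genes), ncol = length(tissues),
         dimnames = list(genes, tissues))
}

# Constant mapping used for the all-weights-1 ablation.
flat_mapping <- function() {
  c(not_detected = 1, low = 1, medium = 1, high = 1)
}

# Independent oracle: row-normalized adjacency matrix of an interaction set
# (self-loops for isolated genes), built with plain dense arithmetic.
adjacency_walk_oracle <- function(interactions, genes) {
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  for (e in seq_len(nrow(interactions))) {
    i <- interactions$gene_a[e]
    j <- interactions$gene_b[e]
    A[i, j] <- 1
    A[j, i] <- 1
  }
  iso <- rowSums(A) == 0
  diag(A)[iso] <- 1
  sweep(A, 1, rowSums(A), "/")
}

# Independent oracle: upper hypergeometric tail by explicit enumeration of
# choose() terms.
hyper_tail_oracle <- function(k, size_a, size_b, universe) {
  ks <- k:min(size_a, size_b)
  sum(choose(size_a, ks) * choose(universe - size_a, size_b - ks)) /
    choose(universe, size_b)
}

# A tiny complete study used by several suites.
small_study <- function(seed = 42) {
  simulate_study(sim_config(n_genes = 80, module_size = 16,
                            seed_fraction = 0.5, n_tissues = 6, n_brain = 2,
                            edge_density = 0.05, n_regions = 2, n_reps = 3,
                            rng_seed = seed))
}
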