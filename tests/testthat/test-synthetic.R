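test_that("gene universe generation is deterministic, unique, and validated", {
  cfg <- sim_config(n_genes = 5, rng_seed = 1, module_size = 2)
  u1 <- generate_universe(cfg)
  u2 <- generate_universe(cfg)
  expect_identical(u1, u2)
  expect_length(u1, 5)

  expect_error(sim_config(n_genes = 1, module_size = 1), "n_genes")

  big <- generate_universe(sim_config(n_genes = 500, rng_seed = 7))
  expect_length(unique(big), 500)
})

test_that("interactome sources honor duplication controls", {
  cfg1 <- sim_config(n_genes = 40, module_size = 8, n_sources = 1,
                     duplicate_rate = 0, edge_density = 0.2, rng_seed = 3)
  u <- generate_universe(cfg1)
  src <- generate_interactome_sources(u, cfg1)
  expect_length(src, 1)
  merged <- merge_and_dedupe(src)
  expect_equal(nrow(merged), nrow(src[[1]]))

  cfg2 <- sim_config(n_genes = 40, module_size = 8, n_sources = 2,
                     duplicate_rate = 1, edge_density = 0.2, rng_seed = 3)
  src2 <- generate_interactome_sources(u, cfg2)
  canon <- function(df) sort(paste(pmin(df$gene_a, df$gene_b),
                                   pmax(df$gene_a, df$gene_b)))
  expect_true(all(canon(src2[[2]]) %in% canon(src2[[1]])))

  expect_error(generate_interactome_sources(character(0), cfg1), "empty")
})

test_that("background edge count matches the binomial model", {
  cfg <- sim_config(n_genes = 100, module_size = 10, edge_density = 0.05,
                    duplicate_rate = 0, n_sources = 1, rng_seed = 3)
  u <- generate_universe(cfg)
  src <- generate_interactome_sources(u, cfg)  # no module wiring
  n_pairs <- choose(100, 2)
  expected <- n_pairs * 0.05
  sd3 <- 3 * sqrt(n_pairs * 0.05 * 0.95)
  expect_gt(nrow(src[[1]]), expected - sd3)
  expect_lt(nrow(src[[1]]), expected + sd3)
})

test_that("localization generation covers degenerate and planted cases", {
  cfg1 <- sim_config(n_genes = 30, module_size = 6, n_domains = 1,
                     rng_seed = 5)
  u <- generate_universe(cfg1)
  loc1 <- generate_localization(u, cfg1)
  expect_true(all(vapply(loc1, identical, logical(1),
                         cfg1$domain_labels[1])))

  cfg2 <- sim_config(n_genes = 30, module_size = 6,
                     module_domain_prob = 1, rng_seed = 5)
  mod <- plant_module(u, cfg2)
  loc2 <- generate_localization(u, cfg2, mod)
  shared <- vapply(loc2[mod$member_genes], function(d)
    cfg2$domain_labels[1] %in% d, logical(1))
  expect_true(all(shared))

  cfg3 <- sim_config(n_genes = 200, module_size = 10, mean_domains = 2,
                     rng_seed = 5)
  u3 <- generate_universe(cfg3)
  loc3 <- generate_localization(u3, cfg3)
  m <- mean(lengths(loc3))
  expect_gte(m, 1.7)
  expect_lte(m, 2.3)
  expect_true(all(lengths(loc3) >= 1))
})

test_that("abundance boost lifts module genes in brain tissues only", {
  cfg <- sim_config(n_genes = 100, module_size = 20, n_tissues = 10,
                    n_brain = 3, rng_seed = 9)
  u <- generate_universe(cfg)
  mod <- plant_module(u, cfg)

  # zero boost: identical to the module-free background draw
  cfg0 <- sim_config(n_genes = 100, module_size = 20, n_tissues = 10,
                     n_brain = 3, abundance_boost = 0, rng_seed = 9)
  expect_identical(generate_abundance(u, mod, cfg0),
                   generate_abundance(u, NULL, cfg0))

  # boost of 3 forces every module cell in target tissues to "high"
  cfg3 <- sim_config(n_genes = 100, module_size = 20, n_tissues = 10,
                     n_brain = 3, abundance_boost = 3, rng_seed = 9)
  ab3 <- generate_abundance(u, mod, cfg3)
  expect_true(all(ab3[mod$member_genes, mod$target_tissues] == "high"))

  # default boost: module genes more abundant in brain than elsewhere
  ab <- generate_abundance(u, mod, cfg)
  map <- default_abundance_mapping()
  brain <- map[ab[mod$member_genes, cfg$brain_tissues]]
  other <- map[ab[mod$member_genes,
                  setdiff(cfg$tissue_labels, cfg$brain_tissues)]]
  expect_gt(mean(brain), mean(other))

  expect_error(generate_abundance(u, list(member_genes = "NOPE",
                                          target_tissues = "x"), cfg),
               "not in universe")
})

test_that("evidence concentrates in seeds and hidden genes stay silent", {
  cfg <- sim_config(n_genes = 120, module_size = 24, seed_fraction = 0.5,
                    rng_seed = 13)
  u <- generate_universe(cfg)
  mod <- plant_module(u, cfg)
  E <- generate_evidence(u, mod, cfg)
  S <- build_signal_vector(E)
  expect_true(all(S[mod$seed_genes] >= 1))
  expect_true(all(S[mod$hidden_genes] == 0))
  expect_lte(max(S), cfg$n_layers)

  no_seeds <- mod
  no_seeds$seed_genes <- character(0)
  expect_error(generate_evidence(u, no_seeds, cfg), "no signal to diffuse")
})

test_that("developmental expression is deterministic with planted shifts", {
  cfg <- sim_config(n_genes = 50, module_size = 10, n_regions = 2,
                    n_reps = 3, de_fraction = 0.3, rng_seed = 17)
  u <- generate_universe(cfg)
  d1 <- generate_dev_expression(u, cfg)
  d2 <- generate_dev_expression(u, cfg)
  expect_identical(d1$expr, d2$expr)
  expect_length(d1$de_genes, round(0.3 * 50))
  expect_equal(nrow(d1$samples), 2 * 7 * 3)
  expect_setequal(unique(stage_group(d1$samples$stage_bin)),
                  c("prenatal", "postnatal"))
})

test_that("marker sets hit their configured module overlap exactly", {
  cfg <- sim_config(n_genes = 200, module_size = 20, rng_seed = 21,
                    marker_set_size = 30,
                    marker_overlap = c(neuronal = 10, glial = 0))
  u <- generate_universe(cfg)
  mod <- plant_module(u, cfg)
  sets <- generate_marker_sets(u, mod, cfg)
  expect_length(intersect(sets$neuronal, mod$member_genes), 10)
  expect_length(intersect(sets$glial, mod$member_genes), 0)
  expect_length(sets$neuronal, 30)

  bad <- sim_config(n_genes = 200, module_size = 20, rng_seed = 21,
                    marker_set_size = 30, marker_overlap = c(neuronal = 25))
  expect_error(generate_marker_sets(u, mod, bad), "exceeds module size")
})

test_that("planted module edges outweigh background edges in brain tissue", {
  sim <- small_study()
  cfg <- sim$config
  ints <- merge_and_dedupe(sim$sources)
  map <- default_abundance_mapping()
  brain <- cfg$brain_tissues[1]
  w <- vapply(seq_len(nrow(ints)), function(e) {
    a <- ints$gene_a[e]; b <- ints$gene_b[e]
    localization_weight(sim$localization[[a]], sim$localization[[b]]) *
      abundance_factor(sim$abundance[a, brain], sim$abundance[b, brain], map)
  }, numeric(1))
  in_module <- ints$gene_a %in% sim$module$member_genes &
    ints$gene_b %in% sim$module$member_genes
  expect_gt(mean(w[in_module]), mean(w[!in_module]))
})

test_that("every generator is reproducible under a fixed configuration seed", {
  s1 <- small_study(seed = 99)
  s2 <- small_study(seed = 99)
  expect_identical(s1$sources, s2$sources)
  expect_identical(s1$localization, s2$localization)
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$evidence, s2$evidence)
  expect_identical(s1$markers, s2$markers)
  expect_identical(s1$module, s2$module)
})
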