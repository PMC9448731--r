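test_that("annotation proportions count gene-set members per label", {
  ann <- data.frame(gene = sprintf("G%02d", 1:10),
                    domain = c(rep("cytosol", 6), rep("nucleus", 4)))
  enr <- enrichment_proportions(sprintf("G%02d", 1:10), ann)
  expect_equal(enr$proportion[enr$domain == "cytosol"], 0.6)
  expect_equal(enr$proportion[enr$domain == "nucleus"], 0.4)

  one <- enrichment_proportions(c("G01", "G02"),
                                data.frame(gene = c("G01", "G02"),
                                           domain = "cytosol"))
  expect_equal(one$proportion, 1)

  expect_error(enrichment_proportions(character(0), ann), "empty gene set")
})

test_that("pooled two-proportion z-test matches the hand formula", {
  eq <- two_proportion_ztest(16, 100, 16, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  deg <- two_proportion_ztest(0, 10, 0, 10)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  zt <- two_proportion_ztest(30, 100, 10, 100)
  z_hand <- 0.2 / sqrt(0.2 * 0.8 * (1 / 100 + 1 / 100))
  expect_equal(zt$z, z_hand, tolerance = 1e-12)
  expect_equal(zt$z, 3.5355, tolerance = 1e-4)
  expect_equal(zt$p_value, 2 * pnorm(-z_hand), tolerance = 1e-12)
  expect_equal(zt$p_value, 4.1e-4, tolerance = 0.02)

  # antisymmetry: swapping groups negates z and preserves p
  sw <- two_proportion_ztest(10, 100, 30, 100)
  expect_equal(sw$z, -zt$z)
  expect_equal(sw$p_value, zt$p_value)

  expect_error(two_proportion_ztest(5, 0, 1, 10), "n >= 1")
  expect_error(two_proportion_ztest(11, 10, 1, 10), "0 <= x <= n")
})

test_that("overlap test reproduces the exact hypergeometric tail", {
  big <- fisher_overlap(letters[1:5], letters[10:14], 1000)
  expect_equal(big$overlap, 0)
  expect_gt(big$p_value, 0.9)

  same <- fisher_overlap(letters[1:5], letters[1:5], 11)
  expect_equal(same$p_value, hyper_tail_oracle(5, 5, 5, 11),
               tolerance = 1e-12)

  toy <- fisher_overlap(letters[1:5], c(letters[2:5], "z"), 20)
  expect_equal(toy$overlap, 4)
  expect_equal(toy$p_value, 76 / 15504, tolerance = 1e-12)

  expect_error(fisher_overlap(letters[1:5], letters[6:10], 8),
               "smaller than the union")
})

test_that("overlap test agrees with fisher.test on random tables", {
  set.seed(77)
  uni <- letters[1:20]
  for (i in 1:10) {
    a <- sample(uni, sample(3:8, 1))
    b <- sample(uni, sample(3:8, 1))
    mine <- fisher_overlap(a, b, 20)
    k <- length(intersect(a, b))
    tab <- matrix(c(k, length(a) - k, length(b) - k,
                    20 - length(a) - length(b) + k), 2)
    ft <- fisher.test(tab, alternative = "greater")
    expect_equal(mine$p_value, ft$p.value, tolerance = 1e-9)
    expect_equal(mine$p_value,
                 hyper_tail_oracle(k, length(a), length(b), 20),
                 tolerance = 1e-12)
  }
})

test_that("BH q-values follow the step-up procedure", {
  expect_equal(bh_fdr(0.04), 0.04)                    # m = 1: q = p
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))      # all equal stay equal
  expect_equal(bh_fdr(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  # permutation equivariance
  p <- c(0.5, 0.001, 0.03, 0.2)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("argmax tissue assignment matches brute force with declared ties", {
  m <- matrix(c(1, 0, 0,
                0, 2, 2,
                0, 0, 5,
                0, 0, 0,
                3, 1, 3), nrow = 5, byrow = TRUE,
              dimnames = list(sprintf("G%d", 1:5), c("cortex", "lung", "liver")))
  expect_warning(expect_warning(res <- max_tissue_assignment(m),
                                "all-zero"), "tied")
  expect_equal(res$assignment$tissue[res$assignment$gene == "G1"], "cortex")
  expect_equal(res$assignment$tissue[res$assignment$gene == "G2"], "lung")
  expect_equal(res$excluded, "G4")
  # first-column tie break
  expect_equal(res$assignment$tissue[res$assignment$gene == "G5"], "cortex")

  set.seed(55)
  m2 <- matrix(runif(15) + 0.01, nrow = 5,
               dimnames = dimnames(m))
  res2 <- max_tissue_assignment(m2, query = c("G1", "G3"))
  oracle <- colnames(m2)[apply(m2, 1, which.max)]
  expect_equal(res2$assignment$tissue, oracle)
  expect_equal(nrow(res2$enrichment), 3)
  expect_true(all(res2$enrichment$p_value >= 0 &
                    res2$enrichment$p_value <= 1))
})

test_that("prenatal/postnatal DE detects planted shifts and respects BH", {
  cfg <- sim_config(n_genes = 60, module_size = 10, n_regions = 1,
                    n_reps = 20, de_fraction = 0.2, de_effect = 10,
                    noise_sd = 1, rng_seed = 3)
  u <- generate_universe(cfg)
  dev <- generate_dev_expression(u, cfg)
  tab <- prenatal_postnatal_de(dev, cfg$region_labels[1])
  planted <- tab$gene %in% dev$de_genes
  # a 10-sigma shift with 20 replicates per bin is detected with q << 0.05
  expect_true(all(tab$de[planted]))
  expect_true(all(tab$q_value[planted] < 1e-6))
  expect_lt(mean(tab$de[!planted]), 0.1)

  # single-gene case: BH with m = 1 keeps q = p
  one <- dev
  one$expr <- dev$expr[1, , drop = FALSE]
  tab1 <- prenatal_postnatal_de(one, cfg$region_labels[1])
  expect_equal(tab1$q_value, tab1$p_value)

  few <- dev
  few$samples <- few$samples[few$samples$stage_bin == "0-12 pcw", ][1:3, ]
  expect_error(prenatal_postnatal_de(few, cfg$region_labels[1]),
               cfg$region_labels[1])
  expect_error(prenatal_postnatal_de(dev, "nowhere"), "no samples")
})

test_that("DE region counts accumulate across regions", {
  cfg <- sim_config(n_genes = 40, module_size = 8, n_regions = 3,
                    n_reps = 12, de_fraction = 0.25, de_effect = 8,
                    noise_sd = 1, rng_seed = 11)
  u <- generate_universe(cfg)
  dev <- generate_dev_expression(u, cfg)
  res <- count_de_regions(dev, u)
  expect_equal(res$n_regions, 3)
  planted <- res$per_gene$gene %in% dev$de_genes
  # the shift applies in every region, so planted genes are DE in all 3
  expect_true(all(res$per_gene$n_de_regions[planted] == 3))
  expect_equal(res$n_de_any, sum(res$per_gene$n_de_regions > 0))
})

test_that("cell-type DE intersections are plain set intersections", {
  cands <- c("A", "B", "C", "D")
  de <- list(neuron = c("B", "C", "X"), astro = "Z",
             micro = character(0))
  res <- intersect_with_celltype_de(cands, de,
                                    classes = c(neuron = "neuronal",
                                                astro = "glial",
                                                micro = "glial"))
  expect_setequal(res$intersections$neuron, c("B", "C"))
  expect_equal(res$intersections$micro, character(0))
  expect_equal(res$summary$n_overlap, c(2, 0, 0))
  expect_equal(res$n_unique, 2)

  all_in <- intersect_with_celltype_de(cands, list(t = cands))
  expect_setequal(all_in$intersections$t, cands)
})
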