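test_that("generated genomes respect layout bounds, exact class fractions and determinism", {
  cfg <- library_sim_config(n_genes = 40, intergenic_fraction = 0.2,
                            frac_neutral = 0.8, frac_detrimental = 0.1,
                            frac_beneficial = 0.05, frac_essential = 0.05)
  g1 <- generate_genome(cfg, seed = 11)
  g2 <- generate_genome(cfg, seed = 11)
  expect_identical(g1, g2)
  expect_false(identical(g1$genome, generate_genome(cfg, seed = 12)$genome))

  expect_gte(nchar(g1$genome), sum(g1$annotation$length) / 0.8 - 1)
  # genes non-overlapping and in order
  expect_true(all(diff(g1$annotation$start) > 0))
  expect_true(all(g1$annotation$start[-1] > g1$annotation$end[-nrow(g1$annotation)]))
  # exact apportionment of classes
  expect_equal(sort(unname(table(g1$truth$class)["neutral"])), 32)
  expect_equal(unname(table(g1$truth$class)["essential"]), 2)
  # neutral genes have true W = 1 exactly
  expect_true(all(g1$truth$true_W[g1$truth$class == "neutral"] == 1))
})

test_that("simulated libraries hit TA sites at the configured saturation, sparing essentials", {
  cfg <- library_sim_config(n_genes = 60, depth = 5e4, frac_neutral = 0.9,
                            frac_detrimental = 0, frac_beneficial = 0,
                            frac_essential = 0.1)
  g <- generate_genome(cfg, seed = 2)
  lib <- simulate_library(g$genome, g$annotation, g$truth, cfg, seed = 2)
  expect_equal(sum(lib$count_t0), 5e4)  # depth conservation, exact
  ess <- g$truth$gene_id[g$truth$essential]
  for (e in ess) {
    i <- match(e, g$annotation$gene_id)
    expect_equal(sum(lib$site >= g$annotation$start[i] &
                     lib$site <= g$annotation$end[i]), 0)
  }
  # saturation 1 with no essential genes hits every TA site
  cfg_full <- library_sim_config(n_genes = 20, depth = 1e4, saturation = 1,
                                 frac_neutral = 1, frac_detrimental = 0,
                                 frac_beneficial = 0, frac_essential = 0)
  gf <- generate_genome(cfg_full, seed = 3)
  libf <- simulate_library(gf$genome, gf$annotation, gf$truth, cfg_full, seed = 3)
  expect_equal(libf$site, enumerate_ta_sites(gf$genome))
})

test_that("realized insert density tracks saturation x TA density over seeds", {
  cfg <- library_sim_config(n_genes = 100, depth = 1e4, frac_neutral = 1,
                            frac_detrimental = 0, frac_beneficial = 0,
                            frac_essential = 0)
  dens <- vapply(1:20, function(s) {
    g <- generate_genome(cfg, seed = s)
    lib <- simulate_library(g$genome, g$annotation, g$truth, cfg, seed = s)
    n_ta <- length(enumerate_ta_sites(g$genome))
    nrow(lib) / (n_ta * cfg$saturation)
  }, numeric(1))
  expect_true(all(abs(dens - 1) < 0.1))
})

test_that("outgrowth conserves depth, is neutral-stable and monotone in true W", {
  fx <- grow_focal_insert(1.0, G = 22, noise = "none")
  f0 <- fx$inserts$count_t0 / sum(fx$inserts$count_t0)
  ff <- fx$inserts$count_tf / sum(fx$inserts$count_tf)
  expect_equal(ff, f0, tolerance = 1e-12)
  expect_equal(fx$d, 2^22)

  # multinomial draw conserves depth exactly
  cfg <- library_sim_config(n_genes = 30, depth = 2e4)
  g <- generate_genome(cfg, seed = 5)
  lib <- simulate_library(g$genome, g$annotation, g$truth, cfg, seed = 5)
  gr <- simulate_outgrowth(lib, g$annotation, g$truth, generations = 22,
                           seed = 5)
  expect_equal(sum(gr$count_tf), 2e4)
  gr2 <- simulate_outgrowth(lib, g$annotation, g$truth, generations = 22,
                            seed = 5)
  expect_identical(gr, gr2)

  # raising one gene's true W does not decrease its expected tf frequency
  freqs <- vapply(c(0.8, 1.0, 1.2), function(w) {
    fx <- grow_focal_insert(w, G = 20, noise = "none")
    fx$inserts$count_tf[fx$inserts$site == 50] / sum(fx$inserts$count_tf)
  }, numeric(1))
  expect_true(all(diff(freqs) > 0))
  expect_error(simulate_outgrowth(lib, g$annotation, g$truth, generations = 0),
               "generations")
})

test_that("replicate fitness correlates strongly under default-style noise with real effects", {
  cfg <- library_sim_config(n_genes = 150, depth = 1e5)
  g <- generate_genome(cfg, seed = 9)
  ex <- simulate_tnseq_experiment(g$genome, g$annotation, g$truth, NULL, cfg,
                                  n_replicates = 2, seed = 9)
  fit <- insert_fitness_table(ex$arms$ref, g$annotation, ex$generations,
                              d = ex$d$ref)
  qc <- replicate_qc(fit)
  expect_gt(qc["rep1", "rep2"], 0.9)
})

test_that("expression simulation honors truth structure, NB noise and determinism", {
  cfg <- expression_sim_config(n_genes = 300, frac_responsive = 0.3)
  s1 <- simulate_expression(cfg, seed = 4)
  s2 <- simulate_expression(cfg, seed = 4)
  expect_identical(s1, s2)
  expect_equal(dim(s1$counts$counts), c(300L, 9L))
  expect_true(all(s1$truth$log2FC_stressA[!s1$truth$responsive] == 0))

  # rho_share = 1: conditions share identical true response vectors
  cfg1 <- expression_sim_config(n_genes = 200, rho_share = 1)
  s <- simulate_expression(cfg1, seed = 6)
  expect_equal(s$truth$log2FC_stressA, s$truth$log2FC_stressB)

  expect_error(expression_sim_config(dispersion = 0), "dispersion")
  expect_error(expression_sim_config(n_replicates = 1), "replicates")
})
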