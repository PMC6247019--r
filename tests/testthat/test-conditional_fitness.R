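make_fit_tab <- function(gene_ws, library_id = "L1") {
  # gene_ws: named list of W vectors
  do.call(rbind, lapply(names(gene_ws), function(g) {
    w <- gene_ws[[g]]
    data.frame(library_id = library_id, site = seq_along(w),
               gene_id = g, W = w, floored = FALSE, stringsAsFactors = FALSE)
  }))
}

test_that("arm comparison applies the joint magnitude-and-Bonferroni rule", {
  set.seed(1)
  # large, precise difference of 0.04: below the magnitude gate regardless of p
  a <- make_fit_tab(list(g1 = rnorm(50, 1.00, 0.001)))
  b <- make_fit_tab(list(g1 = rnorm(50, 0.96, 0.001)))
  cmp <- compare_arms(a, b)
  expect_lt(cmp$p, 1e-6)
  expect_false(cmp$significant)

  # identical samples: delta 0, zero-variance rule p = 1
  w <- rep(0.9, 6)
  cmp2 <- compare_arms(make_fit_tab(list(g1 = w)), make_fit_tab(list(g1 = w)))
  expect_equal(cmp2$delta_W, 0)
  expect_equal(cmp2$p, 1)
  expect_false(cmp2$significant)

  # clear conditional effect passes both gates
  a3 <- make_fit_tab(list(g1 = rnorm(8, 0.8, 0.02), g2 = rnorm(8, 1, 0.02)))
  b3 <- make_fit_tab(list(g1 = rnorm(8, 1.0, 0.02), g2 = rnorm(8, 1, 0.02)))
  cmp3 <- compare_arms(a3, b3)
  expect_true(cmp3$significant[cmp3$gene_id == "g1"])
  expect_false(cmp3$significant[cmp3$gene_id == "g2"])
  # Bonferroni denominator = genes actually tested
  expect_equal(unique(cmp3$p_threshold), 0.05 / 2)
})

test_that("genes without two inserts per arm are reported untestable, never significant", {
  a <- make_fit_tab(list(g1 = c(0.5), g2 = rnorm(5, 1, 0.01)))
  b <- make_fit_tab(list(g1 = rnorm(5, 1, 0.01), g2 = rnorm(5, 1, 0.01)))
  cmp <- compare_arms(a, b)
  r <- cmp[cmp$gene_id == "g1", ]
  expect_equal(r$flag, "untestable")
  expect_false(r$significant)
  expect_equal(r$delta_W, 0.5 - mean(b$W[b$gene_id == "g1"]))
})

test_that("swapping arms negates delta_W and preserves p", {
  set.seed(3)
  a <- make_fit_tab(list(g1 = rnorm(10, 0.85, 0.05), g2 = rnorm(6, 1.02, 0.03)))
  b <- make_fit_tab(list(g1 = rnorm(9, 1.0, 0.05), g2 = rnorm(7, 0.99, 0.03)))
  ab <- compare_arms(a, b)
  ba <- compare_arms(b, a)
  expect_equal(ba$delta_W, -ab$delta_W)
  expect_equal(ba$p, ab$p)
})

test_that("conditional importance requires neutrality in the reference arm", {
  cmp <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    delta_W = c(-0.2, -0.2, 0.15, -0.1),
                    significant = c(TRUE, TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  ref <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    category = c("neutral", "detrimental", "neutral", "neutral"),
                    stringsAsFactors = FALSE)
  sets <- conditionally_important(cmp, ref)
  expect_equal(sets$conditionally_detrimental, "g1")
  expect_equal(sets$conditionally_beneficial, "g3")
  expect_error(conditionally_important(cmp, ref[-1, ]), "mismatch")

  none <- cmp; none$significant <- FALSE
  sets0 <- conditionally_important(none, ref)
  expect_length(sets0$conditionally_detrimental, 0)
  expect_length(sets0$conditionally_beneficial, 0)
})

test_that("strain comparison isolates degradation-dependent genes", {
  set.seed(5)
  mk <- function(mu_g1) make_fit_tab(list(
    g1 = rnorm(10, mu_g1, 0.02),
    g2 = rnorm(10, 1, 0.02),
    g3 = rnorm(10, 0.8, 0.02)))
  # g1 detrimental under selection only in wt; g3 equally detrimental in both
  res <- compare_strains(wt_plus = mk(0.85), wt_minus = mk(1.0),
                         mut_plus = mk(1.0), mut_minus = mk(1.0))
  expect_true(res$degradation_dependent[res$gene_id == "g1"])
  expect_false(res$degradation_dependent[res$gene_id == "g2"])
  expect_false(res$degradation_dependent[res$gene_id == "g3"])

  # identical strains: no strain difference anywhere
  res2 <- compare_strains(mk(0.85), mk(1.0), mk(0.85), mk(1.0))
  expect_false(any(res2$degradation_dependent))

  # gene absent from one strain's library is flagged and excluded
  wtp <- mk(0.85)
  mutp <- mk(1.0); mutp <- mutp[mutp$gene_id != "g1", ]
  mutm <- mk(1.0); mutm <- mutm[mutm$gene_id != "g1", ]
  res3 <- compare_strains(wtp, mk(1.0), mutp, mutm)
  expect_equal(res3$flag[res3$gene_id == "g1"], "absent_one_strain")
  expect_false(res3$degradation_dependent[res3$gene_id == "g1"])
})

test_that("null arm comparisons stay calibrated at the uncorrected level", {
  # small-scale calibration smoke check; the full-scale study is in the
  # acceptance suite
  p <- c()
  for (s in 1:4) {
    cfg <- library_sim_config(n_genes = 100, depth = 1e5, frac_neutral = 1,
                              frac_detrimental = 0, frac_beneficial = 0,
                              frac_essential = 0)
    g <- generate_genome(cfg, seed = s)
    ex <- simulate_tnseq_experiment(g$genome, g$annotation, g$truth, g$truth,
                                    cfg, n_replicates = 2, seed = s)
    fa <- insert_fitness_table(ex$arms$sel, g$annotation, ex$generations, d = ex$d$sel)
    fb <- insert_fitness_table(ex$arms$ref, g$annotation, ex$generations, d = ex$d$ref)
    cmp <- compare_arms(fa, fb)
    expect_equal(sum(cmp$significant), 0)
    p <- c(p, cmp$p[cmp$flag == "ok"])
  }
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})
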