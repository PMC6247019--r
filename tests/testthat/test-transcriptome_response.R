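test_that("low-expression filtering applies the CPM rule", {
  m <- matrix(c(0, 0, 0, 0,     # all-zero gene: removed
                5, 8, 6, 9,
                100, 120, 90, 110,
                1, 0, 0, 0,     # below threshold in 3 of 4 samples
                50, 60, 55, 45), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), NULL))
  x <- tn_counts(m, condition = rep(c("a", "b"), each = 2))
  # library sizes ~ 150-200; min_cpm = 1 needs >= ~0.0002 counts: scale up
  m2 <- m * 50
  rownames(m2) <- rownames(m)
  x2 <- tn_counts(m2, condition = rep(c("a", "b"), each = 2))
  kept <- filter_low_expression(x2, min_cpm = 1000, min_samples = 2)
  expect_false("g1" %in% rownames(kept$counts))
  expect_true("g3" %in% rownames(kept$counts))

  ident <- filter_low_expression(x2, min_cpm = 0)
  expect_equal(dim(ident$counts), dim(x2$counts))
  expect_error(filter_low_expression(x2, min_cpm = 1e9), "review")
})

test_that("identical groups give log2FC of zero and tied p values", {
  m <- matrix(rpois(40, 80), nrow = 10,
              dimnames = list(paste0("g", 1:10), NULL))
  cts <- cbind(m[, 1:2], m[, 1:2])
  colnames(cts) <- NULL
  x <- tn_counts(cts, condition = rep(c("control", "s"), each = 2))
  de <- de_test(x, "s", "control")
  expect_true(all(de$log2FC == 0))
  expect_error(de_test(tn_counts(m[, 1:3, drop = FALSE],
                                 c("control", "s", "s")), "s", "control"),
               "replicates")
})

test_that("DE detects a strong spiked effect and BH gating is strict", {
  set.seed(10)
  detected <- 0
  for (s in 1:20) {
    cfg <- expression_sim_config(n_genes = 400, dispersion = 0.05,
                                 frac_responsive = 0, conditions = "s")
    sim <- simulate_expression(cfg, seed = 100 + s)
    cts <- sim$counts$counts
    cond <- sim$counts$samples$condition
    cts["g0001", ] <- stats::rnbinom(ncol(cts), size = 1 / 0.05,
                                     mu = ifelse(cond == "s", 800, 200))
    de <- de_test(tn_counts(cts, cond), "s", "control")
    de <- significant_de(de)
    detected <- detected + de$significant[de$gene_id == "g0001"]
  }
  expect_gte(detected / 20, 0.9)
})

test_that("BH q values match the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:300) {
    p <- runif(sample(1:40, 1))
    if (i %% 3 == 0) p <- round(p, 1)  # ties
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
  }
})

test_that("the significance gate uses strict fold and FDR inequalities", {
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   log2FC = c(1.1, 1.0, -2, 3),
                   q_value = c(0.005, 0.005, 0.02, 0.0099))
  got <- significant_de(de)
  expect_equal(got$significant, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(got$direction, c(1, 0, 0, 1))
})

test_that("response overlap reproduces trivial and hand-computed cases", {
  mk <- function(lfc, q) data.frame(gene_id = paste0("g", seq_along(lfc)),
                                    log2FC = lfc, q_value = q,
                                    stringsAsFactors = FALSE)
  lfc <- c(3, -2.5, 1.8, 0.2, -0.1, 2.2)
  q <- c(0.001, 0.001, 0.001, 0.5, 0.5, 0.001)
  self <- response_overlap(mk(lfc, q), mk(lfc, q))
  expect_equal(self$spearman_rho, 1)
  expect_equal(self$shared_fraction, 100)

  anti <- response_overlap(mk(lfc, q), mk(-lfc, q))
  expect_equal(anti$spearman_rho, -1)
  expect_equal(anti$shared_fraction, 0)

  # hand-constructed partial overlap
  lfcB <- c(2.9, -2.0, -1.2, 0.3, 0.0, 0.4)
  qB <- c(0.001, 0.001, 0.001, 0.6, 0.6, 0.8)
  ov <- response_overlap(mk(lfc, q), mk(lfcB, qB))
  union_idx <- q < 0.01 | qB < 0.01            # genes 1,2,3,6
  expect_equal(ov$n_union, 4L)
  expect_equal(ov$spearman_rho,
               spearman_oracle(lfc[union_idx], lfcB[union_idx]))
  # A-significant with full gate: genes 1,2,3,6; shared same-sign w/ B gate: 1,2
  expect_equal(ov$n_sig_a, 4L)
  expect_equal(ov$n_shared, 2L)
  expect_equal(ov$shared_fraction, 50)

  none <- response_overlap(mk(lfc, rep(0.5, 6)), mk(lfcB, rep(0.5, 6)))
  expect_equal(none$status, "no significant genes")
  expect_true(is.na(none$spearman_rho))
})

test_that("Spearman in the overlap matches the rank-Pearson oracle including ties", {
  set.seed(12)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    x <- sample(round(rnorm(n), 1))
    y <- round(rnorm(n), 1)
    expect_equal(stats::cor(x, y, method = "spearman"), spearman_oracle(x, y))
  }
})

test_that("label shuffling drives the shared fraction to its chance level", {
  set.seed(13)
  n <- 2000
  sigA <- sample(n, 300); sigB <- sample(n, 300)
  mk <- function(idx, sgn) {
    lfc <- rnorm(n, 0, 0.2); q <- rep(0.5, n)
    lfc[idx] <- sgn * runif(length(idx), 1.5, 3); q[idx] <- 1e-4
    data.frame(gene_id = paste0("g", 1:n), log2FC = lfc, q_value = q)
  }
  deA <- mk(sigA, 1)
  fracs <- vapply(1:30, function(i) {
    deB <- mk(sample(n, 300), 1)
    response_overlap(deA, deB)$shared_fraction
  }, numeric(1))
  # chance level: |sigB|/n of A's genes also significant in B, same sign
  expect_equal(mean(fracs), 100 * 300 / n, tolerance = 0.25)
})

test_that("concordance labels follow the fitness-deficit/expression-direction rule", {
  cmp <- data.frame(gene_id = paste0("g", 1:5),
                    delta_W = c(-0.2, -0.2, 0.2, -0.01, -0.3),
                    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  de <- data.frame(gene_id = paste0("g", 1:5),
                   log2FC = c(3, -2, -2, 4, 0.1),
                   q_value = c(1e-4, 1e-4, 1e-4, 1e-4, 0.5))
  got <- concordance(cmp, de)
  expect_equal(got$label,
               c("appropriate",        # deficit + up
                 "counterproductive",  # deficit + down
                 "appropriate",        # beneficial disruption + down
                 "unclassified",       # fitness-neutral
                 "unclassified"))      # no significant expression change
})
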