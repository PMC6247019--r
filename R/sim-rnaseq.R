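#' Configuration for synthetic stressor-response RNA-seq simulations
#'
#' Defaults emulate a bulk RNA-seq stress-response experiment run in
#' biological triplicate: per-gene baseline means spanning a few orders of
#' magnitude (lognormal), negative-binomial counts with moderate
#' dispersion, one control plus several stressor conditions, and a tunable
#' shared-response structure. Each condition's true log2 fold-change
#' vector is built as \code{sqrt(rho_share) * shared + sqrt(1 - rho_share)
#' * private} over a common set of stress-responsive genes, so the
#' expected Pearson correlation between two conditions' true responses is
#' \code{rho_share}.
#'
#' @param n_genes number of genes.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-gene
#'   baseline mean counts.
#' @param dispersion NB dispersion (scalar, or per-gene vector of length
#'   n_genes); variance = mu + dispersion * mu^2.
#' @param n_replicates replicates per condition (>= 2).
#' @param conditions stressor condition labels (control is separate).
#' @param control control condition label.
#' @param frac_responsive fraction of genes that respond to stress.
#' @param effect_sd standard deviation of true log2FC among responsive
#'   genes.
#' @param rho_share shared-component weight in [0, 1].
#' @param size_factor_range sample-to-sample library-size factor range.
#' @return list of class \code{expression_sim_config}.
#' @export
expression_sim_config <- function(n_genes = 2000,
                                  baseline_meanlog = log(150),
                                  baseline_sdlog = 1.2,
                                  dispersion = 0.05,
                                  n_replicates = 3,
                                  conditions = c("stressA", "stressB"),
                                  control = "control",
                                  frac_responsive = 0.25,
                                  effect_sd = 2,
                                  rho_share = 0.5,
                                  size_factor_range = c(0.8, 1.25)) {
  cfg <- as.list(environment())
  if (any(cfg$dispersion <= 0)) stop_cofit("dispersion must be > 0")
  if (cfg$n_replicates < 2) stop_cofit("n_replicates must be >= 2")
  if (cfg$rho_share < 0 || cfg$rho_share > 1) stop_cofit("rho_share must be in [0, 1]")
  class(cfg) <- "expression_sim_config"
  cfg
}

#' Simulate stressor-response RNA-seq count matrices with known truth
#'
#' Counts are NB(mean = size_factor * baseline * 2^true_log2FC,
#' dispersion); control samples sit at the baseline. A common mask of
#' stress-responsive genes and the \code{rho_share} construction give the
#' conditions' true responses a tunable expected correlation.
#'
#' @param config \code{\link{expression_sim_config}}.
#' @param seed integer seed; identical (config, seed) gives identical
#'   matrices.
#' @return list with \code{counts} (\code{tn_counts} over control +
#'   stressors) and \code{truth} (data.frame gene_id, responsive, then one
#'   true_log2FC column per stressor named \code{log2FC_<condition>}).
#' @export
simulate_expression <- function(config = expression_sim_config(), seed = 1) {
  set.seed(derive_seed(seed, "expression"))
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  disp <- rep_len(config$dispersion, n)

  responsive <- stats::runif(n) < config$frac_responsive
  shared <- stats::rnorm(n, 0, config$effect_sd)
  lfc <- sapply(config$conditions, function(cond) {
    private <- stats::rnorm(n, 0, config$effect_sd)
    z <- sqrt(config$rho_share) * shared + sqrt(1 - config$rho_share) * private
    ifelse(responsive, z, 0)
  })
  lfc <- matrix(lfc, nrow = n,
                dimnames = list(genes, config$conditions))

  all_conds <- c(config$control, config$conditions)
  cond_per_sample <- rep(all_conds, each = config$n_replicates)
  repl_per_sample <- rep(seq_len(config$n_replicates), times = length(all_conds))
  sf <- stats::runif(length(cond_per_sample), config$size_factor_range[1],
                     config$size_factor_range[2])
  counts <- matrix(0L, nrow = n, ncol = length(cond_per_sample),
                   dimnames = list(genes,
                                   paste(cond_per_sample, repl_per_sample, sep = "_")))
  for (j in seq_along(cond_per_sample)) {
    fc <- if (cond_per_sample[j] == config$control) 1 else 2^lfc[, cond_per_sample[j]]
    mu <- sf[j] * baseline * fc
    counts[, j] <- stats::rnbinom(n, size = 1 / disp, mu = mu)
  }
  truth <- data.frame(gene_id = genes, responsive = responsive,
                      stringsAsFactors = FALSE)
  for (cond in config$conditions) truth[[paste0("log2FC_", cond)]] <- lfc[, cond]
  list(counts = tn_counts(counts, cond_per_sample, repl_per_sample),
       truth = truth)
}
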