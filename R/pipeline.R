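#' Pairwise replicate QC of gene fitness
#'
#' Pearson correlation of gene-level mean fitness between every pair of
#' replicate libraries, over the genes with at least one eligible insert
#' in both members of a pair. Well-behaved libraries with genuine fitness
#' variance correlate strongly; all-neutral libraries have no true
#' variance to correlate and sit near zero by construction.
#'
#' @param fit_tab per-insert fitness table (multiple library_id values),
#'   or a list of per-replicate gene-level tables with columns gene_id and
#'   mean_W.
#' @return symmetric correlation matrix, one row/column per replicate.
#' @export
replicate_qc <- function(fit_tab) {
  if (is.data.frame(fit_tab)) {
    libs <- unique(fit_tab$library_id)
    tabs <- lapply(libs, function(l) {
      sub <- fit_tab[fit_tab$library_id == l & !is.na(fit_tab$gene_id), ]
      mw <- tapply(sub$W, sub$gene_id, mean)
      data.frame(gene_id = names(mw), mean_W = as.vector(mw),
                 stringsAsFactors = FALSE)
    })
    names(tabs) <- libs
  } else {
    tabs <- fit_tab
    if (is.null(names(tabs))) names(tabs) <- sprintf("rep%d", seq_along(tabs))
  }
  k <- length(tabs)
  if (k < 2L) stop_cofit("replicate QC needs >= 2 replicates")
  m <- diag(1, k)
  dimnames(m) <- list(names(tabs), names(tabs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    common <- intersect(tabs[[i]]$gene_id, tabs[[j]]$gene_id)
    m[i, j] <- m[j, i] <- stats::cor(
      tabs[[i]]$mean_W[match(common, tabs[[i]]$gene_id)],
      tabs[[j]]$mean_W[match(common, tabs[[j]]$gene_id)])
  }
  m
}

#' Score fitness estimates against simulation truth
#'
#' Confusion matrix of the five-way classification against the truth
#' classes, sensitivity/specificity of detecting non-neutral effects, and
#' the RMSE of gene-level mean W over genes with at least four observed
#' inserts (truth class mapped as essential -> lethal). Sensitivity is
#' computed over true detrimental/beneficial genes with >= 4 inserts;
#' specificity over true neutral genes with >= 4 inserts.
#'
#' @param gf gene-level summary from \code{\link{gene_fitness}}.
#' @param truth truth table from \code{\link{generate_genome}}.
#' @return list (confusion, sensitivity, specificity, rmse_W, n_scored).
#' @export
score_recovery <- function(gf, truth) {
  idx <- match(gf$gene_id, truth$gene_id)
  if (anyNA(idx)) stop_cofit("gene(s) missing from truth table")
  true_class <- truth$class[idx]
  expected <- ifelse(true_class == "essential", "lethal", true_class)
  confusion <- table(truth = expected, called = gf$category)
  enough <- gf$n_inserts >= 4
  eff <- true_class %in% c("detrimental", "beneficial")
  neu <- true_class == "neutral"
  sens <- sum(enough & eff & gf$category == true_class) / sum(enough & eff)
  spec <- sum(enough & neu & gf$category == "neutral") / sum(enough & neu)
  sel <- enough & !is.na(gf$mean_W) & !is.na(truth$true_W[idx])
  rmse <- sqrt(mean((gf$mean_W[sel] - truth$true_W[idx][sel])^2))
  list(confusion = confusion, sensitivity = sens, specificity = spec,
       rmse_W = rmse, n_scored = sum(sel))
}

default_pipeline_config <- function() {
  list(
    tnseq = list(
      n_genes = 300, depth = 2e5, n_replicates = 2, generations = 22,
      saturation = 0.87, gc = 0.64,
      frac_neutral = 0.75, frac_detrimental = 0.10,
      frac_beneficial = 0.05, frac_essential = 0.10,
      conditional = list(n_detrimental = 20, n_beneficial = 5,
                         delta_range = c(0.1, 0.3)),
      delta_threshold = 0.05, alpha = 0.05, edge_trim = 0),
    rnaseq = list(
      n_genes = 2000, n_replicates = 3, dispersion = 0.05,
      conditions = c("stressA", "stressB"), rho_share = 0.5,
      frac_responsive = 0.25, effect_sd = 2,
      fold_threshold = 2, fdr_threshold = 0.01))
}

read_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_cofit("config must be a YAML path or a list")
  unknown <- setdiff(names(config), c("tnseq", "rnaseq"))
  if (length(unknown)) stop_cofit("unknown config block(s): ",
                                  paste(unknown, collapse = ", "))
  for (blk in names(config)) {
    if (is.null(config[[blk]])) { base[[blk]] <- NULL; next }
    bad <- setdiff(names(config[[blk]]), names(base[[blk]]))
    if (length(bad)) stop_cofit("unknown key(s) in '", blk, "': ",
                                paste(bad, collapse = ", "))
    base[[blk]] <- utils::modifyList(base[[blk]], config[[blk]])
  }
  if (is.null(base$tnseq)) stop_cofit("the tnseq block is required")
  base
}

#' Run the full simulate-estimate-compare-report pipeline
#'
#' One deterministic end-to-end run: simulate a genome and a replicated
#' two-arm Tn-seq experiment, estimate and classify gene fitness in both
#' arms, compare arms and call the conditionally important gene sets,
#' run replicate QC, and (unless the config drops the rnaseq block)
#' simulate stressor-response count matrices, test differential
#' expression per stressor, compute response overlap and
#' fitness-expression concordance. Every stage writes its TSV into
#' \code{outdir}; inter-stage contracts are those TSV schemas. A manifest
#' (config hash, seed, package version, thresholds applied) makes the run
#' self-describing, and a recovery scorecard compares estimates with the
#' simulation truth.
#'
#' @param config NULL (defaults), a YAML file path, or a nested list with
#'   blocks \code{tnseq} and optionally \code{rnaseq}; set
#'   \code{rnaseq: ~} in YAML to skip the transcriptomics stage.
#' @param seed integer seed; identical (config, seed) gives byte-identical
#'   outputs.
#' @param outdir report directory (created; must be writable).
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = NULL, seed = 1, outdir = tempfile("cofit_run")) {
  cfg <- read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(outdir, recursive = TRUE), add = TRUE)

  tc <- cfg$tnseq
  lib_cfg <- library_sim_config(
    n_genes = tc$n_genes, depth = tc$depth, generations = tc$generations,
    saturation = tc$saturation, gc = tc$gc,
    frac_neutral = tc$frac_neutral, frac_detrimental = tc$frac_detrimental,
    frac_beneficial = tc$frac_beneficial, frac_essential = tc$frac_essential)
  gen <- generate_genome(lib_cfg, seed = derive_seed(seed, "pipe_genome"))
  write_genome(gen$genome, file.path(outdir, "genome.fasta"))
  write_annotation(gen$annotation, file.path(outdir, "annotation.gff3"))
  write_tsv(gen$truth, file.path(outdir, "truth_tnseq.tsv"))

  # selective-arm truth: conditional effects on genes neutral at baseline
  set.seed(derive_seed(seed, "pipe_cond"))
  neutral_pool <- gen$truth$gene_id[gen$truth$class == "neutral"]
  nc <- tc$conditional
  picks <- sample(neutral_pool, nc$n_detrimental + nc$n_beneficial)
  det <- picks[seq_len(nc$n_detrimental)]
  ben <- setdiff(picks, det)
  truth_sel <- condition_truth(gen$truth, det,
                               -stats::runif(length(det), nc$delta_range[1], nc$delta_range[2]))
  truth_sel <- condition_truth(truth_sel, ben,
                               stats::runif(length(ben), nc$delta_range[1], nc$delta_range[2]))
  write_tsv(truth_sel, file.path(outdir, "truth_tnseq_selective.tsv"))

  exp_tn <- simulate_tnseq_experiment(gen$genome, gen$annotation, gen$truth,
                                      truth_sel, lib_cfg,
                                      n_replicates = tc$n_replicates,
                                      seed = derive_seed(seed, "pipe_tnseq"))
  fits <- list()
  for (arm in names(exp_tn$arms)) {
    write_insertion_table(exp_tn$arms[[arm]],
                          file.path(outdir, sprintf("inserts_%s.tsv", arm)))
    fits[[arm]] <- tnseq_fitness(exp_tn$arms[[arm]], gen$annotation,
                                 generations = exp_tn$generations,
                                 d = exp_tn$d[[arm]], edge_trim = tc$edge_trim)
    write_tsv(fits[[arm]], file.path(outdir, sprintf("gene_fitness_%s.tsv", arm)))
  }
  qc <- replicate_qc(attr(fits$ref, "insert_fitness"))
  write_tsv(data.frame(replicate = rownames(qc), qc, check.names = FALSE),
            file.path(outdir, "replicate_qc_ref.tsv"))

  cmp <- compare_arms(attr(fits$sel, "insert_fitness"),
                      attr(fits$ref, "insert_fitness"),
                      delta_threshold = tc$delta_threshold, alpha = tc$alpha)
  write_tsv(cmp, file.path(outdir, "compare_arms.tsv"))
  cond_sets <- conditionally_important(cmp, fits$ref)
  write_tsv(data.frame(
    gene_id = c(cond_sets$conditionally_detrimental, cond_sets$conditionally_beneficial),
    set = rep(c("conditionally_detrimental", "conditionally_beneficial"),
              c(length(cond_sets$conditionally_detrimental),
                length(cond_sets$conditionally_beneficial)))),
    file.path(outdir, "conditional_sets.tsv"))

  score <- score_recovery(fits$ref, gen$truth)
  write_tsv(as.data.frame(score$confusion), file.path(outdir, "scorecard_confusion.tsv"))
  write_tsv(data.frame(metric = c("sensitivity", "specificity", "rmse_W", "n_scored"),
                       value = c(score$sensitivity, score$specificity,
                                 score$rmse_W, score$n_scored)),
            file.path(outdir, "scorecard.tsv"))

  results <- list(genome = gen, truth_sel = truth_sel, fits = fits, cmp = cmp,
                  conditional_sets = cond_sets, qc = qc, score = score)

  if (!is.null(cfg$rnaseq)) {
    rc <- cfg$rnaseq
    ecfg <- expression_sim_config(
      n_genes = rc$n_genes, n_replicates = rc$n_replicates,
      dispersion = rc$dispersion, conditions = rc$conditions,
      rho_share = rc$rho_share, frac_responsive = rc$frac_responsive,
      effect_sd = rc$effect_sd)
    sim <- simulate_expression(ecfg, seed = derive_seed(seed, "pipe_rnaseq"))
    write_counts(sim$counts, file.path(outdir, "expression_counts.tsv"))
    write_tsv(sim$truth, file.path(outdir, "truth_rnaseq.tsv"))
    filt <- filter_low_expression(sim$counts)
    des <- lapply(rc$conditions, function(cond) {
      de <- significant_de(de_test(filt, cond, ecfg$control),
                           rc$fold_threshold, rc$fdr_threshold)
      write_tsv(de, file.path(outdir, sprintf("de_%s.tsv", cond)))
      de
    })
    names(des) <- rc$conditions
    if (length(des) >= 2L) {
      ov <- response_overlap(des[[1]], des[[2]],
                             fdr_threshold = rc$fdr_threshold,
                             fold_threshold = rc$fold_threshold,
                             shared_fdr_threshold = rc$fdr_threshold)
      write_tsv(data.frame(contrast_a = rc$conditions[1],
                           contrast_b = rc$conditions[2],
                           spearman_rho = ov$spearman_rho, n_union = ov$n_union,
                           shared_fraction = ov$shared_fraction,
                           n_sig_a = ov$n_sig_a, n_shared = ov$n_shared,
                           status = ov$status),
                file.path(outdir, "response_overlap.tsv"))
      results$overlap <- ov
    }
    results$de <- des
    conc <- concordance(cmp, des[[1]])
    write_tsv(conc, file.path(outdir, "concordance.tsv"))
    results$concordance <- conc
  }

  manifest <- list(
    package = "cofit",
    version = as.character(utils::packageVersion("cofit")),
    seed = seed,
    config = cfg,
    config_hash = substr(digest_config(cfg), 1, 16),
    thresholds = list(
      delta_W = cfg$tnseq$delta_threshold,
      bonferroni_m = sum(cmp$flag == "ok"),
      bonferroni_p = unique(cmp$p_threshold)[1],
      fold = if (!is.null(cfg$rnaseq)) cfg$rnaseq$fold_threshold else NULL,
      fdr = if (!is.null(cfg$rnaseq)) cfg$rnaseq$fdr_threshold else NULL))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ok <- TRUE
  message("pipeline report written to ", outdir)
  invisible(results)
}

digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
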