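#' Simulate a mariner insertion library (t0 counts)
#'
#' Enumerates TA sites, removes those inside essential-gene bodies, hits a
#' fraction \code{saturation} of the remaining sites (exact count, sampled
#' without replacement), assigns each hit insert a symmetric-Dirichlet
#' abundance weight, and draws the t0 read counts as one multinomial of
#' size \code{depth} over the inserts. Intergenic inserts are retained:
#' they behave as fitness-neutral and exercise the gene-assignment
#' boundary logic downstream.
#'
#' @param genome \code{tn_genome} (single record).
#' @param ann annotation data.frame.
#' @param truth truth table (for the essential flags).
#' @param config \code{\link{library_sim_config}}.
#' @param seed integer seed.
#' @param library_id label for the simulated library.
#' @return insertion table (site, count_t0, count_tf = NA, library_id)
#'   with the true abundance weights attached as attribute
#'   \code{"weights"}.
#' @export
simulate_library <- function(genome, ann, truth, config = library_sim_config(),
                             seed = 1, library_id = "lib1") {
  set.seed(derive_seed(seed, "library"))
  sites <- enumerate_ta_sites(genome)
  if (length(sites) == 0L) stop_cofit("genome contains no TA site")
  ess <- truth$gene_id[truth$essential]
  if (length(ess)) {
    ei <- match(ess, ann$gene_id)
    in_ess <- rep(FALSE, length(sites))
    for (j in ei) in_ess <- in_ess | (sites >= ann$start[j] & sites <= ann$end[j])
    sites <- sites[!in_ess]
  }
  if (length(sites) == 0L) stop_cofit("no TA site outside essential genes")
  n_hit <- max(1L, round(config$saturation * length(sites)))
  hit <- sort(sample(sites, n_hit))
  w <- stats::rgamma(n_hit, shape = config$dirichlet_alpha, rate = 1)
  w <- w / sum(w)
  counts <- as.vector(stats::rmultinom(1, config$depth, w))
  out <- data.frame(site = hit, count_t0 = counts, count_tf = NA_real_,
                    library_id = library_id, stringsAsFactors = FALSE)
  attr(out, "weights") <- w
  out
}

#' Re-sequence a simulated library at t0
#'
#' Draws a fresh multinomial t0 count vector from the library's true
#' abundance weights: the same physical library measured again, as when
#' one master library seeds several outgrowth arms and each arm's t0 is
#' sequenced independently.
#'
#' @param lib library from \code{\link{simulate_library}} (must carry the
#'   \code{"weights"} attribute).
#' @param seed integer seed.
#' @param library_id label for the re-sequenced library; default keeps the
#'   original.
#' @return insertion table with fresh count_t0.
#' @export
resample_library <- function(lib, seed = 1, library_id = NULL) {
  w <- attr(lib, "weights")
  if (is.null(w)) stop_cofit("library has no abundance weights to resample from")
  set.seed(derive_seed(seed, "resample"))
  out <- lib
  out$count_t0 <- as.vector(stats::rmultinom(1, sum(lib$count_t0), w))
  if (!is.null(library_id)) out$library_id <- library_id
  attr(out, "weights") <- w
  out
}

#' Simulate selective outgrowth of an insertion library
#'
#' Discrete per-generation geometric growth: an insert in a gene with true
#' fitness W multiplies by \code{2^W} per generation (a neutral insert
#' doubles), so after G generations its abundance is multiplied by
#' \code{2^(W G)}. Inserts in essential-free intergenic space are neutral.
#' The population expansion factor realized over the outgrowth,
#' d = (total final abundance) / (total initial abundance), is attached as
#' attribute \code{"realized_d"} and is the d the fitness estimator should
#' use. Final counts are drawn as one multinomial of size \code{depth}
#' over the final frequencies; \code{noise = "none"} instead returns the
#' exact expected (non-integer) counts \code{depth * frequency}, which the
#' per-insert estimator inverts exactly.
#'
#' Inserts observed with zero t0 reads have no measurable abundance and
#' keep count_tf = 0.
#'
#' @param inserts t0 insertion table from \code{\link{simulate_library}}.
#' @param ann annotation data.frame.
#' @param truth truth table for this arm (its true_W drives selection).
#' @param generations generations of outgrowth G (> 0); NULL draws G
#'   uniformly in [20, 25].
#' @param depth reads in the t_final library; default the t0 total.
#' @param noise \code{"multinomial"} (sequencing draw) or \code{"none"}.
#' @param overdispersion extra-Poisson factor k; see
#'   \code{\link{library_sim_config}}.
#' @param seed integer seed.
#' @param edge_trim gene-assignment trim used to map inserts to genes.
#' @return insertion table with count_tf filled; attributes
#'   \code{"realized_d"} and \code{"generations"}.
#' @export
simulate_outgrowth <- function(inserts, ann, truth, generations = 22,
                               depth = NULL, noise = c("multinomial", "none"),
                               overdispersion = 0, seed = 1, edge_trim = 0) {
  noise <- match.arg(noise)
  set.seed(derive_seed(seed, "outgrowth"))
  if (is.null(generations)) generations <- stats::runif(1, 20, 25)
  if (generations <= 0) stop_cofit("generations must be > 0")
  depth <- depth %||% sum(inserts$count_t0)

  assign <- assign_inserts_to_genes(unique(inserts$site), ann, edge_trim)
  # one W per site: intergenic = 1; overlapping genes average their true W
  wmap <- truth$true_W[match(assign$gene_id, truth$gene_id)]
  wmap[is.na(assign$gene_id)] <- 1
  if (anyNA(wmap)) stop_cofit("insert(s) in essential genes have no defined true_W")
  site_W <- vapply(split(wmap, assign$site), mean, numeric(1))
  W <- site_W[as.character(inserts$site)]

  f0 <- inserts$count_t0 / sum(inserts$count_t0)
  a <- f0 * 2^(W * generations)
  if (overdispersion > 0) {
    a <- a * stats::rgamma(length(a), shape = 1 / overdispersion,
                           rate = 1 / overdispersion)
  }
  realized_d <- sum(a)
  ff <- a / realized_d
  out <- inserts
  if (noise == "none") {
    out$count_tf <- depth * ff
  } else {
    out$count_tf <- as.vector(stats::rmultinom(1, depth, ff))
  }
  out$count_tf[inserts$count_t0 == 0] <- 0
  attr(out, "realized_d") <- realized_d
  attr(out, "generations") <- generations
  out
}

#' Simulate a full replicated two-arm Tn-seq experiment
#'
#' Builds one library per replicate and grows it under both arms' truth
#' tables (the same t0 library enters both arms, as when one outgrowth
#' culture is split), returning per-arm insertion tables ready for
#' \code{\link{insert_fitness_table}}.
#'
#' @param genome,ann,truth_ref genome, annotation and reference-arm truth.
#' @param truth_sel truth of the selective arm (e.g. from
#'   \code{\link{condition_truth}}); NULL runs a single-arm experiment.
#' @param config \code{\link{library_sim_config}}.
#' @param n_replicates replicate libraries.
#' @param seed integer seed.
#' @return list with \code{arms}: named list of insertion tables (rows of
#'   all replicates bound together) for \code{"ref"} and (if requested)
#'   \code{"sel"}; \code{d}: named list of per-library realized expansion
#'   factors; \code{generations}.
#' @export
simulate_tnseq_experiment <- function(genome, ann, truth_ref, truth_sel = NULL,
                                      config = library_sim_config(),
                                      n_replicates = 2, seed = 1) {
  arms <- list(ref = truth_ref)
  if (!is.null(truth_sel)) arms$sel <- truth_sel
  set.seed(derive_seed(seed, "experiment"))
  gens <- config$generations %||% stats::runif(1, 20, 25)
  res <- lapply(names(arms), function(arm) list())
  names(res) <- names(arms)
  dmap <- lapply(names(arms), function(arm) numeric(0))
  names(dmap) <- names(arms)
  for (r in seq_len(n_replicates)) {
    lib <- simulate_library(genome, ann, truth_ref, config,
                            seed = derive_seed(seed, "rep", r),
                            library_id = sprintf("rep%d", r))
    for (ai in seq_along(arms)) {
      arm <- names(arms)[ai]
      # each arm sequences its own t0 of the shared library composition
      lib_arm <- if (ai == 1L) lib else {
        resample_library(lib, seed = derive_seed(seed, paste0("t0_", arm), r))
      }
      grown <- simulate_outgrowth(
        lib_arm, ann, arms[[arm]], generations = gens, depth = config$depth,
        noise = "multinomial", overdispersion = config$overdispersion,
        seed = derive_seed(seed, paste0("grow_", arm), r))
      res[[arm]][[r]] <- grown
      dmap[[arm]][sprintf("rep%d", r)] <- attr(grown, "realized_d")
    }
  }
  list(arms = lapply(res, function(x) do.call(rbind, x)),
       d = dmap, generations = gens)
}
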