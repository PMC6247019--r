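#' Configuration for synthetic mariner-library simulations
#'
#' Defaults emulate a saturated Himar1 mariner transposon library in a
#' GC-rich soil alphaproteobacterium passaged under selection: ~87% of
#' available TA sites carry an insert, genes average several hundred bp to
#' a few kb (lognormal; a small tail below 400 bp exercises the
#' short-gene rule), and each library is sequenced to a fixed read depth
#' drawn as one multinomial over inserts. Fitness effects are assigned as
#' a mixture over genes: most disruptions are neutral (true W = 1
#' exactly), a fraction are detrimental or beneficial with effect sizes
#' |W - 1| >= 0.1, and a fraction of genes are essential (no viable
#' insert).
#'
#' @param n_genes number of genes.
#' @param gene_length_meanlog,gene_length_sdlog lognormal parameters of
#'   gene length in bp (defaults give median ~800 bp, ~10% under 400 bp).
#' @param min_gene_length floor on simulated gene length (bp).
#' @param intergenic_fraction fraction of the genome outside genes.
#' @param gc GC content of the random genome sequence; controls TA
#'   density (expected TA per bp = ((1-gc)/2)^2).
#' @param saturation fraction of available TA sites receiving an insert.
#' @param depth reads per library (each of t0 and t_final).
#' @param generations generations of outgrowth G; NULL draws G uniformly
#'   in [20, 25] at simulation time.
#' @param frac_neutral,frac_detrimental,frac_beneficial,frac_essential
#'   gene-category mixture; must sum to 1.
#' @param w_detrimental,w_beneficial ranges of true W for affected genes.
#' @param dirichlet_alpha symmetric Dirichlet concentration of insert
#'   abundances at t0 (1 = flat; smaller = more uneven library).
#' @param overdispersion extra-Poisson noise on outgrowth abundances:
#'   0 disables; k > 0 multiplies each insert's expected final abundance
#'   by a Gamma(shape = 1/k, mean 1) factor before the sequencing draw.
#' @return list of class \code{library_sim_config}.
#' @export
library_sim_config <- function(n_genes = 1000,
                               gene_length_meanlog = log(800),
                               gene_length_sdlog = 0.45,
                               min_gene_length = 150,
                               intergenic_fraction = 0.15,
                               gc = 0.64,
                               saturation = 0.87,
                               depth = 5e5,
                               generations = 22,
                               frac_neutral = 0.75,
                               frac_detrimental = 0.10,
                               frac_beneficial = 0.05,
                               frac_essential = 0.10,
                               w_detrimental = c(0.6, 0.9),
                               w_beneficial = c(1.1, 1.2),
                               dirichlet_alpha = 1,
                               overdispersion = 0) {
  cfg <- as.list(environment())
  if (cfg$saturation <= 0 || cfg$saturation > 1) stop_cofit("saturation must be in (0, 1]")
  if (cfg$depth <= 0) stop_cofit("depth must be > 0")
  if (cfg$intergenic_fraction < 0 || cfg$intergenic_fraction >= 1) {
    stop_cofit("intergenic_fraction must be in [0, 1)")
  }
  fr <- c(frac_neutral, frac_detrimental, frac_beneficial, frac_essential)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop_cofit("category fractions must be non-negative and sum to 1")
  }
  class(cfg) <- "library_sim_config"
  cfg
}

# Exact-count category assignment: largest-remainder apportionment of the
# configured fractions, then a seeded shuffle over genes.
apportion_classes <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a synthetic genome, annotation and fitness truth
#'
#' Lays out non-overlapping genes separated by intergenic spacers on a
#' random sequence at the configured GC content, and assigns each gene a
#' true fitness effect from the configured mixture. Category counts are
#' exact (largest-remainder apportionment) and shuffled across genes;
#' neutral genes have true W = 1 exactly and essential genes are flagged
#' (they will receive no inserts).
#'
#' @param config \code{\link{library_sim_config}}.
#' @param seed integer seed; identical (config, seed) gives byte-identical
#'   output.
#' @return list with \code{genome} (tn_genome), \code{annotation}
#'   (data.frame) and \code{truth} (data.frame gene_id, class, true_W,
#'   essential).
#' @export
generate_genome <- function(config = library_sim_config(), seed = 1) {
  set.seed(derive_seed(seed, "genome"))
  n <- config$n_genes
  lens <- pmax(config$min_gene_length,
               round(stats::rlnorm(n, config$gene_length_meanlog,
                                   config$gene_length_sdlog)))
  total_gene_bp <- sum(lens)
  genome_len <- ceiling(total_gene_bp / (1 - config$intergenic_fraction))
  spacer_bp <- genome_len - total_gene_bp
  # n + 1 spacers (ends included), multinomially split
  spacers <- as.vector(stats::rmultinom(1, spacer_bp, rep(1, n + 1)))
  if (genome_len < total_gene_bp + n + 1) {
    stop_cofit("requested genes do not fit in the genome length")
  }
  starts <- integer(n); ends <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + spacers[i]
    starts[i] <- pos
    ends[i] <- pos + lens[i] - 1L
    pos <- ends[i] + 1L
  }
  genome_len <- ends[n] + spacers[n + 1]
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  seq <- paste(sample(names(p), genome_len, replace = TRUE, prob = p),
               collapse = "")
  genome <- structure(c(chr1 = seq), class = "tn_genome")

  ann <- data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                    start = starts, end = ends,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  ann <- validate_annotation(ann)

  counts <- apportion_classes(n, c(config$frac_neutral, config$frac_detrimental,
                                   config$frac_beneficial, config$frac_essential))
  cls <- sample(rep(c("neutral", "detrimental", "beneficial", "essential"), counts))
  true_W <- rep(1, n)
  true_W[cls == "detrimental"] <- stats::runif(sum(cls == "detrimental"),
                                               config$w_detrimental[1],
                                               config$w_detrimental[2])
  true_W[cls == "beneficial"] <- stats::runif(sum(cls == "beneficial"),
                                              config$w_beneficial[1],
                                              config$w_beneficial[2])
  true_W[cls == "essential"] <- NA_real_
  truth <- data.frame(gene_id = ann$gene_id, class = cls, true_W = true_W,
                      essential = cls == "essential", stringsAsFactors = FALSE)
  list(genome = genome, annotation = ann, truth = truth)
}

#' Impose conditional fitness effects on a truth table
#'
#' Returns a copy of \code{truth} whose \code{true_W} is shifted by
#' \code{delta_W} for the given genes - the truth of the selective arm in a
#' two-arm design. Essential genes cannot be shifted.
#'
#' @param truth truth table from \code{\link{generate_genome}}.
#' @param gene_ids genes to shift.
#' @param delta_W additive shift(s) of true W (recycled over genes).
#' @return modified truth table.
#' @export
condition_truth <- function(truth, gene_ids, delta_W) {
  idx <- match(gene_ids, truth$gene_id)
  if (anyNA(idx)) stop_cofit("unknown gene_id(s): ",
                             paste(gene_ids[is.na(idx)], collapse = ", "))
  if (any(truth$essential[idx])) stop_cofit("cannot shift essential genes")
  truth$true_W[idx] <- truth$true_W[idx] + rep_len(delta_W, length(idx))
  truth
}
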