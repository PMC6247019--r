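#' Enumerate TA dinucleotide sites
#'
#' The Himar1 mariner transposase inserts exclusively at TA dinucleotides,
#' so the TA positions of the genome are the universe of possible insertion
#' sites. A site is reported as the 1-based position of the T; TA is its own
#' reverse complement, so one strandless coordinate identifies the site.
#' Windows containing N are skipped.
#'
#' @param genome a sequence: character scalar or a single-record
#'   \code{tn_genome}.
#' @return integer vector of 1-based T positions, ascending. May be empty.
#' @export
enumerate_ta_sites <- function(genome) {
  seq <- as.character(unclass(genome))
  if (length(seq) != 1L) {
    stop_cofit("enumerate_ta_sites() expects a single sequence; subset the genome first")
  }
  if (nchar(seq) < 2L) return(integer(0))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  which(chars[-n] == "T" & chars[-1L] == "A")
}

#' Assign insertion sites to genes
#'
#' An insert belongs to gene g iff its T position lies within the gene body
#' after trimming \code{edge_trim} of the length (rounded down) from each
#' end; otherwise it is intergenic. Assignment ignores strand. When genes
#' overlap, the insert is assigned to every overlapping gene, with a
#' warning.
#'
#' @param sites integer vector of insertion positions (1-based T position).
#' @param ann annotation data.frame (gene_id, start, end).
#' @param edge_trim fraction of the gene length trimmed from each end
#'   before assignment; in [0, 0.5). Default 0: the literal gene body.
#' @return data.frame (site, gene_id); \code{gene_id} is NA for intergenic
#'   sites. Sites assigned to several overlapping genes appear once per
#'   gene.
#' @export
assign_inserts_to_genes <- function(sites, ann, edge_trim = 0) {
  if (edge_trim < 0 || edge_trim >= 0.5) stop_cofit("edge_trim must be in [0, 0.5)")
  ann <- validate_annotation(ann)
  trim <- floor(edge_trim * ann$length)
  lo <- ann$start + trim
  hi <- ann$end - trim
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = sites, width = 1L),
    IRanges::IRanges(start = lo, end = hi))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(qh)) {
    warning("insert(s) within overlapping genes assigned to all of them",
            call. = FALSE)
  }
  out <- data.frame(site = sites[qh],
                    gene_id = ann$gene_id[sh],
                    stringsAsFactors = FALSE)
  inter <- setdiff(seq_along(sites), qh)
  if (length(inter)) {
    out <- rbind(out, data.frame(site = sites[inter], gene_id = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  out[order(out$site, out$gene_id), , drop = FALSE]
}

#' Per-insert serial-passage fitness
#'
#' Fitness of an insert on the scale where a neutral disruption has W = 1:
#' \deqn{W = \frac{\ln(N_f d / N_0)}{\ln((1 - N_f) d / (1 - N_0))}}
#' where \eqn{N_0} and \eqn{N_f} are the insert's relative read frequencies
#' before and after outgrowth and \eqn{d} is the fold-expansion of the whole
#' population over the outgrowth (\eqn{d = 2^G} for G generations of
#' neutral doubling). Inserts with no reads at the final time point are not
#' dropped (that would bias detrimental genes toward neutral): their final
#' frequency is floored at \code{0.5 / totals_tf} and the value is flagged.
#'
#' @param count_t0,count_tf read counts of the insert at t0 and t_final.
#' @param totals_t0,totals_tf library total read counts at t0 and t_final.
#' @param d population expansion factor over the outgrowth (> 1).
#' @return data.frame (W, floored). Vectorized over inserts.
#' @export
insert_fitness <- function(count_t0, count_tf, totals_t0, totals_tf, d) {
  if (any(d <= 1)) stop_cofit("expansion factor d must exceed 1")
  if (any(count_t0 <= 0)) {
    stop_cofit("insert(s) with count_t0 = 0 are ineligible for fitness estimation")
  }
  n0 <- count_t0 / totals_t0
  if (any(n0 >= 1)) stop_cofit("N0 = 1 (single-insert library): fitness undefined")
  floored <- count_tf == 0
  nf <- ifelse(floored, 0.5 / totals_tf, count_tf / totals_tf)
  W <- log(nf * d / n0) / log((1 - nf) * d / (1 - n0))
  data.frame(W = W, floored = floored)
}

#' Per-insert fitness table for a set of libraries
#'
#' Computes W for every eligible insert (count_t0 > 0) of every library,
#' with library-wise read totals, and attaches the gene assignment. This
#' long table is the unit of all downstream gene-level statistics: per-gene
#' fitness is the mean of its inserts' W values pooled over replicate
#' libraries, and the arm/strain comparisons t-test these per-insert
#' samples.
#'
#' @param inserts insertion table (site, count_t0, count_tf, library_id);
#'   rows with count_t0 = 0 contribute to the observed-site tally but not
#'   to W.
#' @param ann annotation data.frame.
#' @param generations number of generations of outgrowth G (> 0).
#' @param d population expansion factor; default \code{2^generations}. May
#'   be a named vector (one per library) when realized expansions are
#'   known.
#' @param edge_trim passed to \code{\link{assign_inserts_to_genes}}.
#' @return data.frame (library_id, site, gene_id, W, floored).
#' @export
insert_fitness_table <- function(inserts, ann, generations, d = NULL,
                                 edge_trim = 0) {
  if (generations <= 0) stop_cofit("generations must be > 0")
  if (is.null(d)) d <- 2^generations
  inserts <- validate_inserts(inserts)
  assign <- assign_inserts_to_genes(unique(inserts$site), ann, edge_trim)
  out <- lapply(split(inserts, inserts$library_id), function(lib) {
    tot0 <- sum(lib$count_t0)
    totf <- sum(lib$count_tf)
    dl <- if (length(d) > 1L) {
      if (is.null(names(d)) || !lib$library_id[1] %in% names(d)) {
        stop_cofit("per-library d must be named by library_id")
      }
      d[[lib$library_id[1]]]
    } else d
    el <- lib[lib$eligible, , drop = FALSE]
    fit <- insert_fitness(el$count_t0, el$count_tf, tot0, totf, dl)
    merge(data.frame(library_id = el$library_id, site = el$site,
                     W = fit$W, floored = fit$floored,
                     stringsAsFactors = FALSE),
          assign, by = "site")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$library_id, out$site), c("library_id", "site", "gene_id", "W", "floored")]
}

#' Classify a gene from its fitness summary
#'
#' Five-way call from mean fitness, observed insert count and gene length:
#' genes longer than 400 bp with fewer than four observed insertions are
#' apparently lethal to disrupt; short genes (<= 400 bp) with fewer than
#' four insertions carry insufficient information; otherwise disruption is
#' detrimental when mean W < 0.95, beneficial when mean W > 1.05 and
#' neutral in between (boundaries inclusive: the outer classes are strict
#' inequalities).
#'
#' @param mean_W mean insert fitness of the gene (NA allowed when
#'   n_inserts < 4).
#' @param n_inserts number of distinct insertion sites observed in the
#'   gene.
#' @param gene_length gene length in bp.
#' @return character vector of categories in \{detrimental, beneficial,
#'   neutral, lethal, insufficient\}.
#' @export
classify_gene <- function(mean_W, n_inserts, gene_length) {
  stopifnot(all(gene_length > 0), all(n_inserts >= 0))
  n <- max(length(mean_W), length(n_inserts), length(gene_length))
  mean_W <- rep_len(mean_W, n)
  n_inserts <- rep_len(n_inserts, n)
  gene_length <- rep_len(gene_length, n)
  ifelse(n_inserts < 4,
         ifelse(gene_length > 400, "lethal", "insufficient"),
         ifelse(mean_W < 0.95, "detrimental",
                ifelse(mean_W > 1.05, "beneficial", "neutral")))
}

#' Gene-level fitness summary with category
#'
#' Aggregates a per-insert fitness table to genes: mean and sample standard
#' deviation of W (unweighted, pooled over replicate libraries; sd = 0 when
#' a single value), the number of distinct insertion sites observed, the
#' number of floored values, and the five-way category from
#' \code{\link{classify_gene}}. Genes with no observed insert at all are
#' included with n_inserts = 0 so that the lethality rule can apply.
#'
#' @param fit_tab per-insert table from \code{\link{insert_fitness_table}}.
#' @param ann annotation data.frame (supplies the gene universe and
#'   lengths).
#' @return data.frame (gene_id, mean_W, sd_W, n_inserts, n_values,
#'   n_floored, length, category).
#' @export
gene_fitness <- function(fit_tab, ann) {
  ann <- validate_annotation(ann)
  genic <- fit_tab[!is.na(fit_tab$gene_id), , drop = FALSE]
  sp <- split(genic, genic$gene_id)
  agg <- data.frame(
    gene_id   = names(sp),
    mean_W    = vapply(sp, function(g) mean(g$W), numeric(1)),
    sd_W      = vapply(sp, function(g) if (nrow(g) > 1L) stats::sd(g$W) else 0, numeric(1)),
    n_inserts = vapply(sp, function(g) length(unique(g$site)), integer(1)),
    n_values  = vapply(sp, nrow, integer(1)),
    n_floored = vapply(sp, function(g) sum(g$floored), integer(1)),
    stringsAsFactors = FALSE)
  out <- merge(ann[, c("gene_id", "length")], agg, by = "gene_id", all.x = TRUE)
  out$n_inserts[is.na(out$n_inserts)] <- 0L
  out$n_values[is.na(out$n_values)] <- 0L
  out$n_floored[is.na(out$n_floored)] <- 0L
  out$category <- classify_gene(out$mean_W, out$n_inserts, out$length)
  rownames(out) <- NULL
  out[, c("gene_id", "mean_W", "sd_W", "n_inserts", "n_values", "n_floored",
          "length", "category")]
}

#' Tn-seq gene fitness: estimate and classify in one call
#'
#' Convenience wrapper running \code{\link{insert_fitness_table}} then
#' \code{\link{gene_fitness}}.
#'
#' @inheritParams insert_fitness_table
#' @return gene-level summary as from \code{\link{gene_fitness}}; the
#'   per-insert table is attached as attribute \code{"insert_fitness"}.
#' @export
tnseq_fitness <- function(inserts, ann, generations, d = NULL, edge_trim = 0) {
  fit_tab <- insert_fitness_table(inserts, ann, generations, d, edge_trim)
  out <- gene_fitness(fit_tab, ann)
  attr(out, "insert_fitness") <- fit_tab
  out
}
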