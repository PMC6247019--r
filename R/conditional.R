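#' Compare gene fitness between two selection arms
#'
#' For every gene in either arm's per-insert fitness table, computes the
#' fitness difference \code{delta_W = mean(W, arm A) - mean(W, arm B)} and a
#' Welch two-sample t test on the per-insert W samples (pooled over
#' replicate libraries). A gene is significant when both
#' \code{|delta_W| > delta_threshold} (default 0.05) and the p value clears
#' the Bonferroni-corrected level \code{alpha / n_genes_tested}, where the
#' denominator is the number of genes actually testable in this run (at
#' least two eligible inserts in each arm). Genes failing the two-insert
#' precondition are reported with their delta_W, never significant, and
#' flagged \code{"untestable"}.
#'
#' @param fitA,fitB per-insert fitness tables (from
#'   \code{\link{insert_fitness_table}}) for arms A and B.
#' @param delta_threshold minimum absolute fitness difference.
#' @param alpha family-wise error level before Bonferroni correction.
#' @return data.frame (gene_id, mean_W_a, mean_W_b, delta_W, n_a, n_b, t,
#'   p, p_threshold, significant, flag), one row per gene in the union.
#' @export
compare_arms <- function(fitA, fitB, delta_threshold = 0.05, alpha = 0.05) {
  wsA <- split(fitA$W[!is.na(fitA$gene_id)], fitA$gene_id[!is.na(fitA$gene_id)])
  wsB <- split(fitB$W[!is.na(fitB$gene_id)], fitB$gene_id[!is.na(fitB$gene_id)])
  genes <- sort(union(names(wsA), names(wsB)))
  nA <- vapply(genes, function(g) length(wsA[[g]]), integer(1))
  nB <- vapply(genes, function(g) length(wsB[[g]]), integer(1))
  testable <- nA >= 2L & nB >= 2L
  m <- sum(testable)
  if (m < 1L) stop_cofit("no gene is testable (needs >= 2 inserts in each arm)")
  thr <- alpha / m
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    a <- wsA[[g]]; b <- wsB[[g]]
    mA <- if (length(a)) mean(a) else NA_real_
    mB <- if (length(b)) mean(b) else NA_real_
    if (!testable[i]) {
      return(data.frame(gene_id = g, mean_W_a = mA, mean_W_b = mB,
                        delta_W = mA - mB, n_a = length(a), n_b = length(b),
                        t = NA_real_, p = NA_real_, p_threshold = thr,
                        significant = FALSE, flag = "untestable",
                        stringsAsFactors = FALSE))
    }
    tt <- welch_t(a, b)
    dW <- mA - mB
    data.frame(gene_id = g, mean_W_a = mA, mean_W_b = mB, delta_W = dW,
               n_a = length(a), n_b = length(b), t = tt$t, p = tt$p,
               p_threshold = thr,
               significant = abs(dW) > delta_threshold && tt$p < thr,
               flag = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conditionally important gene sets
#'
#' Genes whose disruption changes fitness under the selective condition but
#' is neutral in its absence: conditionally detrimental genes are
#' significant in the arm comparison with \code{delta_W < 0} (selective arm
#' minus reference arm) and classified neutral in the reference arm;
#' conditionally beneficial genes analogously with \code{delta_W > 0}.
#'
#' @param cmp arm-comparison table from \code{\link{compare_arms}} with arm
#'   A the selective condition and arm B its absence.
#' @param ref_fitness gene-level summary (\code{\link{gene_fitness}}) of
#'   the reference (no-selection) arm, supplying the \code{category}
#'   column.
#' @return list with character vectors \code{conditionally_detrimental}
#'   and \code{conditionally_beneficial}.
#' @export
conditionally_important <- function(cmp, ref_fitness) {
  missing_ref <- setdiff(cmp$gene_id, ref_fitness$gene_id)
  if (length(missing_ref)) {
    stop_cofit("gene universe mismatch; missing from reference categories: ",
               paste(utils::head(missing_ref, 10), collapse = ", "))
  }
  cat_ref <- ref_fitness$category[match(cmp$gene_id, ref_fitness$gene_id)]
  neutral <- !is.na(cat_ref) & cat_ref == "neutral"
  list(
    conditionally_detrimental = cmp$gene_id[cmp$significant & cmp$delta_W < 0 & neutral],
    conditionally_beneficial  = cmp$gene_id[cmp$significant & cmp$delta_W > 0 & neutral])
}

#' Compare background-corrected fitness between two strains
#'
#' For each strain, the fitness cost of disruption that is due to the gene
#' itself (rather than the selective condition) is removed by subtracting
#' the no-selection arm: \code{delta = mean W(+sel) - mean W(-sel)} per
#' gene. A Welch two-sample t test then compares the two strains'
#' per-insert fitness samples under selection. A gene is
#' degradation-dependent detrimental when its disruption is
#' significant-detrimental in the wild type's own arm comparison
#' (\code{\link{compare_arms}} within strain) but not in the mutant's - the
#' pattern of genes that matter only when the stressor is being
#' metabolized.
#'
#' @param wt_plus,wt_minus per-insert fitness tables of the wild-type
#'   strain with and without selection.
#' @param mut_plus,mut_minus likewise for the mutant strain.
#' @param delta_threshold,alpha as in \code{\link{compare_arms}}.
#' @return data.frame (gene_id, delta_wt, delta_mut, sig_wt, sig_mut,
#'   t_strain, p_strain, strain_diff_significant, degradation_dependent,
#'   flag); genes absent from one strain's library are flagged
#'   \code{"absent_one_strain"} and excluded from testing.
#' @export
compare_strains <- function(wt_plus, wt_minus, mut_plus, mut_minus,
                            delta_threshold = 0.05, alpha = 0.05) {
  cmp_wt <- compare_arms(wt_plus, wt_minus, delta_threshold, alpha)
  cmp_mut <- compare_arms(mut_plus, mut_minus, delta_threshold, alpha)
  wsW <- split(wt_plus$W[!is.na(wt_plus$gene_id)], wt_plus$gene_id[!is.na(wt_plus$gene_id)])
  wsM <- split(mut_plus$W[!is.na(mut_plus$gene_id)], mut_plus$gene_id[!is.na(mut_plus$gene_id)])
  genes <- sort(union(cmp_wt$gene_id, cmp_mut$gene_id))
  iW <- match(genes, cmp_wt$gene_id)
  iM <- match(genes, cmp_mut$gene_id)
  testable <- vapply(genes, function(g) {
    length(wsW[[g]]) >= 2L && length(wsM[[g]]) >= 2L
  }, logical(1))
  m <- sum(testable)
  thr <- if (m >= 1L) alpha / m else NA_real_
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    in_both <- !is.na(iW[i]) && !is.na(iM[i])
    sig_wt <- in_both && cmp_wt$significant[iW[i]] && cmp_wt$delta_W[iW[i]] < 0
    sig_mut <- in_both && cmp_mut$significant[iM[i]] && cmp_mut$delta_W[iM[i]] < 0
    tt <- if (testable[i]) welch_t(wsW[[g]], wsM[[g]]) else list(t = NA_real_, p = NA_real_)
    data.frame(
      gene_id = g,
      delta_wt = if (is.na(iW[i])) NA_real_ else cmp_wt$delta_W[iW[i]],
      delta_mut = if (is.na(iM[i])) NA_real_ else cmp_mut$delta_W[iM[i]],
      sig_wt = sig_wt, sig_mut = sig_mut,
      t_strain = tt$t, p_strain = tt$p,
      strain_diff_significant = testable[i] && !is.na(tt$p) && tt$p < thr,
      degradation_dependent = in_both && sig_wt && !sig_mut,
      flag = if (!in_both) "absent_one_strain" else if (!testable[i]) "untestable" else "ok",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
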