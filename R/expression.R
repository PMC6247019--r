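#' Filter weakly expressed genes
#'
#' Keeps genes with counts-per-million at or above \code{min_cpm} in at
#' least \code{min_samples} samples; weakly expressed genes carry little
#' information and inflate the multiple-testing burden. The default
#' \code{min_samples} is the size of the smallest condition group.
#'
#' @param x \code{tn_counts}.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples meeting the threshold.
#' @return filtered \code{tn_counts}.
#' @export
filter_low_expression <- function(x, min_cpm = 1, min_samples = NULL) {
  libsize <- colSums(x$counts)
  if (any(libsize <= 0)) stop_cofit("library size(s) of zero")
  min_samples <- min_samples %||% min(table(x$samples$condition))
  cpm <- t(t(x$counts) / libsize) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep)) {
    stop_cofit("all genes removed by the expression filter; review min_cpm/min_samples")
  }
  tn_counts(x$counts[keep, , drop = FALSE],
            x$samples$condition, x$samples$replicate)
}

# Median-of-ratios library-size factors (computed over genes with all-
# positive counts), normalized to geometric mean 1.
size_factors <- function(counts) {
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) stop_cofit("no gene with all-positive counts; cannot normalize")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, stats::median))
  sf / exp(mean(log(sf)))
}

#' Two-group negative-binomial Wald test for differential expression
#'
#' A self-contained DE test for stressor-vs-control contrasts: library
#' sizes are normalized by median-of-ratios; log2 fold changes come from
#' normalized group means with a pseudocount of 0.5; a per-gene NB
#' dispersion is estimated by the method of moments on the normalized
#' counts (pooled within-group, floored at 1e-8) and moderated by
#' shrinking toward the genome-wide median with \code{prior_df} prior
#' degrees of freedom (few replicates make the raw per-gene moment
#' estimate far too noisy to test against); the p value is a normal Wald
#' test of the log-mean difference, whose delta-method variance is
#' \code{(1/mu + alpha)/n} summed over the two groups.
#'
#' @param x \code{tn_counts} containing both groups (other conditions are
#'   ignored).
#' @param condition stressor condition label.
#' @param control control condition label.
#' @param prior_df prior degrees of freedom of the dispersion shrinkage.
#' @return data.frame (gene_id, base_mean, log2FC, p_value, q_value);
#'   log2FC is condition over control; q is Benjamini-Hochberg.
#' @export
de_test <- function(x, condition, control, prior_df = 10) {
  sel <- x$samples$condition %in% c(condition, control)
  cts <- x$counts[, sel, drop = FALSE]
  grp <- x$samples$condition[sel]
  nA <- sum(grp == control); nB <- sum(grp == condition)
  if (nA < 2L || nB < 2L) stop_cofit("each group needs >= 2 replicates")
  sf <- size_factors(cts)
  norm <- t(t(cts) / sf)
  A <- norm[, grp == control, drop = FALSE]
  B <- norm[, grp == condition, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  # pooled within-group moments dispersion: var = mu + alpha mu^2
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  v_pool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mu_pool <- (nA * mA + nB * mB) / (nA + nB)
  alpha_g <- pmax((v_pool - mu_pool) / mu_pool^2, 1e-8)
  resid_df <- nA + nB - 2
  alpha <- (resid_df * alpha_g + prior_df * stats::median(alpha_g)) /
    (resid_df + prior_df)
  delta <- log(mB + 0.5) - log(mA + 0.5)
  se <- sqrt((1 / (mA + 0.5) + alpha) / nA + (1 / (mB + 0.5) + alpha) / nB)
  z <- delta / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene_id = rownames(cts),
             base_mean = mu_pool,
             log2FC = delta / log(2),
             p_value = p,
             q_value = bh_fdr(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q values
#'
#' Step-up false-discovery-rate adjustment: on the sorted scale
#' \code{q_(i) = min_(j >= i) p_(j) m / j}, mapped back to input order.
#'
#' @param p p values in [0, 1].
#' @return q values, same order; element-wise q >= p.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_cofit("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significant differential expression under the fold/FDR gate
#'
#' A gene is called iff \code{|log2FC| > log2(fold_threshold)} and
#' \code{q < fdr_threshold}, both strict; the default gate is >2-fold at
#' FDR < 0.01.
#'
#' @param de DE table from \code{\link{de_test}}.
#' @param fold_threshold fold-change gate (linear scale).
#' @param fdr_threshold FDR gate.
#' @return \code{de} with logical \code{significant} and integer
#'   \code{direction} (+1 up, -1 down, 0 not significant) columns.
#' @export
significant_de <- function(de, fold_threshold = 2, fdr_threshold = 0.01) {
  sig <- abs(de$log2FC) > log2(fold_threshold) & de$q_value < fdr_threshold
  de$significant <- sig
  de$direction <- ifelse(sig, sign(de$log2FC), 0)
  de
}

#' Overlap between two stressors' transcriptional responses
#'
#' Two complementary summaries over a common gene universe:
#' \code{spearman_rho}, the Spearman rank correlation of log2 fold changes
#' over the union of genes significant at FDR < \code{fdr_threshold} in
#' either contrast (no fold gate, average-rank ties); and
#' \code{shared_fraction}, the percentage of genes passing the full
#' fold/FDR gate in contrast A that also pass it in B with the same sign.
#'
#' @param deA,deB DE tables over the same gene universe.
#' @param fdr_threshold FDR gate for the correlation universe.
#' @param fold_threshold,shared_fdr_threshold full gate for the shared
#'   fraction.
#' @return list (spearman_rho, n_union, shared_fraction, n_sig_a,
#'   n_shared, status); when no gene is significant the status is
#'   \code{"no significant genes"} and the values are NA.
#' @export
response_overlap <- function(deA, deB, fdr_threshold = 0.01,
                             fold_threshold = 2, shared_fdr_threshold = 0.01) {
  if (!setequal(deA$gene_id, deB$gene_id)) {
    stop_cofit("DE tables must cover the same gene universe")
  }
  deB <- deB[match(deA$gene_id, deB$gene_id), ]
  union_idx <- deA$q_value < fdr_threshold | deB$q_value < fdr_threshold
  gA <- significant_de(deA, fold_threshold, shared_fdr_threshold)
  gB <- significant_de(deB, fold_threshold, shared_fdr_threshold)
  sigA <- gA$gene_id[gA$significant]
  n_shared <- sum(gA$significant & gB$significant & gA$direction == gB$direction)
  if (!any(union_idx)) {
    return(list(spearman_rho = NA_real_, n_union = 0L,
                shared_fraction = NA_real_, n_sig_a = length(sigA),
                n_shared = n_shared, status = "no significant genes"))
  }
  rho <- stats::cor(deA$log2FC[union_idx], deB$log2FC[union_idx],
                    method = "spearman")
  list(spearman_rho = rho,
       n_union = sum(union_idx),
       shared_fraction = if (length(sigA)) 100 * n_shared / length(sigA) else NA_real_,
       n_sig_a = length(sigA),
       n_shared = n_shared,
       status = "ok")
}

#' Fitness-expression concordance
#'
#' Labels each gene by whether its transcriptional response to the
#' stressor is consistent with its importance for fitness under the
#' stressor: a gene whose disruption is significantly detrimental under
#' selection (conditional fitness deficit) and which is significantly
#' upregulated responds appropriately; significant downregulation of such
#' a gene is counterproductive. Genes whose disruption is significantly
#' beneficial are mirrored (downregulation is appropriate). Everything
#' else is unclassified.
#'
#' @param cmp arm-comparison table (\code{\link{compare_arms}}, selective
#'   arm minus reference).
#' @param de DE table with the significance gate applied
#'   (\code{\link{significant_de}} columns; the gate is applied with
#'   defaults if absent).
#' @return data.frame (gene_id, delta_W, fitness_significant, log2FC,
#'   de_significant, label).
#' @export
concordance <- function(cmp, de) {
  if (!"significant" %in% names(de)) de <- significant_de(de)
  common <- intersect(cmp$gene_id, de$gene_id)
  ci <- match(common, cmp$gene_id)
  di <- match(common, de$gene_id)
  dW <- cmp$delta_W[ci]
  fsig <- cmp$significant[ci]
  lfc <- de$log2FC[di]
  dsig <- de$significant[di]
  dir <- de$direction[di]
  label <- rep("unclassified", length(common))
  label[fsig & dW < 0 & dsig & dir > 0] <- "appropriate"
  label[fsig & dW < 0 & dsig & dir < 0] <- "counterproductive"
  label[fsig & dW > 0 & dsig & dir < 0] <- "appropriate"
  label[fsig & dW > 0 & dsig & dir > 0] <- "counterproductive"
  data.frame(gene_id = common, delta_W = dW, fitness_significant = fsig,
             log2FC = lfc, de_significant = dsig, label = label,
             stringsAsFactors = FALSE)
}
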