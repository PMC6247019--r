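#' @keywords internal
"_PACKAGE"

# Substream seed derivation: every stochastic stage draws its own seed from
# the top-level seed so that stages can be re-run independently and adding a
# stage never perturbs the draws of another. Kept below 2^31 - 1.
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + index * 7919) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cofit <- function(...) stop(..., call. = FALSE)

# Welch two-sample t test with the degenerate-case rule: when both samples
# are constant (zero pooled variance) there is no evidence of a difference,
# so p = 1 and t = 0 rather than an error.
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    return(list(t = NA_real_, p = NA_real_, ok = FALSE))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1, ok = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, ok = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value, ok = TRUE)
}

#' Write a tab-separated table
#'
#' Canonical tabular output: tab-separated, header row, no quoting, no row
#' names, '.' decimal. All pipeline reports use this dialect.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
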