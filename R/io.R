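#' Read a genome from FASTA
#'
#' Parses a (possibly multi-record) FASTA file into a named character vector
#' of uppercase DNA sequences, one element per record. Only the alphabet
#' {A, C, G, T, N} is accepted; any other character is a format error naming
#' the offending record.
#'
#' @param path path to a FASTA file.
#' @return named character vector of class \code{tn_genome}.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_cofit("genome file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop_cofit("not a FASTA file: ", path, " (", conditionMessage(e), ")"))
  if (length(ss) == 0L) stop_cofit("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop_cofit("non-nucleotide characters (outside A/C/G/T/N) in record(s): ",
               paste(names(seqs)[bad], collapse = ", "))
  }
  structure(seqs, class = "tn_genome")
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences (as from
#'   \code{\link{read_genome}}).
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Retains features of the requested type (default \code{"gene"}); the ID
#' attribute becomes \code{gene_id}. Coordinates are 1-based inclusive per
#' the GFF3 standard and stay 1-based inclusive in the returned table.
#'
#' @param path path to a GFF3 file.
#' @param feature_type feature type(s) to retain.
#' @return data.frame with columns gene_id, start, end, strand, length.
#' @export
read_annotation <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop_cofit("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (length(gr) == 0L) stop_cofit("no '", paste(feature_type, collapse = "/"),
                                   "' features in ", path)
  ids <- as.character(gr$ID)
  if (anyNA(ids)) stop_cofit("gene feature(s) without an ID attribute in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop_cofit("duplicate gene IDs: ", paste(dup, collapse = ", "))
  ann <- data.frame(gene_id = ids,
                    start   = GenomicRanges::start(gr),
                    end     = GenomicRanges::end(gr),
                    strand  = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(ann)))
  if (any(ann$start > ann$end)) {
    bad <- ann$gene_id[ann$start > ann$end]
    stop_cofit("start > end for gene(s): ", paste(bad, collapse = ", "))
  }
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup)) stop_cofit("duplicate gene IDs: ", paste(dup, collapse = ", "))
  ann$length <- ann$end - ann$start + 1L
  ann
}

#' Write gene annotation to GFF3
#'
#' @param ann annotation data.frame (gene_id, start, end, strand).
#' @param path output path.
#' @param seqname sequence name for the GFF3 seqid column.
#' @export
write_annotation <- function(ann, path, seqname = "chr") {
  ann <- validate_annotation(ann)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand)
  gr$type <- "gene"
  gr$ID <- ann$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an insertion-site count table
#'
#' Accepts the canonical TSV (columns site, count_t0, count_tf, library_id)
#' or a pair of fixed-step wig-style tracks (t0 and tf) via
#' \code{\link{read_insertion_wig}}. Rows with \code{count_t0 = 0} are
#' retained but flagged ineligible for fitness estimation (column
#' \code{eligible}).
#'
#' @param path path to the TSV.
#' @return data.frame (site, count_t0, count_tf, library_id, eligible).
#' @export
read_insertion_table <- function(path) {
  tab <- read_tsv(path)
  need <- c("site", "count_t0", "count_tf", "library_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_cofit("insertion table missing column(s): ",
                               paste(miss, collapse = ", "))
  for (col in c("count_t0", "count_tf")) {
    v <- tab[[col]]
    if (any(v != floor(v), na.rm = TRUE)) stop_cofit("non-integer counts in ", col)
  }
  validate_inserts(tab[, need])
}

# In-memory validation; integer-ness is only enforced at the file boundary
# (noiseless simulations carry exact expected, non-integer, counts).
validate_inserts <- function(tab) {
  for (col in c("count_t0", "count_tf")) {
    v <- tab[[col]]
    if (any(is.na(v))) stop_cofit("missing values in ", col)
    if (any(v < 0)) stop_cofit("negative counts in ", col)
  }
  if (any(tab$site < 1)) stop_cofit("sites must be 1-based positive positions")
  tab$library_id <- as.character(tab$library_id)
  tab$eligible <- tab$count_t0 > 0
  tab
}

#' Write an insertion-site count table
#'
#' @param inserts insertion table.
#' @param path output path.
#' @export
write_insertion_table <- function(inserts, path) {
  write_tsv(inserts[, c("site", "count_t0", "count_tf", "library_id")], path)
}

#' Read a pair of wig-style per-TA-site tracks as an insertion table
#'
#' Each track is a variableStep wig file: a track line, a
#' \code{variableStep chrom=...} declaration, then one \code{position value}
#' line per insertion site. The t0 and tf tracks of one library are combined
#' on position.
#'
#' @param path_t0,path_tf wig tracks with counts before and after outgrowth.
#' @param library_id library label for the combined table.
#' @return insertion table as from \code{\link{read_insertion_table}}.
#' @export
read_insertion_wig <- function(path_t0, path_tf, library_id = "lib1") {
  t0 <- read_wig_track(path_t0)
  tf <- read_wig_track(path_tf)
  sites <- sort(unique(c(t0$site, tf$site)))
  tab <- data.frame(
    site = sites,
    count_t0 = ifelse(sites %in% t0$site, t0$value[match(sites, t0$site)], 0),
    count_tf = ifelse(sites %in% tf$site, tf$value[match(sites, tf$site)], 0),
    library_id = library_id,
    stringsAsFactors = FALSE)
  validate_inserts(tab)
}

read_wig_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|variableStep|fixedStep|#)", lines) & nzchar(lines)]
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(site = as.numeric(vapply(parts, `[`, "", 1L)),
             value = as.numeric(vapply(parts, `[`, "", 2L)))
}

#' Write insertion counts as a wig-style track
#'
#' @param inserts insertion table.
#' @param path output path.
#' @param column which count column to write.
#' @param chrom chromosome name for the variableStep declaration.
#' @export
write_insertion_wig <- function(inserts, path, column = c("count_t0", "count_tf"),
                                chrom = "chr") {
  column <- match.arg(column)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("track type=wiggle_0 name=%s", column),
               sprintf("variableStep chrom=%s", chrom),
               sprintf("%d %s", as.integer(inserts$site),
                       format(inserts[[column]], scientific = FALSE, trim = TRUE))),
             con)
  invisible(path)
}

#' Read an expression count matrix with sample metadata
#'
#' The TSV has a \code{gene_id} column followed by one column per sample
#' named \code{<condition>_<replicate>}; metadata are recovered from the
#' column names.
#'
#' @param path path to the counts TSV.
#' @return object of class \code{tn_counts}: list with \code{counts}
#'   (integer matrix, genes x samples) and \code{samples} (data.frame with
#'   sample, condition, replicate).
#' @export
read_counts <- function(path) {
  tab <- read_tsv(path)
  if (!"gene_id" %in% names(tab)) stop_cofit("counts table needs a gene_id column")
  m <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  rownames(m) <- tab$gene_id
  if (any(m < 0)) stop_cofit("negative counts in ", path)
  cond <- sub("_[^_]+$", "", colnames(m))
  repl <- sub("^.*_", "", colnames(m))
  tn_counts(m, condition = cond, replicate = repl)
}

#' Construct an expression count container
#'
#' @param counts genes x samples non-negative matrix with rownames.
#' @param condition condition label per sample.
#' @param replicate replicate label per sample.
#' @return object of class \code{tn_counts}.
#' @export
tn_counts <- function(counts, condition, replicate = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop_cofit("negative entries in count matrix")
  if (length(condition) != ncol(counts)) stop_cofit("one condition per sample required")
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste(condition, replicate, sep = "_")
  }
  structure(list(
    counts = counts,
    samples = data.frame(sample = colnames(counts), condition = as.character(condition),
                         replicate = as.character(replicate), stringsAsFactors = FALSE)),
    class = "tn_counts")
}

#' @export
print.tn_counts <- function(x, ...) {
  cat("tn_counts: ", nrow(x$counts), " genes x ", ncol(x$counts), " samples (",
      paste(unique(x$samples$condition), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write an expression count matrix
#'
#' @param x \code{tn_counts} object.
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, path)
}
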