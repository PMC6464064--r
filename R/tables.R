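# TSV readers for the tabular inputs: tissue-wide expression matrices
# (genes x tissues, median RPKM), CRISPR guide-coefficient matrices
# (genes x guides, log10 fold change) and siRNA p-value tables. All readers
# are strict: duplicate gene ids, missing or non-numeric cells raise.

read_numeric_tsv <- function(path, what, allow_negative = TRUE) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L)
    stop(what, ": need a gene id column plus at least one value column",
         call. = FALSE)
  ids <- as.character(d[[1L]])
  dup <- anyDuplicated(ids)
  if (dup)
    stop(what, ": duplicate gene id '", ids[dup], "'", call. = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)))
    stop(what, ": non-numeric or missing cell", call. = FALSE)
  if (any(!is.finite(m)))
    stop(what, ": non-finite value", call. = FALSE)
  if (!allow_negative && any(m < 0))
    stop(what, ": negative value", call. = FALSE)
  rownames(m) <- ids
  m
}

#' Read a genes x tissues expression table
#'
#' Expects a TSV with a header row of tissue names and one row per gene; values
#' are median expression (RPKM), non-negative and finite.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows, tissues in columns.
#' @export
read_expression_table <- function(path) {
  read_numeric_tsv(path, "expression table", allow_negative = FALSE)
}

#' Read a genes x guides CRISPR coefficient matrix
#'
#' Coefficients are log10 fold changes in expression attributed to each guide
#' RNA targeting the perturbed transcription factor.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows, guides in columns.
#' @export
read_guide_coefficients <- function(path) {
  read_numeric_tsv(path, "guide coefficient matrix")
}

#' Read a gene -> p-value table
#'
#' TSV with a header and two columns (gene id, p-value). P-values must lie in
#' \[0, 1\].
#'
#' @param path file path.
#' @return named numeric vector of p-values.
#' @export
read_pvalue_table <- function(path) {
  m <- read_numeric_tsv(path, "p-value table")
  if (ncol(m) != 1L)
    stop("p-value table: expected exactly one value column", call. = FALSE)
  p <- stats::setNames(as.numeric(m[, 1L]), rownames(m))
  if (any(p < 0 | p > 1))
    stop("p-value table: p-value outside [0, 1]", call. = FALSE)
  p
}

#' Read a FASTA genome
#'
#' @param path FASTA file path.
#' @return a named `DNAStringSet`.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome to FASTA
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

contig_length <- function(genome, contig) {
  if (!(contig %in% names(genome)))
    stop("contig '", contig, "' not found in genome", call. = FALSE)
  if (methods::is(genome, "DNAStringSet")) length(genome[[contig]])
  else nchar(genome[[contig]])
}

#' Extract a genomic subsequence
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param contig contig name.
#' @param start,end 0-based half-open coordinates on the contig.
#' @param strand `"+"` for the forward sequence, `"-"` for its reverse
#'   complement.
#' @return uppercase DNA string of length `end - start`.
#' @export
get_sequence <- function(genome, contig, start, end, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  len <- contig_length(genome, contig)
  if (start < 0 || end > len || start >= end)
    stop("interval [", start, ",", end, ") out of bounds on contig '",
         contig, "' (length ", len, ")", call. = FALSE)
  s <- if (methods::is(genome, "DNAStringSet"))
    as.character(Biostrings::subseq(genome[[contig]], start + 1L, end))
  else substr(genome[[contig]], start + 1L, end)
  s <- toupper(s)
  if (strand == "-") revcomp(s) else s
}

#' Read a transcription start site table
#'
#' TSV with header and columns `gene_id`, `contig`, `tss` (1-based position of
#' the TSS), `strand`. The TSS is converted to the package's 0-based frame.
#'
#' @param path file path.
#' @return data.frame with columns gene_id, contig, tss (0-based), strand.
#' @export
read_tss_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "tss", "strand")
  if (!all(need %in% names(d)))
    stop("TSS table: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(d$strand %in% c("+", "-")))
    stop("TSS table: strand must be '+' or '-'", call. = FALSE)
  d$tss <- position_to_zero_based(d$tss)
  d[, need]
}

#' Convert a 1-based genomic position to the 0-based internal frame
#'
#' All external position-valued inputs (VCF-like variant tables, TSS tables)
#' are 1-based; internally everything is 0-based half-open. This is the single
#' audited place where the conversion happens.
#'
#' @param pos integer vector of 1-based positions.
#' @return integer vector of 0-based positions.
#' @export
position_to_zero_based <- function(pos) {
  pos <- as.integer(pos)
  if (any(is.na(pos) | pos < 1L))
    stop("position must be a positive 1-based integer", call. = FALSE)
  pos - 1L
}

#' Read a variant table
#'
#' VCF-like TSV with header and columns `id`, `contig`, `pos` (1-based),
#' `ref`, `alt`. Only single-nucleotide substitutions are supported.
#'
#' @param path file path.
#' @return data.frame with columns id, contig, pos (0-based), ref, alt.
#' @export
read_variants <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("id", "contig", "pos", "ref", "alt")
  if (!all(need %in% names(d)))
    stop("variant table: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- d[, need]
  d$pos <- position_to_zero_based(d$pos)
  validate_variants(d)
  d
}

validate_variants <- function(v) {
  if (nrow(v) == 0L) return(invisible(v))
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  if (!all(v$ref %in% DNA_BASES) || !all(v$alt %in% DNA_BASES))
    stop("variant table: ref/alt must be single bases (SNVs only)",
         call. = FALSE)
  if (any(v$ref == v$alt))
    stop("variant table: ref equals alt", call. = FALSE)
  invisible(v)
}
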