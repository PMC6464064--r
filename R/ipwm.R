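# Information-theoretic position weight matrices (iPWMs). Weights are in bits;
# summing the weights along a k-mer gives that site's individual information
# R_i. R_sequence -- the average R_i over a factor's bound sites, equal to the
# area under the sequence logo -- defines both the scan threshold
# (0.1 * R_sequence) and the "strong site" cutoff (R_i > R_sequence).

DNA_BASES <- c("A", "C", "G", "T")

#' Construct an iPWM
#'
#' @param tf transcription factor name.
#' @param weights numeric matrix, width x 4, per-position per-base weights in
#'   bits; columns in the fixed base order A, C, G, T.
#' @param cell_line cell line the matrix was derived in (metadata).
#' @param r_sequence optional known R_sequence in bits. When absent it can be
#'   recovered from the weights by [matrix_r_sequence()] provided the weights
#'   follow the `w = 2 + log2(f)` convention.
#' @return an object of class `ipwm`.
#' @export
ipwm <- function(tf, weights, cell_line = "", r_sequence = NULL) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 4L)
    stop("ipwm: weights must have 4 columns (A, C, G, T)", call. = FALSE)
  if (nrow(weights) < 1L)
    stop("ipwm: width must be >= 1", call. = FALSE)
  if (any(!is.finite(weights)))
    stop("ipwm: non-finite weight", call. = FALSE)
  colnames(weights) <- DNA_BASES
  rownames(weights) <- NULL
  if (!is.null(r_sequence)) {
    r_sequence <- as.numeric(r_sequence)
    stopifnot(is.finite(r_sequence))
  }
  structure(list(tf = as.character(tf), cell_line = as.character(cell_line),
                 width = nrow(weights), weights = weights,
                 r_sequence = r_sequence),
            class = "ipwm")
}

#' @export
print.ipwm <- function(x, ...) {
  rs <- tryCatch(matrix_r_sequence(x), error = function(e) NA_real_)
  cat(sprintf("iPWM %s [%s], width %d, R_sequence %s bits\n", x$tf,
              x$cell_line, x$width,
              if (is.na(rs)) "unavailable" else sprintf("%.4f", rs)))
  invisible(x)
}

#' Score a k-mer against an iPWM (individual information R_i)
#'
#' `R_i` is the sum of the matrix weights picked out by the k-mer's bases,
#' in bits.
#'
#' @param m an [ipwm()].
#' @param kmer DNA string of length `m$width`, bases in `ACGT` only.
#' @return R_i in bits.
#' @export
score_site <- function(m, kmer) {
  stopifnot(inherits(m, "ipwm"))
  codes <- encode_dna(kmer)
  if (length(codes) != m$width)
    stop("score_site: k-mer length ", length(codes), " != matrix width ",
         m$width, call. = FALSE)
  if (anyNA(codes))
    stop("score_site: non-ACGT base in k-mer", call. = FALSE)
  sum(m$weights[cbind(seq_len(m$width), codes)])
}

# DNA string -> integer codes A=1 C=2 G=3 T=4 (NA for anything else)
encode_dna <- function(s) {
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  match(v, DNA_BASES)
}

decode_dna <- function(codes) paste(DNA_BASES[codes], collapse = "")

#' Reverse complement of a DNA string
#' @param s DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# iPWM that scores the reverse complement of a window read on the forward
# strand: rows reversed, A<->T and C<->G columns swapped.
ipwm_revcomp <- function(m) {
  w <- m$weights[rev(seq_len(m$width)), c("T", "G", "C", "A"), drop = FALSE]
  colnames(w) <- DNA_BASES
  ipwm(m$tf, w, m$cell_line, m$r_sequence)
}

#' R_sequence of an iPWM
#'
#' Returns the matrix's mean information content in bits. File metadata takes
#' precedence; otherwise the per-position base frequencies `f` are recovered
#' from the weights under the `w = 2 + log2(f)` convention and the information
#' content is `sum_j (2 + sum_b f_bj log2 f_bj)`.
#'
#' @param m an [ipwm()].
#' @return R_sequence in bits.
#' @export
matrix_r_sequence <- function(m) {
  stopifnot(inherits(m, "ipwm"))
  if (!is.null(m$r_sequence)) return(m$r_sequence)
  if (any(m$weights > 2 + 1e-9))
    stop("matrix_r_sequence: weights exceed 2 bits; frequencies are not ",
         "recoverable and no R_sequence metadata is present", call. = FALSE)
  f <- 2^(m$weights - 2)
  rs <- rowSums(f)
  if (any(abs(rs - 1) > 0.05))
    stop("matrix_r_sequence: weight rows are not log-frequencies ",
         "(row sums deviate from 1) and no R_sequence metadata is present",
         call. = FALSE)
  f <- f / rs
  plogp <- ifelse(f > 0, f * log2(f), 0)
  sum(2 + rowSums(plogp))
}

#' Read an iPWM file
#'
#' The file dialect is one tab-separated header line
#' (`tf`, `cell_line`, optional `r_sequence`) followed by `width` rows of four
#' tab-separated reals (bit weights for A, C, G, T).
#'
#' @param path file path.
#' @return an [ipwm()].
#' @export
read_ipwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("iPWM file: need a header line and at least one weight row",
         call. = FALSE)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 1L || length(hdr) > 3L)
    stop("iPWM file: malformed header at line 1", call. = FALSE)
  r_seq <- NULL
  if (length(hdr) == 3L) {
    r_seq <- suppressWarnings(as.numeric(hdr[3L]))
    if (is.na(r_seq))
      stop("iPWM file: non-numeric r_sequence in header", call. = FALSE)
  }
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != 4L)
      stop("iPWM file: expected 4 columns at line ", i + 1L, call. = FALSE)
  }
  w <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              ncol = 4L, byrow = TRUE)
  bad <- which(apply(w, 1L, function(r) any(is.na(r))))
  if (length(bad))
    stop("iPWM file: non-numeric weight at line ", bad[1L] + 1L, call. = FALSE)
  ipwm(hdr[1L], w, cell_line = if (length(hdr) >= 2L) hdr[2L] else "",
       r_sequence = r_seq)
}

#' Write an iPWM file
#'
#' Inverse of [read_ipwm()]; round-trips bit-exactly.
#'
#' @param m an [ipwm()].
#' @param path output file path.
#' @export
write_ipwm <- function(m, path) {
  stopifnot(inherits(m, "ipwm"))
  hdr <- c(m$tf, m$cell_line,
           if (!is.null(m$r_sequence)) sprintf("%.17g", m$r_sequence))
  body <- apply(m$weights, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(paste(hdr, collapse = "\t"), body), path)
  invisible(path)
}
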