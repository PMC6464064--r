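# Promoter construction, DNase-accessibility masking, and thresholded iPWM
# scanning. A promoter is the 10 kb interval strictly upstream of a TSS;
# in accessibility-aware mode scanning is restricted to its intersection with
# DNase I hypersensitive sites. Both strands are scanned and sites with
# R_i >= threshold_frac * R_sequence are kept (default 0.1, which removes the
# bulk of weak false-positive matches while retaining bona fide weak sites).

#' Construct a promoter upstream of a TSS
#'
#' On the `+` strand the promoter is `[tss - length, tss)`; on the `-` strand
#' it is `[tss, tss + length)`. Both are clamped to the contig bounds, so a TSS
#' close to a contig edge yields a shorter promoter.
#'
#' @param gene_id gene identifier.
#' @param contig contig name.
#' @param tss 0-based TSS position on the contig.
#' @param strand `"+"` or `"-"` (the gene's strand).
#' @param contig_len length of the contig in bp.
#' @param length promoter length in bp (default 10000).
#' @return an object of class `promoter`: gene_id, contig, tss, strand,
#'   start/end (0-based half-open) and `accessible` (NULL until
#'   [restrict_to_accessible()] is applied; NULL means scan the whole
#'   promoter).
#' @export
make_promoter <- function(gene_id, contig, tss, strand, contig_len,
                          length = 10000L) {
  stopifnot(strand %in% c("+", "-"), length >= 1L)
  tss <- as.integer(tss)
  if (tss < 0L || tss > contig_len)
    stop("make_promoter: TSS outside contig", call. = FALSE)
  if (strand == "+") {
    start <- max(0L, tss - as.integer(length)); end <- tss
  } else {
    start <- tss; end <- min(as.integer(contig_len), tss + as.integer(length))
  }
  if (start >= end)
    stop("make_promoter: empty promoter (TSS at contig edge)", call. = FALSE)
  structure(list(gene_id = as.character(gene_id), contig = as.character(contig),
                 tss = tss, strand = strand, start = start, end = end,
                 accessible = NULL),
            class = "promoter")
}

#' @export
print.promoter <- function(x, ...) {
  acc <- if (is.null(x$accessible)) "unmasked"
  else sprintf("%d accessible interval(s)", nrow(x$accessible))
  cat(sprintf("promoter %s %s:[%d,%d) strand %s, TSS %d, %s\n", x$gene_id,
              x$contig, x$start, x$end, x$strand, x$tss, acc))
  invisible(x)
}

#' Restrict a promoter to its accessible (DHS) intervals
#'
#' Intersects the promoter with a set of DNase I hypersensitive site
#' intervals; overlapping DHSs are merged first. An empty intersection is
#' valid and yields a promoter in which scanning finds no sites.
#'
#' @param p a [make_promoter()] object.
#' @param dhs interval data.frame (contig, start, end; 0-based half-open).
#' @return the promoter with its `accessible` field set (sorted,
#'   non-overlapping, within the promoter interval).
#' @export
restrict_to_accessible <- function(p, dhs) {
  stopifnot(inherits(p, "promoter"))
  prom <- genomic_intervals(p$contig, p$start, p$end)
  p$accessible <- intersect_intervals(prom, dhs)
  p
}

# Scores of all width-L windows of an integer-coded sequence against a weight
# matrix; windows containing non-ACGT bases score NA.
score_windows <- function(weights, codes) {
  L <- nrow(weights)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    wj <- unname(weights[j, ])[codes[j:(j + n - 1L)]]
    s <- s + wj   # NA codes propagate -> window skipped
  }
  s
}

#' Scan a promoter for binding sites of one factor
#'
#' Slides a width-L window over every accessible subinterval of the promoter
#' (over the whole promoter when no accessibility mask is set), scoring the
#' forward k-mer on the `+` strand and its reverse complement on the `-`
#' strand. Sites with `R_i >= threshold_frac * R_sequence` are kept; a site
#' must lie fully inside one accessible subinterval. Windows containing
#' non-ACGT bases are skipped.
#'
#' @param m an [ipwm()].
#' @param p a [make_promoter()] object (optionally with an accessibility
#'   mask).
#' @param genome named character vector or `DNAStringSet`.
#' @param threshold_frac fraction of R_sequence used as the R_i threshold
#'   (default 0.1).
#' @return data.frame of binding sites with columns `tf`, `contig`, `start`
#'   (0-based), `strand`, `sequence` (as read on the site's strand), `r_i`
#'   (bits), sorted by start then strand (`+` before `-`).
#' @export
scan_promoter <- function(m, p, genome, threshold_frac = 0.1) {
  stopifnot(inherits(m, "ipwm"), inherits(p, "promoter"))
  rs <- matrix_r_sequence(m)
  threshold <- threshold_frac * rs
  regions <- if (is.null(p$accessible))
    data.frame(contig = p$contig, start = p$start, end = p$end)
  else p$accessible
  mm <- ipwm_revcomp(m)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    s0 <- regions$start[i]; e0 <- regions$end[i]
    if (e0 - s0 < m$width) next
    seq_fwd <- get_sequence(genome, p$contig, s0, e0, "+")
    codes <- encode_dna(seq_fwd)
    fwd <- score_windows(m$weights, codes)
    rev <- score_windows(mm$weights, codes)
    starts <- s0 + seq_along(fwd) - 1L
    keep_f <- which(!is.na(fwd) & fwd >= threshold)
    keep_r <- which(!is.na(rev) & rev >= threshold)
    if (length(keep_f))
      out[[length(out) + 1L]] <- data.frame(
        tf = m$tf, contig = p$contig, start = starts[keep_f], strand = "+",
        sequence = substring(seq_fwd, keep_f, keep_f + m$width - 1L),
        r_i = fwd[keep_f], stringsAsFactors = FALSE)
    if (length(keep_r))
      out[[length(out) + 1L]] <- data.frame(
        tf = m$tf, contig = p$contig, start = starts[keep_r], strand = "-",
        sequence = vapply(keep_r, function(k)
          revcomp(substring(seq_fwd, k, k + m$width - 1L)), character(1)),
        r_i = rev[keep_r], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_sites())
  out <- do.call(rbind, out)
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_sites <- function() {
  data.frame(tf = character(), contig = character(), start = integer(),
             strand = character(), sequence = character(), r_i = numeric(),
             stringsAsFactors = FALSE)
}

#' Scan a promoter with a panel of iPWMs
#'
#' Convenience wrapper running [scan_promoter()] for each matrix and
#' concatenating the results.
#'
#' @inheritParams scan_promoter
#' @param ipwms list of [ipwm()] objects.
#' @return combined site data.frame sorted by start then strand.
#' @export
scan_panel <- function(ipwms, p, genome, threshold_frac = 0.1) {
  out <- do.call(rbind, lapply(ipwms, scan_promoter, p = p, genome = genome,
                               threshold_frac = threshold_frac))
  if (is.null(out) || nrow(out) == 0L) return(empty_sites())
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
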