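# Positive/negative gene labeling from perturbation screens.
#
# CRISPR (guide coefficient) rule -- a gene is a positive target when
#   (1) the per-guide fold changes 10^coefficient are consistently > 1 or
#       consistently < 1 (a zero coefficient breaks consistency),
#   (2) the mean per-guide fold change exceeds epsilon (up-regulated) or is
#       below 1/epsilon (down-regulated), matching the shared direction, and
#   (3) the 10 kb promoter upstream of any TSS of the gene overlaps a merged
#       ChIP-seq peak of the factor.
# A gene whose coefficients are all exactly zero is a negative (non-target).
# Everything else is unlabeled.
#
# siRNA rule -- positive when the knockdown p-value is <= alpha (0.01) and a
# promoter overlaps a ChIP-seq peak; genes with p > alpha are negatives;
# significant genes without peak support stay unlabeled.

#' Labeling configuration
#'
#' @param epsilon minimum mean fold-change threshold for CRISPR positives
#'   (> 1; the analyses use 1.01, 1.05 and 1.1).
#' @param alpha p-value threshold for siRNA positives (default 0.01).
#' @param promoter_length promoter length in bp (default 10000).
#' @return a list of class `label_config`.
#' @export
label_config <- function(epsilon = 1.05, alpha = 0.01,
                         promoter_length = 10000L) {
  stopifnot(epsilon > 1, alpha > 0, alpha < 1, promoter_length >= 1)
  structure(list(epsilon = epsilon, alpha = alpha,
                 promoter_length = as.integer(promoter_length)),
            class = "label_config")
}

#' Merge ChIP-seq peak sets
#'
#' Coalesces the union of several peak interval sets; overlapping and
#' book-ended peaks become single intervals.
#'
#' @param peak_sets list of interval data.frames.
#' @return merged, sorted interval data.frame.
#' @export
merge_peaks <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  merge_intervals(do.call(rbind, peak_sets))
}

# promoters: data.frame gene_id/contig/start/end (0-based), possibly several
# rows per gene (one per annotated TSS).
promoter_peak_overlap <- function(promoters, peaks) {
  validate_intervals(promoters, "promoter")
  hit <- overlaps_any(promoters, peaks)
  tapply(hit, promoters$gene_id, any)
}

#' Label TF target genes from a CRISPR guide-coefficient matrix
#'
#' @param K numeric matrix, genes x guides, of log10 fold-change coefficients.
#' @param cfg a [label_config()].
#' @param peaks merged ChIP-seq peak intervals (see [merge_peaks()]).
#' @param promoters data.frame with columns `gene_id`, `contig`, `start`,
#'   `end` (0-based half-open promoter intervals; several rows per gene
#'   allowed, one per TSS). Every gene in `K` must have at least one row.
#' @return a `labeled_set`: list with `positives`, `negatives`, `unlabeled`
#'   (character vectors), `provenance` (per-gene rule trace) and
#'   `ref_positive` (the positive with the largest mean coefficient, used as
#'   the reference for class balancing).
#' @export
crispr_labels <- function(K, cfg, peaks, promoters) {
  stopifnot(is.matrix(K), inherits(cfg, "label_config"))
  genes <- rownames(K)
  missing <- setdiff(genes, promoters$gene_id)
  if (length(missing))
    stop("crispr_labels: no promoter record for gene '", missing[1L], "'",
         call. = FALSE)
  overlap <- promoter_peak_overlap(promoters, peaks)
  fc <- 10^K
  all_up <- apply(K, 1L, function(r) all(r > 0))
  all_dn <- apply(K, 1L, function(r) all(r < 0))
  all_zero <- apply(K, 1L, function(r) all(r == 0))
  mean_fc <- rowMeans(fc)
  mean_coef <- rowMeans(K)
  de <- (all_up & mean_fc > cfg$epsilon) | (all_dn & mean_fc < 1 / cfg$epsilon)
  has_peak <- as.logical(overlap[genes])
  pos <- de & has_peak
  neg <- all_zero
  label <- ifelse(pos, "positive", ifelse(neg, "negative", "unlabeled"))
  prov <- data.frame(
    gene = genes,
    consistent = all_up | all_dn,
    direction = ifelse(all_up, "up", ifelse(all_dn, "down", "mixed")),
    mean_fold_change = mean_fc,
    mean_coefficient = mean_coef,
    peak_overlap = has_peak,
    label = label,
    stringsAsFactors = FALSE, row.names = NULL)
  ref <- if (any(pos)) genes[pos][which.max(mean_coef[pos])] else NA_character_
  structure(list(positives = genes[pos], negatives = genes[neg],
                 unlabeled = genes[!pos & !neg], provenance = prov,
                 ref_positive = ref, epsilon = cfg$epsilon),
            class = "labeled_set")
}

#' Balance negatives by expression-profile dissimilarity
#'
#' Computes the Bray-Curtis similarity between every negative's tissue-wide
#' expression profile and that of the reference positive (the positive with
#' the largest mean coefficient), then keeps the `|positives|` negatives with
#' the smallest similarity. Ties are broken by gene id.
#'
#' @param ls a `labeled_set` from [crispr_labels()].
#' @param expr expression matrix (genes x tissues) covering the reference
#'   positive and all negatives.
#' @return the labeled set with `negatives` reduced to `|positives|` genes and
#'   a `balance` data.frame recording each candidate's similarity.
#' @export
balance_negatives <- function(ls, expr) {
  stopifnot(inherits(ls, "labeled_set"), is.matrix(expr))
  np <- length(ls$positives)
  if (length(ls$negatives) < np)
    stop("balance_negatives: fewer negatives than positives", call. = FALSE)
  if (length(ls$negatives) == np) return(ls)
  ref <- ls$ref_positive
  if (is.na(ref) || !(ref %in% rownames(expr)))
    stop("balance_negatives: reference positive absent from expression matrix",
         call. = FALSE)
  missing <- setdiff(ls$negatives, rownames(expr))
  if (length(missing))
    stop("balance_negatives: negative '", missing[1L],
         "' absent from expression matrix", call. = FALSE)
  negs <- sort(ls$negatives)
  sims <- vapply(negs, function(g) bray_curtis(expr[ref, ], expr[g, ]),
                 numeric(1))
  ord <- order(sims, negs)
  keep <- negs[ord][seq_len(np)]
  ls$balance <- data.frame(gene = negs[ord], similarity = sims[ord],
                           kept = negs[ord] %in% keep,
                           stringsAsFactors = FALSE, row.names = NULL)
  ls$negatives <- keep
  ls
}

#' Label TF target genes from siRNA knockdown p-values
#'
#' @param P named numeric vector of per-gene knockdown p-values.
#' @param peaks merged ChIP-seq peak intervals.
#' @param promoters promoter table as in [crispr_labels()].
#' @param cfg a [label_config()] (uses `alpha`).
#' @return a `labeled_set` (no reference positive; siRNA sets are not
#'   balanced by default).
#' @export
sirna_labels <- function(P, peaks, promoters, cfg = label_config()) {
  stopifnot(is.numeric(P), !is.null(names(P)), inherits(cfg, "label_config"))
  genes <- names(P)
  missing <- setdiff(genes, promoters$gene_id)
  if (length(missing))
    stop("sirna_labels: no promoter record for gene '", missing[1L], "'",
         call. = FALSE)
  overlap <- promoter_peak_overlap(promoters, peaks)
  has_peak <- as.logical(overlap[genes])
  pos <- P <= cfg$alpha & has_peak
  neg <- P > cfg$alpha
  label <- ifelse(pos, "positive", ifelse(neg, "negative", "unlabeled"))
  prov <- data.frame(gene = genes, p_value = unname(P),
                     peak_overlap = has_peak, label = label,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(positives = genes[pos], negatives = genes[neg],
                 unlabeled = genes[!pos & !neg], provenance = prov,
                 ref_positive = NA_character_, alpha = cfg$alpha),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("labeled set: %d positives, %d negatives, %d unlabeled\n",
              length(x$positives), length(x$negatives), length(x$unlabeled)))
  invisible(x)
}
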