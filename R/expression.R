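# Tissue-wide expression profiles and their comparison. A gene's profile is
# the vector of its median expression (RPKM) across the tissue panel
# (53 tissues in GTEx v6p). Profiles are compared with the Bray-Curtis
# similarity, which is bounded in [0, 1], equals 1 iff the profiles are
# identical, and is dominated by the tissues with the largest expression
# values -- properties that rank-based or centered correlations lack.

#' Bray-Curtis similarity between two expression profiles
#'
#' For non-negative profiles `a` and `b` over the same tissue panel,
#' \deqn{sim(a, b) = 1 - \sum_i |a_i - b_i| / \sum_i (a_i + b_i),}
#' with the special case `sim = 1` when both profiles are identically zero.
#'
#' @param a,b non-negative numeric vectors over the same tissues. Names, when
#'   present on both, must agree.
#' @return similarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b))
    stop("bray_curtis: profiles have different lengths", call. = FALSE)
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("bray_curtis: mismatched tissue labels", call. = FALSE)
  if (any(a < 0) || any(b < 0) || any(!is.finite(a)) || any(!is.finite(b)))
    stop("bray_curtis: profiles must be finite and non-negative", call. = FALSE)
  tot <- sum(a) + sum(b)
  if (tot == 0) return(1)
  1 - sum(abs(a - b)) / tot
}

#' Rank genes by expression-profile similarity to a query gene
#'
#' Computes the Bray-Curtis similarity between the query gene's tissue-wide
#' profile and every other gene's, and returns the top `k` in descending
#' similarity. Ties are broken by gene id (lexicographic) for determinism.
#'
#' @param m numeric matrix, genes in rows, tissues in columns.
#' @param gene query gene id (must be a rowname of `m`).
#' @param k number of genes to return (`0 <= k <= nrow(m) - 1`).
#' @return data.frame with columns `gene`, `similarity`, `rank`.
#' @export
rank_similar <- function(m, gene, k) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (!(gene %in% rownames(m)))
    stop("rank_similar: gene '", gene, "' not in matrix", call. = FALSE)
  others <- setdiff(rownames(m), gene)
  if (k > length(others))
    stop("rank_similar: k exceeds number of other genes", call. = FALSE)
  if (k == 0L)
    return(data.frame(gene = character(), similarity = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  q <- m[gene, ]
  sims <- vapply(others, function(g) bray_curtis(q, m[g, ]), numeric(1))
  ord <- order(-sims, others)
  sel <- ord[seq_len(k)]
  data.frame(gene = others[sel], similarity = sims[sel], rank = seq_len(k),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect a target gene set with a most-similar-genes list
#'
#' Reports which targets appear among the ranked most-similar genes (e.g. the
#' 500 genes most similar to the factor itself), with their 1-based ranks.
#'
#' @param targets character vector of target gene ids.
#' @param ranked data.frame from [rank_similar()].
#' @return data.frame with columns `gene`, `similarity`, `rank`, restricted to
#'   the intersection, in rank order.
#' @export
intersect_targets_with_similar <- function(targets, ranked) {
  stopifnot(all(c("gene", "rank") %in% names(ranked)))
  out <- ranked[ranked$gene %in% targets, , drop = FALSE]
  rownames(out) <- NULL
  out
}
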