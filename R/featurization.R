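# Featurization of cluster organization. Each cluster contributes a block:
# (1) distance to the TSS, (2) cluster length, (3) cluster information
# content, and per factor in the panel (4) site count, (5) strong-site count
# (R_i strictly greater than that factor's R_sequence), (6) summed R_i and
# (7) summed strong-site R_i. In homotypic (single-factor) mode feature 6
# duplicates feature 3 and is dropped, giving a 6-value block. Genes are
# brought to a common width by padding all-zero "null clusters" at the distal
# (5') end.

#' Feature-panel description
#'
#' @param tf character vector of factor names.
#' @param r_sequence numeric vector of matching R_sequence values (bits).
#' @return data.frame with columns `tf`, `r_sequence`.
#' @export
feature_panel <- function(tf, r_sequence) {
  stopifnot(length(tf) == length(r_sequence), !anyDuplicated(tf))
  data.frame(tf = as.character(tf), r_sequence = as.numeric(r_sequence),
             stringsAsFactors = FALSE)
}

#' Panel from a list of iPWMs
#' @param ipwms list of [ipwm()] objects.
#' @return a [feature_panel()].
#' @export
panel_from_ipwms <- function(ipwms) {
  feature_panel(vapply(ipwms, `[[`, character(1), "tf"),
                vapply(ipwms, matrix_r_sequence, numeric(1)))
}

block_feature_names <- function(panel, mode) {
  base <- c("dist_tss", "length", "info")
  if (mode == "homotypic") {
    stopifnot(nrow(panel) == 1L)
    c(base, "n_sites", "n_strong", "strong_info")
  } else {
    c(base, as.vector(t(outer(panel$tf,
                              c("n_sites", "n_strong", "info", "strong_info"),
                              paste, sep = "."))))
  }
}

#' Featurize one gene's clusters
#'
#' Produces one feature block per cluster, ordered 5' to 3' along the promoter
#' strand (most distal cluster first), so that padding added later at the 5'
#' end represents missing distal clusters.
#'
#' @param clusters list of clusters from [idbc()] (one promoter).
#' @param tss 0-based TSS position.
#' @param panel a [feature_panel()].
#' @param mode `"heterotypic"` (block of `3 + 4K` values for a K-factor
#'   panel) or `"homotypic"` (block of 6 values; requires a 1-factor panel).
#' @param strand promoter strand, `"+"` or `"-"`; controls the 5'-to-3'
#'   ordering of clusters.
#' @return numeric matrix with one row per cluster (0-row matrix for a gene
#'   without clusters); columns named per block feature.
#' @export
featurize_gene <- function(clusters, tss, panel, mode = c("heterotypic",
                                                          "homotypic"),
                           strand = "+") {
  mode <- match.arg(mode)
  cn <- block_feature_names(panel, mode)
  if (length(clusters) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = length(cn),
                  dimnames = list(NULL, cn)))
  starts <- vapply(clusters, function(cl) cl$span[1L], numeric(1))
  ord <- if (strand == "+") order(starts) else order(-starts)
  clusters <- clusters[ord]
  rows <- lapply(clusters, function(cl) {
    st <- cluster_stats(cl, tss)
    unknown <- setdiff(unique(cl$sites$tf), panel$tf)
    if (length(unknown))
      stop("featurize_gene: site for unknown factor '", unknown[1L], "'",
           call. = FALSE)
    blocks <- lapply(seq_len(nrow(panel)), function(i) {
      s <- cl$sites[cl$sites$tf == panel$tf[i], , drop = FALSE]
      strong <- s$r_i > panel$r_sequence[i]   # strict inequality
      v <- c(n_sites = nrow(s), n_strong = sum(strong),
             info = sum(s$r_i), strong_info = sum(s$r_i[strong]))
      if (mode == "homotypic") v[c("n_sites", "n_strong", "strong_info")]
      else v
    })
    c(st["distance_to_tss"], st["length"], st["info_content"],
      unlist(blocks))
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(NULL, cn)
  out
}

#' Assemble per-gene cluster features into a fixed-width matrix
#'
#' Determines the maximum cluster count `M_max` over the dataset (floor 1) and
#' left-pads genes with fewer clusters with all-zero null-cluster blocks at
#' the distal (5') slots. At prediction time pass the training `m_max`: genes
#' with more clusters keep their `m_max` most TSS-proximal clusters.
#'
#' @param features named list of per-gene matrices from [featurize_gene()].
#' @param m_max optional fixed cluster-slot count (training `M_max`).
#' @return numeric matrix, genes x (`m_max` * blocksize); columns named
#'   `c<slot>.<feature>`; attribute `m_max` records the slot count.
#' @export
assemble_matrix <- function(features, m_max = NULL) {
  stopifnot(is.list(features), length(features) > 0L)
  bs <- unique(vapply(features, ncol, integer(1)))
  if (length(bs) != 1L)
    stop("assemble_matrix: inconsistent block sizes", call. = FALSE)
  cn <- colnames(features[[1L]])
  counts <- vapply(features, nrow, integer(1))
  if (is.null(m_max)) m_max <- max(1L, max(counts))
  rows <- lapply(features, function(f) {
    if (nrow(f) > m_max)            # keep the TSS-proximal (last) slots
      f <- f[(nrow(f) - m_max + 1L):nrow(f), , drop = FALSE]
    pad <- m_max - nrow(f)
    v <- c(rep(0, pad * bs), t(f))
    v
  })
  out <- do.call(rbind, rows)
  colnames(out) <- paste0("c", rep(seq_len(m_max), each = bs), ".",
                          rep(cn, m_max))
  rownames(out) <- names(features)
  attr(out, "m_max") <- m_max
  out
}

#' Map assembled-matrix columns back to (slot, feature)
#'
#' @param x matrix from [assemble_matrix()].
#' @return data.frame with columns `column`, `slot`, `feature`.
#' @export
feature_schema <- function(x) {
  cn <- colnames(x)
  m <- regmatches(cn, regexec("^c([0-9]+)\\.(.*)$", cn))
  data.frame(column = cn,
             slot = as.integer(vapply(m, `[[`, character(1), 2L)),
             feature = vapply(m, `[[`, character(1), 3L),
             stringsAsFactors = FALSE)
}
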