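# Information density-based clustering (IDBC). Sites seed intervals of radius
# d around their centers; transitively overlapping seeds are merged into
# groups, and a group is emitted as a cluster when the summed individual
# information of its member sites reaches the threshold I. For heterotypic
# panels the default I is the sum of R_sequence over the panel (939 bits for
# the 94-matrix panel used on real data); for homotypic runs it is the single
# matrix's R_sequence.

#' IDBC parameters
#'
#' @param d radius of the initial per-site clusters in bp (default 25,
#'   determined empirically on promoter data).
#' @param I minimum total information content of an emitted cluster, in bits.
#' @return a list with elements `d` and `I`.
#' @export
idbc_params <- function(d = 25, I) {
  stopifnot(d >= 0, I >= 0)
  list(d = as.numeric(d), I = as.numeric(I))
}

#' Default information threshold for a panel
#'
#' The heterotypic default is the sum of R_sequence values over the panel; for
#' a single-matrix (homotypic) panel this reduces to that matrix's R_sequence.
#'
#' @param ipwms list of [ipwm()] objects.
#' @return threshold I in bits.
#' @export
default_information_threshold <- function(ipwms) {
  sum(vapply(ipwms, matrix_r_sequence, numeric(1)))
}

site_centers <- function(sites) {
  L <- nchar(sites$sequence)
  sites$start + L %/% 2L
}

#' Cluster binding sites by information density
#'
#' Deterministic reconstruction of IDBC: (1) seed the interval
#' `[center - d, center + d)` around each site center
#' (`center = start + floor(L/2)`); (2) transitively merge overlapping seeds;
#' (3) the cluster span is `[min site start, max site end)` over the group's
#' members; (4) emit groups whose summed `r_i` is at least `I` (inclusive),
#' sorted by span start.
#'
#' @param sites binding-site data.frame (one promoter's sites, any order).
#' @param params an [idbc_params()] list.
#' @return list of clusters; each is a list with `span` (c(start, end)),
#'   `sites` (member rows sorted by start), `info_content` (bits) and
#'   `length` (bp).
#' @export
idbc <- function(sites, params) {
  if (is.null(sites) || nrow(sites) == 0L) return(list())
  stopifnot(all(c("start", "sequence", "r_i") %in% names(sites)))
  ord <- order(site_centers(sites))
  sites <- sites[ord, , drop = FALSE]
  centers <- site_centers(sites)
  # seeds [c-d, c+d) overlap iff consecutive centers differ by < 2d
  newgrp <- c(TRUE, diff(centers) >= 2 * params$d)
  grp <- cumsum(newgrp)
  out <- list()
  for (g in unique(grp)) {
    mem <- sites[grp == g, , drop = FALSE]
    mem <- mem[order(mem$start, match(mem$strand, c("+", "-"))), , drop = FALSE]
    rownames(mem) <- NULL
    info <- sum(mem$r_i)
    if (info >= params$I) {
      span <- c(min(mem$start), max(mem$start + nchar(mem$sequence)))
      out[[length(out) + 1L]] <- structure(
        list(span = span, sites = mem, info_content = info,
             length = span[2L] - span[1L]),
        class = "tfbs_cluster")
    }
  }
  out[order(vapply(out, function(cl) cl$span[1L], numeric(1)))]
}

#' Summary statistics of a cluster relative to a TSS
#'
#' The distance to the TSS uses the nearest cluster edge; it is 0 when the TSS
#' lies inside the cluster span.
#'
#' @param cl a cluster from [idbc()].
#' @param tss 0-based TSS position.
#' @return named numeric vector: `distance_to_tss` (bp), `length` (bp),
#'   `info_content` (bits).
#' @export
cluster_stats <- function(cl, tss) {
  stopifnot(inherits(cl, "tfbs_cluster"))
  d <- if (tss >= cl$span[1L] && tss < cl$span[2L]) 0
  else min(abs(tss - cl$span[1L]), abs(tss - cl$span[2L]))
  c(distance_to_tss = d, length = cl$length, info_content = cl$info_content)
}

#' @export
print.tfbs_cluster <- function(x, ...) {
  cat(sprintf("TFBS cluster [%d,%d): %d site(s), %.2f bits\n", x$span[1L],
              x$span[2L], nrow(x$sites), x$info_content))
  invisible(x)
}
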