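# In-silico variant analysis. Single-nucleotide substitutions are applied to
# the promoter sequence, the promoter is re-scanned, re-clustered,
# re-featurized under the training cluster-slot count and re-classified.
# Every wild-type cluster gets a fate: "retained" when a variant cluster that
# still passes the information threshold overlaps its span, otherwise
# "abolished". Sites falling below the scan threshold simply vanish from
# clustering, mirroring how a damaging allele can erase both a site and --
# when the residual information is insufficient -- its whole cluster.

#' Apply single-nucleotide variants to a sequence
#'
#' @param sequence DNA string covering an interval starting at `offset`
#'   (0-based) on its contig.
#' @param offset 0-based start of the sequence on the contig.
#' @param variants data.frame with columns `pos` (0-based), `ref`, `alt`
#'   (and optionally `id`, `contig`).
#' @return mutated sequence of the same length. A reference-allele mismatch
#'   raises an error naming the position (this guards against assembly or
#'   coordinate mix-ups).
#' @export
apply_variants <- function(sequence, offset, variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(sequence)
  validate_variants(variants)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i] - offset
    if (p < 0L || p >= length(chars))
      stop("apply_variants: variant at position ", variants$pos[i],
           " outside the sequence interval", call. = FALSE)
    if (toupper(chars[p + 1L]) != toupper(variants$ref[i]))
      stop("apply_variants: reference mismatch at position ", variants$pos[i],
           " (expected ", variants$ref[i], ", sequence has ", chars[p + 1L],
           ")", call. = FALSE)
    chars[p + 1L] <- toupper(variants$alt[i])
  }
  paste(chars, collapse = "")
}

#' Pair wild-type and variant binding sites and report R_i changes
#'
#' Sites are paired by factor, strand and span overlap (a mutation may create
#' a better-scoring window at a shifted offset, so pairing is by overlap, not
#' exact coordinates; the nearest overlapping site wins). Unpaired wild sites
#' are reported as `lost`, unpaired variant sites as `gained`.
#'
#' @param wild,variant binding-site data.frames from the same promoter and
#'   panel.
#' @return data.frame with columns `tf`, `strand`, `status`
#'   (`paired`/`lost`/`gained`), wild and variant start/sequence/r_i, and
#'   `delta_r_i`.
#' @export
site_delta <- function(wild, variant) {
  used <- rep(FALSE, nrow(variant))
  rows <- list()
  for (i in seq_len(nrow(wild))) {
    w <- wild[i, ]
    wL <- nchar(w$sequence)
    cand <- which(!used & variant$tf == w$tf & variant$strand == w$strand &
                  variant$start < w$start + wL &
                  variant$start + nchar(variant$sequence) > w$start)
    if (length(cand)) {
      j <- cand[which.min(abs(variant$start[cand] - w$start))]
      used[j] <- TRUE
      v <- variant[j, ]
      rows[[length(rows) + 1L]] <- data.frame(
        tf = w$tf, strand = w$strand, status = "paired",
        wild_start = w$start, wild_sequence = w$sequence, wild_r_i = w$r_i,
        variant_start = v$start, variant_sequence = v$sequence,
        variant_r_i = v$r_i, delta_r_i = v$r_i - w$r_i,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        tf = w$tf, strand = w$strand, status = "lost",
        wild_start = w$start, wild_sequence = w$sequence, wild_r_i = w$r_i,
        variant_start = NA_integer_, variant_sequence = NA_character_,
        variant_r_i = NA_real_, delta_r_i = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  for (j in which(!used)) {
    v <- variant[j, ]
    rows[[length(rows) + 1L]] <- data.frame(
      tf = v$tf, strand = v$strand, status = "gained",
      wild_start = NA_integer_, wild_sequence = NA_character_,
      wild_r_i = NA_real_,
      variant_start = v$start, variant_sequence = v$sequence,
      variant_r_i = v$r_i, delta_r_i = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(tf = character(), strand = character(),
                      status = character(), wild_start = integer(),
                      wild_sequence = character(), wild_r_i = numeric(),
                      variant_start = integer(),
                      variant_sequence = character(),
                      variant_r_i = numeric(), delta_r_i = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

spans_overlap <- function(a, b) a[1L] < b[2L] && b[1L] < a[2L]

#' Re-evaluate a promoter after in-silico variants
#'
#' Runs the full pipeline on the wild-type and mutated promoter: scan with the
#' panel, cluster with IDBC, featurize (using the model's training slot count
#' when a model is supplied) and re-classify. Reports per-site R_i changes,
#' per-wild-cluster fates, gained clusters and the classifier output before
#' and after.
#'
#' @param p a [make_promoter()] object (apply any accessibility mask before
#'   calling).
#' @param variants variant data.frame (0-based `pos`, `ref`, `alt`); an empty
#'   set yields a report identical to wild type.
#' @param ipwms list of [ipwm()] objects (the scan panel).
#' @param params [idbc_params()].
#' @param genome named character vector or `DNAStringSet`.
#' @param model optional `regcl_model`; when supplied, predictions before and
#'   after mutation are reported.
#' @param mode featurization mode, `"homotypic"` or `"heterotypic"`.
#' @param threshold_frac scan threshold fraction of R_sequence (default 0.1).
#' @return a `mutation_report`: `sites` (from [site_delta()]), `cluster_fates`
#'   (data.frame span/info/fate per wild cluster), `gained_clusters`,
#'   `wild_clusters`, `variant_clusters`, and `prediction`
#'   (wild/variant score and class, when a model is given).
#' @export
reevaluate_promoter <- function(p, variants, ipwms, params, genome,
                                model = NULL,
                                mode = c("homotypic", "heterotypic"),
                                threshold_frac = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "promoter"))
  panel <- panel_from_ipwms(ipwms)

  run <- function(gen) {
    sites <- scan_panel(ipwms, p, gen, threshold_frac = threshold_frac)
    clusters <- idbc(sites, params)
    list(sites = sites, clusters = clusters)
  }
  wild <- run(genome)

  mut_genome <- genome
  if (!is.null(variants) && nrow(variants) > 0L) {
    if (methods::is(mut_genome, "DNAStringSet")) {
      mut_genome <- stats::setNames(as.character(mut_genome),
                                    names(mut_genome))
    }
    ctg <- mut_genome[[p$contig]]
    mut_genome[[p$contig]] <- apply_variants(ctg, 0L, variants)
  }
  var <- run(mut_genome)

  fates <- if (length(wild$clusters)) data.frame(
    cluster = seq_along(wild$clusters),
    span_start = vapply(wild$clusters, function(cl) cl$span[1L], numeric(1)),
    span_end = vapply(wild$clusters, function(cl) cl$span[2L], numeric(1)),
    wild_info = vapply(wild$clusters, `[[`, numeric(1), "info_content"),
    fate = vapply(wild$clusters, function(cl) {
      hit <- any(vapply(var$clusters, function(v)
        spans_overlap(cl$span, v$span), logical(1)))
      if (hit) "retained" else "abolished"
    }, character(1)),
    stringsAsFactors = FALSE)
  else data.frame(cluster = integer(), span_start = numeric(),
                  span_end = numeric(), wild_info = numeric(),
                  fate = character(), stringsAsFactors = FALSE)

  gained <- Filter(function(v)
    !any(vapply(wild$clusters, function(cl) spans_overlap(cl$span, v$span),
                logical(1))), var$clusters)

  prediction <- NULL
  if (!is.null(model)) {
    feat <- function(cl) {
      f <- featurize_gene(cl, p$tss, panel, mode = mode, strand = p$strand)
      assemble_matrix(stats::setNames(list(f), p$gene_id),
                      m_max = model$m_max)
    }
    sw <- predict_score(model, feat(wild$clusters))
    sv <- predict_score(model, feat(var$clusters))
    prediction <- data.frame(state = c("wild", "variant"),
                             score = c(sw, sv),
                             class = as.integer(c(sw, sv) >= 0.5),
                             stringsAsFactors = FALSE)
  }

  structure(list(sites = site_delta(wild$sites, var$sites),
                 cluster_fates = fates,
                 gained_clusters = gained,
                 wild_clusters = wild$clusters,
                 variant_clusters = var$clusters,
                 prediction = prediction),
            class = "mutation_report")
}

#' @export
print.mutation_report <- function(x, ...) {
  cat(sprintf("mutation report: %d wild cluster(s), %d abolished, %d gained\n",
              nrow(x$cluster_fates),
              sum(x$cluster_fates$fate == "abolished"),
              length(x$gained_clusters)))
  if (!is.null(x$prediction))
    cat(sprintf("prediction: wild %d (%.2f) -> variant %d (%.2f)\n",
                x$prediction$class[1L], x$prediction$score[1L],
                x$prediction$class[2L], x$prediction$score[2L]))
  invisible(x)
}
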