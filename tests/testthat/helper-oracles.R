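# Shared fixtures and independent oracles for the test suite. The oracles
# deliberately re-derive results by brute force (full window enumeration,
# transitive-closure grouping, direct trapezoid integration) so they stay
# independent of the code paths they check.

# Two-position toy matrix: position 1 favours A, position 2 favours C;
# metadata R_sequence fixed at 4 bits.
toy2_ipwm <- function() {
  ipwm("TOY2", rbind(c(2, -1, -1, -1), c(-1, 2, -1, -1)), r_sequence = 4)
}

# Brute-force promoter scan: enumerate every window on both strands in every
# accessible region, score with score_site, filter by threshold.
brute_scan <- function(m, p, genome, threshold_frac = 0.1) {
  rs <- matrix_r_sequence(m)
  thr <- threshold_frac * rs
  regions <- if (is.null(p$accessible))
    data.frame(contig = p$contig, start = p$start, end = p$end)
  else p$accessible
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    s0 <- regions$start[i]; e0 <- regions$end[i]
    if (e0 - s0 < m$width) next
    for (st in s0:(e0 - m$width)) {
      kmer <- get_sequence(genome, p$contig, st, st + m$width, "+")
      if (grepl("[^ACGT]", kmer)) next
      fwd <- score_site(m, kmer)
      if (fwd >= thr)
        rows[[length(rows) + 1L]] <- data.frame(
          tf = m$tf, contig = p$contig, start = st, strand = "+",
          sequence = kmer, r_i = fwd, stringsAsFactors = FALSE)
      rc <- revcomp(kmer)
      rev <- score_site(m, rc)
      if (rev >= thr)
        rows[[length(rows) + 1L]] <- data.frame(
          tf = m$tf, contig = p$contig, start = st, strand = "-",
          sequence = rc, r_i = rev, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(regcl:::empty_sites())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Transitive-closure oracle for IDBC grouping: connect sites whose centers
# are within 2d, take connected components.
brute_idbc_groups <- function(sites, d) {
  n <- nrow(sites)
  centers <- sites$start + nchar(sites$sequence) %/% 2L
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(centers[i] - centers[j]) < 2 * d && grp[i] != grp[j]) {
        grp[grp == max(grp[i], grp[j])] <- min(grp[i], grp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, sort(unique(grp)))
}

# Random single-base "sites" on one contig (width-1 sequences make the site
# center equal its start).
random_sites <- function(n, span = 1000L, max_ri = 10) {
  data.frame(tf = "T1", contig = "chr",
             start = sample.int(span, n, replace = TRUE), strand = "+",
             sequence = sample(c("A", "C", "G", "T"), n, replace = TRUE),
             r_i = runif(n, 0, max_ri), stringsAsFactors = FALSE)
}

# Direct trapezoid AUC over a score vector (threshold sweep oracle).
trapezoid_auc <- function(scores, y) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Small simulated study reused by several files.
small_study_config <- function(seed = 7L) {
  sim_config(seed = seed, n_genes = 24L, n_positives = 12L,
             promoter_length = 4000L, clusters_per_positive = 2L)
}

# A complement helper for building genome-frame variants against a site.
comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

# Variants (genome frame, 0-based pos) knocking out a planted site.
# Greedily substitutes bases so that the BETTER of the two strand readings of
# the site window drops fastest: a single "worst base" substitution in a
# near-palindromic motif can strengthen the opposite-strand reading, so each
# round evaluates both readings of every candidate substitution.
knockout_variant <- function(m, site, contig, id = "ko", n_hits = 3L) {
  L <- nchar(site$sequence)
  gseq <- if (site$strand == "+") site$sequence else revcomp(site$sequence)
  chars <- strsplit(gseq, "", fixed = TRUE)[[1L]]
  both <- function(v) max(score_site(m, paste(v, collapse = "")),
                          score_site(m, revcomp(paste(v, collapse = ""))))
  mutated <- integer(0)
  out <- list()
  for (k in seq_len(min(n_hits, L))) {
    best <- NULL
    for (p in setdiff(seq_len(L), mutated)) {
      for (b in setdiff(regcl:::DNA_BASES, chars[p])) {
        cand <- chars; cand[p] <- b
        val <- both(cand)
        if (is.null(best) || val < best$val) best <- list(p = p, b = b,
                                                          val = val)
      }
    }
    out[[k]] <- data.frame(id = sprintf("%s_%d", id, k), contig = contig,
                           pos = site$start + best$p - 1L,
                           ref = chars[best$p], alt = best$b,
                           stringsAsFactors = FALSE)
    chars[best$p] <- best$b
    mutated <- c(mutated, best$p)
  }
  do.call(rbind, out)
}
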