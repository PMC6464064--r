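# Seeded synthetic-data generators. They emulate every input the pipeline
# consumes -- bit-weight matrices of specified information content, promoters
# with planted homotypic site clusters, DHS/peak intervals around the plants,
# block-structured tissue expression matrices and knockdown matrices with
# planted consistent-sign targets -- so each stage and the end-to-end
# classifier can be exercised without external downloads.
#
# Planted site strength is coupled to the knockdown effect size epsilon:
# targets whose expression responds more strongly to the perturbation carry
# better-organized, more information-dense binding-site clusters. This
# reproduces, inside the simulation, the empirical pattern that classifier
# accuracy grows with the differential-expression threshold.

#' Simulation configuration
#'
#' @param seed integer seed driving every generator.
#' @param n_genes number of genes (default 200).
#' @param n_positives number of planted target genes (default `n_genes / 2`).
#' @param n_tissues tissue panel size (default 53).
#' @param n_tfs number of factors in the panel (default 1, homotypic).
#' @param promoter_length promoter length in bp (default 10000).
#' @param pwm_width matrix width in bp (default 11).
#' @param pwm_info target matrix information content in bits (default 14;
#'   calibrated so that background accessible sequence rarely assembles a
#'   cluster passing the homotypic threshold).
#' @param clusters_per_positive planted clusters per target promoter: a
#'   single count, or a length-2 inclusive range from which each target's
#'   count is drawn (default `c(2, 4)`; variable counts mirror real
#'   promoters, where target genes differ in how many clusters they carry).
#' @param sites_per_cluster planted sites per cluster (default 2).
#' @param site_strength_frac length-2 range of planted site strengths as
#'   fractions of R_sequence, or `NULL` to derive it from `epsilon` as
#'   `c(0.34, 0.50) + 2.5 * log10(epsilon)` (stronger knockdown effects come
#'   with stronger binding-site organization).
#' @param epsilon planted mean fold-change effect size (> 1, default 1.1).
#' @param n_guides guide RNAs per factor (default 4).
#' @param decoy_frac fraction of non-targets given mixed-sign (inconsistent)
#'   knockdown responses (default 0.05).
#' @param n_bg_dhs,bg_dhs_length background accessible intervals per promoter
#'   and their length in bp (defaults 2 and 150).
#' @param base_comp background base composition, length-4 probabilities for
#'   A, C, G, T (default uniform).
#' @param expr_noise_sd,expr_scale_sd multiplicative log-normal noise and
#'   per-gene scale spread for expression generation (defaults 0.25).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, n_positives = n_genes %/% 2L,
                       n_tissues = 53L, n_tfs = 1L, promoter_length = 10000L,
                       pwm_width = 11L, pwm_info = 14,
                       clusters_per_positive = c(2L, 4L),
                       sites_per_cluster = 2L,
                       site_strength_frac = NULL, epsilon = 1.1,
                       n_guides = 4L, decoy_frac = 0.05,
                       n_bg_dhs = 2L, bg_dhs_length = 150L,
                       base_comp = rep(0.25, 4), expr_noise_sd = 0.25,
                       expr_scale_sd = 0.25) {
  stopifnot(n_genes > 0, n_positives > 0, n_positives <= n_genes,
            n_tissues > 0, n_tfs > 0, promoter_length > 0,
            length(clusters_per_positive) %in% 1:2,
            all(clusters_per_positive > 0),
            sites_per_cluster > 0, epsilon > 1,
            n_guides > 0, length(base_comp) == 4, all(base_comp > 0))
  if (is.null(site_strength_frac))
    site_strength_frac <- c(0.34, 0.50) + 2.5 * log10(epsilon)
  stopifnot(length(site_strength_frac) == 2,
            all(site_strength_frac > 0), all(site_strength_frac <= 2))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_positives = as.integer(n_positives),
                 n_tissues = as.integer(n_tissues), n_tfs = as.integer(n_tfs),
                 promoter_length = as.integer(promoter_length),
                 pwm_width = as.integer(pwm_width), pwm_info = pwm_info,
                 clusters_per_positive = as.integer(clusters_per_positive),
                 sites_per_cluster = as.integer(sites_per_cluster),
                 site_strength_frac = site_strength_frac, epsilon = epsilon,
                 n_guides = as.integer(n_guides), decoy_frac = decoy_frac,
                 n_bg_dhs = as.integer(n_bg_dhs),
                 bg_dhs_length = as.integer(bg_dhs_length),
                 base_comp = base_comp / sum(base_comp),
                 expr_noise_sd = expr_noise_sd, expr_scale_sd = expr_scale_sd),
            class = "sim_config")
}

softmax_rows <- function(logits, s) {
  e <- exp(s * (logits - apply(logits, 1L, max)))
  e / rowSums(e)
}

freq_info <- function(f) {
  plogp <- ifelse(f > 0, f * log2(f), 0)
  sum(2 + rowSums(plogp))
}

#' Generate a random iPWM of specified information content
#'
#' Per-position base preferences are drawn once (standard normal logits) and
#' sharpened through a tempered softmax; the inverse temperature is tuned by
#' bisection until the matrix information content matches `target_info`
#' (information is monotone in the sharpening, so the bisection is
#' deterministic and always converges for feasible targets). Weights follow
#' the `w = 2 + log2(f)` convention with a floor at -10 bits.
#'
#' @param width matrix width (bp).
#' @param target_info desired information content in bits,
#'   `0 < target_info <= 2 * width`.
#' @param seed RNG seed; the same seed gives an identical matrix.
#' @param tf,cell_line metadata for the generated matrix.
#' @return an [ipwm()] whose [matrix_r_sequence()] is within 0.5 bits of
#'   `target_info` (in practice much closer).
#' @export
gen_ipwm <- function(width, target_info, seed, tf = "TF1",
                     cell_line = "synthetic") {
  if (target_info <= 0 || target_info > 2 * width)
    stop("gen_ipwm: target information must lie in (0, 2 * width]",
         call. = FALSE)
  logits <- with_seed(seed, matrix(stats::rnorm(width * 4L), nrow = width))
  info_at <- function(s) freq_info(softmax_rows(logits, s))
  lo <- 0; hi <- 1
  while (info_at(hi) < target_info && hi < 1e6) hi <- hi * 2
  if (info_at(hi) < target_info - 0.4)
    stop("gen_ipwm: target information infeasible for these logits",
         call. = FALSE)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (info_at(mid) < target_info) lo <- mid else hi <- mid
  }
  f <- softmax_rows(logits, (lo + hi) / 2)
  w <- pmax(2 + log2(f), -10)
  ipwm(tf, w, cell_line = cell_line, r_sequence = freq_info(f))
}

# Deterministic greedy descent from the consensus towards a target R_i: at
# each step take the single-base substitution losing the least information;
# stop before dropping below the target. Guarantees r_i >= target.
plant_site_sequence <- function(m, target_ri) {
  w <- unname(m$weights)   # strip dimnames so scores stay bare scalars
  codes <- apply(w, 1L, which.max)
  score <- sum(w[cbind(seq_len(m$width), codes)])
  repeat {
    best <- NULL
    for (j in seq_len(m$width)) {
      for (b in seq_len(4L)) {
        if (b == codes[j]) next
        ns <- score + w[j, b] - w[j, codes[j]]
        if (ns < score && (is.null(best) || ns > best$score))
          best <- list(j = j, b = b, score = ns)
      }
    }
    if (is.null(best) || best$score < target_ri) break
    codes[best$j] <- best$b
    score <- best$score
  }
  list(sequence = decode_dna(codes), r_i = score)
}

random_dna <- function(n, base_comp) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_comp), collapse = "")
}

#' Generate promoters with planted binding-site clusters
#'
#' Each gene gets its own contig holding a background promoter (i.i.d. bases)
#' with the TSS at `promoter_length` on the `+` strand. The first
#' `n_positives` genes receive `clusters_per_positive` planted clusters of
#' `sites_per_cluster` consensus-derived sites (strengths drawn from
#' `site_strength_frac` of R_sequence, random strand, centers within the IDBC
#' merge reach). Accessible intervals (DHSs) cover every plant plus
#' `n_bg_dhs` random background windows per promoter; ChIP-style peak
#' intervals cover the plants of positive genes only.
#'
#' @param cfg a [sim_config()].
#' @param ipwms list of [ipwm()]s (sites are planted for panel members drawn
#'   cyclically; with one matrix the plants are homotypic).
#' @return list with `genome` (named character), `tss`, `dhs`, `peaks`,
#'   `promoters` (labeling-style promoter table), `truth_sites` and
#'   `truth_clusters` data.frames, and `positives` (planted target ids).
#' @export
gen_promoters <- function(cfg, ipwms) {
  stopifnot(inherits(cfg, "sim_config"))
  rs <- vapply(ipwms, matrix_r_sequence, numeric(1))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  positives <- genes[seq_len(cfg$n_positives)]
  pl <- cfg$promoter_length
  with_seed(cfg$seed, {
    genome <- character(0)
    dhs <- list(); peaks <- list(); tsites <- list(); tclust <- list()
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      seq_g <- random_dna(pl + 120L, cfg$base_comp)
      if (g %in% positives) {
        cpp <- cfg$clusters_per_positive
        n_cl <- if (length(cpp) == 2L) sample(cpp[1L]:cpp[2L], 1L) else cpp
        anchors <- round(pl * seq_len(n_cl) / (n_cl + 1L)) +
          sample(-200:200, n_cl, replace = TRUE)
        for (k in seq_len(n_cl)) {
          pos <- anchors[k]
          total <- 0; first <- NA_integer_; last <- NA_integer_
          for (s in seq_len(cfg$sites_per_cluster)) {
            m <- ipwms[[((s - 1L) %% length(ipwms)) + 1L]]
            frac <- stats::runif(1, cfg$site_strength_frac[1L],
                                 cfg$site_strength_frac[2L])
            site <- plant_site_sequence(m, frac * matrix_r_sequence(m))
            L <- nchar(site$sequence)
            if (pos + L > pl)
              stop("gen_promoters: plant does not fit the promoter",
                   call. = FALSE)
            strand <- sample(c("+", "-"), 1L)
            ins <- if (strand == "+") site$sequence else revcomp(site$sequence)
            substr(seq_g, pos + 1L, pos + L) <- ins
            tsites[[length(tsites) + 1L]] <- data.frame(
              gene = g, cluster = k, tf = m$tf, start = pos, strand = strand,
              sequence = site$sequence, r_i = site$r_i,
              stringsAsFactors = FALSE)
            if (is.na(first)) first <- pos
            last <- pos + L
            total <- total + site$r_i
            pos <- pos + L + 5L
          }
          tclust[[length(tclust) + 1L]] <- data.frame(
            gene = g, cluster = k, start = first, end = last,
            total_r_i = total, stringsAsFactors = FALSE)
          dhs[[length(dhs) + 1L]] <- data.frame(
            contig = g, start = max(0L, first - 30L),
            end = min(pl, last + 30L), stringsAsFactors = FALSE)
          peaks[[length(peaks) + 1L]] <- data.frame(
            contig = g, start = max(0L, first - 100L),
            end = min(pl, last + 100L), stringsAsFactors = FALSE)
        }
      }
      bg_start <- sample.int(pl - cfg$bg_dhs_length, cfg$n_bg_dhs)
      dhs[[length(dhs) + 1L]] <- data.frame(
        contig = g, start = bg_start, end = bg_start + cfg$bg_dhs_length,
        stringsAsFactors = FALSE)
      genome[[g]] <- seq_g
    }
    list(genome = genome,
         tss = data.frame(gene_id = genes, contig = genes, tss = pl,
                          strand = "+", stringsAsFactors = FALSE),
         dhs = do.call(rbind, dhs),
         peaks = if (length(peaks)) do.call(rbind, peaks)
                 else genomic_intervals(),
         promoters = data.frame(gene_id = genes, contig = genes, start = 0L,
                                end = pl, stringsAsFactors = FALSE),
         truth_sites = if (length(tsites)) do.call(rbind, tsites)
                       else NULL,
         truth_clusters = if (length(tclust)) do.call(rbind, tclust)
                          else NULL,
         positives = positives)
  })
}

#' Generate a block-structured expression matrix
#'
#' Each group of genes shares a log-normal tissue archetype; members are the
#' archetype times a per-gene scale with multiplicative log-normal noise, so
#' within-group Bray-Curtis similarity exceeds between-group similarity.
#'
#' @param cfg a [sim_config()].
#' @param groups named list partitioning gene ids into groups (no empty
#'   groups).
#' @return numeric matrix, genes x `n_tissues`.
#' @export
gen_expression <- function(cfg, groups) {
  stopifnot(inherits(cfg, "sim_config"), is.list(groups))
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("gen_expression: empty group", call. = FALSE)
  with_seed(cfg$seed + 1L, {
    rows <- list()
    for (grp in groups) {
      archetype <- stats::rlnorm(cfg$n_tissues, meanlog = 1, sdlog = 1)
      for (g in grp) {
        scale <- stats::rlnorm(1, 0, cfg$expr_scale_sd)
        rows[[g]] <- archetype * scale *
          exp(stats::rnorm(cfg$n_tissues, 0, cfg$expr_noise_sd))
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
    m
  })
}

#' Generate a CRISPR-style knockdown coefficient matrix
#'
#' Planted targets receive consistent-sign guide coefficients whose mean
#' fold change `10^c` exceeds `epsilon` (or falls below `1/epsilon` for
#' down-regulated targets); non-targets are exact zeros except for a
#' `decoy_frac` fraction given mixed-sign responses (which the labeling rules
#' leave unlabeled).
#'
#' @param cfg a [sim_config()] (`epsilon` must exceed 1).
#' @param targets character vector of planted target gene ids.
#' @param genes full gene id vector (rows of the matrix).
#' @return numeric matrix, genes x `n_guides`, of log10 fold changes.
#' @export
gen_knockdown <- function(cfg, targets, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$epsilon <= 1)
    stop("gen_knockdown: epsilon must exceed 1", call. = FALSE)
  stopifnot(all(targets %in% genes))
  with_seed(cfg$seed + 2L, {
    K <- matrix(0, nrow = length(genes), ncol = cfg$n_guides,
                dimnames = list(genes, sprintf("guide%d",
                                               seq_len(cfg$n_guides))))
    for (g in targets) {
      sgn <- sample(c(-1, 1), 1L)
      base <- stats::runif(1, 1.5, 3) * log10(cfg$epsilon)
      K[g, ] <- sgn * base * (1 + stats::runif(cfg$n_guides, -0.2, 0.2))
    }
    nontargets <- setdiff(genes, targets)
    n_decoy <- floor(cfg$decoy_frac * length(nontargets))
    if (n_decoy > 0L) {
      for (g in sample(nontargets, n_decoy)) {
        v <- stats::runif(cfg$n_guides, 0.002, 0.01) *
          sample(c(-1, 1), cfg$n_guides, replace = TRUE)
        v[1L] <- abs(v[1L]); v[2L] <- -abs(v[2L])   # force mixed signs
        K[g, ] <- v
      }
    }
    K
  })
}

#' Simulate a complete study
#'
#' Generates the matrix panel, promoters with plants, expression matrix
#' (targets and non-targets as the two groups) and the knockdown matrix.
#'
#' @param cfg a [sim_config()].
#' @return list with `ipwms`, everything from [gen_promoters()], `expression`
#'   and `knockdown`.
#' @export
simulate_study <- function(cfg) {
  ipwms <- lapply(seq_len(cfg$n_tfs), function(t)
    gen_ipwm(cfg$pwm_width, cfg$pwm_info, seed = cfg$seed + 10L + t,
             tf = sprintf("TF%d", t)))
  prom <- gen_promoters(cfg, ipwms)
  genes <- prom$tss$gene_id
  groups <- list(targets = prom$positives,
                 background = setdiff(genes, prom$positives))
  groups <- Filter(function(g) length(g) > 0L, groups)
  expr <- gen_expression(cfg, groups)
  K <- gen_knockdown(cfg, prom$positives, genes)
  c(prom, list(ipwms = ipwms, expression = expr, knockdown = K, config = cfg))
}

#' Extract cluster features for every gene of a simulated study
#'
#' Builds each gene's DHS-masked promoter, scans the panel, clusters with
#' IDBC (threshold `I` defaulting to the panel's summed R_sequence) and
#' featurizes.
#'
#' @param study output of [simulate_study()].
#' @param mode featurization mode (default homotypic for 1-factor panels).
#' @param d IDBC radius (default 25 bp).
#' @param I information threshold; default [default_information_threshold()].
#' @param threshold_frac scan threshold fraction (default 0.1).
#' @param use_dhs restrict scanning to accessible intervals (default TRUE).
#' @return list with `features` (per-gene list), `clusters` (per-gene list)
#'   and `sites` (per-gene list).
#' @export
study_features <- function(study, mode = NULL, d = 25,
                           I = default_information_threshold(study$ipwms),
                           threshold_frac = 0.1, use_dhs = TRUE) {
  cfg <- study$config
  if (is.null(mode))
    mode <- if (length(study$ipwms) == 1L) "homotypic" else "heterotypic"
  panel <- panel_from_ipwms(study$ipwms)
  params <- idbc_params(d = d, I = I)
  feats <- list(); clusts <- list(); sites <- list()
  for (i in seq_len(nrow(study$tss))) {
    row <- study$tss[i, ]
    p <- make_promoter(row$gene_id, row$contig, row$tss, row$strand,
                       contig_len = nchar(study$genome[[row$contig]]),
                       length = cfg$promoter_length)
    if (use_dhs) p <- restrict_to_accessible(p, study$dhs)
    s <- scan_panel(study$ipwms, p, study$genome,
                    threshold_frac = threshold_frac)
    cl <- idbc(s, params)
    feats[[row$gene_id]] <- featurize_gene(cl, p$tss, panel, mode = mode,
                                           strand = row$strand)
    clusts[[row$gene_id]] <- cl
    sites[[row$gene_id]] <- s
  }
  list(features = feats, clusters = clusts, sites = sites, mode = mode,
       params = params, panel = panel)
}

#' End-to-end planted-target benchmark
#'
#' Runs the whole pipeline on one simulated study: generate, scan, cluster,
#' featurize, label targets from the knockdown matrix, and cross-validate the
#' decision tree on the labeled genes.
#'
#' @param cfg a [sim_config()].
#' @param rounds,folds cross-validation design (default 10 x 10).
#' @param kind learner (default `"decision_tree"`).
#' @return list with the `eval_report` (`cv`), the feature matrix `X`, labels
#'   `y`, the `labeled_set`, the study and the trained full-data `model`.
#' @export
planted_target_benchmark <- function(cfg, rounds = 10L, folds = 10L,
                                     kind = "decision_tree") {
  study <- simulate_study(cfg)
  sf <- study_features(study)
  X <- assemble_matrix(sf$features)
  labels <- crispr_labels(study$knockdown,
                          label_config(epsilon = cfg$epsilon,
                                       promoter_length = cfg$promoter_length),
                          study$peaks, study$promoters)
  keep <- c(labels$positives, labels$negatives)
  y <- as.integer(keep %in% labels$positives)
  Xk <- X[keep, , drop = FALSE]
  attr(Xk, "m_max") <- attr(X, "m_max")
  cv <- cross_validate(Xk, y, rounds = rounds, folds = folds, kind = kind,
                       seed = cfg$seed + 3L)
  model <- train_classifier(Xk, y, kind = kind, seed = cfg$seed + 4L)
  list(cv = cv, X = Xk, y = y, labels = labels, study = study,
       features = sf, model = model, m_max = attr(X, "m_max"))
}
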