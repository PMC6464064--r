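test_that("variant application substitutes bases with a reference guard", {
  v <- function(pos, ref, alt, id = "v")
    data.frame(id = id, contig = "chr", pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  expect_equal(apply_variants("GAGGGGGCATC", 0L, v(0L, "G", "C")),
               "CAGGGGGCATC")
  expect_equal(apply_variants("ACGT", 100L, v(101L, "C", "T")), "ATGT")
  expect_equal(apply_variants("ACGT", 0L, rbind(v(0L, "A", "T"),
                                                v(3L, "T", "A"))), "TCGA")
  expect_error(apply_variants("ACGT", 0L, v(1L, "A", "G")),
               "reference mismatch at position 1")
  expect_error(apply_variants("ACGT", 0L, v(9L, "A", "G")), "outside")
  expect_equal(apply_variants("ACGT", 0L, NULL), "ACGT")
})

test_that("site pairing reports deltas, losses and gains", {
  w <- data.frame(tf = "T1", contig = "chr", start = c(10L, 50L),
                  strand = c("+", "-"), sequence = c("ACGTA", "GGGTT"),
                  r_i = c(8, 6), stringsAsFactors = FALSE)
  d0 <- site_delta(w, w)
  expect_true(all(d0$status == "paired"))
  expect_true(all(d0$delta_r_i == 0))

  shifted <- w
  shifted$start[1] <- 11L
  shifted$r_i[1] <- 7.5
  d1 <- site_delta(w, shifted)
  expect_equal(d1$status, c("paired", "paired"))
  expect_equal(d1$delta_r_i[1], -0.5)

  d2 <- site_delta(w, w[2, , drop = FALSE])
  expect_equal(d2$status, c("lost", "paired"))
  gained <- rbind(w, data.frame(tf = "T1", contig = "chr", start = 200L,
                                strand = "+", sequence = "ACGTA", r_i = 3,
                                stringsAsFactors = FALSE))
  d3 <- site_delta(w, gained)
  expect_equal(sum(d3$status == "gained"), 1L)
  # same coordinates but opposite strand never pair
  flip <- w; flip$strand <- c("-", "+")
  expect_true(all(site_delta(w, flip)$status %in% c("lost", "gained")))
})

make_single_cluster_fixture <- function(seed = 101) {
  cfg <- sim_config(seed = seed, n_genes = 8L, n_positives = 4L,
                    promoter_length = 3000L, clusters_per_positive = 1L,
                    epsilon = 1.1)
  study <- simulate_study(cfg)
  sf <- study_features(study)
  list(cfg = cfg, study = study, sf = sf)
}

test_that("re-evaluation with no variants is the identity", {
  fx <- make_single_cluster_fixture()
  g <- fx$study$positives[1]
  row <- fx$study$tss[fx$study$tss$gene_id == g, ]
  p <- restrict_to_accessible(
    make_promoter(g, g, row$tss, row$strand, nchar(fx$study$genome[[g]]),
                  length = fx$cfg$promoter_length),
    fx$study$dhs)
  rep0 <- reevaluate_promoter(p, NULL, fx$study$ipwms,
                              fx$sf$params, fx$study$genome)
  expect_true(all(rep0$sites$status == "paired"))
  expect_true(all(rep0$sites$delta_r_i == 0))
  expect_true(all(rep0$cluster_fates$fate == "retained"))
  expect_length(rep0$gained_clusters, 0L)
})

test_that("knocking out the strong site abolishes an information-poor cluster", {
  fx <- make_single_cluster_fixture()
  truth <- fx$study$truth_sites
  # pick a positive gene whose planted cluster was recovered by the pipeline
  g <- NULL
  for (cand in fx$study$positives) {
    span <- fx$study$truth_clusters[fx$study$truth_clusters$gene == cand, ]
    hit <- any(vapply(fx$sf$clusters[[cand]], function(cl)
      cl$span[1L] < span$end && span$start < cl$span[2L], logical(1)))
    if (hit) { g <- cand; break }
  }
  expect_false(is.null(g))
  ts <- truth[truth$gene == g, ]
  strongest <- ts[which.max(ts$r_i), ]
  m <- fx$study$ipwms[[1]]
  row <- fx$study$tss[fx$study$tss$gene_id == g, ]
  p <- restrict_to_accessible(
    make_promoter(g, g, row$tss, row$strand, nchar(fx$study$genome[[g]]),
                  length = fx$cfg$promoter_length),
    fx$study$dhs)
  ko <- knockout_variant(m, strongest, contig = g)
  rep1 <- reevaluate_promoter(p, ko, fx$study$ipwms, fx$sf$params,
                              fx$study$genome)
  # the planted cluster existed in the wild type and is now gone
  expect_gte(nrow(rep1$cluster_fates), 1L)
  planted <- which(rep1$cluster_fates$span_start <= strongest$start &
                   rep1$cluster_fates$span_end > strongest$start)
  expect_length(planted, 1L)
  expect_equal(rep1$cluster_fates$fate[planted], "abolished")
  lost <- rep1$sites[rep1$sites$status == "lost", ]
  expect_true(strongest$start %in% lost$wild_start)
})

test_that("variants away from every site and seed radius change nothing", {
  fx <- make_single_cluster_fixture(seed = 103)
  g <- fx$study$positives[2]
  row <- fx$study$tss[fx$study$tss$gene_id == g, ]
  p <- restrict_to_accessible(
    make_promoter(g, g, row$tss, row$strand, nchar(fx$study$genome[[g]]),
                  length = fx$cfg$promoter_length),
    fx$study$dhs)
  wild_sites <- fx$sf$sites[[g]]
  wild_cl <- fx$sf$clusters[[g]]
  # pick a position > 2 kb away from every detected site
  far <- 100L
  while (any(abs(wild_sites$start - far) < 100) ||
         nrow(fx$study$dhs[fx$study$dhs$contig == g &
                           fx$study$dhs$start <= far + 20 &
                           fx$study$dhs$end > far - 20, ]) > 0)
    far <- far + 37L
  ref <- substr(fx$study$genome[[g]], far + 1L, far + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- data.frame(id = "far", contig = g, pos = far, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  rep2 <- reevaluate_promoter(p, v, fx$study$ipwms, fx$sf$params,
                              fx$study$genome)
  expect_true(all(rep2$sites$status == "paired"))
  expect_equal(length(rep2$wild_clusters), length(wild_cl))
  expect_true(all(rep2$cluster_fates$fate == "retained"))
})

test_that("sequential and simultaneous variant application commute", {
  withr::local_seed(71)
  seqs <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  pos <- sort(sample(0:99, 5))
  refs <- vapply(pos, function(p) substr(seqs, p + 1, p + 1), character(1))
  alts <- vapply(refs, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                 character(1))
  v <- data.frame(id = paste0("v", seq_along(pos)), contig = "chr",
                  pos = pos, ref = refs, alt = alts, stringsAsFactors = FALSE)
  at_once <- apply_variants(seqs, 0L, v)
  one_by_one <- seqs
  for (i in seq_len(nrow(v)))
    one_by_one <- apply_variants(one_by_one, 0L, v[i, , drop = FALSE])
  expect_equal(at_once, one_by_one)
  # order reversal too
  rev_order <- apply_variants(seqs, 0L, v[rev(seq_len(nrow(v))), ])
  expect_equal(at_once, rev_order)
})
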