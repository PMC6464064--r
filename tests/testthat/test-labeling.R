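toy_promoters <- function(genes) {
  data.frame(gene_id = genes, contig = genes, start = 0L, end = 10000L,
             stringsAsFactors = FALSE)
}

peak_on <- function(genes) {
  genomic_intervals(genes, 100L, 200L)
}

test_that("peak merging coalesces overlapping, book-ended and chained peaks", {
  expect_equal(merge_peaks(list(genomic_intervals("c", 10L, 20L),
                                genomic_intervals("c", 15L, 30L))),
               genomic_intervals("c", 10L, 30L))
  two <- merge_peaks(list(genomic_intervals(c("c", "c"), c(0L, 10L),
                                            c(5L, 15L))))
  expect_equal(nrow(two), 2L)
  chain <- merge_peaks(list(genomic_intervals("c", 0L, 12L),
                            genomic_intervals("c", 10L, 25L),
                            genomic_intervals("c", 24L, 40L)))
  expect_equal(chain, genomic_intervals("c", 0L, 40L))
})

test_that("CRISPR labeling applies consistency, threshold and peak criteria", {
  cfg <- label_config(epsilon = 1.05)
  K <- rbind(pos1 = c(0.1, 0.2),       # FCs 1.259, 1.585; mean 1.42 > 1.05
             mixed = c(0.05, -0.01),   # mixed signs -> unlabeled
             zero = c(0, 0),           # exact zeros -> negative
             weak = c(0.01, 0.01),     # mean FC 1.023 < 1.05 -> unlabeled
             down = c(-0.1, -0.15),    # mean FC 0.75 < 1/1.05 -> positive
             nopeak = c(0.3, 0.3))     # DE but no peak -> unlabeled
  proms <- toy_promoters(rownames(K))
  peaks <- peak_on(c("pos1", "down", "zero", "mixed", "weak"))
  ls <- crispr_labels(K, cfg, peaks, proms)
  expect_setequal(ls$positives, c("pos1", "down"))
  expect_equal(ls$negatives, "zero")
  expect_setequal(ls$unlabeled, c("mixed", "weak", "nopeak"))
  expect_equal(ls$ref_positive, "pos1")   # largest mean coefficient
  prov <- ls$provenance
  expect_equal(prov$mean_fold_change[prov$gene == "pos1"],
               mean(10^c(0.1, 0.2)))
  expect_true(all(prov$peak_overlap[prov$label == "positive"]))
  # a single zero coefficient among nonzero ones breaks consistency
  K2 <- rbind(K, halfzero = c(0, 0.5))
  ls2 <- crispr_labels(K2, cfg, peaks,
                       toy_promoters(rownames(K2)))
  expect_true("halfzero" %in% ls2$unlabeled)
  expect_error(crispr_labels(K, cfg, peaks, toy_promoters("pos1")),
               "no promoter")
})

test_that("raising epsilon never adds positives", {
  withr::local_seed(51)
  for (rep in 1:10) {
    K <- matrix(round(runif(60, -0.05, 0.08), 3), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
    proms <- toy_promoters(rownames(K))
    peaks <- peak_on(rownames(K))
    sets <- lapply(c(1.01, 1.05, 1.1), function(e)
      crispr_labels(K, label_config(epsilon = e), peaks, proms)$positives)
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
  }
})

test_that("negative balancing keeps the least-similar negatives, order-invariantly", {
  # profiles built so similarity to the reference is exactly 0.2, 0.5, 0.9
  expr <- rbind(ref = c(1, 0),
                n1 = c(1 / 9, 0),     # sim 0.2
                n2 = c(1 / 3, 0),     # sim 0.5
                n3 = c(9 / 11, 0))    # sim 0.9
  ls <- structure(list(positives = c("ref", "p2"),
                       negatives = c("n3", "n1", "n2"),
                       ref_positive = "ref"), class = "labeled_set")
  b <- balance_negatives(ls, expr)
  expect_setequal(b$negatives, c("n1", "n2"))
  expect_equal(b$balance$similarity[b$balance$kept], c(0.2, 0.5))

  # permuting the candidate order changes nothing
  ls2 <- ls; ls2$negatives <- c("n2", "n3", "n1")
  expect_setequal(balance_negatives(ls2, expr)$negatives, c("n1", "n2"))

  # tie for the last slot resolves to the lexicographically smaller id
  expr_tie <- rbind(ref = c(1, 0), na = c(1 / 3, 0), nb = c(1 / 3, 0),
                    nz = c(1 / 9, 0))
  ls3 <- structure(list(positives = c("ref", "p2"),
                        negatives = c("nb", "na", "nz"),
                        ref_positive = "ref"), class = "labeled_set")
  expect_equal(sort(balance_negatives(ls3, expr_tie)$negatives),
               c("na", "nz"))

  # equal counts pass through; deficit errors
  same <- structure(list(positives = "ref", negatives = "n1",
                         ref_positive = "ref"), class = "labeled_set")
  expect_equal(balance_negatives(same, expr)$negatives, "n1")
  short <- structure(list(positives = c("ref", "p2"), negatives = "n1",
                          ref_positive = "ref"), class = "labeled_set")
  expect_error(balance_negatives(short, expr), "fewer negatives")
})

test_that("siRNA labeling combines the p-value cutoff with peak support", {
  P <- c(hit = 0.01, nearmiss = 0.011, orphan = 0.005, null = 0.8)
  proms <- toy_promoters(names(P))
  peaks <- peak_on(c("hit", "null"))
  ls <- sirna_labels(P, peaks, proms, label_config())
  expect_equal(ls$positives, "hit")            # p = 0.01 is inclusive
  expect_setequal(ls$negatives, c("nearmiss", "null"))
  expect_equal(ls$unlabeled, "orphan")         # significant but peakless
})
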