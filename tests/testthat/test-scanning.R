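test_that("site scoring sums per-position bit weights", {
  m <- toy2_ipwm()
  expect_equal(score_site(m, "AC"), 4)
  expect_equal(score_site(m, "AA"), 1)   # 2 + (-1)
  z <- ipwm("Z", matrix(0, 2, 4), r_sequence = 1)
  expect_equal(score_site(z, "GT"), 0)
  expect_error(score_site(m, "ACG"), "length")
  expect_error(score_site(m, "AN"), "non-ACGT")
})

test_that("R_sequence is recovered from log-frequency weights", {
  uniform <- ipwm("U", matrix(2 + log2(0.25), 3, 4))
  expect_equal(matrix_r_sequence(uniform), 0)
  # near-single-base columns carry close to 2 bits per position
  f <- matrix(2^-12, 3, 4); f[cbind(1:3, c(1, 2, 3))] <- 1
  conserved <- ipwm("C", pmax(2 + log2(f), -10))
  expect_equal(matrix_r_sequence(conserved), 6, tolerance = 0.01)
  # metadata wins over recovery
  expect_equal(matrix_r_sequence(toy2_ipwm()), 4)
  # weights that are not log-frequencies and carry no metadata are an error
  bad <- ipwm("B", rbind(c(2, -1, -1, -1), c(-1, 2, -1, -1)))
  expect_error(matrix_r_sequence(bad), "metadata")
  # generator metadata agrees with recomputation from the weights
  g <- gen_ipwm(9, 10, seed = 3)
  g2 <- g; g2$r_sequence <- NULL
  expect_equal(matrix_r_sequence(g2), matrix_r_sequence(g), tolerance = 0.02)
})

test_that("promoters sit strictly upstream of the TSS and clamp at contig bounds", {
  p <- make_promoter("g", "chr", 10000L, "+", 20000L)
  expect_equal(c(p$start, p$end), c(0L, 10000L))
  p <- make_promoter("g", "chr", 5000L, "-", 20000L)
  expect_equal(c(p$start, p$end), c(5000L, 15000L))
  p <- make_promoter("g", "chr", 400L, "+", 20000L)
  expect_equal(c(p$start, p$end), c(0L, 400L))
  expect_error(make_promoter("g", "chr", 30000L, "+", 20000L), "outside")
})

test_that("accessibility masking intersects and merges DHS intervals", {
  p <- make_promoter("g", "chr", 100L, "+", 500L, length = 100L)
  p1 <- restrict_to_accessible(p, genomic_intervals("chr", 50L, 150L))
  expect_equal(p1$accessible, genomic_intervals("chr", 50L, 100L))
  p2 <- restrict_to_accessible(p, genomic_intervals("chrX", 0L, 400L))
  expect_equal(nrow(p2$accessible), 0L)
  p3 <- restrict_to_accessible(p, genomic_intervals(c("chr", "chr"),
                                                    c(10L, 15L), c(20L, 30L)))
  expect_equal(p3$accessible, genomic_intervals("chr", 10L, 30L))
})

test_that("scanning keeps thresholded sites on both strands in sorted order", {
  m <- toy2_ipwm()
  genome <- list(chr = "ACGT")
  p <- make_promoter("g", "chr", 4L, "+", 4L, length = 4L)
  s <- scan_promoter(m, p, genome, threshold_frac = 0.1)
  expect_equal(s$start, c(0L, 2L))
  expect_equal(s$strand, c("+", "-"))
  expect_equal(s$r_i, c(4, 4))
  expect_equal(s$sequence, c("AC", "AC"))   # minus-strand site read 5'->3'

  # empty accessible set -> no sites
  p0 <- restrict_to_accessible(p, genomic_intervals("chrY", 0L, 4L))
  expect_equal(nrow(scan_promoter(m, p0, genome)), 0L)

  # degenerate threshold on the zero matrix reports every window twice
  z <- ipwm("Z", matrix(0, 2, 4), r_sequence = 1)
  sz <- scan_promoter(z, p, genome, threshold_frac = 0)
  expect_equal(nrow(sz), 6L)
  expect_true(all(sz$r_i == 0))
})

test_that("scan equals the brute-force window oracle on random masked promoters", {
  withr::local_seed(21)
  for (rep in 1:20) {
    w <- sample(6:12, 1)
    m <- gen_ipwm(w, runif(1, 4, 2 * w - 2), seed = 100 + rep)
    n <- sample(200:600, 1)
    genome <- list(chr = paste(sample(c("A", "C", "G", "T", "N"), n,
                                      replace = TRUE,
                                      prob = c(rep(0.2475, 4), 0.01)),
                               collapse = ""))
    p <- make_promoter("g", "chr", n, "+", n, length = n)
    if (rep %% 2 == 0) {
      st <- sort(sample.int(n - 40L, 3L))
      p <- restrict_to_accessible(p, genomic_intervals("chr", st, st + 40L))
    }
    thr <- runif(1, 0.02, 0.2)
    expect_equal(scan_promoter(m, p, genome, threshold_frac = thr),
                 brute_scan(m, p, genome, threshold_frac = thr))
  }
})

test_that("no reported site crosses an accessible-interval boundary", {
  withr::local_seed(5)
  m <- gen_ipwm(8, 4, seed = 9)   # permissive matrix -> many sites
  n <- 1000L
  genome <- list(chr = paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = ""))
  st <- c(100L, 160L, 700L)
  p <- restrict_to_accessible(make_promoter("g", "chr", n, "+", n, length = n),
                              genomic_intervals("chr", st, st + 50L))
  s <- scan_promoter(m, p, genome, threshold_frac = 0)
  expect_gt(nrow(s), 0)
  inside <- vapply(seq_len(nrow(s)), function(i)
    any(s$start[i] >= p$accessible$start &
        s$start[i] + m$width <= p$accessible$end), logical(1))
  expect_true(all(inside))
})
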