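make_track <- function(raw, frag_len = 100, vp = 0) {
  n <- length(raw)
  fourc_track(list(chrom = "chr_syn", pos = vp),
              data.frame(start = (seq_len(n) - 1) * frag_len,
                         end = seq_len(n) * frag_len),
              raw_counts = raw)
}

test_that("per-million normalization matches direct arithmetic", {
  tr <- normalize_rpm(make_track(c(1, 1, 2)))
  expect_equal(tr$norm_signal, c(250000, 250000, 500000))
  set.seed(1)
  tr2 <- normalize_rpm(make_track(rpois(50, 40)))
  expect_equal(sum(tr2$norm_signal), 1e6)
  # idempotent up to scale: renormalizing the normalized track is a no-op
  tr3 <- tr2
  tr3$raw_counts <- tr2$norm_signal
  tr3$raw_counts <- round(tr3$raw_counts)
  expect_equal(normalize_rpm(tr3)$norm_signal * sum(tr3$raw_counts) / 1e6,
               tr3$raw_counts)
  expect_warning(normalize_rpm(make_track(c(0, 0, 0))), "zero total")
})

test_that("running window averages 21 fragments and truncates at edges", {
  const <- running_window(normalize_rpm(make_track(rep(4, 60))))
  expect_equal(const$windowed_signal, rep(1e6 / 60, 60))

  imp <- make_track(c(rep(0, 30), 1, rep(0, 30)))
  imp <- running_window(normalize_rpm(imp))
  w <- imp$windowed_signal
  expect_equal(w[31], 1e6 / 21)
  expect_equal(w[21:41], rep(1e6 / 21, 21)) # the 21 covered positions
  expect_equal(w[10], 0)
  # edge truncation: first fragment sees only 11 fragments of the window
  edge <- running_window(normalize_rpm(make_track(c(1, rep(0, 40)))))
  expect_equal(edge$windowed_signal[1], 1e6 / 11)

  k1 <- running_window(normalize_rpm(make_track(c(5, 1, 7, 2))), k = 1)
  expect_equal(k1$windowed_signal, k1$norm_signal)
  expect_error(running_window(make_track(rep(1, 10)), k = 4), "odd")
})

test_that("window and spline operators are linear in the signal", {
  set.seed(33)
  n <- 80
  xa <- rpois(n, 30)
  xb <- rpois(n, 10)
  mk <- function(raw) {
    tr <- make_track(raw)
    tr$norm_signal <- raw # bypass rpm so linearity is over the raw vectors
    tr
  }
  comb <- mk(2 * xa + 3 * xb)
  wa <- running_window(mk(xa))$windowed_signal
  wb <- running_window(mk(xb))$windowed_signal
  wc <- running_window(comb)$windowed_signal
  expect_equal(wc, 2 * wa + 3 * wb, tolerance = 1e-8)
  sa <- smooth_spline_track(mk(xa))$smoothed_signal
  sb <- smooth_spline_track(mk(xb))$smoothed_signal
  sc <- smooth_spline_track(comb)$smoothed_signal
  expect_equal(sc, 2 * sa + 3 * sb, tolerance = 1e-8)
})

test_that("spline smoothing interpolates at 0, straightens toward 1", {
  set.seed(44)
  n <- 60
  raw <- rpois(n, 50) + round(40 * sin(seq_len(n) / 6))
  tr <- running_window(normalize_rpm(make_track(pmax(raw, 0))))
  y <- tr$windowed_signal
  rss <- vapply(seq(0.1, 0.9, by = 0.2), function(sm) {
    sum((smooth_spline_track(tr, smoothing = sm)$smoothed_signal - y)^2)
  }, numeric(1))
  expect_true(all(diff(rss) >= -1e-8 * max(rss)))
  expect_lt(rss[1], 0.05 * sum((y - mean(y))^2))
  # smoothing >= 1 is exactly the least-squares line
  line <- smooth_spline_track(tr, smoothing = 1)$smoothed_signal
  x <- (tr$fragments$start + tr$fragments$end) / 2
  expect_equal(line, unname(fitted(lm(y ~ x))), tolerance = 1e-10)
  expect_error(smooth_spline_track(make_track(c(1, 2, 3))), "4 fragments")
})

test_that("gene-body extraction keeps captured fragments and logs them", {
  tr <- make_track(c(0, 10, 20, 0, 5), frag_len = 100)
  tr <- normalize_rpm(tr) # totals 35 -> norm per fragment
  body <- genomic_interval("chr_syn", 100, 300) # fragments 2 and 3
  expect_equal(gene_body_signal(tr, body),
               log(c(10, 20) * 1e6 / 35))
  # zero-signal fragment inside the body is dropped
  body2 <- genomic_interval("chr_syn", 100, 400)
  expect_equal(length(gene_body_signal(tr, body2)), 2)
  # pseudocount mode keeps it
  expect_equal(length(gene_body_signal(tr, body2, pseudocount = 1)), 3)
  # empty body
  expect_equal(length(gene_body_signal(tr, genomic_interval("chr_syn", 1e4,
                                                            2e4))), 0)
})

test_that("gene-body comparisons run Welch tests with Bonferroni", {
  base <- make_track(rep(10, 30), frag_len = 100)
  jit <- c(9, 10, 11, 10, 9, 11, 10, 10, 9, 11)
  ta <- make_track(c(jit, rep(10, 10), jit), frag_len = 100)
  tb <- make_track(c(jit, rep(10, 10), jit * 3), frag_len = 100)
  genes <- list(g1 = genomic_interval("chr_syn", 0, 1000),
                g2 = genomic_interval("chr_syn", 1000, 2000),
                g3 = genomic_interval("chr_syn", 2000, 3000))
  cmp <- compare_gene_bodies(ta, tb, genes)
  expect_equal(cmp$gene, c("g1", "g2", "g3"))
  expect_true(cmp$tested[3])
  expect_lt(cmp$p_adj[3], 0.05)
  expect_gt(cmp$shift[3], 0)
  # identical non-constant vectors: t = 0, p = 1, p_adj = 1
  cmp_same <- compare_gene_bodies(ta, ta, genes["g1"])
  expect_equal(cmp_same$t_statistic, 0)
  expect_equal(cmp_same$p_value, 1)
  expect_equal(cmp_same$p_adj, 1)
  # Bonferroni caps at 1
  expect_true(all(is.na(cmp$p_adj) | cmp$p_adj <= 1))
  # fewer than 2 captured fragments -> skipped with flag
  tiny_a <- make_track(c(5, 0, 0, 0), frag_len = 100)
  tiny_b <- make_track(c(5, 5, 5, 5), frag_len = 100)
  cmp_skip <- compare_gene_bodies(tiny_a, tiny_b,
                                  list(genomic_interval("chr_syn", 0, 400)))
  expect_false(cmp_skip$tested)
  expect_true(is.na(cmp_skip$p_value))
})

test_that("QC fractions follow their definitions and thresholds", {
  # all reads cis, all fragments within 100 kb captured
  tr <- normalize_rpm(make_track(rep(5, 20), frag_len = 1000, vp = 500))
  qc <- qc_metrics(tr)
  expect_equal(qc$cis_fraction, 1)
  expect_equal(qc$fraction_coverage_within_1mb, 1)
  expect_equal(qc$fraction_fragments_captured_within_100kb, 1)
  expect_true(qc$pass)

  # half the signal placed beyond 1 Mb
  far <- fourc_track(list(chrom = "chr_syn", pos = 0),
                     data.frame(start = c(0, 2e6), end = c(1000, 2001000)),
                     raw_counts = c(50, 50))
  qc_far <- qc_metrics(normalize_rpm(far))
  expect_equal(qc_far$fraction_coverage_within_1mb, 0.5)
  # pushing more signal past 1 Mb breaks the 40% coverage bound
  far$raw_counts <- c(30, 70)
  qc_far2 <- qc_metrics(normalize_rpm(far))
  expect_false(qc_far2$flags[["coverage_1mb"]])
  expect_false(qc_far2$pass)

  # trans reads cut the cis fraction below threshold
  qc_trans <- qc_metrics(tr, chrom_tally = c(chr_syn = 40, chr_other = 60))
  expect_equal(qc_trans$cis_fraction, 0.4)
  expect_false(qc_trans$flags[["cis"]])
})
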