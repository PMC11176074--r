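small_cfg <- function(...) {
  screen_config(n_cells = 60000, depth = 1e6, ...)
}

test_that("simulated samples conserve depth and are seed-deterministic", {
  bench <- synthetic_benchmark_screen(step = 200)
  cfg <- small_cfg(seed = 11)
  sim1 <- simulate_screen(bench$model, bench$library, cfg, bench$context,
                          bench$target_gene)
  expect_true(all(colSums(sim1$counts$counts) == cfg$depth))
  expect_equal(nrow(sim1$counts$counts), n_guides(bench$library))
  expect_equal(sim1$counts$samples$bin, rep(c("low", "high"), 2))

  sim2 <- simulate_screen(bench$model, bench$library, cfg, bench$context,
                          bench$target_gene)
  expect_identical(sim1$counts$counts, sim2$counts$counts)

  sim3 <- simulate_screen(bench$model, bench$library,
                          small_cfg(seed = 12), bench$context,
                          bench$target_gene)
  expect_false(identical(sim1$counts$counts, sim3$counts$counts))
})

test_that("relabeling guide ids relabels outputs without changing counts", {
  bench <- synthetic_benchmark_screen(step = 200)
  lib2 <- bench$library
  lib2$guides$guide_id <- paste0("renamed_", rev(lib2$guides$guide_id))
  cfg <- small_cfg(seed = 4)
  a <- simulate_screen(bench$model, bench$library, cfg, bench$context,
                       bench$target_gene)
  b <- simulate_screen(bench$model, lib2, cfg, bench$context,
                       bench$target_gene)
  expect_equal(unname(a$counts$counts), unname(b$counts$counts))
  expect_equal(rownames(b$counts$counts), lib2$guides$guide_id)
})

test_that("a null screen centers guide log ratios at zero", {
  null <- synthetic_null_screen(n_guides = 1000)
  cfg <- screen_config(n_cells = 200000, depth = 1e6, e_max = 0, seed = 7)
  sim <- simulate_screen(null$model, null$library, cfg, null$context,
                         null$target_gene)
  lr <- guide_log2_ratio(sim$counts)
  expect_lt(abs(mean(lr)), 0.02)
  expect_true(all(sim$truth$efficacy$efficacy == 0))
})

test_that("an activating element enriches nearby guides in the low bin", {
  span <- genomic_interval("chr_syn", 0, 72000)
  gene <- locus_gene("GOI", genomic_interval("chr_syn", 66000, 70000),
                     tss = 66000,
                     baseline_log_expression = c(Tconv_stim6h = 1))
  el <- reg_element("E", genomic_interval("chr_syn", 9900, 10100),
                    data.frame(gene = "GOI", context = "Tconv_stim6h",
                               kappa = 0.6))
  model <- locus_model(span, list(gene), list(el),
                       contexts = "Tconv_stim6h")
  lib <- tiling_positions_library(genomic_interval("chr_syn", 0, 60000),
                                  step = 50, target_span = span)
  cfg <- screen_config(n_cells = 200000, depth = 2e6, seed = 5)
  sim <- simulate_screen(model, lib, cfg, "Tconv_stim6h", "GOI")
  lr <- guide_log2_ratio(sim$counts)
  centers <- guide_centers(lib)
  near <- abs(centers - 10000) <= cfg$sigma_crispri
  far <- pmin(abs(centers - 9900), abs(centers - 10100)) > 10 * cfg$sigma_crispri
  expect_gt(mean(lr[near]), 0)
  expect_lt(abs(mean(lr[far])), 0.05)
  # efficacy ground truth peaks inside the core at e_max
  eff <- sim$truth$efficacy$efficacy
  expect_equal(max(eff), cfg$e_max)
  expect_true(all(eff[far] < 1e-6))
})

test_that("guide FASTQ emission inverts exactly through read counting", {
  protos <- paste0(strrep("T", 8),
                   c("ACGTACGTACGT", "AAACCCGGGTTT", "ACACACACACAC",
                     "TGCATGCATGCA"))
  lib <- guide_library(
    data.frame(guide_id = paste0("g", 1:4), chrom = "chr_syn",
               five_prime_pos = c(0, 100, 200, 300), strand = "+",
               protospacer = protos),
    genomic_interval("chr_syn", 0, 400))
  set.seed(99)
  K <- matrix(rpois(n_guides(lib) * 4, 6), ncol = 4)
  cm <- count_matrix(K, make_samples(), lib$guides[, c("guide_id",
                                                       "five_prime_pos")])
  dir <- withr::local_tempdir()
  paths <- emit_guide_fastq(cm, lib, dir, flank5 = "GTGGAA", flank3 = "GTT")
  expect_equal(length(paths), 4)
  back <- count_guides(paths, lib, protospacer_offset = 6)
  expect_true(all(attr(back, "unmatched") == 0))
  attr(back, "unmatched") <- NULL
  expect_equal(unname(back), unname(K))
  # total reads per file equals the column sum
  n_reads <- vapply(paths, function(p) length(readLines(p)) / 4L, numeric(1))
  expect_equal(unname(n_reads), colSums(K))
})

test_that("4C simulation normalizes per million and follows the kernel", {
  model <- synthetic_costim_locus()
  tr <- simulate_fourc(model, viewpoint = 203828000, depth = 2e6, seed = 2)
  expect_equal(sum(tr$norm_signal), 1e6)
  expect_true(all(diff(tr$fragments$start) > 0))
  expect_equal(tr$fragments$start[1], model$span$start)
  expect_equal(tr$fragments$end[nrow(tr$fragments)], model$span$end)

  # with all boundary strengths zero the expectation is pure decay
  m0 <- model
  for (i in seq_along(m0$boundaries)) m0$boundaries[[i]]$strength <- 0
  mids <- (tr$fragments$start + tr$fragments$end) / 2
  k <- contact_kernel()
  expect_equal(expected_fourc_signal(m0, 203828000, mids),
               k$c0 * (abs(mids - 203828000) + k$d0)^(-k$gamma))

  # simulated signal tracks the boundary-attenuated expectation
  expd <- expected_fourc_signal(model, 203828000, mids)
  expect_gt(cor(tr$norm_signal, expd / sum(expd)), 0.99)
})

test_that("boundary knockdown redirects 4C signal across the boundary", {
  model <- synthetic_costim_locus()
  cd28 <- model$genes[[1]]
  ctla4 <- model$genes[[2]]
  up <- 0; down <- 0
  for (s in 1:5) {
    ctrl <- simulate_fourc(model, 203828000, depth = 5e5, seed = s,
                           condition = "ctrl")
    kd <- simulate_fourc(model, 203828000, depth = 5e5, seed = s,
                         boundary_knockdown = c("CTCF-2" = 0.9),
                         condition = "kd")
    cmp <- compare_gene_bodies(ctrl, kd, list(cd28, ctla4))
    up <- up + (cmp$shift[1] > 0)
    down <- down + (cmp$shift[2] < 0)
  }
  expect_equal(up, 5)   # cross-boundary gene gains contact
  expect_equal(down, 5) # viewpoint-proximal gene loses share
})
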