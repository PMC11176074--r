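test_that("reads are assigned by exact protospacer match only", {
  protos <- c(strrep("A", 20), paste0(strrep("C", 10), strrep("T", 10)))
  lib <- guide_library(
    data.frame(guide_id = c("g1", "g2"), chrom = "c", five_prime_pos = 0:1,
               strand = "+", protospacer = protos),
    genomic_interval("c", 0, 10))
  dir <- withr::local_tempdir()
  # one matching read, one unknown 20-mer, plus an empty sample
  writeLines(c("@r1", paste0("GT", protos[1], "AA"), "+", strrep("I", 24),
               "@r2", paste0("GT", strrep("G", 20), "AA"), "+",
               strrep("I", 24)),
             file.path(dir, "s1.fastq"))
  file.create(file.path(dir, "s2.fastq"))
  counts <- count_guides(c(s1 = file.path(dir, "s1.fastq"),
                           s2 = file.path(dir, "s2.fastq")),
                         lib, protospacer_offset = 2)
  expect_equal(unname(counts[, "s1"]), c(1L, 0L))
  expect_equal(unname(counts[, "s2"]), c(0L, 0L))
  expect_equal(unname(attr(counts, "unmatched")), c(1L, 0L))

  lib_dup <- lib
  lib_dup$guides$protospacer <- rep(protos[1], 2)
  expect_error(count_guides(c(s1 = file.path(dir, "s1.fastq")), lib_dup),
               "duplicate protospacer")
})

test_that("low-count filtering applies the strict per-condition threshold", {
  K <- rbind(c(3, 3, 2, 1),  # sum 9 -> excluded
             c(3, 3, 2, 2),  # sum 10 -> retained
             c(0, 0, 0, 0),  # all zero -> excluded
             c(50, 50, 50, 50))
  expect_equal(unname(filter_low_counts(K)), c(FALSE, TRUE, FALSE, TRUE))
  # two conditions judged independently
  cond <- c("a", "a", "b", "b")
  keep <- filter_low_counts(K, condition = cond)
  expect_equal(unname(keep[, "a"]), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(unname(keep[, "b"]), c(FALSE, FALSE, FALSE, TRUE))
  # alternate every-sample reading behind the flag
  keep_each <- filter_low_counts(rbind(c(9, 9, 9, 12)), threshold = 10,
                                 mode = "each")
  expect_true(keep_each)
})

test_that("median-of-ratios size factors match hand computation", {
  K <- matrix(c(10, 20, 40, 10, 20, 40), ncol = 2)
  expect_equal(size_factors(K), c(1, 1), ignore_attr = TRUE)

  K2 <- cbind(c(10, 20, 40), c(20, 40, 80))
  sf <- size_factors(K2)
  expect_equal(sf[2] / sf[1], 2, ignore_attr = TRUE)

  # a guide with any zero cannot enter the reference set
  K3 <- rbind(c(0, 1000), c(10, 10), c(20, 20))
  expect_equal(size_factors(K3), c(1, 1), ignore_attr = TRUE)

  expect_error(size_factors(rbind(c(0, 5), c(5, 0))), "positive counts")
})

test_that("dispersion trend recovers simulated overdispersion regimes", {
  samples <- make_samples()
  ds <- design_spec(samples)
  set.seed(21)
  # Poisson data: intercept lands in [0, 0.01]
  pois <- sim_nb_counts(2000, mu = exp(runif(2000, log(50), log(2000))),
                        alpha = 0)
  dp <- estimate_dispersion(pois$counts, rep(1, 4), ds)
  expect_gte(dp$trend[["a0"]], 0)
  expect_lte(dp$trend[["a0"]], 0.01)
  expect_true(all(dp$alpha >= 1e-8))

  # NB alpha = 0.1 around mean 500: intercept within 50% relative error
  nb <- sim_nb_counts(2000, mu = exp(rnorm(2000, log(500), 1)), alpha = 0.1)
  dn <- estimate_dispersion(nb$counts, rep(1, 4), ds)
  expect_gt(dn$trend[["a0"]], 0.05)
  expect_lt(dn$trend[["a0"]], 0.15)

  # the working dispersion respects a raised floor
  dfl <- estimate_dispersion(pois$counts, rep(1, 4), ds, alpha_min = 0.02)
  expect_true(all(dfl$alpha >= 0.02))

  expect_error(estimate_dispersion(pois$counts[, 1:3], rep(1, 3), ds),
               "4 samples")
  expect_error(design_spec(samples[1:2, ]), "2 donors")
})

test_that("Wald fit agrees with the reference GLM implementation", {
  set.seed(8)
  samples <- make_samples()
  ds <- design_spec(samples)
  G <- 40
  cm <- sim_nb_counts(G, mu = exp(runif(G, log(20), log(800))), alpha = 0.05)
  sf <- c(1, 1.3, 0.8, 1.1)
  alpha <- runif(G, 0.01, 0.2)
  st <- nb_wald_test(cm, size_factors = sf, dispersions = alpha,
                     design = ds, retained = rep(TRUE, G))
  df <- data.frame(donor = factor(samples$donor),
                   bin = factor(samples$bin, levels = c("high", "low")))
  for (g in seq(1, G, by = 4)) {
    y <- cm$counts[g, ]
    fit <- suppressWarnings(
      stats::glm(y ~ donor + bin, data = df,
                 family = MASS::negative.binomial(theta = 1 / alpha[g]),
                 offset = log(sf)))
    co <- summary(fit, dispersion = 1)$coefficients["binlow", ]
    expect_lt(abs(st$log2fc[g] - unname(co["Estimate"]) / log(2)), 1e-4)
    expect_lt(abs(st$lfc_se[g] - unname(co["Std. Error"]) / log(2)), 1e-4)
  }
})

test_that("exactly symmetric counts give zero effect and p = 1", {
  set.seed(3)
  base <- matrix(rpois(200, 100), ncol = 2) # one column per donor
  K <- cbind(base[, 1], base[, 1], base[, 2], base[, 2])
  cm <- make_count_matrix(K)
  st <- nb_wald_test(cm, dispersions = 0.05)
  expect_true(all(abs(st$log2fc[!st$filtered]) < 1e-8))
  expect_true(all(st$p_value[!st$filtered] > 1 - 1e-6))
})

test_that("rescaling a sample is absorbed by the size-factor offset", {
  set.seed(13)
  cm <- sim_nb_counts(300, mu = exp(runif(300, log(200), log(2000))),
                      alpha = 0.05)
  # exact offset invariance: a global rescaling of the size factors is
  # absorbed by the intercept and changes nothing
  sf <- size_factors(cm)
  st1 <- nb_wald_test(cm, size_factors = sf, dispersions = 0.05)
  st1b <- nb_wald_test(cm, size_factors = 7 * sf, dispersions = 0.05)
  expect_equal(st1b$wald_z, st1$wald_z, tolerance = 1e-6)
  expect_equal(st1b$log2fc, st1$log2fc, tolerance = 1e-6)
  # multiplying one sample's counts by 3 triples its size factor (up to
  # the common reference rescaling) and leaves the statistics nearly
  # unchanged in the overdispersion-dominated regime
  K2 <- cm$counts
  K2[, 2] <- K2[, 2] * 3L
  cm2 <- make_count_matrix(K2)
  sf2 <- size_factors(cm2)
  expect_equal(unname((sf2[2] / sf2[1]) / (sf[2] / sf[1])), 3,
               tolerance = 0.02)
  st2 <- nb_wald_test(cm2, size_factors = sf2, dispersions = 0.05)
  expect_equal(st2$wald_z, st1$wald_z, tolerance = 0.02)
  expect_gt(cor(st2$log2fc, st1$log2fc), 0.999)
})

test_that("type-I error is near nominal under the synthetic null", {
  null <- synthetic_null_screen(n_guides = 2000)
  cfg <- screen_config(n_cells = 200 * 2000, depth = 1e6, seed = 31)
  sim <- simulate_screen(null$model, null$library, cfg, null$context,
                         null$target_gene)
  st <- nb_wald_test(sim$counts)
  p <- st$p_value[!st$filtered]
  for (level in c(0.01, 0.05, 0.10)) {
    mc_se <- sqrt(level * (1 - level) / length(p))
    expect_lt(abs(mean(p < level) - level), 3 * mc_se + 0.005)
  }
})

test_that("detection power rises with planted effect size", {
  hits <- vapply(c(0.2, 0.4, 0.6), function(kappa) {
    span <- genomic_interval("chr_syn", 0, 20000)
    gene <- locus_gene("GOI", genomic_interval("chr_syn", 16000, 19000),
                       tss = 16000,
                       baseline_log_expression = c(Tconv_stim6h = 1))
    el <- reg_element("E", genomic_interval("chr_syn", 5000, 5500),
                      data.frame(gene = "GOI", context = "Tconv_stim6h",
                                 kappa = kappa))
    model <- locus_model(span, list(gene), list(el),
                         contexts = "Tconv_stim6h")
    lib <- tiling_positions_library(genomic_interval("chr_syn", 0, 10000),
                                    step = 50, target_span = span)
    cfg <- screen_config(n_cells = 40000, depth = 2e6, seed = 55)
    sim <- simulate_screen(model, lib, cfg, "Tconv_stim6h", "GOI")
    st <- nb_wald_test(sim$counts)
    inside <- st$five_prime_pos >= 5000 & st$five_prime_pos < 5500
    mean(st$p_adj[inside] < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
  expect_gt(hits[3], 0.9)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("effect estimates agree with DESeq2 on shared counts", {
  bench <- synthetic_benchmark_screen(step = 200)
  cfg <- screen_config(n_cells = 40000, depth = 1e6, seed = 9)
  sim <- simulate_screen(bench$model, bench$library, cfg, bench$context,
                         bench$target_gene)
  st <- nb_wald_test(sim$counts)
  suppressMessages({
    cd <- data.frame(donor = factor(sim$counts$samples$donor),
                     bin = factor(sim$counts$samples$bin,
                                  levels = c("high", "low")))
    dds <- DESeq2::DESeqDataSetFromMatrix(sim$counts$counts, cd,
                                          ~ donor + bin)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, name = "bin_low_vs_high")
  })
  ok <- !st$filtered & !is.na(res$log2FoldChange)
  expect_gt(cor(st$log2fc[ok], res$log2FoldChange[ok]), 0.98)
  # strong calls agree in direction
  strong <- ok & !is.na(res$padj) & res$padj < 1e-4
  expect_true(all(sign(st$log2fc[strong]) ==
                    sign(res$log2FoldChange[strong])))
})
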