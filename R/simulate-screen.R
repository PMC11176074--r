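#' Configuration of a simulated bin-sorted CRISPRi screen
#'
#' The generator emulates a pooled CRISPRi screen in primary cells: each
#' cell carries one guide (low-MOI transduction followed by selection),
#' guide knockdown efficacy decays with distance from regulatory-element
#' cores on a Gaussian kernel, cells are FACS-sorted into the bottom and
#' top `bin_fraction` of target-protein expression per donor, and guide
#' abundances are sequenced to a fixed depth with Gamma-multinomial
#' (approximately negative-binomial) overdispersion.
#'
#' @param n_cells Cells per donor.
#' @param depth Sequencing reads per sample (per sorted bin).
#' @param bin_fraction Fraction of cells sorted into each tail bin
#'   (default 0.20, the highest/lowest 20% expression bins).
#' @param e_max Maximal knockdown efficacy in \[0, 1\] (default 0.9,
#'   a strong KRAB-repressor CRISPRi system).
#' @param sigma_crispri Gaussian efficacy kernel width in bp (default 150:
#'   CRISPRi silencing is element-proximal).
#' @param n_donors Number of donors (default 2).
#' @param donor_sd SD of the per-donor log-expression offset.
#' @param expr_noise_sd SD of per-cell log-expression noise (default 1.0,
#'   i.e. lognormal biological + staining noise of ~100% CV).
#' @param alpha_sim Count overdispersion injected at the proportion level
#'   (Gamma shape `1/alpha_sim`, mean 1); 0 gives pure multinomial.
#' @param seed Global seed; every stage draws from named substreams of it.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(n_cells = 100000, depth = 1e6, bin_fraction = 0.20,
                          e_max = 0.9, sigma_crispri = 150, n_donors = 2,
                          donor_sd = 0.15, expr_noise_sd = 1.0,
                          alpha_sim = 0.01, seed = 1) {
  assert_scalar_number(n_cells, "n_cells", lower = 1)
  assert_scalar_number(depth, "depth", lower = 1)
  assert_scalar_number(bin_fraction, "bin_fraction", lower = 0,
                       strict_lower = TRUE, upper = 0.5)
  assert_scalar_number(e_max, "e_max", lower = 0, upper = 1)
  assert_scalar_number(sigma_crispri, "sigma_crispri", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(n_donors, "n_donors", lower = 1)
  assert_scalar_number(donor_sd, "donor_sd", lower = 0)
  assert_scalar_number(expr_noise_sd, "expr_noise_sd", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(alpha_sim, "alpha_sim", lower = 0)
  if (n_cells * bin_fraction < 100) {
    stopf("bin too small: n_cells * bin_fraction must be >= 100")
  }
  structure(list(n_cells = as.integer(n_cells), depth = depth,
                 bin_fraction = bin_fraction, e_max = e_max,
                 sigma_crispri = sigma_crispri,
                 n_donors = as.integer(n_donors), donor_sd = donor_sd,
                 expr_noise_sd = expr_noise_sd, alpha_sim = alpha_sim,
                 seed = seed),
            class = "screen_config")
}

#' Integer count matrix with sample metadata
#'
#' @param counts Non-negative integer matrix, guides x samples, with
#'   rownames = guide ids and colnames = sample ids.
#' @param samples `data.frame` with one row per column of `counts`:
#'   `sample_id`, `donor`, `bin` (`"low"`/`"high"`), `target_gene`,
#'   `context`.
#' @param guides `data.frame` with `guide_id` and `five_prime_pos`
#'   matching the rows of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, guides) {
  counts <- as.matrix(counts)
  samples <- as.data.frame(samples)
  guides <- as.data.frame(guides)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be non-negative integers")
  }
  if (nrow(samples) != ncol(counts)) stopf("one sample row per count column")
  if (nrow(guides) != nrow(counts)) stopf("one guide row per count row")
  if (anyDuplicated(paste(samples$donor, samples$bin, samples$target_gene,
                          samples$context))) {
    stopf("(donor, bin) must be unique within a screen")
  }
  rownames(counts) <- guides$guide_id
  colnames(counts) <- samples$sample_id
  rownames(samples) <- NULL
  rownames(guides) <- NULL
  structure(list(counts = counts, samples = samples, guides = guides),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " guides x ", ncol(x$counts),
      " samples\n", sep = "")
  invisible(x)
}

# distance from each center to the nearest base of each element core:
# 0 inside the core, else gap to the closest covered base center
element_distances <- function(centers, starts, ends) {
  d <- outer(centers, starts, function(cc, a) a - cc)
  d2 <- outer(centers, ends - 1, function(cc, b) cc - b)
  pmax(d, d2, 0)
}

#' Simulate a bin-sorted tiling CRISPRi screen
#'
#' Per donor: each cell receives one guide uniformly at random; guide
#' knockdown efficacy toward element E is
#' `e_max * exp(-d_E^2 / (2 * sigma_crispri^2))` with `d_E` the distance
#' from the protospacer center to the nearest base of E's core (0 inside;
#' every TSS acts as an element with kappa = 1 toward its own gene);
#' per-cell log expression is the context baseline plus a donor offset,
#' the summed element effects `log(1 - e_E * kappa_E)`, and Gaussian
#' noise; cells are ranked (stable tie-break by cell index) and the bottom
#' and top `bin_fraction` sorted into the low and high samples; guide
#' proportions per bin receive independent Gamma factors when
#' `alpha_sim > 0` and counts are drawn multinomially at `depth`.
#'
#' @param model A [locus_model()].
#' @param library A [guide_library()].
#' @param cfg A [screen_config()].
#' @param context Context label present in the model.
#' @param target_gene Gene whose protein level is sorted on.
#' @return List with `counts` (a [count_matrix()]) and `truth` (a
#'   `ground_truth` list: `elements`, `boundaries`, per-guide efficacy
#'   `efficacy` at the nearest element).
#' @export
simulate_screen <- function(model, library, cfg, context, target_gene) {
  stopifnot(inherits(model, "locus_model"), inherits(library, "guide_library"),
            inherits(cfg, "screen_config"))
  G <- n_guides(library)
  if (G == 0L) stopf("empty guide library")
  elems <- effective_elements(model, target_gene, context)
  gene <- model_gene(model, target_gene)
  baseline <- gene$baseline_log_expression[[context]] %||% 0

  centers <- guide_centers(library)
  dmat <- element_distances(centers, elems$start, elems$end)
  eff <- cfg$e_max * exp(-dmat^2 / (2 * cfg$sigma_crispri^2))
  mult <- 1 - sweep(eff, 2, elems$kappa, `*`)
  if (any(mult < 0)) stopf("invalid effect: 1 - e*kappa went negative")
  shift <- rowSums(log(pmax(mult, .Machine$double.xmin)))

  n_bin <- floor(cfg$bin_fraction * cfg$n_cells)
  counts <- matrix(0L, nrow = G, ncol = 2L * cfg$n_donors)
  samples <- data.frame(sample_id = character(2L * cfg$n_donors),
                        donor = "", bin = "", target_gene = target_gene,
                        context = context)
  draw_counts <- function(tab) {
    prop <- as.numeric(tab)
    if (cfg$alpha_sim > 0) {
      noise <- stats::rgamma(G, shape = 1 / cfg$alpha_sim,
                             scale = cfg$alpha_sim)
      prop <- prop * noise
    }
    if (sum(prop) <= 0) stopf("no cells in bin")
    stats::rmultinom(1, size = cfg$depth, prob = prop / sum(prop))[, 1]
  }
  for (d in seq_len(cfg$n_donors)) {
    res <- with_stream(cfg$seed, paste0("screen/", target_gene, "/", context,
                                        "/donor", d), {
      assign_g <- sample.int(G, cfg$n_cells, replace = TRUE)
      donor_off <- stats::rnorm(1, 0, cfg$donor_sd)
      expr <- baseline + donor_off + shift[assign_g] +
        stats::rnorm(cfg$n_cells, 0, cfg$expr_noise_sd)
      ord <- order(expr, seq_along(expr)) # stable tie-break by cell index
      low_cells <- ord[seq_len(n_bin)]
      high_cells <- ord[seq.int(cfg$n_cells - n_bin + 1L, cfg$n_cells)]
      low <- draw_counts(tabulate(assign_g[low_cells], nbins = G))
      high <- draw_counts(tabulate(assign_g[high_cells], nbins = G))
      list(low = low, high = high)
    })
    jl <- 2L * d - 1L
    counts[, jl] <- res$low
    counts[, jl + 1L] <- res$high
    samples$sample_id[c(jl, jl + 1L)] <-
      paste0("donor", d, "_", c("low", "high"))
    samples$donor[c(jl, jl + 1L)] <- paste0("donor", d)
    samples$bin[c(jl, jl + 1L)] <- c("low", "high")
  }
  nearest <- apply(dmat, 1, min)
  truth <- structure(list(
    elements = elems,
    boundaries = do.call(rbind, c(list(
      data.frame(id = character(), start = numeric(), end = numeric(),
                 strength = numeric())),
      lapply(model$boundaries, function(b) {
        data.frame(id = b$id, start = b$core$start, end = b$core$end,
                   strength = b$strength)
      }))),
    efficacy = data.frame(guide_id = library$guides$guide_id,
                          efficacy = cfg$e_max *
                            exp(-nearest^2 / (2 * cfg$sigma_crispri^2)))),
    class = "ground_truth")
  list(counts = count_matrix(counts, samples, library$guides[
         , c("guide_id", "five_prime_pos")]),
       truth = truth)
}

#' Per-guide log2 low/high count ratio with a reporting pseudocount
#'
#' The 0.5 pseudocount is for reporting only and never enters the GLM.
#'
#' @param counts A [count_matrix()].
#' @return Per-guide mean over donors of `log2((low + 0.5)/(high + 0.5))`.
#' @export
guide_log2_ratio <- function(counts) {
  low <- counts$counts[, counts$samples$bin == "low", drop = FALSE]
  high <- counts$counts[, counts$samples$bin == "high", drop = FALSE]
  rowMeans(log2((low + 0.5) / (high + 0.5)))
}

#' Emit per-sample guide-read FASTQ files from a count matrix
#'
#' Each count unit becomes one read `flank5 + protospacer + flank3` at
#' fixed quality; read names encode sample and serial number. Inverts
#' exactly through [count_guides()].
#'
#' @param counts A [count_matrix()].
#' @param library The [guide_library()] providing protospacers.
#' @param dir Output directory.
#' @param flank5,flank3 Fixed vector sequences around the protospacer.
#' @param gzip Compress output files.
#' @return Named character vector of FASTQ paths (one per sample).
#' @export
emit_guide_fastq <- function(counts, library, dir,
                             flank5 = "GTGGAAAGGACGAAACACCG",
                             flank3 = "GTTTAAGAGCTATGCTGGAA",
                             gzip = FALSE) {
  if (anyNA(library$guides$protospacer)) {
    stopf("library has guides without protospacer sequences")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(ncol(counts$counts))
  names(paths) <- counts$samples$sample_id
  for (j in seq_len(ncol(counts$counts))) {
    sid <- counts$samples$sample_id[j]
    kj <- counts$counts[, j]
    seqs <- paste0(flank5, rep(library$guides$protospacer, kj), flank3)
    reads <- Biostrings::DNAStringSet(seqs)
    if (length(reads)) {
      names(reads) <- sprintf("%s_read%07d", sid, seq_along(reads))
    }
    path <- file.path(dir, paste0(sid, ".fastq", if (gzip) ".gz" else ""))
    read_len <- nchar(flank5) + 20L + nchar(flank3)
    quals <- Biostrings::BStringSet(rep(strrep("I", read_len), length(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                compress = gzip, qualities = quals)
    paths[j] <- path
  }
  paths
}
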