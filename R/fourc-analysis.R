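#' Per-million normalization of a 4C track
#'
#' Scales raw fragment counts to reads per million, so normalized signal
#' sums to 1e6 on any non-empty track. An all-zero track normalizes to
#' all zeros with a warning.
#'
#' @param track A [fourc_track()].
#' @return The track with `norm_signal` filled.
#' @export
normalize_rpm <- function(track) {
  stopifnot(inherits(track, "fourc_track"))
  total <- sum(track$raw_counts)
  if (total <= 0) {
    warnf("track has zero total reads; normalized signal is all zero")
    track$norm_signal <- rep(0, length(track$raw_counts))
  } else {
    track$norm_signal <- track$raw_counts * 1e6 / total
  }
  track
}

#' Centered running-window mean over fragments
#'
#' Running mean over `k` consecutive fragments (fragment index, not bp).
#' At the track edges the window truncates to the available fragments.
#'
#' @param track A [fourc_track()] with `norm_signal` (run
#'   [normalize_rpm()] first).
#' @param k Odd window size in fragments (default 21).
#' @return The track with `windowed_signal` filled.
#' @export
running_window <- function(track, k = 21) {
  stopifnot(inherits(track, "fourc_track"))
  if (k %% 2 != 1 || k < 1) stopf("window size k must be odd and positive")
  if (is.null(track$norm_signal)) track <- normalize_rpm(track)
  x <- track$norm_signal
  track$windowed_signal <- as.numeric(
    zoo::rollapply(zoo::zoo(x), width = k, FUN = mean, partial = TRUE,
                   align = "center"))
  track
}

#' Spline smoothing of windowed 4C signal
#'
#' Fits a cubic smoothing spline to (fragment midpoint, windowed signal)
#' with a smoothing parameter on a 0-1 scale (`spar` of
#' [stats::smooth.spline()]): values near 0 approach interpolation and
#' values near 1 approach the least-squares line. `smoothing >= 1`
#' returns the exact least-squares line (the infinite-penalty limit).
#'
#' @param track A [fourc_track()]; windowed signal is computed with
#'   `window_k` if absent.
#' @param smoothing Smoothing parameter in \[0, 1\] (default 0.75).
#' @param window_k Running-window size used when the track has no
#'   windowed signal yet.
#' @return The track with `smoothed_signal` filled (fitted values at
#'   fragment midpoints).
#' @export
smooth_spline_track <- function(track, smoothing = 0.75, window_k = 21) {
  stopifnot(inherits(track, "fourc_track"))
  if (nrow(track$fragments) < 4L) stopf("need at least 4 fragments")
  if (is.null(track$windowed_signal)) track <- running_window(track, window_k)
  x <- fragment_midpoints(track)
  y <- track$windowed_signal
  if (smoothing >= 1) {
    fit <- stats::lm(y ~ x)
    track$smoothed_signal <- unname(stats::fitted(fit))
  } else {
    fit <- stats::smooth.spline(x, y, spar = smoothing, cv = FALSE,
                                all.knots = TRUE, keep.data = FALSE)
    track$smoothed_signal <- stats::predict(fit, x)$y
  }
  track
}

#' Log signal of captured fragments in a gene body
#'
#' Selects fragments whose midpoint lies inside the gene body and that
#' were captured (normalized signal > 0; log of zero is undefined and
#' uncaptured fragments carry no contact evidence), and returns the
#' natural log of their normalized signal. `pseudocount` adds to the raw
#' counts before re-normalization instead of dropping zeros.
#'
#' @param track A [fourc_track()] with `norm_signal`.
#' @param gene A [locus_gene()] or [genomic_interval()].
#' @param pseudocount Optional raw pseudocount (default none).
#' @param use `"norm"` (default, unsmoothed normalized signal) or
#'   `"smoothed"`.
#' @return Numeric vector of log signals (possibly empty).
#' @export
gene_body_signal <- function(track, gene, pseudocount = NULL,
                             use = c("norm", "smoothed")) {
  use <- match.arg(use)
  body <- if (inherits(gene, "locus_gene")) gene$body else gene
  stopifnot(inherits(body, "genomic_interval"))
  if (is.null(track$norm_signal)) track <- normalize_rpm(track)
  sig <- switch(use, norm = track$norm_signal,
                smoothed = track$smoothed_signal)
  if (is.null(sig)) stopf("track has no %s signal", use)
  if (!is.null(pseudocount)) {
    raw <- track$raw_counts + pseudocount
    sig <- raw * 1e6 / sum(raw)
  }
  mids <- fragment_midpoints(track)
  inside <- mids >= body$start & mids < body$end
  vals <- sig[inside]
  log(vals[vals > 0])
}

#' Compare gene-body 4C signal between two conditions
#'
#' Per gene: a two-sided two-sample t-test (Welch by default) on the log
#' normalized signals of captured fragments in the gene body, comparing
#' `track_b` against `track_a`; p-values are Bonferroni-corrected by the
#' number of gene bodies in the call. Genes with fewer than 2 captured
#' fragments in either condition are skipped with a flag.
#'
#' @param track_a Reference-condition [fourc_track()] (e.g. nontargeting
#'   control).
#' @param track_b Comparison-condition track (e.g. boundary knockdown).
#' @param genes List of [locus_gene()] (or intervals; names used as gene
#'   labels).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param use Signal passed to [gene_body_signal()].
#' @return `data.frame`: `gene`, `mean_log_a`, `mean_log_b`, `shift`
#'   (b - a), `t_statistic`, `p_value`, `p_adj`
#'   (`min(1, p * n_genes)`), `n_fragments_a`, `n_fragments_b`, `tested`.
#' @export
compare_gene_bodies <- function(track_a, track_b, genes, var_equal = FALSE,
                                use = "norm") {
  if (inherits(genes, "locus_gene") || inherits(genes, "genomic_interval")) {
    genes <- list(genes)
  }
  labels <- vapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    if (inherits(g, "locus_gene")) g$name
    else names(genes)[i] %||% paste0("gene", i)
  }, "")
  n_genes <- length(genes)
  rows <- lapply(seq_along(genes), function(i) {
    va <- gene_body_signal(track_a, genes[[i]], use = use)
    vb <- gene_body_signal(track_b, genes[[i]], use = use)
    row <- data.frame(gene = labels[i],
                      mean_log_a = if (length(va)) mean(va) else NA_real_,
                      mean_log_b = if (length(vb)) mean(vb) else NA_real_,
                      shift = NA_real_, t_statistic = NA_real_,
                      p_value = NA_real_, p_adj = NA_real_,
                      n_fragments_a = length(va), n_fragments_b = length(vb),
                      tested = FALSE)
    if (length(va) >= 2 && length(vb) >= 2) {
      tt <- tryCatch(stats::t.test(vb, va, var.equal = var_equal,
                                   alternative = "two.sided"),
                     error = function(e) NULL) # both vectors constant
      row$shift <- mean(vb) - mean(va)
      if (!is.null(tt)) {
        row$t_statistic <- unname(tt$statistic)
        row$p_value <- tt$p.value
        row$p_adj <- min(1, tt$p.value * n_genes)
        row$tested <- TRUE
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 4C track quality-control metrics
#'
#' Computes the standard viewpoint QC fractions: reads mapping to the
#' viewpoint chromosome (cis fraction), share of normalized coverage
#' within 1 Mb of the viewpoint, and fraction of fragments within 100 kb
#' of the viewpoint that were captured (raw count > 0). Default passing
#' thresholds are cis > 0.55, coverage-within-1Mb > 0.40, and
#' captured-within-100kb > 0.55.
#'
#' @param track A [fourc_track()] with `norm_signal`.
#' @param chrom_tally Optional named vector of read totals per
#'   chromosome (all chromosomes); when absent, all reads are assumed
#'   cis (single-locus simulations).
#' @param thresholds Named vector `cis`, `coverage_1mb`, `captured_100kb`.
#' @return List of the three fractions, per-metric pass flags, and
#'   overall `pass`.
#' @export
qc_metrics <- function(track, chrom_tally = NULL,
                       thresholds = c(cis = 0.55, coverage_1mb = 0.40,
                                      captured_100kb = 0.55)) {
  stopifnot(inherits(track, "fourc_track"))
  if (is.null(track$norm_signal)) track <- normalize_rpm(track)
  vp <- track$viewpoint
  if (is.null(chrom_tally)) {
    cis <- 1
  } else {
    total <- sum(chrom_tally)
    cis <- if (total > 0) sum(chrom_tally[vp$chrom], na.rm = TRUE) / total
    else 0
  }
  mids <- fragment_midpoints(track)
  dist <- abs(mids - vp$pos)
  total_norm <- sum(track$norm_signal)
  coverage_1mb <- if (total_norm > 0) {
    sum(track$norm_signal[dist <= 1e6]) / total_norm
  } else 0
  near <- dist <= 1e5
  captured_100kb <- if (any(near)) mean(track$raw_counts[near] > 0) else 0
  flags <- c(cis = unname(cis > thresholds["cis"]),
             coverage_1mb = unname(coverage_1mb > thresholds["coverage_1mb"]),
             captured_100kb = unname(captured_100kb >
                                       thresholds["captured_100kb"]))
  list(cis_fraction = unname(cis), fraction_coverage_within_1mb = coverage_1mb,
       fraction_fragments_captured_within_100kb = captured_100kb,
       flags = flags, pass = all(flags))
}
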