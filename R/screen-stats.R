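#' Count guide reads from FASTQ files
#'
#' Assigns a read to a guide by exact 20-mer match at a fixed offset
#' (the length of the 5' vector flank). Unmatched reads are tallied per
#' sample in the `unmatched` attribute. Libraries containing duplicate
#' protospacer sequences are rejected at load because assignment would be
#' ambiguous.
#'
#' @param fastq_files Named character vector (sample id -> FASTQ path;
#'   gzip accepted).
#' @param library A [guide_library()] with protospacers.
#' @param protospacer_offset 0-based offset of the protospacer within each
#'   read.
#' @param samples Optional sample `data.frame` (as in [count_matrix()]);
#'   when supplied, a full `count_matrix` is returned, otherwise a plain
#'   integer matrix.
#' @return Integer matrix guides x samples (or [count_matrix()]), with
#'   attribute `unmatched` giving unassigned reads per sample.
#' @export
count_guides <- function(fastq_files, library, protospacer_offset = 0,
                         samples = NULL) {
  proto <- library$guides$protospacer
  if (anyNA(proto)) stopf("library has guides without protospacers")
  if (anyDuplicated(proto)) {
    stopf("duplicate protospacer sequences in library: read assignment would be ambiguous")
  }
  if (is.null(names(fastq_files))) {
    names(fastq_files) <- sub("\\.fastq(\\.gz)?$", "", basename(fastq_files))
  }
  G <- n_guides(library)
  counts <- matrix(0L, nrow = G, ncol = length(fastq_files),
                   dimnames = list(library$guides$guide_id,
                                   names(fastq_files)))
  unmatched <- stats::setNames(integer(length(fastq_files)),
                               names(fastq_files))
  lookup <- stats::setNames(seq_len(G), proto)
  for (j in seq_along(fastq_files)) {
    reads <- Biostrings::readDNAStringSet(fastq_files[j], format = "fastq")
    if (length(reads) == 0L) next
    if (min(Biostrings::width(reads)) < protospacer_offset + 20L) {
      stopf("reads shorter than protospacer_offset + 20 in '%s'",
            fastq_files[j])
    }
    kmers <- as.character(Biostrings::subseq(reads, protospacer_offset + 1L,
                                             protospacer_offset + 20L))
    idx <- lookup[kmers]
    unmatched[j] <- sum(is.na(idx))
    tab <- tabulate(idx[!is.na(idx)], nbins = G)
    counts[, j] <- tab
  }
  if (!is.null(samples)) {
    out <- count_matrix(counts, samples,
                        library$guides[, c("guide_id", "five_prime_pos")])
    attr(out, "unmatched") <- unmatched
    return(out)
  }
  attr(counts, "unmatched") <- unmatched
  counts
}

#' Flag guides with too few reads per condition
#'
#' A guide is excluded for a condition when its read sum across all
#' samples of that condition is below `threshold` (strictly fewer than
#' `threshold` reads). The alternate reading, requiring every single
#' sample to be below the threshold, is available via `mode = "each"`.
#'
#' @param counts A [count_matrix()] or integer matrix.
#' @param threshold Minimum per-condition read total (default 10).
#' @param condition Factor assigning samples to conditions; defaults to a
#'   single condition covering all samples (one screen = one condition).
#' @param mode `"sum"` (default: condition-wise sum below threshold) or
#'   `"each"` (every sample below threshold).
#' @return Logical vector (single condition) or guides x conditions
#'   logical matrix of retained guides.
#' @export
filter_low_counts <- function(counts, threshold = 10, condition = NULL,
                              mode = c("sum", "each")) {
  mode <- match.arg(mode)
  K <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  if (is.null(condition)) condition <- rep("all", ncol(K))
  condition <- as.factor(condition)
  keep <- sapply(levels(condition), function(lv) {
    sub <- K[, condition == lv, drop = FALSE]
    if (mode == "sum") rowSums(sub) >= threshold
    else apply(sub, 1, function(x) any(x >= threshold))
  })
  keep <- matrix(keep, nrow = nrow(K),
                 dimnames = list(rownames(K), levels(condition)))
  if (ncol(keep) == 1L) keep[, 1] else keep
}

#' Median-of-ratios size factors
#'
#' The reference per guide is the geometric mean of its counts across
#' samples, computed over guides with strictly positive counts in every
#' sample; each sample's factor is the median across those guides of
#' count / reference.
#'
#' @param counts A [count_matrix()] or integer matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  K <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  .size_factors(K)
}

.size_factors <- function(K) {
  all_pos <- rowSums(K <= 0) == 0
  if (!any(all_pos)) {
    stopf("no guide has positive counts in every sample; increase depth, relax filtering, or pool fewer samples")
  }
  ref <- exp(rowMeans(log(K[all_pos, , drop = FALSE])))
  apply(K[all_pos, , drop = FALSE] / ref, 2, stats::median)
}

#' Design of the low-vs-high contrast
#'
#' Donor enters as a fixed categorical factor; the tested coefficient is
#' bin low vs high, coded so positive log2 fold change means enriched in
#' the low-expression bin (the guide suppresses target expression).
#'
#' @param samples Sample `data.frame` with `donor` and `bin` columns.
#' @return An object of class `design_spec` carrying the model matrix.
#' @export
design_spec <- function(samples) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("donor", "bin") %in% names(samples)))
  if (!all(samples$bin %in% c("low", "high"))) {
    stopf("bin must be 'low' or 'high'")
  }
  donors <- unique(samples$donor)
  if (length(donors) < 2L) stopf("design requires >= 2 donors")
  per_donor <- tapply(samples$bin, samples$donor,
                      function(b) all(c("low", "high") %in% b))
  if (!all(unlist(per_donor))) stopf("both bins required for every donor")
  df <- data.frame(donor = factor(samples$donor),
                   bin = factor(samples$bin, levels = c("high", "low")))
  X <- stats::model.matrix(~ donor + bin, df)
  if (qr(X)$rank < ncol(X)) stopf("design matrix is not full rank")
  structure(list(samples = samples, matrix = X,
                 coef = "binlow"), class = "design_spec")
}

# Vectorized IRLS for per-guide NB (or Poisson, alpha = 0) log-link GLMs
# sharing one design matrix and per-sample offsets. Returns coefficients,
# the Fisher-information SE of `coef_index`, fitted means and a
# convergence flag. Written for thousands of guides x a handful of
# samples: all S x G quantities are matrices, with one small P x P solve
# per guide per iteration (active-set restricted).
nb_irls <- function(Y, X, offset, alpha, coef_index, maxit = 60L,
                    tol = 1e-9) {
  Yt <- t(Y)                                  # S x G
  S <- nrow(Yt); G <- ncol(Yt); P <- ncol(X)
  if (length(alpha) == 1L) alpha <- rep(alpha, G)
  OFF <- matrix(offset, S, G)
  ETA <- log(Yt + 0.5)
  B <- matrix(0, P, G)
  # initialize B from one working least-squares step at W = 1
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, ETA - OFF)
  active <- rep(TRUE, G)
  failed <- rep(FALSE, G)
  pairs <- which(upper.tri(matrix(0, P, P), diag = TRUE), arr.ind = TRUE)
  A_entries <- matrix(0, nrow(pairs), G)
  RHS <- matrix(0, P, G)
  for (it in seq_len(maxit)) {
    if (!any(active)) break
    ETA <- pmin(pmax(X %*% B + OFF, -30), 30)
    MU <- exp(ETA)
    W <- MU / (1 + sweep(MU, 2, alpha, `*`))
    Z <- ETA - OFF + (Yt - MU) / MU
    WZ <- W * Z
    for (r in seq_len(nrow(pairs))) {
      A_entries[r, ] <- crossprod(X[, pairs[r, 1]] * X[, pairs[r, 2]], W)
    }
    for (a in seq_len(P)) RHS[a, ] <- crossprod(X[, a], WZ)
    idx <- which(active)
    A <- matrix(0, P, P)
    for (g in idx) {
      A[cbind(pairs[, 1], pairs[, 2])] <- A_entries[, g]
      A[cbind(pairs[, 2], pairs[, 1])] <- A_entries[, g]
      bnew <- tryCatch(solve(A, RHS[, g]), error = function(e) NULL)
      if (is.null(bnew) || anyNA(bnew)) {
        failed[g] <- TRUE
        active[g] <- FALSE
        next
      }
      if (max(abs(bnew - B[, g])) < tol) active[g] <- FALSE
      B[, g] <- bnew
    }
  }
  failed <- failed | active # still-active guides did not converge
  # Fisher information at the final fit
  ETA <- pmin(pmax(X %*% B + OFF, -30), 30)
  MU <- exp(ETA)
  W <- MU / (1 + sweep(MU, 2, alpha, `*`))
  for (r in seq_len(nrow(pairs))) {
    A_entries[r, ] <- crossprod(X[, pairs[r, 1]] * X[, pairs[r, 2]], W)
  }
  se <- rep(NA_real_, G)
  A <- matrix(0, P, P)
  for (g in seq_len(G)) {
    A[cbind(pairs[, 1], pairs[, 2])] <- A_entries[, g]
    A[cbind(pairs[, 2], pairs[, 1])] <- A_entries[, g]
    Ai <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ai) || Ai[coef_index, coef_index] <= 0) {
      failed[g] <- TRUE
    } else {
      se[g] <- sqrt(Ai[coef_index, coef_index])
    }
  }
  list(beta = B, se = se, mu = t(MU), failed = failed)
}

# Cox-Reid adjusted NB profile log-likelihood, evaluated per guide on a
# dispersion grid at fixed fitted means. The CR term -1/2 log det(X'WX)
# compensates the degrees of freedom spent on the mean fit, which at one
# residual df would otherwise bias moment estimators low.
cr_apl_genewise <- function(Yt, MU, X, grid) {
  G <- ncol(Yt); P <- ncol(X)
  pairs <- which(upper.tri(matrix(0, P, P), diag = TRUE), arr.ind = TRUE)
  ll <- matrix(-Inf, length(grid), G)
  E <- matrix(0, nrow(pairs), G)
  for (k in seq_along(grid)) {
    a <- grid[k]; r <- 1 / a
    L <- colSums(lgamma(Yt + r) - lgamma(r) + r * log(r / (r + MU)) +
                   Yt * log(MU / (r + MU)))
    W <- MU / (1 + a * MU)
    for (rr in seq_len(nrow(pairs))) {
      E[rr, ] <- crossprod(X[, pairs[rr, 1]] * X[, pairs[rr, 2]], W)
    }
    ldet <- if (P == 3L) {
      a11 <- E[1, ]; a12 <- E[2, ]; a22 <- E[3, ]
      a13 <- E[4, ]; a23 <- E[5, ]; a33 <- E[6, ]
      log(pmax(a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
                 a13 * (a12 * a23 - a22 * a13), 1e-300))
    } else {
      A <- matrix(0, P, P)
      vapply(seq_len(G), function(g) {
        A[cbind(pairs[, 1], pairs[, 2])] <- E[, g]
        A[cbind(pairs[, 2], pairs[, 1])] <- E[, g]
        determinant(A, logarithm = TRUE)$modulus
      }, numeric(1))
    }
    ll[k, ] <- L - 0.5 * ldet
  }
  grid[apply(ll, 2, which.max)]
}

#' Estimate per-guide negative-binomial dispersions
#'
#' Gene-wise dispersions are estimated per guide, at the fitted means of
#' an initial Poisson GLM of the full design, either by maximizing the
#' Cox-Reid adjusted profile likelihood on a dispersion grid (default;
#' the adjustment compensates the degrees of freedom consumed by the mean
#' fit) or by a Pearson method-of-moments estimator (squared residuals
#' scaled by `S / (S - P)`). A mean-dispersion trend
#' `alpha(mu) = a1 / mu + a0` is then fit by least squares across guides
#' (a light 0.1% extreme-magnitude trim; coefficients constrained
#' non-negative by refitting). The default working dispersion is the
#' trend evaluated at each guide's base mean, floored at `alpha_min`;
#' `method = "maximum"` takes the elementwise maximum of the gene-wise
#' estimate and the trend.
#'
#' @param counts A [count_matrix()] or integer matrix (tested guides only).
#' @param size_factors Per-sample size factors.
#' @param design A [design_spec()].
#' @param alpha_min Dispersion floor (default 1e-8).
#' @param method `"trended"` (default) or `"maximum"`.
#' @param genewise_method `"cr_apl"` (default) or `"moments"`.
#' @return An object of class `dispersion_fit`: `alpha` (working values),
#'   `genewise`, `trend` (`a0`, `a1`), `base_mean`.
#' @export
estimate_dispersion <- function(counts, size_factors, design,
                                alpha_min = 1e-8,
                                method = c("trended", "maximum"),
                                genewise_method = c("cr_apl", "moments")) {
  method <- match.arg(method)
  genewise_method <- match.arg(genewise_method)
  K <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  X <- design$matrix
  S <- ncol(K); P <- ncol(X)
  if (S < 4L) stopf("design not estimable with fewer than 4 samples")
  if (S <= P) stopf("no residual degrees of freedom")
  fit <- nb_irls(K, X, log(size_factors), alpha = 0,
                 coef_index = match(design$coef, colnames(X)))
  MU <- fit$mu
  base_mean <- rowMeans(sweep(K, 2, size_factors, `/`))
  genewise <- if (genewise_method == "cr_apl") {
    grid <- exp(seq(log(1e-6), log(32), length.out = 81))
    cr_apl_genewise(t(K), t(MU), X, grid)
  } else {
    resid2 <- (K - MU)^2 * (S / (S - P))
    rowSums(resid2 - MU) / rowSums(MU^2)
  }
  ok <- is.finite(genewise) & base_mean > 0
  if (sum(ok) >= 10) {
    cap <- stats::quantile(abs(genewise[ok]), 0.999, names = FALSE)
    ok <- ok & abs(genewise) <= cap
  }
  x <- 1 / base_mean[ok]
  y <- genewise[ok]
  tf <- stats::lm(y ~ x)
  a0 <- unname(stats::coef(tf)[1]); a1 <- unname(stats::coef(tf)[2])
  if (is.na(a1) || a1 < 0) { # refit without the 1/mu term
    a1 <- 0
    a0 <- mean(y)
  }
  if (a0 < 0) { # refit through the origin
    a0 <- 0
    a1 <- max(0, unname(stats::coef(stats::lm(y ~ x + 0))[1]))
  }
  trend_at <- pmax(a0 + a1 / pmax(base_mean, .Machine$double.eps), alpha_min)
  alpha <- switch(method,
                  trended = trend_at,
                  maximum = pmax(trend_at, genewise, alpha_min))
  structure(list(alpha = unname(alpha), genewise = unname(genewise),
                 trend = c(a0 = a0, a1 = a1), base_mean = unname(base_mean),
                 method = method, genewise_method = genewise_method),
            class = "dispersion_fit")
}

#' Per-guide negative-binomial Wald test, low vs high bin
#'
#' Fits, per guide, an NB GLM with log link, offsets `log(size factor)`,
#' and coefficients intercept + donor + bin, by iteratively reweighted
#' least squares at fixed dispersion; the Wald statistic is the bin
#' coefficient over its Fisher-information standard error with a
#' two-sided normal p-value, and p-values are Benjamini-Hochberg adjusted
#' across tested guides. Convergence failures are flagged and assigned
#' p = 1 (conservative) so downstream peak positions are never silently
#' perturbed. Positive log2 fold change = enriched in the low-expression
#' bin.
#'
#' @param counts A [count_matrix()].
#' @param size_factors Per-sample size factors (default: recomputed).
#' @param dispersions A [estimate_dispersion()] fit, or numeric vector /
#'   scalar of per-guide dispersions (default: estimated, trended).
#' @param design A [design_spec()] (default: built from the samples).
#' @param retained Logical vector of guides to test (default: the
#'   [filter_low_counts()] mask at threshold 10).
#' @return A `data.frame` guide-statistic table: `guide_id`,
#'   `five_prime_pos`, `base_mean`, `log2fc`, `lfc_se`, `wald_z`,
#'   `p_value`, `p_adj`, `filtered`, `converged`. Filtered guides carry
#'   `NA` statistics.
#' @export
nb_wald_test <- function(counts, size_factors = NULL, dispersions = NULL,
                         design = NULL, retained = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  K <- counts$counts
  if (any(K < 0) || any(K != round(K))) {
    stopf("counts must be non-negative integers")
  }
  design <- design %||% design_spec(counts$samples)
  retained <- retained %||% filter_low_counts(counts)
  Ksub <- K[retained, , drop = FALSE]
  sf <- size_factors %||% .size_factors(Ksub)
  disp <- dispersions %||% estimate_dispersion(Ksub, sf, design)
  alpha <- if (inherits(disp, "dispersion_fit")) disp$alpha else disp
  if (length(alpha) == 1L) alpha <- rep(alpha, nrow(Ksub))
  if (length(alpha) != nrow(Ksub)) {
    stopf("need one dispersion per tested guide")
  }
  X <- design$matrix
  ci <- match(design$coef, colnames(X))
  fit <- nb_irls(Ksub, X, log(sf), alpha, coef_index = ci)
  beta <- fit$beta[ci, ]
  z <- beta / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  p[fit$failed | !is.finite(p)] <- 1
  z[fit$failed] <- 0
  out <- data.frame(guide_id = counts$guides$guide_id,
                    five_prime_pos = counts$guides$five_prime_pos,
                    base_mean = NA_real_, log2fc = NA_real_,
                    lfc_se = NA_real_, wald_z = NA_real_,
                    p_value = NA_real_, p_adj = NA_real_,
                    filtered = !retained, converged = NA)
  out$base_mean[retained] <- rowMeans(sweep(Ksub, 2, sf, `/`))
  out$log2fc[retained] <- beta / log(2)
  out$lfc_se[retained] <- fit$se / log(2)
  out$wald_z[retained] <- z
  out$p_value[retained] <- p
  out$p_adj[retained] <- bh_adjust(p)
  out$converged[retained] <- !fit$failed
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1), as
#' provided by [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Write / read a guide-statistic table
#'
#' @param stats A guide-statistic `data.frame` from [nb_wald_test()].
#' @param path TSV path.
#' @export
write_guide_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_guide_stats
#' @export
read_guide_stats <- function(path) {
  read_tsv_checked(path, c("guide_id", "five_prime_pos", "base_mean",
                           "log2fc", "lfc_se", "wald_z", "p_value", "p_adj",
                           "filtered"))
}

#' Write per-guide -log10 p-values as a browser bedGraph
#'
#' @param stats Guide-statistic table.
#' @param path Output bedGraph path.
#' @param chrom Chromosome label.
#' @export
write_pvalue_bedgraph <- function(stats, path, chrom) {
  st <- stats[!stats$filtered & !is.na(stats$p_value), , drop = FALSE]
  st <- st[order(st$five_prime_pos), , drop = FALSE]
  df <- data.frame(chrom = chrom, start = st$five_prime_pos,
                   end = st$five_prime_pos + 1,
                   value = -log10(pmax(st$p_value, 1e-300)))
  write_bedgraph(df, path)
}
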