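#' Contact-map kernel parameters
#'
#' Parameters of the analytic contact predictor: a power-law distance decay
#' `c0 * (d + d0)^(-gamma)` attenuated by `prod(1 - s_b)` over every
#' boundary element lying between the two loci.
#'
#' @param gamma Decay exponent (> 0).
#' @param d0 Distance offset in bp (> 0); sets the diagonal (self-contact)
#'   value `c0 * d0^(-gamma)`.
#' @param c0 Overall scale (> 0).
#' @param bin_size Bin width in bp; the default 2,048 bp gives a ~512-bin
#'   map over a ~1 Mb window, the working resolution of deep contact-map
#'   predictors.
#' @return An object of class `contact_kernel`.
#' @export
contact_kernel <- function(gamma = 1.0, d0 = 5000, c0 = 1.0,
                           bin_size = 2048) {
  assert_scalar_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  assert_scalar_number(d0, "d0", lower = 0, strict_lower = TRUE)
  assert_scalar_number(c0, "c0", lower = 0, strict_lower = TRUE)
  assert_scalar_number(bin_size, "bin_size", lower = 0, strict_lower = TRUE)
  structure(list(gamma = gamma, d0 = d0, c0 = c0, bin_size = bin_size),
            class = "contact_kernel")
}

#' Symmetric binned contact map
#'
#' @param window [genomic_interval()] the map covers.
#' @param bin_size Bin width, bp.
#' @param values `n x n` symmetric matrix of non-negative contact values,
#'   `n = floor(width / bin_size)`.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(window, bin_size, values) {
  stopifnot(inherits(window, "genomic_interval"))
  values <- as.matrix(values)
  n <- floor(gi_width(window) / bin_size)
  if (nrow(values) != n || ncol(values) != n) {
    stopf("values must be %d x %d for this window/bin_size", n, n)
  }
  if (any(values < 0)) stopf("contact values must be non-negative")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12))) {
    stopf("contact map must be symmetric")
  }
  structure(list(window = window, bin_size = bin_size, values = values),
            class = "contact_map")
}

#' Predict a contact map from a locus model
#'
#' Analytic predictor: bin-center distance decay times the product of
#' `1 - strength` over every boundary whose core midpoint lies strictly
#' between the two bin centers. Any other predictor with the same
#' signature and [contact_map()] invariants can be plugged into
#' [scan_deletions()] in its place.
#'
#' @param model A [locus_model()].
#' @param window [genomic_interval()] within the model span, width at least
#'   `2 * bin_size`.
#' @param kernel A [contact_kernel()].
#' @return A [contact_map()].
#' @export
predict_contact_map <- function(model, window, kernel = contact_kernel()) {
  stopifnot(inherits(model, "locus_model"), inherits(window, "genomic_interval"))
  if (!gi_contains(model$span, window)) stopf("window outside model span")
  bs <- kernel$bin_size
  if (gi_width(window) < 2 * bs) stopf("window must span at least two bins")
  n <- floor(gi_width(window) / bs)
  centers <- window$start + (seq_len(n) - 0.5) * bs
  d <- abs(outer(centers, centers, `-`))
  values <- kernel$c0 * (d + kernel$d0)^(-kernel$gamma)
  for (b in model$boundaries) {
    m <- gi_midpoint(b$core)
    left <- centers < m
    right <- centers > m
    cross <- outer(left, right, `&`)
    cross <- cross | t(cross)
    values[cross] <- values[cross] * (1 - b$strength)
  }
  contact_map(window, bs, values)
}

#' Mean squared difference between two contact maps
#'
#' Mean of squared elementwise differences over the strict upper triangle;
#' the diagonal is excluded because self-contact bins dominate magnitude
#' and carry no insulation signal.
#'
#' @param a,b [contact_map()]s over the same window and bin size.
#' @return Non-negative scalar MSE.
#' @export
map_mse <- function(a, b) {
  stopifnot(inherits(a, "contact_map"), inherits(b, "contact_map"))
  if (a$bin_size != b$bin_size ||
      !identical(dim(a$values), dim(b$values)) ||
      a$window$chrom != b$window$chrom ||
      a$window$start != b$window$start || a$window$end != b$window$end) {
    stopf("contact maps differ in window, bin size or shape")
  }
  ut <- upper.tri(a$values)
  mean((a$values[ut] - b$values[ut])^2)
}

#' Write a contact map as a dense TSV
#' @param map A [contact_map()].
#' @param path Output path.
#' @export
write_contact_map_tsv <- function(map, path) {
  utils::write.table(map$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a contact map as bin_i / bin_j / value triplets
#' @param map A [contact_map()].
#' @param path Output path.
#' @export
write_contact_map_triplets <- function(map, path) {
  n <- nrow(map$values)
  idx <- which(upper.tri(map$values, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1], bin_j = idx[, 2],
                   value = map$values[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
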