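#' Viewpoint-anchored 4C fragment track
#'
#' @param viewpoint List with `chrom` and `pos` (0-based bp).
#' @param fragments `data.frame` of non-overlapping, sorted fragment
#'   intervals with columns `start`, `end`.
#' @param raw_counts Integer reads per fragment.
#' @param condition Condition label.
#' @param norm_signal Optional per-million normalized signal.
#' @param smoothed_signal Optional smoothed signal.
#' @param windowed_signal Optional running-window signal.
#' @return An object of class `fourc_track`.
#' @export
fourc_track <- function(viewpoint, fragments, raw_counts,
                        condition = "unknown", norm_signal = NULL,
                        smoothed_signal = NULL, windowed_signal = NULL) {
  fragments <- as.data.frame(fragments)
  stopifnot(all(c("start", "end") %in% names(fragments)))
  n <- nrow(fragments)
  if (length(raw_counts) != n) stopf("one raw count per fragment")
  if (any(raw_counts < 0) || any(raw_counts != round(raw_counts))) {
    stopf("raw counts must be non-negative integers")
  }
  if (n > 1L) {
    if (is.unsorted(fragments$start)) stopf("fragments must be sorted")
    if (any(fragments$start[-1] < fragments$end[-n])) {
      stopf("fragments must be non-overlapping")
    }
  }
  for (v in list(norm_signal, smoothed_signal, windowed_signal)) {
    if (!is.null(v) && length(v) != n) {
      stopf("per-fragment vectors must have equal length")
    }
  }
  structure(list(viewpoint = viewpoint, fragments = fragments,
                 raw_counts = as.numeric(raw_counts),
                 norm_signal = norm_signal,
                 windowed_signal = windowed_signal,
                 smoothed_signal = smoothed_signal, condition = condition),
            class = "fourc_track")
}

#' @export
print.fourc_track <- function(x, ...) {
  cat("<fourc_track> ", nrow(x$fragments), " fragments, viewpoint ",
      x$viewpoint$chrom, ":", x$viewpoint$pos, " (", x$condition, ")\n",
      sep = "")
  invisible(x)
}

fragment_midpoints <- function(track) {
  (track$fragments$start + track$fragments$end) / 2
}

#' Simulate a 4C-seq viewpoint track over a locus model
#'
#' Restriction fragments partition the model span with lognormal lengths;
#' the expected signal of each fragment is the analytic contact between
#' the viewpoint and the fragment midpoint (power-law distance decay
#' attenuated by boundaries, with each boundary's strength scaled by
#' `1 - knockdown`); reads are drawn multinomially at `depth` and stored
#' raw and per-million normalized.
#'
#' @param model A [locus_model()].
#' @param viewpoint Viewpoint position (bp) within the model span.
#' @param kernel A [contact_kernel()].
#' @param n_fragments Ignored when `mean_fragment_bp` fixes the partition;
#'   retained for explicit control of the expected fragment count (the
#'   span is always fully partitioned).
#' @param mean_fragment_bp Mean restriction-fragment length, bp.
#' @param depth Total reads on the track.
#' @param boundary_knockdown Named numeric vector mapping boundary id to a
#'   knockdown fraction in \[0, 1\] (CRISPRi-style boundary disruption).
#' @param seed Global seed (named substream `"fourc/<condition>"`).
#' @param condition Condition label stored on the track.
#' @return A [fourc_track()] with `norm_signal` filled in.
#' @export
simulate_fourc <- function(model, viewpoint, kernel = contact_kernel(),
                           n_fragments = NULL, mean_fragment_bp = 1000,
                           depth = 5e5, boundary_knockdown = numeric(),
                           seed = 1, condition = "control") {
  span <- model$span
  if (viewpoint < span$start || viewpoint >= span$end) {
    stopf("viewpoint outside model span")
  }
  if (length(boundary_knockdown)) {
    for (id in names(boundary_knockdown)) model_boundary_index(model, id)
    if (any(boundary_knockdown < 0 | boundary_knockdown > 1)) {
      stopf("knockdown fractions must be in [0, 1]")
    }
  }
  width <- gi_width(span)
  target_n <- n_fragments %||% ceiling(width / mean_fragment_bp)
  with_stream(seed, paste0("fourc/", condition), {
    sdlog <- 0.6
    meanlog <- log(mean_fragment_bp) - sdlog^2 / 2
    lens <- pmax(50, round(stats::rlnorm(ceiling(2.5 * target_n),
                                         meanlog, sdlog)))
    ends <- cumsum(lens)
    while (ends[length(ends)] < width) {
      more <- pmax(50, round(stats::rlnorm(target_n, meanlog, sdlog)))
      lens <- c(lens, more)
      ends <- cumsum(lens)
    }
    k <- which(ends >= width)[1]
    bounds <- c(0, pmin(ends[seq_len(k)], width))
    frags <- data.frame(start = span$start + bounds[-(k + 1)],
                        end = span$start + bounds[-1])
    mids <- (frags$start + frags$end) / 2
    d <- abs(mids - viewpoint)
    w <- kernel$c0 * (d + kernel$d0)^(-kernel$gamma)
    for (b in model$boundaries) {
      s <- b$strength
      kd <- boundary_knockdown[b$id]
      if (length(kd) && !is.na(kd)) s <- s * (1 - kd)
      m <- gi_midpoint(b$core)
      cross <- (mids < m & viewpoint > m) | (mids > m & viewpoint < m)
      w[cross] <- w[cross] * (1 - s)
    }
    raw <- stats::rmultinom(1, size = depth, prob = w / sum(w))[, 1]
    normalize_rpm(fourc_track(list(chrom = span$chrom, pos = viewpoint),
                              frags, raw, condition = condition))
  })
}

#' Expected (noise-free) 4C signal under the analytic kernel
#'
#' Closed-form expected per-fragment signal used by tests: distance decay
#' from the viewpoint attenuated by boundary insulation.
#'
#' @inheritParams simulate_fourc
#' @param fragment_midpoints Numeric midpoints to evaluate.
#' @return Expected contact value per midpoint (unnormalized).
#' @export
expected_fourc_signal <- function(model, viewpoint, fragment_midpoints,
                                  kernel = contact_kernel(),
                                  boundary_knockdown = numeric()) {
  d <- abs(fragment_midpoints - viewpoint)
  w <- kernel$c0 * (d + kernel$d0)^(-kernel$gamma)
  for (b in model$boundaries) {
    s <- b$strength
    kd <- boundary_knockdown[b$id]
    if (length(kd) && !is.na(kd)) s <- s * (1 - kd)
    m <- gi_midpoint(b$core)
    cross <- (fragment_midpoints < m & viewpoint > m) |
      (fragment_midpoints > m & viewpoint < m)
    w[cross] <- w[cross] * (1 - s)
  }
  w
}
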