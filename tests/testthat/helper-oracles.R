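# Shared fixtures and independent brute-force oracles.

make_samples <- function(n_donors = 2) {
  data.frame(sample_id = paste0("donor", rep(seq_len(n_donors), each = 2),
                                "_", c("low", "high")),
             donor = paste0("donor", rep(seq_len(n_donors), each = 2)),
             bin = rep(c("low", "high"), n_donors),
             target_gene = "GOI", context = "Tconv_stim6h")
}

make_count_matrix <- function(K, samples = make_samples(ncol(K) / 2),
                              positions = NULL) {
  guides <- data.frame(guide_id = sprintf("g%04d", seq_len(nrow(K))),
                       five_prime_pos = positions %||%
                         (seq_len(nrow(K)) - 1) * 50)
  count_matrix(K, samples, guides)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Benjamini-Hochberg by direct step-up definition, independent of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# O(n^2) pairwise merging to fixed point over significant guides
cire_oracle <- function(pos, sig, log2fc, max_gap = 500, min_guides = 2) {
  idx <- which(sig)
  if (!length(idx)) return(list())
  clusters <- lapply(idx, identity)
  repeat {
    merged <- FALSE
    for (i in seq_along(clusters)) {
      if (merged) break
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- min(abs(outer(pos[clusters[[i]]], pos[clusters[[j]]], `-`)))
        if (d < max_gap) {
          clusters[[i]] <- sort(union(clusters[[i]], clusters[[j]]))
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  clusters <- Filter(function(cl) length(cl) >= min_guides, clusters)
  clusters <- lapply(clusters, function(cl) cl[order(pos[cl], cl)])
  clusters[order(vapply(clusters, function(cl) min(pos[cl]), numeric(1)))]
}

# guide-statistic table from raw ingredients, for caller tests
fake_stats <- function(pos, p_adj, log2fc = rep(1, length(pos)),
                       ids = sprintf("g%04d", seq_along(pos))) {
  data.frame(guide_id = ids, five_prime_pos = pos, base_mean = 100,
             log2fc = log2fc, lfc_se = 0.1, wald_z = log2fc / 0.1,
             p_value = p_adj, p_adj = p_adj, filtered = FALSE,
             converged = TRUE)
}

# NB counts under the fitted model, for statistics oracles
sim_nb_counts <- function(G, mu, alpha, samples = make_samples()) {
  S <- nrow(samples)
  if (length(mu) == 1) mu <- rep(mu, G)
  K <- matrix(stats::rnbinom(G * S, mu = rep(mu, S),
                             size = 1 / pmax(alpha, 1e-12)), G, S)
  make_count_matrix(K, samples)
}
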