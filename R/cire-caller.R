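#' Call CRISPRi-responsive elements (CiREs) from guide statistics
#'
#' Significant guides (`p_adj < alpha`) are pooled across the supplied
#' screens (union), deduplicated by guide id (keeping the smallest
#' adjusted p), sorted by 5' position, and merged into runs: a new run
#' starts whenever the gap to the previous significant guide is at least
#' `max_gap` (strictly-less-than-`max_gap` gaps stay together). Each
#' surviving run becomes a CiRE whose boundaries are the 5' genomic start
#' positions of its first and last member guides. Runs with fewer than
#' `min_guides` members are discarded. Direction is the sign of the
#' member mean log2 fold change, flagged `"mixed"` when member signs
#' disagree (mixed runs are kept whole unless `split_by_sign`).
#'
#' @param stats A guide-statistic table (from [nb_wald_test()]) or a named
#'   list of them (one per screen).
#' @param alpha Significance cut on adjusted p (default 0.05).
#' @param max_gap Maximum guide-to-guide distance kept inside a run, bp
#'   (default 500; gaps `>= max_gap` split).
#' @param min_guides Minimum guides per CiRE (default 2: a "run" of
#'   guides; singletons inflate false positives under tiling-library
#'   multiplicity).
#' @param split_by_sign Split runs at sign changes of log2fc instead of
#'   flagging them mixed.
#' @param pad_protospacer Add 20 bp to the interval end for browser
#'   display (off by default: boundaries are the guide start positions
#'   exactly).
#' @return `data.frame` with one row per CiRE: `cire_id`, `start`, `end`,
#'   `n_guides`, `direction` (`"activating"` = low-bin-enriched,
#'   `"repressive"` = high-bin-enriched, or `"mixed"`), `mean_log2fc`,
#'   `min_p_adj`, `source_screens`, and a `members` list-column of guide
#'   ids ordered by position.
#' @export
call_cires <- function(stats, alpha = 0.05, max_gap = 500, min_guides = 2,
                       split_by_sign = FALSE, pad_protospacer = FALSE) {
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1)) {
    stopf("alpha must be in (0, 1)")
  }
  assert_scalar_number(max_gap, "max_gap", lower = 0, strict_lower = TRUE)
  if (is.data.frame(stats)) stats <- list(screen = stats)
  if (is.null(names(stats))) names(stats) <- paste0("screen", seq_along(stats))
  sig <- do.call(rbind, lapply(names(stats), function(nm) {
    st <- stats[[nm]]
    st <- st[!is.na(st$p_adj) & st$p_adj < alpha, , drop = FALSE]
    if (!nrow(st)) return(NULL)
    data.frame(guide_id = st$guide_id, pos = st$five_prime_pos,
               log2fc = st$log2fc, p_adj = st$p_adj, screen = nm)
  }))
  empty <- data.frame(cire_id = character(), start = numeric(),
                      end = numeric(), n_guides = integer(),
                      direction = character(), mean_log2fc = numeric(),
                      min_p_adj = numeric(), source_screens = character())
  empty$members <- list()
  if (is.null(sig) || !nrow(sig)) return(empty)
  pos_by_id <- tapply(sig$pos, sig$guide_id, function(p) length(unique(p)))
  if (any(pos_by_id > 1)) {
    stopf("conflicting positions for guide id(s): %s",
          paste(names(pos_by_id)[pos_by_id > 1], collapse = ", "))
  }
  # dedupe by guide id, keeping the most significant record;
  # remember every screen in which the guide was significant
  sig <- sig[order(sig$guide_id, sig$p_adj), , drop = FALSE]
  screens_by_id <- tapply(sig$screen, sig$guide_id,
                          function(s) paste(sort(unique(s)), collapse = ","))
  sig <- sig[!duplicated(sig$guide_id), , drop = FALSE]
  sig$screens <- unname(screens_by_id[sig$guide_id])
  sig <- sig[order(sig$pos, sig$guide_id), , drop = FALSE]

  run <- cumsum(c(TRUE, diff(sig$pos) >= max_gap))
  if (split_by_sign) {
    sgn <- sign(sig$log2fc)
    run <- cumsum(c(TRUE, diff(sig$pos) >= max_gap | diff(sgn) != 0))
  }
  rows <- lapply(split(seq_len(nrow(sig)), run), function(ii) {
    if (length(ii) < min_guides) return(NULL)
    sub <- sig[ii, , drop = FALSE]
    sgn <- sign(sub$log2fc)
    direction <- if (all(sgn > 0)) "activating"
    else if (all(sgn < 0)) "repressive" else "mixed"
    out <- data.frame(start = sub$pos[1],
                      end = sub$pos[nrow(sub)] + if (pad_protospacer) 20 else 0,
                      n_guides = nrow(sub), direction = direction,
                      mean_log2fc = mean(sub$log2fc),
                      min_p_adj = min(sub$p_adj),
                      source_screens = paste(sort(unique(unlist(
                        strsplit(sub$screens, ",")))), collapse = ","))
    out$members <- list(sub$guide_id)
    out
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(cire_id = sprintf("CiRE_%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Score called CiREs against the generating ground truth
#'
#' A planted element is recovered when a called CiRE of matching
#' direction (activating for kappa > 0, repressive for kappa < 0) lies
#' within `slack_bp` of its core. Recall is scored over the planted
#' regulatory elements (TSS pseudo-elements excluded); precision counts a
#' called CiRE as matched when it lies within `slack_bp` of any truth
#' element including TSSs (a promoter hit is a true finding). With no
#' calls, precision is 1 by convention (no false claims).
#'
#' @param called CiRE table from [call_cires()].
#' @param truth `ground_truth` from [simulate_screen()], or a
#'   `data.frame` of elements with `id`, `start`, `end`, `kappa`
#'   (and optional `is_tss`).
#' @param slack_bp Matching slack in bp (default 500).
#' @return List: `precision`, `recall`, `n_called`, `n_truth`, and
#'   `elements` (per planted element: recovered flag and midpoint offset
#'   of the nearest matching CiRE).
#' @export
evaluate_recovery <- function(called, truth, slack_bp = 500) {
  elems <- if (inherits(truth, "ground_truth")) truth$elements else
    as.data.frame(truth)
  if (is.null(elems$is_tss)) elems$is_tss <- FALSE
  elems <- elems[elems$kappa != 0, , drop = FALSE]
  planted <- elems[!elems$is_tss, , drop = FALSE]

  gap <- function(a1, a2, b1, b2) pmax(0, b1 - a2, a1 - b2)
  dir_of_kappa <- function(k) ifelse(k > 0, "activating", "repressive")

  matches <- function(ci, el) {
    gap(ci$start, ci$end, el$start, el$end) <= slack_bp &&
      ci$direction == dir_of_kappa(el$kappa)
  }
  n_called <- nrow(called)
  called_matched <- logical(n_called)
  if (n_called) {
    for (i in seq_len(n_called)) {
      for (j in seq_len(nrow(elems))) {
        if (matches(called[i, ], elems[j, ])) {
          called_matched[i] <- TRUE
          break
        }
      }
    }
  }
  per_elem <- data.frame(id = planted$id, recovered = FALSE,
                         midpoint_offset = NA_real_)
  if (nrow(planted)) {
    for (j in seq_len(nrow(planted))) {
      best <- NA_real_
      for (i in seq_len(max(n_called, 0))) {
        if (matches(called[i, ], planted[j, ])) {
          per_elem$recovered[j] <- TRUE
          off <- (called$start[i] + called$end[i]) / 2 -
            (planted$start[j] + planted$end[j]) / 2
          if (is.na(best) || abs(off) < abs(best)) best <- off
        }
      }
      per_elem$midpoint_offset[j] <- best
    }
  }
  list(precision = if (n_called == 0) 1 else mean(called_matched),
       recall = if (nrow(planted) == 0) 1 else mean(per_elem$recovered),
       n_called = n_called, n_truth = nrow(planted), elements = per_elem)
}

#' Write called CiREs as BED6 plus a member TSV
#'
#' BED score is `-log10(min p_adj)` capped at 1000; strand is `"."`.
#'
#' @param cires CiRE table from [call_cires()].
#' @param bed_path Output BED path.
#' @param chrom Chromosome label.
#' @param tsv_path Optional member/direction TSV path.
#' @export
write_cires_bed <- function(cires, bed_path, chrom, tsv_path = NULL) {
  df <- data.frame(chrom = chrom, start = cires$start,
                   end = pmax(cires$end, cires$start + 1),
                   name = cires$cire_id,
                   score = pmin(1000, round(-log10(pmax(
                     cires$min_p_adj, 1e-300)), 3)),
                   strand = ".")
  write_bed(df, bed_path)
  if (!is.null(tsv_path)) {
    flat <- cires
    flat$members <- vapply(cires$members, paste, "", collapse = ",")
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed_path)
}
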