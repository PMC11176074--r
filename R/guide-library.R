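#' Guide library container
#'
#' @param guides `data.frame` with columns `guide_id`, `chrom`,
#'   `five_prime_pos` (genomic coordinate of the protospacer's 5' base on
#'   its own strand), `strand` (`"+"`/`"-"`) and `protospacer` (20-nt
#'   string, or `NA` for position-only simulation libraries).
#' @param target_span [genomic_interval()] the library tiles.
#' @return An object of class `guide_library`.
#' @export
guide_library <- function(guides, target_span) {
  stopifnot(inherits(target_span, "genomic_interval"))
  guides <- as.data.frame(guides)
  need <- c("guide_id", "chrom", "five_prime_pos", "strand", "protospacer")
  if (!all(need %in% names(guides))) {
    stopf("'guides' needs columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(guides$guide_id)) stopf("guide ids must be unique")
  if (!all(guides$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  ps <- guides$protospacer[!is.na(guides$protospacer)]
  if (length(ps) && any(nchar(ps) != 20L)) {
    stopf("protospacers must be 20 nt")
  }
  out_of_span <- guides$five_prime_pos < target_span$start |
    guides$five_prime_pos >= target_span$end
  if (any(out_of_span)) stopf("%d guide(s) fall outside the target span",
                              sum(out_of_span))
  rownames(guides) <- NULL
  structure(list(guides = guides, target_span = target_span),
            class = "guide_library")
}

#' @export
print.guide_library <- function(x, ...) {
  cat("<guide_library> ", nrow(x$guides), " guides tiling ",
      format(x$target_span), "\n", sep = "")
  invisible(x)
}

#' Number of guides in a library
#' @param library A [guide_library()].
#' @return Integer count.
#' @export
n_guides <- function(library) nrow(library$guides)

#' Protospacer center positions for a library
#'
#' The + strand protospacer occupies `[pos, pos + 20)`; the - strand
#' protospacer's 5' base sits at `pos` on the minus strand, so it occupies
#' `[pos - 19, pos + 1)` in genome coordinates. Position-only libraries
#' (strand `"+"`, no protospacer) use the 5' position + 10 as well.
#'
#' @param library A [guide_library()].
#' @return Numeric vector of protospacer midpoints.
#' @export
guide_centers <- function(library) {
  g <- library$guides
  ifelse(g$strand == "+", g$five_prime_pos + 10, g$five_prime_pos - 9)
}

iupac_to_regex <- function(motif) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(motif), "")[[1]]
  if (!all(chars %in% names(map))) stopf("non-IUPAC motif: '%s'", motif)
  paste0(vapply(chars, function(ch) {
    base <- map[[ch]]
    if (nchar(base) == 1L) base else paste0("[", base, "]")
  }, ""), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Design a tiling CRISPRi guide library from raw sequence
#'
#' Enumerates every 20-bp protospacer flanked by a 5'-NGG protospacer
#' adjacent motif on either strand of the input sequence, then removes
#' guides whose protospacer (on either of its strands) contains a cloning
#' restriction-site motif (defaults: BstXI `CCANNNNNNTGG`, BlpI `GCTNAGC`;
#' `N` is a wildcard) or fails a caller-supplied off-target filter. Guides
#' with identical protospacers at different positions are all retained.
#'
#' The reported `five_prime_pos` is the genomic coordinate of the
#' protospacer's 5' base on its own strand, for both orientations.
#'
#' @param sequence DNA string over `A`,`C`,`G`,`T`,`N` (character or
#'   [Biostrings::DNAString]).
#' @param origin Genomic coordinate (0-based) of the first base of
#'   `sequence`.
#' @param chrom Chromosome label recorded for each guide.
#' @param exclusion_motifs Character vector of IUPAC motifs to exclude.
#' @param offtarget_filter Optional `function(protospacer) -> logical`
#'   returning `TRUE` for guides to keep; default keeps everything
#'   (genome-wide uniqueness is the caller's responsibility).
#' @return A [guide_library()].
#' @examples
#' lib <- design_tiling_library(paste0(strrep("T", 20), "AGG"), origin = 0)
#' lib$guides$five_prime_pos # 0
#' @export
design_tiling_library <- function(sequence, origin = 0, chrom = "chr_syn",
                                  exclusion_motifs = c(BstXI = "CCANNNNNNTGG",
                                                       BlpI = "GCTNAGC"),
                                  offtarget_filter = NULL) {
  seq_chr <- toupper(as.character(sequence))
  ch <- strsplit(seq_chr, "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "T", "N"))) {
    stopf("sequence may only contain A, C, G, T, N")
  }
  n <- length(ch)
  span <- genomic_interval(chrom, origin, origin + max(n, 1))
  empty <- data.frame(guide_id = character(), chrom = character(),
                      five_prime_pos = numeric(), strand = character(),
                      protospacer = character())
  if (n < 23L) return(guide_library(empty, span))

  # + strand: protospacer at 1-based p..p+19 with PAM N,G,G at p+20..p+22
  gg <- which(ch[-n] == "G" & ch[-1] == "G")        # ch[j] == ch[j+1] == "G"
  p_plus <- gg - 21L
  p_plus <- p_plus[p_plus >= 1L]
  # - strand: CC at 1-based q..q+1 is the PAM's GG on the minus strand;
  # protospacer = revcomp of q+3..q+22, 5' base at genomic origin + q + 21
  cc <- which(ch[-n] == "C" & ch[-1] == "C")
  q_minus <- cc[cc + 22L <= n]

  proto_plus <- if (length(p_plus)) {
    substring(seq_chr, p_plus, p_plus + 19L)
  } else character()
  proto_minus <- if (length(q_minus)) {
    revcomp_chr(substring(seq_chr, q_minus + 3L, q_minus + 22L))
  } else character()

  guides <- data.frame(
    chrom = rep(chrom, length(p_plus) + length(q_minus)),
    five_prime_pos = c(origin + p_plus - 1, origin + q_minus + 21),
    strand = rep(c("+", "-"), c(length(p_plus), length(q_minus))),
    protospacer = c(proto_plus, proto_minus))

  if (nrow(guides)) {
    keep <- rep(TRUE, nrow(guides))
    rc <- revcomp_chr(guides$protospacer)
    for (motif in exclusion_motifs) {
      re <- iupac_to_regex(motif)
      keep <- keep & !grepl(re, guides$protospacer) & !grepl(re, rc)
    }
    if (!is.null(offtarget_filter)) {
      keep <- keep & vapply(guides$protospacer, offtarget_filter, TRUE,
                            USE.NAMES = FALSE)
    }
    guides <- guides[keep, , drop = FALSE]
  }
  guides <- guides[order(guides$five_prime_pos, guides$strand), , drop = FALSE]
  guides$guide_id <- sprintf("sg_%010.0f_%s", guides$five_prime_pos,
                             ifelse(guides$strand == "+", "p", "m"))
  guide_library(guides[, c("guide_id", "chrom", "five_prime_pos", "strand",
                           "protospacer")], span)
}

#' Position-only tiling library for simulation studies
#'
#' Places one guide every `step` bp across `tile_span` without requiring
#' sequence (protospacers are `NA`). Useful when the screen simulator, not
#' read counting, is the entry point.
#'
#' @param tile_span [genomic_interval()] to tile.
#' @param step Spacing between consecutive guide 5' positions, bp.
#' @param target_span Optional enclosing span recorded on the library.
#' @return A [guide_library()].
#' @export
tiling_positions_library <- function(tile_span, step = 50,
                                     target_span = tile_span) {
  pos <- seq(tile_span$start, tile_span$end - 1, by = step)
  guides <- data.frame(guide_id = sprintf("sg_%010.0f_p", pos),
                       chrom = tile_span$chrom, five_prime_pos = pos,
                       strand = "+", protospacer = NA_character_)
  guide_library(guides, target_span)
}

#' Read a FASTA file as a plain DNA string
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a guide library reference file
#'
#' TSV with columns `guide_id`, `chrom`, `five_prime_pos`, `strand`,
#' `protospacer` (the reference-file schema used for read counting).
#'
#' @param library A [guide_library()].
#' @param path Output TSV path.
#' @export
write_guide_library <- function(library, path) {
  utils::write.table(library$guides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a guide library reference file written by [write_guide_library()]
#' @param path TSV path.
#' @param target_span Optional [genomic_interval()]; inferred from the
#'   guide positions when absent.
#' @return A [guide_library()].
#' @export
read_guide_library <- function(path, target_span = NULL) {
  g <- read_tsv_checked(path, c("guide_id", "chrom", "five_prime_pos",
                                "strand", "protospacer"))
  if (is.null(target_span)) {
    target_span <- genomic_interval(g$chrom[1], min(g$five_prime_pos),
                                    max(g$five_prime_pos) + 1)
  }
  guide_library(g, target_span)
}
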