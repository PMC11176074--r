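# Standard-format readers/writers. All on-disk interval formats are BED
# style 0-based half-open, matching the package's internal convention;
# conversion to/from the 1-based GRanges used by rtracklayer happens here
# and nowhere else.

df_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  for (col in setdiff(names(df), c("chrom", "start", "end"))) {
    GenomicRanges::mcols(gr)[[col]] <- df[[col]]
  }
  gr
}

granges_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr))
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}

#' Read / write BED intervals (0-based half-open)
#'
#' @param df `data.frame` with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns.
#' @param path File path.
#' @return `read_bed` returns a `data.frame` in the same convention.
#' @export
write_bed <- function(df, path) {
  rtracklayer::export(df_to_granges(df), path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  granges_to_df(rtracklayer::import(path, format = "BED"))
}

#' Read / write bedGraph signal (0-based half-open)
#'
#' @param df `data.frame` with `chrom`, `start`, `end`, `value`.
#' @param path File path.
#' @return `read_bedgraph` returns a `data.frame` with a `value` column.
#' @export
write_bedgraph <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  gr <- df_to_granges(df[, c("chrom", "start", "end")])
  GenomicRanges::mcols(gr)$score <- df$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  df <- granges_to_df(rtracklayer::import(path, format = "bedGraph"))
  names(df)[names(df) == "score"] <- "value"
  df
}

#' Read a TSV validating its header
#'
#' @param path TSV path.
#' @param required Column names that must be present.
#' @return `data.frame`.
#' @export
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stopf("missing input file: '%s'", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stopf("'%s' lacks required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write / read a count matrix with its sample sheet
#'
#' The matrix TSV has a `guide_id` column followed by one column per
#' sample; the sample sheet carries the per-sample metadata.
#'
#' @param counts A [count_matrix()].
#' @param counts_path Matrix TSV path.
#' @param samples_path Sample-sheet TSV path.
#' @return `read_count_matrix` returns a [count_matrix()].
#' @export
write_count_matrix <- function(counts, counts_path, samples_path) {
  df <- data.frame(guide_id = counts$guides$guide_id,
                   five_prime_pos = counts$guides$five_prime_pos,
                   counts$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(counts$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  df <- read_tsv_checked(counts_path, c("guide_id", "five_prime_pos"))
  samples <- read_tsv_checked(samples_path,
                              c("sample_id", "donor", "bin", "target_gene",
                                "context"))
  K <- as.matrix(df[, samples$sample_id, drop = FALSE])
  count_matrix(K, samples, df[, c("guide_id", "five_prime_pos")])
}

#' Write a 4C track as bedGraph files
#'
#' @param track A [fourc_track()].
#' @param raw_path Raw-count bedGraph path.
#' @param norm_path Optional normalized-signal bedGraph path.
#' @export
write_fourc_bedgraph <- function(track, raw_path, norm_path = NULL) {
  fr <- track$fragments
  chrom <- track$viewpoint$chrom
  write_bedgraph(data.frame(chrom = chrom, start = fr$start, end = fr$end,
                            value = track$raw_counts), raw_path)
  if (!is.null(norm_path)) {
    write_bedgraph(data.frame(chrom = chrom, start = fr$start, end = fr$end,
                              value = track$norm_signal), norm_path)
  }
  invisible(raw_path)
}

#' Write ground-truth elements and boundaries as BED
#'
#' Score column carries kappa (elements) or strength (boundaries).
#'
#' @param truth `ground_truth` from [simulate_screen()].
#' @param path Output BED path.
#' @param chrom Chromosome label.
#' @export
write_ground_truth_bed <- function(truth, path, chrom) {
  el <- truth$elements
  bo <- truth$boundaries
  df <- rbind(
    data.frame(chrom = chrom, start = el$start, end = el$end, name = el$id,
               score = el$kappa),
    if (nrow(bo)) data.frame(chrom = chrom, start = bo$start, end = bo$end,
                             name = bo$id, score = bo$strength))
  df$strand <- "."
  write_bed(df, path)
}

run_metadata <- function(config, seed, inputs = character()) {
  list(package = "cireScreen",
       version = as.character(utils::packageVersion("cireScreen")),
       r_version = R.version.string,
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = config,
       input_checksums = if (length(inputs)) {
         as.list(tools::md5sum(inputs))
       } else list())
}
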