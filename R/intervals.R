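#' Genomic intervals, 0-based half-open
#'
#' All coordinates in this package follow the BED convention: intervals are
#' 0-based and half-open, so an interval covers bases `start, ..., end - 1`
#' and its width is `end - start`.
#'
#' @param chrom Chromosome / sequence name.
#' @param start Integer start (0-based, inclusive).
#' @param end Integer end (exclusive); must satisfy `start <= end`.
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("chr2", 202527032, 203967032)
#' gi_width(gi) # 1440000
#' @export
genomic_interval <- function(chrom, start, end) {
  if (length(chrom) != 1L || is.na(chrom)) stopf("'chrom' must be a single name")
  assert_scalar_number(start, "start", lower = 0)
  assert_scalar_number(end, "end")
  if (start > end) stopf("interval start (%s) exceeds end (%s)", start, end)
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end)),
            class = "genomic_interval")
}

#' Width of a genomic interval
#' @param x A `genomic_interval`.
#' @return `end - start` in bp.
#' @export
gi_width <- function(x) x$end - x$start

#' Midpoint of a genomic interval
#' @param x A `genomic_interval`.
#' @return `(start + end) / 2`, possibly half-integer.
#' @export
gi_midpoint <- function(x) (x$start + x$end) / 2

gi_contains <- function(outer, inner) {
  outer$chrom == inner$chrom && inner$start >= outer$start &&
    inner$end <= outer$end
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom,
          formatC(x$start, format = "d", big.mark = ","),
          formatC(x$end, format = "d", big.mark = ","))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval> ", format(x), "  width=", gi_width(x), " bp\n",
      sep = "")
  invisible(x)
}

#' Parse a printed coordinate string
#'
#' Parses coordinate strings as printed in genomics articles and browsers,
#' e.g. `"chr2:202,527,032-203,967,032"`. Thousands separators are dropped
#' and hyphen, en-dash and em-dash are all accepted as the range separator.
#' The pair is interpreted directly as a 0-based half-open interval, so the
#' width equals `end - start` (printed "1.44-Mb" and "508-bp" style lengths
#' come out exactly).
#'
#' @param text A single coordinate string of the form `"chrN:A-B"`.
#' @return A [genomic_interval()].
#' @examples
#' gi_width(parse_printed_interval("chr2:203,815,414-203,815,922")) # 508
#' @export
parse_printed_interval <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stopf("'text' must be a single string")
  }
  # ‐ hyphen, – en dash, — em dash, − minus
  re <- "^\\s*([^:\\s]+):([0-9,]+)\\s*[-‐–—−]\\s*([0-9,]+)\\s*$"
  m <- regmatches(text, regexec(re, text, perl = TRUE))[[1]]
  if (length(m) != 4L) stopf("cannot parse coordinate string: '%s'", text)
  a <- as.numeric(gsub(",", "", m[3], fixed = TRUE))
  b <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
  if (is.na(a) || is.na(b)) stopf("cannot parse coordinate string: '%s'", text)
  if (a > b) stopf("interval start exceeds end in '%s'", text)
  genomic_interval(m[2], a, b)
}
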