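# One global seed fans out to named substreams so that adding or reordering
# a simulation stage never perturbs the draws of another stage.

#' Derive a deterministic substream seed from a global seed and a name
#'
#' @param seed Global integer seed.
#' @param name Stream label, e.g. `"screen/donor1"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  assert_scalar_number(seed, "seed")
  h <- 0
  for (code in utf8ToInt(as.character(name))) {
    h <- (h * 131 + code) %% 1014283 # small prime keeps products < 2^53
  }
  as.integer((abs(seed) + 1013904223 + h * 2654435761) %% 2147483646)
}

#' Evaluate code under a named RNG substream
#'
#' Runs `code` with the RNG seeded from [substream_seed()] and restores the
#' caller's RNG state afterwards.
#'
#' @param seed Global integer seed.
#' @param name Stream label.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_stream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}
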