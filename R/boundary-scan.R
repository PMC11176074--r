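#' Delete a boundary element in silico
#'
#' Annotation-level analog of removing the boundary's full sequence: the
#' named boundary's insulation strength is set to 0 while all coordinates
#' stay fixed (the window-length-preserving "padding" analog). Under the
#' built-in predictor this multiplies every cross-boundary contact by
#' `1 / (1 - s)` relative to the intact model.
#'
#' @param model A [locus_model()].
#' @param element_id Id of the boundary to delete.
#' @return The edited [locus_model()].
#' @export
delete_element <- function(model, element_id) {
  i <- model_boundary_index(model, element_id)
  model$boundaries[[i]]$strength <- 0
  model
}

#' Apply a single-base in-silico deletion
#'
#' Every boundary whose core contains `position` has its strength scaled
#' to `s * (1 - w(position))`, where `w` is the boundary's triangular
#' disruption profile ([disruption_weight()]); boundaries not containing
#' the position, and all coordinates, are unchanged.
#'
#' @param model A [locus_model()].
#' @param position Integer base position (0-based).
#' @return The edited [locus_model()].
#' @export
apply_point_deletion <- function(model, position) {
  assert_scalar_number(position, "position")
  for (i in seq_along(model$boundaries)) {
    b <- model$boundaries[[i]]
    if (position >= b$core$start && position < b$core$end) {
      w <- disruption_weight(b, position)
      model$boundaries[[i]]$strength <- b$strength * (1 - w)
    }
  }
  model
}

boundary_strengths <- function(model) {
  vapply(model$boundaries, `[[`, numeric(1), "strength")
}

#' Tiling single-base deletion scan scored by contact-map MSE
#'
#' For each base position of `scan_interval`, applies the point deletion,
#' re-predicts the contact map over `window`, and records the MSE against
#' the intact reference map. Positions that leave every boundary strength
#' unchanged score 0 without re-prediction. The argmax position breaks
#' ties toward the smaller coordinate.
#'
#' @param model A [locus_model()].
#' @param window Prediction window, within the model span.
#' @param scan_interval Interval of base positions to delete, within
#'   `window`.
#' @param predictor `function(model, window) -> contact_map`; defaults to
#'   [predict_contact_map()] with `kernel`.
#' @param kernel [contact_kernel()] for the default predictor.
#' @return An object of class `disruption_profile` with fields
#'   `scan_interval`, `positions`, `mse`, `argmax_position`.
#' @export
scan_deletions <- function(model, window, scan_interval, predictor = NULL,
                           kernel = contact_kernel()) {
  stopifnot(inherits(scan_interval, "genomic_interval"))
  if (!gi_contains(window, scan_interval)) {
    stopf("scan_interval must lie within window")
  }
  if (is.null(predictor)) {
    predictor <- function(m, w) predict_contact_map(m, w, kernel)
  }
  reference <- predictor(model, window)
  if (!inherits(reference, "contact_map")) {
    stopf("predictor must return a contact_map")
  }
  s0 <- boundary_strengths(model)
  positions <- seq(scan_interval$start, scan_interval$end - 1)
  mse <- vapply(positions, function(pos) {
    edited <- apply_point_deletion(model, pos)
    if (identical(boundary_strengths(edited), s0)) return(0)
    map_mse(reference, predictor(edited, window))
  }, numeric(1))
  structure(list(scan_interval = scan_interval, positions = positions,
                 mse = mse,
                 argmax_position = positions[which.max(mse)]),
            class = "disruption_profile")
}

#' @export
print.disruption_profile <- function(x, ...) {
  cat("<disruption_profile> ", length(x$positions), " positions over ",
      format(x$scan_interval), "\n  max MSE ", format(max(x$mse)),
      " at position ", x$argmax_position, "\n", sep = "")
  invisible(x)
}

#' Write a disruption profile as bedGraph plus a JSON summary
#'
#' @param profile A `disruption_profile` from [scan_deletions()].
#' @param bedgraph_path Output bedGraph path (position, position + 1, mse).
#' @param json_path Optional JSON summary path (argmax, max MSE, n).
#' @param chrom Chromosome label for the bedGraph records.
#' @export
write_disruption_profile <- function(profile, bedgraph_path,
                                     json_path = NULL,
                                     chrom = profile$scan_interval$chrom) {
  df <- data.frame(chrom = chrom, start = profile$positions,
                   end = profile$positions + 1, value = profile$mse)
  write_bedgraph(df, bedgraph_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(argmax_position = profile$argmax_position,
           max_mse = max(profile$mse), n_positions = length(profile$positions)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(bedgraph_path)
}
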