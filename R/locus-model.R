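#' Gene annotation for a locus model
#'
#' @param name Gene symbol.
#' @param body [genomic_interval()] covering the gene body.
#' @param tss Integer TSS position (0-based); must lie within or adjacent
#'   to the body.
#' @param baseline_log_expression Named numeric vector mapping context label
#'   to baseline log expression (arbitrary log units).
#' @return An object of class `locus_gene`.
#' @export
locus_gene <- function(name, body, tss, baseline_log_expression) {
  stopifnot(inherits(body, "genomic_interval"))
  assert_scalar_number(tss, "tss", lower = 0)
  if (tss < body$start - 1 || tss > body$end) {
    stopf("TSS of '%s' (%s) not within or adjacent to its body", name, tss)
  }
  if (is.null(names(baseline_log_expression)) ||
      anyNA(names(baseline_log_expression))) {
    stopf("'baseline_log_expression' must be a named vector (context labels)")
  }
  structure(list(name = as.character(name), body = body, tss = as.numeric(tss),
                 baseline_log_expression = baseline_log_expression),
            class = "locus_gene")
}

#' Regulatory element with per-gene, per-context effect sizes
#'
#' The effect size kappa lives in (-Inf, 1): kappa > 0 marks an activating
#' element (CRISPRi repression lowers target expression), kappa < 0 a
#' repressive one. Under knockdown efficacy `e` in \[0, 1\] the expression
#' multiplier is `1 - e * kappa`, which stays positive because kappa < 1.
#'
#' @param id Unique element id.
#' @param core [genomic_interval()] of the element core.
#' @param effects `data.frame` with columns `gene`, `context`, `kappa`.
#' @return An object of class `reg_element`.
#' @export
reg_element <- function(id, core, effects) {
  stopifnot(inherits(core, "genomic_interval"))
  effects <- as.data.frame(effects)
  need <- c("gene", "context", "kappa")
  if (!all(need %in% names(effects))) {
    stopf("'effects' needs columns %s", paste(need, collapse = ", "))
  }
  if (any(effects$kappa >= 1)) {
    stopf("element '%s': kappa must be < 1 (expression multiplier 1 - e*kappa)",
          id)
  }
  structure(list(id = as.character(id), core = core, effects = effects,
                 is_tss = FALSE),
            class = "reg_element")
}

element_kappa <- function(element, gene, context) {
  eff <- element$effects
  hit <- eff$gene == gene & eff$context == context
  if (any(hit)) eff$kappa[which(hit)[1]] else 0
}

#' Boundary (insulator) element
#'
#' Models a CTCF-bound boundary as a multiplicative attenuation of contacts
#' crossing it: each cross-boundary contact is scaled by `1 - strength`.
#' The disruption profile `w(x)` weights single-base deletions over the
#' core; the default is triangular with peak 1 at the core center and 0 at
#' (and beyond) the core edges, emulating motif information content.
#'
#' @param id Unique boundary id.
#' @param core [genomic_interval()] of the motif core.
#' @param strength Insulation strength in \[0, 1).
#' @return An object of class `boundary_element`.
#' @export
boundary_element <- function(id, core, strength) {
  stopifnot(inherits(core, "genomic_interval"))
  assert_scalar_number(strength, "strength", lower = 0)
  if (strength >= 1) stopf("boundary strength must be < 1")
  structure(list(id = as.character(id), core = core,
                 strength = as.numeric(strength)),
            class = "boundary_element")
}

#' Evaluate a boundary's disruption-weight profile at base positions
#'
#' The continuous profile is triangular with peak 1 at the core midpoint
#' and 0 outside the core; it is evaluated at integer base positions.
#'
#' @param boundary A [boundary_element()].
#' @param positions Integer base positions.
#' @return Weights in \[0, 1\], one per position.
#' @export
disruption_weight <- function(boundary, positions) {
  core <- boundary$core
  wd <- gi_width(core)
  if (wd <= 0) return(rep(0, length(positions)))
  mid <- gi_midpoint(core)
  # base x covers [x, x+1); evaluate at the base center x + 0.5
  w <- 1 - abs(positions + 0.5 - mid) / (wd / 2)
  inside <- positions >= core$start & positions < core$end
  pmax(0, w) * as.numeric(inside)
}

#' Annotated locus model
#'
#' Container for a (synthetic or real) regulatory locus: its span, genes,
#' regulatory elements with per-gene/context effects, boundary elements,
#' and the list of cellular contexts (e.g. resting/stimulated conventional
#' and regulatory T cells).
#'
#' @param span [genomic_interval()] covered by the model.
#' @param genes List of [locus_gene()].
#' @param elements List of [reg_element()].
#' @param boundaries List of [boundary_element()].
#' @param contexts Character vector of context labels.
#' @return An object of class `locus_model`.
#' @export
locus_model <- function(span, genes = list(), elements = list(),
                        boundaries = list(),
                        contexts = c("Tconv_rest", "Tconv_stim6h",
                                     "Treg_rest", "Treg_stim6h")) {
  stopifnot(inherits(span, "genomic_interval"))
  for (g in genes) {
    stopifnot(inherits(g, "locus_gene"))
    if (!gi_contains(span, g$body)) {
      stopf("gene '%s' body outside model span", g$name)
    }
    bad <- setdiff(names(g$baseline_log_expression), contexts)
    if (length(bad)) {
      stopf("gene '%s' has unknown context(s): %s", g$name,
            paste(bad, collapse = ", "))
    }
  }
  for (e in elements) {
    stopifnot(inherits(e, "reg_element"))
    if (!gi_contains(span, e$core)) stopf("element '%s' outside span", e$id)
  }
  for (b in boundaries) {
    stopifnot(inherits(b, "boundary_element"))
    if (!gi_contains(span, b$core)) stopf("boundary '%s' outside span", b$id)
  }
  ids <- c(vapply(elements, `[[`, "", "id"), vapply(boundaries, `[[`, "", "id"))
  if (anyDuplicated(ids)) stopf("element/boundary ids must be unique")
  structure(list(span = span, genes = genes, elements = elements,
                 boundaries = boundaries, contexts = contexts),
            class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat("<locus_model> ", format(x$span), "\n",
      "  genes:      ", paste(vapply(x$genes, `[[`, "", "name"),
                              collapse = ", "), "\n",
      "  elements:   ", length(x$elements), "\n",
      "  boundaries: ", length(x$boundaries), "\n",
      "  contexts:   ", paste(x$contexts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

model_gene <- function(model, name) {
  for (g in model$genes) if (g$name == name) return(g)
  stopf("gene '%s' not in model", name)
}

model_boundary_index <- function(model, id) {
  for (i in seq_along(model$boundaries)) {
    if (model$boundaries[[i]]$id == id) return(i)
  }
  stopf("boundary '%s' not in model", id)
}

#' Effective elements seen by a CRISPRi screen on one target gene
#'
#' Returns a table of element cores with their kappa toward the given gene
#' and context. The TSS of every gene is included as a pseudo-element with
#' kappa = 1 toward its own gene (full promoter knockdown abolishes
#' expression up to the knockdown efficacy), flagged `is_tss`.
#'
#' @param model A [locus_model()].
#' @param target_gene Gene whose expression is read out.
#' @param context Context label.
#' @return `data.frame` with columns `id`, `start`, `end`, `kappa`, `is_tss`.
#' @export
effective_elements <- function(model, target_gene, context) {
  if (!context %in% model$contexts) stopf("unknown context '%s'", context)
  model_gene(model, target_gene) # validates gene
  rows <- lapply(model$elements, function(e) {
    data.frame(id = e$id, start = e$core$start, end = e$core$end,
               kappa = element_kappa(e, target_gene, context), is_tss = FALSE)
  })
  tss <- lapply(model$genes, function(g) {
    data.frame(id = paste0("TSS_", g$name), start = g$tss, end = g$tss + 1,
               kappa = if (g$name == target_gene) 1 else 0, is_tss = TRUE)
  })
  out <- do.call(rbind, c(rows, tss))
  out[order(out$start), , drop = FALSE]
}
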