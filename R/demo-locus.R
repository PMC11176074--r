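# Built-in synthetic loci. These are the package's study conditions: the
# scenario constructors below fix the locus geometry, effect sizes and
# screen parameters used by the worked examples, the test suite and the
# acceptance script.

#' Synthetic costimulatory-locus model
#'
#' A synthetic analog of a multi-gene costimulatory receptor locus on a
#' 1.44-Mb TAD: three adjacent genes (CD28-like constitutive, CTLA4-like
#' stimulation-induced, ICOS-like induced), a stimulation-responsive
#' enhancer ~40 kb upstream of the middle gene's TSS with a second,
#' Treg-dominant enhancer 5 kb downstream of it, and CTCF boundary
#' elements including a strong 508-bp boundary separating the first gene
#' from the enhancer cluster. Coordinates follow the hg38 chr2q33.2
#' region the geometry is modeled on; effect sizes and insulation
#' strengths are synthetic.
#'
#' @return A [locus_model()].
#' @export
synthetic_costim_locus <- function() {
  span <- parse_printed_interval("chr2:202,527,032-203,967,032")
  genes <- list(
    locus_gene("CD28", parse_printed_interval("chr2:203,706,475-203,738,912"),
               tss = 203706475,
               baseline_log_expression = c(Tconv_rest = 2.0,
                                           Tconv_stim6h = 2.0,
                                           Treg_rest = 1.6,
                                           Treg_stim6h = 1.6)),
    locus_gene("CTLA4", parse_printed_interval("chr2:203,867,771-203,873,965"),
               tss = 203867771,
               baseline_log_expression = c(Tconv_rest = 0.3,
                                           Tconv_stim6h = 1.6,
                                           Treg_rest = 1.8,
                                           Treg_stim6h = 2.3)),
    locus_gene("ICOS", parse_printed_interval("chr2:203,936,763-203,961,577"),
               tss = 203936763,
               baseline_log_expression = c(Tconv_rest = 0.2,
                                           Tconv_stim6h = 1.4,
                                           Treg_rest = 0.8,
                                           Treg_stim6h = 1.5)))
  elements <- list(
    reg_element("stim_responsive",
                genomic_interval("chr2", 203827700, 203828200),
                effects = data.frame(
                  gene = c("CTLA4", "CTLA4", "ICOS"),
                  context = c("Tconv_stim6h", "Treg_stim6h", "Tconv_stim6h"),
                  kappa = c(0.6, 0.25, 0.15))),
    reg_element("treg_dominant",
                genomic_interval("chr2", 203832700, 203833200),
                effects = data.frame(
                  gene = c("CTLA4", "CTLA4"),
                  context = c("Treg_rest", "Treg_stim6h"),
                  kappa = c(0.7, 0.6))))
  boundaries <- list(
    boundary_element("CTCF-1", genomic_interval("chr2", 203744850, 203745151),
                     strength = 0.35),
    boundary_element("CTCF-2",
                     parse_printed_interval("chr2:203,815,414-203,815,922"),
                     strength = 0.8))
  locus_model(span, genes, elements, boundaries)
}

#' Null-screen scenario: a tiled region with no regulatory elements
#'
#' 5,000 guides tile a 250-kb stretch with no regulatory elements; the
#' target gene's TSS sits 5 kb beyond the last guide (> 30 efficacy
#' kernel widths), so every tiled guide is null by construction.
#'
#' @param n_guides Number of tiling guides (default 5000).
#' @param step Guide spacing, bp (default 50).
#' @return List: `model`, `library`, `target_gene`, `context`.
#' @export
synthetic_null_screen <- function(n_guides = 5000, step = 50) {
  tiled <- n_guides * step
  span <- genomic_interval("chr_syn", 0, tiled + 10000)
  gene <- locus_gene("GOI", genomic_interval("chr_syn", tiled + 5000,
                                             tiled + 9000),
                     tss = tiled + 5000,
                     baseline_log_expression = c(Tconv_rest = 1, Tconv_stim6h = 1,
                                                 Treg_rest = 1, Treg_stim6h = 1))
  model <- locus_model(span, genes = list(gene))
  library <- tiling_positions_library(genomic_interval("chr_syn", 0, tiled),
                                      step = step, target_span = span)
  list(model = model, library = library, target_gene = "GOI",
       context = "Tconv_stim6h")
}

#' Recovery-benchmark scenario: three planted elements
#'
#' A 30-kb tiled region carrying two activating elements (kappa 0.6 and
#' 0.3) and one repressive element (kappa -0.4), each with a 500-bp core
#' and separated by >= 5 kb; guides every 50 bp; the target TSS sits 5 kb
#' past the tiled region so promoter signal cannot contaminate element
#' recovery.
#'
#' @param step Guide spacing, bp (default 50).
#' @return List: `model`, `library`, `target_gene`, `context`.
#' @export
synthetic_benchmark_screen <- function(step = 50) {
  span <- genomic_interval("chr_syn", 0, 40000)
  gene <- locus_gene("GOI", genomic_interval("chr_syn", 35000, 39000),
                     tss = 35000,
                     baseline_log_expression = c(Tconv_rest = 1, Tconv_stim6h = 1,
                                                 Treg_rest = 1, Treg_stim6h = 1))
  eff <- function(k) data.frame(gene = "GOI", context = "Tconv_stim6h",
                                kappa = k)
  elements <- list(
    reg_element("E1_strong_act", genomic_interval("chr_syn", 5000, 5500),
                eff(0.6)),
    reg_element("E2_weak_act", genomic_interval("chr_syn", 12000, 12500),
                eff(0.3)),
    reg_element("E3_repressive", genomic_interval("chr_syn", 19000, 19500),
                eff(-0.4)))
  model <- locus_model(span, genes = list(gene), elements = elements)
  library <- tiling_positions_library(genomic_interval("chr_syn", 0, 30000),
                                      step = step, target_span = span)
  list(model = model, library = library, target_gene = "GOI",
       context = "Tconv_stim6h")
}

#' Two-boundary toy model for deletion-scan tests
#'
#' A 131-kb span with two boundary elements of different strengths and
#' odd-width cores (so each triangular disruption profile has a unique
#' peak base at the core midpoint).
#'
#' @param s1,s2 Boundary strengths (defaults 0.3 and 0.7; the second is
#'   the stronger one).
#' @return A [locus_model()].
#' @export
synthetic_two_boundary_model <- function(s1 = 0.3, s2 = 0.7) {
  span <- genomic_interval("chr_syn", 0, 131072)
  locus_model(span,
              boundaries = list(
                boundary_element("B1", genomic_interval("chr_syn", 30000,
                                                        30301), s1),
                boundary_element("B2", genomic_interval("chr_syn", 80000,
                                                        80501), s2)))
}
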