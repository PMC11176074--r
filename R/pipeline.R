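#' Run the screen pipeline: simulate, test, call CiREs, write artifacts
#'
#' Orchestrates simulate-screen -> filter -> normalize -> dispersion ->
#' NB Wald test -> CiRE calling, writing every artifact (counts + sample
#' sheet, guide statistics, -log10 p bedGraph, CiRE BED/TSV, ground-truth
#' BED) plus a JSON run-metadata file recording the resolved
#' configuration and seed. Deterministic given the seed.
#'
#' @param model A [locus_model()].
#' @param library A [guide_library()].
#' @param cfg A [screen_config()].
#' @param context,target_gene Screen condition.
#' @param outdir Output directory (created).
#' @param alpha Adjusted-p cut for CiRE calling.
#' @param max_gap,min_guides CiRE merge parameters (see [call_cires()]).
#' @return List: `counts`, `truth`, `stats`, `cires`, `recovery`,
#'   `paths`.
#' @export
run_screen_pipeline <- function(model, library, cfg, context, target_gene,
                                outdir, alpha = 0.05, max_gap = 500,
                                min_guides = 2) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_screen(model, library, cfg, context, target_gene)
  stats <- nb_wald_test(sim$counts)
  cires <- call_cires(stats, alpha = alpha, max_gap = max_gap,
                      min_guides = min_guides)
  recovery <- evaluate_recovery(cires, sim$truth)
  chrom <- library$guides$chrom[1]
  paths <- list(
    counts = file.path(outdir, "counts.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    stats = file.path(outdir, "guide_stats.tsv"),
    pvals = file.path(outdir, "guide_neglog10p.bedGraph"),
    cires_bed = file.path(outdir, "cires.bed"),
    cires_tsv = file.path(outdir, "cires.tsv"),
    truth_bed = file.path(outdir, "ground_truth.bed"),
    metadata = file.path(outdir, "run_metadata.json"))
  write_count_matrix(sim$counts, paths$counts, paths$samples)
  write_guide_stats(stats, paths$stats)
  write_pvalue_bedgraph(stats, paths$pvals, chrom)
  write_cires_bed(cires, paths$cires_bed, chrom, paths$cires_tsv)
  write_ground_truth_bed(sim$truth, paths$truth_bed, chrom)
  meta <- run_metadata(
    config = list(screen = unclass(cfg), context = context,
                  target_gene = target_gene, alpha = alpha,
                  max_gap = max_gap, min_guides = min_guides,
                  n_guides = n_guides(library)),
    seed = cfg$seed,
    inputs = character())
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(counts = sim$counts, truth = sim$truth, stats = stats, cires = cires,
       recovery = recovery, paths = paths)
}

#' Run the 4C pipeline: simulate two conditions, compare gene bodies
#'
#' Simulates a control track and a boundary-knockdown track anchored on
#' the same viewpoint, normalizes, windows and spline-smooths both, runs
#' the per-gene-body comparison, and writes bedGraphs, the comparison TSV
#' and JSON run metadata.
#'
#' @param model A [locus_model()].
#' @param viewpoint Viewpoint position, bp.
#' @param boundary_knockdown Named knockdown fractions for the disturbed
#'   condition (see [simulate_fourc()]).
#' @param outdir Output directory.
#' @param kernel A [contact_kernel()].
#' @param depth Reads per track.
#' @param mean_fragment_bp Mean fragment length.
#' @param seed Global seed.
#' @param genes Genes to compare (default: all model genes).
#' @param window_k,smoothing Running-window size and spline smoothing.
#' @return List: `control`, `knockdown` (tracks), `comparison`, `qc`,
#'   `paths`.
#' @export
run_fourc_pipeline <- function(model, viewpoint, boundary_knockdown, outdir,
                               kernel = contact_kernel(), depth = 5e5,
                               mean_fragment_bp = 1000, seed = 1,
                               genes = NULL, window_k = 21,
                               smoothing = 0.75) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genes <- genes %||% model$genes
  control <- simulate_fourc(model, viewpoint, kernel,
                            mean_fragment_bp = mean_fragment_bp,
                            depth = depth, seed = seed,
                            condition = "control")
  knock <- simulate_fourc(model, viewpoint, kernel,
                          mean_fragment_bp = mean_fragment_bp,
                          depth = depth,
                          boundary_knockdown = boundary_knockdown,
                          seed = seed, condition = "knockdown")
  control <- smooth_spline_track(control, smoothing, window_k)
  knock <- smooth_spline_track(knock, smoothing, window_k)
  comparison <- compare_gene_bodies(control, knock, genes)
  qc <- list(control = qc_metrics(control), knockdown = qc_metrics(knock))
  paths <- list(
    control_raw = file.path(outdir, "fourc_control_raw.bedGraph"),
    control_norm = file.path(outdir, "fourc_control_norm.bedGraph"),
    knockdown_raw = file.path(outdir, "fourc_knockdown_raw.bedGraph"),
    knockdown_norm = file.path(outdir, "fourc_knockdown_norm.bedGraph"),
    comparison = file.path(outdir, "gene_body_comparison.tsv"),
    metadata = file.path(outdir, "run_metadata.json"))
  write_fourc_bedgraph(control, paths$control_raw, paths$control_norm)
  write_fourc_bedgraph(knock, paths$knockdown_raw, paths$knockdown_norm)
  utils::write.table(comparison, paths$comparison, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- run_metadata(
    config = list(viewpoint = viewpoint,
                  boundary_knockdown = as.list(boundary_knockdown),
                  depth = depth, mean_fragment_bp = mean_fragment_bp,
                  window_k = window_k, smoothing = smoothing,
                  kernel = unclass(kernel)),
    seed = seed)
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(control = control, knockdown = knock, comparison = comparison,
       qc = qc, paths = paths)
}

#' End-to-end demonstration run
#'
#' Simulates a small tiling screen over the synthetic costimulatory locus
#' (CTLA4-like target, stimulated conventional T cells, guides every
#' 50 bp across the enhancer cluster) plus the matching 4C boundary
#' knockdown experiment, and writes all artifacts under `outdir`.
#'
#' @param outdir Output directory.
#' @param seed Global seed.
#' @param coverage Cells per guide per donor.
#' @param depth Reads per screen sample.
#' @return List with `screen` and `fourc` results.
#' @export
run_demo <- function(outdir, seed = 1, coverage = 300, depth = 2e6) {
  model <- synthetic_costim_locus()
  library <- tiling_positions_library(
    genomic_interval("chr2", 203820000, 203845000), step = 50,
    target_span = model$span)
  cfg <- screen_config(n_cells = coverage * n_guides(library), depth = depth,
                       seed = seed)
  screen <- run_screen_pipeline(model, library, cfg,
                                context = "Tconv_stim6h",
                                target_gene = "CTLA4",
                                outdir = file.path(outdir, "screen"))
  fourc <- run_fourc_pipeline(model, viewpoint = 203828000,
                              boundary_knockdown = c("CTCF-2" = 0.9),
                              outdir = file.path(outdir, "fourc"),
                              seed = seed)
  list(screen = screen, fourc = fourc)
}
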