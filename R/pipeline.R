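# One reproducible end-to-end run: simulate (or load) -> quantify ->
# classify -> differential expression -> binding calls -> circuits,
# with per-stage tables and a machine-readable summary.

#' Pipeline run configuration
#'
#' Exactly one of `sim` (simulate-first mode) or `inputs` (paths to real
#' files) must be supplied. Every stage's rule/threshold object lives
#' here; the defaults are the analysis's canonical thresholds (500 bp
#' promoter window, 2x category folds, fold < 0.5 and FDR < 0.05 for the
#' DE filter, 623291645 spike-in molecules).
#'
#' @param sim A [sim_config()], or `NULL`.
#' @param inputs A list with elements `annotation` (path),
#'   `annotation_dialect`, `peak_manifest` (path or data frame),
#'   `counts`, `meta`, and optionally `de_counts`, `de_meta`; or `NULL`.
#' @param category_rules,de_thresholds,binding_rules,spikein Stage
#'   rule objects.
#' @param averaging Replicate averaging for the expression profile.
#' @param de_normalization Normalization for [de_test()].
#' @param user_edges Optional asserted regulatory edges merged into the
#'   circuit graph; defaults to the activating A-MYB -> TCFL5 edge of
#'   the known architecture.
#' @param outdir Optional output directory for per-stage TSVs and the
#'   JSON summary.
#' @param seed Optional override of the simulation seed.
#' @export
run_config <- function(sim = NULL, inputs = NULL,
                       category_rules = meioreg::category_rules(),
                       de_thresholds = meioreg::de_thresholds(),
                       binding_rules = meioreg::binding_rules(),
                       spikein = spikein_model(),
                       averaging = c("mean", "median"),
                       de_normalization = c("spikein", "library_size"),
                       user_edges = data.frame(source = "A-MYB",
                                               target = "TCFL5",
                                               sign = "+",
                                               stringsAsFactors = FALSE),
                       outdir = NULL, seed = NULL) {
  if (is.null(sim) == is.null(inputs))
    stopf("exactly one of 'sim' (simulate-first) or 'inputs' must be supplied")
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    stopf("'sim' must be a sim_config object")
  averaging <- match.arg(averaging)
  de_normalization <- match.arg(de_normalization)
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, inputs = inputs,
                 category_rules = category_rules,
                 de_thresholds = de_thresholds,
                 binding_rules = binding_rules, spikein = spikein,
                 averaging = averaging,
                 de_normalization = de_normalization,
                 user_edges = user_edges, outdir = outdir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order and returns every intermediate object
#' plus a summary (category counts, per-TF bound counts and median
#' distances, per-category bound fractions, DE gene count, feedforward
#' loops, seed and configuration hash). With `outdir` set, writes the
#' binding, category, DE, and FFL tables as TSVs and the summary as
#' JSON. Deterministic: the same configuration (including seed) gives
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of all stage outputs and `summary`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  de_ct <- NULL
  if (!is.null(config$sim)) {
    cfg <- config$sim
    ann <- gen_annotation(cfg)
    truth <- gen_truth(ann, cfg)
    pks <- gen_peaks(ann, truth, cfg)
    ct <- gen_counts(ann, truth, cfg)$counts
    de_ct <- gen_de_dataset(ann, truth, cfg)
  } else {
    ins <- config$inputs
    ann <- read_annotation(ins$annotation,
                           ins$annotation_dialect %||% "bed6")
    pks <- read_peak_sets(ins$peak_manifest, config$binding_rules)
    ct <- read_counts(ins$counts, ins$meta, config$spikein$spike_prefix)
    if (!is.null(ins$de_counts))
      de_ct <- read_counts(ins$de_counts, ins$de_meta,
                           config$spikein$spike_prefix)
  }

  profile <- expression_profile(ct, ann, config$spikein, config$averaging)
  categories <- classify_genes(profile, config$category_rules)

  de <- NULL
  if (!is.null(de_ct)) {
    de <- de_test(de_ct, normalization = config$de_normalization)
    de$q_value <- bh_fdr(de$p_value)
    de$passes <- de_filter(de$fold_change, de$q_value, config$de_thresholds)
  }

  calls <- call_binding(ann, pks, config$binding_rules)
  bsum <- binding_summary(calls, categories)
  tfs <- names(config$binding_rules$tf_rules)
  graph <- build_graph(calls, tfs, user_edges = config$user_edges)
  circuits <- find_coherent_ffls(graph)

  hash_input <- unclass(config)
  hash_input$outdir <- NULL
  summary <- list(
    n_genes = nrow(ann),
    seed = if (!is.null(config$sim)) config$sim$seed else NA_integer_,
    config_hash = rlang::hash(hash_input),
    category_counts = as.list(table(categories$category)),
    binding_per_tf = bsum$per_tf,
    bound_fraction_per_category = bsum$per_category,
    n_de_pass = if (!is.null(de)) sum(de$passes) else NA_integer_,
    n_ffls = nrow(circuits$ffls),
    n_coherent_ffls = nrow(circuits$coherent))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_table(calls, file.path(config$outdir, "binding_calls.tsv"),
                "binding")
    write_table(categories, file.path(config$outdir, "categories.tsv"),
                "categories")
    if (!is.null(de))
      write_table(de, file.path(config$outdir, "de_results.tsv"), "de")
    write_table(circuits$ffls[, c("x", "y", "z", "type"), drop = FALSE],
                file.path(config$outdir, "ffl_triads.tsv"), "ffl")
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(annotation = ann, truth = truth, peaks = pks,
                 counts = ct, profile = profile, categories = categories,
                 de = de, binding = calls, graph = graph,
                 circuits = circuits, summary = summary))
}
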