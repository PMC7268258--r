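#' Run the full synthetic TnSeq pipeline
#'
#' Orchestrates simulate -> assign -> classify -> score -> call:
#' generates a genome and input library from `config`, passes the library
#' through nodule selection, computes essentiality calls on the input
#' library and impairment scores on the input/output pair, and writes all
#' artifacts (GFF3 annotation, insertion TSVs, ground-truth JSON, per-gene
#' tables, summary JSON, resolved config) to `out_dir`. Reruns with an
#' identical config are bit-identical.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param loss_rate neutral loss rate used for scoring; `NULL` estimates
#'   it from all genes via [estimate_loss_rate()].
#' @param alpha,correction passed to [call_symbiosis_genes()].
#' @return invisibly, a list with the summary, tables and file paths.
#' @export
run_pipeline <- function(config, out_dir, loss_rate = NULL,
                         alpha = 0.05, correction = "none") {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop_bad_arg("pipeline stage '", name, "' failed: ",
                   conditionMessage(e))
    })
    message(sprintf("[catchn] %-22s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  annotation <- stage("generate_genome", generate_genome(config))
  input <- stage("generate_input_library",
                 generate_input_library(annotation, config))
  sel <- stage("simulate_nodule_selection",
               simulate_nodule_selection(annotation, input, config))
  write_annotation(annotation, file.path(out_dir, "annotation.gff3"))
  write_insertions(input, file.path(out_dir, "input_library.tsv"))
  write_insertions(sel$library, file.path(out_dir, "output_library.tsv"))
  jsonlite::write_json(sel$truth, file.path(out_dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)

  ess <- stage("essentiality", essentiality_table(annotation, input))
  inputs <- stage("depletion_inputs",
                  depletion_inputs(annotation, input, sel$library))
  l <- loss_rate %||% estimate_loss_rate(inputs)
  scores <- stage("score_depletion", score_depletion(inputs, l = l))
  calls <- stage("call_symbiosis_genes",
                 call_symbiosis_genes(scores, alpha = alpha,
                                      correction = correction))
  write.table(ess, file.path(out_dir, "essentiality.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(calls$table, file.path(out_dir, "impairment_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  rollup <- functional_rollup(calls$genes, annotation)
  summary <- list(
    seed = config$seed,
    loss_rate_used = l,
    genes_total = nrow(annotation$features),
    sites_input = nrow(input),
    sites_output = nrow(sel$library),
    symbiosis_genes_flagged = length(calls$genes),
    flagged_by_replicon = rollup$by_replicon,
    flagged_by_category = rollup$by_category,
    essentiality_counts = as.list(table(ess$category))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  jsonlite::write_json(
    list(config = unclass(config), loss_rate = l, alpha = alpha,
         correction = correction),
    file.path(out_dir, "resolved_config.json"),
    auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(list(summary = summary, annotation = annotation,
                 essentiality = ess, scores = calls$table,
                 symbiosis_genes = calls$genes, truth = sel$truth,
                 out_dir = out_dir))
}

#' Functional and replicon roll-up of flagged genes
#'
#' Counts and percentages of a flagged gene set per functional category
#' and per replicon. Percentages are computed against the flagged-gene
#' total and rounded half-up to two decimals.
#'
#' @param genes character vector of flagged gene ids (may be empty).
#' @param annotation a `GenomeAnnotation` supplying `functional_category`
#'   and `replicon` per gene.
#' @return list with data.frames `by_category` and `by_replicon`
#'   (columns: category/replicon, count, percent).
#' @export
functional_rollup <- function(genes, annotation) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  f <- annotation$features
  hit <- f[f$id %in% genes, , drop = FALSE]
  total <- nrow(hit)
  tab <- function(x, label) {
    if (total == 0) {
      return(setNames(data.frame(character(0), integer(0), numeric(0),
                                 stringsAsFactors = FALSE),
                      c(label, "count", "percent")))
    }
    counts <- table(x)
    out <- data.frame(names(counts), as.integer(counts),
                      round_half_up(100 * as.integer(counts) / total, 2),
                      stringsAsFactors = FALSE)
    setNames(out, c(label, "count", "percent"))
  }
  list(by_category = tab(hit$functional_category, "category"),
       by_replicon = tab(hit$replicon, "replicon"))
}
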