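# small in-code fixtures shared across test files

toy_annotation <- function() {
  genome_annotation(
    replicons = data.frame(name = c("chr", "pA"),
                           length = c(10000L, 5000L),
                           stringsAsFactors = FALSE),
    features = data.frame(
      id = c("g1", "g2", "g3", "g4", "g5"),
      replicon = c("chr", "chr", "chr", "pA", "pA"),
      start = c(100L, 1000L, 2500L, 200L, 1200L),
      end = c(200L, 1900L, 3400L, 900L, 2100L),
      strand = c("+", "-", "+", "+", "-"),
      product = paste("protein", 1:5),
      functional_category = c("metabolism", "regulation", "other",
                              "metabolism", "nodulation-related"),
      stringsAsFactors = FALSE)
  )
}

toy_library <- function(positions, replicon = "chr", stage = "input") {
  insertion_library(
    data.frame(replicon = replicon, position = positions, strand = "+",
               library = "pool1", reads = 5L, stringsAsFactors = FALSE),
    stage)
}

# AUROC for "low score flags positives": pROC when present, else midranks
auroc_low <- function(score, is_positive) {
  if (requireNamespace("pROC", quietly = TRUE)) {
    as.numeric(pROC::auc(pROC::roc(response = as.integer(is_positive),
                                   predictor = score,
                                   direction = ">", quiet = TRUE)))
  } else {
    pos <- as.logical(is_positive)
    r <- rank(score)
    n1 <- sum(pos); n0 <- sum(!pos)
    (sum(r[!pos]) - n0 * (n0 + 1) / 2) / (n0 * n1)
  }
}

# the scaled-down screen used by the recovery tests: 500 genes of ~960 bp
# at the study insertion density, 10% depleted 20-fold, l = 6.84
recovery_config <- function(seed) {
  simulation_config(
    replicon_specs = data.frame(name = "chr", length = 600000L,
                                cds_count = 500L, stringsAsFactors = FALSE),
    insertion_density = 0.112,
    neutral_loss_rate = 6.84,
    depleted_gene_fraction = 0.1,
    depletion_factor = 20,
    contiguity_weight = 0.5,
    seed = seed)
}

run_recovery_screen <- function(seed, l = 6.84) {
  cfg <- recovery_config(seed)
  ann <- generate_genome(cfg)
  lib <- generate_input_library(ann, cfg)
  sel <- simulate_nodule_selection(ann, lib, cfg)
  inputs <- depletion_inputs(ann, lib, sel$library)
  scores <- score_depletion(inputs, l = l)
  truth <- sel$truth[match(scores$gene, sel$truth$gene), ]
  list(scores = scores, truth = truth, annotation = ann,
       input = lib, output = sel$library)
}
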