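# All random draws go through with_seed() on the single config seed, so a
# given (config, seed) pair reproduces files byte-for-byte.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Configuration for the synthetic TnSeq study generator
#'
#' Defaults emulate the scale of a hyper-saturated Tn5 screen on a tripartite
#' ~6.7 Mb rhizobial genome: ~750k unique insertion sites (density 0.112
#' sites/bp), a neutral plant-passage bottleneck shrinking site diversity
#' about 6.84-fold, and a minority of symbiosis genes whose mutants are
#' additionally depleted during nodule selection with contiguous loss runs.
#'
#' @param replicon_specs data.frame with columns `name`, `length` (bp),
#'   `cds_count`. Default: a 3.65 Mb chromosome and two megaplasmids of
#'   1.35 and 1.68 Mb carrying 6200 CDS in total.
#' @param insertion_density expected unique insertion sites per bp
#'   (0 < density < 1). Default 0.112.
#' @param neutral_loss_rate the factor `l >= 1` by which neutral insertion
#'   diversity shrinks through the bottleneck; each neutral site survives
#'   with probability `1/l`. Default 6.84.
#' @param depleted_gene_fraction fraction of CDS designated symbiosis genes.
#'   Default 0.157.
#' @param depletion_factor fold reduction in per-site recovery probability
#'   inside depleted genes (`>= 1`, may be `Inf`). Default 20.
#' @param contiguity_weight 0-1; fraction of the losses inside a depleted
#'   gene laid down as one contiguous run of consecutive sites. Default 0.5.
#' @param read_mean mean simulated read count per site (geometric).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(replicon_specs = NULL,
                              insertion_density = 0.112,
                              neutral_loss_rate = 6.84,
                              depleted_gene_fraction = 0.157,
                              depletion_factor = 20,
                              contiguity_weight = 0.5,
                              read_mean = 10,
                              seed = 1L) {
  if (is.null(replicon_specs)) {
    replicon_specs <- data.frame(
      name = c("chromosome", "pSymA", "pSymB"),
      length = c(3650000L, 1350000L, 1680000L),
      cds_count = c(3400L, 1300L, 1500L),
      stringsAsFactors = FALSE
    )
  }
  replicon_specs <- as.data.frame(replicon_specs, stringsAsFactors = FALSE)
  assert_that(all(c("name", "length", "cds_count") %in% names(replicon_specs)),
              "replicon_specs needs columns name, length, cds_count")
  assert_that(nrow(replicon_specs) > 0, "replicon_specs must be nonempty")
  assert_that(all(replicon_specs$length > 0), "replicon lengths must be > 0")
  assert_that(insertion_density >= 0 && insertion_density < 1,
              "insertion_density must be in [0, 1)")
  assert_that(neutral_loss_rate >= 1, "neutral_loss_rate must be >= 1")
  assert_that(depletion_factor >= 1, "depletion_factor must be >= 1")
  assert_that(contiguity_weight >= 0 && contiguity_weight <= 1,
              "contiguity_weight must be in [0, 1]")
  assert_that(depleted_gene_fraction >= 0 && depleted_gene_fraction <= 1,
              "depleted_gene_fraction must be in [0, 1]")
  structure(list(replicon_specs = replicon_specs,
                 insertion_density = insertion_density,
                 neutral_loss_rate = neutral_loss_rate,
                 depleted_gene_fraction = depleted_gene_fraction,
                 depletion_factor = depletion_factor,
                 contiguity_weight = contiguity_weight,
                 read_mean = read_mean,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Generate a synthetic annotated genome
#'
#' Lays out `cds_count` non-overlapping CDS per replicon, both strands, by
#' slotting one gene into each of `cds_count` equal windows. Coordinates are
#' 1-based inclusive, writable as valid GFF3.
#'
#' @param config a [simulation_config()].
#' @return A [genome_annotation()] object.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  specs <- config$replicon_specs
  with_seed(config$seed, {
    feats <- vector("list", nrow(specs))
    for (j in seq_len(nrow(specs))) {
      L <- specs$length[j]
      m <- specs$cds_count[j]
      if (m == 0L) {
        feats[[j]] <- NULL
        next
      }
      slot <- floor(L / m)
      if (slot < 10L) {
        stop_bad_arg(sprintf(
          "cds_count %d infeasible for replicon %s of length %d",
          m, specs$name[j], L))
      }
      # gene length: ~80% of the slot with mild variation, >= 8 bp
      len <- pmin(slot - 2L,
                  pmax(8L, round(0.8 * slot + 0.1 * slot * runif(m, -1, 1))))
      slack <- slot - len
      start <- (seq_len(m) - 1L) * slot + 1L +
        floor(runif(m) * (slack + 1L))
      feats[[j]] <- data.frame(
        id = sprintf("%s_g%04d", specs$name[j], seq_len(m)),
        replicon = specs$name[j],
        start = start,
        end = start + len - 1L,
        strand = sample(c("+", "-"), m, replace = TRUE),
        product = "hypothetical protein",
        functional_category = sample(
          c("metabolism", "regulation", "other", "nodulation-related"),
          m, replace = TRUE, prob = c(0.5, 0.2, 0.25, 0.05)),
        stringsAsFactors = FALSE
      )
    }
    genome_annotation(
      replicons = data.frame(name = specs$name, length = specs$length,
                             stringsAsFactors = FALSE),
      features = do.call(rbind, feats)
    )
  })
}

#' Generate a hyper-saturated input insertion library
#'
#' Draws the number of unique sites per replicon as Binomial(length,
#' density), places them uniformly without replacement, assigns random
#' strands and geometric read counts (mean `read_mean`).
#'
#' @param annotation a `GenomeAnnotation` (from [generate_genome()]).
#' @param config a [simulation_config()].
#' @return An `InsertionLibrary` with stage `"input"`.
#' @export
generate_input_library <- function(annotation, config) {
  stopifnot(inherits(annotation, "GenomeAnnotation"),
            inherits(config, "SimulationConfig"))
  with_seed(config$seed + 1L, {
    reps <- annotation$replicons
    pieces <- vector("list", nrow(reps))
    for (j in seq_len(nrow(reps))) {
      L <- reps$length[j]
      n <- rbinom(1L, L, config$insertion_density)
      if (n == 0L) next
      pos <- sort(sample.int(L, n))
      pieces[[j]] <- data.frame(
        replicon = reps$name[j],
        position = pos,
        strand = sample(c("+", "-"), n, replace = TRUE),
        library = "pool1",
        reads = rgeom(n, 1 / config$read_mean) + 1L,
        stringsAsFactors = FALSE
      )
    }
    pieces <- pieces[!vapply(pieces, is.null, TRUE)]
    sites <- if (length(pieces)) do.call(rbind, pieces) else
      data.frame(replicon = character(0), position = integer(0),
                 strand = character(0), library = character(0),
                 reads = integer(0), stringsAsFactors = FALSE)
    insertion_library(sites, "input")
  })
}

#' Simulate nodule selection of an insertion library
#'
#' Passes the input library through the plant bottleneck: each site in a
#' neutral gene (or intergenic) survives independently with probability
#' `1/l`; sites in depleted (symbiosis) genes survive with probability
#' `(1/l)/depletion_factor`, and a `contiguity_weight` fraction of the
#' losses inside each depleted gene is laid down as one contiguous run of
#' consecutive sites (run start uniform), emulating the contiguous loss
#' structure that the run-length statistic k is designed to detect.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param input the input `InsertionLibrary` (nonempty).
#' @param config a [simulation_config()].
#' @return list with elements `library` (output `InsertionLibrary`) and
#'   `truth` (data.frame: gene, is_depleted, true_depletion_factor,
#'   n_input, i_recovered — every annotated CDS exactly once).
#' @export
simulate_nodule_selection <- function(annotation, input, config) {
  stopifnot(inherits(annotation, "GenomeAnnotation"),
            inherits(input, "InsertionLibrary"),
            inherits(config, "SimulationConfig"))
  assert_that(nrow(input) > 0, "input library is empty")
  l <- config$neutral_loss_rate
  fac <- config$depletion_factor
  w <- config$contiguity_weight
  assignment <- assign_insertions(annotation, input)
  gene_ids <- annotation$features$id
  with_seed(config$seed + 2L, {
    n_dep <- round(config$depleted_gene_fraction * length(gene_ids))
    depleted <- sample(gene_ids, n_dep)
    keep_key <- character(0)
    drop_key <- character(0)
    # depleted genes: thinned retention with a contiguous loss block
    for (g in depleted) {
      pos <- assignment[[g]]
      m <- length(pos)
      if (m == 0L) next
      p_d <- (1 / l) / fac
      r <- rbinom(1L, m, p_d)
      lost <- m - r
      lost_idx <- integer(0)
      if (lost > 0L) {
        b <- min(lost, round(w * lost))
        if (b > 0L) {
          s <- sample.int(m - b + 1L, 1L)
          lost_idx <- s:(s + b - 1L)
        }
        rest <- setdiff(seq_len(m), lost_idx)
        extra <- lost - length(lost_idx)
        if (extra > 0L)
          lost_idx <- c(lost_idx, rest[sample.int(length(rest), extra)])
      }
      rep_name <- annotation$features$replicon[match(g, gene_ids)]
      drop_key <- c(drop_key, paste(rep_name, pos[lost_idx]))
      keep_key <- c(keep_key, paste(rep_name, pos[setdiff(seq_len(m), lost_idx)]))
    }
    site_key <- paste(input$replicon, input$position)
    decided_drop <- site_key %in% drop_key
    decided_keep <- site_key %in% keep_key & !decided_drop
    undecided <- !(decided_drop | decided_keep)
    survive <- logical(nrow(input))
    survive[decided_keep] <- TRUE
    survive[undecided] <- runif(sum(undecided)) < 1 / l
    out <- insertion_library(as.data.frame(input)[survive, , drop = FALSE],
                             "output")
    out_assign <- assign_insertions(annotation, out)
    truth <- data.frame(
      gene = gene_ids,
      is_depleted = gene_ids %in% depleted,
      true_depletion_factor = ifelse(gene_ids %in% depleted, fac, 1),
      n_input = vapply(assignment[gene_ids], length, 0L),
      i_recovered = vapply(out_assign[gene_ids], length, 0L),
      stringsAsFactors = FALSE
    )
    rownames(truth) <- NULL
    list(library = out, truth = truth)
  })
}
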