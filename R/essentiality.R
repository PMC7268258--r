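#' Per-gene insertion statistics
#'
#' Computes the insertion density and the insertion-free gap structure of a
#' CDS. Gaps are maximal insertion-free intervals; a gap touching a CDS end
#' is a *boundary* gap, a gap flanked by two insertion sites is *internal*.
#' Each insertion site occupies one base, so the gap between consecutive
#' sites is their distance minus one.
#'
#' @param gene one row of `annotation$features` (or any list with `id`,
#'   `start`, `end`).
#' @param sites sorted insertion positions within the gene bounds.
#' @return An object of class `GeneInsertionProfile`: gene id, length,
#'   n_sites, density, a `gaps` data.frame (start, end, length, type), and
#'   the fractions `largest_gap_fraction` (over all gaps) and
#'   `top2_internal_gap_fraction` (sum of the two largest internal gaps).
#' @export
gene_stats <- function(gene, sites) {
  start <- gene$start
  end <- gene$end
  len <- end - start + 1L
  assert_that(len > 0, "gene has non-positive length")
  sites <- sort(unique(sites))
  assert_that(all(sites >= start & sites <= end),
              "sites outside gene bounds")
  n <- length(sites)
  bounds <- c(start - 1L, sites, end + 1L)  # virtual sites framing the CDS
  gstart <- head(bounds, -1L) + 1L
  gend <- tail(bounds, -1L) - 1L
  glen <- gend - gstart + 1L
  keep <- glen > 0L
  gaps <- data.frame(start = gstart[keep], end = gend[keep],
                     length = glen[keep],
                     type = ifelse(gstart[keep] == start | gend[keep] == end,
                                   "boundary", "internal"),
                     stringsAsFactors = FALSE)
  # a single gap spanning the whole CDS (0 sites) counts as boundary
  largest <- if (nrow(gaps)) max(gaps$length) else 0L
  internal <- sort(gaps$length[gaps$type == "internal"], decreasing = TRUE)
  top2 <- sum(head(internal, 2L))
  structure(list(gene = gene$id %||% NA_character_,
                 length = len,
                 n_sites = n,
                 density = n / len,
                 gaps = gaps,
                 largest_gap_fraction = largest / len,
                 top2_internal_gap_fraction = top2 / len),
            class = "GeneInsertionProfile")
}

#' @export
print.GeneInsertionProfile <- function(x, ...) {
  cat(sprintf(
    "GeneInsertionProfile %s: %d bp, %d sites (density %.4g/bp)\n",
    x$gene, x$length, x$n_sites, x$density))
  cat(sprintf("  largest gap %.1f%% of CDS; top-2 internal gaps %.1f%%\n",
              100 * x$largest_gap_fraction,
              100 * x$top2_internal_gap_fraction))
  invisible(x)
}

#' Genome-wide average insertion density
#'
#' Total unique insertion sites divided by total genome length, all
#' replicons pooled.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param library an `InsertionLibrary`.
#' @return sites per bp (numeric scalar).
#' @export
genome_average_density <- function(annotation, library) {
  stopifnot(inherits(annotation, "GenomeAnnotation"),
            inherits(library, "InsertionLibrary"))
  L <- genome_length(annotation)
  assert_that(L > 0, "zero-length genome")
  nrow(library) / L
}

#' Classify a CDS as essential / fitness / non-essential
#'
#' A CDS is *essential* when its insertion density falls below
#' `essential_density_factor` times the genome average AND its gap structure
#' shows either a single insertion-free gap covering more than
#' `single_gap_threshold` of the CDS or two internal gaps jointly covering
#' more than `two_gap_threshold`. A CDS that fails the essential call but
#' has density below `fitness_density_factor` times the average is a
#' *fitness* gene; everything else is *non-essential*.
#'
#' The density factors default to 1/6 and 1/4: an essential gene must have
#' *fewer* insertions than the genome average. Both are exposed so a
#' different reading of the cutoffs is selectable.
#'
#' @param profile a [gene_stats()] result.
#' @param avg_density genome-wide average density
#'   ([genome_average_density()]).
#' @param essential_density_factor,fitness_density_factor multiples of
#'   `avg_density` below which the density criterion fires.
#' @param single_gap_threshold,two_gap_threshold gap-fraction cutoffs
#'   (defaults 0.60 and 0.80).
#' @param min_length genes shorter than this (bp) are flagged
#'   low-confidence but still classified.
#' @return An `EssentialityCall`: `category` in
#'   `c("essential", "fitness", "non_essential")`, the triggered criteria
#'   flags, and the thresholds used.
#' @export
classify_essentiality <- function(profile, avg_density,
                                  essential_density_factor = 1 / 6,
                                  fitness_density_factor = 1 / 4,
                                  single_gap_threshold = 0.60,
                                  two_gap_threshold = 0.80,
                                  min_length = 100L) {
  stopifnot(inherits(profile, "GeneInsertionProfile"))
  assert_that(essential_density_factor > 0 && fitness_density_factor > 0,
              "density factors must be positive")
  flags <- list(
    low_density_essential = profile$density <
      avg_density * essential_density_factor,
    single_gap = profile$largest_gap_fraction > single_gap_threshold,
    two_internal_gaps = profile$top2_internal_gap_fraction >
      two_gap_threshold,
    low_density_fitness = profile$density <
      avg_density * fitness_density_factor,
    low_confidence = profile$length < min_length
  )
  category <- if (flags$low_density_essential &&
                  (flags$single_gap || flags$two_internal_gaps)) {
    "essential"
  } else if (flags$low_density_fitness) {
    "fitness"
  } else {
    "non_essential"
  }
  structure(list(category = category, flags = flags,
                 thresholds = list(
                   essential_density_factor = essential_density_factor,
                   fitness_density_factor = fitness_density_factor,
                   single_gap_threshold = single_gap_threshold,
                   two_gap_threshold = two_gap_threshold,
                   min_length = min_length)),
            class = "EssentialityCall")
}

#' @export
print.EssentialityCall <- function(x, ...) {
  on <- names(Filter(isTRUE, x$flags))
  cat("EssentialityCall:", x$category,
      if (length(on)) paste0("(", paste(on, collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}

#' Essentiality table for a whole library
#'
#' Convenience wrapper running [gene_stats()] and [classify_essentiality()]
#' over every CDS of an annotation.
#'
#' @inheritParams classify_essentiality
#' @param annotation a `GenomeAnnotation`.
#' @param library an `InsertionLibrary`.
#' @param ... passed on to [classify_essentiality()].
#' @return data.frame: gene, length, n_sites, density, largest_gap_frac,
#'   top2_internal_gap_frac, category.
#' @export
essentiality_table <- function(annotation, library, ...) {
  assignment <- assign_insertions(annotation, library)
  avg <- genome_average_density(annotation, library)
  f <- annotation$features
  rows <- lapply(seq_len(nrow(f)), function(j) {
    prof <- gene_stats(f[j, ], assignment[[f$id[j]]])
    call <- classify_essentiality(prof, avg, ...)
    data.frame(gene = f$id[j], length = prof$length,
               n_sites = prof$n_sites, density = prof$density,
               largest_gap_frac = prof$largest_gap_fraction,
               top2_internal_gap_frac = prof$top2_internal_gap_fraction,
               category = call$category, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
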