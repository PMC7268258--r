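#' Genome annotation container
#'
#' A lightweight container for a (multi-replicon) bacterial genome
#' annotation: replicon names and lengths, plus CDS features with 1-based
#' inclusive coordinates. This is the coordinate frame for all insertion
#' statistics.
#'
#' @param replicons data.frame with columns `name`, `length` (bp).
#' @param features data.frame with columns `id`, `replicon`, `start`, `end`,
#'   `strand` ("+" or "-"), `product`, `functional_category`.
#' @return An object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(replicons, features) {
  replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  assert_that(all(c("name", "length") %in% names(replicons)),
              "replicons needs columns name, length")
  needed <- c("id", "replicon", "start", "end", "strand")
  assert_that(all(needed %in% names(features)),
              paste("features needs columns", paste(needed, collapse = ", ")))
  if (is.null(features$product)) features$product <- ""
  if (is.null(features$functional_category)) features$functional_category <- "other"
  assert_that(all(replicons$length > 0), "replicon lengths must be > 0")
  assert_that(!anyDuplicated(replicons$name), "replicon names must be unique")
  assert_that(!anyDuplicated(features$id), "feature ids must be unique")
  assert_that(all(features$replicon %in% replicons$name),
              "feature on unknown replicon")
  len <- setNames(replicons$length, replicons$name)
  bad <- which(features$start < 1 | features$start > features$end |
                 features$end > len[features$replicon])
  if (length(bad)) {
    stop_bad_arg("feature(s) with coordinates outside replicon bounds: ",
                 paste(features$id[bad], collapse = ", "))
  }
  structure(list(replicons = replicons, features = features),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", nrow(x$replicons), "replicon(s),",
      nrow(x$features), "CDS\n")
  for (j in seq_len(nrow(x$replicons))) {
    cat(sprintf("  %s  %d bp  (%d CDS)\n", x$replicons$name[j],
                x$replicons$length[j],
                sum(x$features$replicon == x$replicons$name[j])))
  }
  invisible(x)
}

#' Total genome length in bp (all replicons pooled)
#' @param annotation a [genome_annotation()] object.
#' @export
genome_length <- function(annotation) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  sum(as.numeric(annotation$replicons$length))
}

#' Read / write a genome annotation as GFF3
#'
#' Feature records are parsed with rtracklayer; replicon lengths are carried
#' by `##sequence-region` directives. Only CDS-type features are retained.
#'
#' @param path file path of a GFF3 file.
#' @return [read_annotation()] returns a `GenomeAnnotation`;
#'   [write_annotation()] returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  assert_that(length(sr) > 0,
              "GFF3 lacks ##sequence-region directives (replicon lengths)")
  parts <- strsplit(trimws(sr), "[ \t]+")
  replicons <- data.frame(
    name = vapply(parts, `[`, "", 2L),
    length = as.integer(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  mc <- S4Vectors::mcols(gr)
  features <- data.frame(
    id = as.character(mc$ID),
    replicon = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = if (!is.null(mc$product)) as.character(mc$product) else "",
    functional_category = if (!is.null(mc$functional_category))
      as.character(mc$functional_category) else "other",
    stringsAsFactors = FALSE
  )
  features$strand[!features$strand %in% c("+", "-")] <- "+"
  ann <- try(genome_annotation(replicons, features), silent = TRUE)
  if (inherits(ann, "try-error")) {
    stop_bad_arg("malformed annotation in ", path, ": ",
                 attr(ann, "condition")$message)
  }
  ann
}

#' @param annotation a `GenomeAnnotation`.
#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  f <- annotation$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$replicon,
    ranges = IRanges::IRanges(f$start, f$end),
    strand = f$strand,
    type = "CDS", ID = f$id, product = f$product,
    functional_category = f$functional_category
  )
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp), add = TRUE)
  suppressWarnings(rtracklayer::export(gr, tmp, format = "gff3"))
  lines <- readLines(tmp, warn = FALSE)
  # drop rtracklayer's date/source stamps so identical inputs give
  # byte-identical files, and add the replicon-length directives
  lines <- lines[!grepl("^##(date|source-version)", lines)]
  sr <- sprintf("##sequence-region %s 1 %d",
                annotation$replicons$name, annotation$replicons$length)
  writeLines(c(lines[1L], sr, lines[-1L]), path)
  invisible(path)
}

#' Insertion library container
#'
#' Unique transposon insertion sites, one row per (replicon, position), with
#' strand, library tag and read count. `stage` records whether the library is
#' the mutagenesis input pool or the nodule-selected output pool.
#'
#' @param sites data.frame with columns `replicon`, `position`, `strand`,
#'   `library`, `reads`.
#' @param stage `"input"` or `"output"`.
#' @return An object of class `InsertionLibrary` (a data.frame).
#' @export
insertion_library <- function(sites, stage = c("input", "output")) {
  stage <- match.arg(stage)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  needed <- c("replicon", "position", "strand", "library", "reads")
  assert_that(all(needed %in% names(sites)),
              paste("sites needs columns", paste(needed, collapse = ", ")))
  sites <- sites[needed]
  assert_that(all(sites$position >= 1), "positions must be >= 1")
  key <- paste(sites$replicon, sites$position)
  assert_that(!anyDuplicated(key), "duplicate (replicon, position) sites")
  sites <- sites[order(sites$replicon, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, stage = stage, class = c("InsertionLibrary", "data.frame"))
}

#' @export
print.InsertionLibrary <- function(x, ...) {
  cat(sprintf("InsertionLibrary (%s): %d unique sites on %d replicon(s)\n",
              attr(x, "stage"), nrow(x), length(unique(x$replicon))))
  if (nrow(x)) print(head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read / write insertion-site tables
#'
#' Tab-separated text with header
#' `replicon  position  strand  library  reads` (1-based positions).
#' Duplicate (replicon, position) rows are collapsed with summed read counts
#' and a warning.
#'
#' @param path file path.
#' @param stage stage label to attach, `"input"` or `"output"`.
#' @param annotation optional `GenomeAnnotation`; if given, replicon names
#'   and position bounds are validated against it.
#' @return [read_insertions()] returns an `InsertionLibrary`;
#'   [write_insertions()] returns `path` invisibly.
#' @export
read_insertions <- function(path, stage = c("input", "output"),
                            annotation = NULL) {
  stage <- match.arg(stage)
  assert_that(file.exists(path), paste("no such file:", path))
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  needed <- c("replicon", "position", "strand", "library", "reads")
  assert_that(all(needed %in% names(tab)),
              paste("insertion table must have header:",
                    paste(needed, collapse = "  ")))
  if (any(tab$position <= 0)) {
    stop_bad_arg("non-positive position at data row(s): ",
                 paste(head(which(tab$position <= 0)), collapse = ", "))
  }
  key <- paste(tab$replicon, tab$position)
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(sprintf("collapsed %d duplicated site row(s); reads summed", ndup),
            call. = FALSE)
    reads <- tapply(tab$reads, key, sum)
    first <- tab[!duplicated(key), , drop = FALSE]
    first$reads <- as.integer(reads[paste(first$replicon, first$position)])
    tab <- first
  }
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "GenomeAnnotation"))
    unknown <- setdiff(unique(tab$replicon), annotation$replicons$name)
    if (length(unknown)) {
      stop_bad_arg("unknown replicon(s) in ", path, ": ",
                   paste(unknown, collapse = ", "))
    }
    len <- setNames(annotation$replicons$length, annotation$replicons$name)
    bad <- tab$position > len[tab$replicon]
    if (any(bad)) {
      stop_bad_arg("position beyond replicon end at data row(s): ",
                   paste(head(which(bad)), collapse = ", "))
    }
  }
  insertion_library(tab, stage)
}

#' @param library an `InsertionLibrary`.
#' @rdname read_insertions
#' @export
write_insertions <- function(library, path) {
  stopifnot(inherits(library, "InsertionLibrary"))
  write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Assign insertion sites to CDS features
#'
#' A site belongs to gene *g* iff `start <= position <= end` (1-based
#' inclusive, strand-insensitive). Sites under overlapping CDS are assigned
#' to every overlapping feature (double counting, documented convention).
#' Sites outside every CDS are pooled under the reserved key `.intergenic`.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param library an `InsertionLibrary` on the same replicons.
#' @return Named list: one sorted position vector per feature id, plus a
#'   `.intergenic` data.frame of (replicon, position).
#' @export
assign_insertions <- function(annotation, library) {
  stopifnot(inherits(annotation, "GenomeAnnotation"),
            inherits(library, "InsertionLibrary"))
  f <- annotation$features
  unknown <- setdiff(unique(library$replicon), annotation$replicons$name)
  assert_that(length(unknown) == 0,
              paste("library on unknown replicon(s):",
                    paste(unknown, collapse = ", ")))
  out <- setNames(vector("list", nrow(f)), f$id)
  for (j in seq_along(out)) out[[j]] <- numeric(0)
  if (nrow(library)) {
    genes <- GenomicRanges::GRanges(f$replicon, IRanges::IRanges(f$start, f$end))
    sites <- GenomicRanges::GRanges(library$replicon,
                                    IRanges::IRanges(library$position,
                                                     library$position))
    hits <- GenomicRanges::findOverlaps(sites, genes, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      assigned <- split(library$position[qh], f$id[sh])
      for (g in names(assigned)) out[[g]] <- sort(unique(assigned[[g]]))
    }
    inter <- setdiff(seq_len(nrow(library)), unique(qh))
    out$.intergenic <- data.frame(replicon = library$replicon[inter],
                                  position = library$position[inter],
                                  stringsAsFactors = FALSE)
  } else {
    out$.intergenic <- data.frame(replicon = character(0),
                                  position = numeric(0),
                                  stringsAsFactors = FALSE)
  }
  out
}
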