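#' Estimate the neutral loss rate l
#'
#' The plant-passage bottleneck shrinks insertion diversity by a factor
#' `l`: with `n` input insertions in a set of selectively neutral genes and
#' `i` of them recovered from nodules, `l = sum(n) / sum(i)`.
#'
#' @param inputs data.frame with per-gene columns `gene`, `n`, `i` (see
#'   [depletion_inputs()]).
#' @param neutral_set optional character vector of neutral gene ids used
#'   for the calibration; when `NULL`, all genes are used.
#' @return the loss rate `l` (numeric scalar >= 1 in sane data).
#' @export
estimate_loss_rate <- function(inputs, neutral_set = NULL) {
  assert_that(all(c("n", "i") %in% names(inputs)),
              "inputs needs columns n, i")
  if (!is.null(neutral_set)) {
    inputs <- inputs[inputs$gene %in% neutral_set, , drop = FALSE]
  }
  total_n <- sum(inputs$n)
  total_i <- sum(inputs$i)
  assert_that(total_n > 0, "no input insertions in the calibration set")
  assert_that(total_i > 0, "no recovered insertions: loss rate undefined")
  total_n / total_i
}

#' Poisson recovery probability p1
#'
#' Probability of recovering at most `i` insertions when `lambda` are
#' expected under Poisson sampling through the bottleneck:
#' `p1 = sum_{s=0}^{i} exp(-lambda) lambda^s / s!`. Evaluated with the
#' Poisson CDF, which is computed in log space and stable for large
#' `lambda`.
#'
#' @param lambda expected number of recovered insertions (>= 0).
#' @param i observed number of recovered insertions (integer >= 0).
#' @return `P(X <= i)` for `X ~ Poisson(lambda)`; vectorised.
#' @export
p1_poisson <- function(lambda, i) {
  assert_that(all(lambda >= 0), "lambda must be >= 0")
  assert_that(all(i >= 0), "i must be >= 0")
  ppois(floor(i), lambda)
}

#' Longest run of insertions lost during selection
#'
#' Orders the input sites by coordinate, marks those absent from the output
#' library, and returns the per-gene triple (n, i, k): total input sites,
#' recovered sites, and the length of the longest run of consecutive input
#' sites that were lost. Site identity is positional.
#'
#' @param input_sites input insertion positions of one gene.
#' @param output_sites recovered positions; must be a subset of
#'   `input_sites`.
#' @return list with integers `n`, `i`, `k`.
#' @export
max_loss_run <- function(input_sites, output_sites) {
  input_sites <- sort(unique(input_sites))
  output_sites <- unique(output_sites)
  extra <- setdiff(output_sites, input_sites)
  if (length(extra)) {
    stop_bad_arg("output site(s) not present in input: ",
                 paste(head(extra), collapse = ", "))
  }
  lost <- !(input_sites %in% output_sites)
  list(n = length(input_sites),
       i = length(input_sites) - sum(lost),
       k = as.integer(longest_true_run(lost)))
}

# ---- p2: probability of a loss run >= k under uniform retention --------

# exhaustive enumeration over all choose(n, i) retention patterns;
# the independent oracle for small n
p2_enumerate <- function(n, i, k) {
  if (k == 0L) return(1)
  if (k > n - i) return(0)
  if (i == 0L) return(as.numeric(n >= k))
  hits <- 0
  total <- choose(n, i)
  sets <- utils::combn(n, i)
  for (col in seq_len(ncol(sets))) {
    lost <- rep(TRUE, n)
    lost[sets[, col]] <- FALSE
    if (longest_true_run(lost) >= k) hits <- hits + 1
  }
  hits / total
}

# the single-run closed form h/h_tot = (i+1) C(n-k, i) / C(n, i);
# counts patterns with a loss run >= k and is exact when at most one run
# can reach k, i.e. k > (n - i)/2
p2_closed_form <- function(n, i, k) {
  if (k == 0L) return(1)
  if (k > n - i) return(0)
  if (!(k > (n - i) / 2)) {
    stop_bad_arg("closed form requires k > (n - i)/2; use ",
                 "inclusion_exclusion or enumeration")
  }
  exp(log(i + 1) + lchoose(n - k, i) - lchoose(n, i))
}

# exact inclusion-exclusion over the i+1 loss-run slots:
# p2 = sum_{j>=1} (-1)^(j+1) C(i+1, j) C(n - j k, i) / C(n, i).
# Small regimes are evaluated in exact integer arithmetic (doubles hold
# integers exactly below 2^53); larger ones in log space with Kahan
# summation of the signed terms.
p2_inclusion_exclusion <- function(n, i, k) {
  if (k == 0L) return(1)
  if (k > n - i) return(0)
  j_max <- (n - i) %/% k
  js <- seq_len(j_max)
  js <- js[n - js * k >= i]
  if (!length(js)) return(0)
  log_terms <- lchoose(i + 1, js) + lchoose(n - js * k, i)
  log_total <- lchoose(n, i)
  if (max(log_terms) < 52 * log(2) && log_total < 52 * log(2)) {
    h <- sum((-1)^(js + 1) * choose(i + 1, js) * choose(n - js * k, i))
    return(h / choose(n, i))
  }
  terms <- (-1)^(js + 1) * exp(log_terms - log_total)
  # compensated (Kahan) summation: the series alternates
  s <- 0; c <- 0
  for (t in terms) {
    y <- t - c
    tt <- s + y
    c <- (tt - s) - y
    s <- tt
  }
  min(max(s, 0), 1)
}

# Monte-Carlo estimate: sample retained subsets uniformly and count how
# often the longest loss run reaches k
p2_monte_carlo <- function(n, i, k, reps = 1e5, seed = NULL) {
  if (k == 0L) return(list(p2 = 1, se = 0))
  if (k > n - i) return(list(p2 = 0, se = 0))
  run_once <- function() {
    lost <- rep(TRUE, n)
    if (i > 0L) lost[sample.int(n, i)] <- FALSE
    longest_true_run(lost) >= k
  }
  draw <- function() {
    hits <- 0L
    for (r in seq_len(reps)) if (run_once()) hits <- hits + 1L
    hits
  }
  hits <- if (is.null(seed)) draw() else with_seed(seed, draw())
  p <- hits / reps
  list(p2 = p, se = sqrt(p * (1 - p) / reps))
}

#' Run-length probability p2
#'
#' Probability that the longest run of consecutively lost insertions is at
#' least `k`, when `i` of `n` coordinate-ordered input sites are retained
#' uniformly at random. The lost sites fall into the `i + 1` ordered gaps
#' between retained sites (a bounded composition of `n - i`), and p2 asks
#' for at least one gap of size `>= k`.
#'
#' Methods: `"inclusion_exclusion"` is exact in every regime and is the
#' `"auto"` default; `"closed_form"` is the single-run formula
#' `(i+1) C(n-k, i) / C(n, i)`, valid iff `k > (n - i)/2`;
#' `"enumeration"` exhausts all `choose(n, i)` patterns (small `n` oracle);
#' `"monte_carlo"` samples retention patterns and reports a binomial
#' standard error.
#'
#' @param n total input insertions (integer >= 0).
#' @param i recovered insertions, `0 <= i <= n`.
#' @param k run-length threshold; `k > n - i` gives p2 = 0.
#' @param method one of `"auto"`, `"closed_form"`, `"inclusion_exclusion"`,
#'   `"enumeration"`, `"monte_carlo"`.
#' @param reps,seed Monte-Carlo replicates and optional seed.
#' @return list with `p2`, `method` used, and `se` (Monte-Carlo only).
#' @export
p2_loss_run <- function(n, i, k,
                        method = c("auto", "inclusion_exclusion",
                                   "closed_form", "enumeration",
                                   "monte_carlo"),
                        reps = 1e5, seed = NULL) {
  method <- match.arg(method)
  assert_that(n >= 0 && i >= 0 && k >= 0, "n, i, k must be >= 0")
  assert_that(i <= n, "need i <= n")
  n <- as.integer(n); i <- as.integer(i); k <- as.integer(k)
  if (k > n - i) {
    return(list(p2 = 0, method = "bound", se = NULL))
  }
  if (method == "auto") method <- "inclusion_exclusion"
  res <- switch(method,
    inclusion_exclusion = list(p2 = p2_inclusion_exclusion(n, i, k),
                               se = NULL),
    closed_form = list(p2 = p2_closed_form(n, i, k), se = NULL),
    enumeration = list(p2 = p2_enumerate(n, i, k), se = NULL),
    monte_carlo = p2_monte_carlo(n, i, k, reps = reps, seed = seed)
  )
  list(p2 = res$p2, method = method, se = res$se)
}

#' Symbiosis impairment score of one gene
#'
#' The score is the product of two probabilities: `p1`, the Poisson
#' probability of recovering at most `i` insertions when `lambda = n / l`
#' are expected through a neutral bottleneck of loss rate `l`, and `p2`,
#' the probability of a run of at least `k` consecutive lost insertions
#' under uniform retention. Small scores indicate genes whose mutants are
#' specifically depleted during nodule selection.
#'
#' @param n,i,k per-gene insertion counts and longest loss run (see
#'   [max_loss_run()]).
#' @param l neutral loss rate (>= 1), e.g. from [estimate_loss_rate()];
#'   the study-scale calibration value is 6.840.
#' @param p2_method,reps,seed passed to [p2_loss_run()].
#' @return A `DepletionScore`: lambda, p1, p2, `score = p1 * p2`,
#'   `p2_method`, `mc_se` (Monte-Carlo only), and a `no_data` flag when
#'   `n = 0`.
#' @export
impairment_score <- function(n, i, k, l = 6.840, p2_method = "auto",
                             reps = 1e5, seed = NULL) {
  assert_that(l >= 1, "loss rate l must be >= 1")
  if (n == 0) {
    return(structure(list(lambda = 0, p1 = NA_real_, p2 = NA_real_,
                          score = NA_real_, p2_method = NA_character_,
                          mc_se = NULL, no_data = TRUE),
                     class = "DepletionScore"))
  }
  lambda <- n / l
  p1 <- p1_poisson(lambda, i)
  p2 <- p2_loss_run(n, i, k, method = p2_method, reps = reps, seed = seed)
  structure(list(lambda = lambda, p1 = p1, p2 = p2$p2,
                 score = p1 * p2$p2, p2_method = p2$method,
                 mc_se = p2$se, no_data = FALSE),
            class = "DepletionScore")
}

#' @export
print.DepletionScore <- function(x, ...) {
  if (isTRUE(x$no_data)) {
    cat("DepletionScore: no input insertions (no_data)\n")
  } else {
    cat(sprintf(
      "DepletionScore: lambda %.3f, p1 %.4g, p2 %.4g (%s) -> score %.4g\n",
      x$lambda, x$p1, x$p2, x$p2_method, x$score))
  }
  invisible(x)
}

#' Per-gene (n, i, k) from paired input/output libraries
#'
#' @param annotation a `GenomeAnnotation`.
#' @param input,output input and nodule-selected `InsertionLibrary`s.
#' @return data.frame: gene, n, i, k (one row per CDS).
#' @export
depletion_inputs <- function(annotation, input, output) {
  ain <- assign_insertions(annotation, input)
  aout <- assign_insertions(annotation, output)
  ids <- annotation$features$id
  rows <- lapply(ids, function(g) {
    trip <- max_loss_run(ain[[g]], aout[[g]])
    data.frame(gene = g, n = trip$n, i = trip$i, k = trip$k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score every gene of a paired TnSeq experiment
#'
#' @param inputs data.frame from [depletion_inputs()] (columns gene, n, i,
#'   k).
#' @param l neutral loss rate.
#' @param ... passed to [impairment_score()].
#' @return data.frame: gene, n, i, k, lambda, p1, p2, score, method.
#' @export
score_depletion <- function(inputs, l = 6.840, ...) {
  rows <- lapply(seq_len(nrow(inputs)), function(j) {
    s <- impairment_score(inputs$n[j], inputs$i[j], inputs$k[j], l = l, ...)
    data.frame(gene = inputs$gene[j], n = inputs$n[j], i = inputs$i[j],
               k = inputs$k[j], lambda = s$lambda, p1 = s$p1, p2 = s$p2,
               score = s$score,
               method = ifelse(isTRUE(s$no_data), "no_data", s$p2_method),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call symbiosis genes from impairment scores
#'
#' A gene is called a symbiosis gene when its (optionally
#' multiplicity-adjusted) impairment score falls below `alpha`, i.e. its
#' representation in the nodule-recovered library is significantly below
#' the neutral expectation from the input library.
#'
#' @param scores data.frame from [score_depletion()].
#' @param alpha significance cutoff (default 0.05).
#' @param correction `"none"` or `"benjamini_hochberg"`.
#' @return list with `genes` (character vector of flagged ids) and `table`
#'   (scores plus `adjusted` and `symbiosis` columns, sorted ascending by
#'   score).
#' @export
call_symbiosis_genes <- function(scores, alpha = 0.05,
                                 correction = c("none",
                                                "benjamini_hochberg")) {
  correction <- match.arg(correction)
  tab <- scores
  tab$adjusted <- if (correction == "benjamini_hochberg") {
    p.adjust(tab$score, method = "BH")
  } else {
    tab$score
  }
  tab$symbiosis <- !is.na(tab$adjusted) & tab$adjusted < alpha
  tab <- tab[order(tab$score), , drop = FALSE]
  rownames(tab) <- NULL
  list(genes = tab$gene[tab$symbiosis], table = tab)
}
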