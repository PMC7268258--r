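# shared helpers, not exported

# round half away from zero (commercial rounding); base round() is half-even
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_bad_arg(msg)
  invisible(TRUE)
}

# longest run of TRUE in a logical vector (0 if none)
longest_true_run <- function(lost) {
  if (!length(lost)) return(0L)
  r <- rle(lost)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

# area under the ROC curve for scores where LOW score should flag positives;
# computed from ranks (Mann-Whitney), ties handled by midranks
rank_auroc <- function(score, is_positive) {
  stopifnot(length(score) == length(is_positive))
  pos <- as.logical(is_positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)          # low score = more depleted
  (sum(r[!pos]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}
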