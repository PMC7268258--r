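test_that("loss rate is the ratio of input to recovered insertion totals", {
  inputs <- data.frame(gene = c("a", "b"), n = c(700000, 50128),
                       i = c(93000, 6623))
  expect_equal(estimate_loss_rate(inputs), 750128 / 99623)
  expect_equal(round(estimate_loss_rate(inputs), 3), 7.530)
  same <- data.frame(gene = "a", n = 10, i = 10)
  expect_equal(estimate_loss_rate(same), 1)
  none <- data.frame(gene = "a", n = 10, i = 0)
  expect_error(estimate_loss_rate(none), "no recovery|undefined")
  # restricting to a neutral set uses only those genes
  mix <- data.frame(gene = c("neu", "dep"), n = c(100, 100), i = c(50, 1))
  expect_equal(estimate_loss_rate(mix, neutral_set = "neu"), 2)
})

test_that("p1 is the Poisson CDF of the recovered count", {
  expect_equal(p1_poisson(1, 0), exp(-1))
  expect_equal(p1_poisson(20 / 6.84, 0), exp(-2.924), tolerance = 1e-3)
  expect_equal(p1_poisson(5, 10000), 1)
  expect_error(p1_poisson(-1, 0), ">= 0")
  expect_error(p1_poisson(1, -2), ">= 0")
})

test_that("the longest lost run is measured on coordinate-ordered sites", {
  r <- max_loss_run(c(10, 20, 30, 40, 50), c(30))
  expect_equal(r, list(n = 5L, i = 1L, k = 2L))
  expect_equal(max_loss_run(1:7, 1:7)$k, 0L)
  expect_equal(max_loss_run(1:7, numeric(0))$k, 7L)
  expect_error(max_loss_run(c(10, 20), c(30)), "not present")
  # k = 0 iff full recovery
  expect_gt(max_loss_run(1:5, c(1, 3, 4, 5))$k, 0L)
})

test_that("p2 reproduces enumerable compositions of small libraries", {
  expect_equal(p2_loss_run(3, 1, 2)$p2, 2 / 3)
  expect_equal(p2_loss_run(4, 1, 2)$p2, 1)
  expect_equal(p2_loss_run(10, 4, 0)$p2, 1)       # a run >= 0 always exists
  expect_equal(p2_loss_run(10, 4, 7)$p2, 0)       # k > n - i is impossible
  expect_equal(p2_loss_run(5, 2, 1)$p2, 1)        # 18 - 9 + 1 = 10 of C(5,2)
  expect_error(p2_loss_run(3, 5, 1), "i <= n")
})

test_that("all p2 estimators agree on a small grid", {
  for (n in c(4L, 6L, 8L)) {
    for (i in 0:n) {
      for (k in 0:(n - i)) {
        exact <- p2_loss_run(n, i, k, method = "enumeration")$p2
        ie <- p2_loss_run(n, i, k, method = "inclusion_exclusion")$p2
        expect_equal(ie, exact, tolerance = 1e-12,
                     label = sprintf("I-E vs enumeration at (%d,%d,%d)",
                                     n, i, k))
        if (k > (n - i) / 2 && k > 0) {
          cf <- p2_loss_run(n, i, k, method = "closed_form")$p2
          expect_equal(cf, exact, tolerance = 1e-12,
                       label = sprintf("closed form at (%d,%d,%d)", n, i, k))
        }
      }
    }
  }
})

test_that("p2 is monotone non-increasing in k and exact at k = n - i", {
  for (n in c(12L, 30L)) {
    for (i in c(2L, 5L)) {
      p2s <- vapply(0:(n - i), function(k) p2_loss_run(n, i, k)$p2, 1)
      expect_true(all(diff(p2s) <= 1e-12))
      expect_equal(p2s[n - i + 1], (i + 1) / choose(n, i))
    }
  }
})

test_that("closed form refuses the multi-run regime", {
  expect_error(p2_loss_run(20, 2, 3, method = "closed_form"),
               "k > \\(n - i\\)/2")
})

test_that("Monte-Carlo p2 is consistent with the exact value", {
  cases <- list(c(60, 9, 8), c(60, 20, 4))
  for (cs in cases) {
    exact <- p2_loss_run(cs[1], cs[2], cs[3])$p2
    mc <- p2_loss_run(cs[1], cs[2], cs[3], method = "monte_carlo",
                      reps = 2e4, seed = 99L)
    expect_true(abs(mc$p2 - exact) <= 4 * max(mc$se, 1e-3))
  }
})

test_that("impairment score composes p1 and p2 and flags empty genes", {
  s <- impairment_score(20, 0, 20, l = 6.84)
  expect_equal(s$lambda, 20 / 6.84)
  expect_equal(s$p2, 1)
  expect_equal(s$score, exp(-20 / 6.84))
  expect_equal(s$score, 0.0538, tolerance = 2e-3)

  full <- impairment_score(20, 20, 0, l = 6.84)
  expect_equal(full$p2, 1)
  expect_gt(full$score, 0.5)

  nodata <- impairment_score(0, 0, 0)
  expect_true(nodata$no_data)
  expect_true(is.na(nodata$score))

  # the Poisson factor is non-increasing as recovery worsens, and total
  # loss scores below full recovery
  p1s <- vapply(10:0, function(i) impairment_score(10, i, 10 - i,
                                                   l = 6.84)$p1, 1)
  expect_true(all(diff(p1s) <= 1e-12))
  expect_lt(impairment_score(10, 0, 10, l = 6.84)$score,
            impairment_score(10, 10, 0, l = 6.84)$score)
})

test_that("symbiosis calls honor alpha and multiplicity correction", {
  sc <- data.frame(gene = letters[1:5], n = 10, i = 5, k = 2,
                   lambda = 2, p1 = 1, p2 = 1,
                   score = c(0.9, 0.8, 0.001, 0.04, 0.2),
                   method = "inclusion_exclusion")
  all_one <- transform(sc, score = 1)
  expect_length(call_symbiosis_genes(all_one)$genes, 0L)
  expect_length(call_symbiosis_genes(sc, alpha = 1)$genes, 5L)
  got <- call_symbiosis_genes(sc, alpha = 0.05)
  expect_setequal(got$genes, c("c", "d"))
  expect_equal(got$table$gene[1], "c")  # sorted ascending
  bh <- call_symbiosis_genes(sc, alpha = 0.05,
                             correction = "benjamini_hochberg")
  expect_true(all(bh$table$adjusted >= bh$table$score))
})

test_that("neutral-gene scores match the exact null of the statistic", {
  # Simulate a pure bottleneck (no depleted genes) and compare the observed
  # fraction of scores below alpha with the exact mixture over (i, k):
  # i ~ Binomial(n, 1/l), K | (n, i) from the run-length distribution.
  l <- 6.84; alpha <- 0.05
  cfg <- simulation_config(
    replicon_specs = data.frame(name = "chr", length = 150000L,
                                cds_count = 300L),
    insertion_density = 0.11, neutral_loss_rate = l,
    depleted_gene_fraction = 0, seed = 17L)
  ann <- generate_genome(cfg)
  lib <- generate_input_library(ann, cfg)
  sel <- simulate_nodule_selection(ann, lib, cfg)
  inputs <- depletion_inputs(ann, lib, sel$library)
  scores <- score_depletion(inputs, l = l)

  null_below <- function(n) {
    lam <- n / l
    p_i <- dbinom(0:n, n, 1 / l)
    tot <- 0
    for (i in 0:n) {
      if (p_i[i + 1] < 1e-12) next
      p1 <- p1_poisson(lam, i)
      p2v <- vapply(0:(n - i), function(k) p2_loss_run(n, i, k)$p2, 1)
      pK <- p2v - c(p2v[-1], 0)
      tot <- tot + p_i[i + 1] * sum(pK[p1 * p2v < alpha])
    }
    tot
  }
  by_n <- vapply(sort(unique(inputs$n)), null_below, 1)
  names(by_n) <- sort(unique(inputs$n))
  expected <- mean(by_n[as.character(inputs$n)])
  observed <- mean(scores$score < alpha, na.rm = TRUE)
  se <- sqrt(expected * (1 - expected) / nrow(scores))
  expect_lt(abs(observed - expected), 4 * se + 0.01)
})
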