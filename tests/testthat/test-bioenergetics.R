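test_that("builtin pathway fixtures carry the expected stoichiometry", {
  pw <- builtin_pathways()
  expect_named(pw, c("CATCH-N1", "CATCH-N2", "CATCH-N3", "CATCH-N4",
                     "TCA-malate", "TCA-succinate"))
  expect_equal(vapply(pw, `[[`, 0, "reaction_steps"),
               c(9, 9, 9, 9, 11, 11), ignore_attr = TRUE)
  expect_true(all(vapply(pw, `[[`, 0, "nadh_total") == 8))
  expect_equal(vapply(pw, `[[`, 0, "qh2_catabolic"),
               c(4, 4, 1, 1, 1.6, 3.2), ignore_attr = TRUE)
  expect_equal(vapply(pw, `[[`, 0, "h_enzymatic_consumed"),
               c(8, 4, 8, 4, 5.2, 5.2), ignore_attr = TRUE)
  expect_equal(vapply(pw, `[[`, 0, "substrate_level_atp"),
               c(2, 2, 2, 2, 1.6, 1.6), ignore_attr = TRUE)
  ox <- vapply(pw, function(p) energy_budget(p)$electrons_to_oxidase, 0)
  expect_equal(ox, c(16, 16, 12, 12, 11.2, 43.6 / 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(pw[["TCA-succinate"]]$non_reconciled)
  expect_false(any(vapply(pw[1:5], `[[`, TRUE, "non_reconciled")))
})

test_that("energy budgets reproduce the comparative pathway table", {
  pw <- builtin_pathways()[1:5]
  b <- lapply(pw, energy_budget)
  round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100
  expect_equal(vapply(b, function(x) round2(x$atp_net), 0),
               c(2.80, 1.60, -0.80, -2.00, -2.76), ignore_attr = TRUE)
  expect_equal(vapply(b, `[[`, 0, "h_influx_total"),
               c(56, 52, 44, 40, 38.8), ignore_attr = TRUE)
  expect_equal(vapply(b, `[[`, 0, "o2_consumed"),
               c(-4, -4, -3, -3, -2.8), ignore_attr = TRUE)
  # the budget identity: proton ATP + substrate-level ATP - nitrogenase cost
  for (x in b) {
    expect_equal(x$atp_net,
                 x$h_influx_total * 3 / 10 + x$substrate_level_atp - 16)
    expect_equal(x$h_influx_total, x$h_translocated + x$h_enzymatic)
  }
})

test_that("a pathway providing nothing pays the full nitrogenase bill", {
  dead <- pathway_definition(list(
    name = "null", substrates = list(x = 1), products = list(y = 1),
    reaction_steps = 1, nadh_total = 0, nadh_bifurcated = 0,
    qh2_catabolic = 0, extra_electrons_to_oxidase = 0,
    h_enzymatic_consumed = 0, substrate_level_atp = 0))
  expect_warning(b <- energy_budget(dead), "not self-sufficient")
  expect_equal(b$atp_net, -16)
})

test_that("electron bookkeeping closes for the succinate-fed cycles", {
  pw <- builtin_pathways()
  for (nm in c("CATCH-N1", "CATCH-N2")) {
    p <- pw[[nm]]
    b <- energy_budget(p)
    sourced <- 2 * p$nadh_total + 2 * p$qh2_catabolic +
      p$extra_electrons_to_oxidase
    expect_equal(b$electrons_to_nitrogenase + b$electrons_to_oxidase,
                 sourced)
  }
})

test_that("net ATP moves the right way with each lever", {
  p <- builtin_pathways()[["CATCH-N1"]]
  base <- energy_budget(p)$atp_net
  up_h <- p; up_h$h_enzymatic_consumed <- p$h_enzymatic_consumed + 1
  expect_gt(energy_budget(up_h)$atp_net, base)
  up_s <- p; up_s$substrate_level_atp <- p$substrate_level_atp + 1
  expect_gt(energy_budget(up_s)$atp_net, base)
  costly <- energy_constants()
  costly$atp_per_n2_nitrogenase <- 20
  expect_lt(energy_budget(p, costly)$atp_net, base)
})

test_that("NADH:QH2 ratios separate the CATCH-N cycles from the TCA", {
  pw <- builtin_pathways()
  expect_equal(nadh_qh2_ratio(pw[["CATCH-N1"]]), 2)
  expect_equal(nadh_qh2_ratio(pw[["CATCH-N2"]]), 2)
  expect_equal(nadh_qh2_ratio(pw[["TCA-malate"]]), 5)
  expect_equal(nadh_qh2_ratio(pw[["TCA-succinate"]]), 5 / 2)
  noq <- pw[["CATCH-N1"]]; noq$qh2_catabolic <- 0
  expect_equal(nadh_qh2_ratio(noq), Inf)
})

test_that("nitrogen bookkeeping yields 2 alanine + 3 ammonium per arginine", {
  p <- builtin_pathways()[["CATCH-N1"]]
  ny <- nitrogen_yield(p)
  expect_equal(ny$n_in_organic, 4)
  expect_equal(ny$n_fixed, 1)
  expect_equal(ny$n_out_amino, 2)
  expect_equal(ny$n_out_ammonium, 3)
  expect_equal(ny$n_yield_per_arginine, 5)
  expect_equal(ny$pct_vs_classical, 25)
  # conservation: organic in + fixed = out
  expect_equal(ny$n_in_organic + ny$n_fixed,
               ny$n_out_amino + ny$n_out_ammonium)
})

test_that("nitrogen yield is scale-invariant and null for classical catabolism", {
  p <- builtin_pathways()[["CATCH-N1"]]
  doubled <- p
  doubled$substrates <- lapply(p$substrates, `*`, 2)
  doubled$products <- lapply(p$products, `*`, 2)
  doubled$nadh_total <- p$nadh_total * 2
  doubled$nadh_bifurcated <- p$nadh_bifurcated * 2
  expect_equal(nitrogen_yield(doubled)$pct_vs_classical, 25)

  classical <- p
  classical$nadh_bifurcated <- 0
  classical$nadh_total <- 0
  classical$transaminations_per_arginine <- 0
  expect_equal(nitrogen_yield(classical)$pct_vs_classical, 0)

  no_arg <- builtin_pathways()[["TCA-malate"]]
  expect_error(nitrogen_yield(no_arg), "arginine")
})

test_that("the comparative report formats signs, brackets and rounding", {
  tab <- pathway_comparison()
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$influx_h[1], "56 (48 + 8)")
  expect_equal(tab$influx_h[5], "38.8 (33.6 + 5.2)")
  expect_equal(tab$atp_net_gain[4], -2.00)
  expect_equal(tab$o2_consumed_per_n2[5], -2.8)
  empty <- pathway_comparison(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("pathway", "influx_h", "atp_net_gain") %in%
                    names(empty)))
})
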