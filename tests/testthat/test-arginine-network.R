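test_that("the default network has the expected backbone structure", {
  m <- default_network()
  core <- c("ARG", "ORN", "GOP", "AGM", "AOP", "PUT", "GBL", "ABL",
            "GBA", "GABA", "SSA", "SUCC")
  expect_true(all(core %in% m$metabolites$id))
  expect_silent(validate_network(m))
  paths <- network_paths(m)
  expect_gt(length(paths), 0L)
  steps <- vapply(paths, length, 0L) - 1L
  expect_true(all(steps >= 6L))
  expect_true(any(steps == 6L))
  # every route from arginine to succinate spends exactly two pyruvates
  pyr <- vapply(paths, function(p) pyruvate_balance(m, p), 0L)
  expect_true(all(pyr == 2L))
})

test_that("named routes consume two pyruvate equivalents", {
  m <- default_network()
  expect_equal(pyruvate_balance(
    m, c("ARG", "GOP", "GBL", "GBA", "GABA", "SSA", "SUCC")), 2L)
  expect_equal(pyruvate_balance(
    m, c("ARG", "ORN", "PUT", "ABL", "GABA", "SSA", "SUCC")), 2L)
  expect_error(pyruvate_balance(m, c("ARG", "SUCC")), "not a directed path")
})

test_that("validation rejects imbalanced edges and unreachable succinate", {
  m <- default_network()
  # an arginase edge mislabelled as dehydrogenase loses the urea co-product
  bad_edges <- m$edges
  bad_edges$class[bad_edges$substrate == "ARG" &
                    bad_edges$product == "ORN"] <- "dehydrogenase"
  expect_error(network_model(m$metabolites, bad_edges),
               "atom-imbalanced.*ARG>ORN")
  cut_edges <- m$edges[!(m$edges$substrate == "SSA"), ]
  expect_error(network_model(m$metabolites, cut_edges),
               "not reachable")
})

test_that("optional branches toggle on", {
  m <- default_network(deiminase = TRUE, urease = TRUE)
  expect_true("CIT" %in% m$metabolites$id)
  expect_true(any(m$edges$class == "urease"))
  expect_false("CIT" %in% default_network()$metabolites$id)
})

test_that("the reconstitution time course behaves like the in vitro assay", {
  m <- default_network()
  tc <- simulate_network(m, t_end = 360, dt = 2)
  expect_true(all(as.matrix(tc[m$metabolites$id]) >= 0))
  # substrate decays monotonically, products accumulate
  expect_true(all(diff(tc$ARG) <= 1e-9))
  expect_true(all(diff(tc$SUCC) >= -1e-9))
  expect_true(all(diff(tc$ALA) >= -1e-9))
  # most arginine consumed within ~30 min, as in the assay
  expect_lt(tc$ARG[tc$time == 30] / tc$ARG[1], 0.2)
  # first-tier intermediates peak before second-tier ones
  tier1 <- max(peak_times(tc, c("ORN", "GOP", "AGM")))
  tier2 <- min(peak_times(tc, c("PUT", "AOP", "ABL")))
  expect_lt(tier1, tier2)
  # atom conservation
  at <- atom_totals(tc)
  expect_lt(max(abs(at$carbon - at$carbon[1])) / at$carbon[1], 1e-6)
  expect_lt(max(abs(at$nitrogen - at$nitrogen[1])) / at$nitrogen[1], 1e-6)
  # two alanines per consumed arginine at (near-)complete conversion
  consumed <- tc$ARG[1] - tail(tc$ARG, 1)
  expect_equal(tail(tc$ALA, 1), 2 * consumed, tolerance = 0.01)
})

test_that("zero rates freeze the system", {
  m <- default_network()
  m0 <- network_model(m$metabolites,
                      transform(m$edges, rate = 0))
  tc <- simulate_network(m0, t_end = 50, dt = 5)
  expect_equal(tail(tc$ARG, 1), tc$ARG[1])
  expect_equal(tail(tc$SUCC, 1), 0)
})

test_that("label fractions stay bounded and decay downstream of the clamp", {
  m <- default_network()
  ls <- propagate_labels(m, c(ARG = 0.9943), t_end = 120, dt = 5)
  vals <- as.matrix(ls[m$metabolites$id])
  expect_true(all(vals >= -1e-9 & vals <= 1 + 1e-9, na.rm = TRUE))
  expect_true(all(abs(ls$ARG - 0.9943) < 1e-9))
  # single-source chain GBL -> GBA: the downstream pool lags its feeder
  late <- ls[ls$time > 0, ]
  expect_true(all(late$GBL <= late$ARG + 1e-9))
  expect_true(all(late$GBA <= late$GBL + 1e-9))
  expect_true(all(late$ORN <= late$ARG + 1e-9))
})

test_that("labeling approaches the clamp value far downstream at long times", {
  # pyruvate is co-clamped so the transaminase fluxes persist to steady state
  m <- default_network()
  ls <- propagate_labels(m, c(ARG = 0.9943, PYR = 0), t_end = 1500,
                         dt = 50)
  expect_equal(tail(ls$ORN, 1), 0.9943, tolerance = 1e-3)
  expect_equal(tail(ls$GBA, 1), 0.9943, tolerance = 1e-2)
})

test_that("labeling order mirrors distance from the arginine source", {
  m <- default_network(deiminase = TRUE)
  ls <- propagate_labels(m, c(ARG = 0.9943), t_end = 60, dt = 5)
  at30 <- ls[ls$time == 30, ]
  expect_gt(at30$ARG, at30$ORN)
  expect_gt(at30$ORN, at30$GABA)
})

test_that("no label sources means no label anywhere", {
  m <- default_network()
  ls <- propagate_labels(m, c(ARG = 0), t_end = 60, dt = 10)
  vals <- as.matrix(ls[m$metabolites$id])
  expect_true(all(vals[!is.na(vals)] < 1e-9))
  expect_error(propagate_labels(m, c(XYZ = 0.5)), "unknown clamp")
})
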