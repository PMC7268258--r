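# Co-species pattern implied by each reaction class (substrate S -> P):
#   aminotransferase: S + PYR -> P + ALA          (bimolecular in PYR)
#   decarboxylase:    S -> P + CO2
#   ureohydrolase:    S -> P + UREA
#   dehydrogenase:    S -> P + NADH               (NAD+ pool non-limiting)
#   deiminase:        S -> P + NH4
#   urease:           UREA -> 2 NH4 + CO2
.edge_classes <- c("aminotransferase", "decarboxylase", "ureohydrolase",
                   "dehydrogenase", "deiminase", "urease")

#' Reaction network container
#'
#' Builds a validated arginine-catabolism reaction network from a
#' metabolite table (with whole-molecule carbon/nitrogen counts) and an
#' edge table whose reaction class determines the co-substrates and
#' co-products. The species-by-reaction stoichiometric matrix is
#' constructed and every column checked for carbon and nitrogen balance.
#'
#' @param metabolites data.frame: `id`, `carbon`, `nitrogen`, optional
#'   `guanidino`, `name`.
#' @param edges data.frame: `substrate`, `product`, `class`, `enzymes`
#'   (label), `rate` (min^-1; aminotransferases mM^-1 min^-1).
#' @return object of class `NetworkModel` with elements `metabolites`,
#'   `edges`, `stoichiometry` (species x reactions).
#' @export
network_model <- function(metabolites, edges) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  assert_that(all(c("id", "carbon", "nitrogen") %in% names(metabolites)),
              "metabolites needs columns id, carbon, nitrogen")
  assert_that(all(c("substrate", "product", "class", "rate") %in%
                    names(edges)),
              "edges needs columns substrate, product, class, rate")
  assert_that(!anyDuplicated(metabolites$id), "duplicate metabolite ids")
  assert_that(all(edges$class %in% .edge_classes),
              paste("unknown reaction class; expected one of",
                    paste(.edge_classes, collapse = ", ")))
  ids <- metabolites$id
  known <- c(edges$substrate, edges$product)
  assert_that(all(known %in% ids),
              paste("edge references unknown metabolite:",
                    paste(setdiff(known, ids), collapse = ", ")))
  assert_that(all(edges$rate >= 0), "rates must be >= 0")
  S <- matrix(0, nrow = length(ids), ncol = nrow(edges),
              dimnames = list(ids, paste0(edges$substrate, ">",
                                          edges$product)))
  for (e in seq_len(nrow(edges))) {
    sub <- edges$substrate[e]; prod <- edges$product[e]
    cls <- edges$class[e]
    if (cls == "urease") {
      assert_that(sub == "UREA" && prod == "NH4",
                  "urease edge must be UREA -> NH4")
      S["UREA", e] <- -1; S["NH4", e] <- 2
      if ("CO2" %in% ids) S["CO2", e] <- 1
      next
    }
    S[sub, e] <- S[sub, e] - 1
    S[prod, e] <- S[prod, e] + 1
    co <- switch(cls,
                 aminotransferase = c(PYR = -1, ALA = 1),
                 decarboxylase = c(CO2 = 1),
                 ureohydrolase = c(UREA = 1),
                 dehydrogenase = c(NADH = 1),
                 deiminase = c(NH4 = 1))
    for (sp in names(co)) {
      assert_that(sp %in% ids,
                  paste0("class ", cls, " needs co-species ", sp))
      S[sp, e] <- S[sp, e] + co[[sp]]
    }
  }
  model <- structure(list(metabolites = metabolites, edges = edges,
                          stoichiometry = S),
                     class = "NetworkModel")
  validate_network(model)
  model
}

#' @export
print.NetworkModel <- function(x, ...) {
  cat(sprintf("NetworkModel: %d metabolites, %d reactions\n",
              nrow(x$metabolites), nrow(x$edges)))
  cat(paste0("  ", x$edges$substrate, " -> ", x$edges$product,
             " (", x$edges$class, ")", collapse = "\n"), "\n")
  invisible(x)
}

#' The default arginine-to-succinate transamination network
#'
#' Loads the shipped network fixture: twelve core metabolites from
#' arginine to succinate connected by aminotransferase, decarboxylase,
#' ureohydrolase and dehydrogenase steps, all irreversible, with pyruvate
#' as the common amino acceptor (yielding alanine). The off-path arginine
#' deiminase branch (to citrulline), the classical ornithine-proline-
#' glutamate branch, and urea hydrolysis are optional sub-networks.
#'
#' @param deiminase include the ARG -> CIT deiminase branch.
#' @param classical include the ORN -> PRO -> GLU branch.
#' @param urease include urea hydrolysis (UREA -> 2 NH4 + CO2).
#' @param rates optional named numeric vector of rate overrides, named
#'   `"SUB>PROD"`.
#' @return a `NetworkModel`.
#' @export
default_network <- function(deiminase = FALSE, classical = FALSE,
                            urease = FALSE, rates = NULL) {
  path <- system.file("extdata", "network", "arginine_network.yaml",
                      package = "catchn")
  spec <- yaml::read_yaml(path)
  mets <- do.call(rbind, lapply(spec$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id, carbon = m$carbon,
               nitrogen = m$nitrogen, guanidino = isTRUE(m$guanidino),
               optional = isTRUE(m$optional), stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(spec$edges, function(e) {
    data.frame(substrate = e$substrate, product = e$product,
               class = e$class,
               enzymes = paste(unlist(e$enzymes), collapse = "/"),
               rate = e$rate, optional = isTRUE(e$optional),
               stringsAsFactors = FALSE)
  }))
  drop <- edges$optional
  if (deiminase) drop <- drop & !(edges$product == "CIT")
  if (classical) drop <- drop & !(edges$substrate %in% c("ORN", "PRO") &
                                    edges$product %in% c("PRO", "GLU"))
  if (urease) drop <- drop & !(edges$class == "urease")
  edges <- edges[!drop, , drop = FALSE]
  used <- unique(c(edges$substrate, edges$product,
                   "PYR", "ALA", "UREA", "NH4", "CO2", "NADH"))
  mets <- mets[!mets$optional | mets$id %in% used, , drop = FALSE]
  if (!is.null(rates)) {
    key <- paste0(edges$substrate, ">", edges$product)
    hit <- match(names(rates), key)
    assert_that(!anyNA(hit), "rate override names unknown edges")
    edges$rate[hit] <- unname(rates)
  }
  network_model(mets, edges)
}

#' Validate a reaction network
#'
#' Checks carbon and nitrogen balance of every reaction column of the
#' stoichiometric matrix, class/co-species consistency, and that succinate
#' is reachable from arginine. Imbalance or unreachability is an error
#' naming the offending edge.
#'
#' @param model a `NetworkModel`.
#' @return invisibly, a list with `valid = TRUE` and the per-check
#'   messages.
#' @export
validate_network <- function(model) {
  S <- model$stoichiometry
  carbon <- model$metabolites$carbon[match(rownames(S),
                                           model$metabolites$id)]
  nitrogen <- model$metabolites$nitrogen[match(rownames(S),
                                               model$metabolites$id)]
  c_bal <- as.numeric(carbon %*% S)
  n_bal <- as.numeric(nitrogen %*% S)
  bad <- which(abs(c_bal) > 1e-9 | abs(n_bal) > 1e-9)
  if (length(bad)) {
    stop_bad_arg("atom-imbalanced reaction(s): ",
                 paste(colnames(S)[bad], collapse = ", "),
                 " (dC = ", paste(c_bal[bad], collapse = ","),
                 "; dN = ", paste(n_bal[bad], collapse = ","), ")")
  }
  msgs <- sprintf("%d reactions atom-balanced", ncol(S))
  if (all(c("ARG", "SUCC") %in% model$metabolites$id)) {
    g <- network_graph(model)
    reach <- igraph::distances(g, v = "ARG", to = "SUCC", mode = "out")
    if (!is.finite(reach[1, 1])) {
      stop_bad_arg("succinate is not reachable from arginine")
    }
    msgs <- c(msgs, sprintf("ARG -> SUCC reachable (shortest path %d steps)",
                            as.integer(reach[1, 1])))
  }
  invisible(list(valid = TRUE, messages = msgs))
}

# directed backbone graph (substrate -> product edges only)
network_graph <- function(model) {
  igraph::graph_from_data_frame(
    model$edges[, c("substrate", "product")],
    directed = TRUE,
    vertices = model$metabolites$id)
}

#' All directed backbone paths between two metabolites
#'
#' @param model a `NetworkModel`.
#' @param from,to metabolite ids (defaults ARG, SUCC).
#' @return list of character vectors of metabolite ids.
#' @export
network_paths <- function(model, from = "ARG", to = "SUCC") {
  g <- network_graph(model)
  lapply(igraph::all_simple_paths(g, from = from, to = to, mode = "out"),
         function(p) igraph::as_ids(p))
}

#' Net pyruvate consumption along a path
#'
#' Each aminotransferase edge consumes one pyruvate equivalent (exporting
#' one alanine); the other classes neither consume nor produce pyruvate.
#'
#' @param model a `NetworkModel`.
#' @param path character vector of metabolite ids forming a directed path.
#' @return integer, net pyruvate consumed along the path.
#' @export
pyruvate_balance <- function(model, path) {
  assert_that(length(path) >= 2, "path must have >= 2 metabolites")
  key <- paste0(model$edges$substrate, ">", model$edges$product)
  steps <- paste0(head(path, -1L), ">", tail(path, -1L))
  hit <- match(steps, key)
  if (anyNA(hit)) {
    stop_bad_arg("not a directed path in the network: missing edge(s) ",
                 paste(steps[is.na(hit)], collapse = ", "))
  }
  sum(model$edges$class[hit] == "aminotransferase")
}

#' The in vitro reconstitution scenario
#'
#' Initial concentrations of the 14-enzyme reconstitution assay: 2 mM
#' arginine and 20 mM pyruvate in an otherwise empty pool set.
#'
#' @param model a `NetworkModel`.
#' @return named numeric vector of initial concentrations (mM).
#' @export
reconstitution_initial <- function(model = default_network()) {
  init <- setNames(numeric(nrow(model$metabolites)), model$metabolites$id)
  init["ARG"] <- 2
  init["PYR"] <- 20
  init
}

# mass-action fluxes for one state vector
.network_fluxes <- function(model, y) {
  y <- pmax(y, 0)
  v <- numeric(nrow(model$edges))
  for (e in seq_along(v)) {
    s <- y[[model$edges$substrate[e]]]
    v[e] <- if (model$edges$class[e] == "aminotransferase") {
      model$edges$rate[e] * s * y[["PYR"]]
    } else {
      model$edges$rate[e] * s
    }
  }
  v
}

#' Simulate the network as a mass-action ODE system
#'
#' Irreversible mass-action kinetics: unimolecular in the backbone
#' substrate, bimolecular (substrate x pyruvate) for aminotransferases.
#' Integrated with a stiff-safe solver (`deSolve::ode`, lsoda);
#' non-negativity is enforced in the rate law.
#'
#' @param model a `NetworkModel`.
#' @param initial named initial concentrations in mM (missing species
#'   start at 0); see [reconstitution_initial()].
#' @param t_end end time (min).
#' @param dt output grid spacing (min).
#' @return object of class `TimeCourse`: data.frame `time` plus one column
#'   per species, with the model attached as attribute.
#' @export
simulate_network <- function(model, initial = reconstitution_initial(model),
                             t_end = 360, dt = 1) {
  stopifnot(inherits(model, "NetworkModel"))
  assert_that(all(initial >= 0), "initial concentrations must be >= 0")
  ids <- model$metabolites$id
  y0 <- setNames(numeric(length(ids)), ids)
  y0[names(initial)] <- initial
  S <- model$stoichiometry
  rhs <- function(t, y, parms) {
    v <- .network_fluxes(model, y)
    list(as.numeric(S %*% v))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    stop_bad_arg("ODE integration failed (istate ",
                 attr(sol, "istate")[1], ")")
  }
  tc <- as.data.frame(sol)
  tc[ids] <- pmax(tc[ids], 0)
  structure(tc, model = model, class = c("TimeCourse", "data.frame"))
}

#' @export
print.TimeCourse <- function(x, ...) {
  cat(sprintf("TimeCourse: %d time points, %d species, t in [%g, %g] min\n",
              nrow(x), ncol(x) - 1L, min(x$time), max(x$time)))
  invisible(x)
}

#' Total carbon and nitrogen over a time course
#'
#' @param timecourse a [simulate_network()] result.
#' @return data.frame: time, carbon, nitrogen (mM atoms).
#' @export
atom_totals <- function(timecourse) {
  model <- attr(timecourse, "model")
  ids <- model$metabolites$id
  conc <- as.matrix(timecourse[ids])
  data.frame(
    time = timecourse$time,
    carbon = as.numeric(conc %*% model$metabolites$carbon),
    nitrogen = as.numeric(conc %*% model$metabolites$nitrogen)
  )
}

#' Peak times of intermediate pools
#'
#' @param timecourse a [simulate_network()] result.
#' @param species character vector of species ids.
#' @return named numeric vector of times (min) at which each pool peaks.
#' @export
peak_times <- function(timecourse, species) {
  vapply(species, function(sp) {
    timecourse$time[which.max(timecourse[[sp]])]
  }, numeric(1))
}

#' Propagate isotope labels through the network
#'
#' Duplicates every pool into labeled and unlabeled species sharing the
#' same rate constants. Reaction fluxes are computed from total
#' concentrations and split by the substrate's current labeled fraction
#' (the backbone label travels with the backbone; the alanine co-product
#' carries the pyruvate label; urea/ammonium/CO2 side products carry the
#' substrate label). Clamped sources are held at a constant concentration
#' and labeled fraction.
#'
#' @param model a `NetworkModel`.
#' @param clamped_sources named vector of labeled fractions in `[0, 1]`,
#'   e.g. `c(ARG = 0.9943)`.
#' @param initial named initial total concentrations (mM). Default: 2 mM
#'   arginine, 20 mM pyruvate, 1 mM in each backbone intermediate pool
#'   (pre-filled unlabeled).
#' @param t_end,dt time grid (min).
#' @return object of class `LabelState`: data.frame `time` plus the
#'   labeled fraction of each species (NA while a pool is empty).
#' @export
propagate_labels <- function(model, clamped_sources = c(ARG = 0.9943),
                             initial = NULL, t_end = 360, dt = 1) {
  stopifnot(inherits(model, "NetworkModel"))
  assert_that(all(clamped_sources >= 0 & clamped_sources <= 1),
              "clamped fractions must be in [0, 1]")
  ids <- model$metabolites$id
  unknown <- setdiff(names(clamped_sources), ids)
  if (length(unknown)) {
    stop_bad_arg("unknown clamp source(s): ",
                 paste(unknown, collapse = ", "))
  }
  if (is.null(initial)) {
    backbone <- setdiff(ids, c("PYR", "ALA", "ASP", "UREA", "NH4",
                               "CO2", "NADH"))
    initial <- setNames(rep(1, length(backbone)), backbone)
    initial["ARG"] <- 2
    initial <- c(initial, PYR = 20)
  }
  tot0 <- setNames(numeric(length(ids)), ids)
  tot0[names(initial)] <- initial
  lab0 <- setNames(numeric(length(ids)), ids)
  lab0[names(clamped_sources)] <-
    clamped_sources * tot0[names(clamped_sources)]
  y0 <- c(lab0, setNames(tot0 - lab0, paste0(ids, ".u")))
  names(y0)[seq_along(ids)] <- paste0(ids, ".l")
  clamped <- names(clamped_sources)
  S <- model$stoichiometry
  edges <- model$edges
  rhs <- function(t, y, parms) {
    lab <- pmax(y[paste0(ids, ".l")], 0)
    unl <- pmax(y[paste0(ids, ".u")], 0)
    names(lab) <- names(unl) <- ids
    tot <- lab + unl
    frac <- ifelse(tot > 1e-12, lab / tot, 0)
    v <- .network_fluxes(model, tot)
    dlab <- setNames(numeric(length(ids)), ids)
    dunl <- setNames(numeric(length(ids)), ids)
    for (e in seq_len(nrow(edges))) {
      sub <- edges$substrate[e]
      fs <- frac[[sub]]
      for (sp in ids) {
        coef <- S[sp, e]
        if (coef == 0) next
        f <- if (coef < 0) {
          frac[[sp]]              # consumption leaves at the pool's own mix
        } else if (sp == "ALA" && edges$class[e] == "aminotransferase") {
          frac[["PYR"]]           # alanine backbone comes from pyruvate
        } else if (sp == "NADH") {
          0
        } else {
          fs                      # backbone and side products carry S label
        }
        dlab[sp] <- dlab[sp] + coef * v[e] * f
        dunl[sp] <- dunl[sp] + coef * v[e] * (1 - f)
      }
    }
    dlab[clamped] <- 0
    dunl[clamped] <- 0
    list(c(dlab, dunl))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    stop_bad_arg("label ODE integration failed")
  }
  df <- as.data.frame(sol)
  lab <- as.matrix(df[paste0(ids, ".l")])
  unl <- as.matrix(df[paste0(ids, ".u")])
  tot <- lab + unl
  frac <- ifelse(tot > 1e-9, pmin(pmax(lab / tot, 0), 1), NA_real_)
  colnames(frac) <- ids
  out <- data.frame(time = df$time)
  out <- cbind(out, as.data.frame(frac))
  structure(out, model = model, class = c("LabelState", "data.frame"))
}

#' @export
print.LabelState <- function(x, ...) {
  cat(sprintf("LabelState: %d time points, %d pools\n",
              nrow(x), ncol(x) - 1L))
  invisible(x)
}
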