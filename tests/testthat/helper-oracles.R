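# Shared fixtures and independent oracles.
#
# The vertex-enumeration oracle solves small LPs by brute force (every
# candidate basic solution over bound patterns), entirely independently of
# the simplex implementation under test.

vertex_enumerate_lp <- function(A, b, obj, lower, upper, sense = "max",
                                tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  best <- if (sense == "max") -Inf else Inf
  bestx <- NULL
  k <- n - qr(A)$rank
  if (k < 0) k <- 0
  for (nb in utils::combn(n, k, simplify = FALSE)) {
    fr <- setdiff(seq_len(n), nb)
    patterns <- if (length(nb)) expand.grid(rep(list(1:2), length(nb)))
      else data.frame(row.names = 1)
    for (si in seq_len(nrow(patterns))) {
      x <- numeric(n)
      if (length(nb))
        x[nb] <- ifelse(unlist(patterns[si, ]) == 1, lower[nb], upper[nb])
      rhs <- b - if (length(nb)) A[, nb, drop = FALSE] %*% x[nb] else 0
      Af <- A[, fr, drop = FALSE]
      sol <- tryCatch(qr.solve(Af, rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(Af %*% sol - rhs)) > tol) next
      x[fr] <- sol
      if (any(x < lower - tol) || any(x > upper + tol)) next
      v <- sum(obj * x)
      if ((sense == "max" && v > best) || (sense == "min" && v < best)) {
        best <- v
        bestx <- x
      }
    }
  }
  list(objective = best, x = bestx)
}

vertex_enumerate_model <- function(model, sense = "max") {
  S <- as.matrix(build_stoichiometric_matrix(model))
  obj <- as.numeric(colnames(S) == model$objective_id)
  vertex_enumerate_lp(S, rep(0, nrow(S)), obj,
                      model$reactions$lower_bound,
                      model$reactions$upper_bound, sense)
}

# Linear chain: EX_A (uptake up to 10) -> A -> B -> biomass drain.
chain_model <- function(uptake_lb = -10) {
  metabolic_model(
    metabolites = data.frame(
      id = c("A", "B"), name = c("A", "B"),
      compartment = c("extracellular", "intracellular"),
      stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_A", "R1", "BIO"),
      name = c("A exchange", "A to B", "biomass"),
      lower_bound = c(uptake_lb, 0, 0),
      upper_bound = c(0, 1000, 1000),
      gpr = "", subsystem = "",
      kind = c("exchange", "transport", "biomass"),
      stringsAsFactors = FALSE),
    stoichiometry = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
                         BIO = c(B = -1)),
    objective_id = "BIO")
}

# Small branched fermentation variants (<= 12 reactions) for the
# vertex-enumeration cross-checks. Each returns a valid model whose optimum
# is reachable by enumeration in well under a second.
toy_variant <- function(which) {
  mk <- function(mets, comps, rxns) {
    ids <- vapply(rxns, `[[`, "", "id")
    metabolic_model(
      metabolites = data.frame(id = mets, name = mets, compartment = comps,
                               stringsAsFactors = FALSE),
      reactions = data.frame(
        id = ids,
        name = ids,
        lower_bound = vapply(rxns, function(r) r$lb, 0),
        upper_bound = vapply(rxns, function(r) r$ub, 0),
        gpr = "", subsystem = "",
        kind = vapply(rxns, function(r) r$kind, ""),
        stringsAsFactors = FALSE),
      stoichiometry = stats::setNames(lapply(rxns, `[[`, "s"), ids),
      objective_id = "BIO")
  }
  r <- function(id, s, lb, ub, kind = "intracellular")
    list(id = id, s = s, lb = lb, ub = ub, kind = kind)
  switch(which,
    # branch: substrate splits between biomass precursor and by-product
    branch = mk(
      c("S_e", "S", "P", "W_e"),
      c("extracellular", "intracellular", "intracellular", "extracellular"),
      list(r("EX_S", c(S_e = -1), -10, 0, "exchange"),
           r("T1", c(S_e = -1, S = 1), 0, 100, "transport"),
           r("R1", c(S = -1, P = 1), 0, 6),
           r("R2", c(S = -1, W_e = 1), 0, 100, "transport"),
           r("EX_W", c(W_e = -1), 0, 100, "exchange"),
           r("BIO", c(P = -1), 0, 100, "biomass"))),
    # redox-coupled pair: biomass needs both branches in fixed proportion
    coupled = mk(
      c("S_e", "S", "X", "Y", "C_e"),
      c("extracellular", "intracellular", "intracellular", "intracellular",
        "extracellular"),
      list(r("EX_S", c(S_e = -1), -8, 0, "exchange"),
           r("T1", c(S_e = -1, S = 1), 0, 100, "transport"),
           r("R1", c(S = -1, X = 1, Y = 1), 0, 100),
           r("R2", c(Y = -1, C_e = 1), 0, 5, "transport"),
           r("EX_C", c(C_e = -1), 0, 100, "exchange"),
           r("BIO", c(X = -1, Y = -1), 0, 100, "biomass"))),
    # reversible shuttle with two substrates
    shuttle = mk(
      c("A_e", "B_e", "A", "B", "P"),
      c("extracellular", "extracellular", "intracellular", "intracellular",
        "intracellular"),
      list(r("EX_A", c(A_e = -1), -5, 0, "exchange"),
           r("EX_B", c(B_e = -1), -3, 0, "exchange"),
           r("TA", c(A_e = -1, A = 1), 0, 100, "transport"),
           r("TB", c(B_e = -1, B = 1), 0, 100, "transport"),
           r("ISO", c(A = -1, B = 1), -100, 100),
           r("R1", c(B = -1, P = 1), 0, 100),
           r("BIO", c(P = -1), 0, 100, "biomass"))),
    stop("unknown variant"))
}

rand_toy_config <- function(seed) {
  set.seed(seed)
  toy_network_config(
    seed = seed,
    include_malolactic = runif(1) < 0.7,
    include_citrate = runif(1) < 0.7,
    n_essential_amino_acids = sample(1:3, 1),
    n_synthesizable_amino_acids = 1L,
    protons_per_atp = sample(2:4, 1),
    mannitol_branch = runif(1) < 0.8,
    erythritol_branch = runif(1) < 0.8,
    oxygen_branch = TRUE,
    planted_orphan_metabolites = sample(0:3, 1))
}

# one shared default toy per test run (ground truth included)
TOY <- make_toy_lab_model()
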