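test_that("FVA brackets every flux and collapses when rates are fixed", {
  m <- chain_model()
  rng <- fva(m)
  expect_equal(rng$min_flux[rng$reaction_id == "R1"], 0)
  expect_equal(rng$max_flux[rng$reaction_id == "R1"], 10)

  fixed <- fix_flux(m, "EX_A", -10)
  rng <- fva(fixed)
  expect_equal(rng$span, rep(0, 3), tolerance = 1e-9)
  expect_equal(rng$min_flux[rng$reaction_id == "BIO"], 10, tolerance = 1e-9)
})

test_that("FVA is order-independent and matches a brute-force scan", {
  m <- toy_variant("shuttle")
  rng <- fva(m)
  set.seed(99)
  shuffled <- fva(m, reactions = sample(m$reactions$id))
  shuffled <- shuffled[match(rng$reaction_id, shuffled$reaction_id), ]
  expect_equal(shuffled$min_flux, rng$min_flux, tolerance = 1e-9)
  expect_equal(shuffled$max_flux, rng$max_flux, tolerance = 1e-9)
  # independent per-reaction vertex enumeration
  S <- as.matrix(build_stoichiometric_matrix(m))
  for (k in seq_along(rng$reaction_id)) {
    obj <- as.numeric(colnames(S) == rng$reaction_id[k])
    lo <- vertex_enumerate_lp(S, rep(0, nrow(S)), obj,
                              m$reactions$lower_bound,
                              m$reactions$upper_bound, "min")
    hi <- vertex_enumerate_lp(S, rep(0, nrow(S)), obj,
                              m$reactions$lower_bound,
                              m$reactions$upper_bound, "max")
    expect_equal(rng$min_flux[k], lo$objective, tolerance = 1e-7)
    expect_equal(rng$max_flux[k], hi$objective, tolerance = 1e-7)
  }
})

test_that("the FBA optimum lies inside the optimum-constrained FVA ranges", {
  m <- TOY$model
  s <- solve_fba(m)
  rng <- fva(m, fraction_of_optimum = 1)
  for (k in seq_len(nrow(rng))) {
    v <- s$fluxes[rng$reaction_id[k]]
    expect_gte(v, rng$min_flux[k] - 1e-6)
    expect_lte(v, rng$max_flux[k] + 1e-6)
  }
})

test_that("blocked reactions are exactly those unable to carry flux", {
  # dangling product: nothing consumes B downstream of R1
  m <- chain_model()
  m2 <- remove_reaction(m, "BIO")
  m2$objective_id <- NA_character_
  expect_setequal(find_blocked(m2), c("EX_A", "R1"))
  # complete chain: nothing blocked
  expect_length(find_blocked(m), 0)
  # toy: blocked set is invariant to bound scaling
  blk <- find_blocked(TOY$model)
  expect_true(all(c("ORPHS1", "ORPHS2", "EX_glyc_e") %in% blk))
  scaled <- TOY$model
  scaled$reactions$lower_bound <- 2.5 * scaled$reactions$lower_bound
  scaled$reactions$upper_bound <- 2.5 * scaled$reactions$upper_bound
  expect_setequal(find_blocked(scaled, open = FALSE),
                  find_blocked(TOY$model, open = FALSE))
})

test_that("structural dead ends follow the reversibility expansion", {
  # -> A with no consumer: dead
  m1 <- metabolic_model(
    data.frame(id = "A", name = "A", compartment = "intracellular"),
    data.frame(id = "R", name = "R", lower_bound = 0, upper_bound = 10,
               gpr = "", subsystem = "", kind = "sink"),
    list(R = c(A = 1)))
  S <- build_stoichiometric_matrix(m1)
  expect_equal(find_dead_ends_structural(S, FALSE), "A")
  # reversible A<->B plus B->C: B not a dead end
  m2 <- metabolic_model(
    data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
               compartment = "intracellular"),
    data.frame(id = c("R1", "R2"), name = c("R1", "R2"),
               lower_bound = c(-10, 0), upper_bound = c(10, 10),
               gpr = "", subsystem = "", kind = "intracellular"),
    list(R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1)))
  S <- build_stoichiometric_matrix(m2)
  dead <- find_dead_ends_structural(S, c(TRUE, FALSE))
  # the reversible reaction makes both A and B producible and consumable;
  # C is only ever produced
  expect_setequal(dead, "C")
})

test_that("planted orphans are exactly the toy's dead ends", {
  cfg <- toy_network_config(planted_orphan_metabolites = 3)
  toy <- make_toy_lab_model(cfg, ground_truth = FALSE)
  open <- open_exchanges(toy$model)
  S <- build_stoichiometric_matrix(open)
  dead <- find_dead_ends_structural(S, open$reactions$lower_bound < 0)
  expect_setequal(dead, toy$ground_truth$orphan_metabolites)
  expect_length(dead, 3)
  expect_setequal(find_dead_ends_functional(toy$model), dead)
})

test_that("a metabolite in an unreachable cycle is functionally dead only", {
  m <- metabolic_model(
    data.frame(id = c("A", "B"), name = c("A", "B"),
               compartment = "intracellular"),
    data.frame(id = c("R1", "R2"), name = c("R1", "R2"),
               lower_bound = 0, upper_bound = 10,
               gpr = "", subsystem = "", kind = "intracellular"),
    list(R1 = c(A = -1, B = 1), R2 = c(B = -1, A = 1)))
  S <- build_stoichiometric_matrix(m)
  expect_length(find_dead_ends_structural(S, c(FALSE, FALSE)), 0)
  expect_setequal(find_dead_ends_functional(m), c("A", "B"))
})

test_that("chain metabolites are alive and dead ends imply blocked", {
  expect_length(find_dead_ends_functional(chain_model()), 0)
  rep <- blocked_report(TOY$model)
  expect_true(all(rep$blocked_with_dead_end %in% rep$blocked))
  # every reaction touching a functional dead end is blocked
  for (rid in TOY$model$reactions$id) {
    touches <- any(names(TOY$model$stoichiometry[[rid]]) %in%
                     rep$dead_end_metabolites)
    if (touches) expect_true(rid %in% rep$blocked, label = rid)
  }
})

test_that("span histogram bins at integer log10 boundaries", {
  rng <- data.frame(reaction_id = c("a", "b", "c"),
                    min_flux = 0, max_flux = c(10, 10, 10),
                    span = c(10, 10, 10))
  h <- span_histogram(rng)
  expect_equal(h$bins, data.frame(log10_bin = 1L, count = 3L))
  rng$span <- c(0.1, 1, 10)
  h <- span_histogram(rng)
  expect_equal(h$bins$log10_bin, c(-1L, 0L, 1L))
  expect_equal(h$bins$count, c(1L, 1L, 1L))
  rng$span <- c(0, 1e-12, 5)
  h <- span_histogram(rng)
  expect_equal(h$n_zero_span, 2L)
  expect_equal(sum(h$bins$count), 1L)
})

test_that("experimental constraints narrow the flux ranges", {
  m <- TOY$model
  free <- open_exchanges(m)
  free$objective_id <- m$objective_id
  rng_free <- fva(free)
  sr <- make_synthetic_rates(TOY, true_ngam = 2.3)
  con <- oenoflux:::.apply_rates(m, sr$rates)
  con <- fix_flux(con, "ATPM", 2.3)
  rng_con <- fva(con)
  med_free <- stats::median(rng_free$span)
  med_con <- stats::median(rng_con$span)
  expect_lt(med_con, med_free)
})
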